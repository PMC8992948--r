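#' Paired t-test on DVH indices
#'
#' Classical paired t on the differences `a - b`, two-sided p from the t
#' distribution with n - 1 degrees of freedom. A zero-variance difference
#' vector is degenerate: p is reported as 1 (no difference at all) or 0
#' (identical nonzero shift) with a warning.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `mean_diff`, `n`.
#' @export
paired_t_test <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  d <- values_a - values_b
  if (stats::sd(d) <= 1e-10 * max(1, abs(mean(d)))) {
    warning("zero variance of paired differences; p degenerate")
    p <- if (all(d == 0)) 1 else 0
    return(list(t = if (all(d == 0)) 0 else sign(mean(d)) * Inf, p = p,
                mean_diff = mean(d), n = length(d)))
  }
  ht <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean_diff = unname(ht$estimate), n = length(d))
}

#' McNemar's test on paired goal-achievement flags
#'
#' Counts discordant pairs `b` (A passes, B fails) and `c` (A fails, B
#' passes). For `b + c < 25` the exact two-sided binomial p-value is used;
#' otherwise the chi-square statistic `(b - c)^2 / (b + c)` on 1 df
#' (without continuity correction).
#'
#' @param pass_a,pass_b paired logical vectors.
#' @return list with `statistic` (chi-square, NA for the exact branch),
#'   `p`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(pass_a, pass_b) {
  stopifnot(length(pass_a) == length(pass_b))
  pass_a <- as.logical(pass_a); pass_b <- as.logical(pass_b)
  b <- sum(pass_a & !pass_b)
  cc <- sum(!pass_a & pass_b)
  n <- b + cc
  if (n == 0) {
    return(list(statistic = NA_real_, p = 1, b = b, c = cc,
                method = "degenerate (no discordant pairs)"))
  }
  if (n < 25) {
    p <- stats::binom.test(b, n, 0.5)$p.value
    list(statistic = NA_real_, p = p, b = b, c = cc,
         method = "exact binomial")
  } else {
    stat <- (b - cc)^2 / n
    list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
         b = b, c = cc, method = "chi-square")
  }
}
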