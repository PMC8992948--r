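#' Planning goals and clinical goals
#'
#' Planning dose objectives of the original-plan protocol: target CTV
#' D99 above 100 % and Dmax below 110 % of the 63 Gy(RBE) / 21 fraction
#' prescription, with rectum V50 < 20 %, rectum V30 < 50 % and bladder
#' V30 < 30 % as organ-at-risk constraints, target priority above OAR.
#' Clinical (evaluation) goals put the three D99 indices at 95 % of the
#' prescription — 59.85 Gy(RBE) — with rectum Dmax < 66 Gy(RBE) and
#' bladder V63 < 10 ml as additional thresholds.
#'
#' @param prescription_gy prescribed course dose, Gy(RBE).
#' @param n_fractions number of fractions.
#' @return object of class `planning_goals`. Fields `ctv_d99_min` and
#'   `ctv_dmax_max` are derived (100 % / 110 % of prescription), clinical
#'   D99 goals are 95 % of prescription.
#' @export
planning_goals <- function(prescription_gy = 63, n_fractions = 21) {
  structure(list(
    prescription_gy = prescription_gy,
    n_fractions = n_fractions,
    ctv_d99_min = prescription_gy,
    ctv_dmax_max = 1.10 * prescription_gy,
    oar = list(
      list(structure = "rectum", threshold = 50, limit_pct = 20),
      list(structure = "rectum", threshold = 30, limit_pct = 50),
      list(structure = "bladder", threshold = 30, limit_pct = 30)),
    clinical = list(
      d99_min = 0.95 * prescription_gy,
      rectum_dmax_max = 66,
      rectum_v30_max = 50, rectum_v50_max = 20,
      bladder_v30_max = 30, bladder_v63ml_max = 10)),
    class = "planning_goals")
}

#' Robust-optimization uncertainty setting
#'
#' @param setup_mm set-up uncertainty magnitude (mm), realized as
#'   isocenter shifts along the six cardinal directions.
#' @param range_pct range (stopping-power) uncertainty in percent.
#' @export
robust_setting <- function(setup_mm = 3, range_pct = 3.5) {
  stopifnot(setup_mm >= 0, range_pct >= 0)
  structure(list(setup_mm = setup_mm, range_pct = range_pct),
            class = "robust_setting")
}

#' Enumerate the robustness scenarios
#'
#' Nominal plus six axis-aligned isocenter shifts of `setup_mm` (right,
#' left, anterior, posterior, head, foot) plus two uniform range scales
#' `1 +/- range_pct/100`. Shift and range errors are not combined, giving
#' nine scenarios at the defaults; zero magnitudes drop the corresponding
#' scenarios.
#'
#' @param setting a [robust_setting()].
#' @return list of [scenario()]s, the nominal one first.
#' @export
build_scenarios <- function(setting = robust_setting()) {
  out <- list(scenario())
  if (setting$setup_mm > 0) {
    for (ax in 1:3) for (sgn in c(1, -1)) {
      sh <- c(0, 0, 0); sh[ax] <- sgn * setting$setup_mm
      out[[length(out) + 1L]] <- scenario(shift_mm = sh)
    }
  }
  if (setting$range_pct > 0) {
    out[[length(out) + 1L]] <- scenario(range_scale = 1 + setting$range_pct / 100)
    out[[length(out) + 1L]] <- scenario(range_scale = 1 - setting$range_pct / 100)
  }
  out
}

#' Voxel-wise worst-case composition of scenario doses
#'
#' Under-dose worst case (voxel-wise minimum over scenarios) for the
#' target and over-dose worst case (voxel-wise maximum) for everything
#' else, after Pflugfelder-style worst-case optimization.
#'
#' @param per_scenario_doses non-empty list of co-registered
#'   `dose_grid`s (or plain numeric arrays/vectors of identical shape).
#' @param structures optional structure-set list (with `$ctv`); only
#'   recorded in the output for downstream bookkeeping.
#' @return list with `worst_target_dose` (min) and `worst_oar_dose`
#'   (max), same class as the inputs.
#' @export
worst_case_dose <- function(per_scenario_doses, structures = NULL) {
  if (length(per_scenario_doses) == 0L) stop("empty scenario dose list")
  vals <- lapply(per_scenario_doses, function(d)
    if (inherits(d, "voxel_grid")) as.numeric(d$values) else as.numeric(d))
  n <- unique(lengths(vals))
  if (length(n) != 1L) stop("scenario doses are not co-registered")
  vmin <- do.call(pmin, vals)
  vmax <- do.call(pmax, vals)
  tmpl <- per_scenario_doses[[1]]
  wrap <- function(v) {
    if (inherits(tmpl, "voxel_grid")) {
      out <- tmpl; out$values <- array(v, tmpl$shape); out
    } else if (is.array(tmpl)) array(v, dim(tmpl)) else v
  }
  list(worst_target_dose = wrap(vmin), worst_oar_dose = wrap(vmax))
}

# deterministic subsample of mask voxel indices
sample_mask_voxels <- function(mask, cap, seed) {
  idx <- which(mask)
  if (length(idx) <= cap) return(idx)
  rng <- local_rng(seed); on.exit(rng$restore())
  sort(sample(idx, cap))
}

#' Fit a robustly optimized spot plan to an anatomy
#'
#' The central planning routine: places pencil-beam spots over the CTV for
#' two opposed lateral fields and minimizes, over non-negative spot
#' weights, a weighted sum of one-sided quadratic penalties evaluated on
#' the worst-case scenario doses — CTV under-dose below the planning aim
#' and over-dose above the Dmax limit on the voxel-wise worst case over
#' the nine 3 mm / 3.5 % scenarios, smooth logistic DVH surrogates for the
#' rectum V50/V30 and bladder V30 constraints, and a hot-spot penalty in
#' normal tissue. Target penalties outweigh OAR penalties, so coverage is
#' prioritized. Optimization is bound-constrained L-BFGS-B in restarted
#' chunks (the recorded objective trace is non-increasing), followed by a
#' clinical-style renormalization of the weights so the nominal CTV D99
#' sits at the planning aim.
#'
#' @param anatomy an `anatomy_instance` with structures.
#' @param goals a [planning_goals()].
#' @param setting a [robust_setting()].
#' @param beam a [beam_model()].
#' @param control list of optimizer knobs: `caps` (objective voxel caps
#'   per structure class), `chunks`, `maxit_per_chunk`, `rel_tol`,
#'   `weights` (penalty weights `under`, `over`, `dvh`, `normal`),
#'   `aim_frac` (planning aim as fraction of prescription),
#'   `renorm_clamp`, `seed`.
#' @return an `impt_plan` with convergence metadata in `$meta`.
#' @export
plan_impt <- function(anatomy, goals = planning_goals(),
                      setting = robust_setting(), beam = beam_model(),
                      control = list()) {
  ctl <- utils::modifyList(list(
    caps = c(ctv = 450, rectum = 320, bladder = 320, normal = 260),
    chunks = 6L, maxit_per_chunk = 30L, rel_tol = 1e-5,
    weights = c(under = 100, under_tail = 60, over = 150, dvh = 40,
                normal = 4, alap = 6),
    tail_frac = 0.05,
    aim_frac = 63.5 / 63, dmax_aim_frac = 66.5 / 63, alap_threshold = 45,
    renorm_clamp = c(0.85, 1.15), seed = 1203L), control)
  stopifnot(inherits(anatomy, "anatomy_instance"),
            !is.null(anatomy$structures))
  s <- anatomy$structures
  if (!any(s$ctv)) stop("planning error: CTV is empty")
  ctx <- dose_context(anatomy)
  ctx$beam <- beam
  # online-adaptive re-optimization can reuse an existing spot lattice
  # (and warm-start from its weights) instead of re-placing spots
  spots <- ctl$spots %||% place_spots(ctx, beam)
  if (nrow(spots) == 0L)
    stop("planning error: no deliverable spots reach the CTV")
  rx <- goals$prescription_gy
  aim <- ctl$aim_frac * rx
  dmax_aim <- ctl$dmax_aim_frac * rx

  # objective voxels: full (capped) CTV, OAR samples, normal-tissue shell
  ctv_idx <- sample_mask_voxels(s$ctv, ctl$caps[["ctv"]], ctl$seed)
  rec_idx <- sample_mask_voxels(s$rectum, ctl$caps[["rectum"]],
                                ctl$seed + 1L)
  bla_idx <- sample_mask_voxels(s$bladder, ctl$caps[["bladder"]],
                                ctl$seed + 2L)
  shell <- normal_shell_mask(anatomy)
  nor_idx <- sample_mask_voxels(shell, ctl$caps[["normal"]], ctl$seed + 3L)
  all_idx <- c(ctv_idx, rec_idx, bla_idx, nor_idx)
  grp <- rep(c("ctv", "rectum", "bladder", "normal"),
             c(length(ctv_idx), length(rec_idx), length(bla_idx),
               length(nor_idx)))
  pts <- grid_coords(anatomy$grid)[all_idx, , drop = FALSE]
  # coverage must hold on the target continuum, not only at the voxel
  # centres a coarse grid happens to sample (thin seminal-vesicle
  # sections can fall between them): add points drawn uniformly inside
  # the analytic target shapes
  apts <- sample_analytic_ctv_points(anatomy, ctl$n_analytic %||% 240,
                                     ctl$seed + 7L)
  pts <- rbind(pts, apts)
  grp <- c(grp, rep("ctv", nrow(apts)))

  scens <- build_scenarios(setting)
  infl <- lapply(scens, function(sc) dose_influence(ctx, spots, pts, sc))

  i_ctv <- which(grp == "ctv"); i_rec <- which(grp == "rectum")
  i_bla <- which(grp == "bladder"); i_nor <- which(grp == "normal")
  dvh_terms <- list(
    list(idx = i_rec, thr = 50, limit = 0.20),
    list(idx = i_rec, thr = 30, limit = 0.50),
    list(idx = i_bla, thr = 30, limit = 0.30))
  beta <- 1.5  # Gy, logistic width of the DVH volume surrogate
  wts <- ctl$weights
  rx2 <- rx^2

  objective <- function(w, want_grad = FALSE) {
    d <- vapply(infl, function(M) as.numeric(M %*% w),
                numeric(nrow(pts)))
    smin <- max.col(-d, ties.method = "first")
    smax <- max.col(d, ties.method = "first")
    dmin <- d[cbind(seq_along(smin), smin)]
    dmax <- d[cbind(seq_along(smax), smax)]
    g <- matrix(0, nrow(pts), length(scens))  # dF/d(dose)
    # CTV under-dose on the worst-case minimum: a mean term plus a
    # coldest-tail term so isolated cold spots (thin SV sections) are
    # not diluted away by the averaging
    under <- pmax(0, aim - dmin[i_ctv])
    f_under <- wts[["under"]] * mean(under^2) / rx2
    k_tail <- max(1L, ceiling(ctl$tail_frac * length(i_ctv)))
    i_tail <- order(under, decreasing = TRUE)[seq_len(k_tail)]
    f_under <- f_under +
      wts[["under_tail"]] * mean(under[i_tail]^2) / rx2
    # CTV over-dose on the worst-case maximum
    over <- pmax(0, dmax[i_ctv] - dmax_aim)
    f_over <- wts[["over"]] * mean(over^2) / rx2
    # smooth DVH-volume surrogates on the worst-case maximum
    f_dvh <- 0
    dvh_pen <- numeric(length(dvh_terms))
    for (ti in seq_along(dvh_terms)) {
      tm <- dvh_terms[[ti]]
      if (length(tm$idx) == 0L) next
      sg <- 1 / (1 + exp(-(dmax[tm$idx] - tm$thr) / beta))
      excess <- max(0, mean(sg) - tm$limit)
      dvh_pen[ti] <- excess
      f_dvh <- f_dvh + wts[["dvh"]] * excess^2
      if (want_grad && excess > 0) {
        dd <- wts[["dvh"]] * 2 * excess * sg * (1 - sg) /
          (beta * length(tm$idx))
        rows <- cbind(tm$idx, smax[tm$idx])
        g[rows] <- g[rows] + dd
      }
    }
    # normal-tissue hot spots on the worst-case maximum
    hot <- pmax(0, dmax[i_nor] - rx)
    f_nor <- wts[["normal"]] * mean(hot^2) / rx2
    # rectum high dose as low as possible (protocol note on V50)
    alap <- if (length(i_rec))
      pmax(0, dmax[i_rec] - ctl$alap_threshold) else numeric(0)
    f_alap <- if (length(i_rec))
      wts[["alap"]] * mean(alap^2) / rx2 else 0
    f <- f_under + f_over + f_dvh + f_nor + f_alap
    if (!want_grad)
      return(structure(f, parts = c(under = f_under, over = f_over,
                                    dvh = f_dvh, normal = f_nor,
                                    alap = f_alap),
                       dvh_excess = dvh_pen))
    if (length(i_ctv)) {
      rows <- cbind(i_ctv, smin[i_ctv])
      g[rows] <- g[rows] - wts[["under"]] * 2 * under / (length(i_ctv) * rx2)
      hot_tail <- i_tail[under[i_tail] > 0]
      if (length(hot_tail)) {
        rows <- cbind(i_ctv[hot_tail], smin[i_ctv[hot_tail]])
        g[rows] <- g[rows] - wts[["under_tail"]] * 2 *
          under[hot_tail] / (k_tail * rx2)
      }
      rows <- cbind(i_ctv, smax[i_ctv])
      g[rows] <- g[rows] + wts[["over"]] * 2 * over / (length(i_ctv) * rx2)
    }
    if (length(i_nor)) {
      rows <- cbind(i_nor, smax[i_nor])
      g[rows] <- g[rows] + wts[["normal"]] * 2 * hot / (length(i_nor) * rx2)
    }
    if (length(i_rec)) {
      rows <- cbind(i_rec, smax[i_rec])
      g[rows] <- g[rows] + wts[["alap"]] * 2 * alap / (length(i_rec) * rx2)
    }
    grad <- numeric(length(w))
    for (si in seq_along(infl)) {
      gs <- g[, si]
      nz <- gs != 0
      if (any(nz))
        grad <- grad + as.numeric(crossprod(infl[[si]][nz, , drop = FALSE],
                                            gs[nz]))
    }
    list(value = f, grad = grad)
  }

  # start from supplied weights (warm start) or a uniform fluence,
  # scaled so the nominal mean CTV dose equals the prescription
  w <- ctl$w_init %||% rep(1, nrow(spots))
  mean_ctv <- mean(infl[[1]][i_ctv, , drop = FALSE] %*% w)
  w <- w * rx / mean_ctv
  trace <- as.numeric(objective(w))
  for (ch in seq_len(ctl$chunks)) {
    fit <- stats::optim(w, fn = function(w) as.numeric(objective(w)),
                        gr = function(w) objective(w, TRUE)$grad,
                        method = "L-BFGS-B", lower = 0,
                        control = list(maxit = ctl$maxit_per_chunk))
    w <- fit$par
    trace <- c(trace, fit$value)
    k <- length(trace)
    if (abs(trace[k - 1] - trace[k]) <=
        ctl$rel_tol * max(trace[k - 1], 1e-12)) break
  }

  plan <- spot_plan(cbind(spots[setdiff(names(spots), "weight")],
                          weight = w),
                    beam, prescription_gy = rx,
                    n_fractions = goals$n_fractions)
  # clinical-style renormalization: nominal CTV D99 to the planning aim
  d99 <- dvh_index_D(compute_dvh(
    compute_dose(plan, ctx, points = grid_coords(anatomy$grid,
                                                 s$ctv))), 99)
  f <- min(max(aim / d99, ctl$renorm_clamp[1]), ctl$renorm_clamp[2])
  plan$spots$weight <- plan$spots$weight * f
  final <- objective(plan$spots$weight)
  plan$meta <- list(objective_trace = trace, renorm_factor = f,
                    nominal_ctv_d99_prenorm = d99,
                    n_scenarios = length(scens),
                    scenarios = lapply(scens, unclass),
                    penalty_parts = attr(final, "parts"),
                    dvh_excess = attr(final, "dvh_excess"),
                    robust_setting = unclass(setting),
                    goals_prescription = rx)
  plan
}

# uniform samples inside the analytic daily target (prostate + SV),
# allocated per shape proportionally to volume; rejection sampling in
# each shape's bounding box under a local deterministic stream
sample_analytic_ctv_points <- function(anatomy, n, seed) {
  keys <- c("prostate", "sv_left", "sv_right")
  vols <- vapply(keys, function(k) {
    st <- anatomy$states[[if (grepl("^sv", k)) "sv" else k]]
    shape_volume(anatomy$config$shapes[[k]]) * st$vol_scale
  }, numeric(1))
  alloc <- pmax(1L, round(n * vols / sum(vols)))
  rng <- local_rng(seed); on.exit(rng$restore())
  out <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    st <- anatomy$states[[if (grepl("^sv", k)) "sv" else k]]
    bb <- shape_bbox(anatomy$config$shapes[[k]], st, anatomy$setup,
                     margin = 0)
    got <- matrix(numeric(0), 0, 3)
    for (round in 1:40) {
      if (nrow(got) >= alloc[i]) break
      cand <- cbind(stats::runif(4 * alloc[i], bb$lo[1], bb$hi[1]),
                    stats::runif(4 * alloc[i], bb$lo[2], bb$hi[2]),
                    stats::runif(4 * alloc[i], bb$lo[3], bb$hi[3]))
      keep <- organ_inside_daily(anatomy, k, cand)
      got <- rbind(got, cand[keep, , drop = FALSE])
    }
    out[[i]] <- got[seq_len(min(nrow(got), alloc[i])), , drop = FALSE]
  }
  do.call(rbind, out)
}

# soft-tissue shell around the target where hot spots are penalized
normal_shell_mask <- function(anatomy, margin = 35) {
  s <- anatomy$structures
  pts_ctv <- grid_coords(anatomy$grid, s$ctv)
  lo <- apply(pts_ctv, 2, min) - margin
  hi <- apply(pts_ctv, 2, max) + margin
  pts <- grid_coords(anatomy$grid)
  inbox <- array(pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
                 pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
                 pts[, 3] >= lo[3] & pts[, 3] <= hi[3],
                 anatomy$grid$shape)
  inbox & s$body & !s$ctv & !s$rectum & !s$bladder
}

#' @export
print.impt_plan <- function(x, ...) {
  cat("<impt_plan> ", nrow(x$spots), " spots, 2 opposed lateral fields\n",
      "  prescription ", x$prescription_gy, " Gy(RBE) in ",
      x$n_fractions, " fractions (RBE ", x$rbe, ")\n", sep = "")
  if (!is.null(x$meta$objective_trace))
    cat("  objective ", signif(utils::tail(x$meta$objective_trace, 1), 4),
        " after ", length(x$meta$objective_trace) - 1, " chunks; renorm x",
        round(x$meta$renorm_factor, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.impt_plan <- function(object, ...) object$spots$weight

#' Predict the dose of a fitted plan on an anatomy
#'
#' @param object an `impt_plan`.
#' @param anatomy target `anatomy_instance` (the planning anatomy or a
#'   daily instance).
#' @param sc a [scenario()].
#' @param ... passed to [compute_dose()].
#' @export
predict.impt_plan <- function(object, anatomy, sc = scenario(), ...) {
  compute_dose(object, anatomy, sc = sc, ...)
}
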