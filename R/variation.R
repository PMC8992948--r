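#' Daily anatomical variation parameters
#'
#' Per-organ percent volume-difference distributions, seminal-vesicle
#' displacement coupling, residual prostate motion and rigid set-up error.
#' Defaults are the cohort statistics the generator is calibrated to:
#' prostate -2.13 +/- 12.88 %, SV 12.18 +/- 28.88 %, rectum 14.54 +/-
#' 24.54 %, bladder 34.10 +/- 46.22 % (mean +/- SD of daily-vs-planning
#' volume difference), with the fraction of days on which rectum/bladder
#' are larger than at planning calibrated to 71 % / 82 %.
#'
#' Percent differences are drawn from a shifted lognormal
#' `X = c + exp(N(mu, sigma^2))` matched to the configured mean and SD by
#' moment matching; the shift `c = mean - k * SD` with `k` solved so
#' `P(X > 0)` hits `p_increase` where one is configured (rectum, bladder),
#' and `k = 2` (mild right skew) otherwise. Draws are truncated below at
#' -80 % to stay physical.
#'
#' @param organ_mean,organ_sd named numeric (%), organs
#'   prostate/sv/rectum/bladder.
#' @param p_increase named numeric, target `P(volume increases)`; `NA`
#'   leaves the skew at its default.
#' @param sv_coupling_rectum,sv_coupling_bladder anterior-posterior SV
#'   centroid shift per percent rectum/bladder volume change (mm/%,
#'   LPS: +y posterior). Rectal filling pushes the SV anteriorly
#'   (negative), bladder filling pushes it posteriorly (positive). The
#'   rectal default (-0.15) matches the advance of the anteriorly
#'   distending rectal wall (about `radius x dV% / 100`) so the abutting
#'   SV rides on the wall; the bladder default (+0.02) matches the small
#'   posterior displacement of the neck-anchored bladder surface.
#' @param setup_trans_sd,setup_rot_sd per-axis set-up error SD (mm, deg),
#'   zero-mean Gaussian truncated at `setup_trunc` SD.
#' @param prostate_shift_sd per-axis SD (mm) of residual prostate motion
#'   relative to bone (carried by the SV as well).
#' @param rho within-patient correlation of daily draws on the latent
#'   Gaussian (copula) scale; 0 treats fractions as exchangeable.
#' @param sampling `"stratified"` balances each patient's daily quantiles
#'   over the unit interval (randomly permuted across fractions);
#'   `"iid"` draws independently.
#' @param n_fractions fractions per patient (stratification granularity).
#' @param truncate_pct lower truncation of percent volume change.
#' @return object of class `variation_params` with calibrated
#'   distribution constants in `$dist`.
#' @export
variation_params <- function(
    organ_mean = c(prostate = -2.13, sv = 12.18, rectum = 14.54,
                   bladder = 34.10),
    organ_sd = c(prostate = 12.88, sv = 28.88, rectum = 24.54,
                 bladder = 46.22),
    p_increase = c(prostate = NA, sv = NA, rectum = 0.71, bladder = 0.82),
    sv_coupling_rectum = -0.15, sv_coupling_bladder = 0.02,
    setup_trans_sd = 2, setup_rot_sd = 1, setup_trunc = 3,
    prostate_shift_sd = c(0.3, 1, 1),
    rho = 0, sampling = c("stratified", "iid"),
    n_fractions = 21, truncate_pct = -80) {
  sampling <- match.arg(sampling)
  stopifnot(all(organ_sd >= 0), rho >= 0, rho < 1)
  dist <- lapply(organ_names, function(o) {
    calibrate_shifted_lognormal(organ_mean[[o]], organ_sd[[o]],
                                p_increase[[o]])
  })
  names(dist) <- organ_names
  structure(list(organ_mean = organ_mean, organ_sd = organ_sd,
                 p_increase = p_increase, dist = dist,
                 sv_coupling_rectum = sv_coupling_rectum,
                 sv_coupling_bladder = sv_coupling_bladder,
                 setup_trans_sd = setup_trans_sd,
                 setup_rot_sd = setup_rot_sd, setup_trunc = setup_trunc,
                 prostate_shift_sd = rep(prostate_shift_sd,
                                         length.out = 3),
                 rho = rho, sampling = sampling,
                 n_fractions = n_fractions,
                 truncate_pct = truncate_pct),
            class = "variation_params")
}

#' Calibrate a shifted lognormal to mean, SD and exceedance probability
#'
#' `X = c + exp(N(mu, sigma^2))` with `c = m - k s`; moment matching gives
#' `sigma^2 = log(1 + 1/k^2)` and `mu = log(k s) - sigma^2 / 2`. When
#' `p_increase` is given, `k` is solved so `P(X > 0) = p_increase`.
#'
#' @param m,s target mean and SD.
#' @param p_increase target `P(X > 0)`, or `NA` for the default `k = 2`.
#' @return list with `shift`, `mu`, `sigma`, `k`.
#' @export
calibrate_shifted_lognormal <- function(m, s, p_increase = NA) {
  if (s == 0) return(list(shift = m, mu = -Inf, sigma = 0, k = NA))
  p_of_k <- function(k) {
    sig2 <- log(1 + 1 / k^2)
    mu <- log(k * s) - sig2 / 2
    thr <- k * s - m  # P(X > 0) = P(lognormal > -c)
    if (thr <= 0) return(1)
    1 - stats::pnorm((log(thr) - mu) / sqrt(sig2))
  }
  if (is.na(p_increase)) {
    k <- 2
  } else {
    # p_of_k decreases in k on this bracket (skew decreasing)
    k <- stats::uniroot(function(k) p_of_k(k) - p_increase,
                        lower = 0.55, upper = 1.95, tol = 1e-9)$root
  }
  sig2 <- log(1 + 1 / k^2)
  list(shift = m - k * s, mu = log(k * s) - sig2 / 2,
       sigma = sqrt(sig2), k = k)
}

q_shifted_lognormal <- function(dist, u) {
  if (dist$sigma == 0) return(rep(dist$shift, length(u)))
  dist$shift + exp(dist$mu + dist$sigma * stats::qnorm(u))
}

# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483629
  for (x in c(...)) h <- (h * 48271 + as.numeric(x) + 1) %% 2147483629
  as.integer(h) + 1L
}

rtruncnorm1 <- function(n, sd, trunc) {
  if (sd == 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n, 0, sd), -trunc * sd), trunc * sd)
}

# per-(patient seed, fraction) variation draw
draw_variation <- function(params, fraction_index, seed) {
  nf <- params$n_fractions
  # per-patient stream: stratum permutations and latent patient effect
  rngp <- local_rng(derive_seed(seed, 77003))
  perms <- lapply(organ_names, function(o) sample.int(nf))
  names(perms) <- organ_names
  zp <- stats::rnorm(length(organ_names))
  names(zp) <- organ_names
  rngp$restore()
  # per-fraction stream
  rngf <- local_rng(derive_seed(seed, 104729, fraction_index))
  on.exit(rngf$restore(), add = TRUE)
  percent <- numeric(0)
  for (o in organ_names) {
    if (params$sampling == "stratified" && fraction_index >= 1 &&
        fraction_index <= nf) {
      stratum <- perms[[o]][fraction_index]
      u <- (stratum - stats::runif(1)) / nf
    } else {
      u <- stats::runif(1)
    }
    zf <- stats::qnorm(u)
    z <- sqrt(params$rho) * zp[[o]] + sqrt(1 - params$rho) * zf
    x <- q_shifted_lognormal(params$dist[[o]], stats::pnorm(z))
    percent[o] <- max(x, params$truncate_pct)
  }
  setup <- rigid_transform(
    rotation_deg = rtruncnorm1(3, params$setup_rot_sd, params$setup_trunc),
    translation_mm = rtruncnorm1(3, params$setup_trans_sd,
                                 params$setup_trunc))
  pshift <- vapply(1:3, function(i)
    rtruncnorm1(1, params$prostate_shift_sd[i], params$setup_trunc),
    numeric(1))
  sv_ap <- params$sv_coupling_rectum * percent[["rectum"]] +
           params$sv_coupling_bladder * percent[["bladder"]]
  list(percent = percent, setup = setup, prostate_shift = pshift,
       sv_shift = pshift + c(0, sv_ap, 0), sv_ap = sv_ap,
       seed = seed, fraction_index = fraction_index)
}

#' Sample one daily anatomy from a planning reference
#'
#' Draws per-organ volume changes from the calibrated distributions,
#' displaces the SV anterior-posteriorly in proportion to the rectum and
#' bladder volume changes, applies residual prostate motion and a rigid
#' set-up error, and records the generating deformation parameters
#' (ground-truth correspondence). Deterministic in
#' `(seed, fraction_index, params)`.
#'
#' @param reference planning `anatomy_instance` from
#'   [build_reference_phantom()].
#' @param params a [variation_params()].
#' @param fraction_index fraction number (1-based; used both as the
#'   stratification slot and in the random stream).
#' @param seed integer patient seed.
#' @param voxelize build structure masks and the HU grid (set `FALSE` when
#'   only the analytic state — e.g. organ volumes — is needed).
#' @return a daily `anatomy_instance`.
#' @export
sample_daily_anatomy <- function(reference, params, fraction_index, seed,
                                 voxelize = TRUE) {
  stopifnot(inherits(reference, "anatomy_instance"), reference$is_reference)
  v <- draw_variation(params, fraction_index, seed)
  states <- list(
    prostate = list(vol_scale = 1 + v$percent[["prostate"]] / 100,
                    shift = v$prostate_shift),
    sv = list(vol_scale = 1 + v$percent[["sv"]] / 100, shift = v$sv_shift),
    rectum = list(vol_scale = 1 + v$percent[["rectum"]] / 100,
                  shift = c(0, 0, 0)),
    bladder = list(vol_scale = 1 + v$percent[["bladder"]] / 100,
                   shift = c(0, 0, 0)))
  v$setup$isocenter <- reference$config$isocenter
  anat <- new_anatomy(reference$config, states, v$setup,
                      variation = v, is_reference = FALSE)
  if (voxelize) {
    anat$structures <- voxelize_structures(anat)
    anat$grid <- anatomy_hu_grid(anat)
  }
  anat
}

# ---- ground-truth deformation -------------------------------------------

# Organ-state deformation realized as a composition of small sub-steps.
# Each step carries an affine fraction of every organ's scaling and
# shift, with a smooth compactly supported decay into the surrounding
# soft tissue; small steps keep every layer invertible even for large
# volume changes. Inside an organ the composed map is exactly the
# organ's total affine (priority prostate > SV > rectum > bladder where
# supports overlap), so the analytic daily masks agree with the field.

deform_organ_keys <- c("prostate", "sv_left", "sv_right", "rectum",
                       "bladder")

organ_state_of <- function(anatomy, key) {
  organ <- if (grepl("^sv", key)) "sv" else key
  anatomy$states[[organ]]
}

# number of sub-steps needed so each step's scale stays near identity
deform_n_steps <- function(anatomy, per_step = 0.045) {
  worst <- 0
  for (key in deform_organ_keys) {
    state <- organ_state_of(anatomy, key)
    if (is.null(state)) next
    shape <- anatomy$config$shapes[[key]]
    lin <- shape_linear_scale(shape, state$vol_scale)
    worst <- max(worst, abs(lin - 1))
  }
  max(1L, min(12L, as.integer(ceiling(worst / per_step))))
}

# organ shape and step state after k of n sub-steps
partial_shape <- function(shape, state, k, n) {
  lin <- shape_linear_scale(shape, state$vol_scale)
  l1 <- lin^(1 / n)
  # per-step shift chosen so the composed shift equals the total shift
  s_step <- if (abs(l1 - 1) < 1e-12) state$shift / n else
    state$shift * (l1 - 1) / (lin - 1)
  s_cum <- if (abs(l1 - 1) < 1e-12) state$shift * k / n else
    state$shift * (l1^k - 1) / (lin - 1)
  lk <- l1^k
  out <- shape
  if (shape$type %in% c("ellipsoid", "box")) {
    p <- shape$anchor
    out$center <- p + lk * (shape$center - p) + s_cum
    out$anchor <- p + s_cum
    if (shape$type == "ellipsoid") out$semi <- shape$semi * lk
    else out$half <- shape$half * lk
  } else if (shape$type == "tube") {
    a <- shape$anchor_xy
    out$center_xy <- a + lk * (shape$center_xy - a) + s_cum[1:2]
    out$anchor_xy <- a + s_cum[1:2]
    out$radius <- shape$radius * lk
    out$zlim <- shape$zlim + s_cum[3]
  }
  step_state <- list(vol_scale = if (shape$type == "tube") l1^2 else l1^3,
                     shift = s_step)
  list(shape = out, step_state = step_state)
}

# displacement of one sub-step, evaluated at current positions
step_displacement <- function(anatomy, pts, k, n) {
  u <- matrix(0, nrow(pts), 3)
  claimed <- logical(nrow(pts))
  for (key in deform_organ_keys) {
    state <- organ_state_of(anatomy, key)
    if (is.null(state)) next
    if (state$vol_scale == 1 && all(state$shift == 0)) next
    shape0 <- anatomy$config$shapes[[key]]
    ps <- partial_shape(shape0, state, k - 1, n)
    w <- shape_support_weight(ps$shape, pts)
    idx <- which(w > 0)
    if (length(idx) == 0L) next
    aff <- shape_affine_points(ps$shape, ps$step_state,
                               pts[idx, , drop = FALSE])
    delta <- aff - pts[idx, , drop = FALSE]
    inside_idx <- w[idx] >= 1
    own <- idx[inside_idx & !claimed[idx]]
    blend <- idx[!inside_idx & !claimed[idx]]
    if (length(own))
      u[own, ] <- delta[match(own, idx), , drop = FALSE]
    if (length(blend))
      u[blend, ] <- u[blend, , drop = FALSE] +
        w[blend] * delta[match(blend, idx), , drop = FALSE]
    claimed[idx[inside_idx]] <- TRUE
  }
  u
}

#' Map planning-frame points to their daily-frame positions
#'
#' The generator's forward deformation: local organ displacement followed
#' by the rigid set-up transform.
#'
#' @param anatomy a daily `anatomy_instance`.
#' @param pts n x 3 planning-frame coordinates (mm).
#' @return n x 3 daily-frame coordinates.
#' @export
deform_forward <- function(anatomy, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  n <- deform_n_steps(anatomy)
  x <- pts
  for (k in seq_len(n)) x <- x + step_displacement(anatomy, x, k, n)
  apply_rigid(anatomy$setup, x)
}

#' Map daily-frame points back to the planning frame
#'
#' Inverse of [deform_forward()], obtained by fixed-point iteration on the
#' local displacement.
#'
#' @param anatomy a daily `anatomy_instance`.
#' @param pts n x 3 daily-frame coordinates (mm).
#' @param iter fixed-point iterations.
#' @return n x 3 planning-frame coordinates.
#' @export
deform_inverse <- function(anatomy, pts, iter = 6) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  x <- apply_rigid(invert_rigid(anatomy$setup), pts)
  n <- deform_n_steps(anatomy)
  for (k in rev(seq_len(n))) {
    z <- x
    # per-step fixed point; each sub-step is a mild contraction
    for (i in seq_len(iter))
      x <- z - step_displacement(anatomy, x, k, n)
  }
  x
}
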