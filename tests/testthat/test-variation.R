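test_that("shifted-lognormal calibration reproduces the moments and the
           exceedance probabilities", {
  p <- variation_params()
  set.seed(31)
  u <- runif(2e5)
  for (o in c("prostate", "sv", "rectum", "bladder")) {
    x <- adaptrt:::q_shifted_lognormal(p$dist[[o]], u)
    expect_equal(mean(x), p$organ_mean[[o]], tolerance = 0.02 *
                   max(1, abs(p$organ_mean[[o]])) + 0.3)
    expect_equal(sd(x), p$organ_sd[[o]], tolerance = 0.02)
    if (!is.na(p$p_increase[[o]]))
      expect_equal(mean(x > 0), p$p_increase[[o]], tolerance = 0.01)
  }
  # a plain normal would miss the bladder exceedance (about 0.77 vs 0.82)
  expect_gt(mean(adaptrt:::q_shifted_lognormal(p$dist$bladder, u) > 0),
            pnorm(34.10 / 46.22) + 0.03)
})

test_that("zero variation reproduces the reference bitwise across all
           fractions", {
  ref <- coarse_reference()
  p0 <- zero_variation_params()
  for (f in c(1, 11, 21)) {
    d <- sample_daily_anatomy(ref, p0, f, seed = 123)
    expect_identical(d$structures, ref$structures)
    expect_identical(d$grid$values, ref$grid$values)
  }
})

test_that("sampling is deterministic in (seed, fraction) and differs
           across fractions", {
  ref <- coarse_reference()
  p <- variation_params()
  a <- sample_daily_anatomy(ref, p, 4, seed = 99, voxelize = FALSE)
  b <- sample_daily_anatomy(ref, p, 4, seed = 99, voxelize = FALSE)
  cc <- sample_daily_anatomy(ref, p, 5, seed = 99, voxelize = FALSE)
  expect_identical(a$variation, b$variation)
  expect_false(identical(a$variation$percent, cc$variation$percent))
})

test_that("cohort draws recover the configured means and SDs within
           three standard errors (483 draws)", {
  ref <- coarse_reference()
  p <- variation_params()
  draws <- matrix(0, 483, 4,
                  dimnames = list(NULL, c("prostate", "sv", "rectum",
                                          "bladder")))
  k <- 0
  ref_vol <- organ_volumes(ref)
  for (pat in 1:23) for (f in 1:21) {
    k <- k + 1
    d <- sample_daily_anatomy(ref, p, f, seed = 5000 + pat,
                              voxelize = FALSE)
    draws[k, ] <- 100 * (organ_volumes(d) / ref_vol - 1)
  }
  for (o in colnames(draws)) {
    se <- sd(draws[, o]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, o]) - p$organ_mean[[o]]), 3 * se + 1e-9)
    # SD recovery: generous MC band
    expect_equal(sd(draws[, o]), p$organ_sd[[o]],
                 tolerance = 0.15)
  }
  # directions of the exceedance fractions
  expect_equal(mean(draws[, "rectum"] > 0), 0.71, tolerance = 0.08)
  expect_equal(mean(draws[, "bladder"] > 0), 0.82, tolerance = 0.08)
})

test_that("SV displacement couples to rectum and bladder filling with
           the documented signs", {
  ref <- coarse_reference()
  p <- variation_params()
  vars <- lapply(1:80, function(i)
    sample_daily_anatomy(ref, p, (i - 1) %% 21 + 1, seed = 300 + i,
                         voxelize = FALSE)$variation)
  rect <- vapply(vars, function(v) v$percent[["rectum"]], numeric(1))
  blad <- vapply(vars, function(v) v$percent[["bladder"]], numeric(1))
  sv_ap <- vapply(vars, function(v) v$sv_ap, numeric(1))
  fit <- lm(sv_ap ~ rect + blad)
  expect_lt(coef(fit)[["rect"]], 0)   # rectal filling pushes SV anterior
  expect_gt(coef(fit)[["blad"]], 0)   # bladder filling pushes SV posterior
})

test_that("the recorded deformation composed with its inverse is the
           identity within half a voxel over the body", {
  ref <- coarse_reference()
  p <- variation_params()
  pts <- grid_coords(ref$grid, ref$structures$body)
  set.seed(2)
  pts <- pts[sample(nrow(pts), 2500), ]
  for (seed in c(77, 78)) {
    d <- sample_daily_anatomy(ref, p, 5, seed, voxelize = FALSE)
    fwd <- deform_forward(d, pts)
    back <- deform_inverse(d, fwd)
    err <- sqrt(rowSums((back - pts)^2))
    expect_lt(max(err), 0.5 * min(ref$grid$spacing))
  }
})

test_that("draws are truncated below at the physical floor", {
  p <- variation_params(
    organ_mean = c(prostate = -70, sv = 0, rectum = 0, bladder = 0),
    organ_sd = c(prostate = 40, sv = 1, rectum = 1, bladder = 1),
    p_increase = c(prostate = NA, sv = NA, rectum = NA, bladder = NA))
  ref <- coarse_reference()
  mins <- vapply(1:40, function(i)
    sample_daily_anatomy(ref, p, (i - 1) %% 21 + 1, seed = i,
                         voxelize = FALSE)$variation$percent[["prostate"]],
    numeric(1))
  expect_gte(min(mins), -80)
})
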