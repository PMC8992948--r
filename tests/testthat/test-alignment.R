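test_that("bone matching recovers a known set-up error to sub-voxel
           precision", {
  ref <- memo("fine_reference",
              build_reference_phantom(patient_config(seed = 4,
                                                     spacing = c(2, 2, 2))))
  applied <- rigid_transform(c(0.5, 0.5, 0.5), c(2, -2, 2))
  daily <- transform_anatomy(ref, applied)
  rec <- rigid_align_bone(daily, ref)
  expect_lt(max(abs(rec$translation_mm + applied$translation_mm)), 0.2)
  expect_lt(max(abs(rec$rotation_deg + applied$rotation_deg)), 0.1)
  # identity for daily = reference
  rec0 <- rigid_align_bone(ref, ref, refine = 0)
  expect_lt(max(abs(rec0$translation_mm)), 1e-6)
  expect_lt(max(abs(rec0$rotation_deg)), 1e-6)
  # alignment idempotence: applying the recovered correction twice
  # changes nothing the second time
  corrected <- transform_anatomy(daily, rec)
  rec2 <- rigid_align_bone(corrected, ref)
  expect_lt(max(abs(rec2$translation_mm)), 0.2)
  expect_lt(max(abs(rec2$rotation_deg)), 0.1)
})

test_that("Monte-Carlo set-up errors are recovered within half a voxel", {
  ref <- build_reference_phantom(patient_config(seed = 21,
                                                spacing = c(5, 5, 5)))
  p <- variation_params()
  residual <- vapply(1:50, function(i) {
    d <- sample_daily_anatomy(ref, p, (i - 1) %% 21 + 1, seed = 700 + i)
    rec <- rigid_align_bone(d, ref)
    res <- compose_rigid(rec, d$setup)
    max(abs(res$translation_mm))
  }, numeric(1))
  expect_lt(max(residual), 0.5 * 5)
  boneless <- ref; boneless$structures$bone[] <- FALSE
  expect_error(rigid_align_bone(boneless, ref), "bone mask")
})

test_that("prostate-centre registration maps the daily centroid onto
           the isocenter", {
  ref <- coarse_reference()
  # identical anatomies need no correction at all
  expect_equal(align_prostate_center(ref, ref), c(0, 0, 0),
               tolerance = 1e-12)
  # constructed +4 mm anterior shift recovered within grid resolution
  shifted <- transform_anatomy(ref, rigid_transform(
    translation_mm = c(0, -4, 0)))
  t1 <- align_prostate_center(shifted, ref)
  expect_equal(t1, c(0, 4, 0), tolerance = 1.2)
  # translation equals the brute-force centroid difference of the two
  # voxel-coordinate lists
  centroid <- function(anat) {
    idx <- which(anat$structures$prostate, arr.ind = TRUE)
    colMeans(sweep(sweep(idx - 1, 2, anat$grid$spacing, "*"),
                   2, anat$grid$origin, "+"))
  }
  expect_equal(as.numeric(t1),
               as.numeric(centroid(ref) - centroid(shifted)),
               tolerance = 1e-9)
  empty <- ref; empty$structures$prostate[] <- FALSE
  expect_error(align_prostate_center(empty, ref), "prostate")
})

test_that("dose mapping through the known deformation matches the
           point-by-point resampling oracle", {
  ref <- coarse_reference()
  crop <- adaptrt:::trial_crop_grid(ref, 6, 12)
  set.seed(3)
  dose <- crop
  dose$values <- array(runif(prod(crop$shape), 0, 3), crop$shape)
  dose <- adaptrt:::as_dose_grid(dose, fractions = 1)
  # identity deformation: output equals input
  d0 <- sample_daily_anatomy(ref, zero_variation_params(), 1, 1)
  out0 <- map_dose_to_reference(dose, d0, crop)
  expect_equal(out0$values, dose$values, tolerance = 1e-12)
  # pure translation by exactly one voxel shifts the grid by one voxel
  tr <- transform_anatomy(d0, rigid_transform(
    translation_mm = c(6, 0, 0)), voxelize = FALSE)
  out1 <- map_dose_to_reference(dose, tr, crop)
  n1 <- crop$shape[1]
  expect_equal(out1$values[1:(n1 - 1), , ], dose$values[2:n1, , ],
               tolerance = 1e-9)
  # smooth synthetic deformation: per-voxel agreement with a direct
  # interpolation oracle
  d <- sample_daily_anatomy(ref, variation_params(), 7, 19,
                            voxelize = FALSE)
  out <- map_dose_to_reference(dose, d, crop)
  pts <- grid_coords(crop)
  oracle <- interp_trilinear(dose, deform_forward(d, pts), outside = 0)
  expect_equal(as.numeric(out$values), oracle, tolerance = 1e-6)
})

test_that("accumulation is the exact fraction sum, permutation-invariant
           and strict about its inputs", {
  g <- grid_from_box(c(0, 0, 0), c(10, 10, 10), 5)
  mk <- function(v) {
    out <- g; out$values <- array(v, g$shape)
    adaptrt:::as_dose_grid(out, fractions = 1)
  }
  uniform <- replicate(21, mk(3), simplify = FALSE)
  acc <- accumulate_dose(uniform, 21)
  expect_true(all(acc$values == 63))
  zeros <- replicate(21, mk(0), simplify = FALSE)
  expect_true(all(accumulate_dose(zeros, 21)$values == 0))
  set.seed(6)
  rand <- replicate(21, mk(runif(prod(g$shape))), simplify = FALSE)
  acc1 <- accumulate_dose(rand, 21)
  oracle <- Reduce(`+`, lapply(rand, function(x) x$values))
  expect_equal(acc1$values, oracle)
  acc2 <- accumulate_dose(rev(rand), 21)
  expect_equal(acc2$values, acc1$values)
  expect_error(accumulate_dose(rand[1:20], 21), "21")
})

test_that("integral dose is conserved by pure-translation mapping", {
  ref <- coarse_reference()
  crop <- adaptrt:::trial_crop_grid(ref, 6, 12)
  # smooth compact dose blob well inside the crop box
  pts <- grid_coords(crop)
  ctr <- (apply(pts, 2, min) + apply(pts, 2, max)) / 2
  r2 <- rowSums(sweep(pts, 2, ctr)^2)
  blob <- crop
  blob$values <- array(exp(-r2 / (2 * 15^2)), crop$shape)
  blob <- adaptrt:::as_dose_grid(blob, 1)
  d0 <- sample_daily_anatomy(ref, zero_variation_params(), 1, 1)
  tr <- transform_anatomy(d0, rigid_transform(
    translation_mm = c(2.3, -1.7, 3.1)), voxelize = FALSE)
  out <- map_dose_to_reference(blob, tr, crop)
  expect_equal(sum(out$values), sum(blob$values), tolerance = 0.005)
})

test_that("scaling a fraction dose to the course multiplies element-wise
           and refuses double scaling", {
  g <- grid_from_box(c(0, 0, 0), c(8, 8, 8), 4)
  g$values <- array(runif(prod(g$shape)), g$shape)
  fd <- adaptrt:::as_dose_grid(g, fractions = 1)
  sc <- scale_fraction_dose(fd, 21)
  expect_equal(sc$values, 21 * fd$values)
  expect_equal(sc$fractions_represented, 21)
  expect_error(scale_fraction_dose(sc, 21), "refusing")
  u3 <- fd; u3$values[] <- 3
  expect_true(all(scale_fraction_dose(u3, 21)$values == 63))
})
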