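test_that("reference phantom structures are disjoint with CTV the exact
           union of prostate and SV", {
  ref <- coarse_reference()
  s <- ref$structures
  pairs <- combn(c("prostate", "sv", "rectum", "bladder"), 2)
  for (k in seq_len(ncol(pairs)))
    expect_equal(sum(s[[pairs[1, k]]] & s[[pairs[2, k]]]), 0)
  expect_equal(sum(s$ctv), sum(s$prostate) + sum(s$sv))
  for (st in c("prostate", "sv", "rectum", "bladder", "bone"))
    expect_true(all(s$body[s[[st]]]))
})

test_that("voxelized prostate volume matches the analytic ellipsoid", {
  cfg <- patient_config(spacing = c(2, 2, 2))
  cfg$shapes$prostate <- adaptrt:::shape_ellipsoid(c(0, 0, 0), c(20, 20, 20))
  ref <- build_reference_phantom(cfg)
  vol_voxel <- sum(ref$structures$prostate) * prod(ref$grid$spacing)
  expect_equal(vol_voxel, 4 / 3 * pi * 8000, tolerance = 0.05)
  # analytic and voxel-count measurements agree
  vols_a <- organ_volumes(ref, "analytic")
  vols_v <- organ_volumes(ref, "voxel", spacing = c(2, 2, 2))
  expect_equal(vols_v[["prostate"]], vols_a[["prostate"]],
               tolerance = 0.05)
})

test_that("overlapping requested geometry raises a geometry error", {
  cfg <- patient_config()
  cfg$shapes$bladder <- adaptrt:::shape_ellipsoid(c(0, 5, 0), c(30, 30, 30))
  expect_error(build_reference_phantom(cfg), "geometry error")
})

test_that("HU map is class-constant and anchored to the configured
           tissue values", {
  ref <- coarse_reference()
  hu <- ref$config$hu
  expect_true(all(ref$grid$values[ref$structures$bone] == hu[["bone"]]))
  expect_true(all(ref$grid$values[ref$structures$bladder] ==
                    hu[["bladder"]]))
  expect_true(all(ref$grid$values[!ref$structures$body] == hu[["air"]]))
})

test_that("HU to stopping power calibration hits the air and water
           anchors and interpolates linearly", {
  expect_equal(hu_to_stopping_power(0), 1.0)
  expect_equal(hu_to_stopping_power(-1000), 0.001)
  # independent linear-interpolation oracle on the calibration table
  tab <- rsp_calibration_table()
  oracle <- function(hu) {
    i <- max(which(tab[, "hu"] <= hu))
    if (tab[i, "hu"] == hu) return(unname(tab[i, "rsp"]))
    unname(tab[i, "rsp"] + (hu - tab[i, "hu"]) /
             (tab[i + 1, "hu"] - tab[i, "hu"]) *
             (tab[i + 1, "rsp"] - tab[i, "rsp"]))
  }
  for (hu in c(800, 850, -320, 125))
    expect_equal(hu_to_stopping_power(hu), oracle(hu),
                 tolerance = 1e-12)
  expect_true(hu_to_stopping_power(700) > 1)
  # monotone over the whole domain
  hu_grid <- seq(-1000, 3000, by = 10)
  expect_true(all(diff(hu_to_stopping_power(hu_grid)) >= 0))
  expect_warning(hu_to_stopping_power(5000), "clamped")
})

test_that("anatomy YAML directory round trip is exact", {
  ref <- build_reference_phantom(patient_config(seed = 3,
                                                spacing = c(8, 8, 8)))
  dir <- withr::local_tempdir()
  write_anatomy(ref, file.path(dir, "ref"), volumes = TRUE)
  r2 <- read_anatomy(file.path(dir, "ref"))
  expect_identical(r2$structures, ref$structures)
  expect_identical(r2$grid$values, ref$grid$values)
  # volumes written alongside agree with the in-memory grids
  hu <- read_nrrd(file.path(dir, "ref", "hu.nrrd"))
  expect_equal(hu$values, ref$grid$values)
  d <- sample_daily_anatomy(ref, variation_params(), 2, 9)
  write_anatomy(d, file.path(dir, "daily"))
  d2 <- read_anatomy(file.path(dir, "daily"))
  expect_identical(d2$structures, d$structures)
  expect_equal(d2$variation$percent, d$variation$percent)
})

test_that("fixture cohorts are deterministic and have the right shape", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_fixture_cohort(2, 3, seed = 7, out_dir = d1, spacing = 10)
  generate_fixture_cohort(2, 3, seed = 7, out_dir = d2, spacing = 10)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  metas <- grep("meta.yaml", f1, value = TRUE)
  expect_identical(unname(tools::md5sum(file.path(d1, metas))),
                   unname(tools::md5sum(file.path(d2, metas))))
  # 2 patients x (1 reference + 3 fractions)
  expect_length(metas, 8)
  # degenerate: references only
  d3 <- withr::local_tempdir()
  generate_fixture_cohort(1, 0, seed = 1, out_dir = d3, spacing = 10)
  expect_length(grep("meta.yaml", list.files(d3, recursive = TRUE)), 1)
})
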