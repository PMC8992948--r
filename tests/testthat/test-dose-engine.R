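make_water_anatomy <- function(spacing = c(4, 4, 4)) {
  memo(paste0("water_anat_", spacing[1]),
       build_reference_phantom(water_box_config(spacing = spacing)))
}

single_spot_plan <- function(field = 0, y = 0, z = 0, range = 160,
                             weight = 1, beam = beam_model()) {
  spot_plan(data.frame(field = field, y = y, z = z, range = range,
                       weight = weight), beam)
}

test_that("dose is linear in spot weights and the RBE factor is applied
           exactly once", {
  wat <- make_water_anatomy()
  pts <- rbind(c(0, 0, 0), c(-20, 4, 8), c(30, -12, 0), c(60, 0, 20))
  p1 <- single_spot_plan(weight = 1)
  p2 <- single_spot_plan(weight = 2)
  d1 <- compute_dose(p1, wat, points = pts)
  d2 <- compute_dose(p2, wat, points = pts)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # two-spot plan equals the sum of its single-spot doses
  pa <- single_spot_plan(y = 10); pb <- single_spot_plan(y = -10)
  pab <- spot_plan(rbind(pa$spots, pb$spots), pa$beam)
  expect_equal(compute_dose(pab, wat, points = pts),
               compute_dose(pa, wat, points = pts) +
                 compute_dose(pb, wat, points = pts),
               tolerance = 1e-12)
  # physical 10 Gy reported as 11 Gy(RBE)
  p_phys <- single_spot_plan(); p_phys$rbe <- 1
  d_phys <- compute_dose(p_phys, wat, points = pts)
  expect_equal(d1, 1.1 * d_phys, tolerance = 1e-12)
})

test_that("a single spot in uniform water equals the Bragg curve times a
           lateral Gaussian, point by point", {
  wat <- make_water_anatomy()
  bm <- beam_model()
  plan <- single_spot_plan(y = 5, z = -3, range = 150, beam = bm)
  set.seed(4)
  pts <- cbind(runif(60, -100, 100), runif(60, -25, 25),
               runif(60, -25, 25))
  got <- compute_dose(plan, wat, points = pts)
  # oracle: depth from the body surface at x = -155 (water, RSP 1)
  ctx <- adaptrt:::dose_context(wat)
  depth <- interp_trilinear(ctx$wepl[[1]], pts, clamp = TRUE)
  sig <- bm$sigma0 + bm$sigma_growth * depth
  oracle <- 1.1 * bragg_depth_dose(150, depth, bm) *
    exp(-((pts[, 2] - 5)^2 + (pts[, 3] + 3)^2) / (2 * sig^2)) /
    (2 * pi * sig^2)
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("opposed-field mirrored plans give mirror-symmetric dose in a
           symmetric water phantom", {
  wat <- make_water_anatomy()
  bm <- beam_model()
  pr <- single_spot_plan(field = 0, y = 6, z = 4, range = 150, beam = bm)
  pl <- single_spot_plan(field = 1, y = 6, z = 4, range = 150, beam = bm)
  set.seed(8)
  pts <- cbind(runif(50, 5, 120), runif(50, -20, 20), runif(50, -20, 20))
  mirrored <- pts; mirrored[, 1] <- -pts[, 1]
  expect_equal(compute_dose(pr, wat, points = mirrored),
               compute_dose(pl, wat, points = pts),
               tolerance = 1e-8)
})

test_that("increasing the scenario range scale moves the distal 80 %
           point deeper, never shallower", {
  wat <- make_water_anatomy()
  plan <- single_spot_plan(range = 150)
  xs <- seq(-140, 140, by = 1)
  pts <- cbind(xs, 0, 0)
  d80 <- function(scale) {
    d <- compute_dose(plan, wat, points = pts,
                      sc = scenario(range_scale = scale))
    max(xs[d >= 0.8 * max(d)])
  }
  depths <- vapply(c(0.965, 1, 1.035), d80, numeric(1))
  expect_true(all(diff(depths) > 0))
})

test_that("an isocenter-shift scenario displaces the dose rigidly", {
  wat <- make_water_anatomy()
  plan <- single_spot_plan(range = 150)
  pts <- cbind(seq(-60, 60, by = 4), 0, 0)
  d0 <- compute_dose(plan, wat, points = pts)
  sh <- compute_dose(plan, wat, points = sweep(pts, 2, c(0, 4, 0), "-"),
                     sc = scenario(shift_mm = c(0, 4, 0)))
  expect_equal(sh, d0, tolerance = 1e-6)
  # empty plan gives zero dose
  p0 <- spot_plan(data.frame(field = integer(0), y = numeric(0),
                             z = numeric(0), range = numeric(0),
                             weight = numeric(0)), beam_model())
  expect_equal(compute_dose(p0, wat, points = pts), rep(0, nrow(pts)))
})

test_that("spot placement covers the CTV envelope within machine limits", {
  ref <- coarse_reference()
  beam <- beam_model(sigma0 = 8, spot_spacing = 12, layer_spacing = 12)
  spots <- place_spots(ref, beam)
  expect_gt(nrow(spots), 50)
  expect_true(all(spots$range >= beam$range_limits[1] &
                    spots$range <= beam$range_limits[2]))
  expect_setequal(unique(spots$field), c(0, 1))
  # every CTV voxel has a spot nearby in the BEV plane
  pts <- grid_coords(ref$grid, ref$structures$ctv)
  for (i in sample(nrow(pts), 25)) {
    dmin <- min(pmax(abs(spots$y - pts[i, 2]), abs(spots$z - pts[i, 3])))
    expect_lt(dmin, beam$spot_spacing)
  }
})

test_that("plan JSON round trip preserves spots, beam and prescription", {
  ref <- coarse_reference()
  spots <- place_spots(ref, beam_model(spot_spacing = 14,
                                       layer_spacing = 14))
  plan <- spot_plan(spots, beam_model(spot_spacing = 14,
                                      layer_spacing = 14))
  path <- withr::local_tempfile(fileext = ".json")
  write_plan_json(plan, path)
  p2 <- read_plan_json(path)
  expect_equal(p2$spots, plan$spots)
  expect_equal(p2$prescription_gy, 63)
  expect_equal(p2$beam$sigma0, plan$beam$sigma0)
})
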