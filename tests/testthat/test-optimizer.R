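test_that("scenario enumeration matches the 3 mm / 3.5 % protocol", {
  scens <- build_scenarios(robust_setting())
  expect_length(scens, 9)
  nominal <- vapply(scens, adaptrt:::is_nominal_scenario, logical(1))
  expect_equal(sum(nominal), 1)
  shifts <- t(vapply(scens[!nominal], function(s) s$shift_mm,
                     numeric(3)))
  shifted <- rowSums(abs(shifts)) > 0
  # every non-nominal shift is axis-aligned with L-infinity norm 3 mm
  expect_equal(sum(shifted), 6)
  expect_true(all(apply(abs(shifts[shifted, ]), 1, max) == 3))
  expect_true(all(apply(shifts[shifted, ] != 0, 1, sum) == 1))
  scales <- vapply(scens, function(s) s$range_scale, numeric(1))
  expect_setequal(round(scales[scales != 1], 3), c(0.965, 1.035))
  # degenerate setting collapses to the nominal scenario
  expect_length(build_scenarios(robust_setting(0, 0)), 1)
})

test_that("worst-case composition equals the brute-force per-voxel
           min and max", {
  set.seed(12)
  doses <- lapply(1:9, function(i) array(runif(4 * 3 * 2), c(4, 3, 2)))
  wc <- worst_case_dose(doses)
  oracle_min <- oracle_max <- array(0, c(4, 3, 2))
  for (i in 1:4) for (j in 1:3) for (k in 1:2) {
    v <- vapply(doses, function(d) d[i, j, k], numeric(1))
    oracle_min[i, j, k] <- min(v); oracle_max[i, j, k] <- max(v)
  }
  expect_equal(wc$worst_target_dose, oracle_min)
  expect_equal(wc$worst_oar_dose, oracle_max)
  # single scenario: both outputs equal the input
  wc1 <- worst_case_dose(doses[1])
  expect_equal(wc1$worst_target_dose, doses[[1]])
  expect_equal(wc1$worst_oar_dose, doses[[1]])
  # ordering: D vs 2D
  wc2 <- worst_case_dose(list(doses[[1]], 2 * doses[[1]]))
  expect_equal(wc2$worst_target_dose, doses[[1]])
  expect_equal(wc2$worst_oar_dose, 2 * doses[[1]])
  expect_error(worst_case_dose(list()), "empty")
})

test_that("the robust plan on the water-box phantom meets the planning
           dose objectives", {
  wat <- memo("water_anat_4",
              build_reference_phantom(water_box_config(spacing = c(4, 4, 4))))
  plan <- memo("water_plan", plan_impt(wat))
  expect_true(all(coef(plan) >= 0))
  d <- compute_dose(plan, wat,
                    points = grid_coords(wat$grid, wat$structures$ctv))
  dvh <- compute_dvh(d, voxel_ml = prod(wat$grid$spacing) / 1000)
  expect_gte(dvh_index_D(dvh, 99), 63)
  expect_lt(dvh_index_Dmax(dvh), 69.3)
  # recorded objective trace is non-increasing
  expect_true(all(diff(plan$meta$objective_trace) <= 1e-12))
})

test_that("planning is deterministic for a fixed phantom", {
  ref <- coarse_reference()
  cfg <- small_trial_config()
  p1 <- plan_impt(ref, beam = cfg$beam, control = cfg$opt_control)
  p2 <- plan_impt(ref, beam = cfg$beam, control = cfg$opt_control)
  expect_identical(coef(p1), coef(p2))
})

test_that("robust optimization protects worst-scenario coverage better
           than nominal-only optimization", {
  # robustness dividend over several random phantoms
  cfg <- small_trial_config()
  worst_d99 <- function(plan, anat) {
    pts <- grid_coords(anat$grid, anat$structures$ctv)
    per <- lapply(build_scenarios(robust_setting()), function(sc)
      compute_dose(plan, anat, sc = sc, points = pts))
    dvh_index_D(compute_dvh(do.call(pmin, per)), 99)
  }
  wins <- 0; n <- 4
  for (i in seq_len(n)) {
    anat <- build_reference_phantom(patient_config(seed = 400 + i,
                                                   spacing = c(7, 7, 7)))
    robust <- plan_impt(anat, beam = cfg$beam, control = cfg$opt_control)
    nominal_only <- plan_impt(anat, setting = robust_setting(0, 0),
                              beam = cfg$beam, control = cfg$opt_control)
    if (worst_d99(robust, anat) > worst_d99(nominal_only, anat))
      wins <- wins + 1
  }
  expect_gte(wins, n - 1)
})

test_that("error-scenario evaluation reports zero delta for the nominal
           control and small mean CTV D99 degradation", {
  ref <- coarse_reference()
  cfg <- small_trial_config()
  plan <- memo("coarse_plan",
               plan_impt(ref, beam = cfg$beam,
                         control = cfg$opt_control))
  tab <- evaluate_plan_robustness(plan, ref)
  expect_equal(unlist(tab[tab$scenario == "nominal",
                          c("ctv_d99", "rectum_v60", "bladder_v60")]),
               c(ctv_d99 = 0, rectum_v60 = 0, bladder_v60 = 0))
  sm <- attr(tab, "summary")
  expect_lt(abs(sm["mean", "ctv_d99"]), 2)
  # opposite HU errors move the distal dose edge in opposite directions:
  # with two opposed lateral fields the D99 degrades on both sides
  hu <- tab[grepl("^hu", tab$scenario), ]
  expect_equal(nrow(hu), 2)
})
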