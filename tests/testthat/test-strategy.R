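test_that("with zero anatomical variation every NART fraction delivers
           the planning dose and accumulation restores the course", {
  parts <- zero_var_trial_parts()
  nart <- parts$nart
  # all fractions identical
  v <- nart$fractional
  for (key in unique(paste(v$structure, v$index))) {
    vals <- v$value[paste(v$structure, v$index) == key]
    expect_lt(diff(range(vals)), 1e-9)
  }
  # x-scaled fractional CTV D99 equals the plan's nominal CTV D99 on the
  # evaluation grid, and the accumulated dose equals fraction x count
  acc <- parts$nart$accumulated_dose
  expect_equal(acc$fractions_represented, 3)
  frac_d99 <- v$value[v$structure == "ctv" & v$index == "D99"][1]
  acc_d99 <- index_of(nart$accumulated, "ctv", "D99")
  expect_equal(acc_d99, frac_d99, tolerance = 0.05)
})

test_that("NART and DART coincide in the zero-variation limit", {
  parts <- zero_var_trial_parts()
  expect_equal(parts$dart$fractional$value, parts$nart$fractional$value,
               tolerance = 1e-8)
  expect_equal(parts$dart$accumulated$value,
               parts$nart$accumulated$value, tolerance = 1e-8)
})

test_that("the cohort reproduces the directional NART-vs-DART contrasts
           over ten synthetic patients", {
  trial <- small_trial()
  ctv_n <- acc_by_patient(trial, "nart", "ctv", "D99")
  ctv_d <- acc_by_patient(trial, "dart", "ctv", "D99")
  sv_n <- acc_by_patient(trial, "nart", "sv", "D99")
  sv_d <- acc_by_patient(trial, "dart", "sv", "D99")
  pro_n <- acc_by_patient(trial, "nart", "prostate", "D99")
  pro_d <- acc_by_patient(trial, "dart", "prostate", "D99")
  # daily replanning maintains target coverage that the fixed plan loses
  expect_gt(mean(ctv_d), mean(ctv_n))
  expect_gt(mean(sv_d), mean(sv_n))
  # the prostate itself is aligned every day: its D99 deficit is small
  # compared to the SV deficit
  expect_lt(abs(mean(pro_d) - mean(pro_n)),
            abs(mean(sv_d) - mean(sv_n)))
  expect_lt(abs(mean(pro_d) - mean(pro_n)), 2)
  # rectum V50: adaptive replanning does not dose the rectum more
  frac <- trial$fractional
  v50 <- function(st) mean(frac$value[frac$strategy == st &
                                        frac$structure == "rectum" &
                                        frac$index == "V50"])
  expect_gte(v50("nart"), v50("dart"))
})

test_that("trial runs are reproducible end to end from the master
           seed", {
  cfg <- small_trial_config(n_patients = 1, n_fractions = 2, seed = 31)
  t1 <- run_trial(cfg, strategies = "nart", progress = FALSE)
  t2 <- run_trial(cfg, strategies = "nart", progress = FALSE)
  expect_identical(t1$fractional, t2$fractional)
  expect_identical(t1$accumulated, t2$accumulated)
})

test_that("summary tables and statistics regenerate from the stored
           per-fraction records", {
  trial <- small_trial()
  # indices that are identically zero under both strategies give
  # degenerate paired tests (flagged by design)
  sm <- suppressWarnings(summary(trial))
  # achievement rates recompute exactly from the flag tables
  flags <- trial$fractional_flags
  dart_flags <- flags[flags$strategy == "dart", ]
  expect_equal(sm$fractional_rates["dart", "ctv_d99"],
               100 * mean(dart_flags$ctv_d99))
  # paired tests match direct recomputation
  row <- sm$tests[sm$tests$scope == "accumulated" &
                    sm$tests$structure == "sv" &
                    sm$tests$index == "D99", ]
  oracle <- paired_t_test(acc_by_patient(trial, "nart", "sv", "D99"),
                          acc_by_patient(trial, "dart", "sv", "D99"))
  expect_equal(row$t, oracle$t, tolerance = 1e-10)
  expect_equal(row$p, oracle$p, tolerance = 1e-10)
  expect_true(all(c("b", "c", "p") %in% names(sm$mcnemar)))
})

test_that("trial CSV round trip preserves the cohort tables", {
  trial <- small_trial()
  dir <- withr::local_tempdir()
  write_trial_csv(trial, dir)
  frac <- utils::read.csv(file.path(dir, "fractional_indices.csv"))
  expect_equal(nrow(frac), nrow(trial$fractional))
  expect_equal(frac$value, trial$fractional$value, tolerance = 1e-12)
})
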