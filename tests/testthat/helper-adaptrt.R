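# Shared fixtures. Heavy simulation products are memoized so several
# test files (and the acceptance suite) can share one computation.

.adaptrt_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .adaptrt_cache)) {
    assign(name, force(expr), envir = .adaptrt_cache)
  }
  get(name, envir = .adaptrt_cache)
}

# zero-variation parameter set: daily anatomy identical to planning
zero_variation_params <- function(n_fractions = 21) {
  variation_params(
    organ_mean = c(prostate = 0, sv = 0, rectum = 0, bladder = 0),
    organ_sd = c(prostate = 0, sv = 0, rectum = 0, bladder = 0),
    p_increase = c(prostate = NA, sv = NA, rectum = NA, bladder = NA),
    setup_trans_sd = 0, setup_rot_sd = 0,
    prostate_shift_sd = c(0, 0, 0), n_fractions = n_fractions)
}

# coarse pelvic reference used across files
coarse_reference <- function() {
  memo("coarse_reference",
       build_reference_phantom(patient_config(seed = 11,
                                              spacing = c(6, 6, 6))))
}

# a uniform-water slab grid for dose-engine oracles
water_rsp <- function(n = c(60, 30, 30), spacing = c(4, 4, 4),
                      origin = NULL) {
  if (is.null(origin)) origin <- -(n - 1) * spacing / 2
  voxel_grid(array(1, n), origin, spacing)
}

# small fast trial profile for directional property checks
small_trial_config <- function(n_patients = 10, n_fractions = 21,
                               seed = 7) {
  trial_config(
    n_patients = n_patients, n_fractions = n_fractions,
    master_seed = seed, spacing = 7,
    beam = beam_model(sigma0 = 9.5, spot_spacing = 14,
                      layer_spacing = 14),
    opt_control = list(caps = c(ctv = 280, rectum = 170, bladder = 170,
                                normal = 140),
                       chunks = 3L, maxit_per_chunk = 20L))
}

small_trial <- function() {
  memo("small_trial",
       run_trial(small_trial_config(), strategies = c("nart", "dart"),
                 progress = FALSE))
}

# the full-shape DART cohort (23 patients x 21 fractions, coarse grid)
cohort_dart_trial <- function() {
  memo("cohort_dart_trial",
       run_trial(trial_config(master_seed = 1), strategies = "dart",
                 progress = FALSE))
}

# one-patient zero-variation NART/DART pair (shared across files)
zero_var_trial_parts <- function() {
  memo("zero_var_parts", {
    cfg <- small_trial_config(n_patients = 1, n_fractions = 3, seed = 5)
    cfg$params <- zero_variation_params(n_fractions = 3)
    pat <- make_patient(cfg, 1)
    plan0 <- plan_impt(pat$reference, cfg$goals, cfg$setting, cfg$beam,
                       cfg$opt_control)
    list(cfg = cfg, pat = pat, plan0 = plan0,
         nart = run_nart(pat, plan0, cfg),
         dart = run_dart(pat, original_plan = plan0, config = cfg))
  })
}

index_of <- function(tab, structure, index) {
  tab$value[tab$structure == structure & tab$index == index]
}

acc_by_patient <- function(trial, strategy, structure, index) {
  tab <- trial$accumulated
  sub <- tab[tab$strategy == strategy & tab$structure == structure &
             tab$index == index, ]
  sub$value[order(sub$patient)]
}
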