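# The in-silico trial: per-fraction NART and DART dose recalculation over
# a synthetic cohort, deformable accumulation and error-scenario
# robustness evaluation.

#' Trial configuration
#'
#' Defaults reproduce the study shape: 23 patients x 21 fractions = 483
#' daily anatomies, 63 Gy(RBE) prescription, 3 mm / 3.5 % robust setting.
#' The numerical profile (grid spacing, spot lattice, optimizer budget)
#' is the desk-scale cohort profile; single-plan work can use finer
#' settings directly through [plan_impt()].
#'
#' @param n_patients,n_fractions cohort shape.
#' @param master_seed all randomness derives from this one integer.
#' @param spacing cohort voxel pitch (mm).
#' @param goals,setting,params planning goals, robust setting and
#'   variation parameters.
#' @param beam cohort beam model (coarser spot lattice than the
#'   single-plan default).
#' @param opt_control optimizer knobs passed to [plan_impt()].
#' @param align_refine bone-registration refinement iterations.
#' @param crop_margin margin (mm) of the dose-evaluation crop box around
#'   the structures.
#' @param dart_reuse_lattice daily replans re-optimize the weights of
#'   the original plan's spot lattice, warm-started from its weights
#'   (the usual online-adaptive workflow); `FALSE` re-places spots on
#'   every daily anatomy.
#' @return object of class `trial_config`.
#' @export
trial_config <- function(n_patients = 23, n_fractions = 21,
                         master_seed = 1L, spacing = 6,
                         goals = planning_goals(),
                         setting = robust_setting(),
                         params = variation_params(
                           n_fractions = n_fractions),
                         beam = beam_model(sigma0 = 8.5,
                                           spot_spacing = 13,
                                           layer_spacing = 13),
                         opt_control = list(
                           caps = c(ctv = 400, rectum = 220,
                                    bladder = 220, normal = 180),
                           chunks = 4L, maxit_per_chunk = 25L),
                         align_refine = 0L, crop_margin = 15,
                         dart_reuse_lattice = FALSE) {
  structure(list(n_patients = n_patients, n_fractions = n_fractions,
                 master_seed = as.integer(master_seed), spacing = spacing,
                 goals = goals, setting = setting, params = params,
                 beam = beam, opt_control = opt_control,
                 align_refine = align_refine, crop_margin = crop_margin,
                 dart_reuse_lattice = dart_reuse_lattice),
            class = "trial_config")
}

patient_seed <- function(config, patient) {
  derive_seed(config$master_seed, 811, patient)
}

#' Build one synthetic patient of a trial
#'
#' @param config a [trial_config()].
#' @param patient patient index (1-based).
#' @return list with the reference anatomy, the patient seed and a daily
#'   anatomy generator `daily(f)`.
#' @export
make_patient <- function(config, patient) {
  ps <- patient_seed(config, patient)
  cfg <- patient_config(seed = ps, spacing = config$spacing)
  ref <- build_reference_phantom(cfg)
  list(reference = ref, seed = ps, patient = patient,
       daily = function(f) sample_daily_anatomy(ref, config$params, f, ps))
}

# planning-frame crop grid on which fraction doses are evaluated/mapped
trial_crop_grid <- function(reference, spacing, margin) {
  s <- reference$structures
  pts <- grid_coords(reference$grid,
                     s$prostate | s$sv | s$rectum | s$bladder)
  grid_from_box(apply(pts, 2, min) - margin, apply(pts, 2, max) + margin,
                spacing)
}

crop_masks <- function(anatomy, crop) {
  m <- voxelize_structures(anatomy, crop)
  m[c("ctv", "prostate", "sv", "rectum", "bladder")]
}

mask_doses <- function(dose_vals, masks) {
  lapply(masks, function(m) dose_vals[m])
}

#' Run one treatment strategy for one patient
#'
#' For every fraction: align the daily anatomy (bone six-axis rigid
#' correction, then prostate-centre-to-isocenter translation), obtain the
#' fraction's plan — the original plan for NART, a fresh robust
#' re-optimization on the aligned daily anatomy for DART — compute the
#' nominal-scenario dose, evaluate the x-fraction-scaled fractional DVH
#' indices on the daily structures, and map the fraction dose onto the
#' planning grid through the generator's deformation. The 21 mapped
#' doses are summed into the accumulated dose and evaluated on the
#' planning structures.
#'
#' @param patient list from [make_patient()], or
#'   `list(reference=, daily=)` where `daily` is a list of 21 instances
#'   or a generator function.
#' @param strategy `"nart"` or `"dart"`.
#' @param original_plan the planning `impt_plan` (required for NART; used
#'   as fallback when a DART re-optimization fails, with the fraction
#'   flagged).
#' @param config a [trial_config()].
#' @return object of class `strategy_result`: fractional and accumulated
#'   index tables, clinical-goal flags, the accumulated `dose_grid` and
#'   per-fraction provenance.
#' @export
run_strategy <- function(patient, strategy = c("nart", "dart"),
                         original_plan = NULL, config = trial_config()) {
  strategy <- match.arg(strategy)
  ref <- patient$reference
  nf <- config$n_fractions
  get_daily <- if (is.function(patient$daily)) patient$daily
               else function(f) patient$daily[[f]]
  if (strategy == "nart" && is.null(original_plan))
    stop("NART requires the original plan")
  crop <- trial_crop_grid(ref, config$spacing, config$crop_margin)
  crop_pts <- grid_coords(crop)
  vml <- voxel_volume(crop) / 1000
  # accumulated indices are evaluated by direct composition: the
  # fraction dose is computed exactly at the deformation-mapped
  # positions of the planning structure voxels, avoiding the smoothing
  # of an intermediate resampling grid
  s_ref <- ref$structures
  ref_struct <- list(ctv = s_ref$ctv, prostate = s_ref$prostate,
                     sv = s_ref$sv, rectum = s_ref$rectum,
                     bladder = s_ref$bladder)
  ref_counts <- vapply(ref_struct, sum, integer(1))
  ref_pts <- do.call(rbind, lapply(ref_struct, function(m)
    grid_coords(ref$grid, m)))
  ref_grp <- rep(names(ref_struct), ref_counts)
  acc_vals <- numeric(nrow(ref_pts))
  vml_ref <- voxel_volume(ref$grid) / 1000
  frac_idx <- list(); frac_flags <- list(); mapped <- vector("list", nf)
  prov <- vector("list", nf)
  for (f in seq_len(nf)) {
    daily <- get_daily(f)
    a_bone <- rigid_align_bone(daily, ref, refine = config$align_refine)
    t_pro <- align_prostate_center(daily, ref, after = a_bone)
    a_tot <- compose_rigid(
      rigid_transform(translation_mm = t_pro,
                      isocenter = ref$config$isocenter), a_bone)
    aligned <- transform_anatomy(daily, a_tot)
    failed <- FALSE
    plan_f <- if (strategy == "nart") original_plan else
      tryCatch({
        ctl <- config$opt_control
        if (!is.null(original_plan) && isTRUE(config$dart_reuse_lattice)) {
          # online-adaptive replan: same spot lattice, warm-started
          ctl$spots <- original_plan$spots
          ctl$w_init <- original_plan$spots$weight
        }
        plan_impt(aligned, config$goals, config$setting, config$beam,
                  ctl)
      }, error = function(e) { failed <<- TRUE; original_plan })
    course <- compute_dose(plan_f, aligned, eval_grid = crop)
    frac <- fraction_dose_from_course(course, nf)
    scaled <- scale_fraction_dose(frac, nf)
    dmasks <- crop_masks(aligned, crop)
    idx <- structure_indices(mask_doses(as.numeric(scaled$values), dmasks),
                             vml)
    flags <- clinical_goal_pass(idx, config$goals)
    if (failed) flags[] <- FALSE  # optimization failure: goal-failed
    frac_idx[[f]] <- cbind(fraction = f, idx)
    frac_flags[[f]] <- data.frame(fraction = f, t(flags),
                                  replan_failed = failed)
    acc_vals <- acc_vals +
      compute_dose(plan_f, aligned,
                   points = deform_forward(aligned, ref_pts)) / nf
    mapped[[f]] <- map_dose_to_reference(frac, aligned, crop)
    prov[[f]] <- list(fraction = f,
                      bone_align = a_bone, prostate_shift = t_pro,
                      applied_setup = unclass(daily$setup),
                      variation_percent = daily$variation$percent,
                      replan_failed = failed,
                      n_outside = attr(mapped[[f]], "n_outside"))
  }
  acc <- accumulate_dose(mapped, nf,
                         provenance = list(strategy = strategy,
                                           seed = patient$seed))
  acc_idx <- structure_indices(split(acc_vals, factor(ref_grp,
                                                      names(ref_struct))),
                               vml_ref)
  structure(list(
    strategy = strategy,
    fractional = do.call(rbind, frac_idx),
    fractional_flags = do.call(rbind, frac_flags),
    accumulated = acc_idx,
    accumulated_flags = clinical_goal_pass(acc_idx, config$goals),
    accumulated_dose = acc, provenance = prov),
    class = "strategy_result")
}

#' @rdname run_strategy
#' @export
run_nart <- function(patient, original_plan, config = trial_config())
  run_strategy(patient, "nart", original_plan, config)

#' @rdname run_strategy
#' @export
run_dart <- function(patient, original_plan = NULL,
                     config = trial_config())
  run_strategy(patient, "dart", original_plan, config)

#' Error-scenario robustness evaluation of a plan
#'
#' Recomputes the dose under the eight error scenarios — six 3 mm
#' isocenter shifts and voxel-by-voxel scaling of the stopping-power map
#' at +/- 3.5 % (the patient-density error the protocol's
#' Hounsfield-unit variation represents; the HU map is class-constant
#' here, so the density error is applied on the stopping-power scale
#' directly) — plus the nominal control, and reports the change of CTV
#' D99, rectum V60 and bladder V60 relative to the nominal plan.
#'
#' @param plan an `impt_plan`.
#' @param anatomy the planning `anatomy_instance`.
#' @param setting a [robust_setting()] (magnitudes of the evaluation
#'   scenarios).
#' @return data frame of per-scenario index deltas plus a `mean`/`sd`
#'   summary in `attr(, "summary")`.
#' @export
evaluate_plan_robustness <- function(plan, anatomy,
                                     setting = robust_setting()) {
  s <- anatomy$structures
  masks <- list(ctv = s$ctv, rectum = s$rectum, bladder = s$bladder)
  pts <- lapply(masks, function(m) grid_coords(anatomy$grid, m))
  vml <- voxel_volume(anatomy$grid) / 1000
  eval_one <- function(anat, sc) {
    d_ctv <- compute_dose(plan, anat, sc = sc, points = pts$ctv)
    d_rec <- compute_dose(plan, anat, sc = sc, points = pts$rectum)
    d_bla <- compute_dose(plan, anat, sc = sc, points = pts$bladder)
    c(ctv_d99 = dvh_index_D(compute_dvh(d_ctv, voxel_ml = vml), 99),
      rectum_v60 = dvh_index_V(compute_dvh(d_rec, voxel_ml = vml), 60),
      bladder_v60 = dvh_index_V(compute_dvh(d_bla, voxel_ml = vml), 60))
  }
  nominal <- eval_one(anatomy, scenario())
  rows <- list(data.frame(scenario = "nominal", t(nominal - nominal)))
  for (ax in 1:3) for (sgn in c(1, -1)) {
    sh <- c(0, 0, 0); sh[ax] <- sgn * setting$setup_mm
    v <- eval_one(anatomy, scenario(shift_mm = sh))
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = paste0("shift_", c("x", "y", "z")[ax],
                        ifelse(sgn > 0, "+", "-")), t(v - nominal))
  }
  for (sgn in c(1, -1)) {
    # stopping power over(+)/under(-)estimated voxel-by-voxel: the beam
    # respectively undershoots / overshoots
    v <- eval_one(anatomy,
                  scenario(range_scale = 1 / (1 + sgn *
                                              setting$range_pct / 100)))
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = paste0("hu", ifelse(sgn > 0, "+", "-")), t(v - nominal))
  }
  out <- do.call(rbind, rows)
  err <- out[out$scenario != "nominal", -1]
  attr(out, "summary") <- rbind(mean = colMeans(err),
                                sd = apply(err, 2, stats::sd))
  attr(out, "nominal") <- nominal
  out
}

#' Run the full NART-vs-DART in-silico trial
#'
#' For each synthetic patient: build the reference phantom, fit the
#' original robust plan, simulate the requested strategies fraction by
#' fraction, and collect fractional (x21-scaled) and accumulated DVH
#' indices and clinical-goal flags for the whole cohort.
#'
#' @param config a [trial_config()].
#' @param strategies character subset of `c("nart", "dart")`.
#' @param keep_doses keep each patient's accumulated `dose_grid`s.
#' @param progress print one line per patient.
#' @return object of class `adaptive_trial` with cohort tables
#'   `fractional`, `fractional_flags`, `accumulated`,
#'   `accumulated_flags`, per-patient plan metadata, and the config.
#' @export
run_trial <- function(config = trial_config(),
                      strategies = c("nart", "dart"),
                      keep_doses = FALSE, progress = interactive()) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  frac <- list(); fflags <- list(); acc <- list(); aflags <- list()
  plan_meta <- list(); doses <- list()
  for (p in seq_len(config$n_patients)) {
    t0 <- Sys.time()
    pat <- make_patient(config, p)
    plan0 <- plan_impt(pat$reference, config$goals, config$setting,
                       config$beam, config$opt_control)
    plan_meta[[p]] <- list(patient = p, seed = pat$seed,
                           renorm = plan0$meta$renorm_factor,
                           d99_prenorm = plan0$meta$nominal_ctv_d99_prenorm)
    for (st in strategies) {
      res <- run_strategy(pat, st, original_plan = plan0, config = config)
      frac[[length(frac) + 1L]] <- cbind(patient = p, strategy = st,
                                         res$fractional)
      fflags[[length(fflags) + 1L]] <- cbind(patient = p, strategy = st,
                                             res$fractional_flags)
      acc[[length(acc) + 1L]] <- cbind(patient = p, strategy = st,
                                       res$accumulated)
      aflags[[length(aflags) + 1L]] <- data.frame(patient = p,
                                                  strategy = st,
                                                  t(res$accumulated_flags))
      if (keep_doses) doses[[paste(p, st, sep = "_")]] <- res$accumulated_dose
    }
    if (progress)
      message(sprintf("patient %d/%d done (%.1f s)", p, config$n_patients,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  structure(list(config = config, strategies = strategies,
                 fractional = do.call(rbind, frac),
                 fractional_flags = do.call(rbind, fflags),
                 accumulated = do.call(rbind, acc),
                 accumulated_flags = do.call(rbind, aflags),
                 plan_meta = plan_meta, accumulated_doses = doses),
            class = "adaptive_trial")
}

trial_index_matrix <- function(tab, structure, index) {
  sub <- tab[tab$structure == structure & tab$index == index, ]
  out <- tapply(sub$value, list(sub$patient, sub$strategy), mean)
  out
}

#' @export
print.adaptive_trial <- function(x, ...) {
  cat("<adaptive_trial> ", x$config$n_patients, " patients x ",
      x$config$n_fractions, " fractions; strategies: ",
      paste(x$strategies, collapse = ", "), "\n", sep = "")
  for (st in x$strategies) {
    sub <- x$accumulated[x$accumulated$strategy == st &
                         x$accumulated$index == "D99", ]
    for (s2 in c("ctv", "sv")) {
      v <- sub$value[sub$structure == s2]
      cat(sprintf("  %s accumulated %s D99: %.2f +/- %.2f Gy(RBE)\n",
                  toupper(st), toupper(s2), mean(v), stats::sd(v)))
    }
  }
  invisible(x)
}

#' Summarize an in-silico trial
#'
#' Cohort means of the fractional and accumulated DVH indices per
#' strategy, clinical-goal achievement rates, and NART-vs-DART paired
#' t-tests (indices) and McNemar tests (achievement), when both
#' strategies were simulated.
#'
#' @param object an `adaptive_trial`.
#' @param ... unused.
#' @export
summary.adaptive_trial <- function(object, ...) {
  x <- object
  summarize <- function(tab) {
    ag <- stats::aggregate(value ~ strategy + structure + index, tab,
                           function(v) c(mean = mean(v), sd = stats::sd(v)))
    data.frame(ag[1:3], mean = ag$value[, "mean"], sd = ag$value[, "sd"])
  }
  goal_cols <- function(flags)
    setdiff(names(flags)[vapply(flags, is.logical, logical(1))],
            "replan_failed")
  rates <- function(flags) {
    do.call(rbind, lapply(split(flags, flags$strategy), function(s)
      data.frame(strategy = s$strategy[1],
                 t(achievement_rates(s, goal_cols(flags))))))
  }
  out <- list(
    fractional = summarize(x$fractional),
    accumulated = summarize(x$accumulated),
    fractional_rates = rates(x$fractional_flags),
    accumulated_rates = rates(x$accumulated_flags))
  if (all(c("nart", "dart") %in% x$strategies)) {
    keys <- unique(x$accumulated[c("structure", "index")])
    tests <- list()
    for (i in seq_len(nrow(keys))) {
      for (scope in c("fractional", "accumulated")) {
        tab <- x[[scope]]
        sub <- tab[tab$structure == keys$structure[i] &
                   tab$index == keys$index[i], ]
        wide <- merge(sub[sub$strategy == "nart",
                          c("patient", if (scope == "fractional") "fraction",
                            "value")],
                      sub[sub$strategy == "dart",
                          c("patient", if (scope == "fractional") "fraction",
                            "value")],
                      by = c("patient",
                             if (scope == "fractional") "fraction"))
        tt <- paired_t_test(wide$value.x, wide$value.y)
        tests[[length(tests) + 1L]] <- data.frame(
          scope = scope, structure = keys$structure[i],
          index = keys$index[i], mean_nart = mean(wide$value.x),
          mean_dart = mean(wide$value.y), t = tt$t, p = tt$p)
      }
    }
    out$tests <- do.call(rbind, tests)
    mcn <- list()
    for (scope in c("fractional_flags", "accumulated_flags")) {
      flags <- x[[scope]]
      by <- c("patient", if (scope == "fractional_flags") "fraction")
      for (g in goal_cols(flags)) {
        wide <- merge(flags[flags$strategy == "nart", c(by, g)],
                      flags[flags$strategy == "dart", c(by, g)], by = by)
        mt <- mcnemar_test(wide[[paste0(g, ".x")]],
                           wide[[paste0(g, ".y")]])
        mcn[[length(mcn) + 1L]] <- data.frame(
          scope = sub("_flags", "", scope), goal = g,
          rate_nart = 100 * mean(wide[[paste0(g, ".x")]]),
          rate_dart = 100 * mean(wide[[paste0(g, ".y")]]),
          b = mt$b, c = mt$c, p = mt$p, method = mt$method)
      }
    }
    out$mcnemar <- do.call(rbind, mcn)
  }
  class(out) <- "summary.adaptive_trial"
  out
}

#' @export
print.summary.adaptive_trial <- function(x, ...) {
  cat("Accumulated DVH indices (cohort mean +/- SD):\n")
  print(x$accumulated, row.names = FALSE, digits = 4)
  cat("\nFractional clinical-goal achievement (%):\n")
  print(x$fractional_rates, row.names = FALSE, digits = 4)
  cat("\nAccumulated clinical-goal achievement (%):\n")
  print(x$accumulated_rates, row.names = FALSE, digits = 4)
  if (!is.null(x$tests)) {
    cat("\nNART vs DART paired t-tests:\n")
    print(x$tests, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
plot.adaptive_trial <- function(x, index = "D99", structure = "ctv",
                                scope = c("accumulated", "fractional"),
                                ...) {
  scope <- match.arg(scope)
  tab <- x[[scope]]
  sub <- tab[tab$structure == structure & tab$index == index, ]
  graphics::boxplot(value ~ strategy, data = sub,
                    ylab = paste(toupper(structure), index, "[Gy(RBE)]"),
                    main = paste(scope, "dose"), ...)
  invisible(x)
}
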