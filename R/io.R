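# Anatomy/cohort serialization and the run manifest.
#
# Anatomies are stored as a YAML description of the analytic geometry and
# daily state (authoritative, lossless) plus optional NRRD volumes (HU,
# per-structure masks and a combined label map) for interoperability.

label_codes <- c(air = 0, body = 1, prostate = 2, sv = 3, rectum = 4,
                 bladder = 5, bone = 6)

# collapse YAML lists of scalars back into numeric vectors, recursively
normalize_yaml_numeric <- function(x) {
  if (!is.list(x)) return(x)
  if (length(x) && all(!vapply(x, is.list, logical(1))) &&
      all(vapply(x, is.numeric, logical(1))) && is.null(names(x)))
    return(unlist(x))
  lapply(x, normalize_yaml_numeric)
}

#' Write an anatomy instance to a directory
#'
#' `meta.yaml` holds the full analytic description (organ shapes, daily
#' state, set-up transform, variation draw and seeds) from which the
#' instance can be rebuilt exactly; with `volumes = TRUE` the HU grid,
#' one 8-bit mask per structure and a combined label map are written as
#' NRRD.
#'
#' @param anatomy an `anatomy_instance`.
#' @param dir output directory (created).
#' @param volumes also write NRRD volumes.
#' @export
write_anatomy <- function(anatomy, dir, volumes = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- anatomy$config
  meta <- list(
    spacing = cfg$spacing, grid_lo = cfg$grid_lo, grid_hi = cfg$grid_hi,
    isocenter = cfg$isocenter, hu = as.list(cfg$hu),
    config_seed = cfg$seed,
    shapes = cfg$shapes,
    states = anatomy$states,
    setup = unclass(anatomy$setup),
    is_reference = anatomy$is_reference,
    variation = if (!is.null(anatomy$variation))
      list(percent = as.list(anatomy$variation$percent),
           sv_ap = anatomy$variation$sv_ap,
           prostate_shift = anatomy$variation$prostate_shift,
           seed = anatomy$variation$seed,
           fraction_index = anatomy$variation$fraction_index))
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (volumes) {
    if (is.null(anatomy$structures)) {
      anatomy$structures <- voxelize_structures(anatomy)
      anatomy$grid <- anatomy_hu_grid(anatomy)
    }
    write_nrrd(anatomy$grid, file.path(dir, "hu.nrrd"), encoding = "raw")
    lab <- array(label_codes[["air"]], anatomy$grid$shape)
    for (st in c("body", "bladder", "rectum", "sv", "prostate", "bone")) {
      m <- anatomy$structures[[st]]
      lab[m] <- label_codes[[st]]
      mg <- voxel_grid(array(as.numeric(m), anatomy$grid$shape),
                       anatomy$grid$origin, anatomy$grid$spacing)
      write_nrrd(mg, file.path(dir, paste0("mask_", st, ".nrrd")),
                 encoding = "raw", type = "uint8")
    }
    write_nrrd(voxel_grid(lab, anatomy$grid$origin, anatomy$grid$spacing),
               file.path(dir, "labels.nrrd"), encoding = "raw",
               type = "uint8")
  }
  invisible(dir)
}

#' Read an anatomy instance back from a directory
#'
#' Rebuilds the instance from `meta.yaml` (re-voxelizing from the
#' analytic geometry, which is bit-exact with the original).
#'
#' @param dir directory written by [write_anatomy()].
#' @param voxelize rebuild masks and HU.
#' @export
read_anatomy <- function(dir, voxelize = TRUE) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  cfg <- structure(list(
    shapes = lapply(meta$shapes, normalize_yaml_numeric),
    hu = unlist(meta$hu), spacing = unlist(meta$spacing),
    grid_lo = unlist(meta$grid_lo), grid_hi = unlist(meta$grid_hi),
    isocenter = unlist(meta$isocenter), seed = meta$config_seed),
    class = "patient_config")
  states <- lapply(meta$states, function(st)
    list(vol_scale = st$vol_scale, shift = unlist(st$shift)))
  setup <- rigid_transform(unlist(meta$setup$rotation_deg),
                           unlist(meta$setup$translation_mm),
                           unlist(meta$setup$isocenter))
  variation <- if (!is.null(meta$variation))
    list(percent = unlist(meta$variation$percent),
         sv_ap = meta$variation$sv_ap,
         prostate_shift = unlist(meta$variation$prostate_shift),
         seed = meta$variation$seed,
         fraction_index = meta$variation$fraction_index)
  anat <- new_anatomy(cfg, states, setup, variation,
                      isTRUE(meta$is_reference))
  if (voxelize) {
    anat$structures <- voxelize_structures(anat)
    anat$grid <- anatomy_hu_grid(anat)
  }
  anat
}

#' Generate a seeded fixture cohort on disk
#'
#' Writes `P01/reference`, `P01/F01` ... for `n_patients` patients and
#' `n_fractions` daily anatomies each, plus a run manifest. Default
#' spacing is coarse (continuous-integration scale); the full study
#' shape is 23 x 21.
#'
#' @param n_patients,n_fractions cohort shape (`n_fractions = 0` writes
#'   references only).
#' @param seed master seed.
#' @param out_dir output directory.
#' @param spacing voxel pitch (mm).
#' @param volumes write NRRD volumes as well as the analytic YAML.
#' @return the manifest, invisibly.
#' @export
generate_fixture_cohort <- function(n_patients, n_fractions, seed,
                                    out_dir, spacing = 8,
                                    volumes = FALSE) {
  stopifnot(n_patients >= 1, n_fractions >= 0)
  cfg <- trial_config(n_patients = n_patients,
                      n_fractions = max(n_fractions, 1L),
                      master_seed = seed, spacing = spacing)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- integer(n_patients)
  for (p in seq_len(n_patients)) {
    ps <- patient_seed(cfg, p)
    seeds[p] <- ps
    pdir <- file.path(out_dir, sprintf("P%02d", p))
    pcfg <- patient_config(seed = ps, spacing = spacing)
    ref <- build_reference_phantom(pcfg)
    write_anatomy(ref, file.path(pdir, "reference"), volumes = volumes)
    for (f in seq_len(n_fractions)) {
      daily <- sample_daily_anatomy(ref, cfg$params, f, ps,
                                    voxelize = volumes)
      write_anatomy(daily, file.path(pdir, sprintf("F%02d", f)),
                    volumes = volumes)
    }
  }
  manifest <- run_manifest(
    stage = "phantom",
    config = list(n_patients = n_patients, n_fractions = n_fractions,
                  spacing = spacing, volumes = volumes),
    master_seed = seed, stage_seeds = list(patients = seeds),
    paths = list.files(out_dir, recursive = TRUE, full.names = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Build a run manifest
#'
#' Snapshot of configuration, software version, master and per-stage
#' seeds, output file hashes and a timestamp; a completed run is
#' reproducible from its manifest alone.
#'
#' @param stage pipeline stage name.
#' @param config configuration list (snapshotted as-is).
#' @param master_seed integer master seed.
#' @param stage_seeds named list of derived seeds.
#' @param paths files to hash.
#' @export
run_manifest <- function(stage, config, master_seed, stage_seeds = list(),
                         paths = character(0)) {
  hashes <- if (length(paths))
    as.list(tools::md5sum(sort(paths))) else list()
  list(stage = stage,
       package = "adaptrt",
       version = as.character(utils::packageVersion("adaptrt")),
       master_seed = master_seed,
       stage_seeds = stage_seeds,
       config = config,
       file_md5 = hashes,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write trial result tables as CSV
#'
#' Fractional indices/flags (one row per patient-fraction-strategy-index)
#' and accumulated tables, in a fixed column order.
#'
#' @param trial an `adaptive_trial`.
#' @param dir output directory.
#' @export
write_trial_csv <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$fractional,
                   file.path(dir, "fractional_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$fractional_flags,
                   file.path(dir, "fractional_flags.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$accumulated,
                   file.path(dir, "accumulated_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(trial$accumulated_flags,
                   file.path(dir, "accumulated_flags.csv"),
                   row.names = FALSE)
  invisible(dir)
}
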