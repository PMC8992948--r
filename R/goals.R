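# DVH index tables and goal scoring against planning and clinical goals.

target_structures <- c("ctv", "prostate", "sv")

#' DVH index table for a dose distribution
#'
#' Computes the evaluation index set — CTV/prostate/SV D99; rectum Dmax,
#' V30, V50, V60; bladder V30, V60 and V63 in ml — from per-structure
#' voxel doses.
#'
#' @param doses named list of numeric voxel-dose vectors (Gy(RBE)) with
#'   entries `ctv`, `prostate`, `sv`, `rectum`, `bladder`.
#' @param voxel_ml voxel volume in ml.
#' @return data frame with columns `structure`, `index`, `value`.
#' @export
structure_indices <- function(doses, voxel_ml) {
  rows <- list()
  add <- function(structure, index, value)
    rows[[length(rows) + 1L]] <<- data.frame(structure = structure,
                                             index = index, value = value)
  for (st in target_structures) {
    dv <- compute_dvh(doses[[st]], voxel_ml = voxel_ml)
    add(st, "D99", dvh_index_D(dv, 99))
  }
  dv <- compute_dvh(doses$rectum, voxel_ml = voxel_ml)
  add("rectum", "Dmax", dvh_index_Dmax(dv))
  add("rectum", "V30", dvh_index_V(dv, 30))
  add("rectum", "V50", dvh_index_V(dv, 50))
  add("rectum", "V60", dvh_index_V(dv, 60))
  dv <- compute_dvh(doses$bladder, voxel_ml = voxel_ml)
  add("bladder", "V30", dvh_index_V(dv, 30))
  add("bladder", "V60", dvh_index_V(dv, 60))
  add("bladder", "V63ml", dvh_index_V(dv, 63, absolute = TRUE))
  do.call(rbind, rows)
}

index_value <- function(indices, structure, index) {
  v <- indices$value[indices$structure == structure &
                     indices$index == index]
  if (length(v) != 1L) NA_real_ else v
}

#' Score an index table against the clinical goals
#'
#' Clinical goals: the three D99 indices above 95 % of the
#' prescription, rectum Dmax < 66 Gy(RBE), rectum V30 < 50 %, rectum
#' V50 < 20 %, bladder V30 < 30 %, bladder V63 < 10 ml.
#'
#' @param indices data frame from [structure_indices()].
#' @param goals a [planning_goals()].
#' @return named logical vector of per-goal pass flags.
#' @export
clinical_goal_pass <- function(indices, goals = planning_goals()) {
  cl <- goals$clinical
  c(ctv_d99 = index_value(indices, "ctv", "D99") > cl$d99_min,
    prostate_d99 = index_value(indices, "prostate", "D99") > cl$d99_min,
    sv_d99 = index_value(indices, "sv", "D99") > cl$d99_min,
    rectum_dmax = index_value(indices, "rectum", "Dmax") < cl$rectum_dmax_max,
    rectum_v30 = index_value(indices, "rectum", "V30") < cl$rectum_v30_max,
    rectum_v50 = index_value(indices, "rectum", "V50") < cl$rectum_v50_max,
    bladder_v30 = index_value(indices, "bladder", "V30") < cl$bladder_v30_max,
    bladder_v63ml = index_value(indices, "bladder", "V63ml") <
      cl$bladder_v63ml_max)
}

#' Score an index table against the planning goals
#'
#' @param indices data frame from [structure_indices()]; must contain a
#'   CTV Dmax row (added by [plan_quality_indices()]) for the Dmax goal.
#' @param goals a [planning_goals()].
#' @return named logical vector.
#' @export
planning_goal_pass <- function(indices, goals = planning_goals()) {
  c(ctv_d99 = index_value(indices, "ctv", "D99") > goals$ctv_d99_min,
    ctv_dmax = index_value(indices, "ctv", "Dmax") < goals$ctv_dmax_max,
    rectum_v50 = index_value(indices, "rectum", "V50") < 20,
    rectum_v30 = index_value(indices, "rectum", "V30") < 50,
    bladder_v30 = index_value(indices, "bladder", "V30") < 30)
}

#' Full plan-quality index table on the planning anatomy
#'
#' Nominal-scenario indices of a plan, including CTV Dmax (planning-goal
#' set) alongside the clinical evaluation set.
#'
#' @param plan an `impt_plan`.
#' @param anatomy the planning `anatomy_instance`.
#' @return data frame as [structure_indices()] plus a CTV Dmax row.
#' @export
plan_quality_indices <- function(plan, anatomy) {
  s <- anatomy$structures
  doses <- lapply(list(ctv = s$ctv, prostate = s$prostate, sv = s$sv,
                       rectum = s$rectum, bladder = s$bladder),
                  function(m) compute_dose(plan, anatomy,
                                           points = grid_coords(anatomy$grid, m)))
  idx <- structure_indices(doses, voxel_volume(anatomy$grid) / 1000)
  rbind(idx, data.frame(structure = "ctv", index = "Dmax",
                        value = max(doses$ctv)))
}

#' Achievement rates over a collection of goal flags
#'
#' @param flags data frame with logical goal columns (one row per
#'   fraction or patient).
#' @param goal_cols columns to summarize (default: all logical columns).
#' @return named numeric vector of percentages.
#' @export
achievement_rates <- function(flags, goal_cols = NULL) {
  if (is.null(goal_cols))
    goal_cols <- names(flags)[vapply(flags, is.logical, logical(1))]
  vapply(flags[goal_cols], function(x) 100 * mean(x), numeric(1))
}
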