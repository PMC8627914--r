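# Plain-text exports: branch tables and truth trees as CSV, trees and CV
# plans as JSON.

#' Write a branch table as CSV
#'
#' @param tree An `airway_tree`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_branch_table <- function(tree, path) {
  write.csv(branch_table(tree), path, row.names = FALSE)
  invisible(path)
}

#' Write an airway tree as JSON
#'
#' Serializes the branch table together with the centerline polylines.
#'
#' @param tree An `airway_tree`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(branches = branch_table(tree),
              root_branch_id = tree$root_branch_id,
              spacing_mm = tree$spacing_mm,
              polylines = lapply(tree$polylines, function(p) unname(as.matrix(p))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a ground-truth tree as CSV
#'
#' @param truth An `airway_truth`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  write.csv(truth$branches, path, row.names = FALSE)
  invisible(path)
}

#' Write per-subject summaries as CSV
#'
#' @param summaries List of `segmentation_summary` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries_csv <- function(summaries, path) {
  rows <- do.call(rbind, lapply(summaries, function(s)
    data.frame(subject_id = s$subject_id, variant = s$variant,
               airway_count = s$airway_count, n_unassigned = s$n_unassigned,
               total_length_mm = s$total_length_mm,
               total_length_all_mm = s$total_length_all_mm,
               median_diameter_mm = s$median_diameter_mm)))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a comparison report as CSV
#'
#' @param comparisons A `comparison_result` from [compare_paired()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_comparisons_csv <- function(comparisons, path) {
  write.csv(as.data.frame(comparisons), path, row.names = FALSE)
  invisible(path)
}

#' Write a cross-validation plan as JSON
#'
#' @param plan A `cv_plan`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cv_plan_json <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
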