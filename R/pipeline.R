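# One-call measurement pipeline and the phantom recovery oracle.

#' Measure an airway segmentation mask
#'
#' Runs the full morphometry pipeline on a binary airway mask: thinning to a
#' centerline graph, cycle removal (maximum-total-length spanning tree),
#' root detection (most superior endpoint of the largest component), spur
#' pruning, branch decomposition with generation numbering, bridging of
#' disconnected (post-occlusion) components, and per-branch length and lumen
#' diameter measurement.
#'
#' @param mask A [binary_mask()].
#' @param min_spur_length_mm Terminal chains shorter than this are treated
#'   as thinning artifacts and removed (default 2 mm).
#' @param bridge_max_mm Maximum distance over which a disconnected component
#'   is bridged back onto the tree (default 5 mm; 0 disables).
#' @param interval_mm Diameter sampling interval along the centerline
#'   (default 1 mm).
#' @param junction_fuse_mm Scale below which adjacent skeleton junctions
#'   count as one bifurcation event (default 1.5 mm).
#' @param smooth_window Odd moving-average window for branch polylines
#'   (default 5 skeleton points; 0 keeps raw voxel chains).
#' @return A measured `airway_tree`.
#' @export
measure_airways <- function(mask, min_spur_length_mm = 2, bridge_max_mm = 5,
                            interval_mm = 1, junction_fuse_mm = 1.5,
                            smooth_window = 5) {
  stopifnot(inherits(mask, "binary_mask"))
  graph <- skeletonize(mask)
  graph <- break_cycles(graph)
  root <- find_root(graph, mask)
  graph <- prune_spurs(graph, root, min_spur_length_mm)
  root <- find_root(graph, mask)
  tree <- decompose_branches(graph, root, junction_fuse_mm, smooth_window)
  tree <- attach_disconnected(tree, graph, mask, bridge_max_mm,
                              junction_fuse_mm, smooth_window)
  measure_tree(tree, mask, interval_mm)
}

#' Compare a measured tree against phantom ground truth
#'
#' Matches each recovered branch to the ground-truth branch whose distal
#' endpoint is nearest to the recovered branch's distal endpoint, then
#' checks that the matching is one-to-one and that parent relations and
#' generation numbers agree. For matched pairs it reports the per-branch
#' length and diameter errors.
#'
#' @param tree A measured `airway_tree`.
#' @param truth An `airway_truth` (possibly degraded).
#' @return A list: `n_recovered`, `n_truth`, `count_equal`, `bijective`,
#'   `parents_equal`, `generations_equal`, `topology_equal` (all three), and
#'   a data frame `matches` with per-branch `truth_id`, `generation_truth`,
#'   `generation_rec`, `length_truth`, `length_rec`, `radius_truth`,
#'   `mean_diameter_rec`.
#' @export
compare_tree_to_truth <- function(tree, truth) {
  stopifnot(inherits(tree, "airway_tree"), inherits(truth, "airway_truth"))
  tb <- truth$branches
  rb <- tree$branches
  tEnd <- as.matrix(tb[, c("end_x", "end_y", "end_z")])
  rEnd <- t(vapply(tree$polylines, function(p) p[nrow(p), ], numeric(3)))
  # nearest truth end for each recovered branch
  assign_idx <- integer(nrow(rb))
  for (i in seq_len(nrow(rb))) {
    dd <- colSums((t(tEnd) - rEnd[i, ])^2)
    assign_idx[i] <- which.min(dd)
  }
  bijective <- length(unique(assign_idx)) == nrow(rb) &&
    nrow(rb) == nrow(tb)
  # truth generation: for degraded truths the distal fragment of an occluded
  # branch keeps the original generation
  gen_rec <- rb$generation
  gen_tru <- tb$generation[assign_idx]
  generations_equal <- bijective && !any(is.na(gen_rec)) &&
    all(gen_rec == gen_tru)
  # parent agreement on the truth side of the mapping
  parents_equal <- bijective
  if (bijective) {
    for (i in seq_len(nrow(rb))) {
      tp <- tb$parent_id[assign_idx[i]]
      rp <- rb$parent_id[i]
      if (is.na(rp) || is.na(tp)) {
        # root of a component: both sides must agree it has no parent
        # within reach (occlusion fragments map parent to the cut piece)
        if (is.na(rp) != is.na(tp)) {
          # bridged fragments keep a parent on the recovered side
          if (!isTRUE(rb$bridged[i])) { parents_equal <- FALSE; break }
        }
        next
      }
      if (tb$branch_id[assign_idx[match(rp, rb$branch_id)]] != tp) {
        parents_equal <- FALSE
        break
      }
    }
  }
  matches <- data.frame(
    branch_id = rb$branch_id,
    truth_id = tb$branch_id[assign_idx],
    generation_truth = gen_tru,
    generation_rec = gen_rec,
    length_truth = truth_branch_length(tb)[assign_idx],
    length_rec = rb$length_mm,
    radius_truth = tb$radius_mm[assign_idx],
    mean_diameter_rec = rb$mean_diameter_mm)
  list(n_recovered = nrow(rb), n_truth = nrow(tb),
       count_equal = nrow(rb) == nrow(tb),
       bijective = bijective,
       parents_equal = parents_equal,
       generations_equal = generations_equal,
       topology_equal = bijective && parents_equal && generations_equal,
       matches = matches)
}
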