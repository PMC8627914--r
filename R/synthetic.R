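# Synthetic airway phantoms: branching-tube trees with known topology,
# generations, radii and lengths, rasterized to binary masks at CT-like
# spacing.  Degradations emulate the contrasts seen between automatic and
# corrected airway segmentations: missing distal subtrees, over-inclusive
# (dilated) lumens, and focal occlusions that split the air column.

#' Specify a synthetic airway tree
#'
#' Defines the geometry of a recursive branching-tube phantom. The root
#' branch (the trachea analogue) runs along the inferior direction so that
#' its proximal end is the most superior structure, as in a chest scan. At
#' each bifurcation every child direction is obtained by tilting the parent
#' direction by `branch_angle_deg` (plus uniform jitter) about azimuths that
#' are spread evenly among siblings and rotated by 90 degrees per generation
#' (plus jitter); the structured azimuths keep non-adjacent branches well
#' separated while the jitter varies geometry across seeds. Child length and
#' radius shrink geometrically. Growth stops at `max_generation` or when the
#' child radius would fall below `min_radius_mm`.
#'
#' Defaults are desk-scale but anatomically proportioned: homothetic
#' branching (equal length and radius ratios of 0.72) keeps the branch
#' length close to five times the lumen radius at every generation, the
#' slender aspect typical of bronchi, at 0.7 mm isotropic CT spacing.
#'
#' @param seed Integer RNG seed; identical seed and spec give identical trees.
#' @param max_generation Integer >= 0, deepest generation to grow (<= 10).
#' @param branching_factor Integer >= 1 children per bifurcation (default 2).
#' @param root_length_mm,root_radius_mm Positive reals, root branch geometry.
#' @param length_ratio,radius_ratio Reals in (0, 1]; child = parent * ratio.
#' @param branch_angle_deg Real in (0, 90), tilt of children from the parent.
#' @param angle_jitter_deg Real >= 0, uniform jitter on tilt and azimuth.
#' @param spacing_mm Positive length-3 voxel spacing used when rasterizing.
#' @param min_radius_mm Positive real; growth stops below this radius.
#' @return An object of class `tree_spec`.
#' @export
tree_spec <- function(seed = 1L,
                      max_generation = 4L,
                      branching_factor = 2L,
                      root_length_mm = 20,
                      root_radius_mm = 4,
                      length_ratio = 0.72,
                      radius_ratio = 0.72,
                      branch_angle_deg = 35,
                      angle_jitter_deg = 5,
                      spacing_mm = c(0.7, 0.7, 0.7),
                      min_radius_mm = 1) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  max_generation <- as.integer(max_generation)
  if (is.na(max_generation) || max_generation < 0L || max_generation > 10L)
    stop("'max_generation' must be an integer in [0, 10]")
  branching_factor <- as.integer(branching_factor)
  if (is.na(branching_factor) || branching_factor < 1L)
    stop("'branching_factor' must be a positive integer")
  if (root_length_mm <= 0 || root_radius_mm <= 0)
    stop("root length and radius must be positive")
  if (length_ratio <= 0 || length_ratio > 1 || radius_ratio <= 0 || radius_ratio > 1)
    stop("'length_ratio' and 'radius_ratio' must lie in (0, 1]")
  if (branch_angle_deg <= 0 || branch_angle_deg >= 90)
    stop("'branch_angle_deg' must lie in (0, 90)")
  if (angle_jitter_deg < 0) stop("'angle_jitter_deg' must be >= 0")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("'spacing_mm' must be 3 positive numbers")
  if (min_radius_mm <= 0) stop("'min_radius_mm' must be positive")
  structure(
    list(seed = as.integer(seed), max_generation = max_generation,
         branching_factor = branching_factor,
         root_length_mm = root_length_mm, root_radius_mm = root_radius_mm,
         length_ratio = length_ratio, radius_ratio = radius_ratio,
         branch_angle_deg = branch_angle_deg,
         angle_jitter_deg = angle_jitter_deg,
         spacing_mm = spacing_mm, min_radius_mm = min_radius_mm),
    class = "tree_spec")
}

new_airway_truth <- function(branches, spacing_mm) {
  structure(list(branches = branches, spacing_mm = spacing_mm),
            class = "airway_truth")
}

#' Generate a ground-truth airway tree
#'
#' Grows the recursive branching tree described by a [tree_spec()]. The
#' result is an analytic branch list (start/end points, radius, generation,
#' parent) that serves both as rasterization input and as the recovery oracle
#' for the measurement pipeline.
#'
#' @param spec A [tree_spec()].
#' @return An object of class `airway_truth`: a list with `branches`
#'   (data frame with columns `branch_id`, `parent_id`, `generation`,
#'   `component`, `start_x/y/z`, `end_x/y/z`, `radius_mm`) and `spacing_mm`.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "tree_spec"))
  if (spec$root_radius_mm < spec$min_radius_mm)
    stop("empty tree: root radius is below 'min_radius_mm'")
  deg2rad <- pi / 180

  with_seed(spec$seed, {
    rows <- list()
    # queue entries carry the branch geometry plus the tilt direction used
    # at the parent junction, so each junction branches in the plane
    # perpendicular to its parent's branching plane (alternating planes,
    # as successive airway bifurcations do)
    queue <- list(list(parent = NA_integer_, gen = 0L,
                       start = c(0, 0, 0), dir = c(0, 0, -1),
                       pvec = c(1, 0, 0),
                       len = spec$root_length_mm, rad = spec$root_radius_mm))
    next_id <- 1L
    while (length(queue) > 0L) {
      b <- queue[[1L]]
      queue <- queue[-1L]
      id <- next_id
      next_id <- next_id + 1L
      end <- b$start + b$dir * b$len
      rows[[id]] <- data.frame(
        branch_id = id, parent_id = b$parent, generation = b$gen,
        component = 0L,
        start_x = b$start[1], start_y = b$start[2], start_z = b$start[3],
        end_x = end[1], end_y = end[2], end_z = end[3],
        radius_mm = b$rad)
      child_rad <- b$rad * spec$radius_ratio
      if (b$gen < spec$max_generation && child_rad >= spec$min_radius_mm) {
        w <- unit(cross3(b$dir, b$pvec))      # tilt axis: perpendicular to
        v <- unit(cross3(b$dir, w))           # the previous branching plane
        k <- spec$branching_factor
        az0 <- runif(1, -spec$angle_jitter_deg, spec$angle_jitter_deg) * deg2rad
        for (ci in seq_len(k)) {
          theta <- (spec$branch_angle_deg +
                      runif(1, -spec$angle_jitter_deg, spec$angle_jitter_deg)) * deg2rad
          az <- az0 + (ci - 1) * 2 * pi / k
          cdir <- cos(theta) * b$dir +
            sin(theta) * (cos(az) * w + sin(az) * v)
          queue <- c(queue, list(list(
            parent = id, gen = b$gen + 1L, start = end,
            dir = unit(cdir), pvec = w,
            len = b$len * spec$length_ratio,
            rad = child_rad)))
        }
      }
    }
    branches <- do.call(rbind, rows)
    rownames(branches) <- NULL
    new_airway_truth(branches, spec$spacing_mm)
  })
}

truth_branch_length <- function(branches) {
  sqrt((branches$end_x - branches$start_x)^2 +
       (branches$end_y - branches$start_y)^2 +
       (branches$end_z - branches$start_z)^2)
}

#' Minimum surface clearance between non-adjacent branches
#'
#' Computes, over all pairs of branches that do not share an endpoint, the
#' minimum of (segment-to-segment distance - sum of radii). Positive values
#' mean the tubes are separated everywhere; the recovery guarantees of the
#' measurement pipeline assume a clearance of at least a couple of voxels.
#'
#' @param truth An `airway_truth`.
#' @return Minimum clearance in mm (`Inf` if fewer than two non-adjacent
#'   branches exist).
#' @export
branch_clearance <- function(truth) {
  b <- truth$branches
  n <- nrow(b)
  if (n < 2) return(Inf)
  S <- as.matrix(b[, c("start_x", "start_y", "start_z")])
  E <- as.matrix(b[, c("end_x", "end_y", "end_z")])
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shares <- any(c(
        isTRUE(all.equal(S[i, ], S[j, ], tolerance = 1e-9, check.attributes = FALSE)),
        isTRUE(all.equal(S[i, ], E[j, ], tolerance = 1e-9, check.attributes = FALSE)),
        isTRUE(all.equal(E[i, ], S[j, ], tolerance = 1e-9, check.attributes = FALSE)),
        isTRUE(all.equal(E[i, ], E[j, ], tolerance = 1e-9, check.attributes = FALSE))))
      if (shares) next
      d <- segment_distance(S[i, ], E[i, ], S[j, ], E[j, ]) -
        b$radius_mm[i] - b$radius_mm[j]
      if (d < best) best <- d
    }
  }
  best
}

#' @export
print.airway_truth <- function(x, ...) {
  b <- x$branches
  cat(sprintf("airway_truth: %d branches, generations 0-%d, %d component(s)\n",
              nrow(b), max(b$generation), length(unique(b$component))))
  invisible(x)
}

# Build the segment matrix consumed by the capsule rasterizer.
truth_segments <- function(branches, dilation_mm = 0) {
  cbind(branches$start_x, branches$start_y, branches$start_z,
        branches$end_x, branches$end_y, branches$end_z,
        branches$radius_mm + dilation_mm,
        if (is.null(branches$flat_start)) 0 else as.numeric(branches$flat_start),
        if (is.null(branches$flat_end)) 0 else as.numeric(branches$flat_end))
}

#' Rasterize a ground-truth tree to a binary mask
#'
#' Every branch is rendered as a capsule (cylinder with hemispherical caps):
#' a voxel is foreground iff its center lies within the branch radius of the
#' centerline segment. The grid is sized to contain every capsule plus
#' `margin_mm` of background on all sides.
#'
#' @param truth An `airway_truth`.
#' @param spacing_mm Voxel spacing (mm); defaults to the truth's spacing.
#' @param margin_mm Background margin around the tree (mm, > 0).
#' @param max_voxels Error guard on total grid size.
#' @return A [binary_mask()] with attribute `root_voxel`, the 1-based voxel
#'   index of the root branch's proximal end.
#' @export
rasterize_tree <- function(truth, spacing_mm = truth$spacing_mm,
                           margin_mm = 5, max_voxels = 2.5e8) {
  stopifnot(inherits(truth, "airway_truth"))
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (any(spacing_mm <= 0)) stop("'spacing_mm' must be positive")
  if (margin_mm <= 0) stop("'margin_mm' must be positive")
  b <- truth$branches
  segs <- truth_segments(b, dilation_mm = 0)
  lo <- pmin(apply(segs[, 1:3, drop = FALSE] - segs[, 7], 2, min),
             apply(segs[, 4:6, drop = FALSE] - segs[, 7], 2, min)) - margin_mm
  hi <- pmax(apply(segs[, 1:3, drop = FALSE] + segs[, 7], 2, max),
             apply(segs[, 4:6, drop = FALSE] + segs[, 7], 2, max)) + margin_mm
  dims <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
  if (prod(as.numeric(dims)) > max_voxels)
    stop(sprintf("tree extent needs %.0f voxels, above 'max_voxels' (%g)",
                 prod(as.numeric(dims)), max_voxels))
  vox <- cpp_rasterize_capsules(dims, lo, spacing_mm, segs)
  mask <- binary_mask(array(vox, dims), spacing_mm, origin_mm = lo)
  root <- b[is.na(b$parent_id) & b$component == 0L, ][1, ]
  start <- c(root$start_x, root$start_y, root$start_z)
  attr(mask, "root_voxel") <- as.integer(round((start - lo) / spacing_mm)) + 1L
  mask
}

#' Specify segmentation degradations
#'
#' Describes how to corrupt a ground-truth tree into an "initial,
#' incomplete"-style segmentation: random removal of whole distal subtrees
#' (missed continuations), isotropic lumen dilation (over-inclusion of the
#' airway wall), and focal occlusion gaps that split the air column into
#' disconnected components, as mucous plugging does.
#'
#' @param seed Integer RNG seed for the pruning draws.
#' @param prune_from_generation Integer generation at/after which branches
#'   may be pruned, or `NULL` for no pruning.
#' @param prune_probability Probability in \[0, 1\] that each eligible branch
#'   (still present after its ancestors' draws) is removed with its subtree.
#' @param dilation_mm Real >= 0 added to every branch radius.
#' @param occlusions List of `list(branch_id=, gap_center_fraction=,
#'   gap_length_mm=)`; each cuts a gap strictly inside the named branch.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(seed = 1L, prune_from_generation = NULL,
                             prune_probability = 0, dilation_mm = 0,
                             occlusions = list()) {
  if (!is.null(prune_from_generation)) {
    prune_from_generation <- as.integer(prune_from_generation)
    if (is.na(prune_from_generation) || prune_from_generation < 0L)
      stop("'prune_from_generation' must be a non-negative integer or NULL")
  }
  if (prune_probability < 0 || prune_probability > 1)
    stop("'prune_probability' must lie in [0, 1]")
  if (dilation_mm < 0) stop("'dilation_mm' must be >= 0")
  for (oc in occlusions) {
    if (!all(c("branch_id", "gap_center_fraction", "gap_length_mm") %in% names(oc)))
      stop("each occlusion needs branch_id, gap_center_fraction, gap_length_mm")
    if (oc$gap_center_fraction <= 0 || oc$gap_center_fraction >= 1)
      stop("'gap_center_fraction' must lie strictly in (0, 1)")
    if (oc$gap_length_mm <= 0) stop("'gap_length_mm' must be positive")
  }
  structure(
    list(seed = as.integer(seed), prune_from_generation = prune_from_generation,
         prune_probability = prune_probability, dilation_mm = dilation_mm,
         occlusions = occlusions),
    class = "degradation_spec")
}

# Remove a branch and all its descendants from a branch table.
drop_subtree <- function(branches, id) {
  drop <- id
  repeat {
    more <- branches$branch_id[branches$parent_id %in% drop &
                                 !(branches$branch_id %in% drop)]
    if (length(more) == 0L) break
    drop <- c(drop, more)
  }
  branches[!(branches$branch_id %in% drop), , drop = FALSE]
}

#' Degrade a ground-truth tree and rasterize it
#'
#' Applies a [degradation_spec()] to a truth tree and rasterizes the result.
#' Pruning removes whole subtrees (a missed branch is missed together with
#' everything distal to it). Dilation inflates all radii before
#' rasterization. An occlusion cuts a flat-faced gap out of a branch; the
#' part distal to the gap is kept in the returned truth as a separate
#' component (the segmentation beyond the plug survives, disconnected).
#'
#' @param truth An `airway_truth`.
#' @param spec A [degradation_spec()].
#' @param spacing_mm Voxel spacing for rasterization (default truth spacing).
#' @param margin_mm,max_voxels Passed to the rasterizer.
#' @return `list(mask = binary_mask, truth = airway_truth)` where `truth` is
#'   the degraded branch table (with `component` > 0 for post-occlusion
#'   fragments and dilated radii included).
#' @export
degrade_mask <- function(truth, spec, spacing_mm = truth$spacing_mm,
                         margin_mm = 5, max_voxels = 2.5e8) {
  stopifnot(inherits(truth, "airway_truth"), inherits(spec, "degradation_spec"))
  b <- truth$branches
  b$flat_start <- FALSE
  b$flat_end <- FALSE

  for (oc in spec$occlusions) {
    if (!(oc$branch_id %in% truth$branches$branch_id))
      stop(sprintf("occlusion references unknown branch_id %s", oc$branch_id))
  }

  # Pruning: draw in branch_id order for branches still present.
  if (!is.null(spec$prune_from_generation) && spec$prune_probability > 0) {
    b <- with_seed(spec$seed, {
      bb <- b
      for (id in sort(bb$branch_id)) {
        if (!(id %in% bb$branch_id)) next  # already gone with an ancestor
        row <- bb[bb$branch_id == id, ]
        if (row$generation < spec$prune_from_generation) next
        if (runif(1) < spec$prune_probability) bb <- drop_subtree(bb, id)
      }
      bb
    })
    if (nrow(b) == 0L) stop("degradation removed every branch")
  }

  # Dilation: inflate radii in the degraded truth itself, so that the
  # returned truth describes the mask that is actually rasterized.
  b$radius_mm <- b$radius_mm + spec$dilation_mm

  # Occlusions: split the branch into a proximal piece (same component) and
  # a distal piece in a fresh component; the distal subtree follows it.
  next_comp <- max(b$component) + 1L
  next_id <- max(truth$branches$branch_id) + 1L
  for (oc in spec$occlusions) {
    if (!(oc$branch_id %in% b$branch_id)) next  # pruned away
    i <- which(b$branch_id == oc$branch_id)
    row <- b[i, ]
    s <- c(row$start_x, row$start_y, row$start_z)
    e <- c(row$end_x, row$end_y, row$end_z)
    L <- vnorm(e - s)
    d <- (e - s) / L
    c0 <- oc$gap_center_fraction * L
    a <- c0 - oc$gap_length_mm / 2
    z <- c0 + oc$gap_length_mm / 2
    if (a <= 0 || z >= L)
      stop(sprintf("occlusion gap on branch %d falls outside the branch interior",
                   oc$branch_id))
    pcut <- s + d * a
    dcut <- s + d * z
    # proximal piece keeps the id; flat distal face
    b[i, c("end_x", "end_y", "end_z")] <- as.list(pcut)
    b$flat_end[i] <- TRUE
    distal <- row
    distal$branch_id <- next_id
    distal$parent_id <- row$branch_id
    distal[, c("start_x", "start_y", "start_z")] <- as.list(dcut)
    distal$component <- next_comp
    distal$flat_start <- TRUE
    distal$flat_end <- FALSE
    b <- rbind(b, distal)
    # distal subtree: reattach children to the distal piece, relabel component
    kids <- drop_ids <- integer(0)
    kids <- b$branch_id[!is.na(b$parent_id) & b$parent_id == row$branch_id &
                          b$branch_id != next_id]
    sub <- kids
    repeat {
      more <- b$branch_id[b$parent_id %in% sub & !(b$branch_id %in% sub)]
      if (length(more) == 0L) break
      sub <- c(sub, more)
    }
    b$parent_id[b$branch_id %in% kids] <- next_id
    b$component[b$branch_id %in% sub] <- next_comp
    next_comp <- next_comp + 1L
    next_id <- next_id + 1L
  }

  dtruth <- new_airway_truth(b, truth$spacing_mm)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)

  segs <- truth_segments(b, dilation_mm = 0)
  lo <- pmin(apply(segs[, 1:3, drop = FALSE] - segs[, 7], 2, min),
             apply(segs[, 4:6, drop = FALSE] - segs[, 7], 2, min)) - margin_mm
  hi <- pmax(apply(segs[, 1:3, drop = FALSE] + segs[, 7], 2, max),
             apply(segs[, 4:6, drop = FALSE] + segs[, 7], 2, max)) + margin_mm
  dims <- as.integer(ceiling((hi - lo) / spacing_mm)) + 1L
  if (prod(as.numeric(dims)) > max_voxels)
    stop(sprintf("tree extent needs %.0f voxels, above 'max_voxels' (%g)",
                 prod(as.numeric(dims)), max_voxels))
  vox <- cpp_rasterize_capsules(dims, lo, spacing_mm, segs)
  mask <- binary_mask(array(vox, dims), spacing_mm, origin_mm = lo)
  root <- b[is.na(b$parent_id) & b$component == 0L, ][1, ]
  attr(mask, "root_voxel") <-
    as.integer(round((c(root$start_x, root$start_y, root$start_z) - lo) / spacing_mm)) + 1L
  list(mask = mask, truth = dtruth)
}
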