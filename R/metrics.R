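# Branch length and lumen diameter.
#
# Lumen diameter is measured as twice the Euclidean distance from a
# centerline point to the background (the inscribed-sphere diameter), read
# from an exact anisotropic distance transform by trilinear interpolation
# and sampled every millimetre of arc length along the branch; the
# per-branch value is the unweighted mean of those samples.  Branch length
# is the cumulative arc length of the centerline polyline between
# bifurcations.

#' Euclidean distance field of a mask
#'
#' Exact Euclidean distance transform in physical millimetres (anisotropic
#' spacing respected): each foreground voxel carries the distance from its
#' center to the nearest background voxel center; background voxels are 0.
#'
#' @param mask A non-empty [binary_mask()].
#' @return A `distance_field` with the mask's geometry.
#' @export
compute_distance_field <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("cannot compute a distance field of an empty mask")
  d <- dim(mask$voxels)
  vals <- array(cpp_edt(as.vector(mask$voxels), d, mask$spacing_mm), d)
  structure(list(values = vals, spacing_mm = mask$spacing_mm,
                 origin_mm = mask$origin_mm, orientation = mask$orientation),
            class = "distance_field")
}

#' @export
print.distance_field <- function(x, ...) {
  cat(sprintf("distance_field: %s voxels, max distance %.2f mm\n",
              paste(dim(x$values), collapse = " x "), max(x$values)))
  invisible(x)
}

#' Resample a polyline at fixed arc-length intervals
#'
#' Samples are placed at arc positions 0, interval, 2 * interval, ... up to
#' the polyline length (position 0 always included; the distal endpoint only
#' when the total length is a multiple of the interval), with linear
#' interpolation between vertices. Consecutive samples are therefore exactly
#' `interval_mm` apart in arc length.
#'
#' @param polyline n x 3 matrix of ordered points (mm), n >= 2.
#' @param interval_mm Positive sampling interval (default 1 mm).
#' @return m x 3 matrix of sample points with attribute `arc_mm`.
#' @export
resample_centerline <- function(polyline, interval_mm = 1) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline must have at least 2 points")
  if (interval_mm <= 0) stop("'interval_mm' must be positive")
  seg <- sqrt(rowSums((polyline[-1, , drop = FALSE] -
                         polyline[-nrow(polyline), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  nsmp <- floor(L / interval_mm + 1e-9)
  pos <- (0:nsmp) * interval_mm
  out <- matrix(NA_real_, length(pos), 3)
  for (ii in seq_along(pos)) {
    p <- min(pos[ii], L)
    s <- findInterval(p, cum, rightmost.closed = TRUE)
    s <- min(max(s, 1L), length(seg))
    t <- if (seg[s] > 0) (p - cum[s]) / seg[s] else 0
    out[ii, ] <- (1 - t) * polyline[s, ] + t * polyline[s + 1, ]
  }
  attr(out, "arc_mm") <- pos
  out
}

#' Lumen diameter at a point
#'
#' Twice the trilinearly interpolated distance-field value at a physical
#' point: the diameter of the sphere inscribed in the lumen at that
#' location. A point that falls on background (interpolated distance 0)
#' returns 0 with a warning, since it indicates a skeleton/mask mismatch.
#'
#' @param field A `distance_field`.
#' @param point_mm Length-3 physical coordinate (mm), inside the grid.
#' @return Diameter in mm.
#' @export
lumen_diameter_at <- function(field, point_mm) {
  v <- interp_field(field, matrix(point_mm, 1, 3))
  if (v <= 0) {
    warning("centerline point lies on background (distance 0)")
    return(0)
  }
  2 * v
}

# Trilinear interpolation of the distance field at an n x 3 matrix of
# physical points.  Errors if any point lies outside the voxel-center grid.
interp_field <- function(field, pts) {
  d <- dim(field$values)
  t <- sweep(sweep(pts, 2, field$origin_mm, "-"), 2, field$spacing_mm, "/")
  if (any(t < -1e-9) || any(sweep(t, 2, d - 1, "-") > 1e-9))
    stop("point outside the distance-field grid")
  t <- pmax(t, 0)
  t <- sweep(t, 2, d - 1, pmin)
  i0 <- pmin(floor(t), matrix(rep(d - 2, each = nrow(t)), ncol = 3))
  i0 <- pmax(i0, 0)
  f <- t - i0
  v <- numeric(nrow(pts))
  for (r in seq_len(nrow(pts))) {
    c000 <- i0[r, ] + 1  # 1-based corner
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[r, 1] else 1 - f[r, 1]) *
           (if (dy) f[r, 2] else 1 - f[r, 2]) *
           (if (dz) f[r, 3] else 1 - f[r, 3])
      if (w > 0)
        acc <- acc + w * field$values[c000[1] + dx, c000[2] + dy, c000[3] + dz]
    }
    v[r] <- acc
  }
  v
}

#' Measure one branch
#'
#' Fills in the measurements for a single branch polyline: diameter samples
#' every `interval_mm` of arc length, their unweighted mean, and the branch
#' length (cumulative polyline arc length). A branch shorter than the
#' sampling interval receives exactly one sample, at its proximal end.
#'
#' @param polyline n x 3 matrix of centerline points (mm), proximal first.
#' @param field A `distance_field` from [compute_distance_field()].
#' @param interval_mm Sampling interval (default 1 mm).
#' @return `list(length_mm, diameter_samples_mm, mean_diameter_mm, arc_mm)`.
#' @export
measure_branch <- function(polyline, field, interval_mm = 1) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) {
    smp <- polyline[1, , drop = FALSE]
    attr(smp, "arc_mm") <- 0
  } else {
    smp <- resample_centerline(polyline, interval_mm)
  }
  dia <- 2 * interp_field(field, smp)
  if (any(dia <= 0))
    warning("some centerline samples lie on background (distance 0)")
  list(length_mm = polyline_length(polyline),
       diameter_samples_mm = dia,
       mean_diameter_mm = mean(dia),
       arc_mm = attr(smp, "arc_mm"))
}

# Caliber-profile tip localization.  A free tube end is where the lumen
# caliber collapses: walking along the centerline towards (and, if need be,
# straight past) the skeleton tip, the distance-field value stays near the
# branch radius inside the tube and falls off once the rounded end is
# reached.  The skeleton itself ends anywhere within about one radius of
# the true end -- it may freeze a spike into the rounded tip or stop short
# while the distance value is still large -- so the branch end is relocated
# to the outermost point whose interpolated distance value still reaches
# the branch's median caliber minus half a voxel.  Junction-facing ends are
# never touched.
fix_tip_points <- function(pts, field, at_start) {
  if (nrow(pts) < 3) return(pts)
  idx <- if (at_start) seq_len(nrow(pts)) else rev(seq_len(nrow(pts)))
  p <- pts[idx, , drop = FALSE]                 # tip-first orientation
  seg <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))                      # arc distance from the tip
  vox <- mean(field$spacing_mm)
  r_all <- interp_field(field, p)
  r_b <- median(r_all)
  thr <- r_b - 0.5 * vox
  if (thr <= 0) return(pts)
  cand <- which(r_all >= thr)
  if (length(cand) == 0L) return(pts)
  j <- cand[1]                                  # vertex nearest the tip at caliber
  dir_ext <- unit(p[1, ] - p[2, ])              # straight continuation past tip
  lo <- field$origin_mm
  hi <- field$origin_mm + (dim(field$values) - 1) * field$spacing_mm
  position <- function(t) {
    if (t >= 0) {
      s <- findInterval(t, arc, rightmost.closed = TRUE)
      s <- min(max(s, 1L), length(seg))
      f <- if (seg[s] > 0) (t - arc[s]) / seg[s] else 0
      (1 - f) * p[s, ] + f * p[s + 1, ]
    } else {
      p[1, ] + (-t) * dir_ext
    }
  }
  step <- 0.25 * vox
  t_last <- arc[j]
  t <- arc[j] - step
  t_min <- -(r_b + 2 * vox)
  while (t >= t_min) {
    q <- position(t)
    if (any(q < lo) || any(q > hi)) break
    if (interp_field(field, matrix(q, 1, 3)) < thr) break
    t_last <- t
    t <- t - step
  }
  keep <- which(arc > t_last + 1e-9)
  if (length(keep) < 2) keep <- (nrow(p) - 1):nrow(p)
  out <- rbind(position(t_last), p[keep, , drop = FALSE])
  if (at_start) out else out[rev(seq_len(nrow(out))), , drop = FALSE]
}

# Bifurcation-point refinement.  The skeleton junction node sits inside the
# inflated union of parent and daughter lumens and can sit a millimetre or
# two away from the anatomical carina, proximally or distally.  Airway
# branches are locally straight, so the carina is re-estimated as the
# least-squares intersection of the branch axes fitted just outside the
# junction ball (the region within one junction-ball radius of the node is
# excluded from the fits), and the shared end/start points of the incident
# polylines are moved there.
refine_junction_points <- function(tree, field) {
  vox <- mean(field$spacing_mm)
  br <- tree$branches
  for (j in seq_len(nrow(br))) {
    kids <- which(!is.na(br$parent_id) & br$parent_id == br$branch_id[j] &
                    !br$bridged & br$component == br$component[j])
    if (length(kids) < 2L) next
    pj <- tree$polylines[[j]]
    if (nrow(pj) < 3) next
    Jpt <- pj[nrow(pj), ]
    r_j <- max(interp_field(field, matrix(Jpt, 1, 3)), vox)
    clear <- r_j
    fit_len <- max(2, 1.5 * r_j)
    # a chain portion [clear, clear + fit_len] away from the junction
    portion <- function(pts, from_end) {
      if (from_end) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      arc <- c(0, cumsum(seg))
      sel <- which(arc >= clear & arc <= clear + fit_len)
      if (length(sel) < 2) sel <- which(arc >= min(clear, max(arc) / 2))
      if (length(sel) < 2) return(NULL)
      pts[sel, , drop = FALSE]
    }
    lines <- list()
    pp <- portion(pj, TRUE)
    if (is.null(pp)) next
    lines[[1]] <- list(a = pp[1, ], d = unit(pp[1, ] - pp[nrow(pp), ]))
    ok <- TRUE
    for (ki in kids) {
      pk <- tree$polylines[[ki]]
      if (nrow(pk) < 3 || sqrt(sum((pk[1, ] - Jpt)^2)) > 2 * vox) { ok <- FALSE; break }
      pc <- portion(pk, FALSE)
      if (is.null(pc)) { ok <- FALSE; break }
      lines[[length(lines) + 1L]] <- list(a = pc[1, ], d = unit(pc[nrow(pc), ] - pc[1, ]))
    }
    if (!ok) next
    # least-squares point closest to all fitted axes
    A <- matrix(0, 3, 3); b <- numeric(3)
    for (ln in lines) {
      P <- diag(3) - tcrossprod(ln$d)
      A <- A + P
      b <- b + P %*% ln$a
    }
    x <- try(solve(A, b), silent = TRUE)
    if (inherits(x, "try-error")) next
    x <- as.numeric(x)
    if (sqrt(sum((x - Jpt)^2)) > 1.5 * r_j) next  # implausible: keep the node
    # rebuild the incident chain ends outside the junction ball
    cut_to <- function(pts, from_end, newpt) {
      if (from_end) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      arc <- c(0, cumsum(seg))
      keep <- which(arc > clear)
      if (length(keep) < 2) keep <- (nrow(pts) - 1):nrow(pts)
      out <- rbind(newpt, pts[keep, , drop = FALSE])
      if (from_end) out[rev(seq_len(nrow(out))), , drop = FALSE] else out
    }
    tree$polylines[[j]] <- cut_to(pj, TRUE, x)
    for (ki in kids) tree$polylines[[ki]] <- cut_to(tree$polylines[[ki]], FALSE, x)
  }
  tree
}

#' Measure every branch of an airway tree
#'
#' Fills in per-branch length, diameter samples and mean diameter. With
#' `refine_tips = TRUE` (the default), branch ends that are free skeleton
#' endpoints (the proximal trachea end and every terminal tip) are first
#' relocated by the caliber-profile rule: the branch is ended at the
#' outermost centerline point (walking along the skeleton chain and its
#' straight continuation) where the lumen radius still reaches the branch's
#' median caliber minus half a voxel, which removes the roughly one-radius
#' tip uncertainty that thinning leaves at free tube ends.
#'
#' @param tree An `airway_tree`.
#' @param mask_or_field The source [binary_mask()] or a precomputed
#'   `distance_field`.
#' @param interval_mm Sampling interval along the centerline (default 1 mm).
#' @param refine_tips Apply caliber-profile tip localization (default `TRUE`).
#' @param refine_junctions Relocate bifurcation points to the least-squares
#'   intersection of the locally fitted branch axes (default `TRUE`).
#' @return The `airway_tree` with `length_mm`, `mean_diameter_mm`,
#'   `n_samples` and per-branch diameter samples filled in.
#' @export
measure_tree <- function(tree, mask_or_field, interval_mm = 1,
                         refine_tips = TRUE, refine_junctions = TRUE) {
  stopifnot(inherits(tree, "airway_tree"))
  field <- if (inherits(mask_or_field, "distance_field")) mask_or_field
           else compute_distance_field(mask_or_field)
  if (refine_junctions) tree <- refine_junction_points(tree, field)
  for (i in seq_len(nrow(tree$branches))) {
    p <- tree$polylines[[i]]
    if (refine_tips && nrow(p) >= 3) {
      if (isTRUE(tree$branches$tip_prox[i])) p <- fix_tip_points(p, field, TRUE)
      if (isTRUE(tree$branches$tip_dist[i])) p <- fix_tip_points(p, field, FALSE)
      tree$polylines[[i]] <- p
    }
    m <- measure_branch(p, field, interval_mm)
    tree$branches$length_mm[i] <- m$length_mm
    tree$branches$mean_diameter_mm[i] <- m$mean_diameter_mm
    tree$branches$n_samples[i] <- length(m$diameter_samples_mm)
    tree$diameters[[i]] <- m$diameter_samples_mm
  }
  tree
}
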