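# Independent brute-force oracles used across the test files.  These stay
# deliberately naive -- recursion, exhaustive scans, full enumeration -- so
# they share no code path with the package internals they check.

# Branch count of the recursive growth process by direct recursion over the
# stopping rule (generation cap and minimum radius).
oracle_branch_count <- function(max_generation, branching_factor,
                                root_radius, radius_ratio, min_radius) {
  count_from <- function(gen, radius) {
    if (radius < min_radius) return(0L)
    n <- 1L
    if (gen < max_generation) {
      child <- radius * radius_ratio
      if (child >= min_radius)
        n <- n + branching_factor * count_from(gen + 1L, child)
    }
    n
  }
  count_from(0L, root_radius)
}

# Connected components of a voxel set under 26-connectivity, via igraph on
# an explicitly constructed voxel adjacency graph.
oracle_components26 <- function(voxels) {
  idx <- which(voxels)
  if (length(idx) == 0L) return(0L)
  d <- dim(voxels)
  ijk <- arrayInd(idx, d)
  id <- array(0L, d)
  id[idx] <- seq_along(idx)
  edges <- NULL
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    q <- cbind(ijk[, 1] + dx, ijk[, 2] + dy, ijk[, 3] + dz)
    ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
      q[, 3] >= 1 & q[, 3] <= d[3]
    if (!any(ok)) next
    a <- id[ijk[ok, , drop = FALSE]]
    b <- id[q[ok, , drop = FALSE]]
    keep <- b > 0L
    if (any(keep)) edges <- rbind(edges, cbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$no
}

# All-pairs Euclidean distance transform (anisotropic) by exhaustive scan.
oracle_edt <- function(voxels, spacing) {
  d <- dim(voxels)
  fg <- which(voxels)
  bg <- which(!voxels)
  out <- array(0, d)
  if (length(bg) == 0L) stop("oracle needs background voxels")
  fgc <- sweep(arrayInd(fg, d) - 1, 2, spacing, "*")
  bgc <- sweep(arrayInd(bg, d) - 1, 2, spacing, "*")
  for (i in seq_along(fg)) {
    dif <- sweep(bgc, 2, fgc[i, ], "-")
    out[fg[i]] <- sqrt(min(rowSums(dif^2)))
  }
  out
}

# Exact two-sided signed-rank p-value by full enumeration of the 2^n sign
# assignments, with Wilcoxon's conventions (zeros dropped, average ranks).
oracle_wilcoxon <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wplus <- as.vector(signs %*% r)
  p <- 2 * mean(wplus <= w_obs + 1e-12)
  list(statistic = w_obs, p_value = min(1, p))
}

# Foreground count of a capsule by brute-force point-in-capsule testing at
# every voxel center of the given grid.
oracle_capsule_count <- function(dims, origin, spacing, a, b, r) {
  cnt <- 0L
  ab <- b - a
  vv <- sum(ab^2)
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
    p <- origin + (c(i, j, k) - 1) * spacing
    t <- if (vv > 0) sum((p - a) * ab) / vv else 0
    t <- min(max(t, 0), 1)
    if (sum((p - (a + t * ab))^2) <= r^2 + 1e-12) cnt <- cnt + 1L
  }
  cnt
}

# Small straight-tube phantom helpers -------------------------------------

single_branch_truth <- function(len = 20, r = 2, spacing = c(1, 1, 1),
                                dir = c(0, 0, -1), start = c(0, 0, 0)) {
  end <- start + dir * len
  branches <- data.frame(
    branch_id = 1L, parent_id = NA_integer_, generation = 0L, component = 0L,
    start_x = start[1], start_y = start[2], start_z = start[3],
    end_x = end[1], end_y = end[2], end_z = end[3], radius_mm = r)
  structure(list(branches = branches, spacing_mm = spacing),
            class = "airway_truth")
}

# Y-shaped truth: one parent and two children at +-45 degrees.
y_truth <- function(r = 2, spacing = c(1, 1, 1)) {
  s <- sqrt(2) / 2
  branches <- data.frame(
    branch_id = 1:3,
    parent_id = c(NA_integer_, 1L, 1L),
    generation = c(0L, 1L, 1L),
    component = 0L,
    start_x = c(0, 0, 0), start_y = c(0, 0, 0), start_z = c(0, -15, -15),
    end_x = c(0, 12 * s, -12 * s), end_y = c(0, 0, 0),
    end_z = c(-15, -15 - 12 * s, -15 - 12 * s),
    radius_mm = r)
  structure(list(branches = branches, spacing_mm = spacing),
            class = "airway_truth")
}

# Shared measured phantom, built once per test run (used by several files).
phantom_cache <- new.env(parent = emptyenv())
measured_phantom <- function(seed = 1, max_generation = 2) {
  key <- paste0("p", seed, "_", max_generation)
  if (!is.null(phantom_cache[[key]])) return(phantom_cache[[key]])
  truth <- generate_tree(tree_spec(seed = seed, max_generation = max_generation))
  mask <- rasterize_tree(truth)
  tree <- measure_airways(mask)
  res <- list(truth = truth, mask = mask, tree = tree)
  phantom_cache[[key]] <- res
  res
}
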