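# Branch decomposition of the centerline graph and the airway_tree class.

new_airway_tree <- function(branches, polylines, diameters, root_branch_id,
                            root_node, graph) {
  structure(list(branches = branches, polylines = polylines,
                 diameters = diameters, root_branch_id = root_branch_id,
                 root_node = root_node,
                 spacing_mm = graph$spacing_mm, origin_mm = graph$origin_mm,
                 orientation = graph$orientation),
            class = "airway_tree")
}

# Walk maximal chains of a component from a set of marker nodes.
# Returns raw branches: list(prox, dist, nodes, parent_raw).
chain_decompose <- function(graph, root) {
  adj <- cg_adjacency(graph)
  deg <- cg_degree(graph)
  n <- nrow(graph$nodes)
  if (!root %in% graph$nodes$node_id) stop("root node is not in the graph")
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  raw <- list()
  queue <- list(list(node = root, parent_raw = NA_integer_))
  while (length(queue) > 0L) {
    it <- queue[[1L]]
    queue <- queue[-1L]
    m <- it$node
    for (nb in sort(adj[[m]])) {
      if (exists(ekey(m, nb), envir = visited_edge)) next
      assign(ekey(m, nb), TRUE, envir = visited_edge)
      chain <- c(m, nb)
      prev <- m
      cur <- nb
      while (deg[cur] == 2L) {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0L) break
        nxt <- nxt[1]
        if (exists(ekey(cur, nxt), envir = visited_edge)) break
        assign(ekey(cur, nxt), TRUE, envir = visited_edge)
        chain <- c(chain, nxt)
        prev <- cur
        cur <- nxt
      }
      id <- length(raw) + 1L
      raw[[id]] <- list(prox = m, dist = cur, nodes = chain,
                        parent_raw = it$parent_raw)
      if (deg[cur] >= 3L)
        queue <- c(queue, list(list(node = cur, parent_raw = id)))
    }
  }
  raw
}

branch_polyline <- function(graph, node_ids, smooth_window = 0) {
  pts <- as.matrix(graph$nodes[match(node_ids, graph$nodes$node_id),
                               c("x", "y", "z")])
  dimnames(pts) <- NULL
  if (smooth_window >= 3 && nrow(pts) > 2) {
    w <- smooth_window
    half <- floor(w / 2)
    sm <- pts
    for (i in 2:(nrow(pts) - 1)) {
      lo <- max(1, i - half)
      hi <- min(nrow(pts), i + half)
      sm[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
    }
    pts <- sm
  }
  pts
}

#' Decompose a centerline graph into generation-numbered branches
#'
#' Branches are the maximal chains between the root, junction nodes (degree
#' >= 3) and leaves, oriented proximal to distal; junction nodes are shared
#' between a parent and its children, so branch lengths are additive along
#' paths. The root branch has generation 0 and every bifurcation event
#' increments the generation of all its daughter branches by one; a junction
#' of degree d spawns d - 1 daughters at the same generation, so a
#' voxel-level trifurcation does not double-increment. Junction nodes closer
#' together than `junction_fuse_mm` along the skeleton are treated as one
#' bifurcation event (thinning occasionally smears a single anatomical
#' bifurcation over two adjacent voxels); the sub-voxel connecting chain is
#' dropped from the branch list.
#'
#' @param graph An acyclic, spur-pruned `centerline_graph`.
#' @param root Root `node_id` (see [find_root()]).
#' @param junction_fuse_mm Junction-merging scale (mm); about two voxel
#'   steps at CT spacing by default.
#' @param smooth_window Odd integer >= 3 to smooth branch polylines with a
#'   centered moving average (endpoints fixed); 0 keeps the raw voxel chain.
#' @return An `airway_tree`: branch table (`branch_id`, `parent_id`,
#'   `component`, `generation`, `length_mm`, ...) plus one proximal-to-distal
#'   polyline per branch.
#' @export
decompose_branches <- function(graph, root, junction_fuse_mm = 1.5,
                               smooth_window = 5) {
  stopifnot(inherits(graph, "centerline_graph"))
  comp <- igraph::components(cg_igraph(graph))$membership
  keep <- which(comp == comp[root])
  sub <- cg_subset_nodes(graph, keep)
  root_sub <- match(root, sub$nodes$old_id)
  old_ids <- sub$nodes$old_id
  sub$nodes$old_id <- NULL

  raw <- chain_decompose(sub, root_sub)
  res <- finalize_branches(sub, raw, junction_fuse_mm, smooth_window,
                           base_generation = 0L)
  branches <- res$branches
  branches$component <- 0L
  branches$bridged <- FALSE
  # map node references back to the full graph's ids
  branches$prox_node <- old_ids[branches$prox_node]
  branches$dist_node <- old_ids[branches$dist_node]
  new_airway_tree(branches, res$polylines,
                  vector("list", nrow(branches)),
                  root_branch_id = 1L, root_node = root, graph = graph)
}

# Turn raw chains into the final branch table: fuse sub-voxel junction
# chains, assign generations from parent links, renumber breadth-first.
finalize_branches <- function(graph, raw, junction_fuse_mm, smooth_window,
                              base_generation = 0L) {
  nb <- length(raw)
  deg <- cg_degree(graph)
  if (nb == 0L) {
    # single-node component: synthesize one degenerate branch at the root
    pt <- as.matrix(graph$nodes[, c("x", "y", "z")])
    dimnames(pt) <- NULL
    branches <- data.frame(branch_id = 1L, parent_id = NA_integer_,
                           generation = base_generation, length_mm = 0,
                           mean_diameter_mm = NA_real_, n_samples = NA_integer_,
                           prox_node = graph$nodes$node_id[1],
                           dist_node = graph$nodes$node_id[1],
                           tip_prox = TRUE, tip_dist = TRUE)
    return(list(branches = branches, polylines = list(pt[1, , drop = FALSE])))
  }
  parent <- vapply(raw, function(b) b$parent_raw, integer(1))
  len <- vapply(raw, function(b)
    polyline_length(branch_polyline(graph, b$nodes, 0)), numeric(1))
  has_child <- seq_len(nb) %in% parent[!is.na(parent)]
  alive <- rep(TRUE, nb)
  # fuse: internal branches shorter than the junction scale are collapsed,
  # their children re-attached to the grandparent (one bifurcation event)
  repeat {
    cand <- which(alive & has_child & !is.na(parent) & len < junction_fuse_mm)
    if (length(cand) == 0L) break
    b <- cand[1]
    kids <- which(alive & !is.na(parent) & parent == b)
    parent[kids] <- parent[b]
    alive[b] <- FALSE
  }
  keep <- which(alive)
  # breadth-first renumbering for deterministic ids
  old2new <- integer(nb)
  order_bfs <- integer(0)
  frontier <- keep[is.na(parent[keep])]
  while (length(frontier) > 0L) {
    order_bfs <- c(order_bfs, frontier)
    frontier <- keep[!is.na(parent[keep]) & parent[keep] %in% frontier &
                       !(keep %in% order_bfs)]
  }
  old2new[order_bfs] <- seq_along(order_bfs)
  gen <- rep(NA_integer_, nb)
  for (b in order_bfs) {
    gen[b] <- if (is.na(parent[b])) base_generation else gen[parent[b]] + 1L
  }
  branches <- data.frame(
    branch_id = old2new[order_bfs],
    parent_id = ifelse(is.na(parent[order_bfs]), NA_integer_,
                       old2new[parent[order_bfs]]),
    generation = gen[order_bfs],
    length_mm = NA_real_,
    mean_diameter_mm = NA_real_,
    n_samples = NA_integer_,
    prox_node = vapply(raw[order_bfs], function(b) b$prox, integer(1)),
    dist_node = vapply(raw[order_bfs], function(b) b$dist, integer(1)))
  branches$tip_prox <- deg[branches$prox_node] <= 1L
  branches$tip_dist <- deg[branches$dist_node] <= 1L
  polylines <- lapply(raw[order_bfs], function(b)
    branch_polyline(graph, b$nodes, smooth_window))
  branches$length_mm <- vapply(polylines, polyline_length, numeric(1))
  list(branches = branches, polylines = polylines)
}

#' Attach disconnected skeleton components to the main tree
#'
#' Occlusions (e.g. mucous plugging) split an airway into components the
#' skeleton cannot connect. A secondary component is bridged back onto the
#' tree when its air column comes within `bridge_max_mm` of the main
#' component's air column (the gap is measured between mask foreground
#' voxels, since skeleton endpoints retreat unpredictably at occlusion
#' faces); the bridge is attached at the nearest pair of skeleton
#' endpoints. Bridged branches get generations that continue across the
#' bridge (a degree-1 to degree-1 bridge is a continuation, not a
#' bifurcation), their parent link points at the bridged main-tree branch,
#' and the bridge gap itself contributes no length. Components beyond
#' `bridge_max_mm` keep generation `NA` ("unassigned") and a positive
#' component label; all their branches remain in the branch list.
#'
#' @param tree An `airway_tree` from [decompose_branches()].
#' @param graph The full (cycle-broken, spur-pruned) `centerline_graph`.
#' @param mask The originating [binary_mask()].
#' @param bridge_max_mm Maximum bridging distance (mm); 0 disables bridging.
#' @param junction_fuse_mm,smooth_window As in [decompose_branches()].
#' @return The `airway_tree` with all components' branches listed.
#' @export
attach_disconnected <- function(tree, graph, mask, bridge_max_mm = 5,
                                junction_fuse_mm = 1.5, smooth_window = 5) {
  stopifnot(inherits(tree, "airway_tree"), inherits(graph, "centerline_graph"))
  comp <- igraph::components(cg_igraph(graph))$membership
  main <- comp[tree$root_node]
  others <- setdiff(unique(comp), main)
  if (length(others) == 0L) return(tree)
  sizes <- vapply(others, function(cc) sum(comp == cc), integer(1))
  others <- others[order(-sizes, others)]

  deg <- cg_degree(graph)
  main_ends <- which(comp == main & deg <= 1L)
  P <- as.matrix(graph$nodes[, c("x", "y", "z")])

  # air-column gap: distance from every voxel to the main mask component
  d <- dim(mask$voxels)
  lab <- array(cpp_label26(as.vector(mask$voxels), d), d)
  root_node <- graph$nodes[tree$root_node, ]
  main_lab <- lab[root_node$i, root_node$j, root_node$k]
  dist_to_main <- array(cpp_edt(as.vector(lab != main_lab), d, mask$spacing_mm), d)

  next_id <- max(tree$branches$branch_id)
  for (ci in seq_along(others)) {
    cc <- others[ci]
    cnodes <- which(comp == cc)
    cends <- cnodes[deg[cnodes] <= 1L]
    if (length(cends) == 0L) cends <- cnodes
    # nearest endpoint pair between this component and the main tree
    dmat <- as.matrix(dist(rbind(P[cends, , drop = FALSE],
                                 P[main_ends, , drop = FALSE])))
    dmat <- dmat[seq_along(cends), length(cends) + seq_along(main_ends),
                 drop = FALSE]
    best <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
    comp_lab <- lab[graph$nodes$i[cnodes[1]], graph$nodes$j[cnodes[1]],
                    graph$nodes$k[cnodes[1]]]
    gap <- min(dist_to_main[lab == comp_lab])
    bridged <- bridge_max_mm > 0 && gap <= bridge_max_mm
    if (bridged) {
      entry <- cends[best[1]]
      attach_node <- main_ends[best[2]]
      bidx <- which(tree$branches$dist_node == attach_node)
      if (length(bidx) == 0L)
        bidx <- which(tree$branches$prox_node == attach_node)
      base_branch <- tree$branches$branch_id[bidx[1]]
      g0 <- tree$branches$generation[bidx[1]]
      entry_deg <- deg[entry]
      base_gen <- if (entry_deg <= 1L) g0 else g0 + 1L
    } else {
      # deterministic proximal end: most superior endpoint, lowest id tie
      sup <- superior_axis(mask)
      coord <- P[cends, sup$axis] * sup$sign
      entry <- cends[order(-coord, cends)][1]
      base_branch <- NA_integer_
      base_gen <- 0L
    }
    sub <- cg_subset_nodes(graph, cnodes)
    old_ids <- sub$nodes$old_id
    sub$nodes$old_id <- NULL
    entry_sub <- match(entry, old_ids)
    raw <- chain_decompose(sub, entry_sub)
    res <- finalize_branches(sub, raw, junction_fuse_mm, smooth_window,
                             base_generation = base_gen)
    b <- res$branches
    b$prox_node <- old_ids[b$prox_node]
    b$dist_node <- old_ids[b$dist_node]
    b$component <- ci
    b$bridged <- bridged
    if (!bridged) b$generation <- NA_integer_
    # renumber into the global id space; roots of the component attach to
    # the bridged main branch (or stay parentless when unassigned)
    b$parent_id <- ifelse(is.na(b$parent_id), NA_integer_,
                          b$parent_id + next_id)
    b$branch_id <- b$branch_id + next_id
    if (bridged) b$parent_id[is.na(b$parent_id)] <- base_branch
    next_id <- max(b$branch_id)
    tree$branches <- rbind(tree$branches,
                           b[, names(tree$branches), drop = FALSE])
    tree$polylines <- c(tree$polylines, res$polylines)
    tree$diameters <- c(tree$diameters, vector("list", nrow(b)))
  }
  rownames(tree$branches) <- NULL
  tree
}

#' @export
print.airway_tree <- function(x, ...) {
  b <- x$branches
  g <- b$generation
  cat(sprintf("airway_tree: %d branches (%d unassigned), generations 0-%s, total length %.1f mm\n",
              nrow(b), sum(is.na(g)),
              if (all(is.na(g))) "-" else max(g, na.rm = TRUE),
              sum(b$length_mm)))
  invisible(x)
}

#' @export
summary.airway_tree <- function(object, ...) {
  summarize_segmentation(object, subject_id = "tree", variant = "tree")
}

#' Branch table of an airway tree
#'
#' @param tree An `airway_tree`.
#' @return A data frame with one row per branch: `branch_id`, `parent_id`,
#'   `component`, `generation`, `length_mm`, `mean_diameter_mm`, `n_samples`.
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "airway_tree"))
  tree$branches[, c("branch_id", "parent_id", "component", "generation",
                    "length_mm", "mean_diameter_mm", "n_samples")]
}

#' Plot an airway tree projection
#'
#' Draws the branch centerlines projected on a coordinate plane, colored by
#' generation (unassigned branches in grey).
#'
#' @param x An `airway_tree`.
#' @param plane Two axes to project on, default `c(1, 3)` (x-z, a coronal
#'   view with the trachea on top).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.airway_tree <- function(x, plane = c(1, 3), ...) {
  pts <- do.call(rbind, x$polylines)
  gmax <- suppressWarnings(max(x$branches$generation, na.rm = TRUE))
  if (!is.finite(gmax)) gmax <- 0
  pal <- grDevices::hcl.colors(gmax + 1, "viridis")
  graphics::plot(pts[, plane[1]], pts[, plane[2]], type = "n",
                 xlab = c("x", "y", "z")[plane[1]],
                 ylab = c("x", "y", "z")[plane[2]], asp = 1, ...)
  for (i in seq_len(nrow(x$branches))) {
    p <- x$polylines[[i]]
    g <- x$branches$generation[i]
    graphics::lines(p[, plane[1]], p[, plane[2]],
                    col = if (is.na(g)) "grey60" else pal[g + 1], lwd = 2)
  }
  invisible(x)
}
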