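# From binary mask to rooted branch decomposition.
#
# The centerline graph is the 26-adjacency graph of the 1-voxel-wide
# skeleton produced by topology-preserving thinning.  Loops (which thinning
# preserves when the mask itself has handles) are broken by keeping a
# maximum-total-length spanning tree; short terminal chains are pruned as
# thinning artifacts; the remainder is decomposed into branches between
# junction nodes, numbered by bronchial generation: the trachea branch is
# generation 0, every bifurcation event increments the generation of all
# its daughter branches by one, and a single junction voxel of degree > 3
# (a voxel-level trifurcation) still counts as one event.

new_centerline_graph <- function(nodes, edges, mask) {
  structure(list(nodes = nodes, edges = edges,
                 dims = dim(mask$voxels), spacing_mm = mask$spacing_mm,
                 origin_mm = mask$origin_mm, orientation = mask$orientation),
            class = "centerline_graph")
}

#' @export
print.centerline_graph <- function(x, ...) {
  cat(sprintf("centerline_graph: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

cg_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = nrow(graph$nodes), directed = FALSE)
  if (nrow(graph$edges) > 0)
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
  g
}

cg_degree <- function(graph) {
  deg <- integer(nrow(graph$nodes))
  if (nrow(graph$edges) > 0) {
    t1 <- tabulate(graph$edges$from, nbins = nrow(graph$nodes))
    t2 <- tabulate(graph$edges$to, nbins = nrow(graph$nodes))
    deg <- t1 + t2
  }
  deg
}

cg_adjacency <- function(graph) {
  n <- nrow(graph$nodes)
  adj <- vector("list", n)
  if (nrow(graph$edges) > 0) {
    for (r in seq_len(nrow(graph$edges))) {
      f <- graph$edges$from[r]; t <- graph$edges$to[r]
      adj[[f]] <- c(adj[[f]], t)
      adj[[t]] <- c(adj[[t]], f)
    }
  }
  adj
}

#' Skeletonize a binary mask to a centerline graph
#'
#' Topology-preserving sequential 3-D thinning (simple-point deletion with
#' curve-endpoint preservation) reduces the mask to a 1-voxel-wide skeleton;
#' skeleton voxels become nodes (with physical mm coordinates) and every
#' pair of 26-adjacent skeleton voxels becomes an edge weighted by the
#' physical distance between their centers. One graph component is produced
#' per 26-connected mask component, so occlusion fragments stay separate.
#'
#' @param mask A non-empty [binary_mask()].
#' @return A `centerline_graph` with `nodes` (node_id, voxel index `i,j,k`,
#'   physical `x,y,z`) and `edges` (from, to, length_mm).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$voxels)) stop("no foreground: the mask is empty")
  d <- dim(mask$voxels)
  edt <- cpp_edt(as.vector(mask$voxels), d, mask$spacing_mm)
  skel <- array(cpp_thin(as.vector(mask$voxels), d, edt, -1), d)

  idx <- which(skel)
  ijk <- arrayInd(idx, d)
  xyz <- voxel_to_mm(mask, ijk)
  nodes <- data.frame(node_id = seq_along(idx),
                      i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  idmap <- array(0L, d)
  idmap[idx] <- nodes$node_id

  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[offsets$dx != 0 | offsets$dy != 0 | offsets$dz != 0, ]
  # half of the 26 offsets, to create each edge once
  offsets <- offsets[offsets$dz > 0 |
                       (offsets$dz == 0 & (offsets$dy > 0 |
                                             (offsets$dy == 0 & offsets$dx > 0))), ]
  from <- integer(0); to <- integer(0); len <- numeric(0)
  for (r in seq_len(nrow(offsets))) {
    o <- as.integer(offsets[r, ])
    xr <- max(1, 1 - o[1]):min(d[1], d[1] - o[1])
    yr <- max(1, 1 - o[2]):min(d[2], d[2] - o[2])
    zr <- max(1, 1 - o[3]):min(d[3], d[3] - o[3])
    a <- idmap[xr, yr, zr, drop = FALSE]
    b <- idmap[xr + o[1], yr + o[2], zr + o[3], drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) {
      from <- c(from, a[keep])
      to <- c(to, b[keep])
      len <- c(len, rep(sqrt(sum((o * mask$spacing_mm)^2)), sum(keep)))
    }
  }
  edges <- data.frame(from = pmin(from, to), to = pmax(from, to), length_mm = len)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new_centerline_graph(nodes, edges, mask)
}

#' Find the root (trachea end) of a centerline graph
#'
#' The root is the degree-1 node with the most superior physical coordinate
#' within the largest connected component, where "largest" is measured by
#' the voxel count of the corresponding 26-connected mask component (the
#' trachea-bearing component of a chest segmentation). Ties on the superior
#' coordinate are broken by the lowest node id.
#'
#' @param graph A `centerline_graph` (run [break_cycles()] first if the
#'   structure may contain pure loops).
#' @param mask The [binary_mask()] the graph was extracted from.
#' @return The root `node_id`.
#' @export
find_root <- function(graph, mask) {
  stopifnot(inherits(graph, "centerline_graph"), inherits(mask, "binary_mask"))
  if (nrow(graph$nodes) == 0L) stop("empty centerline graph")
  d <- dim(mask$voxels)
  lab <- array(cpp_label26(as.vector(mask$voxels), d), d)
  node_lab <- lab[cbind(graph$nodes$i, graph$nodes$j, graph$nodes$k)]
  sizes <- tabulate(lab[lab > 0L])
  present <- sort(unique(node_lab))
  big <- present[which.max(sizes[present])]
  deg <- cg_degree(graph)
  cand <- which(node_lab == big & deg == 1L)
  if (length(cand) == 0L) {
    if (all(deg[node_lab == big] == 0L)) {
      cand <- which(node_lab == big)  # single-voxel component
    } else {
      stop("largest component has no degree-1 node (pure loop); run break_cycles() first")
    }
  }
  sup <- superior_axis(mask)
  coord <- graph$nodes[[c("x", "y", "z")[sup$axis]]][cand] * sup$sign
  cand[order(-coord, cand)][1]
}

#' Break cycles in a centerline graph
#'
#' Within each connected component, keeps a maximum-total-length spanning
#' tree and removes all other edges, so long anatomical paths survive and
#' short spurious shortcuts (including the edge triangles that 26-adjacency
#' creates at diagonal steps) are discarded. The node set is unchanged and
#' the result is acyclic. Ties are resolved deterministically by the
#' canonical edge ordering of the graph.
#'
#' @param graph A `centerline_graph`.
#' @return The acyclic `centerline_graph`.
#' @export
break_cycles <- function(graph) {
  stopifnot(inherits(graph, "centerline_graph"))
  if (nrow(graph$edges) == 0L) return(graph)
  g <- cg_igraph(graph)
  tree <- igraph::mst(g, weights = -graph$edges$length_mm)
  kept <- igraph::as_edgelist(tree, names = FALSE)
  if (nrow(kept) > 0) {
    key <- paste(pmin(kept[, 1], kept[, 2]), pmax(kept[, 1], kept[, 2]))
    sel <- paste(graph$edges$from, graph$edges$to) %in% key
  } else {
    sel <- logical(nrow(graph$edges))
  }
  graph$edges <- graph$edges[sel, , drop = FALSE]
  rownames(graph$edges) <- NULL
  graph
}

#' Prune short terminal chains (skeleton spurs)
#'
#' Iteratively removes terminal chains (from a leaf back to, but excluding,
#' the nearest junction node) whose centerline length is below
#' `min_spur_length_mm`, until no such chain remains. The chain containing
#' the root node is never removed, and a component that is a bare path with
#' no junction is left intact. Below roughly three voxels of length, a
#' terminal chain is a thinning artifact rather than a resolvable airway.
#'
#' @param graph An acyclic `centerline_graph`.
#' @param root Root `node_id` from [find_root()].
#' @param min_spur_length_mm Threshold (mm); 0 disables pruning.
#' @return The pruned `centerline_graph`.
#' @export
prune_spurs <- function(graph, root, min_spur_length_mm = 2) {
  stopifnot(inherits(graph, "centerline_graph"))
  if (min_spur_length_mm <= 0) return(graph)
  repeat {
    adj <- cg_adjacency(graph)
    deg <- cg_degree(graph)
    elen <- new.env(hash = TRUE)
    for (r in seq_len(nrow(graph$edges)))
      assign(paste(graph$edges$from[r], graph$edges$to[r]),
             graph$edges$length_mm[r], envir = elen)
    edge_len <- function(a, b) get(paste(min(a, b), max(a, b)), envir = elen)
    leaves <- which(deg == 1L)
    leaves <- leaves[leaves != root]
    removed <- FALSE
    for (leaf in leaves) {
      chain <- leaf
      len <- 0
      prev <- -1L
      cur <- leaf
      hit_junction <- FALSE
      repeat {
        nxt <- setdiff(adj[[cur]], prev)
        if (length(nxt) == 0L) break            # bare path, other leaf
        nxt <- nxt[1]
        len <- len + edge_len(cur, nxt)
        if (deg[nxt] >= 3L) { hit_junction <- TRUE; break }
        if (nxt == root) break
        chain <- c(chain, nxt)
        prev <- cur
        cur <- nxt
      }
      if (!hit_junction) next                   # not a spur
      if (root %in% chain) next
      if (len < min_spur_length_mm) {
        keep <- !(graph$nodes$node_id %in% chain)
        graph <- cg_subset_nodes(graph, which(keep))
        root <- match(root, graph$nodes$old_id)
        graph$nodes$old_id <- NULL
        removed <- TRUE
        break                                   # rebuild before next leaf
      }
    }
    if (!removed) break
  }
  graph
}

# Keep the given node row indices, renumbering node ids to 1..n and
# remapping edges; records the previous ids in nodes$old_id.
cg_subset_nodes <- function(graph, keep_idx) {
  old <- graph$nodes$node_id[keep_idx]
  map <- integer(max(graph$nodes$node_id))
  map[old] <- seq_along(old)
  nodes <- graph$nodes[keep_idx, , drop = FALSE]
  nodes$old_id <- nodes$node_id
  nodes$node_id <- seq_along(old)
  rownames(nodes) <- NULL
  e <- graph$edges
  sel <- e$from %in% old & e$to %in% old
  e <- e[sel, , drop = FALSE]
  e$from <- map[e$from]
  e$to <- map[e$to]
  e[c("from", "to")] <- list(pmin(e$from, e$to), pmax(e$from, e$to))
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  graph$nodes <- nodes
  graph$edges <- e
  graph
}
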