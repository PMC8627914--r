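# Skeletonization, root finding, cycle/spur handling, branch decomposition.

make_graph <- function(coords, edges) {
  # coords: n x 3 matrix of mm positions; edges: 2-column matrix
  nodes <- data.frame(node_id = seq_len(nrow(coords)),
                      i = seq_len(nrow(coords)), j = 1L, k = 1L,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3])
  if (is.null(edges) || nrow(edges) == 0) {
    e <- data.frame(from = integer(0), to = integer(0), length_mm = numeric(0))
  } else {
    len <- sqrt(rowSums((coords[edges[, 1], , drop = FALSE] -
                           coords[edges[, 2], , drop = FALSE])^2))
    e <- data.frame(from = pmin(edges[, 1], edges[, 2]),
                    to = pmax(edges[, 1], edges[, 2]), length_mm = len)
  }
  structure(list(nodes = nodes, edges = e, dims = c(1L, 1L, 1L),
                 spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0),
                 orientation = c("R", "A", "S")),
            class = "centerline_graph")
}

test_that("degenerate and tubular masks skeletonize as expected", {
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  g <- skeletonize(binary_mask(v, c(1, 1, 1)))
  expect_equal(nrow(g$nodes), 1L)
  expect_equal(nrow(g$edges), 0L)

  expect_error(skeletonize(binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))),
               "no foreground")

  # straight axial tube: a path graph with two endpoints
  tube <- rasterize_tree(single_branch_truth(len = 20, r = 2,
                                             spacing = c(1, 1, 1)))
  gt <- skeletonize(tube)
  deg <- tabulate(c(gt$edges$from, gt$edges$to), nbins = nrow(gt$nodes))
  expect_equal(sum(deg == 1L), 2L)
  expect_true(all(deg[deg != 1L] == 2L))
  # skeleton containment: every node on mask foreground
  expect_true(all(tube$voxels[cbind(gt$nodes$i, gt$nodes$j, gt$nodes$k)]))
})

test_that("a Y-shaped phantom yields three tips and one junction", {
  m <- rasterize_tree(y_truth(r = 2, spacing = c(1, 1, 1)))
  g <- break_cycles(skeletonize(m))
  root <- find_root(g, m)
  g <- prune_spurs(g, root, 2)
  deg <- tabulate(c(g$edges$from, g$edges$to), nbins = nrow(g$nodes))
  expect_equal(sum(deg == 1L), 3L)
  expect_equal(sum(deg >= 3L), 1L)
})

test_that("find_root picks the most superior endpoint of the largest component", {
  ph <- measured_phantom(seed = 1, max_generation = 2)
  g <- break_cycles(skeletonize(ph$mask))
  root <- find_root(g, ph$mask)
  rootpt <- g$nodes[root, c("x", "y", "z")]
  # proximal end of the generation-0 truth branch is at the origin, top of z
  expect_lt(sqrt(sum((as.numeric(rootpt) - c(0, 0, 0))^2)), 2)

  # two components: the smaller one is more superior, root stays in the larger
  big <- single_branch_truth(len = 20, r = 2, spacing = c(1, 1, 1),
                             start = c(0, 0, 0))
  small <- single_branch_truth(len = 5, r = 1.5, spacing = c(1, 1, 1),
                               start = c(12, 0, 10))
  both <- big
  b2 <- small$branches; b2$branch_id <- 2L; b2$component <- 1L
  both$branches <- rbind(both$branches, b2)
  m <- rasterize_tree(both)
  g2 <- break_cycles(skeletonize(m))
  r2 <- find_root(g2, m)
  expect_lt(abs(g2$nodes$x[r2]), 5)  # on the big tube, not at x = 12

  # superior-coordinate tie breaks to the lowest node id
  gt <- make_graph(rbind(c(0, 0, 5), c(1, 0, 5), c(2, 0, 5)),
                   rbind(c(1, 2), c(2, 3)))
  v <- array(FALSE, c(3, 1, 1)); v[, 1, 1] <- TRUE
  mk <- binary_mask(v, c(1, 1, 1))
  gt$nodes$i <- 1:3; gt$nodes$j <- 1L; gt$nodes$k <- 1L
  expect_equal(find_root(gt, mk), 1L)
})

test_that("break_cycles removes exactly the cycle rank of each component", {
  # acyclic input is untouched
  g <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                  rbind(c(1, 2), c(2, 3)))
  expect_identical(break_cycles(g)$edges, g$edges)

  # a single 4-cycle loses exactly one edge, deterministically
  sq <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                   rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  b1 <- break_cycles(sq)
  expect_equal(nrow(b1$edges), 3L)
  expect_identical(b1$edges, break_cycles(sq)$edges)

  # random graphs: edges removed == E - N + C (cycle rank)
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    coords <- matrix(runif(3 * n, 0, 10), ncol = 3)
    all_pairs <- t(combn(n, 2))
    m <- sample(seq_len(nrow(all_pairs)), sample(seq_len(min(nrow(all_pairs), 2 * n)), 1))
    g <- make_graph(coords, all_pairs[m, , drop = FALSE])
    gi <- igraph::make_empty_graph(n = n, directed = FALSE)
    gi <- igraph::add_edges(gi, rbind(g$edges$from, g$edges$to))
    rank <- nrow(g$edges) - n + igraph::components(gi)$no
    removed <- nrow(g$edges) - nrow(break_cycles(g)$edges)
    expect_equal(removed, rank)
  }
})

test_that("cycle breaking keeps the maximum-total-length spanning tree", {
  # triangle with one long edge: the two longest edges survive
  tri <- make_graph(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                    rbind(c(1, 2), c(2, 3), c(1, 3)))
  kept <- break_cycles(tri)$edges
  expect_equal(sum(kept$length_mm), max(combn(tri$edges$length_mm, 2, sum)))
})

test_that("prune_spurs removes short whiskers and nothing else", {
  # a 20-mm path with a 1.2-mm whisker off its middle
  coords <- rbind(cbind(0, 0, seq(0, -20, by = -1)), c(1.2, 0, -10))
  n <- nrow(coords)
  edges <- rbind(cbind(1:(n - 2), 2:(n - 1)), c(11, n))
  g <- make_graph(coords, edges)
  p <- prune_spurs(g, root = 1L, min_spur_length_mm = 2)
  expect_equal(nrow(p$nodes), n - 1L)        # whisker gone
  expect_equal(nrow(p$edges), n - 2L)
  # nothing shorter than the threshold: unchanged
  p2 <- prune_spurs(p, root = 1L, min_spur_length_mm = 1)
  expect_equal(nrow(p2$nodes), nrow(p$nodes))
  # threshold zero is the identity
  p3 <- prune_spurs(g, root = 1L, min_spur_length_mm = 0)
  expect_equal(nrow(p3$nodes), n)
})

test_that("branch decomposition assigns bronchial generations", {
  ph <- measured_phantom(seed = 1, max_generation = 2)
  tree <- ph$tree
  b <- tree$branches
  root_branch <- b[b$branch_id == tree$root_branch_id, ]
  expect_equal(root_branch$generation, 0L)            # trachea
  mains <- b[!is.na(b$parent_id) & b$parent_id == tree$root_branch_id, ]
  expect_equal(nrow(mains), 2L)
  expect_equal(mains$generation, c(1L, 1L))           # main bronchi

  # full binary phantom: generation histogram equals {g: 2^g}
  ph3 <- measured_phantom(seed = 2, max_generation = 3)
  hist_rec <- table(ph3$tree$branches$generation)
  hist_tru <- table(ph3$truth$branches$generation)
  expect_equal(as.vector(hist_rec), as.vector(hist_tru))
  expect_equal(as.vector(hist_rec), 2^(0:3))

  # generation recursion holds for every branch of component 0
  b3 <- ph3$tree$branches
  kid <- !is.na(b3$parent_id) & b3$component == 0
  expect_equal(b3$generation[kid],
               b3$generation[match(b3$parent_id[kid], b3$branch_id)] + 1L)
})

test_that("a trifurcation increments the generation once", {
  # one parent with three children leaving the same junction
  s <- sqrt(2) / 2
  br <- data.frame(
    branch_id = 1:4, parent_id = c(NA, 1L, 1L, 1L), generation = c(0L, 1L, 1L, 1L),
    component = 0L,
    start_x = 0, start_y = 0, start_z = c(0, -14, -14, -14),
    end_x = c(0, 10 * s, -10 * s, 0), end_y = c(0, 0, 0, 10 * s),
    end_z = c(-14, -14 - 10 * s, -14 - 10 * s, -14 - 10 * s),
    radius_mm = c(2.5, 1.8, 1.8, 1.8))
  truth <- structure(list(branches = br, spacing_mm = c(0.7, 0.7, 0.7)),
                     class = "airway_truth")
  tree <- measure_airways(rasterize_tree(truth))
  expect_equal(sort(tree$branches$generation), c(0L, 1L, 1L, 1L))
})

test_that("every skeleton edge of the root component is used exactly once", {
  ph <- measured_phantom(seed = 3, max_generation = 2)
  g <- break_cycles(skeletonize(ph$mask))
  root <- find_root(g, ph$mask)
  g <- prune_spurs(g, root, 2)
  tree <- decompose_branches(g, root, junction_fuse_mm = 0, smooth_window = 0)
  # with no fusing/smoothing the polylines partition the component's edges
  n_segments <- sum(vapply(tree$polylines, nrow, integer(1)) - 1L)
  comp <- igraph::components(airwaymorph:::cg_igraph(g))$membership
  n_edges_root_comp <- sum(comp[g$edges$from] == comp[root])
  expect_equal(n_segments, n_edges_root_comp)
})

test_that("disconnected components bridge or stay unassigned as configured", {
  tr <- generate_tree(tree_spec(seed = 11, max_generation = 2))
  dg <- degrade_mask(tr, degradation_spec(
    seed = 1, occlusions = list(list(branch_id = 2, gap_center_fraction = 0.5,
                                     gap_length_mm = 3))))
  bridged <- measure_airways(dg$mask, bridge_max_mm = 5)
  cmp <- compare_tree_to_truth(bridged, dg$truth)
  expect_true(cmp$generations_equal)

  unbridged <- measure_airways(dg$mask, bridge_max_mm = 0)
  bu <- unbridged$branches
  expect_equal(sum(is.na(bu$generation)), sum(dg$truth$branches$component > 0))
  expect_true(all(bu$component[is.na(bu$generation)] > 0))

  # with no secondary component attach_disconnected is the identity
  ph <- measured_phantom(seed = 1, max_generation = 2)
  g <- break_cycles(skeletonize(ph$mask))
  root <- find_root(g, ph$mask)
  g <- prune_spurs(g, root, 2)
  t0 <- decompose_branches(g, root)
  expect_identical(attach_disconnected(t0, g, ph$mask, 5), t0)
})
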