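# Distance field, centerline resampling, lumen diameters, branch measures.

test_that("the distance field matches closed forms and a brute-force scan", {
  # 1-voxel-thick slab: every slab voxel is one step from background
  v <- array(FALSE, c(7, 7, 3)); v[, , 2] <- TRUE
  f <- compute_distance_field(binary_mask(v, c(1, 1, 1)))
  expect_equal(unique(as.vector(f$values[, , 2])), 1)
  expect_equal(unique(as.vector(f$values[, , c(1, 3)])), 0)

  # solid ball of radius 5 mm: center value within half a voxel diagonal
  dims <- c(15, 15, 15)
  ctr <- c(8, 8, 8)
  g <- expand.grid(i = 1:15, j = 1:15, k = 1:15)
  ball <- array(sqrt((g$i - 8)^2 + (g$j - 8)^2 + (g$k - 8)^2) <= 5, dims)
  fb <- compute_distance_field(binary_mask(ball, c(1, 1, 1)))
  expect_lt(abs(fb$values[8, 8, 8] - 5), sqrt(3) / 2 + 1e-9)

  # anisotropic spacing against the exhaustive all-pairs oracle
  set.seed(7)
  v <- array(runif(12^3) < 0.5, c(12, 12, 12))
  v[1, 1, 1] <- FALSE  # ensure background exists
  m <- binary_mask(v, c(0.6, 0.6, 1.0))
  f <- compute_distance_field(m)
  expect_equal(f$values, oracle_edt(v, c(0.6, 0.6, 1.0)), tolerance = 1e-9)

  expect_error(compute_distance_field(
    binary_mask(array(FALSE, c(3, 3, 3)), c(1, 1, 1))), "empty")
})

test_that("the distance field is Lipschitz on voxel steps", {
  set.seed(8)
  v <- array(runif(10^3) < 0.6, c(10, 10, 10))
  v[1, , ] <- FALSE
  f <- compute_distance_field(binary_mask(v, c(0.7, 0.7, 0.7)))
  d <- f$values
  expect_true(all(abs(d[-1, , ] - d[-10, , ]) <= 0.7 + 1e-9))
  expect_true(all(abs(d[, -1, ] - d[, -10, ]) <= 0.7 + 1e-9))
  expect_true(all(abs(d[, , -1] - d[, , -10]) <= 0.7 + 1e-9))
})

test_that("centerline resampling places samples on the arc-length grid", {
  straight <- cbind(0, 0, seq(0, -10, by = -2))
  s <- resample_centerline(straight, 1)
  expect_equal(nrow(s), 11L)
  expect_equal(attr(s, "arc_mm"), 0:10)

  # length 5.4 -> floor(5.4) + 1 = 6 samples
  short <- cbind(c(0, 5.4), c(0, 0), c(0, 0))
  expect_equal(nrow(resample_centerline(short, 1)), 6L)

  # zig-zag: consecutive samples exactly 1 mm apart in arc length,
  # verified against dense numeric arc-length integration
  set.seed(3)
  zig <- cbind(cumsum(runif(8, 0.5, 2)), sin(1:8), cos(1:8))
  s <- resample_centerline(zig, 1)
  dense_t <- seq(0, 1, length.out = 20001)
  dense <- NULL
  for (i in 1:(nrow(zig) - 1))
    dense <- rbind(dense, outer(1 - dense_t, zig[i, ]) + outer(dense_t, zig[i + 1, ]))
  dense_arc <- c(0, cumsum(sqrt(rowSums(diff(dense)^2))))
  for (k in seq_len(nrow(s))) {
    nearest <- which.min(colSums((t(dense) - s[k, ])^2))
    expect_lt(abs(dense_arc[nearest] - (k - 1)), 5e-3)
  }

  expect_error(resample_centerline(straight[1, , drop = FALSE], 1), "2 points")
  expect_error(resample_centerline(straight, 0), "positive")
})

test_that("lumen diameter is twice the interpolated inscribed radius", {
  tube <- rasterize_tree(single_branch_truth(len = 20, r = 3, spacing = c(1, 1, 1)))
  f <- compute_distance_field(tube)
  mid <- c(0, 0, -10)
  expect_lt(abs(lumen_diameter_at(f, mid) - 6), 1 + 1e-9)

  # single-voxel mask: diameter = 2 x distance to the nearest background center
  v <- array(FALSE, c(5, 5, 5)); v[3, 3, 3] <- TRUE
  m <- binary_mask(v, c(1, 1, 1))
  fd <- compute_distance_field(m)
  expect_equal(lumen_diameter_at(fd, c(2, 2, 2)), 2)

  # point on background: zero with a warning
  expect_warning(d0 <- lumen_diameter_at(fd, c(0, 0, 0)), "background")
  expect_equal(d0, 0)
  expect_error(lumen_diameter_at(fd, c(99, 0, 0)), "outside")

  # trilinear interpolation equals the hand-rolled stencil at an off-grid point
  p <- c(1.3, 2.6, 2.2)
  w <- p - floor(p)
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    acc <- acc + prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w)) *
      fd$values[floor(p[1]) + 1 + dx, floor(p[2]) + 1 + dy, floor(p[3]) + 1 + dz]
  expect_equal(lumen_diameter_at(fd, p), 2 * acc, tolerance = 1e-12)
})

test_that("measure_branch fills lengths, samples and means", {
  tube <- rasterize_tree(single_branch_truth(len = 20, r = 3, spacing = c(1, 1, 1)))
  f <- compute_distance_field(tube)
  poly <- cbind(0, 0, seq(-2, -18, by = -0.5))
  m <- measure_branch(poly, f, 1)
  expect_equal(m$length_mm, 16)
  expect_equal(length(m$diameter_samples_mm), 17L)
  expect_lt(abs(m$mean_diameter_mm - 6), 1)

  # branch shorter than the interval: one sample at the proximal end
  m1 <- measure_branch(cbind(c(0, 0), c(0, 0), c(-5, -5.5)), f, 1)
  expect_equal(length(m1$diameter_samples_mm), 1L)
  expect_equal(m1$arc_mm, 0)

  # constant-radius tube: doubling the interval barely moves the mean
  m2 <- measure_branch(poly, f, 2)
  expect_lt(abs(m2$mean_diameter_mm - m$mean_diameter_mm) / m$mean_diameter_mm,
            0.01)
})

test_that("branch lengths are additive along root-to-leaf paths", {
  ph <- measured_phantom(seed = 2, max_generation = 2)
  tree <- ph$tree
  b <- tree$branches
  leaves <- b$branch_id[!(b$branch_id %in% b$parent_id)]
  for (leaf in leaves) {
    path <- leaf
    while (!is.na(b$parent_id[match(path[1], b$branch_id)]))
      path <- c(b$parent_id[match(path[1], b$branch_id)], path)
    concat <- do.call(rbind, tree$polylines[match(path, b$branch_id)])
    expect_equal(sum(b$length_mm[match(path, b$branch_id)]),
                 airwaymorph:::polyline_length(concat), tolerance = 1e-6)
  }
  # positive diameters everywhere on the trachea-connected tree
  expect_true(all(b$mean_diameter_mm[b$component == 0] > 0))
})

test_that("dilation never shrinks measured diameters", {
  tr <- generate_tree(tree_spec(seed = 6, max_generation = 2))
  base <- measure_airways(rasterize_tree(tr))
  dil <- measure_airways(degrade_mask(tr, degradation_spec(seed = 1,
                                                           dilation_mm = 0.7))$mask)
  cb <- compare_tree_to_truth(base, tr)$matches
  cd <- compare_tree_to_truth(dil, tr)$matches
  joined <- merge(cb[, c("truth_id", "mean_diameter_rec")],
                  cd[, c("truth_id", "mean_diameter_rec")], by = "truth_id")
  expect_true(all(joined$mean_diameter_rec.y >=
                    joined$mean_diameter_rec.x - 0.35))
})

test_that("diameters converge to the truth as spacing is refined", {
  tr <- single_branch_truth(len = 16, r = 2.2, spacing = c(1, 1, 1))
  err <- sapply(c(1.0, 0.5), function(sp) {
    tree <- measure_airways(rasterize_tree(tr, spacing_mm = rep(sp, 3)))
    abs(tree$branches$mean_diameter_mm[1] - 4.4)
  })
  expect_lt(err[2], err[1] + 1e-9)
  expect_lt(err[2], 0.5)
})
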