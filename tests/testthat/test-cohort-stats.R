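# Aggregation, per-generation tables, Wilcoxon signed-rank, CV planning.

fake_branches <- function(lengths, diameters, generations = NULL) {
  n <- length(lengths)
  data.frame(branch_id = seq_len(n),
             parent_id = c(NA_integer_, rep(1L, n - 1))[seq_len(n)],
             component = 0L,
             generation = generations %||% rep(0L, n),
             length_mm = lengths, mean_diameter_mm = diameters,
             n_samples = pmax(1L, floor(lengths)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("summaries aggregate counts, lengths and median diameters", {
  s <- summarize_segmentation(fake_branches(c(10, 20, 30), c(2, 4, 6)),
                              "s1", "initial")
  expect_equal(s$airway_count, 3L)
  expect_equal(s$total_length_mm, 60)
  expect_equal(s$median_diameter_mm, 4)

  s1 <- summarize_segmentation(fake_branches(12.5, 3.1), "s1", "initial")
  expect_equal(s1$airway_count, 1L)
  expect_equal(s1$total_length_mm, 12.5)

  expect_error(summarize_segmentation(fake_branches(1, 1)[0, ], "s", "v"),
               "empty")
})

test_that("a full binary tree summary matches the truth enumeration", {
  truth <- generate_tree(tree_spec(seed = 4, max_generation = 5,
                                   min_radius_mm = 0.3))
  b <- truth$branches
  b$length_mm <- sqrt((b$end_x - b$start_x)^2 + (b$end_y - b$start_y)^2 +
                        (b$end_z - b$start_z)^2)
  b$mean_diameter_mm <- 2 * b$radius_mm
  s <- summarize_segmentation(b, "s1", "truth")
  expect_equal(s$airway_count, 2^6 - 1)
  expect_equal(s$per_generation$count, 2^(0:5))
  # conservation: per-generation lengths add up to the total
  expect_equal(sum(s$per_generation$total_length_mm), s$total_length_all_mm)
})

test_that("per-generation tables honour variants, IQRs and absent rows", {
  s <- summarize_segmentation(fake_branches(c(5, 6, 7), c(1, 2, 3),
                                            generations = c(0L, 1L, 1L)),
                              "s1", "initial")
  tab <- per_generation_table(list(s), "count")
  expect_equal(tab$median[tab$generation == "0"], 1)
  expect_equal(tab$median[tab$generation == "1"], 2)
  # IQR of a single value degenerates to that value
  expect_equal(tab$q1, tab$median)
  expect_equal(tab$q3, tab$median)

  # a generation absent from one variant shows as NA, not zero
  s2 <- summarize_segmentation(fake_branches(5, 1, generations = 0L),
                               "s1", "pruned")
  tab2 <- per_generation_table(list(s, s2), "count")
  pruned_g1 <- tab2[tab2$variant == "pruned" & tab2$generation == "1", ]
  expect_true(is.na(pruned_g1$median))
  expect_equal(pruned_g1$n_subjects, 0L)

  expect_error(per_generation_table(list(s), "no_such_metric"), "valid metrics")
})

test_that("the exact signed-rank test matches full sign enumeration", {
  # constant positive shift, n = 6: statistic 0, p = 2 / 2^6
  w <- wilcoxon_signed_rank(1:6 + 3, 1:6)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.03125)

  # zero differences are dropped, all-zero is degenerate
  expect_error(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  wz <- wilcoxon_signed_rank(c(1, 2, 3, 9), c(1, 2, 3, 4))
  expect_equal(wz$n_effective, 1L)

  # randomized fixtures, including ties, against the 2^n enumeration oracle
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    a <- sample(seq(0, 4, by = 0.5), n, replace = TRUE)
    b <- sample(seq(0, 4, by = 0.5), n, replace = TRUE)
    if (all(a == b)) a[1] <- a[1] + 1
    got <- wilcoxon_signed_rank(a, b)
    want <- oracle_wilcoxon(a, b)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
  }
})

test_that("the large-sample branch uses a tie-corrected normal approximation", {
  set.seed(5)
  a <- rnorm(40, 0.4)
  b <- rnorm(40)
  w <- wilcoxon_signed_rank(a, b)
  expect_match(w$method, "normal")
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-9)
})

test_that("paired comparisons apply Bonferroni over non-baseline variants", {
  set.seed(31)
  mk <- function(subject, variant, count) {
    structure(list(subject_id = subject, variant = variant,
                   airway_count = count, n_unassigned = 0L,
                   total_length_mm = count * 10,
                   total_length_all_mm = count * 10,
                   median_diameter_mm = 5,
                   per_generation = NULL),
              class = "segmentation_summary")
  }
  summ <- list()
  for (i in 1:8) {
    base <- 100 + i
    summ <- c(summ, list(mk(i, "initial", base),
                         mk(i, "corrected", base + sample(1:5, 1)),
                         mk(i, "retrained", base + sample(-2:2, 1)),
                         mk(i, "combined", base + sample(-1:3, 1))))
  }
  res <- suppressWarnings(compare_paired(summ, "initial",
                                         metrics = "airway_count"))
  expect_equal(nrow(res), 3L)
  # m = 3 non-baseline variants; adjusted p = min(1, 3 * raw)
  expect_equal(res$p_adjusted, pmin(1, 3 * res$p_raw))
  expect_equal(res$significant, res$p_adjusted < 0.05)

  # Bonferroni arithmetic at the boundary cases
  expect_equal(min(1, 3 * 0.02), 0.06)  # not significant at 0.05
  expect_equal(min(1, 3 * 0.3), 0.9)
  res_m1 <- suppressWarnings(compare_paired(summ, "initial",
                                            metrics = "airway_count",
                                            m_comparisons = 10))
  expect_equal(res_m1$p_adjusted, pmin(1, 10 * res_m1$p_raw))

  # subject-set mismatch is an error that names the offender
  bad <- c(summ, list(mk(99, "corrected", 140)))
  expect_error(compare_paired(bad, "initial"), "99")
})

test_that("cross-validation plans partition subjects deterministically", {
  ids <- sprintf("subj%02d", 1:15)
  plan <- plan_cross_validation(ids, k = 5, seed = 7)
  expect_equal(vapply(plan$folds, function(f) length(f$training), integer(1)),
               rep(12L, 5))
  expect_equal(vapply(plan$folds, function(f) length(f$update), integer(1)),
               rep(10L, 5))   # round(0.83 * 12)
  expect_equal(vapply(plan$folds, function(f) length(f$selection), integer(1)),
               rep(2L, 5))
  # test folds partition the subjects
  tests <- unlist(lapply(plan$folds, function(f) f$test))
  expect_setequal(tests, ids)
  expect_equal(anyDuplicated(tests), 0L)
  for (f in plan$folds) {
    expect_setequal(c(f$test, f$training), ids)
    expect_setequal(c(f$update, f$selection), f$training)
  }
  # deterministic in the seed
  expect_identical(plan, plan_cross_validation(ids, k = 5, seed = 7))
  expect_false(identical(plan$folds,
                         plan_cross_validation(ids, k = 5, seed = 8)$folds))

  # leave-one-out degenerate case
  p5 <- plan_cross_validation(ids[1:5], k = 5, seed = 1)
  expect_equal(vapply(p5$folds, function(f) length(f$test), integer(1)),
               rep(1L, 5))
  expect_equal(vapply(p5$folds, function(f) length(f$training), integer(1)),
               rep(4L, 5))

  expect_error(plan_cross_validation(ids[1:3], k = 5), "at least")
  expect_error(plan_cross_validation(ids, k = 1), "at least 2")
})
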