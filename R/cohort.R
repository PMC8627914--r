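# Per-segmentation aggregates and paired cohort comparison.
#
# The three aggregate measures are the total airway count, the total airway
# length, and the median luminal diameter of a segmentation; the median is
# taken over per-branch MEAN diameters (branch-level, so long branches do
# not dominate), matching a workflow that first averages diameter samples
# within each branch.  Paired variants (e.g. an initial automatic
# segmentation versus its corrected version) are compared per subject with
# the exact Wilcoxon signed-rank test under Bonferroni correction.

#' Summarize a measured segmentation
#'
#' Aggregates a measured branch set into per-segmentation statistics:
#' airway count, total airway length, median of per-branch mean diameters,
#' and a per-generation breakdown. Branches whose generation could not be
#' assigned (disconnected components that were not bridged) are excluded
#' from the headline aggregates and tallied under an `"unassigned"` row of
#' the per-generation table, with `*_all` fields reporting the totals that
#' include them, so the choice is auditable either way.
#'
#' @param x A measured `airway_tree`, or a branch data frame with columns
#'   `generation`, `length_mm`, `mean_diameter_mm` (and optionally
#'   `component`).
#' @param subject_id Subject identifier.
#' @param variant Segmentation variant label (e.g. `"initial"`,
#'   `"corrected"`, `"retrained"`, `"combined"`).
#' @return A `segmentation_summary`: list with `subject_id`, `variant`,
#'   `airway_count`, `n_unassigned`, `total_length_mm`,
#'   `total_length_all_mm`, `median_diameter_mm`, and `per_generation`
#'   (data frame `generation`, `count`, `total_length_mm`,
#'   `median_diameter_mm`).
#' @export
summarize_segmentation <- function(x, subject_id, variant) {
  b <- if (inherits(x, "airway_tree")) x$branches else as.data.frame(x)
  if (nrow(b) == 0L) stop("cannot summarize an empty branch list")
  if (is.null(b$generation)) stop("branches must carry a 'generation' column")
  assigned <- !is.na(b$generation)
  if (!any(assigned)) stop("no branch has an assigned generation")
  ba <- b[assigned, , drop = FALSE]
  gen_levels <- sort(unique(ba$generation))
  per_gen <- do.call(rbind, lapply(gen_levels, function(g) {
    bg <- ba[ba$generation == g, , drop = FALSE]
    data.frame(generation = as.character(g), count = nrow(bg),
               total_length_mm = sum(bg$length_mm),
               median_diameter_mm = median(bg$mean_diameter_mm))
  }))
  if (any(!assigned)) {
    bu <- b[!assigned, , drop = FALSE]
    per_gen <- rbind(per_gen, data.frame(
      generation = "unassigned", count = nrow(bu),
      total_length_mm = sum(bu$length_mm),
      median_diameter_mm = median(bu$mean_diameter_mm)))
  }
  rownames(per_gen) <- NULL
  structure(
    list(subject_id = subject_id, variant = variant,
         airway_count = nrow(ba),
         n_unassigned = sum(!assigned),
         total_length_mm = sum(ba$length_mm),
         total_length_all_mm = sum(b$length_mm),
         median_diameter_mm = median(ba$mean_diameter_mm),
         per_generation = per_gen),
    class = "segmentation_summary")
}

#' @export
print.segmentation_summary <- function(x, ...) {
  cat(sprintf("segmentation_summary [%s / %s]: %d airways (+%d unassigned), total length %.1f mm, median diameter %.2f mm\n",
              x$subject_id, x$variant, x$airway_count, x$n_unassigned,
              x$total_length_mm, x$median_diameter_mm))
  invisible(x)
}

summary_metrics <- c("airway_count", "total_length_mm", "median_diameter_mm")
per_gen_metrics <- c("count", "total_length_mm", "median_diameter_mm")

#' Cross-variant per-generation table
#'
#' For one metric, tabulates the per-subject median and interquartile range
#' in each generation, per variant. Generations absent from every summary
#' of a variant are reported as `NA`, not zero.
#'
#' @param summaries List of [summarize_segmentation()] results.
#' @param metric One of `"count"`, `"total_length_mm"`,
#'   `"median_diameter_mm"` (per-generation columns).
#' @return A long data frame: `generation`, `variant`, `n_subjects`,
#'   `median`, `q1`, `q3`.
#' @export
per_generation_table <- function(summaries, metric = "count") {
  if (length(summaries) == 0L) stop("need at least one summary")
  if (!metric %in% per_gen_metrics)
    stop(sprintf("unknown metric '%s'; valid metrics: %s", metric,
                 paste(per_gen_metrics, collapse = ", ")))
  rows <- do.call(rbind, lapply(summaries, function(s) {
    d <- s$per_generation
    data.frame(subject_id = s$subject_id, variant = s$variant,
               generation = d$generation, value = d[[metric]])
  }))
  gens <- unique(rows$generation)
  num <- suppressWarnings(as.numeric(gens))
  gens <- gens[order(is.na(num), num)]
  out <- list()
  for (v in unique(rows$variant)) {
    for (g in gens) {
      vals <- rows$value[rows$variant == v & rows$generation == g]
      if (length(vals) == 0L) {
        out[[length(out) + 1L]] <- data.frame(
          generation = g, variant = v, n_subjects = 0L,
          median = NA_real_, q1 = NA_real_, q3 = NA_real_)
      } else {
        q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
        out[[length(out) + 1L]] <- data.frame(
          generation = g, variant = v, n_subjects = length(vals),
          median = q[2], q1 = q[1], q3 = q[3])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Exact Wilcoxon signed-rank test for paired samples
#'
#' Classical signed-rank test on within-pair differences: zero differences
#' are dropped, ties among absolute differences receive average ranks, and
#' the statistic is `min(W+, W-)`. The two-sided p-value is exact -- the
#' tail of the permutation distribution over all 2^n sign assignments,
#' computed by convolution -- whenever the effective n is at most 25, and a
#' normal approximation with tie correction otherwise.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @return `list(statistic, p_value, n_effective, method)`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  if (length(a) < 1L) stop("need at least one pair")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate: no nonzero pairs")
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  stat <- min(wpos, wneg)
  if (n <= 25L) {
    # distribution of W+ over all sign assignments; doubled ranks are
    # integers even with average ranks, so a convolution is exact
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1)  # counts[w+1] = #assignments with 2*W+ == w
    counts[1] <- 1
    for (rr in r2) {
      shifted <- c(rep(0, rr), counts[seq_len(total + 1 - rr)])
      counts <- counts + shifted
    }
    w2 <- as.integer(round(2 * stat))
    p <- 2 * sum(counts[seq_len(w2 + 1)]) / 2^n
    p <- min(1, p)
    method <- "exact (sign-assignment distribution)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (wpos - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(statistic = stat, p_value = p, n_effective = n, method = method)
}

#' Compare paired segmentation variants
#'
#' For each metric and each non-baseline variant, pairs subjects by
#' `subject_id`, runs [wilcoxon_signed_rank()] against the baseline, and
#' applies a Bonferroni correction with `m` equal to the number of
#' non-baseline variants per metric (unless overridden). Significance is
#' declared at adjusted p < 0.05.
#'
#' @param summaries List of [summarize_segmentation()] results covering the
#'   same subjects in every variant.
#' @param baseline_variant Variant all others are compared to.
#' @param metrics Summary fields to test (default: airway count, total
#'   length, median diameter).
#' @param m_comparisons Bonferroni multiplier; default = number of
#'   non-baseline variants.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return A data frame of class `comparison_result`: `metric`, `variant`,
#'   `baseline`, `n_pairs`, `statistic`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
compare_paired <- function(summaries, baseline_variant,
                           metrics = summary_metrics,
                           m_comparisons = NULL, alpha = 0.05) {
  if (!all(metrics %in% summary_metrics))
    stop(sprintf("unknown metric(s) %s; valid metrics: %s",
                 paste(setdiff(metrics, summary_metrics), collapse = ", "),
                 paste(summary_metrics, collapse = ", ")))
  variants <- unique(vapply(summaries, function(s) s$variant, character(1)))
  if (!baseline_variant %in% variants)
    stop(sprintf("baseline variant '%s' not present", baseline_variant))
  by_var <- split(summaries, vapply(summaries, function(s) s$variant, character(1)))
  subj <- lapply(by_var, function(g)
    sort(vapply(g, function(s) as.character(s$subject_id), character(1))))
  base_subj <- subj[[baseline_variant]]
  for (v in names(subj)) {
    missing <- setdiff(base_subj, subj[[v]])
    extra <- setdiff(subj[[v]], base_subj)
    if (length(missing) || length(extra))
      stop(sprintf("subject sets differ for variant '%s': missing [%s], extra [%s]",
                   v, paste(missing, collapse = ", "),
                   paste(extra, collapse = ", ")))
  }
  others <- setdiff(variants, baseline_variant)
  m <- m_comparisons %||% length(others)
  pull <- function(group, metric) {
    ids <- vapply(group, function(s) as.character(s$subject_id), character(1))
    vals <- vapply(group, function(s) as.numeric(s[[metric]]), numeric(1))
    vals[order(ids)]
  }
  out <- list()
  for (metric in metrics) {
    base_vals <- pull(by_var[[baseline_variant]], metric)
    for (v in others) {
      w <- tryCatch(wilcoxon_signed_rank(pull(by_var[[v]], metric), base_vals),
                    error = function(e) {
                      warning(sprintf("%s, %s vs %s: %s", metric, v,
                                      baseline_variant, conditionMessage(e)))
                      list(statistic = NA_real_, p_value = NA_real_,
                           n_effective = 0L)
                    })
      p_adj <- min(1, m * w$p_value)
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, variant = v, baseline = baseline_variant,
        n_pairs = w$n_effective, statistic = w$statistic,
        p_raw = w$p_value, p_adjusted = p_adj,
        significant = isTRUE(p_adj < alpha))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("comparison_result", class(res))
  res
}

#' Plan a k-fold cross-validation split
#'
#' Shuffles the subjects with the given seed and deals them into k test
#' folds of near-equal size (differing by at most one). Each fold's
#' training list is the complement of its test set; within each training
#' list, `round(inner_update_fraction * n_training)` subjects are assigned
#' to weight updating and the remainder to model selection. With 15
#' subjects and k = 5 this gives training folds of 12, split 10 / 2.
#'
#' @param subject_ids Character or numeric subject identifiers (n >= k).
#' @param k Number of folds (>= 2), default 5.
#' @param inner_update_fraction Fraction of each training fold used for
#'   weight updating (default 0.83).
#' @param seed Integer RNG seed; the plan is deterministic in it.
#' @return A `cv_plan`: list with `k`, `seed`, and `folds`, each fold a
#'   list of `test`, `training`, `update`, `selection` subject vectors.
#' @export
plan_cross_validation <- function(subject_ids, k = 5, inner_update_fraction = 0.83,
                                  seed = 1L) {
  subject_ids <- as.character(subject_ids)
  n <- length(subject_ids)
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (k < 2) stop("'k' must be at least 2")
  if (n < k) stop(sprintf("need at least k = %d subjects, got %d", k, n))
  if (inner_update_fraction <= 0 || inner_update_fraction > 1)
    stop("'inner_update_fraction' must lie in (0, 1]")
  with_seed(seed, {
    shuffled <- sample(subject_ids)
    fold_of <- rep(seq_len(k), length.out = n)
    folds <- lapply(seq_len(k), function(f) {
      test <- shuffled[fold_of == f]
      training <- setdiff(shuffled, test)
      n_up <- round(inner_update_fraction * length(training))
      n_up <- max(1L, min(length(training), n_up))
      inner <- sample(training)
      list(test = sort(test), training = sort(training),
           update = sort(inner[seq_len(n_up)]),
           selection = sort(inner[setdiff(seq_along(inner), seq_len(n_up))]))
    })
    structure(list(k = as.integer(k), seed = as.integer(seed), folds = folds),
              class = "cv_plan")
  })
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d folds, seed %d\n", x$k, x$seed))
  for (f in seq_along(x$folds)) {
    fd <- x$folds[[f]]
    cat(sprintf("  fold %d: test %d, training %d (update %d / selection %d)\n",
                f, length(fd$test), length(fd$training),
                length(fd$update), length(fd$selection)))
  }
  invisible(x)
}
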