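#' Feature-by-sample microbiome count container
#'
#' Bundles a non-negative count matrix (species or pathways in rows, samples
#' in columns) with per-sample condition labels.
#'
#' @param counts features x samples matrix of non-negative counts with
#'   positive column sums.
#' @param meta data.frame with columns `sample` (matching `colnames(counts)`)
#'   and `condition` (>= 2 distinct values).
#' @param kind "species" or "pathway".
#' @return A `taxa_table` list(counts, meta, kind).
#' @export
taxa_table <- function(counts, meta, kind = c("species", "pathway")) {
  kind <- match.arg(kind)
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0), !is.null(colnames(counts)),
            all(c("sample", "condition") %in% names(meta)),
            all(colnames(counts) == meta$sample))
  if (any(colSums(counts) == 0)) stop("taxa_table: zero-total samples present")
  if (length(unique(meta$condition)) < 2) {
    stop("taxa_table: need >= 2 conditions")
  }
  structure(list(counts = counts, meta = meta, kind = kind),
            class = "taxa_table")
}

#' Prevalence filtering
#'
#' Retains features with a nonzero count in at least
#' `ceiling(min_prevalence * n_samples)` samples (60\% for species, 80\% for
#' pathways in the default analysis).
#'
#' @param table a [taxa_table()].
#' @param min_prevalence required prevalence in (0, 1].
#' @return The filtered `taxa_table`.
#' @export
prevalence_filter <- function(table, min_prevalence) {
  stopifnot(inherits(table, "taxa_table"),
            min_prevalence > 0, min_prevalence <= 1)
  need <- ceiling(min_prevalence * ncol(table$counts))
  keep <- rowSums(table$counts > 0) >= need
  table$counts <- table$counts[keep, , drop = FALSE]
  table
}

# CLR point-estimate transform of a count matrix (features x samples):
# log proportions (with additive prior) minus their per-sample mean.
clr_point <- function(counts, prior = 0.5) {
  p <- sweep(counts + prior, 2, colSums(counts + prior), "/")
  lg <- log(p)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Dirichlet Monte Carlo CLR instances
#'
#' Propagates count uncertainty compositionally: for each sample, `n_mc`
#' probability vectors are drawn from Dirichlet(counts + prior) and each draw
#' is centred-log-ratio transformed (log proportions minus their per-sample
#' mean, which therefore sum to zero over features). All downstream tests are
#' run per instance and summarised by medians, the ALDEx2 convention.
#'
#' @param table a (filtered) [taxa_table()].
#' @param n_mc number of Monte Carlo instances (>= 2; default 128).
#' @param prior additive Dirichlet prior per feature (default 0.5).
#' @param seed RNG seed.
#' @return A `clr_instances` list: `values` (n_mc x features x samples
#'   array), `conditions`, `features`, `samples`, `n_mc`.
#' @export
dirichlet_clr_instances <- function(table, n_mc = 128, prior = 0.5, seed = 1L) {
  stopifnot(inherits(table, "taxa_table"))
  if (n_mc < 2) stop("dirichlet_clr_instances: n_mc must be >= 2")
  set.seed(seed)
  cnt <- table$counts
  nf <- nrow(cnt); ns <- ncol(cnt)
  vals <- array(NA_real_, c(n_mc, nf, ns),
                dimnames = list(NULL, rownames(cnt), colnames(cnt)))
  for (j in seq_len(ns)) {
    g <- matrix(stats::rgamma(n_mc * nf, shape = rep(cnt[, j] + prior, each = n_mc)),
                n_mc, nf)
    lg <- log(g / rowSums(g))
    vals[, , j] <- lg - rowMeans(lg)
  }
  structure(list(values = vals, conditions = table$meta$condition,
                 features = rownames(cnt), samples = colnames(cnt),
                 n_mc = n_mc),
            class = "clr_instances")
}

#' Kruskal-Wallis differential abundance across conditions
#'
#' Runs a Kruskal-Wallis test of CLR values across all conditions within
#' every Monte Carlo instance; the per-feature p-value is the median across
#' instances, adjusted across features by Benjamini-Hochberg.
#'
#' @param instances a [dirichlet_clr_instances()] result.
#' @param conditions optional condition labels overriding those stored.
#' @return data.frame(feature, kw_p, kw_fdr_p).
#' @export
kw_test_clr <- function(instances, conditions = NULL) {
  stopifnot(inherits(instances, "clr_instances"))
  cond <- factor(if (is.null(conditions)) instances$conditions else conditions)
  if (nlevels(cond) < 2) stop("kw_test_clr: need >= 2 conditions")
  if (any(table(cond) < 2)) stop("kw_test_clr: every condition needs >= 2 samples")
  vals <- instances$values
  nf <- dim(vals)[2]
  p_med <- vapply(seq_len(nf), function(f) {
    pv <- apply(vals[, f, , drop = TRUE], 1, function(x) {
      if (stats::var(x) == 0) return(1)
      stats::kruskal.test(x, cond)$p.value
    })
    stats::median(pv)
  }, numeric(1))
  data.frame(feature = instances$features, kw_p = p_med,
             kw_fdr_p = bh_fdr(p_med), stringsAsFactors = FALSE)
}

#' Welch test and standardized effect size between two conditions
#'
#' For a condition pair (baseline vs day 4 by default), each Monte Carlo
#' instance yields a Welch t-test p-value and a standardized effect,
#' `(median(group2) - median(group1)) / max(within-group dispersion)`, where
#' a group's dispersion is the absolute difference between one random draw
#' and the group median (the ALDEx2-style denominator). Reported values are
#' medians across instances; the effect is positive when the second condition
#' (day 4) is more abundant. Random draws are keyed to the condition label,
#' so swapping the pair flips every effect's sign exactly.
#'
#' @param instances a [dirichlet_clr_instances()] result.
#' @param pair length-2 character vector (reference, comparison).
#' @param seed RNG seed for the dispersion draws.
#' @return data.frame(feature, welch_p, welch_fdr_p, effect_size, direction).
#' @export
welch_effect <- function(instances, pair = c("baseline", "day4"), seed = 1L) {
  stopifnot(inherits(instances, "clr_instances"), length(pair) == 2)
  cond <- instances$conditions
  i1 <- which(cond == pair[1]); i2 <- which(cond == pair[2])
  if (length(i1) < 2 || length(i2) < 2) {
    stop("welch_effect: both conditions need >= 2 samples")
  }
  vals <- instances$values
  n_mc <- dim(vals)[1]; nf <- dim(vals)[2]

  # dispersion draws keyed to the (sorted) condition label, not the pair order
  set.seed(seed)
  ord <- order(pair)
  draws <- list()
  for (g in pair[ord]) {
    idx <- which(cond == g)
    draws[[g]] <- matrix(idx[sample.int(length(idx), n_mc * nf, replace = TRUE)],
                         n_mc, nf)
  }

  eff <- p <- matrix(NA_real_, n_mc, nf)
  for (f in seq_len(nf)) {
    x1 <- vals[, f, i1, drop = TRUE]   # n_mc x |group1|
    x2 <- vals[, f, i2, drop = TRUE]
    m1 <- apply(x1, 1, stats::median)
    m2 <- apply(x2, 1, stats::median)
    d1 <- abs(vals[cbind(seq_len(n_mc), f, draws[[pair[1]]][, f])] - m1)
    d2 <- abs(vals[cbind(seq_len(n_mc), f, draws[[pair[2]]][, f])] - m2)
    eff[, f] <- (m2 - m1) / pmax(d1, d2, 1e-8)
    p[, f] <- vapply(seq_len(n_mc), function(i) {
      if (stats::var(c(x1[i, ], x2[i, ])) == 0) return(1)
      stats::t.test(x2[i, ], x1[i, ])$p.value
    }, numeric(1))
  }
  p_med <- apply(p, 2, stats::median)
  e_med <- apply(eff, 2, stats::median)
  data.frame(feature = instances$features,
             welch_p = p_med, welch_fdr_p = bh_fdr(p_med),
             effect_size = e_med,
             direction = ifelse(e_med > 0, "up", ifelse(e_med < 0, "down", "none")),
             stringsAsFactors = FALSE)
}

#' Per-pathway ANOVA across conditions
#'
#' One-way ANOVA of normalized pathway abundance (CLR by default, relative
#' abundance optionally) across the three conditions, BH-adjusted across
#' pathways.
#'
#' @param table a prevalence-filtered [taxa_table()] of pathways.
#' @param use_clr transform to CLR (default) rather than relative abundance.
#' @param prior CLR additive prior.
#' @return data.frame(feature, F, p, fdr_p).
#' @export
anova_pathways <- function(table, use_clr = TRUE, prior = 0.5) {
  stopifnot(inherits(table, "taxa_table"))
  cond <- factor(table$meta$condition)
  if (any(table(cond) < 2)) stop("anova_pathways: every condition needs >= 2 samples")
  vals <- if (use_clr) {
    clr_point(table$counts, prior)
  } else {
    sweep(table$counts, 2, colSums(table$counts), "/")
  }
  res <- t(apply(vals, 1, function(x) {
    if (stats::var(x) == 0) return(c(0, 1))
    s <- summary(stats::aov(x ~ cond))[[1]]
    c(s[["F value"]][1], s[["Pr(>F)"]][1])
  }))
  data.frame(feature = rownames(table$counts),
             F = res[, 1], p = res[, 2], fdr_p = bh_fdr(res[, 2]),
             stringsAsFactors = FALSE)
}

# hclust merge tree as a portable nested list (JSON-serialisable)
hclust_to_list <- function(h) {
  build <- function(i) {
    if (i < 0) return(list(leaf = h$labels[-i]))
    list(height = h$height[i],
         left = build(h$merge[i, 1]),
         right = build(h$merge[i, 2]))
  }
  build(nrow(h$merge))
}

#' Hierarchical clustering of CLR abundances
#'
#' Computes the single CLR point-estimate transform (prior 0.5), Euclidean
#' distances and average-linkage dendrograms for features and samples, and
#' returns the leaf orders plus the reordered CLR matrix — the inputs a
#' heatmap renderer needs.
#'
#' @param table a (filtered) [taxa_table()].
#' @param prior CLR additive prior.
#' @return list(feature_hclust, sample_hclust, feature_order, sample_order,
#'   clr = ordered CLR matrix, feature_tree, sample_tree) where the `_tree`
#'   entries are portable nested lists.
#' @export
cluster_heatmap_order <- function(table, prior = 0.5) {
  stopifnot(inherits(table, "taxa_table"))
  if (nrow(table$counts) < 2) stop("cluster_heatmap_order: need >= 2 features")
  clr <- clr_point(table$counts, prior)
  hf <- stats::hclust(stats::dist(clr), method = "average")
  hs <- stats::hclust(stats::dist(t(clr)), method = "average")
  list(feature_hclust = hf, sample_hclust = hs,
       feature_order = rownames(clr)[hf$order],
       sample_order = colnames(clr)[hs$order],
       clr = clr[hf$order, hs$order, drop = FALSE],
       feature_tree = hclust_to_list(hf),
       sample_tree = hclust_to_list(hs))
}
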