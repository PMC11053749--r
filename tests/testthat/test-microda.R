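make_taxa <- function(counts, conds) {
  colnames(counts) <- sprintf("s%02d", seq_len(ncol(counts)))
  taxa_table(counts, data.frame(sample = colnames(counts), condition = conds))
}

test_that("prevalence filtering applies the ceiling-count rule", {
  set.seed(1)
  n_s <- 19
  counts <- matrix(rpois(4 * n_s, 50), 4, n_s,
                   dimnames = list(paste0("sp", 1:4), NULL))
  counts[counts == 0] <- 1
  counts[2, 1:7] <- 0    # present in 12/19 = 63% -> passes at 60%
  counts[3, 1:8] <- 0    # present in 11/19 = 58% -> fails
  counts[4, ] <- 0       # absent everywhere -> always removed
  counts[1, 1] <- 5      # keep column sums positive
  tt <- make_taxa(counts, rep(c("baseline", "day4", "day7"), length.out = n_s))
  filt <- prevalence_filter(tt, 0.60)
  expect_equal(rownames(filt$counts), c("sp1", "sp2"))
  # minimal positive threshold keeps everything observed somewhere
  expect_equal(nrow(prevalence_filter(tt, 1e-9)$counts), 3)
})

test_that("Dirichlet CLR instances satisfy the compositional identities", {
  set.seed(2)
  counts <- matrix(rpois(8 * 9, 100) + 1, 8, 9,
                   dimnames = list(paste0("sp", 1:8), NULL))
  tt <- make_taxa(counts, rep(c("baseline", "day4", "day7"), each = 3))
  inst <- dirichlet_clr_instances(tt, n_mc = 16, seed = 3)
  sums <- apply(inst$values, c(1, 3), sum)
  expect_lt(max(abs(sums)), 1e-8)
  expect_error(dirichlet_clr_instances(tt, n_mc = 1), "n_mc")

  # two-feature sample, counts (4,1), prior ~ 0: mean CLR near the CLR of the
  # expected proportions, (log(4)/2, -log(4)/2)
  tt2 <- make_taxa(matrix(c(4, 1), 2, 2,
                          dimnames = list(c("a", "b"), NULL)),
                   c("baseline", "day4"))
  i2 <- dirichlet_clr_instances(tt2, n_mc = 10000, prior = 1e-8, seed = 4)
  # invert each CLR draw back to proportions; their average is E[p]
  props <- exp(i2$values[, , 1])
  props <- props / rowSums(props)
  p_mean <- colMeans(props)
  clr_exp <- log(p_mean) - mean(log(p_mean))
  expect_equal(unname(clr_exp[1]), log(4) / 2, tolerance = 0.05)
  expect_equal(unname(clr_exp[2]), -log(4) / 2, tolerance = 0.05)

  # equal counts: CLR centred on zero in expectation
  tt3 <- make_taxa(matrix(50, 3, 4,
                          dimnames = list(paste0("sp", 1:3), NULL)),
                   rep(c("baseline", "day4"), 2))
  i3 <- dirichlet_clr_instances(tt3, n_mc = 10000, seed = 5)
  expect_lt(max(abs(rowMeans(apply(i3$values, c(2, 3), mean)))), 0.02)
})

test_that("Kruskal-Wallis on CLR instances matches a rank-based oracle", {
  set.seed(6)
  counts <- matrix(rpois(5 * 9, 80) + 1, 5, 9,
                   dimnames = list(paste0("sp", 1:5), NULL))
  conds <- rep(c("baseline", "day4", "day7"), each = 3)
  tt <- make_taxa(counts, conds)
  inst <- dirichlet_clr_instances(tt, n_mc = 8, seed = 7)
  res <- kw_test_clr(inst)
  expect_equal(nrow(res), 5)
  expect_true(all(res$kw_fdr_p >= res$kw_p))

  # oracle on one instance/feature: explicit rank-sum formula, no ties
  x <- inst$values[1, 1, ]
  g <- factor(conds)
  rk <- rank(x)
  n <- length(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(rk, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  expect_equal(unname(stats::kruskal.test(x, g)$statistic), H, tolerance = 1e-12)

  # a strongly shifted feature beats null features on the median p
  hits <- vapply(1:10, function(r) {
    eff <- matrix(0, 20, 3, dimnames = list(NULL, c("baseline", "day4", "day7")))
    eff[1, "day4"] <- 4
    m <- simulate_microbiome_counts(
      microbiome_sim_params(n_species = 20, effect_log2fc = eff,
                            sequencing_depth = 5e4, prevalence_sparsity = 0,
                            sample_noise_sd = 0.3, seed = 600 + r))
    ii <- dirichlet_clr_instances(m$table, n_mc = 16, seed = r)
    kk <- kw_test_clr(ii)
    kk$kw_p[1] < min(kk$kw_p[-1])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Welch effect sizes are antisymmetric and detect planted shifts", {
  set.seed(8)
  counts <- matrix(rpois(6 * 12, 60) + 1, 6, 12,
                   dimnames = list(paste0("sp", 1:6), NULL))
  tt <- make_taxa(counts, rep(c("baseline", "day4"), each = 6))
  inst <- dirichlet_clr_instances(tt, n_mc = 32, seed = 9)
  fwd <- welch_effect(inst, pair = c("baseline", "day4"), seed = 11)
  rev <- welch_effect(inst, pair = c("day4", "baseline"), seed = 11)
  expect_equal(fwd$effect_size, -rev$effect_size)
  expect_true(all(fwd$welch_fdr_p >= fwd$welch_p))

  # identical groups: effect 0 and p near 1 (duplicate the same samples)
  cdup <- cbind(counts[, 1:3], counts[, 1:3])
  colnames(cdup) <- sprintf("s%02d", 1:6)
  ttd <- taxa_table(cdup, data.frame(sample = colnames(cdup),
                                     condition = rep(c("baseline", "day4"), each = 3)))
  instd <- dirichlet_clr_instances(ttd, n_mc = 64, seed = 10)
  fd <- welch_effect(instd, seed = 12)
  expect_lt(max(abs(fd$effect_size)), 0.75)
  expect_gt(min(fd$welch_p), 0.2)

  # planted 16-fold shifts produce |effect| > 1 with the right sign
  eff <- matrix(0, 30, 3, dimnames = list(NULL, c("baseline", "day4", "day7")))
  eff[1, "day4"] <- 4; eff[2, "day4"] <- -4
  m <- simulate_microbiome_counts(
    microbiome_sim_params(n_species = 30, effect_log2fc = eff, seed = 13))
  im <- dirichlet_clr_instances(m$table, n_mc = 64, seed = 13)
  wm <- welch_effect(im, seed = 13)
  expect_gt(wm$effect_size[1], 1)
  expect_lt(wm$effect_size[2], -1)
})

test_that("pathway ANOVA matches textbook F and the two-group identity", {
  vals <- c(3, 4, 5, 6, 7, 8, 3, 4, 5)
  counts <- matrix(rpois(4 * 9, 100) + 1, 4, 9,
                   dimnames = list(paste0("pw", 1:4), NULL))
  tt <- make_taxa(counts, rep(c("baseline", "day4", "day7"), each = 3))
  tt$kind <- "pathway"
  res <- anova_pathways(tt)
  expect_true(all(res$fdr_p >= res$p))

  # oracle on raw values: F for {3,4,5},{6,7,8},{3,4,5} is 9
  g <- factor(rep(1:3, each = 3))
  s <- summary(stats::aov(vals ~ g))[[1]]
  expect_equal(s[["F value"]][1], 9)

  # two conditions: pathway F equals the squared pooled t on the CLR values
  tt2 <- make_taxa(counts[, 1:6], rep(c("baseline", "day4"), each = 3))
  tt2$kind <- "pathway"
  res2 <- anova_pathways(tt2)
  clr <- stdrmait:::clr_point(tt2$counts)
  tstat <- apply(clr, 1, function(x)
    stats::t.test(x[4:6], x[1:3], var.equal = TRUE)$statistic)
  expect_equal(res2$F, unname(tstat^2), tolerance = 1e-10)

  # constant input: F pinned to zero
  cst <- matrix(100, 3, 6, dimnames = list(paste0("pw", 1:3), NULL))
  ttc <- make_taxa(cst, rep(c("baseline", "day4"), each = 3))
  ttc$kind <- "pathway"
  expect_equal(anova_pathways(ttc)$F, rep(0, 3))
})

test_that("CLR hierarchical clustering groups planted condition blocks", {
  set.seed(14)
  base <- rnorm(12, 4, 0.2)
  counts <- sapply(1:8, function(j) {
    shift <- if (j <= 4) 0 else rep(c(3, -3), each = 6)
    rpois(12, exp(base + shift + rnorm(12, 0, 0.05))) + 1
  })
  rownames(counts) <- paste0("sp", 1:12)
  tt <- make_taxa(counts, rep(c("baseline", "day4"), each = 4))
  ord <- cluster_heatmap_order(tt)
  pos <- match(tt$meta$sample, ord$sample_order)
  # the two condition blocks occupy contiguous leaf ranges
  expect_true(max(pos[1:4]) < min(pos[5:8]) || min(pos[1:4]) > max(pos[5:8]))

  # duplicated samples merge at height 0; distances symmetric, zero diagonal
  dup <- cbind(counts, counts[, 1])
  colnames(dup) <- sprintf("s%02d", 1:9)
  ttd <- taxa_table(dup, data.frame(sample = colnames(dup),
                                    condition = rep(c("baseline", "day4", "day7"), 3)))
  ordd <- cluster_heatmap_order(ttd)
  expect_equal(min(ordd$sample_hclust$height), 0)
  D <- as.matrix(dist(t(stdrmait:::clr_point(dup))))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))

  expect_error(cluster_heatmap_order(
    make_taxa(matrix(5, 1, 4, dimnames = list("sp1", NULL)),
              rep(c("baseline", "day4"), 2))), ">= 2 features")

  # the exported tree is JSON-serialisable
  expect_silent(jsonlite::toJSON(ordd$sample_tree, auto_unbox = TRUE))
})
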