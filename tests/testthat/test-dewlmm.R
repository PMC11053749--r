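test_that("voom weights are positive, flat under homoscedasticity, rising under Poisson", {
  set.seed(31)
  layout <- make_cell_layout(n_subjects = 2, cells_per_sample = 25)
  n <- nrow(layout$meta)
  # homoscedastic log-scale simulation: large counts, constant log-variance
  logc <- matrix(rnorm(100 * n, mean = 10, sd = 0.25), 100, n)
  counts_flat <- round(2^logc)
  w_flat <- compute_voom_weights(counts_flat, layout$design)
  expect_true(all(w_flat > 0))
  expect_lt(sd(w_flat) / mean(w_flat), 0.1)

  # Poisson counts: variance of log-CPM falls with abundance, weights rise
  mu <- exp(seq(log(1), log(200), length.out = 80))
  counts_pois <- matrix(rpois(80 * n, rep(mu, n)), 80, n)
  keep <- rowSums(counts_pois) > 0
  w_pois <- compute_voom_weights(counts_pois[keep, ], layout$design)
  rho <- cor(mu[keep], rowMeans(w_pois), method = "spearman")
  expect_gt(rho, 0.9)

  expect_error(compute_voom_weights(counts_flat[1:5, ], layout$design), ">= 10")
})

test_that("ZINB fits recover mixture parameters and degenerate cases", {
  set.seed(41)
  # no zeros at all: no evidence of zero inflation
  y_nz <- rpois(200, 20) + 1
  expect_lt(fit_zinb_gene(y_nz)$pi, 0.01)

  # plain NB (pi = 0): pi_hat consistent at n = 5000
  y_nb <- rnbinom(5000, mu = 4, size = 1.5)
  expect_lt(fit_zinb_gene(y_nb)$pi, 0.05)

  # true ZINB with pi = 0.3: recovered within +/-0.05
  y_zi <- rnbinom(5000, mu = 6, size = 2)
  y_zi[runif(5000) < 0.3] <- 0
  fit <- fit_zinb_gene(y_zi)
  expect_equal(fit$pi, 0.3, tolerance = 0.05 / 0.3)
  expect_equal(fit$mu[1], 6, tolerance = 0.1)

  expect_error(fit_zinb_gene(rep(0, 100)), "all counts are zero")
  expect_error(fit_zinb_gene(c(1, 2, 3)), ">= 20 cells")
})

test_that("dropout weights follow the posterior-zero formula", {
  counts <- matrix(c(0, 3, 0, 1), 1, 4)
  # pi = 0.5 and f_NB(0) = 0.5 -> weight at a zero = 1/3
  size <- 1
  mu <- 1  # f_NB(0) = (1/(1+1))^1 = 0.5
  fit <- list(pi = 0.5, mu = rep(mu, 4), size = size)
  w <- compute_zinb_weights(counts, list(fit))
  expect_equal(w[1, c(1, 3)], c(1 / 3, 1 / 3))
  expect_equal(w[1, c(2, 4)], c(1, 1))   # positive counts: exactly 1

  # pi = 0: every weight is 1
  w0 <- compute_zinb_weights(counts, list(list(pi = 0, mu = rep(1, 4), size = 1)))
  expect_true(all(w0 == 1))
  expect_error(compute_zinb_weights(counts, list(list(pi = NA))), "invalid fit")

  # combined weights are the exact elementwise product
  a <- matrix(runif(12, 0.5, 2), 3)
  b <- matrix(runif(12, 0, 1), 3)
  expect_identical(combine_weights(a, b), a * b)
})

test_that("weighted REML reduces to WLS and respects reparameterization", {
  set.seed(51)
  layout <- make_cell_layout(n_subjects = 4, cells_per_sample = 15)
  w <- runif(nrow(layout$meta), 0.2, 3)
  sim <- simulate_lmm_response(layout, beta = c(1, 0.5, -0.2, 0.1), tau = 0,
                               weights = w)
  fit <- fit_weighted_lmm(sim$y, layout$design, w, layout$meta$subject)
  wls <- lm.wfit(layout$design, sim$y, w)
  if (fit$lambda == 0) {
    expect_equal(unname(fit$beta), unname(wls$coefficients), tolerance = 1e-6)
  } else {
    # tau is estimated, not fixed: allow the REML fit a tiny positive lambda
    expect_equal(unname(fit$beta), unname(wls$coefficients), tolerance = 1e-3)
  }

  # adding c to all baseline cells shifts beta0 by c, leaves contrasts alone
  y2 <- sim$y + ifelse(layout$meta$timepoint == "baseline", 2.5, 0)
  # a baseline-only shift alters the intercept and shifts every contrast by -c
  fit2 <- fit_weighted_lmm(y2, layout$design, w, layout$meta$subject)
  expect_equal(fit2$beta[1], fit$beta[1] + 2.5, tolerance = 1e-6)
  expect_equal(fit2$beta[-1], fit$beta[-1] - 2.5, tolerance = 1e-6)
  # whereas a global shift moves only the intercept
  fit3 <- fit_weighted_lmm(sim$y + 2.5, layout$design, w, layout$meta$subject)
  expect_equal(fit3$beta[1], fit$beta[1] + 2.5, tolerance = 1e-6)
  expect_equal(fit3$beta[-1], fit$beta[-1], tolerance = 1e-6)

  bad <- cbind(layout$design, dup = layout$design[, 2])
  expect_error(fit_weighted_lmm(sim$y, bad, w, layout$meta$subject), "dup")
})

test_that("weighted REML agrees with lme4 on heteroscedastic grouped data", {
  skip_if_not_installed("lme4")
  set.seed(61)
  layout <- make_cell_layout(n_subjects = 6, cells_per_sample = 12)
  w <- runif(nrow(layout$meta), 0.3, 2.5)
  sim <- simulate_lmm_response(layout, beta = c(0.5, 0.6, -0.3, 0), tau = 0.4,
                               weights = w)
  fit <- fit_weighted_lmm(sim$y, layout$design, w, layout$meta$subject)
  df <- data.frame(y = sim$y, subject = layout$meta$subject)
  lf <- lme4::lmer(y ~ layout$design[, -1] + (1 | subject), data = df,
                   weights = w, REML = TRUE)
  expect_equal(unname(fit$beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(lf))))),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(lf))$vcov
  expect_equal(c(fit$tau2, fit$sigma2), vc, tolerance = 1e-4)
})

test_that("mean beta1 over simulated genes recovers the planted 0.6", {
  set.seed(71)
  layout <- make_cell_layout()   # 7 subjects x 4 time points x 50 cells
  b1 <- vapply(1:100, function(g) {
    w <- runif(nrow(layout$meta), 0.3, 3)
    sim <- simulate_lmm_response(layout, beta = c(0.5, 0.6, 0.2, 0), tau = 0.3,
                                 weights = w)
    fit_weighted_lmm(sim$y, layout$design, w, layout$meta$subject)$beta[2]
  }, numeric(1))
  expect_equal(mean(b1), 0.6, tolerance = 0.1 / 0.6)
})

test_that("ignoring the subject effect inflates null calls under unbalanced sampling", {
  # cells per subject-time sample vary (as in real droplet data); with a real
  # subject effect the naive fixed-effects model then understates uncertainty
  set.seed(81)
  tps <- c("baseline", "day2", "day4", "day7")
  n_rep <- 200
  p_mixed <- p_naive <- numeric(n_rep)
  # one unbalanced layout shared across replicate genes
  meta <- do.call(rbind, lapply(sprintf("S%d", 1:7), function(s) {
    do.call(rbind, lapply(tps, function(tp) {
      data.frame(subject = s, timepoint = tp,
                 cell = seq_len(sample(5:80, 1)))
    }))
  }))
  X <- timepoint_design(meta$timepoint)
  for (r in seq_len(n_rep)) {
    a <- rnorm(7, 0, 0.6)
    names(a) <- sprintf("S%d", 1:7)
    y <- a[meta$subject] + rnorm(nrow(meta))
    fit <- fit_weighted_lmm(y, X, NULL, meta$subject)
    t_mixed <- fit$beta[2] / fit$se[2]
    p_mixed[r] <- 2 * pt(-abs(t_mixed), fit$df_residual)
    ols <- summary(lm(y ~ X[, -1]))$coefficients
    p_naive[r] <- ols[2, 4]
  }
  expect_lte(mean(p_mixed < 0.05), 0.10)          # mixed model holds its level
  expect_gt(mean(p_naive < 0.05), mean(p_mixed < 0.05) + 0.05)
})

test_that("moderation limits, estimation and calibration behave as derived", {
  set.seed(91)
  G <- 1000; df <- 50; d0_true <- 8; s0_true <- 0.5
  v_true <- s0_true * d0_true / rchisq(G, d0_true)
  s2 <- v_true * rchisq(G, df) / df
  c_unit <- 0.04                      # common coefficient variance factor
  beta <- matrix(rnorm(G, 0, sqrt(v_true * c_unit)), G, 1)
  se <- matrix(sqrt(s2 * c_unit), G, 1)

  # d0 -> 0: ordinary t exactly
  m0 <- moderate_statistics(beta, se, s2, df, ebayes = list(d0 = 0, s0_sq = 1))
  expect_equal(m0$t[, 1], beta[, 1] / se[, 1], tolerance = 1e-10)
  expect_equal(m0$s2_post, s2, tolerance = 1e-12)

  # d0 -> Inf: full shrinkage to s0^2 for every gene
  mi <- moderate_statistics(beta, se, s2, df,
                            ebayes = list(d0 = Inf, s0_sq = 0.7))
  expect_equal(mi$s2_post, rep(0.7, G), tolerance = 1e-12)

  # estimated prior: close to truth, p-values uniform under the null
  me <- moderate_statistics(beta, se, s2, df)
  expect_equal(me$d0, d0_true, tolerance = 0.35)
  expect_equal(me$s0_sq, s0_true, tolerance = 0.15)
  ks <- suppressWarnings(ks.test(me$p[, 1], "punif"))
  expect_gt(ks$p.value, 0.01)

  # cross-check hyperparameters against the limma implementation
  sq <- limma::squeezeVar(s2, df)
  expect_equal(me$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(me$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(me$s2_post, sq$var.post, tolerance = 1e-10)
})

test_that("BH adjustment follows the step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_error(bh_fdr(c(0.1, NaN)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "lie in")
})

test_that("DEG calling applies all three criteria with direction", {
  res <- data.frame(gene = c("CD69_like", "subthreshold", "rare", "up_gene"),
                    expressed_frac = c(0.30, 0.40, 0.04, 0.20),
                    beta_day2 = c(-0.66, -0.38, -1.2, 0.9),
                    fdr_day2 = c(1e-4, 1e-6, 1e-8, 0.004))
  degs <- call_degs(res, "day2")
  expect_equal(degs$deg, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(degs$direction, c("down", NA, NA, "up"))
})

test_that("direction-by-time chi-square matches the Pearson formula", {
  # perfectly proportional table: statistic 0, p = 1
  prop <- matrix(c(10, 20, 30, 60, 5, 10), 2)
  expect_equal(direction_summary(prop)$statistic, 0)
  expect_equal(direction_summary(prop)$p, 1)

  # 2x2 toy table against the direct summation oracle
  tab <- matrix(c(12, 5, 3, 10), 2)
  res <- direction_summary(tab)
  exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - exp_tab)^2 / exp_tab))
  expect_equal(res$df, 1)

  # from a long DEG table
  degs <- data.frame(gene = letters[1:6],
                     contrast = rep(c("day2", "day4"), each = 3),
                     deg = TRUE,
                     direction = c("up", "down", "down", "down", "down", "up"))
  ds <- direction_summary(degs)
  expect_equal(unname(ds$table["up", ]), c(1, 1))
  expect_equal(unname(ds$table["down", ]), c(2, 2))
})

test_that("full DE pipeline detects planted effects at the stated criteria", {
  # power: beta = 0.8 in 10% of genes on a reduced version of the default
  # design; sensitivity must clear 0.6 at the |LogFc| >= 0.4 / FDR < 0.01 rule
  d <- study_design(seed = 101)
  p <- sc_sim_params(n_genes = 400, de_fraction = 0.1,
                     beta_true = c(0.8, 0.8, 0.8))
  sim <- simulate_sc_counts(d, p)
  de <- de_analysis(sim$counts, sim$meta)
  truth_de <- sim$truth$gene[sim$truth$is_de]
  called <- de$degs$gene[de$degs$deg & de$degs$contrast == "day2"]
  sens <- mean(truth_de %in% called)
  expect_gte(sens, 0.6)
  # false calls among null genes stay rare
  null_genes <- setdiff(de$table$gene, truth_de)
  fp <- mean(null_genes %in% called)
  expect_lt(fp, 0.05)
  # weight layers multiply exactly
  expect_equal(de$weights$combined, de$weights$voom * de$weights$zinb)
})
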