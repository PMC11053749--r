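#' Time-point design matrix with baseline reference
#'
#' Builds the fixed-effect design for the per-gene model: an intercept plus
#' one dummy indicator per non-baseline time point, so the coefficients are
#' the mean log-expression changes of each time point relative to baseline.
#'
#' @param timepoint per-cell time-point labels.
#' @param levels ordered time-point levels; the first is the baseline.
#' @return cells x (1 + T - 1) numeric model matrix with columns
#'   `(Intercept)`, then one per non-baseline level.
#' @export
timepoint_design <- function(timepoint,
                             levels = c("baseline", "day2", "day4", "day7")) {
  levels <- levels[levels %in% unique(timepoint)]
  f <- factor(timepoint, levels = levels)
  if (anyNA(f)) stop("timepoint_design: labels outside the stated levels")
  stats::model.matrix(~f)[, , drop = FALSE] |>
    (\(m) {colnames(m) <- c("(Intercept)", levels[-1]); m})()
}

# Profiled REML for y ~ N(X beta, sigma2 * (W^-1 + lambda Z Z')) with a single
# random intercept per subject. Per-subject Woodbury identities make each
# evaluation O(n_subjects) after an O(n) precomputation, so the 1-D profile
# over lambda = tau2/sigma2 is essentially free per gene.
reml_profile <- function(lambda, pre) {
  ci <- lambda / (1 + lambda * pre$s)
  A <- pre$XtWX - crossprod(pre$U, pre$U * ci)
  b <- pre$XtWy - crossprod(pre$U, ci * pre$v)[, 1]
  q <- pre$ytWy - sum(ci * pre$v^2)
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(list(crit = Inf))
  beta <- backsolve(R, forwardsolve(t(R), b))
  rss <- max(q - sum(b * beta), 1e-12)
  logdet_Sigma <- -pre$sumlogw + sum(log1p(lambda * pre$s))
  logdet_A <- 2 * sum(log(diag(R)))
  crit <- (pre$n - pre$p) * log(rss) + logdet_Sigma + logdet_A
  list(crit = crit, beta = beta, rss = rss, R = R)
}

#' Weighted linear mixed model for one gene
#'
#' Fits the repeated-measures model for a single gene: per-cell response
#' (log-normalized expression) regressed on the time-point design with a
#' random intercept per subject and heteroscedastic residuals,
#' `y_ij = x_ij' beta + alpha_i + e_ij`, `alpha_i ~ N(0, tau2)`,
#' `e_ij ~ N(0, sigma2 / w_ij)` where `w_ij` is the combined voom x dropout
#' observation weight. Estimation is REML, profiled down to a one-dimensional
#' search over the variance ratio `lambda = tau2/sigma2` using per-subject
#' Woodbury inverses.
#'
#' @param y numeric response per cell.
#' @param design model matrix from [timepoint_design()].
#' @param weights positive observation weights (default all 1).
#' @param subject per-cell subject identifiers (>= 2 distinct).
#' @return list(beta, se, tau2, sigma2, df_residual, lambda, n).
#' @export
fit_weighted_lmm <- function(y, design, weights = NULL, subject) {
  X <- as.matrix(design)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, length(subject) == n)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0)) stop("fit_weighted_lmm: weights must be positive")
  subj <- as.factor(subject)
  S <- nlevels(subj)
  if (S < 2) stop("fit_weighted_lmm: need >= 2 subjects")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    stop("fit_weighted_lmm: singular design; collapsed column(s): ",
         paste(bad, collapse = ", "))
  }

  w <- weights
  wX <- X * w
  pre <- list(
    n = n, p = p,
    XtWX = crossprod(X, wX),
    XtWy = crossprod(wX, y)[, 1],
    ytWy = sum(w * y^2),
    U = rowsum(wX, subj),            # S x p: X_i' w_i
    v = rowsum(w * y, subj)[, 1],    # S:     1' W_i y_i
    s = rowsum(w, subj)[, 1],        # S:     1' W_i 1
    sumlogw = sum(log(w)))

  f <- function(loglam) reml_profile(exp(loglam), pre)$crit
  opt <- stats::optimize(f, interval = c(-15, 10), tol = 1e-6)
  cand <- list(c(0, reml_profile(0, pre)$crit),
               c(exp(opt$minimum), opt$objective))
  lambda <- cand[[which.min(vapply(cand, `[`, numeric(1), 2))]][1]

  fit <- reml_profile(lambda, pre)
  sigma2 <- fit$rss / (n - p)
  Ainv <- chol2inv(fit$R)
  se <- sqrt(pmax(diag(Ainv), 0) * sigma2)
  names(fit$beta) <- names(se) <- colnames(X)
  list(beta = fit$beta, se = se,
       tau2 = lambda * sigma2, sigma2 = sigma2,
       df_residual = n - p - (S - 1),
       lambda = lambda, n = n)
}
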