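#' voom precision weights
#'
#' Computes limma-voom observation weights for a count matrix: log-CPM with
#' prior count 0.5, a lowess trend of the square-root residual standard
#' deviation against average log-count fitted across genes, and per-observation
#' weights equal to the predicted standard deviation to the power -4 at the
#' fitted log-count. These weights unlock linear modelling of log-scale
#' single-cell expression by encoding the count mean-variance relationship.
#'
#' @param counts genes x cells count matrix (already restricted to analysis
#'   genes; >= 10 genes needed to fit the trend).
#' @param design model matrix used for the gene-wise trend fits (cells x
#'   coefficients).
#' @param lib_size optional library sizes; column sums by default.
#' @return genes x cells matrix of positive finite weights.
#' @export
compute_voom_weights <- function(counts, design, lib_size = NULL) {
  if (nrow(counts) < 10) {
    stop("compute_voom_weights: need >= 10 genes to fit the mean-variance trend")
  }
  if (is.null(lib_size)) lib_size <- Matrix::colSums(counts)
  if (any(lib_size <= 0)) stop("compute_voom_weights: library sizes must be > 0")
  v <- limma::voom(as.matrix(counts), design = design, lib.size = lib_size)
  w <- v$weights
  dimnames(w) <- dimnames(counts)
  stopifnot(all(is.finite(w)), all(w > 0))
  w
}

zinb_negll <- function(par, y, offsets) {
  pi0 <- stats::plogis(par[1])
  mu <- exp(par[2] + offsets)
  size <- exp(par[3])
  f <- stats::dnbinom(y, mu = mu, size = size)
  ll <- ifelse(y == 0, log(pi0 + (1 - pi0) * f), log1p(-pi0) + log(f))
  ll[!is.finite(ll)] <- -1e10
  -sum(ll)
}

zinb_negll_grad <- function(par, y, offsets) {
  p0 <- stats::plogis(par[1])
  mu <- exp(par[2] + offsets)
  k <- exp(par[3])
  z <- y == 0
  f0 <- (k / (k + mu))^k
  mix <- p0 + (1 - p0) * f0
  # d/d logit(pi)
  ga <- numeric(length(y))
  ga[z] <- p0 * (1 - p0) * (1 - f0[z]) / mix[z]
  ga[!z] <- -p0
  # d log f_NB / d b0 (via mu) and the y = 0 mixture chain
  gb_nb <- y - mu * (y + k) / (k + mu)
  gb <- gb_nb
  gb[z] <- (1 - p0) * f0[z] * (-k * mu[z] / (k + mu[z])) / mix[z]
  # d log f_NB / d log k
  gk_nb <- k * (digamma(y + k) - digamma(k) + log(k / (k + mu)) +
                  (mu - y) / (k + mu))
  gk <- gk_nb
  gk[z] <- (1 - p0) * f0[z] * gk_nb[z] / mix[z]
  g <- -c(sum(ga), sum(gb), sum(gk))
  g[!is.finite(g)] <- 0
  g
}

#' Intercept-only zero-inflated negative binomial fit
#'
#' Maximum-likelihood fit of the dropout model used for observation weights:
#' a cell's count is a structural zero with probability `pi`, otherwise
#' NB(mean = exp(b0 + offset), size = k). Fitted by direct box-constrained
#' quasi-Newton optimization of the mixture likelihood.
#'
#' @param counts_g integer counts for one gene across cells (>= 20 cells,
#'   not all zero).
#' @param offsets per-cell log library-size offsets (default 0).
#' @return list(pi, b0, size, mu = per-cell NB means, loglik, convergence).
#' @export
fit_zinb_gene <- function(counts_g, offsets = 0) {
  y <- as.numeric(counts_g)
  if (length(y) < 20) stop("fit_zinb_gene: need >= 20 cells")
  if (all(y == 0)) stop("fit_zinb_gene: all counts are zero; exclude gene upstream")
  offsets <- rep_len(offsets, length(y))

  pos_mean <- mean(y / exp(offsets))
  start <- c(stats::qlogis(0.1), log(max(pos_mean, 1e-3)), 0)
  opt <- stats::optim(start, zinb_negll, gr = zinb_negll_grad,
                      y = y, offsets = offsets,
                      method = "L-BFGS-B",
                      lower = c(-12, -30, -7), upper = c(12, 30, 7),
                      control = list(maxit = 500))
  list(pi = stats::plogis(opt$par[1]),
       b0 = opt$par[2],
       size = exp(opt$par[3]),
       mu = exp(opt$par[2] + offsets),
       loglik = -opt$value,
       convergence = opt$convergence)
}

#' ZINB dropout weights
#'
#' Converts per-gene ZINB fits into observation weights: a positive count is
#' a certain NB observation (weight 1); a zero is weighted by the posterior
#' probability that it came from the NB component,
#' `(1 - pi) f_NB(0) / (pi + (1 - pi) f_NB(0))`, which lies in (0, 1].
#'
#' @param counts genes x cells count matrix.
#' @param fits list of [fit_zinb_gene()] results, one per row of `counts`.
#' @return genes x cells weight matrix in (0, 1].
#' @export
compute_zinb_weights <- function(counts, fits) {
  counts <- as.matrix(counts)
  stopifnot(length(fits) == nrow(counts))
  w <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (g in seq_len(nrow(counts))) {
    f <- fits[[g]]
    if (is.null(f$pi) || !is.finite(f$pi) || f$pi < 0 || f$pi > 1) {
      stop("compute_zinb_weights: invalid fit for gene ", g)
    }
    z <- counts[g, ] == 0
    if (any(z)) {
      f0 <- stats::dnbinom(0, mu = f$mu[z], size = f$size)
      w[g, z] <- (1 - f$pi) * f0 / (f$pi + (1 - f$pi) * f0)
    }
  }
  w
}

#' Combine voom and dropout weights
#'
#' The model's observation weight is the elementwise product of the voom
#' precision weight and the ZINB dropout weight.
#'
#' @param voom_w,zinb_w conformable genes x cells weight matrices.
#' @return genes x cells combined weight matrix.
#' @export
combine_weights <- function(voom_w, zinb_w) {
  stopifnot(all(dim(voom_w) == dim(zinb_w)))
  voom_w * zinb_w
}
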