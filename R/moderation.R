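# Newton solve of trigamma(y) = x, vectorised; needed for the
# method-of-moments fit of the scaled inverse-chi-square variance prior.
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Empirical-Bayes variance moderation
#'
#' Shrinks per-gene residual variances toward a common prior and rescales
#' t-statistics accordingly. The prior `(d0, s0^2)` is estimated by
#' closed-form method of moments on the log residual variances (matching the
#' scaled-F model of the limma framework): with `z_g = log s_g^2`,
#' `E z_g = digamma(df_g/2) - log(df_g/2) + log s0^2 - digamma(d0/2) + log(d0/2)`
#' and `Var z_g = trigamma(df_g/2) + trigamma(d0/2)`. The posterior variance is
#' `s~_g^2 = (d0 s0^2 + df_g s_g^2) / (d0 + df_g)` and the moderated t for a
#' coefficient is the ordinary t scaled by `s_g/s~_g`, on `df_g + d0` degrees
#' of freedom. `d0 = 0` reproduces ordinary t-statistics; `d0 = Inf` shrinks
#' every variance fully to `s0^2`.
#'
#' @param beta genes x contrasts coefficient matrix.
#' @param se genes x contrasts standard-error matrix (from the per-gene fits).
#' @param sigma2 per-gene residual variances.
#' @param df per-gene residual degrees of freedom (scalar or vector).
#' @param ebayes optional list(d0, s0_sq) overriding the estimated prior.
#' @return list(t = moderated t matrix, p = two-sided p matrix,
#'   s2_post = posterior variances, d0, s0_sq, df_total).
#' @export
moderate_statistics <- function(beta, se, sigma2, df, ebayes = NULL) {
  beta <- as.matrix(beta); se <- as.matrix(se)
  G <- nrow(beta)
  if (is.null(ebayes) && G < 20) {
    stop("moderate_statistics: need >= 20 genes to estimate the prior")
  }
  df <- rep_len(df, G)
  stopifnot(all(sigma2 > 0), all(df > 0))

  if (is.null(ebayes)) {
    z <- log(sigma2)
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    } else {
      # variances more concentrated than sampling noise allows: full shrinkage
      d0 <- Inf
      s0_sq <- exp(mean(e))
    }
  } else {
    d0 <- ebayes$d0
    s0_sq <- ebayes$s0_sq
  }

  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, G)
  } else if (d0 == 0) {
    sigma2
  } else {
    (d0 * s0_sq + df * sigma2) / (d0 + df)
  }
  scale <- sqrt(s2_post / sigma2)
  tmod <- beta / (se * scale)
  df_total <- pmin(df + d0, .Machine$double.xmax)
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  list(t = tmod, p = p, s2_post = s2_post, d0 = d0, s0_sq = s0_sq,
       df_total = df_total)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone, capped at 1, standard cumulative-minimum
#' handling of ties.
#'
#' @param p numeric vector of p-values in \[0, 1\] (no missing values).
#' @return adjusted p-values in input order.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(!is.finite(p))) stop("bh_fdr: p-values must be finite")
  if (any(p < 0 | p > 1)) stop("bh_fdr: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' A gene is a DEG for a contrast iff all three criteria hold: expressed in
#' at least `min_expr_frac` of the analysed MAIT cells, absolute log-fold
#' change (the fitted coefficient) at least `min_abs_lfc`, and FDR-adjusted
#' p-value below `max_fdr`. Direction is the sign of the coefficient.
#'
#' @param results per-gene fit table as returned by [de_analysis()]: must
#'   contain `gene`, `expressed_frac` and per-contrast columns
#'   `beta_<c>`, `fdr_<c>`.
#' @param contrasts contrast names (e.g. c("day2", "day4", "day7")).
#' @param min_expr_frac expression-fraction criterion (default 0.05).
#' @param min_abs_lfc absolute log-fold-change criterion (default 0.4).
#' @param max_fdr FDR criterion (default 0.01; 0.05 reproduces the relaxed
#'   convention some displays use).
#' @return Long data.frame: gene, contrast, beta, fdr_p, expressed_frac,
#'   deg (logical), direction ("up"/"down"/NA).
#' @export
call_degs <- function(results, contrasts, min_expr_frac = 0.05,
                      min_abs_lfc = 0.4, max_fdr = 0.01) {
  out <- do.call(rbind, lapply(contrasts, function(ct) {
    beta <- results[[paste0("beta_", ct)]]
    fdr <- results[[paste0("fdr_", ct)]]
    deg <- results$expressed_frac >= min_expr_frac &
      abs(beta) >= min_abs_lfc &
      fdr < max_fdr
    data.frame(gene = results$gene, contrast = ct, beta = beta, fdr_p = fdr,
               expressed_frac = results$expressed_frac, deg = deg,
               direction = ifelse(deg, ifelse(beta > 0, "up", "down"), NA),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Up/down DEG counts and the direction-by-time chi-square test
#'
#' Tabulates DEG directions per contrast into a 2 x T contingency table and
#' tests independence of direction and time point with a Pearson chi-square
#' test (no continuity correction).
#'
#' @param x either the long DEG table from [call_degs()] (rows with
#'   `deg = TRUE` are used) or a 2 x T numeric matrix of up/down counts.
#' @return list(table = 2 x T matrix (rows up/down), statistic, df, p).
#' @export
direction_summary <- function(x) {
  if (is.matrix(x)) {
    tab <- x
    if (is.null(rownames(tab))) rownames(tab) <- c("up", "down")
  } else {
    d <- x[x$deg, , drop = FALSE]
    if (nrow(d) == 0) stop("direction_summary: no DEGs to tabulate")
    tab <- table(factor(d$direction, levels = c("up", "down")), d$contrast)
    tab <- unclass(tab)
  }
  if (any(dim(tab) < 2)) stop("direction_summary: need >= 2 contrasts with calls")
  # small tables trip the asymptotic-approximation warning; the Pearson
  # statistic itself is still the quantity reported
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p = ct$p.value)
}
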