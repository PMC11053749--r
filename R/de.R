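#' Repeated-measures weighted mixed-model differential expression
#'
#' End-to-end differential-expression engine for a MAIT-cell count matrix:
#' (1) genes expressed in fewer than `min_expr_frac` of cells are dropped
#' (matching the DEG universe and stabilising the dropout fits);
#' (2) the response is library-size log-normalized expression;
#' (3) observation weights are the product of voom precision weights and
#' ZINB dropout weights; (4) each gene is fitted with the weighted
#' random-subject-intercept model of [fit_weighted_lmm()]; (5) per-contrast
#' t-statistics are empirically moderated and BH-adjusted; (6) DEGs are
#' called on the expression-fraction / |LogFc| / FDR criteria.
#'
#' @param counts genes x cells raw UMI matrix (MAIT cells).
#' @param meta per-cell metadata aligned to columns: subject, timepoint.
#' @param timepoint_levels ordered time-point levels, baseline first.
#' @param min_expr_frac expression-fraction filter and DEG criterion.
#' @param min_abs_lfc,max_fdr DEG criteria (defaults 0.4 and 0.01).
#' @param scale_factor log-normalization scale factor.
#' @param use_zinb_weights,use_voom_weights toggles for the two weight
#'   layers (both on by default; turning both off gives the unweighted
#'   mixed model).
#' @return list: `table` (per-gene fits and statistics), `degs` (long DEG
#'   table from [call_degs()]), `ebayes` (list(d0, s0_sq)), `contrasts`,
#'   `weights` (list(voom, zinb, combined)), `design`.
#' @export
de_analysis <- function(counts, meta,
                        timepoint_levels = c("baseline", "day2", "day4", "day7"),
                        min_expr_frac = 0.05,
                        min_abs_lfc = 0.4,
                        max_fdr = 0.01,
                        scale_factor = 1e4,
                        use_zinb_weights = TRUE,
                        use_voom_weights = TRUE) {
  stopifnot(ncol(counts) == nrow(meta),
            all(c("subject", "timepoint") %in% names(meta)))
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("de_analysis: zero-total cells present")

  expressed_frac <- Matrix::rowMeans(counts > 0)
  keep <- expressed_frac >= min_expr_frac
  if (sum(keep) < 20) stop("de_analysis: fewer than 20 genes pass the expression filter")
  sub <- as.matrix(counts[keep, , drop = FALSE])

  design <- timepoint_design(meta$timepoint, timepoint_levels)
  contrasts <- colnames(design)[-1]
  norm <- as.matrix(log_normalize(counts, scale_factor))[keep, , drop = FALSE]

  voom_w <- if (use_voom_weights) {
    compute_voom_weights(sub, design, lib_size = lib)
  } else matrix(1, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  offsets <- log(lib) - mean(log(lib))
  zinb_fits <- NULL
  zinb_w <- if (use_zinb_weights) {
    zinb_fits <- apply(sub, 1, fit_zinb_gene, offsets = offsets,
                       simplify = FALSE)
    compute_zinb_weights(sub, zinb_fits)
  } else matrix(1, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  w <- combine_weights(voom_w, zinb_w)

  G <- nrow(sub)
  nc <- length(contrasts)
  beta <- se <- matrix(NA_real_, G, nc, dimnames = list(rownames(sub), contrasts))
  beta0 <- sigma2 <- tau2 <- df <- numeric(G)
  for (g in seq_len(G)) {
    fit <- fit_weighted_lmm(norm[g, ], design, w[g, ], meta$subject)
    beta0[g] <- fit$beta[1]
    beta[g, ] <- fit$beta[-1]
    se[g, ] <- fit$se[-1]
    sigma2[g] <- fit$sigma2
    tau2[g] <- fit$tau2
    df[g] <- fit$df_residual
  }

  mod <- moderate_statistics(beta, se, sigma2, df)
  fdr <- apply(mod$p, 2, bh_fdr)

  tab <- data.frame(gene = rownames(sub),
                    expressed_frac = expressed_frac[keep],
                    beta0 = beta0, tau2 = tau2, sigma2 = sigma2,
                    df_residual = df,
                    stringsAsFactors = FALSE)
  for (ct in contrasts) {
    tab[[paste0("beta_", ct)]] <- beta[, ct]
    tab[[paste0("se_", ct)]] <- se[, ct]
    tab[[paste0("t_", ct)]] <- mod$t[, ct]
    tab[[paste0("p_", ct)]] <- mod$p[, ct]
    tab[[paste0("fdr_", ct)]] <- fdr[, ct]
  }
  rownames(tab) <- NULL

  degs <- call_degs(tab, contrasts, min_expr_frac = min_expr_frac,
                    min_abs_lfc = min_abs_lfc, max_fdr = max_fdr)
  list(table = tab, degs = degs,
       ebayes = list(d0 = mod$d0, s0_sq = mod$s0_sq),
       contrasts = contrasts,
       weights = list(voom = voom_w, zinb = zinb_w, combined = w),
       zinb_fits = zinb_fits,
       design = design)
}
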