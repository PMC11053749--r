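#' Per-cell quality-control metrics
#'
#' Computes the three standard droplet QC metrics: number of detected
#' features (genes with count > 0), mitochondrial fraction (counts on genes
#' whose name matches `mito_pattern`, divided by total counts; 0 by convention
#' for an all-zero cell) and total UMI counts.
#'
#' @param counts genes x cells count matrix (sparse or dense, non-negative).
#' @param mito_pattern regular expression identifying mitochondrial genes by
#'   feature name; default the human "MT-" prefix, case-insensitive.
#' @return data.frame(barcode, n_features, mito_fraction, total_counts).
#' @export
compute_qc_metrics <- function(counts, mito_pattern = "^MT-") {
  if (nrow(counts) == 0) stop("compute_qc_metrics: matrix has no genes")
  if (is.null(rownames(counts))) stop("compute_qc_metrics: rownames required")
  total <- Matrix::colSums(counts)
  nfeat <- Matrix::colSums(counts > 0)
  mito <- grepl(mito_pattern, rownames(counts), ignore.case = TRUE)
  mito_counts <- if (any(mito)) {
    Matrix::colSums(counts[mito, , drop = FALSE])
  } else rep(0, ncol(counts))
  frac <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(barcode = colnames(counts),
             n_features = as.integer(nfeat),
             mito_fraction = as.numeric(frac),
             total_counts = as.numeric(total),
             stringsAsFactors = FALSE)
}

#' Filter cells on QC metrics
#'
#' Retains cells with `min_features <= n_features <= max_features` and
#' `mito_fraction <= max_mito`. Bounds are inclusive on the feature counts
#' and on the mitochondrial fraction, i.e. a cell at exactly 200 or 7500
#' features, or at exactly 10\% mitochondrial reads, passes; only strictly
#' worse cells are removed. Cell order is preserved; filtering is idempotent.
#'
#' @param counts genes x cells matrix.
#' @param metrics output of [compute_qc_metrics()] aligned to `counts`.
#' @param max_mito maximum mitochondrial fraction (default 0.10).
#' @param min_features,max_features detected-feature bounds (default 200,
#'   7500).
#' @return The column-subset matrix (possibly with zero columns).
#' @export
filter_cells <- function(counts, metrics, max_mito = 0.10,
                         min_features = 200, max_features = 7500) {
  stopifnot(nrow(metrics) == ncol(counts))
  keep <- metrics$n_features >= min_features &
    metrics$n_features <= max_features &
    metrics$mito_fraction <= max_mito
  counts[, keep, drop = FALSE]
}

#' Library-size log-normalization
#'
#' Scales each cell to `scale_factor` total counts and applies log1p:
#' `value = ln(1 + scale_factor * count / cell_total)`. Zeros map to zeros,
#' so sparsity is preserved, and the transform is invariant to rescaling a
#' cell's depth.
#'
#' @param counts genes x cells matrix with positive column sums.
#' @param scale_factor target library size (default 1e4).
#' @return A sparse genes x cells matrix of log-normalized values.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  total <- Matrix::colSums(counts)
  if (any(total == 0)) {
    stop("log_normalize: zero-total cells present; filter cells first")
  }
  x <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  x@x <- log1p(x@x * scale_factor / rep.int(total, diff(x@p)))
  x
}

#' Select highly variable genes
#'
#' Ranks genes by standardized variance: a loess trend of log10(variance) on
#' log10(mean) is fitted to the raw counts, each observation is z-scored with
#' the trend-predicted SD, clipped at sqrt(n_cells), and the variance of the
#' clipped z-scores is the ranking statistic (the vst selection used by the
#' standard single-cell workflow). Constant genes get standardized variance 0
#' and rank last.
#'
#' @param counts genes x cells raw count matrix.
#' @param n_top number of genes to keep (default 2000); all genes are
#'   returned if fewer are available.
#' @return Character vector of selected gene names, highest variance first.
#' @export
select_hvg <- function(counts, n_top = 2000) {
  x <- as.matrix(counts)
  mu <- rowMeans(x)
  v <- apply(x, 1, stats::var)
  std_var <- numeric(nrow(x))
  fit_ok <- v > 0 & mu > 0
  if (sum(fit_ok) >= 3) {
    tr <- stats::loess(log10(v[fit_ok]) ~ log10(mu[fit_ok]), span = 0.3)
    sd_exp <- sqrt(10^stats::predict(tr, newdata = log10(mu[fit_ok])))
    clip <- sqrt(ncol(x))
    z <- (x[fit_ok, , drop = FALSE] - mu[fit_ok]) / sd_exp
    z <- pmin(pmax(z, -clip), clip)
    std_var[fit_ok] <- rowSums(z^2) / (ncol(x) - 1)
  } else {
    std_var[fit_ok] <- v[fit_ok]
  }
  names(std_var) <- rownames(x)
  n_top <- min(n_top, nrow(x))
  names(sort(std_var, decreasing = TRUE))[seq_len(n_top)]
}

#' Principal components of the normalized expression
#'
#' Centers each gene and computes the first `n_components` principal
#' component scores of the cells (cells x components), via the exact SVD of
#' the centered matrix. Component variances are non-increasing.
#'
#' @param norm genes x cells normalized matrix (typically restricted to the
#'   highly variable genes).
#' @param n_components number of components (default 20).
#' @return list(scores = cells x n_components matrix, sdev = component SDs).
#' @export
run_pca <- function(norm, n_components = 20) {
  x <- t(as.matrix(norm))  # cells x genes
  if (n_components > min(dim(x))) {
    stop("run_pca: n_components exceeds matrix rank bound")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       sdev = pc$sdev[seq_len(n_components)])
}

#' Gate MAIT cells on marker co-expression
#'
#' Flags a cell as MAIT when the normalized expression of every marker gene
#' (KLRB1 and SLC4A10 by default) exceeds `min_expr`. The rule is a strict
#' conjunction: a cell positive for one marker only is not called.
#'
#' @param norm genes x cells normalized matrix with gene rownames.
#' @param meta per-cell metadata data.frame aligned to columns of `norm`;
#'   must contain `barcode`. If a `timepoint` column is present, per-condition
#'   MAIT counts and percentages are attached as an attribute.
#' @param markers marker gene names required to be co-expressed.
#' @param min_expr expression threshold (default 0: any positive expression).
#' @return `meta` with an `is_mait` logical column; per-condition summary in
#'   `attr(, "mait_summary")` when time points are available.
#' @export
gate_maits <- function(norm, meta, markers = c("KLRB1", "SLC4A10"),
                       min_expr = 0) {
  missing <- setdiff(markers, rownames(norm))
  if (length(missing)) {
    stop("gate_maits: marker gene(s) not in matrix: ",
         paste(missing, collapse = ", "))
  }
  stopifnot(nrow(meta) == ncol(norm))
  expr <- as.matrix(norm[markers, , drop = FALSE])
  meta$is_mait <- apply(expr > min_expr, 2, all)
  if ("timepoint" %in% names(meta)) {
    tab <- tapply(meta$is_mait, meta$timepoint, sum)
    tot <- tapply(meta$is_mait, meta$timepoint, length)
    attr(meta, "mait_summary") <- data.frame(
      timepoint = names(tab),
      n_mait = as.integer(tab),
      n_cells = as.integer(tot),
      pct_mait = 100 * as.integer(tab) / as.integer(tot),
      stringsAsFactors = FALSE)
  }
  meta
}

#' One-way ANOVA on per-sample MAIT counts
#'
#' Compares the number of MAIT cells per subject-by-time sample across
#' conditions with a standard one-way ANOVA.
#'
#' @param meta per-cell metadata with columns subject, timepoint, is_mait.
#' @return list(F = F statistic, p = p-value, table = per-sample counts).
#' @export
compare_mait_counts <- function(meta) {
  stopifnot(all(c("subject", "timepoint", "is_mait") %in% names(meta)))
  per_sample <- stats::aggregate(is_mait ~ subject + timepoint, data = meta,
                                 FUN = sum)
  names(per_sample)[3] <- "n_mait"
  n_per_cond <- table(per_sample$timepoint)
  if (length(n_per_cond) < 2 || any(n_per_cond < 2)) {
    stop("compare_mait_counts: need >= 2 conditions with >= 2 samples each")
  }
  if (stats::var(per_sample$n_mait) == 0) {
    # degenerate: no variation at all -> no evidence of condition effect
    return(list(F = 0, p = 1, table = per_sample))
  }
  fit <- stats::aov(n_mait ~ timepoint, data = per_sample)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], table = per_sample)
}
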