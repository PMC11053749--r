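#' Resting energy expenditure (Mifflin-St Jeor)
#'
#' Computes resting energy expenditure in kcal/day from weight, height, age
#' and sex using the Mifflin-St Jeor equation,
#' \deqn{REE = 9.99 w + 6.25 h - 4.92 a + 166 s - 161,}
#' with weight in kg, height in cm, age in years and `sex` coded male = 1,
#' female = 0. This is the basal component of the caloric prescription used
#' to individualise a dietary-restriction intervention; activity adjustment
#' is outside the scope of this package.
#'
#' @param weight_kg body mass in kilograms (finite, positive).
#' @param height_cm stature in centimetres (finite, positive).
#' @param age_yr age in years (finite, non-negative).
#' @param sex 1 for male, 0 for female.
#' @return Resting energy expenditure in kcal/day (vectorised).
#' @examples
#' compute_ree(70, 175, 25, 1) # 1675.05
#' @export
compute_ree <- function(weight_kg, height_cm, age_yr, sex) {
  args <- cbind(weight_kg, height_cm, age_yr, sex)
  if (!all(is.finite(args))) {
    stop("compute_ree: all inputs must be finite numbers")
  }
  if (!all(sex %in% c(0, 1))) {
    stop("compute_ree: sex must be coded male = 1, female = 0")
  }
  9.99 * weight_kg + 6.25 * height_cm - 4.92 * age_yr + 166 * sex - 161
}

#' Participant characteristics table
#'
#' Returns the bundled seven-participant demographics table (sex, age, BMI,
#' prescribed daily energy requirement) used for cohort summary statistics.
#'
#' @return A data.frame with one row per participant.
#' @export
participant_table <- function() {
  path <- system.file("extdata", "participants.tsv", package = "stdrmait",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Repeated-measures single-cell study design
#'
#' Describes the sampling layout the simulator emulates: `n_subjects`
#' participants each measured at every time point, with a fixed number of
#' cells retained per subject-by-time sample. The first time point is the
#' reference (baseline) level for all downstream contrasts.
#'
#' @param n_subjects number of participants (>= 2).
#' @param timepoints ordered character vector of time-point labels; the first
#'   is the baseline.
#' @param cells_per_sample cells simulated per subject-time sample.
#' @param seed integer RNG seed recorded with the design.
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 7,
                         timepoints = c("baseline", "day2", "day4", "day7"),
                         cells_per_sample = 50,
                         seed = 1L) {
  stopifnot(n_subjects >= 2, length(timepoints) >= 2, !anyDuplicated(timepoints))
  if (cells_per_sample < 1) stop("cells_per_sample must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 timepoints = as.character(timepoints),
                 cells_per_sample = as.integer(cells_per_sample),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' Parameters for the zero-inflated NB single-cell simulator
#'
#' The simulator draws UMI counts per gene and cell from a zero-inflated
#' negative binomial: with probability `pi = plogis(dropout_logit_intercept)`
#' a structural zero is emitted, otherwise an NB count with
#' `log mean = log(base mean) + log(lib/1e4) + subject effect + time effect`.
#' The NB is parameterised by mean `mu` and size `k` (Var = mu + mu^2/k).
#' Subject effects are `N(0, tau^2)`; a fraction `de_fraction` of genes carry
#' the per-time-point log-fold-changes in `beta_true`. Baseline per-gene mean
#' counts (at a 1e4 library) are lognormal(`base_log_mean`, `base_log_sd`);
#' library sizes are lognormal around 1e4 with sd `lib_size_lognorm_sd` on the
#' log scale. The first two genes are named after the MAIT marker genes
#' KLRB1 and SLC4A10 and are forced high in cells designated MAIT-like
#' (a fraction `mait_fraction` of cells) and structurally zero elsewhere, so
#' marker gating can be validated against exact truth labels.
#'
#' @param n_genes number of genes (including the two markers).
#' @param de_fraction fraction of non-marker genes carrying `beta_true`.
#' @param beta_true numeric vector of log-fold-changes, one per non-baseline
#'   time point (recycled if shorter).
#' @param sign_mix fraction of DE genes whose planted log-fold-changes are
#'   negated, so the simulation carries both up- and down-regulation
#'   (default 0.5).
#' @param tau SD of the subject random intercept (>= 0).
#' @param nb_dispersion NB size parameter k (> 0).
#' @param dropout_logit_intercept logit of the structural-zero probability.
#' @param lib_size_lognorm_sd log-scale SD of library sizes.
#' @param base_log_mean,base_log_sd lognormal parameters of baseline per-gene
#'   mean counts at a 1e4 library.
#' @param mait_fraction fraction of cells designated MAIT-like.
#' @param marker_mean NB mean of the marker genes in MAIT-like cells, on top
#'   of a floor of 5 counts that guarantees positive normalized expression.
#' @return An `sc_sim_params` list.
#' @export
sc_sim_params <- function(n_genes = 2000,
                          de_fraction = 0.1,
                          beta_true = c(0.6, 0.6, 0.6),
                          sign_mix = 0.5,
                          tau = 0.3,
                          nb_dispersion = 2,
                          dropout_logit_intercept = -1.5,
                          lib_size_lognorm_sd = 0.3,
                          base_log_mean = log(5),
                          base_log_sd = 1,
                          mait_fraction = 1,
                          marker_mean = 10) {
  stopifnot(n_genes >= 3,
            de_fraction >= 0, de_fraction <= 1,
            sign_mix >= 0, sign_mix <= 1,
            tau >= 0, nb_dispersion > 0,
            lib_size_lognorm_sd >= 0,
            mait_fraction >= 0, mait_fraction <= 1)
  structure(as.list(environment()), class = "sc_sim_params")
}

#' Simulate a repeated-measures single-cell UMI count matrix
#'
#' Draws a genes-by-cells sparse UMI matrix under the design and ZINB model
#' described in [sc_sim_params()], together with per-cell metadata and a
#' per-gene truth table recording which genes carry differential expression
#' and with which log-fold-changes.
#'
#' @param design a [study_design()].
#' @param params an [sc_sim_params()].
#' @return A list with elements `counts` (dgCMatrix, genes x cells, dimnames
#'   set), `meta` (data.frame: barcode, subject, timepoint, is_mait), and
#'   `truth` (data.frame: gene, is_de, one beta column per non-baseline time
#'   point).
#' @export
simulate_sc_counts <- function(design, params = sc_sim_params()) {
  stopifnot(inherits(design, "study_design"), inherits(params, "sc_sim_params"))
  if (design$cells_per_sample == 0) stop("cells_per_sample must be positive")
  set.seed(design$seed)

  tps <- design$timepoints
  n_tp <- length(tps)
  n_contr <- n_tp - 1L
  subjects <- sprintf("S%02d", seq_len(design$n_subjects))
  meta <- expand.grid(cell = seq_len(design$cells_per_sample),
                      timepoint = tps, subject = subjects,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_cells <- nrow(meta)
  meta$barcode <- sprintf("%s_%s_c%03d", meta$subject, meta$timepoint, meta$cell)
  meta$cell <- NULL

  genes <- c("KLRB1", "SLC4A10", sprintf("G%04d", seq_len(params$n_genes - 2L)))
  n_genes <- params$n_genes

  # truth: which non-marker genes carry the planted time effects
  beta <- matrix(0, n_genes, n_contr,
                 dimnames = list(genes, paste0("beta_", tps[-1])))
  n_de <- floor(params$de_fraction * (n_genes - 2L))
  de_idx <- if (n_de > 0) 2L + sample.int(n_genes - 2L, n_de) else integer(0)
  if (n_de > 0) {
    bt <- rep_len(params$beta_true, n_contr)
    sgn <- ifelse(stats::runif(n_de) < params$sign_mix, -1, 1)
    beta[de_idx, ] <- sgn * matrix(bt, n_de, n_contr, byrow = TRUE)
  }
  truth <- data.frame(gene = genes, is_de = seq_len(n_genes) %in% de_idx, beta)

  lib <- exp(stats::rnorm(n_cells, log(1e4), params$lib_size_lognorm_sd))
  alpha <- stats::rnorm(design$n_subjects, 0, params$tau)
  names(alpha) <- subjects
  base_mean <- exp(stats::rnorm(n_genes, params$base_log_mean, params$base_log_sd))
  tp_idx <- match(meta$timepoint, tps) - 1L   # 0 = baseline

  is_mait <- stats::runif(n_cells) < params$mait_fraction
  meta$is_mait <- is_mait

  # per-cell time-effect column selector (0 -> no effect)
  eff <- matrix(0, n_genes, n_cells)
  nz <- tp_idx > 0L
  if (any(nz)) eff[, nz] <- beta[, tp_idx[nz], drop = FALSE]

  log_mu <- log(base_mean) +
    eff +
    matrix(log(lib / 1e4) + alpha[meta$subject], n_genes, n_cells, byrow = TRUE)
  counts <- matrix(stats::rnbinom(n_genes * n_cells,
                                  mu = exp(log_mu),
                                  size = params$nb_dispersion),
                   n_genes, n_cells)
  pi0 <- stats::plogis(params$dropout_logit_intercept)
  if (pi0 > 0) {
    counts[stats::runif(n_genes * n_cells) < pi0] <- 0L
  }
  # markers: floored high in MAIT-like cells, structural zero elsewhere
  for (m in 1:2) {
    mk <- integer(n_cells)
    mk[is_mait] <- 5L + stats::rnbinom(sum(is_mait), mu = params$marker_mean,
                                       size = params$nb_dispersion)
    counts[m, ] <- mk
  }
  dimnames(counts) <- list(genes, meta$barcode)
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       meta = meta[, c("barcode", "subject", "timepoint", "is_mait")],
       truth = truth)
}

#' Parameters for the compositional microbiome simulator
#'
#' Samples are drawn per condition (baseline / day4 / day7 by default, with
#' the 7 + 5 + 7 stool schedule of a seven-participant cohort missing two
#' day-4 samples). Expected relative abundances are the softmax of per-species
#' base log-abundances plus a condition shift (log2 scale) plus lognormal
#' sample noise; sparsity is induced by zeroing each species-sample proportion
#' with probability `prevalence_sparsity` before renormalising; counts are
#' multinomial at `sequencing_depth`.
#'
#' @param n_species number of species.
#' @param n_samples_per_condition named integer vector of sample counts.
#' @param base_log_abundances optional vector of base log-abundances; drawn
#'   N(0, 1.5) if NULL.
#' @param effect_log2fc optional n_species x n_conditions matrix of log2
#'   shifts (baseline column must be zero). If NULL, a fraction
#'   `effect_fraction` of species get +/-`effect_size_log2` at day 4 and no
#'   shift at day 7 (the rebound the intervention literature reports).
#' @param effect_fraction,effect_size_log2 used only when `effect_log2fc` is
#'   NULL.
#' @param sequencing_depth multinomial depth per sample (> 0).
#' @param prevalence_sparsity per-entry structural zero probability.
#' @param sample_noise_sd lognormal noise SD on the log-abundance scale.
#' @param seed integer RNG seed.
#' @return A `microbiome_sim_params` list.
#' @export
microbiome_sim_params <- function(n_species = 150,
                                  n_samples_per_condition = c(baseline = 7, day4 = 5, day7 = 7),
                                  base_log_abundances = NULL,
                                  effect_log2fc = NULL,
                                  effect_fraction = 0.1,
                                  effect_size_log2 = 4,
                                  sequencing_depth = 1e5,
                                  prevalence_sparsity = 0.1,
                                  sample_noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(n_species >= 2, length(n_samples_per_condition) >= 2,
            all(n_samples_per_condition >= 1),
            prevalence_sparsity >= 0, prevalence_sparsity < 1,
            sample_noise_sd >= 0)
  if (sequencing_depth <= 0) stop("sequencing_depth must be positive")
  structure(as.list(environment()), class = "microbiome_sim_params")
}

#' Simulate a species-by-sample microbiome count table
#'
#' @param params a [microbiome_sim_params()].
#' @return A list with `table` (a `taxa_table`: counts matrix + sample
#'   metadata + feature kind) and `truth` (data.frame: species, is_de and the
#'   log2 shift per condition).
#' @seealso [taxa_table()]
#' @export
simulate_microbiome_counts <- function(params = microbiome_sim_params()) {
  stopifnot(inherits(params, "microbiome_sim_params"))
  set.seed(params$seed)
  n_sp <- params$n_species
  conds <- names(params$n_samples_per_condition)
  species <- sprintf("sp%03d", seq_len(n_sp))

  base <- params$base_log_abundances
  if (is.null(base)) base <- stats::rnorm(n_sp, 0, 1.5)
  stopifnot(length(base) == n_sp)

  eff <- params$effect_log2fc
  if (is.null(eff)) {
    eff <- matrix(0, n_sp, length(conds), dimnames = list(species, conds))
    n_de <- floor(params$effect_fraction * n_sp)
    if (n_de > 0 && "day4" %in% conds) {
      de_idx <- sample.int(n_sp, n_de)
      eff[de_idx, "day4"] <- sample(c(-1, 1), n_de, replace = TRUE) *
        params$effect_size_log2
    }
  }
  stopifnot(nrow(eff) == n_sp, ncol(eff) == length(conds))
  if (any(eff[, 1] != 0)) stop("baseline column of effect_log2fc must be zero")

  sample_ids <- character(0)
  cond_of <- character(0)
  counts <- NULL
  for (ci in seq_along(conds)) {
    for (r in seq_len(params$n_samples_per_condition[ci])) {
      loga <- base + eff[, ci] * log(2) +
        stats::rnorm(n_sp, 0, params$sample_noise_sd)
      p <- exp(loga - max(loga))
      p[stats::runif(n_sp) < params$prevalence_sparsity] <- 0
      if (sum(p) == 0) p[which.max(loga)] <- 1
      p <- p / sum(p)
      cnt <- stats::rmultinom(1, size = params$sequencing_depth, prob = p)
      counts <- cbind(counts, cnt[, 1])
      sample_ids <- c(sample_ids, sprintf("%s_s%02d", conds[ci], r))
      cond_of <- c(cond_of, conds[ci])
    }
  }
  dimnames(counts) <- list(species, sample_ids)
  truth <- data.frame(species = species,
                      is_de = rowSums(eff != 0) > 0,
                      eff, check.names = FALSE)
  names(truth)[-(1:2)] <- paste0("log2fc_", conds)
  list(table = taxa_table(counts,
                          data.frame(sample = sample_ids, condition = cond_of,
                                     stringsAsFactors = FALSE)),
       truth = truth)
}

#' Write a single-cell fixture in 10x-style plain-text layout
#'
#' Emits `matrix.mtx` (Matrix Market, 1-based coordinates), `features.tsv`
#' and `barcodes.tsv` (tab-separated, no header) and `metadata.tsv` (header:
#' barcode, subject, timepoint, ...) under `out_dir`. The round trip through
#' [read_fixture()] is lossless.
#'
#' @param counts genes x cells matrix (sparse or dense).
#' @param meta data.frame with a `barcode` column aligned to `colnames(counts)`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(counts, meta, out_dir) {
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  if (ncol(counts) != nrow(meta)) {
    stop("write_fixture: meta rows must match matrix columns")
  }
  if (!all(meta$barcode == colnames(counts))) {
    stop("write_fixture: meta$barcode must equal colnames(counts)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(counts, file.path(out_dir, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(counts), name = rownames(counts),
               type = "Gene Expression"),
    file.path(out_dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(counts)),
                     file.path(out_dir, "barcodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(meta, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Read a fixture written by [write_fixture()]
#'
#' @param dir directory holding matrix.mtx / features.tsv / barcodes.tsv /
#'   metadata.tsv.
#' @return list(counts = dgCMatrix with dimnames, meta = data.frame).
#' @export
read_fixture <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  read_col <- function(f) {
    lines <- readLines(f, warn = FALSE)
    if (length(lines) == 0) return(character(0))
    vapply(strsplit(lines, "\t", fixed = TRUE), `[`, character(1), 1)
  }
  dimnames(counts) <- list(read_col(file.path(dir, "features.tsv")),
                           read_col(file.path(dir, "barcodes.tsv")))
  meta_path <- file.path(dir, "metadata.tsv")
  meta <- if (file.exists(meta_path)) {
    utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else NULL
  list(counts = counts, meta = meta)
}
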