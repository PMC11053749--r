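#' Default pipeline configuration
#'
#' Every analysis threshold is a named key defaulting to the study's value:
#' 10\% mitochondrial cutoff, 200/7500 feature bounds, 2000 variable genes,
#' 20 principal components, 5\% expression filter, 0.4 |LogFc|, FDR 0.01
#' (DEGs) / 0.05 (pathways) / 0.01 (regulators), 60\%/80\% prevalence,
#' species FDR 0.10, pathway FDR 0.05, |z| 2.0.
#'
#' @param seed integer seed recorded in the report and used for every stage.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = list(simulate = TRUE, qc = TRUE, de = TRUE,
                  enrich = TRUE, microbiome = TRUE),
    design = list(n_subjects = 7, cells_per_sample = 50,
                  timepoints = c("baseline", "day2", "day4", "day7")),
    sc_sim = list(n_genes = 2000),
    qc = list(max_mito = 0.10, min_features = 200, max_features = 7500,
              n_hvg = 2000, n_pcs = 20,
              markers = c("KLRB1", "SLC4A10")),
    de = list(min_expr_frac = 0.05, min_abs_lfc = 0.4, max_fdr = 0.01),
    enrich = list(fdr_cut = 0.05, regulator_fdr_cut = 0.01, z_cut = 2.0,
                  gmt = system.file("extdata", "toy_pathways.gmt",
                                    package = "stdrmait")),
    microbiome = list(species_prevalence = 0.60, pathway_prevalence = 0.80,
                      species_fdr = 0.10, pathway_fdr = 0.05,
                      effect_cut = 1.0, n_mc = 128, prior = 0.5,
                      n_species = 150, n_pathways = 80)
  )
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented range and returns all
#' violations (empty character vector when the configuration is valid).
#'
#' @param config configuration list (see [default_config()]).
#' @return Character vector of error messages, one per violated constraint.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  chk(is.numeric(config$seed), "seed: must be numeric")
  chk(in01(config$qc$max_mito), "qc$max_mito: must lie in [0, 1]")
  chk(config$qc$min_features >= 0, "qc$min_features: must be >= 0")
  chk(config$qc$max_features >= config$qc$min_features,
      "qc$max_features: must be >= qc$min_features")
  chk(in01(config$de$min_expr_frac), "de$min_expr_frac: must lie in [0, 1]")
  chk(config$de$min_abs_lfc >= 0, "de$min_abs_lfc: must be >= 0")
  chk(in01(config$de$max_fdr) && config$de$max_fdr > 0,
      "de$max_fdr: must lie in (0, 1]")
  chk(in01(config$enrich$fdr_cut) && config$enrich$fdr_cut > 0,
      "enrich$fdr_cut: must lie in (0, 1]")
  chk(config$enrich$z_cut >= 0, "enrich$z_cut: must be >= 0")
  chk(is.numeric(config$microbiome$species_prevalence) &&
        config$microbiome$species_prevalence > 0 &&
        config$microbiome$species_prevalence <= 1,
      "microbiome$species_prevalence: must lie in (0, 1]")
  chk(is.numeric(config$microbiome$pathway_prevalence) &&
        config$microbiome$pathway_prevalence > 0 &&
        config$microbiome$pathway_prevalence <= 1,
      "microbiome$pathway_prevalence: must lie in (0, 1]")
  chk(config$microbiome$n_mc >= 2, "microbiome$n_mc: must be >= 2")
  errs
}

#' Run the full simulated analysis pipeline
#'
#' Executes the enabled stages in order — simulate, QC + MAIT gating,
#' differential expression, enrichment, microbiome differential abundance —
#' and returns (and optionally writes) a machine-readable report: cell counts
#' before/after QC, MAIT counts and percentages per condition, DEG counts
#' up/down per contrast with the direction chi-square test, enrichment call
#' counts, and differential-abundance feature counts. Deterministic under a
#' fixed seed.
#'
#' @param config configuration list (see [default_config()]) or path to a
#'   YAML file with the same structure.
#' @param outdir optional directory; when given, `report.json`, the DEG
#'   table and the DA tables are written there.
#' @return The report list, invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  config <- utils::modifyList(base, config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  ", paste(errs, collapse = "\n  "))

  report <- list(seed = config$seed,
                 stages = names(Filter(isTRUE, config$stages)))
  sim <- norm <- meta <- de <- NULL

  if (isTRUE(config$stages$simulate) || isTRUE(config$stages$qc) ||
      isTRUE(config$stages$de) || isTRUE(config$stages$enrich)) {
    if (!isTRUE(config$stages$simulate)) {
      if (any(unlist(config$stages[c("qc", "de", "enrich")]))) {
        stop("run_pipeline: downstream stages need the simulate stage enabled")
      }
    }
  }

  if (isTRUE(config$stages$simulate)) {
    des <- do.call(study_design, c(config$design, list(seed = config$seed)))
    sp <- do.call(sc_sim_params, config$sc_sim)
    sim <- simulate_sc_counts(des, sp)
    report$simulate <- list(n_genes = nrow(sim$counts),
                            n_cells = ncol(sim$counts),
                            n_de_genes_true = sum(sim$truth$is_de))
  }

  if (isTRUE(config$stages$qc)) {
    metrics <- compute_qc_metrics(sim$counts)
    filtered <- filter_cells(sim$counts, metrics,
                             max_mito = config$qc$max_mito,
                             min_features = config$qc$min_features,
                             max_features = config$qc$max_features)
    meta <- sim$meta[match(colnames(filtered), sim$meta$barcode), ]
    norm <- log_normalize(filtered)
    hvg <- select_hvg(filtered, n_top = config$qc$n_hvg)
    n_pcs <- min(config$qc$n_pcs, length(hvg) - 1, ncol(filtered) - 1)
    pcs <- run_pca(norm[hvg, , drop = FALSE], n_components = n_pcs)
    truth_mait <- meta$is_mait
    gated <- gate_maits(norm, meta, markers = config$qc$markers)
    meta$is_mait <- gated$is_mait
    anova <- compare_mait_counts(meta)
    report$qc <- list(n_cells_pre = ncol(sim$counts),
                      n_cells_post = ncol(filtered),
                      n_pcs = n_pcs,
                      mait_summary = attr(gated, "mait_summary"),
                      mait_recall = if (any(truth_mait))
                        mean(gated$is_mait[truth_mait]) else NA,
                      mait_anova_F = anova$F, mait_anova_p = anova$p)
    sim$counts <- filtered
  }

  if (isTRUE(config$stages$de)) {
    mait <- meta$is_mait
    de <- de_analysis(sim$counts[, mait, drop = FALSE], meta[mait, ],
                      timepoint_levels = config$design$timepoints,
                      min_expr_frac = config$de$min_expr_frac,
                      min_abs_lfc = config$de$min_abs_lfc,
                      max_fdr = config$de$max_fdr)
    counts_ud <- with(de$degs[de$degs$deg, ],
                      table(factor(direction, levels = c("up", "down")),
                            factor(contrast, levels = de$contrasts)))
    dirsum <- tryCatch(direction_summary(de$degs), error = function(e) NULL)
    report$de <- list(n_genes_tested = nrow(de$table),
                      deg_up = as.list(as.integer(counts_ud["up", ])) |>
                        stats::setNames(de$contrasts),
                      deg_down = as.list(as.integer(counts_ud["down", ])) |>
                        stats::setNames(de$contrasts),
                      d0 = de$ebayes$d0,
                      direction_chisq_p = if (is.null(dirsum)) NA else dirsum$p)
  }

  if (isTRUE(config$stages$enrich)) {
    db <- read_gmt(config$enrich$gmt)
    universe <- de$table$gene
    calls <- list()
    for (ct in de$contrasts) {
      d <- de$degs[de$degs$deg & de$degs$contrast == ct, ]
      if (nrow(d) == 0) next
      res <- enrich_test(d$gene,
                         stats::setNames(ifelse(d$direction == "up", 1, -1),
                                         d$gene),
                         db, universe)
      res <- call_pathways(res, fdr_cut = config$enrich$fdr_cut,
                           z_cut = config$enrich$z_cut)
      calls[[ct]] <- table(factor(res$call,
                                  levels = c("activated", "inhibited",
                                             "enriched-only", "not-significant")))
    }
    report$enrich <- lapply(calls, function(x) as.list(as.integer(x)) |>
                              stats::setNames(names(x)))
  }

  mb <- NULL
  if (isTRUE(config$stages$microbiome)) {
    sp_par <- microbiome_sim_params(n_species = config$microbiome$n_species,
                                    seed = config$seed)
    mb_sim <- simulate_microbiome_counts(sp_par)
    filt <- prevalence_filter(mb_sim$table, config$microbiome$species_prevalence)
    inst <- dirichlet_clr_instances(filt, n_mc = config$microbiome$n_mc,
                                    prior = config$microbiome$prior,
                                    seed = config$seed)
    kw <- kw_test_clr(inst)
    we <- welch_effect(inst, seed = config$seed)
    pw_par <- microbiome_sim_params(n_species = config$microbiome$n_pathways,
                                    seed = config$seed + 1L)
    pw_sim <- simulate_microbiome_counts(pw_par)
    pw_sim$table$kind <- "pathway"
    pw_filt <- prevalence_filter(pw_sim$table,
                                 config$microbiome$pathway_prevalence)
    pw <- anova_pathways(pw_filt)
    mb <- list(kw = kw, welch = we, pathways = pw)
    report$microbiome <- list(
      n_species = nrow(mb_sim$table$counts),
      n_species_prevalent = nrow(filt$counts),
      n_species_significant = sum(kw$kw_fdr_p < config$microbiome$species_fdr),
      n_species_large_effect = sum(abs(we$effect_size) > config$microbiome$effect_cut),
      n_pathways = nrow(pw_sim$table$counts),
      n_pathways_prevalent = nrow(pw_filt$counts),
      n_pathways_significant = sum(pw$fdr_p < config$microbiome$pathway_fdr))
  }

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(de)) {
      utils::write.table(de$table, file.path(outdir, "de_table.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(de$degs, file.path(outdir, "degs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(mb)) {
      utils::write.table(merge(mb$kw, mb$welch, by = "feature"),
                         file.path(outdir, "microbiome_da.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(mb$pathways, file.path(outdir, "microbiome_pathways.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(invisible(report))
  }
  report
}
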