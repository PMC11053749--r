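#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT layout (set name, description,
#' member genes). Members may carry an expected-direction annotation as a
#' `|+1` or `|-1` suffix (e.g. `TNF|+1`), mirroring the signed
#' gene-to-pathway relationships a curated knowledge base provides; plain
#' members are treated as unsigned. Duplicate members within a set are
#' deduplicated (first annotation wins); if a set name recurs, the last
#' definition wins with a warning; empty lines or member-less sets are
#' skipped with a warning.
#'
#' @param path GMT file path.
#' @return A `gene_set_db`: named list of sets, each
#'   list(genes = character, directions = named numeric of +/-1 for the
#'   annotated subset, description).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: cannot read ", path)
  lines <- readLines(path, warn = FALSE)
  db <- list()
  for (ln in lines) {
    if (!nzchar(trimws(ln))) {
      warning("read_gmt: skipping empty line")
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      warning("read_gmt: skipping set without members: ", parts[1])
      next
    }
    name <- parts[1]
    members <- parts[-(1:2)]
    members <- members[nzchar(members)]
    tok <- strsplit(members, "|", fixed = TRUE)
    genes <- vapply(tok, `[`, character(1), 1)
    dir_raw <- vapply(tok, function(t) if (length(t) > 1) t[2] else NA_character_,
                      character(1))
    dup <- duplicated(genes)
    genes <- genes[!dup]; dir_raw <- dir_raw[!dup]
    dirs <- suppressWarnings(as.numeric(dir_raw))
    if (any(!is.na(dirs) & !dirs %in% c(-1, 1))) {
      stop("read_gmt: direction annotations must be +1 or -1 in set ", name)
    }
    ann <- !is.na(dirs)
    if (name %in% names(db)) {
      warning("read_gmt: set '", name, "' listed twice; last definition wins")
    }
    db[[name]] <- list(genes = genes,
                       directions = stats::setNames(dirs[ann], genes[ann]),
                       description = parts[2])
  }
  structure(db, class = "gene_set_db")
}

#' One-sided Fisher overlap test
#'
#' Enrichment p-value of the overlap between a query gene list and a gene
#' set within a finite universe, from the one-sided (greater) Fisher exact
#' test on the 2x2 membership table — equivalently the hypergeometric upper
#' tail.
#'
#' @param deg_genes query genes (subset of `universe`).
#' @param set_genes gene-set members (subset of `universe`).
#' @param universe background gene identifiers.
#' @return p-value.
#' @export
fisher_overlap <- function(deg_genes, set_genes, universe) {
  if (length(universe) == 0) stop("fisher_overlap: empty universe")
  deg_genes <- intersect(unique(deg_genes), universe)
  set_genes <- intersect(unique(set_genes), universe)
  a <- length(intersect(deg_genes, set_genes))
  b <- length(deg_genes) - a
  c_ <- length(set_genes) - a
  d <- length(universe) - a - b - c_
  stats::fisher.test(matrix(c(a, b, c_, d), 2, 2),
                     alternative = "greater")$p.value
}

#' Directional activation z-score
#'
#' Sign-concordance activation statistic: over genes with both an observed
#' direction (from the DEG table) and an expected direction (from the set
#' annotation), `z = (n_consistent - n_inconsistent) / sqrt(n_annotated)`.
#' Positive z predicts activation, negative z inhibition. This is the
#' unweighted form of the commercial pathway-analysis z-score (no edge
#' weights or bias correction).
#'
#' @param deg_directions named numeric (+1 up / -1 down) observed directions.
#' @param set_directions named numeric (+1 / -1) expected directions.
#' @return z, or NA_real_ when no annotated overlap exists.
#' @export
activation_zscore <- function(deg_directions, set_directions) {
  common <- intersect(names(deg_directions), names(set_directions))
  if (length(common) == 0) return(NA_real_)
  concord <- deg_directions[common] * set_directions[common]
  sum(concord) / sqrt(length(common))
}

#' Gene-set enrichment with activation scores
#'
#' Computes, for every set in the database: the overlap with the query
#' genes, the one-sided Fisher enrichment p-value within the universe, the
#' BH-adjusted p-value across sets, and the activation z-score where
#' direction annotations exist.
#'
#' @param deg_genes character vector of query (differentially expressed)
#'   genes.
#' @param deg_directions named numeric (+1/-1) observed directions for the
#'   query genes (optional; z is NA without it).
#' @param db a [read_gmt()] database.
#' @param universe background genes (e.g. all genes passing the expression
#'   filter).
#' @return data.frame(set, n_set, overlap, fisher_p, fdr_p, z).
#' @export
enrich_test <- function(deg_genes, deg_directions = NULL, db, universe) {
  stopifnot(inherits(db, "gene_set_db"))
  if (length(db) == 0) stop("enrich_test: empty gene-set database")
  rows <- lapply(names(db), function(nm) {
    s <- db[[nm]]
    genes <- intersect(s$genes, universe)
    ov <- intersect(deg_genes, genes)
    z <- if (is.null(deg_directions)) NA_real_ else {
      activation_zscore(deg_directions, s$directions)
    }
    data.frame(set = nm, n_set = length(genes), overlap = length(ov),
               fisher_p = fisher_overlap(deg_genes, genes, universe),
               z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_p <- bh_fdr(out$fisher_p)
  out[, c("set", "n_set", "overlap", "fisher_p", "fdr_p", "z")]
}

#' Call pathway enrichment and activation states
#'
#' Labels each set: `"activated"` when enriched (FDR < `fdr_cut`) with
#' z >= `z_cut`; `"inhibited"` when enriched with z <= -`z_cut`;
#' `"enriched-only"` when enriched but |z| below the cut (or z unavailable);
#' `"not-significant"` otherwise.
#'
#' @param results output of [enrich_test()].
#' @param fdr_cut enrichment FDR threshold (default 0.05 for pathways).
#' @param z_cut activation threshold on |z| (default 2.0).
#' @return `results` with a `call` column appended.
#' @export
call_pathways <- function(results, fdr_cut = 0.05, z_cut = 2.0) {
  enriched <- results$fdr_p < fdr_cut
  z <- results$z
  call <- rep("not-significant", nrow(results))
  call[enriched] <- "enriched-only"
  call[enriched & !is.na(z) & z >= z_cut] <- "activated"
  call[enriched & !is.na(z) & z <= -z_cut] <- "inhibited"
  results$call <- call
  results
}

#' Call upstream-regulator activation states
#'
#' Identical machinery to [call_pathways()] with the stricter regulator
#' overlap threshold (FDR < 0.01 by default).
#'
#' @inheritParams call_pathways
#' @export
call_regulators <- function(results, fdr_cut = 0.01, z_cut = 2.0) {
  call_pathways(results, fdr_cut = fdr_cut, z_cut = z_cut)
}
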