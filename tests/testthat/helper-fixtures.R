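# Shared fixture builders. Everything is generated in code at test time.

# balanced cell metadata + design matrix for the default 7 x 4 layout
make_cell_layout <- function(n_subjects = 7, cells_per_sample = 50,
                             timepoints = c("baseline", "day2", "day4", "day7")) {
  meta <- expand.grid(cell = seq_len(cells_per_sample),
                      timepoint = timepoints,
                      subject = sprintf("S%02d", seq_len(n_subjects)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  list(meta = meta, design = timepoint_design(meta$timepoint, timepoints))
}

# Gaussian responses drawn from the weighted mixed model itself
simulate_lmm_response <- function(layout, beta, tau, sigma = 1, weights = NULL) {
  n <- nrow(layout$meta)
  subj <- unique(layout$meta$subject)
  a <- stats::rnorm(length(subj), 0, tau)
  names(a) <- subj
  if (is.null(weights)) weights <- rep(1, n)
  y <- as.numeric(layout$design %*% beta) + a[layout$meta$subject] +
    stats::rnorm(n, 0, sigma / sqrt(weights))
  list(y = y, weights = weights)
}

# tiny GMT written to a temp file
write_test_gmt <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}
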