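# Stage II: count QC. Feature filter (row totals), sample filter (column
# totals), vehicle-control diagnostics (PCA, pairwise correlations) and the
# D-statistic rule that drops controls poorly correlated with their peers.
# Canonical order in the pipeline: features -> samples -> D-statistic.

#' Filter low-count features (genes)
#'
#' Removes genes whose total count across all samples falls below
#' `min_row_total`. The default of 2 keeps rows with more than one count,
#' the panel-wide convention for flagging unexpressed probes.
#'
#' @param counts Counts tibble (gene + samples) or matrix.
#' @param min_row_total Minimum row total to keep a gene (kept when
#'   total >= `min_row_total`).
#' @return List with `counts` (filtered tibble) and `removed_genes`.
#' @export
filter_features <- function(counts, min_row_total = 2) {
  m <- counts_matrix(counts)
  keep <- rowSums(m) >= min_row_total
  if (!any(keep)) stop("no features pass filter (min_row_total = ", min_row_total, ")")
  list(counts = counts_tbl(m[keep, , drop = FALSE]),
       removed_genes = rownames(m)[!keep])
}

#' Filter low-depth samples
#'
#' Drops sample columns whose total count is below `min_col_total`
#' (default 100,000, appropriate for a ~3,000-feature targeted panel);
#' a column at exactly the threshold is kept.
#'
#' @param counts Counts tibble or matrix.
#' @param min_col_total Minimum column total to keep a sample.
#' @return List with `counts` and `removed_samples`.
#' @export
filter_samples <- function(counts, min_col_total = 100000) {
  m <- counts_matrix(counts)
  keep <- colSums(m) >= min_col_total
  if (!any(keep)) stop("no samples pass filter (min_col_total = ", min_col_total, ")")
  list(counts = counts_tbl(m[, keep, drop = FALSE]),
       removed_samples = colnames(m)[!keep])
}

#' PCA of vehicle-control samples
#'
#' Diagnostic only (no automatic exclusion): principal components of the
#' log2(count + 0.5), gene-centered control columns, for spotting control
#' clusters or drifting plates.
#'
#' @param counts Counts tibble or matrix.
#' @param controls Character vector of control sample ids.
#' @param n_components Number of components to report.
#' @return A list with `scores` (tibble: sample_id, PC1..PCk) and
#'   `var_explained` (fraction per component), or NULL with a warning when
#'   fewer than 3 controls are available.
#' @export
control_pca <- function(counts, controls, n_components = 3) {
  m <- counts_matrix(counts)
  controls <- intersect(controls, colnames(m))
  if (length(controls) < 3) {
    warning("control PCA skipped: fewer than 3 controls")
    return(NULL)
  }
  x <- log2p(m[, controls, drop = FALSE])
  x <- x - rowMeans(x)                      # center each gene across controls
  pc <- prcomp(t(x), center = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::bind_cols(tibble::tibble(sample_id = controls), scores)
  ve <- pc$sdev^2 / max(sum(pc$sdev^2), .Machine$double.eps)
  list(scores = scores, var_explained = ve[seq_len(k)])
}

#' Pairwise correlations among control samples
#'
#' @param counts Counts tibble or matrix.
#' @param controls Control sample ids.
#' @param method Correlation type (Pearson default), computed on
#'   log2(count + 0.5) values.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
control_correlations <- function(counts, controls, method = "pearson") {
  m <- counts_matrix(counts)
  x <- log2p(m[, intersect(controls, colnames(m)), drop = FALSE])
  cor(x, method = method)
}

#' D-statistic outlier detection for vehicle controls
#'
#' For each control sample i, D_i is the mean correlation of its
#' log2(count + 0.5) profile with every other control. Controls whose D
#' falls more than `sd_cut` standard deviations below the mean D are
#' excluded, in a single pass. A zero-variance control (correlation
#' undefined) is excluded with an explicit reason. When sd(D) is zero
#' (e.g. identical controls) nothing is excluded.
#'
#' @param counts Counts tibble or matrix.
#' @param controls Control sample ids (need at least 4 for a meaningful SD).
#' @param sd_cut Exclusion threshold in SD units (default 3).
#' @param method Correlation type (Pearson default; Spearman available).
#' @return Tibble: `sample_id`, `d`, `excluded`, `reason`.
#' @export
d_statistic <- function(counts, controls, sd_cut = 3, method = "pearson") {
  m <- counts_matrix(counts)
  controls <- intersect(controls, colnames(m))
  if (length(controls) < 4) stop("D-statistic needs at least 4 controls")
  x <- log2p(m[, controls, drop = FALSE])

  degenerate <- apply(x, 2, sd) == 0
  cc <- suppressWarnings(cor(x, method = method))
  diag(cc) <- NA
  d <- rowMeans(cc, na.rm = TRUE)
  d[degenerate] <- NA

  ok <- !is.na(d)
  excluded <- degenerate
  reason <- ifelse(degenerate, "zero-variance profile", NA_character_)
  if (sum(ok) >= 2 && sd(d[ok]) > 0) {
    cut <- mean(d[ok]) - sd_cut * sd(d[ok])
    low <- ok & d < cut
    excluded <- excluded | low
    reason[low] <- sprintf("D below mean - %g SD", sd_cut)
  }
  tibble::tibble(sample_id = controls, d = unname(d),
                 excluded = unname(excluded), reason = unname(reason))
}

#' Run the full count QC stage
#'
#' Applies, in order: the feature filter, the sample (depth) filter, and the
#' control D-statistic rule (excluded controls are dropped from the matrix).
#' Control PCA and pairwise correlations are attached as diagnostics.
#'
#' @param counts Counts tibble or matrix.
#' @param layout Layout tibble (see [validate_layout()]).
#' @param min_row_total,min_col_total,d_sd QC thresholds.
#' @param cor_method Correlation type for the D statistic.
#' @return A `crpod_qc` list: `counts` (cleaned tibble), `layout` (rows for
#'   retained samples), `d` (D-statistic table), `pca`, `control_cor`, and
#'   `report` (a one-row tibble of conservation counts).
#' @export
qc_counts <- function(counts, layout, min_row_total = 2, min_col_total = 100000,
                      d_sd = 3, cor_method = "pearson") {
  layout <- validate_layout(layout, counts)
  m <- counts_matrix(counts)
  genes_in <- nrow(m)
  samples_in <- ncol(m)

  ff <- filter_features(m, min_row_total)
  fs <- filter_samples(counts_matrix(ff$counts), min_col_total)
  m2 <- counts_matrix(fs$counts)

  controls <- intersect(layout$sample_id[layout$is_vehicle], colnames(m2))
  dstat <- d_statistic(m2, controls, sd_cut = d_sd, method = cor_method)
  dropped_controls <- dstat$sample_id[dstat$excluded]
  keep <- setdiff(colnames(m2), dropped_controls)
  m3 <- m2[, keep, drop = FALSE]

  report <- tibble::tibble(
    genes_in = genes_in,
    genes_removed = length(ff$removed_genes),
    genes_kept = nrow(m3),
    samples_in = samples_in,
    samples_removed_lowcount = length(fs$removed_samples),
    controls_removed_dstat = length(dropped_controls),
    samples_kept = ncol(m3)
  )
  structure(list(
    counts = counts_tbl(m3),
    layout = layout[layout$sample_id %in% colnames(m3), , drop = FALSE],
    d = dstat,
    pca = control_pca(m3, setdiff(controls, dropped_controls)),
    control_cor = control_correlations(m3, setdiff(controls, dropped_controls),
                                       method = cor_method),
    removed = list(genes = ff$removed_genes, samples = fs$removed_samples,
                   controls = dropped_controls),
    report = report
  ), class = "crpod_qc")
}

#' @export
print.crpod_qc <- function(x, ...) {
  r <- x$report
  cat("crpod QC: ", r$genes_kept, "/", r$genes_in, " genes kept (",
      r$genes_removed, " low-count); ", r$samples_kept, "/", r$samples_in,
      " samples kept (", r$samples_removed_lowcount, " low-depth, ",
      r$controls_removed_dstat, " control outlier)\n", sep = "")
  invisible(x)
}
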