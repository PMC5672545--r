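# Shared helpers: count-table <-> matrix conversion, layout validation,
# the log2(x + 0.5) transform used throughout the pipeline.

#' Convert a counts tibble to a numeric matrix
#'
#' Throughout crpod a count matrix travels as a tibble whose first column
#' (`gene`) holds feature identifiers and whose remaining columns are samples.
#' This helper converts that representation (or a matrix with rownames, which
#' is passed through) to a base matrix for numerical work.
#'
#' @param counts A tibble with a `gene` column and one numeric column per
#'   sample, or a numeric matrix with gene rownames.
#' @return A numeric matrix, genes in rows (rownames), samples in columns.
#' @export
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    if (is.null(rownames(counts))) stop("count matrix must have gene rownames")
    return(counts)
  }
  if (!is.data.frame(counts) || !"gene" %in% names(counts)) {
    stop("`counts` must be a matrix with rownames or a data frame with a `gene` column")
  }
  m <- as.matrix(counts[setdiff(names(counts), "gene")])
  if (!is.numeric(m)) stop("count columns must be numeric")
  rownames(m) <- counts$gene
  m
}

#' Convert a count matrix to the tibble representation
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @return A tibble with a `gene` column followed by one column per sample.
#' @export
counts_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# log2 with the pipeline-wide pseudocount of 0.5 (allows zero counts)
log2p <- function(x, pseudocount = 0.5) log2(x + pseudocount)

#' Validate an experimental layout ("hash file") against a count matrix
#'
#' The layout table maps every count-matrix column to its chemical,
#' concentration (uM) and vehicle-control status. Required columns:
#' `sample_id`, `chemical`, `conc_uM`, `is_vehicle`; extra columns are
#' passed through untouched.
#'
#' @param layout A data frame with the required columns.
#' @param counts Optional counts tibble/matrix; when given, every sample
#'   column must have exactly one layout row.
#' @return The layout as a tibble, invisibly validated.
#' @export
validate_layout <- function(layout, counts = NULL) {
  required <- c("sample_id", "chemical", "conc_uM", "is_vehicle")
  missing <- setdiff(required, names(layout))
  if (length(missing) > 0) {
    stop("layout is missing required column(s): ", paste(missing, collapse = ", "))
  }
  layout <- tibble::as_tibble(layout)
  layout$conc_uM[is.na(layout$conc_uM)] <- 0
  layout$is_vehicle <- as.logical(layout$is_vehicle)
  if (any(duplicated(layout$sample_id))) {
    stop("layout has duplicated sample_id(s): ",
         paste(unique(layout$sample_id[duplicated(layout$sample_id)]), collapse = ", "))
  }
  if (any(layout$is_vehicle & layout$conc_uM != 0)) {
    stop("vehicle-control rows must have conc_uM of 0 (or blank)")
  }
  if (!is.null(counts)) {
    samples <- colnames(counts_matrix(counts))
    absent <- setdiff(samples, layout$sample_id)
    if (length(absent) > 0) {
      stop("count-matrix column(s) with no layout row: ", paste(absent, collapse = ", "))
    }
  }
  layout
}

# stable seed derivation: combine a base seed with a small stream offset,
# staying inside 32-bit integer range
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7L
}
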