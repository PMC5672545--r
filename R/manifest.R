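# Probe manifest handling: the alignment reference for a targeted panel is a
# CSV of (probe id, gene symbol, fixed-length probe sequence).

#' Read and validate a probe manifest
#'
#' The manifest is the manufacturer-style CSV describing the targeted panel:
#' one row per detector probe with its identifier, the gene symbol it reports
#' on, and its fixed-length (typically 50-mer) DNA sequence. Reads are later
#' assigned by comparing their first L bases against these sequences.
#'
#' @param path Path to a CSV file.
#' @param col_probe,col_gene,col_seq Names of the columns holding the probe
#'   id, gene symbol and probe sequence.
#' @return A `probe_manifest`: a tibble with columns `probe_id`, `gene_symbol`,
#'   `sequence`, carrying the probe length as attribute `probe_length`.
#'   Probes sharing an identical sequence under different ids are kept but
#'   trigger an ambiguity warning listing the ids involved.
#' @export
read_probe_manifest <- function(path, col_probe = "probe_id",
                                col_gene = "gene_symbol", col_seq = "sequence") {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(col_probe, col_gene, col_seq), names(raw))
  if (length(missing) > 0) {
    stop("manifest ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  probe_manifest(tibble::tibble(
    probe_id = as.character(raw[[col_probe]]),
    gene_symbol = as.character(raw[[col_gene]]),
    sequence = toupper(as.character(raw[[col_seq]]))
  ))
}

#' Construct a probe manifest from a data frame
#'
#' @param df Data frame with columns `probe_id`, `gene_symbol`, `sequence`.
#' @return A validated `probe_manifest` tibble.
#' @export
probe_manifest <- function(df) {
  df <- tibble::as_tibble(df[c("probe_id", "gene_symbol", "sequence")])
  df$sequence <- toupper(df$sequence)

  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup) > 0) {
    stop("duplicated probe id(s) in manifest: ", paste(unique(dup), collapse = ", "))
  }
  bad <- grepl("[^ACGT]", df$sequence)
  if (any(bad)) {
    stop("non-DNA characters in probe sequence(s) of: ",
         paste(df$probe_id[bad], collapse = ", "))
  }
  len <- unique(nchar(df$sequence))
  if (length(len) != 1) {
    stop("probe sequences must share one length; found lengths ",
         paste(sort(len), collapse = ", "))
  }
  dup_seq <- df$sequence[duplicated(df$sequence)]
  if (length(dup_seq) > 0) {
    groups <- vapply(unique(dup_seq), function(s) {
      paste(df$probe_id[df$sequence == s], collapse = "/")
    }, character(1))
    warning("identical sequences under different probe ids (reads matching them ",
            "may be ambiguous): ", paste(groups, collapse = "; "))
  }
  attr(df, "probe_length") <- len
  class(df) <- c("probe_manifest", class(df))
  df
}

#' @export
print.probe_manifest <- function(x, ...) {
  cat("Probe manifest: ", nrow(x), " probes, ",
      length(unique(x$gene_symbol)), " genes, ",
      attr(x, "probe_length"), "-mers\n", sep = "")
  NextMethod()
}
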