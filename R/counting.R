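# Stage I: build a probe/gene x sample count matrix from demultiplexed FASTQ
# files. Probes are fixed-length (50-mer) panel sequences, so alignment is
# direct matching of each read's first L bases: a hash lookup for exact hits
# and minimum Hamming distance (default tolerance 2) otherwise.

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# sequence -> probe row index; 0 flags sequences shared across genes
# (ambiguous at distance 0), duplicates within one gene collapse to the first
exact_lookup <- function(manifest) {
  idx <- seq_len(nrow(manifest))
  first <- !duplicated(manifest$sequence)
  map <- setNames(idx[first], manifest$sequence[first])
  dups <- unique(manifest$sequence[duplicated(manifest$sequence)])
  for (s in dups) {
    hits <- idx[manifest$sequence == s]
    if (length(unique(manifest$gene_symbol[hits])) > 1) map[s] <- 0L
  }
  map
}

probe_char_matrix <- function(manifest) {
  L <- attr(manifest, "probe_length")
  matrix(unlist(strsplit(manifest$sequence, "")), nrow = L,
         dimnames = list(NULL, manifest$probe_id))
}

#' Assign reads to panel probes by Hamming matching
#'
#' Each read's first L bases (L = probe length) are compared against every
#' probe sequence; the read is assigned to the probe at minimum Hamming
#' distance, provided that distance does not exceed `max_mismatch`. Ties
#' between probes of the same gene assign to the gene (the downstream count
#' unit); ties across distinct genes are left unassigned as ambiguous.
#' Reads shorter than L are flagged `short`.
#'
#' @param reads Character vector of read sequences; names (if any) are used
#'   as read ids.
#' @param manifest A [probe_manifest()].
#' @param max_mismatch Maximum Hamming distance for an assignment (default 2).
#' @param reverse_complement Also try the reverse complement of each read
#'   prefix (off by default: the assay reads the probe strand).
#' @return A tibble with one row per read: `read_id`, `probe_id` (NA when not
#'   assigned), `gene_symbol`, `mismatches`, and `status` in
#'   `assigned`/`ambiguous`/`unassigned`/`short`.
#' @export
assign_reads <- function(reads, manifest, max_mismatch = 2,
                         reverse_complement = FALSE) {
  stopifnot(inherits(manifest, "probe_manifest"))
  L <- attr(manifest, "probe_length")
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_len(n))

  probe <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  mm <- rep(NA_integer_, n)
  status <- rep("unassigned", n)

  short <- nchar(reads) < L
  status[short] <- "short"

  prefix <- substr(reads, 1L, L)
  lookup <- exact_lookup(manifest)
  hit <- lookup[prefix]
  hit[short] <- NA_integer_

  exact <- !is.na(hit) & hit > 0L
  probe[exact] <- manifest$probe_id[hit[exact]]
  gene[exact] <- manifest$gene_symbol[hit[exact]]
  mm[exact] <- 0L
  status[exact] <- "assigned"
  amb0 <- !is.na(hit) & hit == 0L
  status[amb0] <- "ambiguous"
  mm[amb0] <- 0L

  todo <- which(!short & !exact & !amb0)
  if (length(todo) > 0 && max_mismatch > 0) {
    pm <- probe_char_matrix(manifest)
    for (i in todo) {
      cand_prefix <- prefix[i]
      if (reverse_complement) cand_prefix <- c(cand_prefix, revcomp_chr(cand_prefix))
      best_d <- Inf
      best <- integer(0)
      for (p in cand_prefix) {
        rc <- strsplit(p, "")[[1]]
        d <- colSums(pm != rc)
        dm <- min(d)
        if (dm < best_d) {
          best_d <- dm
          best <- which(d == dm)
        } else if (dm == best_d) {
          best <- union(best, which(d == dm))
        }
      }
      if (best_d <= max_mismatch) {
        genes <- unique(manifest$gene_symbol[best])
        mm[i] <- as.integer(best_d)
        if (length(genes) == 1L) {
          probe[i] <- manifest$probe_id[best[1L]]
          gene[i] <- genes
          status[i] <- "assigned"
        } else {
          status[i] <- "ambiguous"
        }
      }
    }
  }

  tibble::tibble(read_id = ids, probe_id = probe, gene_symbol = gene,
                 mismatches = mm, status = status)
}

# strict 4-line-record FASTQ reader (gzip transparent); the targeted-panel
# contract treats any structural defect as a hard error naming the record
read_fastq_seqs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) return(character(0))
  if (length(lines) %% 4 != 0) {
    stop("ill-formed FASTQ file ", path, ": truncated record ",
         length(lines) %/% 4 + 1, call. = FALSE)
  }
  heads <- lines[seq(1, length(lines), by = 4)]
  seps <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(heads, "@") | !startsWith(seps, "+"))
  if (length(bad) > 0) {
    stop("ill-formed FASTQ file ", path, ": record ", bad[1],
         " lacks @/+ markers", call. = FALSE)
  }
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  setNames(seqs, sub("^@", "", sub("\\s.*", "", heads)))
}

#' Count a directory of demultiplexed FASTQ files against a probe manifest
#'
#' One FASTQ file per sample (gzip allowed); the sample id is the filename
#' stem. Produces probe-level and gene-level (sum over a gene's probes) count
#' tables plus a per-sample assignment summary. The summary categories
#' (`assigned`, `ambiguous`, `unassigned`, `short`) always sum to the total
#' reads of the sample.
#'
#' @param fastq_dir Directory containing the FASTQ files.
#' @param manifest A [probe_manifest()].
#' @param max_mismatch,reverse_complement Passed to [assign_reads()].
#' @param sample_pattern Regex stripped from filenames to obtain sample ids.
#' @return A `crpod_counts` list: `probe_counts` (tibble, probe_id + gene
#'   + one column per sample), `gene_counts` (gene + samples), and `summary`.
#' @export
count_fastq_dir <- function(fastq_dir, manifest, max_mismatch = 2,
                            reverse_complement = FALSE,
                            sample_pattern = "\\.(fastq|fq)(\\.gz)?$") {
  files <- sort(list.files(fastq_dir, pattern = sample_pattern, full.names = TRUE))
  if (length(files) == 0) stop("no FASTQ files found in ", fastq_dir)
  samples <- sub(sample_pattern, "", basename(files))

  probe_mat <- matrix(0L, nrow(manifest), length(files),
                      dimnames = list(manifest$probe_id, samples))
  summ <- vector("list", length(files))
  for (k in seq_along(files)) {
    seqs <- read_fastq_seqs(files[k])
    if (length(seqs) == 0) {
      warning("empty FASTQ file: ", files[k])
      summ[[k]] <- tibble::tibble(sample_id = samples[k], total = 0L,
                                  assigned = 0L, ambiguous = 0L,
                                  unassigned = 0L, short = 0L)
      next
    }
    asn <- assign_reads(seqs, manifest, max_mismatch = max_mismatch,
                        reverse_complement = reverse_complement)
    tab <- table(factor(asn$probe_id[asn$status == "assigned"],
                        levels = manifest$probe_id))
    probe_mat[, k] <- as.integer(tab)
    summ[[k]] <- tibble::tibble(
      sample_id = samples[k],
      total = nrow(asn),
      assigned = sum(asn$status == "assigned"),
      ambiguous = sum(asn$status == "ambiguous"),
      unassigned = sum(asn$status == "unassigned"),
      short = sum(asn$status == "short")
    )
  }

  probe_counts <- dplyr::bind_cols(
    tibble::tibble(probe_id = manifest$probe_id, gene = manifest$gene_symbol),
    tibble::as_tibble(probe_mat, .name_repair = "minimal")
  )
  structure(list(
    probe_counts = probe_counts,
    gene_counts = aggregate_gene_counts(probe_counts),
    summary = dplyr::bind_rows(summ)
  ), class = "crpod_counts")
}

#' Collapse probe-level counts to gene level
#'
#' @param probe_counts Tibble with `probe_id`, `gene` and sample columns.
#' @return Tibble with a `gene` column and per-gene summed sample counts.
#' @export
aggregate_gene_counts <- function(probe_counts) {
  probe_counts |>
    dplyr::select(-"probe_id") |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum), .groups = "drop") |>
    dplyr::arrange(.data$gene)
}

#' Merge per-sample probe count tables into one matrix
#'
#' @param tables Named list of data frames, each with columns `probe_id` and
#'   `count` for one sample. Probes absent from a table are imputed as 0;
#'   probes not in the manifest are an error. Column order follows the input
#'   order of `tables`.
#' @param manifest A [probe_manifest()] defining the probe universe.
#' @return A `crpod_counts`-style list with `probe_counts` and `gene_counts`.
#' @export
merge_count_tables <- function(tables, manifest) {
  stopifnot(length(tables) > 0)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  m <- matrix(0L, nrow(manifest), length(tables),
              dimnames = list(manifest$probe_id, names(tables)))
  for (k in seq_along(tables)) {
    tab <- tables[[k]]
    unknown <- setdiff(tab$probe_id, manifest$probe_id)
    if (length(unknown) > 0) {
      stop("table ", names(tables)[k], " has probe id(s) not in manifest: ",
           paste(unknown, collapse = ", "))
    }
    m[tab$probe_id, k] <- as.integer(tab$count)
  }
  probe_counts <- dplyr::bind_cols(
    tibble::tibble(probe_id = manifest$probe_id, gene = manifest$gene_symbol),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
  structure(list(probe_counts = probe_counts,
                 gene_counts = aggregate_gene_counts(probe_counts),
                 summary = NULL),
            class = "crpod_counts")
}

#' @export
print.crpod_counts <- function(x, ...) {
  cat("crpod counts: ", nrow(x$gene_counts), " genes x ",
      ncol(x$gene_counts) - 1L, " samples\n", sep = "")
  if (!is.null(x$summary)) {
    rate <- sum(x$summary$assigned) / max(1, sum(x$summary$total))
    cat(sprintf("overall assignment rate: %.1f%%\n", 100 * rate))
  }
  invisible(x)
}
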