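# End-to-end orchestration: (optional probe counting) -> QC/normalization ->
# max-dose differential expression -> statistical flags -> model fits and
# PODs, with every stage's tables written to the output directory and a
# machine-readable run manifest recording configuration and input hashes.

default_run_config <- function() {
  list(
    counts = NULL, fastq_dir = NULL, manifest = NULL, layout = NULL,
    out_dir = "crpod_run",
    min_row_total = 2, min_col_total = 100000, d_sd = 3,
    de_alpha = 0.05, flag_q = 0.05, bsd_multiplier = 1,
    trend_mode = "moment_approx", n_perm = 10000, error_model = "gaussian",
    max_mismatch = 2, seed = 1
  )
}

read_counts_file <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "gene"
  tbl
}

read_layout_file <- function(path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  validate_layout(readr::read_delim(path, delim = delim,
                                    show_col_types = FALSE, progress = FALSE))
}

#' Run the full concentration-response pipeline
#'
#' Executes, in order: probe counting (when `fastq_dir` and `manifest` are
#' given instead of `counts`), count QC and normalization, differential
#' expression at maximum dose, statistical-flag generation, and model
#' fitting with POD estimation. Each stage's tables are written under
#' `out_dir` and a `run_manifest.json` records the package version, the
#' full configuration and MD5 hashes of file inputs. A stage failure halts
#' the run with the stage name.
#'
#' @param config Named list (or path to a YAML file) overriding the
#'   defaults: input paths/objects (`counts` or `fastq_dir` + `manifest`,
#'   plus `layout`), `out_dir`, thresholds (`min_row_total` 2,
#'   `min_col_total` 100000, `d_sd` 3, `de_alpha` 0.05, `flag_q` 0.05,
#'   `bsd_multiplier` 1), `trend_mode`, `n_perm`, `error_model`,
#'   `max_mismatch`, `seed`.
#' @return Invisibly, a list with every stage's result (`counting`, `qc`,
#'   `normalized`, `size_factors`, `de`, `flags`, `pods`, `summaries`).
#' @export
crpod_run <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  hashes <- list()
  note_hash <- function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      hashes[[x]] <<- unname(tools::md5sum(x))
    }
  }

  counting <- NULL
  counts <- stage("count", {
    if (!is.null(cfg$counts)) {
      note_hash(cfg$counts)
      if (is.character(cfg$counts)) read_counts_file(cfg$counts) else cfg$counts
    } else if (!is.null(cfg$fastq_dir) && !is.null(cfg$manifest)) {
      note_hash(cfg$manifest)
      man <- if (is.character(cfg$manifest)) {
        read_probe_manifest(cfg$manifest)
      } else cfg$manifest
      counting <<- count_fastq_dir(cfg$fastq_dir, man,
                                   max_mismatch = cfg$max_mismatch)
      readr::write_tsv(counting$summary,
                       file.path(cfg$out_dir, "alignment_summary.tsv"))
      counting$gene_counts
    } else {
      stop("config must provide `counts` or both `fastq_dir` and `manifest`")
    }
  })
  layout <- stage("layout", {
    if (is.null(cfg$layout)) stop("config must provide `layout`")
    note_hash(cfg$layout)
    lt <- if (is.character(cfg$layout)) read_layout_file(cfg$layout) else
      validate_layout(cfg$layout)
    validate_layout(lt, counts)
  })

  qc <- stage("qc", {
    qc <- qc_counts(counts, layout, min_row_total = cfg$min_row_total,
                    min_col_total = cfg$min_col_total, d_sd = cfg$d_sd)
    readr::write_tsv(qc$counts, file.path(cfg$out_dir, "cleaned_counts.tsv"))
    readr::write_tsv(qc$d, file.path(cfg$out_dir, "d_statistic.tsv"))
    jsonlite::write_json(c(as.list(qc$report), qc$removed),
                         file.path(cfg$out_dir, "qc_report.json"),
                         auto_unbox = TRUE, digits = NA)
    qc
  })

  norm <- stage("normalize", {
    nr <- normalize_counts(qc$counts)
    readr::write_tsv(nr$normalized, file.path(cfg$out_dir, "normalized_counts.tsv"))
    readr::write_tsv(tibble::tibble(sample_id = names(nr$size_factors),
                                    size_factor = nr$size_factors),
                     file.path(cfg$out_dir, "size_factors.tsv"))
    nr
  })

  de <- stage("de", {
    de <- de_max_dose(qc$counts, qc$layout, sf = norm$size_factors)
    readr::write_tsv(de, file.path(cfg$out_dir, "de.tsv"))
    de
  })

  set.seed(cfg$seed)
  flags <- stage("flags", {
    fl <- flag_pairs(norm$normalized, qc$layout, q_threshold = cfg$flag_q,
                     mode = cfg$trend_mode, n_perm = cfg$n_perm)
    readr::write_tsv(fl, file.path(cfg$out_dir, "flags.tsv"))
    readr::write_tsv(dplyr::filter(fl, .data$route == "manual_review"),
                     file.path(cfg$out_dir, "manual_review.tsv"))
    fl
  })

  pods <- stage("fit", {
    pods <- estimate_pods(norm$normalized, qc$layout, flags,
                          bsd_multiplier = cfg$bsd_multiplier,
                          error_model = cfg$error_model)
    readr::write_tsv(pods, file.path(cfg$out_dir, "pods.tsv"))
    pods
  })

  summaries <- stage("summarise", {
    sm <- list(
      deg_counts = deg_count(de, alpha = cfg$de_alpha),
      l2fc_summary = l2fc_summary(de),
      route_tally = dplyr::count(flags, .data$chemical, .data$route),
      pod = pod_summary(pods)
    )
    jsonlite::write_json(sm, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    sm
  })

  manifest_out <- list(
    package = "crpod",
    version = as.character(utils::packageVersion("crpod")),
    config = cfg[setdiff(names(cfg), c("counts", "layout", "manifest"))],
    input_hashes = hashes
  )
  jsonlite::write_json(manifest_out, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(counting = counting, qc = qc, normalized = norm$normalized,
                 size_factors = norm$size_factors, de = de, flags = flags,
                 pods = pods, summaries = summaries, config = cfg))
}

#' Summarise a pipeline run as a report
#'
#' Collates per-chemical DEG counts, decision-tree route tallies,
#' winning-model frequencies, POD distributions and the manual-review list,
#' optionally writing a plain-markdown report.
#'
#' @param run A [crpod_run()] result.
#' @param file Optional path for a markdown rendering of the report.
#' @return List of report tibbles.
#' @export
crpod_report <- function(run, file = NULL) {
  rep <- list(
    deg_counts = run$summaries$deg_counts,
    route_tally = run$summaries$route_tally,
    winner_models = run$summaries$pod$winners,
    pod_distribution = run$summaries$pod$distribution,
    manual_review = dplyr::filter(run$flags, .data$route == "manual_review")
  )
  if (!is.null(file)) {
    fmt <- function(df) paste(utils::capture.output(print(as.data.frame(df))),
                              collapse = "\n")
    writeLines(c(
      "# crpod run report", "",
      "## DEGs at maximum dose", fmt(rep$deg_counts), "",
      "## Decision-tree routes", fmt(rep$route_tally), "",
      "## Winning models", fmt(rep$winner_models), "",
      "## POD distribution (log10 uM, fitted pairs)", fmt(rep$pod_distribution), "",
      sprintf("## Manual review: %d gene-treatment pair(s)", nrow(rep$manual_review)),
      if (nrow(rep$manual_review) > 0) fmt(rep$manual_review) else NULL
    ), file)
  }
  rep
}
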