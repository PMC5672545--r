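# Synthetic-data generator: NB count matrices with a shared-vehicle-control
# plate layout and spiked dose-responsive genes (Hill-shaped shifts of log2
# expression), plus barcoded synthetic FASTQ for the counting stage. Every
# fixture is seed-determined and ships with a truth table.

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Defaults mirror the reference study design: a ~3,000-probe panel, 24
#' shared vehicle controls, four chemicals at 0.1/1/10 uM with a single
#' replicate per concentration, a per-sample depth giving ~212 mean reads
#' per gene, and NB overdispersion 0.05 (typical for targeted sequencing).
#' The `replicated` preset is the smaller illustration design of 12 controls
#' with three replicates per concentration.
#'
#' @param preset `"screen"` (default) or `"replicated"`.
#' @param ... Overrides of any config field: `n_genes`, `n_controls`,
#'   `chemicals` (named list of concentration vectors, uM), `n_reps`,
#'   `depth`, `dispersion`, `frac_responsive`, `baseline_log2_mean`,
#'   `baseline_log2_sd`, `effect_tp_range`, `effect_ga_range`,
#'   `effect_gw_range`, `depth_multipliers` (named, per sample),
#'   `n_lowcount_samples`, `lowcount_factor`, `n_outlier_controls`,
#'   `n_subthreshold_genes`, `seed`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(preset = c("screen", "replicated"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_genes = 2982,
    n_controls = 24,
    chemicals = list(drugA = c(0.1, 1, 10), drugB = c(0.1, 1, 10),
                     drugC = c(0.1, 1, 10), drugD = c(0.1, 1, 10)),
    n_reps = 1,
    depth = 632000,
    dispersion = 0.05,
    frac_responsive = c(drugA = 0.32, drugB = 0.15, drugC = 0.011,
                        drugD = 0.010),
    baseline_log2_mean = log2(150),
    baseline_log2_sd = 1.5,
    effect_tp_range = c(0.5, 3),
    effect_ga_range = c(-1, 1),
    effect_gw_range = c(0.5, 4),
    depth_multipliers = NULL,
    n_lowcount_samples = 0,
    lowcount_factor = 0.05,
    n_outlier_controls = 0,
    n_subthreshold_genes = 0,
    seed = 1
  )
  if (preset == "replicated") {
    cfg$n_controls <- 12
    cfg$n_reps <- 3
  }
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]   # replace, never merge
  class(cfg) <- "sim_config"
  cfg
}

sim_layout <- function(cfg) {
  ctl <- tibble::tibble(
    sample_id = sprintf("ctrl%02d", seq_len(cfg$n_controls)),
    chemical = "vehicle", conc_uM = 0, is_vehicle = TRUE
  )
  trt <- purrr::map_dfr(names(cfg$chemicals), function(ch) {
    tidyr::expand_grid(conc_uM = cfg$chemicals[[ch]], rep = seq_len(cfg$n_reps)) |>
      dplyr::mutate(
        sample_id = sprintf("%s_%guM_r%d", ch, .data$conc_uM, .data$rep),
        chemical = ch, is_vehicle = FALSE
      ) |>
      dplyr::select("sample_id", "chemical", "conc_uM", "is_vehicle")
  })
  dplyr::bind_rows(ctl, trt)
}

#' Simulate a NB count matrix with spiked dose-responsive genes
#'
#' Baseline log2 expression per gene is drawn once; responsive genes shift
#' their mean log2 expression at each concentration by a three-parameter
#' Hill curve in log10 dose (negated for down-regulated genes). Each
#' responsive gene responds to exactly one chemical (distinct signatures);
#' `frac_responsive` may be a single fraction or a named per-chemical
#' vector, whose defaults emulate the strongly heterogeneous activity of a
#' typical cardiotoxicant screen (one highly active chemical, one moderate,
#' two nearly inert). Counts are NB with variance mu + dispersion * mu^2.
#' Planted QC defects (low-depth samples, a shuffled outlier control,
#' sub-threshold genes) are injected last and recorded in the truth table.
#'
#' @param cfg A [sim_config()].
#' @return List: `counts` (tibble, gene + samples), `layout`, `truth`
#'   (one row per gene: `responsive`, `chemical` responded to, `model`,
#'   `tp`, `ga`, `gw`, `direction`, `baseline_mean`, `subthreshold`,
#'   `expected_bsd`, `expected_pod`), `defects` (planted sample defects).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    layout <- sim_layout(cfg)
    n <- cfg$n_genes
    genes <- sprintf("G%04d", seq_len(n))

    w <- 2^rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    p_base <- w / sum(w)

    chems <- names(cfg$chemicals)
    frac <- cfg$frac_responsive
    frac <- if (is.null(names(frac))) {
      setNames(rep_len(frac, length(chems)), chems)
    } else {
      # chemicals without a stated fraction are unresponsive
      setNames(ifelse(chems %in% names(frac), frac[chems], 0), chems)
    }
    n_per_chem <- pmin(round(frac * n), n)
    resp_idx <- if (sum(n_per_chem) > 0) {
      sort(sample.int(n, min(sum(n_per_chem), n)))
    } else integer(0)
    n_resp <- length(resp_idx)
    truth <- tibble::tibble(
      gene = genes, responsive = FALSE, chemical = NA_character_,
      model = NA_character_,
      tp = NA_real_, ga = NA_real_, gw = NA_real_, direction = NA_character_,
      baseline_mean = cfg$depth * p_base, subthreshold = FALSE
    )
    if (n_resp > 0) {
      truth$responsive[resp_idx] <- TRUE
      truth$chemical[resp_idx] <- rep(chems, n_per_chem)[seq_len(n_resp)]
      truth$model[resp_idx] <- "hill3"
      truth$tp[resp_idx] <- runif(n_resp, cfg$effect_tp_range[1], cfg$effect_tp_range[2])
      truth$ga[resp_idx] <- runif(n_resp, cfg$effect_ga_range[1], cfg$effect_ga_range[2])
      truth$gw[resp_idx] <- runif(n_resp, cfg$effect_gw_range[1], cfg$effect_gw_range[2])
      truth$direction[resp_idx] <- sample(c("up", "down"), n_resp, replace = TRUE)
    }

    mult <- setNames(rep(1, nrow(layout)), layout$sample_id)
    if (!is.null(cfg$depth_multipliers)) {
      mult[names(cfg$depth_multipliers)] <- cfg$depth_multipliers
    }
    low <- character(0)
    if (cfg$n_lowcount_samples > 0) {
      trt_ids <- layout$sample_id[!layout$is_vehicle]
      low <- trt_ids[seq_len(cfg$n_lowcount_samples)]
      mult[low] <- mult[low] * cfg$lowcount_factor
    }

    mu <- matrix(0, n, nrow(layout), dimnames = list(genes, layout$sample_id))
    for (j in seq_len(nrow(layout))) {
      fold <- rep(1, n)
      if (!layout$is_vehicle[j] && n_resp > 0) {
        hit <- which(truth$responsive & truth$chemical == layout$chemical[j])
        if (length(hit) > 0) {
          x <- log10(layout$conc_uM[j])
          d <- truth$tp[hit] / (1 + 10^((truth$ga[hit] - x) * truth$gw[hit]))
          d <- ifelse(truth$direction[hit] == "down", -d, d)
          fold[hit] <- 2^d
        }
      }
      mu[, j] <- cfg$depth * mult[j] * p_base * fold
    }

    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
      nrow = n, dimnames = dimnames(mu)
    )

    shuffled <- character(0)
    if (cfg$n_outlier_controls > 0) {
      ctl_ids <- layout$sample_id[layout$is_vehicle]
      shuffled <- utils::tail(ctl_ids, cfg$n_outlier_controls)
      for (sid in shuffled) counts[, sid] <- counts[sample.int(n), sid]
    }

    if (cfg$n_subthreshold_genes > 0) {
      sub_idx <- utils::tail(setdiff(seq_len(n), resp_idx), cfg$n_subthreshold_genes)
      counts[sub_idx, ] <- 0L
      # give every other planted row a single count: still below a total of 2
      ones <- sub_idx[seq_along(sub_idx) %% 2 == 1]
      counts[cbind(ones, rep_len(seq_len(ncol(counts)), length(ones)))] <- 1L
      truth$subthreshold[sub_idx] <- TRUE
    }

    logd <- log10(sort(unique(layout$conc_uM[!layout$is_vehicle])))
    truth$expected_bsd <- sqrt(pmax(1 / truth$baseline_mean + cfg$dispersion, 0)) / log(2)
    crosses <- truth$responsive & truth$tp > truth$expected_bsd
    truth$expected_pod <- NA_real_
    truth$expected_pod[crosses] <- truth$ga[crosses] -
      log10(truth$tp[crosses] / truth$expected_bsd[crosses] - 1) / truth$gw[crosses]

    list(counts = counts_tbl(counts), layout = layout, truth = truth,
         defects = list(lowcount_samples = low, outlier_controls = shuffled))
  })
}

#' Generate a synthetic probe manifest
#'
#' Random fixed-length probe sequences over a set of gene symbols; some
#' genes may carry two probes, and an ambiguous probe pair (identical
#' sequence under two genes) can be planted for testing.
#'
#' @param n_probes Number of probes.
#' @param L Probe length (default 50).
#' @param n_genes Number of distinct genes (default = `n_probes`; when
#'   smaller, extra probes are spread over the first genes).
#' @param ambiguous_pair Plant two identical sequences under different genes.
#' @param seed RNG seed.
#' @return A [probe_manifest()].
#' @export
make_manifest <- function(n_probes, L = 50, n_genes = n_probes,
                          ambiguous_pair = FALSE, seed = 1) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n_probes), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    }, character(1))
    while (anyDuplicated(seqs)) {
      i <- which(duplicated(seqs))
      seqs[i] <- vapply(i, function(.) {
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
      }, character(1))
    }
    gene <- sprintf("GENE%03d", rep_len(seq_len(n_genes), n_probes))
    if (ambiguous_pair && n_probes >= 2 && n_genes >= 2) {
      seqs[2] <- seqs[1]  # identical sequence under two different genes
      gene[1:2] <- c("GENE001", "GENE002")
    }
    suppressWarnings(probe_manifest(tibble::tibble(
      probe_id = sprintf("P%03d", seq_len(n_probes)),
      gene_symbol = gene, sequence = seqs
    )))
  })
}

mutate_read <- function(seq, n_err) {
  if (n_err == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(chars), n_err)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate FASTQ files with known probe composition
#'
#' Reads are copies of probe sequences with iid substitution errors at the
#' stated rate. One plain-text FASTQ per sample is written to `dir`, and the
#' true per-probe composition is returned for oracle checks.
#'
#' @param manifest A [probe_manifest()].
#' @param composition Named list: sample id -> named integer vector of reads
#'   per probe id.
#' @param error_rate Per-base substitution probability.
#' @param dir Output directory (created if needed).
#' @param seed RNG seed.
#' @return Tibble of truth counts: `sample_id`, `probe_id`, `n_reads`.
#' @export
simulate_fastq <- function(manifest, composition, error_rate = 0, dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  L <- attr(manifest, "probe_length")
  with_seed(seed, {
    truth <- purrr::imap_dfr(composition, function(comp, sid) {
      lines <- character(0)
      ridx <- 0L
      for (pid in names(comp)) {
        seq0 <- manifest$sequence[manifest$probe_id == pid]
        if (length(seq0) != 1) stop("unknown probe id in composition: ", pid)
        nerr <- rbinom(comp[[pid]], L, error_rate)
        for (k in seq_len(comp[[pid]])) {
          ridx <- ridx + 1L
          lines <- c(lines, sprintf("@%s_read%05d src=%s", sid, ridx, pid),
                     mutate_read(seq0, nerr[k]), "+", strrep("I", L))
        }
      }
      writeLines(lines, file.path(dir, paste0(sid, ".fastq")))
      tibble::tibble(sample_id = sid, probe_id = names(comp),
                     n_reads = as.integer(comp))
    })
    truth
  })
}

#' Write a self-describing fixture bundle
#'
#' Materialises a [simulate_counts()] draw as a directory of plain-text
#' files (`counts.tsv`, `layout.tsv`, `truth.tsv`, `bundle.json` with the
#' generating configuration) ready for the end-to-end pipeline.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return The simulation list, invisibly.
#' @export
write_fixture_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_counts(cfg)
  readr::write_tsv(sim$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$layout, file.path(dir, "layout.tsv"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  cfg_json <- unclass(cfg)
  jsonlite::write_json(cfg_json, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sim)
}
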