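# Shared fixture builders; everything is generated in code.

# three-probe manifest as a CSV on disk
write_toy_manifest_csv <- function(path,
                                   probe_id = c("P1", "P2", "P3"),
                                   gene = c("A", "B", "C"),
                                   seqs = c("ACGTACGTAC", "TTTTGGGGCC",
                                            "CCCCAAAATT")) {
  write.csv(data.frame(probe_id = probe_id, gene_symbol = gene,
                       sequence = seqs), path, row.names = FALSE)
  path
}

toy_manifest <- function() {
  probe_manifest(tibble::tibble(
    probe_id = c("P1", "P2", "P3"),
    gene_symbol = c("A", "B", "C"),
    sequence = c("ACGTACGTAC", "TTTTGGGGCC", "CCCCAAAATT")
  ))
}

# flip `k` positions of a DNA string (deterministic positions)
mutate_at <- function(seq, pos) {
  chars <- strsplit(seq, "")[[1]]
  for (p in pos) chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  paste(chars, collapse = "")
}

# small counts matrix + matching layout for QC / DE / flags tests
toy_experiment <- function(n_genes = 50, n_controls = 8,
                           concs = c(0.1, 1, 10), depth = 20000,
                           dispersion = 0.05, seed = 99, n_reps = 1,
                           chemicals = c("chemX", "chemY")) {
  cfg <- sim_config(
    n_genes = n_genes, n_controls = n_controls,
    chemicals = setNames(rep(list(concs), length(chemicals)), chemicals),
    n_reps = n_reps, depth = depth, dispersion = dispersion,
    frac_responsive = 0, seed = seed
  )
  simulate_counts(cfg)
}

# layout for an externally constructed matrix: first n_controls columns are
# vehicle, remaining columns cycle over chemicals/concentrations
layout_for <- function(samples, n_controls, chemical = "chemX",
                       concs = c(0.1, 1, 10)) {
  trt <- samples[-seq_len(n_controls)]
  tibble::tibble(
    sample_id = samples,
    chemical = c(rep("vehicle", n_controls), rep(chemical, length(trt))),
    conc_uM = c(rep(0, n_controls), rep_len(concs, length(trt))),
    is_vehicle = c(rep(TRUE, n_controls), rep(FALSE, length(trt)))
  )
}

# independent brute-force two-sided rank-sum p-value: enumerate every
# assignment of the pooled values into the two groups
wilcox_brute_force <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(w_all)
  min(1, 2 * min(mean(w_all >= w_obs - 1e-9), mean(w_all <= w_obs + 1e-9)))
}

# independent BH step-up reference
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# hill3 closed-form POD (response scale |f| = bsd)
hill3_pod_closed_form <- function(tp, ga, gw, bsd) {
  ga - log10(tp / bsd - 1) / gw
}

# assemble a synthetic dose-response series without a count matrix
make_series <- function(dose, response, n_control = sum(dose == min(dose)),
                        control_sd = NULL) {
  s <- tibble::tibble(
    sample_id = paste0("s", seq_along(dose)), dose = dose,
    response = response, is_control = dose == min(dose)
  )
  attr(s, "n_control") <- n_control
  attr(s, "control_sd") <- control_sd %||%
    stats::sd(response[s$is_control])
  attr(s, "pseudo_dose") <- min(dose)
  attr(s, "max_dose") <- max(dose)
  class(s) <- c("dose_response_series", class(s))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
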