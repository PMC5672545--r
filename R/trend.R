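# Stage IV-a: dose/response series construction and the statistical flags
# (overall trend, treatment-only trend, control-vs-treatment Wilcoxon) whose
# q-values drive the decision tree selecting gene-treatment pairs for
# concentration-response fitting.

#' Build the dose/response series for one gene-treatment pair
#'
#' Treatment doses are log10(concentration in uM); vehicle controls receive a
#' pseudo-dose one average log10-dose spacing below the lowest treatment
#' concentration. Responses are log2(normalized count + 0.5), mean-centered
#' to the vehicle controls (so control responses average exactly 0).
#'
#' @param normalized Normalized counts tibble or matrix.
#' @param layout Layout tibble.
#' @param gene Gene id (row of the matrix).
#' @param chemical Chemical name.
#' @return A `dose_response_series` tibble: `sample_id`, `dose` (log10 uM),
#'   `response`, `is_control`, ordered controls first then increasing dose,
#'   with attributes `gene`, `chemical`, `n_control`, `control_sd`,
#'   `pseudo_dose`, `max_dose`.
#' @export
build_series <- function(normalized, layout, gene, chemical) {
  layout <- validate_layout(layout)
  m <- counts_matrix(normalized)
  if (!gene %in% rownames(m)) stop("gene ", gene, " not in matrix")

  ctl <- layout[layout$is_vehicle & layout$sample_id %in% colnames(m), ]
  trt <- layout[!layout$is_vehicle & layout$chemical == chemical &
                  layout$sample_id %in% colnames(m), ]
  if (any(trt$conc_uM <= 0)) {
    stop("non-positive concentration on a treatment row for ", chemical)
  }
  concs <- sort(unique(trt$conc_uM))
  if (length(concs) < 2) stop("need >= 2 distinct treatment concentrations")
  if (nrow(ctl) < 2) stop("need >= 2 vehicle controls")

  logd <- sort(log10(concs))
  pseudo <- min(logd) - mean(diff(logd))
  trt <- trt[order(trt$conc_uM), ]

  resp_ctl <- log2p(m[gene, ctl$sample_id])
  resp_trt <- log2p(m[gene, trt$sample_id])
  center <- mean(resp_ctl)

  out <- tibble::tibble(
    sample_id = c(ctl$sample_id, trt$sample_id),
    dose = c(rep(pseudo, nrow(ctl)), log10(trt$conc_uM)),
    response = unname(c(resp_ctl, resp_trt) - center),
    is_control = rep(c(TRUE, FALSE), c(nrow(ctl), nrow(trt)))
  )
  attr(out, "gene") <- gene
  attr(out, "chemical") <- chemical
  attr(out, "n_control") <- nrow(ctl)
  attr(out, "control_sd") <- sd(out$response[out$is_control])
  attr(out, "pseudo_dose") <- pseudo
  attr(out, "max_dose") <- max(logd)
  class(out) <- c("dose_response_series", class(out))
  out
}

#' All permutations of 1..n
#'
#' Row-wise matrix of the n! permutations, in a deterministic order. Used by
#' the exact trend test; practical for n <= 8.
#'
#' @param n Number of elements (capped at 9).
#' @return Integer matrix, n! rows by n columns.
#' @export
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 9)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    out[rows, -1L] <- sub + (sub >= i)
  }
  out
}

# exact permutation moments (2nd-4th central) of the correlation statistic
# r = sum(a_c * b_c) / sqrt(S_a2 * S_b2) under uniform permutation of b
perm_moments <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  Sa2 <- sum(a^2); Sa3 <- sum(a^3); Sa4 <- sum(a^4)
  Sb2 <- sum(b^2); Sb3 <- sum(b^3); Sb4 <- sum(b^4)
  m2 <- Sa2 * Sb2 / (n - 1)
  m3 <- if (n >= 3) n * Sa3 * Sb3 / ((n - 1) * (n - 2)) else 0
  m4 <- Sa4 * Sb4 / n +
    4 * Sa4 * Sb4 / (n * (n - 1)) +
    3 * (Sa2^2 - Sa4) * (Sb2^2 - Sb4) / (n * (n - 1))
  if (n >= 3) m4 <- m4 + 6 * (2 * Sa4 - Sa2^2) * (2 * Sb4 - Sb2^2) /
      (n * (n - 1) * (n - 2))
  if (n >= 4) m4 <- m4 + (3 * Sa2^2 - 6 * Sa4) * (3 * Sb2^2 - 6 * Sb4) /
      (n * (n - 1) * (n - 2) * (n - 3))
  sc <- sqrt(Sa2 * Sb2)
  list(var = m2 / sc^2, m3 = m3 / sc^3, m4 = m4 / sc^4)
}

# CDF of the moment-matched Pearson type I (4-parameter beta) distribution
# with mean 0; falls back to a normal when outside the beta region
beta_moment_cdf <- function(q, sigma2, g1, b2) {
  denom <- 6 + 3 * g1^2 - 2 * b2
  normal <- function() pnorm(q, 0, sqrt(sigma2))
  if (!is.finite(denom) || denom <= 0) return(normal())
  nu <- 6 * (b2 - g1^2 - 1) / denom
  if (!is.finite(nu) || nu <= 0) return(normal())
  d <- nu * g1 * (nu + 2) / sqrt(16 * (nu + 1) + g1^2 * (nu + 2)^2)
  shape1 <- (nu - d) / 2
  shape2 <- (nu + d) / 2
  if (shape1 <= 0 || shape2 <= 0) return(normal())
  len <- sqrt(sigma2) * nu * sqrt((nu + 1) / (shape1 * shape2))
  lower <- -len * shape1 / nu
  pbeta((q - lower) / len, shape1, shape2)
}

two_sided <- function(p_up, p_down) min(1, 2 * min(p_up, p_down))

#' Permutation trend test for a dose-response association
#'
#' Tests for association between dose and response with the Pearson
#' correlation as statistic and the permutation distribution of the response
#' as the null. Modes: `permutation_exact` enumerates all n! permutations
#' (n <= 8); `permutation_mc` samples `n_perm` random permutations (p
#' estimated with the add-one rule); `moment_approx` matches the exact
#' permutation moments (variance, skewness, kurtosis, computed analytically)
#' of the correlation to a shifted/scaled beta and reads the tail off that
#' fit -- for n <= 8, where enumeration is cheaper than approximating, it
#' enumerates instead. The default `auto` enumerates for n <= 8 and uses
#' Monte Carlo otherwise. P-values are two-sided (twice the smaller tail).
#'
#' @param dose,response Numeric vectors of equal length (>= 3 points).
#' @param mode One of `auto`, `permutation_exact`, `permutation_mc`,
#'   `moment_approx`.
#' @param n_perm Monte Carlo draws for `permutation_mc` (default 10,000);
#'   uses the session RNG stream.
#' @return Two-sided p-value. A constant response returns p = 1; a constant
#'   dose is an error.
#' @export
trend_test <- function(dose, response,
                       mode = c("auto", "permutation_exact", "permutation_mc",
                                "moment_approx"),
                       n_perm = 10000) {
  mode <- match.arg(mode)
  n <- length(dose)
  stopifnot(length(response) == n)
  if (n < 3) stop("trend test needs >= 3 points")
  if (sd(dose) == 0) stop("dose vector is constant")
  if (sd(response) == 0) return(1)

  a <- dose - mean(dose)
  b <- response - mean(response)
  sc <- sqrt(sum(a^2) * sum(b^2))
  r_obs <- sum(a * b) / sc
  eps <- 1e-12

  if (mode == "auto") mode <- if (n <= 8) "permutation_exact" else "permutation_mc"
  if (mode == "moment_approx" && n <= 8) mode <- "permutation_exact"

  if (mode == "permutation_exact") {
    if (n > 8) stop("exact enumeration limited to n <= 8; use permutation_mc")
    P <- all_permutations(n)
    rp <- as.vector(matrix(b[P], nrow(P), n) %*% a) / sc
    return(two_sided(mean(rp >= r_obs - eps), mean(rp <= r_obs + eps)))
  }
  if (mode == "permutation_mc") {
    rp <- vapply(seq_len(n_perm), function(i) sum(a * b[sample.int(n)]), 0.0) / sc
    up <- (1 + sum(rp >= r_obs - eps)) / (n_perm + 1)
    down <- (1 + sum(rp <= r_obs + eps)) / (n_perm + 1)
    return(two_sided(up, down))
  }
  mm <- perm_moments(dose, response)
  g1 <- mm$m3 / mm$var^1.5
  b2 <- mm$m4 / mm$var^2
  Fq <- beta_moment_cdf(r_obs, mm$var, g1, b2)
  two_sided(1 - Fq, Fq)
}

#' Wilcoxon rank-sum test between control and treatment responses
#'
#' Two-sided rank-sum p-value: exact enumeration when both groups are small
#' (min(n, m) <= 10) and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param control,treatment Numeric vectors (both nonempty).
#' @return Two-sided p-value.
#' @export
wilcoxon_test <- function(control, treatment) {
  stopifnot(length(control) > 0, length(treatment) > 0)
  ties <- anyDuplicated(c(control, treatment)) > 0
  exact <- !ties && min(length(control), length(treatment)) <= 10
  suppressWarnings(
    wilcox.test(control, treatment, exact = exact, correct = TRUE)$p.value
  )
}

#' FDR q-values for a vector of p-values
#'
#' Benjamini-Hochberg step-up by default; optionally scaled by Storey's
#' pi0 estimate (lambda = 0.5). NAs are preserved and excluded from the
#' denominator.
#'
#' @param p Numeric vector of p-values.
#' @param pi0 Use Storey's pi0 correction (default FALSE = plain BH).
#' @return Vector of q-values, same length/order as `p`.
#' @export
q_values <- function(p, pi0 = FALSE) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- p.adjust(p[ok], method = "BH")
  if (pi0 && sum(ok) > 0) {
    lambda <- 0.5
    pi0_hat <- min(1, max(0, mean(p[ok] > lambda) / (1 - lambda)))
    q[ok] <- pmin(1, q[ok] * pi0_hat)
  }
  q
}

#' Decision-tree routing from statistical flags
#'
#' Pure function of the three q-values and the significance threshold.
#' No overall trend: the maximum tested dose becomes the POD. Otherwise a
#' significant control-vs-treatment Wilcoxon, or failing that a significant
#' treatment-only trend, selects the pair for curve fitting; pairs passing
#' the overall trend but neither follow-up go to manual review.
#'
#' @param q_overall,q_wilcox,q_trt Vectors of q-values (recycled).
#' @param threshold Significance threshold on q (default 0.05).
#' @return Character vector: `no_trend_pod_max`, `fit_wilcoxon`,
#'   `fit_treatment_trend` or `manual_review`.
#' @export
route_flags <- function(q_overall, q_wilcox, q_trt, threshold = 0.05) {
  dplyr::case_when(
    is.na(q_overall) | q_overall >= threshold ~ "no_trend_pod_max",
    !is.na(q_wilcox) & q_wilcox < threshold ~ "fit_wilcoxon",
    !is.na(q_trt) & q_trt < threshold ~ "fit_treatment_trend",
    .default = "manual_review"
  )
}

#' Compute statistical flags for every gene-treatment pair
#'
#' For each gene and chemical: builds the dose/response series, runs the
#' overall trend test (all points), the treatment-only trend test, and the
#' control-versus-treatment Wilcoxon test, converts each p-value family to
#' q-values across genes within the chemical, and routes the pair through
#' the decision tree.
#'
#' @param normalized Normalized counts tibble or matrix.
#' @param layout Layout tibble.
#' @param q_threshold Routing threshold on q (default 0.05).
#' @param mode Trend-test mode (see [trend_test()]); the default is the
#'   moment-corrected accelerator, which matches the permutation null
#'   without a Monte Carlo p-value floor (exact enumeration still applies
#'   for short series such as the treatment-only test).
#' @param n_perm Monte Carlo permutations for the trend test.
#' @param genes Genes to process (default: all rows).
#' @param pi0 Use Storey's pi0 in [q_values()].
#' @return A `crpod_flags` tibble: `chemical`, `gene`, the three p/q pairs,
#'   `control_sd` and `route`.
#' @export
flag_pairs <- function(normalized, layout, q_threshold = 0.05,
                       mode = "moment_approx", n_perm = 10000, genes = NULL,
                       pi0 = FALSE) {
  layout <- validate_layout(layout)
  m <- counts_matrix(normalized)
  if (is.null(genes)) genes <- rownames(m)
  chems <- sort(unique(layout$chemical[!layout$is_vehicle]))

  res <- purrr::map_dfr(chems, function(ch) {
    rows <- purrr::map_dfr(genes, function(g) {
      s <- build_series(m, layout, g, ch)
      trt <- !s$is_control
      p_overall <- trend_test(s$dose, s$response, mode = mode, n_perm = n_perm)
      p_trt <- if (sum(trt) >= 3 && length(unique(s$dose[trt])) > 1) {
        trend_test(s$dose[trt], s$response[trt], mode = mode, n_perm = n_perm)
      } else NA_real_
      p_wilcox <- wilcoxon_test(s$response[s$is_control], s$response[trt])
      tibble::tibble(gene = g, p_overall = p_overall, p_trt = p_trt,
                     p_wilcox = p_wilcox,
                     control_sd = attr(s, "control_sd"))
    })
    rows |>
      dplyr::mutate(chemical = ch,
                    q_overall = q_values(.data$p_overall, pi0 = pi0),
                    q_trt = q_values(.data$p_trt, pi0 = pi0),
                    q_wilcox = q_values(.data$p_wilcox, pi0 = pi0))
  })
  res <- res |>
    dplyr::mutate(route = route_flags(.data$q_overall, .data$q_wilcox,
                                      .data$q_trt, threshold = q_threshold)) |>
    dplyr::select("chemical", "gene", "p_overall", "q_overall", "p_trt",
                  "q_trt", "p_wilcox", "q_wilcox", "control_sd", "route")
  class(res) <- c("crpod_flags", class(res))
  res
}
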