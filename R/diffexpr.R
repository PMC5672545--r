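# Stage III: differential expression at the maximum tested concentration of
# each chemical versus the shared vehicle controls. Self-contained NB Wald
# test: per-gene method-of-moments dispersion on normalized counts, shrunk
# toward a parametric mean-dispersion trend (a0 + a1/mu), then a NB GLM with
# log link and size-factor offsets; raw MLE log2 fold changes (no shrinkage).

# pooled within-group method-of-moments dispersion estimates on normalized
# counts; returns per-gene raw alpha (can be negative) and residual df
mom_dispersion <- function(norm, group, sf) {
  levels <- unique(group)
  num <- rep(0, nrow(norm)); df <- 0
  for (g in levels) {
    idx <- which(group == g)
    if (length(idx) < 2) next
    mu <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, var)
    shot <- mu * mean(1 / sf[idx])          # Poisson part of Var(y/s)
    a <- ifelse(mu > 0, (v - shot) / mu^2, NA_real_)
    num <- num + (length(idx) - 1) * a
    df <- df + (length(idx) - 1)
  }
  if (df == 0) stop("dispersion estimation needs a group with >= 2 samples")
  list(alpha = num / df, df = df)
}

# parametric dispersion trend alpha(mu) = a0 + a1/mu, least squares over
# genes with a usable raw estimate, coefficients clipped to >= 0
dispersion_trend <- function(alpha_raw, mu) {
  use <- is.finite(alpha_raw) & alpha_raw > 0 & mu > 0
  if (sum(use) < 10) {
    a0 <- max(mean(alpha_raw[is.finite(alpha_raw)], na.rm = TRUE), 1e-4)
    return(c(a0 = a0, a1 = 0))
  }
  fit <- stats::lm.fit(cbind(1, 1 / mu[use]), alpha_raw[use])
  a0 <- max(fit$coefficients[1], 1e-6)
  a1 <- max(fit$coefficients[2], 0)
  c(a0 = unname(a0), a1 = unname(a1))
}

#' Negative-binomial Wald test for one treatment-versus-control contrast
#'
#' Tests each gene for differential expression between the vehicle controls
#' and one chemical's samples at one concentration (the maximum tested
#' concentration when `dose` is NULL). Dispersion is estimated gene-wise by
#' method of moments on normalized counts within replicated groups (with a
#' single-replicate treatment it therefore comes from the pooled controls),
#' shrunk toward a parametric trend `a0 + a1/mu`; the group effect is then
#' fit by a NB GLM with log link and log size-factor offsets and tested with
#' a Wald statistic referred to a t distribution on n - 2 degrees of
#' freedom (a finite-sample reference for the plug-in dispersion). Fold
#' changes are raw MLEs.
#'
#' @param counts Counts tibble or matrix (cleaned, from QC).
#' @param layout Layout tibble.
#' @param chemical Chemical name as in the layout.
#' @param dose Concentration (uM) of the treatment group; maximum tested
#'   when NULL.
#' @param sf Size factors for all involved samples; computed experiment-wide
#'   from `counts` when NULL.
#' @param prior_df Weight (in residual degrees of freedom) of the dispersion
#'   trend in the shrinkage.
#' @return Tibble: `gene`, `base_mean`, `l2fc`, `se`, `stat`, `p`, `padj`
#'   (BH within this contrast), `dispersion`. Genes with zero counts across
#'   the contrast get NA p and are excluded from the BH denominator.
#' @export
nb_test <- function(counts, layout, chemical, dose = NULL, sf = NULL,
                    prior_df = 10) {
  layout <- validate_layout(layout)
  m <- counts_matrix(counts)
  if (is.null(sf)) sf <- size_factors(m)
  sf <- sf[colnames(m)]

  trt_rows <- layout$chemical == chemical & !layout$is_vehicle
  if (!any(trt_rows)) stop("no treatment rows for chemical ", chemical)
  if (is.null(dose)) dose <- max(layout$conc_uM[trt_rows])
  trt <- intersect(layout$sample_id[trt_rows & layout$conc_uM == dose],
                   colnames(m))
  ctl <- intersect(layout$sample_id[layout$is_vehicle], colnames(m))
  if (length(ctl) < 2) stop("need at least 2 vehicle controls")
  if (length(trt) < 1) stop("no samples for ", chemical, " at ", dose, " uM")

  cols <- c(ctl, trt)
  y <- m[, cols, drop = FALSE]
  s <- sf[cols]
  grp <- factor(rep(c("control", "treatment"), c(length(ctl), length(trt))),
                levels = c("control", "treatment"))
  norm <- sweep(y, 2, s, "/")
  base_mean <- rowMeans(norm)

  disp <- mom_dispersion(norm, grp, s)
  trend <- dispersion_trend(disp$alpha, base_mean)
  alpha_trend <- trend["a0"] + trend["a1"] / pmax(base_mean, 1e-8)
  alpha_raw <- pmax(disp$alpha, 0)
  alpha_raw[!is.finite(alpha_raw)] <- alpha_trend[!is.finite(alpha_raw)]
  alpha <- (prior_df * alpha_trend + disp$df * alpha_raw) / (prior_df + disp$df)
  alpha <- pmin(pmax(alpha, 1e-8), 10)

  off <- log(s)
  xg <- as.integer(grp == "treatment")
  res <- matrix(NA_real_, nrow(y), 3,
                dimnames = list(rownames(y), c("l2fc", "se", "stat")))
  for (i in seq_len(nrow(y))) {
    yi <- y[i, ]
    if (all(yi == 0)) next
    fam <- if (alpha[i] < 1e-6) stats::poisson() else
      MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- tryCatch(
      suppressWarnings(glm(yi ~ xg + offset(off), family = fam)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    sm <- suppressWarnings(summary(fit, dispersion = 1))$coefficients
    if (nrow(sm) < 2) next
    res[i, ] <- c(sm[2, 1] / log(2), sm[2, 2] / log(2), sm[2, 1] / sm[2, 2])
  }

  # t reference with n - 2 df: finite-sample correction for the plug-in
  # dispersion (a normal reference is measurably liberal at these n)
  p <- 2 * pt(-abs(res[, "stat"]), df = max(length(cols) - 2, 1))
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- p.adjust(p[ok], method = "BH")
  tibble::tibble(gene = rownames(y), base_mean = unname(base_mean),
                 l2fc = unname(res[, "l2fc"]), se = unname(res[, "se"]),
                 stat = unname(res[, "stat"]), p = unname(p),
                 padj = padj, dispersion = unname(alpha))
}

#' Differential expression at maximum dose for every chemical
#'
#' @param counts Cleaned counts tibble or matrix.
#' @param layout Layout tibble.
#' @param sf Experiment-wide size factors (computed when NULL).
#' @param ... Passed to [nb_test()].
#' @return Tibble of per-gene results stacked over chemicals (column
#'   `chemical` first), one [nb_test()] contrast per chemical at its maximum
#'   tested concentration.
#' @export
de_max_dose <- function(counts, layout, sf = NULL, ...) {
  layout <- validate_layout(layout)
  chems <- sort(unique(layout$chemical[!layout$is_vehicle]))
  if (is.null(sf)) sf <- size_factors(counts)
  purrr::map_dfr(chems, function(ch) {
    dplyr::bind_cols(tibble::tibble(chemical = ch),
                     nb_test(counts, layout, ch, sf = sf, ...))
  })
}

#' Count differentially expressed genes
#'
#' @param de Result tibble from [nb_test()] or [de_max_dose()].
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return Tibble with `chemical` (when present) and `n_deg`.
#' @export
deg_count <- function(de, alpha = 0.05) {
  if ("chemical" %in% names(de)) {
    de |>
      dplyr::group_by(.data$chemical) |>
      dplyr::summarise(n_deg = sum(.data$padj < alpha, na.rm = TRUE),
                       .groups = "drop")
  } else {
    tibble::tibble(n_deg = sum(de$padj < alpha, na.rm = TRUE))
  }
}

#' PCA of per-chemical log2-fold-change vectors
#'
#' @param de Stacked DE tibble from [de_max_dose()].
#' @param n_components Number of components to report (default 3).
#' @return List with `scores` (chemical x PC tibble) and `var_explained`.
#' @export
l2fc_pca <- function(de, n_components = 3) {
  wide <- de |>
    dplyr::select("chemical", "gene", "l2fc") |>
    tidyr::pivot_wider(names_from = "gene", values_from = "l2fc")
  m <- as.matrix(wide[-1])
  m[!is.finite(m)] <- 0
  if (nrow(m) < 2) stop("l2fc PCA needs at least 2 chemicals")
  pc <- prcomp(m, center = TRUE)
  k <- min(n_components, ncol(pc$x))
  list(scores = dplyr::bind_cols(tibble::tibble(chemical = wide$chemical),
                                 tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])),
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)])
}

#' Per-chemical dispersion summaries of absolute log2 fold changes
#'
#' @param de Stacked DE tibble from [de_max_dose()].
#' @return Tibble per chemical: mean, quartiles and SD of |l2fc|.
#' @export
l2fc_summary <- function(de) {
  de |>
    dplyr::filter(is.finite(.data$l2fc)) |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(
      mean_abs_l2fc = mean(abs(.data$l2fc)),
      q25 = unname(quantile(abs(.data$l2fc), 0.25)),
      median_abs_l2fc = median(abs(.data$l2fc)),
      q75 = unname(quantile(abs(.data$l2fc), 0.75)),
      sd_abs_l2fc = sd(abs(.data$l2fc)),
      .groups = "drop"
    )
}
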