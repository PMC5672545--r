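# Point-of-departure estimation: the concentration at which the winning
# fitted curve departs one baseline deviation (BSD = 1 control SD, by
# default) from the control mean, located by bracketing plus bisection on
# the log10 dose scale.

#' Point of departure from a fitted model
#'
#' Searches [vehicle pseudo-dose, max dose] for the smallest log10 dose at
#' which |f(x)| equals the baseline deviation, where f is the winning fitted
#' curve on the centered response scale (negated for `down` fits of the
#' floor-0 models). A sign-change bracket on a fine grid is refined by
#' bisection to 1e-6. A constant winner, or a curve that never reaches the
#' BSD, yields the maximum tested dose with basis `max_dose_no_crossing`.
#' PODs below the lowest tested concentration are flagged `extrapolated`.
#'
#' @param fit A `crpod_fit` (the winning model) or `crpod_fitset`.
#' @param series The [build_series()] data the model was fit to (taken from
#'   the fit when omitted).
#' @param bsd Baseline deviation; default `bsd_multiplier` times the control
#'   SD of the series.
#' @param bsd_multiplier Multiplier on the control SD (default 1).
#' @return One-row tibble: `winner`, `direction`, `pod_log10`, `pod_uM`,
#'   `bsd`, `basis`, `extrapolated`.
#' @export
pod_from_fit <- function(fit, series = NULL, bsd = NULL, bsd_multiplier = 1) {
  if (inherits(fit, "crpod_fitset")) {
    series <- fit$series
    fit <- fit$fits[[fit$winner]]
  }
  if (is.null(series)) series <- fit$series
  pseudo <- attr(series, "pseudo_dose") %||% min(series$dose)
  dmax <- attr(series, "max_dose") %||% max(series$dose)
  dmin_trt <- min(series$dose[series$dose > pseudo], na.rm = TRUE)
  if (is.null(bsd)) {
    csd <- attr(series, "control_sd")
    if (is.null(csd)) stop("series lacks a control SD; supply `bsd`")
    bsd <- bsd_multiplier * csd
  }

  out <- function(pod, basis) {
    tibble::tibble(winner = fit$model, direction = fit$direction,
                   pod_log10 = pod, pod_uM = 10^pod, bsd = bsd, basis = basis,
                   extrapolated = pod < dmin_trt & basis == "curve_crossing")
  }
  if (fit$model == "constant" || !fit$converged) {
    return(out(dmax, "max_dose_no_crossing"))
  }

  sgn <- if (fit$model != "hill4" && fit$direction == "down") -1 else 1
  g <- function(x) abs(sgn * cr_curve(fit$model, fit$params, x)) - bsd

  grid <- seq(pseudo, dmax, length.out = 513)
  gv <- g(grid)
  if (gv[1] >= 0) return(out(pseudo, "curve_crossing"))
  cross <- which(gv[-1] * gv[-length(gv)] <= 0)
  if (length(cross) == 0) return(out(dmax, "max_dose_no_crossing"))
  i <- cross[1]
  root <- uniroot(g, lower = grid[i], upper = grid[i + 1], tol = 1e-6)$root
  out(root, "curve_crossing")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit models and estimate PODs for all flagged gene-treatment pairs
#'
#' Pairs routed to fitting (`fit_wilcoxon`, `fit_treatment_trend`) are fit
#' with all candidate models, the AIC winner is selected and its BSD
#' crossing located. Pairs with no overall trend receive the maximum tested
#' dose as POD (basis `max_dose_no_trend`); manual-review pairs are carried
#' with NA POD for the report.
#'
#' @param normalized Normalized counts tibble or matrix.
#' @param layout Layout tibble.
#' @param flags Flag table from [flag_pairs()].
#' @param bsd_multiplier Multiplier on the control SD (default 1).
#' @param models,error_model Passed to [fit_cr_models()].
#' @return A `crpod_pods` tibble: `chemical`, `gene`, `route`, `winner`,
#'   `direction`, `pod_log10`, `pod_uM`, `bsd`, `basis`, `extrapolated`,
#'   `aic`.
#' @export
estimate_pods <- function(normalized, layout, flags, bsd_multiplier = 1,
                          models = c("constant", "hill3", "gainloss", "hill4"),
                          error_model = "gaussian") {
  layout <- validate_layout(layout)
  m <- counts_matrix(normalized)

  res <- purrr::pmap_dfr(
    flags[c("chemical", "gene", "route")],
    function(chemical, gene, route) {
      s <- build_series(m, layout, gene, chemical)
      dmax <- attr(s, "max_dose")
      base <- tibble::tibble(chemical = chemical, gene = gene, route = route)
      if (route %in% c("fit_wilcoxon", "fit_treatment_trend")) {
        fs <- fit_cr_models(s, models = models, error_model = error_model)
        pod <- pod_from_fit(fs, bsd_multiplier = bsd_multiplier)
        dplyr::bind_cols(base, pod,
                         tibble::tibble(aic = fs$fits[[fs$winner]]$aic))
      } else if (route == "no_trend_pod_max") {
        dplyr::bind_cols(base, tibble::tibble(
          winner = NA_character_, direction = NA_character_,
          pod_log10 = dmax, pod_uM = 10^dmax,
          bsd = bsd_multiplier * attr(s, "control_sd"),
          basis = "max_dose_no_trend", extrapolated = FALSE, aic = NA_real_))
      } else {
        dplyr::bind_cols(base, tibble::tibble(
          winner = NA_character_, direction = NA_character_,
          pod_log10 = NA_real_, pod_uM = NA_real_,
          bsd = bsd_multiplier * attr(s, "control_sd"),
          basis = "manual_review", extrapolated = FALSE, aic = NA_real_))
      }
    })
  class(res) <- c("crpod_pods", class(res))
  res
}

#' Summarise PODs per chemical
#'
#' @param pods A [estimate_pods()] result.
#' @param fitted_only Summarise only curve-crossing PODs (default TRUE;
#'   otherwise all non-NA PODs including max-dose assignments).
#' @return List with `distribution` (per-chemical n, mean, median, SD of
#'   log10 POD) and `winners` (winning-model frequency table over fitted
#'   pairs).
#' @export
pod_summary <- function(pods, fitted_only = TRUE) {
  dist_src <- if (fitted_only) {
    dplyr::filter(pods, .data$basis == "curve_crossing")
  } else {
    dplyr::filter(pods, !is.na(.data$pod_log10))
  }
  distribution <- dist_src |>
    dplyr::group_by(.data$chemical) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pod = mean(.data$pod_log10),
                     median_pod = median(.data$pod_log10),
                     sd_pod = sd(.data$pod_log10),
                     .groups = "drop")
  winners <- pods |>
    dplyr::filter(!is.na(.data$winner)) |>
    dplyr::count(.data$chemical, .data$winner, name = "n_genes") |>
    dplyr::group_by(.data$chemical) |>
    dplyr::mutate(fraction = .data$n_genes / sum(.data$n_genes)) |>
    dplyr::ungroup()
  list(distribution = distribution, winners = winners)
}
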