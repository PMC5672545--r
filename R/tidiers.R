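# broom-style accessors for fitted objects.

#' @export
tidy.crpod_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.crpod_fit <- function(x, ...) {
  tibble::tibble(model = x$model, direction = x$direction, logLik = x$loglik,
                 AIC = x$aic, k = x$k, sigma = x$sigma, n = x$n,
                 converged = x$converged, degenerate = x$degenerate)
}

#' @export
augment.crpod_fit <- function(x, ...) {
  s <- tibble::as_tibble(x$series)
  sgn <- if (x$model != "hill4" && x$direction == "down") -1 else 1
  fitted <- if (all(is.finite(unlist(x$params)))) {
    sgn * cr_curve(x$model, x$params, s$dose)
  } else rep(NA_real_, nrow(s))
  s$.fitted <- fitted
  s$.resid <- s$response - fitted
  s
}

#' @export
tidy.crpod_fitset <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    dplyr::mutate(tidy(f), model = f$model, .before = 1)
  })
}

#' @export
glance.crpod_fitset <- function(x, ...) {
  purrr::map_dfr(x$fits, glance) |>
    dplyr::mutate(winner = .data$model == x$winner)
}
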