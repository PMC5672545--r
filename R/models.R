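# Stage IV-b model fitting: constant, three-parameter Hill (floor 0),
# gain-loss (product of gain and loss sigmoids, floor 0) and four-parameter
# Hill curves in log10 dose, fit by Gaussian maximum likelihood (least
# squares; a heavy-tailed t(4) likelihood is available) with deterministic
# multi-start bounded optimization, compared by AIC.

#' Evaluate a concentration-response model curve
#'
#' Functional forms (x = log10 dose):
#' * `constant`: mu
#' * `hill3`: tp / (1 + 10^((ga - x) * gw)) -- floor fixed at 0; `tp` top
#'   asymptote, `ga` log10 AC50, `gw` slope
#' * `gainloss`: tp * 1/(1 + 10^((ga - x) * gw)) * 1/(1 + 10^((x - la) * lw))
#'   -- a gain sigmoid times a loss sigmoid (rise-then-fall)
#' * `hill4`: floor + (top - floor) / (1 + 10^((ec50 - x) * slope))
#'
#' @param name Model name.
#' @param params Named numeric vector/list of parameters (above).
#' @param x Log10 dose vector.
#' @return Predicted response vector.
#' @export
cr_curve <- function(name, params, x) {
  p <- as.list(params)
  switch(name,
    constant = rep(p$mu, length(x)),
    hill3 = p$tp / (1 + 10^((p$ga - x) * p$gw)),
    gainloss = p$tp / (1 + 10^((p$ga - x) * p$gw)) / (1 + 10^((x - p$la) * p$lw)),
    hill4 = p$floor + (p$top - p$floor) / (1 + 10^((p$ec50 - x) * p$slope)),
    stop("unknown model: ", name)
  )
}

# free-parameter count including the residual scale
model_k <- c(constant = 2, hill3 = 4, hill4 = 5, gainloss = 6)

# Gaussian (profile) or t(4) negative log-likelihood of residuals
resid_nll <- function(resid, error_model) {
  n <- length(resid)
  if (error_model == "gaussian") {
    s2 <- max(sum(resid^2) / n, 1e-12)
    n / 2 * (log(2 * pi * s2) + 1)
  } else {
    s <- max(sqrt(sum(resid^2) / n), 1e-6)  # profile-ish scale for t(4)
    opt <- optim(log(s), function(ls) {
      -sum(dt(resid / exp(ls), df = 4, log = TRUE) - ls)
    }, method = "Brent", lower = log(s) - 6, upper = log(s) + 6)
    opt$value
  }
}

fit_one_start <- function(x, y, name, start, lower, upper, error_model) {
  obj <- function(par) {
    pred <- cr_curve(name, setNames(par, names(start)), x)
    if (any(!is.finite(pred))) return(1e10)
    if (error_model == "gaussian") sum((y - pred)^2) else
      resid_nll(y - pred, error_model)
  }
  fit <- tryCatch(
    nlminb(unlist(start), obj, lower = lower, upper = upper,
           control = list(iter.max = 500)),
    error = function(e) NULL
  )
  if (is.null(fit) || !is.finite(fit$objective)) return(NULL)
  fit$par <- setNames(fit$par, names(start))
  fit
}

# deterministic multi-start grids over the observed dose range
start_grid <- function(name, x, y) {
  qs <- unname(quantile(range(x), c(0.25, 0.5, 0.75)))
  amax <- max(abs(y), 0.1)
  tp0 <- min(max(max(y), 0.1 * amax), 1.2 * amax)
  switch(name,
    hill3 = {
      g <- expand.grid(ga = qs, gw = c(0.5, 1, 4))
      lapply(seq_len(nrow(g)), function(i) list(tp = tp0, ga = g$ga[i], gw = g$gw[i]))
    },
    gainloss = {
      g <- expand.grid(ga = qs[1:2], la = qs[2:3], w = c(0.5, 1, 4))
      g <- g[g$la >= g$ga, ]
      lapply(seq_len(nrow(g)), function(i) {
        list(tp = tp0, ga = g$ga[i], gw = g$w[i], la = g$la[i], lw = g$w[i])
      })
    },
    hill4 = {
      lo <- min(y); hi <- max(y)
      g <- expand.grid(ec50 = qs, slope = c(0.5, 1, 4), flip = c(FALSE, TRUE))
      lapply(seq_len(nrow(g)), function(i) {
        if (g$flip[i]) list(floor = hi, top = lo, slope = g$slope[i], ec50 = g$ec50[i])
        else list(floor = lo, top = hi, slope = g$slope[i], ec50 = g$ec50[i])
      })
    }
  )
}

model_bounds <- function(name, x, y) {
  amax <- max(abs(y), 0.1)
  dlo <- min(x) - 1; dhi <- max(x) + 1
  switch(name,
    hill3 = list(lower = c(tp = 0, ga = dlo, gw = 0.3),
                 upper = c(tp = 1.2 * amax, ga = dhi, gw = 8)),
    gainloss = list(lower = c(tp = 0, ga = dlo, gw = 0.3, la = dlo, lw = 0.3),
                    upper = c(tp = 1.2 * amax, ga = dhi, gw = 8, la = dhi, lw = 8)),
    hill4 = list(lower = c(floor = -1.2 * amax, top = -1.2 * amax,
                           slope = 0.3, ec50 = dlo),
                 upper = c(floor = 1.2 * amax, top = 1.2 * amax,
                           slope = 8, ec50 = dhi))
  )
}

#' Fit one concentration-response model to a series
#'
#' Least-squares (Gaussian ML) fit with deterministic multi-start bounded
#' optimization. The floor-0 models (`hill3`, `gainloss`) are fit to both
#' the response and its negation; the better sign is kept and reported as
#' the response `direction` (`up`/`down`). `hill4` covers both directions
#' with its free floor. The residual scale counts as a free parameter in
#' AIC (k: constant 2, hill3 4, hill4 5, gainloss 6).
#'
#' @param series A [build_series()] result (or any data frame with `dose`
#'   and `response`).
#' @param name Model name: `constant`, `hill3`, `gainloss`, `hill4`.
#' @param error_model `gaussian` (default) or `t4`.
#' @return A `crpod_fit` list: `model`, `params`, `direction`, `loglik`,
#'   `aic`, `k`, `sigma`, `converged`, `degenerate` (gain-loss fits with
#'   the loss midpoint left of the gain midpoint are flagged).
#' @export
fit_cr_model <- function(series, name = c("constant", "hill3", "gainloss", "hill4"),
                         error_model = c("gaussian", "t4")) {
  name <- match.arg(name)
  error_model <- match.arg(error_model)
  x <- series$dose
  y <- series$response
  n <- length(y)

  finish <- function(params, resid, direction, converged, degenerate = FALSE) {
    nll <- resid_nll(resid, error_model)
    k <- model_k[[name]]
    structure(list(model = name, params = params, direction = direction,
                   loglik = -nll, aic = 2 * k + 2 * nll, k = k,
                   sigma = sqrt(sum(resid^2) / n), converged = converged,
                   degenerate = degenerate, n = n,
                   series = series, error_model = error_model),
              class = "crpod_fit")
  }

  if (name == "constant") {
    mu <- mean(y)
    return(finish(c(mu = mu), y - mu, "none", TRUE))
  }

  bounds <- model_bounds(name, x, y)
  signs <- if (name == "hill4") 1 else c(1, -1)
  best <- NULL; best_obj <- Inf; best_sign <- 1
  for (sgn in signs) {
    ys <- sgn * y
    for (st in start_grid(name, x, ys)) {
      st <- pmin(pmax(unlist(st), bounds$lower), bounds$upper)
      fit <- fit_one_start(x, ys, name, as.list(st), bounds$lower,
                           bounds$upper, error_model)
      if (!is.null(fit) && fit$objective < best_obj - 1e-12) {
        best <- fit; best_obj <- fit$objective; best_sign <- sgn
      }
    }
  }
  if (is.null(best)) {
    out <- finish(setNames(rep(NA_real_, length(bounds$lower)),
                           names(bounds$lower)), y, "none", FALSE)
    return(out)
  }
  pred <- best_sign * cr_curve(name, best$par, x)
  direction <- if (name == "hill4") {
    if (best$par[["top"]] >= best$par[["floor"]]) "up" else "down"
  } else if (best_sign > 0) "up" else "down"
  degenerate <- name == "gainloss" && best$par[["la"]] < best$par[["ga"]]
  finish(best$par, y - pred, direction, best$convergence == 0, degenerate)
}

#' Fit all candidate models and select a winner by AIC
#'
#' @param series A [build_series()] result.
#' @param models Models to fit.
#' @param error_model Passed to [fit_cr_model()].
#' @return A `crpod_fitset`: list with `fits` (named list of `crpod_fit`),
#'   `winner` (model name) and `series`.
#' @export
fit_cr_models <- function(series,
                          models = c("constant", "hill3", "gainloss", "hill4"),
                          error_model = "gaussian") {
  fits <- setNames(lapply(models, function(nm) {
    fit_cr_model(series, nm, error_model)
  }), models)
  structure(list(fits = fits, winner = select_cr_model(fits), series = series),
            class = "crpod_fitset")
}

#' Select the winning model by smallest AIC
#'
#' Unconverged fits are excluded; if none converged the constant model is
#' the fallback. AIC ties resolve to fewer parameters, then to the fixed
#' order constant < hill3 < hill4 < gainloss.
#'
#' @param fits Named list of `crpod_fit` objects.
#' @return Winning model name.
#' @export
select_cr_model <- function(fits) {
  order_pref <- c("constant", "hill3", "hill4", "gainloss")
  ok <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (length(ok) == 0) return("constant")
  tab <- tibble::tibble(
    model = vapply(ok, `[[`, "", "model"),
    aic = vapply(ok, `[[`, 0.0, "aic"),
    k = vapply(ok, `[[`, 0.0, "k"),
    pref = match(vapply(ok, `[[`, "", "model"), order_pref)
  )
  tab <- tab[tab$aic <= min(tab$aic) + 1e-9, ]
  tab <- tab[order(tab$k, tab$pref), ]
  unname(tab$model[1])
}

#' @export
print.crpod_fit <- function(x, ...) {
  cat("crpod fit:", x$model, "(", x$direction, ")",
      if (!x$converged) "[unconverged]", "\n")
  print(round(x$params, 4))
  cat(sprintf("loglik %.3f  AIC %.3f  sigma %.4f\n", x$loglik, x$aic, x$sigma))
  invisible(x)
}

#' @export
print.crpod_fitset <- function(x, ...) {
  aics <- vapply(x$fits, `[[`, 0.0, "aic")
  cat("crpod model comparison (winner:", x$winner, ")\n")
  print(round(sort(aics), 3))
  invisible(x)
}
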