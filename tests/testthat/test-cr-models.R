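test_that("model curves satisfy their defining identities", {
  expect_equal(cr_curve("hill3", c(tp = 2, ga = 0, gw = 1), 0), 1)  # tp/2
  expect_equal(cr_curve("hill3", c(tp = 2, ga = 0, gw = 1), 50), 2,
               tolerance = 1e-10)
  expect_equal(cr_curve("hill3", c(tp = 2, ga = 0, gw = 1), -50), 0,
               tolerance = 1e-10)
  expect_equal(cr_curve("hill4",
                        c(floor = -1, top = 3, slope = 2, ec50 = 0.5), 0.5), 1)
  expect_equal(cr_curve("constant", c(mu = 0.7), seq(-2, 1, 0.5)),
               rep(0.7, 7))

  # gain-loss degenerates to hill3 when the loss phase is far to the right
  x <- seq(-2, 1, length.out = 40)
  gl <- cr_curve("gainloss", c(tp = 1.5, ga = -0.3, gw = 2, la = 10, lw = 8), x)
  h3 <- cr_curve("hill3", c(tp = 1.5, ga = -0.3, gw = 2), x)
  expect_equal(gl, h3, tolerance = 1e-6)
  expect_error(cr_curve("spline", list(), 0), "unknown model")
})

test_that("noise-free hill3 data is recovered to high precision", {
  x <- c(rep(-2, 12), -1, 0, 1)
  truth <- c(tp = 2, ga = 0, gw = 1)
  s <- make_series(x, cr_curve("hill3", truth, x), control_sd = 0.1)
  fit <- fit_cr_model(s, "hill3")
  expect_true(fit$converged)
  expect_equal(fit$direction, "up")
  expect_equal(unname(fit$params[c("tp", "ga", "gw")]), unname(truth),
               tolerance = 1e-3)
  fs <- fit_cr_models(s)
  expect_true(fs$winner %in% c("hill3", "hill4"))
})

test_that("sign symmetry: negated responses flip direction, not fit quality", {
  x <- c(rep(-2, 12), rep(c(-1, 0, 1), each = 3))
  set.seed(7)
  y <- cr_curve("hill3", c(tp = 1.5, ga = -0.5, gw = 2), x) + rnorm(length(x), 0, 0.05)
  up <- fit_cr_model(make_series(x, y, control_sd = 0.3), "hill3")
  dn <- fit_cr_model(make_series(x, -y, control_sd = 0.3), "hill3")
  expect_equal(up$direction, "up")
  expect_equal(dn$direction, "down")
  expect_equal(up$aic, dn$aic, tolerance = 1e-6)
  expect_equal(unname(up$params), unname(dn$params), tolerance = 1e-4)

  sp <- make_series(x, y, control_sd = 0.3)
  sn <- make_series(x, -y, control_sd = 0.3)
  pu <- pod_from_fit(fit_cr_models(sp), bsd = 0.5)
  pd <- pod_from_fit(fit_cr_models(sn), bsd = 0.5)
  expect_equal(pu$pod_log10, pd$pod_log10, tolerance = 1e-4)
})

test_that("a free floor is rewarded only when the data demand it", {
  # noise-free curve whose left tail is already rising at the control dose:
  # a floor-0 model cannot pass exactly through the centered control level,
  # so the free floor earns its extra parameter
  x <- c(rep(-2.5, 12), rep(c(-1, 0, 1), each = 3))
  pars <- c(floor = -0.3, top = 1, slope = 1, ec50 = -1.5)
  y <- cr_curve("hill4", pars, x)
  # recenter so controls average 0, as build_series guarantees
  y <- y - mean(y[x == -2.5])
  fs <- fit_cr_models(make_series(x, y, control_sd = 0.2))
  h3 <- fs$fits$hill3; h4 <- fs$fits$hill4
  expect_lt(h4$aic, h3$aic)
})

test_that("AIC model selection follows the tie-breaking rules", {
  mk <- function(model, aic, k, converged = TRUE) {
    structure(list(model = model, aic = aic, k = k, converged = converged),
              class = "crpod_fit")
  }
  fits <- list(constant = mk("constant", 10, 2, converged = TRUE),
               hill3 = mk("hill3", 99, 4, converged = FALSE))
  expect_equal(select_cr_model(fits), "constant")

  fits2 <- list(hill3 = mk("hill3", 5, 4), hill4 = mk("hill4", 5, 5))
  expect_equal(select_cr_model(fits2), "hill3")   # tie: fewer parameters

  fits3 <- list(gainloss = mk("gainloss", 5, 6), hill4 = mk("hill4", 5, 5))
  expect_equal(select_cr_model(fits3), "hill4")

  fits4 <- list(hill3 = mk("hill3", 99, 4, FALSE),
                gainloss = mk("gainloss", 99, 6, FALSE))
  expect_equal(select_cr_model(fits4), "constant")  # nothing converged
})

test_that("POD bisection matches the hill3 closed form", {
  s <- make_series(c(rep(-2, 12), -1, 0, 1), rep(0, 15), control_sd = 1)
  fit <- structure(list(model = "hill3", params = c(tp = 2, ga = 0, gw = 1),
                        direction = "up", converged = TRUE),
                   class = "crpod_fit")
  pod <- pod_from_fit(fit, s, bsd = 1)
  expect_equal(pod$pod_log10, 0, tolerance = 1e-6)   # tp/2 crossing at ga
  expect_equal(pod$basis, "curve_crossing")

  pod2 <- pod_from_fit(fit, s, bsd = 0.5)
  expect_equal(pod2$pod_log10, -log10(3), tolerance = 1e-5)

  # curve bounded below the BSD: no crossing, max dose returned
  low <- structure(list(model = "hill3", params = c(tp = 0.5, ga = 0, gw = 1),
                        direction = "up", converged = TRUE),
                   class = "crpod_fit")
  pod3 <- pod_from_fit(low, s, bsd = 1)
  expect_equal(pod3$pod_log10, 1)
  expect_equal(pod3$basis, "max_dose_no_crossing")

  # constant winner is treated as no crossing
  cfit <- fit_cr_model(s, "constant")
  pod4 <- pod_from_fit(cfit, s, bsd = 1)
  expect_equal(pod4$basis, "max_dose_no_crossing")

  # a POD below the lowest tested dose is flagged extrapolated
  early <- structure(list(model = "hill3", params = c(tp = 3, ga = -1.8, gw = 4),
                          direction = "up", converged = TRUE),
                     class = "crpod_fit")
  pod5 <- pod_from_fit(early, s, bsd = 0.5)
  expect_true(pod5$extrapolated)
})

test_that("hill3 parameters are recovered from NB noise at plate depth", {
  set.seed(53)
  x <- c(rep(-2, 23), -1, 0, 1)
  err <- replicate(200, {
    tp <- runif(1, 1, 2.5); ga <- runif(1, -1, 0.5); gw <- runif(1, 1, 4)
    mu <- 200 * 2^cr_curve("hill3", c(tp = tp, ga = ga, gw = gw), x)
    y <- log2(rnbinom(length(x), mu = mu, size = 20) + 0.5)
    y <- y - mean(y[x == -2])
    fit <- fit_cr_model(make_series(x, y, control_sd = 0.3), "hill3")
    abs(fit$params[["ga"]] - ga)
  })
  expect_lt(median(err), 0.25)
})

test_that("POD summaries aggregate distributions and winner frequencies", {
  pods <- tibble::tibble(
    chemical = rep(c("a", "b"), c(3, 2)),
    gene = paste0("g", 1:5),
    route = "fit_wilcoxon",
    winner = c("hill3", "hill3", "hill4", "hill3", "gainloss"),
    direction = "up",
    pod_log10 = c(-1, 0, 1, 0.5, 0.5), pod_uM = 10^c(-1, 0, 1, 0.5, 0.5),
    bsd = 0.3, basis = "curve_crossing", extrapolated = FALSE, aic = 1
  )
  sm <- pod_summary(pods)
  a <- sm$distribution[sm$distribution$chemical == "a", ]
  expect_equal(a$mean_pod, 0)
  expect_equal(a$median_pod, 0)
  expect_equal(a$sd_pod, 1)
  b <- sm$distribution[sm$distribution$chemical == "b", ]
  expect_equal(b$sd_pod, 0)
  expect_equal(sum(sm$winners$n_genes), 5)
  expect_equal(sm$winners$fraction[sm$winners$chemical == "a" &
                                     sm$winners$winner == "hill3"], 2 / 3)

  # broom-style accessors expose the same fit
  s <- make_series(c(rep(-2, 6), -1, 0, 1),
                   cr_curve("hill3", c(tp = 2, ga = 0, gw = 1),
                            c(rep(-2, 6), -1, 0, 1)), control_sd = 0.2)
  fs <- fit_cr_models(s)
  gl <- glance(fs)
  expect_true(any(gl$winner))
  expect_equal(nrow(tidy(fs$fits$hill3)), 3)
  aug <- augment(fs$fits$hill3)
  expect_equal(nrow(aug), nrow(s))
  expect_lt(max(abs(aug$.resid)), 1e-4)
})
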