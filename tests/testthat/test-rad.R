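test_that("expected RAD sequences match their closed forms", {
  expect_equal(expected_rad("brokenstick", S = 2, N = 3), c(2.25, 0.75))
  expect_equal(sum(expected_rad("brokenstick", S = 15, N = 600)), 600)
  expect_equal(expected_rad("preemption", list(alpha = 0.5), S = 2, N = 3),
               c(2, 1))
  expect_equal(sum(expected_rad("preemption", list(alpha = 0.37), S = 9, N = 120)),
               120)
  expect_equal(expected_rad("zipf", list(p1 = 0.5, gamma = -1), S = 2, N = 10),
               c(5, 2.5))
  # mandelbrot at beta = 0 reduces to zipf
  expect_equal(expected_rad("mandelbrot", list(c = 0.5, beta = 0, gamma = -1.2),
                            S = 6, N = 10),
               expected_rad("zipf", list(p1 = 0.5, gamma = -1.2), S = 6, N = 10))
  # lognormal plotting-position form, checked at S = 2 by direct substitution
  ln <- expected_rad("lognormal", list(mu = 1, sigma = 0.5), S = 2, N = 1)
  expect_equal(ln, exp(1 + 0.5 * qnorm(1 - (1:2 - 0.5) / 2)))
})

test_that("expected RAD rejects out-of-domain parameters by name", {
  expect_error(expected_rad("preemption", list(alpha = 1.2), 5, 10), "alpha")
  expect_error(expected_rad("zipf", list(p1 = 0.5, gamma = 0.1), 5, 10), "gamma")
  expect_error(expected_rad("mandelbrot", list(c = 1, beta = -2, gamma = -1),
                            5, 10), "beta")
  expect_error(expected_rad("lognormal", list(mu = 0, sigma = -1), 5, 10),
               "sigma")
})

test_that("expected RAD is strictly positive and non-increasing in rank", {
  cases <- list(
    list(model = "brokenstick", params = list()),
    list(model = "preemption", params = list(alpha = 0.2)),
    list(model = "preemption", params = list(alpha = 0.9)),
    list(model = "lognormal", params = list(mu = 0.5, sigma = 1.3)),
    list(model = "zipf", params = list(p1 = 0.4, gamma = -0.8)),
    list(model = "mandelbrot", params = list(c = 0.8, beta = 2, gamma = -1.5)))
  for (cs in cases) {
    for (S in c(1, 4, 25)) {
      ab <- expected_rad(cs$model, cs$params, S = S, N = 500)
      expect_true(all(ab > 0))
      expect_true(all(diff(ab) <= 1e-12))
    }
  }
})

test_that("preemption MLE recovers an exact geometric series", {
  a <- c(64, 32, 16, 8, 4, 2)
  fit <- rad_fit(a, "preemption")
  expect_equal(unname(coef(fit)["alpha"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(fitted(fit)), a, tolerance = 1e-3)
  # numerical stationarity: no alpha on a fine grid beats the MLE
  ll <- function(alpha) {
    oracle_pois_ll(sort(a, decreasing = TRUE),
                   expected_rad("preemption", list(alpha = alpha), 6, sum(a)))
  }
  grid <- seq(0.01, 0.99, by = 0.001)
  expect_true(max(vapply(grid, ll, 0)) <= ll(coef(fit)["alpha"]) + 1e-8)
})

test_that("fits report consistent likelihood, AIC and round-trip fitted values", {
  counts <- c(sp1 = 120L, sp2 = 60L, sp3 = 31L, sp4 = 14L, sp5 = 8L,
              sp6 = 4L, sp7 = 2L, sp8 = 1L)
  for (m in rad_models()) {
    fit <- rad_fit(counts, m)
    expect_s3_class(fit, "rad_fit")
    expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
    expect_equal(fit$loglik, oracle_pois_ll(fit$counts, fit$fitted))
    expect_true(all(fit$fitted > 0))
    expect_true(all(diff(fit$fitted) <= 1e-8))
    # round trip: the stored parameters regenerate the fitted sequence
    expect_equal(unname(fit$fitted),
                 expected_rad(m, fit$params, S = length(fit$counts),
                              N = sum(fit$counts)),
                 tolerance = 1e-10)
  }
  # brokenstick has no parameters and depends only on S and N
  bs <- rad_fit(counts, "brokenstick")
  expect_equal(bs$k, 0L)
  expect_length(coef(bs), 0)
})

test_that("counts are ranked descending with lexicographic tie-break", {
  counts <- c(zeb = 5L, abe = 5L, mid = 9L)
  fit <- rad_fit(counts, "brokenstick")
  expect_equal(names(fit$counts), c("mid", "abe", "zeb"))
})

test_that("model selection picks the generating model and applies tie rules", {
  set.seed(31)
  truth <- generate_community("preemption", list(alpha = 0.4), S = 20, N = 1000)
  counts <- stats::setNames(rpois(20, truth), names(truth))
  sel <- sad_select(counts)
  expect_equal(sel$best, "preemption")
  expect_equal(unname(sel$delta_aic[sel$best]), 0)

  # data equal to rounded brokenstick expectations: brokenstick competitive
  bs <- round(expected_rad("brokenstick", S = 15, N = 600))
  sel2 <- sad_select(stats::setNames(bs, sprintf("s%02d", 1:15)))
  expect_true(sel2$delta_aic["brokenstick"] <= 2)

  # S = 3: mandelbrot (k = 3) is not eligible
  sel3 <- sad_select(c(a = 30L, b = 9L, c = 2L))
  expect_false("mandelbrot" %in% names(sel3$fits))
  expect_error(sad_select(c(a = 5L)), "eligible")
})

test_that("AIC ranking is invariant to a constant log-likelihood shift", {
  counts <- c(a = 80L, b = 40L, c = 22L, d = 9L, e = 3L)
  sel <- sad_select(counts)
  shifted <- sel$aic - 2 * 7.5  # same constant off every model's loglik
  expect_equal(names(which.min(shifted)), names(which.min(sel$aic)))
})

test_that("strict four-model selection can exclude zipf", {
  counts <- c(a = 80L, b = 40L, c = 22L, d = 9L, e = 3L)
  sel <- sad_select(counts, models = setdiff(rad_models(), "zipf"))
  expect_false("zipf" %in% names(sel$fits))
})
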