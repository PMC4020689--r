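#' Expected rank-abundance sequence under a species-abundance model
#'
#' Closed-form expected abundance at each rank r = 1..S for five classical
#' SAD models:
#' \describe{
#'   \item{brokenstick}{`(N/S) * sum_{k=r..S} 1/k` — the null model, no free
#'     parameters.}
#'   \item{preemption}{`N * alpha * (1-alpha)^(r-1) / (1 - (1-alpha)^S)` —
#'     geometric series normalized over the S observed species, so the
#'     sequence sums to N exactly; `alpha` in (0,1).}
#'   \item{lognormal}{`exp(mu + sigma * qnorm(1 - (r - 0.5)/S))`, using the
#'     (r - 0.5)/S plotting-position convention; `mu`, `sigma` on the log
#'     scale, `sigma > 0`.}
#'   \item{zipf}{`N * p1 * r^gamma` with `p1 > 0` (fraction of the most
#'     abundant species) and decay `gamma < 0`.}
#'   \item{mandelbrot}{`N * c * (r + beta)^gamma` with `c > 0`,
#'     `beta > -1`, `gamma < 0`; reduces to zipf at `beta = 0`.}
#' }
#'
#' @param model one of `"brokenstick"`, `"preemption"`, `"lognormal"`,
#'   `"zipf"`, `"mandelbrot"`.
#' @param params named list/vector of model parameters (empty for
#'   brokenstick; `alpha`; `mu`,`sigma`; `p1`,`gamma`; `c`,`beta`,`gamma`).
#' @param S number of species (ranks).
#' @param N total abundance used for scaling (not used by lognormal).
#' @return numeric vector of expected abundances at ranks 1..S
#'   (strictly positive, non-increasing).
#' @export
expected_rad <- function(model, params = list(), S, N) {
  model <- match.arg(model, rad_model_names)
  if (S < 1) stop("S must be >= 1")
  if (N <= 0) stop("N must be > 0")
  params <- as.list(params)
  r <- seq_len(S)
  switch(model,
    brokenstick = (N / S) * rev(cumsum(1 / rev(r))),
    preemption = {
      alpha <- params$alpha
      if (is.null(alpha) || alpha <= 0 || alpha >= 1) {
        stop("preemption requires alpha in (0, 1)")
      }
      N * alpha * (1 - alpha)^(r - 1) / (1 - (1 - alpha)^S)
    },
    lognormal = {
      mu <- params$mu; sigma <- params$sigma
      if (is.null(mu) || is.null(sigma) || sigma <= 0) {
        stop("lognormal requires mu and sigma > 0")
      }
      exp(mu + sigma * stats::qnorm(1 - (r - 0.5) / S))
    },
    zipf = {
      p1 <- params$p1; gamma <- params$gamma
      if (is.null(p1) || p1 <= 0) stop("zipf requires p1 > 0")
      if (is.null(gamma) || gamma >= 0) stop("zipf requires gamma < 0")
      N * p1 * r^gamma
    },
    mandelbrot = {
      cc <- params$c; beta <- params$beta; gamma <- params$gamma
      if (is.null(cc) || cc <= 0) stop("mandelbrot requires c > 0")
      if (is.null(beta) || beta <= -1) stop("mandelbrot requires beta > -1")
      if (is.null(gamma) || gamma >= 0) stop("mandelbrot requires gamma < 0")
      N * cc * (r + beta)^gamma
    })
}

rad_model_names <- c("brokenstick", "preemption", "lognormal", "zipf", "mandelbrot")
rad_model_k <- c(brokenstick = 0L, preemption = 1L, lognormal = 2L,
                 zipf = 2L, mandelbrot = 3L)

# counts sorted to ranks: descending abundance, lexicographic species tie-break
rank_counts <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("no positive counts")
  if (is.null(names(counts))) names(counts) <- sprintf("sp%03d", seq_along(counts))
  counts[order(-counts, names(counts))]
}

# Poisson deviance part of the negative log-likelihood (constant dropped)
rad_nll <- function(a, fitted) {
  if (any(!is.finite(fitted)) || any(fitted <= 0)) return(Inf)
  -sum(a * log(fitted) - fitted)
}

# map optimizer-scale parameters theta -> natural parameters, per model
rad_untransform <- function(model, theta) {
  switch(model,
    preemption = list(alpha = stats::plogis(theta[1])),
    lognormal = list(mu = theta[1], sigma = exp(theta[2])),
    zipf = list(p1 = exp(theta[1]), gamma = -exp(theta[2])),
    mandelbrot = list(c = exp(theta[1]), beta = expm1(theta[2]),
                      gamma = -exp(theta[3])))
}

# documented deterministic starting points on the optimizer scale
rad_starts <- function(model, a, N) {
  S <- length(a)
  r <- seq_len(S)
  la <- log(a + 0.5)
  sl <- stats::coef(stats::lm(la ~ log(r)))  # power-law moment start
  switch(model,
    lognormal = list(c(mean(la), log(max(stats::sd(la), 0.1))),
                     c(mean(la), 0),
                     c(log(N / S), log(1))),
    zipf = list(c(sl[1] - log(N), log(max(-min(sl[2], -0.05), 0.05))),
                c(log(a[1] / N), log(1)),
                c(log(a[1] / N), log(0.5))),
    mandelbrot = list(c(sl[1] - log(N), log1p(0), log(max(-min(sl[2], -0.05), 0.05))),
                      c(log(a[1] / N), log1p(1), log(1)),
                      c(log(a[1] / N), log1p(5), log(2))))
}

#' Fit a rank-abundance model by Poisson maximum likelihood
#'
#' Counts are sorted internally to ranks (descending, species-name
#' tie-break) and the chosen model's expected-abundance sequence (see
#' [expected_rad()]) is fitted by maximizing the Poisson log-likelihood
#' `sum_r (a_r * log(ahat_r) - ahat_r)` (the `log(a_r!)` constant does not
#' affect the optimum and is dropped during optimization). The reported
#' `loglik` includes the constant so AIC values are comparable across
#' models fitted to the same counts. The single-parameter preemption model
#' is optimized by deterministic 1-D golden-section search; multi-parameter
#' models use Nelder-Mead from three fixed starting points (best result
#' kept), with parameters transformed to enforce their domains.
#'
#' @param counts named non-negative integer vector of pooled species counts.
#' @param model model name (see [expected_rad()]).
#' @return object of class `rad_fit`: `model`, `params` (named list), `k`
#'   (free-parameter count), `fitted` (expected abundance per rank, named by
#'   species), `counts` (ranked data), `loglik`, `aic`.
#' @export
rad_fit <- function(counts, model) {
  model <- match.arg(model, rad_model_names)
  a <- rank_counts(counts)
  S <- length(a)
  k <- rad_model_k[[model]]
  if (S < k + 1L) {
    stop(sprintf("model %s needs at least %d species, got %d", model, k + 1L, S))
  }
  N <- sum(a)
  if (model == "brokenstick") {
    fitted <- expected_rad("brokenstick", S = S, N = N)
    params <- list()
  } else if (model == "preemption") {
    eps <- 1e-9
    opt <- stats::optimize(function(alpha) {
      rad_nll(a, expected_rad("preemption", list(alpha = alpha), S, N))
    }, interval = c(eps, 1 - eps), tol = 1e-10)
    params <- list(alpha = opt$minimum)
    fitted <- expected_rad("preemption", params, S, N)
  } else {
    obj <- function(theta) {
      rad_nll(a, expected_rad(model, rad_untransform(model, theta), S, N))
    }
    best <- NULL
    diagnostics <- list()
    for (start in rad_starts(model, a, N)) {
      fit <- tryCatch(
        stats::optim(start, obj, method = "Nelder-Mead",
                     control = list(maxit = 5000, reltol = 1e-10)),
        error = function(e) NULL)
      if (is.null(fit)) next
      diagnostics[[length(diagnostics) + 1L]] <- fit
      if (is.finite(fit$value) && (is.null(best) || fit$value < best$value)) {
        best <- fit
      }
    }
    if (is.null(best) || !is.finite(best$value)) {
      stop(sprintf("rad_fit(%s) did not converge from any start; best objective: %s",
                   model,
                   paste(vapply(diagnostics, function(d) format(d$value), ""),
                         collapse = ", ")))
    }
    params <- rad_untransform(model, best$par)
    fitted <- expected_rad(model, params, S, N)
  }
  names(fitted) <- names(a)
  loglik <- sum(a * log(fitted) - fitted - lgamma(a + 1))
  structure(list(model = model, params = params, k = k,
                 fitted = fitted, counts = a,
                 loglik = loglik, aic = -2 * loglik + 2 * k),
            class = "rad_fit")
}

#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("RAD fit: %s (%d free parameter%s)\n", x$model, x$k,
              if (x$k == 1) "" else "s"))
  if (length(x$params) > 0) {
    cat("  ", paste(sprintf("%s = %.6g", names(x$params), unlist(x$params)),
                    collapse = ", "), "\n", sep = "")
  }
  cat(sprintf("  S = %d, N = %d, logLik = %.3f, AIC = %.3f\n",
              length(x$counts), sum(x$counts), x$loglik, x$aic))
  invisible(x)
}

#' @export
coef.rad_fit <- function(object, ...) unlist(object$params)

#' @export
fitted.rad_fit <- function(object, ...) object$fitted

#' @export
logLik.rad_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = length(object$counts),
            class = "logLik")
}

#' @export
plot.rad_fit <- function(x, ...) {
  r <- seq_along(x$counts)
  graphics::plot(r, x$counts, log = "y", xlab = "Rank",
                 ylab = "Abundance", pch = 19,
                 main = sprintf("%s fit", x$model), ...)
  graphics::lines(r, x$fitted, col = "red3", lwd = 2)
  invisible(x)
}

#' Fit all eligible SAD models and select the best by AIC
#'
#' Each model is fitted by [rad_fit()]; a model is eligible only if the
#' number of observed species exceeds its free-parameter count
#' (`S >= k + 1`). The winner is the smallest AIC; ties within 1e-6 AIC
#' units go to the model with fewer parameters, then to the fixed order
#' brokenstick, preemption, lognormal, zipf, mandelbrot.
#'
#' @param counts named non-negative integer vector of pooled species counts.
#' @param models candidate model names; by default all five. Set
#'   `models = setdiff(rad_models(), "zipf")` for the strict four-model set.
#' @return object of class `sad_select`: `fits` (named list of `rad_fit`),
#'   `best` (model name), `aic`, `delta_aic`, and `failed` (models that did
#'   not converge, normally none).
#' @export
sad_select <- function(counts, models = rad_model_names) {
  models <- match.arg(models, rad_model_names, several.ok = TRUE)
  a <- rank_counts(counts)
  S <- length(a)
  eligible <- models[rad_model_k[models] + 1L <= S]
  if (length(eligible) < 2L) {
    stop(sprintf("only %d eligible model(s) for S = %d species; need >= 2",
                 length(eligible), S))
  }
  fits <- list()
  failed <- character()
  for (m in eligible) {
    f <- tryCatch(rad_fit(a, m), error = function(e) e)
    if (inherits(f, "error")) failed <- c(failed, m) else fits[[m]] <- f
  }
  if (length(fits) < 2L) {
    stop("fewer than 2 models converged (failed: ",
         paste(failed, collapse = ", "), ")")
  }
  aic <- vapply(fits, function(f) f$aic, 0)
  delta <- aic - min(aic)
  contenders <- names(fits)[delta < 1e-6]
  if (length(contenders) > 1L) {
    kk <- rad_model_k[contenders]
    contenders <- contenders[kk == min(kk)]
    contenders <- contenders[order(match(contenders, rad_model_names))]
  }
  structure(list(fits = fits, best = contenders[1L],
                 aic = aic, delta_aic = delta, failed = failed),
            class = "sad_select")
}

#' Candidate SAD model names, in the fixed tie-break order
#' @return character vector.
#' @export
rad_models <- function() rad_model_names

#' @export
print.sad_select <- function(x, ...) {
  ord <- order(x$aic)
  tab <- data.frame(model = names(x$aic),
                    k = rad_model_k[names(x$aic)],
                    AIC = round(x$aic, 3),
                    dAIC = round(x$delta_aic, 3))[ord, ]
  rownames(tab) <- NULL
  cat("SAD model selection (Poisson ML, AIC):\n")
  print(tab)
  cat("best:", x$best, "\n")
  invisible(x)
}

#' @export
plot.sad_select <- function(x, ...) {
  best <- x$fits[[x$best]]
  plot(best, ...)
  invisible(x)
}
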