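#' Individual-based rarefaction (expected richness at m individuals)
#'
#' Expected number of species in a random subsample of `m` individuals
#' drawn without replacement from the pooled counts, by the hypergeometric
#' closed form `E[S_m] = sum_i (1 - C(N - N_i, m) / C(N, m))`, evaluated
#' with log-binomial coefficients for numerical stability.
#'
#' @param counts named non-negative integer vector of species counts.
#' @param m subsample size(s), `0 <= m <= sum(counts)`; may be a vector.
#' @return expected richness, one value per element of `m`.
#' @export
rarefy_richness <- function(counts, m) {
  counts <- counts[counts > 0]
  if (any(counts != floor(counts))) stop("counts must be integers")
  N <- sum(counts)
  if (any(m < 0) || any(m > N)) stop(sprintf("m must be in [0, %d]", N))
  vapply(m, function(mm) {
    if (mm == 0) return(0)
    # P(species i absent from the subsample)
    p_absent <- exp(lchoose(N - counts, mm) - lchoose(N, mm))
    sum(1 - p_absent)
  }, 0)
}

#' Rarefaction curve with exact variance
#'
#' Expected richness and its exact hypergeometric variance
#' (including pairwise-absence covariance terms) on a grid of subsample
#' sizes. The curve is non-decreasing and reaches the observed richness at
#' `m = N`.
#'
#' @param counts named non-negative integer vector of species counts.
#' @param m increasing integer grid; defaults to ~25 evenly spaced sizes.
#' @return data.frame with columns `m`, `expected_richness`, `variance`.
#' @export
rarefaction_curve <- function(counts, m = NULL) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (is.null(m)) m <- unique(round(seq(0, N, length.out = 26)))
  m <- sort(unique(as.integer(m)))
  es <- rarefy_richness(counts, m)
  v <- vapply(m, function(mm) {
    if (mm == 0 || mm == N) return(0)
    q <- exp(lchoose(N - counts, mm) - lchoose(N, mm))  # absence probabilities
    vv <- sum(q * (1 - q))
    S <- length(counts)
    if (S > 1) {
      for (i in 1:(S - 1)) {
        qij <- exp(lchoose(N - counts[i] - counts[(i + 1):S], mm) - lchoose(N, mm))
        vv <- vv + 2 * sum(qij - q[i] * q[(i + 1):S])
      }
    }
    max(vv, 0)
  }, 0)
  data.frame(m = m, expected_richness = es, variance = v)
}

#' Bootstrap species-richness estimate from incidence data
#'
#' Point estimate by the incidence-based bootstrap estimator
#' `S_hat = S_obs + sum_i (1 - p_i)^n`, where `p_i` is the fraction of the
#' `n` sampling units (by default trap x collection-interval) in which
#' species `i` occurs: the correction term is the expected number of
#' observed species missed by a same-sized resurvey, so `S_hat` estimates
#' the richness one would record if even the least catchable species were
#' encountered. The confidence interval is the percentile interval of the
#' estimator recomputed over `n_boot` resamples of units drawn with
#' replacement.
#'
#' @param incidence units x species matrix (logical, or counts; any
#'   positive entry is an occurrence). Needs >= 2 units and at least one
#'   occupied unit.
#' @param n_boot number of bootstrap resamples (default 999).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95, percentile method).
#' @param unit label recorded on the result (e.g. `"trap_interval"`).
#' @return object of class `richness_estimate`: `s_obs`, `s_expected`,
#'   `ci_low`, `ci_high`, `n_units`, `n_boot`, `unit`, `seed`.
#' @export
bootstrap_richness <- function(incidence, n_boot = 999, seed = 1,
                               conf = 0.95, unit = "trap_interval") {
  inc <- as.matrix(incidence) > 0
  if (nrow(inc) < 2L) stop("need at least 2 sampling units")
  if (!any(inc)) stop("all sampling units are empty")
  n <- nrow(inc)
  est <- function(rows) {
    p <- colMeans(inc[rows, , drop = FALSE])
    p <- p[p > 0]
    length(p) + sum((1 - p)^n)
  }
  s_obs <- sum(colSums(inc) > 0)
  s_hat <- est(seq_len(n))
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    est(sample.int(n, n, replace = TRUE))
  }, 0)
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), type = 7))
  structure(list(s_obs = s_obs, s_expected = s_hat,
                 ci_low = ci[1], ci_high = ci[2],
                 n_units = n, n_boot = n_boot, unit = unit, seed = seed),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf(
    "Richness: %d observed; expected %.1f (%.0f%% c.i. %.1f-%.1f)\n",
    x$s_obs, x$s_expected, 95, x$ci_low, x$ci_high))
  cat(sprintf("  bootstrap over %d %s units, %d resamples\n",
              x$n_units, x$unit, x$n_boot))
  invisible(x)
}

#' Incidence matrix (sampling unit x species) from a catch table
#'
#' @param records catch data.frame (see [validate_catch_records()]).
#' @param unit `"trap_interval"` (trap x collection interval, the most
#'   granular unit), `"trap"`, or `"site"`.
#' @return logical matrix, rows = units, columns = species.
#' @export
incidence_matrix <- function(records,
                             unit = c("trap_interval", "trap", "site")) {
  unit <- match.arg(unit)
  records <- validate_catch_records(records)
  records <- records[records$count > 0, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records")
  key <- switch(unit,
    trap_interval = paste(records$site, records$trap, records$interval_start,
                          sep = "|"),
    trap = paste(records$site, records$trap, sep = "|"),
    site = records$site)
  tab <- table(key, records$species)
  mat <- unclass(tab) > 0
  # keep empty-unit rows out: table() only produces observed keys anyway
  mat
}

#' Rescale the denser of two count sets to a common density
#'
#' For comparing richness between surveys with different total catch, the
#' larger sample is scaled down to the smaller sample's total: each count
#' is multiplied by `sum(small)/sum(large)` and rounded half-to-even.
#' The exact (unrounded) expected richness at the common total is also
#' returned via the rarefaction closed form, which is the recommended
#' quantity (rounding is only for producing an integer pseudo-sample).
#'
#' @param counts_large named integer vector, the denser sample.
#' @param counts_small named integer vector (or a single total) to match.
#' @return list with `rescaled` (rounded counts), `m` (common total) and
#'   `expected_richness` (exact rarefied richness of the large sample at m).
#' @export
rescale_to_common_density <- function(counts_large, counts_small) {
  total_small <- if (length(counts_small) == 1L && is.null(names(counts_small)))
    counts_small else sum(counts_small)
  total_large <- sum(counts_large)
  if (total_large < total_small) {
    stop("counts_large must have the larger (or equal) total")
  }
  rescaled <- round(counts_large * total_small / total_large)
  list(rescaled = rescaled, m = as.integer(total_small),
       expected_richness = rarefy_richness(counts_large, total_small))
}
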