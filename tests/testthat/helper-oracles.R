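# Fixture builders and independent brute-force oracles used across tests.

# one catch record row
rec <- function(site = "A", period = "1980", trap = "T1",
                start = "1980-06-15", end = "1980-07-15",
                species = "spA", count = 1L) {
  data.frame(site = site, period = period, trap = trap,
             interval_start = start, interval_end = end,
             species = species, count = count, stringsAsFactors = FALSE)
}

# community_sample straight from a named count vector (one trap, 10 days,
# so aAD == counts and proportions are untouched)
sample_from_counts <- function(counts, site = "A", period = "1980",
                               n_traps = 1, exposure_days = 10) {
  compute_aad(counts, n_traps = n_traps, exposure_days = exposure_days,
              site = site, period = period)
}

random_abundance <- function(s, max_n = 50) {
  n <- sample(seq_len(s), 1)
  sp <- sample(sprintf("sp%02d", seq_len(s)), n)
  stats::setNames(sample(seq_len(max_n), n, replace = TRUE), sp)
}

# Brute-force IRC oracle: ranks computed by direct pairwise counting
# (strictly-more-abundant species + earlier-named ties), absent species at
# S_present + 1; deliberately a different algorithm from rank_species().
oracle_irc <- function(a, b) {
  universe <- union(names(a), names(b))
  rank_of <- function(ab) {
    present <- names(ab)
    r <- stats::setNames(rep(length(present) + 1L, length(universe)), universe)
    for (sp in present) {
      higher <- sum(ab > ab[[sp]])
      ties_before <- sum(ab == ab[[sp]] & names(ab) < sp)
      r[sp] <- 1L + higher + ties_before
    }
    r
  }
  ra <- rank_of(a); rb <- rank_of(b)
  sum(abs(ra - rb)) / length(universe)
}

# Monte-Carlo rarefaction oracle: subsample m individuals without
# replacement, count species, average.
oracle_rarefy_mc <- function(counts, m, n_draws = 10000) {
  pool <- rep(names(counts), counts)
  mean(vapply(seq_len(n_draws), function(i) {
    length(unique(sample(pool, m)))
  }, 0))
}

# Poisson log-likelihood of a fitted RAD sequence (constant included)
oracle_pois_ll <- function(a, fitted) sum(stats::dpois(a, fitted, log = TRUE))
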