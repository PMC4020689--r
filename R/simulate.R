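#' Scenario configuration for paired before/now trap surveys
#'
#' Defaults emulate a six-site alpine pitfall-trap resurvey: a regional
#' pool of 36 species with fixed traits; 6 sites sampled in two periods
#' with a row of 6 traps emptied over 3 collection intervals spanning
#' ~90 days (June-September); per-site species pools of 5-12 species drawn
#' from the regional pool; roughly 300 individuals expected per
#' site-period. Between the periods, cold-adapted (microtherm) and
#' moisture-demanding (hygrophilic) species face elevated extinction risk,
#' warm-adapted (thermophilic) species increase in abundance, a couple of
#' colonist species arrive from the regional pool at low-to-mid abundance,
#' and a log-normal jitter reshuffles ranks.
#'
#' @param n_sites number of sites.
#' @param pool_S regional species-pool size.
#' @param S per-site richness: a single value or a `c(min, max)` range
#'   sampled per site.
#' @param N expected total individuals per site-period.
#' @param sad_model SAD model generating each "before" assemblage
#'   (see [expected_rad()]).
#' @param sad_params parameters for `sad_model`.
#' @param n_traps,n_intervals,exposure_days trap design.
#' @param periods two period labels, before then now.
#' @param turnover list: `p_extinct_microtherm`, `p_extinct_hygrophilic`,
#'   `p_extinct_other` (extinction probabilities), `n_colonists`,
#'   `thermophilic_multiplier`, `rank_jitter` (sd of log-normal abundance
#'   jitter).
#' @param trait_probs list of category probability vectors for
#'   `wing_morph`, `diet`, `thermal`, `moisture`.
#' @param seed master seed; all randomness is derived from it.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 6, pool_S = 36, S = c(5, 12), N = 300,
                            sad_model = "lognormal",
                            sad_params = list(mu = 0, sigma = 1),
                            n_traps = 6, n_intervals = 3, exposure_days = 90,
                            periods = c("1980", "2008"),
                            turnover = list(), trait_probs = list(),
                            seed = 1) {
  turnover_default <- list(p_extinct_microtherm = 0.5,
                           p_extinct_hygrophilic = 0.7,
                           p_extinct_other = 0.1,
                           n_colonists = 2,
                           thermophilic_multiplier = 6,
                           rank_jitter = 0.3)
  trait_default <- list(
    wing_morph = c(macropterous = 0.35, brachypterous = 0.45, dimorphic = 0.20),
    diet = c(specialized_predator = 0.35, generalist_predator = 0.45,
             zoophytophagous = 0.20),
    thermal = c(microtherm = 0.25, thermophilic = 0.25, neutral = 0.50),
    moisture = c(hygrophilic = 0.30, xerophilic = 0.20, neutral = 0.50))
  turnover <- utils::modifyList(turnover_default, turnover)
  trait_probs <- utils::modifyList(trait_default, trait_probs)
  cfg <- structure(list(n_sites = n_sites, pool_S = pool_S, S = S, N = N,
                        sad_model = sad_model, sad_params = sad_params,
                        n_traps = n_traps, n_intervals = n_intervals,
                        exposure_days = exposure_days, periods = periods,
                        turnover = turnover, trait_probs = trait_probs,
                        seed = as.integer(seed)),
                   class = "scenario_config")
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  stopifnot(cfg$n_sites >= 1, all(cfg$S >= 2), cfg$pool_S >= max(cfg$S),
            cfg$N > 0, cfg$n_traps >= 1, cfg$n_intervals >= 1,
            cfg$exposure_days > 0,
            length(cfg$periods) == 2, cfg$periods[1] != cfg$periods[2])
  tv <- cfg$turnover
  probs <- unlist(tv[c("p_extinct_microtherm", "p_extinct_hygrophilic",
                       "p_extinct_other")])
  if (any(probs < 0 | probs > 1)) stop("extinction probabilities must be in [0,1]")
  if (tv$thermophilic_multiplier <= 0) stop("thermophilic_multiplier must be > 0")
  if (tv$rank_jitter < 0) stop("rank_jitter must be >= 0")
  if (tv$n_colonists < 0) stop("n_colonists must be >= 0")
  cfg
}

# deterministic seed-splitting: one master seed -> stream k.
# Modulus 2^31 - 1 keeps derived seeds valid 32-bit integers.
split_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483647)
}

#' Expected species abundances under a SAD model
#'
#' Deterministic expected community: the model's expected rank-abundance
#' sequence (see [expected_rad()]) rescaled to sum to `N`, with species
#' named `sp001..spS` in rank order (zero-padding keeps lexicographic
#' tie-breaking deterministic downstream).
#'
#' @param sad_model,params model and parameters, see [expected_rad()].
#' @param S species-pool size.
#' @param N expected total individuals.
#' @param species optional species names to use instead of `sp001..`
#'   (assigned in rank order).
#' @return named numeric vector of expected abundances.
#' @export
generate_community <- function(sad_model, params = list(), S, N,
                               species = NULL) {
  ab <- expected_rad(sad_model, params, S = S, N = N)
  ab <- ab * (N / sum(ab))
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(S))
  stopifnot(length(species) == S)
  stats::setNames(ab, species)
}

#' Draw a synthetic trait table for a set of species
#'
#' @param species character vector of species names.
#' @param trait_probs category probability vectors (see [scenario_config()]).
#' @param seed integer seed.
#' @return trait data.frame (see [validate_trait_table()]).
#' @export
generate_traits <- function(species, trait_probs = scenario_config()$trait_probs,
                            seed = 1) {
  set.seed(seed)
  draw <- function(p) sample(names(p), length(species), replace = TRUE, prob = p)
  validate_trait_table(data.frame(
    species = species,
    wing_morph = draw(trait_probs$wing_morph),
    diet = draw(trait_probs$diet),
    thermal = draw(trait_probs$thermal),
    moisture = draw(trait_probs$moisture),
    stringsAsFactors = FALSE))
}

#' Apply trait-dependent turnover to an expected community
#'
#' Emulates ~30 years of change: microtherm and hygrophilic species go
#' locally extinct with their configured probabilities (other species with
#' the background probability), surviving thermophilic species are
#' multiplied by `thermophilic_multiplier`, `n_colonists` new species are
#' added with abundances drawn uniformly between the smallest and the
#' median "before" abundance (colonists arrive at low-to-mid rank), and a
#' log-normal jitter of scale `rank_jitter` perturbs every abundance.
#'
#' @param community named expected-abundance vector (the "before" state).
#' @param traits trait table covering all species in `community` (and, if
#'   `colonist_pool` is given, the pool species too).
#' @param turnover turnover parameter list (see [scenario_config()]).
#' @param seed integer seed.
#' @param colonist_pool optional character vector of regional-pool species
#'   absent from the site, from which colonists are drawn; when absent or
#'   exhausted, colonists get fresh names `new001..`.
#' @return list with `now` (named expected abundances), `extinct`,
#'   `colonists` (species name vectors, disjoint by construction).
#' @export
apply_turnover <- function(community, traits,
                           turnover = scenario_config()$turnover, seed = 1,
                           colonist_pool = NULL) {
  uncovered <- setdiff(names(community), traits$species)
  if (length(uncovered) > 0L) {
    stop("traits missing for species: ", paste(uncovered, collapse = ", "))
  }
  tr <- traits[match(names(community), traits$species), ]
  p_ext <- ifelse(!is.na(tr$thermal) & tr$thermal == "microtherm",
                  turnover$p_extinct_microtherm,
           ifelse(!is.na(tr$moisture) & tr$moisture == "hygrophilic",
                  turnover$p_extinct_hygrophilic,
                  turnover$p_extinct_other))
  set.seed(seed)
  extinct <- names(community)[stats::runif(length(community)) < p_ext]
  now <- community[setdiff(names(community), extinct)]
  thermo <- !is.na(tr$thermal) & tr$thermal == "thermophilic"
  boost <- intersect(names(community)[thermo], names(now))
  now[boost] <- now[boost] * turnover$thermophilic_multiplier
  colonists <- character()
  if (turnover$n_colonists > 0L) {
    pool <- setdiff(colonist_pool, names(community))
    n_from_pool <- min(length(pool), turnover$n_colonists)
    if (n_from_pool > 0L) {
      colonists <- sample(pool, n_from_pool)
    }
    n_new <- turnover$n_colonists - n_from_pool
    if (n_new > 0L) colonists <- c(colonists, sprintf("new%03d", seq_len(n_new)))
    lo <- min(community); hi <- stats::median(community)
    now <- c(now, stats::setNames(stats::runif(length(colonists), lo, hi),
                                  colonists))
  }
  if (turnover$rank_jitter > 0 && length(now) > 0L) {
    now <- now * stats::rlnorm(length(now), 0, turnover$rank_jitter)
  }
  list(now = now, extinct = extinct, colonists = colonists)
}

#' Realize noisy trap-catch records from an expected community
#'
#' Sampling-noise model: the pooled total catch of each species is Poisson
#' with mean `expected_abundance * n_traps * exposure_days / 10`, so that
#' the aAD computed from the records is an unbiased estimate of the
#' expected abundance; totals are then spread over the trap x interval
#' cells multinomially with equal probabilities. Collection intervals
#' split the exposure span evenly, starting 15 June of the period year
#' (or of 2000 for non-numeric period labels).
#'
#' @param community named expected-abundance (aAD-scale) vector.
#' @param n_traps,n_intervals,exposure_days trap design.
#' @param seed integer seed.
#' @param site,period labels for the records.
#' @return catch data.frame (rows with positive counts only; every trap is
#'   represented in the noise model even if it caught nothing).
#' @export
realize_trap_counts <- function(community, n_traps = 6, n_intervals = 3,
                                exposure_days = 90, seed = 1,
                                site = "site01", period = "1980") {
  year <- suppressWarnings(as.integer(period))
  if (is.na(year)) year <- 2000L
  start <- as.Date(sprintf("%d-06-15", year))
  bounds <- start + round(seq(0, exposure_days, length.out = n_intervals + 1))
  set.seed(seed)
  totals <- stats::rpois(length(community),
                         community * n_traps * exposure_days / 10)
  cells <- n_traps * n_intervals
  rows <- list()
  for (i in seq_along(community)) {
    if (totals[i] == 0) next
    alloc <- stats::rmultinom(1, totals[i], rep(1 / cells, cells))[, 1]
    pos <- which(alloc > 0)
    trap_idx <- ((pos - 1) %% n_traps) + 1
    int_idx <- ((pos - 1) %/% n_traps) + 1
    rows[[length(rows) + 1L]] <- data.frame(
      site = site, period = period,
      trap = sprintf("T%d", trap_idx),
      interval_start = bounds[int_idx],
      interval_end = bounds[int_idx + 1],
      species = names(community)[i],
      count = alloc[pos],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(site = character(), period = character(),
                      trap = character(),
                      interval_start = as.Date(character()),
                      interval_end = as.Date(character()),
                      species = character(), count = integer()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$trap, out$interval_start, out$species), ]
}

#' Simulate a full paired before/now survey scenario
#'
#' Traits are drawn once for the regional species pool (a species is
#' microtherm everywhere, not per site). For each site: draw the site
#' richness, sample that many species from the regional pool and assign
#' them the configured SAD's expected abundances in random rank order,
#' apply trait-dependent turnover, and realize both periods as noisy
#' trap-catch records. Colonists are drawn from species occupying other
#' sites in the "before" period — a within-region range shift — so the
#' regional species total can only shrink or hold unless the shift pool
#' runs out. All randomness derives from the master seed through a fixed
#' splitting scheme (one stream per site and step), so identical configs
#' give identical data.
#'
#' @param config a [scenario_config()].
#' @return object of class `scenario_data`: `records` (long catch table
#'   over all sites and both periods), `traits` (regional-pool trait
#'   table), `truth` (per-site list: `S`, `sad_model`, `sad_params`,
#'   expected `before`/`now` abundances, `extinct`, `colonists`),
#'   `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  config <- validate_scenario_config(config)
  pool <- sprintf("sp%03d", seq_len(config$pool_S))
  traits <- generate_traits(pool, config$trait_probs,
                            seed = split_seed(config$seed, 1))
  # first pass: site membership and expected "before" assemblages
  before_all <- list()
  for (i in seq_len(config$n_sites)) {
    set.seed(split_seed(config$seed, i * 10 + 1))
    S <- if (length(config$S) > 1)
      sample(seq(config$S[1], config$S[2]), 1) else config$S
    members <- sample(pool, S)  # random order = random rank assignment
    before_all[[i]] <- generate_community(config$sad_model, config$sad_params,
                                          S = S, N = config$N,
                                          species = members)
  }
  occupied <- unique(unlist(lapply(before_all, names)))
  records <- list()
  truth <- list()
  for (i in seq_len(config$n_sites)) {
    site <- sprintf("site%02d", i)
    before <- before_all[[i]]
    members <- names(before)
    S <- length(before)
    # colonists shift in from assemblages of other sites (range shift
    # within the region); truly new arrivals only if those run out
    delta <- apply_turnover(before, traits, config$turnover,
                            seed = split_seed(config$seed, i * 10 + 3),
                            colonist_pool = setdiff(occupied, members))
    new_sp <- setdiff(delta$colonists, traits$species)
    if (length(new_sp) > 0L) {
      traits <- rbind(traits,
                      generate_traits(new_sp, config$trait_probs,
                                      seed = split_seed(config$seed, i * 10 + 4)))
    }
    rec_b <- realize_trap_counts(before, config$n_traps, config$n_intervals,
                                 config$exposure_days,
                                 seed = split_seed(config$seed, i * 10 + 5),
                                 site = site, period = config$periods[1])
    rec_n <- realize_trap_counts(delta$now, config$n_traps, config$n_intervals,
                                 config$exposure_days,
                                 seed = split_seed(config$seed, i * 10 + 6),
                                 site = site, period = config$periods[2])
    records[[site]] <- rbind(rec_b, rec_n)
    truth[[site]] <- list(S = S, sad_model = config$sad_model,
                          sad_params = config$sad_params,
                          before = before, now = delta$now,
                          extinct = delta$extinct,
                          colonists = delta$colonists)
  }
  structure(list(records = do.call(rbind, c(records, make.row.names = FALSE)),
                 traits = traits, truth = truth, config = config),
            class = "scenario_data")
}

#' @export
print.scenario_data <- function(x, ...) {
  cat(sprintf("Synthetic paired survey: %d sites x 2 periods (%s vs %s)\n",
              x$config$n_sites, x$config$periods[1], x$config$periods[2]))
  cat(sprintf("  %d catch records, %d regional-pool species, seed %d\n",
              nrow(x$records), nrow(x$traits), x$config$seed))
  invisible(x)
}
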