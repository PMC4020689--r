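test_that("generated communities follow the model's expected proportions", {
  expect_equal(unname(generate_community("preemption", list(alpha = 0.5),
                                         S = 3, N = 7)),
               c(4, 2, 1))
  expect_equal(unname(generate_community("brokenstick", S = 2, N = 3)),
               c(2.25, 0.75))
  c1 <- generate_community("lognormal", list(mu = 0, sigma = 1), S = 8, N = 200)
  expect_equal(sum(c1), 200)
  expect_equal(names(c1), sprintf("sp%03d", 1:8))
  expect_identical(c1, generate_community("lognormal", list(mu = 0, sigma = 1),
                                          S = 8, N = 200))
  expect_error(generate_community("preemption", list(alpha = 2), 5, 10), "alpha")
})

test_that("turnover respects trait-specific rules and records deltas", {
  community <- generate_community("preemption", list(alpha = 0.4), S = 6, N = 60)
  traits <- data.frame(
    species = names(community),
    wing_morph = "brachypterous", diet = "generalist_predator",
    thermal = c("microtherm", "microtherm", "thermophilic", rep("neutral", 3)),
    moisture = c("neutral", "neutral", "neutral", "hygrophilic", "neutral",
                 "neutral"))
  off <- list(p_extinct_microtherm = 0, p_extinct_hygrophilic = 0,
              p_extinct_other = 0, n_colonists = 0,
              thermophilic_multiplier = 1, rank_jitter = 0)
  res <- apply_turnover(community, traits, off, seed = 3)
  expect_equal(res$now, community)
  expect_length(res$extinct, 0)

  forced <- utils::modifyList(off, list(p_extinct_microtherm = 1))
  res2 <- apply_turnover(community, traits, forced, seed = 3)
  expect_setequal(res2$extinct, c("sp001", "sp002"))
  expect_false(any(c("sp001", "sp002") %in% names(res2$now)))

  doubled <- utils::modifyList(off, list(thermophilic_multiplier = 2))
  res3 <- apply_turnover(community, traits, doubled, seed = 3)
  expect_equal(res3$now[["sp003"]], community[["sp003"]] * 2)

  expect_error(apply_turnover(community, traits[-1, ], off, 1),
               "traits missing")
  expect_length(intersect(res2$extinct, res2$colonists), 0)
})

test_that("colonists arrive between the minimum and median prior abundance", {
  community <- generate_community("preemption", list(alpha = 0.4), S = 8, N = 80)
  traits <- data.frame(species = c(names(community), "poolA", "poolB"),
                       wing_morph = "macropterous", diet = "zoophytophagous",
                       thermal = "neutral", moisture = "neutral")
  tv <- list(p_extinct_microtherm = 0, p_extinct_hygrophilic = 0,
             p_extinct_other = 0, n_colonists = 2,
             thermophilic_multiplier = 1, rank_jitter = 0)
  res <- apply_turnover(community, traits, tv, seed = 4,
                        colonist_pool = c("poolA", "poolB"))
  expect_setequal(res$colonists, c("poolA", "poolB"))
  arrivals <- res$now[res$colonists]
  expect_true(all(arrivals >= min(community) & arrivals <= median(community)))
})

test_that("trap-count realization is reproducible and inverts to aAD", {
  community <- c(sp001 = 2.0, sp002 = 0.5, sp003 = 0)
  r1 <- realize_trap_counts(community, seed = 42)
  r2 <- realize_trap_counts(community, seed = 42)
  expect_identical(r1, r2)
  expect_false("sp003" %in% r1$species)
  expect_silent(validate_catch_records(r1))

  # Monte-Carlo calibration: mean recovered aAD within 5% of truth
  means <- colMeans(do.call(rbind, lapply(1:200, function(s) {
    recs <- realize_trap_counts(c(sp001 = 2.0), n_traps = 6, n_intervals = 3,
                                exposure_days = 90, seed = s)
    smp <- community_sample(recs)
    c(aad = unname(smp$abundance["sp001"]), total = sum(smp$raw_counts))
  })))
  expect_equal(unname(means["aad"]), 2.0, tolerance = 0.05)
  expect_equal(unname(means["total"]), 108, tolerance = 0.05)
})

test_that("scenario simulation is deterministic and internally consistent", {
  cfg <- scenario_config(n_sites = 3, seed = 11)
  sim1 <- simulate_scenario(cfg)
  sim2 <- simulate_scenario(cfg)
  expect_identical(sim1$records, sim2$records)
  expect_identical(sim1$traits, sim2$traits)
  expect_s3_class(validate_trait_table(sim1$traits), "data.frame")
  expect_silent(validate_catch_records(sim1$records))
  expect_setequal(unique(sim1$records$period), cfg$periods)
  for (tr in sim1$truth) {
    expect_true(tr$S >= cfg$S[1] && tr$S <= cfg$S[2])
    expect_length(intersect(tr$extinct, tr$colonists), 0)
    expect_true(all(sim1$records$species %in% sim1$traits$species))
  }
  sim3 <- simulate_scenario(scenario_config(n_sites = 3, seed = 12))
  expect_false(identical(sim1$records, sim3$records))
})

test_that("scenario config validates probabilities and design", {
  expect_error(scenario_config(turnover = list(p_extinct_other = 1.5)),
               "probabilities")
  expect_error(scenario_config(turnover = list(thermophilic_multiplier = 0)),
               "multiplier")
  expect_error(scenario_config(turnover = list(rank_jitter = -1)), "jitter")
  expect_error(scenario_config(S = c(5, 50), pool_S = 36))
})

test_that("with turnover off, before and now stay close downstream", {
  off <- list(p_extinct_microtherm = 0, p_extinct_hygrophilic = 0,
              p_extinct_other = 0, n_colonists = 0,
              thermophilic_multiplier = 1, rank_jitter = 0)
  cfg <- scenario_config(n_sites = 4, N = 2000, turnover = off, seed = 21)
  sim <- simulate_scenario(cfg)
  for (s in unique(sim$records$site)) {
    before <- community_sample(sim$records, site = s, period = "1980")
    now <- community_sample(sim$records, site = s, period = "2008")
    expect_true(renkonen(before, now) > 0.9)
    expect_true(irc(before, now)$value <= 2)
  }
})
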