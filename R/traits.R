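#' Trait-based summary of a community sample
#'
#' Three indicator percentages used to interpret assemblage change:
#' \describe{
#'   \item{hd_pct}{dispersal power — percent of total aAD contributed by
#'     macropterous (fully winged) plus wing-dimorphic species; high values
#'     flag unstable or disturbed habitats.}
#'   \item{zp_ad_pct}{percent of total aAD contributed by zoophytophagous
#'     (mixed/seed-feeding) species, which track xeric vegetation.}
#'   \item{spc_spp_pct}{percent of species (not individuals) that are
#'     specialized predators.}
#' }
#'
#' @param sample a `community_sample` or named abundance vector.
#' @param traits trait table covering every species in the sample.
#' @return list with `site`, `period`, `hd_pct`, `zp_ad_pct`,
#'   `spc_spp_pct`.
#' @export
trait_summary <- function(sample, traits) {
  ab <- abundance_map(sample)
  traits <- validate_trait_table(traits)
  missing <- setdiff(names(ab), traits$species)
  if (length(missing) > 0L) {
    stop("species missing from trait table: ", paste(missing, collapse = ", "))
  }
  tr <- traits[match(names(ab), traits$species), ]
  total <- sum(ab)
  list(site = if (inherits(sample, "community_sample")) sample$site else NA_character_,
       period = if (inherits(sample, "community_sample")) sample$period else NA_character_,
       hd_pct = 100 * sum(ab[tr$wing_morph %in% c("macropterous", "dimorphic")]) / total,
       zp_ad_pct = 100 * sum(ab[tr$diet == "zoophytophagous"]) / total,
       spc_spp_pct = 100 * sum(tr$diet == "specialized_predator") / length(ab))
}

# nearest integer, halves away from zero (reporting layer only)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percent of expected species actually observed
#'
#' `round(100 * s_obs / s_expected)` to the nearest integer percent
#' (halves away from zero) — the sampling-coverage figure quoted alongside
#' bootstrap richness estimates.
#'
#' @param s_obs observed species richness.
#' @param s_expected expected (bootstrap) species richness, > 0.
#' @return integer percent.
#' @export
richness_coverage <- function(s_obs, s_expected) {
  if (s_expected <= 0) stop("s_expected must be > 0")
  as.integer(round_half_up(100 * s_obs / s_expected))
}
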