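#' Read a pipeline configuration from YAML
#'
#' Two modes: a `scenario:` block (keys as in [scenario_config()]) for
#' simulated input, or `catch:`/`traits:` file paths for real data, plus
#' optional top-level `periods`, `n_boot`, `richness_unit`, `seed`.
#'
#' @param path YAML file path.
#' @return config list suitable for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scenario)) {
    cfg$scenario <- do.call(scenario_config, cfg$scenario)
  }
  cfg
}

# tiny polynomial string hash for run metadata (config fingerprint)
config_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full before/now comparison pipeline
#'
#' Orchestrates every stage on a dataset, real or simulated: trap pooling
#' and aAD standardization per site-period; per-period bootstrap richness
#' and coverage; SAD model selection per sample; per-site turnover, IRC,
#' Renkonen and trait summaries; chord-distance minimum-variance
#' clustering over all samples. Identical config and seed give identical
#' outputs.
#'
#' @param config either a [scenario_config()] (simulation mode), a list
#'   with elements `catch` and `traits` (CSV paths) and optionally
#'   `periods`, or a list with a `scenario` element (e.g. from
#'   [read_pipeline_config()]).
#' @param out_dir if non-NULL, write `report.json`, `comparison.csv`,
#'   `richness.csv`, `radfit.csv` and `dendrogram.nwk` there (directory is
#'   created; partial outputs are removed if a stage fails).
#' @param n_boot bootstrap resamples for richness estimation.
#' @param richness_unit resampling unit, see [incidence_matrix()].
#' @param seed seed for the richness bootstrap (simulation draws its
#'   randomness from the scenario seed instead).
#' @return object of class `comparison_report`: `samples`, `sites`
#'   (per-site comparison list), `comparison` (per-site data.frame),
#'   `richness` (per-period estimates + coverage), `sad` (per-sample
#'   model selections), `clustering` (`hclust`), `truth` (simulation mode
#'   only), `meta`.
#' @export
run_pipeline <- function(config, out_dir = NULL, n_boot = 999,
                         richness_unit = "trap_interval", seed = 1) {
  if (inherits(config, "scenario_config")) config <- list(scenario = config)
  truth <- NULL
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_scenario(config$scenario))
    records <- sim$records
    traits <- sim$traits
    truth <- sim$truth
    periods <- config$scenario$periods
    seed <- config$scenario$seed
  } else {
    if (is.null(config$catch)) stop("stage 'input': config needs 'catch' or 'scenario'")
    if (is.null(config$traits)) stop("stage 'input': config needs a 'traits' path")
    if (!file.exists(config$catch)) {
      stop("stage 'input': catch file not found: ", config$catch)
    }
    if (!file.exists(config$traits)) {
      stop("stage 'input': trait file not found: ", config$traits)
    }
    records <- stage("input", read_long_table(config$catch))
    traits <- stage("input", read_trait_table(config$traits))
    periods <- config$periods %||% sort(unique(records$period))
  }
  if (!is.null(config$n_boot)) n_boot <- config$n_boot
  if (!is.null(config$richness_unit)) richness_unit <- config$richness_unit
  if (length(periods) != 2L) stop("stage 'input': need exactly 2 periods")

  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ok <- FALSE
    on.exit(if (!ok) unlink(files), add = TRUE)
  }

  sites <- sort(unique(records$site))
  samples <- stage("standardize", {
    out <- list()
    for (s in sites) for (p in periods) {
      rec <- records[records$site == s & records$period == p, , drop = FALSE]
      if (nrow(rec) == 0L) {
        stop(sprintf("no records for site %s period %s", s, p))
      }
      out[[paste0(s, "_", p)]] <- community_sample(rec, site = s, period = p)
    }
    out
  })

  richness <- stage("richness", {
    out <- list()
    for (p in periods) {
      rec <- records[records$period == p, , drop = FALSE]
      inc <- incidence_matrix(rec, unit = richness_unit)
      est <- bootstrap_richness(inc, n_boot = n_boot,
                                seed = split_seed(seed, 900 + match(p, periods)),
                                unit = richness_unit)
      est$coverage_pct <- richness_coverage(est$s_obs, est$s_expected)
      out[[p]] <- est
    }
    out
  })

  sad <- stage("radfit", {
    lapply(samples, function(sm) {
      tryCatch(sad_select(sm$raw_counts),
               error = function(e) structure(list(message = conditionMessage(e)),
                                             class = "sad_skipped"))
    })
  })

  site_cmp <- stage("compare", {
    out <- list()
    for (s in sites) {
      before <- samples[[paste0(s, "_", periods[1])]]
      now <- samples[[paste0(s, "_", periods[2])]]
      out[[s]] <- list(
        site = s,
        turnover = turnover(before, now),
        irc = irc(before, now),
        renkonen = renkonen(before, now),
        traits_before = trait_summary(before, traits),
        traits_now = trait_summary(now, traits))
    }
    out
  })

  clustering <- stage("cluster", ward_cluster(samples))

  comparison <- do.call(rbind, lapply(site_cmp, function(x) {
    best <- function(key) {
      sel <- sad[[paste0(x$site, "_", key)]]
      if (inherits(sel, "sad_select")) sel$best else NA_character_
    }
    data.frame(site = x$site,
               renkonen = x$renkonen,
               irc = x$irc$value,
               n_union = x$irc$n_union,
               s_before = x$turnover$s_before,
               s_now = x$turnover$s_now,
               shared = x$turnover$shared,
               only_before = x$turnover$only_before,
               only_now = x$turnover$only_now,
               sad_before = best(periods[1]),
               sad_now = best(periods[2]),
               hd_pct_before = x$traits_before$hd_pct,
               hd_pct_now = x$traits_now$hd_pct,
               zp_ad_pct_before = x$traits_before$zp_ad_pct,
               zp_ad_pct_now = x$traits_now$zp_ad_pct,
               spc_spp_pct_before = x$traits_before$spc_spp_pct,
               spc_spp_pct_now = x$traits_now$spc_spp_pct,
               aad_before = sum(samples[[paste0(x$site, "_", periods[1])]]$abundance),
               aad_now = sum(samples[[paste0(x$site, "_", periods[2])]]$abundance),
               stringsAsFactors = FALSE)
  }))
  rownames(comparison) <- NULL

  meta <- list(seed = seed, periods = periods, n_boot = n_boot,
               richness_unit = richness_unit,
               package_version = as.character(utils::packageVersion("rankshift")),
               config_hash = config_hash(paste(utils::capture.output(utils::str(config)),
                                               collapse = "\n")))

  report <- structure(list(samples = samples, sites = site_cmp,
                           comparison = comparison, richness = richness,
                           sad = sad, clustering = clustering,
                           truth = truth, meta = meta),
                      class = "comparison_report")

  if (!is.null(out_dir)) {
    stage("write", {
      f <- function(name) file.path(out_dir, name)
      files <- vapply(c("report.json", "comparison.csv", "richness.csv",
                        "radfit.csv", "dendrogram.nwk"), f, "")
      utils::write.csv(comparison, f("comparison.csv"), row.names = FALSE)
      rich_df <- do.call(rbind, lapply(names(richness), function(p) {
        e <- richness[[p]]
        data.frame(period = p, s_obs = e$s_obs, s_expected = e$s_expected,
                   ci_low = e$ci_low, ci_high = e$ci_high,
                   coverage_pct = e$coverage_pct, n_units = e$n_units,
                   n_boot = e$n_boot, unit = e$unit)
      }))
      utils::write.csv(rich_df, f("richness.csv"), row.names = FALSE)
      rad_df <- do.call(rbind, lapply(names(sad), function(lbl) {
        sel <- sad[[lbl]]
        if (!inherits(sel, "sad_select")) return(NULL)
        data.frame(sample = lbl, model = names(sel$aic),
                   k = rad_model_k[names(sel$aic)],
                   aic = sel$aic, delta_aic = sel$delta_aic,
                   selected = names(sel$aic) == sel$best,
                   row.names = NULL)
      }))
      utils::write.csv(rad_df, f("radfit.csv"), row.names = FALSE)
      write_newick(clustering, f("dendrogram.nwk"))
      jsonlite::write_json(report_as_list(report), f("report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ok <- TRUE
    })
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-serializable view of a comparison_report (schema v1)
report_as_list <- function(report) {
  list(schema = "rankshift-report/1",
       meta = report$meta,
       richness = lapply(report$richness, function(e) {
         list(s_obs = e$s_obs, s_expected = e$s_expected,
              ci_low = e$ci_low, ci_high = e$ci_high,
              coverage_pct = e$coverage_pct, n_units = e$n_units,
              n_boot = e$n_boot, unit = e$unit)
       }),
       sites = lapply(report$sites, function(x) {
         list(turnover = x$turnover,
              irc = list(value = x$irc$value, n_union = x$irc$n_union,
                         shifts = as.list(x$irc$shifts)),
              renkonen = x$renkonen,
              traits_before = x$traits_before,
              traits_now = x$traits_now)
       }),
       sad_best = lapply(report$sad, function(sel) {
         if (inherits(sel, "sad_select")) sel$best else NA
       }))
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("Before/now comparison: %d sites (%s vs %s)\n",
              length(x$sites), x$meta$periods[1], x$meta$periods[2]))
  for (p in names(x$richness)) {
    e <- x$richness[[p]]
    cat(sprintf("  %s: %d species observed, %.1f expected (%d%% coverage)\n",
                p, e$s_obs, e$s_expected, e$coverage_pct))
  }
  cols <- c("site", "renkonen", "irc", "shared", "only_before", "only_now",
            "sad_before", "sad_now")
  df <- x$comparison[, cols]
  df$renkonen <- round(df$renkonen, 3)
  df$irc <- round(df$irc, 3)
  print(df, row.names = FALSE)
  invisible(x)
}
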