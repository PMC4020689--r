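#' Validate a long-format trap-catch table
#'
#' A trap-catch table holds one row per species count in one pitfall trap
#' over one collection interval: columns `site`, `period`, `trap`,
#' `interval_start`, `interval_end`, `species`, `count`. Dates are ISO-8601,
#' counts are non-negative integers, and the key
#' (site, period, trap, interval_start, species) must be unique.
#'
#' @param records a data.frame of trap-catch rows.
#' @return the validated data.frame, with date columns as `Date` and
#'   `count` as integer.
#' @export
validate_catch_records <- function(records) {
  required <- c("site", "period", "trap", "interval_start", "interval_end",
                "species", "count")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  records$interval_start <- as.Date(records$interval_start)
  records$interval_end <- as.Date(records$interval_end)
  if (anyNA(records$interval_start) || anyNA(records$interval_end)) {
    stop("interval_start/interval_end must be ISO-8601 dates")
  }
  if (any(records$interval_end <= records$interval_start)) {
    stop("interval_end must be after interval_start")
  }
  cnt <- records$count
  if (is.character(cnt)) cnt <- suppressWarnings(as.numeric(cnt))
  if (anyNA(cnt) || any(cnt != floor(cnt)) || any(cnt < 0)) {
    stop("count must be a non-negative integer")
  }
  records$count <- as.integer(cnt)
  key <- paste(records$site, records$period, records$trap,
               records$interval_start, records$species, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (site, period, trap, interval, species) keys")
  }
  records
}

#' Pool trap catches for one site and period
#'
#' Pitfall catches from a row of traps are pooled across traps and
#' collection intervals into a single per-species count, the unit the rest
#' of the analysis works on. Pooling also absorbs occasional trap losses:
#' an optional per-trap active-day override replaces the assumption that
#' every trap ran for the full exposure span.
#'
#' @param records trap-catch data.frame (see [validate_catch_records()]).
#' @param site,period if given, subset `records`; otherwise all rows must
#'   already share one site and period.
#' @param trap_days optional named numeric vector of active days per trap,
#'   overriding the default assumption that all traps were active over the
#'   whole union span of intervals.
#' @return a list with `counts` (named integer, species with positive pooled
#'   count), `n_traps`, `exposure_days` (union span from earliest
#'   interval_start to latest interval_end) and `trap_days_total`.
#' @export
pool_traps <- function(records, site = NULL, period = NULL, trap_days = NULL) {
  records <- validate_catch_records(records)
  if (!is.null(site)) records <- records[records$site == site, , drop = FALSE]
  if (!is.null(period)) records <- records[records$period == period, , drop = FALSE]
  if (nrow(records) == 0L) stop("no records")
  if (length(unique(records$site)) > 1L || length(unique(records$period)) > 1L) {
    stop("records span more than one site/period; pool one site-period at a time")
  }
  counts <- tapply(records$count, records$species, sum)
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  n_traps <- length(unique(records$trap))
  exposure_days <- as.numeric(max(records$interval_end) - min(records$interval_start))
  if (is.null(trap_days)) {
    trap_days_total <- n_traps * exposure_days
  } else {
    unknown <- setdiff(names(trap_days), unique(records$trap))
    if (length(unknown) > 0L) {
      stop("trap_days names unknown traps: ", paste(unknown, collapse = ", "))
    }
    full <- rep(exposure_days, n_traps)
    names(full) <- unique(records$trap)
    full[names(trap_days)] <- trap_days
    trap_days_total <- sum(full)
  }
  list(counts = as.integer(counts) |> stats::setNames(names(counts)),
       n_traps = n_traps, exposure_days = exposure_days,
       trap_days_total = trap_days_total)
}

#' Standardize pooled counts to annual activity density
#'
#' Annual activity density (aAD) is the mean number of individuals per trap
#' in a standard period of 10 trapping days:
#' `aAD = (count / n_traps) / (exposure_days / 10)`. It makes catches
#' comparable across sites and years with different trap effort. Species
#' with zero pooled count are dropped from the abundance map; the raw
#' pooled integer counts are kept alongside for likelihood-based fitting.
#'
#' @param counts named non-negative integer vector of pooled counts.
#' @param n_traps number of traps pooled (>= 1).
#' @param exposure_days total exposure span in days (> 0).
#' @param site,period identifiers carried on the sample.
#' @param trap_days_total optional total trap-days (overrides
#'   `n_traps * exposure_days`, e.g. when traps were lost part-season).
#' @return a `community_sample`: list with `site`, `period`, `n_traps`,
#'   `exposure_days`, `abundance` (named aAD, positive species only) and
#'   `raw_counts`.
#' @export
compute_aad <- function(counts, n_traps, exposure_days,
                        site = "site", period = "period",
                        trap_days_total = NULL) {
  if (n_traps < 1) stop("n_traps must be >= 1")
  if (exposure_days <= 0) stop("exposure_days must be > 0")
  if (any(counts < 0)) stop("negative count")
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop("counts must be named by species")
  }
  if (is.null(trap_days_total)) trap_days_total <- n_traps * exposure_days
  keep <- counts > 0
  counts <- counts[keep]
  aad <- counts / (trap_days_total / 10)
  structure(list(site = site, period = period,
                 n_traps = n_traps, exposure_days = exposure_days,
                 abundance = aad,
                 raw_counts = as.integer(counts) |> stats::setNames(names(counts))),
            class = "community_sample")
}

#' @export
print.community_sample <- function(x, ...) {
  cat(sprintf("Community sample %s / %s: %d species, %d individuals\n",
              x$site, x$period, length(x$abundance), sum(x$raw_counts)))
  cat(sprintf("  %d traps, %.0f exposure days; total aAD %.3f\n",
              x$n_traps, x$exposure_days, sum(x$abundance)))
  top <- sort(x$abundance, decreasing = TRUE)
  top <- utils::head(top, 5L)
  cat("  top species (aAD): ",
      paste(sprintf("%s=%.3g", names(top), top), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# abundance map (named numeric) from a community_sample or a bare named vector
abundance_map <- function(x) {
  if (inherits(x, "community_sample")) return(x$abundance)
  if (is.numeric(x) && !is.null(names(x))) return(x[x > 0])
  stop("expected a community_sample or a named numeric abundance vector")
}

#' Build a community sample for one site-period from a catch table
#'
#' Convenience wrapper: [pool_traps()] then [compute_aad()].
#'
#' @inheritParams pool_traps
#' @return a `community_sample`.
#' @export
community_sample <- function(records, site = NULL, period = NULL, trap_days = NULL) {
  pooled <- pool_traps(records, site = site, period = period, trap_days = trap_days)
  if (is.null(site)) site <- records$site[1]
  if (is.null(period)) period <- records$period[1]
  compute_aad(pooled$counts, pooled$n_traps, pooled$exposure_days,
              site = site, period = period,
              trap_days_total = pooled$trap_days_total)
}

#' Read a long-format catch table from CSV
#'
#' Expected header: `site,period,trap,interval_start,interval_end,species,count`.
#'
#' @param path CSV file path.
#' @return validated catch data.frame.
#' @export
read_long_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  validate_catch_records(df)
}

#' Write a long-format catch table to CSV
#'
#' @param records catch data.frame.
#' @param path output CSV path.
#' @export
write_long_table <- function(records, path) {
  records <- validate_catch_records(records)
  records$interval_start <- format(records$interval_start, "%Y-%m-%d")
  records$interval_end <- format(records$interval_end, "%Y-%m-%d")
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

trait_levels <- list(
  wing_morph = c("macropterous", "brachypterous", "dimorphic"),
  diet = c("specialized_predator", "generalist_predator", "zoophytophagous"),
  thermal = c("microtherm", "thermophilic", "neutral"),
  moisture = c("hygrophilic", "xerophilic", "neutral"))

#' Validate / read a species-trait table
#'
#' Columns: `species`, `wing_morph` (macropterous/brachypterous/dimorphic),
#' `diet` (specialized_predator/generalist_predator/zoophytophagous) and
#' optional `thermal` (microtherm/thermophilic/neutral) and `moisture`
#' (hygrophilic/xerophilic/neutral). Each species appears once.
#'
#' @param traits a data.frame (for `validate_trait_table`).
#' @param path a CSV path (for `read_trait_table`).
#' @return validated trait data.frame.
#' @export
validate_trait_table <- function(traits) {
  required <- c("species", "wing_morph", "diet")
  missing <- setdiff(required, names(traits))
  if (length(missing) > 0L) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(traits$species)) stop("duplicated species in trait table")
  for (col in intersect(names(trait_levels), names(traits))) {
    vals <- traits[[col]]
    ok <- is.na(vals) | vals %in% trait_levels[[col]]
    if (!all(ok)) {
      stop(sprintf("invalid %s value(s): %s", col,
                   paste(unique(vals[!ok]), collapse = ", ")))
    }
  }
  traits
}

#' @rdname validate_trait_table
#' @export
read_trait_table <- function(path) {
  validate_trait_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname validate_trait_table
#' @param path output CSV path.
#' @export
write_trait_table <- function(traits, path) {
  utils::write.csv(validate_trait_table(traits), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a wide species x sample abundance matrix
#'
#' Rows are species (union over samples, sorted), columns are samples
#' labelled `<site>_<period>`, cells are aAD (zero for absences).
#'
#' @param samples list of `community_sample` objects.
#' @return numeric matrix.
#' @export
community_matrix <- function(samples) {
  labels <- vapply(samples, function(s) paste0(s$site, "_", s$period), "")
  if (anyDuplicated(labels)) stop("duplicate sample labels: ",
                                  paste(labels[duplicated(labels)], collapse = ", "))
  species <- sort(unique(unlist(lapply(samples, function(s) names(s$abundance)))))
  mat <- matrix(0, nrow = length(species), ncol = length(samples),
                dimnames = list(species, labels))
  for (j in seq_along(samples)) {
    ab <- samples[[j]]$abundance
    mat[names(ab), j] <- ab
  }
  mat
}

#' Write / read the wide community matrix as CSV
#'
#' aAD values are written with 6 significant digits; the first column is
#' `species`.
#'
#' @param samples list of `community_sample` objects (or a matrix from
#'   [community_matrix()]).
#' @param path CSV path.
#' @return `write_community_matrix` returns the path; `read_community_matrix`
#'   a species x sample numeric matrix.
#' @export
write_community_matrix <- function(samples, path) {
  mat <- if (is.matrix(samples)) samples else community_matrix(samples)
  df <- data.frame(species = rownames(mat),
                   signif(mat, 6), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_community_matrix
#' @export
read_community_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("missing required column(s): species")
  mat <- as.matrix(df[, setdiff(names(df), "species"), drop = FALSE])
  rownames(mat) <- df$species
  storage.mode(mat) <- "double"
  mat
}
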