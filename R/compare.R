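#' Renkonen minimum percentage similarity
#'
#' `PS = sum_i min(p_Ai, p_Bi)` over the species union, where `p` are
#' relative abundances (aAD proportions) within each sample. 1 for
#' identical relative-abundance profiles, 0 for disjoint species sets;
#' robust to differences in absolute abundance between samples.
#'
#' @param A,B `community_sample` objects or named abundance vectors.
#' @return similarity in \[0, 1\].
#' @export
renkonen <- function(A, B) {
  a <- abundance_map(A); b <- abundance_map(B)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  union <- sort(unique(c(names(a), names(b))))
  pa <- pb <- stats::setNames(numeric(length(union)), union)
  pa[names(a)] <- a / sum(a)
  pb[names(b)] <- b / sum(b)
  sum(pmin(pa, pb))
}

#' Chord distance between two abundance profiles
#'
#' Euclidean distance between the abundance vectors (on the species union,
#' zeros for absences) after normalizing each to unit Euclidean norm.
#' Ranges from 0 (proportional profiles) to sqrt(2) (disjoint sets);
#' invariant to rescaling either sample.
#'
#' @param A,B `community_sample` objects or named abundance vectors.
#' @return distance in \[0, sqrt(2)\].
#' @export
chord_distance <- function(A, B) {
  a <- abundance_map(A); b <- abundance_map(B)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  union <- sort(unique(c(names(a), names(b))))
  va <- vb <- stats::setNames(numeric(length(union)), union)
  va[names(a)] <- a
  vb[names(b)] <- b
  sqrt(sum((va / sqrt(sum(va^2)) - vb / sqrt(sum(vb^2)))^2))
}

#' Chord-distance matrix over a set of samples
#'
#' @param samples list of `community_sample` objects (labels
#'   `<site>_<period>` must be unique) or a species x sample matrix.
#' @return `dist` object of pairwise chord distances.
#' @export
chord_dist_matrix <- function(samples) {
  mat <- if (is.matrix(samples)) samples else community_matrix(samples)
  norms <- sqrt(colSums(mat^2))
  if (any(norms == 0)) stop("zero abundance vector in: ",
                            paste(colnames(mat)[norms == 0], collapse = ", "))
  stats::dist(t(sweep(mat, 2, norms, "/")))
}

#' Minimum-variance (Ward) clustering on chord distances
#'
#' Agglomerative clustering of site-period samples by the minimum-variance
#' criterion on the chord-distance matrix (Lance-Williams `ward.D` update
#' on squared chord distances, so merge heights are on the squared-distance
#' / variance scale). Chord distance is Euclidean on the normalized
#' profiles, which makes the Ward criterion valid. `stats::hclust` is
#' deterministic; exact distance ties are resolved by the input order of
#' the samples, which is itself fixed by sorted labels.
#'
#' @param samples list of `community_sample` objects or a species x sample
#'   abundance matrix.
#' @return an `hclust` object with labels `<site>_<period>`.
#' @export
ward_cluster <- function(samples) {
  d <- chord_dist_matrix(samples)
  if (attr(d, "Size") < 2L) stop("need at least 2 samples")
  stats::hclust(d^2, method = "ward.D")
}

#' Export a dendrogram as Newick
#'
#' @param hc an `hclust` object (e.g. from [ward_cluster()]).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Rank species of a sample within a comparison universe
#'
#' Present species get ranks 1..S_present by decreasing abundance, ties
#' broken lexicographically by species name. Every universe species absent
#' from the sample gets the same rank just below the last present species
#' (`S_present + 1`, the default), or alternatively the universe size.
#'
#' @param sample a `community_sample` or named abundance vector.
#' @param universe character vector of species to rank (must contain all
#'   species present in the sample); defaults to the sample's own species.
#' @param absent_rank `"after_last"` (rank `S_present + 1`, default) or
#'   `"union_size"` (rank `length(universe)`).
#' @return named integer vector of ranks over the universe.
#' @export
rank_species <- function(sample, universe = NULL,
                         absent_rank = c("after_last", "union_size")) {
  absent_rank <- match.arg(absent_rank)
  ab <- abundance_map(sample)
  present <- names(ab)
  if (is.null(universe)) universe <- present
  extra <- setdiff(present, universe)
  if (length(extra) > 0L) {
    stop("universe must contain all present species; missing: ",
         paste(extra, collapse = ", "))
  }
  ord <- present[order(-ab, present)]
  s_present <- length(ord)
  ranks <- stats::setNames(
    rep(if (absent_rank == "after_last") s_present + 1L
        else length(universe), length(universe)),
    universe)
  ranks[ord] <- seq_len(s_present)
  ranks[sort(universe)]
}

#' Index of Rank-abundance Change (IRC)
#'
#' Quantifies the reordering of a community between two samples of the
#' same site: rank every species of the union in each sample (absent
#' species take rank `S_present + 1`, see [rank_species()]), sum the
#' absolute rank shifts (a city-block distance in rank space), and divide
#' by the number of species in the union:
#' `IRC = sum_i |R_A(sp_i) - R_B(sp_i)| / |A U B|`.
#' 0 means identical rank order; larger values mean stronger reordering,
#' bounded above by `|A U B| - 1`.
#'
#' @param A,B `community_sample` objects or named abundance vectors.
#' @param absent_rank rank policy for absent species, see [rank_species()].
#' @return object of class `irc_result`: `value`, `n_union`, `shifts`
#'   (named per-species |rank difference|), `ranks_a`, `ranks_b`.
#' @export
irc <- function(A, B, absent_rank = c("after_last", "union_size")) {
  absent_rank <- match.arg(absent_rank)
  a <- abundance_map(A); b <- abundance_map(B)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  universe <- sort(unique(c(names(a), names(b))))
  ra <- rank_species(a, universe, absent_rank)
  rb <- rank_species(b, universe, absent_rank)
  shifts <- abs(ra - rb)
  structure(list(value = sum(shifts) / length(universe),
                 n_union = length(universe),
                 shifts = shifts, ranks_a = ra, ranks_b = rb),
            class = "irc_result")
}

#' @export
print.irc_result <- function(x, ...) {
  cat(sprintf("IRC = %.4f over %d species (sum of rank shifts = %d)\n",
              x$value, x$n_union, sum(x$shifts)))
  moved <- sort(x$shifts[x$shifts > 0], decreasing = TRUE)
  if (length(moved) > 0) {
    cat("  largest shifts: ",
        paste(utils::head(sprintf("%s (%d)", names(moved), moved), 5L),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Species turnover between two samples
#'
#' Plain set arithmetic on the present-species sets.
#'
#' @param A,B `community_sample` objects or named abundance vectors
#'   (before and now).
#' @return list with `s_before`, `s_now`, `shared`, `only_before`,
#'   `only_now`, `union`.
#' @export
turnover <- function(A, B) {
  a <- names(abundance_map(A)); b <- names(abundance_map(B))
  shared <- length(intersect(a, b))
  list(s_before = length(a), s_now = length(b), shared = shared,
       only_before = length(a) - shared, only_now = length(b) - shared,
       union = length(union(a, b)))
}
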