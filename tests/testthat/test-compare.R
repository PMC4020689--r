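test_that("Renkonen similarity matches hand-computed minima", {
  A <- sample_from_counts(c(a = 5L, b = 5L))
  expect_equal(renkonen(A, A), 1.0)
  expect_equal(renkonen(c(a = 3, b = 1), c(x = 9, y = 2)), 0)
  expect_equal(renkonen(c(a = 0.5, b = 0.5), c(a = 0.25, b = 0.25, c = 0.5)),
               0.5)
  expect_error(renkonen(numeric(0), c(a = 1)), "empty|named")
})

test_that("Renkonen is symmetric, bounded and 1 only for identical profiles", {
  set.seed(5)
  for (i in 1:50) {
    a <- random_abundance(8)
    b <- random_abundance(8)
    r <- renkonen(a, b)
    expect_equal(r, renkonen(b, a))
    expect_true(r >= 0 && r <= 1 + 1e-12)
    expect_equal(renkonen(a, a * 3.7), 1.0)
    if (!setequal(names(a), names(b))) expect_true(r < 1)
  }
})

test_that("chord distance matches its closed form and scale invariance", {
  expect_equal(chord_distance(c(a = 3, b = 4), c(a = 4, b = 3)),
               sqrt((0.6 - 0.8)^2 + (0.8 - 0.6)^2))
  expect_equal(chord_distance(c(a = 2, b = 6), c(a = 1, b = 3)), 0)
  expect_equal(chord_distance(c(a = 5), c(b = 2)), sqrt(2))
})

test_that("chord distance is a metric and agrees with vegan's normalization", {
  skip_if_not_installed("vegan")
  set.seed(8)
  for (i in 1:30) {
    x <- random_abundance(6); y <- random_abundance(6); z <- random_abundance(6)
    dxy <- chord_distance(x, y); dxz <- chord_distance(x, z)
    dyz <- chord_distance(y, z)
    expect_true(dxy <= dxz + dyz + 1e-12)
    union <- sort(unique(c(names(x), names(y))))
    mat <- rbind(replace(setNames(numeric(length(union)), union), names(x), x),
                 replace(setNames(numeric(length(union)), union), names(y), y))
    vg <- dist(vegan::decostand(mat, "normalize"))
    expect_equal(dxy, as.numeric(vg), tolerance = 1e-12)
  }
})

test_that("minimum-variance clustering merges identical samples first", {
  s1 <- sample_from_counts(c(a = 10L, b = 2L), site = "P1")
  s2 <- sample_from_counts(c(a = 20L, b = 4L), site = "P2")   # same profile
  s3 <- sample_from_counts(c(c = 7L, d = 7L), site = "Q1")
  s4 <- sample_from_counts(c(c = 14L, d = 14L), site = "Q2")  # same profile
  hc <- ward_cluster(list(s1, s2, s3, s4))
  expect_s3_class(hc, "hclust")
  expect_equal(hc$height[1:2], c(0, 0))
  expect_true(all(diff(hc$height) >= -1e-12))

  two <- ward_cluster(list(s1, s3))
  expect_equal(two$height, chord_distance(s1, s3)^2)
})

test_that("dendrogram export writes valid Newick with sample labels", {
  samples <- list(sample_from_counts(c(a = 5L, b = 1L), site = "A"),
                  sample_from_counts(c(a = 1L, b = 5L), site = "B"),
                  sample_from_counts(c(c = 4L), site = "C"))
  hc <- ward_cluster(samples)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("A_1980", "B_1980", "C_1980"))
})

test_that("species ranking follows abundance with stated tie and absence rules", {
  r <- rank_species(c(a = 10, b = 5, c = 5))
  expect_equal(r, c(a = 1L, b = 2L, c = 3L))
  r2 <- rank_species(c(b = 7), universe = c("a", "b", "c"))
  expect_equal(r2, c(a = 2L, b = 1L, c = 2L))
  expect_equal(rank_species(c(a = 1, b = 2) * 17),
               rank_species(c(a = 1, b = 2)))
  r3 <- rank_species(c(b = 7), universe = c("a", "b", "c"),
                     absent_rank = "union_size")
  expect_equal(unname(r3[c("a", "c")]), c(3L, 3L))
  expect_error(rank_species(c(z = 1), universe = c("a")), "universe")
})

test_that("IRC matches hand-derived examples", {
  A <- sample_from_counts(c(a = 5L, b = 3L, c = 1L))
  expect_equal(irc(A, A)$value, 0)
  # shared species reordered (1,2,3) vs (2,1,3)
  B <- sample_from_counts(c(a = 3L, b = 5L, c = 1L))
  expect_equal(irc(A, B)$value, 2 / 3)
  # absence rule: one species drops out
  res <- irc(c(sp1 = 10, sp2 = 5), c(sp2 = 8))
  expect_equal(res$value, 1.0)
  expect_equal(res$n_union, 2L)
  expect_equal(sort(res$shifts), sort(c(sp1 = 1L, sp2 = 1L)))
})

test_that("IRC is symmetric, bounded, scale- and relabel-invariant", {
  set.seed(13)
  for (i in 1:100) {
    a <- random_abundance(9)
    b <- random_abundance(9)
    res <- irc(a, b)
    expect_equal(res$value, sum(res$shifts) / res$n_union)
    expect_equal(res$value, irc(b, a)$value)
    expect_true(res$value >= 0 && res$value <= res$n_union - 1)
    expect_equal(res$value, irc(a * 2.5, b * 0.3)$value)
    # consistent relabeling of both samples leaves IRC unchanged
    relabel <- setNames(sprintf("q%02d", 1:9), sprintf("sp%02d", 1:9))
    a2 <- setNames(a, unname(relabel[names(a)]))
    b2 <- setNames(b, unname(relabel[names(b)]))
    expect_equal(irc(a2, b2)$value, res$value)
  }
})

test_that("IRC equals the brute-force rank-enumeration oracle", {
  set.seed(17)
  for (i in 1:200) {
    a <- random_abundance(10)
    b <- random_abundance(10)
    expect_equal(irc(a, b)$value, oracle_irc(a, b))
  }
})

test_that("turnover arithmetic reproduces the printed species accounting", {
  # 32 species before, 27 now, 23 shared -> union 36, 9 lost, 4 gained
  before <- sprintf("sp%02d", 1:32)
  now <- c(sprintf("sp%02d", 1:23), sprintf("nw%02d", 1:4))
  tv <- turnover(setNames(rep(1, 32), before), setNames(rep(1, 27), now))
  expect_equal(tv$union, 36)
  expect_equal(tv$only_before, 9)
  expect_equal(tv$only_now, 4)
  expect_equal(tv$union, tv$s_before + tv$s_now - tv$shared)

  a <- c(x = 2, y = 1)
  same <- turnover(a, a)
  expect_equal(same$shared, 2)
  expect_equal(same$only_before + same$only_now, 0)
  disj <- turnover(a, c(p = 1, q = 1, r = 1))
  expect_equal(disj$shared, 0)
  expect_equal(disj$union, 5)
})
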