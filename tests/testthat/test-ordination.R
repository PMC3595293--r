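mkbin <- function(m) {
  b <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = list(sprintf("H%02d", seq_len(nrow(m))),
                              sprintf("P%02d", seq_len(ncol(m)))))
  binarize(score_matrix(b))
}

test_that("community similarity counts agreements and shared detections", {
  b <- mkbin(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(community_similarity(b)$similarity["H01", "H02"], 1)
  b2 <- mkbin(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))
  expect_equal(community_similarity(b2)$similarity["H01", "H02"], 0)
  b3 <- mkbin(rbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  expect_equal(community_similarity(b3)$similarity["H01", "H02"], 0.5)
  expect_equal(community_similarity(b3, "jaccard")$similarity["H01", "H02"],
               1 / 3)
  cs <- community_similarity(b3)
  expect_equal(cs$distance, 1 - cs$similarity)
  expect_error(community_similarity(mkbin(matrix(1, 1, 3))), "at least 2")
})

test_that("geographic distances honor both survey modes", {
  h <- validate_habitat_table(data.frame(
    habitat_id = c("a", "b"), ph = c(7, 7),
    latitude = c(48, 48), longitude = c(14, 14)))
  expect_true(all(geo_distance(h) == 0))
  expect_true(all(geo_distance(h, "equator-1d") == 0))
  h$latitude <- c(48, 49)
  expect_equal(geo_distance(h, "equator-1d")["a", "b"], 111319.49)
  # the 1-D equator transform is blind to longitude
  h2 <- validate_habitat_table(data.frame(
    habitat_id = c("a", "b"), ph = c(7, 7),
    latitude = c(48, 48), longitude = c(14, 15)))
  expect_equal(geo_distance(h2, "equator-1d")["a", "b"], 0)
  expect_gt(geo_distance(h2, "great-circle")["a", "b"], 0)
  h2$latitude[2] <- NA
  expect_error(geo_distance(h2), "missing coordinates.*b")
})

test_that("great-circle distances satisfy the triangle inequality", {
  set.seed(23)
  for (i in 1:20) {
    h <- validate_habitat_table(data.frame(
      habitat_id = c("a", "b", "c"), ph = 7,
      latitude = runif(3, -80, 80), longitude = runif(3, -179, 179)))
    d <- geo_distance(h)
    expect_lte(d["a", "c"], d["a", "b"] + d["b", "c"] + 1e-6)
  }
})

test_that("environmental-delta matrices are absolute covariate differences", {
  h <- validate_habitat_table(data.frame(habitat_id = c("a", "b", "c"),
                                         ph = c(4, 7, 9.1)))
  d <- env_delta_matrix(h, "ph")
  expect_equal(d["a", "c"], 5.1)
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))
  expect_error(env_delta_matrix(h, "oxygen"), "missing oxygen")
})

test_that("mantel matches the exhaustive relabeling oracle on small n", {
  set.seed(33)
  for (i in 1:5) {
    p1 <- matrix(runif(8), 4); p2 <- matrix(runif(8), 4)
    d1 <- as.matrix(dist(p1)); d2 <- as.matrix(dist(p2))
    for (tail in c("two-sided", "one-sided-positive", "one-sided-negative")) {
      got <- mantel(d1, d2, tail = tail, method = "exhaustive")
      expect_equal(got$p, oracle_mantel_exhaustive(d1, d2, tail))
      expect_equal(got$n_permutations, 24)
    }
  }
})

test_that("mantel is seeded, bounded below, and rejects degenerate input", {
  set.seed(44)
  p1 <- matrix(runif(20), 10); p2 <- matrix(runif(20), 10)
  d1 <- as.matrix(dist(p1)); d2 <- as.matrix(dist(p2))
  a <- mantel(d1, d2, 499, seed = 9)
  b <- mantel(d1, d2, 499, seed = 9)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 500)
  expect_equal(mantel(d1, d1, 99, seed = 1)$r, 1)
  expect_error(mantel(d1, matrix(1, 10, 10) - diag(10) * 0, 99),
               "zero variance")
  expect_error(mantel(d1[1:3, 1:3], d2[1:3, 1:3]), "at least 4")
})

test_that("mantel r agrees with vegan's statistic", {
  skip_if_not_installed("vegan")
  set.seed(55)
  p1 <- matrix(runif(30), 15); p2 <- p1 + matrix(rnorm(30, 0, 0.2), 15)
  d1 <- as.matrix(dist(p1)); d2 <- as.matrix(dist(p2))
  ours <- mantel(d1, d2, 999, tail = "one-sided-positive", seed = 2)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})

test_that("signal beats noise in expectation across seeded replicates", {
  set.seed(66)
  wins <- replicate(20, {
    p1 <- matrix(runif(24), 12)
    d1 <- as.matrix(dist(p1))
    d_noisy <- d1 + as.matrix(dist(matrix(runif(24, 0, 0.2), 12)))
    d_shuf <- d1[sample(12), sample(12)]
    dimnames(d_noisy) <- dimnames(d_shuf) <- NULL
    cor(d1[lower.tri(d1)], d_noisy[lower.tri(d_noisy)]) >
      cor(d1[lower.tri(d1)], d_shuf[lower.tri(d_shuf)])
  })
  expect_gt(mean(wins), 0.8)
})

test_that("binary PCA matches a direct eigensolve and fixes axis signs", {
  b <- mkbin(rbind(c(1, 0, 0), c(0, 0, 0), c(1, 0, 0), c(0, 0, 0)))
  p <- pca_binary(b)
  expect_equal(p$explained_fraction[1], 1)
  set.seed(77)
  for (i in 1:10) {
    b <- mkbin(matrix(rbinom(50, 1, 0.5), 10))
    if (all(apply(b, 2, var) == 0)) next
    p <- pca_binary(b)
    expect_equal(sum(p$explained_fraction), 1, tolerance = 1e-10)
    expect_true(all(diff(p$explained_fraction) <= 1e-12))
    ev <- eigen(cov(scale(unclass(b), center = TRUE, scale = FALSE)),
                symmetric = TRUE)$values
    expect_equal(p$explained_fraction, ev / sum(ev), tolerance = 1e-9)
    # sign convention: dominant loading positive on every axis
    for (ax in seq_len(ncol(p$loadings))) {
      l <- p$loadings[, ax]
      expect_gte(l[which.max(abs(l))], 0)
    }
  }
  expect_error(pca_binary(mkbin(matrix(1, 4, 3))), "constant")
})

test_that("probe clustering recovers planted occurrence archetypes", {
  b0 <- mkbin(cbind(c(1, 1, 0, 0, 1), c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 0)))
  cl <- cluster_probes(b0, 2)
  expect_equal(cl$assignment[["P01"]], cl$assignment[["P02"]])
  expect_false(cl$assignment[["P01"]] == cl$assignment[["P03"]])
  expect_length(unique(cluster_probes(b0, 3)$assignment), 3)
  expect_error(cluster_probes(b0, 9), "k must be")
  # four planted archetypes, several probes each, light noise
  set.seed(88)
  arch <- matrix(rbinom(4 * 60, 1, 0.5), ncol = 4)
  truth <- rep(1:4, each = 3)
  cols <- sapply(truth, function(g) {
    v <- arch[, g]
    flip <- runif(60) < 0.03
    ifelse(flip, 1 - v, v)
  })
  rownames(cols) <- sprintf("H%02d", 1:60)
  colnames(cols) <- sprintf("P%02d", seq_along(truth))
  b <- binarize(score_matrix(cols))
  cl <- cluster_probes(b, 4)
  # perfect agreement up to label permutation
  tab <- table(cl$assignment, truth)
  expect_equal(sum(apply(tab, 1, max)), length(truth))
  expect_true(all(colSums(tab > 0) == 1))
})
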