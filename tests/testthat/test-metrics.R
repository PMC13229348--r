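test_that("trustworthiness is exact on preserved and hand-enumerated cases", {
  set.seed(1)
  # d informative dims: taking them as the embedding preserves neighbours
  X <- cbind(matrix(rnorm(60), 20), matrix(0, 20, 4))
  expect_equal(trustworthiness(X, X[, 1:3], k = 3), 1.0)
  # n = 8 points on a line with one interior pair swapped in the embedding
  x <- matrix(seq_len(8), ncol = 1)
  y <- x; y[c(4, 5), 1] <- y[c(5, 4), 1]
  expect_equal(trustworthiness(x, y, k = 2),
               oracle_trustworthiness(x, y, 2), tolerance = 1e-12)
  # invalid k is rejected with the normalization bound
  expect_error(trustworthiness(x, y, k = 6), "2n - 3k - 1")
})

test_that("a shuffled embedding always scores below the identity", {
  worse <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(200 * 5), 200)
    Y <- X[sample(200), ]
    worse <- worse + (trustworthiness(X, Y, 10) < trustworthiness(X, X, 10))
  }
  expect_equal(worse, 20)
})

test_that("lcmc handles full, empty and enumerated overlap", {
  set.seed(2)
  X <- matrix(rnorm(30), 10)
  expect_equal(lcmc(X, X, k = 3), 1.0)
  # k = 1 pairing construction with provably disjoint neighbour sets:
  # original pairs (1,2)(3,4)(5,6); embedding pairs (1,3)(2,5)(4,6)
  xo <- matrix(c(0, 0.1, 10, 10.1, 20, 20.1), ncol = 1)
  ye <- matrix(c(0, 10, 0.1, 20, 10.1, 20.1), ncol = 1)
  expect_equal(lcmc(xo, ye, k = 1), 0)
  # 12-point instance vs exhaustive set-intersection oracle
  set.seed(3)
  A <- matrix(rnorm(12 * 4), 12); B <- matrix(rnorm(12 * 2), 12)
  expect_equal(lcmc(A, B, k = 3), oracle_lcmc(A, B, 3), tolerance = 1e-12)
  expect_error(lcmc(A, B, k = 12), "k must be <")
})

test_that("distance correlations behave under scaling and monotone maps", {
  set.seed(4)
  X <- matrix(rnorm(40), 10)
  dc <- distance_correlations(X, 2.5 * X)
  expect_equal(unname(dc), c(1, 1), tolerance = 1e-9)
  # exp() of distances keeps order but breaks linearity: a small triangle
  # with exp'd side lengths still embeds exactly in the plane
  # side lengths (1.3, 1.5, 1.65): exp'd sides still satisfy the triangle
  # inequality, so the construction embeds exactly in the plane
  tri <- matrix(c(0, 0, 1.65, 0, 0.6553, 1.1228), 3, byrow = TRUE)
  Dtri <- as.matrix(dist(tri))
  emb3 <- cmdscale(exp(Dtri) - 1, k = 2)
  d_orig <- Dtri[upper.tri(Dtri)]
  d_emb <- dist(emb3)
  expect_equal(as.vector(d_emb), as.vector(exp(d_orig) - 1),
               tolerance = 1e-9)             # construction is exact
  dc2 <- distance_correlations(tri, emb3)
  expect_equal(unname(dc2[["spearman_rho"]]), 1, tolerance = 1e-9)
  expect_lt(dc2[["pearson_r"]], 1 - 1e-6)
  # textbook-formula oracle on a 5-point hand dataset
  H <- matrix(c(0, 0, 1, 0, 0, 2, 3, 1, 5, 5), 5, byrow = TRUE)
  L <- matrix(c(0, 0, 1.2, 0.1, 0.2, 1.9, 2.8, 1.4, 4.0, 6.1), 5,
              byrow = TRUE)
  dh <- dist_mat(H)[upper.tri(dist_mat(H))]
  dl <- dist_mat(L)[upper.tri(dist_mat(L))]
  pear <- sum((dh - mean(dh)) * (dl - mean(dl))) /
    sqrt(sum((dh - mean(dh))^2) * sum((dl - mean(dl))^2))
  rh <- rank(dh); rl <- rank(dl)
  spear <- sum((rh - mean(rh)) * (rl - mean(rl))) /
    sqrt(sum((rh - mean(rh))^2) * sum((rl - mean(rl))^2))
  dc3 <- distance_correlations(H, L)
  expect_equal(unname(dc3[["pearson_r"]]), pear, tolerance = 1e-12)
  expect_equal(unname(dc3[["spearman_rho"]]), spear, tolerance = 1e-12)
  expect_error(distance_correlations(matrix(0, 4, 2), matrix(rnorm(8), 4)),
               "constant")
})

test_that("composite scores satisfy the exact LS/GS/SPS identities", {
  set.seed(5)
  for (i in 1:25) {
    Tv <- runif(1); Lv <- runif(1); r <- runif(1, -1, 1)
    rho <- runif(1, -1, 1); w <- runif(1)
    s <- composite_scores(Tv, Lv, r, rho, w_LS = w)
    expect_equal(s$LS, 0.5 * Tv + 0.5 * Lv, tolerance = 1e-15)
    expect_equal(s$GS, 0.5 * r + 0.5 * rho, tolerance = 1e-15)
    expect_equal(s$SPS, w * s$LS + (1 - w) * s$GS, tolerance = 1e-15)
    expect_equal(s$w_LS + s$w_GS, 1)
  }
  expect_error(composite_scores(0.5, 0.5, 0, 0, w_LS = 1.2), "w_LS")
})

test_that("reporting rounds half away from zero at 3 decimals", {
  expect_equal(round_report(0.79575), 0.796)
  expect_equal(round_report(0.82225), 0.822)
  expect_equal(round_report(-0.0005), -0.001)
})

test_that("BTS trivial, degenerate and hand-evaluated cases", {
  # regular simplex with all pairwise distances e - 1: every term 1/log(e)
  Y <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  Y <- Y * (exp(1) - 1) / sqrt(2)           # edge length e - 1
  D <- dist_mat(Y)
  expect_true(max(abs(D[upper.tri(D)] - (exp(1) - 1))) < 1e-9)
  r <- bts(Y, rep("mushroom", 4), k = 3)
  expect_equal(r$bts, 1.0, tolerance = 1e-9)
  # thin/stubby-only neighbours under the default scheme: zero denominator
  Z <- matrix(c(0, 0.1, 5, 5.1), ncol = 1)
  expect_error(bts(Z, c("thin", "stubby", "thin", "stubby"), k = 1),
               "undefined")
  # 6-point, 2-NN mixed-label configuration vs the direct double sum
  set.seed(6)
  P <- matrix(rnorm(12), 6)
  lab <- c("mushroom", "mushroom", "stubby", "thin", "stubby", "thin")
  sch <- default_transition_scheme()
  expect_equal(bts(P, lab, sch, k = 2)$bts,
               oracle_bts(P, lab, sch$W, 2), tolerance = 1e-12)
})

test_that("BTS invariances: relabeling symmetry and distance scaling", {
  set.seed(7)
  P <- matrix(rnorm(40), 20)
  lab <- sample(c("mushroom", "stubby", "thin"), 20, replace = TRUE)
  sch <- default_transition_scheme()
  # stubby <-> thin swap preserves the default weight matrix
  swap <- c(mushroom = "mushroom", stubby = "thin", thin = "stubby")
  expect_equal(bts(P, lab, sch, k = 3)$bts,
               bts(P, unname(swap[lab]), sch, k = 3)$bts, tolerance = 1e-12)
  # scaling all distances by c > 1 strictly decreases the score
  expect_lt(bts(3 * P, lab, sch, k = 3)$bts, bts(P, lab, sch, k = 3)$bts)
})

test_that("transition schemes are validated", {
  expect_error(transition_scheme(c("a", "b"), matrix(c(1, .5, .2, 1), 2)),
               "symmetric")
  expect_error(transition_scheme(c("a", "b"), matrix(c(.4, .5, .5, 1), 2)),
               "maximum")
  expect_error(transition_scheme(c("a", "b"), matrix(c(1, -.1, -.1, 1), 2)),
               "negative")
  sch <- default_transition_scheme()
  expect_equal(sch$W["mushroom", "thin"], 0.5)
  expect_equal(sch$W["thin", "stubby"], 0)
  expect_equal(diag(sch$W), c(mushroom = 1, stubby = 1, thin = 1))
})

test_that("class overlap matches near-1, near-0 and grid-oracle regimes", {
  set.seed(8)
  # identically distributed classes: overlap near 1
  Y <- matrix(rnorm(400 * 2), 400)
  lab <- rep(c("a", "b"), each = 200)
  ov <- class_overlap(Y, lab, seed = 1)
  expect_gt(ov$pairs$overlap[1], 0.8)
  # separation by many bandwidths: overlap near 0
  Y2 <- rbind(matrix(rnorm(200, 0, 0.1), 100),
              matrix(rnorm(200, 50, 0.1), 100))
  ov2 <- class_overlap(Y2, rep(c("a", "b"), each = 100), seed = 1)
  expect_lt(ov2$AO, 0.01)
  # known 2D Gaussians vs dense-grid numerical integration
  xa <- matrix(rnorm(240, 0, 1), 120)
  xb <- matrix(rnorm(240, 1.5, 1), 120)
  got <- class_overlap(rbind(xa, xb), rep(c("a", "b"), each = 120),
                       n_draws = 20000, seed = 2)
  want <- oracle_kde_overlap_grid(xa, xb)
  expect_equal(got$AO, want, tolerance = 0.02)
  # symmetry in the pair and rotation invariance
  rot <- cbind(c(cos(0.7), sin(0.7)), c(-sin(0.7), cos(0.7)))
  got_rot <- class_overlap(rbind(xa, xb) %*% rot,
                           rep(c("a", "b"), each = 120),
                           n_draws = 20000, seed = 2)
  expect_equal(got$AO, got_rot$AO, tolerance = 0.03)
})

test_that("sensitivity suite row counts, consistency and stability flag", {
  set.seed(9)
  tab <- scale_features(generate_feature_continuum(
    c(mushroom = 20, stubby = 20, thin = 20), mixing_fraction = 0, seed = 9))
  idn <- tab$values[, 1:3]
  corrupted <- idn[sample(60), ]
  lows <- list(identity = idn, shuffled = corrupted)
  out <- sensitivity_suite(tab, lows, labels = tab$labels,
                           k_range = 10, w_range = 0.5)
  expect_equal(nrow(out$local), 2)
  expect_equal(nrow(out$sps), 2)
  # single default scheme: BTS columns equal bts() called directly
  direct <- bts(idn, tab$labels, k = 10)$bts
  expect_equal(out$bts$bts[out$bts$method == "identity" &
                             out$bts$metric == "euclidean"], direct,
               tolerance = 1e-12)
  # identity embedding dominates the corrupted one across a k grid
  out2 <- sensitivity_suite(tab, lows, labels = NULL, k_range = c(5, 10, 15),
                            w_range = c(0.3, 0.5, 0.7))
  expect_true(out2$stability$local)
  expect_true(out2$stability$sps)
})
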