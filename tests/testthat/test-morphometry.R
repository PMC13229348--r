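test_that("contour features: disk circularity, convexity, degenerate mask", {
  cr <- spine_crop(matrix(1, 80, 80), disk_mask(30), id = "disk")
  f <- extract_contour_features(cr)
  expect_gt(f[["circularity"]], 0.9)
  expect_lt(f[["circularity"]], 1.05)
  expect_lt(f[["eccentricity"]], 0.2)
  # convex blob: solidity and convex hull ratio exactly 1
  m <- matrix(FALSE, 40, 40); m[10:30, 8:32] <- TRUE
  fr <- extract_contour_features(spine_crop(matrix(1, 40, 40), m, id = "r"))
  expect_equal(fr[["solidity"]], 1.0, tolerance = 1e-6)
  expect_equal(fr[["convex_hull_ratio"]], 1.0, tolerance = 1e-6)
  # too-small mask is rejected
  tiny <- matrix(FALSE, 20, 20); tiny[10, 10:12] <- TRUE
  expect_error(extract_contour_features(
    spine_crop(matrix(1, 20, 20), tiny, id = "t")), "degenerate")
})

test_that("box-counting dimension of a straight line is near 1", {
  m <- matrix(FALSE, 64, 64); m[32, 5:60] <- TRUE
  expect_gt(fractal_dimension(m), 0.9)
  expect_lt(fractal_dimension(m), 1.1)
})

test_that("geometry: stubby necks vanish, head diameter tracks truth", {
  stub <- make_spine_crop(head_radius = 20, neck_length = 0,
                          neck_width = 18)
  g <- extract_geometry_features(stub)
  expect_lte(g[["neck_length"]], 2)          # pixel_size 1: 2 px equivalent
  mush <- make_spine_crop(head_radius = 12, neck_length = 25, neck_width = 6)
  gm <- extract_geometry_features(mush)
  expect_lt(abs(gm[["head_diameter"]] - 24) / 24, 0.15)
  expect_gt(gm[["head_neck_ratio"]], 1)
})

test_that("contour and geometry features are invariant to 90-degree rotation", {
  cr <- make_spine_crop(head_radius = 14, neck_length = 22, neck_width = 7,
                        orientation = pi / 2, psf = 1, size = 96)
  rot <- spine_crop(rot90(cr$intensity), rot90(cr$mask), id = "rot")
  f1 <- c(extract_contour_features(cr), extract_geometry_features(cr))
  f2 <- c(extract_contour_features(rot), extract_geometry_features(rot))
  rel <- abs(f2 - f1) / pmax(abs(f1), 1e-6)
  expect_true(all(rel < 0.05), info = paste(names(which(rel >= 0.05)),
                                            collapse = ", "))
})

test_that("translation leaves contour and geometry features unchanged", {
  cr <- make_spine_crop(head_radius = 10, neck_length = 15, neck_width = 5,
                        size = 96)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  tr <- spine_crop(matrix(1, 96, 96) * 0 +
                     as.numeric(shift(cr$intensity > 0, 7, 5)) *
                     max(cr$intensity), shift(cr$mask, 7, 5), id = "tr")
  f1 <- extract_contour_features(cr)
  f2 <- extract_contour_features(tr)
  expect_equal(f1[c("area", "solidity", "extent", "eccentricity")],
               f2[c("area", "solidity", "extent", "eccentricity")],
               tolerance = 1e-9)
})

test_that("scale-free features are stable under 2x nearest-neighbour upsampling", {
  cr <- make_spine_crop(head_radius = 12, neck_length = 18, neck_width = 6,
                        size = 96)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  cu <- spine_crop(up(cr$intensity), up(cr$mask), id = "up")
  keep <- c("circularity", "solidity", "eccentricity", "aspect_ratio")
  f1 <- extract_contour_features(cr)[keep]
  f2 <- extract_contour_features(cu)[keep]
  expect_true(all(abs(f2 - f1) / abs(f1) < 0.10))
})

test_that("intensity features: constant image, symmetry, GLCM oracle", {
  m <- disk_mask(12, pad = 4)
  fc <- extract_intensity_features(spine_crop(matrix(5, 32, 32), m,
                                              id = "const"))
  expect_equal(fc[["glcm_energy"]], 1.0)
  expect_equal(fc[["glcm_contrast"]], 0.0)
  expect_equal(fc[["glcm_correlation"]], 0.0)   # documented fallback
  # symmetric bimodal histogram: zero skewness
  img <- matrix(rep(c(1, 9), 512), 32)
  fs <- extract_intensity_features(spine_crop(img, matrix(TRUE, 32, 32),
                                              id = "sym"))
  expect_equal(fs[["int_skewness"]], 0, tolerance = 1e-6)
  # checkerboard of two levels: hand-computed co-occurrence contrast.
  # Horizontal and vertical distance-1 offsets always pair different
  # levels, so each contributes (Delta level)^2 = 15^2 on 16 quantized
  # levels; both diagonal offsets pair equal levels (contrast 0), so the
  # 4-offset average is 225 / 2.
  chk <- outer(1:16, 1:16, function(i, j) (i + j) %% 2) * 8 + 1
  g <- spinemorph:::glcm_stats(chk, matrix(TRUE, 16, 16))
  expect_equal(unname(g["contrast"]), 225 / 2, tolerance = 1e-12)
  # all-zero masked intensity is rejected
  expect_error(extract_intensity_features(
    spine_crop(matrix(0, 32, 32), m, id = "z")), "all-zero")
})

test_that("feature assembly produces the default 31-column table", {
  set <- generate_spine_image_set(8, seed = 41)
  tab <- assemble_feature_table(set$crops, standardize = TRUE)
  expect_equal(dim(tab), c(8, 31))
  expect_lt(max(abs(colMeans(tab$values))), 1e-8)
  expect_true(all(abs(apply(tab$values, 2, sd) - 1) < 1e-8))
  expect_equal(nrow(tab$rejects), 0)
  expect_error(assemble_feature_table(list()), "empty")
  expect_equal(length(default_feature_set()), 31)
  expect_equal(length(extract_all_features(set$crops[[1]])), 35)
})

test_that("failed crops land in the reject report, not silently dropped", {
  set <- generate_spine_image_set(4, seed = 42)
  bad <- spine_crop(matrix(1, 20, 20),
                    {m <- matrix(FALSE, 20, 20); m[9:10, 9:11] <- TRUE; m},
                    id = "bad")
  tab <- assemble_feature_table(c(set$crops, list(bad)),
                                standardize = FALSE)
  expect_equal(nrow(tab$values), 4)
  expect_equal(tab$rejects$id, "bad")
  expect_match(tab$rejects$reason, "degenerate")
})

test_that("screening flags null features, duplicates, and uses alpha 0.05", {
  expect_equal(formals(screen_features)$alpha, 0.05)
  # a feature identically distributed across classes is flagged
  # non-discriminative in the vast majority of replicates
  hits <- 0
  reps <- 60
  for (s in seq_len(reps)) {
    set.seed(s)
    vals <- cbind(null_f = rnorm(100),
                  real_f = c(rnorm(50, 0), rnorm(50, 3)))
    tab <- feature_table(vals, labels = rep(c("a", "b"), each = 50))
    rep_s <- screen_features(tab)
    hits <- hits + (rep_s$flags$status[1] == "dropped:non-discriminative")
    expect_equal(rep_s$flags$status[2], "retained")
  }
  expect_gte(hits / reps, 0.9)
  # exact duplicate columns: one flagged redundant
  set.seed(99)
  v <- c(rnorm(30, 0), rnorm(30, 2))
  tab2 <- feature_table(cbind(f1 = v, f2 = v, f3 = rnorm(60, 5)),
                        labels = rep(c("a", "b"), each = 30))
  rep2 <- screen_features(tab2)
  expect_equal(sum(rep2$flags$status == "dropped:redundant"), 1)
  expect_true(all(c("f1", "f2") %in%
                    c(rep2$retained, rep2$flags$feature[
                      rep2$flags$status == "dropped:redundant"])))
  expect_error(screen_features(feature_table(cbind(a = rnorm(10)),
                                             labels = rep("x", 10))),
               ">= 2 classes")
})

test_that("screening false-positive rate under a permuted null matches alpha", {
  # under label permutation, a feature is 'discriminative in some pair'
  # with probability ~ 1 - (1 - alpha)^3 for three class pairs
  set.seed(7)
  n <- 60
  hits <- 0
  reps <- 200
  for (i in seq_len(reps)) {
    vals <- cbind(f = rnorm(n))
    labs <- sample(rep(c("m", "s", "t"), each = n / 3))
    rp <- screen_features(feature_table(vals, labels = labs))
    hits <- hits + (min(rp$p_values[1, ]) < 0.05)
  }
  p_expected <- 1 - 0.95^3
  # binomial check at ~4 sigma
  se <- sqrt(p_expected * (1 - p_expected) / reps)
  expect_lt(abs(hits / reps - p_expected), 4 * se + 0.02)
})

test_that("feature tables round-trip through CSV", {
  tab <- generate_feature_continuum(c(mushroom = 5, stubby = 5, thin = 5),
                                    seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(back$values, tab$values, tolerance = 1e-12)
  expect_equal(as.character(back$labels), as.character(tab$labels))
})
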