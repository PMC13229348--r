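## Morphometric feature extraction: the shape, contour and intensity
## feature families computed from crop + mask pairs, their assembly into a
## standardized feature table, and statistical screening.

#' Construct a spine crop
#'
#' A single spine's grayscale intensity image plus a binary mask of the
#' spine silhouette, with the pixel size and optional expert label.
#'
#' @param intensity numeric matrix of non-negative intensities.
#' @param mask logical matrix, same shape, at least one foreground pixel.
#' @param pixel_size micrometres per pixel.
#' @param label optional class label ("mushroom", "stubby", "thin", ...).
#' @param id spine identifier.
#' @return a `spine_crop` object.
#' @export
spine_crop <- function(intensity, mask, pixel_size = 1, label = NULL,
                       id = "spine") {
  intensity <- as.matrix(intensity); mask <- as.matrix(mask)
  stop_if(!all(dim(intensity) == dim(mask)),
          "intensity and mask must have identical shape")
  stop_if(any(!is.finite(intensity)), "intensity must be finite")
  stop_if(any(intensity < 0), "intensity must be non-negative")
  mask <- mask > 0
  stop_if(!any(mask), "mask must contain at least one foreground pixel")
  check_number(pixel_size, "pixel_size", lower = 1e-12)
  structure(list(intensity = intensity, mask = mask, pixel_size = pixel_size,
                 label = label, id = id), class = "spine_crop")
}

#' @export
print.spine_crop <- function(x, ...) {
  cat(sprintf("Spine crop '%s': %d x %d px (%.4f um/px), %d mask px%s\n",
              x$id, nrow(x$intensity), ncol(x$intensity), x$pixel_size,
              sum(x$mask),
              if (is.null(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

## largest 4-connected component of a mask (frontier BFS with vectorized
## neighbour arithmetic on linear indices)
largest_component <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  mask_v <- as.vector(mask)
  lab <- integer(n1 * n2)
  cur <- 0L
  remaining <- which(mask_v)
  while (length(remaining) > 0) {
    cur <- cur + 1L
    frontier <- remaining[1]
    lab[frontier] <- cur
    while (length(frontier) > 0) {
      r <- (frontier - 1L) %% n1 + 1L
      up <- ifelse(r == 1L, NA_integer_, frontier - 1L)
      dn <- ifelse(r == n1, NA_integer_, frontier + 1L)
      lf <- frontier - n1; lf[lf < 1L] <- NA_integer_
      rt <- frontier + n1; rt[rt > n1 * n2] <- NA_integer_
      nb <- unique(c(up, dn, lf, rt))
      nb <- nb[!is.na(nb)]
      nb <- nb[mask_v[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
    remaining <- remaining[lab[remaining] == 0L]
  }
  if (cur <= 1L) return(mask)
  matrix(lab == which.max(tabulate(lab[lab > 0L])), n1, n2)
}

## trim a mask (and companions) to its bounding box plus a margin; feature
## values are location-free, so extraction on the trimmed crop is exact
bbox_trim <- function(mask, pad = 2) {
  px <- which(mask, arr.ind = TRUE)
  r <- max(1, min(px[, 1]) - pad):min(nrow(mask), max(px[, 1]) + pad)
  cc <- max(1, min(px[, 2]) - pad):min(ncol(mask), max(px[, 2]) + pad)
  list(rows = r, cols = cc)
}

## sub-pixel boundary polygon of a mask (marching squares at level 0.5)
## smoothed with a circular moving average; the smoothing removes the
## rasterization staircase so that a disk's perimeter is measured within
## ~1% of the true circumference
mask_contour <- function(mask, smooth = 5) {
  z <- matrix(0, nrow(mask) + 2, ncol(mask) + 2)
  z[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask * 1
  cl <- grDevices::contourLines(seq_len(nrow(z)), seq_len(ncol(z)), z,
                                levels = 0.5)
  cl <- cl[[which.max(vapply(cl, function(p) length(p$x), 0))]]
  x <- cl$x; y <- cl$y
  if (smooth > 1 && length(x) > smooth) {
    k <- (smooth - 1) / 2
    sm <- function(v) {
      n <- length(v)
      idx <- outer(seq_len(n), -k:k, `+`); idx <- ((idx - 1) %% n) + 1
      rowMeans(matrix(v[idx], n))
    }
    x <- sm(x); y <- sm(y)
  }
  cbind(x = x, y = y)
}

polygon_perimeter <- function(p)
  sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

## boundary pixels: foreground with at least one 4-neighbour background
boundary_pixels <- function(mask) {
  m <- mask * 1L
  nb <- shift_mat(m, 1, 0) + shift_mat(m, -1, 0) +
    shift_mat(m, 0, 1) + shift_mat(m, 0, -1)
  mask & nb < 4
}

#' Box-counting fractal dimension of a mask boundary
#'
#' Counts occupied boxes over dyadic box sizes and fits the slope of
#' log N against log(1/s) by least squares. A straight one-pixel line has
#' dimension ~1; increasingly irregular contours approach 2.
#'
#' @param mask logical matrix.
#' @return estimated fractal dimension.
#' @export
fractal_dimension <- function(mask) {
  bp <- which(boundary_pixels(mask), arr.ind = TRUE)
  if (nrow(bp) < 2) return(1)
  ext <- max(diff(range(bp[, 1])), diff(range(bp[, 2]))) + 1
  sizes <- 2^(0:floor(log2(max(ext / 2, 2))))
  sizes <- sizes[sizes <= ext]
  if (length(sizes) < 2) return(1)
  counts <- vapply(sizes, function(s) {
    nrow(unique(cbind(floor((bp[, 1] - min(bp[, 1])) / s),
                      floor((bp[, 2] - min(bp[, 2])) / s))))
  }, 0)
  stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[[2]]
}

#' Contour feature family
#'
#' Region and boundary descriptors of the spine silhouette: area, perimeter,
#' circularity (4 * pi * A / P^2), eccentricity, solidity and convex hull
#' ratio (area / convex area), extent, aspect ratio, major/minor axis
#' lengths (moment-based), equivalent diameter and the box-counting fractal
#' dimension of the boundary. Lengths are in micrometres via `pixel_size`.
#' Masks with more than one connected component are reduced to the largest
#' (with a warning); masks of fewer than 8 pixels are rejected as
#' degenerate.
#'
#' @param crop a [spine_crop()].
#' @return named numeric vector of features.
#' @export
extract_contour_features <- function(crop) {
  stopifnot(inherits(crop, "spine_crop"))
  mask <- crop$mask
  stop_if(sum(mask) < 8, "mask of < 8 px: degenerate contour")
  lc <- largest_component(mask)
  if (sum(lc) < sum(mask)) {
    warning("mask not connected; largest component taken", call. = FALSE)
    mask <- lc
  }
  bb <- bbox_trim(mask)
  mask <- mask[bb$rows, bb$cols, drop = FALSE]
  ps <- crop$pixel_size
  A_px <- sum(mask)
  ctr <- mask_contour(mask)
  P_px <- polygon_perimeter(ctr)
  px <- which(mask, arr.ind = TRUE)
  ## moment-based axes: eigenvalues of the pixel-coordinate covariance,
  ## with the 1/12 single-pixel term so 1-px-wide shapes are well defined
  cv <- stats::cov(px) * (nrow(px) - 1) / nrow(px) + diag(1 / 12, 2)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- sqrt(max(0, 1 - ev[2] / ev[1]))
  ## convex area: pixels whose centers fall in the hull of mask pixel centers
  hull <- px[grDevices::chull(px[, 1], px[, 2]), , drop = FALSE]
  bb <- expand.grid(r = min(px[, 1]):max(px[, 1]),
                    c = min(px[, 2]):max(px[, 2]))
  inhull <- pracma::inpolygon(bb$r, bb$c, hull[, 1], hull[, 2],
                              boundary = TRUE)
  conv_px <- sum(inhull)
  bbox_px <- (diff(range(px[, 1])) + 1) * (diff(range(px[, 2])) + 1)
  c(area = A_px * ps^2,
    perimeter = P_px * ps,
    circularity = 4 * pi * A_px / P_px^2,
    eccentricity = ecc,
    solidity = A_px / conv_px,
    convex_hull_ratio = A_px / conv_px,
    extent = A_px / bbox_px,
    aspect_ratio = major / minor,
    major_axis_length = major * ps,
    minor_axis_length = minor * ps,
    equivalent_diameter = 2 * sqrt(A_px / pi) * ps,
    fractal_dimension = fractal_dimension(mask))
}

#' Geometry feature family (neck / head morphometry)
#'
#' Skeletonizes the mask and measures the medial path from the
#' shaft-attachment end (the skeleton point geodesically farthest from the
#' head) to the head center (the maximum of the Euclidean distance
#' transform). Head diameter is twice the maximal inscribed-disk radius in
#' the head region; neck width is twice the minimal distance-transform
#' value along the middle third of the path; neck length is the path length
#' minus the head and attachment radii. Also emits the total medial spine
#' length, head/neck ratio, and the length-to-width (LAR) and
#' width-to-length ratios. Lengths in micrometres.
#'
#' @param crop a [spine_crop()].
#' @return named numeric vector of features.
#' @export
extract_geometry_features <- function(crop) {
  stopifnot(inherits(crop, "spine_crop"))
  mask <- largest_component(crop$mask)
  stop_if(sum(mask) < 8, "mask of < 8 px: degenerate geometry")
  bb <- bbox_trim(mask)
  mask <- mask[bb$rows, bb$cols, drop = FALSE]
  ps <- crop$pixel_size
  dt <- distance_transform(mask)
  head_px <- which(dt == max(dt), arr.ind = TRUE)[1, ]
  r_head <- max(dt)
  skel <- skeletonize(mask)
  if (!any(skel)) skel[head_px[1], head_px[2]] <- TRUE
  stop_if(!any(skel), "empty skeleton")
  sg <- skeleton_graph(skel)
  i_head <- nearest_skeleton_node(sg, head_px)
  gd <- suppressWarnings(igraph::distances(sg$graph, v = i_head))[1, ]
  gd[!is.finite(gd)] <- -1           # unreachable components ignored
  i_att <- which.max(gd)
  path <- skeleton_path(sg, i_att, i_head)
  plen <- path$length
  np0 <- nrow(path$pixels)
  ## neck = path segment between the shaft-junction ball and the head ball.
  ## The junction ball is the inscribed disc covering the attachment end:
  ## argmax of dt(p) - arclength(p) picks the medial centre of whichever
  ## blob contains the path start (the shaft stub), not a mid-neck pixel.
  steps <- if (np0 > 1)
    c(0, cumsum(sqrt(rowSums((path$pixels[-1, , drop = FALSE] -
                                path$pixels[-np0, , drop = FALSE])^2))))
  else 0
  dts <- dt[path$pixels]
  ## shaft-junction centre: the first crest of the running maximum of dt
  ## walking in from the attachment end (skeleton spurs into the shaft
  ## corner have small dt and are skipped; mid-neck plateaus are not
  ## reached because the first crest wins)
  j_att <- np0
  run <- -Inf
  for (j in seq_len(np0)) {
    if (dts[j] >= run) {
      run <- dts[j]
      if (j == np0 || dts[j + 1] <= dts[j]) { j_att <- j; break }
    }
  }
  r_att <- dts[j_att]
  d_from_att <- sqrt(rowSums(sweep(path$pixels, 2,
                                   path$pixels[j_att, ])^2))
  d_from_head <- sqrt((path$pixels[, 1] - head_px[1])^2 +
                        (path$pixels[, 2] - head_px[2])^2)
  ## sub-pixel arclengths where the path exits the junction ball and
  ## enters the head ball (linear interpolation between path pixels keeps
  ## the measurement stable under rotation of the pixel grid)
  cross_out <- function(dvec, r, j0) {
    j <- j0
    while (j < np0 && dvec[j + 1] <= r) j <- j + 1
    if (j >= np0) return(steps[np0])
    t <- (r - dvec[j]) / (dvec[j + 1] - dvec[j])
    steps[j] + max(0, min(1, t)) * (steps[j + 1] - steps[j])
  }
  s_start <- cross_out(d_from_att, r_att, j_att)
  in_head <- which(d_from_head <= r_head)
  s_end <- if (length(in_head) == 0) steps[np0] else {
    j <- min(in_head)
    if (j == 1) 0 else {
      t <- (d_from_head[j - 1] - r_head) /
        (d_from_head[j - 1] - d_from_head[j])
      steps[j - 1] + max(0, min(1, t)) * (steps[j] - steps[j - 1])
    }
  }
  neck_len <- max(0, s_end - s_start)
  np <- nrow(path$pixels)
  mid <- path$pixels[max(1, floor(np / 3)):max(1, ceiling(2 * np / 3)), ,
                     drop = FALSE]
  neck_w <- 2 * min(dt[mid])
  spine_len <- plen + r_head + r_att
  width <- 2 * max(dt)
  c(spine_length = spine_len * ps,
    neck_length = neck_len * ps,
    neck_width = neck_w * ps,
    head_diameter = 2 * r_head * ps,
    head_neck_ratio = (2 * r_head) / max(neck_w, 1e-6),
    length_width_ratio = spine_len / max(width, 1e-6),
    width_length_ratio = width / max(spine_len, 1e-6))
}

## quantize masked intensities to `levels` gray levels (1-based)
quantize_gray <- function(vals, levels = 16) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rep(1L, length(vals)))
  q <- floor((vals - rng[1]) / diff(rng) * levels) + 1L
  pmin(q, levels)
}

## gray-level co-occurrence matrix statistics averaged over the 4 symmetric
## distance-1 offsets (0, 45, 90, 135 degrees), computed on mask pixels
glcm_stats <- function(img, mask, levels = 16) {
  qimg <- matrix(NA_integer_, nrow(img), ncol(img))
  qimg[mask] <- quantize_gray(img[mask], levels)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- c(contrast = 0, homogeneity = 0, energy = 0, correlation = 0,
           entropy = 0)
  ii <- matrix(rep(seq_len(levels), levels), levels)
  jj <- t(ii)
  for (d in offs) {
    P <- matrix(0, levels, levels)
    sh <- shift_mat(ifelse(is.na(qimg), 0L, qimg), d[1], d[2])
    ok <- !is.na(qimg) & sh > 0
    if (any(ok)) {
      cnt <- matrix(tabulate((qimg[ok] - 1L) * levels + sh[ok],
                             levels * levels), levels, byrow = TRUE)
      P <- P + cnt + t(cnt)                      # symmetric counts
    }
    tot <- sum(P)
    if (tot == 0) next
    P <- P / tot
    mu_i <- sum(ii * P); mu_j <- sum(jj * P)
    s_i <- sqrt(sum((ii - mu_i)^2 * P)); s_j <- sqrt(sum((jj - mu_j)^2 * P))
    corr <- if (s_i > 0 && s_j > 0)
      sum((ii - mu_i) * (jj - mu_j) * P) / (s_i * s_j) else 0
    acc <- acc + c(contrast = sum((ii - jj)^2 * P),
                   homogeneity = sum(P / (1 + (ii - jj)^2)),
                   energy = sum(P^2),
                   correlation = corr,
                   entropy = -sum(P[P > 0] * log(P[P > 0])))
  }
  acc / length(offs)
}

## histogram-of-oriented-gradients descriptor: 9 unsigned orientation bins,
## 8 x 8 px cells, per-cell L2 normalization; summarized by moments
hog_descriptor <- function(img, cell = 8, bins = 9) {
  n1 <- nrow(img); n2 <- ncol(img)
  gx <- matrix(0, n1, n2); gy <- matrix(0, n1, n2)
  gx[, 2:(n2 - 1)] <- (img[, 3:n2] - img[, 1:(n2 - 2)]) / 2
  gy[2:(n1 - 1), ] <- (img[3:n1, ] - img[1:(n1 - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                     # unsigned [0, pi)
  bin <- pmin(floor(ang / pi * bins) + 1L, bins)
  desc <- numeric(0)
  for (r0 in seq(1, n1 - cell + 1, by = cell))
    for (c0 in seq(1, n2 - cell + 1, by = cell)) {
      rs <- r0:(r0 + cell - 1); cs <- c0:(c0 + cell - 1)
      h <- vapply(seq_len(bins), function(b)
        sum(mag[rs, cs][bin[rs, cs] == b]), 0)
      nz <- sqrt(sum(h^2))
      if (nz > 0) h <- h / nz
      desc <- c(desc, h)
    }
  desc
}

#' Intensity feature family
#'
#' First-order statistics of the masked intensities (mean, SD, skewness,
#' kurtosis, Shannon entropy on 16 gray levels, coefficient of variation and
#' range), Haralick-style GLCM statistics (contrast, homogeneity, energy,
#' correlation and entropy averaged over the four symmetric distance-1
#' offsets at 16 quantized levels), and moment summaries of a HOG
#' descriptor (9 orientations, 8 x 8 px cells).
#'
#' If the masked intensity is constant the GLCM correlation falls back to 0
#' (single co-occurrence bin); an all-zero masked intensity is rejected.
#'
#' @param crop a [spine_crop()].
#' @return named numeric vector of features.
#' @export
extract_intensity_features <- function(crop) {
  stopifnot(inherits(crop, "spine_crop"))
  vals <- crop$intensity[crop$mask]
  stop_if(all(vals == 0), "all-zero intensity under mask")
  q <- quantize_gray(vals)
  pq <- tabulate(q, 16) / length(q)
  ent <- -sum(pq[pq > 0] * log(pq[pq > 0]))
  skw <- if (stats::sd(vals) > 0) e1071::skewness(vals, type = 1) else 0
  krt <- if (stats::sd(vals) > 0) e1071::kurtosis(vals, type = 1) else 0
  g <- glcm_stats(crop$intensity, crop$mask)
  hd <- hog_descriptor(crop$intensity)
  hog_k <- if (length(hd) > 3 && stats::sd(hd) > 0)
    e1071::kurtosis(hd, type = 1) else 0
  c(int_mean = mean(vals), int_sd = stats::sd(vals),
    int_skewness = skw, int_kurtosis = krt, int_entropy = ent,
    int_cv = stats::sd(vals) / max(mean(vals), 1e-12),
    int_range = diff(range(vals)),
    glcm_contrast = unname(g["contrast"]),
    glcm_homogeneity = unname(g["homogeneity"]),
    glcm_energy = unname(g["energy"]),
    glcm_correlation = unname(g["correlation"]),
    glcm_entropy = unname(g["entropy"]),
    hog_mean = if (length(hd)) mean(hd) else 0,
    hog_sd = if (length(hd) > 1) stats::sd(hd) else 0,
    hog_kurtosis = hog_k,
    hog_skewness = if (length(hd) > 2 && stats::sd(hd) > 0)
      e1071::skewness(hd, type = 1) else 0)
}

#' Extract all feature families from one crop
#'
#' @param crop a [spine_crop()].
#' @return named numeric vector (35 features across the contour, geometry
#'   and intensity families).
#' @export
extract_all_features <- function(crop) {
  c(extract_contour_features(crop),
    extract_geometry_features(crop),
    extract_intensity_features(crop))
}

#' Default retained feature set
#'
#' The 35 extracted descriptors minus four that duplicate another feature
#' up to a deterministic transform (`convex_hull_ratio` = solidity,
#' `width_length_ratio` = 1 / LAR on the same measurements, `int_cv` and
#' `int_range` rescalings of first-order statistics), leaving the default
#' 31-feature morphometric representation.
#'
#' @return character vector of 31 feature names.
#' @export
default_feature_set <- function() {
  all35 <- c("area", "perimeter", "circularity", "eccentricity", "solidity",
             "convex_hull_ratio", "extent", "aspect_ratio",
             "major_axis_length", "minor_axis_length", "equivalent_diameter",
             "fractal_dimension", "spine_length", "neck_length", "neck_width",
             "head_diameter", "head_neck_ratio", "length_width_ratio",
             "width_length_ratio", "int_mean", "int_sd", "int_skewness",
             "int_kurtosis", "int_entropy", "int_cv", "int_range",
             "glcm_contrast", "glcm_homogeneity", "glcm_energy",
             "glcm_correlation", "glcm_entropy", "hog_mean", "hog_sd",
             "hog_kurtosis", "hog_skewness")
  setdiff(all35, c("convex_hull_ratio", "width_length_ratio",
                   "int_cv", "int_range"))
}

#' Assemble a feature table from crops
#'
#' Extracts all feature families from each crop, keeps the requested
#' feature subset, and optionally z-score standardizes the columns. Crops
#' failing extraction are collected in a reject report attached as the
#' `rejects` element, never silently dropped.
#'
#' @param crops list of [spine_crop()].
#' @param standardize z-score standardize columns (default TRUE).
#' @param features feature names to keep (default [default_feature_set()]).
#' @return a [feature_table()]; `rejects` holds `data.frame(id, reason)`.
#' @export
assemble_feature_table <- function(crops, standardize = TRUE,
                                   features = default_feature_set()) {
  stop_if(length(crops) == 0, "empty crop list")
  rows <- list(); rejects <- list()
  for (cr in crops) {
    f <- tryCatch(extract_all_features(cr), error = function(e) e)
    if (inherits(f, "error")) {
      rejects[[length(rejects) + 1]] <-
        data.frame(id = cr$id, reason = conditionMessage(f))
    } else rows[[cr$id]] <- f[features]
  }
  stop_if(length(rows) == 0, "no crop could be feature-extracted")
  vals <- do.call(rbind, rows)
  colnames(vals) <- features
  kept <- names(rows)
  labs <- vapply(crops, function(cr) cr$label %||% NA_character_, "")
  names(labs) <- vapply(crops, `[[`, "", "id")
  labels <- if (all(is.na(labs))) NULL else labs[kept]
  tab <- feature_table(vals, ids = kept, labels = labels)
  if (standardize) tab <- scale_features(tab)
  tab$rejects <- if (length(rejects)) do.call(rbind, rejects) else
    data.frame(id = character(0), reason = character(0))
  tab
}

#' Screen features for discriminative power and redundancy
#'
#' For every feature and class pair a two-sided Mann-Whitney U test is run;
#' features failing `alpha` in all class pairs are flagged
#' non-discriminative. Among feature pairs whose absolute Pearson
#' correlation reaches `corr_threshold` the member with the larger minimum
#' p-value is flagged redundant. Raw p-values are reported by default; a
#' Benjamini-Hochberg switch is provided.
#'
#' @param table a labeled [feature_table()] (>= 2 classes, >= 2 per class).
#' @param alpha significance level (default 0.05).
#' @param corr_threshold absolute correlation for redundancy (default 0.95).
#' @param p_adjust "none" (default) or "BH".
#' @return a `screening_report`: p-value matrix (feature x class pair),
#'   per-feature retained/dropped flags with reasons, redundancy pairs and
#'   the retained feature set.
#' @export
screen_features <- function(table, alpha = 0.05, corr_threshold = 0.95,
                            p_adjust = c("none", "BH")) {
  stopifnot(inherits(table, "feature_table"))
  p_adjust <- match.arg(p_adjust)
  stop_if(is.null(table$labels), "screening requires labels")
  cls <- levels(droplevels(table$labels))
  stop_if(length(cls) < 2, "screening requires >= 2 classes")
  stop_if(any(table(table$labels) < 2), "each class needs >= 2 samples")
  pairs <- utils::combn(cls, 2)
  pmat <- matrix(NA_real_, ncol(table$values), ncol(pairs),
                 dimnames = list(table$feature_names,
                                 apply(pairs, 2, paste, collapse = ":")))
  for (j in seq_len(ncol(pairs))) {
    a <- table$values[table$labels == pairs[1, j], , drop = FALSE]
    b <- table$values[table$labels == pairs[2, j], , drop = FALSE]
    pmat[, j] <- vapply(seq_len(ncol(a)), function(f)
      suppressWarnings(stats::wilcox.test(a[, f], b[, f],
                                          exact = FALSE)$p.value), 0)
  }
  pm <- if (p_adjust == "BH")
    matrix(stats::p.adjust(pmat, "BH"), nrow(pmat),
           dimnames = dimnames(pmat)) else pmat
  nondisc <- apply(pm >= alpha, 1, all)
  minp <- apply(pm, 1, min)
  ## redundancy among still-alive features: drop larger-min-p member
  alive <- table$feature_names[!nondisc]
  C <- stats::cor(table$values[, alive, drop = FALSE])
  redundant <- character(0); red_pairs <- list()
  ord <- alive[order(minp[alive])]          # keep better discriminators first
  for (i in seq_along(ord)) {
    fi <- ord[i]
    if (fi %in% redundant) next
    for (fj in ord[-seq_len(i)]) {
      if (fj %in% redundant) next
      if (abs(C[fi, fj]) >= corr_threshold) {
        redundant <- c(redundant, fj)
        red_pairs[[length(red_pairs) + 1]] <-
          data.frame(kept = fi, dropped = fj, correlation = C[fi, fj])
      }
    }
  }
  status <- ifelse(nondisc, "dropped:non-discriminative",
                   ifelse(table$feature_names %in% redundant,
                          "dropped:redundant", "retained"))
  structure(list(
    p_values = pm, alpha = alpha, corr_threshold = corr_threshold,
    p_adjust = p_adjust,
    flags = data.frame(feature = table$feature_names, status = status,
                       min_p = minp, row.names = NULL),
    redundancy = if (length(red_pairs)) do.call(rbind, red_pairs) else
      data.frame(kept = character(0), dropped = character(0),
                 correlation = numeric(0)),
    retained = table$feature_names[status == "retained"]),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Feature screening: %d retained / %d dropped (alpha = %g)\n",
              length(x$retained), sum(x$flags$status != "retained"), x$alpha))
  print(table(x$flags$status))
  invisible(x)
}
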