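## Synthetic spine generator
##
## Emulates the study conditions the framework is designed for: three spine
## archetypes (mushroom, stubby, thin) on a morphological continuum, class
## imbalance, and a low-resolution degraded variant of the image set.

SPINE_LABELS <- c("mushroom", "stubby", "thin")

#' Define a spine archetype
#'
#' An archetype is a point in feature space (mean vector + covariance)
#' together with the parametric silhouette used to rasterize crops of that
#' class: a near-circular head of radius `head_radius`, a rectangular neck
#' of length `neck_length` and width `neck_width`, and a half-disc shaft
#' junction. Stubby archetypes carry `neck_length` near 0, since stubby
#' spines lack a distinct neck.
#'
#' @param label one of "mushroom", "stubby", "thin".
#' @param feature_means named numeric vector of F feature means.
#' @param feature_cov F x F symmetric positive-semidefinite covariance;
#'   a numeric vector is taken as a diagonal.
#' @param image_params list with `head_radius`, `neck_length`, `neck_width`
#'   (pixels) and `orientation` (radians).
#' @return an `archetype_spec` object.
#' @export
archetype_spec <- function(label, feature_means, feature_cov, image_params) {
  label <- match.arg(label, SPINE_LABELS)
  stop_if(is.null(names(feature_means)), "feature_means must be named")
  if (is.vector(feature_cov) && is.null(dim(feature_cov)))
    feature_cov <- diag(feature_cov, nrow = length(feature_cov))
  feature_cov <- as.matrix(feature_cov)
  stop_if(nrow(feature_cov) != length(feature_means) ||
            ncol(feature_cov) != length(feature_means),
          "feature_cov must be F x F")
  stop_if(max(abs(feature_cov - t(feature_cov))) > 1e-8,
          "feature_cov must be symmetric")
  ev <- eigen(feature_cov, symmetric = TRUE, only.values = TRUE)$values
  stop_if(min(ev) < -1e-8 * max(abs(ev), 1),
          "feature_cov must be positive semi-definite")
  ip <- image_params
  stop_if(is.null(ip$head_radius) || ip$head_radius <= 0,
          "head_radius must be > 0")
  stop_if(is.null(ip$neck_width) || ip$neck_width <= 0,
          "neck_width must be > 0")
  stop_if(is.null(ip$neck_length) || ip$neck_length < 0,
          "neck_length must be >= 0")
  ip$orientation <- ip$orientation %||% pi / 2
  structure(list(label = label, feature_means = feature_means,
                 feature_cov = feature_cov, image_params = ip),
            class = "archetype_spec")
}

#' Default mushroom / stubby / thin archetypes
#'
#' Feature means follow the classical morphological contrasts: mushroom =
#' large head + narrow neck, stubby = neckless and compact, thin = small
#' head + long thin neck with an elongated, more irregular contour. Units
#' are micrometres for lengths (pixel size 0.0193 um/px, a 19.8 um / 1024 px
#' field of view). Per-feature SD defaults to 10% of the across-archetype
#' range, a clean-imaging noise regime.
#'
#' @param noise_scale multiplier on the default per-feature SD.
#' @return named list of three [archetype_spec()] objects.
#' @export
default_archetypes <- function(noise_scale = 1) {
  means <- rbind(
    mushroom = c(head_diameter = 1.20, neck_length = 0.80, neck_width = 0.25,
                 area = 1.10, circularity = 0.85, eccentricity = 0.45,
                 solidity = 0.95, aspect_ratio = 1.40, length_width_ratio = 1.8,
                 int_mean = 0.75, glcm_contrast = 8, fractal_dimension = 1.10),
    stubby   = c(head_diameter = 0.80, neck_length = 0.10, neck_width = 0.60,
                 area = 0.70, circularity = 0.92, eccentricity = 0.35,
                 solidity = 0.97, aspect_ratio = 1.10, length_width_ratio = 1.1,
                 int_mean = 0.65, glcm_contrast = 5, fractal_dimension = 1.05),
    thin     = c(head_diameter = 0.45, neck_length = 1.50, neck_width = 0.15,
                 area = 0.40, circularity = 0.55, eccentricity = 0.85,
                 solidity = 0.80, aspect_ratio = 2.80, length_width_ratio = 4.0,
                 int_mean = 0.50, glcm_contrast = 12, fractal_dimension = 1.25))
  rng <- apply(means, 2, function(v) diff(range(v)))
  sds <- 0.10 * noise_scale * rng
  ip <- list(
    mushroom = list(head_radius = 31, neck_length = 41, neck_width = 13,
                    orientation = pi / 2),
    stubby   = list(head_radius = 21, neck_length = 3, neck_width = 31,
                    orientation = pi / 2),
    thin     = list(head_radius = 12, neck_length = 78, neck_width = 8,
                    orientation = pi / 2))
  out <- lapply(SPINE_LABELS, function(lb)
    archetype_spec(lb, means[lb, ], sds^2, ip[[lb]]))
  names(out) <- SPINE_LABELS
  out
}

#' Default class-imbalance preset
#'
#' Mirrors the natural ordering of spine-type prevalence (more mushroom and
#' stubby examples than thin) with a 3:2:1 ratio.
#'
#' @param n total number of spines.
#' @return named integer vector of per-class counts summing to `n`.
#' @export
default_imbalance <- function(n = 300) {
  w <- c(mushroom = 3, stubby = 2, thin = 1) / 6
  cnt <- floor(n * w)
  rem <- n - sum(cnt)
  if (rem > 0) cnt[seq_len(rem)] <- cnt[seq_len(rem)] + 1L
  cnt
}

## draw one multivariate normal sample set given a covariance (PSD-safe)
rmvn <- function(n, mu, Sigma) {
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values))
  z <- matrix(stats::rnorm(n * length(mu)), n)
  sweep(z %*% t(L), 2, mu, "+")
}

#' Generate a labeled feature table along the morphological continuum
#'
#' Draws spines at archetype feature means plus archetype-specific Gaussian
#' noise. A `mixing_fraction` share of each class is transitional: drawn on
#' the line segment between its own archetype mean and a randomly chosen
#' partner archetype, at a latent position `t ~ U(0, 0.5)` so the point
#' remains on its own side of the segment midpoint and its class label keeps
#' its meaning. The latent position is recorded in the `latent_t` element.
#'
#' @param n_per_class named integer vector of counts per label.
#' @param archetypes list of [archetype_spec()] covering all requested labels.
#' @param mixing_fraction share of transitional spines per class, in [0, 1].
#' @param seed integer seed; identical seeds give identical tables.
#' @return a [feature_table()] with labels and a `latent_t` vector
#'   (0 for pure archetype draws).
#' @export
generate_feature_continuum <- function(n_per_class = default_imbalance(300),
                                       archetypes = default_archetypes(),
                                       mixing_fraction = 0.2, seed = 1) {
  check_number(mixing_fraction, "mixing_fraction", 0, 1)
  stop_if(any(n_per_class < 0), "counts must be >= 0")
  names(archetypes) <- vapply(archetypes, `[[`, "", "label")
  missing <- setdiff(names(n_per_class), names(archetypes))
  stop_if(length(missing) > 0,
          paste("unknown label(s):", paste(missing, collapse = ", ")))
  with_seed(seed, {
    rows <- list(); labs <- character(0); tt <- numeric(0)
    for (lb in names(n_per_class)) {
      n <- as.integer(n_per_class[[lb]])
      if (n == 0) next
      a <- archetypes[[lb]]
      n_mix <- round(mixing_fraction * n)
      mu <- matrix(rep(a$feature_means, n), n, byrow = TRUE)
      t_i <- rep(0, n)
      if (n_mix > 0) {
        others <- setdiff(names(archetypes), lb)
        idx <- seq_len(n_mix)
        partner <- sample(others, n_mix, replace = TRUE)
        t_i[idx] <- stats::runif(n_mix, 0, 0.5)
        for (j in idx) {
          pm <- archetypes[[partner[j]]]$feature_means
          mu[j, ] <- (1 - t_i[j]) * a$feature_means + t_i[j] * pm
        }
      }
      noise <- rmvn(n, rep(0, length(a$feature_means)), a$feature_cov)
      rows[[lb]] <- mu + noise
      labs <- c(labs, rep(lb, n))
      tt <- c(tt, t_i)
    }
    vals <- do.call(rbind, rows)
    colnames(vals) <- names(archetypes[[1]]$feature_means)
    out <- feature_table(vals, ids = sprintf("spine_%04d", seq_len(nrow(vals))),
                         labels = factor(labs, levels = SPINE_LABELS))
    out$latent_t <- tt
    out$seed <- seed
    out
  })
}

## --- parametric spine images -------------------------------------------

## silhouette indicator on pixel centers: head ellipse (axis ratio 0.92)
## joined to a neck rectangle and a half-disc shaft junction, rotated by
## `orientation` and centered in the crop
rasterize_spine <- function(params, size, brightness = NULL) {
  hr <- params$head_radius; nl <- params$neck_length
  nw <- params$neck_width; th <- params$orientation
  shaft_r <- max(nw * 0.7, 6)
  len <- nl + 2 * hr                    # attachment (0) to head tip
  ext <- len + shaft_r                  # full extent incl. shaft stub
  lat <- 2 * (max(hr, nw / 2, shaft_r) + abs(params$bend %||% 0) * len)
  stop_if(ext + 2 > size || lat + 2 > size,
          sprintf(paste("spine geometry (extent %.1f px) exceeds the",
                        "%d px crop"), max(ext, lat), size))
  cx <- (size + 1) / 2; cy <- (size + 1) / 2
  ## attachment point so that the silhouette midline is crop-centered
  ax <- cx - cos(th) * (len - shaft_r) / 2
  ay <- cy - sin(th) * (len - shaft_r) / 2
  xs <- matrix(rep(seq_len(size), size), size)        # column index
  ys <- t(xs)                                          # row index
  ## axial (u, along spine) / lateral (v) coordinates; an optional
  ## quadratic bend curves the neck the way real spines curve
  bend <- params$bend %||% 0
  u <- (xs - ax) * cos(th) + (ys - ay) * sin(th)
  v <- -(xs - ax) * sin(th) + (ys - ay) * cos(th)
  v <- v - bend * pmax(u, 0)^2 / max(len, 1)
  ## the neck rectangle reaches the head centre so the silhouette stays
  ## connected even at neck_length = 0 (stubby: head sits on the shaft)
  neck <- u >= 0 & u <= nl + hr & abs(v) <= nw / 2
  hu <- u - (nl + hr)
  head <- (hu / hr)^2 + (v / (0.95 * hr))^2 <= 1
  shaft <- u <= 0 & (u^2 + v^2) <= shaft_r^2
  mask <- neck | head | shaft
  ## intensity plateaus: head brightest, neck dimmer (2PLSM-like contrast);
  ## per-crop brightness levels and a weak background fluorescence plane
  ## emulate illumination variability across an imaging session
  b <- brightness %||% list(head = 0.90, neck = 0.60, shaft = 0.70,
                            bg = c(0, 0, 0))
  inten <- matrix(b$bg[1], size, size) +
    b$bg[2] * (xs - cx) / size + b$bg[3] * (ys - cy) / size
  inten[shaft] <- b$shaft
  inten[neck] <- b$neck
  inten[head] <- b$head
  inten <- pmax(inten, 0)
  list(mask = mask, intensity = inten,
       head_center = c(ax + cos(th) * (nl + hr), ay + sin(th) * (nl + hr)))
}

## separable Gaussian blur, replicate padding
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma); k <- k / sum(k)
  pad_conv <- function(m) {
    n <- nrow(m)
    mp <- rbind(m[rep(1, r), , drop = FALSE], m,
                m[rep(n, r), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img))))
}

#' Generate a synthetic spine image set
#'
#' Rasterizes parametric spine silhouettes (head ellipse + neck rectangle +
#' half-disc shaft junction), applies a Gaussian point-spread blur and
#' additive Gaussian noise to the intensity channel, and keeps the clean
#' silhouette as the binary mask. Per-spine geometry is jittered around the
#' archetype image parameters (8% relative SD) and the orientation is drawn
#' uniformly; ground-truth parameters are stored with every crop.
#'
#' @param n number of spines.
#' @param archetypes list of [archetype_spec()].
#' @param noise_sd additive Gaussian noise SD (intensity units, image in
#'   \[0, 1\]).
#' @param psf_sigma Gaussian blur SD in pixels (>= 0).
#' @param seed integer seed.
#' @param size crop side in pixels.
#' @param proportions per-class sampling weights (default 3:2:1 imbalance).
#' @param pixel_size micrometres per pixel.
#' @param jitter relative SD of per-spine geometry jitter (0 disables).
#' @return a `spine_set`: list of [spine_crop()] with `labels`, `latent_t`,
#'   `params` (ground truth per crop) and `seed`.
#' @export
generate_spine_image_set <- function(n, archetypes = default_archetypes(),
                                     noise_sd = 0.02, psf_sigma = 1.5,
                                     seed = 1, size = 128,
                                     proportions = c(mushroom = 3, stubby = 2,
                                                     thin = 1),
                                     pixel_size = 0.0193, jitter = 0.08) {
  check_count(n, "n"); check_number(psf_sigma, "psf_sigma", 0)
  check_number(noise_sd, "noise_sd", 0)
  names(archetypes) <- vapply(archetypes, `[[`, "", "label")
  with_seed(seed, {
    labs <- rep(names(proportions), diff(round(cumsum(c(0, proportions)) /
                                                 sum(proportions) * n)))
    labs <- factor(labs, levels = SPINE_LABELS)
    crops <- vector("list", n); truth <- vector("list", n)
    for (i in seq_len(n)) {
      a <- archetypes[[as.character(labs[i])]]
      p <- a$image_params
      sub <- 0L
      if (jitter > 0) {
        ## within-class variability is a continuum of sub-morphologies:
        ## head size, neck length/width, neck curvature, brightness and
        ## optics vary independently, emulating the morphological spectrum
        ## real spine populations show within each named class
        sub <- sample.int(3L, 1L)           # brightness regime
        p$head_radius <- max(4, p$head_radius *
                               (1 + stats::rnorm(1, 0, 2 * jitter)))
        p$neck_length <- max(0, p$neck_length *
                               (1 + stats::rnorm(1, 0, 3 * jitter)))
        p$neck_width <- max(2, p$neck_width * (1 + stats::rnorm(1, 0, jitter)))
        p$orientation <- stats::runif(1, 0, 2 * pi)
        p$bend <- max(-0.3, min(0.3, stats::rnorm(1, 0, 0.15)))
      }
      ## shrink jittered geometry that would spill over the crop margin
      ext_of <- function(q) {
        len <- q$neck_length + 2 * q$head_radius
        shaft_r <- max(q$neck_width * 0.7, 6)
        lat <- 2 * (max(q$head_radius, q$neck_width / 2, shaft_r) +
                      abs(q$bend %||% 0) * (len + shaft_r))
        max(len + shaft_r + 3, lat + 3)
      }
      while (ext_of(p) > size) {
        p$head_radius <- p$head_radius * 0.95
        p$neck_length <- p$neck_length * 0.95
        p$neck_width <- p$neck_width * 0.95
        if (!is.null(p$bend)) p$bend <- p$bend * 0.9
      }
      bright <- if (jitter > 0) {
        hb <- stats::runif(1, 0.72 + 0.09 * sub, 0.81 + 0.09 * sub)
        list(head = hb, neck = hb * stats::runif(1, 0.55, 0.8),
             shaft = hb * stats::runif(1, 0.65, 0.9),
             bg = c(stats::runif(1, 0, 0.08),
                    stats::rnorm(2, 0, 0.04)))
      } else NULL
      psf_i <- if (jitter > 0)
        max(0, psf_sigma * (1 + stats::rnorm(1, 0, jitter))) else psf_sigma
      p$subtype <- sub
      ras <- rasterize_spine(p, size, brightness = bright)
      img <- gaussian_blur(ras$intensity, psf_i)
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(size^2, 0, noise_sd), size)
      img <- pmin(pmax(img, 0), 1)
      crops[[i]] <- spine_crop(img, ras$mask, pixel_size = pixel_size,
                               label = as.character(labs[i]),
                               id = sprintf("spine_%04d", i))
      truth[[i]] <- p
    }
    structure(list(crops = crops, labels = labs,
                   latent_t = rep(0, n), params = truth, seed = seed),
              class = "spine_set")
  })
}

#' @export
print.spine_set <- function(x, ...) {
  cat(sprintf("Synthetic spine set: %d crops (%s px)\n", length(x$crops),
              paste(dim(x$crops[[1]]$intensity), collapse = " x ")))
  print(table(labels = x$labels))
  invisible(x)
}

## block-mean downsample of a matrix by integer factor
block_reduce <- function(m, f, fun = mean) {
  n1 <- floor(nrow(m) / f) * f; n2 <- floor(ncol(m) / f) * f
  m <- m[seq_len(n1), seq_len(n2), drop = FALSE]
  a <- array(m, dim = c(f, n1 / f, f, n2 / f))
  apply(a, c(2, 4), fun)
}

#' Degrade a spine image set (resolution + noise)
#'
#' Emulates a low-resolution acquisition: images are block-mean downsampled
#' by an integer factor (e.g. a 1024 px field reduced by 8 becomes 128 px)
#' and re-noised; masks are downsampled by majority vote with ties counted
#' as foreground so that thin necks survive. Labels, ids, latent positions
#' and ground-truth parameters are preserved.
#'
#' @param set a `spine_set` from [generate_spine_image_set()].
#' @param downsample integer factor >= 1.
#' @param extra_noise_sd additional Gaussian noise SD after downsampling.
#' @param seed integer seed for the added noise.
#' @return a degraded `spine_set`.
#' @export
degrade_image_set <- function(set, downsample = 4, extra_noise_sd = 0.05,
                              seed = 1) {
  stopifnot(inherits(set, "spine_set"))
  downsample <- check_count(downsample, "downsample")
  side <- nrow(set$crops[[1]]$intensity)
  stop_if(downsample > side, "downsample factor exceeds the image side")
  if (downsample == 1 && extra_noise_sd == 0) return(set)
  with_seed(seed, {
    out <- set
    out$crops <- lapply(set$crops, function(cr) {
      img <- cr$intensity; msk <- cr$mask
      if (downsample > 1) {
        img <- block_reduce(img, downsample)
        msk <- block_reduce(msk * 1, downsample) >= 0.5   # ties -> foreground
      }
      if (extra_noise_sd > 0) {
        img <- img + matrix(stats::rnorm(length(img), 0, extra_noise_sd),
                            nrow(img))
        img <- pmin(pmax(img, 0), 1)
      }
      spine_crop(img, msk, pixel_size = cr$pixel_size * downsample,
                 label = cr$label, id = cr$id)
    })
    out$degraded <- list(downsample = downsample,
                         extra_noise_sd = extra_noise_sd, seed = seed)
    out
  })
}

#' Write a spine set as TIFF pairs plus a manifest CSV
#'
#' Each crop is saved as a 16-bit grayscale TIFF with a matching mask TIFF;
#' the manifest lists `id,label,latent_t,image_path,mask_path` and the
#' ground-truth geometry columns.
#'
#' @param set a `spine_set`.
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_spine_set <- function(set, dir) {
  stopifnot(inherits(set, "spine_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(set$crops), function(i) {
    cr <- set$crops[[i]]
    ip <- file.path(dir, paste0(cr$id, ".tif"))
    mp <- file.path(dir, paste0(cr$id, "_mask.tif"))
    tiff::writeTIFF(cr$intensity, ip, bits.per.sample = 16)
    tiff::writeTIFF(cr$mask * 1, mp, bits.per.sample = 16)
    p <- set$params[[i]] %||% list(head_radius = NA, neck_length = NA,
                                   neck_width = NA, orientation = NA)
    data.frame(id = cr$id, label = cr$label %||% NA,
               latent_t = set$latent_t[i],
               image_path = basename(ip), mask_path = basename(mp),
               pixel_size = cr$pixel_size,
               head_radius = p$head_radius, neck_length = p$neck_length,
               neck_width = p$neck_width, orientation = p$orientation)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a spine set from a manifest CSV
#'
#' Accepts the schema written by [write_spine_set()] (or a user manifest
#' with the same columns); paths are resolved relative to the manifest.
#'
#' @param manifest path to the manifest CSV.
#' @return a `spine_set`.
#' @export
read_spine_manifest <- function(manifest) {
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("id", "image_path", "mask_path")
  stop_if(!all(need %in% names(df)),
          paste("manifest must contain columns:", paste(need, collapse = ", ")))
  base <- dirname(manifest)
  crops <- lapply(seq_len(nrow(df)), function(i) {
    img <- tiff::readTIFF(file.path(base, df$image_path[i]))
    msk <- tiff::readTIFF(file.path(base, df$mask_path[i])) > 0.5
    spine_crop(img, msk,
               pixel_size = if ("pixel_size" %in% names(df))
                 df$pixel_size[i] else 1,
               label = if ("label" %in% names(df)) df$label[i] else NULL,
               id = df$id[i])
  })
  labs <- if ("label" %in% names(df))
    factor(df$label, levels = union(SPINE_LABELS, unique(df$label))) else NULL
  structure(list(crops = crops, labels = labs,
                 latent_t = if ("latent_t" %in% names(df)) df$latent_t
                 else rep(NA_real_, nrow(df)),
                 params = NULL, seed = NA_integer_),
            class = "spine_set")
}
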