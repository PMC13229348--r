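# Small programmatic fixtures shared across test files.

# c well-separated isotropic Gaussian blobs in d dimensions
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(k)
    sweep(matrix(rnorm(n_per * ncol(centers), 0, sd), n_per), 2,
          centers[k, ], `+`)))
  list(X = X, lab = rep(seq_len(nrow(centers)), each = n_per))
}

# a filled disk mask of radius r centred in a square crop
disk_mask <- function(r, pad = 10) {
  side <- 2 * r + 2 * pad
  ctr <- (side + 1) / 2
  outer(seq_len(side), seq_len(side),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

# parametric spine crop with exact geometry (no jitter, no noise)
make_spine_crop <- function(head_radius, neck_length, neck_width,
                            orientation = pi / 2, size = 96, psf = 0,
                            noise = 0, pixel_size = 1, id = "fix") {
  ras <- spinemorph:::rasterize_spine(
    list(head_radius = head_radius, neck_length = neck_length,
         neck_width = neck_width, orientation = orientation), size)
  img <- spinemorph:::gaussian_blur(ras$intensity, psf)
  if (noise > 0) img <- pmax(img + matrix(rnorm(size^2, 0, noise), size), 0)
  spine_crop(img, ras$mask, pixel_size = pixel_size, id = id)
}

# rotate a matrix by 90 degrees clockwise (rotation-invariance checks)
rot90 <- function(m) t(apply(m, 2, rev))
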