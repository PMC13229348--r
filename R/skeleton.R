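## Binary-mask skeletonization and path extraction used by the geometry
## feature family. Zhang-Suen thinning, vectorized over whole-image shifts.

shift_mat <- function(m, dr, dc) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(0L, n1, n2)
  rs <- max(1, 1 + dr):min(n1, n1 + dr)
  cs <- max(1, 1 + dc):min(n2, n2 + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
## rows increase downwards ("north" = row - 1)
zs_neighbours <- function(m) {
  list(p2 = shift_mat(m, 1, 0),  p3 = shift_mat(m, 1, -1),
       p4 = shift_mat(m, 0, -1), p5 = shift_mat(m, -1, -1),
       p6 = shift_mat(m, -1, 0), p7 = shift_mat(m, -1, 1),
       p8 = shift_mat(m, 0, 1),  p9 = shift_mat(m, 1, 1))
}

#' Skeletonize a binary mask (Zhang-Suen thinning)
#'
#' @param mask logical matrix.
#' @return logical matrix of the one-pixel-wide skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      nb <- zs_neighbours(m)
      B <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      A <- (nb$p2 == 0 & nb$p3 == 1) + (nb$p3 == 0 & nb$p4 == 1) +
        (nb$p4 == 0 & nb$p5 == 1) + (nb$p5 == 0 & nb$p6 == 1) +
        (nb$p6 == 0 & nb$p7 == 1) + (nb$p7 == 0 & nb$p8 == 1) +
        (nb$p8 == 0 & nb$p9 == 1) + (nb$p9 == 0 & nb$p2 == 1)
      if (pass == 1) {
        c1 <- nb$p2 * nb$p4 * nb$p6
        c2 <- nb$p4 * nb$p6 * nb$p8
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8
        c2 <- nb$p2 * nb$p6 * nb$p8
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & c1 == 0 & c2 == 0
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

## exact Euclidean distance transform: distance from each foreground pixel
## to the nearest background pixel (pixels outside the matrix count as
## background), via nearest-neighbour search on boundary background pixels
distance_transform <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  padded <- matrix(FALSE, n1 + 2, n2 + 2)
  padded[2:(n1 + 1), 2:(n2 + 1)] <- mask
  ## background pixels 4-adjacent to foreground
  fg4 <- shift_mat(padded * 1L, 1, 0) + shift_mat(padded * 1L, -1, 0) +
    shift_mat(padded * 1L, 0, 1) + shift_mat(padded * 1L, 0, -1)
  bnd <- which(!padded & fg4 > 0, arr.ind = TRUE)
  out <- matrix(0, n1, n2)
  fg <- which(mask, arr.ind = TRUE)
  if (nrow(fg) == 0 || nrow(bnd) == 0) return(out)
  nn <- FNN::get.knnx(bnd, cbind(fg[, 1] + 1, fg[, 2] + 1), k = 1)
  out[fg] <- nn$nn.dist[, 1]
  out
}

## weighted 8-connectivity graph over skeleton pixels (steps cost 1 / sqrt 2)
skeleton_graph <- function(skel) {
  px <- which(skel, arr.ind = TRUE)
  n <- nrow(px)
  key <- px[, 1] + nrow(skel) * (px[, 2] - 1)
  idx <- stats::setNames(seq_len(n), key)
  edges <- list(); wts <- numeric(0)
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nb_key <- (px[, 1] + d[1]) + nrow(skel) * (px[, 2] + d[2] - 1)
    j <- idx[as.character(nb_key)]
    hit <- !is.na(j)
    if (any(hit)) {
      edges[[length(edges) + 1]] <- rbind(which(hit), j[hit])
      wts <- c(wts, rep(sqrt(sum(d^2)), sum(hit)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0)
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)), weight = wts)
  list(graph = g, pixels = px)
}

## geodesic path between two skeleton-pixel graph nodes
skeleton_path <- function(sg, i_from, i_to) {
  sp <- suppressWarnings(igraph::shortest_paths(sg$graph, i_from, i_to,
                                                output = "vpath"))
  vp <- sp$vpath[[1]]
  if (length(vp) < 2) return(list(pixels = sg$pixels[as.integer(vp), ,
                                                     drop = FALSE], length = 0))
  path <- sg$pixels[as.integer(vp), , drop = FALSE]
  ## measure along a stride-resampled polyline: the raw 8-connected chain
  ## overestimates the Euclidean length of oblique segments by up to ~8%
  idx <- unique(c(seq(1, nrow(path), by = 4), nrow(path)))
  poly <- path[idx, , drop = FALSE]
  steps <- sqrt(rowSums((poly[-1, , drop = FALSE] -
                           poly[-nrow(poly), , drop = FALSE])^2))
  list(pixels = path, length = sum(steps))
}

## graph-node index of the skeleton pixel nearest a (row, col) target
nearest_skeleton_node <- function(sg, target) {
  d <- (sg$pixels[, 1] - target[1])^2 + (sg$pixels[, 2] - target[2])^2
  which.min(d)
}
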