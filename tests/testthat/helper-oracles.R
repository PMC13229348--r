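# Independent brute-force reference implementations used to validate the
# package's metric code. Deliberately written as plain double loops over
# textbook formulas, sharing no code with the package internals.

euc <- function(a, b) sqrt(sum((a - b)^2))

dist_mat <- function(X) {
  n <- nrow(X)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- euc(X[i, ], X[j, ])
  D
}

# k nearest neighbours of i, ties by index
oracle_knn <- function(D, i, k) {
  d <- D[i, ]
  ord <- order(d, seq_along(d))
  setdiff(ord, i)[1:k]
}

# rank of j among i's neighbours: 1 + number of points strictly closer,
# plus earlier-indexed ties
oracle_rank <- function(D, i, j) {
  d <- D[i, -i]
  idx <- setdiff(seq_len(ncol(D)), i)
  dj <- D[i, j]
  sum(d < dj) + sum(d == dj & idx < j) + 1
}

oracle_trustworthiness <- function(X, Y, k) {
  n <- nrow(X)
  DX <- dist_mat(X); DY <- dist_mat(Y)
  pen <- 0
  for (i in seq_len(n))
    for (j in oracle_knn(DY, i, k))
      pen <- pen + max(0, oracle_rank(DX, i, j) - k)
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * pen
}

oracle_lcmc <- function(X, Y, k) {
  n <- nrow(X)
  DX <- dist_mat(X); DY <- dist_mat(Y)
  tot <- 0
  for (i in seq_len(n))
    tot <- tot + length(intersect(oracle_knn(DX, i, k),
                                  oracle_knn(DY, i, k)))
  tot / (k * n)
}

oracle_silhouette <- function(Y, lab) {
  n <- nrow(Y)
  D <- dist_mat(Y)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(D[i, lab == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

oracle_db <- function(Y, lab) {
  ks <- sort(unique(lab))
  cent <- lapply(ks, function(k) colMeans(Y[lab == k, , drop = FALSE]))
  s <- vapply(seq_along(ks), function(j) {
    pts <- Y[lab == ks[j], , drop = FALSE]
    mean(apply(pts, 1, euc, b = cent[[j]]))
  }, 0)
  tot <- 0
  for (i in seq_along(ks)) {
    best <- -Inf
    for (j in seq_along(ks)) if (j != i)
      best <- max(best, (s[i] + s[j]) / euc(cent[[i]], cent[[j]]))
    tot <- tot + best
  }
  tot / length(ks)
}

oracle_ch <- function(Y, lab) {
  ks <- sort(unique(lab))
  n <- nrow(Y); K <- length(ks)
  gm <- colMeans(Y)
  trB <- trW <- 0
  for (k in ks) {
    pts <- Y[lab == k, , drop = FALSE]
    ck <- colMeans(pts)
    trB <- trB + nrow(pts) * sum((ck - gm)^2)
    for (i in seq_len(nrow(pts))) trW <- trW + sum((pts[i, ] - ck)^2)
  }
  if (trB == 0) return(0)
  (trB / trW) * (n - K) / (K - 1)
}

oracle_soft <- function(M) {
  n <- nrow(M); K <- ncol(M)
  H <- numeric(n)
  for (i in seq_len(n))
    for (k in seq_len(K))
      if (M[i, k] > 0) H[i] <- H[i] - M[i, k] * log(M[i, k])
  c(avg_entropy = mean(H),
    avg_sharpness = mean(1 - H / log(K)),
    avg_max_prob = mean(apply(M, 1, max)))
}

oracle_bts <- function(Y, lab, W, k, epsilon = 1e-6) {
  D <- dist_mat(Y)
  num <- den <- 0
  for (i in seq_len(nrow(Y)))
    for (j in oracle_knn(D, i, k)) {
      w <- W[lab[i], lab[j]]
      d <- max(D[i, j], epsilon)
      num <- num + w / log(d + 1)
      den <- den + w
    }
  num / den
}

# naive Ward agglomeration under D(A,B) = |A||B|/(|A|+|B|) ||mu_A - mu_B||^2
oracle_ward_labels <- function(Y, K) {
  groups <- lapply(seq_len(nrow(Y)), identity)
  while (length(groups) > K) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(groups)) for (b in seq_along(groups)) if (a < b) {
      ma <- colMeans(Y[groups[[a]], , drop = FALSE])
      mb <- colMeans(Y[groups[[b]], , drop = FALSE])
      cost <- length(groups[[a]]) * length(groups[[b]]) /
        (length(groups[[a]]) + length(groups[[b]])) * sum((ma - mb)^2)
      if (cost < best[1]) best <- c(cost, a, b)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups <- groups[-best[3]]
  }
  lab <- integer(nrow(Y))
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# overlap coefficient of two 2D product-Gaussian KDEs on a dense grid
oracle_kde_overlap_grid <- function(xa, xb, ngrid = 120) {
  scott <- function(x) apply(x, 2, sd) * nrow(x)^(-1 / (ncol(x) + 4))
  ha <- scott(xa); hb <- scott(xb)
  dens <- function(x, h, q1, q2) {
    out <- 0
    for (j in seq_len(nrow(x)))
      out <- out + dnorm(q1, x[j, 1], h[1]) * dnorm(q2, x[j, 2], h[2])
    out / nrow(x)
  }
  lo <- pmin(apply(xa, 2, min), apply(xb, 2, min)) - 4 * pmax(ha, hb)
  hi <- pmax(apply(xa, 2, max), apply(xb, 2, max)) + 4 * pmax(ha, hb)
  g1 <- seq(lo[1], hi[1], length.out = ngrid)
  g2 <- seq(lo[2], hi[2], length.out = ngrid)
  q <- expand.grid(g1, g2)
  pa <- dens(xa, ha, q[, 1], q[, 2])
  pb <- dens(xb, hb, q[, 1], q[, 2])
  sum(pmin(pa, pb)) * diff(g1[1:2]) * diff(g2[1:2])
}
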