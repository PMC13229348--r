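## Clustering on an embedding: Ward agglomeration, fuzzy c-means and
## Gaussian-mixture EM with soft partitions, cluster-number diagnostics
## (silhouette first peak, CHull elbow, Davies-Bouldin, size balance) and
## hard / soft validity metrics.

new_partition <- function(membership, method, converged = TRUE, n_iter = 0L,
                          objective_trace = numeric(0), seed = NA_integer_,
                          extra = list()) {
  membership <- as.matrix(membership)
  stop_if(any(membership < -1e-12) || any(membership > 1 + 1e-12),
          "memberships must lie in [0, 1]")
  rs <- rowSums(membership)
  stop_if(any(abs(rs - 1) > 1e-9), "membership rows must sum to 1")
  structure(c(list(membership = membership,
                   hard_labels = max.col(membership, ties.method = "first"),
                   K = ncol(membership), method = method,
                   converged = converged, n_iter = n_iter,
                   objective_trace = objective_trace, seed = seed), extra),
            class = "soft_partition")
}

#' @export
print.soft_partition <- function(x, ...) {
  cat(sprintf("%s partition: N = %d, K = %d%s\n", x$method,
              nrow(x$membership), x$K,
              if (x$method == "ward") "" else
                sprintf(", %sconverged in %d iter",
                        if (x$converged) "" else "NOT ", x$n_iter)))
  print(table(cluster = x$hard_labels))
  invisible(x)
}

#' Ward hierarchical clustering
#'
#' Agglomerative clustering under Ward's criterion
#' `D(A, B) = |A||B| / (|A| + |B|) * ||mu_A - mu_B||^2` with Euclidean
#' distances, cut at `K` clusters. Memberships are exactly one-hot. The
#' recorded `merge_costs` are the Ward criterion values of each merge
#' (hclust "ward.D2" heights `h` transformed by `h^2 / 2`, an exact
#' identity for this linkage).
#'
#' @param low embedding or coordinate matrix.
#' @param K number of clusters, 1 <= K <= N.
#' @return a one-hot `soft_partition` with a `merge_costs` element.
#' @export
ward_cluster <- function(low, K) {
  Y <- coords_of(low)
  K <- check_count(K, "K")
  stop_if(K > nrow(Y), "K must be <= N")
  hc <- stats::hclust(stats::dist(Y), method = "ward.D2")
  lab <- stats::cutree(hc, k = K)
  M <- matrix(0, nrow(Y), K)
  M[cbind(seq_len(nrow(Y)), lab)] <- 1
  new_partition(M, "ward", extra = list(merge_costs = hc$height^2 / 2,
                                        hclust = hc))
}

#' Fuzzy c-means configuration
#'
#' @param m fuzzifier > 1 controlling membership softness (default 2).
#' @param tol stop when the largest membership change falls below this.
#' @param max_iter iteration cap.
#' @param seed integer seed for the Dirichlet-random initial memberships.
#' @return an `fcm_config` list.
#' @export
fcm_config <- function(m = 2, tol = 1e-6, max_iter = 300, seed = 1) {
  check_number(m, "m"); stop_if(m <= 1, "fuzzifier m must be > 1")
  list(m = m, tol = tol, max_iter = max_iter, seed = seed)
}

#' Fuzzy c-means clustering
#'
#' Minimizes `J_m = sum_i sum_k u_ik^m ||z_i - c_k||^2` by alternating
#' centroid updates `c_k = sum u^m z / sum u^m` and membership updates
#' `u_ik = 1 / sum_j (||z_i - c_k|| / ||z_i - c_j||)^(2 / (m - 1))`,
#' starting from seeded Dirichlet-random memberships. Points coinciding
#' with a centroid get full membership there (split equally over ties).
#' The objective trace is recorded; non-convergence at `max_iter` is
#' returned with `converged = FALSE`, not raised.
#'
#' @param low embedding or coordinate matrix.
#' @param K number of clusters (>= 2, < N).
#' @param cfg an [fcm_config()].
#' @return a `soft_partition` with `centroids` and `objective_trace`.
#' @export
fcm_cluster <- function(low, K, cfg = fcm_config()) {
  Y <- coords_of(low)
  n <- nrow(Y)
  K <- check_count(K, "K")
  stop_if(K < 2, "K must be >= 2")
  stop_if(n <= K, "need N > K")
  m <- cfg$m
  U <- with_seed(cfg$seed, {
    g <- matrix(stats::rgamma(n * K, 1), n)
    g / rowSums(g)
  })
  trace <- numeric(0)
  conv <- FALSE
  it <- 0
  C <- NULL
  while (it < cfg$max_iter) {
    it <- it + 1
    Um <- U^m
    C <- sweep(crossprod(Um, Y), 1, colSums(Um), "/")
    D2 <- outer(rowSums(Y^2), rep(1, K)) + outer(rep(1, n), rowSums(C^2)) -
      2 * Y %*% t(C)
    D2[D2 < 0] <- 0
    Unew <- matrix(0, n, K)
    zero <- D2 < 1e-24
    hit <- rowSums(zero) > 0
    if (any(hit))                          # coincident with >= 1 centroid
      Unew[hit, ] <- zero[hit, , drop = FALSE] /
        rowSums(zero[hit, , drop = FALSE])
    if (any(!hit)) {
      P <- D2[!hit, , drop = FALSE]^(-1 / (m - 1))
      Unew[!hit, ] <- P / rowSums(P)
    }
    trace <- c(trace, sum(Unew^m * D2))
    delta <- max(abs(Unew - U))
    U <- Unew
    if (delta < cfg$tol) { conv <- TRUE; break }
  }
  new_partition(U, "fcm", converged = conv, n_iter = it,
                objective_trace = trace, seed = cfg$seed,
                extra = list(centroids = C, m = m))
}

#' Gaussian mixture configuration
#'
#' @param K number of components.
#' @param covariance "full" or "diagonal".
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @param n_init number of seeded restarts; the best log-likelihood wins.
#' @param seed integer seed.
#' @return a `gmm_config` list.
#' @export
gmm_config <- function(K, covariance = c("full", "diagonal"), tol = 1e-8,
                       max_iter = 200, n_init = 5, seed = 1) {
  K <- check_count(K, "K")
  list(K = K, covariance = match.arg(covariance), tol = tol,
       max_iter = max_iter, n_init = n_init, seed = seed)
}

## log multivariate normal density, covariance pre-factorized
log_dmvnorm <- function(Y, mu, chl) {
  z <- forwardsolve(t(chl), t(Y) - mu)
  -0.5 * colSums(z^2) - sum(log(diag(chl))) - ncol(Y) / 2 * log(2 * pi)
}

## responsibilities from explicit parameters (also the test hook for
## symmetric-component behaviour)
gmm_responsibilities <- function(Y, pi_k, mu_list, sigma_list) {
  K <- length(pi_k)
  lg <- vapply(seq_len(K), function(k) {
    chl <- chol(sigma_list[[k]])
    log(pi_k[k]) + log_dmvnorm(Y, mu_list[[k]], chl)
  }, numeric(nrow(Y)))
  mx <- apply(lg, 1, max)
  w <- exp(lg - mx)
  list(gamma = w / rowSums(w),
       loglik = sum(mx + log(rowSums(w))))
}

gmm_em_once <- function(Y, cfg, init_idx) {
  n <- nrow(Y); d <- ncol(Y); K <- cfg$K
  reg <- diag(1e-6, d)
  ## seeded centroid sample + one-step nearest assignment
  mu <- lapply(init_idx, function(i) Y[i, ])
  D2 <- vapply(mu, function(m) rowSums(sweep(Y, 2, m)^2), numeric(n))
  assign0 <- max.col(-D2, ties.method = "first")
  pi_k <- pmax(tabulate(assign0, K), 1) / sum(pmax(tabulate(assign0, K), 1))
  sigma <- lapply(seq_len(K), function(k) {
    pts <- Y[assign0 == k, , drop = FALSE]
    if (nrow(pts) > d) stats::cov(pts) + reg else diag(1, d)
  })
  mu <- lapply(seq_len(K), function(k) {
    pts <- Y[assign0 == k, , drop = FALSE]
    if (nrow(pts) > 0) colMeans(pts) else Y[init_idx[k], ]
  })
  ll_trace <- numeric(0)
  ll_old <- -Inf
  gam <- NULL
  converged <- FALSE
  for (it in seq_len(cfg$max_iter)) {
    r <- tryCatch(gmm_responsibilities(Y, pi_k, mu, sigma),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)          # singular despite regularization
    if (it > 1 && r$loglik - ll_old < cfg$tol) {
      ## sub-tolerance terminal fluctuation (the covariance floor can move
      ## the bound by ~1e-7): stop without accepting the non-improving step
      converged <- TRUE
      break
    }
    gam <- r$gamma
    ll_trace <- c(ll_trace, r$loglik)
    ll_old <- r$loglik
    Nk <- colSums(gam)
    pi_k <- Nk / n
    for (k in seq_len(K)) {
      if (Nk[k] < 1e-10) return(NULL)
      mu[[k]] <- colSums(gam[, k] * Y) / Nk[k]
      Yc <- sweep(Y, 2, mu[[k]])
      S <- crossprod(Yc * gam[, k], Yc) / Nk[k]
      if (cfg$covariance == "diagonal") S <- diag(diag(S), d)
      sigma[[k]] <- S + reg
    }
  }
  list(gamma = gam, loglik = ll_trace[length(ll_trace)],
       ll_trace = ll_trace, pi_k = pi_k, mu = mu, sigma = sigma,
       n_iter = length(ll_trace), converged = converged)
}

#' Gaussian mixture clustering (EM)
#'
#' Fits a mixture of multivariate Gaussians
#' `p(z) = sum_k pi_k N(z | mu_k, Sigma_k)` by expectation-maximization;
#' memberships are the posterior responsibilities
#' `gamma_ik = pi_k N(z_i | mu_k, Sigma_k) / sum_j pi_j N(...)`.
#' Initialization samples K seeded centroids with a one-step nearest
#' assignment; of `n_init` restarts the best log-likelihood is kept.
#' Covariances are regularized by `1e-6 * I`; restarts that still go
#' singular are discarded, and an error is raised only if all fail.
#'
#' @param low embedding or coordinate matrix.
#' @param cfg a [gmm_config()]; requires `N > K * (d + 1)`.
#' @return a `soft_partition` with mixture parameters and the
#'   log-likelihood trace of the winning run.
#' @export
gmm_cluster <- function(low, cfg) {
  Y <- coords_of(low)
  n <- nrow(Y); d <- ncol(Y)
  stop_if(n <= cfg$K * (d + 1),
          sprintf("need N > K(d+1) = %d", cfg$K * (d + 1)))
  fits <- with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_init), function(r)
      gmm_em_once(Y, cfg, sample.int(n, cfg$K)))
  })
  fits <- Filter(Negate(is.null), fits)
  stop_if(length(fits) == 0, "all GMM initializations failed (singular)")
  best <- fits[[which.max(vapply(fits, `[[`, 0, "loglik"))]]
  new_partition(best$gamma, "gmm", converged = best$converged,
                n_iter = best$n_iter, objective_trace = best$ll_trace,
                seed = cfg$seed,
                extra = list(pi_k = best$pi_k, mu = best$mu,
                             sigma = best$sigma))
}

## fit one clustering method at one K (shared by diagnostics and stages)
fit_clustering <- function(low, method, K, seed = 1) {
  switch(method,
         ward = ward_cluster(low, K),
         fcm = fcm_cluster(low, K, fcm_config(seed = seed)),
         gmm = gmm_cluster(low, gmm_config(K, seed = seed)),
         stop("unknown clustering method: ", method))
}

#' Hard cluster validity metrics
#'
#' Computes on Euclidean embedding distances: mean silhouette
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` (via `cluster::silhouette`),
#' the Davies-Bouldin index
#' `(1/n) sum_i max_{j != i} (s_i + s_j) / d_ij` over cluster centroids,
#' and the Calinski-Harabasz index
#' `[Tr(B) / Tr(W)] * (n - k) / (k - 1)`.
#'
#' @param low embedding or coordinate matrix.
#' @param hard_labels integer cluster label per point (>= 2 non-empty
#'   clusters; not all singletons).
#' @return named vector `c(silhouette, db, ch)`.
#' @export
hard_validity <- function(low, hard_labels) {
  Y <- coords_of(low)
  lab <- as.integer(factor(hard_labels))
  ks <- sort(unique(lab))
  stop_if(length(ks) < 2, "need >= 2 clusters")
  stop_if(length(lab) < 3 || all(tabulate(lab) == 1),
          "singleton-only clustering: validity undefined")
  sil <- mean(cluster::silhouette(lab, stats::dist(Y))[, "sil_width"])
  cent <- t(vapply(ks, function(k) colMeans(Y[lab == k, , drop = FALSE]),
                   numeric(ncol(Y))))
  s_i <- vapply(seq_along(ks), function(j)
    mean(sqrt(rowSums(sweep(Y[lab == ks[j], , drop = FALSE], 2,
                            cent[j, ])^2))), 0)
  dc <- as.matrix(stats::dist(cent))
  db <- mean(vapply(seq_along(ks), function(i)
    max(vapply(setdiff(seq_along(ks), i), function(j)
      (s_i[i] + s_i[j]) / dc[i, j], 0)), 0))
  gm <- colMeans(Y)
  trB <- sum(vapply(seq_along(ks), function(j)
    sum(lab == ks[j]) * sum((cent[j, ] - gm)^2), 0))
  trW <- sum(vapply(seq_along(ks), function(j)
    sum(sweep(Y[lab == ks[j], , drop = FALSE], 2, cent[j, ])^2), 0))
  n <- nrow(Y); k <- length(ks)
  ch <- if (trW == 0) Inf else (trB / trW) * (n - k) / (k - 1)
  if (trB == 0) ch <- 0
  c(silhouette = sil, db = db, ch = ch)
}

#' Soft cluster validity metrics
#'
#' From the membership matrix: average Shannon entropy
#' `H_i = -sum_k p_ik log p_ik` (natural log, `0 log 0 = 0`), average
#' sharpness `1 - H_i / log K`, and the average maximum membership
#' probability. One-hot memberships give (0, 1, 1); uniform memberships
#' give (log K, 0, 1/K).
#'
#' @param partition a `soft_partition` (or membership matrix) with K >= 2.
#' @return named vector `c(avg_entropy, avg_sharpness, avg_max_prob)`.
#' @export
soft_validity <- function(partition) {
  M <- if (inherits(partition, "soft_partition")) partition$membership
  else as.matrix(partition)
  K <- ncol(M)
  stop_if(K < 2, "sharpness undefined for K = 1")
  stop_if(any(abs(rowSums(M) - 1) > 1e-9), "membership rows must sum to 1")
  H <- -rowSums(ifelse(M > 0, M * log(M), 0))
  c(avg_entropy = mean(H),
    avg_sharpness = mean(1 - H / log(K)),
    avg_max_prob = mean(apply(M, 1, max)))
}

## CHull scree elbow on a (complexity, fit) curve: restrict to the upper
## convex hull and take the point with the largest ratio of preceding to
## following hull-segment slope
chull_elbow <- function(K_grid, fit) {
  o <- order(K_grid)
  x <- K_grid[o]; y <- fit[o]
  ## upper hull by monotone scan
  hull <- 1L
  for (i in 2:length(x)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((y[b] - y[a]) * (x[i] - x[b]) <= (y[i] - y[b]) * (x[b] - x[a]))
        hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  if (length(hull) < 3) return(x[hull[length(hull)]])
  ratios <- vapply(2:(length(hull) - 1), function(j) {
    a <- hull[j - 1]; b <- hull[j]; cc <- hull[j + 1]
    s1 <- (y[b] - y[a]) / (x[b] - x[a])
    s2 <- (y[cc] - y[b]) / (x[cc] - x[b])
    if (s2 <= 0) Inf * sign(s1) else s1 / s2
  }, 0)
  x[hull[which.max(ratios) + 1]]
}

#' Cluster-number selection diagnostics
#'
#' Evaluates a K grid with one clustering method and reports, per K, the
#' mean silhouette, Davies-Bouldin index, within-cluster distortion and the
#' standard deviation of cluster sizes (partition balance); derives three
#' candidate K: the silhouette first peak (smallest K beating both grid
#' neighbours, one-sided at the ends), the CHull distortion elbow, and the
#' Davies-Bouldin minimum. The chosen K is the CHull elbow when it lies
#' between the silhouette peak and the D-B minimum, otherwise the median of
#' the three candidates; the rationale string records which criteria
#' supported it.
#'
#' @param low embedding or coordinate matrix.
#' @param method "ward", "fcm" or "gmm".
#' @param K_grid candidate cluster numbers (default 2:10).
#' @param seed integer seed passed to the clustering fits.
#' @return a `k_diagnostics` object.
#' @export
k_selection_diagnostics <- function(low, method = c("fcm", "ward", "gmm"),
                                    K_grid = 2:10, seed = 1) {
  method <- match.arg(method)
  Y <- coords_of(low)
  stop_if(length(K_grid) == 0, "empty K grid")
  stop_if(any(K_grid < 2) || any(K_grid > nrow(Y) - 1),
          "K_grid must lie in [2, N - 1]")
  K_grid <- sort(unique(as.integer(K_grid)))
  res <- lapply(K_grid, function(K) {
    p <- fit_clustering(Y, method, K, seed)
    hv <- hard_validity(Y, p$hard_labels)
    cent <- t(vapply(seq_len(K), function(k)
      colMeans(Y[p$hard_labels == k, , drop = FALSE]), numeric(ncol(Y))))
    distortion <- sum(vapply(seq_len(K), function(k)
      sum(sweep(Y[p$hard_labels == k, , drop = FALSE], 2,
                cent[k, ])^2), 0))
    sizes <- tabulate(p$hard_labels, K)
    c(hv, distortion = distortion, size_std = stats::sd(sizes))
  })
  tab <- as.data.frame(do.call(rbind, res))
  tab$K <- K_grid
  sil <- tab$silhouette
  peak <- vapply(seq_along(sil), function(i) {
    left <- i == 1 || sil[i] > sil[i - 1]
    right <- i == length(sil) || sil[i] > sil[i + 1]
    left && right
  }, TRUE)
  first_peak_K <- K_grid[which(peak)[1]]
  db_K <- K_grid[which.min(tab$db)]
  elbow_K <- chull_elbow(K_grid, -tab$distortion)
  cand <- c(first_peak = first_peak_K, chull = elbow_K, db = db_K)
  lo <- min(first_peak_K, db_K); hi <- max(first_peak_K, db_K)
  if (elbow_K >= lo && elbow_K <= hi) {
    chosen <- elbow_K
    why <- sprintf(paste("CHull elbow K = %d lies within the range spanned",
                         "by the silhouette first peak (K = %d) and the",
                         "D-B minimum (K = %d)"), elbow_K, first_peak_K, db_K)
  } else {
    chosen <- as.integer(round(stats::median(cand)))
    chosen <- K_grid[which.min(abs(K_grid - chosen))]
    why <- sprintf(paste("CHull elbow K = %d outside [%d, %d]; median of",
                         "the three candidates taken"), elbow_K, lo, hi)
  }
  structure(list(K_grid = K_grid, method = method,
                 silhouette_by_K = stats::setNames(sil, K_grid),
                 db_by_K = stats::setNames(tab$db, K_grid),
                 distortion_by_K = stats::setNames(tab$distortion, K_grid),
                 size_std_by_K = stats::setNames(tab$size_std, K_grid),
                 chull_elbow_K = elbow_K, first_peak_K = first_peak_K,
                 db_min_K = db_K, chosen_K = chosen, rationale = why,
                 seed = seed),
            class = "k_diagnostics")
}

#' @export
print.k_diagnostics <- function(x, ...) {
  cat(sprintf("K selection (%s): chosen K = %d\n", x$method, x$chosen_K))
  cat(sprintf("  silhouette first peak %d | CHull elbow %d | D-B min %d\n",
              x$first_peak_K, x$chull_elbow_K, x$db_min_K))
  cat(" ", x$rationale, "\n")
  invisible(x)
}
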