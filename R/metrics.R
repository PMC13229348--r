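## Structure-preservation and biological metrics for comparing embeddings:
## local neighbourhood fidelity (trustworthiness, LCMC), global distance
## correlations, the composite LS / GS / SPS scores, the Biological
## Transition Score, and kernel-density class overlap.

coords_of <- function(x) {
  if (inherits(x, "spine_embedding")) return(x$coords)
  if (inherits(x, "feature_table")) return(x$values)
  as.matrix(x)
}

#' Trustworthiness of an embedding
#'
#' Rank-based local metric in \[0, 1\] penalizing points that are nearest
#' neighbours in the embedding but distant in the original space:
#' `T(k) = 1 - 2 / (n k (2n - 3k - 1)) * sum_i sum_{j in N_i^embed}
#' max(0, r(i, j) - k)`, with `r(i, j)` the rank of `j` among `i`'s
#' neighbours in the original space.
#'
#' @param high original-space data ([feature_table()] or matrix).
#' @param low embedding ([fit_embedding()] result or matrix).
#' @param k neighbourhood size (default 10, small enough to probe local
#'   relationships while mitigating noise).
#' @return trustworthiness value in \[0, 1\].
#' @export
trustworthiness <- function(high, low, k = 10) {
  X <- coords_of(high); Y <- coords_of(low)
  n <- nrow(X)
  stop_if(nrow(Y) != n, "high and low must have the same number of rows")
  k <- check_count(k, "k")
  stop_if(2 * n - 3 * k - 1 <= 0,
          sprintf("k too large for the normalization: need 2n - 3k - 1 > 0, i.e. k < %.1f",
                  (2 * n - 1) / 3))
  Dh <- pairwise_dist(X); Dl <- pairwise_dist(Y)
  Rh <- rank_matrix(Dh)
  NNl <- knn_index_matrix(Dl, k)
  pen <- 0
  for (i in seq_len(n))
    pen <- pen + sum(pmax(0, Rh[i, NNl[i, ]] - k))
  1 - 2 / (n * k * (2 * n - 3 * k - 1)) * pen
}

#' Local continuity meta-criterion (LCMC)
#'
#' Average fractional overlap of the k-nearest-neighbour sets between the
#' original and embedded spaces: `(1 / (k n)) * sum_i |N_i^orig
#' intersect N_i^embed|`. Implemented exactly as stated, with no
#' random-overlap adjustment term.
#'
#' @inheritParams trustworthiness
#' @return LCMC value in \[0, 1\].
#' @export
lcmc <- function(high, low, k = 10) {
  X <- coords_of(high); Y <- coords_of(low)
  n <- nrow(X)
  stop_if(nrow(Y) != n, "high and low must have the same number of rows")
  k <- check_count(k, "k")
  stop_if(k >= n, sprintf("k must be < n (k = %d, n = %d)", k, n))
  NNh <- knn_index_matrix(pairwise_dist(X), k)
  NNl <- knn_index_matrix(pairwise_dist(Y), k)
  ov <- vapply(seq_len(n), function(i)
    length(intersect(NNh[i, ], NNl[i, ])), 0L)
  sum(ov) / (k * n)
}

#' Pearson and Spearman correlations of pairwise distances
#'
#' Global structure metrics: the sample Pearson correlation between the
#' condensed (i < j) pairwise-distance vectors of the original and embedded
#' spaces, and the Spearman coefficient computed as Pearson on
#' average-rank-transformed distances.
#'
#' @inheritParams trustworthiness
#' @param metric distance metric for both spaces.
#' @return named vector `c(pearson_r, spearman_rho)`.
#' @export
distance_correlations <- function(high, low,
                                  metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  X <- coords_of(high); Y <- coords_of(low)
  n <- nrow(X)
  stop_if(n < 3, "need n >= 3")
  dx <- condensed(pairwise_dist(X, metric))
  dy <- condensed(pairwise_dist(Y, metric))
  stop_if(stats::sd(dx) == 0 || stats::sd(dy) == 0,
          "constant distance vector: correlation undefined")
  c(pearson_r = stats::cor(dx, dy),
    spearman_rho = stats::cor(rank(dx), rank(dy)))
}

#' Combine component metrics into LS, GS and SPS
#'
#' The local score is the equal-weight average `LS = 0.5 T + 0.5 LCMC`, the
#' global score `GS = 0.5 r + 0.5 rho`, and the overall structure
#' preservation score the weighted sum `SPS = w_LS * LS + (1 - w_LS) * GS`.
#' Values are kept at full precision; rounding (3 decimals, half away from
#' zero) happens only in reporting via [round_report()].
#'
#' @param T trustworthiness in \[0, 1\].
#' @param LCMC local continuity in \[0, 1\].
#' @param pearson_r Pearson distance correlation in \[-1, 1\].
#' @param spearman_rho Spearman distance correlation in \[-1, 1\].
#' @param w_LS local-score weight in \[0, 1\] (default 0.5, equal
#'   preference for local and global preservation).
#' @param k neighbourhood size the local metrics used (bookkeeping).
#' @return a `structure_scores` object with fields T, LCMC, LS, pearson_r,
#'   spearman_rho, GS, SPS, w_LS, w_GS, k.
#' @export
composite_scores <- function(T, LCMC, pearson_r, spearman_rho, w_LS = 0.5,
                             k = 10) {
  check_number(T, "T", 0, 1); check_number(LCMC, "LCMC", 0, 1)
  check_number(pearson_r, "pearson_r", -1, 1)
  check_number(spearman_rho, "spearman_rho", -1, 1)
  check_number(w_LS, "w_LS", 0, 1)
  LS <- 0.5 * T + 0.5 * LCMC
  GS <- 0.5 * pearson_r + 0.5 * spearman_rho
  structure(list(T = T, LCMC = LCMC, LS = LS, pearson_r = pearson_r,
                 spearman_rho = spearman_rho, GS = GS,
                 SPS = w_LS * LS + (1 - w_LS) * GS,
                 w_LS = w_LS, w_GS = 1 - w_LS, k = k),
            class = "structure_scores")
}

#' @export
print.structure_scores <- function(x, ...) {
  v <- round_report(unlist(x[c("T", "LCMC", "LS", "pearson_r",
                               "spearman_rho", "GS", "SPS")]))
  cat(sprintf("T(k)=%.3f LCMC=%.3f LS=%.3f r=%.3f rho=%.3f GS=%.3f SPS=%.3f (w_LS=%g, k=%d)\n",
              v[1], v[2], v[3], v[4], v[5], v[6], v[7], x$w_LS, x$k))
  invisible(x)
}

#' Transition weight schemes for the Biological Transition Score
#'
#' A symmetric label-pair weight matrix in \[0, 1\] encoding how
#' biologically plausible a morphological transition between two spine
#' types is. Within-type weights must be the matrix maximum. The default
#' scheme rewards same-type adjacency (1.0) and the common
#' mushroom-to-thin / mushroom-to-stubby transitions (0.5), and fully
#' penalizes the rarely observed thin-to-stubby transition (0.0).
#'
#' @param labels ordered label set.
#' @param W symmetric |labels| x |labels| matrix in \[0, 1\].
#' @param name scheme name for reporting.
#' @return a `transition_scheme` object.
#' @export
transition_scheme <- function(labels, W, name = "custom") {
  W <- as.matrix(W)
  stop_if(nrow(W) != length(labels) || ncol(W) != length(labels),
          "W must be |labels| x |labels|")
  stop_if(any(W < 0), "negative transition weights are not allowed")
  stop_if(any(W > 1), "transition weights must be in [0, 1]")
  stop_if(max(abs(W - t(W))) > 1e-12, "W must be symmetric")
  stop_if(any(diag(W) < max(W) - 1e-12),
          "within-type weights must be the maximum entry")
  dimnames(W) <- list(labels, labels)
  structure(list(labels = labels, W = W, name = name),
            class = "transition_scheme")
}

#' @rdname transition_scheme
#' @param common weight of mushroom-to-thin / mushroom-to-stubby
#'   transitions (default 0.5).
#' @param rare weight of thin-to-stubby transitions (default 0).
#' @export
default_transition_scheme <- function(common = 0.5, rare = 0) {
  W <- matrix(c(1, common, common,
                common, 1, rare,
                common, rare, 1), 3, byrow = TRUE)
  transition_scheme(SPINE_LABELS, W,
                    name = sprintf("default(common=%g,rare=%g)", common, rare))
}

#' Biological Transition Score (BTS)
#'
#' A label-aware embedding metric: over each point's k nearest embedded
#' neighbours, a weighted average of the inverse-log distance
#' `1 / log(d_ij + 1)` with weights taken from the transition scheme of
#' the two labels, `BTS = sum w * (1 / log(d + 1)) / sum w` (natural log).
#' Embeddings that keep biologically adjacent spine types close score
#' higher. Distances below `epsilon` are floored at `epsilon` to keep the
#' inverse log finite.
#'
#' @param low embedding ([fit_embedding()] result or coordinate matrix).
#' @param labels class label per point (levels must appear in the scheme).
#' @param scheme a [transition_scheme()].
#' @param k neighbours per point (default 10, matching the local metrics).
#' @param metric "euclidean" or "cosine".
#' @param epsilon distance floor (default 1e-6).
#' @return a `bts_result` with fields `bts`, `distance_metric`, `k`,
#'   `scheme_name`, `epsilon`, `n_floored`.
#' @export
bts <- function(low, labels, scheme = default_transition_scheme(), k = 10,
                metric = c("euclidean", "cosine"), epsilon = 1e-6) {
  metric <- match.arg(metric)
  stopifnot(inherits(scheme, "transition_scheme"))
  Y <- coords_of(low)
  labels <- as.character(labels)
  stop_if(length(labels) != nrow(Y), "one label per embedded point required")
  unknown <- setdiff(unique(labels), scheme$labels)
  stop_if(length(unknown) > 0,
          paste("labels missing from scheme:", paste(unknown, collapse = ", ")))
  check_number(epsilon, "epsilon", lower = 1e-300)
  D <- pairwise_dist(Y, metric)
  NN <- knn_index_matrix(D, k)
  n <- nrow(Y)
  w <- num <- 0; floored <- 0L
  for (i in seq_len(n)) {
    js <- NN[i, ]
    wij <- scheme$W[labels[i], labels[js]]
    dij <- D[i, js]
    floored <- floored + sum(dij < epsilon)
    dij <- pmax(dij, epsilon)
    num <- num + sum(wij / log(dij + 1))
    w <- w + sum(wij)
  }
  stop_if(w == 0,
          "BTS undefined: all neighbour pairs have zero transition weight")
  if (floored > 0)
    message(sprintf("bts: %d distance(s) floored at epsilon = %g",
                    floored, epsilon))
  structure(list(bts = num / w, distance_metric = metric, k = k,
                 scheme_name = scheme$name, epsilon = epsilon,
                 n_floored = floored), class = "bts_result")
}

#' @export
print.bts_result <- function(x, ...) {
  cat(sprintf("BTS = %.3f (%s distance, k = %d, scheme %s)\n",
              round_report(x$bts), x$distance_metric, x$k, x$scheme_name))
  invisible(x)
}

## Gaussian product-kernel density with Scott's-rule bandwidth per class
kde_fit <- function(x) {
  n <- nrow(x); d <- ncol(x)
  h <- apply(x, 2, stats::sd) * n^(-1 / (d + 4))
  h[h == 0] <- 1e-8
  list(x = x, h = h, n = n, d = d)
}

kde_eval <- function(fit, q) {
  ## density at query rows q: mean over kernels of the product of
  ## univariate normals
  n <- fit$n
  out <- numeric(nrow(q))
  for (j in seq_len(n)) {
    z <- sweep(q, 2, fit$x[j, ]) / matrix(fit$h, nrow(q), fit$d, byrow = TRUE)
    out <- out + exp(rowSums(stats::dnorm(z, log = TRUE)) -
                       sum(log(fit$h)))
  }
  out / n
}

kde_sample <- function(fit, m) {
  idx <- sample.int(fit$n, m, replace = TRUE)
  fit$x[idx, , drop = FALSE] +
    matrix(stats::rnorm(m * fit$d), m) %*% diag(fit$h, fit$d)
}

#' Kernel-density overlap between label groups in an embedding
#'
#' For each class pair, the overlap coefficient `int min(p, q)` of the two
#' Gaussian kernel density estimates (Scott's-rule bandwidth per class),
#' estimated by importance-corrected Monte Carlo: draws come from the
#' balanced mixture `(p + q) / 2` and `min(p, q) / mixture` is averaged.
#' Also returns the average overlap (AO) across all pairs; lower AO means
#' better class separation in the embedding.
#'
#' @param low embedding or coordinate matrix.
#' @param labels class label per point; each class needs >= d + 2 points.
#' @param n_draws Monte-Carlo draws per pair (default 10000).
#' @param seed integer seed for the draws.
#' @return list with `pairs` (data.frame class_a, class_b, overlap) and
#'   `AO`.
#' @export
class_overlap <- function(low, labels, n_draws = 10000, seed = 1) {
  Y <- coords_of(low)
  labels <- droplevels(as.factor(labels))
  stop_if(length(labels) != nrow(Y), "one label per point required")
  cls <- levels(labels)
  stop_if(length(cls) < 2, "need >= 2 classes")
  d <- ncol(Y)
  cnt <- table(labels)
  small <- names(cnt)[cnt < d + 2]
  stop_if(length(small) > 0,
          sprintf("class(es) %s too small for KDE (need >= %d points)",
                  paste(small, collapse = ", "), d + 2))
  prs <- utils::combn(cls, 2)
  with_seed(seed, {
    ov <- vapply(seq_len(ncol(prs)), function(j) {
      fa <- kde_fit(Y[labels == prs[1, j], , drop = FALSE])
      fb <- kde_fit(Y[labels == prs[2, j], , drop = FALSE])
      na <- ceiling(n_draws / 2); nb <- n_draws - na
      q <- rbind(kde_sample(fa, na), kde_sample(fb, nb))
      pa <- kde_eval(fa, q); pb <- kde_eval(fb, q)
      mix <- (pa + pb) / 2
      mean(pmin(pa, pb) / mix)
    }, 0)
    list(pairs = data.frame(class_a = prs[1, ], class_b = prs[2, ],
                            overlap = ov), AO = mean(ov))
  })
}

#' Sensitivity sweeps for the embedding-selection metrics
#'
#' Recomputes the local metrics over a grid of neighbourhood sizes, the
#' SPS over a grid of local-weight values, and the BTS over a list of
#' transition schemes and both distance metrics, for a set of embeddings of
#' the same table. Each sweep carries a stability flag that is TRUE iff the
#' top-ranked method is constant across the whole grid.
#'
#' @param high the original [feature_table()].
#' @param low_set named list of embeddings.
#' @param labels expert labels (for BTS); NULL skips the BTS sweep.
#' @param k_range neighbourhood sizes (default 5:50, clamped to valid k).
#' @param w_range local weights for the SPS sweep (default 0.3-0.7).
#' @param schemes list of [transition_scheme()] (default: the default
#'   scheme).
#' @param k reference k for the SPS sweep's local metrics.
#' @return list of long-format data.frames `local`, `sps`, `bts` and
#'   logical `stability` flags per sweep.
#' @export
sensitivity_suite <- function(high, low_set, labels = NULL,
                              k_range = 5:50,
                              w_range = seq(0.3, 0.7, by = 0.1),
                              schemes = list(default_transition_scheme()),
                              k = 10) {
  stop_if(length(k_range) == 0 || length(w_range) == 0, "empty grid")
  stop_if(is.null(names(low_set)), "low_set must be a named list")
  n <- nrow(coords_of(high))
  k_range <- k_range[k_range >= 1 & (2 * n - 3 * k_range - 1) > 0 &
                       k_range < n]
  local <- do.call(rbind, lapply(names(low_set), function(m) {
    do.call(rbind, lapply(k_range, function(kk) {
      Tv <- trustworthiness(high, low_set[[m]], kk)
      Lv <- lcmc(high, low_set[[m]], kk)
      data.frame(method = m, k = kk, T = Tv, LCMC = Lv,
                 LS = 0.5 * Tv + 0.5 * Lv)
    }))
  }))
  base <- lapply(low_set, function(lo) {
    dc <- distance_correlations(high, lo)
    c(T = trustworthiness(high, lo, k), LCMC = lcmc(high, lo, k), dc)
  })
  sps <- do.call(rbind, lapply(names(low_set), function(m) {
    b <- base[[m]]
    do.call(rbind, lapply(w_range, function(w) {
      s <- composite_scores(b[["T"]], b[["LCMC"]], b[["pearson_r"]],
                            b[["spearman_rho"]], w_LS = w, k = k)
      data.frame(method = m, w_LS = w, SPS = s$SPS)
    }))
  }))
  bts_tab <- NULL
  if (!is.null(labels)) {
    grid <- expand.grid(scheme = seq_along(schemes),
                        metric = c("euclidean", "cosine"),
                        stringsAsFactors = FALSE)
    bts_tab <- do.call(rbind, lapply(names(low_set), function(m) {
      do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
        sc <- schemes[[grid$scheme[g]]]
        r <- bts(low_set[[m]], labels, sc, k = k, metric = grid$metric[g])
        data.frame(method = m, scheme = sc$name, metric = grid$metric[g],
                   bts = r$bts)
      }))
    }))
  }
  argmax_const <- function(df, key, val) {
    tops <- vapply(split(df, df[[key]]), function(s)
      s$method[which.max(s[[val]])], "")
    length(unique(tops)) == 1
  }
  stability <- list(
    local = argmax_const(local, "k", "LS"),
    sps = argmax_const(sps, "w_LS", "SPS"),
    bts = if (is.null(bts_tab)) NA else
      argmax_const(transform(bts_tab,
                             key = paste(scheme, metric)), "key", "bts"))
  list(local = local, sps = sps, bts = bts_tab, stability = stability)
}
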