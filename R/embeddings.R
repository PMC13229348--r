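## Dimensionality-reduction harness: five methods behind one seeded,
## deterministic interface, plus the correlation-refined UMAP variant.

EMBED_METHODS <- c("pca", "isomap", "tsne", "umap", "pcumap")

new_embedding <- function(coords, method, dim, params, seed,
                          source_table_id = "", extra = list()) {
  coords <- as.matrix(coords)
  stop_if(any(!is.finite(coords)), "embedding coordinates must be finite")
  colnames(coords) <- paste0("dim", seq_len(ncol(coords)))
  structure(c(list(coords = coords, method = method, dim = ncol(coords),
                   params = params, seed = seed,
                   source_table_id = source_table_id), extra),
            class = "spine_embedding")
}

#' @export
print.spine_embedding <- function(x, ...) {
  cat(sprintf("%s embedding: %d points in %d dims (seed %s)\n",
              toupper(x$method), nrow(x$coords), x$dim, x$seed))
  invisible(x)
}

#' Fit a low-dimensional embedding of a feature table
#'
#' One seeded front-end for the five supported methods:
#' \describe{
#'   \item{pca}{principal components (linear, deterministic).}
#'   \item{isomap}{geodesic multidimensional scaling on a k-neighbour
#'     graph (`vegan::isomap`); the neighbour count is grown automatically
#'     until the graph is connected.}
#'   \item{tsne}{t-SNE (`Rtsne`), perplexity clamped to (n - 1) / 3;
#'     exact gradients are used above 3 output dimensions.}
#'   \item{umap}{UMAP (`uwot`), single-threaded for bit reproducibility.}
#'   \item{pcumap}{UMAP followed by [refine_pcumap()], a gradient ascent on
#'     the Pearson correlation between low- and high-dimensional pairwise
#'     distances.}
#' }
#' High-dimensional distances are Euclidean on the standardized table
#' throughout, so all methods are scored on the same basis.
#'
#' @param table a standardized [feature_table()].
#' @param method one of "pca", "isomap", "tsne", "umap", "pcumap".
#' @param dim embedding dimension in \[2, 5\] (default 3).
#' @param params optional method parameters: `n_neighbors` (umap/isomap,
#'   default 15), `perplexity` (tsne, default 30), and the
#'   [refine_pcumap()] arguments for pcumap.
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return a `spine_embedding` with coords, method, params and seed.
#' @export
fit_embedding <- function(table, method = EMBED_METHODS, dim = 3,
                          params = list(), seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(table, "feature_table"))
  stop_if(!table$scaled, "table must be standardized (see scale_features)")
  dim <- check_count(dim, "dim")
  stop_if(dim < 2 || dim > 5, "dim must be in [2, 5]")
  X <- table$values
  n <- nrow(X)
  stop_if(n < dim + 2, sprintf("need at least %d rows for dim %d",
                               dim + 2, dim))
  id <- paste0("tbl", substr(paste(dim(X), collapse = "x"), 1, 16))
  if (method == "pca") {
    p <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    co <- p$x[, seq_len(dim), drop = FALSE]
    return(new_embedding(co, "pca", dim,
                         list(explained_variance = p$sdev^2), seed, id))
  }
  if (method == "isomap") {
    k0 <- min(params$n_neighbors %||% 15, n - 1)
    D <- stats::dist(X)
    for (k in k0:(n - 1)) {
      fit <- tryCatch(vegan::isomap(D, ndim = dim, k = k),
                      error = function(e) NULL)
      if (!is.null(fit)) {
        return(new_embedding(fit$points[, seq_len(dim), drop = FALSE],
                             "isomap", dim, list(n_neighbors = k), seed, id))
      }
    }
    stop("isomap: neighbour graph never became connected", call. = FALSE)
  }
  if (method == "tsne") {
    perp <- min(params$perplexity %||% 30, floor((n - 1) / 3))
    stop_if(perp < 2, sprintf("n = %d too small for t-SNE (need n >= 7)", n))
    theta <- if (dim > 3) 0 else params$theta %||% 0.5
    co <- with_seed(seed,
      Rtsne::Rtsne(X, dims = dim, perplexity = perp, theta = theta,
                   pca = FALSE, check_duplicates = FALSE,
                   num_threads = 1)$Y)
    return(new_embedding(co, "tsne", dim,
                         list(perplexity = perp, theta = theta), seed, id))
  }
  ## umap / pcumap
  nb <- min(params$n_neighbors %||% 15, n - 1)
  co <- with_seed(seed,
    uwot::umap(X, n_neighbors = nb, n_components = dim,
               n_threads = 1, n_sgd_threads = 0))
  base <- new_embedding(co, "umap", dim, list(n_neighbors = nb), seed, id)
  if (method == "umap") return(base)
  refine_pcumap(base, table,
                lambda_global = params$lambda_global %||% 3,
                iters = params$iters %||% 80,
                lr = params$lr %||% 0.05, seed = seed)
}

## gradient of pearson(dl(Z), v_fixed) with respect to Z; returns list with
## value r and gradient matrix
pearson_dist_grad <- function(Z, v, vb, vc) {
  D <- as.matrix(stats::dist(Z))
  u <- condensed(D)
  ub <- u - mean(u)
  B <- sum(ub^2)
  A <- sum(ub * vb)
  r <- A / sqrt(B * vc)
  ## d r / d u_p, mapped back to a symmetric matrix over pairs
  g <- (vb - (A / B) * ub) / sqrt(B * vc)
  G <- matrix(0, nrow(D), nrow(D))
  G[upper.tri(G)] <- g
  G <- G + t(G)
  Ds <- D; Ds[Ds == 0] <- 1
  W <- G / Ds
  grad <- (Z * rowSums(W)) - W %*% Z   # sum_j w_ij (z_i - z_j)
  list(r = r, grad = grad)
}

#' Refine a UMAP embedding toward global distance preservation
#'
#' Post-hoc gradient ascent on the objective
#' `lambda_global * pearson(d_low, d_high) - mean((Z - Z0)^2)`, where `Z0`
#' is the base UMAP embedding. The quadratic anchor keeps each point near
#' its UMAP position (and thereby its local neighbourhood) while the
#' correlation term recovers global structure; steps are accepted only if
#' the objective increases (backtracking halves the learning rate on
#' rejection), so the objective trace is non-decreasing over accepted
#' steps.
#'
#' @param base a `spine_embedding` with `method == "umap"`.
#' @param table the standardized source [feature_table()].
#' @param lambda_global weight of the global correlation term (>= 0).
#' @param iters maximum gradient steps.
#' @param lr initial learning rate.
#' @param seed bookkeeping seed (the refinement itself is deterministic).
#' @return a `spine_embedding` with `method == "pcumap"` and an
#'   `objective_trace` of accepted objective values.
#' @export
refine_pcumap <- function(base, table, lambda_global = 1, iters = 60,
                          lr = 0.05, seed = 1) {
  stopifnot(inherits(base, "spine_embedding"))
  stop_if(base$method != "umap", "base embedding must be a umap fit")
  check_number(lambda_global, "lambda_global", lower = 0)
  stopifnot(inherits(table, "feature_table"))
  Z0 <- base$coords
  v <- condensed(pairwise_dist(table$values))
  vb <- v - mean(v); vc <- sum(vb^2)
  Z <- Z0
  obj <- function(Z) {
    pg <- pearson_dist_grad(Z, v, vb, vc)
    list(value = lambda_global * pg$r - mean((Z - Z0)^2),
         grad = lambda_global * pg$grad - 2 * (Z - Z0) / length(Z0))
  }
  cur <- obj(Z)
  trace <- cur$value
  step <- lr
  it <- 0
  while (it < iters && step > 1e-10) {
    it <- it + 1
    stop_if(any(!is.finite(cur$grad)), "non-finite gradient in refinement")
    cand <- Z + step * cur$grad
    nxt <- obj(cand)
    if (nxt$value > cur$value) {
      Z <- cand; cur <- nxt
      trace <- c(trace, cur$value)
      step <- step * 1.1
    } else step <- step / 2
  }
  new_embedding(Z, "pcumap", base$dim,
                c(base$params, list(lambda_global = lambda_global,
                                    iters = iters, lr = lr)),
                seed, base$source_table_id,
                extra = list(objective_trace = trace, base_method = "umap"))
}

#' Sweep embedding methods across output dimensions
#'
#' Fits every (method, dim) combination and scores each with the full
#' structure metrics at neighbourhood size `k`.
#'
#' @param table a standardized [feature_table()].
#' @param methods methods to fit (default all five).
#' @param dims subset of 2:5 (default 2:5).
#' @param seed integer seed.
#' @param k neighbourhood size for the local metrics.
#' @return data.frame with one row per combination (method, dim, T, LCMC,
#'   LS, pearson_r, spearman_rho, GS, SPS), plus an `embeddings` attribute.
#' @export
sweep_dimensions <- function(table, methods = EMBED_METHODS, dims = 2:5,
                             seed = 1, k = 10) {
  stop_if(length(dims) == 0, "dims must be non-empty")
  stop_if(!all(dims %in% 2:5), "dims must be a subset of 2:5")
  fits <- list()
  rows <- list()
  for (m in methods) for (d in dims) {
    emb <- fit_embedding(table, m, dim = d, seed = seed)
    dc <- distance_correlations(table, emb)
    sc <- composite_scores(trustworthiness(table, emb, k),
                           lcmc(table, emb, k),
                           dc[["pearson_r"]], dc[["spearman_rho"]], k = k)
    fits[[paste(m, d, sep = "_")]] <- emb
    rows[[paste(m, d, sep = "_")]] <-
      data.frame(method = m, dim = d, T = sc$T, LCMC = sc$LCMC, LS = sc$LS,
                 pearson_r = sc$pearson_r, spearman_rho = sc$spearman_rho,
                 GS = sc$GS, SPS = sc$SPS)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "embeddings") <- fits
  out
}
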