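#' @keywords internal
"_PACKAGE"

## shared helpers; not exported unless noted

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  stop_if(x < lower || x > upper,
          sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x))
  invisible(x)
}

check_count <- function(x, name, lower = 1L) {
  check_number(x, name, lower = lower)
  stop_if(x != round(x), sprintf("'%s' must be an integer", name))
  as.integer(x)
}

#' Round half away from zero (reporting convention)
#'
#' Rounds to `digits` decimals with ties going away from zero, the
#' convention used for all reported structure-preservation scores.
#'
#' @param x numeric vector.
#' @param digits number of decimals (default 3).
#' @return rounded numeric vector.
#' @export
round_report <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## pairwise distances as a full symmetric matrix
pairwise_dist <- function(x, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (metric == "euclidean") return(as.matrix(stats::dist(x)))
  nrm <- sqrt(rowSums(x^2))
  nrm[nrm == 0] <- 1
  s <- tcrossprod(x / nrm)
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

## condensed (i < j) vector of a symmetric distance matrix
condensed <- function(D) D[upper.tri(D)]

## k nearest neighbour index matrix (n x k), self excluded, distance ties
## broken by index for determinism
knn_index_matrix <- function(D, k) {
  n <- nrow(D)
  stop_if(k >= n, sprintf("k must be < n (k = %d, n = %d)", k, n))
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(D[i, ], seq_len(n))
    o <- o[o != i]
    out[i, ] <- o[seq_len(k)]
  }
  out
}

## neighbourhood rank matrix: R[i, j] = rank of j among i's neighbours
## (1 = nearest, self excluded); ties broken by index
rank_matrix <- function(D) {
  n <- nrow(D)
  R <- matrix(NA_integer_, n, n)
  for (i in seq_len(n)) {
    o <- order(D[i, ], seq_len(n))
    o <- o[o != i]
    R[i, o] <- seq_len(n - 1L)
  }
  R
}

## seeded RNG evaluation that does not disturb the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
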