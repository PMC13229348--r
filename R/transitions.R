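## Post-clustering continuum analyses: label-cluster structure, embedded
## nearest-neighbour connectivity between clusters, ambiguous-spine
## detection with feature-shift effect sizes, and robustness reruns.

#' Cluster-by-label contingency matrix
#'
#' Counts of expert labels within each cluster, with marginals and
#' row-normalized proportions.
#'
#' @param partition a `soft_partition` (hard labels are used).
#' @param labels expert label per spine.
#' @return a `contingency_matrix`: list with `counts`, `proportions`,
#'   `row_marginals`, `col_marginals`.
#' @export
contingency <- function(partition, labels) {
  stopifnot(inherits(partition, "soft_partition"))
  stop_if(length(labels) != nrow(partition$membership),
          "labels length must match partition size")
  tab <- table(cluster = factor(partition$hard_labels,
                                levels = seq_len(partition$K)),
               label = labels)
  counts <- unclass(tab)
  rs <- rowSums(counts)
  props <- sweep(counts, 1, ifelse(rs == 0, 1, rs), "/")
  structure(list(counts = counts, proportions = props,
                 row_marginals = rs, col_marginals = colSums(counts)),
            class = "contingency_matrix")
}

#' @export
print.contingency_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

#' Nearest-neighbour connectivity between clusters
#'
#' For each spine, its k Euclidean nearest neighbours in the embedding are
#' tallied by (own cluster, neighbour cluster); counts are normalized by
#' the total number of neighbour pairs and symmetrized by averaging the two
#' directions, so the weights over all ordered pairs (including self pairs)
#' sum to 1. High off-diagonal mass indicates interleaved clusters,
#' consistent with transitional morphologies.
#'
#' @param low embedding or coordinate matrix.
#' @param partition a `soft_partition`.
#' @param k neighbours per spine (default 10).
#' @return a `connectivity_graph`: K x K weight matrix plus an edge list.
#' @export
nn_connectivity <- function(low, partition, k = 10) {
  Y <- coords_of(low)
  stopifnot(inherits(partition, "soft_partition"))
  n <- nrow(Y)
  k <- check_count(k, "k")
  stop_if(k >= n, "k must be < N")
  NN <- knn_index_matrix(pairwise_dist(Y), k)
  K <- partition$K
  W <- matrix(0, K, K)
  lab <- partition$hard_labels
  for (i in seq_len(n)) {
    tgt <- lab[NN[i, ]]
    for (j in tgt) W[lab[i], j] <- W[lab[i], j] + 1
  }
  W <- W / (n * k)
  W <- (W + t(W)) / 2
  el <- which(W > 0, arr.ind = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2], weight = W[el])
  structure(list(weights = W, edges = edges, k = k),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("Cluster connectivity (k = %d): diagonal mass %.3f\n",
              x$k, sum(diag(x$weights))))
  print(round(x$weights, 3))
  invisible(x)
}

#' Ambiguous-spine analysis
#'
#' Flags spines whose maximum membership probability falls below
#' `threshold` (default 0.60) as ambiguous, reports per-spine maximum
#' membership and normalized entropy `H_i / log K`, and quantifies which
#' features shift between confident and ambiguous spines via Cohen's d
#' (pooled-SD standardized mean difference, confident minus ambiguous),
#' ranked by absolute effect size. If either group is empty the report is
#' still emitted with the effect sizes flagged undefined.
#'
#' @param partition a soft `soft_partition` (fcm or gmm).
#' @param features a [feature_table()] over the same spines (raw scale
#'   preferred; effect sizes are scale-invariant either way).
#' @param threshold ambiguity cutoff on the maximum membership.
#' @return an `ambiguity_report`.
#' @export
ambiguity_analysis <- function(partition, features, threshold = 0.60) {
  stopifnot(inherits(partition, "soft_partition"),
            inherits(features, "feature_table"))
  stop_if(partition$method == "ward",
          "ambiguity analysis requires a soft partition (fcm/gmm)")
  M <- partition$membership
  stop_if(nrow(M) != nrow(features$values),
          "partition and feature table must cover the same spines")
  maxp <- apply(M, 1, max)
  H <- -rowSums(ifelse(M > 0, M * log(M), 0))
  norm_H <- H / log(partition$K)
  amb <- maxp < threshold
  d <- rep(NA_real_, ncol(features$values))
  names(d) <- features$feature_names
  defined <- any(amb) && any(!amb) && sum(amb) >= 2 && sum(!amb) >= 2
  if (defined) {
    a <- features$values[!amb, , drop = FALSE]   # confident
    b <- features$values[amb, , drop = FALSE]    # ambiguous
    n1 <- nrow(a); n2 <- nrow(b)
    sp <- sqrt(((n1 - 1) * apply(a, 2, stats::var) +
                  (n2 - 1) * apply(b, 2, stats::var)) / (n1 + n2 - 2))
    d <- (colMeans(a) - colMeans(b)) / ifelse(sp == 0, NA, sp)
  }
  shifts <- data.frame(feature = features$feature_names, cohens_d = d,
                       row.names = NULL)
  shifts <- shifts[order(-abs(shifts$cohens_d), shifts$feature), ]
  shifts$rank <- seq_len(nrow(shifts))
  structure(list(threshold = threshold,
                 ambiguous_ids = features$ids[amb],
                 confident_ids = features$ids[!amb],
                 per_spine = data.frame(id = features$ids,
                                        max_prob = maxp,
                                        norm_entropy = norm_H,
                                        ambiguous = amb, row.names = NULL),
                 feature_shifts = shifts,
                 d_defined = defined),
            class = "ambiguity_report")
}

#' @export
print.ambiguity_report <- function(x, ...) {
  cat(sprintf("Ambiguity report: %d ambiguous / %d confident (max prob < %.2f)\n",
              length(x$ambiguous_ids), length(x$confident_ids), x$threshold))
  if (x$d_defined) {
    cat("Top feature shifts (Cohen's d, confident - ambiguous):\n")
    print(utils::head(x$feature_shifts, 5), row.names = FALSE)
  } else cat("Effect sizes undefined (one group empty or too small)\n")
  invisible(x)
}

## one-hot partition from labels (for expert labels in comparisons)
labels_to_partition <- function(labels) {
  f <- droplevels(as.factor(labels))
  M <- matrix(0, length(f), nlevels(f))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  new_partition(M, "labels", extra = list(level_names = levels(f)))
}

#' Compare partitions on a common embedding
#'
#' Computes the hard validity metrics for each partition (expert labels may
#' be included as a one-hot partition) on the same embedding, plus the
#' adjusted Rand index of each partition against the first one — e.g. to
#' ask whether a K = 5 solution preserves or strengthens structural
#' organization relative to the canonical three classes.
#'
#' @param low embedding or coordinate matrix.
#' @param partitions named list of `soft_partition`s and/or label vectors.
#' @return data.frame (partition, K, silhouette, db, ch, ari_vs_first).
#' @export
compare_partitions <- function(low, partitions) {
  Y <- coords_of(low)
  stop_if(length(partitions) == 0, "no partitions given")
  stop_if(is.null(names(partitions)), "partitions must be named")
  parts <- lapply(partitions, function(p)
    if (inherits(p, "soft_partition")) p else labels_to_partition(p))
  ref <- parts[[1]]$hard_labels
  rows <- lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    stop_if(nrow(p$membership) != nrow(Y),
            "all partitions must cover the embedded spines")
    hv <- hard_validity(Y, p$hard_labels)
    data.frame(partition = nm, K = p$K, silhouette = hv[["silhouette"]],
               db = hv[["db"]], ch = hv[["ch"]],
               ari_vs_first = mclust::adjustedRandIndex(ref, p$hard_labels))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balanced-subset robustness rerun
#'
#' Subsamples every class down to the smallest class count (seeded), reruns
#' the embedding and clustering on the balanced subset, and reports cluster
#' size dispersion and the cluster-by-label contingency before and after —
#' probing whether the cluster organization is driven by class imbalance.
#'
#' @param features a labeled [feature_table()] (raw or standardized).
#' @param method embedding method (default "pca").
#' @param dim embedding dimension.
#' @param cluster_method "ward", "fcm" or "gmm".
#' @param K number of clusters (default: K-selection on the full set's
#'   embedding is *not* rerun; pass the K under study).
#' @param seed integer seed for subsampling and the refits.
#' @return list with `subset_ids`, `full` and `balanced` results (each:
#'   partition, contingency, size_std).
#' @export
balanced_subset_rerun <- function(features, method = "pca", dim = 3,
                                  cluster_method = "fcm", K = 3, seed = 1) {
  stopifnot(inherits(features, "feature_table"))
  stop_if(is.null(features$labels), "labels required")
  cnt <- table(droplevels(features$labels))
  stop_if(min(cnt) < 2, "each class needs >= 2 spines")
  m <- min(cnt)
  idx <- with_seed(seed, {
    unlist(lapply(names(cnt), function(cl) {
      w <- which(features$labels == cl)
      if (length(w) > m) sort(sample(w, m)) else w
    }))
  })
  run_one <- function(tab) {
    tab_s <- if (tab$scaled) tab else scale_features(tab)
    emb <- fit_embedding(tab_s, method, dim = dim, seed = seed)
    part <- fit_clustering(emb, cluster_method, K, seed)
    list(partition = part,
         contingency = contingency(part, tab$labels),
         size_std = stats::sd(tabulate(part$hard_labels, part$K)))
  }
  sub <- feature_table(features$values[idx, , drop = FALSE],
                       ids = features$ids[idx],
                       labels = features$labels[idx],
                       scaled = FALSE)
  full_tab <- feature_table(features$values, ids = features$ids,
                            labels = features$labels, scaled = FALSE)
  list(subset_ids = features$ids[idx],
       full = run_one(full_tab),
       balanced = run_one(sub))
}
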