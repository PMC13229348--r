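## Two-stage decision framework: (A) fit candidate embeddings and rank them
## by the composite structure-preservation score with the Biological
## Transition Score as tiebreaker; (B) select a cluster number, run all
## clustering methods, and carry out the continuum analyses.

#' Build and validate a run configuration
#'
#' Collects every tunable of the two decision stages into one validated
#' list that is serialized with each report for provenance.
#'
#' @param methods embedding methods to evaluate.
#' @param dim embedding dimension in \[2, 5\].
#' @param k neighbourhood size for local metrics, BTS and connectivity.
#' @param w_ls local weight of the SPS.
#' @param scheme a [transition_scheme()] for the BTS.
#' @param sps_tie SPS difference below which the Euclidean BTS breaks the
#'   tie between top-ranked embedding methods.
#' @param K_grid candidate cluster numbers.
#' @param cluster_methods clustering methods to run.
#' @param diagnostic_method method used for the K-selection diagnostics.
#' @param ambiguity_threshold maximum-membership cutoff for ambiguity.
#' @param seed integer seed threaded to every stochastic step.
#' @param compute_overlap compute the KDE class overlap (needs labels).
#' @param sensitivity also run the neighbourhood-size / SPS-weight / BTS
#'   scheme sensitivity sweeps in stage A (slower; off by default).
#' @return a validated `spine_config` list.
#' @export
spine_config <- function(methods = EMBED_METHODS, dim = 3, k = 10,
                         w_ls = 0.5, scheme = default_transition_scheme(),
                         sps_tie = 0.005, K_grid = 2:10,
                         cluster_methods = c("ward", "fcm", "gmm"),
                         diagnostic_method = "fcm",
                         ambiguity_threshold = 0.60, seed = 1,
                         compute_overlap = TRUE, sensitivity = FALSE) {
  stop_if(!all(methods %in% EMBED_METHODS),
          paste("unknown embedding method(s):",
                paste(setdiff(methods, EMBED_METHODS), collapse = ", ")))
  dim <- check_count(dim, "dim"); stop_if(dim < 2 || dim > 5,
                                          "dim must be in [2, 5]")
  k <- check_count(k, "k")
  check_number(w_ls, "w_ls", 0, 1)
  stopifnot(inherits(scheme, "transition_scheme"))
  stop_if(!all(cluster_methods %in% c("ward", "fcm", "gmm")),
          "cluster_methods must be among ward/fcm/gmm")
  stop_if(!diagnostic_method %in% cluster_methods,
          "diagnostic_method must be one of cluster_methods")
  check_number(ambiguity_threshold, "ambiguity_threshold", 0, 1)
  structure(list(methods = methods, dim = dim, k = k, w_ls = w_ls,
                 scheme = scheme, sps_tie = sps_tie, K_grid = K_grid,
                 cluster_methods = cluster_methods,
                 diagnostic_method = diagnostic_method,
                 ambiguity_threshold = ambiguity_threshold,
                 seed = as.integer(seed),
                 compute_overlap = compute_overlap,
                 sensitivity = sensitivity),
            class = "spine_config")
}

## pure selection rule over a metrics table: max SPS, Euclidean BTS breaks
## near-ties; unit-testable without any fitting
select_embedding_method <- function(scores, sps_tie = 0.005) {
  ok <- scores[!is.na(scores$SPS), , drop = FALSE]
  stop_if(nrow(ok) == 0, "no surviving embedding method")
  o <- order(-ok$SPS)
  best <- ok[o[1], ]
  if (nrow(ok) > 1) {
    near <- ok[ok$SPS > best$SPS - sps_tie & !is.na(ok$bts_euclidean), ,
               drop = FALSE]
    if (nrow(near) > 1 && !is.na(best$bts_euclidean))
      best <- near[which.max(near$bts_euclidean), ]
  }
  best$method
}

#' Decision stage A: evaluate and select an embedding method
#'
#' Fits every configured method on the standardized table, scores each with
#' the local metrics (trustworthiness, LCMC), global distance correlations,
#' the composite LS / GS / SPS, the BTS under Euclidean and cosine
#' distances, and the KDE class overlap (AO); ranks methods by SPS with the
#' Euclidean BTS as tiebreaker for near-equal scores. A method that errors
#' is recorded as a failed row and the stage continues as long as at least
#' one method survives.
#'
#' @param table a [feature_table()] (standardized automatically if not).
#' @param cfg a [spine_config()].
#' @return a `dr_report`: `scores` data.frame, `selected`, `embeddings`
#'   list, `failures`, and the serialized `config`.
#' @export
run_dr_stage <- function(table, cfg = spine_config()) {
  stopifnot(inherits(table, "feature_table"), inherits(cfg, "spine_config"))
  if (!table$scaled) table <- scale_features(table)
  has_labels <- !is.null(table$labels)
  rows <- list(); embs <- list(); fails <- list()
  for (m in cfg$methods) {
    res <- tryCatch({
      emb <- fit_embedding(table, m, dim = cfg$dim, seed = cfg$seed)
      dc <- distance_correlations(table, emb)
      sc <- composite_scores(trustworthiness(table, emb, cfg$k),
                             lcmc(table, emb, cfg$k),
                             dc[["pearson_r"]], dc[["spearman_rho"]],
                             w_LS = cfg$w_ls, k = cfg$k)
      be <- bc <- ao <- NA_real_
      if (has_labels) {
        be <- bts(emb, table$labels, cfg$scheme, cfg$k, "euclidean")$bts
        bc <- bts(emb, table$labels, cfg$scheme, cfg$k, "cosine")$bts
        if (cfg$compute_overlap)
          ao <- class_overlap(emb, table$labels, seed = cfg$seed)$AO
      }
      list(emb = emb,
           row = data.frame(method = m, T = sc$T, LCMC = sc$LCMC, LS = sc$LS,
                            pearson_r = sc$pearson_r,
                            spearman_rho = sc$spearman_rho, GS = sc$GS,
                            SPS = sc$SPS, bts_euclidean = be,
                            bts_cosine = bc, AO = ao))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[m]] <- conditionMessage(res)
      rows[[m]] <- data.frame(method = m, T = NA, LCMC = NA, LS = NA,
                              pearson_r = NA, spearman_rho = NA, GS = NA,
                              SPS = NA, bts_euclidean = NA, bts_cosine = NA,
                              AO = NA)
    } else {
      embs[[m]] <- res$emb
      rows[[m]] <- res$row
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  stop_if(length(embs) == 0,
          paste("all embedding methods failed:",
                paste(unlist(fails), collapse = "; ")))
  sel <- select_embedding_method(scores, cfg$sps_tie)
  sens <- NULL
  if (isTRUE(cfg$sensitivity))
    sens <- sensitivity_suite(table, lapply(embs, `[[`, "coords"),
                              labels = table$labels,
                              schemes = list(cfg$scheme), k = cfg$k)
  structure(list(scores = scores, selected = sel, sensitivity = sens,
                 justification = sprintf(
                   "highest SPS (ties below %.3g broken by Euclidean BTS)",
                   cfg$sps_tie),
                 embeddings = embs, failures = fails, config = cfg),
            class = "dr_report")
}

#' @export
print.dr_report <- function(x, ...) {
  df <- x$scores
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round_report)
  print(df, row.names = FALSE)
  cat(sprintf("Selected embedding: %s (%s)\n", x$selected, x$justification))
  invisible(x)
}

#' Decision stage B: cluster-number selection, clustering and continuum
#' analyses
#'
#' Runs the K-selection diagnostics on the given embedding, fits every
#' configured clustering method at the chosen K, evaluates hard validity
#' for all methods and soft validity for the probabilistic ones (Ward's
#' soft fields are reported as NA), selects the method with the best
#' silhouette, and attaches the continuum analyses: cluster-by-label
#' contingency, nearest-neighbour connectivity, ambiguity analysis against
#' `features`, and a partition comparison including expert labels when
#' available.
#'
#' @param embedding a `spine_embedding` (typically the stage-A winner).
#' @param cfg a [spine_config()].
#' @param labels optional expert labels per spine.
#' @param features optional [feature_table()] for the ambiguity effect
#'   sizes (defaults to none; pass the raw-scale table when available).
#' @return a `cluster_report`.
#' @export
run_cluster_stage <- function(embedding, cfg = spine_config(),
                              labels = NULL, features = NULL) {
  stopifnot(inherits(cfg, "spine_config"))
  stop_if(is.null(embedding) || nrow(coords_of(embedding)) == 0,
          "config error: empty embedding")
  Y <- coords_of(embedding)
  diag_k <- k_selection_diagnostics(Y, cfg$diagnostic_method,
                                    cfg$K_grid, cfg$seed)
  K <- diag_k$chosen_K
  parts <- list(); vrows <- list()
  for (m in cfg$cluster_methods) {
    p <- fit_clustering(Y, m, K, cfg$seed)
    hv <- hard_validity(Y, p$hard_labels)
    sv <- if (m == "ward") c(avg_entropy = NA_real_,
                             avg_sharpness = NA_real_,
                             avg_max_prob = NA_real_) else soft_validity(p)
    parts[[m]] <- p
    vrows[[m]] <- data.frame(method = m, K = K,
                             silhouette = hv[["silhouette"]],
                             ch = hv[["ch"]], db = hv[["db"]],
                             avg_entropy = sv[["avg_entropy"]],
                             avg_sharpness = sv[["avg_sharpness"]],
                             avg_max_prob = sv[["avg_max_prob"]])
  }
  validity <- do.call(rbind, vrows)
  rownames(validity) <- NULL
  sel <- validity$method[which.max(validity$silhouette)]
  best <- parts[[sel]]
  cont <- if (!is.null(labels)) contingency(best, labels) else NULL
  conn <- nn_connectivity(Y, best, k = min(cfg$k, nrow(Y) - 1))
  amb <- if (!is.null(features) && best$method != "ward")
    ambiguity_analysis(best, features, cfg$ambiguity_threshold) else NULL
  cmp <- if (!is.null(labels)) {
    pl <- c(list(expert = labels), parts)
    compare_partitions(Y, pl)
  } else NULL
  structure(list(diagnostics = diag_k, chosen_K = K, partitions = parts,
                 validity = validity, selected = sel,
                 contingency = cont, connectivity = conn, ambiguity = amb,
                 comparison = cmp, config = cfg),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  print(x$diagnostics)
  df <- x$validity
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) round_report(v, 3))
  print(df, row.names = FALSE)
  cat(sprintf("Selected clustering: %s (best silhouette at K = %d)\n",
              x$selected, x$chosen_K))
  invisible(x)
}
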