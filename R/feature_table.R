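#' Construct a feature table
#'
#' The central container of the package: an N x F numeric matrix of
#' per-spine features with unique feature names, spine identifiers and
#' optional expert labels. Tables may be z-score standardized
#' (`scaled = TRUE`), in which case the scaling parameters are retained so
#' the transform can be reused or inverted.
#'
#' @param values numeric matrix, one row per spine.
#' @param ids character vector of spine identifiers (defaults to row index).
#' @param labels optional factor/character of expert labels per spine.
#' @param feature_names column names (defaults to existing colnames).
#' @param scaled logical; is the table already standardized?
#' @param scaling optional list(center, scale) recorded at standardization.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(values, ids = NULL, labels = NULL,
                          feature_names = NULL, scaled = FALSE,
                          scaling = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if(anyNA(values) || any(!is.finite(values)),
          "feature table must be free of NA/Inf after assembly")
  feature_names <- feature_names %||% colnames(values) %||%
    paste0("f", seq_len(ncol(values)))
  stop_if(anyDuplicated(feature_names) > 0, "feature names must be unique")
  ids <- as.character(ids %||% seq_len(nrow(values)))
  stop_if(length(ids) != nrow(values), "length(ids) must equal nrow(values)")
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    stop_if(length(labels) != nrow(values),
            "length(labels) must equal nrow(values)")
  }
  colnames(values) <- feature_names
  rownames(values) <- ids
  structure(list(values = values, ids = ids, labels = labels,
                 feature_names = feature_names, scaled = scaled,
                 scaling = scaling),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d spines x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              if (x$scaled) "standardized" else "raw"))
  if (!is.null(x$labels))
    print(table(labels = x$labels))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$labels)) df$label <- as.character(x$labels)
  cbind(df, as.data.frame(x$values, row.names = NULL))
}

#' Z-score standardize a feature table
#'
#' Columns are centered and scaled to unit standard deviation. Constant
#' columns are rejected, because a zero-variance feature carries no
#' morphometric information and breaks the scaling contract.
#'
#' @param table a [feature_table()].
#' @return a standardized `feature_table` with `scaling` recorded.
#' @export
scale_features <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (table$scaled) return(table)
  ctr <- colMeans(table$values)
  sds <- apply(table$values, 2, stats::sd)
  stop_if(any(sds == 0),
          paste("cannot standardize constant feature(s):",
                paste(table$feature_names[sds == 0], collapse = ", ")))
  v <- sweep(sweep(table$values, 2, ctr), 2, sds, "/")
  out <- feature_table(v, table$ids, table$labels, table$feature_names,
                       scaled = TRUE, scaling = list(center = ctr, scale = sds))
  out$latent_t <- table$latent_t
  out
}

#' Write / read a feature table as CSV
#'
#' The CSV schema is `id[,label],<feature columns>`; round-trips through
#' [read_feature_table()].
#'
#' @param table a [feature_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param scaled logical hint recorded on the table read back.
#' @export
read_feature_table <- function(path, scaled = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stop_if(!"id" %in% names(df), "feature CSV must have an 'id' column")
  labels <- if ("label" %in% names(df)) df$label else NULL
  feat <- setdiff(names(df), c("id", "label"))
  feature_table(as.matrix(df[feat]), ids = df$id, labels = labels,
                scaled = scaled)
}
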