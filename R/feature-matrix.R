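#' Construct a feature matrix
#'
#' The central data container: an `n x d` real matrix of per-sequence
#' physicochemical features, with sample identifiers on rows, feature
#' (AAindex accession) identifiers on columns, and optional class labels
#' in `{+1, -1}` (`+1` = positive class, e.g. bioluminescent).
#'
#' @param X Numeric matrix, samples in rows.
#' @param sample_ids Character vector, one per row.
#' @param feature_ids Character vector of unique feature identifiers, one
#'   per column.
#' @param y Optional integer labels in `{+1, -1}`, one per row.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(X, sample_ids, feature_ids, y = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(sample_ids) != nrow(X))
    stop_format("sample_ids length (", length(sample_ids),
                ") does not match rows (", nrow(X), ")")
  if (length(feature_ids) != ncol(X))
    stop_format("feature_ids length (", length(feature_ids),
                ") does not match columns (", ncol(X), ")")
  if (anyDuplicated(feature_ids))
    stop_format("duplicated feature id: ",
                feature_ids[anyDuplicated(feature_ids)])
  if (any(!is.finite(X)))
    stop_format("feature matrix contains non-finite entries")
  if (!is.null(y)) {
    if (length(y) != nrow(X))
      stop_format("labels length does not match rows")
    if (!all(y %in% c(-1, 1)))
      stop_format("labels must be +1 or -1")
    y <- as.integer(y)
  }
  dimnames(X) <- list(as.character(sample_ids), as.character(feature_ids))
  structure(list(X = X, sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids), y = y),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("<feature_matrix>", nrow(x$X), "samples x", ncol(x$X), "features",
      if (!is.null(x$y)) sprintf("(labeled: %d pos / %d neg)",
                                 sum(x$y == 1L), sum(x$y == -1L))
      else "(unlabeled)", "\n")
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$X)

#' Subset the feature columns of a feature matrix
#'
#' @param m A [feature_matrix()].
#' @param feature_ids Feature identifiers to keep, in the requested order.
#' @return A [feature_matrix()] restricted to those features.
#' @export
subset_features <- function(m, feature_ids) {
  missing <- setdiff(feature_ids, m$feature_ids)
  if (length(missing))
    stop_format("unknown feature id(s): ", paste(missing, collapse = ", "))
  feature_matrix(m$X[, feature_ids, drop = FALSE], m$sample_ids,
                 feature_ids, m$y)
}

#' Write and read feature matrices as TSV
#'
#' The on-disk layout is a header row `sample_id<TAB>label<TAB><feature ids>`
#' followed by one row per sample. Unlabeled matrices store `NA` in the
#' label column. Values are written with full (round-trip) float precision,
#' so `read_feature_matrix(write_feature_matrix(m, f))` reproduces `m`.
#'
#' @param m A [feature_matrix()].
#' @param path TSV path.
#' @return For the writer, `path` invisibly; for the reader, a
#'   [feature_matrix()].
#' @export
write_feature_matrix <- function(m, path) {
  stopifnot(inherits(m, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "label", m$feature_ids), collapse = "\t"), con)
  lab <- if (is.null(m$y)) rep("NA", nrow(m$X)) else sprintf("%+d", m$y)
  for (i in seq_len(nrow(m$X))) {
    writeLines(paste(c(m$sample_ids[i], lab[i],
                       formatC(m$X[i, ], format = "g", digits = 17)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop_format("feature matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop_format("feature matrix TSV needs header + rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 3L || header[1L] != "sample_id" || header[2L] != "label")
    stop_format("malformed feature matrix header")
  feature_ids <- header[-(1:2)]
  if (anyDuplicated(feature_ids))
    stop_format("duplicated feature id in header: ",
                feature_ids[anyDuplicated(feature_ids)])
  body <- fields[-1L]
  n_field <- lengths(body)
  if (any(n_field != length(header)))
    stop_format("ragged row at line ", which(n_field != length(header))[1L] + 1L)
  sample_ids <- vapply(body, `[[`, "", 1L)
  lab_tok <- vapply(body, `[[`, "", 2L)
  if (all(lab_tok == "NA")) {
    y <- NULL
  } else {
    if (!all(lab_tok %in% c("+1", "1", "-1")))
      stop_format("labels must be +1 or -1, found '",
                  setdiff(lab_tok, c("+1", "1", "-1"))[1L], "'")
    y <- as.integer(lab_tok)
  }
  X <- matrix(as.numeric(unlist(lapply(body, `[`, -(1:2)))),
              nrow = length(body), byrow = TRUE)
  feature_matrix(X, sample_ids, feature_ids, y)
}
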