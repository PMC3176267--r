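#' Encode one sequence against one property table
#'
#' A protein's value for a physicochemical property is the sum of that
#' property over all residues of the sequence divided by the number of
#' residues — i.e. the mean property value, a pure composition statistic.
#' Residues outside the 20 standard amino acids, and residues whose value
#' is missing in the table, contribute to neither the numerator nor the
#' denominator, so the result remains an unbiased mean over the residues
#' the scale actually covers.
#'
#' @param residues Uppercase residue string (or a one-row record data frame
#'   from [read_fasta()]).
#' @param table A [property_table()].
#' @return The mean property value, a single number bounded by the range of
#'   the table's values.
#' @export
encode_sequence <- function(residues, table) {
  if (is.data.frame(residues)) residues <- residues$residues[[1L]]
  stopifnot(inherits(table, "property_table"))
  aa <- strsplit(residues, "", fixed = TRUE)[[1L]]
  vals <- table$values[match(aa, AA_ORDER)]  # NA for non-standard residues
  contributing <- !is.na(vals)
  if (!any(contributing))
    stop("sequence has no residue with a value in property ", table$accession)
  mean(vals[contributing])
}

#' Encode a set of sequences into a feature matrix
#'
#' Applies [encode_sequence()] to every (sequence, property) pair:
#' `X[i, j]` is the mean value of property `j` over sequence `i`. With a
#' full AAindex1 release this yields the d = 544 dimensional feature vector
#' per protein.
#'
#' @param records Data frame from [read_fasta()] (columns `id`, `residues`).
#' @param tables List of [property_table()] objects.
#' @param y Optional labels in `{+1, -1}`.
#' @return A [feature_matrix()] with features in table order.
#' @export
encode_dataset <- function(records, tables, y = NULL) {
  if (nrow(records) < 1L) stop("need at least one sequence")
  if (length(tables) < 1L) stop("need at least one property table")
  # residue composition counts per sequence: encoding is composition %*% values
  comp <- t(vapply(strsplit(records$residues, "", fixed = TRUE),
                   function(aa) tabulate(match(aa, AA_ORDER), nbins = 20L),
                   integer(20L)))
  V <- vapply(tables, function(tab) tab$values, numeric(20L))  # 20 x d
  miss <- is.na(V)
  V0 <- ifelse(miss, 0, V)
  num <- comp %*% V0                      # n x d sums over covered residues
  den <- comp %*% (!miss)                 # contributing residue counts
  if (any(den == 0)) {
    bad <- which(den == 0, arr.ind = TRUE)[1L, ]
    stop("sequence '", records$id[bad[1L]],
         "' has no residue with a value in property ",
         tables[[bad[2L]]]$accession)
  }
  ids <- vapply(tables, function(tab) tab$accession, "")
  feature_matrix(num / den, records$id, ids, y)
}

#' Fit and apply z-score standardization
#'
#' `fit_standardizer()` learns per-feature center (mean) and scale (sample
#' standard deviation, `n - 1` denominator) from a training matrix;
#' `apply_standardizer()` applies the stored parameters unchanged to any
#' matrix with the same features. Raw AAindex scales differ by orders of
#' magnitude, and both the Gaussian-kernel SVM and the distance-based
#' ReliefF selector are scale-sensitive, so standardization precedes both.
#' Zero-variance features get scale 1 (yielding all-zero columns) so that
#' feature indices stay aligned with their accessions.
#'
#' @param m Training [feature_matrix()], `n >= 2`.
#' @param params A list with `center` and `scale` from `fit_standardizer()`.
#' @return `fit_standardizer()`: a list with named numeric vectors `center`
#'   and `scale`. `apply_standardizer()`: the transformed
#'   [feature_matrix()].
#' @export
fit_standardizer <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  if (nrow(m$X) < 2L) stop("need n >= 2 to fit a standardizer")
  center <- colMeans(m$X)
  scale <- apply(m$X, 2L, stats::sd)
  scale[scale == 0] <- 1
  list(center = stats::setNames(center, m$feature_ids),
       scale = stats::setNames(scale, m$feature_ids))
}

#' @rdname fit_standardizer
#' @export
apply_standardizer <- function(m, params) {
  stopifnot(inherits(m, "feature_matrix"))
  if (length(params$center) != ncol(m$X) ||
      !identical(names(params$center), m$feature_ids))
    stop("standardizer parameters do not match the matrix features")
  X <- sweep(sweep(m$X, 2L, params$center, "-"), 2L, params$scale, "/")
  feature_matrix(X, m$sample_ids, m$feature_ids, m$y)
}
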