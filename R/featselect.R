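#' Feature ranking container
#'
#' Holds an ordered set of features produced by one of the filter selection
#' methods, together with the score that ordered them and the
#' hyperparameters used. For score-based methods (`relieff`, `infogain`)
#' the order is descending score with ties broken by ascending original
#' feature index; for `mrmr` it is the greedy selection order with the
#' stepwise criterion values.
#'
#' @param method One of `"relieff"`, `"infogain"`, `"mrmr"`.
#' @param feature_ids Ordered feature identifiers.
#' @param scores Scores aligned with `feature_ids`.
#' @param params Named list of hyperparameters used.
#' @return An object of class `feature_ranking`.
#' @export
feature_ranking <- function(method, feature_ids, scores, params = list()) {
  method <- match.arg(method, c("relieff", "infogain", "mrmr"))
  if (length(feature_ids) != length(scores))
    stop("feature_ids and scores must align")
  if (any(!is.finite(scores))) stop("ranking scores must be finite")
  structure(list(method = method, feature_ids = as.character(feature_ids),
                 scores = as.numeric(scores), params = params),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat("<feature_ranking>", x$method, "-", length(x$feature_ids),
      "features; top:", paste(utils::head(x$feature_ids, 3L), collapse = ", "),
      "\n")
  invisible(x)
}

#' Take the top k features of a ranking
#'
#' @param ranking A [feature_ranking()].
#' @param k Number of features, `1 <= k <= length(ranking)`.
#' @return Character vector of the first `k` feature identifiers.
#' @export
top_k <- function(ranking, k) {
  stopifnot(inherits(ranking, "feature_ranking"))
  n <- length(ranking$feature_ids)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n)
    stop_config("k must be in [1, ", n, "], got ", k)
  ranking$feature_ids[seq_len(k)]
}

#' ReliefF feature weights
#'
#' Instance-based feature weighting for continuous features: each instance
#' is compared against its `k` nearest hits (same class) and `k` nearest
#' misses (each opposite class, weighted by class prior). A feature is
#' rewarded when it separates an instance from its misses and penalized
#' when it separates it from its hits:
#' `W[f] <- W[f] - diff(f, R, hit)/(m k) + P(miss)/(1 - P(class(R))) *
#' diff(f, R, miss)/(m k)`, with `diff` the absolute difference normalized
#' by the feature's observed range. Neighbor distances are Manhattan sums
#' of the same normalized diffs. Every instance is used exactly once in a
#' fixed order (`m = n` samplings), so the procedure is deterministic and
#' invariant to row order.
#'
#' @param m Labeled [feature_matrix()] with both classes present.
#' @param k_neighbors Number of hits/misses per instance; must be smaller
#'   than the smaller class.
#' @return A [feature_ranking()] with one weight per feature.
#' @export
relieff_weights <- function(m, k_neighbors = 10L) {
  stopifnot(inherits(m, "feature_matrix"))
  y <- assert_labels(m$y)
  k <- as.integer(k_neighbors)
  n_min <- min(table(y))
  if (k < 1L || k >= n_min)
    stop_config("k_neighbors must be >= 1 and < size of the smaller class (",
                n_min, ")")
  X <- m$X
  n <- nrow(X)
  rng <- apply(X, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- 1  # constant features: diff is 0 everywhere regardless
  Xn <- sweep(X, 2L, rng, "/")
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  prior <- table(factor(y, levels = c(-1L, 1L))) / n
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    same <- which(y == y[i] & seq_len(n) != i)
    hits <- same[order(D[i, same], same)][seq_len(k)]
    W <- W - colSums(abs(Xn[hits, , drop = FALSE] -
                           rep(Xn[i, ], each = k))) / (n * k)
    for (cl in setdiff(c(-1L, 1L), y[i])) {
      other <- which(y == cl)
      misses <- other[order(D[i, other], other)][seq_len(k)]
      w_cl <- prior[[as.character(cl)]] / (1 - prior[[as.character(y[i])]])
      W <- W + w_cl * colSums(abs(Xn[misses, , drop = FALSE] -
                                    rep(Xn[i, ], each = k))) / (n * k)
    }
  }
  ord <- order_scores(W)
  feature_ranking("relieff", m$feature_ids[ord], W[ord],
                  params = list(k_neighbors = k, n_samplings = n))
}

# Shannon entropy (bits) of a label vector.
entropy_bits <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Fayyad-Irani MDL recursive binary discretization: returns accepted cut
# points (possibly none).
mdl_cuts <- function(x, y) {
  n <- length(x)
  if (n < 2L || length(unique(y)) < 2L) return(numeric(0))
  o <- order(x)
  xs <- x[o]; ys <- y[o]
  ux <- unique(xs)
  if (length(ux) < 2L) return(numeric(0))
  cand <- (ux[-1L] + ux[-length(ux)]) / 2
  hS <- entropy_bits(ys)
  best <- NULL; best_gain <- -Inf
  for (cut in cand) {
    left <- ys[xs <= cut]; right <- ys[xs > cut]
    gain <- hS - (length(left) * entropy_bits(left) +
                    length(right) * entropy_bits(right)) / n
    if (gain > best_gain + 1e-12) {
      best_gain <- gain
      best <- list(cut = cut, left = left, right = right)
    }
  }
  k0 <- length(unique(ys))
  k1 <- length(unique(best$left)); k2 <- length(unique(best$right))
  delta <- log2(3^k0 - 2) -
    (k0 * hS - k1 * entropy_bits(best$left) - k2 * entropy_bits(best$right))
  if (best_gain <= (log2(n - 1) + delta) / n) return(numeric(0))
  keep_l <- xs <= best$cut
  c(mdl_cuts(xs[keep_l], ys[keep_l]), best$cut,
    mdl_cuts(xs[!keep_l], ys[!keep_l]))
}

#' Information-gain feature scores
#'
#' Each continuous feature is discretized with the Fayyad-Irani minimum
#' description length (MDL) recursive binary-split method on the given
#' data; its score is then the information gain
#' `H(class) - H(class | discretized feature)` in bits. Features for which
#' the MDL criterion accepts no split score 0.
#'
#' @param m Labeled [feature_matrix()] with both classes present.
#' @return A [feature_ranking()] ordered by descending gain.
#' @export
infogain_scores <- function(m) {
  stopifnot(inherits(m, "feature_matrix"))
  y <- assert_labels(m$y)
  hY <- entropy_bits(y)
  scores <- apply(m$X, 2L, function(x) {
    cuts <- mdl_cuts(x, y)
    if (length(cuts) == 0L) return(0)
    bins <- findInterval(x, sort(cuts))
    hY - sum(vapply(split(y, bins), function(yy)
      length(yy) * entropy_bits(yy), 0)) / length(y)
  })
  ord <- order_scores(scores)
  feature_ranking("infogain", m$feature_ids[ord], scores[ord],
                  params = list(discretization = "mdl"))
}

# Three-state discretization at mean +/- one standard deviation.
discretize3 <- function(x) {
  mu <- mean(x); s <- stats::sd(x)
  ifelse(x < mu - s, -1L, ifelse(x > mu + s, 1L, 0L))
}

# Mutual information (bits) between two discrete vectors.
mutual_info_bits <- function(a, b) {
  tab <- table(a, b) / length(a)
  pi_ <- rowSums(tab); pj <- colSums(tab)
  terms <- tab * log2(tab / outer(pi_, pj))
  sum(terms[tab > 0])
}

#' Minimum-redundancy maximum-relevance (mRMR) selection order
#'
#' Greedy forward selection on mutual information after discretizing each
#' feature into three states at its mean plus/minus one standard deviation.
#' The first feature maximizes relevance `I(f; class)`; each subsequent
#' feature maximizes the MID (difference) criterion
#' `I(f; class) - mean over selected s of I(f; s)`. Ties take the lower
#' original feature index.
#'
#' @param m Labeled [feature_matrix()].
#' @param n_select Number of features to select, `1 <= n_select <= d`.
#' @return A [feature_ranking()] in selection order; `scores` are the
#'   stepwise criterion values (the first is plain relevance).
#' @export
mrmr_order <- function(m, n_select) {
  stopifnot(inherits(m, "feature_matrix"))
  y <- assert_labels(m$y)
  d <- ncol(m$X)
  if (!is.numeric(n_select) || length(n_select) != 1L ||
      n_select < 1L || n_select > d)
    stop_config("n_select must be in [1, ", d, "], got ", n_select)
  n_select <- as.integer(n_select)
  Xd <- apply(m$X, 2L, discretize3)
  relevance <- apply(Xd, 2L, mutual_info_bits, b = y)
  selected <- integer(0)
  crit_vals <- numeric(0)
  remaining <- seq_len(d)
  redundancy_sum <- numeric(d)
  for (step in seq_len(n_select)) {
    crit <- if (step == 1L) relevance[remaining] else
      relevance[remaining] - redundancy_sum[remaining] / length(selected)
    pick <- remaining[order(-crit, remaining)][1L]
    crit_vals <- c(crit_vals, crit[match(pick, remaining)])
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redundancy_sum[remaining] <- redundancy_sum[remaining] +
        apply(Xd[, remaining, drop = FALSE], 2L, mutual_info_bits,
              b = Xd[, pick])
  }
  feature_ranking("mrmr", m$feature_ids[selected], crit_vals,
                  params = list(discretization = "mean_pm_sd", criterion = "MID",
                                n_select = n_select))
}
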