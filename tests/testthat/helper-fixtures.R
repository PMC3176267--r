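# Fixture builders and independent brute-force oracles. The oracles are
# deliberately written as explicit loops sharing no code with the package.

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# A minimal two-record AAindex1 fixture in release format, one NA slot (W
# of the second record) and one record with values 1..20.
aaindex_fixture_lines <- function() {
  c("H TEST0001",
    "D seq of integers one to twenty",
    "R",
    "A test",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0     2.0     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0",
    "    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//",
    "H TEST0002",
    "D halves with a missing tryptophan",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     0.5     0.5     0.5     0.5     0.5     0.5     0.5     0.5     0.5     0.5",
    "     0.5     0.5     0.5     0.5     0.5     0.5     0.5      NA     0.5     0.5",
    "//")
}

tiny_labeled_matrix <- function(X, y, prefix = "s") {
  feature_matrix(X, sprintf("%s%d", prefix, seq_len(nrow(X))),
                 sprintf("f%d", seq_len(ncol(X))), y)
}

# ---- brute-force ReliefF (continuous attributes, m = n fixed order) ----
brute_relieff <- function(X, y, k) {
  n <- nrow(X); d <- ncol(X)
  rng <- numeric(d)
  for (f in 1:d) rng[f] <- max(X[, f]) - min(X[, f])
  rng[rng == 0] <- 1
  diff_f <- function(f, i, j) abs(X[i, f] - X[j, f]) / rng[f]
  dist_ij <- function(i, j) {
    s <- 0
    for (f in 1:d) s <- s + diff_f(f, i, j)
    s
  }
  classes <- c(-1L, 1L)
  prior <- c(sum(y == -1L), sum(y == 1L)) / n
  names(prior) <- c("-1", "1")
  W <- numeric(d)
  for (i in 1:n) {
    for (cl in classes) {
      idx <- setdiff(which(y == cl), i)
      dists <- vapply(idx, function(j) dist_ij(i, j), 0)
      sel <- idx[order(dists, idx)][1:k]
      for (j in sel) {
        for (f in 1:d) {
          if (cl == y[i]) {
            W[f] <- W[f] - diff_f(f, i, j) / (n * k)
          } else {
            w_cl <- prior[[as.character(cl)]] /
              (1 - prior[[as.character(y[i])]])
            W[f] <- W[f] + w_cl * diff_f(f, i, j) / (n * k)
          }
        }
      }
    }
  }
  W
}

# ---- brute-force discrete mutual information (bits) ----
brute_mi <- function(a, b) {
  n <- length(a)
  mi <- 0
  for (va in unique(a)) for (vb in unique(b)) {
    pab <- sum(a == va & b == vb) / n
    if (pab > 0)
      mi <- mi + pab * log2(pab / ((sum(a == va) / n) * (sum(b == vb) / n)))
  }
  mi
}

# ---- brute-force mRMR (MID) over explicitly tabulated MI values ----
brute_mrmr <- function(X, y, n_select) {
  d <- ncol(X)
  disc <- matrix(0L, nrow(X), d)
  for (f in 1:d) {
    mu <- mean(X[, f]); s <- sd(X[, f])
    for (i in seq_len(nrow(X)))
      disc[i, f] <- if (X[i, f] < mu - s) -1L else if (X[i, f] > mu + s) 1L else 0L
  }
  rel <- vapply(1:d, function(f) brute_mi(disc[, f], y), 0)
  mi_ff <- matrix(NA_real_, d, d)
  for (f in 1:d) for (g in 1:d) mi_ff[f, g] <- brute_mi(disc[, f], disc[, g])
  sel <- integer(0)
  for (step in seq_len(n_select)) {
    remaining <- setdiff(1:d, sel)
    crit <- vapply(remaining, function(f) {
      if (length(sel) == 0L) rel[f]
      else rel[f] - mean(mi_ff[f, sel])
    }, 0)
    sel <- c(sel, remaining[order(-crit, remaining)][1L])
  }
  sel
}

# ---- brute-force AUC by pair counting ----
brute_auc <- function(scores, y) {
  pos <- which(y == 1L); neg <- which(y == -1L)
  s <- 0
  for (i in pos) for (j in neg) {
    if (scores[i] > scores[j]) s <- s + 1
    else if (scores[i] == scores[j]) s <- s + 0.5
  }
  s / (length(pos) * length(neg))
}
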