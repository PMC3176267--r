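#' Specification of a synthetic two-class benchmark
#'
#' Describes a self-contained benchmark emulating the study design of a
#' binary protein-class problem: two sequence sets whose residue
#' compositions differ along a controllable number of axes with a
#' controllable effect size, plus a bank of synthetic amino-acid property
#' scales. Because the encoder measures exactly residue composition
#' (weighted by the scales), the class signal carried by the features is
#' analytically controllable.
#'
#' The negative class draws residues i.i.d. from `base_freq`; the positive
#' class shifts a total of `delta` extra probability mass, split equally
#' over the first `n_informative` residues of the canonical order
#' `A R N D C ...`, and renormalizes. `delta = 0` makes the classes
#' exchangeable (a null benchmark).
#'
#' @param n_pos,n_neg Training sequences per class (default 300 + 300).
#' @param n_test_pos,n_test_neg Held-out sequences per class.
#' @param length_range Sequence length bounds (uniform draw), min >= 10.
#' @param n_tables Number of synthetic property tables.
#' @param n_informative Number of residue-composition axes that differ
#'   between classes (0..20).
#' @param delta Effect size: total extra frequency mass moved onto the
#'   informative residues in the positive class (`>= 0`).
#' @param base_freq Baseline residue frequencies (20-vector, summed to 1);
#'   default uniform.
#' @param x_rate Rate at which residues are replaced by the non-standard
#'   letter `X`, exercising the encoder's missing-residue path.
#' @param missing_frac Fraction of missing (`NA`) entries in the synthetic
#'   property tables.
#' @param marker_contrast Property value given to the informative residues
#'   in the designated marker tables of [make_benchmark()].
#' @param seed Integer seed; all generation is deterministic given the spec.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_pos = 300L, n_neg = 300L,
                       n_test_pos = 100L, n_test_neg = 100L,
                       length_range = c(80L, 300L),
                       n_tables = 100L, n_informative = 5L, delta = 0.3,
                       base_freq = NULL, x_rate = 0.005,
                       missing_frac = 0.02, marker_contrast = 3,
                       seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length_range[1L] >= 10L,
            length_range[1L] <= length_range[2L],
            n_informative >= 0L, n_informative <= 20L, delta >= 0,
            n_tables >= 1L, x_rate >= 0, x_rate < 1,
            missing_frac >= 0, missing_frac < 1)
  if (is.null(base_freq)) base_freq <- rep(1 / 20, 20L)
  if (length(base_freq) != 20L || any(base_freq < 0) ||
      abs(sum(base_freq) - 1) > 1e-8)
    stop_config("base_freq must be 20 nonnegative frequencies summing to 1")
  structure(as.list(environment()), class = "synth_spec")
}

# Positive-class residue frequencies: delta mass onto the informative
# residues, renormalized. Errors if the shift breaks the simplex.
shifted_freq <- function(spec) {
  p <- spec$base_freq
  if (spec$n_informative > 0L && spec$delta > 0) {
    p[seq_len(spec$n_informative)] <-
      p[seq_len(spec$n_informative)] + spec$delta / spec$n_informative
    p <- p / sum(p)
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop_config("shifted frequencies leave the simplex")
  p
}

#' Generate synthetic amino-acid property tables
#'
#' Values are drawn independently per residue from a standard normal; a
#' fraction of entries is set missing (never all 20). Accessions are
#' `SYN0001`, `SYN0002`, ...; generation is deterministic per seed.
#'
#' @param n_tables Number of tables.
#' @param seed Integer seed.
#' @param missing_frac Fraction of missing entries.
#' @return A list of [property_table()] objects.
#' @export
synth_property_tables <- function(n_tables, seed = 1L, missing_frac = 0.02) {
  stopifnot(n_tables >= 1L)
  set.seed(seed)
  lapply(seq_len(n_tables), function(i) {
    v <- stats::rnorm(20L)
    miss <- stats::runif(20L) < missing_frac
    if (all(miss)) miss[1L] <- FALSE
    v[miss] <- NA_real_
    property_table(sprintf("SYN%04d", i), v,
                   title = "synthetic standard-normal property scale")
  })
}

#' Generate a synthetic two-class sequence set
#'
#' Sequences are drawn i.i.d. residue-by-residue from the class frequency
#' vectors of `spec` (see [synth_spec()]); lengths are uniform in
#' `length_range`; a small rate of positions is replaced by `X`.
#'
#' @param spec A [synth_spec()].
#' @param n_pos,n_neg Class sizes (default: the training sizes in `spec`).
#' @param seed Integer seed (default: `spec$seed`).
#' @param id_prefix Prefix for the generated sequence identifiers.
#' @return A list with `records` (data frame as from [read_fasta()]) and
#'   `y` (labels, `+1` then `-1` blocks).
#' @export
synth_sequences <- function(spec, n_pos = spec$n_pos, n_neg = spec$n_neg,
                            seed = spec$seed, id_prefix = "seq") {
  stopifnot(inherits(spec, "synth_spec"))
  p_pos <- shifted_freq(spec)
  p_neg <- spec$base_freq
  set.seed(seed)
  draw <- function(n, p, cls) {
    vapply(seq_len(n), function(i) {
      len <- sample(seq.int(spec$length_range[1L], spec$length_range[2L]), 1L)
      aa <- sample(AA_ORDER, len, replace = TRUE, prob = p)
      if (spec$x_rate > 0)
        aa[stats::runif(len) < spec$x_rate] <- "X"
      paste(aa, collapse = "")
    }, "")
  }
  res_pos <- draw(n_pos, p_pos)
  res_neg <- draw(n_neg, p_neg)
  records <- data.frame(
    id = c(sprintf("%s_pos%04d", id_prefix, seq_len(n_pos)),
           sprintf("%s_neg%04d", id_prefix, seq_len(n_neg))),
    description = rep(c("synthetic positive", "synthetic negative"),
                      c(n_pos, n_neg)),
    residues = c(res_pos, res_neg), stringsAsFactors = FALSE)
  list(records = records, y = rep(c(1L, -1L), c(n_pos, n_neg)))
}

#' Build a full synthetic benchmark (train/test feature matrices)
#'
#' Generates property tables and disjoint train/test sequence sets from
#' one [synth_spec()], encodes them, and reports the ground truth needed
#' by selector tests. When `delta > 0` and `n_informative > 0`, the first
#' `n_informative` tables are turned into *marker* scales: their values on
#' the informative residues are set to `marker_contrast`, so these
#' features carry the bulk of the class signal and form a known
#' informative set; at `delta = 0` no feature carries signal and the
#' ground-truth set is empty.
#'
#' @param spec A [synth_spec()].
#' @return A list with `train` and `test` (labeled [feature_matrix()]
#'   objects with disjoint sample ids), `tables`, `informative_features`
#'   (accessions of the marker tables; empty under the null), and `spec`.
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  tables <- synth_property_tables(spec$n_tables, seed = spec$seed + 1L,
                                  missing_frac = spec$missing_frac)
  informative <- character(0)
  if (spec$n_informative > 0L && spec$delta > 0) {
    for (i in seq_len(min(spec$n_informative, spec$n_tables))) {
      tables[[i]]$values[seq_len(spec$n_informative)] <- spec$marker_contrast
      informative <- c(informative, tables[[i]]$accession)
    }
  }
  train_seq <- synth_sequences(spec, spec$n_pos, spec$n_neg,
                               seed = spec$seed + 2L, id_prefix = "train")
  test_seq <- synth_sequences(spec, spec$n_test_pos, spec$n_test_neg,
                              seed = spec$seed + 3L, id_prefix = "test")
  list(train = encode_dataset(train_seq$records, tables, y = train_seq$y),
       test = encode_dataset(test_seq$records, tables, y = test_seq$y),
       tables = tables,
       informative_features = informative,
       spec = spec)
}
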