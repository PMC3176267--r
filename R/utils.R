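# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("luxpred_format_error", "error")))
}

#' @keywords internal
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("luxpred_config_error", "error")))
}

# The 20 standard amino acids in AAindex row order:
# first row A R N D C Q E G H I, second row L K M F P S T W Y V.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(name, " must be a single finite number")
  if (positive && x <= 0)
    stop_config(name, " must be > 0")
  invisible(x)
}

assert_labels <- function(y) {
  if (is.null(y) || !all(y %in% c(-1L, 1L)))
    stop_format("labels must be +1 or -1")
  if (length(unique(y)) < 2L)
    stop("both classes (+1 and -1) must be present")
  invisible(as.integer(y))
}

# Deterministic order: descending score, ties broken by ascending original
# index. `idx` is the original feature index of each score.
order_scores <- function(scores, idx = seq_along(scores)) {
  idx[order(-scores, idx)]
}
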