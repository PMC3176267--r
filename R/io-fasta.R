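#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a data frame of sequence records. Sequence lines
#' belonging to one header are concatenated, lowercase residues are mapped to
#' uppercase, and the translation-stop symbol `*` as well as alignment gaps
#' (`-`, `.`) are removed, so records read from aligned or raw files encode
#' identically. Non-standard residue letters (such as `B`, `Z`, `X`, `U`)
#' are retained; how they contribute to features is decided at encoding
#' time (see [encode_sequence()]).
#'
#' Only `>` headers are accepted; old-style `;` comment lines are rejected
#' rather than silently skipped.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with one row per record and columns `id` (first
#'   whitespace-delimited word of the header), `description` (remainder of
#'   the header, possibly empty) and `residues` (uppercase residue string).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 a luciferase", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  raw_lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(raw_lines, ">")))
    stop_format("not a FASTA file (no '>' header): ", path)
  if (any(startsWith(raw_lines, ";")))
    stop_format("';' comment lines are not supported: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop_format("FASTA parse failure in ", path, ": ",
                                    conditionMessage(e))
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- sub("^\\S+\\s*", "", headers)
  residues <- toupper(as.character(set))
  residues <- gsub("[*.\\-]", "", residues)
  empty <- !nzchar(residues)
  if (any(empty))
    stop_format("empty sequence for header '", ids[which(empty)[1L]], "'")
  data.frame(id = unname(ids), description = unname(desc),
             residues = unname(residues), stringsAsFactors = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' Inverse of [read_fasta()] for normalized records; reading the written
#' file reproduces the records exactly.
#'
#' @param records Data frame with columns `id`, `description`, `residues`.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "residues") %in% names(records)))
  desc <- records$description %||% rep("", nrow(records))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i])) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", header), con)
    seq <- records$residues[i]
    starts <- seq.int(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))), con)
  }
  invisible(path)
}
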