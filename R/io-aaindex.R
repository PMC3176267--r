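#' Construct an amino-acid property table
#'
#' One AAindex1 entry: a numerical index assigning one value to each of the
#' 20 standard amino acids. Missing values (printed as `NA` in the flat
#' file) are allowed for individual residues as long as at least one value
#' is present.
#'
#' @param accession Accession token (e.g. `"ARGP820101"`).
#' @param values Numeric vector of length 20 named by the one-letter amino
#'   acid codes in AAindex order (`A R N D C Q E G H I L K M F P S T W Y V`),
#'   or unnamed in that order. `NA` marks a missing value.
#' @param title Free-text description.
#' @return An object of class `property_table`.
#' @export
property_table <- function(accession, values, title = "") {
  if (!is.character(accession) || length(accession) != 1L || !nzchar(accession))
    stop_format("accession must be a non-empty string")
  values <- as.numeric(values)
  if (length(values) != 20L)
    stop_format("property table ", accession, ": expected 20 values, got ",
                length(values))
  if (all(is.na(values)))
    stop_format("property table ", accession, ": all 20 values missing")
  names(values) <- AA_ORDER
  structure(list(accession = accession, title = title, values = values),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat("<property_table>", x$accession, "-", x$title, "\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Read amino-acid indices from an AAindex1 flat file
#'
#' Parses the AAindex1 release format: records separated by `//`, with an
#' `H` line carrying the accession, `D` line(s) the title, and an `I` line
#' followed by two rows of ten values in the order
#' `A R N D C Q E G H I` / `L K M F P S T W Y V`. The literal token `NA`
#' is read as a missing value.
#'
#' @param path Path to an AAindex1 flat file.
#' @return A list of [property_table()] objects, in file order, named by
#'   accession.
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop_format("AAindex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop_format("empty AAindex file: ", path)
  rec_end <- grepl("^//", lines)
  rec_id <- cumsum(c(TRUE, head(rec_end, -1L)))
  tables <- list()
  for (rec in split(lines[!rec_end], rec_id[!rec_end])) {
    if (!any(grepl("^[A-Z] |^[A-Z]$", rec))) next  # trailing blank chunk
    h <- grep("^H ", rec, value = TRUE)
    if (length(h) != 1L)
      stop_format("AAindex record without a single 'H' accession line")
    accession <- trimws(sub("^H ", "", h))
    d <- grep("^D ", rec, value = TRUE)
    title <- if (length(d)) trimws(sub("^D ", "", d[1L])) else ""
    i_at <- grep("^I ", rec)
    if (length(i_at) != 1L)
      stop_format("record ", accession, ": missing 'I' index line")
    value_lines <- rec[-seq_len(i_at)]
    # value rows are the continuation lines (indented) directly after 'I'
    value_lines <- value_lines[!grepl("^[A-Z] ", value_lines)]
    tokens <- unlist(strsplit(trimws(value_lines), "\\s+"))
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) != 20L)
      stop_format("record ", accession, ": expected 20 value slots, found ",
                  length(tokens))
    values <- suppressWarnings(as.numeric(ifelse(tokens == "NA", NA, tokens)))
    bad <- !is.na(tokens) & tokens != "NA" & is.na(values)
    if (any(bad))
      stop_format("record ", accession, ": non-numeric value '",
                  tokens[which(bad)[1L]], "'")
    tables[[accession]] <- property_table(accession, values, title)
  }
  if (length(tables) == 0L)
    stop_format("no AAindex records found in ", path)
  tables
}

#' Write property tables in AAindex1 flat format
#'
#' Emits the minimal record structure ([read_aaindex1()] round-trips it):
#' `H`, `D` and `I` lines plus two rows of ten values, `//` terminated.
#'
#' @param tables List of [property_table()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(tables, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (tab in tables) {
    fmt <- ifelse(is.na(tab$values), "NA", formatC(tab$values, format = "g", digits = 15))
    writeLines(c(
      paste("H", tab$accession),
      paste("D", tab$title),
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      paste0("    ", paste(fmt[1:10], collapse = " ")),
      paste0("    ", paste(fmt[11:20], collapse = " ")),
      "//"), con)
  }
  invisible(path)
}
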