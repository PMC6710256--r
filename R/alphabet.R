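#' @useDynLib sspredict, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Canonical alphabets. The 20-letter order is fixed package-wide: every
# profile/one-hot column index refers to this order.
AA_STANDARD <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_NONSTANDARD <- c("B", "J", "O", "U", "Z", "X")
AA_ALL <- sort(c(AA_STANDARD, AA_NONSTANDARD))
SS8_STATES <- c("H", "G", "I", "E", "B", "T", "S", "C")
SS3_STATES <- c("H", "E", "C")

#' Amino-acid and secondary-structure alphabets
#'
#' The package works over the 26-letter amino-acid alphabet (20 standard
#' residues in the fixed canonical order `ACDEFGHIKLMNPQRSTVWY`, plus the
#' non-standard/unknown letters `B J O U Z X`) and the 8-state DSSP
#' secondary-structure alphabet `H G I E B T S C` ('C' is the catch-all
#' "other" state). The 3-state alphabet is `H E C`.
#'
#' @param what one of `"aa"`, `"aa_standard"`, `"aa_nonstandard"`,
#'   `"ss8"`, `"ss3"`.
#' @return character vector of symbols, in canonical order.
#' @export
#' @examples
#' ss_alphabet("ss3")
ss_alphabet <- function(what = c("aa", "aa_standard", "aa_nonstandard", "ss8", "ss3")) {
  switch(match.arg(what),
    aa = AA_ALL,
    aa_standard = AA_STANDARD,
    aa_nonstandard = AA_NONSTANDARD,
    ss8 = SS8_STATES,
    ss3 = SS3_STATES
  )
}

# Split a string into single characters.
chars <- function(x) {
  if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1]]
}

validate_aa <- function(sequence, id = "?") {
  cc <- chars(toupper(sequence))
  bad <- which(!(cc %in% AA_ALL))
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s': illegal amino-acid character '%s' at position %d",
      id, cc[bad[1]], bad[1]
    ), call. = FALSE)
  }
  paste(cc, collapse = "")
}

# DSSP writers sometimes emit ' ', '-' or '~' for unassigned residues;
# these are normalised to the catch-all coil state 'C'.
normalize_ss8 <- function(ss8, id = "?") {
  cc <- chars(toupper(ss8))
  cc[cc %in% c(" ", "-", "~")] <- "C"
  bad <- which(!(cc %in% SS8_STATES))
  if (length(bad) > 0L) {
    stop(sprintf(
      "record '%s': unknown secondary-structure symbol '%s' at position %d",
      id, cc[bad[1]], bad[1]
    ), call. = FALSE)
  }
  paste(cc, collapse = "")
}

#' Create a protein record
#'
#' A protein record holds an identifier, an amino-acid sequence over the
#' 26-letter alphabet, and optionally a DSSP 8-state secondary-structure
#' string of the same length. It is the unit all pipelines operate on.
#'
#' @param id record identifier.
#' @param sequence amino-acid sequence (no gaps).
#' @param ss8 optional 8-state string over `H G I E B T S C`; blank,
#'   `-` and `~` are normalised to `C`.
#' @return an object of class `protein_record`.
#' @export
#' @examples
#' protein_record("p1", "ACDE", "HHCC")
protein_record <- function(id, sequence, ss8 = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nchar(sequence) >= 1L)
  sequence <- validate_aa(sequence, id)
  if (grepl("-", sequence, fixed = TRUE)) {
    stop(sprintf("record '%s': sequence contains gap characters", id), call. = FALSE)
  }
  if (!is.null(ss8)) {
    ss8 <- normalize_ss8(ss8, id)
    if (nchar(ss8) != nchar(sequence)) {
      stop(sprintf(
        "record '%s': sequence length %d != secondary-structure length %d",
        id, nchar(sequence), nchar(ss8)
      ), call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, ss8 = ss8),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf(
    "<protein_record> %s (%d aa%s)\n", x$id, nchar(x$sequence),
    if (is.null(x$ss8)) "" else ", with ss8"
  ))
  invisible(x)
}

#' Map 8-state DSSP labels to 3 states
#'
#' The default dialect merges the three DSSP helix states into helix
#' (`H,G,I -> H`), the two strand states into sheet (`E,B -> E`) and the
#' rest into coil (`T,S,C -> C`). The `g_to_coil` dialect differs only in
#' assigning the 3-10 helix state `G` to coil, the convention used by
#' some older benchmark comparisons.
#'
#' @param ss8 string (or character vector of strings) over the 8-state
#'   alphabet.
#' @param dialect `"default"` or `"g_to_coil"`.
#' @return string(s) over `H E C`, same lengths as the input.
#' @export
#' @examples
#' map_ss8_to_ss3("GHIEBTSC")            # "HHHEECCC"
#' map_ss8_to_ss3("GHIEBTSC", "g_to_coil")
map_ss8_to_ss3 <- function(ss8, dialect = c("default", "g_to_coil")) {
  dialect <- match.arg(dialect)
  map <- ss3_of_ss8(dialect)
  out <- vapply(ss8, function(s) {
    cc <- chars(s)
    if (length(cc) == 0L) {
      return("")
    }
    bad <- which(!(cc %in% SS8_STATES))
    if (length(bad) > 0L) {
      stop(sprintf(
        "unknown secondary-structure symbol '%s' at position %d",
        cc[bad[1]], bad[1]
      ), call. = FALSE)
    }
    paste(map[cc], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (length(ss8) == 1L) out[[1]] else out
}

# Named map SS8 symbol -> SS3 symbol for a dialect.
ss3_of_ss8 <- function(dialect = "default") {
  map <- c(
    H = "H", G = "H", I = "H",
    E = "E", B = "E",
    T = "C", S = "C", C = "C"
  )
  if (dialect == "g_to_coil") map[["G"]] <- "C"
  map
}

#' Class composition of a labelled dataset
#'
#' Counts residues per secondary-structure class over a set of labelled
#' records, at the 8-state or (mapped) 3-state level.
#'
#' @param records list of [protein_record()]s, all carrying `ss8`.
#' @param level `"ss8"` or `"ss3"`.
#' @param dialect 8-to-3 mapping dialect, see [map_ss8_to_ss3()].
#' @return a data.frame with columns `class`, `count`, `fraction`
#'   (fractions sum to 1), rows in canonical class order.
#' @export
#' @examples
#' r <- protein_record("p", "ACDE", "HHEE")
#' class_counts(list(r), "ss3")
class_counts <- function(records, level = c("ss3", "ss8"),
                         dialect = c("default", "g_to_coil")) {
  level <- match.arg(level)
  dialect <- match.arg(dialect)
  if (is.null(names(records)) && inherits(records, "protein_record")) {
    records <- list(records)
  }
  labs <- unlist(lapply(records, function(r) {
    if (is.null(r$ss8)) {
      stop(sprintf("record '%s' carries no secondary-structure labels", r$id),
        call. = FALSE
      )
    }
    chars(r$ss8)
  }))
  classes <- if (level == "ss8") SS8_STATES else SS3_STATES
  if (level == "ss3") labs <- ss3_of_ss8(dialect)[labs]
  counts <- vapply(classes, function(k) sum(labs == k), numeric(1))
  data.frame(
    class = classes,
    count = as.numeric(counts),
    fraction = if (sum(counts) > 0) counts / sum(counts) else counts,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
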