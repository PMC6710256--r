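#' Reference DSSP composition table
#'
#' Published per-state residue counts of a large 25%-redundancy-reduced
#' PDB-derived training set and of two later, independent test sets
#' ("2017" and "2019" releases). Useful for calibrating class priors and
#' for checking 8-to-3-state mapping arithmetic against printed 3-state
#' fractions.
#'
#' @param set optional subset: `"training"`, `"test2017"` or
#'   `"test2019"`.
#' @return data.frame with columns `set`, `ss8`, `count`.
#' @export
#' @examples
#' comp <- reference_composition("training")
#' sum(comp$count) # 3,797,426 residues
reference_composition <- function(set = NULL) {
  path <- system.file("extdata", "dssp_composition_reference.csv",
    package = "sspredict", mustWork = TRUE
  )
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(set)) {
    set <- match.arg(set, unique(df$set))
    df <- df[df$set == set, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' 3-state fractions implied by an 8-state composition
#'
#' Maps per-state counts through the 8-to-3 class partition and returns
#' the resulting helix/sheet/coil residue fractions (as percentages).
#'
#' @param counts named numeric vector of 8-state counts (names over
#'   `H G I E B T S C`) or a data.frame with `ss8` and `count` columns.
#' @param dialect mapping dialect, see [map_ss8_to_ss3()].
#' @return named numeric vector (percent) over `H`, `E`, `C`.
#' @export
#' @examples
#' comp <- reference_composition("training")
#' composition_to_ss3_percent(comp) # ~ c(H = 38.0, E = 22.15, C = 39.85)
composition_to_ss3_percent <- function(counts, dialect = "default") {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$count, counts$ss8)
  }
  stopifnot(setequal(names(counts), SS8_STATES))
  map <- ss3_of_ss8(dialect)
  out <- stats::setNames(numeric(3), SS3_STATES)
  for (s in SS8_STATES) out[map[[s]]] <- out[map[[s]]] + counts[[s]]
  100 * out / sum(out)
}
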