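# Evaluation: Q accuracy (per residue and per protein), segment overlap
# scores (SOV'99 and a refined-allowance SOV), and the two-proportion
# significance threshold.

#' Maximal secondary-structure segments of a label string
#'
#' @param s label string.
#' @return data.frame with columns `class`, `start`, `end`, `len`
#'   (1-based inclusive); adjacent segments have different classes and
#'   the segments tile the string.
#' @export
ss_segments <- function(s) {
  cc <- chars(s)
  if (length(cc) == 0L) {
    return(data.frame(
      class = character(0), start = integer(0),
      end = integer(0), len = integer(0)
    ))
  }
  r <- rle(cc)
  end <- cumsum(r$lengths)
  data.frame(
    class = r$values, start = end - r$lengths + 1L, end = end,
    len = r$lengths, stringsAsFactors = FALSE
  )
}

check_paired_lengths <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  bad <- which(nchar(pred) != nchar(obs))
  if (length(bad) > 0L) {
    stop(sprintf(
      "protein %d: predicted length %d != observed length %d",
      bad[1], nchar(pred[bad[1]]), nchar(obs[bad[1]])
    ), call. = FALSE)
  }
}

#' Per-residue and per-protein accuracy (Q3/Q8)
#'
#' Accuracy is the fraction of residues whose predicted class equals
#' the observed class. The per-residue figure pools all residues of all
#' proteins; the per-protein figure averages the per-protein fractions
#' uniformly, so short proteins weigh as much as long ones.
#'
#' @param pred,obs character vectors of label strings (pairwise equal
#'   lengths).
#' @return list with `per_aa` and `per_protein`, both percentages.
#' @export
q_accuracy <- function(pred, obs) {
  check_paired_lengths(pred, obs)
  correct <- mapply(function(p, o) sum(chars(p) == chars(o)), pred, obs)
  len <- nchar(obs)
  list(
    per_aa = 100 * sum(correct) / sum(len),
    per_protein = 100 * mean(correct / len)
  )
}

# Shared segment-overlap machinery. For each class, overlapping
# observed/predicted segment pairs contribute
# len(s1) * (minov + delta) / maxov to the numerator and len(s1) to the
# normaliser; observed segments with no overlapping predicted segment of
# their class contribute len(s1) to the normaliser only. minov is the
# overlap length, maxov the length of the total extent of the pair.
sov_accumulate <- function(pred, obs, classes, delta_fun) {
  num <- stats::setNames(numeric(length(classes)), classes)
  den <- stats::setNames(numeric(length(classes)), classes)
  for (i in seq_along(obs)) {
    ro <- rle(chars(obs[i]))
    rp <- rle(chars(pred[i]))
    oe <- cumsum(ro$lengths)
    os <- oe - ro$lengths + 1L
    pe <- cumsum(rp$lengths)
    ps <- pe - rp$lengths + 1L
    for (cl in classes) {
      oi <- which(ro$values == cl)
      if (length(oi) == 0L) next
      pj <- which(rp$values == cl)
      for (a in oi) {
        ov <- pj[ps[pj] <= oe[a] & pe[pj] >= os[a]]
        if (length(ov) == 0L) {
          den[cl] <- den[cl] + ro$lengths[a]
          next
        }
        for (b in ov) {
          minov <- min(oe[a], pe[b]) - max(os[a], ps[b]) + 1L
          maxov <- max(oe[a], pe[b]) - min(os[a], ps[b]) + 1L
          delta <- delta_fun(minov, maxov, ro$lengths[a], rp$lengths[b])
          num[cl] <- num[cl] + ro$lengths[a] * (minov + delta) / maxov
          den[cl] <- den[cl] + ro$lengths[a]
        }
      }
    }
  }
  per_class <- ifelse(den > 0, 100 * num / den, NA_real_)
  overall <- if (sum(den) > 0) 100 * sum(num) / sum(den) else NA_real_
  list(overall = overall, per_class = per_class)
}

# labels must come from the 8-state alphabet (of which the 3-state one
# is a subset); `classes` only selects which classes are scored
sov_check_classes <- function(pred, obs) {
  seen <- unique(unlist(strsplit(c(pred, obs), "", fixed = TRUE)))
  bad <- setdiff(seen, SS8_STATES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown class symbol '%s'", bad[1]), call. = FALSE)
  }
}

#' Segment overlap score, 1999 definition (SOV'99)
#'
#' Segment-level score treating secondary-structure segments, not
#' single residues, as the prediction unit. Overlapping pairs score
#' `len(s1) * (minov + delta) / maxov` with the allowance
#' `delta = min(maxov - minov, minov, len(s1) %/% 2, len(s2) %/% 2)`;
#' the normaliser sums `len(s1)` over paired and unpaired observed
#' segments. The overall score pools numerators and normalisers over
#' all classes. Note the allowance deliberately forgives small boundary
#' shifts, so 100 does not imply a character-identical prediction.
#'
#' @param pred,obs character vectors of label strings.
#' @param classes class symbols to score over (default: all symbols
#'   occurring in `obs`/`pred`).
#' @return list with `overall` (%) and `per_class` (named vector, NA
#'   for classes absent from the observations).
#' @export
sov99 <- function(pred, obs, classes = NULL) {
  check_paired_lengths(pred, obs)
  sov_check_classes(pred, obs)
  if (is.null(classes)) {
    classes <- sort(unique(unlist(strsplit(c(obs, pred), "", fixed = TRUE))))
  }
  delta99 <- function(minov, maxov, len1, len2) {
    min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
  }
  sov_accumulate(pred, obs, classes, delta99)
}

#' Segment overlap score with a refined allowance
#'
#' Same pairing and normalisation as [sov99()], but the allowance is
#' scaled by the overlap quality and by `lambda`:
#' `delta = lambda * (minov / maxov) *
#'   min(maxov - minov, minov, len(s1) %/% 2, len(s2) %/% 2)`.
#' Because `minov / maxov < 1` whenever the pair is imperfect, the
#' allowance is strictly smaller than `maxov - minov`, so (unlike
#' SOV'99) the refined score is 100 only for character-identical
#' predictions. As `lambda -> 0` the score approaches the plain
#' no-allowance overlap ratio.
#'
#' @param pred,obs character vectors of label strings.
#' @param classes class symbols to score over.
#' @param lambda positive allowance scale in `(0, 1]`, default 1.
#' @return list with `overall` (%) and `per_class`.
#' @export
sov_refine <- function(pred, obs, classes = NULL, lambda = 1) {
  stopifnot(lambda > 0, lambda <= 1)
  check_paired_lengths(pred, obs)
  sov_check_classes(pred, obs)
  if (is.null(classes)) {
    classes <- sort(unique(unlist(strsplit(c(obs, pred), "", fixed = TRUE))))
  }
  delta_ref <- function(minov, maxov, len1, len2) {
    lambda * (minov / maxov) *
      min(maxov - minov, minov, len1 %/% 2L, len2 %/% 2L)
  }
  sov_accumulate(pred, obs, classes, delta_ref)
}

#' Significance threshold for an accuracy difference
#'
#' Two-proportion z threshold at p = 0.05: the accuracy difference (in
#' percentage points) beyond which two predictors evaluated on the same
#' `n` residues differ significantly, `100 * 1.96 * sqrt(2 p (1-p) / n)`.
#'
#' @param p accuracy as a fraction in (0, 1).
#' @param n_residues number of residues evaluated.
#' @return threshold in percentage points.
#' @export
significance_threshold <- function(p, n_residues) {
  stopifnot(p > 0, p < 1, n_residues >= 1)
  100 * 1.96 * sqrt(2 * p * (1 - p) / n_residues)
}

#' Full evaluation report
#'
#' @param pred,obs character vectors of label strings (same class
#'   level).
#' @param classes class symbols (default: all observed).
#' @return a `metrics_report` list: `q_per_aa`, `q_per_protein`,
#'   `sov99`, `sov_refine` (all %), `per_class` data.frame,
#'   `n_residues`, `n_proteins`.
#' @export
evaluate_predictions <- function(pred, obs, classes = NULL) {
  q <- q_accuracy(pred, obs)
  s99 <- sov99(pred, obs, classes)
  sre <- sov_refine(pred, obs, classes)
  structure(list(
    q_per_aa = q$per_aa, q_per_protein = q$per_protein,
    sov99 = s99$overall, sov_refine = sre$overall,
    per_class = data.frame(
      class = names(s99$per_class),
      sov99 = as.numeric(s99$per_class),
      sov_refine = as.numeric(sre$per_class),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    n_residues = sum(nchar(obs)), n_proteins = length(obs)
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<metrics_report> %d proteins, %d residues\n",
      "  Q per AA      %6.2f%%\n  Q per protein %6.2f%%\n",
      "  SOV'99        %6.2f%%\n  SOV_refine    %6.2f%%\n"
    ),
    x$n_proteins, x$n_residues, x$q_per_aa, x$q_per_protein,
    x$sov99, x$sov_refine
  ))
  invisible(x)
}

#' Write a metrics report as tab-separated text
#'
#' @param report a `metrics_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("metric\tvalue", con)
  for (nm in c("q_per_aa", "q_per_protein", "sov99", "sov_refine",
               "n_residues", "n_proteins")) {
    writeLines(sprintf("%s\t%.6g", nm, report[[nm]]), con)
  }
  for (i in seq_len(nrow(report$per_class))) {
    writeLines(sprintf(
      "sov99_%s\t%.6g", report$per_class$class[i], report$per_class$sov99[i]
    ), con)
  }
  invisible(path)
}
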