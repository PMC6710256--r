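# Per-residue input encodings.
#
# All encoders return an `encoded_sequence`: a numeric L x D matrix (one
# row per residue) with a `scheme` attribute. Widths: one-hot 20,
# profiles 22 (20 standard AA in canonical order, pooled
# non-standard/unknown, gap), concatenated two-source profiles 44,
# 3-state-augmented profiles 25 (or 47).

encoded_sequence <- function(mat, scheme) {
  structure(mat, scheme = scheme, class = c("encoded_sequence", class(mat)))
}

#' @export
print.encoded_sequence <- function(x, ...) {
  cat(sprintf(
    "<encoded_sequence> %d residues x %d inputs (scheme '%s')\n",
    nrow(x), ncol(x), attr(x, "scheme")
  ))
  invisible(x)
}

enc_scheme <- function(enc) attr(enc, "scheme") %||% "unknown"

profile_colnames <- c(AA_STANDARD, "nonstd", "gap")

#' One-hot encoding of a protein sequence
#'
#' Standard residues map to a unit vector over the 20 canonical
#' amino-acid positions; the non-standard/unknown letters
#' (`B J O U Z X`) map to the all-zero vector.
#'
#' @param record a [protein_record()].
#' @return an `encoded_sequence` of width 20.
#' @export
onehot_encode <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  cc <- chars(record$sequence)
  mat <- matrix(0, nrow = length(cc), ncol = 20L,
    dimnames = list(NULL, AA_STANDARD)
  )
  idx <- match(cc, AA_STANDARD)
  hit <- which(!is.na(idx))
  mat[cbind(hit, idx[hit])] <- 1
  encoded_sequence(mat, "onehot")
}

# Character matrix (rows x columns) of an alignment.
aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

# Map a character vector to profile slots 1..21 (NA for gaps).
profile_slot <- function(cc) {
  slot <- match(cc, AA_STANDARD)
  slot[is.na(slot) & cc != "-"] <- 21L
  slot
}

# Shared worker: build a 22-wide profile from per-row weights.
# gap_mode "all": gap fraction = weighted share of gaps among all rows;
# "internal": leading/trailing gap runs of each row are excluded from
# both numerator and denominator of the gap fraction.
profile_from_weights <- function(aln, w, gap_mode, scheme) {
  M <- aln_char_matrix(aln)
  L <- ncol(M)
  n <- nrow(M)
  stopifnot(length(w) == n)
  out <- matrix(0, nrow = L, ncol = 22L, dimnames = list(NULL, profile_colnames))
  nongap <- M != "-"
  # first..last non-gap position of each row (query row covers 1..L)
  span_lo <- apply(nongap, 1L, function(z) if (any(z)) which(z)[1] else L + 1L)
  span_hi <- apply(nongap, 1L, function(z) if (any(z)) max(which(z)) else 0L)
  for (j in seq_len(L)) {
    cc <- M[, j]
    slot <- profile_slot(cc)
    ok <- !is.na(slot)
    stopifnot(any(ok)) # query row is ungapped, so the column is non-empty
    acc <- numeric(21L)
    for (i in which(ok)) acc[slot[i]] <- acc[slot[i]] + w[i]
    tot <- sum(acc)
    if (tot > 0) out[j, 1:21] <- acc / tot
    if (gap_mode == "all") {
      out[j, 22L] <- sum(w[!ok]) / sum(w)
    } else {
      covers <- span_lo <= j & span_hi >= j
      denom <- sum(w[covers])
      out[j, 22L] <- if (denom > 0) sum(w[covers & !ok]) / denom else 0
    }
  }
  encoded_sequence(out, scheme)
}

#' Plain alignment profile
#'
#' Per column of the query-anchored alignment (query included as a row),
#' the first 21 components are residue frequencies (20 standard amino
#' acids in canonical order plus one pooled non-standard/unknown
#' component) normalised over the non-gap characters only; the 22nd
#' component is the total fraction of gap characters in the column.
#'
#' @param aln an [alignment()].
#' @return an `encoded_sequence` of width 22.
#' @export
plain_profile <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  profile_from_weights(aln, rep(1, length(aln$rows)), "all", "plain")
}

#' Entropy-based sequence weights
#'
#' Each alignment row is weighted by the total surprisal of its residues
#' under the per-column residue frequencies:
#' \deqn{W_{seq} = \sum_n -\log f[aa_{seq}(n)]}
#' where `f` is the relative frequency of the row's residue within
#' column `n`, counted over non-gap characters only; gap positions of a
#' row contribute no term. Rare sequences therefore get large weights,
#' maximising the information content of the weighted profile. The log
#' base is irrelevant: it rescales all weights by a common factor that
#' cancels in profile normalisation (natural log is used). If every
#' weight is zero (all rows identical) the weights fall back to uniform.
#'
#' @param aln an [alignment()].
#' @param base log base (default `exp(1)`).
#' @return numeric vector of non-negative weights, one per row.
#' @export
sequence_weights <- function(aln, base = exp(1)) {
  stopifnot(inherits(aln, "alignment"))
  M <- aln_char_matrix(aln)
  n <- nrow(M)
  W <- numeric(n)
  for (j in seq_len(ncol(M))) {
    cc <- M[, j]
    ok <- cc != "-"
    freq <- table(cc[ok]) / sum(ok)
    W[ok] <- W[ok] - log(as.numeric(freq[cc[ok]]), base = base)
  }
  if (all(W == 0)) W <- rep(1 / n, n) # degenerate: all rows identical
  W
}

#' Entropy-weighted alignment profile
#'
#' As [plain_profile()], but residue counts are replaced by sums of the
#' per-row weights from [sequence_weights()]. The gap component is also
#' weight-based but excludes *external* gaps: the leading and trailing
#' gap runs of each row (outside its first..last residue span) count
#' neither in the numerator nor the denominator of the gap fraction.
#'
#' @param aln an [alignment()].
#' @return an `encoded_sequence` of width 22.
#' @export
weighted_profile <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  profile_from_weights(aln, sequence_weights(aln), "internal", "weighted")
}

#' Clip a profile to the query residues
#'
#' Overwrites, in every row of a 22-wide profile, the component
#' associated with the query's residue at that position with 1 (the
#' pooled non-standard component for non-standard residues). Nothing is
#' renormalised, so the encoding remains lossless: the overwritten value
#' is recoverable as 1 minus the sum of the other 20 of the first 21
#' components. Clipping merges one-hot information (which residue is
#' actually there) into the evolutionary profile at no cost in width.
#'
#' @param enc an `encoded_sequence` of width 22.
#' @param query the [protein_record()] the profile belongs to.
#' @return an `encoded_sequence` of width 22 (scheme suffix `_clipped`).
#' @export
clip_profile <- function(enc, query) {
  stopifnot(ncol(enc) == 22L, inherits(query, "protein_record"))
  if (nrow(enc) != nchar(query$sequence)) {
    stop("profile length does not match query length", call. = FALSE)
  }
  slot <- profile_slot(chars(query$sequence))
  out <- unclass(enc)
  out[cbind(seq_len(nrow(out)), slot)] <- 1
  encoded_sequence(out, paste0(enc_scheme(enc), "_clipped"))
}

#' Combine two alignments of the same query
#'
#' `union` concatenates the two row sets, de-duplicating identical
#' aligned rows (the query appears once, first). `intersection` keeps
#' the rows of `a` whose ungapped sequence also occurs among the
#' ungapped rows of `b` (the query row is always kept). Combining the
#' homolog sets of two alignment sources before profile construction is
#' one way of pooling their evolutionary information.
#'
#' @param a,b [alignment()]s over the same query sequence.
#' @param mode `"union"` or `"intersection"`.
#' @return an [alignment()].
#' @export
combine_alignments <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "alignment"), inherits(b, "alignment"))
  if (!identical(a$query$sequence, b$query$sequence)) {
    stop("alignments have different query sequences", call. = FALSE)
  }
  rows <- if (mode == "union") {
    unique(c(a$rows, b$rows))
  } else {
    ungap <- function(x) gsub("-", "", x, fixed = TRUE)
    keep <- ungap(a$rows) %in% ungap(b$rows)
    unique(c(a$query$sequence, a$rows[keep]))
  }
  rows <- c(a$query$sequence, setdiff(rows, a$query$sequence))
  alignment(a$query, rows = rows[-1])
}

#' Average or concatenate two profiles
#'
#' `average_profiles` takes the componentwise mean of two equally sized
#' encodings (a convex combination, so first-21 normalisation is
#' preserved); `concat_profiles` concatenates them per residue, e.g. two
#' 22-wide profiles from different alignment sources into a 44-wide
#' input.
#'
#' @param p,q `encoded_sequence`s of equal dimensions.
#' @return an `encoded_sequence`.
#' @export
average_profiles <- function(p, q) {
  if (!all(dim(p) == dim(q))) {
    stop("profiles have different dimensions", call. = FALSE)
  }
  encoded_sequence((unclass(p) + unclass(q)) / 2, "averaged")
}

#' @rdname average_profiles
#' @export
concat_profiles <- function(p, q) {
  if (nrow(p) != nrow(q)) {
    stop("profiles have different lengths", call. = FALSE)
  }
  encoded_sequence(cbind(unclass(p), unclass(q)), "concat")
}

#' Augment an encoding with 3-state probabilities
#'
#' Concatenates per-residue 3-state class probabilities (e.g. the output
#' of a 3-state ensemble) to the right of an existing encoding, turning
#' a 22-wide profile into the 25-wide input of an 8-state model (or a
#' 44-wide concatenated profile into 47 inputs).
#'
#' @param enc an `encoded_sequence`.
#' @param ss3_probs numeric L x 3 matrix of row-normalised class
#'   probabilities (tolerance 1e-6).
#' @return an `encoded_sequence` (scheme `ss3_augmented`).
#' @export
augment_with_ss3 <- function(enc, ss3_probs) {
  ss3_probs <- as.matrix(ss3_probs)
  if (nrow(enc) != nrow(ss3_probs) || ncol(ss3_probs) != 3L) {
    stop("ss3 probability matrix must be L x 3 with L matching the encoding",
      call. = FALSE
    )
  }
  bad <- which(abs(rowSums(ss3_probs) - 1) > 1e-6 | apply(ss3_probs, 1, min) < 0)
  if (length(bad) > 0L) {
    stop(sprintf("ss3 probabilities at position %d are not a distribution", bad[1]),
      call. = FALSE
    )
  }
  encoded_sequence(cbind(unclass(enc), unclass(ss3_probs)), "ss3_augmented")
}

#' Windowed input vector at one position
#'
#' Concatenates the encoding rows `n-l ... n+l` into a single vector of
#' width `(2l+1) * D`; rows beyond the termini contribute zero vectors.
#' This is the input a window-based feed-forward network sees at
#' position `n`.
#'
#' @param enc an `encoded_sequence` (L x D).
#' @param n 1-based residue position.
#' @param l window half-width (`l = 0` gives just row `n`).
#' @return numeric vector of length `(2l+1) * D`.
#' @export
make_window_input <- function(enc, n, l) {
  if (l < 0) stop("window half-width must be non-negative", call. = FALSE)
  L <- nrow(enc)
  D <- ncol(enc)
  stopifnot(n >= 1L, n <= L)
  out <- numeric((2L * l + 1L) * D)
  for (k in seq(-l, l)) {
    p <- n + k
    if (p >= 1L && p <= L) {
      out[(k + l) * D + seq_len(D)] <- enc[p, ]
    }
  }
  out
}
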