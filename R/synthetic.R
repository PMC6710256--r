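# Synthetic dataset generator.
#
# Emulates the statistical structure the predictor exploits in real
# data, at desk scale and with no downloads: secondary structure as
# segments with class-dependent mean lengths, amino-acid emission with
# class-dependent propensities, and simulated homolog alignments (two
# pseudo-sources with different depths and substitution rates) so that
# alignment profiles carry learnable evolutionary signal.

# Default amino-acid propensity multipliers per 3-state class, canonical
# residue order. Helix formers are enriched in H, beta-branched and
# aromatic residues in E, breakers/polar residues in C (Chou-Fasman-like
# in spirit; the values are generator choices, not fits).
default_propensity <- function() {
  m <- rbind(
    H = c(1.6, 0.8, 0.8, 1.6, 1.0, 0.5, 1.0, 1.0, 1.2, 1.5,
          1.4, 0.8, 0.3, 1.3, 1.1, 0.8, 0.8, 0.9, 1.1, 0.9),
    E = c(0.8, 1.3, 0.6, 0.8, 1.4, 0.7, 0.9, 1.7, 0.8, 1.2,
          1.0, 0.7, 0.4, 0.9, 0.9, 0.9, 1.2, 1.8, 1.3, 1.4),
    C = c(0.8, 0.9, 1.5, 0.9, 0.7, 1.7, 1.0, 0.6, 1.0, 0.7,
          0.8, 1.4, 1.8, 1.0, 1.0, 1.4, 1.1, 0.6, 0.8, 0.9)
  )
  colnames(m) <- AA_STANDARD
  m / rowSums(m)
}

# Default 8-state sub-state distributions within each 3-state class,
# approximating the DSSP state composition of large non-redundant PDB
# sets (alpha helix dominates the helix class, bridges are rare, the
# coil class splits between C, S and T).
default_substates <- function() {
  list(
    H = c(H = 0.905, G = 0.094, I = 0.001),
    E = c(E = 0.951, B = 0.049),
    C = c(C = 0.505, S = 0.219, T = 0.276)
  )
}

#' Synthetic dataset configuration
#'
#' Defaults describe the fixture used throughout the package: 200
#' proteins of 50-150 residues, helix/sheet/coil residue targets around
#' 38/22/40% (the composition of large non-redundant PDB sets), mean
#' segment lengths of 10/5/6 residues, and two alignment sources with
#' different depths and substitution rates (emulating two homology
#' -search tools run on different databases).
#'
#' @param n_proteins number of proteins.
#' @param length_range inclusive residue-length range.
#' @param target_ss3 named residue-fraction targets for H/E/C; segment
#'   class draw weights are `target / mean_seg_len` normalised (see
#'   [expected_ss3_fractions()] for the exact implied fractions).
#' @param mean_seg_len named mean segment lengths (geometric).
#' @param substates per-class 8-state sub-state distributions.
#' @param propensity 3 x 20 amino-acid emission table (rows H/E/C).
#' @param homologs_a,homologs_b homolog rows per alignment source.
#' @param sub_rate_a,sub_rate_b per-position substitution rates.
#' @param indel_rate_a,indel_rate_b per-position deletion (gap) rates.
#' @param seed integer seed; the full generation pipeline is
#'   deterministic given it.
#' @return a `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200L, length_range = c(50L, 150L),
                             target_ss3 = c(H = 0.38, E = 0.22, C = 0.40),
                             mean_seg_len = c(H = 10, E = 5, C = 6),
                             substates = default_substates(),
                             propensity = default_propensity(),
                             homologs_a = 25L, sub_rate_a = 0.35, indel_rate_a = 0.05,
                             homologs_b = 10L, sub_rate_b = 0.20, indel_rate_b = 0.10,
                             seed = 1L) {
  stopifnot(
    n_proteins >= 1L, length(length_range) == 2L, length_range[1] >= 1L,
    length_range[1] <= length_range[2],
    identical(names(target_ss3), SS3_STATES) || setequal(names(target_ss3), SS3_STATES),
    all(target_ss3 >= 0), sum(target_ss3) > 0, all(mean_seg_len >= 1),
    all(vapply(substates, function(p) abs(sum(p) - 1) < 1e-6, logical(1))),
    nrow(propensity) == 3L, ncol(propensity) == 20L,
    sub_rate_a >= 0, sub_rate_a <= 1, sub_rate_b >= 0, sub_rate_b <= 1,
    indel_rate_a >= 0, indel_rate_a <= 1, indel_rate_b >= 0, indel_rate_b <= 1
  )
  target_ss3 <- target_ss3[SS3_STATES] / sum(target_ss3)
  mean_seg_len <- mean_seg_len[SS3_STATES]
  class_weights <- target_ss3 / mean_seg_len
  class_weights <- class_weights / sum(class_weights)
  structure(list(
    n_proteins = as.integer(n_proteins),
    length_range = as.integer(length_range),
    target_ss3 = target_ss3, mean_seg_len = mean_seg_len,
    class_weights = class_weights,
    substates = substates[SS3_STATES],
    propensity = propensity / rowSums(propensity),
    homologs_a = as.integer(homologs_a), sub_rate_a = sub_rate_a,
    indel_rate_a = indel_rate_a,
    homologs_b = as.integer(homologs_b), sub_rate_b = sub_rate_b,
    indel_rate_b = indel_rate_b,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Exact expected 3-state residue fractions of the generator
#'
#' The generator draws segment classes from a jump chain with no
#' immediate self-transition (next-class weights proportional to the
#' configured class weights, excluding the current class) and geometric
#' segment lengths. The expected residue fraction of a class is its
#' stationary jump probability weighted by its mean segment length.
#'
#' @param cfg a [synthetic_config()].
#' @return named numeric vector over H/E/C summing to 1.
#' @export
expected_ss3_fractions <- function(cfg) {
  w <- cfg$class_weights
  if (any(w >= 1)) {
    return(stats::setNames(as.numeric(w >= 1), SS3_STATES))
  }
  P <- matrix(0, 3, 3, dimnames = list(SS3_STATES, SS3_STATES))
  for (i in 1:3) {
    for (j in 1:3) if (i != j) P[i, j] <- w[j] / (1 - w[i])
  }
  e <- eigen(t(P))
  pi <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi <- pi / sum(pi)
  f <- pi * cfg$mean_seg_len
  stats::setNames(f / sum(f), SS3_STATES)
}

#' Generate one 8-state secondary-structure string
#'
#' Semi-Markov generation: draw a 3-state class (never repeating the
#' previous class), a geometric segment length with the class's mean,
#' then per-position 8-state sub-labels from the class's sub-state
#' distribution; truncate at the requested length. Uses the current RNG
#' stream.
#'
#' @param length string length.
#' @param cfg a [synthetic_config()].
#' @return an 8-state label string.
#' @export
generate_ss <- function(length, cfg) {
  stopifnot(length >= 1L)
  out <- character(0)
  prev <- 0L
  while (length(out) < length) {
    w <- cfg$class_weights
    if (prev > 0L && sum(w[-prev]) > 0) {
      # no immediate self-transition (unless only one class has mass)
      w[prev] <- 0
      w <- w / sum(w)
    }
    cls <- sample.int(3L, 1L, prob = w)
    seg_len <- 1L + stats::rgeom(1L, 1 / cfg$mean_seg_len[cls])
    sub <- cfg$substates[[cls]]
    out <- c(out, sample(names(sub), seg_len, replace = TRUE, prob = sub))
    prev <- cls
  }
  paste(out[seq_len(length)], collapse = "")
}

#' Emit an amino-acid sequence for a secondary-structure string
#'
#' Each residue is drawn from the propensity-table row of the 3-state
#' class of its position. Uses the current RNG stream.
#'
#' @param ss8 8-state label string.
#' @param propensity 3 x 20 emission table (rows H/E/C, canonical
#'   residue order).
#' @return amino-acid sequence string.
#' @export
emit_sequence <- function(ss8, propensity) {
  cls3 <- chars(map_ss8_to_ss3(ss8))
  aa <- vapply(cls3, function(k) {
    sample(AA_STANDARD, 1L, prob = propensity[k, ])
  }, character(1), USE.NAMES = FALSE)
  paste(aa, collapse = "")
}

#' Simulate a homolog alignment for a labelled record
#'
#' Each homolog row is derived from the query position by position:
#' deleted (gap) with probability `indel_rate`, otherwise substituted
#' with probability `sub_rate` by a residue drawn from the propensity
#' row of the position's class, otherwise copied. No insertion states
#' are generated, so the alignment is query-anchored by construction.
#' The query is included as the first row. Uses the current RNG stream.
#'
#' @param record a labelled [protein_record()].
#' @param n number of homolog rows.
#' @param sub_rate,indel_rate per-position rates in `[0, 1]`.
#' @param propensity 3 x 20 emission table.
#' @return an [alignment()].
#' @export
simulate_homologs <- function(record, n, sub_rate, indel_rate, propensity) {
  stopifnot(inherits(record, "protein_record"), !is.null(record$ss8), n >= 0L)
  qc <- chars(record$sequence)
  cls3 <- chars(map_ss8_to_ss3(record$ss8))
  L <- length(qc)
  rows <- vapply(seq_len(n), function(i) {
    cc <- qc
    gap <- stats::runif(L) < indel_rate
    sub <- !gap & stats::runif(L) < sub_rate
    for (p in which(sub)) {
      cc[p] <- sample(AA_STANDARD, 1L, prob = propensity[cls3[p], ])
    }
    cc[gap] <- "-"
    paste(cc, collapse = "")
  }, character(1))
  alignment(record, rows = rows)
}

#' Generate a full synthetic dataset
#'
#' Generates `cfg$n_proteins` labelled records plus, for each record,
#' homolog alignments from two pseudo-sources A and B with different
#' depths and substitution/indel rates (so that profile averaging,
#' concatenation and alignment-combination experiments are meaningful).
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @return a `synthetic_dataset`: list with `records`, `alignments`
#'   (lists `a` and `b`, parallel to `records`) and `config`.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  records <- vector("list", cfg$n_proteins)
  aln_a <- vector("list", cfg$n_proteins)
  aln_b <- vector("list", cfg$n_proteins)
  for (i in seq_len(cfg$n_proteins)) {
    lens <- seq(cfg$length_range[1], cfg$length_range[2])
    L <- lens[sample.int(length(lens), 1L)]
    ss8 <- generate_ss(L, cfg)
    seqs <- emit_sequence(ss8, cfg$propensity)
    rec <- protein_record(sprintf("syn%04d", i), seqs, ss8)
    records[[i]] <- rec
    aln_a[[i]] <- simulate_homologs(
      rec, cfg$homologs_a, cfg$sub_rate_a, cfg$indel_rate_a, cfg$propensity
    )
    aln_b[[i]] <- simulate_homologs(
      rec, cfg$homologs_b, cfg$sub_rate_b, cfg$indel_rate_b, cfg$propensity
    )
  }
  structure(list(
    records = records, alignments = list(a = aln_a, b = aln_b), config = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d proteins (%d residues), %d+%d homologs per protein (sources A/B), seed %d\n",
    length(x$records), sum(vapply(x$records, function(r) nchar(r$sequence), numeric(1))),
    x$config$homologs_a, x$config$homologs_b, x$config$seed
  ))
  invisible(x)
}

#' Encode the records of a synthetic dataset
#'
#' Convenience wrapper producing one encoding per record: one-hot from
#' the sequence, or a (plain/weighted, optionally clipped) profile from
#' the chosen alignment source.
#'
#' @param ds a `synthetic_dataset` (or list with `records`,
#'   `alignments`).
#' @param scheme one of `"onehot"`, `"plain"`, `"weighted"`,
#'   `"weighted_clipped"`.
#' @param source `"a"` or `"b"` (ignored for one-hot).
#' @return list of `encoded_sequence`s, parallel to `ds$records`.
#' @export
encode_records <- function(ds, scheme = c("weighted_clipped", "weighted", "plain", "onehot"),
                           source = c("a", "b")) {
  scheme <- match.arg(scheme)
  source <- match.arg(source)
  if (scheme == "onehot") {
    return(lapply(ds$records, onehot_encode))
  }
  lapply(seq_along(ds$records), function(i) {
    aln <- ds$alignments[[source]][[i]]
    enc <- if (scheme == "plain") plain_profile(aln) else weighted_profile(aln)
    if (scheme == "weighted_clipped") enc <- clip_profile(enc, ds$records[[i]])
    enc
  })
}
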