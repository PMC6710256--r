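# Independent oracles and small generators shared across tests.

# Brute-force segment-overlap oracle, written independently of the
# package implementation: explicit position scans and pair loops.
oracle_segments <- function(s) {
  cc <- strsplit(s, "", fixed = TRUE)[[1]]
  segs <- list()
  i <- 1L
  while (i <= length(cc)) {
    j <- i
    while (j < length(cc) && cc[j + 1L] == cc[i]) j <- j + 1L
    segs[[length(segs) + 1L]] <- list(class = cc[i], start = i, end = j)
    i <- j + 1L
  }
  segs
}

oracle_sov <- function(pred, obs, refine = FALSE, lambda = 1) {
  num <- 0
  den <- 0
  for (i in seq_along(obs)) {
    so <- oracle_segments(obs[i])
    sp <- oracle_segments(pred[i])
    for (s1 in so) {
      l1 <- s1$end - s1$start + 1L
      paired <- FALSE
      for (s2 in sp) {
        if (s2$class != s1$class) next
        if (s2$start > s1$end || s2$end < s1$start) next
        paired <- TRUE
        l2 <- s2$end - s2$start + 1L
        minov <- min(s1$end, s2$end) - max(s1$start, s2$start) + 1L
        maxov <- max(s1$end, s2$end) - min(s1$start, s2$start) + 1L
        dl <- min(maxov - minov, minov, l1 %/% 2L, l2 %/% 2L)
        if (refine) dl <- lambda * (minov / maxov) * dl
        num <- num + l1 * (minov + dl) / maxov
        den <- den + l1
      }
      if (!paired) den <- den + l1
    }
  }
  if (den == 0) NA_real_ else 100 * num / den
}

# every label string of a given length over an alphabet
all_label_strings <- function(len, alphabet = c("H", "E", "C")) {
  g <- do.call(expand.grid, c(rep(list(alphabet), len),
    stringsAsFactors = FALSE
  ))
  apply(g, 1L, paste, collapse = "")
}

# random query-anchored alignment (query ungapped, first row)
random_alignment <- function(L = sample(4:10, 1), n_hom = sample(0:6, 1),
                             gap_p = 0.2) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  q <- paste(sample(aa, L, replace = TRUE), collapse = "")
  rows <- replicate(n_hom, {
    cc <- sample(aa, L, replace = TRUE)
    cc[runif(L) < gap_p] <- "-"
    paste(cc, collapse = "")
  })
  alignment(protein_record("q", q), rows = as.character(rows))
}

# random valid profile row set (first 21 normalised) for clip tests
random_profile <- function(L = 8) {
  m <- matrix(runif(L * 22), L, 22,
    dimnames = list(NULL, c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "nonstd", "gap"))
  )
  m[, 1:21] <- m[, 1:21, drop = FALSE] / rowSums(m[, 1:21, drop = FALSE])
  sspredict:::encoded_sequence(m, "weighted")
}

random_ss8 <- function(L) {
  paste(sample(c("H", "G", "I", "E", "B", "T", "S", "C"), L, replace = TRUE),
    collapse = ""
  )
}

tiny_cbrcnn <- function(n_inputs = 6, n_classes = 3) {
  cbrcnn_config(n_inputs, n_classes,
    nf = 4, nb = 4, nhf = 5, nhb = 5, nhy = 6,
    cofb = 2, cseg = 3, cwin = 3
  )
}

rand_enc <- function(L, D, scheme = "test") {
  sspredict:::encoded_sequence(matrix(runif(L * D), L, D), scheme)
}

# stage-1 cross-entropy of a cascaded model, via the public forward pass
cbrcnn_stage1_loss <- function(theta, X, y, cfg) {
  p <- sspredict:::from_flat(cfg, theta)
  enc <- sspredict:::encoded_sequence(t(X), "t")
  P1 <- forward_cbrcnn(p, enc, cfg)$stage1
  -sum(log(P1[cbind(seq_along(y), y)]))
}
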