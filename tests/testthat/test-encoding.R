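test_that("one-hot encoding maps standard residues to unit vectors", {
  e <- onehot_encode(protein_record("p", "A"))
  expect_equal(dim(e), c(1L, 20L))
  expect_equal(unname(unclass(e)[1, "A"]), 1)
  expect_equal(sum(e), 1)
  # non-standard residues are the all-zero vector
  ex <- onehot_encode(protein_record("p", "AX"))
  expect_equal(sum(ex[2, ]), 0)
  expect_equal(sum(ex[1, ]), 1)
})

test_that("plain profiles normalise residues over non-gaps and count gaps separately", {
  # single-row alignment: one-hot extended to width 22
  aln <- alignment(protein_record("q", "ACD"))
  p <- plain_profile(aln)
  expect_equal(dim(p), c(3L, 22L))
  expect_equal(unname(unclass(p)[cbind(1:3, match(c("A", "C", "D"), ss_alphabet("aa_standard")))]), rep(1, 3))
  expect_equal(unname(rowSums(p[, 1:21])), rep(1, 3))
  expect_equal(unname(p[, 22]), rep(0, 3))

  two <- alignment(protein_record("q", "A"), rows = "C")
  pt <- unclass(plain_profile(two))
  expect_equal(unname(pt[1, "A"]), 0.5)
  expect_equal(unname(pt[1, "C"]), 0.5)
  expect_equal(unname(pt[1, "gap"]), 0)

  gapped <- alignment(protein_record("q", "A"), rows = "-")
  pg <- unclass(plain_profile(gapped))
  expect_equal(unname(pg[1, "A"]), 1) # normalised without gaps
  expect_equal(unname(pg[1, "gap"]), 0.5)

  # non-standard residues pool into the 21st component
  nonstd <- alignment(protein_record("q", "A"), rows = "X")
  expect_equal(unname(unclass(plain_profile(nonstd))[1, "nonstd"]), 0.5)
})

test_that("sequence weights implement per-column surprisal sums", {
  sym <- alignment(protein_record("q", "AC"), rows = "AD")
  w <- sequence_weights(sym)
  expect_equal(w[1], w[2])

  tri <- alignment(protein_record("q", "AA"), rows = c("AC", "CC"))
  w3 <- sequence_weights(tri)
  expect_equal(w3, c(log(9 / 2), 2 * log(3 / 2), log(9 / 2)), tolerance = 1e-12)

  # all-identical rows: zero surprisal everywhere, uniform fallback
  same <- alignment(protein_record("q", "AC"), rows = c("AC", "AC"))
  expect_equal(sequence_weights(same), rep(1 / 3, 3))
})

test_that("weighted profiles reweight columns and ignore external gaps", {
  tri <- alignment(protein_record("q", "AA"), rows = c("AC", "CC"))
  w <- sequence_weights(tri)
  wp <- unclass(weighted_profile(tri))
  expect_equal(unname(wp[1, "A"]), unname((w[1] + w[2]) / sum(w)), tolerance = 1e-12)
  expect_equal(unname(wp[1, "A"]), 0.606, tolerance = 1e-3)
  expect_equal(unname(wp[1, "C"]), 0.394, tolerance = 1e-3)

  # equal weights: weighted profile equals plain profile on the first 21
  sym <- alignment(protein_record("q", "AC"), rows = "AD")
  expect_equal(
    unclass(weighted_profile(sym))[, 1:21],
    unclass(plain_profile(sym))[, 1:21],
    tolerance = 1e-12
  )

  # external gaps contribute nothing to the gap frequency
  ext <- alignment(protein_record("q", "ACDE"), rows = "-CD-")
  wpe <- unclass(weighted_profile(ext))
  expect_equal(unname(wpe[c(1, 4), "gap"]), c(0, 0))
  # an internal gap does
  int <- alignment(protein_record("q", "ACDE"), rows = "A-DE")
  expect_gt(unclass(weighted_profile(int))[2, "gap"], 0)
})

test_that("weighted profiles are invariant to the log base of the weights", {
  set.seed(21)
  for (i in 1:15) {
    aln <- random_alignment(n_hom = sample(2:6, 1))
    we <- sequence_weights(aln, base = exp(1))
    w2 <- sequence_weights(aln, base = 2)
    # weights scale by the common constant 1/log(2), which cancels in
    # the profile normalisation
    expect_equal(w2 * log(2), we, tolerance = 1e-9)
    p <- sspredict:::profile_from_weights(aln, we, "internal", "weighted")
    q <- sspredict:::profile_from_weights(aln, w2, "internal", "weighted")
    expect_equal(unclass(p), unclass(q), tolerance = 1e-9)
  }
})

test_that("clipping overwrites the query component losslessly", {
  q <- protein_record("q", "AC")
  enc <- sspredict:::encoded_sequence(
    rbind(
      c(0.4, 0.6, rep(0, 19), 0),
      c(0, 1, rep(0, 19), 0)
    ), "weighted"
  )
  colnames(enc) <- c(ss_alphabet("aa_standard"), "nonstd", "gap")
  cl <- clip_profile(enc, q)
  expect_equal(unname(unclass(cl)[1, "A"]), 1)
  expect_equal(unname(unclass(cl)[1, "C"]), 0.6) # untouched
  # row already one-hot at the query residue is a fixed point
  expect_equal(unclass(cl)[2, ], unclass(enc)[2, ], ignore_attr = TRUE)
  # pre-clip value recoverable as 1 - sum of the other 20 of the first 21
  expect_equal(1 - sum(unclass(cl)[1, c(2:21)]), 0.4)

  # property over random profiles
  set.seed(31)
  for (i in 1:10) {
    p <- random_profile(6)
    qr <- protein_record("q", paste(sample(ss_alphabet("aa_standard"), 6, replace = TRUE), collapse = ""))
    cp <- clip_profile(p, qr)
    slot <- match(strsplit(qr$sequence, "")[[1]], ss_alphabet("aa_standard"))
    for (r in 1:6) {
      expect_equal(
        1 - sum(unclass(cp)[r, setdiff(1:21, slot[r])]),
        unname(unclass(p)[r, slot[r]]),
        tolerance = 1e-12
      )
    }
  }
  # a non-standard query residue clips the pooled component
  px <- random_profile(1)
  cx <- clip_profile(px, protein_record("q", "X"))
  expect_equal(unname(unclass(cx)[1, "nonstd"]), 1)
})

test_that("alignment union and intersection behave like set algebra", {
  q <- protein_record("q", "ACD")
  a <- alignment(q, rows = c("AC-", "-CD"))
  b <- alignment(q, rows = c("AC-", "AAD"))

  expect_identical(sort(combine_alignments(a, a, "union")$rows), sort(a$rows))
  expect_identical(sort(combine_alignments(a, a, "intersection")$rows), sort(a$rows))

  disj_a <- alignment(q, rows = "AC-")
  disj_b <- alignment(q, rows = "AAD")
  expect_identical(combine_alignments(disj_a, disj_b, "intersection")$rows, "ACD")

  u <- combine_alignments(a, b, "union")
  expect_lte(length(u$rows), length(a$rows) + length(b$rows))
  expect_setequal(u$rows, c("ACD", "AC-", "-CD", "AAD"))

  other <- alignment(protein_record("q", "ACC"))
  expect_error(combine_alignments(a, other, "union"), "different query")

  # union then plain profile equals the count-pooled profile of both row sets
  set.seed(41)
  for (i in 1:10) {
    L <- sample(3:6, 1)
    base <- random_alignment(L = L, n_hom = 3)
    a1 <- alignment(base$query, rows = base$rows[-1])
    extra <- random_alignment(L = L, n_hom = 3)
    b1 <- alignment(base$query, rows = extra$rows[-1])
    u1 <- combine_alignments(a1, b1, "union")
    pooled_rows <- unique(c(a1$rows, b1$rows))
    pooled <- alignment(base$query, rows = setdiff(pooled_rows, base$query$sequence))
    expect_equal(unclass(plain_profile(u1)), unclass(plain_profile(pooled)))
  }
})

test_that("profile averaging and concatenation preserve structure", {
  set.seed(51)
  p <- random_profile(5)
  q <- random_profile(5)
  expect_equal(unclass(average_profiles(p, p)), unclass(p), ignore_attr = TRUE)
  av <- average_profiles(p, q)
  expect_equal(unname(rowSums(av[, 1:21])), rep(1, 5), tolerance = 1e-12)
  cc <- concat_profiles(p, q)
  expect_equal(ncol(cc), 44L)
  expect_equal(unclass(cc)[, 1:22], unclass(p), ignore_attr = TRUE)
  expect_error(average_profiles(p, random_profile(4)), "dimensions")
})

test_that("3-state augmentation appends validated probability columns", {
  p <- random_profile(4)
  probs <- matrix(rep(c(1, 0, 0), each = 4), 4, 3)
  a <- augment_with_ss3(p, probs)
  expect_equal(ncol(a), 25L)
  expect_equal(unclass(a)[, 23:25], probs, ignore_attr = TRUE)
  expect_error(
    augment_with_ss3(p, matrix(0.5, 4, 3)),
    "not a distribution"
  )
})

test_that("window inputs concatenate rows with zero padding", {
  set.seed(61)
  enc <- rand_enc(5, 4)
  w <- make_window_input(enc, 3, 3)
  expect_length(w, 7 * 4)
  expect_equal(make_window_input(enc, 2, 0), as.numeric(enc[2, ]))
  w2 <- make_window_input(enc, 1, 2)
  expect_equal(w2[1:8], rep(0, 8)) # two out-of-range rows
  expect_equal(w2[9:12], as.numeric(enc[1, ]))
  expect_error(make_window_input(enc, 1, -1), "non-negative")
})

test_that("single-row alignments collapse all profile flavours to one-hot", {
  set.seed(71)
  for (i in 1:5) {
    q <- protein_record("q", paste(sample(ss_alphabet("aa_standard"), 6, replace = TRUE), collapse = ""))
    aln <- alignment(q)
    oh <- onehot_encode(q)
    for (enc in list(plain_profile(aln), weighted_profile(aln))) {
      expect_equal(unclass(enc)[, 1:20], unclass(oh), ignore_attr = TRUE)
      expect_equal(enc[, 21], rep(0, 6), ignore_attr = TRUE)
      expect_equal(enc[, 22], rep(0, 6), ignore_attr = TRUE)
    }
  }
})
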