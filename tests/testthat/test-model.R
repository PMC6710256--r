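test_that("parameter counting matches closed forms and enumeration", {
  # one-hidden-layer FFNN with window 1: (D+1)h + (h+1)K
  h <- 13L
  cfg <- ffnn_config(20, 3, window = 0, hidden = h)
  expect_equal(count_parameters(cfg), (20 + 1) * h + (h + 1) * 3)

  # toy cascaded config against an independent enumeration of the blocks
  cc <- cbrcnn_config(10, 3,
    nf = 4, nb = 5, nhf = 6, nhb = 7, nhy = 8,
    cofb = 2, cseg = 3, cwin = 3, cell_context = 1
  )
  stage_count <- function(din, k, nf, nb, nhf, nhb, nhy, span, xw) {
    nhf * (nf + xw * din + 1) + nf * (nhf + 1) + # forward cell
      nhb * (nb + xw * din + 1) + nb * (nhb + 1) + # backward cell
      nhy * ((nf + nb) * span + 1) + # conv over chain memories
      k * (nhy + 1) # kernel-1 softmax conv
  }
  expected <- stage_count(10, 3, 4, 5, 6, 7, 8, span = 5, xw = 3) +
    stage_count(3 * 3, 3, 2, 3, 3, 4, 4, span = 5, xw = 3) # halved sizes
  expect_equal(count_parameters(cc), expected)

  # the count equals the number of scalars actually materialised
  for (config in list(cfg, cc, tiny_cbrcnn())) {
    p <- init_params(config, seed = 1)
    expect_equal(count_parameters(config), length(sspredict:::as_flat(p)))
  }
})

test_that("published configurations imply the printed kernel and segment span", {
  m <- reference_ensemble_configs(3)[[1]]$config
  expect_equal(2 * m$cofb + 1, 7) # conv kernel of 7 time steps
  expect_equal(length(reference_ensemble_configs(3)), 7)
  expect_equal(length(reference_ensemble_configs(8)), 7)
  # 3+3+1 composition
  schemes <- vapply(reference_ensemble_configs(8), `[[`, character(1), "scheme")
  expect_equal(sum(schemes == "a"), 3)
  expect_equal(sum(schemes == "b"), 3)
  expect_equal(sum(schemes == "concat"), 1)
  # stage-2 sizes are ceiling halves of stage-1 sizes
  d2 <- sspredict:::stage_dims_list(m, 2L)
  expect_equal(d2$nf, ceiling(m$nf / 2))
  expect_equal(d2$nhy, ceiling(m$nhy / 2))
})

test_that("forward passes emit valid distributions deterministically", {
  set.seed(3)
  cfg <- ffnn_config(6, 3, window = 2, hidden = c(5, 4))
  p <- init_params(cfg, seed = 7)
  enc <- rand_enc(11, 6)
  out <- forward_ffnn(p, enc, cfg)
  expect_equal(rowSums(out), rep(1, 11), tolerance = 1e-9)
  expect_true(all(out >= 0))
  expect_identical(out, forward_ffnn(p, enc, cfg))
  # zero weights give the uniform distribution
  p0 <- sspredict:::from_flat(cfg, numeric(count_parameters(cfg)))
  expect_equal(unname(forward_ffnn(p0, enc, cfg)), matrix(1 / 3, 11, 3))

  ccfg <- tiny_cbrcnn(6, 8)
  cp <- init_params(ccfg, seed = 9)
  cout <- forward_cbrcnn(cp, enc, ccfg)
  expect_equal(rowSums(cout$stage1), rep(1, 11), tolerance = 1e-9)
  expect_equal(rowSums(cout$stage2), rep(1, 11), tolerance = 1e-9)
})

test_that("segment averaging tiles blocks around the position", {
  # constant stage-1 output: every interior block average is that row
  # (15 x 21 blocks span 315 positions, so the position must be at
  # least 157 from either end)
  P <- matrix(rep(c(0.2, 0.5, 0.3), each = 400), 400, 3)
  v <- segment_average(P, 200, cseg = 15, cwin = 21)
  expect_length(v, 45) # 15 segments x 3 classes, 315 positions covered
  expect_equal(v, rep(c(0.2, 0.5, 0.3), 15), tolerance = 1e-12)
  # identity case
  set.seed(5)
  P2 <- matrix(runif(30), 10, 3)
  expect_equal(segment_average(P2, 4, 1, 1), as.numeric(P2[4, ]))
  # positions beyond the termini count as zero rows in the mean
  P3 <- matrix(1, 3, 1)
  expect_equal(segment_average(P3, 1, 1, 3), 2 / 3)
})

test_that("the receptive field is the conv window once the chains are cut", {
  cfg <- tiny_cbrcnn(4, 3) # cofb = 2, cell_context = 1
  p <- init_params(cfg, seed = 13)
  # zero the recurrent transition columns: memories now depend only on
  # the local cell input window
  p$blocks$s1_wf1[, seq_len(cfg$nf)] <- 0
  p$blocks$s1_wb1[, seq_len(cfg$nb)] <- 0
  set.seed(14)
  L <- 15
  enc <- rand_enc(L, 4)
  base <- forward_cbrcnn(p, enc, cfg)$stage1
  n <- 8
  reach <- cfg$cofb + cfg$cell_context # conv window + cell context
  for (pos in c(1, 2, n - reach, n + reach, L)) {
    mod <- unclass(enc)
    mod[pos, ] <- runif(4)
    out <- forward_cbrcnn(p, sspredict:::encoded_sequence(mod, "t"), cfg)$stage1
    if (abs(pos - n) <= reach) {
      expect_false(isTRUE(all.equal(out[n, ], base[n, ])))
    } else {
      expect_equal(out[n, ], base[n, ], tolerance = 1e-12)
    }
  }
})

test_that("reversing the sequence and mirroring the parameters reverses the output", {
  set.seed(17)
  cfg <- cbrcnn_config(5, 3,
    nf = 4, nb = 4, nhf = 6, nhb = 6, nhy = 7,
    cofb = 2, cseg = 3, cwin = 3
  )
  for (i in 1:5) {
    p <- init_params(cfg)
    L <- sample(6:14, 1)
    enc <- rand_enc(L, 5)
    rev_enc <- sspredict:::encoded_sequence(unclass(enc)[L:1, , drop = FALSE], "t")
    pm <- sspredict:::mirror_cbrcnn_params(p, cfg)
    a <- forward_cbrcnn(p, enc, cfg)
    b <- forward_cbrcnn(pm, rev_enc, cfg)
    expect_equal(a$stage1, b$stage1[L:1, ], tolerance = 1e-12)
    expect_equal(a$stage2, b$stage2[L:1, ], tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences", {
  set.seed(19)
  cfg <- tiny_cbrcnn(5, 3)
  p <- init_params(cfg)
  theta <- sspredict:::as_flat(p)
  X <- matrix(rnorm(5 * 8), nrow = 5)
  y <- sample(3, 8, replace = TRUE)
  cc <- sspredict:::cbrcnn_cpp_cfg(cfg)
  for (w1 in c(0, 1)) {
    g <- sspredict:::.cbrcnn_loss_grad_cpp(list(X), list(y), theta, cc, w1)
    loss_at <- function(th) {
      r <- sspredict:::.cbrcnn_loss_grad_cpp(list(X), list(y), th, cc, w1)
      # the optimised objective includes the stage-1 term
      r$loss + if (w1 > 0) w1 * cbrcnn_stage1_loss(th, X, y, cfg) else 0
    }
    idx <- sample(length(theta), 25)
    eps <- 1e-6
    num <- vapply(idx, function(i) {
      tp <- theta
      tp[i] <- tp[i] + eps
      tm <- theta
      tm[i] <- tm[i] - eps
      (loss_at(tp) - loss_at(tm)) / (2 * eps)
    }, numeric(1))
    expect_equal(num, g$grad[idx], tolerance = 1e-5)
  }

  fcfg <- ffnn_config(4, 3, window = 1, hidden = c(5, 4))
  fp <- init_params(fcfg)
  th <- sspredict:::as_flat(fp)
  fcc <- sspredict:::ffnn_cpp_cfg(fcfg)
  Xf <- matrix(rnorm(4 * 8), nrow = 4)
  gf <- sspredict:::.ffnn_loss_grad_cpp(list(Xf), list(y), th, fcc)
  idx <- sample(length(th), 25)
  eps <- 1e-6
  num <- vapply(idx, function(i) {
    tp <- th
    tp[i] <- tp[i] + eps
    tm <- th
    tm[i] <- tm[i] - eps
    (sspredict:::.ffnn_loss_grad_cpp(list(Xf), list(y), tp, fcc)$loss -
      sspredict:::.ffnn_loss_grad_cpp(list(Xf), list(y), tm, fcc)$loss) / (2 * eps)
  }, numeric(1))
  expect_equal(num, gf$grad[idx], tolerance = 1e-5)
})

test_that("argmax strings break ties towards the lowest class index", {
  P <- rbind(c(1 / 3, 1 / 3, 1 / 3), c(0.2, 0.4, 0.4), c(0.1, 0.2, 0.7))
  colnames(P) <- c("H", "E", "C")
  expect_identical(sspredict:::probs_to_string(P), "HEC")
})
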