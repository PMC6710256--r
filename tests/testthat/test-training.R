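# small shared fixture: a handful of labelled records with one-hot
# encodings (built fresh per call so tests stay independent)
toy_training_set <- function(n = 8, L = 20, seed = 123) {
  set.seed(seed)
  recs <- lapply(seq_len(n), function(i) {
    ss8 <- random_ss8(L)
    seqs <- paste(sample(ss_alphabet("aa_standard"), L, replace = TRUE), collapse = "")
    protein_record(sprintf("t%02d", i), seqs, ss8)
  })
  encs <- lapply(recs, onehot_encode)
  list(records = recs, data = build_training_data(encs, recs, 3L))
}

test_that("training is bit-reproducible from the seed", {
  fx <- toy_training_set()
  cfg <- ffnn_config(20, 3, window = 1, hidden = 6)
  tc <- training_config(max_epochs = 5, seed = 99)
  a <- train_model(cfg, tc, fx$data)
  b <- train_model(cfg, tc, fx$data)
  expect_identical(a$history, b$history)
  expect_identical(a$params$blocks, b$params$blocks)
  # a different seed gives a different trajectory
  c <- train_model(cfg, training_config(max_epochs = 5, seed = 100), fx$data)
  expect_false(identical(a$params$blocks, c$params$blocks))
})

test_that("a single momentum-free step moves by the scaled gradient", {
  fx <- toy_training_set(n = 3)
  cfg <- ffnn_config(20, 3, window = 0, hidden = 5)
  init <- init_params(cfg, seed = 5)
  lr <- 1e-3
  tc <- training_config(
    learning_rate = lr, momentum = 0, minibatch_proteins = 10,
    max_epochs = 1, seed = 1
  )
  fit <- train_model(cfg, tc, fx$data, init = init)
  theta0 <- sspredict:::as_flat(init)
  g <- sspredict:::batch_loss_grad(
    cfg, lapply(fx$data, function(d) t(d$x)), lapply(fx$data, `[[`, "y"), theta0
  )
  delta <- sspredict:::as_flat(fit$params) - theta0
  expect_equal(delta, -lr * g$grad / g$n, tolerance = 1e-12)
  # step size is bounded by lr * ||gradient||
  expect_lte(sqrt(sum(delta^2)), lr * sqrt(sum(g$grad^2)) + 1e-12)
})

test_that("the learning rate halves exactly after a patience-long plateau", {
  # a single protein keeps the epoch loss bit-identical across epochs
  # (no order-dependent floating-point summation)
  fx <- toy_training_set(n = 1)
  cfg <- ffnn_config(20, 3, window = 0, hidden = 4)
  init <- init_params(cfg, seed = 8)
  # freezing every block constructs a perfect plateau: parameters never
  # move, so the epoch loss is constant from epoch 1 onwards
  attr(init, "frozen") <- names(init$blocks)
  tc <- training_config(
    learning_rate = 0.25, patience_epochs = 5, max_epochs = 14, seed = 2
  )
  fit <- train_model(cfg, tc, fx$data, init = init)
  expect_equal(length(unique(fit$history$loss)), 1L)
  lr <- fit$history$learning_rate
  expect_equal(lr[1:6], rep(0.25, 6))
  expect_equal(lr[7:11], rep(0.125, 5)) # halved after 5 stalled epochs
  expect_equal(lr[12:14], rep(0.0625, 3))
  # drops are exactly x0.5 and the trace is non-increasing
  expect_true(all(diff(lr) <= 0))
  expect_true(all(lr[-1][diff(lr) < 0] == lr[-length(lr)][diff(lr) < 0] / 2))
  # and the frozen parameters are bit-identical to the input
  expect_identical(fit$params$blocks, init$blocks)
})

test_that("incremental deepening freezes the lower layers and grows the count", {
  fx <- toy_training_set(n = 5)
  cfg <- ffnn_config(20, 3, window = 1, hidden = 8)
  tc <- training_config(max_epochs = 3, seed = 3)
  base <- train_model(cfg, tc, fx$data)

  set.seed(4)
  deep <- incremental_deepen(base$params, cfg, new_hidden_size = 6)
  expect_equal(deep$config$hidden, c(8L, 6L))
  # count grows by (h_old+1) h_new + (h_new+1) K - (h_old+1) K
  expect_equal(
    count_parameters(deep$config) - count_parameters(cfg),
    (8 + 1) * 6 + (6 + 1) * 3 - (8 + 1) * 3
  )
  # training the deepened net leaves the donor blocks bit-identical
  fit2 <- train_model(deep$config, tc, fx$data, init = deep$params)
  expect_identical(fit2$params$blocks$hidden1, base$params$blocks$hidden1)
  expect_false(identical(fit2$params$blocks$output, deep$params$blocks$output))
  # lifting the freeze lets the lower layers move (end-to-end refinement)
  fit3 <- train_model(deep$config, tc, fx$data, init = unfreeze_params(fit2$params))
  expect_false(identical(fit3$params$blocks$hidden1, base$params$blocks$hidden1))

  # applying deepening twice yields a three-hidden-layer network
  set.seed(6)
  deeper <- incremental_deepen(fit2$params, deep$config, 5)
  expect_equal(deeper$config$hidden, c(8L, 6L, 5L))
  expect_error(
    incremental_deepen(init_params(tiny_cbrcnn(), 1), tiny_cbrcnn(), 4),
    "feed-forward"
  )
})

test_that("refinement continues from a donor model without reinitialisation", {
  fx <- toy_training_set(n = 6)
  cfg <- ffnn_config(20, 3, window = 1, hidden = 6)
  tc <- training_config(max_epochs = 6, seed = 11)
  donor <- train_model(cfg, tc, fx$data)
  # continuing on a second pseudo-source starts from the donor's loss
  # level, not from a fresh model's
  fx2 <- toy_training_set(n = 6, seed = 321)
  cont <- train_model(cfg, training_config(max_epochs = 2, seed = 12), fx2$data,
    init = donor$params
  )
  fresh <- train_model(cfg, training_config(max_epochs = 2, seed = 12), fx2$data)
  expect_lt(abs(cont$history$loss[1] - fresh$history$loss[1]) / fresh$history$loss[1], 0.5)
  expect_equal(nrow(cont$history), 2L)
})

test_that("training rejects empty and mismatched inputs", {
  cfg <- ffnn_config(20, 3, window = 0, hidden = 4)
  tc <- training_config(max_epochs = 1)
  expect_error(train_model(cfg, tc, list()), "empty training set")
  fx <- toy_training_set(n = 2)
  wrong <- ffnn_config(22, 3, window = 0, hidden = 4)
  expect_error(train_model(wrong, tc, fx$data), "input width")
})

test_that("cross-validation folds partition the records reproducibly", {
  recs <- as.list(letters[1:10])
  folds <- make_cv_folds(recs, k = 5, seed = 77)
  expect_length(folds, 5)
  expect_equal(vapply(folds, length, integer(1)), rep(2L, 5))
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(duplicated(unlist(folds))), 0)
  expect_identical(folds, make_cv_folds(recs, k = 5, seed = 77))
  # uneven sizes differ by at most one
  f11 <- make_cv_folds(as.list(1:11), k = 3, seed = 1)
  expect_lte(diff(range(vapply(f11, length, integer(1)))), 1)
})

test_that("a separable cipher dataset is learned to high training accuracy", {
  # one amino acid per class: the sequence is a cipher of the structure
  prop <- matrix(1e-9, 3, 20, dimnames = list(c("H", "E", "C"), ss_alphabet("aa_standard")))
  prop["H", "A"] <- 1
  prop["E", "V"] <- 1
  prop["C", "G"] <- 1
  cfg <- synthetic_config(
    n_proteins = 30, length_range = c(30, 60),
    propensity = prop, seed = 55
  )
  ds <- generate_dataset(cfg)
  encs <- encode_records(ds, "onehot")
  data <- build_training_data(encs, ds$records, 3L)
  mcfg <- ffnn_config(20, 3, window = 1, hidden = 8)
  fit <- train_model(
    mcfg, training_config(learning_rate = 0.1, max_epochs = 40, seed = 5), data
  )
  pred <- vapply(seq_along(ds$records), function(i) {
    sspredict:::probs_to_string(forward_ffnn(fit$params, encs[[i]], mcfg))
  }, character(1))
  obs <- map_ss8_to_ss3(vapply(ds$records, `[[`, character(1), "ss8"))
  expect_gte(q_accuracy(pred, obs)$per_aa, 95)
})
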