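# Optimisation: plain SGD with momentum, an adaptive (halving) learning
# rate, minibatches of whole proteins and epoch-end reshuffling; plus
# incremental deepening of FFNN baselines and cross-validation folds.

#' Training configuration
#'
#' @param learning_rate initial learning rate (applied to the summed
#'   cross-entropy gradient of a minibatch).
#' @param momentum momentum coefficient in `[0, 1)`.
#' @param patience_epochs the learning rate is halved whenever the
#'   training cross-entropy has not improved on its best value for this
#'   many consecutive epochs.
#' @param minibatch_proteins proteins per gradient step (the last batch
#'   of an epoch may be smaller).
#' @param max_epochs epochs to run.
#' @param stage1_loss_weight weight of the stage-1 auxiliary
#'   cross-entropy for cascaded models (both stages predict secondary
#'   structure, so both are trained on the labels; 0 trains through the
#'   stage-2 objective alone). Ignored for FFNNs.
#' @param seed integer seed; the whole run is reproducible from it.
#' @return a `training_config`.
#' @export
training_config <- function(learning_rate = 0.01, momentum = 0.9,
                            patience_epochs = 100L, minibatch_proteins = 10L,
                            max_epochs = 100L, stage1_loss_weight = 1,
                            seed = 1L) {
  stopifnot(
    learning_rate > 0, momentum >= 0, momentum < 1,
    patience_epochs >= 1L, minibatch_proteins >= 1L, max_epochs >= 1L,
    stage1_loss_weight >= 0
  )
  structure(list(
    learning_rate = learning_rate, momentum = momentum,
    patience_epochs = as.integer(patience_epochs),
    minibatch_proteins = as.integer(minibatch_proteins),
    max_epochs = as.integer(max_epochs),
    stage1_loss_weight = stage1_loss_weight,
    seed = as.integer(seed)
  ), class = "training_config")
}

# Integer class labels (1-based, canonical order) for a label string.
label_indices <- function(ss, n_classes, dialect = "default") {
  cc <- chars(ss)
  if (n_classes == 3L) {
    if (!all(cc %in% SS3_STATES)) cc <- chars(map_ss8_to_ss3(ss, dialect))
    match(cc, SS3_STATES)
  } else {
    match(cc, SS8_STATES)
  }
}

#' Assemble a training set from encodings and labelled records
#'
#' @param encodings list of `encoded_sequence`s, one per record.
#' @param records list of labelled [protein_record()]s (same order).
#' @param n_classes 3 or 8.
#' @param dialect 8-to-3 mapping dialect for 3-state labels.
#' @return list of `list(x, y)` entries consumable by [train_model()].
#' @export
build_training_data <- function(encodings, records, n_classes = 3L,
                                dialect = "default") {
  stopifnot(length(encodings) == length(records))
  lapply(seq_along(records), function(i) {
    r <- records[[i]]
    if (is.null(r$ss8)) {
      stop(sprintf("record '%s' carries no labels", r$id), call. = FALSE)
    }
    if (nrow(encodings[[i]]) != nchar(r$ss8)) {
      stop(sprintf("record '%s': encoding/label length mismatch", r$id), call. = FALSE)
    }
    y <- label_indices(r$ss8, n_classes, dialect)
    if (anyNA(y)) {
      stop(sprintf("record '%s': unknown label symbol", r$id), call. = FALSE)
    }
    list(x = unclass(encodings[[i]]), y = as.integer(y))
  })
}

# flat 0/1 mask of trainable parameters (0 = frozen block)
freeze_mask <- function(params, config) {
  frozen <- attr(params, "frozen")
  layout <- param_layout(config)
  unlist(lapply(names(layout), function(nm) {
    rep(if (nm %in% frozen) 0 else 1, prod(layout[[nm]]))
  }), use.names = FALSE)
}

batch_loss_grad <- function(config, Xs, ys, theta, stage1_weight = 1) {
  res <- if (config$architecture == "cbrcnn") {
    .cbrcnn_loss_grad_cpp(Xs, ys, theta, cbrcnn_cpp_cfg(config), stage1_weight)
  } else {
    .ffnn_loss_grad_cpp(Xs, ys, theta, ffnn_cpp_cfg(config))
  }
  res$grad <- as.numeric(res$grad)
  res
}

#' Train a model by SGD with momentum and adaptive learning rate
#'
#' Minimises the summed per-residue cross-entropy of the model output
#' (stage-2 output for the cascaded network) by stochastic gradient
#' descent: one gradient step per minibatch of `minibatch_proteins`
#' proteins (the learning rate applies to the per-residue-averaged
#' gradient of the batch), momentum buffer, training order reshuffled at the end of
#' every epoch, and the learning rate halved whenever the epoch training
#' cross-entropy has not improved on its best value for
#' `patience_epochs` epochs. The epoch loss is the running sum of
#' minibatch losses (each evaluated just before its update). Runs are
#' bit-reproducible from `tc$seed`. If `init` is given, training
#' continues from it (refinement); frozen blocks of `init` receive no
#' updates.
#'
#' @param config a `model_config`.
#' @param tc a [training_config()].
#' @param data training set from [build_training_data()].
#' @param init optional `model_params` to continue from.
#' @return list with `params` (trained `model_params`) and `history`
#'   (data.frame: epoch, loss, learning_rate).
#' @export
train_model <- function(config, tc, data, init = NULL) {
  stopifnot(inherits(config, "model_config"), inherits(tc, "training_config"))
  if (length(data) == 0L) stop("empty training set", call. = FALSE)
  for (d in data) {
    if (ncol(d$x) != config$n_inputs) {
      stop("training encodings do not match the configured input width", call. = FALSE)
    }
  }
  set.seed(tc$seed)
  params <- if (is.null(init)) init_params(config) else init
  check_params_config(params, config)
  theta <- as_flat(params)
  mask <- freeze_mask(params, config)
  velocity <- numeric(length(theta))
  lr <- tc$learning_rate
  best <- Inf
  stall <- 0L
  history <- data.frame(
    epoch = integer(0), loss = numeric(0), learning_rate = numeric(0)
  )
  Xs_all <- lapply(data, function(d) t(d$x))
  ys_all <- lapply(data, function(d) d$y)
  n <- length(data)

  for (epoch in seq_len(tc$max_epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    starts <- seq(1L, n, by = tc$minibatch_proteins)
    for (s in starts) {
      idx <- perm[s:min(s + tc$minibatch_proteins - 1L, n)]
      res <- batch_loss_grad(
        config, Xs_all[idx], ys_all[idx], theta, tc$stage1_loss_weight
      )
      if (!is.finite(res$loss)) {
        stop(sprintf(
          "training diverged (non-finite loss) at epoch %d; reduce the learning rate",
          epoch
        ), call. = FALSE)
      }
      epoch_loss <- epoch_loss + res$loss
      # learning rate is on the per-residue-averaged gradient scale
      velocity <- tc$momentum * velocity - lr * (res$grad * mask) / res$n
      theta <- theta + velocity
    }
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epoch_loss, learning_rate = lr
    ))
    if (epoch_loss < best) {
      best <- epoch_loss
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tc$patience_epochs) {
        lr <- lr / 2
        stall <- 0L
      }
    }
  }
  out <- from_flat(config, theta)
  attr(out, "frozen") <- attr(params, "frozen")
  list(params = out, history = history)
}

#' Deepen a feed-forward network incrementally
#'
#' Replaces the trained softmax layer of an FFNN with a fresh hidden
#' layer plus softmax, freezing every existing hidden layer: a
#' subsequent [train_model()] call updates only the new top blocks, and
#' a final call after [unfreeze_params()] refines the whole network end
#' to end. This grows one-hidden-layer baselines into deeper ones
#' without retraining the lower layers from scratch.
#'
#' @param params trained FFNN `model_params`.
#' @param config the matching `model_config`.
#' @param new_hidden_size size of the inserted hidden layer.
#' @return list with the deepened `config` and `params` (lower blocks
#'   identical to the input and marked frozen; new blocks freshly
#'   initialised from the current RNG stream).
#' @export
incremental_deepen <- function(params, config, new_hidden_size) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture != "ffnn") {
    stop("incremental deepening applies to feed-forward networks only", call. = FALSE)
  }
  check_params_config(params, config)
  new_config <- ffnn_config(
    config$n_inputs, config$n_classes, config$window,
    c(config$hidden, as.integer(new_hidden_size))
  )
  layout <- param_layout(new_config)
  old_hidden <- sprintf("hidden%d", seq_along(config$hidden))
  blocks <- params$blocks[old_hidden]
  for (nm in setdiff(names(layout), old_hidden)) {
    dd <- layout[[nm]]
    a <- 1 / sqrt(dd[2])
    blocks[[nm]] <- matrix(stats::runif(prod(dd), -a, a), dd[1], dd[2])
  }
  blocks <- blocks[names(layout)]
  out <- structure(list(blocks = blocks), class = "model_params")
  attr(out, "frozen") <- old_hidden
  list(config = new_config, params = out)
}

#' Lift all freeze flags from a parameter set
#'
#' @param params a `model_params`.
#' @return the same parameters with no frozen blocks.
#' @export
unfreeze_params <- function(params) {
  attr(params, "frozen") <- NULL
  params
}

#' Random cross-validation folds
#'
#' Partitions records into `k` disjoint folds of sizes differing by at
#' most one, reproducibly from `seed`.
#'
#' @param records list (or vector) to partition.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` integer index vectors.
#' @export
make_cv_folds <- function(records, k = 5L, seed = 1L) {
  n <- length(records)
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  perm <- sample.int(n)
  # contiguous chunks of the permutation, sizes differing by <= 1
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) sort(perm[starts[i]:ends[i]]))
}
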