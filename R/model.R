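# Model configurations and forward passes.
#
# Two architectures are supported:
#  - "ffnn": a window-based feed-forward network (the classical baseline);
#  - "cbrcnn": the two-stage cascaded bidirectional-recurrent +
#    convolutional sequence labeler at the core of the predictor.
#
# Parameters are named blocks of real matrices whose shapes are fully
# determined by the configuration; a flat-vector view (in fixed block
# order, column-major, bias as last column) is shared with the compiled
# code.

#' Configure a window-based feed-forward network
#'
#' @param n_inputs input encoding width D.
#' @param n_classes 3 or 8.
#' @param window window half-width `l`; the network sees `2l + 1`
#'   residues per prediction (`l = 0` is the single-residue baseline).
#' @param hidden integer vector of hidden layer sizes (tanh units).
#' @return a `model_config`.
#' @export
ffnn_config <- function(n_inputs, n_classes = 3L, window = 3L, hidden = 20L) {
  stopifnot(n_inputs >= 1L, n_classes %in% c(3L, 8L), window >= 0L,
            length(hidden) >= 1L, all(hidden >= 1L))
  structure(list(
    architecture = "ffnn",
    n_inputs = as.integer(n_inputs), n_classes = as.integer(n_classes),
    window = as.integer(window), hidden = as.integer(hidden)
  ), class = "model_config")
}

#' Configure a cascaded bidirectional-recurrent + convolutional network
#'
#' The network has two cascaded stages. Stage 1 runs a forward memory
#' chain (size `nf`, updated left to right) and an independent backward
#' chain (`nb`, right to left); each chain transition is a two-layer
#' tanh cell (hidden sizes `nhf`/`nhb`) reading the previous memory plus
#' a small window of input columns (`cell_context` residues per side).
#' A convolutional layer with kernel `2*cofb + 1` reads windows of the
#' concatenated chain memories into `nhy` tanh units, and a kernel-1
#' convolution maps these to the class softmax. Stage 2 has the same
#' topology at half the layer sizes (ceiling division) and reads, at
#' every position, `cseg` block averages of the stage-1 output, each
#' block covering `cwin` positions, tiled contiguously around the
#' position. Stage-2 output is the model's prediction.
#'
#' @param n_inputs input encoding width D (22 for single-source
#'   profiles, 44 concatenated, 25/47 with 3-state augmentation).
#' @param n_classes 3 or 8.
#' @param nf,nb forward/backward chain memory sizes.
#' @param nhf,nhb hidden sizes inside the forward/backward cells.
#' @param nhy hidden size of the first convolutional layer.
#' @param cofb convolution half-width (kernel size `2*cofb + 1`).
#' @param cseg number of stage-2 segments.
#' @param cwin segment length in positions.
#' @param cell_context input context per side seen by each recurrent
#'   cell (default 1; this wiring matches the published model sizes).
#' @param conv_input should the convolutional layer also see the raw
#'   input window (default `FALSE`: it reads chain memories only).
#' @return a `model_config`.
#' @export
cbrcnn_config <- function(n_inputs, n_classes = 3L, nf = 25L, nb = 30L,
                          nhf = 40L, nhb = 40L, nhy = 50L, cofb = 3L,
                          cseg = 10L, cwin = 7L, cell_context = 1L,
                          conv_input = FALSE) {
  stopifnot(n_inputs >= 1L, n_classes %in% c(3L, 8L),
            nf >= 1L, nb >= 1L, nhf >= 1L, nhb >= 1L, nhy >= 1L,
            cofb >= 0L, cseg >= 1L, cwin >= 1L, cell_context >= 0L)
  structure(list(
    architecture = "cbrcnn",
    n_inputs = as.integer(n_inputs), n_classes = as.integer(n_classes),
    nf = as.integer(nf), nb = as.integer(nb),
    nhf = as.integer(nhf), nhb = as.integer(nhb), nhy = as.integer(nhy),
    cofb = as.integer(cofb), cseg = as.integer(cseg), cwin = as.integer(cwin),
    cell_context = as.integer(cell_context), conv_input = isTRUE(conv_input)
  ), class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  if (x$architecture == "ffnn") {
    cat(sprintf(
      "<model_config> ffnn: %d inputs, window %d (%d residues), hidden %s, %d classes (%d parameters)\n",
      x$n_inputs, x$window, 2 * x$window + 1,
      paste(x$hidden, collapse = "-"), x$n_classes, count_parameters(x)
    ))
  } else {
    cat(sprintf(
      "<model_config> cbrcnn: %d inputs, NF/NB %d/%d, NHF/NHB %d/%d, NHY %d, kernel %d, %dx%d segments, %d classes (%d parameters)\n",
      x$n_inputs, x$nf, x$nb, x$nhf, x$nhb, x$nhy, 2 * x$cofb + 1,
      x$cseg, x$cwin, x$n_classes, count_parameters(x)
    ))
  }
  invisible(x)
}

# stage-2 sizes: ceiling half of stage 1
half <- function(x) as.integer(ceiling(x / 2))

# per-stage dimension list shared with the compiled code
stage_dims_list <- function(config, stage) {
  if (stage == 1L) {
    list(
      din = config$n_inputs, k = config$n_classes,
      nf = config$nf, nb = config$nb, nhf = config$nhf, nhb = config$nhb,
      nhy = config$nhy, cofb = config$cofb, cc = config$cell_context,
      convin = as.integer(config$conv_input)
    )
  } else {
    list(
      din = config$cseg * config$n_classes, k = config$n_classes,
      nf = half(config$nf), nb = half(config$nb),
      nhf = half(config$nhf), nhb = half(config$nhb), nhy = half(config$nhy),
      cofb = config$cofb, cc = config$cell_context,
      convin = as.integer(config$conv_input)
    )
  }
}

stage_layout <- function(d) {
  xw <- (2L * d$cc + 1L) * d$din
  list(
    wf1 = c(d$nhf, d$nf + xw + 1L),
    wf2 = c(d$nf, d$nhf + 1L),
    wb1 = c(d$nhb, d$nb + xw + 1L),
    wb2 = c(d$nb, d$nhb + 1L),
    wc1 = c(d$nhy, (d$nf + d$nb + if (d$convin) d$din else 0L) * (2L * d$cofb + 1L) + 1L),
    wc2 = c(d$k, d$nhy + 1L)
  )
}

# Named list of block dimensions, in flat-vector order.
param_layout <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture == "ffnn") {
    sizes <- c((2L * config$window + 1L) * config$n_inputs, config$hidden)
    out <- list()
    for (i in seq_along(config$hidden)) {
      out[[sprintf("hidden%d", i)]] <- c(config$hidden[i], sizes[i] + 1L)
    }
    out[["output"]] <- c(config$n_classes, config$hidden[length(config$hidden)] + 1L)
    out
  } else {
    l1 <- stage_layout(stage_dims_list(config, 1L))
    l2 <- stage_layout(stage_dims_list(config, 2L))
    names(l1) <- paste0("s1_", names(l1))
    names(l2) <- paste0("s2_", names(l2))
    c(l1, l2)
  }
}

#' Number of trainable parameters
#'
#' Exact count of trainable scalars (weights and biases) implied by a
#' model configuration.
#'
#' @param config a `model_config`.
#' @return integer.
#' @export
count_parameters <- function(config) {
  sum(vapply(param_layout(config), prod, numeric(1)))
}

#' Initialise model parameters
#'
#' Symmetric uniform initialisation scaled by fan-in: each block is
#' drawn from `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`.
#'
#' @param config a `model_config`.
#' @param seed optional integer seed (uses the current RNG stream if
#'   `NULL`).
#' @return a `model_params` object (named list of weight matrices).
#' @export
init_params <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(param_layout(config), function(dd) {
    a <- 1 / sqrt(dd[2])
    matrix(stats::runif(prod(dd), -a, a), nrow = dd[1], ncol = dd[2])
  })
  structure(list(blocks = blocks), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  n <- sum(vapply(x$blocks, length, numeric(1)))
  cat(sprintf(
    "<model_params> %d blocks, %d parameters%s\n",
    length(x$blocks), n,
    if (length(attr(x, "frozen")) > 0) {
      paste0(" (frozen: ", paste(attr(x, "frozen"), collapse = ", "), ")")
    } else ""
  ))
  invisible(x)
}

check_params_config <- function(params, config) {
  stopifnot(inherits(params, "model_params"), inherits(config, "model_config"))
  layout <- param_layout(config)
  if (!identical(names(params$blocks), names(layout))) {
    stop("parameter blocks do not match the configuration", call. = FALSE)
  }
  for (nm in names(layout)) {
    if (!identical(as.integer(dim(params$blocks[[nm]])), as.integer(layout[[nm]]))) {
      stop(sprintf(
        "parameter block '%s' has shape %s, configuration requires %s",
        nm, paste(dim(params$blocks[[nm]]), collapse = "x"),
        paste(layout[[nm]], collapse = "x")
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

as_flat <- function(params) {
  unlist(lapply(params$blocks, as.numeric), use.names = FALSE)
}

from_flat <- function(config, theta) {
  layout <- param_layout(config)
  stopifnot(length(theta) == sum(vapply(layout, prod, numeric(1))))
  off <- 0L
  blocks <- lapply(layout, function(dd) {
    n <- prod(dd)
    m <- matrix(theta[off + seq_len(n)], nrow = dd[1], ncol = dd[2])
    off <<- off + n
    m
  })
  structure(list(blocks = blocks), class = "model_params")
}

cbrcnn_cpp_cfg <- function(config) {
  list(
    stage1 = stage_dims_list(config, 1L),
    stage2 = stage_dims_list(config, 2L),
    cseg = config$cseg, cwin = config$cwin
  )
}

ffnn_cpp_cfg <- function(config) {
  list(
    din = config$n_inputs, k = config$n_classes,
    l = config$window, hidden = as.integer(config$hidden)
  )
}

check_enc_width <- function(enc, config) {
  if (ncol(enc) != config$n_inputs) {
    stop(sprintf(
      "encoding width %d does not match the configured %d inputs",
      ncol(enc), config$n_inputs
    ), call. = FALSE)
  }
}

class_names_for <- function(n_classes) {
  if (n_classes == 3L) SS3_STATES else SS8_STATES
}

#' Feed-forward network forward pass
#'
#' @param params a `model_params` for `config`.
#' @param enc an `encoded_sequence` (L x D).
#' @param config an `ffnn` `model_config`.
#' @return L x n_classes matrix of per-residue class probabilities
#'   (rows sum to 1).
#' @export
forward_ffnn <- function(params, enc, config) {
  stopifnot(config$architecture == "ffnn")
  check_params_config(params, config)
  check_enc_width(enc, config)
  P <- .ffnn_forward_cpp(t(unclass(enc)), as_flat(params), ffnn_cpp_cfg(config))
  colnames(P) <- class_names_for(config$n_classes)
  P
}

#' Cascaded network forward pass
#'
#' Runs both stages of the cascaded recurrent-convolutional network.
#' The stage-2 output is the model's prediction; the stage-1 output is
#' returned as well (it is what the segment averaging feeds forward).
#'
#' @param params a `model_params` for `config`.
#' @param enc an `encoded_sequence` (L x D).
#' @param config a `cbrcnn` `model_config`.
#' @return list with `stage1` and `stage2`, each an L x n_classes matrix
#'   of per-residue class probabilities.
#' @export
forward_cbrcnn <- function(params, enc, config) {
  stopifnot(config$architecture == "cbrcnn")
  check_params_config(params, config)
  check_enc_width(enc, config)
  out <- .cbrcnn_forward_cpp(t(unclass(enc)), as_flat(params), cbrcnn_cpp_cfg(config))
  cls <- class_names_for(config$n_classes)
  colnames(out$p1) <- cls
  colnames(out$p2) <- cls
  list(stage1 = out$p1, stage2 = out$p2)
}

#' Segment-averaged stage-2 input at one position
#'
#' Tiles `cseg` contiguous blocks of `cwin` positions around position
#' `n` (central block centred on `n`; for even `cseg` the extra block
#' sits to the right) and returns the per-block means of the stage-1
#' output rows, positions beyond the termini counting as zero rows.
#' With `cseg = 1, cwin = 1` this is the identity on row `n`.
#'
#' @param stage1_out L x K matrix of stage-1 class probabilities.
#' @param n 1-based position.
#' @param cseg number of blocks.
#' @param cwin block length.
#' @return numeric vector of width `cseg * K`.
#' @export
segment_average <- function(stage1_out, n, cseg, cwin) {
  stopifnot(n >= 1L, n <= nrow(stage1_out), cseg >= 1L, cwin >= 1L)
  S <- .segment_average_cpp(t(as.matrix(stage1_out)), as.integer(cseg), as.integer(cwin))
  S[, n]
}

# Mirror a cbrcnn parameter set: swap forward/backward blocks, reverse
# every window order (cell input windows, conv windows) and reverse the
# stage-2 segment-block order, so that running the mirrored model on the
# reversed sequence reproduces the reversed output. Requires symmetric
# chain sizes (nf == nb, nhf == nhb), odd cseg/cwin and conv_input off.
# Used by the symmetry property tests.
mirror_cbrcnn_params <- function(params, config) {
  stopifnot(
    config$architecture == "cbrcnn", !config$conv_input,
    config$nf == config$nb, config$nhf == config$nhb,
    config$cseg %% 2L == 1L, config$cwin %% 2L == 1L
  )
  out <- params
  for (st in 1:2) {
    d <- stage_dims_list(config, st)
    p <- paste0("s", st, "_")
    span_cc <- 2L * d$cc + 1L
    # permutation of the din components under sequence reversal: stage-1
    # inputs are unpermuted; stage-2 inputs are cseg blocks of K that
    # tile the sequence, so the block order reverses.
    dperm <- if (st == 1L) {
      seq_len(d$din)
    } else {
      k <- config$n_classes
      as.vector(vapply(rev(seq_len(config$cseg)) - 1L,
        function(b) b * k + seq_len(k), integer(k)
      ))
    }
    # within a cell, reverse the input-window order and permute din
    flip_cell <- function(W, nmem) {
      xwc <- nmem + seq_len(span_cc * d$din)
      ord <- as.vector(vapply(rev(seq_len(span_cc)) - 1L,
        function(b) b * d$din + dperm, integer(d$din)
      ))
      W[, xwc] <- W[, xwc[ord], drop = FALSE]
      W
    }
    wf1 <- flip_cell(params$blocks[[paste0(p, "wf1")]], d$nf)
    wb1 <- flip_cell(params$blocks[[paste0(p, "wb1")]], d$nb)
    out$blocks[[paste0(p, "wf1")]] <- wb1
    out$blocks[[paste0(p, "wf2")]] <- params$blocks[[paste0(p, "wb2")]]
    out$blocks[[paste0(p, "wb1")]] <- wf1
    out$blocks[[paste0(p, "wb2")]] <- params$blocks[[paste0(p, "wf2")]]
    # conv: window position w, sub-block (F,B) -> reversed window, (B,F)
    span <- 2L * d$cofb + 1L
    fb <- d$nf + d$nb
    Wc1 <- params$blocks[[paste0(p, "wc1")]]
    perm <- integer(span * fb)
    for (w in seq_len(span)) {
      src <- (span - w) * fb
      perm[((w - 1L) * fb) + seq_len(d$nf)] <- src + d$nb + seq_len(d$nf)
      perm[((w - 1L) * fb) + d$nf + seq_len(d$nb)] <- src + seq_len(d$nb)
    }
    keep <- setdiff(seq_len(ncol(Wc1)), seq_len(span * fb))
    out$blocks[[paste0(p, "wc1")]] <-
      cbind(Wc1[, perm, drop = FALSE], Wc1[, keep, drop = FALSE])
  }
  out
}

restore_model_config <- function(lst) {
  stopifnot(!is.null(lst$architecture))
  if (lst$architecture == "ffnn") {
    ffnn_config(lst$n_inputs, lst$n_classes, lst$window, unlist(lst$hidden))
  } else {
    cbrcnn_config(
      lst$n_inputs, lst$n_classes, lst$nf, lst$nb, lst$nhf, lst$nhb,
      lst$nhy, lst$cofb, lst$cseg, lst$cwin, lst$cell_context,
      isTRUE(lst$conv_input)
    )
  }
}

#' Released ensemble configurations
#'
#' The seven model configurations of the released predictor at a given
#' class level: three members trained on alignment source A, three on
#' source B (all six sharing one single-source configuration) and one
#' trained on the 44-wide concatenation of both profile sources. At the
#' 8-state level every input is augmented with the 3-state ensemble
#' output (+3 inputs). Hyperparameters follow the published model table;
#' mean parameter counts are about 40k (3-state) and 58k (8-state).
#'
#' @param n_classes 3 or 8.
#' @return list of 7 entries, each `list(config = <model_config>,
#'   scheme = "a"|"b"|"concat")`.
#' @export
reference_ensemble_configs <- function(n_classes = 3L) {
  stopifnot(n_classes %in% c(3L, 8L))
  if (n_classes == 3L) {
    single <- cbrcnn_config(22L, 3L, nf = 25L, nb = 30L, nhf = 40L, nhb = 40L, nhy = 50L)
    concat <- cbrcnn_config(44L, 3L, nf = 30L, nb = 25L, nhf = 45L, nhb = 40L, nhy = 55L)
  } else {
    single <- cbrcnn_config(25L, 8L, nf = 30L, nb = 35L, nhf = 45L, nhb = 55L, nhy = 50L)
    concat <- cbrcnn_config(47L, 8L, nf = 36L, nb = 30L, nhf = 60L, nhb = 45L, nhy = 48L)
  }
  schemes <- c("a", "a", "a", "b", "b", "b", "concat")
  lapply(seq_len(7L), function(i) {
    list(config = if (i == 7L) concat else single, scheme = schemes[i])
  })
}

# argmax class string with fixed tie-break: ties go to the lowest class
# index in canonical order (H before E before C, etc.).
probs_to_string <- function(P) {
  cls <- colnames(P)
  stopifnot(!is.null(cls))
  paste(cls[max.col(P, ties.method = "first")], collapse = "")
}
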