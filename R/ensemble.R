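# Ensembling and the 3-to-8-state prediction cascade.

#' Average the softmax outputs of ensemble members
#'
#' Bayesian-model-averaging style combination: the per-residue class
#' distributions of the members are averaged component by component
#' (rows stay valid distributions by convexity).
#'
#' @param outputs list of L x K probability matrices of equal shape.
#' @return L x K matrix.
#' @export
ensemble_average <- function(outputs) {
  stopifnot(length(outputs) >= 1L)
  d <- dim(outputs[[1]])
  for (o in outputs) {
    if (!identical(dim(o), d)) {
      stop("ensemble member outputs have different shapes", call. = FALSE)
    }
  }
  Reduce(`+`, outputs) / length(outputs)
}

#' Build an ensemble member
#'
#' @param params `model_params`.
#' @param config matching `model_config`.
#' @param scheme which input the member expects: `"a"` (source-A
#'   profile), `"b"` (source-B profile) or `"concat"` (44-wide
#'   concatenation).
#' @return list usable in [predict_cascade()] member lists.
#' @export
ensemble_member <- function(params, config, scheme = c("a", "b", "concat")) {
  scheme <- match.arg(scheme)
  check_params_config(params, config)
  list(params = params, config = config, scheme = scheme)
}

member_forward <- function(member, enc) {
  if (member$config$architecture == "cbrcnn") {
    forward_cbrcnn(member$params, enc, member$config)$stage2
  } else {
    forward_ffnn(member$params, enc, member$config)
  }
}

#' Predict secondary structure with the full ensemble cascade
#'
#' Every 3-state member is evaluated on the profile of its own input
#' scheme and the outputs are averaged into the 3-state prediction.
#' Each 8-state member then receives its profile augmented with the
#' 3-state output of the matching source group: source-A 8-state
#' members get the average of the source-A 3-state members, source-B
#' members the source-B average, and the concatenated-input member the
#' average of all 3-state members. Final label strings are argmax calls
#' with ties broken towards the lowest canonical class index.
#'
#' @param profiles named list of encodings: `a` and/or `b` (width 22)
#'   and optionally `concat` (width 44), covering every scheme the
#'   members use.
#' @param members3 list of 3-state [ensemble_member()]s.
#' @param members8 optional list of 8-state members (inputs are
#'   augmented internally, so their configs expect widths 25/47).
#' @return list with `ss3_probs`, `ss3` and, when `members8` is given,
#'   `ss8_probs`, `ss8`.
#' @export
predict_cascade <- function(profiles, members3, members8 = NULL) {
  stopifnot(length(members3) >= 1L)
  get_profile <- function(scheme) {
    enc <- profiles[[scheme]]
    if (is.null(enc)) {
      stop(sprintf("no profile provided for input scheme '%s'", scheme), call. = FALSE)
    }
    enc
  }
  outs3 <- lapply(members3, function(m) member_forward(m, get_profile(m$scheme)))
  p3 <- ensemble_average(outs3)
  colnames(p3) <- SS3_STATES
  res <- list(ss3_probs = p3, ss3 = probs_to_string(p3))
  if (!is.null(members8)) {
    schemes3 <- vapply(members3, `[[`, character(1), "scheme")
    group_avg <- function(scheme) {
      sel <- if (scheme == "concat") seq_along(outs3) else which(schemes3 == scheme)
      if (length(sel) == 0L) sel <- seq_along(outs3) # no source-matched members
      ensemble_average(outs3[sel])
    }
    outs8 <- lapply(members8, function(m) {
      enc <- augment_with_ss3(get_profile(m$scheme), group_avg(m$scheme))
      member_forward(m, enc)
    })
    p8 <- ensemble_average(outs8)
    colnames(p8) <- SS8_STATES
    res$ss8_probs <- p8
    res$ss8 <- probs_to_string(p8)
  }
  res
}

#' Frequency-baseline reference from a training split
#'
#' Collects the reference statistics both baseline predictors need: the
#' overall most frequent class and, per amino-acid letter, that
#' residue type's most frequent class.
#'
#' @param records labelled [protein_record()]s.
#' @param level `"ss3"` or `"ss8"`.
#' @param dialect 8-to-3 mapping dialect.
#' @return a `baseline_reference` list.
#' @export
baseline_reference <- function(records, level = c("ss3", "ss8"),
                               dialect = "default") {
  level <- match.arg(level)
  classes <- if (level == "ss3") SS3_STATES else SS8_STATES
  aa <- unlist(lapply(records, function(r) chars(r$sequence)))
  lab <- unlist(lapply(records, function(r) {
    if (level == "ss3") chars(map_ss8_to_ss3(r$ss8, dialect)) else chars(r$ss8)
  }))
  counts <- table(factor(aa, levels = AA_ALL), factor(lab, levels = classes))
  global <- classes[which.max(colSums(counts))]
  per_aa <- apply(counts, 1L, function(row) {
    if (sum(row) == 0) global else classes[which.max(row)]
  })
  structure(list(
    level = level, classes = classes, global_class = global,
    per_aa_class = per_aa, counts = counts
  ), class = "baseline_reference")
}

#' Frequency-baseline predictions
#'
#' `global_majority` labels every residue with the single most frequent
#' class of the reference split; `per_residue_majority` labels each
#' residue with the most frequent class of its amino-acid type.
#'
#' @param records [protein_record()]s to predict.
#' @param mode `"global_majority"` or `"per_residue_majority"`.
#' @param reference a [baseline_reference()].
#' @return character vector of predicted label strings.
#' @export
baseline_predict <- function(records, mode = c("global_majority", "per_residue_majority"),
                             reference) {
  mode <- match.arg(mode)
  stopifnot(inherits(reference, "baseline_reference"))
  vapply(records, function(r) {
    if (mode == "global_majority") {
      strrep(reference$global_class, nchar(r$sequence))
    } else {
      paste(reference$per_aa_class[chars(r$sequence)], collapse = "")
    }
  }, character(1))
}
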