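#' Create a query-anchored alignment
#'
#' An alignment holds an ungapped query record plus homolog rows aligned
#' in query coordinates: every row has exactly the query length and is a
#' string over the amino-acid alphabet plus `-`. The query itself is
#' stored as the first row, so single-sequence "alignments" are well
#' defined and no profile column can be empty.
#'
#' @param query a [protein_record()] (ungapped).
#' @param rows character vector of aligned *homolog* rows (may be
#'   empty); the query row is always prepended, so a homolog that
#'   happens to equal the query sequence is kept as a separate row.
#' @return an object of class `alignment`.
#' @export
alignment <- function(query, rows = character(0)) {
  stopifnot(inherits(query, "protein_record"))
  L <- nchar(query$sequence)
  rows <- c(query$sequence, toupper(rows))
  for (i in seq_along(rows)) {
    if (nchar(rows[i]) != L) {
      stop(sprintf(
        "alignment row %d has length %d, query length is %d",
        i, nchar(rows[i]), L
      ), call. = FALSE)
    }
    cc <- chars(rows[i])
    bad <- which(!(cc %in% c(AA_ALL, "-")))
    if (length(bad) > 0L) {
      stop(sprintf(
        "alignment row %d: illegal character '%s' at column %d",
        i, cc[bad[1]], bad[1]
      ), call. = FALSE)
    }
  }
  structure(list(query = query, rows = rows), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment> query %s: %d columns, %d rows (incl. query)\n",
    x$query$id, nchar(x$query$sequence), length(x$rows)
  ))
  invisible(x)
}

# Parse FASTA text into (id, seq) pairs; seqs uppercased, line-wrapped
# sequences concatenated. `allowed` is the legal character set.
parse_fasta_lines <- function(lines, path, allowed) {
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    stop(sprintf("'%s': empty FASTA file", path), call. = FALSE)
  }
  if (!startsWith(lines[1], ">")) {
    stop(sprintf("'%s': line %d: expected '>' header", path, lineno[1]), call. = FALSE)
  }
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) seqs <- c(seqs, cur)
      header <- sub("^>\\s*", "", ln)
      ids <- c(ids, strsplit(header, "\\s+")[[1]][1])
      cur <- ""
    } else {
      cc <- chars(ln)
      bad <- which(!(toupper(cc) %in% allowed))
      if (length(bad) > 0L) {
        stop(sprintf(
          "'%s': line %d: illegal character '%s'",
          path, lineno[i], cc[bad[1]]
        ), call. = FALSE)
      }
      cur <- paste0(cur, ln)
    }
  }
  seqs <- c(seqs, cur)
  if (any(nchar(seqs) == 0L)) {
    stop(sprintf(
      "'%s': record '%s' has an empty sequence",
      path, ids[which(nchar(seqs) == 0L)[1]]
    ), call. = FALSE)
  }
  list(ids = ids, seqs = seqs)
}

#' Read a FASTA file
#'
#' @param path FASTA file; headers are `>` lines (id = first token),
#'   multi-line sequences are concatenated and uppercased.
#' @return list of [protein_record()]s in file order.
#' @export
read_fasta <- function(path) {
  p <- parse_fasta_lines(readLines(path), path, AA_ALL)
  mapply(protein_record, p$ids, toupper(p$seqs),
    SIMPLIFY = FALSE, USE.NAMES = FALSE
  )
}

#' Write records to a FASTA file
#'
#' @param records list of [protein_record()]s.
#' @param path output file.
#' @param width sequence line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    writeLines(paste0(">", r$id), con)
    writeLines(wrap_seq(r$sequence, width), con)
  }
  invisible(path)
}

wrap_seq <- function(s, width) {
  if (nchar(s) <= width) {
    return(s)
  }
  starts <- seq(1L, nchar(s), by = width)
  vapply(starts, function(i) substr(s, i, min(i + width - 1L, nchar(s))), character(1))
}

#' Read a multiple sequence alignment
#'
#' Reads a query-anchored MSA in one of two dialects. The first record is
#' the query and must be ungapped.
#'
#' * `aligned_fasta`: all rows have equal length; gaps are `-`.
#' * `a3m`: lowercase letters are insertions relative to the query and
#'   are deleted (columns where the query has no residue are dropped);
#'   `.` is treated as `-`. After normalisation every row has the query
#'   length.
#'
#' @param path MSA file.
#' @param dialect `"aligned_fasta"` or `"a3m"`.
#' @return an [alignment()].
#' @export
read_msa <- function(path, dialect = c("aligned_fasta", "a3m")) {
  dialect <- match.arg(dialect)
  allowed <- c(AA_ALL, "-", ".", letters)
  p <- parse_fasta_lines(readLines(path), path, allowed)
  seqs <- p$seqs
  if (dialect == "a3m") {
    # Lowercase = insertion state relative to the query: delete.
    seqs <- gsub("[a-z]", "", seqs)
    seqs <- gsub(".", "-", seqs, fixed = TRUE)
  } else {
    if (any(grepl("[a-z.]", seqs))) {
      stop(sprintf(
        "'%s': lowercase or '.' characters are not legal in the aligned_fasta dialect",
        path
      ), call. = FALSE)
    }
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop(sprintf(
      "'%s': alignment rows have unequal lengths after normalisation (%s)",
      path, paste(unique(nchar(seqs)), collapse = ", ")
    ), call. = FALSE)
  }
  if (grepl("-", seqs[1], fixed = TRUE)) {
    stop(sprintf(
      "'%s': the query (first record '%s') must be ungapped",
      path, p$ids[1]
    ), call. = FALSE)
  }
  query <- protein_record(p$ids[1], seqs[1])
  alignment(query, rows = seqs[-1])
}

#' Write an alignment as aligned FASTA
#'
#' @param aln an [alignment()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  ids <- c(aln$query$id, sprintf("%s_hom%d", aln$query$id, seq_len(length(aln$rows) - 1L)))
  for (i in seq_along(aln$rows)) {
    writeLines(c(paste0(">", ids[i]), aln$rows[i]), con)
  }
  invisible(path)
}

#' Read a flat labelled secondary-structure dataset
#'
#' The flat dataset format is repeated 3-line blocks: a `>id` header, the
#' amino-acid sequence, and the 8-state secondary-structure string of
#' equal length. Records containing a run of 10 or more consecutive
#' undetermined residues (`X`) are skipped with a warning, mirroring the
#' standard dataset-construction filter for poorly determined chains.
#'
#' @param path dataset file.
#' @param min_x_run length of the X run that triggers rejection.
#' @return list of [protein_record()]s with `ss8` set.
#' @export
read_ss_dataset <- function(path, min_x_run = 10L) {
  lines <- sub("\r$", "", readLines(path))
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    stop(sprintf("'%s': empty dataset file", path), call. = FALSE)
  }
  if (length(lines) %% 3L != 0L) {
    stop(sprintf(
      "'%s': malformed dataset (expected repeated '>id'/sequence/ss8 3-line blocks)",
      path
    ), call. = FALSE)
  }
  out <- list()
  for (i in seq(1L, length(lines), by = 3L)) {
    if (!startsWith(lines[i], ">")) {
      stop(sprintf("'%s': expected '>' header at block starting line %d", path, i),
        call. = FALSE
      )
    }
    id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
    seqs <- toupper(lines[i + 1L])
    ss8 <- lines[i + 2L]
    if (nchar(seqs) != nchar(ss8)) {
      stop(sprintf(
        "'%s': record '%s': sequence length %d != label length %d",
        path, id, nchar(seqs), nchar(ss8)
      ), call. = FALSE)
    }
    if (grepl(strrep("X", min_x_run), seqs, fixed = TRUE)) {
      warning(sprintf(
        "record '%s' contains >=%d consecutive undetermined residues (X); skipped",
        id, min_x_run
      ), call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- protein_record(id, seqs, ss8)
  }
  out
}

#' Write a flat labelled secondary-structure dataset
#'
#' @param records list of [protein_record()]s with `ss8` set (records may
#'   also carry predicted strings; any 8- or 3-state string of matching
#'   length is written as-is).
#' @param path output file.
#' @param labels optional character vector of label strings overriding
#'   each record's `ss8` (used to write predictions).
#' @return `path`, invisibly.
#' @export
write_ss_dataset <- function(records, path, labels = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    r <- records[[i]]
    lab <- if (is.null(labels)) r$ss8 else labels[[i]]
    if (is.null(lab) || nchar(lab) != nchar(r$sequence)) {
      stop(sprintf("record '%s': missing or mismatched label string", r$id),
        call. = FALSE
      )
    }
    writeLines(c(paste0(">", r$id), r$sequence, lab), con)
  }
  invisible(path)
}

CHECKPOINT_FORMAT_VERSION <- "1"

#' Write a model checkpoint
#'
#' Checkpoints are JSON containers with a versioned header, the full
#' model configuration, named parameter blocks and training metadata.
#' Parameters are stored as C99 hexadecimal floating-point literals so
#' that a write-then-read round trip reproduces every parameter
#' bit-exactly.
#'
#' @param params a `model_params` object (see [init_params()]).
#' @param config the matching `model_config`.
#' @param path output file.
#' @param training_meta optional list (seed, epochs run, final learning
#'   rate, ...).
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(params, config, path, training_meta = list()) {
  check_params_config(params, config)
  blocks <- lapply(params$blocks, function(m) {
    # hex floats round-trip IEEE doubles exactly
    list(dim = dim(m), data = sprintf("%a", as.numeric(m)))
  })
  payload <- list(
    format_version = CHECKPOINT_FORMAT_VERSION,
    model_config = unclass(config),
    parameter_blocks = blocks,
    frozen = attr(params, "frozen") %||% character(0),
    training_meta = training_meta
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = FALSE
  )
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path checkpoint file written by [write_checkpoint()].
#' @return list with elements `params`, `config`, `training_meta`.
#' @export
read_checkpoint <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop(sprintf("'%s': corrupt or truncated checkpoint (%s)", path, conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  if (is.null(payload$format_version) ||
    !identical(as.character(payload$format_version), CHECKPOINT_FORMAT_VERSION)) {
    stop(sprintf(
      "'%s': unsupported checkpoint format version '%s' (supported: %s)",
      path, payload$format_version %||% "<missing>", CHECKPOINT_FORMAT_VERSION
    ), call. = FALSE)
  }
  config <- restore_model_config(payload$model_config)
  blocks <- lapply(payload$parameter_blocks, function(b) {
    vals <- as.numeric(b$data)
    if (anyNA(vals)) {
      stop(sprintf("'%s': non-numeric parameter data", path), call. = FALSE)
    }
    matrix(vals, nrow = b$dim[1], ncol = b$dim[2])
  })
  layout <- param_layout(config)
  if (!identical(names(blocks), names(layout))) {
    stop(sprintf("'%s': checkpoint parameter blocks do not match its configuration", path),
      call. = FALSE
    )
  }
  for (nm in names(layout)) {
    if (!identical(dim(blocks[[nm]]), layout[[nm]])) {
      stop(sprintf(
        "'%s': block '%s' has shape %s, configuration requires %s",
        path, nm, paste(dim(blocks[[nm]]), collapse = "x"),
        paste(layout[[nm]], collapse = "x")
      ), call. = FALSE)
    }
  }
  params <- structure(list(blocks = blocks), class = "model_params")
  frozen <- unlist(payload$frozen)
  if (length(frozen) > 0) attr(params, "frozen") <- as.character(frozen)
  list(params = params, config = config, training_meta = payload$training_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
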