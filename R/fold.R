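# Secondary-structure prediction and structure-file import.

#' Fold an RNA/DNA window into a secondary structure
#'
#' Predicts a pseudoknot-free secondary structure with a stacking-energy
#' dynamic programme: the structure minimising the sum of published
#' nearest-neighbour stack energies over helices, with a minimum hairpin
#' loop of 3 unpaired bases. Lone pairs contribute nothing, so the returned
#' minimum free energy (MFE) is always \eqn{\le 0}. Watson-Crick and G-U
#' wobble pairs are allowed.
#'
#' For exact thermodynamics an externally computed structure can be
#' imported with [parse_fold_file()] and used anywhere a fold result is
#' accepted.
#'
#' @param window sequence (DNA or RNA alphabet), length >= 40.
#' @param min_loop minimum hairpin-loop size (unpaired bases).
#' @return list with `structure` (dot-bracket string), `mfe` (kcal/mol),
#'   and `sequence` (normalised DNA).
#' @export
fold <- function(window, min_loop = 3L) {
  window <- normalize_seq(window)
  if (nchar(window) < 40L) stop("window too short")
  res <- .fold_dp(window, STACK100, as.integer(min_loop))
  list(sequence = window, structure = res$structure, mfe = res$mfe)
}

# unrestricted variant used internally on trimmed precursors / short stems
fold_any <- function(window, min_loop = 3L) {
  window <- normalize_seq(window)
  res <- .fold_dp(window, STACK100, as.integer(min_loop))
  list(sequence = window, structure = res$structure, mfe = res$mfe)
}

#' Parse an RNAfold-format structure file
#'
#' Reads records of the form produced by RNAfold:
#' \preformatted{>id
#' GCGC...
#' (((...))) ( -1.20)}
#'
#' @param path file path.
#' @return list of fold results (`sequence`, `structure`, `mfe`), named by
#'   record id when headers are present.
#' @export
parse_fold_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines)]
  out <- list(); ids <- character(0)
  i <- 1L
  while (i <= length(lines)) {
    id <- NA_character_
    if (startsWith(lines[i], ">")) {
      id <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
    }
    if (i + 1L > length(lines)) stop("truncated structure record at line ", i)
    seq <- normalize_seq(lines[i])
    sl <- lines[i + 1L]
    m <- regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$", sl)[[1L]]
    if (m[1L] == -1L) stop("malformed structure line at line ", i + 1L, ": ", sl)
    g <- regmatches(sl, regexec("^([.()]+)\\s*\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$",
                                sl))[[1L]]
    db <- g[2L]; mfe <- as.numeric(g[3L])
    if (nchar(db) != nchar(seq)) {
      stop("structure length differs from sequence at line ", i + 1L)
    }
    check_balanced(db)
    out[[length(out) + 1L]] <- list(sequence = seq, structure = db, mfe = mfe)
    ids <- c(ids, id)
    i <- i + 2L
  }
  if (!all(is.na(ids))) names(out) <- ids
  out
}

check_balanced <- function(db) {
  v <- cumsum(ifelse(strsplit(db, "", fixed = TRUE)[[1L]] == "(", 1L,
                     ifelse(strsplit(db, "", fixed = TRUE)[[1L]] == ")",
                            -1L, 0L)))
  if (any(v < 0L) || v[length(v)] != 0L) {
    stop("unbalanced dot-bracket string")
  }
  invisible(TRUE)
}

#' Pair table of a dot-bracket structure
#'
#' @param db dot-bracket string.
#' @return integer vector `p` with `p[i]` the partner of position `i`, or
#'   `0` if unpaired (1-based).
#' @export
pair_table <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1L]]
  p <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[i] <- j; p[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket string")
  p
}

#' GC content of a sequence, in percent
#'
#' @param x sequence string.
#' @return percentage in `[0, 100]`.
#' @export
gc_percent <- function(x) {
  x <- normalize_seq(x)
  100 * nchar(gsub("[^GC]", "", x)) / nchar(x)
}
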