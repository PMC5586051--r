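# Read cleaning and library-level summaries.

#' Cleaning configuration
#'
#' Parameters of the raw-read cleaning stage. Defaults retain inserts of
#' 18-30 nt, the size window selected at library construction for plant
#' small-RNA sequencing.
#'
#' @param min_len,max_len retained length window (nt), inclusive.
#' @param adapter_5p,adapter_3p adapter sequences (DNA, may be `""`). Reads
#'   beginning with the 5' adapter are discarded as adaptor contaminants; a
#'   detected 3' adapter suffix is trimmed.
#' @param max_n_fraction maximum tolerated fraction of N bases (default 0).
#' @param min_qual minimum per-base Phred quality when qualities are
#'   available; reads with any base below it are discarded as low-quality.
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(min_len = 18L, max_len = 30L,
                            adapter_5p = "", adapter_3p = "",
                            max_n_fraction = 0, min_qual = 20L) {
  stopifnot(min_len > 0L, min_len <= max_len,
            max_n_fraction >= 0, max_n_fraction <= 1)
  if (nzchar(adapter_5p)) adapter_5p <- normalize_seq(adapter_5p)
  if (nzchar(adapter_3p)) adapter_3p <- normalize_seq(adapter_3p)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 adapter_5p = adapter_5p, adapter_3p = adapter_3p,
                 max_n_fraction = max_n_fraction,
                 min_qual = as.integer(min_qual)),
            class = "cleaning_config")
}

# Locate the 3' adapter in a read: exact match of the adapter's first
# 8 nt (or the whole adapter if shorter) anywhere in the read; returns the
# match start or NA.
find_adapter3 <- function(seqs, adapter) {
  seed <- substr(adapter, 1L, min(8L, nchar(adapter)))
  pos <- regexpr(seed, seqs, fixed = TRUE)
  ifelse(pos > 0L, as.integer(pos), NA_integer_)
}

#' Clean raw small-RNA reads
#'
#' Applies, in order: low-quality discard (any base below `min_qual`, FASTQ
#' input only), 5'-adaptor-contaminant discard (read begins with the 5'
#' adapter), 3' adapter trimming, N-content filtering, and the length
#' window. Surviving reads are collapsed into distinct-sequence tag records
#' with summed counts.
#'
#' @param raw_reads either a character vector of sequences, a data.frame
#'   from [read_fastq()], or a list of [tag_record] (already-collapsed
#'   input, counts preserved).
#' @param config a [cleaning_config()].
#' @param library_id library label for the resulting counts.
#' @return list with `tags` (list of [tag_record]) and `stats`, a named
#'   vector of read counts: `input`, `low_quality`, `adapter5_contaminant`,
#'   `n_filtered`, `too_short`, `too_long`, `clean`. The removals and the
#'   clean count always sum to the input count.
#' @export
clean_reads <- function(raw_reads, config = cleaning_config(),
                        library_id = "lib1") {
  quals <- NULL
  if (is.data.frame(raw_reads)) {
    seqs <- raw_reads$sequence
    quals <- raw_reads$quality
    weights <- rep(1, length(seqs))
  } else if (is.list(raw_reads)) {
    seqs <- vapply(raw_reads, function(t) t$sequence, character(1L))
    weights <- vapply(raw_reads, function(t) sum(t$counts), numeric(1L))
  } else {
    seqs <- chartr("Uu", "Tt", toupper(as.character(raw_reads)))
    weights <- rep(1, length(seqs))
  }
  stats <- c(input = sum(weights), low_quality = 0,
             adapter5_contaminant = 0, n_filtered = 0,
             too_short = 0, too_long = 0, clean = 0)
  alive <- rep(TRUE, length(seqs))

  if (!is.null(quals) && length(seqs)) {
    bad <- vapply(quals, function(q) length(q) > 0 && min(q) < config$min_qual,
                  logical(1L))
    stats["low_quality"] <- sum(weights[alive & bad])
    alive <- alive & !bad
  }
  if (nzchar(config$adapter_5p) && length(seqs)) {
    bad <- startsWith(seqs, config$adapter_5p)
    stats["adapter5_contaminant"] <- sum(weights[alive & bad])
    alive <- alive & !bad
  }
  if (nzchar(config$adapter_3p) && any(alive)) {
    pos <- find_adapter3(seqs, config$adapter_3p)
    trim <- alive & !is.na(pos)
    seqs[trim] <- substr(seqs[trim], 1L, pos[trim] - 1L)
  }
  if (length(seqs)) {
    nfrac <- ifelse(nchar(seqs) > 0,
                    nchar(gsub("[^N]", "", seqs)) / nchar(seqs), 0)
    bad <- nfrac > config$max_n_fraction
    stats["n_filtered"] <- sum(weights[alive & bad])
    alive <- alive & !bad
    short <- nchar(seqs) < config$min_len
    stats["too_short"] <- sum(weights[alive & short])
    alive <- alive & !short
    long <- nchar(seqs) > config$max_len
    stats["too_long"] <- sum(weights[alive & long])
    alive <- alive & !long
  }
  stats["clean"] <- sum(weights[alive])

  tags <- list()
  if (any(alive)) {
    agg <- tapply(weights[alive], seqs[alive], sum)
    agg <- agg[order(names(agg))]
    tags <- lapply(seq_along(agg), function(i) {
      tag_record(names(agg)[i], stats::setNames(unname(agg[i]), library_id))
    })
  }
  list(tags = tags, stats = stats)
}

#' Read-length distribution of a cleaned library
#'
#' Fractions are computed on read counts (each tag weighted by its total
#' count), not on distinct sequences.
#'
#' @param tags list of [tag_record].
#' @return data.frame with columns `length`, `count`, `fraction` (fractions
#'   sum to 1); zero rows for an empty library.
#' @export
length_distribution <- function(tags) {
  if (length(tags) == 0L) {
    return(data.frame(length = integer(0), count = numeric(0),
                      fraction = numeric(0)))
  }
  len <- vapply(tags, function(t) nchar(t$sequence), integer(1L))
  cnt <- vapply(tags, function(t) sum(t$counts), numeric(1L))
  agg <- tapply(cnt, len, sum)
  data.frame(length = as.integer(names(agg)), count = unname(agg),
             fraction = unname(agg) / sum(agg))
}
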