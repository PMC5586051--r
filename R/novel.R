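# Novel miRNA prediction: excision of candidate precursor windows around
# genome-mapped tags, folding, hairpin-geometry checks and the minimal
# folding energy index (MFEI) filter.

#' Locate exact occurrences of a tag in a genome
#'
#' Both strands are searched; minus-strand hits are reported with plus-
#' strand coordinates (1-based inclusive).
#'
#' @param tag tag sequence.
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
locate_tag <- function(tag, genome) {
  tag <- normalize_seq(tag)
  rc <- revcomp(tag)
  hits <- list()
  for (chrom in names(genome)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") tag else rc
      m <- gregexpr(pat, genome[[chrom]], fixed = TRUE)[[1L]]
      if (m[1L] != -1L) {
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = as.integer(m),
          end = as.integer(m) + nchar(tag) - 1L, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Excise candidate precursor windows around a mapped tag
#'
#' For each exact genomic locus of the tag, up to two windows are cut:
#' one extending `flank` nt upstream and 20 nt downstream of the locus, and
#' one extending 20 nt upstream and `flank` nt downstream, both clipped to
#' the chromosome bounds. This covers precursors hosting the mature on
#' either arm. Minus-strand loci yield reverse-complemented windows so the
#' mature always reads 5' to 3' on the window.
#'
#' @param tag tag sequence.
#' @param genome named character vector of chromosome sequences.
#' @param flank flank length in nt (default 250).
#' @return list of candidate windows, each a list with `sequence`,
#'   `mature_start`/`mature_end` (1-based on the window), `chrom`,
#'   `win_start`/`win_end` (plus-strand genomic), `strand`.
#' @export
excise_candidates <- function(tag, genome, flank = 250L) {
  loci <- locate_tag(tag, genome)
  out <- list()
  for (i in seq_len(nrow(loci))) {
    chrom_len <- nchar(genome[[loci$chrom[i]]])
    for (side in 1:2) {
      if (side == 1L) {
        ws <- max(1L, loci$start[i] - flank)
        we <- min(chrom_len, loci$end[i] + 20L)
      } else {
        ws <- max(1L, loci$start[i] - 20L)
        we <- min(chrom_len, loci$end[i] + flank)
      }
      seq <- substr(genome[[loci$chrom[i]]], ws, we)
      if (loci$strand[i] == "+") {
        ms <- loci$start[i] - ws + 1L
      } else {
        seq <- revcomp(seq)
        ms <- we - loci$end[i] + 1L
      }
      out[[length(out) + 1L]] <- list(
        sequence = seq, mature_start = ms,
        mature_end = ms + nchar(tag) - 1L,
        chrom = loci$chrom[i], win_start = ws, win_end = we,
        strand = loci$strand[i])
    }
  }
  out
}

#' Minimal folding energy index
#'
#' `MFEI = AMFE / GC%`, with `AMFE = -MFE / length * 100` (the adjusted
#' MFE per 100 nt). Dimensionless; values of genuine plant pre-miRNAs are
#' typically high, and the filter threshold used here is 0.9. Absolute
#' values depend on the energy model used to compute the MFE.
#'
#' @param mfe minimum free energy, kcal/mol, `<= 0`.
#' @param length sequence length, nt, `> 0`.
#' @param gc_percent GC content in percent, `(0, 100]`.
#' @return MFEI, `>= 0`.
#' @export
mfei <- function(mfe, length, gc_percent) {
  stopifnot(length > 0, mfe <= 0)
  if (any(gc_percent <= 0)) stop("MFEI undefined for GC percent of 0")
  stopifnot(gc_percent <= 100)
  (-mfe / length * 100) / gc_percent
}

# number of hairpin loops lying entirely within window positions
# [from, to]: maximal unpaired runs closed by a pair (i-1, j+1)
count_hairpin_loops <- function(p, from, to) {
  n <- 0L
  i <- from
  while (i <= to) {
    if (p[i] == 0L) {
      j <- i
      while (j < length(p) && p[j + 1L] == 0L) j <- j + 1L
      if (i > 1L && j < length(p) && p[i - 1L] == j + 1L && j <= to) {
        n <- n + 1L
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  n
}

#' Evaluate one excised window as a miRNA precursor hairpin
#'
#' Folds the window (or uses a supplied fold result), checks the hairpin
#' geometry around the mature, locates the star segment, trims the
#' enclosing mature-to-star span as the precursor, and computes MFE, GC%
#' and MFEI on that precursor. The geometric criteria follow common plant
#' novel-miRNA practice: mature wholly on one arm with at most
#' `max_unpaired_mature` unpaired bases, a star with 2-nt 3' overhang
#' duplex geometry and at most `max_duplex_mm` mismatched duplex
#' positions, and no more than one loop between mature and star.
#'
#' @param cand candidate window from [excise_candidates()].
#' @param fold_result optional precomputed fold of `cand$sequence`.
#' @param max_unpaired_mature maximum unpaired mature bases (default 4).
#' @param max_duplex_mm maximum mismatched positions in the mature/star
#'   duplex (default 4).
#' @return a `hairpin_candidate` list (with `ok = TRUE` and fields
#'   `structure`, `mfe`, `arm`, `star_start`, `star_end`,
#'   `precursor_start`, `precursor_end`, `gc_percent`, `mfei`) or a list
#'   with `ok = FALSE` and a `reason`.
#' @export
analyze_hairpin <- function(cand, fold_result = NULL,
                            max_unpaired_mature = 4L, max_duplex_mm = 4L) {
  fail <- function(reason) list(ok = FALSE, reason = reason, cand = cand)
  if (is.null(fold_result)) fold_result <- fold(cand$sequence)
  db <- fold_result$structure
  p <- pair_table(db)
  m <- cand$mature_start:cand$mature_end
  if (m[length(m)] > nchar(cand$sequence)) return(fail("mature outside window"))
  partners <- p[m][p[m] > 0L]
  if (length(partners) == 0L) return(fail("mature unpaired"))
  if (any(partners %in% m)) return(fail("mature spans the loop"))
  unpaired <- sum(p[m] == 0L)
  if (unpaired > max_unpaired_mature) return(fail("mature too unpaired"))
  if (all(partners > cand$mature_end)) {
    arm <- "5p"
  } else if (all(partners < cand$mature_start)) {
    arm <- "3p"
  } else {
    return(fail("mature pairs to both arms"))
  }
  # star: span of the mature's partners, extended 2 nt at the star's
  # 3' end (always the higher window coordinate) for the Dicer duplex
  # overhang
  s1 <- min(partners)
  s2 <- min(max(partners) + 2L, nchar(cand$sequence))
  star <- c(s1, s2)
  if (star[1L] <= cand$mature_end && star[2L] >= cand$mature_start) {
    return(fail("star overlaps mature"))
  }
  # duplex defects: unpaired mature bases plus bulged star positions
  # inside the pairing span (a clean Dicer duplex has neither)
  n_paired <- length(partners)
  span_width <- max(partners) - min(partners) + 1L
  mm <- (length(m) - n_paired) + (span_width - n_paired)
  if (mm > max_duplex_mm) return(fail("mature/star duplex too mismatched"))
  gap <- if (arm == "5p") c(cand$mature_end + 1L, star[1L] - 1L) else
    c(star[2L] + 1L, cand$mature_start - 1L)
  if (gap[1L] <= gap[2L] &&
      count_hairpin_loops(p, gap[1L], gap[2L]) > 1L) {
    return(fail("more than one loop between mature and star"))
  }
  pre <- c(min(cand$mature_start, star[1L]), max(cand$mature_end, star[2L]))
  pre_seq <- substr(cand$sequence, pre[1L], pre[2L])
  pre_fold <- fold_any(pre_seq)
  gc <- gc_percent(pre_seq)
  if (gc <= 0) return(fail("GC content zero"))
  idx <- mfei(pre_fold$mfe, nchar(pre_seq), gc)
  c(list(ok = TRUE, structure = db, mfe = fold_result$mfe, arm = arm,
         star_start = star[1L], star_end = star[2L],
         precursor_start = pre[1L], precursor_end = pre[2L],
         precursor_seq = pre_seq, precursor_mfe = pre_fold$mfe,
         gc_percent = gc, mfei = idx),
    cand)
}

# Trim an excised candidate to `new_left`/`new_right` nt of context around
# the mature, keeping genomic coordinates consistent with the strand.
trim_candidate <- function(cand, new_left, new_right) {
  n <- nchar(cand$sequence)
  left <- cand$mature_start - 1L
  right <- n - cand$mature_end
  dl <- max(0L, left - as.integer(new_left))
  dr <- max(0L, right - as.integer(new_right))
  if (dl == 0L && dr == 0L) return(cand)
  cand$sequence <- substr(cand$sequence, dl + 1L, n - dr)
  cand$mature_start <- cand$mature_start - dl
  cand$mature_end <- cand$mature_end - dl
  if (identical(cand$strand, "-")) {
    cand$win_start <- cand$win_start + dr
    cand$win_end <- cand$win_end - dl
  } else {
    cand$win_start <- cand$win_start + dl
    cand$win_end <- cand$win_end - dr
  }
  cand
}

# Window extents evaluated per candidate: the full excision plus tighter
# cuts of the flank side.  Precursor boundaries are unknown a priori and
# long windows let unrelated flanking sequence distort the fold, so each
# locus is folded at several nested extents and the best passing hairpin
# wins.
candidate_windows <- function(cand, extents = c(100L, 60L)) {
  left <- cand$mature_start - 1L
  right <- nchar(cand$sequence) - cand$mature_end
  out <- list(cand)
  for (e in extents) {
    v <- if (left >= right) trim_candidate(cand, e, right) else
      trim_candidate(cand, left, e)
    if (nchar(v$sequence) < nchar(out[[length(out)]]$sequence)) {
      out[[length(out) + 1L]] <- v
    }
  }
  out
}

#' Call a novel miRNA from folded candidate windows
#'
#' Returns the best candidate passing all hairpin criteria and the MFEI
#' threshold (`MFEI >= min_mfei`, default 0.9), or `NULL`. Ties between
#' passing candidates are broken by lower precursor MFE. A novel call
#' additionally requires expression support: total tag count
#' `>= min_count` reads (default 5).
#'
#' @param tag a [tag_record] or a plain sequence (then `count` supplies
#'   the expression support).
#' @param candidates list from [excise_candidates()].
#' @param min_mfei MFEI acceptance threshold.
#' @param min_count minimum supporting read count.
#' @param count tag read count when `tag` is a plain sequence.
#' @param ... geometry thresholds passed to [analyze_hairpin()].
#' @return best passing `hairpin_candidate`, or `NULL`.
#' @export
call_novel <- function(tag, candidates, min_mfei = 0.9, min_count = 5L,
                       count = NULL, ...) {
  if (inherits(tag, "tag_record")) count <- sum(tag$counts)
  if (is.null(count)) count <- min_count
  if (count < min_count) return(NULL)
  best <- NULL
  for (cand in candidates) {
    for (win in candidate_windows(cand)) {
      h <- analyze_hairpin(win, ...)
      if (!isTRUE(h$ok)) next
      if (h$mfei < min_mfei) next
      if (is.null(best) || h$precursor_mfe < best$precursor_mfe) best <- h
    }
  }
  best
}

#' Hairpin-precursor verifier for the cross-species known-miRNA rule
#'
#' @param genome named character vector of chromosome sequences.
#' @param flank excision flank (nt).
#' @param min_mfei MFEI threshold applied to the verifying hairpin.
#' @return function(tag_sequence) -> logical.
#' @export
make_precursor_check <- function(genome, flank = 250L, min_mfei = 0.9) {
  function(tag) {
    cands <- excise_candidates(tag, genome, flank)
    !is.null(call_novel(tag, cands, min_mfei = min_mfei, min_count = 0L,
                        count = 0L))
  }
}
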