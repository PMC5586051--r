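# Degradome (PARE) tag mapping, T-plot profiles, and cleavage-site
# validation of predicted target sites.

#' Map degradome 5' tags onto transcripts
#'
#' A tag increments position `p` of a transcript when the tag matches the
#' transcript exactly starting at `p` (sense strand only: degradome tags
#' derive from the cleaved mRNA itself). Multi-mapping tags increment
#' every locus, so tag mass is conserved as
#' `sum(profile totals) = sum(tag count x number of loci)`.
#'
#' @param tags data.frame with columns `sequence`, `count` (e.g. from
#'   [read_degradome_tags()]); tags shorter than `min_tag_len` are ignored.
#' @param transcripts named character vector of transcript sequences.
#' @param min_tag_len minimum tag length (default 15 nt).
#' @return named list of `degradome_profile` objects: numeric vectors of
#'   per-position summed 5'-tag counts (length = transcript length) with
#'   attribute `total`.
#' @export
map_tags <- function(tags, transcripts, min_tag_len = 15L) {
  profiles <- lapply(transcripts, function(tx) numeric(nchar(tx)))
  keep <- nchar(tags$sequence) >= min_tag_len
  for (i in which(keep)) {
    tg <- tags$sequence[i]
    for (tx_id in names(transcripts)) {
      m <- gregexpr(tg, transcripts[[tx_id]], fixed = TRUE)[[1L]]
      if (m[1L] != -1L) {
        profiles[[tx_id]][as.integer(m)] <-
          profiles[[tx_id]][as.integer(m)] + tags$count[i]
      }
    }
  }
  lapply(profiles, function(p) {
    structure(p, total = sum(p), class = "degradome_profile")
  })
}

#' Validate a predicted target site against a degradome profile
#'
#' Looks for a tag-abundance peak within `window` nt of the site's
#' expected cleavage coordinate (`end - 9`). The site is validated when
#' the best on-site count reaches `min_reads` (default 2). Peaks are
#' assigned the de-facto degradome abundance categories:
#' \describe{
#'   \item{0}{the unique transcript-wide maximum}
#'   \item{1}{equal to the maximum, but not unique}
#'   \item{2}{above the median of nonzero positions}
#'   \item{3}{at most the median, count > 1}
#'   \item{4}{count of 1}
#' }
#' Categories are reported for all sites with on-site signal; only the
#' read gate decides validation.
#'
#' @param site one site row (list or 1-row data.frame) with `expected_cut`.
#' @param profile a `degradome_profile` for the site's transcript.
#' @param window half-width of the search window around the expected cut
#'   (default 1 nt, absorbing 1-nt mapping ambiguity).
#' @param min_reads minimum on-site tag count for validation.
#' @return list with `validated` (logical) and `peak` (`NULL`, or list
#'   with `position`, `count`, `category`).
#' @export
validate_site <- function(site, profile, window = 1L, min_reads = 2L) {
  cut <- as.integer(site$expected_cut)
  lo <- max(1L, cut - window); hi <- min(length(profile), cut + window)
  if (lo > hi) return(list(validated = FALSE, peak = NULL))
  win <- as.numeric(profile[lo:hi])
  cmax <- max(win)
  if (cmax <= 0) return(list(validated = FALSE, peak = NULL))
  cand <- (lo:hi)[win == cmax]
  pos <- cand[order(abs(cand - cut), cand)][1L]
  tx_max <- max(as.numeric(profile))
  nz <- as.numeric(profile[profile > 0])
  category <- if (cmax == tx_max && sum(profile == tx_max) == 1L) 0L
    else if (cmax == tx_max) 1L
    else if (cmax > stats::median(nz)) 2L
    else if (cmax > 1) 3L
    else 4L
  list(validated = cmax >= min_reads,
       peak = list(position = pos, count = cmax, category = category))
}

#' Report degradome-validated miRNA-target pairs
#'
#' Keeps only sites validated by [validate_site()] and annotates each with
#' its peak position, count and category. Off-site positions whose
#' abundance is at least the on-site peak are listed in `other_peaks`
#' (comma-separated coordinates), mirroring published cleavage tables that
#' report a secondary transcript-wide peak next to the site peak.
#'
#' @param sites data.frame of predicted sites ([scan_transcript()] rows).
#' @param profiles named list of `degradome_profile` from [map_tags()].
#' @param window,min_reads passed to [validate_site()].
#' @return data.frame of validated sites with added columns `validated`,
#'   `category`, `peak_position`, `peak_count`, `other_peaks`.
#' @export
report_validated_pairs <- function(sites, profiles, window = 1L,
                                   min_reads = 2L) {
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, , drop = FALSE]
    profile <- profiles[[site$transcript_id]]
    if (is.null(profile)) next
    v <- validate_site(site, profile, window = window,
                       min_reads = min_reads)
    if (!v$validated) next
    off <- which(as.numeric(profile) >= v$peak$count)
    off <- off[abs(off - v$peak$position) > window]
    row <- site
    row$validated <- TRUE
    row$category <- v$peak$category
    row$peak_position <- v$peak$position
    row$peak_count <- v$peak$count
    row$other_peaks <- paste(off, collapse = ",")
    rows[[i]] <- row
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    out <- sites[0, , drop = FALSE]
    out$validated <- logical(0); out$category <- integer(0)
    out$peak_position <- integer(0); out$peak_count <- numeric(0)
    out$other_peaks <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out[order(out$transcript_id, out$start, out$mirna_id), , drop = FALSE]
}
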