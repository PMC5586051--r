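# Ordered reference classification and known-miRNA identification.
#
# Tags are first assigned to non-coding / structural classes by exact
# substring matching against prioritised reference sets (rRNA before tRNA
# before ... before exon/intron), the order in which sRNA annotation
# pipelines discard structural RNA before miRNA prediction. Unassigned and
# exon/intron tags proceed to miRNA identification.

#' Build a reference set
#'
#' @param class sequence class label: one of `rRNA`, `tRNA`, `snRNA`,
#'   `snoRNA`, `repeat`, `exon`, `intron`, `miRNA_precursor`,
#'   `miRNA_mature`, `genome`.
#' @param seqs named character vector of DNA sequences.
#' @return object of class `reference_set`.
#' @export
reference_set <- function(class, seqs) {
  class <- match.arg(class, c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat",
                              "exon", "intron", "miRNA_precursor",
                              "miRNA_mature", "genome"))
  seqs <- vapply(seqs, normalize_seq, character(1L))
  structure(list(class = class, seqs = seqs), class = "reference_set")
}

# TRUE for each tag that occurs as an exact substring (forward or reverse
# complement) of any sequence in `refs`.
substring_hit <- function(tags, refs) {
  if (length(refs) == 0L || length(tags) == 0L) {
    return(rep(FALSE, length(tags)))
  }
  haystack <- paste(c(refs, revcomp(refs)), collapse = "\x01")
  vapply(tags, function(tg) grepl(tg, haystack, fixed = TRUE), logical(1L),
         USE.NAMES = FALSE)
}

#' Classify tags against ordered reference sets
#'
#' Each tag receives the class of the first reference set (in the supplied
#' priority order) containing it as an exact substring on either strand;
#' tags matching nothing are `unassigned`. Classification is a partition:
#' exactly one annotation per tag.
#'
#' @param tags character vector of tag sequences or list of [tag_record].
#' @param reference_sets list of [reference_set] in priority order.
#' @return character vector of annotations, parallel to `tags`.
#' @export
classify_tags <- function(tags, reference_sets) {
  if (length(tags) && is.list(tags) && inherits(tags[[1L]], "tag_record")) {
    tags <- vapply(tags, function(t) t$sequence, character(1L))
  }
  ann <- rep("unassigned", length(tags))
  todo <- rep(TRUE, length(tags))
  for (rs in reference_sets) {
    if (!any(todo)) break
    hit <- substring_hit(tags[todo], rs$seqs)
    ann[todo][hit] <- rs$class
    todo[todo] <- !hit
  }
  ann
}

#' @rdname classify_tags
#' @param tag a single tag sequence.
#' @export
classify_tag <- function(tag, reference_sets) {
  classify_tags(tag, reference_sets)[1L]
}

#' miRBase-style reference database
#'
#' @param mature,hairpin named character vectors; ids carry a `species-`
#'   prefix (e.g. `hvu-miR156a`).
#' @return object of class `mirna_db`.
#' @export
mirna_db <- function(mature, hairpin) {
  structure(list(mature = vapply(mature, normalize_seq, character(1L)),
                 hairpin = vapply(hairpin, normalize_seq, character(1L))),
            class = "mirna_db")
}

species_of <- function(ids) sub("-.*$", "", ids)

# Best ungapped overlap between tag and mature: slides the tag across all
# offsets and returns the longest mismatch-free overlap length together
# with the id achieving it.
best_overlap <- function(tag, matures, min_overlap = 16L) {
  tl <- nchar(tag)
  tchars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  best <- 0L; best_id <- NA_character_
  for (j in seq_along(matures)) {
    m <- matures[[j]]
    ml <- nchar(m)
    mchars <- strsplit(m, "", fixed = TRUE)[[1L]]
    for (off in seq(-(tl - 1L), ml - 1L)) {
      a <- max(1L, 1L - off); b <- min(tl, ml - off)
      if (b - a + 1L < min_overlap) next
      if (all(tchars[a:b] == mchars[(a + off):(b + off)])) {
        if (b - a + 1L > best) {
          best <- b - a + 1L
          best_id <- names(matures)[j]
        }
      }
    }
  }
  list(len = best, id = best_id)
}

# Minimum edit distance (mismatches + gaps pooled) between the tag and any
# same-length-window substring of `ref` (allowing +/- `max_d` length slack),
# i.e. a free-end-gap alignment of the short tag inside the longer
# reference.
min_sub_edit <- function(tag, ref, max_d = 2L) {
  tl <- nchar(tag); rl <- nchar(ref)
  best <- Inf
  for (w in seq(max(1L, tl - max_d), tl + max_d)) {
    if (w > rl) next
    subs <- substring(ref, seq_len(rl - w + 1L), seq_len(rl - w + 1L) + w - 1L)
    d <- utils::adist(tag, subs)
    best <- min(best, min(d))
    if (best == 0L) break
  }
  best
}

#' Identify a known miRNA
#'
#' Implements the tiered identification rules used for annotating conserved
#' miRNAs from sequencing tags:
#' 1. `precursor_exact` — the tag is an exact substring of a same-species
#'    precursor (no mismatch);
#' 2. `barley_overlap16` — an ungapped, mismatch-free overlap of at least
#'    `min_overlap` nt (default 16) with a same-species mature miRNA;
#' 3. `cross_species_2mm` — an alignment to any plant mature or precursor
#'    with at most `max_cross_mm` mismatches or gaps (pooled budget,
#'    default 2) AND a verifiable hairpin precursor at the tag's locus
#'    (checked through `precursor_check` when a genome is supplied).
#'
#' Matching is stranded: mature miRNAs are single-stranded, so no
#' reverse-complement matching is performed here.
#'
#' @param tag tag sequence (DNA).
#' @param db a [mirna_db()].
#' @param species same-species prefix (default `"hvu"`, barley).
#' @param min_overlap minimum ungapped overlap for the same-species mature
#'   rule.
#' @param overlap_mismatches mismatches tolerated inside the overlap
#'   (default 0, the strictest reading).
#' @param max_cross_mm pooled mismatch+gap budget for the cross-species rule.
#' @param precursor_check function(tag) -> logical, verifying a fold-back
#'   precursor at the tag's genomic locus (used only by the cross-species
#'   rule); `NULL` disables the cross-species tier.
#' @return `NULL`, or a list with `mirna_id`, `mode`, `mismatches`.
#' @export
call_known_mirna <- function(tag, db, species = "hvu", min_overlap = 16L,
                             overlap_mismatches = 0L, max_cross_mm = 2L,
                             precursor_check = NULL) {
  tag <- normalize_seq(tag)
  same_hp <- db$hairpin[species_of(names(db$hairpin)) == species]
  same_mat <- db$mature[species_of(names(db$mature)) == species]

  if (length(same_hp)) {
    hit <- vapply(same_hp, function(h) grepl(tag, h, fixed = TRUE),
                  logical(1L))
    if (any(hit)) {
      return(list(mirna_id = names(same_hp)[which(hit)[1L]],
                  mode = "precursor_exact", mismatches = 0))
    }
  }
  if (length(same_mat)) {
    ov <- if (overlap_mismatches == 0L) {
      best_overlap(tag, same_mat, min_overlap)
    } else {
      best_overlap_mm(tag, same_mat, min_overlap, overlap_mismatches)
    }
    if (ov$len >= min_overlap) {
      return(list(mirna_id = ov$id, mode = "barley_overlap16",
                  mismatches = 0))
    }
  }
  if (!is.null(precursor_check)) {
    cross <- c(db$mature[species_of(names(db$mature)) != species],
               db$hairpin[species_of(names(db$hairpin)) != species])
    for (j in seq_along(cross)) {
      d <- min_sub_edit(tag, cross[[j]], max_cross_mm)
      if (d <= max_cross_mm && isTRUE(precursor_check(tag))) {
        return(list(mirna_id = names(cross)[j], mode = "cross_species_2mm",
                    mismatches = d))
      }
    }
  }
  NULL
}

# Overlap search tolerating up to `mm` mismatches inside the overlap.
best_overlap_mm <- function(tag, matures, min_overlap, mm) {
  tl <- nchar(tag)
  tchars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  best <- 0L; best_id <- NA_character_
  for (j in seq_along(matures)) {
    mchars <- strsplit(matures[[j]], "", fixed = TRUE)[[1L]]
    ml <- length(mchars)
    for (off in seq(-(tl - 1L), ml - 1L)) {
      a <- max(1L, 1L - off); b <- min(tl, ml - off)
      len <- b - a + 1L
      if (len < min_overlap || len <= best) next
      if (sum(tchars[a:b] != mchars[(a + off):(b + off)]) <= mm) {
        best <- len; best_id <- names(matures)[j]
      }
    }
  }
  list(len = best, id = best_id)
}
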