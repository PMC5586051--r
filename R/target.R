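# miRNA target prediction under the six plant complementarity rules.
#
# A candidate site is an ungapped antiparallel duplex between the miRNA
# (5'->3') and a transcript window of the same length (5'->3' on the
# transcript): miRNA position i pairs site position L - i + 1.  G-U wobble
# pairs count 0.5 towards mismatch totals (rules 1 and 5) but are treated
# as pairs, not mismatches, for the adjacency and position rules (2-4),
# following common plant target-rule practice; set `gu_is_mismatch = TRUE`
# to count them as mismatches there as well.

#' Per-position pair states of a miRNA/target duplex
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site target site sequence, 5' to 3' on the transcript, same
#'   length as the miRNA.
#' @return object of class `duplex_alignment`: list with `mirna`, `site`,
#'   `states` (character vector over miRNA positions 1..L: `"WC"`, `"GU"`
#'   or `"MM"`), `mismatch_total`, `mismatch_5p_1_12` (G-U = 0.5 each),
#'   and energies filled by [duplex_energy()].
#' @export
pair_states <- function(mirna, site) {
  mirna <- normalize_seq(mirna); site <- normalize_seq(site)
  L <- nchar(mirna)
  if (nchar(site) != L) stop("miRNA and site must have equal lengths")
  mc <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  sc <- rev(strsplit(site, "", fixed = TRUE)[[1L]])  # antiparallel partner
  key <- paste0(mc, sc)
  states <- ifelse(key %in% c("AT", "TA", "GC", "CG"), "WC",
                   ifelse(key %in% c("GT", "TG"), "GU", "MM"))
  w <- ifelse(states == "MM", 1, ifelse(states == "GU", 0.5, 0))
  d <- list(mirna = mirna, site = site, states = states,
            mismatch_total = sum(w),
            mismatch_5p_1_12 = sum(w[seq_len(min(12L, L))]),
            energy = NA_real_, energy_ratio = NA_real_)
  class(d) <- "duplex_alignment"
  d
}

#' Free energy of an ungapped duplex
#'
#' Sums published nearest-neighbour RNA/RNA stack energies over maximal
#' runs of consecutive paired positions (Watson-Crick or G-U); mismatches
#' contribute nothing and break stacks. The result is `<= 0`, and
#' converting a paired position to a mismatch can never make the energy
#' more negative.
#'
#' @param duplex a `duplex_alignment` from [pair_states()].
#' @return energy in kcal/mol.
#' @export
duplex_energy <- function(duplex) {
  mc <- strsplit(duplex$mirna, "", fixed = TRUE)[[1L]]
  sc <- rev(strsplit(duplex$site, "", fixed = TRUE)[[1L]])
  L <- length(mc)
  paired <- duplex$states != "MM"
  e <- 0L
  for (i in seq_len(L - 1L)) {
    if (paired[i] && paired[i + 1L]) {
      t1 <- pair_type_idx(mc[i], sc[i])
      t2 <- pair_type_idx(sc[i + 1L], mc[i + 1L])  # inner pair, reversed
      s <- STACK100[t1, t2]
      if (s < 0L) e <- e + s  # destabilising stacks contribute nothing
    }
  }
  e / 100
}

#' Evaluate a duplex and its energy ratio
#'
#' Fills `energy` and `energy_ratio` of a duplex: the ratio of the duplex
#' energy to the energy of the miRNA bound to its perfect complement
#' (computed under the same energy model, so the ratio criterion is
#' model-consistent).
#'
#' @param duplex a `duplex_alignment`.
#' @return the duplex with `energy` and `energy_ratio` set.
#' @export
score_duplex <- function(duplex) {
  duplex$energy <- duplex_energy(duplex)
  perfect <- pair_states(duplex$mirna, revcomp(duplex$mirna))
  ep <- duplex_energy(perfect)
  duplex$energy_ratio <- if (ep == 0) as.numeric(duplex$energy == 0) else
    duplex$energy / ep
  duplex
}

#' Apply the six plant miRNA-target complementarity rules
#'
#' The rules, evaluated on the antiparallel duplex with positions counted
#' from the miRNA 5' end:
#' 1. no more than `max_mismatch` (default 4) mismatches, G-U counting 0.5;
#' 2. no more than two adjacent mismatches anywhere;
#' 3. no adjacent mismatches within positions 2-12;
#' 4. no mismatch at positions 10-11 (the slicing positions);
#' 5. no more than `max_5p_mismatch` (default 2.5) mismatches in
#'    positions 1-12;
#' 6. duplex free energy at least `min_energy_ratio` (default 0.75) of the
#'    perfect-complement energy.
#'
#' @param duplex a `duplex_alignment` (scored with [score_duplex()] if
#'   `energy_ratio` is still `NA`).
#' @param max_mismatch rule-1 budget.
#' @param max_5p_mismatch rule-5 budget.
#' @param min_energy_ratio rule-6 threshold.
#' @param gu_is_mismatch treat G-U wobbles as mismatches for rules 2-4.
#' @return list with `pass` (logical) and `failed_rules` (integer vector,
#'   subset of 1:6).
#' @export
apply_rules <- function(duplex, max_mismatch = 4, max_5p_mismatch = 2.5,
                        min_energy_ratio = 0.75, gu_is_mismatch = FALSE) {
  if (is.na(duplex$energy_ratio)) duplex <- score_duplex(duplex)
  mm <- if (gu_is_mismatch) duplex$states != "WC" else duplex$states == "MM"
  L <- length(mm)
  failed <- integer(0)
  if (duplex$mismatch_total > max_mismatch) failed <- c(failed, 1L)
  runs <- rle(mm)
  if (any(runs$values & runs$lengths > 2L)) failed <- c(failed, 2L)
  idx <- 2:min(12L, L)
  if (any(mm[idx[-length(idx)]] & mm[idx[-1L]])) failed <- c(failed, 3L)
  if (any(mm[intersect(10:11, seq_len(L))])) failed <- c(failed, 4L)
  if (duplex$mismatch_5p_1_12 > max_5p_mismatch) failed <- c(failed, 5L)
  if (duplex$energy_ratio < min_energy_ratio) failed <- c(failed, 6L)
  list(pass = length(failed) == 0L, failed_rules = failed)
}

#' Scan a transcript for miRNA binding sites
#'
#' Every window of miRNA length is evaluated under [apply_rules()];
#' passing windows are returned sorted by (mismatch total, decreasing
#' energy ratio, start). The expected degradome cleavage coordinate of a
#' site is `end - 9`: cleavage occurs opposite miRNA positions 10-11, i.e.
#' 10 nt upstream of the transcript position paired with the miRNA 5' end.
#' Overlapping passing windows are all reported; degradome validation
#' disambiguates downstream.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcript transcript/CDS sequence (5'->3').
#' @param transcript_id id used in the report.
#' @param mirna_id id used in the report.
#' @inheritParams apply_rules
#' @return data.frame with one row per passing site: `mirna_id`,
#'   `transcript_id`, `start`, `end`, `expected_cut`, `mismatch_total`,
#'   `mismatch_5p_1_12`, `energy`, `energy_ratio` (1-based inclusive
#'   coordinates).
#' @export
scan_transcript <- function(mirna, transcript, transcript_id = "tx",
                            mirna_id = "mir", max_mismatch = 4,
                            max_5p_mismatch = 2.5, min_energy_ratio = 0.75,
                            gu_is_mismatch = FALSE) {
  mirna <- normalize_seq(mirna)
  transcript <- normalize_seq(transcript)
  L <- nchar(mirna)
  if (nchar(transcript) < L) {
    stop("transcript shorter than miRNA")
  }
  e_perfect <- duplex_energy(pair_states(mirna, revcomp(mirna)))
  # integer-coded fast path: per-window pair states via lookup tables
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
  tx_int <- code[strsplit(transcript, "", fixed = TRUE)[[1L]]]
  m_int <- code[strsplit(mirna, "", fixed = TRUE)[[1L]]]
  state_lut <- matrix("MM", 5L, 5L)  # [mirna base, site base]
  state_lut[1L, 4L] <- "WC"; state_lut[4L, 1L] <- "WC"
  state_lut[2L, 3L] <- "WC"; state_lut[3L, 2L] <- "WC"
  state_lut[3L, 4L] <- "GU"; state_lut[4L, 3L] <- "GU"
  w_lut <- matrix(1, 5L, 5L)
  w_lut[state_lut == "WC"] <- 0; w_lut[state_lut == "GU"] <- 0.5
  # site position p of a window pairs miRNA position L - p + 1
  m_by_site <- rev(m_int)
  mask12 <- rev(seq_len(L)) <= 12L  # site positions pairing miRNA 1..12
  starts <- seq_len(nchar(transcript) - L + 1L)
  rows <- vector("list", length(starts))
  for (s in starts) {
    si <- tx_int[s:(s + L - 1L)]
    idx <- cbind(m_by_site, si)
    w <- w_lut[idx]
    mt <- sum(w)
    if (mt > max_mismatch) next  # cannot pass rule 1
    d <- structure(list(mirna = mirna,
                        site = substr(transcript, s, s + L - 1L),
                        states = rev(state_lut[idx]),
                        mismatch_total = mt,
                        mismatch_5p_1_12 = sum(w[mask12]),
                        energy = NA_real_, energy_ratio = NA_real_),
                   class = "duplex_alignment")
    d$energy <- duplex_energy(d)
    d$energy_ratio <- if (e_perfect == 0) as.numeric(d$energy == 0) else
      d$energy / e_perfect
    verdict <- apply_rules(d, max_mismatch = max_mismatch,
                           max_5p_mismatch = max_5p_mismatch,
                           min_energy_ratio = min_energy_ratio,
                           gu_is_mismatch = gu_is_mismatch)
    if (!verdict$pass) next
    rows[[s]] <- data.frame(
      mirna_id = mirna_id, transcript_id = transcript_id,
      start = s, end = s + L - 1L, expected_cut = s + L - 1L - 9L,
      mismatch_total = d$mismatch_total,
      mismatch_5p_1_12 = d$mismatch_5p_1_12,
      energy = d$energy, energy_ratio = d$energy_ratio,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      expected_cut = integer(0), mismatch_total = numeric(0),
                      mismatch_5p_1_12 = numeric(0), energy = numeric(0),
                      energy_ratio = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$mismatch_total, -out$energy_ratio, out$start), ,
      drop = FALSE]
}
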