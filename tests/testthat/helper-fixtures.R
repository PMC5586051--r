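# Shared fixtures and independent oracles.

set.seed(20260901)  # helpers only; tests set their own seeds

RAND_BASES <- c("A", "C", "G", "T")

rand_dna <- function(n) paste(sample(RAND_BASES, n, replace = TRUE),
                              collapse = "")

# Published barley miRNA-target cleavage table: binding site on the
# CDS (1-based inclusive) and the degradome (PARE) cut site, for known
# and novel miRNA families. Where the table lists a secondary
# transcript-wide peak next to the site cut, `cut` is the on-site
# coordinate.
cleavage_fixture <- function() {
  rows <- rbind(
    c("miR156",  "AK356077",     839, 858,  849),
    c("miR156",  "AK374598",     860, 879,  870),
    c("miR156",  "MLOC_11199.2", 1154, 1173, 1164),
    c("miR159",  "AK251726.1",   962, 982,  973),
    c("miR159",  "AK370348",     1009, 1028, 1019),
    c("miR160",  "MLOC_64795.1", 1329, 1349, 1340),
    c("miR160",  "MLOC_69988.1", 717, 737,  728),
    c("miR165",  "MLOC_44268.1", 159, 179,  170),
    c("miR165",  "AK362009",     578, 598,  589),
    c("miR165",  "AK364215",     639, 658,  649),
    c("miR165",  "MLOC_58644.1", 980, 1000, 991),
    c("miR166",  "AK362009",     578, 598,  589),
    c("miR166",  "AK364215",     638, 658,  649),
    c("miR166",  "AK364215.2",   640, 658,  649),
    c("miR166",  "AK365312",     563, 583,  574),
    c("miR166",  "MLOC_44268.1", 159, 179,  170),
    c("miR166",  "MLOC_58644.1", 980, 1000, 991),
    c("miR167",  "MLOC_51932.2", 2343, 2363, 2354),
    c("miR167",  "MLOC_58330.2", 2528, 2549, 2540),
    c("miR167",  "MLOC_63938.1", 2402, 2423, 2414),
    c("miR171",  "AK371946",     1090, 1109, 1100),
    c("miR172",  "AK355002",     1214, 1234, 1225),
    c("miR319",  "AK370348",     1009, 1028, 1019),
    c("miR319",  "MLOC_63989.1", 976, 995,  986),
    c("miR360",  "MLOC_69988.1", 717, 737,  728),
    c("miR393",  "AK355927",     1560, 1580, 1571),
    c("miR393",  "AK374984",     1974, 1994, 1985),
    c("miR396",  "MLOC_64055.4", 375, 395,  386),
    c("miR396",  "AK250947.1",   480, 500,  491),
    c("miR396",  "AK353813",     387, 407,  398),
    c("miR396",  "AK376404",     417, 437,  428),
    c("miR396",  "MLOC_67201.4", 741, 761,  752),
    c("miR396",  "MLOC_80060.1", 507, 527,  518),
    c("miR396",  "MLOC_12347.1", 1438, 1458, 1449),
    c("miR396",  "AK375237",     184, 204,  195),
    c("miR444",  "MLOC_16182.1", 1035, 1055, 1046),
    c("miR5051", "MLOC_57965.3", 595, 615,  606),
    c("miR7757", "MLOC_17471.2", 194, 215,  206),
    c("miR9863", "MLOC_24045.1", 1259, 1280, 1271),
    c("novel-mir-119", "AK362090",     1362, 1382, 1373),
    c("novel-mir-119", "AK369226",     423, 443,  434),
    c("novel-mir-400", "MLOC_53497.2", 587, 609,  600),
    c("novel-mir-205", "MLOC_54213.1", 389, 410,  401))
  data.frame(mirna = rows[, 1L], transcript = rows[, 2L],
             start = as.integer(rows[, 3L]), end = as.integer(rows[, 4L]),
             cut = as.integer(rows[, 5L]), stringsAsFactors = FALSE)
}

# A designed clean hairpin: GC-rich perfect stem, 6-nt loop, short tails;
# the mature is stem positions 3..23 of the 5' arm.
designed_hairpin <- function(stem = "GCGCATGGCTAAGCTTGGCATGCGATCGGT",
                             loop = "AATTAA", tail = "ATATATATAT") {
  win <- paste0(tail, stem, loop, revcomp(stem), tail)
  m_start <- nchar(tail) + 3L
  list(sequence = win, mature_start = m_start, mature_end = m_start + 20L,
       mature = substr(win, m_start, m_start + 20L))
}

# Independent per-position duplex recount: position i of the miRNA
# against site position L - i + 1, classified pair by pair.
oracle_pair_states <- function(mirna, site) {
  L <- nchar(mirna)
  states <- character(L)
  for (i in seq_len(L)) {
    a <- substr(mirna, i, i)
    b <- substr(site, L - i + 1L, L - i + 1L)
    states[i] <- if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
                     (a == "G" && b == "C") || (a == "C" && b == "G")) "WC"
      else if ((a == "G" && b == "T") || (a == "T" && b == "G")) "GU"
      else "MM"
  }
  states
}

# Independent rule-by-rule verdict on a state vector (G-U treated as a
# pair for rules 2-4, 0.5 mismatch for rules 1 and 5).
oracle_rules <- function(states, energy_ratio,
                         max_mm = 4, max_5p = 2.5, min_ratio = 0.75) {
  w <- ifelse(states == "MM", 1, ifelse(states == "GU", 0.5, 0))
  mm <- states == "MM"
  L <- length(states)
  failed <- integer(0)
  if (sum(w) > max_mm) failed <- c(failed, 1L)
  run <- 0L; worst <- 0L
  for (i in seq_len(L)) {
    run <- if (mm[i]) run + 1L else 0L
    worst <- max(worst, run)
  }
  if (worst > 2L) failed <- c(failed, 2L)
  adj <- FALSE
  for (i in 2:11) if (mm[i] && mm[i + 1L]) adj <- TRUE
  if (adj) failed <- c(failed, 3L)
  if (mm[10L] || mm[11L]) failed <- c(failed, 4L)
  if (sum(w[1:12]) > max_5p) failed <- c(failed, 5L)
  if (energy_ratio < min_ratio) failed <- c(failed, 6L)
  failed
}

# Independent duplex energy: re-summation of negative stack terms over
# consecutive paired positions, straight off the embedded table.
oracle_duplex_energy <- function(mirna, site) {
  st <- mirseed:::STACK100
  states <- oracle_pair_states(mirna, site)
  L <- nchar(mirna)
  sc <- rev(strsplit(site, "", fixed = TRUE)[[1L]])
  mc <- strsplit(mirna, "", fixed = TRUE)[[1L]]
  e <- 0
  for (i in seq_len(L - 1L)) {
    if (states[i] != "MM" && states[i + 1L] != "MM") {
      t1 <- match(paste0(mc[i], sc[i]), rownames(st))
      t2 <- match(paste0(sc[i + 1L], mc[i + 1L]), rownames(st))
      v <- st[t1, t2]
      if (v < 0) e <- e + v
    }
  }
  e / 100
}

# Brute-force two-sided Audic-Claverie p-value by log-space summation of
# the posterior pmf (no distribution functions).
oracle_ac_p <- function(a, ta, b, tb) {
  tail_p <- function(x, y, t1, t2) {
    r <- t2 / t1
    lp <- function(yy) yy * log(r) + lchoose(x + yy, yy) -
      (x + yy + 1) * log(1 + r)
    lower <- sum(exp(lp(0:y)))
    # upper tail summed directly to convergence (avoids 1 - lower
    # cancellation)
    upper <- 0; yy <- y
    repeat {
      term <- exp(lp(yy))
      upper <- upper + term
      yy <- yy + 1
      if (term < upper * 1e-16 || term < 1e-300) break
    }
    min(lower, upper)
  }
  min(1, tail_p(a, b, ta, tb) + tail_p(b, a, tb, ta))
}

# alter one site base so that it does not pair (WC or wobble) its miRNA
# partner
break_pair <- function(site, mirna, mirna_pos) {
  L <- nchar(mirna)
  p <- L - mirna_pos + 1L
  a <- substr(mirna, mirna_pos, mirna_pos)
  substr(site, p, p) <- a  # X vs X never pairs in this alphabet
  site
}
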