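# Synthetic-data generators.  Every generator is a pure function of
# (parameters, seed): the RNG state is set locally and restored, so the
# same call is byte-reproducible and does not disturb the caller's RNG.
#
# The simulated cohort emulates the statistical structure of a cereal
# embryo small-RNA experiment: libraries dominated by 24-nt reads with a
# 21-nt secondary population, mature miRNAs residing on fold-back
# precursors planted in a random background genome, transcripts carrying
# binding sites that obey (or deliberately violate) the six duplex rules,
# and degradome tags peaked at the position opposite miRNA positions
# 10-11 (site end - 9).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# dinucleotide-preserving shuffle (Altschul-Erikson style, via random
# Eulerian walk approximated by repeated edge swaps on the dinucleotide
# sequence); defeats composition-only discrimination
dinucleotide_shuffle <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  if (n < 4L) return(x)
  for (it in seq_len(4L * n)) {
    # pick i < j with identical preceding characters and swap suffix edges
    i <- sample(2:(n - 1L), 1L)
    cand <- which(chars[seq(2L, n - 1L)] == chars[i]) + 1L
    cand <- cand[cand != i]
    if (length(cand) == 0L) next
    j <- if (length(cand) == 1L) cand else sample(cand, 1L)
    # swapping the successors of two identical states preserves
    # dinucleotide counts
    tmp <- chars[i + 1L]
    chars[i + 1L] <- chars[j + 1L]
    chars[j + 1L] <- tmp
  }
  paste(chars, collapse = "")
}

# build one hairpin: stem of `stem_len` bp with >= 80% WC pairs (the rest
# G.U wobbles), loop of 6-12 nt; the mature occupies arm positions 3..23
build_hairpin <- function(stem_len = NULL, wc_frac = 0.9) {
  if (is.null(stem_len)) stem_len <- sample(26:32, 1L)
  arm5 <- rand_seq(stem_len, gc = 0.55)
  arm3 <- revcomp(arm5)
  # convert some pairs to G.U wobbles (keep the mature span clean)
  n_wob <- max(0L, round((1 - wc_frac) * stem_len))
  a5 <- strsplit(arm5, "", fixed = TRUE)[[1L]]
  a3 <- strsplit(arm3, "", fixed = TRUE)[[1L]]
  wobblable <- which(a5 %in% c("G", "T"))
  wobblable <- setdiff(wobblable, 10:16)  # keep the duplex core paired
  if (length(wobblable) && n_wob > 0L) {
    for (i in sample(wobblable, min(n_wob, length(wobblable)))) {
      # partner of arm5 position i sits at arm3 position stem_len - i + 1
      a3[stem_len - i + 1L] <- if (a5[i] == "G") "T" else "G"
    }
  }
  loop <- rand_seq(sample(6:12, 1L), gc = 0.3)
  hairpin <- paste0(paste(a5, collapse = ""), loop, paste(a3, collapse = ""))
  arm <- sample(c("5p", "3p"), 1L)
  if (arm == "5p") {
    m_start <- 3L
  } else {
    # last 21 nt of the 3' arm, leaving 2 nt at the precursor 3' end
    m_start <- nchar(hairpin) - 23L
  }
  list(sequence = hairpin, mature_start = m_start,
       mature_end = m_start + 20L,
       mature = substr(hairpin, m_start, m_start + 20L), arm = arm)
}

#' Generate a synthetic genome with planted miRNA hairpins and decoys
#'
#' Hairpins are stem-loops (stem >= 25 bp, >= 80% Watson-Crick, loop
#' 6-12 nt) carrying a 21-nt mature on one arm, embedded at recorded loci
#' in an i.i.d.-uniform background. Decoys are dinucleotide-shuffled
#' copies of hairpin-like sequences: same composition, no planted
#' fold-back.
#'
#' @param n_hairpins,n_decoys numbers of planted hairpins and decoys.
#' @param seed RNG seed (mandatory; generators are pure in it).
#' @param spacing background nt between consecutive inserts (default 120).
#' @return list with `genome` (named character vector, one chromosome)
#'   and `truth` (list with data.frames `mirnas` and `decoys`).
#' @export
make_genome <- function(n_hairpins, n_decoys, seed, spacing = 120L) {
  with_seed(seed, {
    pieces <- character(0)
    pos <- 1L
    mirnas <- list(); decoys <- list()
    inserts <- c(rep("hairpin", n_hairpins), rep("decoy", n_decoys))
    if (length(inserts)) inserts <- sample(inserts)
    for (k in seq_along(inserts)) {
      bg <- rand_seq(spacing)
      pieces <- c(pieces, bg)
      pos <- pos + spacing
      hp <- build_hairpin()
      if (inserts[k] == "hairpin") {
        mirnas[[length(mirnas) + 1L]] <- data.frame(
          id = sprintf("planted-mir-%03d", length(mirnas) + 1L),
          chrom = "chr1", start = pos, end = pos + nchar(hp$sequence) - 1L,
          mature = hp$mature, arm = hp$arm,
          mature_start = pos + hp$mature_start - 1L,
          stringsAsFactors = FALSE)
        pieces <- c(pieces, hp$sequence)
        pos <- pos + nchar(hp$sequence)
      } else {
        shuf <- dinucleotide_shuffle(hp$sequence)
        decoys[[length(decoys) + 1L]] <- data.frame(
          id = sprintf("decoy-%03d", length(decoys) + 1L),
          chrom = "chr1", start = pos, end = pos + nchar(shuf) - 1L,
          tag = substr(shuf, hp$mature_start, hp$mature_end),
          stringsAsFactors = FALSE)
        pieces <- c(pieces, shuf)
        pos <- pos + nchar(shuf)
      }
    }
    pieces <- c(pieces, rand_seq(spacing))
    genome <- c(chr1 = paste(pieces, collapse = ""))
    truth <- list(
      mirnas = if (length(mirnas)) do.call(rbind, mirnas) else
        data.frame(id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   mature = character(0), arm = character(0),
                   mature_start = integer(0), stringsAsFactors = FALSE),
      decoys = if (length(decoys)) do.call(rbind, decoys) else
        data.frame(id = character(0), chrom = character(0),
                   start = integer(0), end = integer(0),
                   tag = character(0), stringsAsFactors = FALSE),
      seed = seed)
    list(genome = genome, truth = truth)
  })
}

#' Simulate a small-RNA library
#'
#' Draws `depth` background reads multinomially over `length_mix`
#' (substrings of the genome when supplied, i.i.d. random otherwise) and
#' adds `mirna_reads` copies of every planted mature (set 0 to omit
#' planted signal). Collapsed to tag records.
#'
#' @param truth truth list from [make_genome()] (may have zero miRNAs).
#' @param depth number of background reads, `>= 1`.
#' @param length_mix named numeric vector: probability per read length,
#'   lengths within 18-30. Default `c("24" = .7, "21" = .2, "22" = .1)`,
#'   the 24-nt-dominant / 21-nt-secondary structure of cereal embryo
#'   libraries.
#' @param seed RNG seed.
#' @param mirna_reads read count planted per mature miRNA (default 50).
#' @param genome optional named character vector; background reads are
#'   sampled from it when given.
#' @param library_id library label.
#' @return list of [tag_record].
#' @export
make_srna_library <- function(truth, depth,
                              length_mix = c("24" = 0.7, "21" = 0.2,
                                             "22" = 0.1),
                              seed = 1L, mirna_reads = 50L, genome = NULL,
                              library_id = "lib1") {
  stopifnot(depth >= 1)
  lens <- as.integer(names(length_mix))
  stopifnot(all(lens >= 18L), all(lens <= 30L))
  with_seed(seed, {
    n_per_len <- as.vector(stats::rmultinom(1L, depth,
                                            length_mix / sum(length_mix)))
    seqs <- character(0); counts <- numeric(0)
    for (i in seq_along(lens)) {
      if (n_per_len[i] == 0L) next
      reads <- if (is.null(genome)) {
        vapply(seq_len(n_per_len[i]), function(j) rand_seq(lens[i]),
               character(1L))
      } else {
        chrom <- genome[[1L]]
        starts <- sample(nchar(chrom) - lens[i], n_per_len[i],
                         replace = TRUE)
        substring(chrom, starts, starts + lens[i] - 1L)
      }
      agg <- table(reads)
      seqs <- c(seqs, names(agg)); counts <- c(counts, as.numeric(agg))
    }
    if (mirna_reads > 0L && nrow(truth$mirnas)) {
      seqs <- c(seqs, truth$mirnas$mature)
      counts <- c(counts, rep(mirna_reads, nrow(truth$mirnas)))
    }
    agg <- tapply(counts, seqs, sum)
    agg <- agg[order(names(agg))]
    lapply(seq_along(agg), function(i) {
      tag_record(names(agg)[i],
                 stats::setNames(unname(agg[i]), library_id))
    })
  })
}

# mutate one transcript position so it neither Watson-Crick- nor
# wobble-pairs the given miRNA base
non_pairing_base <- function(mirna_base) {
  switch(mirna_base,
         A = "A",   # A pairs only T
         C = "C",   # C pairs only G
         G = "G",   # G pairs C and T; G vs G is a mismatch
         T = "T")   # T pairs A and G
}

#' Plant miRNA target sites in transcripts and simulate a degradome
#'
#' Builds `transcripts_n` random transcripts, plants one binding site per
#' transcript for the planted miRNAs (cycled), alternating rule-compliant
#' sites (perfect or near-perfect complements) and rule-violating sites
#' (a recorded violation of one of the six rules), then simulates a
#' degradome library: `signal_reads` 5' tags starting exactly at each
#' planted cut (`site end - 9`) plus Poisson(`noise_rate`) background
#' tags per transcript position.
#'
#' @param truth truth list from [make_genome()]; must contain at least one
#'   planted miRNA.
#' @param transcripts_n number of transcripts (= number of planted sites).
#' @param signal_reads degradome tag count at each planted cut.
#' @param noise_rate Poisson rate of background tags per position.
#' @param seed RNG seed.
#' @param tx_len transcript length (default 1200 nt).
#' @param violating_fraction fraction of sites planted as rule violators
#'   (default 0.5).
#' @return list with `transcripts` (named character vector), `degradome`
#'   (data.frame `sequence`, `count`) and `sites` (data.frame:
#'   `mirna_id`, `mirna`, `transcript_id`, `start`, `end`, `cut`,
#'   `class`, `violated_rule`).
#' @export
make_targets_and_degradome <- function(truth, transcripts_n, signal_reads,
                                       noise_rate, seed, tx_len = 1200L,
                                       violating_fraction = 0.5) {
  stopifnot(signal_reads >= 0, nrow(truth$mirnas) >= 1L)
  with_seed(seed, {
    mirnas <- truth$mirnas
    txs <- character(transcripts_n)
    names(txs) <- sprintf("tx%03d", seq_len(transcripts_n))
    site_rows <- vector("list", transcripts_n)
    n_viol <- round(violating_fraction * transcripts_n)
    classes <- sample(c(rep("violating", n_viol),
                        rep("compliant", transcripts_n - n_viol)))
    deg_seqs <- character(0); deg_counts <- numeric(0)
    for (t in seq_len(transcripts_n)) {
      mi <- ((t - 1L) %% nrow(mirnas)) + 1L
      mirna <- mirnas$mature[mi]
      L <- nchar(mirna)
      tx <- rand_seq(tx_len)
      start <- sample(seq(30L, tx_len - L - 30L), 1L)
      site <- revcomp(mirna)
      violated <- NA_integer_
      if (classes[t] == "compliant") {
        # optionally one benign mismatch at miRNA position 15-19
        if (stats::runif(1) < 0.5) {
          p_mir <- sample(15:19, 1L)
          p_site <- L - p_mir + 1L
          substr(site, p_site, p_site) <-
            non_pairing_base(substr(mirna, p_mir, p_mir))
        }
      } else {
        violated <- sample(c(1L, 2L, 4L), 1L)
        if (violated == 4L) {
          # mismatch at a slicing position (10 or 11)
          p_mir <- sample(10:11, 1L)
          p_site <- L - p_mir + 1L
          substr(site, p_site, p_site) <-
            non_pairing_base(substr(mirna, p_mir, p_mir))
        } else if (violated == 2L) {
          # three adjacent mismatches at miRNA positions 14-16
          for (p_mir in 14:16) {
            p_site <- L - p_mir + 1L
            substr(site, p_site, p_site) <-
              non_pairing_base(substr(mirna, p_mir, p_mir))
          }
        } else {
          # five scattered mismatches (rule 1), none adjacent, away from
          # positions 10-11
          for (p_mir in c(3L, 5L, 7L, 15L, 18L)) {
            p_site <- L - p_mir + 1L
            substr(site, p_site, p_site) <-
              non_pairing_base(substr(mirna, p_mir, p_mir))
          }
        }
      }
      substr(tx, start, start + L - 1L) <- site
      txs[t] <- tx
      cut <- start + L - 1L - 9L
      site_rows[[t]] <- data.frame(
        mirna_id = mirnas$id[mi], mirna = mirna,
        transcript_id = names(txs)[t], start = start,
        end = start + L - 1L, cut = cut, class = classes[t],
        violated_rule = violated, stringsAsFactors = FALSE)
      if (signal_reads > 0L) {
        deg_seqs <- c(deg_seqs, substr(tx, cut, min(cut + 19L, tx_len)))
        deg_counts <- c(deg_counts, signal_reads)
      }
      if (noise_rate > 0) {
        n_noise <- stats::rpois(tx_len - 19L, noise_rate)
        at <- which(n_noise > 0L)
        if (length(at)) {
          deg_seqs <- c(deg_seqs, substring(tx, at, at + 19L))
          deg_counts <- c(deg_counts, n_noise[at])
        }
      }
    }
    deg <- if (length(deg_seqs)) {
      agg <- tapply(deg_counts, deg_seqs, sum)
      data.frame(sequence = names(agg), count = unname(agg),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sequence = character(0), count = numeric(0),
                 stringsAsFactors = FALSE)
    }
    list(transcripts = txs, degradome = deg[order(deg$sequence), ,
                                            drop = FALSE],
         sites = do.call(rbind, site_rows))
  })
}

#' Write a full synthetic cohort to a directory
#'
#' Generates genome, small-RNA library, transcripts and degradome with
#' [make_genome()], [make_srna_library()] and
#' [make_targets_and_degradome()] and writes `genome.fa`, `srna.fa`
#' (collapsed), `transcripts.fa`, `degradome.tsv` and `truth.json`.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed driving every generator.
#' @param n_hairpins,n_decoys,depth,signal_reads,noise_rate,transcripts_n
#'   cohort parameters; defaults are the package's standard benchmark
#'   (50 planted hairpins, 50 decoys, 40 planted sites half of which are
#'   deliberate rule violators, 50-read cleavage signal over
#'   Poisson(0.1) noise).
#' @return invisibly, the truth list (with `sites` attached).
#' @export
simulate_cohort <- function(dir, seed, n_hairpins = 50L, n_decoys = 50L,
                            depth = 10000L, transcripts_n = 40L,
                            signal_reads = 50L, noise_rate = 0.1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- make_genome(n_hairpins, n_decoys, seed = seed)
  tags <- make_srna_library(gen$truth, depth = depth, seed = seed + 1L,
                            genome = gen$genome)
  td <- make_targets_and_degradome(gen$truth, transcripts_n = transcripts_n,
                                   signal_reads = signal_reads,
                                   noise_rate = noise_rate,
                                   seed = seed + 2L)
  write_fasta(gen$genome, file.path(dir, "genome.fa"), width = 70L)
  write_collapsed_fasta(tags, file.path(dir, "srna.fa"))
  write_fasta(td$transcripts, file.path(dir, "transcripts.fa"), width = 70L)
  utils::write.table(td$degradome, file.path(dir, "degradome.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  truth <- gen$truth
  truth$sites <- td$sites
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(truth)
}
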