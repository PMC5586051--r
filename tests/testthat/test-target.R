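MIR396 <- "TTCCACAGCTTTCTTGAACTG"  # a 21-nt plant miRNA-like sequence

test_that("pair states classify the antiparallel duplex position by position", {
  m <- "TGACAGAAGAGAGTGAGCAC"
  d <- pair_states(m, revcomp(m))
  expect_true(all(d$states == "WC"))
  expect_equal(d$mismatch_total, 0)

  # one G.U wobble (miRNA G opposite site T) at miRNA position 6
  site <- revcomp(m)
  L <- nchar(m)
  stopifnot(substr(m, 6, 6) == "G")
  substr(site, L - 5, L - 5) <- "T"
  d <- pair_states(m, site)
  expect_identical(d$states[6], "GU")
  expect_equal(d$mismatch_total, 0.5)

  expect_error(pair_states(m, "ACGT"), "equal lengths")
})

test_that("pair-state totals equal an independent recount on random duplexes", {
  set.seed(71)
  for (rep in 1:50) {
    m <- rand_dna(21); s <- rand_dna(21)
    d <- pair_states(m, s)
    states <- oracle_pair_states(m, s)
    expect_identical(d$states, states)
    w <- ifelse(states == "MM", 1, ifelse(states == "GU", 0.5, 0))
    expect_equal(d$mismatch_total, sum(w))
    expect_equal(d$mismatch_5p_1_12, sum(w[1:12]))
  }
})

test_that("duplex energy equals re-summation over the stack table and is monotone", {
  expect_equal(duplex_energy(pair_states("AAAA", "AAAA")), 0)

  m <- MIR396
  d0 <- score_duplex(pair_states(m, revcomp(m)))
  expect_equal(d0$energy_ratio, 1.0)
  expect_lt(d0$energy, 0)

  set.seed(73)
  for (rep in 1:100) {
    mm <- rand_dna(21); ss <- rand_dna(21)
    expect_equal(duplex_energy(pair_states(mm, ss)),
                 oracle_duplex_energy(mm, ss))
  }

  # breaking any pair never strengthens the duplex
  site <- revcomp(m)
  for (pos in seq_len(nchar(m))) {
    weaker <- duplex_energy(pair_states(m, break_pair(site, m, pos)))
    expect_gte(weaker, d0$energy)
  }
})

test_that("six-rule verdicts match an independent oracle over all 1- and 2-mismatch variants", {
  m <- MIR396
  L <- nchar(m)
  perfect <- revcomp(m)
  check <- function(site) {
    d <- score_duplex(pair_states(m, site))
    v <- apply_rules(d)
    expected <- oracle_rules(oracle_pair_states(m, site), d$energy_ratio)
    expect_identical(sort(v$failed_rules), sort(expected))
    expect_identical(v$pass, length(expected) == 0L)
  }
  v0 <- apply_rules(score_duplex(pair_states(m, perfect)))
  expect_true(v0$pass)
  expect_length(v0$failed_rules, 0L)

  for (i in seq_len(L)) check(break_pair(perfect, m, i))
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      check(break_pair(break_pair(perfect, m, i), m, j))
    }
  }
})

test_that("a mismatch at a slicing position fails rule 4", {
  m <- MIR396
  site <- break_pair(revcomp(m), m, 10)
  v <- apply_rules(score_duplex(pair_states(m, site)))
  expect_false(v$pass)
  expect_true(4L %in% v$failed_rules)
})

test_that("G.U wobbles can be counted as mismatches for the positional rules", {
  m <- MIR396
  stopifnot(substr(m, 10, 10) == "T")  # T opposite G is a wobble
  site <- revcomp(m)
  substr(site, nchar(m) - 9, nchar(m) - 9) <- "G"
  d <- score_duplex(pair_states(m, site))
  expect_identical(d$states[10], "GU")
  lenient <- apply_rules(d)
  strict <- apply_rules(d, gu_is_mismatch = TRUE)
  expect_false(4L %in% lenient$failed_rules)
  expect_true(4L %in% strict$failed_rules)
})

test_that("transcript scanning finds planted sites with the printed cut geometry", {
  set.seed(79)
  m <- MIR396
  tx <- paste0(rand_dna(838), revcomp(m), rand_dna(200))
  s <- scan_transcript(m, tx)
  expect_true(any(s$start == 839 & s$end == 858 + 1))  # 21-mer: end 859
  # exact published geometry with a 21-nt site at 839-859 is end - 9
  expect_true(all(s$expected_cut == s$end - 9))
})

test_that("scanning equals brute-force window evaluation on random sequence", {
  set.seed(83)
  m <- rand_dna(21)
  tx <- paste0(rand_dna(400), revcomp(m), rand_dna(400),
               break_pair(revcomp(m), m, 15), rand_dna(400))
  got <- scan_transcript(m, tx)
  L <- nchar(m)
  brute <- integer(0)
  for (st in seq_len(nchar(tx) - L + 1)) {
    d <- score_duplex(pair_states(m, substr(tx, st, st + L - 1)))
    failed <- oracle_rules(oracle_pair_states(m, substr(tx, st, st + L - 1)),
                           d$energy_ratio)
    if (length(failed) == 0L) brute <- c(brute, st)
  }
  expect_setequal(got$start, brute)
  expect_gte(length(brute), 2L)  # both planted sites found by the oracle
})

test_that("site sort order is (mismatch total, energy ratio, start)", {
  set.seed(89)
  m <- MIR396
  tx <- paste0(rand_dna(100), break_pair(revcomp(m), m, 15),
               rand_dna(100), revcomp(m), rand_dna(100))
  s <- scan_transcript(m, tx)
  expect_gte(nrow(s), 2L)
  expect_true(!is.unsorted(s$mismatch_total))
  expect_equal(s$start[1], 222)  # perfect site ranks first
})

test_that("scanning is stranded: the reverse-complemented transcript has no sites", {
  set.seed(97)
  m <- MIR396
  tx <- paste0(rand_dna(300), revcomp(m), rand_dna(300))
  expect_gte(nrow(scan_transcript(m, tx)), 1L)
  expect_equal(nrow(scan_transcript(m, revcomp(tx))), 0L)
})

test_that("every published binding-site row reproduces its cut coordinate", {
  fx <- cleavage_fixture()
  expect_true(all(fx$cut == fx$end - 9L))
  set.seed(101)
  # plant a handful of rows as real scans, spanning both tables
  for (i in c(1L, 26L, 40L)) {
    L <- fx$end[i] - fx$start[i] + 1L
    m <- rand_dna(L)
    tx <- paste0(rand_dna(fx$start[i] - 1L), revcomp(m), rand_dna(30))
    s <- scan_transcript(m, tx, transcript_id = fx$transcript[i],
                         mirna_id = fx$mirna[i])
    hit <- s[s$start == fx$start[i], ]
    expect_equal(nrow(hit), 1L)
    expect_equal(hit$end, fx$end[i])
    expect_equal(hit$expected_cut, fx$cut[i])
  }
})

test_that("degrading any paired position never flips a failing duplex to passing", {
  set.seed(103)
  m <- MIR396
  site <- break_pair(revcomp(m), m, 10)  # already failing (rule 4)
  for (pos in sample(setdiff(1:21, 10), 8)) {
    worse <- break_pair(site, m, pos)
    v <- apply_rules(score_duplex(pair_states(m, worse)))
    expect_false(v$pass)
  }
})
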