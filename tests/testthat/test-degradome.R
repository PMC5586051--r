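test_that("5' tags map by exact sense-strand prefix matching", {
  set.seed(111)
  tx <- c(t1 = rand_dna(1000))
  tag <- substr(tx[["t1"]], 849, 868)
  while (length(gregexpr(tag, tx[["t1"]], fixed = TRUE)[[1]]) > 1) {
    tx <- c(t1 = rand_dna(1000)); tag <- substr(tx[["t1"]], 849, 868)
  }
  tags <- data.frame(sequence = tag, count = 7)
  prof <- map_tags(tags, tx)
  expect_equal(as.numeric(prof$t1[849]), 7)
  expect_equal(attr(prof$t1, "total"), 7)

  # one mismatch anywhere: contributes nowhere
  mut <- tag
  substr(mut, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 10, 10))[1]
  prof2 <- map_tags(data.frame(sequence = mut, count = 5), tx)
  expect_equal(attr(prof2$t1, "total"), 0)

  # antisense tags do not map
  prof3 <- map_tags(data.frame(sequence = revcomp(tag), count = 5), tx)
  expect_equal(attr(prof3$t1, "total"), 0)
})

test_that("tag mass is conserved over multi-mapping and matches a brute-force recount", {
  set.seed(113)
  txs <- c(t1 = rand_dna(600), t2 = rand_dna(600))
  tags <- data.frame(
    sequence = c(vapply(1:30, function(i) {
      id <- sample(names(txs), 1); s <- sample(580, 1)
      substr(txs[[id]], s, s + 19)
    }, character(1)), replicate(10, rand_dna(20))),
    count = sample(1:20, 40, replace = TRUE))
  profs <- map_tags(tags, txs)
  # brute-force recount of every profile entry
  for (id in names(txs)) {
    brute <- numeric(nchar(txs[[id]]))
    for (i in seq_len(nrow(tags))) {
      m <- gregexpr(tags$sequence[i], txs[[id]], fixed = TRUE)[[1]]
      if (m[1] != -1) brute[as.integer(m)] <- brute[as.integer(m)] +
          tags$count[i]
    }
    expect_equal(as.numeric(profs[[id]]), brute)
  }
  n_loci <- vapply(seq_len(nrow(tags)), function(i) {
    sum(vapply(txs, function(tx) {
      m <- gregexpr(tags$sequence[i], tx, fixed = TRUE)[[1]]
      if (m[1] == -1) 0L else length(m)
    }, integer(1)))
  }, integer(1))
  expect_equal(sum(vapply(profs, function(p) attr(p, "total"), numeric(1))),
               sum(tags$count * n_loci))
})

test_that("sites validate on an on-site peak and carry abundance categories", {
  prof <- structure(c(rep(0, 848), 50, rep(0, 151)), total = 50,
                    class = "degradome_profile")
  v <- validate_site(list(expected_cut = 849), prof)
  expect_true(v$validated)
  expect_equal(v$peak$category, 0L)
  expect_equal(v$peak$position, 849)

  # all-zero profile: nothing to validate
  empty <- structure(numeric(1000), total = 0, class = "degradome_profile")
  expect_false(validate_site(list(expected_cut = 849), empty)$validated)

  # tied transcript-wide maximum: category 1
  prof2 <- prof; prof2[100] <- 50
  v2 <- validate_site(list(expected_cut = 849), prof2)
  expect_equal(v2$peak$category, 1L)

  # single-read peak: category 4, below the default read gate
  prof4 <- structure(c(rep(0, 848), 1, rep(0, 151), 5), total = 6,
                     class = "degradome_profile")
  v4 <- validate_site(list(expected_cut = 849), prof4)
  expect_false(v4$validated)
  expect_equal(v4$peak$category, 4L)

  # the window absorbs a 1-nt offset, ties resolve toward the expected cut
  prof5 <- prof; prof5[849] <- 0; prof5[850] <- 50
  v5 <- validate_site(list(expected_cut = 849), prof5)
  expect_true(v5$validated)
  expect_equal(v5$peak$position, 850)
})

test_that("category improves (never worsens) as the on-site count grows", {
  base <- c(rep(0, 500), 30, rep(0:1, 100), rep(0, 299))
  cats <- vapply(c(1, 2, 5, 29, 30, 40), function(cnt) {
    prof <- structure(replace(base, 400, cnt), total = sum(base) + cnt,
                      class = "degradome_profile")
    validate_site(list(expected_cut = 400), prof)$peak$category
  }, integer(1))
  expect_true(all(diff(cats) <= 0))
})

test_that("random-noise profiles rarely validate at high-confidence categories", {
  set.seed(117)
  n_validated <- 0L
  for (rep in 1:200) {
    counts <- stats::rpois(800, 0.1)
    prof <- structure(counts, total = sum(counts),
                      class = "degradome_profile")
    v <- validate_site(list(expected_cut = 400), prof)
    if (v$validated && v$peak$category <= 1L) n_validated <- n_validated + 1L
  }
  expect_lte(n_validated / 200, 0.05)
})

test_that("validated-pair reports keep only degradome-supported sites and list bigger off-site peaks", {
  set.seed(119)
  m <- "TTCCACAGCTTTCTTGAACTG"
  tx <- c(AK370348 = paste0(rand_dna(1008), revcomp(m), rand_dna(200)))
  sites <- scan_transcript(m, tx[[1]], transcript_id = "AK370348",
                           mirna_id = "miR159")
  stopifnot(any(sites$start == 1009))
  cut <- 1009 + nchar(m) - 1 - 9  # 21-nt site from 1009: cut at 1019
  deg <- data.frame(
    sequence = c(substr(tx[[1]], cut, cut + 19),
                 substr(tx[[1]], 948, 967)),
    count = c(30, 80))
  profs <- map_tags(deg, tx)
  rep1 <- report_validated_pairs(sites, profs)
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$peak_position, cut)
  expect_true("948" %in% strsplit(rep1$other_peaks, ",")[[1]])

  # no degradome support anywhere near the site: no row
  rep0 <- report_validated_pairs(sites,
                                 map_tags(deg[2, , drop = FALSE], tx))
  expect_equal(nrow(rep0), 0L)
})

test_that("sites that fail the duplex rules never reach the degradome report", {
  set.seed(121)
  m <- "TTCCACAGCTTTCTTGAACTG"
  bad_site <- break_pair(revcomp(m), m, 10)  # rule-4 violation
  tx <- c(t1 = paste0(rand_dna(500), bad_site, rand_dna(200)))
  sites <- scan_transcript(m, tx[[1]], transcript_id = "t1")
  expect_false(any(sites$start == 501))
  cut <- 501 + nchar(m) - 1 - 9
  deg <- data.frame(sequence = substr(tx[[1]], cut, cut + 19), count = 100)
  rep <- report_validated_pairs(sites, map_tags(deg, tx))
  expect_false(any(rep$start == 501))
})
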