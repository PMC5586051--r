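test_that("FASTA reading normalises U to T and handles edge cases", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "ACGU"), f)
  expect_identical(read_fasta(f), c(a = "ACGT"))

  writeLines(character(0), f)
  expect_length(read_fasta(f), 0L)

  writeLines(c("ACGT", ">a", "ACGT"), f)
  expect_error(read_fasta(f), "line 1")

  writeLines(c(">a", "ACGT", ">a", "TTTT"), f)
  expect_warning(res <- read_fasta(f), "duplicate")
  expect_identical(names(res), c("a", "a.1"))
})

test_that("FASTA round-trips a large synthetic file and agrees with an independent reader", {
  set.seed(101)
  seqs <- stats::setNames(
    vapply(1:1000, function(i) rand_dna(sample(18:200, 1)), character(1)),
    sprintf("seq%04d", 1:1000))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(seqs, f1)
  back <- read_fasta(f1)
  expect_identical(back, seqs)
  write_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  skip_if_not_installed("Biostrings")
  ext <- Biostrings::readDNAStringSet(f1)
  expect_identical(as.character(ext), seqs)
})

test_that("collapsed FASTA parses counts, merges duplicates, and round-trips", {
  f <- withr::local_tempfile()
  writeLines(c(">t1_x5", "ACGTACGTACGTACGTAC"), f)
  tags <- read_collapsed_fasta(f)
  expect_length(tags, 1L)
  expect_equal(sum(tags[[1]]$counts), 5)

  writeLines(c(">t1_x2", "ACGTACGTACGTACGTAC",
               ">t2_x3", "ACGTACGTACGTACGTAC"), f)
  tags <- read_collapsed_fasta(f)
  expect_length(tags, 1L)
  expect_equal(sum(tags[[1]]$counts), 5)

  writeLines(c(">t1", "ACGT"), f)
  expect_error(read_collapsed_fasta(f), "_x<count>")

  # round trip of a random multiset; order-independence of collapsing
  set.seed(7)
  seqs <- replicate(500, rand_dna(sample(18:24, 1)))
  counts <- sample(1:50, 500, replace = TRUE)
  writeLines(as.vector(rbind(sprintf(">r%d_x%d", 1:500, counts), seqs)), f)
  tags <- read_collapsed_fasta(f)
  truth <- c(tapply(counts, seqs, sum))
  got <- stats::setNames(vapply(tags, function(t) sum(t$counts), numeric(1)),
                         vapply(tags, function(t) t$sequence, character(1)))
  expect_equal(got[sort(names(truth))], truth[sort(names(truth))])
  f2 <- withr::local_tempfile()
  write_collapsed_fasta(tags, f2)
  tags2 <- read_collapsed_fasta(f2)
  expect_equal(lapply(tags2, function(t) t[c("sequence", "counts")]),
               lapply(tags, function(t) t[c("sequence", "counts")]))
})

test_that("tag records enforce their invariants", {
  expect_error(tag_record("ACGU", c(lib1 = 0)), "total count")
  expect_error(tag_record("ACXT", c(lib1 = 2)), "invalid nucleotide")
  expect_error(tag_record("ACGT", c(2)), "named")
  t <- tag_record("acgu", c(lib1 = 2, lib2 = 1))
  expect_identical(t$sequence, "ACGT")
  expect_equal(sum(t$counts), 3)
})

test_that("site reports are deterministic and carry printed coordinates", {
  site <- data.frame(mirna_id = "miR156", transcript_id = "AK356077",
                     start = 839L, end = 858L, expected_cut = 849L,
                     mismatch_total = 0, mismatch_5p_1_12 = 0,
                     energy = -40, energy_ratio = 1)
  f <- withr::local_tempfile()
  write_site_report(site, f)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_identical(strsplit(lines[2], "\t")[[1]][3:5],
                   c("839", "858", "849"))

  write_site_report(site[0, ], f)
  expect_length(readLines(f), 1L)  # header only

  set.seed(3)
  many <- do.call(rbind, lapply(1:50, function(i) {
    s <- sample(1000, 1)
    data.frame(mirna_id = sprintf("m%02d", sample(9, 1)),
               transcript_id = sprintf("tx%02d", sample(9, 1)),
               start = s, end = s + 20L, expected_cut = s + 11L,
               mismatch_total = 0, mismatch_5p_1_12 = 0,
               energy = -30, energy_ratio = 1)
  }))
  f2 <- withr::local_tempfile()
  write_site_report(many, f)
  write_site_report(many[sample(nrow(many)), ], f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("count tables round-trip with library totals intact", {
  tags <- list(tag_record("ACGTACGTACGTACGTAC", c(a = 3, b = 1)),
               tag_record("TTTTACGTACGTACGTAC", c(a = 1, b = 7)))
  m <- count_matrix(tags, library_totals = c(a = 100, b = 200))
  f <- withr::local_tempfile()
  write_count_table(m, f)
  back <- read_count_table(f)
  expect_equal(unclass(back)[rownames(m), ], unclass(m)[, ])
  expect_equal(attr(back, "library_totals"), c(a = 100, b = 200))
  expect_error(count_matrix(tags, library_totals = c(a = 1, b = 1)),
               "column sums")
})

test_that("degradome tags load from both FASTA and TSV forms", {
  f <- withr::local_tempfile()
  writeLines(c(">d1_x7", "ACGTACGTACGTACGTACGT"), f)
  d1 <- read_degradome_tags(f)
  writeLines("ACGTACGTACGTACGTACGT\t7", f)
  d2 <- read_degradome_tags(f)
  expect_equal(d1$sequence, d2$sequence)
  expect_equal(d1$count, d2$count)
})
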