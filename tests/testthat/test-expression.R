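test_that("TPM follows its definition and conserves to one million", {
  expect_equal(tpm(5, 1e6), 5)
  expect_equal(tpm(0, 1e6), 0)
  expect_error(tpm(1, 0), "library_total")
  set.seed(131)
  counts <- rpois(200, 40) + 1L
  expect_equal(sum(tpm(counts, sum(counts))), 1e6)
})

test_that("log2 fold change uses the floor only for vanishing values", {
  expect_equal(log2_fold_change(8, 2), 2)
  expect_equal(log2_fold_change(3.7, 3.7), 0)
  expect_equal(log2_fold_change(0, 100), log2(0.01 / 100))
  expect_equal(log2_fold_change(0, 100), -13.28771, tolerance = 1e-5)
})

test_that("tag-count tests are symmetric and give p = 1 for identical evidence", {
  expect_equal(de_test(5, 1e6, 5, 1e6), 1.0)
  expect_equal(de_test(0, 1e6, 0, 1e6), 1.0)
  expect_equal(de_test(0, 5e5, 0, 1e6, method = "fisher"), 1.0)
  set.seed(137)
  for (rep in 1:20) {
    a <- rpois(1, 30); b <- rpois(1, 60)
    ta <- 1e6; tb <- 2e6
    for (meth in c("audic_claverie", "fisher")) {
      expect_equal(de_test(a, ta, b, tb, method = meth),
                   de_test(b, tb, a, ta, method = meth), tolerance = 1e-12)
    }
  }
})

test_that("Audic-Claverie p-values equal brute-force tail summation", {
  set.seed(139)
  for (rep in 1:50) {
    a <- rpois(1, sample(c(3, 30, 300), 1))
    b <- rpois(1, sample(c(3, 30, 300), 1))
    ta <- sample(c(5e5, 1e6, 2e6), 1)
    tb <- sample(c(5e5, 1e6, 2e6), 1)
    expect_equal(de_test(a, ta, b, tb), oracle_ac_p(a, ta, b, tb),
                 tolerance = 1e-8)
  }
})

test_that("differential-expression calls require both the fold and p gates", {
  set.seed(149)
  cnt <- rbind(c(100, 100),   # identical: not significant
               c(20, 160),    # strong change: significant
               c(2, 16))      # 8-fold but underpowered: p too large
  rownames(cnt) <- c("same", "strong", "weak")
  colnames(cnt) <- c("A", "B")
  m <- structure(cnt, library_totals = c(A = 1e6, B = 1e6),
                 class = c("count_matrix", class(cnt)))
  de <- call_de(m, c("A", "B"))
  expect_false(de$significant[de$feature == "same"])
  expect_true(de$significant[de$feature == "strong"])
  expect_false(de$significant[de$feature == "weak"])
  expect_gte(abs(de$log2fc[de$feature == "weak"]), 1)  # fails only on p
  # significance is exactly the conjunction of the two gates
  expect_equal(de$significant,
               abs(de$log2fc) >= 1 & de$p_value < 1e-5)
})

test_that("type-I error under the null stays within twice nominal", {
  set.seed(151)
  n <- 2000
  a <- rpois(n, 50); b <- rpois(n, 50)
  p <- mapply(function(x, y) de_test(x, 1e6, y, 1e6), a, b)
  expect_lte(mean(p < 1e-3), 2e-3)
})

test_that("planted 8-fold features are detected with high power", {
  set.seed(157)
  cnt <- rbind(cbind(rpois(20, 100), rpois(20, 800)),
               cbind(rpois(180, 150), rpois(180, 150)))
  rownames(cnt) <- sprintf("f%03d", 1:200)
  colnames(cnt) <- c("A", "B")
  m <- structure(cnt, library_totals = c(A = 1e6, B = 1e6),
                 class = c("count_matrix", class(cnt)))
  de <- call_de(m, c("A", "B"))
  expect_gte(sum(de$significant[1:20]), 18)
  expect_lte(sum(de$significant[21:200]), 2)
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  genes <- sprintf("g%02d", 1:20)
  tt <- lapply(stats::setNames(genes, genes), function(g) {
    c(if (g %in% genes[1:5]) "GO:A", "GO:ALL")
  })

  res <- hypergeom_enrich(genes[1:5], genes, tt)
  expect_equal(res$p_value[res$term == "GO:A"], 1 / choose(20, 5))
  expect_equal(res$p_value[res$term == "GO:ALL"], 1.0)
  expect_error(hypergeom_enrich("zz", genes, tt), "subset")

  # exhaustive enumeration on a toy background of 9 genes
  bg <- sprintf("t%d", 1:9)
  term_genes <- bg[c(1, 3, 5, 7)]
  tt2 <- lapply(stats::setNames(bg, bg),
                function(g) if (g %in% term_genes) "T1" else character(0))
  n_study <- 4
  combos <- utils::combn(bg, n_study)
  for (k_obs in 0:4) {
    enum <- mean(apply(combos, 2, function(st)
      sum(st %in% term_genes) >= k_obs))
    study <- c(term_genes[seq_len(k_obs)],
               setdiff(bg, term_genes)[seq_len(n_study - k_obs)])
    res <- hypergeom_enrich(study, bg, tt2)
    expect_equal(res$p_value[res$term == "T1"], enum, tolerance = 1e-12)
  }
})

test_that("null study sets produce uniform enrichment p-values", {
  set.seed(163)
  bg <- sprintf("g%03d", 1:100)
  tt <- lapply(stats::setNames(bg, bg),
               function(g) if (g %in% bg[1:20]) "T1" else character(0))
  hits <- 0L; n_draws <- 2000L
  for (i in seq_len(n_draws)) {
    study <- sample(bg, 15)
    res <- hypergeom_enrich(study, bg, tt)
    p <- res$p_value[res$term == "T1"]
    if (length(p) && p < 0.05) hits <- hits + 1L
  }
  # discrete test: the attainable size at the 0.05 threshold is 0.046
  expect_lte(hits / n_draws, 0.07)
  expect_gte(hits / n_draws, 0.03)
})

test_that("delta-delta-Ct reproduces calibrator-relative folds", {
  expect_equal(ddct_relative(20, 15, 20, 15), 1.0)
  expect_equal(ddct_relative(19, 15, 20, 15), 2.0)  # ddCt = -1
  expect_equal(ddct_relative(22, 18, 25, 18), 8.0)  # quartet: 2^-(4-7)
  expect_error(ddct_relative(NA, 1, 1, 1), "finite")
})
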