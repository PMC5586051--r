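# Expression quantification, differential expression, term enrichment and
# delta-delta-Ct relative quantification.

#' Tags per million
#'
#' `TPM = count / library_total * 1e6`, the tag-count normalisation used
#' for sequencing-based miRNA expression ("transcript per million" in the
#' small-RNA literature). Summed over all features of a library whose
#' total equals the column sum, TPM adds up to exactly 1e6.
#'
#' @param count feature read count(s), `>= 0`.
#' @param library_total total clean reads of the library, `> 0`.
#' @return TPM value(s).
#' @export
tpm <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library_total must be > 0")
  stopifnot(all(count >= 0))
  count / library_total * 1e6
}

#' Log2 fold change between two TPM values
#'
#' `log2(treatment / control)` with both values floored at `floor`
#' (default 0.01 TPM) so zero counts give a finite fold change. The floor
#' affects only fold changes, never the significance test.
#'
#' @param tpm_treat,tpm_control TPM values, `>= 0`.
#' @param floor lower bound substituted for small/zero values.
#' @return log2 fold change.
#' @export
log2_fold_change <- function(tpm_treat, tpm_control, floor = 0.01) {
  log2(pmax(tpm_treat, floor) / pmax(tpm_control, floor))
}

# log P(Y = y | x) of the Audic-Claverie posterior for library-size ratio
# r = total_b / total_a: the negative binomial NB(size = x + 1,
# prob = total_a / (total_a + total_b)).
ac_log_pmf <- function(y, x, total_a, total_b) {
  stats::dnbinom(y, size = x + 1, prob = total_a / (total_a + total_b),
                 log = TRUE)
}

#' Differential-expression test for a tag-count pair
#'
#' Two library-aware tests for a single feature observed `count_a` of
#' `total_a` reads versus `count_b` of `total_b` reads:
#' \describe{
#'   \item{`audic_claverie`}{two-sided tail of the Audic-Claverie
#'     posterior of `count_b` given `count_a` and the library-size ratio
#'     (the classic SAGE/tag-count test):
#'     `p = min(1, 2 * min(P(Y <= b), P(Y >= b)))`.}
#'   \item{`fisher`}{two-sided Fisher exact test on the 2x2 table
#'     `[count_a, total_a - count_a; count_b, total_b - count_b]`.}
#' }
#' Both are symmetric under swapping the two libraries, and equal counts
#' at equal totals give `p = 1`.
#'
#' @param count_a,count_b feature counts in the two libraries.
#' @param total_a,total_b library totals (`> 0`).
#' @param method `"audic_claverie"` (default) or `"fisher"`.
#' @return p-value in `(0, 1]`.
#' @export
de_test <- function(count_a, total_a, count_b, total_b,
                    method = c("audic_claverie", "fisher")) {
  method <- match.arg(method)
  stopifnot(total_a > 0, total_b > 0)
  if (method == "audic_claverie") {
    prob <- total_a / (total_a + total_b)
    lower <- stats::pnbinom(count_b, size = count_a + 1, prob = prob)
    upper <- 1 - stats::pnbinom(count_b - 1, size = count_a + 1, prob = prob)
    # symmetrise: average with the test in the swapped direction so
    # p(a, b) == p(b, a) exactly
    prob2 <- total_b / (total_a + total_b)
    lower2 <- stats::pnbinom(count_a, size = count_b + 1, prob = prob2)
    upper2 <- 1 - stats::pnbinom(count_a - 1, size = count_b + 1,
                                 prob = prob2)
    p <- min(1, min(lower, upper) + min(lower2, upper2))
    max(p, .Machine$double.xmin)
  } else {
    tab <- matrix(c(count_a, total_a - count_a,
                    count_b, total_b - count_b), nrow = 2L)
    stats::fisher.test(tab)$p.value
  }
}

#' Call differentially expressed features between two libraries
#'
#' Per feature: TPM in both libraries, log2 fold change, a [de_test()]
#' p-value, and a significance call requiring both gates, the default
#' thresholds being at least a two-fold change (`|log2FC| >= 1`) and
#' `p < 1e-5`. No multiple-testing correction is applied: the fixed
#' per-feature cutoff is the published convention for these tag-count
#' screens.
#'
#' @param mat a `count_matrix` (features x libraries with
#'   `library_totals`).
#' @param pair character vector of two library ids: `c(control,
#'   treatment)`.
#' @param fc_threshold minimum `|log2FC|` (default 1, i.e. two-fold).
#' @param alpha p-value cutoff (default 1e-5).
#' @param method passed to [de_test()].
#' @param floor TPM floor for fold changes.
#' @return data.frame with columns `feature`, `tpm_a`, `tpm_b`, `log2fc`,
#'   `p_value`, `significant`.
#' @export
call_de <- function(mat, pair, fc_threshold = 1, alpha = 1e-5,
                    method = "audic_claverie", floor = 0.01) {
  stopifnot(all(pair %in% colnames(mat)))
  totals <- attr(mat, "library_totals")
  a <- unclass(mat)[, pair[1L]]; b <- unclass(mat)[, pair[2L]]
  ta <- totals[[pair[1L]]]; tb <- totals[[pair[2L]]]
  tpm_a <- tpm(a, ta); tpm_b <- tpm(b, tb)
  p <- vapply(seq_along(a), function(i) {
    de_test(a[i], ta, b[i], tb, method = method)
  }, numeric(1L))
  lfc <- log2_fold_change(tpm_b, tpm_a, floor = floor)
  data.frame(feature = rownames(mat), tpm_a = tpm_a, tpm_b = tpm_b,
             log2fc = lfc, p_value = p,
             significant = abs(lfc) >= fc_threshold & p < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation among the study genes relative
#' to the background: the upper tail `P(X >= k)` with
#' `X ~ Hypergeometric(N, K, n)`, where `N` is the background size, `K`
#' the background genes carrying the term, `n` the study size and `k` the
#' study genes carrying it. Raw p-values are reported (the conventional
#' `p < 0.05` screen); a Benjamini-Hochberg column can be added.
#'
#' @param study_genes character vector, must be a subset of
#'   `background_genes`.
#' @param background_genes character vector of background gene ids.
#' @param term_table named list gene -> character vector of term ids (see
#'   [read_term_table()]).
#' @param adjust add a BH-adjusted column (default `FALSE`).
#' @return data.frame with columns `term`, `k`, `n`, `K`, `N`, `p_value`
#'   (and `p_adjust` when requested), ordered by `p_value`.
#' @export
hypergeom_enrich <- function(study_genes, background_genes, term_table,
                             adjust = FALSE) {
  study_genes <- unique(study_genes)
  background_genes <- unique(background_genes)
  if (!all(study_genes %in% background_genes)) {
    stop("study genes must be a subset of the background")
  }
  N <- length(background_genes)
  n <- length(study_genes)
  bg_terms <- term_table[intersect(names(term_table), background_genes)]
  terms <- sort(unique(unlist(bg_terms)))
  study_terms <- term_table[intersect(names(term_table), study_genes)]
  res <- lapply(terms, function(tm) {
    K <- sum(vapply(bg_terms, function(ts) tm %in% ts, logical(1L)))
    k <- sum(vapply(study_terms, function(ts) tm %in% ts, logical(1L)))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(term = character(0), k = integer(0), n = integer(0),
               K = integer(0), N = integer(0), p_value = numeric(0))
  if (adjust) out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$term), , drop = FALSE]
}

#' Relative quantification by the delta-delta-Ct method
#'
#' `fold = 2^-((Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator))`: the expression of the
#' target gene in a sample relative to a calibrator sample (set to 1.0),
#' each normalised to a reference gene.
#'
#' @param ct_target_sample,ct_ref_sample target- and reference-gene Ct in
#'   the sample.
#' @param ct_target_cal,ct_ref_cal the same in the calibrator.
#' @return relative fold level (calibrator = 1).
#' @export
ddct_relative <- function(ct_target_sample, ct_ref_sample,
                          ct_target_cal, ct_ref_cal) {
  stopifnot(is.finite(ct_target_sample), is.finite(ct_ref_sample),
            is.finite(ct_target_cal), is.finite(ct_ref_cal))
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}
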