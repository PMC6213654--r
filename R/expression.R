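# Normalization and differential-expression calls for transcript (RPKM)
# and miRNA (common-set) count matrices. With duplicate experiments per
# condition, replicate counts are pooled and tested with a two-sided exact
# test on the 2x2 table of (feature reads, remaining library reads);
# fold changes come from mean normalized expression with a pseudocount.

#' RPKM-normalize a transcript count matrix
#'
#' RPKM[f, s] = count[f, s] * 1e9 / (length[f] * library_size[s]) with the
#' library size taken as the column sum.
#'
#' @param cm A [count_matrix()] carrying `feature_lengths`.
#' @return Numeric matrix of RPKM values, same dimnames as the counts.
#' @export
rpkm_normalize <- function(cm) {
  if (is.null(cm$feature_lengths)) {
    stopf("RPKM normalization requires feature lengths")
  }
  lib <- colSums(cm$counts)
  if (any(lib == 0)) stopf("zero library size in sample '%s'",
                           colnames(cm$counts)[lib == 0][1])
  sweep(cm$counts / cm$feature_lengths, 2L, lib, "/") * 1e9
}

#' Common-set normalization for small-RNA counts
#'
#' Scales each library by the summed counts of the common set: the
#' features detected (count > 0) in every sample. Each sample's counts are
#' multiplied by (mean common-set total) / (its common-set total), so
#' libraries differing only in depth are brought onto a shared scale.
#'
#' @param cm A [count_matrix()].
#' @param fallback_total If the common set is empty, fall back to
#'   total-count scaling instead of raising an error.
#' @return Numeric matrix of normalized counts.
#' @export
common_set_normalize <- function(cm, fallback_total = FALSE) {
  m <- cm$counts
  common <- rowSums(m > 0L) == ncol(m)
  if (!any(common)) {
    if (!fallback_total) {
      stopf(paste("no miRNA is detected in every sample (empty common set);",
                  "rerun with fallback_total = TRUE for total-count scaling"))
    }
    totals <- colSums(m)
  } else {
    totals <- colSums(m[common, , drop = FALSE])
  }
  if (any(totals == 0)) stopf("zero normalization total in sample '%s'",
                              colnames(m)[totals == 0][1])
  sweep(m, 2L, mean(totals) / totals, "*")
}

#' Two-sided exact test on a 2x2 count table
#'
#' Conditional on the margins of `[[count_a, total_a - count_a],
#' [count_b, total_b - count_b]]`, sums the hypergeometric probabilities
#' of all tables no more probable than the observed one (the standard
#' two-sided exact test for count data). Vectorized over its arguments.
#'
#' @param count_a,total_a Reads for the feature and library total in
#'   group A.
#' @param count_b,total_b Same for group B.
#' @return Two-sided p-value(s) in `[0, 1]`.
#' @examples
#' fisher_exact_de(5, 5, 0, 5)  # 2/choose(10, 5)
#' @export
fisher_exact_de <- function(count_a, total_a, count_b, total_b) {
  n <- max(length(count_a), length(total_a), length(count_b),
           length(total_b))
  count_a <- rep_len(count_a, n); total_a <- rep_len(total_a, n)
  count_b <- rep_len(count_b, n); total_b <- rep_len(total_b, n)
  if (any(total_a <= 0 | total_b <= 0)) stopf("library totals must be > 0")
  if (any(count_a < 0 | count_b < 0 | count_a > total_a |
          count_b > total_b)) {
    stopf("counts must satisfy 0 <= count <= total")
  }
  vapply(seq_len(n), function(i) {
    k <- count_a[i] + count_b[i]        # feature-read margin
    lo <- max(0L, k - total_b[i])
    hi <- min(k, total_a[i])
    supp <- lo:hi
    dens <- dhyper(supp, total_a[i], total_b[i], k)
    obs <- dens[supp == count_a[i]]
    # the conventional relative tolerance absorbs floating-point ties
    min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Chi-squared alternative to the exact test
#'
#' Pearson chi-squared (without continuity correction) on the same 2x2
#' table as [fisher_exact_de()]; offered as the option the exact test can
#' be swapped for on deep libraries.
#'
#' @inheritParams fisher_exact_de
#' @return Two-sided p-value(s).
#' @export
chisq_de <- function(count_a, total_a, count_b, total_b) {
  n <- max(length(count_a), length(total_a), length(count_b),
           length(total_b))
  count_a <- rep_len(count_a, n); total_a <- rep_len(total_a, n)
  count_b <- rep_len(count_b, n); total_b <- rep_len(total_b, n)
  vapply(seq_len(n), function(i) {
    tab <- matrix(c(count_a[i], total_a[i] - count_a[i],
                    count_b[i], total_b[i] - count_b[i]), nrow = 2)
    suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
  }, numeric(1))
}

#' Pseudocounted log2 fold change
#'
#' `log2((expr_num + pseudocount) / (expr_den + pseudocount))` on the
#' normalized expression scale; the pseudocount keeps zero-expression
#' features finite.
#'
#' @param expr_num,expr_den Non-negative normalized expression values.
#' @param pseudocount Positive stabilizer (default 1 on the normalized
#'   scale).
#' @return Numeric log2 fold change(s).
#' @export
log2_fold_change <- function(expr_num, expr_den, pseudocount = 1) {
  if (pseudocount <= 0) stopf("pseudocount must be > 0")
  log2((expr_num + pseudocount) / (expr_den + pseudocount))
}

#' Default significance thresholds per feature mode
#'
#' Transcripts are called at |log2FC| >= 1 and p < 0.05; miRNAs at
#' p < 0.05 with no fold-change gate.
#'
#' @param mode `"gene"` or `"mirna"`.
#' @return List with `min_abs_log2fc` and `max_p`.
#' @export
de_thresholds <- function(mode = c("gene", "mirna")) {
  mode <- match.arg(mode)
  if (mode == "gene") list(min_abs_log2fc = 1, max_p = 0.05)
  else list(min_abs_log2fc = 0, max_p = 0.05)
}

#' Call differential expression for one comparison
#'
#' For the comparison `numerator vs denominator`, replicate raw counts are
#' pooled (summed) within each condition and tested feature-by-feature
#' with the exact test on pooled reads against pooled library sizes; the
#' log2 fold change is computed from mean normalized expression (RPKM in
#' gene mode, common-set normalized counts in miRNA mode). A feature is
#' significant iff `p < max_p` and `|log2fc| >= min_abs_log2fc`;
#' `direction` is `up`/`down` by the sign of the fold change for
#' significant features and `unchanged` otherwise ("up" always refers to
#' the first-named condition relative to the second).
#'
#' @param cm A [count_matrix()] (gene mode requires feature lengths).
#' @param design Named character vector mapping sample id -> condition
#'   label, covering all samples of `cm`.
#' @param comparison Character vector `c(numerator, denominator)` of
#'   condition labels.
#' @param mode `"gene"` or `"mirna"`; selects normalization and default
#'   thresholds.
#' @param thresholds Optional list overriding [de_thresholds()].
#' @param pseudocount Pseudocount for [log2_fold_change()].
#' @param test `"fisher"` (exact, default) or `"chisq"`.
#' @param p_adjust Apply Benjamini-Hochberg correction before thresholding
#'   (off by default; the raw-p convention is the field's).
#' @param fallback_total Passed to [common_set_normalize()] in miRNA mode.
#' @return Data frame with one row per feature: `feature_id`,
#'   `comparison`, `mean_expr_num`, `mean_expr_den`, `log2fc`, `p_value`,
#'   `direction`, `significant`.
#' @export
call_de <- function(cm, design, comparison, mode = c("gene", "mirna"),
                    thresholds = NULL, pseudocount = 1,
                    test = c("fisher", "chisq"), p_adjust = FALSE,
                    fallback_total = FALSE) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  thresholds <- thresholds %||% de_thresholds(mode)
  samples <- colnames(cm$counts)
  miss <- setdiff(samples, names(design))
  if (length(miss)) stopf("design lacks sample(s): %s",
                          paste(miss, collapse = ", "))
  cond <- design[samples]
  if (length(comparison) != 2L) stopf("comparison must be c(num, den)")
  for (lbl in comparison) {
    if (!any(cond == lbl)) stopf("condition '%s' absent from design", lbl)
  }
  num_s <- samples[cond == comparison[1]]
  den_s <- samples[cond == comparison[2]]
  norm <- if (mode == "gene") rpkm_normalize(cm)
          else common_set_normalize(cm, fallback_total)
  mean_num <- rowMeans(norm[, num_s, drop = FALSE])
  mean_den <- rowMeans(norm[, den_s, drop = FALSE])
  lfc <- log2_fold_change(mean_num, mean_den, pseudocount)
  lib <- colSums(cm$counts)
  pooled_num <- rowSums(cm$counts[, num_s, drop = FALSE])
  pooled_den <- rowSums(cm$counts[, den_s, drop = FALSE])
  tot_num <- sum(lib[num_s]); tot_den <- sum(lib[den_s])
  p <- if (test == "fisher") {
    fisher_exact_de(pooled_num, tot_num, pooled_den, tot_den)
  } else {
    chisq_de(pooled_num, tot_num, pooled_den, tot_den)
  }
  if (p_adjust) p <- p.adjust(p, method = "BH")
  sig <- p < thresholds$max_p & abs(lfc) >= thresholds$min_abs_log2fc &
    lfc != 0
  direction <- ifelse(!sig, "unchanged", ifelse(lfc > 0, "up", "down"))
  data.frame(feature_id = rownames(cm$counts),
             comparison = paste(comparison, collapse = "_vs_"),
             mean_expr_num = unname(mean_num),
             mean_expr_den = unname(mean_den),
             log2fc = unname(lfc), p_value = unname(p),
             direction = direction, significant = sig,
             row.names = NULL, stringsAsFactors = FALSE)
}
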