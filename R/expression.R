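#' Differential-expression thresholds
#'
#' @param lfc_threshold absolute log2 fold-change bound (inclusive), default 1.
#' @param padj_threshold adjusted p-value bound (inclusive), default 0.01.
#' @param expression_percentile percentile of TPMmean defining the
#'   expression gate, default 5.
#' @return object of class `de_config`.
#' @export
de_config <- function(lfc_threshold = 1, padj_threshold = 0.01,
                      expression_percentile = 5) {
  stopifnot(lfc_threshold > 0, padj_threshold > 0,
            expression_percentile > 0, expression_percentile < 100)
  structure(list(lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold,
                 expression_percentile = expression_percentile),
            class = "de_config")
}

#' Transcripts per million from counts and gene lengths
#'
#' Per sample: `rate_g = count_g / length_g`, `TPM_g = 1e6 * rate_g /
#' sum(rate)`.  Columns sum to 1e6 except for all-zero samples, whose TPMs
#' are defined as 0 with a warning.
#'
#' @param counts genes x samples matrix.
#' @param lengths per-gene lengths in bp (recycled by gene order or matched
#'   by name when named).
#' @return TPM matrix with the same dimnames.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  stopifnot(length(lengths) == nrow(counts), all(lengths > 0))
  rate <- counts / lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s); TPMs set to 0", call. = FALSE)
    denom[zero] <- 1
  }
  sweep(rate, 2L, denom, "/") * 1e6
}

#' Mean TPM per condition
#'
#' @param tpm TPM matrix.
#' @param condition per-sample condition labels.
#' @return genes x conditions matrix of TPM means.
#' @export
tpm_mean_by_condition <- function(tpm, condition) {
  stopifnot(ncol(tpm) == length(condition))
  conds <- unique(condition)
  out <- vapply(conds, function(cc) {
    rowMeans(tpm[, condition == cc, drop = FALSE])
  }, numeric(nrow(tpm)))
  colnames(out) <- conds
  out
}

#' Expression gate at a TPMmean percentile
#'
#' The threshold is the `percentile`-th percentile (linear interpolation
#' between order statistics, quantile type 7) of the TPMmean vector
#' including zeros; a gene counts as expressed when its TPMmean is strictly
#' above the threshold.
#'
#' @param tpm_means numeric vector of per-gene TPM means.
#' @param percentile percentile in (0, 100), default 5.
#' @return list: `threshold` and logical `expressed`.
#' @export
expression_gate <- function(tpm_means, percentile = 5) {
  stopifnot(length(tpm_means) >= 1L)
  tau <- unname(quantile(tpm_means, percentile / 100, type = 7))
  list(threshold = tau, expressed = tpm_means > tau)
}

#' Classify differential expression
#'
#' `down` iff log2fc <= -lfc_threshold and padj <= padj_threshold; `up` iff
#' log2fc >= lfc_threshold and padj <= padj_threshold; otherwise `not_de`.
#' All bounds inclusive.  Missing padj yields `not_de`.
#'
#' @param log2fc,padj numeric vectors.
#' @param config a [de_config()].
#' @return character vector in `{"up", "down", "not_de"}`.
#' @export
classify_de <- function(log2fc, padj, config = de_config()) {
  sig <- !is.na(padj) & padj <= config$padj_threshold
  ifelse(sig & log2fc >= config$lfc_threshold, "up",
         ifelse(sig & log2fc <= -config$lfc_threshold, "down", "not_de"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment of raw p-values.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Build a DE record table
#'
#' @param gene_id,log2fc,padj per-gene vectors.
#' @param tpm_mean genes x conditions matrix from [tpm_mean_by_condition()];
#'   must contain a `"wt"` column and one mutant column.
#' @param contrast contrast label, e.g. `"mut_vs_wt"`.
#' @param config a [de_config()].
#' @return data frame with class column and per-condition TPM means.
#' @export
de_table <- function(gene_id, log2fc, padj, tpm_mean, contrast = "mut_vs_wt",
                     config = de_config()) {
  stopifnot("wt" %in% colnames(tpm_mean))
  mut_col <- setdiff(colnames(tpm_mean), "wt")[1L]
  data.frame(gene_id = gene_id, contrast = contrast, log2fc = log2fc,
             padj = padj, class = classify_de(log2fc, padj, config),
             tpm_mean_wt = tpm_mean[gene_id, "wt"],
             tpm_mean_mut = tpm_mean[gene_id, mut_col],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Exclusive-expression and silenced gene sets
#'
#' Activated (exclusively expressed in the mutant): significantly
#' upregulated and wild-type TPMmean exactly 0.  Silenced: significantly
#' downregulated and mutant TPMmean exactly 0.  The zero comparison is
#' exact, not a tolerance.
#'
#' @param de_records data frame from [de_table()].
#' @return list of gene-id vectors: `activated`, `silenced`.
#' @export
exclusive_sets <- function(de_records) {
  list(activated = de_records$gene_id[de_records$class == "up" &
                                        de_records$tpm_mean_wt == 0],
       silenced = de_records$gene_id[de_records$class == "down" &
                                       de_records$tpm_mean_mut == 0])
}

#' Overlaps between named gene sets
#'
#' @param sets named list of gene-id vectors (one per contrast).
#' @return list: `shared` (genes in every set), `n_shared`, and a pairwise
#'   data frame with intersection sizes and percentages relative to each set.
#' @export
overlap_stats <- function(sets) {
  stopifnot(length(sets) >= 1L)
  sets <- lapply(sets, unique)
  shared <- Reduce(intersect, sets)
  pairs <- if (length(sets) >= 2L) {
    cmb <- utils::combn(names(sets), 2L)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      a <- cmb[1L, j]; b <- cmb[2L, j]
      n <- length(intersect(sets[[a]], sets[[b]]))
      data.frame(set_a = a, set_b = b, n_shared = n,
                 pct_of_a = if (length(sets[[a]])) 100 * n / length(sets[[a]])
                   else NA_real_,
                 pct_of_b = if (length(sets[[b]])) 100 * n / length(sets[[b]])
                   else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  list(shared = sort(shared), n_shared = length(shared), pairwise = pairs,
       sizes = vapply(sets, length, integer(1)))
}

#' Median log2 fold change per DE class
#'
#' @param de_records data frame from [de_table()].
#' @return data frame of contrast, class and median log2fc.
#' @export
fc_summary <- function(de_records) {
  agg <- aggregate(log2fc ~ contrast + class, data = de_records, FUN = median)
  names(agg)[names(agg) == "log2fc"] <- "median_log2fc"
  agg[order(agg$contrast, agg$class), , drop = FALSE]
}

#' Self-contained naive differential-expression path
#'
#' A demonstration route when no external DE engine output is available:
#' log2fc = log2((mean TPM + 1, mutant) / (mean TPM + 1, wt)) with label
#' permutation p-values on the difference of mean log2(TPM + 1) (exact
#' enumeration when feasible, Monte Carlo otherwise) and BH adjustment.
#' It is not a replacement for a count-model fitter.
#'
#' @param tpm TPM matrix.
#' @param condition per-sample labels (`"wt"` vs one mutant label).
#' @param n_perm Monte Carlo permutations when exact enumeration exceeds
#'   `max_exact` label splits.
#' @param max_exact enumeration cap.
#' @param seed seed for Monte Carlo permutations.
#' @return data frame: gene_id, log2fc, pvalue, padj.
#' @export
naive_de <- function(tpm, condition, n_perm = 1000L, max_exact = 2000L,
                     seed = 1L) {
  conds <- unique(condition)
  stopifnot(length(conds) == 2L, "wt" %in% conds)
  mut <- setdiff(conds, "wt")
  x <- log2(tpm + 1)
  is_mut <- condition == mut
  obs <- rowMeans(x[, is_mut, drop = FALSE]) -
    rowMeans(x[, !is_mut, drop = FALSE])
  n <- ncol(x); n1 <- sum(is_mut)
  stat_for <- function(idx) {
    sel <- logical(n); sel[idx] <- TRUE
    rowMeans(x[, sel, drop = FALSE]) - rowMeans(x[, !sel, drop = FALSE])
  }
  exact <- choose(n, n1) <= max_exact
  perms <- if (exact) utils::combn(n, n1, simplify = FALSE)
    else with_seed(seed, replicate(n_perm, sample.int(n, n1),
                                   simplify = FALSE))
  null_stats <- vapply(perms, stat_for, numeric(nrow(x)))
  n_extreme <- rowSums(abs(null_stats) >= abs(obs) - 1e-12)
  # exact enumeration contains the identity split; Monte Carlo adds it
  pvalue <- if (exact) n_extreme / length(perms)
    else (n_extreme + 1) / (length(perms) + 1)
  mean_tpm <- tpm_mean_by_condition(tpm, condition)
  log2fc <- log2(mean_tpm[, mut] + 1) - log2(mean_tpm[, "wt"] + 1)
  data.frame(gene_id = rownames(tpm) %||% as.character(seq_len(nrow(tpm))),
             log2fc = unname(log2fc), pvalue = unname(pvalue),
             padj = unname(bh_adjust(pvalue)), stringsAsFactors = FALSE,
             row.names = NULL)
}
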