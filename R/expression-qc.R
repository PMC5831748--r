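# Library-level QC: FPKM, replicate correlations, PCA component retention,
# and germline-enrichment classification from wild-type vs germline-ablated
# expression.

#' Fragments per kilobase of transcript per million mapped reads
#'
#' FPKM = counts * 1e9 / (length * total_mapped).
#'
#' @param counts numeric vector of per-gene fragment counts.
#' @param lengths gene lengths in bp (> 0).
#' @param total_mapped total mapped reads in the library (> 0).
#' @return numeric vector of FPKM values.
#' @export
compute_fpkm <- function(counts, lengths, total_mapped) {
  if (length(counts) != length(lengths)) abort("length mismatch")
  if (any(lengths <= 0)) abort("gene lengths must be > 0")
  if (!is_scalar_number(total_mapped) || total_mapped <= 0) {
    abort("'total_mapped' must be > 0")
  }
  counts * 1e9 / (lengths * total_mapped)
}

#' Pearson correlation between replicate libraries
#'
#' Correlation of two count vectors, by default on the log2(count + 1)
#' scale. The p-value uses the t transform of r; `df_mode = "legacy"` uses
#' n - 1 degrees of freedom (some published QC panels print correlations
#' computed this way), `"standard"` the conventional n - 2.
#'
#' @param x,y count vectors of equal length (>= 3), not constant.
#' @param df_mode `"legacy"` (df = n - 1, default) or `"standard"`
#'   (df = n - 2).
#' @param transform `"log2"` (default, log2(count + 1)) or `"raw"`.
#' @return list with `r`, `p_value`, `df`, `n`.
#' @export
replicate_pearson <- function(x, y, df_mode = c("legacy", "standard"),
                              transform = c("log2", "raw")) {
  df_mode <- match.arg(df_mode)
  transform <- match.arg(transform)
  if (length(x) != length(y)) abort("vectors must have equal length")
  if (length(x) < 3) abort("need >= 3 observations")
  if (transform == "log2") {
    x <- log2(x + 1); y <- log2(y + 1)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  df <- if (df_mode == "legacy") n - 1 else n - 2
  tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df), df = df, n = n)
}

#' Broken-stick expected variance shares
#'
#' b_k = (1/p) * sum_{i=k..p} 1/i: the expected share of the k-th largest
#' piece of a unit stick broken at p - 1 uniform points. Sums to 1.
#'
#' @param p number of components (>= 1).
#' @return numeric vector of length `p`.
#' @export
broken_stick <- function(p) {
  if (!is_scalar_number(p) || p < 1) abort("'p' must be >= 1")
  p <- as.integer(p)
  rev(cumsum(1 / rev(seq_len(p)))) / p
}

#' PCA of library replicates with Kaiser and broken-stick retention
#'
#' Principal components of the sample-correlation structure: the
#' correlation matrix among samples is computed over genes on the
#' log2(count + 1) scale (or raw counts) and eigen-decomposed.
#' Zero-variance genes are removed first. A component is significant under
#' the Kaiser criterion when its eigenvalue exceeds 1, and under the
#' broken-stick model when its variance share exceeds b_k.
#'
#' @param counts numeric matrix, genes x samples (>= 2 samples).
#' @param transform `"log2"` (default) or `"raw"`.
#' @return object of class `pca_retention`: list with `eigenvalues`,
#'   `variance_share`, `broken_stick`, logical flags `kaiser_significant`
#'   and `broken_stick_significant`, `n_genes_used`, `n_dropped`.
#' @export
pc_significance <- function(counts, transform = c("log2", "raw")) {
  transform <- match.arg(transform)
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort("need >= 2 samples")
  x <- if (transform == "log2") log2(counts + 1) else counts
  v <- apply(x, 1, stats::var)
  dropped <- sum(v == 0 | is.na(v))
  x <- x[v > 0 & !is.na(v), , drop = FALSE]
  if (nrow(x) < 2) abort("fewer than 2 non-degenerate genes")
  csd <- apply(x, 2, stats::sd)
  if (any(csd == 0)) abort("fewer than 2 non-degenerate samples")
  if (dropped > 0) message(dropped, " zero-variance gene(s) removed")
  lambda <- eigen(stats::cor(x), symmetric = TRUE, only.values = TRUE)$values
  lambda <- pmax(lambda, 0)
  share <- lambda / sum(lambda)
  bs <- broken_stick(length(lambda))
  structure(
    list(
      eigenvalues = lambda,
      variance_share = share,
      broken_stick = bs,
      kaiser_significant = lambda > 1,
      broken_stick_significant = share > bs,
      n_genes_used = nrow(x),
      n_dropped = dropped
    ),
    class = "pca_retention"
  )
}

#' @export
print.pca_retention <- function(x, ...) {
  p <- length(x$eigenvalues)
  cat("PCA component retention (", p, "components )\n")
  for (k in seq_len(p)) {
    cat(sprintf(
      "  PC%d: lambda %.3f, share %.3f (broken stick %.3f)%s%s\n",
      k, x$eigenvalues[k], x$variance_share[k], x$broken_stick[k],
      if (x$kaiser_significant[k]) " [Kaiser]" else "",
      if (x$broken_stick_significant[k]) " [broken-stick]" else ""
    ))
  }
  invisible(x)
}

#' Classify genes as germline-enriched from wild-type vs ablated FPKM
#'
#' A gene is germline-enriched when its expression collapses after germline
#' ablation: ratio = (fpkm_ablated + pseudocount) / (fpkm_wt + pseudocount)
#' at or below `ratio_threshold`. Genes with wild-type FPKM at or below the
#' pseudocount are `undetermined`. Optionally a reference germline gene
#' list is tested for enrichment among the called genes with
#' [fisher_two_tailed()].
#'
#' @param fpkm_wt,fpkm_ablated named numeric FPKM vectors over the same
#'   genes (names = gene ids; if unnamed, positional identity is assumed).
#' @param ratio_threshold enrichment call threshold on the ablated/wt ratio
#'   (default 0.5).
#' @param pseudocount added to both FPKM values (default 0.1).
#' @param reference_germline optional character vector of known germline
#'   gene ids.
#' @return list with `calls` (data frame `gene_id`, `fpkm_wt`,
#'   `fpkm_ablated`, `ratio`, `label`), `summary` (median ratio, fraction
#'   enriched), and `fisher_p` vs the reference list (NA when absent).
#' @export
germline_enrichment_classify <- function(fpkm_wt, fpkm_ablated,
                                         ratio_threshold = 0.5,
                                         pseudocount = 0.1,
                                         reference_germline = NULL) {
  if (length(fpkm_wt) != length(fpkm_ablated)) abort("length mismatch")
  ids <- names(fpkm_wt)
  if (is.null(ids)) ids <- paste0("g", seq_along(fpkm_wt))
  ratio <- (fpkm_ablated + pseudocount) / (fpkm_wt + pseudocount)
  label <- ifelse(fpkm_wt <= pseudocount, "undetermined",
                  ifelse(ratio <= ratio_threshold,
                         "germline_enriched", "not_enriched"))
  calls <- data.frame(gene_id = ids, fpkm_wt = as.numeric(fpkm_wt),
                      fpkm_ablated = as.numeric(fpkm_ablated),
                      ratio = as.numeric(ratio), label = label,
                      stringsAsFactors = FALSE)
  determined <- label != "undetermined"
  summary <- list(
    median_ratio = stats::median(ratio[determined]),
    fraction_enriched = if (any(determined)) {
      mean(label[determined] == "germline_enriched")
    } else NaN,
    n_undetermined = sum(!determined)
  )
  fisher_p <- NA_real_
  if (!is.null(reference_germline)) {
    enr <- label == "germline_enriched"
    ref <- ids %in% reference_germline
    fisher_p <- fisher_two_tailed(sum(enr & ref), sum(enr & !ref),
                                  sum(!enr & ref), sum(!enr & !ref))
  }
  list(calls = calls, summary = summary, fisher_p = fisher_p)
}
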