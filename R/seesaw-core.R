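# Quadrant classification and seesaw gene calling.
#
# A "seesaw" gene changes expression in opposite directions after the two
# dauer-inducing stresses: postdauer/control (PD/CON) log2 fold change
# positive under pheromone and negative under starvation, or vice versa.
# "Significant" seesaw requires FDR < alpha in both contrasts; "trend"
# seesaw requires an inverse change of at least `min_fold` regardless of
# significance.

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: q_i is the minimum over ranks
#' j >= rank(i) of p_(j) * m / j, clipped to 1, returned in input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @examples
#' bh_fdr(c(0.01, 0.04, 0.03, 0.002))
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  check_probability(pvalues, "pvalues")
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify a fold-change pair into an expression quadrant
#'
#' Quadrants of the (pheromone, starvation) log2 PD/CON fold-change plane:
#' Q1 = Phe up / Stv down, Q2 = Phe down / Stv down, Q3 = Phe down / Stv up,
#' Q4 = Phe up / Stv up. A pair with either coordinate exactly zero is
#' labelled BOUNDARY and excluded from quadrant tallies.
#'
#' @param log2fc_phe,log2fc_stv numeric vectors of log2 fold changes
#'   (recycled to common length must match).
#' @return character vector of labels in
#'   `c("Q1","Q2","Q3","Q4","BOUNDARY")`.
#' @examples
#' classify_quadrant(1.2, -0.8)  # "Q1"
#' @export
classify_quadrant <- function(log2fc_phe, log2fc_stv) {
  if (length(log2fc_phe) != length(log2fc_stv)) {
    abort("fold-change vectors must have equal length")
  }
  if (!all(is.finite(log2fc_phe)) || !all(is.finite(log2fc_stv))) {
    abort("fold changes must be finite")
  }
  out <- rep("BOUNDARY", length(log2fc_phe))
  out[log2fc_phe > 0 & log2fc_stv < 0] <- "Q1"
  out[log2fc_phe < 0 & log2fc_stv < 0] <- "Q2"
  out[log2fc_phe < 0 & log2fc_stv > 0] <- "Q3"
  out[log2fc_phe > 0 & log2fc_stv > 0] <- "Q4"
  out
}

# Restrict two DE tables to their common gene universe, erroring when empty.
common_universe <- function(de_phe, de_stv) {
  universe <- intersect(de_phe$gene_id, de_stv$gene_id)
  if (length(universe) == 0L) abort("DE tables share no genes")
  list(
    phe = de_phe[match(universe, de_phe$gene_id), , drop = FALSE],
    stv = de_stv[match(universe, de_stv$gene_id), , drop = FALSE],
    universe = universe
  )
}

#' Call significant seesaw genes from two DE contrasts
#'
#' A gene is `up_down` (Phe up :: Stv down) when FDR < `alpha` in both
#' contrasts with log2fc > 0 under pheromone and < 0 under starvation;
#' `down_up` is the mirror image. Genes significant in both contrasts with
#' the same sign are reported as `shared_up` / `shared_down`.
#'
#' @param de_phe,de_stv differential-expression data frames with columns
#'   `gene_id`, `log2fc`, `fdr` (see [read_de_table()]).
#' @param alpha FDR cutoff applied independently in each contrast
#'   (default 0.05).
#' @param loose non-default variant: require significance in only one of
#'   the two contrasts (the sign pattern must still hold in both).
#' @return an object of class `seesaw_calls`: a list with character-vector
#'   gene sets `up_down`, `down_up`, `shared_up`, `shared_down`, the common
#'   `universe`, per-gene `quadrant` labels (named by gene), and `alpha`.
#' @export
call_significant_seesaw <- function(de_phe, de_stv, alpha = 0.05,
                                    loose = FALSE) {
  check_probability(alpha, "alpha")
  tabs <- common_universe(de_phe, de_stv)
  phe <- tabs$phe; stv <- tabs$stv
  sig <- if (loose) {
    phe$fdr < alpha | stv$fdr < alpha
  } else {
    phe$fdr < alpha & stv$fdr < alpha
  }
  up_down <- sig & phe$log2fc > 0 & stv$log2fc < 0
  down_up <- sig & phe$log2fc < 0 & stv$log2fc > 0
  shared_up <- sig & phe$log2fc > 0 & stv$log2fc > 0
  shared_down <- sig & phe$log2fc < 0 & stv$log2fc < 0
  quadrant <- classify_quadrant(phe$log2fc, stv$log2fc)
  names(quadrant) <- tabs$universe
  structure(
    list(
      up_down = tabs$universe[up_down],
      down_up = tabs$universe[down_up],
      shared_up = tabs$universe[shared_up],
      shared_down = tabs$universe[shared_down],
      universe = tabs$universe,
      quadrant = quadrant,
      alpha = alpha
    ),
    class = "seesaw_calls"
  )
}

#' @export
print.seesaw_calls <- function(x, ...) {
  cat("Seesaw calls (FDR <", x$alpha, "in both contrasts)\n")
  cat("  universe:    ", length(x$universe), "genes\n")
  cat("  up_down:     ", length(x$up_down), "(Phe up :: Stv down)\n")
  cat("  down_up:     ", length(x$down_up), "(Phe down :: Stv up)\n")
  cat("  shared_up:   ", length(x$shared_up), "\n")
  cat("  shared_down: ", length(x$shared_down), "\n")
  invisible(x)
}

#' Trend-level seesaw sets (inverse change, significance ignored)
#'
#' Genes with an inverse directional change of at least `min_fold` in the two
#' contrasts regardless of statistical significance; the threshold is
#' inclusive (|log2fc| >= log2(min_fold)).
#'
#' @inheritParams call_significant_seesaw
#' @param min_fold minimum fold change (> 1; default 2).
#' @return list with character vectors `up_down_trend`, `down_up_trend`
#'   and the common `universe`.
#' @export
trend_seesaw <- function(de_phe, de_stv, min_fold = 2) {
  if (!is_scalar_number(min_fold) || min_fold <= 1) {
    abort("'min_fold' must be > 1")
  }
  thr <- log2(min_fold)
  tabs <- common_universe(de_phe, de_stv)
  up_down <- tabs$phe$log2fc >= thr & tabs$stv$log2fc <= -thr
  down_up <- tabs$phe$log2fc <= -thr & tabs$stv$log2fc >= thr
  list(
    up_down_trend = tabs$universe[up_down],
    down_up_trend = tabs$universe[down_up],
    universe = tabs$universe
  )
}

#' Percentage as reported in text
#'
#' 100 * numerator / denominator, rounded half away from zero to `decimals`
#' places — the arithmetic behind reported figures such as "249 (56%) of
#' the 441".
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @param decimals decimal places kept (default 0).
#' @return numeric scalar percentage.
#' @examples
#' percentage_report(249, 441)        # 56
#' percentage_report(12454, 18570, 1) # 67.1
#' @export
percentage_report <- function(numerator, denominator, decimals = 0) {
  if (!is_scalar_number(denominator) || denominator <= 0) {
    abort("'denominator' must be > 0")
  }
  round_half_away(100 * numerator / denominator, decimals)
}

#' Classify how a mutant disrupts wild-type seesaw expression
#'
#' Given genes with a known wild-type seesaw orientation, classify each
#' gene's behaviour in a mutant from the mutant's own two contrasts:
#' \itemize{
#'   \item significant in both conditions with opposite signs:
#'     `retained_seesaw_same` if the orientation matches wild type,
#'     otherwise `inverted_both` (both directions flipped);
#'   \item significant in both with the same sign: `follows_phe` if the
#'     shared sign equals the wild-type pheromone sign, else `follows_stv`;
#'   \item anything else: `loss_of_significance`.
#' }
#'
#' @param wt_orientation named character vector per gene, `"up_down"` or
#'   `"down_up"` (the wild-type seesaw call).
#' @param mut_de_phe,mut_de_stv mutant DE tables (`gene_id`, `log2fc`,
#'   `fdr`).
#' @param alpha FDR cutoff for mutant significance (default 0.05).
#' @return list with `category` (named character vector, one of
#'   `inverted_both`, `follows_phe`, `follows_stv`, `loss_of_significance`,
#'   `retained_seesaw_same`) and `frequency` (data frame of counts and
#'   rounded percentages).
#' @export
mutant_disruption_classify <- function(wt_orientation, mut_de_phe,
                                       mut_de_stv, alpha = 0.05) {
  if (is.null(names(wt_orientation)) || any(names(wt_orientation) == "")) {
    abort("'wt_orientation' must be named by gene id")
  }
  if (!all(wt_orientation %in% c("up_down", "down_up"))) {
    abort("wild-type orientation must be 'up_down' or 'down_up'")
  }
  genes <- names(wt_orientation)
  i_phe <- match(genes, mut_de_phe$gene_id)
  i_stv <- match(genes, mut_de_stv$gene_id)
  if (anyNA(i_phe) || anyNA(i_stv)) {
    abort("every gene with a wild-type call must be present in both mutant tables")
  }
  wt_phe_sign <- ifelse(wt_orientation == "up_down", 1, -1)
  fc_phe <- mut_de_phe$log2fc[i_phe]
  fc_stv <- mut_de_stv$log2fc[i_stv]
  sig <- mut_de_phe$fdr[i_phe] < alpha & mut_de_stv$fdr[i_stv] < alpha
  s_phe <- sign(fc_phe); s_stv <- sign(fc_stv)

  category <- rep("loss_of_significance", length(genes))
  opposite <- sig & s_phe != 0 & s_stv != 0 & s_phe == -s_stv
  same <- sig & s_phe != 0 & s_phe == s_stv
  category[opposite & s_phe == wt_phe_sign] <- "retained_seesaw_same"
  category[opposite & s_phe == -wt_phe_sign] <- "inverted_both"
  category[same & s_phe == wt_phe_sign] <- "follows_phe"
  category[same & s_phe == -wt_phe_sign] <- "follows_stv"
  names(category) <- genes

  levels <- c("inverted_both", "follows_phe", "follows_stv",
              "loss_of_significance", "retained_seesaw_same")
  counts <- table(factor(category, levels = levels))
  freq <- data.frame(
    category = levels,
    count = as.integer(counts),
    percent = vapply(as.integer(counts), percentage_report,
                     numeric(1), denominator = length(genes)),
    stringsAsFactors = FALSE
  )
  list(category = category, frequency = freq)
}
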