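# Independent brute-force oracles and fixture builders used across tests.
# These deliberately re-derive each statistic from its definition, by a
# different route than the package implementation.

# Literal step-up FDR: q_(k) = min_{j >= k} p_(j) * m / j, clipped at 1.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    q_sorted[k] <- min(1, min(p[ord][k:m] * m / (k:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Two-sided Fisher p by explicit enumeration with choose() arithmetic.
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  total <- choose(m + n, k)
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / total, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Maximal-run cluster search by an explicit per-start walk: a cluster
# starts at an attribute gene whose predecessor (if any) is further than
# max_gap away, and extends while successive attribute genes stay within
# max_gap intervening non-attribute genes.
glc_brute <- function(flags, chrom, min_size, max_gap) {
  out <- list()
  for (ch in unique(chrom)) {
    pos <- which(flags & chrom == ch)
    if (length(pos) == 0) next
    i <- 1
    while (i <= length(pos)) {
      j <- i
      while (j < length(pos) && pos[j + 1] - pos[j] - 1 <= max_gap) {
        j <- j + 1
      }
      if (j - i + 1 >= min_size) {
        out[[length(out) + 1]] <- pos[i:j]
      }
      i <- j + 1
    }
  }
  out
}

# Toy annotation: n genes per chromosome, unit-spaced 1 kb genes.
toy_annotation <- function(n_per_chrom, chroms = c("I", "II")) {
  rows <- lapply(seq_along(chroms), function(i) {
    n <- n_per_chrom[min(i, length(n_per_chrom))]
    start <- seq(0, by = 2000, length.out = n)
    data.frame(
      gene_id = sprintf("%s_g%03d", chroms[i], seq_len(n)),
      chrom = chroms[i], start = start, end = start + 1000,
      strand = "+", operon_id = NA_character_,
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, rows)
  ann$chrom <- factor(ann$chrom, levels = chroms)
  ann
}

# Minimal DE table from explicit vectors.
toy_de <- function(gene_id, log2fc, fdr = rep(0.01, length(gene_id)),
                   pvalue = fdr) {
  data.frame(gene_id = gene_id, log2fc = log2fc, pvalue = pvalue,
             fdr = fdr, mean_expr = 10, stringsAsFactors = FALSE)
}

# Small generator config for fast structural tests.
small_config <- function(n_genes = 2000, seed = 42,
                         attribute_chromosome_weights = NULL, ...) {
  generator_config(
    n_genes = n_genes,
    seed = seed,
    genome = data.frame(
      name = c("I", "II", "III"),
      length = c(6e6, 6e6, 6e6),
      stringsAsFactors = FALSE
    ),
    class_chromosome_weights = list(
      seesaw_up_down = c(I = 0.6, II = 0.2, III = 0.2),
      seesaw_down_up = c(I = 0.2, II = 0.6, III = 0.2)
    ),
    attribute_chromosome_weights = attribute_chromosome_weights,
    ...
  )
}
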