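# Spatial genomics: chromosome bias, sliding windows, co-localization
# clusters with randomized gene-order nulls, and operon summaries.

#' Per-chromosome over/under-representation of a gene class
#'
#' For each chromosome, a 2x2 chi-squared test with Yates continuity
#' correction of (class on this chromosome vs class elsewhere) against
#' (non-class on this chromosome vs elsewhere). The corrected statistic is
#' `sum(max(|O - E| - 0.5, 0)^2 / E)` over the four cells, with p from the
#' chi-squared distribution on 1 degree of freedom. An alternative
#' `method = "proportional"` performs a one-sample goodness-of-fit test of
#' the class's chromosome counts against expectation proportional to the
#' per-chromosome gene totals.
#'
#' @param class_genes character vector of gene ids (subset of annotation).
#' @param annotation gene annotation data frame (columns `gene_id`,
#'   `chrom`).
#' @param method `"two_by_two"` (default, vs remaining chromosomes) or
#'   `"proportional"`.
#' @return data frame with one row per chromosome: `chrom`, `observed`,
#'   `expected`, `chi2`, `p_value`, `direction` ("over"/"under"/"none"),
#'   `testable`.
#' @export
chrom_bias_chi2 <- function(class_genes, annotation,
                            method = c("two_by_two", "proportional")) {
  method <- match.arg(method)
  if (!all(class_genes %in% annotation$gene_id)) {
    abort("class genes must be annotated")
  }
  chroms <- unique(as.character(annotation$chrom))
  if (length(chroms) < 2) abort("need >= 2 chromosomes")
  total_per_chrom <- table(factor(as.character(annotation$chrom),
                                  levels = chroms))
  in_class <- annotation$gene_id %in% class_genes
  class_per_chrom <- table(factor(as.character(annotation$chrom[in_class]),
                                  levels = chroms))
  n_class <- sum(in_class)
  n_total <- nrow(annotation)

  res <- lapply(chroms, function(ch) {
    o_class <- as.numeric(class_per_chrom[[ch]])
    t_chrom <- as.numeric(total_per_chrom[[ch]])
    e_class <- n_class * t_chrom / n_total
    if (method == "two_by_two") {
      obs <- c(o_class, n_class - o_class,
               t_chrom - o_class, (n_total - t_chrom) - (n_class - o_class))
      exp_ <- c(
        e_class, n_class - e_class,
        t_chrom - e_class, (n_total - t_chrom) - (n_class - e_class)
      )
    } else {
      obs <- c(o_class, n_class - o_class)
      exp_ <- c(e_class, n_class - e_class)
    }
    if (any(exp_ <= 0)) {
      return(data.frame(chrom = ch, observed = o_class, expected = e_class,
                        chi2 = NA_real_, p_value = NA_real_,
                        direction = "none", testable = FALSE,
                        stringsAsFactors = FALSE))
    }
    dev <- pmax(abs(obs - exp_) - 0.5, 0)
    chi2 <- sum(dev^2 / exp_)
    data.frame(
      chrom = ch, observed = o_class, expected = e_class, chi2 = chi2,
      p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
      direction = if (o_class > e_class) "over"
                  else if (o_class < e_class) "under" else "none",
      testable = TRUE, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

#' Sliding-window enrichment of a gene class along chromosomes
#'
#' Windows of `window` bp advance by `step` bp from position 0 while the
#' window start is inside the chromosome (terminal windows are truncated
#' and flagged). A gene belongs to a window iff its midpoint falls in
#' `[start, end)`. Enrichment is the window's class fraction divided by the
#' genome-wide class fraction; windows holding fewer than `min_genes` genes
#' are set to `NA`.
#'
#' @param class_genes character vector of gene ids.
#' @param annotation annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`), 0-based half-open.
#' @param genome data frame with `name` and `length` per chromosome.
#' @param window,step window width and step in bp (defaults 2.5 Mb /
#'   500 kb).
#' @param min_genes minimum genes per window for a defined ratio
#'   (default 10).
#' @return data frame per window: `chrom`, `start`, `end`, `truncated`,
#'   `n_genes`, `n_class`, `enrichment`.
#' @export
sliding_window_enrichment <- function(class_genes, annotation, genome,
                                      window = 2.5e6, step = 5e5,
                                      min_genes = 10) {
  if (window <= 0) abort("'window' must be > 0")
  if (step <= 0) abort("'step' must be > 0")
  if (!all(class_genes %in% annotation$gene_id)) {
    abort("class genes must be annotated")
  }
  class_frac <- length(unique(class_genes)) / nrow(annotation)
  mid <- (annotation$start + annotation$end) / 2
  in_class <- annotation$gene_id %in% class_genes

  tracks <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$name[i]; len <- genome$length[i]
    starts <- seq(0, len - 1e-9, by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    on_ch <- as.character(annotation$chrom) == ch
    m <- mid[on_ch]; cl <- in_class[on_ch]
    n_genes <- n_class <- integer(length(starts))
    for (w in seq_along(starts)) {
      hit <- m >= starts[w] & m < ends[w]
      n_genes[w] <- sum(hit)
      n_class[w] <- sum(cl[hit])
    }
    enr <- ifelse(
      n_genes >= min_genes & class_frac > 0,
      (n_class / pmax(n_genes, 1L)) / class_frac,
      NA_real_
    )
    data.frame(chrom = ch, start = starts, end = ends,
               truncated = (starts + window) > len,
               n_genes = n_genes, n_class = n_class, enrichment = enr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, tracks)
}

# Fast cluster counting used by the permutation null: returns
# c(n_clusters, n_clustered) without materializing member lists.
glc_counts <- function(flags, chrom_id, min_size, max_gap) {
  idx <- which(flags)
  if (length(idx) == 0L) return(c(0L, 0L))
  new_cluster <- c(TRUE,
                   diff(idx) - 1L > max_gap | diff(chrom_id[idx]) != 0L)
  grp <- cumsum(new_cluster)
  sizes <- tabulate(grp)
  keep <- sizes >= min_size
  c(sum(keep), sum(sizes[keep]))
}

#' Maximal co-localization clusters of attribute genes (GLC)
#'
#' Within each chromosome (genes in positional order), a cluster is a
#' maximal run of attribute-flagged genes in which consecutive attribute
#' genes are separated by at most `max_gap` non-attribute genes, containing
#' at least `min_size` attribute genes. Cluster size counts attribute genes
#' only; gap genes are not members.
#'
#' @param flags logical vector of attribute flags aligned to the
#'   annotation's gene order (sorted by chromosome, then start).
#' @param annotation annotation data frame in the same order.
#' @param min_size minimum attribute genes per cluster (default 3).
#' @param max_gap maximum intervening non-attribute genes (default 1; at
#'   attribute densities near 0.2 this keeps the randomized gene-order
#'   null sparse enough that both the cluster count and the clustered-gene
#'   count of a genuinely clustered set exceed their nulls).
#' @return object of class `cluster_set`: list with `clusters` (data frame
#'   `cluster_id`, `chrom`, `span_start`, `span_end`, `size`, `members`
#'   list-column), `n_clusters`, `n_clustered`, `n_attribute`,
#'   `fraction_clustered`, and the parameters.
#' @export
glc_cluster <- function(flags, annotation, min_size = 3, max_gap = 1) {
  if (length(flags) != nrow(annotation)) {
    abort("flags must align with the annotation (length mismatch)")
  }
  flags <- as.logical(flags)
  chrom_id <- as.integer(factor(as.character(annotation$chrom),
                                levels = unique(as.character(annotation$chrom))))
  idx <- which(flags)
  clusters <- data.frame(cluster_id = integer(0), chrom = character(0),
                         span_start = numeric(0), span_end = numeric(0),
                         size = integer(0), stringsAsFactors = FALSE)
  members <- list()
  if (length(idx) > 0L) {
    new_cluster <- c(TRUE,
                     diff(idx) - 1L > max_gap | diff(chrom_id[idx]) != 0L)
    grp <- cumsum(new_cluster)
    runs <- split(idx, grp)
    runs <- runs[lengths(runs) >= min_size]
    if (length(runs) > 0L) {
      clusters <- data.frame(
        cluster_id = seq_along(runs),
        chrom = vapply(runs, function(r)
          as.character(annotation$chrom[r[1]]), character(1)),
        span_start = vapply(runs, function(r)
          annotation$start[r[1]], numeric(1)),
        span_end = vapply(runs, function(r)
          annotation$end[r[length(r)]], numeric(1)),
        size = lengths(runs),
        stringsAsFactors = FALSE
      )
      members <- lapply(runs, function(r) annotation$gene_id[r])
    }
  }
  n_attr <- sum(flags)
  structure(
    list(
      clusters = clusters,
      members = unname(members),
      n_clusters = nrow(clusters),
      n_clustered = sum(clusters$size),
      n_attribute = n_attr,
      fraction_clustered = if (n_attr > 0) sum(clusters$size) / n_attr
                           else NaN,
      min_size = min_size, max_gap = max_gap
    ),
    class = "cluster_set"
  )
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Co-localization clusters (min_size =", x$min_size,
      ", max_gap =", x$max_gap, ")\n")
  cat("  clusters:       ", x$n_clusters, "\n")
  cat("  clustered genes:", x$n_clustered, "of", x$n_attribute,
      sprintf("(%.0f%%)\n", 100 * x$fraction_clustered))
  if (x$n_clusters > 0) {
    cat("  size range:     ", min(x$clusters$size), "-",
        max(x$clusters$size), "\n")
  }
  if (!is.null(x$null)) {
    cat(sprintf("  fold vs null:    clusters %.2fx (p %s), genes %.2fx (p %s)\n",
                x$null$fold_n_clusters, x$null$p_string_n_clusters,
                x$null$fold_n_clustered, x$null$p_string_n_clustered))
  }
  invisible(x)
}

#' Randomized gene-order null for co-localization clustering
#'
#' Repeats [glc_cluster()] on `S` uniform permutations of the attribute
#' flags over gene positions (chromosome sizes and gene order preserved)
#' and reports fold enrichment and empirical p-values for the number of
#' clusters and the number of clustered attribute genes.
#'
#' @param attribute_genes character vector of attribute gene ids.
#' @param annotation annotation data frame sorted by (chrom, start).
#' @inheritParams glc_cluster
#' @param S number of permutations (default 10000).
#' @param seed integer seed.
#' @return a `cluster_set` (observed clustering) with an additional `null`
#'   element: null means/sds, folds, empirical p-values and p-strings for
#'   both statistics, plus `S` and `seed`.
#' @export
cluster_null <- function(attribute_genes, annotation, min_size = 3,
                         max_gap = 1, S = 10000, seed = 1) {
  if (S < 1) abort("'S' must be >= 1")
  flags <- annotation$gene_id %in% attribute_genes
  obs <- glc_cluster(flags, annotation, min_size, max_gap)
  chrom_id <- as.integer(factor(as.character(annotation$chrom),
                                levels = unique(as.character(annotation$chrom))))
  n <- length(flags)
  set.seed(seed)
  sim <- matrix(0L, nrow = S, ncol = 2)
  for (s in seq_len(S)) {
    sim[s, ] <- glc_counts(flags[sample.int(n)], chrom_id, min_size, max_gap)
  }
  mk <- function(obs_val, col) {
    mu <- mean(sim[, col]); sdv <- stats::sd(sim[, col])
    exceed <- sum(sim[, col] >= obs_val)
    list(
      mean = mu, sd = sdv,
      fold = if (mu > 0) obs_val / mu else NaN,
      p_value = exceed / S,
      p_string = if (exceed == 0) {
        paste0("< ", format(1 / S, scientific = TRUE, digits = 3))
      } else {
        format(exceed / S, digits = 4)
      }
    )
  }
  ncl <- mk(obs$n_clusters, 1)
  ngn <- mk(obs$n_clustered, 2)
  obs$null <- list(
    null_mean_n_clusters = ncl$mean, null_sd_n_clusters = ncl$sd,
    fold_n_clusters = ncl$fold, p_n_clusters = ncl$p_value,
    p_string_n_clusters = ncl$p_string,
    null_mean_n_clustered = ngn$mean, null_sd_n_clustered = ngn$sd,
    fold_n_clustered = ngn$fold, p_n_clustered = ngn$p_value,
    p_string_n_clustered = ngn$p_string,
    S = S, seed = seed
  )
  obs
}

#' Operon membership of a gene set
#'
#' @param gene_set character vector of gene ids.
#' @param operon_table data frame with columns `operon_id`, `gene_id`.
#' @return list with `count` (members of the set found in operons) and
#'   `percent` (via [percentage_report()]; errors on an empty set).
#' @export
operon_membership <- function(gene_set, operon_table) {
  gene_set <- unique(gene_set)
  count <- sum(gene_set %in% operon_table$gene_id)
  list(count = count,
       percent = percentage_report(count, length(gene_set)))
}

#' Quadrant classification of operons from member-gene fold changes
#'
#' Each operon's per-condition fold change is the mean of its quantified
#' members' log2 fold changes; the operon is then assigned a quadrant with
#' [classify_quadrant()] (a mean of exactly 0 in either condition gives
#' BOUNDARY). Operons with no member present in both DE tables are skipped
#' and counted.
#'
#' @param operon_table data frame with `operon_id`, `gene_id`.
#' @param de_phe,de_stv DE tables (`gene_id`, `log2fc`).
#' @return list with `operons` (data frame `operon_id`, `n_members`,
#'   `n_quantified`, `mean_phe`, `mean_stv`, `quadrant`), `tally` (named
#'   quadrant counts), `n_skipped`.
#' @export
operon_quadrant_classify <- function(operon_table, de_phe, de_stv) {
  universe <- intersect(de_phe$gene_id, de_stv$gene_id)
  fc_phe <- de_phe$log2fc[match(universe, de_phe$gene_id)]
  fc_stv <- de_stv$log2fc[match(universe, de_stv$gene_id)]
  names(fc_phe) <- names(fc_stv) <- universe

  ops <- split(operon_table$gene_id, operon_table$operon_id)
  rows <- lapply(names(ops), function(op) {
    genes <- ops[[op]]
    quant <- genes[genes %in% universe]
    if (length(quant) == 0L) {
      return(data.frame(operon_id = op, n_members = length(genes),
                        n_quantified = 0L, mean_phe = NA_real_,
                        mean_stv = NA_real_, quadrant = NA_character_,
                        stringsAsFactors = FALSE))
    }
    mp <- mean(fc_phe[quant]); ms <- mean(fc_stv[quant])
    data.frame(operon_id = op, n_members = length(genes),
               n_quantified = length(quant), mean_phe = mp, mean_stv = ms,
               quadrant = classify_quadrant(mp, ms),
               stringsAsFactors = FALSE)
  })
  operons <- do.call(rbind, rows)
  skipped <- sum(is.na(operons$quadrant))
  if (skipped > 0) {
    message(skipped, " operon(s) without quantified members skipped")
  }
  tally <- table(factor(operons$quadrant,
                        levels = c("Q1", "Q2", "Q3", "Q4", "BOUNDARY")))
  list(operons = operons, tally = c(tally), n_skipped = skipped)
}
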