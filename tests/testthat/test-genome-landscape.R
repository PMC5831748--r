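# Chromosome bias, sliding windows, GLC clustering, operons.

test_that("Yates chi-squared matches hand arithmetic and chisq.test", {
  ann <- toy_annotation(c(100, 100))
  class_genes <- c(ann$gene_id[1:30], ann$gene_id[101:110])
  res <- chrom_bias_chi2(class_genes, ann)
  # chromosome I table: [[30, 10], [70, 90]] -> E = 20/20/80/80
  expect_equal(res$chi2[res$chrom == "I"], 11.281, tolerance = 1e-3)
  ref <- chisq.test(matrix(c(30, 10, 70, 90), 2), correct = TRUE)
  expect_equal(res$chi2[res$chrom == "I"], unname(ref$statistic),
               tolerance = 1e-9)
  expect_equal(res$p_value[res$chrom == "I"], ref$p.value,
               tolerance = 1e-9)
  expect_identical(res$direction[res$chrom == "I"], "over")
})

test_that("proportionally distributed classes give zero chi-squared", {
  ann <- toy_annotation(c(100, 100))
  class_genes <- c(ann$gene_id[1:20], ann$gene_id[101:120])
  res <- chrom_bias_chi2(class_genes, ann)
  expect_true(all(res$chi2 == 0))
})

test_that("a class planted on one chromosome is flagged strongly over-represented", {
  ann <- toy_annotation(c(200, 200))
  res <- chrom_bias_chi2(ann$gene_id[1:60], ann)
  expect_identical(res$direction[res$chrom == "I"], "over")
  expect_lt(res$p_value[res$chrom == "I"], 1e-6)
})

test_that("sliding windows count midpoints and normalize by the class fraction", {
  # 10 genes on a 5 Mb chromosome: class at 0.2-1.8 Mb, others at
  # 2.6-4.2 Mb; class fraction 0.5
  start <- c(seq(0.2e6, 1.8e6, length.out = 5),
             seq(2.6e6, 4.2e6, length.out = 5)) - 500
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:10), chrom = "I",
    start = start, end = start + 1000, strand = "+",
    operon_id = NA_character_, stringsAsFactors = FALSE
  )
  ann$chrom <- factor(ann$chrom)
  genome <- data.frame(name = "I", length = 5e6)
  tr <- sliding_window_enrichment(ann$gene_id[1:5], ann, genome,
                                  window = 2.5e6, step = 2.5e6,
                                  min_genes = 1)
  expect_equal(tr$enrichment[1], 2.0)
  expect_equal(tr$enrichment[2], 0.0)
})

test_that("class = all genes gives enrichment exactly 1 in non-NA windows", {
  st <- simulate_study(small_config(n_genes = 500), include_counts = FALSE)
  tr <- sliding_window_enrichment(st$annotation$gene_id, st$annotation,
                                  st$genome, window = 2e6, step = 1e6,
                                  min_genes = 1)
  vals <- tr$enrichment[!is.na(tr$enrichment)]
  expect_true(all(vals == 1))
})

test_that("sparse windows are NA, never an error", {
  ann <- toy_annotation(c(5, 5))
  genome <- data.frame(name = c("I", "II"), length = c(1e6, 1e6))
  tr <- sliding_window_enrichment(ann$gene_id[1:2], ann, genome,
                                  window = 1e5, step = 1e5, min_genes = 3)
  expect_true(anyNA(tr$enrichment))
  # every gene midpoint is covered when window >= step
  expect_gte(sum(tr$n_genes), nrow(ann))
})

test_that("glc_cluster resolves the worked flag examples", {
  ann <- toy_annotation(9, chroms = "I")
  flags <- c(1, 1, 0, 1, 0, 0, 1, 1, 1) == 1
  cs1 <- glc_cluster(flags, ann, min_size = 3, max_gap = 1)
  expect_equal(cs1$n_clusters, 2)
  expect_identical(cs1$members[[1]], ann$gene_id[c(1, 2, 4)])
  expect_identical(cs1$members[[2]], ann$gene_id[c(7, 8, 9)])
  cs0 <- glc_cluster(flags, ann, min_size = 3, max_gap = 0)
  expect_equal(cs0$n_clusters, 1)
  expect_identical(cs0$members[[1]], ann$gene_id[7:9])
  expect_equal(glc_cluster(rep(FALSE, 9), ann)$n_clusters, 0)
  expect_error(glc_cluster(flags[1:5], ann), "length")
})

test_that("clusters never span chromosomes", {
  ann <- toy_annotation(c(3, 3))
  cs <- glc_cluster(rep(TRUE, 6), ann, min_size = 3, max_gap = 2)
  expect_equal(cs$n_clusters, 2)
  expect_identical(unique(cs$clusters$chrom), c("I", "II"))
})

test_that("glc_cluster equals the brute-force maximal-run oracle", {
  set.seed(71)
  for (i in 1:500) {
    n <- sample(10:200, 1)
    flags <- runif(n) < runif(1, 0.1, 0.6)
    chrom <- sort(sample(c("I", "II"), n, replace = TRUE))
    ann <- data.frame(
      gene_id = sprintf("g%03d", 1:n), chrom = factor(chrom),
      start = ave(seq_len(n), chrom, FUN = function(z)
        seq(0, by = 2000, length.out = length(z))),
      end = 1000, strand = "+", operon_id = NA_character_,
      stringsAsFactors = FALSE
    )
    ann$end <- ann$start + 1000
    min_size <- sample(2:4, 1)
    max_gap <- sample(0:2, 1)
    got <- glc_cluster(flags, ann, min_size, max_gap)
    want <- glc_brute(flags, chrom, min_size, max_gap)
    expect_equal(got$n_clusters, length(want))
    expect_equal(got$n_clustered, sum(lengths(want)))
    if (length(want) > 0) {
      expect_identical(lapply(got$members, function(g)
        match(g, ann$gene_id)), unname(want))
    }
    # maximality: flanking attribute genes violate max_gap
    for (cl in want) {
      pos_all <- which(flags & chrom == chrom[cl[1]])
      before <- pos_all[pos_all < min(cl)]
      after <- pos_all[pos_all > max(cl)]
      if (length(before)) {
        expect_gt(min(cl) - max(before) - 1, max_gap)
      }
      if (length(after)) {
        expect_gt(min(after) - max(cl) - 1, max_gap)
      }
    }
  }
})

test_that("cluster_null: attribute = all genes gives fold exactly 1", {
  ann <- toy_annotation(c(20, 20))
  cs <- cluster_null(ann$gene_id, ann, S = 20, seed = 2)
  expect_equal(cs$null$fold_n_clusters, 1)
  expect_equal(cs$null$fold_n_clustered, 1)
})

test_that("planted runs of 5 with no gaps are recovered and beat the null", {
  cfg <- small_config(
    attribute_fraction = 0.15,
    attribute_cluster_sizes = 5,
    attribute_cluster_size_probs = 1,
    attribute_cluster_gap = 0,
    attribute_scatter_fraction = 0
  )
  st <- simulate_study(cfg, include_counts = FALSE)
  flags <- st$truth$attribute
  cs <- glc_cluster(flags, st$annotation, min_size = 3, max_gap = 0)
  # >= 95% of planted attribute genes fall into recovered clusters
  recovered <- unlist(cs$members)
  expect_gte(length(intersect(recovered, st$attribute_genes)) /
               length(st$attribute_genes), 0.95)
  null <- cluster_null(st$attribute_genes, st$annotation, min_size = 3,
                       max_gap = 0, S = 200, seed = 5)
  expect_gt(null$null$fold_n_clusters, 1)
  expect_gt(null$null$fold_n_clustered, 1)
  expect_equal(null$null$p_n_clusters, 0)
  expect_equal(null$null$p_n_clustered, 0)
})

test_that("random attribute sets sit within the cluster null", {
  set.seed(81)
  ann <- toy_annotation(c(300, 300))
  attr_set <- sample(ann$gene_id, 120)
  cs <- cluster_null(attr_set, ann, S = 400, seed = 6)
  z <- (cs$n_clusters - cs$null$null_mean_n_clusters) /
    max(cs$null$null_sd_n_clusters, 1e-9)
  expect_lt(abs(z), 4)
})

test_that("operon membership counts and percentage", {
  op <- data.frame(operon_id = c("op1", "op1", "op2", "op2"),
                   gene_id = c("a", "b", "c", "d"), rank = c(1, 2, 1, 2),
                   stringsAsFactors = FALSE)
  res <- operon_membership(c("a", "b", "x", "y"), op)
  expect_equal(res$count, 2)
  expect_equal(res$percent, 50)
  expect_equal(operon_membership(c("91in", "x"), op)$count, 0)
})

test_that("operon quadrants use member-mean fold changes", {
  op <- data.frame(operon_id = c("op1", "op1", "op2", "op2"),
                   gene_id = c("a", "b", "c", "d"), rank = c(1, 2, 1, 2),
                   stringsAsFactors = FALSE)
  de_phe <- toy_de(c("a", "b", "c", "d"), c(1.0, 0.5, 1, -1))
  de_stv <- toy_de(c("a", "b", "c", "d"), c(-1.0, -0.2, 2, -2))
  res <- operon_quadrant_classify(op, de_phe, de_stv)
  expect_identical(res$operons$quadrant[res$operons$operon_id == "op1"],
                   "Q1")
  expect_identical(res$operons$quadrant[res$operons$operon_id == "op2"],
                   "BOUNDARY")
  expect_equal(unname(res$tally[["Q1"]]), 1)
})

test_that("operon tally matches a brute-force per-operon recomputation", {
  st <- simulate_study(small_config(n_genes = 1000), include_counts = FALSE)
  res <- operon_quadrant_classify(st$operon_table, st$de$phe, st$de$stv)
  ops <- split(st$operon_table$gene_id, st$operon_table$operon_id)
  brute <- vapply(ops, function(genes) {
    mp <- mean(st$de$phe$log2fc[match(genes, st$de$phe$gene_id)])
    ms <- mean(st$de$stv$log2fc[match(genes, st$de$stv$gene_id)])
    classify_quadrant(mp, ms)
  }, character(1))
  expect_equal(unname(res$tally),
               unname(c(table(factor(brute,
                 levels = c("Q1", "Q2", "Q3", "Q4", "BOUNDARY"))))))
})
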