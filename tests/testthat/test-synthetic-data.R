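# Generator: determinism, planted fractions, placement bias, DE model.

test_that("identical config and seed give identical artifacts", {
  cfg <- small_config(n_genes = 600)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  expect_identical(a$de, b$de)
  expect_identical(a$counts$counts, b$counts$counts)
})

test_that("different master seeds change the layout", {
  a <- simulate_study(small_config(n_genes = 300, seed = 1),
                      include_counts = FALSE)
  b <- simulate_study(small_config(n_genes = 300, seed = 2),
                      include_counts = FALSE)
  expect_false(identical(a$annotation$start, b$annotation$start))
})

test_that("annotation is sorted, non-overlapping, and inside chromosomes", {
  st <- simulate_study(small_config(), include_counts = FALSE)
  ann <- st$annotation
  for (ch in levels(ann$chrom)) {
    sub <- ann[ann$chrom == ch, ]
    expect_true(all(diff(sub$start) > 0))
    expect_true(all(sub$end[-nrow(sub)] <= sub$start[-1]))
    expect_true(all(sub$start >= 0))
    expect_true(all(sub$end <= st$genome$length[st$genome$name == ch]))
  }
  expect_false(anyDuplicated(ann$gene_id) > 0)
})

test_that("infeasible packing raises an explicit error", {
  cfg <- generator_config(
    n_genes = 200, seed = 1,
    genome = data.frame(name = "I", length = 1e5),
    class_chromosome_weights = list(),
    attribute_chromosome_weights = NULL
  )
  expect_error(generate_genome(cfg), "infeasible packing")
})

test_that("planted class fractions land within binomial tolerance", {
  cfg <- small_config(n_genes = 2000)
  st <- simulate_study(cfg, include_counts = FALSE)
  tab <- table(st$truth$class)
  n_seesaw <- sum(tab[c("seesaw_up_down", "seesaw_down_up")])
  f <- cfg$seesaw_fraction_significant
  expect_lt(abs(n_seesaw / 2000 - f), 3 * sqrt(f * (1 - f) / 2000) + 1e-3)
})

test_that("no central bias leaves every class uniform along chromosomes", {
  cfg <- small_config(n_genes = 5000, central_concentration = 0)
  st <- simulate_study(cfg, include_counts = FALSE)
  mid <- (st$annotation$start + st$annotation$end) / 2
  rel <- mid / st$genome$length[match(as.character(st$annotation$chrom),
                                      st$genome$name)]
  for (cl in unique(st$truth$class)) {
    m <- mean(rel[st$truth$class == cl])
    expect_gt(m, 0.43)
    expect_lt(m, 0.57)
  }
})

test_that("central concentration pulls planted seesaw genes toward centers", {
  cfg <- small_config(n_genes = 5000, central_concentration = 0.9,
                      seesaw_fraction_significant = 0.1)
  st <- simulate_study(cfg, include_counts = FALSE)
  mid <- (st$annotation$start + st$annotation$end) / 2
  rel <- mid / st$genome$length[match(as.character(st$annotation$chrom),
                                      st$genome$name)]
  d <- abs(rel - 0.5)
  d_class <- d[st$truth$class == "seesaw_up_down"]
  d_null <- d[st$truth$class == "null"]
  expect_lt(mean(d_class), mean(d_null))
  # rank-test oracle on the distance-to-center distributions
  w <- wilcox.test(d_class, d_null, alternative = "less")
  expect_lt(w$p.value, 1e-6)
})

test_that("operons are consecutive same-strand runs at the configured fraction", {
  cfg <- small_config(n_genes = 2000, operon_fraction = 0.15,
                      operon_sizes = 2:3, operon_size_probs = c(0.6, 0.4))
  st <- simulate_study(cfg, include_counts = FALSE)
  ann <- st$annotation
  frac <- mean(!is.na(ann$operon_id))
  expect_gte(frac, 0.12)
  expect_lte(frac, 0.18)
  idx_by_op <- split(seq_len(nrow(ann)), ann$operon_id)
  for (run in idx_by_op) {
    expect_true(all(diff(run) == 1))           # consecutive in gene order
    expect_length(unique(as.character(ann$chrom[run])), 1)
    expect_length(unique(ann$strand[run]), 1)  # shared strand
    expect_gte(length(run), 2)
  }
})

test_that("operon_fraction 0 leaves all operon ids missing", {
  st <- simulate_study(small_config(n_genes = 300, operon_fraction = 0),
                       include_counts = FALSE)
  expect_true(all(is.na(st$annotation$operon_id)))
  expect_equal(nrow(st$operon_table), 0)
})

test_that("attribute fraction and uniform-weight spread behave binomially", {
  cfg <- small_config(n_genes = 2000, attribute_fraction = 0.2,
                      attribute_chromosome_weights = NULL)
  st <- simulate_study(cfg, include_counts = FALSE)
  expect_equal(length(st$attribute_genes) / 2000, 0.2, tolerance = 0.01)
  per <- tapply(st$truth$attribute, st$annotation$chrom, mean)
  n_per <- table(st$annotation$chrom)
  for (ch in names(per)) {
    tol <- 3 * sqrt(0.2 * 0.8 / n_per[[ch]])
    expect_lt(abs(per[[ch]] - 0.2), tol + 0.02)
  }
})

test_that("attribute_fraction 1 flags every gene", {
  st <- simulate_study(small_config(n_genes = 300, attribute_fraction = 1),
                       include_counts = FALSE)
  expect_setequal(st$attribute_genes, st$annotation$gene_id)
})

test_that("planted seesaw genes have deterministic sign structure", {
  st <- simulate_study(small_config(n_genes = 2000),
                       include_counts = FALSE)
  up_down <- st$truth$class == "seesaw_up_down"
  down_up <- st$truth$class == "seesaw_down_up"
  expect_true(all(st$de$phe$log2fc[up_down] > 0))
  expect_true(all(st$de$stv$log2fc[up_down] < 0))
  expect_true(all(st$de$phe$log2fc[down_up] < 0))
  expect_true(all(st$de$stv$log2fc[down_up] > 0))
})

test_that("p-value model: p = 1 at log2fc = 0 and monotone in |fc|", {
  # the DE p-value model is a two-sided normal tail in |log2fc|/noise_sd
  expect_equal(2 * pnorm(-abs(0) / 0.3), 1)
  st <- simulate_study(small_config(n_genes = 500), include_counts = FALSE)
  de <- st$de$phe
  expect_equal(de$pvalue,
               2 * pnorm(-abs(de$log2fc) / st$config$noise_sd),
               tolerance = 1e-12)
  expect_error(
    generate_de_tables(st$truth, small_config(noise_sd = -1)),
    "noise_sd"
  )
})

test_that("with no planted seesaw genes the caller stays at chance level", {
  cfg <- generator_config(n_genes = 10000, seed = 42,
                          seesaw_fraction_significant = 0,
                          concordant_fraction = 0)
  st <- simulate_study(cfg, include_counts = FALSE)
  calls <- call_significant_seesaw(st$de$phe, st$de$stv, alpha = 0.05)
  # null p-values are uniform; BH at 5% controls false positives near zero,
  # bounded by the analytic expectation of chance double-significance
  n_sig_phe <- sum(st$de$phe$fdr < 0.05)
  n_sig_stv <- sum(st$de$stv$fdr < 0.05)
  bound <- hypergeometric_expected(max(n_sig_phe, 1), max(n_sig_stv, 1),
                                   10000)
  expect_lte(length(calls$up_down),
             bound[["mean"]] + 3 * sqrt(bound[["variance"]]) + 1)
  expect_lte(length(calls$down_up),
             bound[["mean"]] + 3 * sqrt(bound[["variance"]]) + 1)
})

test_that("near-zero dispersion gives near-perfect replicate correlation", {
  cfg <- small_config(n_genes = 5000, dispersion = 0)
  st <- simulate_study(cfg)
  r <- replicate_pearson(st$counts$counts[, "wt_rep1"],
                         st$counts$counts[, "wt_rep2"],
                         transform = "raw")$r
  expect_gte(r, 0.99)
})

test_that("germline ablation is recovered by the enrichment classifier", {
  cfg <- small_config(n_genes = 3000, dispersion = 0.02,
                      germline_ablation_scale = 0.2)
  st <- simulate_study(cfg)
  fpkm_wt <- rowMeans(st$counts$fpkm[, c("wt_rep1", "wt_rep2")])
  fpkm_ab <- rowMeans(st$counts$fpkm[, c("ablated_rep1", "ablated_rep2")])
  names(fpkm_wt) <- names(fpkm_ab) <- st$truth$gene_id
  calls <- germline_enrichment_classify(fpkm_wt, fpkm_ab)
  germline <- st$truth$gene_id[st$truth$germline]
  called <- calls$calls$gene_id[calls$calls$label == "germline_enriched"]
  determined <- calls$calls$gene_id[calls$calls$label != "undetermined"]
  recov <- length(intersect(called, germline)) /
    length(intersect(germline, determined))
  expect_gte(recov, 0.95)
  expect_error(
    generate_count_matrix(st$truth, st$annotation,
                          small_config(n_samples = 1)),
    "n_samples"
  )
})
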