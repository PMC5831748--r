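# End-to-end orchestration: config validation, staged execution, report.

#' Build and validate a pipeline configuration
#'
#' A configuration names the input files and all stage parameters. It can
#' be supplied as a YAML file or built directly. Mandatory inputs:
#' annotation, both DE tables. Optional: attribute gene list, operon
#' table, count matrix (their stages are skipped when absent).
#'
#' @param annotation,de_phe,de_stv paths to the annotation (GFF3/BED6) and
#'   the two DE tables.
#' @param genome optional path to a chromosome-length TSV (`name`,
#'   `length`); when absent, chromosome spans are taken from the furthest
#'   annotated gene end.
#' @param attribute,operons,counts optional paths (gene list, operon TSV,
#'   counts TSV with `gene_id` first column).
#' @param out_dir output directory.
#' @param alpha FDR cutoff; `min_fold` trend threshold; `window`, `step`,
#'   `min_genes` sliding-window settings; `min_size`, `max_gap` cluster
#'   settings; `S` simulation count; `ratio_threshold`, `pseudocount`
#'   germline-call settings; `seed` master seed.
#' @param alpha,min_fold,window,step,min_genes,min_size,max_gap,S,ratio_threshold,pseudocount,seed
#'   stage parameters (see above).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation, de_phe, de_stv, genome = NULL,
                            attribute = NULL, operons = NULL,
                            counts = NULL, out_dir = "seesaw-results",
                            alpha = 0.05, min_fold = 2, window = 2.5e6,
                            step = 5e5, min_genes = 10, min_size = 3,
                            max_gap = 1, S = 10000,
                            ratio_threshold = 0.5, pseudocount = 0.1,
                            seed = 1) {
  for (p in c(annotation, de_phe, de_stv, genome, attribute, operons,
              counts)) {
    if (!is.null(p) && !file.exists(p)) abort("file not found: ", p)
  }
  check_probability(alpha, "alpha")
  if (min_fold <= 1) abort("'min_fold' must be > 1")
  if (window <= 0 || step <= 0) abort("window and step must be > 0")
  if (S < 1) abort("'S' must be >= 1")
  cfg <- as.list(environment())
  cfg$p <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

genome_from_annotation <- function(annotation) {
  spans <- tapply(annotation$end, annotation$chrom, max)
  data.frame(name = names(spans), length = as.numeric(spans),
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: seesaw calling (significant + trend + quadrants),
#' overlap enrichment of the two directional DE sets, genome landscape
#' (per-chromosome bias for each quadrant class and the attribute set,
#' sliding windows for the trend sets, attribute clustering with
#' randomized gene-order null), operon analysis, and expression QC.
#' Optional stages without inputs are skipped with a message.
#'
#' @param config a `pipeline_config` or path to a YAML config.
#' @param write write result files to `config$out_dir` (default TRUE).
#' @return list of stage outputs plus `report` (see [make_report()]),
#'   invisibly when `write = TRUE`.
#' @export
run_pipeline <- function(config, write = TRUE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  ann <- read_annotation(config$annotation)
  genome <- if (!is.null(config$genome)) {
    g <- utils::read.delim(config$genome, stringsAsFactors = FALSE)
    g[, c("name", "length")]
  } else {
    genome_from_annotation(ann)
  }
  de_phe <- read_de_table(config$de_phe, condition = "Phe")
  de_stv <- read_de_table(config$de_stv, condition = "Stv")

  # --- seesaw stage (deterministic, untouched by the master seed)
  calls <- call_significant_seesaw(de_phe, de_stv, alpha = config$alpha)
  trend <- trend_seesaw(de_phe, de_stv, min_fold = config$min_fold)
  seed_log <- list()

  # --- overlap stage: directional DE sets vs each other
  sig_phe_up <- with_de_sets(de_phe, config$alpha, "up")
  sig_phe_down <- with_de_sets(de_phe, config$alpha, "down")
  sig_stv_up <- with_de_sets(de_stv, config$alpha, "up")
  sig_stv_down <- with_de_sets(de_stv, config$alpha, "down")
  ov_seed <- stage_seed(config$seed, "overlap")
  seed_log$overlap <- ov_seed
  universe <- calls$universe
  overlap_up_down <- overlap_enrichment(
    intersect(sig_phe_up, universe), intersect(sig_stv_down, universe),
    universe, S = config$S, seed = ov_seed
  )
  overlap_down_up <- overlap_enrichment(
    intersect(sig_phe_down, universe), intersect(sig_stv_up, universe),
    universe, S = config$S, seed = ov_seed
  )

  # --- landscape stage
  annotated_universe <- intersect(universe, ann$gene_id)
  quadrant_classes <- split(names(calls$quadrant), calls$quadrant)
  bias <- lapply(quadrant_classes[setdiff(names(quadrant_classes),
                                          "BOUNDARY")], function(genes) {
    chrom_bias_chi2(intersect(genes, ann$gene_id), ann)
  })
  windows_up_down <- sliding_window_enrichment(
    intersect(trend$up_down_trend, ann$gene_id), ann, genome,
    window = config$window, step = config$step,
    min_genes = config$min_genes
  )
  windows_down_up <- sliding_window_enrichment(
    intersect(trend$down_up_trend, ann$gene_id), ann, genome,
    window = config$window, step = config$step,
    min_genes = config$min_genes
  )

  clusters <- NULL
  attribute <- NULL
  if (!is.null(config$attribute)) {
    attribute <- read_gene_list(config$attribute)
    cl_seed <- stage_seed(config$seed, "cluster_null")
    seed_log$cluster_null <- cl_seed
    clusters <- cluster_null(attribute, ann,
                             min_size = config$min_size,
                             max_gap = config$max_gap,
                             S = config$S, seed = cl_seed)
    bias$attribute <- chrom_bias_chi2(intersect(attribute, ann$gene_id),
                                      ann)
  } else {
    message("no attribute list: clustering stage skipped")
  }

  # --- operon stage
  operons <- NULL
  if (!is.null(config$operons)) {
    operon_table <- read_operon_table(config$operons)
    seesaw_set <- c(calls$up_down, calls$down_up)
    membership <- if (length(seesaw_set) > 0) {
      operon_membership(seesaw_set, operon_table)
    } else {
      list(count = 0L, percent = NA_real_)
    }
    operons <- list(
      membership = membership,
      quadrants = operon_quadrant_classify(operon_table, de_phe, de_stv)
    )
  } else {
    message("no operon table: operon stage skipped")
  }

  # --- QC stage
  qc <- NULL
  if (!is.null(config$counts)) {
    cts <- utils::read.delim(config$counts, stringsAsFactors = FALSE)
    mat <- as.matrix(cts[, -1, drop = FALSE])
    rownames(mat) <- cts[[1]]
    if (ncol(mat) >= 2) {
      qc <- list(
        replicate_r = replicate_pearson(mat[, 1], mat[, 2]),
        pca = pc_significance(mat)
      )
    }
  } else {
    message("no count matrix: QC stage skipped")
  }

  stages <- list(
    config = config,
    annotation = ann,
    genome = genome,
    calls = calls,
    trend = trend,
    overlap = list(up_down = overlap_up_down, down_up = overlap_down_up),
    chrom_bias = bias,
    windows = list(up_down = windows_up_down, down_up = windows_down_up),
    clusters = clusters,
    operons = operons,
    qc = qc,
    seeds = seed_log
  )
  stages$report <- make_report(stages)

  if (write) {
    out <- list(
      quadrants = data.frame(gene_id = names(calls$quadrant),
                             quadrant = unname(calls$quadrant),
                             stringsAsFactors = FALSE),
      windows_up_down = windows_up_down,
      windows_down_up = windows_down_up,
      report = stages$report
    )
    if (!is.null(clusters)) out$clusters <- clusters$clusters
    for (nm in names(bias)) out[[paste0("bias_", nm)]] <- bias[[nm]]
    write_results(out, config$out_dir)
    write_gene_list(calls$up_down,
                    file.path(config$out_dir, "seesaw_up_down.txt"))
    write_gene_list(calls$down_up,
                    file.path(config$out_dir, "seesaw_down_up.txt"))
    return(invisible(stages))
  }
  stages
}

with_de_sets <- function(de, alpha, direction) {
  sel <- de$fdr < alpha &
    if (direction == "up") de$log2fc > 0 else de$log2fc < 0
  de$gene_id[sel]
}

#' Assemble the consolidated report
#'
#' Collects every stage's headline numbers into one summary list:
#' per-class seesaw counts and percentages, quadrant tallies with the
#' Q1+Q3 (inverse-trend) percentage, overlap folds with empirical
#' p-strings, cluster summary, operon tallies, and QC figures.
#'
#' @param stages stage output list from [run_pipeline()].
#' @return a named list (JSON-serializable).
#' @export
make_report <- function(stages) {
  calls <- stages$calls
  n_up <- length(calls$up_down)
  n_down <- length(calls$down_up)
  quad <- table(factor(calls$quadrant,
                       levels = c("Q1", "Q2", "Q3", "Q4", "BOUNDARY")))
  n_univ <- length(calls$universe)
  report <- list(
    universe_size = n_univ,
    seesaw = list(
      up_down = n_up,
      down_up = n_down,
      total = n_up + n_down,
      shared_up = length(calls$shared_up),
      shared_down = length(calls$shared_down),
      alpha = calls$alpha
    ),
    quadrants = as.list(quad),
    inverse_trend_percent = percentage_report(
      sum(quad[c("Q1", "Q3")]), max(n_univ, 1), 1
    ),
    overlap = lapply(stages$overlap, function(o) {
      list(k_obs = o$k_obs, null_mean = o$null_mean, fold = o$fold,
           p = o$p_string)
    })
  )
  if (!is.null(stages$clusters)) {
    cl <- stages$clusters
    sizes <- cl$clusters$size
    report$clusters <- list(
      n_clusters = cl$n_clusters,
      n_clustered = cl$n_clustered,
      percent_attribute_clustered =
        if (cl$n_attribute > 0)
          percentage_report(cl$n_clustered, cl$n_attribute) else NA,
      size_range = if (length(sizes)) range(sizes) else c(NA, NA),
      percent_size_3_to_10 = if (length(sizes))
        percentage_report(sum(sizes >= 3 & sizes <= 10),
                          length(sizes)) else NA,
      fold_n_clusters = cl$null$fold_n_clusters,
      p_n_clusters = cl$null$p_string_n_clusters,
      fold_n_clustered = cl$null$fold_n_clustered,
      p_n_clustered = cl$null$p_string_n_clustered
    )
  }
  if (!is.null(stages$operons)) {
    report$operons <- list(
      seesaw_in_operons = stages$operons$membership$count,
      seesaw_in_operons_percent = stages$operons$membership$percent,
      quadrant_tally = as.list(stages$operons$quadrants$tally)
    )
  }
  if (!is.null(stages$qc)) {
    report$qc <- list(
      replicate_r = stages$qc$replicate_r$r,
      pc1_share = stages$qc$pca$variance_share[1],
      significant_pcs_kaiser = sum(stages$qc$pca$kaiser_significant),
      significant_pcs_broken_stick =
        sum(stages$qc$pca$broken_stick_significant)
    )
  }
  report$seeds <- stages$seeds
  report
}
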