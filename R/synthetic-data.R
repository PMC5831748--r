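# Synthetic-data generator.
#
# Generates a C. elegans-like genome with planted response classes,
# attribute (CSR-1-target-like) gene clusters, operons, paired DE tables
# and replicate count matrices, together with a per-gene truth table, so
# every downstream statistic can be exercised against known ground truth.
#
# All randomness flows from a single master seed, fanned out to per-stage
# child seeds by stage_seed(); identical configs give byte-identical
# artifacts.

#' Generator configuration
#'
#' Builds and validates the configuration for the synthetic study. The
#' defaults emulate the study design the downstream statistics assume: a
#' ~100 Mb six-chromosome genome, 18,570 quantified genes, 500 planted
#' significant seesaw genes (half per orientation) with |log2FC| ~
#' N(1.5, 0.2) and a normal-tail p-value model with noise_sd = 0.3, a
#' genome-wide inverse-trend (Q1+Q3) share of 0.671 planted through the
#' null-gene fold-change correlation, a clustered attribute set covering
#' 4191/18570 of genes enriched on chromosomes I and III, and ~15% of
#' genes in operons of 2-4 genes.
#'
#' @param n_genes number of genes (>= 10).
#' @param seed master seed; all stages derive child seeds from it.
#' @param genome data frame with columns `name`, `length` (bp).
#' @param seesaw_fraction_significant fraction of genes planted as
#'   significant seesaw (split evenly between orientations).
#' @param concordant_fraction fraction planted as concordant (same-sign)
#'   responders, split evenly between up and down.
#' @param inverse_trend_fraction target genome-wide Q1+Q3 share among null
#'   genes, planted via the fold-change correlation
#'   `rho = -sin(pi * (f - 1/2))`.
#' @param effect_size_location,effect_size_scale mean and sd of planted
#'   |log2FC| (normal, truncated at 0).
#' @param noise_sd standard error in the p-value model
#'   `p = 2 * pnorm(-|log2fc| / noise_sd)`; also the sd of null-gene fold
#'   changes (making null p-values uniform).
#' @param central_concentration strength in \[0, 1) of placement bias of
#'   planted seesaw genes toward chromosome centers (Beta(a, a) relative
#'   midpoint with `a = 1 / (1 - c)`; 0 = uniform).
#' @param class_chromosome_weights named list mapping a planted class to a
#'   per-chromosome placement weight vector; classes absent from the list
#'   are placed proportionally to chromosome length.
#' @param attribute_fraction fraction of genes flagged as attribute
#'   targets.
#' @param attribute_cluster_sizes,attribute_cluster_size_probs support and
#'   probabilities of planted attribute-cluster sizes.
#' @param attribute_cluster_gap maximum intervening non-attribute genes
#'   inside a planted cluster (gaps drawn uniformly from 0..gap).
#' @param attribute_scatter_fraction fraction of attribute genes placed
#'   singly at random positions rather than in planted runs; keeps the
#'   clustered fraction near the ~3/4 seen in real target sets so that
#'   both clustering statistics exceed their gene-order nulls.
#' @param attribute_chromosome_weights per-chromosome weights for planted
#'   attribute clusters (`NULL` = proportional to gene counts).
#' @param operon_fraction fraction of genes inside operons.
#' @param operon_sizes,operon_size_probs operon size distribution
#'   (support >= 2).
#' @param gene_length_range uniform range of gene lengths in bp.
#' @param n_samples replicates per strain for count matrices (>= 2).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param germline_ablation_scale factor applied to germline-enriched gene
#'   means in the ablated-like strain.
#' @param count_meanlog,count_sdlog log-normal baseline expression
#'   parameters.
#' @return validated list of class `generator_config`.
#' @export
generator_config <- function(
    n_genes = 18570,
    seed = 1,
    genome = default_genome(),
    seesaw_fraction_significant = 500 / 18570,
    concordant_fraction = 0.01,
    inverse_trend_fraction = 0.671,
    effect_size_location = 1.5,
    effect_size_scale = 0.2,
    noise_sd = 0.3,
    central_concentration = 0.9,
    class_chromosome_weights = list(
      seesaw_up_down = c(I = 0.40, II = 0.03, III = 0.40,
                         IV = 0.03, V = 0.07, X = 0.07),
      seesaw_down_up = c(I = 0.05, II = 0.28, III = 0.05,
                         IV = 0.07, V = 0.30, X = 0.25)
    ),
    attribute_fraction = 4191 / 18570,
    attribute_cluster_sizes = 3:8,
    attribute_cluster_size_probs = NULL,
    attribute_cluster_gap = 1,
    attribute_scatter_fraction = 0.25,
    attribute_chromosome_weights = c(I = 0.21, II = 0.17, III = 0.19,
                                     IV = 0.18, V = 0.13, X = 0.12),
    operon_fraction = 0.15,
    operon_sizes = 2:4,
    operon_size_probs = c(0.6, 0.3, 0.1),
    gene_length_range = c(500, 5000),
    n_samples = 2,
    dispersion = 0.05,
    germline_ablation_scale = 0.2,
    count_meanlog = 4,
    count_sdlog = 1.5) {
  if (n_genes < 10) abort("'n_genes' must be >= 10")
  stopifnot(is.data.frame(genome),
            all(c("name", "length") %in% names(genome)))
  if (any(genome$length <= 0)) abort("chromosome lengths must be > 0")
  if (anyDuplicated(genome$name)) abort("chromosome names must be unique")
  for (nm in c("seesaw_fraction_significant", "concordant_fraction",
               "inverse_trend_fraction", "attribute_fraction",
               "operon_fraction")) {
    check_probability(get(nm), nm)
  }
  if (noise_sd <= 0) abort("'noise_sd' must be > 0")
  if (central_concentration < 0 || central_concentration >= 1) {
    abort("'central_concentration' must lie in [0, 1)")
  }
  if (any(operon_sizes < 2)) abort("operon sizes must be >= 2")
  if (operon_fraction > 0 && length(operon_sizes) == 0) {
    abort("operon_fraction > 0 requires a size distribution")
  }
  if (is.null(attribute_cluster_size_probs)) {
    attribute_cluster_size_probs <-
      0.55^seq_along(attribute_cluster_sizes)
    attribute_cluster_size_probs <-
      attribute_cluster_size_probs / sum(attribute_cluster_size_probs)
  }
  for (w in class_chromosome_weights) {
    if (!all(names(w) %in% genome$name)) {
      abort("class chromosome weights name unknown chromosomes")
    }
  }
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

#' Default six-chromosome genome
#'
#' Chromosome names and approximate lengths (Mb: I 15.1, II 15.3,
#' III 13.8, IV 17.5, V 20.9, X 17.7).
#'
#' @return data frame with `name` and `length` (bp).
#' @export
default_genome <- function() {
  data.frame(
    name = c("I", "II", "III", "IV", "V", "X"),
    length = c(15.1, 15.3, 13.8, 17.5, 20.9, 17.7) * 1e6,
    stringsAsFactors = FALSE
  )
}

# Planted class counts for a config: even split within seesaw and
# concordant groups, remainder null.
planted_class_counts <- function(config) {
  n <- config$n_genes
  n_seesaw <- round(config$seesaw_fraction_significant * n)
  n_conc <- round(config$concordant_fraction * n)
  counts <- c(
    seesaw_up_down = floor(n_seesaw / 2),
    seesaw_down_up = ceiling(n_seesaw / 2),
    concordant_up = floor(n_conc / 2),
    concordant_down = ceiling(n_conc / 2)
  )
  c(counts, null = n - sum(counts))
}

#' Generate a genome annotation with planted response classes
#'
#' Genes are non-overlapping intervals with uniformly drawn lengths,
#' scattered along each chromosome. Each gene carries a planted response
#' class; planted seesaw classes are biased toward configured chromosomes
#' (`class_chromosome_weights`) and toward chromosome centers: a class
#' gene on a chromosome picks its interval slot with weight given by the
#' Beta(a, a) density at the slot's relative midpoint, with
#' `a = 1 / (1 - central_concentration)`.
#'
#' @param config a [generator_config()].
#' @return list with `genome` (the chromosome table), `annotation` (data
#'   frame `gene_id`, `chrom`, `start`, `end`, `strand`, `operon_id`,
#'   0-based half-open, sorted by chromosome then start) and `truth` (data
#'   frame `gene_id`, `class`, `attribute`, `operon_id`, `cluster_id`,
#'   `germline`).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(stage_seed(config$seed, "genome"))
  genome <- config$genome
  n <- config$n_genes
  counts <- planted_class_counts(config)
  classes <- rep(names(counts), counts)

  # chromosome assignment: class weights where configured, else length
  len_w <- genome$length / sum(genome$length)
  names(len_w) <- genome$name
  chrom <- character(n)
  for (cl in unique(classes)) {
    sel <- classes == cl
    w <- config$class_chromosome_weights[[cl]]
    probs <- if (is.null(w)) len_w else {
      full <- setNames(rep(0, nrow(genome)), genome$name)
      full[names(w)] <- w
      full / sum(full)
    }
    chrom[sel] <- sample(genome$name, sum(sel), replace = TRUE,
                         prob = probs)
  }

  a_shape <- 1 / (1 - config$central_concentration)
  central_classes <- c("seesaw_up_down", "seesaw_down_up")

  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    ch <- genome$name[i]; L <- genome$length[i]
    on_ch <- which(chrom == ch)
    n_c <- length(on_ch)
    if (n_c == 0L) return(NULL)
    lens <- round(stats::runif(n_c, config$gene_length_range[1],
                               config$gene_length_range[2]))
    if (sum(lens) > L) {
      abort("infeasible packing: ", n_c, " genes (", sum(lens),
            " bp) exceed chromosome ", ch, " (", L, " bp)")
    }
    free <- L - sum(lens)
    gaps <- diff(c(0, sort(stats::runif(n_c)), 1)) * free
    starts <- round(cumsum(gaps[seq_len(n_c)]) +
                      c(0, cumsum(lens))[seq_len(n_c)])
    ends <- starts + lens
    rel_mid <- ((starts + ends) / 2) / L

    # planted seesaw classes pick central slots; everything else uniform
    slot_of <- integer(n_c)
    avail <- seq_len(n_c)
    cls_ch <- classes[on_ch]
    for (cl in central_classes) {
      k <- sum(cls_ch == cl)
      if (k == 0L) next
      w <- stats::dbeta(rel_mid[avail], a_shape, a_shape)
      w <- pmax(w, 1e-12)
      pick <- if (length(avail) == 1L) avail else
        sample(avail, k, prob = w)
      slot_of[cls_ch == cl] <- pick
      avail <- setdiff(avail, pick)
    }
    rest <- which(slot_of == 0L)
    slot_of[rest] <- if (length(avail) == 1L) avail else
      sample(avail, length(rest))

    data.frame(
      chrom = ch,
      start = starts[slot_of],
      end = ends[slot_of],
      class = cls_ch,
      stringsAsFactors = FALSE
    )
  })
  ann <- do.call(rbind, per_chrom)
  ann$chrom <- factor(ann$chrom, levels = genome$name)
  ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  ann$gene_id <- sprintf("g%05d", seq_len(nrow(ann)))
  ann$strand <- sample(c("+", "-"), nrow(ann), replace = TRUE)
  ann$operon_id <- NA_character_
  rownames(ann) <- NULL

  truth <- data.frame(
    gene_id = ann$gene_id,
    class = ann$class,
    attribute = FALSE,
    operon_id = NA_character_,
    cluster_id = NA_character_,
    germline = ann$class == "seesaw_up_down",
    stringsAsFactors = FALSE
  )
  ann$class <- NULL
  ann <- ann[, c("gene_id", "chrom", "start", "end", "strand", "operon_id")]
  list(genome = genome, annotation = ann, truth = truth)
}

#' Assign operons to runs of adjacent same-strand genes
#'
#' Operons are placed as runs of consecutive genes on one chromosome;
#' member genes are forced onto a shared strand. The realized in-operon
#' gene fraction targets `operon_fraction`.
#'
#' @param annotation annotation data frame from [generate_genome()].
#' @param config a [generator_config()].
#' @return the annotation with `operon_id` filled (`opNNNN`) and operon
#'   members' strands harmonized.
#' @export
assign_operons <- function(annotation, config) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(annotation)
  if (config$operon_fraction == 0) return(annotation)
  set.seed(stage_seed(config$seed, "operons"))
  target <- round(config$operon_fraction * n)
  chrom_id <- as.integer(annotation$chrom)
  in_operon <- !is.na(annotation$operon_id)
  placed <- 0L
  op_i <- 0L
  attempts <- 0L
  max_attempts <- 200L * max(target, 1L)
  while (placed < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    size <- sample_one(config$operon_sizes, config$operon_size_probs)
    size <- min(size, target - placed + 1L)
    if (size < 2L) size <- 2L
    start <- sample.int(n - size + 1L, 1L)
    run <- start:(start + size - 1L)
    if (any(in_operon[run])) next
    if (chrom_id[run[1]] != chrom_id[run[length(run)]]) next
    op_i <- op_i + 1L
    annotation$operon_id[run] <- sprintf("op%04d", op_i)
    annotation$strand[run] <- sample(c("+", "-"), 1L)
    in_operon[run] <- TRUE
    placed <- placed + size
  }
  realized <- placed / n
  tol <- 3 * sqrt(config$operon_fraction *
                    (1 - config$operon_fraction) / n)
  if (abs(realized - config$operon_fraction) > max(tol, 2 / n)) {
    abort("could not realize operon_fraction ",
          config$operon_fraction, " (achieved ", round(realized, 4), ")")
  }
  annotation
}

#' Extract the operon table from an annotation
#'
#' @param annotation annotation with `operon_id` filled.
#' @return data frame `operon_id`, `gene_id`, `rank` (1-based within the
#'   operon, in gene order).
#' @export
operon_table_from_annotation <- function(annotation) {
  keep <- !is.na(annotation$operon_id)
  df <- annotation[keep, c("operon_id", "gene_id")]
  df <- df[order(df$operon_id), , drop = FALSE]
  df$rank <- stats::ave(seq_len(nrow(df)), df$operon_id,
                        FUN = seq_along)
  rownames(df) <- NULL
  df
}

#' Plant a clustered attribute gene set
#'
#' Attribute genes are planted as local runs: a chromosome is chosen by
#' `attribute_chromosome_weights`, a run start is chosen uniformly on it,
#' a cluster size is drawn from the configured distribution, and
#' consecutive attribute genes within the run are separated by gaps drawn
#' uniformly from 0..`attribute_cluster_gap`. Planting stops when the
#' overall attribute fraction is reached.
#'
#' @inheritParams assign_operons
#' @return list with `gene_ids` (character vector of attribute genes) and
#'   `cluster_id` (character vector aligned to the annotation, NA for
#'   non-attribute genes).
#' @export
assign_attribute <- function(annotation, config) {
  stopifnot(inherits(config, "generator_config"))
  n <- nrow(annotation)
  flags <- logical(n)
  cluster_id <- rep(NA_character_, n)
  target <- round(config$attribute_fraction * n)
  if (target == 0L) {
    return(list(gene_ids = character(0), cluster_id = cluster_id))
  }
  set.seed(stage_seed(config$seed, "attribute"))
  chroms <- levels(annotation$chrom)
  w <- config$attribute_chromosome_weights
  probs <- if (is.null(w)) {
    as.numeric(table(annotation$chrom)) / n
  } else {
    full <- setNames(rep(0, length(chroms)), chroms)
    full[names(w)] <- w
    full / sum(full)
  }
  idx_by_chrom <- split(seq_len(n), annotation$chrom)
  target_clustered <-
    round((1 - config$attribute_scatter_fraction) * target)
  cl_i <- 0L
  placed <- 0L
  attempts <- 0L
  while (placed < target_clustered && attempts < 200L * target) {
    attempts <- attempts + 1L
    ch <- sample(chroms, 1L, prob = probs)
    idx <- idx_by_chrom[[ch]]
    if (length(idx) == 0L) next
    size <- sample_one(config$attribute_cluster_sizes,
                       config$attribute_cluster_size_probs)
    size <- min(size, target_clustered - placed)
    if (size < 1L) break
    start_pos <- sample.int(length(idx), 1L)
    gaps <- if (config$attribute_cluster_gap > 0 && size > 1L) {
      sample.int(config$attribute_cluster_gap + 1L, size - 1L,
                 replace = TRUE) - 1L
    } else {
      rep(0L, max(size - 1L, 0L))
    }
    offsets <- cumsum(c(0L, gaps + 1L))
    pos <- start_pos + offsets
    pos <- pos[pos <= length(idx)]
    sel <- idx[pos]
    sel <- sel[!flags[sel]]
    if (length(sel) == 0L) next
    cl_i <- cl_i + 1L
    flags[sel] <- TRUE
    cluster_id[sel] <- sprintf("cl%04d", cl_i)
    placed <- placed + length(sel)
  }
  # remaining attribute genes are scattered singly, chromosome-weighted
  attempts <- 0L
  while (placed < target && attempts < 200L * target) {
    attempts <- attempts + 1L
    ch <- sample(chroms, 1L, prob = probs)
    idx <- idx_by_chrom[[ch]]
    open <- idx[!flags[idx]]
    if (length(open) == 0L) next
    sel <- open[sample.int(length(open), 1L)]
    flags[sel] <- TRUE
    placed <- placed + 1L
  }
  list(gene_ids = annotation$gene_id[flags], cluster_id = cluster_id)
}

#' Generate paired differential-expression tables
#'
#' Planted seesaw genes get opposite-signed fold changes with magnitudes
#' drawn from N(location, scale) truncated at 0; concordant genes get
#' same-signed magnitudes; null genes get bivariate-normal fold changes
#' with sd `noise_sd` and correlation `-sin(pi * (f - 1/2))`, which makes
#' the expected Q1+Q3 share equal the configured inverse-trend fraction
#' `f` while keeping null p-values uniform. P-values follow
#' `p = 2 * pnorm(-|log2fc| / noise_sd)`; q-values are Benjamini-Hochberg
#' within each table.
#'
#' @param truth truth table from [generate_genome()].
#' @param config a [generator_config()].
#' @return list with data frames `phe` and `stv`, each `gene_id`,
#'   `log2fc`, `pvalue`, `fdr`, `mean_expr` over the identical gene
#'   universe.
#' @export
generate_de_tables <- function(truth, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$noise_sd <= 0) abort("'noise_sd' must be > 0")
  set.seed(stage_seed(config$seed, "de"))
  n <- nrow(truth)
  cls <- truth$class
  draw_mag <- function(k) {
    pmax(stats::rnorm(k, config$effect_size_location,
                      config$effect_size_scale), 1e-3)
  }
  fc_phe <- fc_stv <- numeric(n)

  for (cl in c("seesaw_up_down", "seesaw_down_up",
               "concordant_up", "concordant_down")) {
    sel <- which(cls == cl)
    k <- length(sel)
    if (k == 0L) next
    sgn <- switch(cl,
      seesaw_up_down = c(1, -1), seesaw_down_up = c(-1, 1),
      concordant_up = c(1, 1), concordant_down = c(-1, -1)
    )
    fc_phe[sel] <- sgn[1] * draw_mag(k)
    fc_stv[sel] <- sgn[2] * draw_mag(k)
  }
  nul <- which(cls == "null")
  if (length(nul) > 0L) {
    rho <- -sin(pi * (config$inverse_trend_fraction - 0.5))
    z1 <- stats::rnorm(length(nul))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(length(nul))
    fc_phe[nul] <- config$noise_sd * z1
    fc_stv[nul] <- config$noise_sd * z2
  }
  mean_expr <- stats::rlnorm(n, config$count_meanlog, config$count_sdlog)
  mk <- function(fc) {
    p <- 2 * stats::pnorm(-abs(fc) / config$noise_sd)
    data.frame(gene_id = truth$gene_id, log2fc = fc, pvalue = p,
               fdr = bh_fdr(p), mean_expr = mean_expr,
               stringsAsFactors = FALSE)
  }
  list(phe = mk(fc_phe), stv = mk(fc_stv))
}

#' Generate replicate count matrices and FPKM for two strains
#'
#' Per-gene baseline means are log-normal and shared across replicates;
#' counts are negative binomial with the configured dispersion (Poisson at
#' dispersion 0). In the germline-ablated-like strain, means of genes
#' flagged `germline` in the truth table are multiplied by
#' `germline_ablation_scale`. FPKM uses each library's own total.
#'
#' @param truth truth table with a logical `germline` column.
#' @param annotation annotation providing gene lengths.
#' @param config a [generator_config()].
#' @return list with integer matrix `counts` (genes x samples; columns
#'   `wt_rep*` then `ablated_rep*`), matrix `fpkm` of the same shape, and
#'   `gene_lengths`.
#' @export
generate_count_matrix <- function(truth, annotation, config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_samples < 2) abort("'n_samples' must be >= 2")
  set.seed(stage_seed(config$seed, "counts"))
  n <- nrow(truth)
  lens <- annotation$end[match(truth$gene_id, annotation$gene_id)] -
    annotation$start[match(truth$gene_id, annotation$gene_id)]
  mu <- stats::rlnorm(n, config$count_meanlog, config$count_sdlog)
  mu_abl <- mu * ifelse(truth$germline, config$germline_ablation_scale, 1)
  draw <- function(m) {
    if (config$dispersion == 0) {
      stats::rpois(length(m), m)
    } else {
      stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion)
    }
  }
  cols <- c(
    lapply(seq_len(config$n_samples), function(i) draw(mu)),
    lapply(seq_len(config$n_samples), function(i) draw(mu_abl))
  )
  counts <- do.call(cbind, cols)
  colnames(counts) <- c(paste0("wt_rep", seq_len(config$n_samples)),
                        paste0("ablated_rep", seq_len(config$n_samples)))
  rownames(counts) <- truth$gene_id
  fpkm <- apply(counts, 2, function(co)
    compute_fpkm(co, lens, max(sum(co), 1)))
  rownames(fpkm) <- truth$gene_id
  list(counts = counts, fpkm = fpkm, gene_lengths = lens)
}

#' Generate the full synthetic study
#'
#' Runs every generator stage in order (genome, operons, attribute set,
#' DE tables, optionally counts) and assembles the complete artifact
#' bundle.
#'
#' @param config a [generator_config()] (default: the standard study
#'   conditions).
#' @param include_counts generate count matrices too (default TRUE).
#' @return list with `config`, `genome`, `annotation`, `truth`,
#'   `attribute_genes`, `operon_table`, `de` (list `phe`, `stv`), and
#'   `counts` (or NULL).
#' @export
simulate_study <- function(config = generator_config(),
                           include_counts = TRUE) {
  g <- generate_genome(config)
  ann <- assign_operons(g$annotation, config)
  attr_set <- assign_attribute(ann, config)
  truth <- g$truth
  truth$attribute <- truth$gene_id %in% attr_set$gene_ids
  truth$cluster_id <- attr_set$cluster_id
  truth$operon_id <- ann$operon_id[match(truth$gene_id, ann$gene_id)]
  truth$germline <- truth$attribute | truth$class == "seesaw_up_down"
  de <- generate_de_tables(truth, config)
  counts <- if (include_counts) {
    generate_count_matrix(truth, ann, config)
  }
  list(
    config = config,
    genome = g$genome,
    annotation = ann,
    truth = truth,
    attribute_genes = attr_set$gene_ids,
    operon_table = operon_table_from_annotation(ann),
    de = de,
    counts = counts
  )
}
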