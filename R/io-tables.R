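# On-disk formats: GFF3/BED6 annotations, DE tables, gene lists, operon
# tables, result bundles.
#
# Internal coordinates are 0-based half-open everywhere; conversion
# happens only at format boundaries (GFF3 on disk is 1-based inclusive,
# BED is 0-based half-open).

ANNOTATION_COLS <- c("gene_id", "chrom", "start", "end", "strand",
                     "operon_id")
DE_COLS <- c("gene_id", "log2fc", "pvalue", "fdr", "mean_expr")

detect_format <- function(path, format) {
  if (format != "auto") return(format)
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "bed") return("bed6")
  abort("cannot detect annotation format from extension '.", ext,
        "'; pass format explicitly")
}

# Pre-scan a file so malformed lines are reported with their line number,
# which the generic parsers do not do.
check_field_counts <- function(path, n_fields, sep = "\t",
                               allow_track = FALSE) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    if (allow_track && grepl("^(track|browser)", ln)) next
    k <- length(strsplit(ln, sep, fixed = TRUE)[[1]])
    if (k < n_fields) {
      abort("malformed line ", i, " in ", basename(path), ": expected ",
            n_fields, " fields, found ", k)
    }
  }
  invisible(TRUE)
}

#' Read a gene annotation from GFF3 or BED6
#'
#' GFF3 coordinates (1-based inclusive) are converted to the internal
#' 0-based half-open convention; only records of feature type `gene` are
#' retained. BED6 is taken as is. Genes are sorted by (chromosome, start,
#' gene_id).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"gff3"`, or `"bed6"`.
#' @return annotation data frame: `gene_id`, `chrom` (factor in order of
#'   appearance), `start`, `end` (0-based half-open), `strand`
#'   (`+`/`-`/`*`), `operon_id` (NA when the format does not carry it).
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed6")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("file not found: ", path)
  format <- detect_format(path, format)
  if (format == "gff3") {
    check_field_counts(path, 9)
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    op <- S4Vectors::mcols(gr)$operon_id
    ann <- data.frame(
      gene_id = as.character(ids),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      operon_id = if (is.null(op)) NA_character_ else as.character(op),
      stringsAsFactors = FALSE
    )
  } else {
    check_field_counts(path, 6, allow_track = TRUE)
    gr <- rtracklayer::import(path, format = "bed")
    ann <- data.frame(
      gene_id = as.character(S4Vectors::mcols(gr)$name),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      operon_id = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  if (anyDuplicated(ann$gene_id)) {
    abort("duplicate gene_id in ", basename(path), ": ",
          ann$gene_id[anyDuplicated(ann$gene_id)])
  }
  if (any(ann$start < 0 | ann$start >= ann$end)) {
    abort("invalid coordinates (need 0 <= start < end)")
  }
  ann$chrom <- factor(ann$chrom, levels = unique(ann$chrom))
  ann <- ann[order(ann$chrom, ann$start, ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL
  ann
}

#' Write a gene annotation as GFF3 or BED6
#'
#' @param annotation internal annotation data frame (0-based half-open).
#' @param path output path.
#' @param format `"gff3"` or `"bed6"`.
#' @return the path, invisibly.
#' @export
write_annotation <- function(annotation, path,
                             format = c("gff3", "bed6")) {
  format <- match.arg(format)
  strand <- ifelse(annotation$strand %in% c("+", "-"),
                   annotation$strand, "*")
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(annotation$chrom),
    ranges = IRanges::IRanges(start = annotation$start + 1L,
                              end = annotation$end),
    strand = strand
  )
  if (format == "gff3") {
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- annotation$gene_id
    if (any(!is.na(annotation$operon_id))) {
      S4Vectors::mcols(gr)$operon_id <- annotation$operon_id
    }
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    S4Vectors::mcols(gr)$name <- annotation$gene_id
    S4Vectors::mcols(gr)$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a differential-expression table
#'
#' Tab-separated with header `gene_id log2fc pvalue fdr mean_expr`. Rows
#' with missing `log2fc` or `pvalue` are dropped with a message.
#'
#' @param path file path.
#' @param condition,strain optional labels stored as attributes.
#' @return data frame with the five columns; attributes `condition`,
#'   `strain`, `n_dropped`.
#' @export
read_de_table <- function(path, condition = NA_character_,
                          strain = NA_character_) {
  if (!file.exists(path)) abort("file not found: ", path)
  de <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  missing_cols <- setdiff(DE_COLS, names(de))
  if (length(missing_cols) > 0) {
    abort("missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  de <- de[, DE_COLS]
  drop <- is.na(de$log2fc) | is.na(de$pvalue)
  if (any(drop)) {
    message(sum(drop), " row(s) with missing log2fc/pvalue dropped")
    de <- de[!drop, , drop = FALSE]
  }
  if (any(de$pvalue < 0 | de$pvalue > 1)) {
    abort("pvalue outside [0, 1]")
  }
  if (any(!is.na(de$fdr) & (de$fdr < 0 | de$fdr > 1))) {
    abort("fdr outside [0, 1]")
  }
  if (anyDuplicated(de$gene_id)) abort("duplicate gene_id in DE table")
  rownames(de) <- NULL
  attr(de, "condition") <- condition
  attr(de, "strain") <- strain
  attr(de, "n_dropped") <- sum(drop)
  de
}

#' Write a differential-expression table
#'
#' @param de DE data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de[, DE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one id per line)
#'
#' Empty lines and `#` comments are ignored; duplicates are removed with a
#' message. An empty file yields an empty set with a warning.
#'
#' @param path file path.
#' @return character vector of unique gene ids, with attribute
#'   `n_duplicates`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- ids[ids != "" & !startsWith(ids, "#")]
  n_dup <- length(ids) - length(unique(ids))
  if (n_dup > 0) message(n_dup, " duplicate id(s) removed")
  ids <- unique(ids)
  if (length(ids) == 0) warning("empty gene list: ", basename(path))
  attr(ids, "n_duplicates") <- n_dup
  ids
}

#' Write a gene list
#' @param ids character vector of gene ids.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Read an operon table
#'
#' Tab-separated with header `operon_id gene_id rank`.
#'
#' @param path file path.
#' @return data frame `operon_id`, `gene_id`, `rank`.
#' @export
read_operon_table <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  needed <- c("operon_id", "gene_id")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    abort("missing required column(s): ",
          paste(missing_cols, collapse = ", "))
  }
  if (!"rank" %in% names(tab)) {
    tab$rank <- stats::ave(seq_len(nrow(tab)), tab$operon_id,
                           FUN = seq_along)
  }
  tab[, c("operon_id", "gene_id", "rank")]
}

#' Write an operon table
#' @param operon_table data frame `operon_id`, `gene_id`, `rank`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_operon_table <- function(operon_table, path) {
  utils::write.table(operon_table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Strip non-serializable structure from a result object for the JSON
# summary: data frames become record lists, everything else is passed to
# jsonlite as is.
summarize_for_json <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "cluster_set")) {
    return(list(
      n_clusters = x$n_clusters, n_clustered = x$n_clustered,
      n_attribute = x$n_attribute,
      fraction_clustered = x$fraction_clustered,
      min_size = x$min_size, max_gap = x$max_gap,
      null = x$null
    ))
  }
  if (inherits(x, c("overlap_enrichment", "seesaw_calls",
                    "pca_retention"))) {
    return(unclass(x))
  }
  x
}

#' Write a result bundle (TSVs plus a JSON summary)
#'
#' Every data-frame element of `objects` is written as
#' `<out_dir>/<name>.tsv` at full precision; a `summary.json` mirrors all
#' elements machine-readably.
#'
#' @param objects named list of results (data frames, lists, scalars).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_results <- function(objects, out_dir) {
  stopifnot(is.list(objects), !is.null(names(objects)),
            all(names(objects) != ""))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort("cannot create ", out_dir)
  files <- character(0)
  for (nm in names(objects)) {
    x <- objects[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      utils::write.table(x, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, f)
    }
  }
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(lapply(objects, summarize_for_json), summary_path,
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(c(files, summary_path))
}
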