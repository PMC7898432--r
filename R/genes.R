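#' Read a gene position table
#'
#' Simple 3+ column TSV with header `lg`, `bp`, `annotation` (optionally a
#' `gene` id column), the layout used for published candidate-gene tables
#' that list one bp position per gene.
#'
#' @param path TSV path.
#' @return data frame `gene`, `lg`, `bp`, `end`, `annotation` (`end`
#'   equals `bp` when only a single position is given).
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("lg", "bp", "annotation") %in% names(df)))
  if (is.null(df$gene)) df$gene <- sprintf("%s_%d", df$lg, df$bp)
  if (is.null(df$end)) df$end <- df$bp
  if (any(df$bp < 1)) stop("gene positions must be >= 1")
  df[, c("gene", "lg", "bp", "end", "annotation")]
}

#' Read gene features from a GFF3 annotation
#'
#' Imports with `rtracklayer` and keeps features of the requested type.
#' Sequence names can be remapped to linkage-group ids via `lg_map`.
#'
#' @param path GFF3 path.
#' @param feature_type feature type to keep (default `"gene"`).
#' @param lg_map optional named character vector mapping GFF seqids to
#'   linkage-group ids.
#' @return data frame `gene`, `lg`, `bp`, `end`, `annotation`.
#' @export
read_genes_gff3 <- function(path, feature_type = "gene", lg_map = NULL) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == feature_type]
  seqid <- as.character(GenomicRanges::seqnames(gr))
  if (!is.null(lg_map)) {
    mapped <- unname(lg_map[seqid])
    seqid <- ifelse(is.na(mapped), seqid, mapped)
  }
  ann <- gr$Name %||% gr$ID
  if (is.null(ann)) ann <- rep(NA_character_, length(gr))
  id <- gr$ID %||% ann
  data.frame(gene = as.character(id), lg = seqid,
             bp = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             annotation = as.character(ann), stringsAsFactors = FALSE)
}

#' Genes lying within a QTL region
#'
#' Membership rules (coordinates are 1-based, boundaries inclusive):
#' * `"start-in-region"` (default) — the gene's start position lies within
#'   the region bounds; the natural rule when the annotation lists a single
#'   bp position per gene.
#' * `"overlap"` — any part of the gene's `[bp, end]` span overlaps the
#'   region.
#'
#' The result is sorted by gene start and does not depend on the input
#' record order. A region on a linkage group absent from the annotation
#' returns an empty list with a warning.
#'
#' @param genes data frame from [read_gene_table()] or [read_genes_gff3()].
#' @param region a region (`lg`, `start_bp`, `end_bp`).
#' @param rule membership rule.
#' @return the matching rows of `genes`, sorted by `bp`.
#' @export
genes_in_region <- function(genes, region,
                            rule = c("start-in-region", "overlap")) {
  rule <- match.arg(rule)
  stopifnot(region$start_bp <= region$end_bp)
  if (!region$lg %in% genes$lg) {
    warning("linkage group ", region$lg, " absent from the annotation")
    return(genes[0, , drop = FALSE])
  }
  on_lg <- genes$lg == region$lg
  hit <- if (rule == "start-in-region") {
    on_lg & genes$bp >= region$start_bp & genes$bp <= region$end_bp
  } else {
    gend <- genes$end %||% genes$bp
    on_lg & gend >= region$start_bp & genes$bp <= region$end_bp
  }
  out <- genes[hit, , drop = FALSE]
  out <- out[order(out$bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Path to the bundled fruit-weight QTL candidate-gene table
#'
#' Gene positions and annotations for the two mango fruit-weight QTL
#' regions (LG4 and LG7), transcribed from the published candidate-gene
#' table of the 'Tommy Atkins' x 'Kensington Pride' study.
#'
#' @return file path of the TSV.
#' @export
fruit_weight_gene_table <- function() {
  system.file("extdata", "fruit_weight_qtl_genes.tsv", package = "ptxqtl",
              mustWork = TRUE)
}

#' The published fruit-weight QTL region bounds
#'
#' LG4 8,275,233–8,495,231 and LG7 3,831,615–3,914,160 (bp, 1-based
#' inclusive), as reported for the mango fruit-weight association.
#'
#' @return a `qtl_regions` data frame with two rows.
#' @export
fruit_weight_regions <- function() {
  out <- data.frame(
    region_id = c("LG04:8275233-8495231", "LG07:3831615-3914160"),
    lg = c("LG04", "LG07"),
    start_bp = c(8275233, 3831615),
    end_bp = c(8495231, 3914160),
    n_snps = NA_integer_, min_p = NA_real_, markers = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("qtl_regions", "data.frame")
  out
}
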