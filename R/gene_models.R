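#' Read gene models from GTF
#'
#' Builds an exon-level index used for splice-junction distances and gene
#' assignment. Requires `gene_id` and `transcript_id` attributes on exon rows.
#'
#' @param path GTF path.
#' @return an object of class `rnasm_genes` holding an exon tibble, gene span
#'   tibble and precomputed exon-boundary positions per gene.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  exons <- tibble(
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = as.character(ex$gene_id),
    transcript_id = as.character(ex$transcript_id)
  )
  gene_model_index(exons)
}

#' Build a gene-model index from an exon table
#'
#' @param exons tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `gene_id`, `transcript_id` (1-based inclusive intervals).
#' @return an `rnasm_genes` object.
#' @export
gene_model_index <- function(exons) {
  assert_columns(exons, c("chrom", "start", "end", "strand", "gene_id",
                          "transcript_id"), "exon table")
  if (nrow(exons) == 0) {
    return(structure(
      list(exons = exons,
           genes = tibble(gene_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character()),
           boundaries = tibble(gene_id = character(), bp = integer())),
      class = "rnasm_genes"))
  }
  # exons within one transcript must be non-overlapping and strand-consistent
  chk <- exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      ok_overlap = all(.data$start[-1] > .data$end[-n()]) || n() == 1,
      ok_strand = dplyr::n_distinct(.data$strand) == 1,
      .groups = "drop"
    )
  if (!all(chk$ok_overlap)) abort("overlapping exons within a transcript")
  if (!all(chk$ok_strand)) abort("strand-inconsistent transcript")
  genes <- exons |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end), strand = first(.data$strand),
              .groups = "drop")
  boundaries <- exons |>
    tidyr::pivot_longer(c("start", "end"), values_to = "bp") |>
    distinct(.data$gene_id, .data$bp)
  structure(list(exons = exons, genes = genes, boundaries = boundaries),
            class = "rnasm_genes")
}

#' @export
print.rnasm_genes <- function(x, ...) {
  cat("<rnasm_genes> ", nrow(x$genes), " gene(s), ", nrow(x$exons),
      " exon record(s)\n", sep = "")
  invisible(x)
}

gene_granges <- function(genes) {
  GenomicRanges::GRanges(genes$genes$chrom,
                         IRanges::IRanges(genes$genes$start, genes$genes$end),
                         gene_id = genes$genes$gene_id)
}

#' Distance to the nearest splice junction
#'
#' Minimum absolute distance (bp) from each position to any exon boundary of a
#' gene overlapping that position; -1 when no gene model overlaps.
#'
#' @param genes an `rnasm_genes` index.
#' @param chrom,pos equal-length position vectors (1-based).
#' @return numeric vector of distances (0 = on a boundary), -1 for intergenic.
#' @export
junction_distance <- function(genes, chrom, pos) {
  stopifnot(inherits(genes, "rnasm_genes"))
  n <- length(pos)
  out <- rep(-1, n)
  if (n == 0 || nrow(genes$genes) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, gene_granges(genes))
  if (length(hits) == 0) return(out)
  hdf <- tibble(qi = S4Vectors::queryHits(hits),
                gene_id = genes$genes$gene_id[S4Vectors::subjectHits(hits)]) |>
    left_join(genes$boundaries, by = "gene_id",
              relationship = "many-to-many") |>
    mutate(d = abs(pos[.data$qi] - .data$bp)) |>
    group_by(.data$qi) |>
    summarise(d = min(.data$d), .groups = "drop")
  out[hdf$qi] <- hdf$d
  out
}

#' Assign positions to genes (by gene span)
#'
#' @inheritParams junction_distance
#' @return character vector of gene IDs (first overlapping gene), NA when
#'   intergenic.
#' @export
assign_gene <- function(genes, chrom, pos) {
  stopifnot(inherits(genes, "rnasm_genes"))
  out <- rep(NA_character_, length(pos))
  if (length(pos) == 0 || nrow(genes$genes) == 0) return(out)
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(q, gene_granges(genes), select = "first")
  ok <- !is.na(hits)
  out[ok] <- genes$genes$gene_id[hits[ok]]
  out
}

#' Genic region of a position (exon, intron or intergenic)
#'
#' @inheritParams junction_distance
#' @return character vector with values `"exon"`, `"intron"`, `"intergenic"`.
#' @export
genic_region <- function(genes, chrom, pos) {
  gene <- assign_gene(genes, chrom, pos)
  out <- ifelse(is.na(gene), "intergenic", "intron")
  if (nrow(genes$exons) > 0 && length(pos) > 0) {
    q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    egr <- GenomicRanges::GRanges(
      genes$exons$chrom,
      IRanges::IRanges(genes$exons$start, genes$exons$end))
    inx <- GenomicRanges::findOverlaps(q, egr, select = "first")
    out[!is.na(inx) & out != "intergenic"] <- "exon"
  }
  out
}
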