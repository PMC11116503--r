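#' Read variant candidates from a VCF file
#'
#' Multi-allelic records are split into one candidate per ALT allele.
#' Positions stay 1-based. Records with a missing ALT are skipped with a
#' warning.
#'
#' @param path path to a VCF 4.x file (plain text or bgzipped).
#' @param sample_id sample identifier attached to every candidate.
#' @return a tibble with columns `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `variant_type` (one of `"SNV"`, `"insertion"`, `"deletion"`),
#'   `caller_qual`.
#' @export
read_vcf_candidates <- function(path, sample_id = "sample") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(sample_id = character(), chrom = character(),
                  pos = integer(), ref = character(), alt = character(),
                  variant_type = character(), caller_qual = double()))
  }
  no_alt <- is.na(fix$ALT) | fix$ALT == "." | fix$ALT == ""
  if (any(no_alt)) {
    warn(sprintf("skipped %d record(s) with missing ALT", sum(no_alt)))
    fix <- fix[!no_alt, , drop = FALSE]
  }
  out <- as_tibble(fix) |>
    mutate(pos = as.integer(.data$POS),
           caller_qual = suppressWarnings(as.numeric(.data$QUAL))) |>
    rename(chrom = "CHROM", ref = "REF", alt = "ALT") |>
    select("chrom", "pos", "ref", "alt", "caller_qual") |>
    tidyr::separate_rows("alt", sep = ",") |>
    mutate(
      sample_id = sample_id,
      variant_type = case_when(
        nchar(.data$ref) == 1 & nchar(.data$alt) == 1 ~ "SNV",
        nchar(.data$ref) < nchar(.data$alt) ~ "insertion",
        TRUE ~ "deletion"
      )
    ) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "variant_type",
           "caller_qual")
  bad <- out$ref == out$alt
  if (any(bad)) abort(sprintf("%d record(s) have REF == ALT", sum(bad)))
  out
}

#' Read known RNA-editing sites from BED
#'
#' BED is 0-based half-open; every covered position becomes one 1-based site.
#' A strand column (BED column 6) is carried through when present.
#'
#' @param path path to a BED file with at least 3 columns.
#' @return tibble with columns `chrom`, `pos`, `strand`.
#' @export
read_editing_sites <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (length(gr) == 0) {
    return(tibble(chrom = character(), pos = integer(), strand = character()))
  }
  if (any(IRanges::width(gr) < 1)) abort("BED interval with start >= end")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    mutate(pos = purrr::map2(.data$start, .data$end, seq)) |>
    tidyr::unnest("pos") |>
    mutate(pos = as.integer(.data$pos)) |>
    select("chrom", "pos", "strand") |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE)
}

#' Read germline variants from a matched-normal VCF
#'
#' @param path VCF of germline variants.
#' @return tibble with `chrom`, `pos`, `ref`, `alt` (allele-exact keys).
#' @export
read_germline_vcf <- function(path) {
  read_vcf_candidates(path, sample_id = "germline") |>
    select("chrom", "pos", "ref", "alt")
}

#' Read a reference mutational-signature matrix
#'
#' Expects a tab-delimited file with 96 data rows in COSMIC SBS channel order
#' (first column channel labels such as `A[C>A]A`) and one column per
#' signature. Columns are renormalized to sum to one when within 1e-3 of one;
#' larger deviations or negative entries are errors.
#'
#' @param path TSV path.
#' @return numeric 96 x K matrix, rownames channel labels, colnames signature
#'   names.
#' @export
read_signature_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) != 96) {
    abort(sprintf("signature matrix must have 96 data rows, found %d", nrow(df)))
  }
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  if (any(m < 0)) abort("signature matrix has negative entries")
  if (!setequal(labels, sbs_channels())) {
    abort("channel labels do not match the 96 COSMIC SBS channels")
  }
  m <- m[sbs_channels(), , drop = FALSE]
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-3)) {
    abort("signature column sums deviate from 1 by more than 1e-3")
  }
  sweep(m, 2, cs, "/")
}

#' Write a signature matrix in the layout accepted by [read_signature_matrix()]
#' @param sigs 96 x K matrix with channel rownames.
#' @param path output TSV path.
#' @export
write_signature_matrix <- function(sigs, path) {
  df <- bind_cols(tibble(Type = rownames(sigs)), as_tibble(sigs))
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a gene expression table (gene_id, tpm)
#' @param path TSV with columns `gene_id` and `tpm`.
#' @return tibble.
#' @export
read_tpm_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(df, c("gene_id", "tpm"), "TPM table")
  df |> mutate(tpm = as.numeric(.data$tpm))
}

# minimal single-sample VCF writer used for candidate sets and final calls
write_vcf <- function(df, path, info_cols = character(), filter_col = NULL,
                      contigs = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs)) {
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                       as.integer(contigs)), con)
  }
  for (ic in info_cols) {
    writeLines(sprintf(
      "##INFO=<ID=%s,Number=1,Type=String,Description=\"%s\">",
      toupper(ic), ic), con)
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(df) == 0) return(invisible(path))
  qual <- if ("caller_qual" %in% names(df)) {
    ifelse(is.na(df$caller_qual), ".", format(df$caller_qual, trim = TRUE))
  } else "."
  filt <- if (!is.null(filter_col)) df[[filter_col]] else "."
  filt[is.na(filt) | filt == ""] <- "PASS"
  info <- if (length(info_cols) == 0) "." else {
    apply(df[, info_cols, drop = FALSE], 1, function(r) {
      paste(sprintf("%s=%s", toupper(info_cols), as.character(r)),
            collapse = ";")
    })
  }
  writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t%s\t%s",
                     df$chrom, df$pos, df$ref, df$alt, qual, filt, info), con)
  invisible(path)
}

#' Write annotated mutation calls as VCF and TSV
#'
#' The VCF FILTER column holds `PASS` or the semicolon-joined IDs of the
#' failed filters; the TSV mirrors every column of `calls`. Reading the VCF
#' back with [read_vcf_candidates()] recovers positions and alleles exactly.
#'
#' @param calls tibble of calls; must contain `chrom`, `pos`, `ref`, `alt` and
#'   a `failed_filters` column ("" or NA for PASS). A `prob_dna` classifier
#'   probability column is written to INFO when present.
#' @param path output path without extension; `<path>.vcf` and `<path>.tsv`
#'   are written.
#' @param genome optional `rnasm_genome` used to emit contig headers.
#' @return invisibly, the two paths written.
#' @export
write_calls <- function(calls, path, genome = NULL) {
  assert_columns(calls, c("chrom", "pos", "ref", "alt"), "calls")
  df <- calls
  if (!"failed_filters" %in% names(df)) df$failed_filters <- ""
  info_cols <- intersect(c("prob_dna", "variant_type"), names(df))
  vcf_path <- paste0(path, ".vcf")
  tsv_path <- paste0(path, ".tsv")
  write_vcf(df, vcf_path, info_cols = info_cols,
            filter_col = "failed_filters",
            contigs = if (!is.null(genome)) genome$lengths else NULL)
  readr::write_tsv(df, tsv_path, progress = FALSE)
  invisible(c(vcf = vcf_path, tsv = tsv_path))
}
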