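# Validation harness: overlap of RNA-derived mutations with DNA-derived
# reference sets under a coverage-exclusion rule, per-patient precision and
# sensitivity, per-transition-class FDR, and depth/GC-binned validation.

mutation_key <- function(df) {
  paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Validate RNA-derived mutations against DNA reference sets
#'
#' Sites covered by fewer than `min_depth` reads in ANY platform are excluded
#' from both numerator and denominator. A mutation is validated when an
#' allele-exact match exists in the union of the reference sets
#' (position-only matching via `match_alleles = FALSE`). Sensitivity counts
#' reference mutations with adequate coverage that are recovered.
#'
#' @param predictions tibble of calls with `sample_id`, `chrom`, `pos`,
#'   `ref`, `alt`.
#' @param references one reference tibble or a named list of them (same
#'   columns); validation is against their union, per-set overlaps are also
#'   reported.
#' @param depths named list of per-platform depth tibbles (`sample_id`,
#'   `chrom`, `pos`, `depth`), e.g. `list(rna = ..., wxs = ...)`. Sites
#'   absent from a table count as depth 0.
#' @param min_depth coverage floor (reads, default 10).
#' @param match_alleles allele-exact matching (default) or position-only.
#' @return an `rnasm_validation` list: `per_patient` tibble, `summary`
#'   (cohort lower-medians), `overlaps`, `n_excluded_predictions`,
#'   `n_excluded_reference`.
#' @export
validate_calls <- function(predictions, references, depths, min_depth = 10,
                           match_alleles = TRUE) {
  if (is.data.frame(references)) references <- list(reference = references)
  if (length(depths) == 0) abort("at least one depth lookup is required")
  key_fun <- if (match_alleles) mutation_key else {
    function(df) paste(df$sample_id, df$chrom, df$pos, sep = ":")
  }
  pos_key <- function(df) paste(df$sample_id, df$chrom, df$pos, sep = ":")
  covered <- function(df) {
    ok <- rep(TRUE, nrow(df))
    for (d in depths) {
      dep <- d$depth[match(pos_key(df), pos_key(d))]
      dep[is.na(dep)] <- 0
      ok <- ok & dep >= min_depth
    }
    ok
  }
  pred_ok <- covered(predictions)
  ref_union <- bind_rows(references) |> distinct()
  ref_ok <- covered(ref_union)
  pred <- predictions[pred_ok, , drop = FALSE]
  refc <- ref_union[ref_ok, , drop = FALSE]
  validated <- key_fun(pred) %in% key_fun(refc)
  recovered <- key_fun(refc) %in% key_fun(pred)

  per_patient <- tibble(sample_id = sort(unique(c(pred$sample_id,
                                                  refc$sample_id)))) |>
    mutate(
      n_predicted = vapply(.data$sample_id,
                           function(s) sum(pred$sample_id == s), integer(1),
                           USE.NAMES = FALSE),
      n_validated = vapply(.data$sample_id,
                           function(s) sum(validated[pred$sample_id == s]),
                           integer(1), USE.NAMES = FALSE),
      n_reference = vapply(.data$sample_id,
                           function(s) sum(refc$sample_id == s), integer(1),
                           USE.NAMES = FALSE),
      n_recovered = vapply(.data$sample_id,
                           function(s) sum(recovered[refc$sample_id == s]),
                           integer(1), USE.NAMES = FALSE),
      precision = ifelse(.data$n_predicted > 0,
                         .data$n_validated / .data$n_predicted, NA_real_),
      sensitivity = ifelse(.data$n_reference > 0,
                           .data$n_recovered / .data$n_reference, NA_real_)
    )
  overlaps <- purrr::imap_dfr(references, function(r, nm) {
    rr <- r[covered(r), , drop = FALSE]
    tibble(reference = nm,
           n_reference = nrow(rr),
           n_overlap = sum(key_fun(pred) %in% key_fun(rr)))
  }) |>
    bind_rows(tibble(reference = "rna_only",
                     n_reference = NA_integer_,
                     n_overlap = sum(!validated)))
  structure(
    list(per_patient = per_patient,
         summary = tibble(
           n_predictions_compared = nrow(pred),
           n_validated = sum(validated),
           precision_overall = ifelse(nrow(pred) > 0,
                                      mean(validated), NA_real_),
           median_precision = lower_median(
             per_patient$precision[!is.na(per_patient$precision)]),
           median_sensitivity = lower_median(
             per_patient$sensitivity[!is.na(per_patient$sensitivity)])),
         overlaps = overlaps,
         n_excluded_predictions = sum(!pred_ok),
         n_excluded_reference = sum(!ref_ok)),
    class = "rnasm_validation")
}

#' @export
print.rnasm_validation <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<rnasm_validation> %d compared, %d validated (%.1f%%); median precision %.3f, median sensitivity %.3f\n",
    s$n_predictions_compared, s$n_validated, 100 * s$precision_overall,
    s$median_precision, s$median_sensitivity))
  invisible(x)
}

#' @export
tidy.rnasm_validation <- function(x, ...) x$per_patient

#' @export
glance.rnasm_validation <- function(x, ...) x$summary

#' Per-transition-class false discovery rate
#'
#' @param predictions tibble of SNV calls with `ref`, `alt` and a logical
#'   `is_true` column (TRUE = real somatic mutation).
#' @return tibble with one row per substitution class: `n_predictions`,
#'   `n_false`, `fdr` (NA, not 0, for classes with no predictions).
#' @export
fdr_by_transition <- function(predictions) {
  assert_columns(predictions, c("ref", "alt", "is_true"), "predictions")
  snv <- predictions |> filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  cls <- substitution_class(snv$ref, snv$alt)
  tibble(subst_class = subst_classes()) |>
    mutate(
      n_predictions = vapply(.data$subst_class,
                             function(cl) sum(cls == cl), integer(1),
                             USE.NAMES = FALSE),
      n_false = vapply(.data$subst_class,
                       function(cl) sum(cls == cl & !snv$is_true),
                       integer(1), USE.NAMES = FALSE),
      fdr = ifelse(.data$n_predictions > 0,
                   .data$n_false / .data$n_predictions, NA_real_)
    )
}

#' Validation fraction within depth or GC bins
#'
#' @param sites tibble with a logical `validated` column and the binning
#'   variable named in `by`.
#' @param by column to bin on (e.g. `"depth"` or `"gc"`).
#' @param breaks bin edges (left-closed). Defaults: depth
#'   `c(0,10,30,50,100,Inf)`; otherwise deciles of the observed values.
#' @param min_support bins with fewer sites are flagged `low_support`.
#' @return tibble per bin: `bin`, `n`, `n_validated`, `fraction` (NA for
#'   empty bins), `low_support`.
#' @export
binned_validation <- function(sites, by = "depth", breaks = NULL,
                              min_support = 5) {
  assert_columns(sites, c("validated", by), "sites")
  if (is.null(breaks)) {
    breaks <- if (by == "depth") c(0, 10, 30, 50, 100, Inf) else {
      unique(quantile(sites[[by]], probs = seq(0, 1, 0.1), na.rm = TRUE))
    }
  }
  bins <- cut(sites[[by]], breaks = breaks, right = FALSE,
              include.lowest = TRUE)
  tibble(bin = levels(bins)) |>
    mutate(
      n = vapply(.data$bin, function(b) sum(bins == b, na.rm = TRUE),
                 integer(1), USE.NAMES = FALSE),
      n_validated = vapply(.data$bin,
                           function(b) sum(sites$validated[bins == b],
                                           na.rm = TRUE), integer(1),
                           USE.NAMES = FALSE),
      fraction = ifelse(.data$n > 0, .data$n_validated / .data$n, NA_real_),
      low_support = .data$n < min_support
    )
}

#' Gate a mutation table to expressed genes for SMG analysis
#'
#' Maps mutations to genes, drops genes with mean TPM below `min_tpm`
#' (lowly expressed genes lack the RNA coverage to support selection
#' inference) and returns the per-mutation table formatted for downstream
#' dN/dS tools plus per-gene counts.
#'
#' @param mutations tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genes an `rnasm_genes` index.
#' @param tpm TPM tibble (`gene_id`, `tpm`; one row per gene or per
#'   gene/sample, averaged).
#' @param min_tpm expression floor (default 1).
#' @return list with `mutations` (gated per-mutation table with `gene_id`),
#'   `gene_counts`, `n_unmapped` (mutations outside any gene, dropped) and
#'   `genes_excluded`.
#' @export
smg_input_table <- function(mutations, genes, tpm, min_tpm = 1) {
  gid <- assign_gene(genes, mutations$chrom, mutations$pos)
  n_unmapped <- sum(is.na(gid))
  df <- mutations |>
    mutate(gene_id = gid) |>
    filter(!is.na(.data$gene_id))
  mean_tpm <- tpm |>
    group_by(.data$gene_id) |>
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop")
  expressed <- mean_tpm$gene_id[mean_tpm$mean_tpm >= min_tpm]
  gated <- df |> filter(.data$gene_id %in% expressed)
  list(
    mutations = gated |>
      select("sample_id", "chrom", "pos", "ref", "alt", "gene_id"),
    gene_counts = gated |> count(.data$gene_id, name = "n_mutations"),
    n_unmapped = n_unmapped,
    genes_excluded = setdiff(unique(df$gene_id), expressed)
  )
}

#' Plot binned validation fractions
#' @param object output tibble of [binned_validation()].
#' @param ... unused.
#' @export
plot_binned_validation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "bin", y = "validated fraction")
}
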