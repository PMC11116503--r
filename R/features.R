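# 26 per-candidate mutational features consumed by the stacking classifier.
# The feature list is config-visible (feature_names()) and its order is part
# of the fitted-model contract.

#' Names of the 26 classifier features, in model order
#' @return character vector of length 26.
#' @export
feature_names <- function() {
  c("vaf", "alt_count", "depth_total", "log_depth",
    "median_bq_alt", "bq_delta", "median_mq_alt", "mq_delta",
    "strand_bias_stat", "mean_relpos_alt", "frac_softclip_alt",
    "frac_multimap_alt", "mean_nm_alt", "dist_to_junction",
    "flank_unevenness", "gc100", "homopolymer_run",
    "trinuc_context_index", "subst_class_index", "is_tc_class",
    "editing_site_proximity", "cluster_density", "caller_qual",
    "aligner2_vaf_delta", "caller2_alt_count", "gene_tpm")
}

# sentinels used when optional evidence is unavailable; documented values so
# a fitted model's behaviour on imputed rows is reproducible
feature_sentinels <- function() {
  c(dist_to_junction = 1e4, editing_site_proximity = 1e4,
    caller_qual = 0, aligner2_vaf_delta = 0, caller2_alt_count = 0,
    gene_tpm = 0)
}

#' Extract classifier features for candidates
#'
#' Produces the 26-feature matrix used by [train_classifier()] /
#' [classify()]. Missing optional evidence is imputed with documented
#' sentinels: absent junction annotation and editing proximity are capped at
#' 1e4 bp, absent concordance columns behave as zero counts, unexpressed or
#' intergenic genes get TPM 0.
#'
#' @param candidates candidate tibble.
#' @param evidence evidence tibble.
#' @param genome `rnasm_genome` (GC, homopolymer and trinucleotide context).
#' @param editing editing-site tibble (may be empty).
#' @param genes optional `rnasm_genes` for gene TPM lookup.
#' @param tpm optional TPM tibble (`gene_id`, `tpm`).
#' @return tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`, then the 26
#'   features of [feature_names()], all finite.
#' @export
extract_features <- function(candidates, evidence, genome,
                             editing = tibble(chrom = character(),
                                              pos = integer()),
                             genes = NULL, tpm = NULL) {
  df <- candidates |>
    left_join(evidence, by = c("chrom", "pos", "ref", "alt"))
  sent <- feature_sentinels()

  vaf <- df$alt_count / pmax(1, df$alt_count + df$ref_count)
  sb_p <- strand_bias_p(df)
  sb_stat <- pmin(-log10(pmax(sb_p, 1e-100)), 100)

  snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1
  cls_idx <- rep(-1, nrow(df))
  tri_idx <- rep(-1, nrow(df))
  if (any(snv)) {
    cls_idx[snv] <- match(substitution_class(df$ref[snv], df$alt[snv]),
                          subst_classes()) - 1
    ctx <- trinucleotide_context(genome, df$chrom[snv], df$pos[snv],
                                 df$ref[snv], df$alt[snv])
    tri_idx[snv] <- ctx$channel_index
  }
  edist <- pmin(editing_distance(editing, df$chrom, df$pos),
                sent["editing_site_proximity"])

  # same-class T>C candidates within 150 bp (including self)
  tc <- is_tc_class(df)
  cdens <- rep(0, nrow(df))
  for (ch in unique(df$chrom[tc])) {
    sel <- which(tc & df$chrom == ch)
    p <- df$pos[sel]
    cdens[sel] <- vapply(p, function(x) sum(abs(p - x) <= 150), integer(1))
  }

  gene_tpm <- rep(0, nrow(df))
  if (!is.null(genes) && !is.null(tpm)) {
    gid <- assign_gene(genes, df$chrom, df$pos)
    gene_tpm <- tpm$tpm[match(gid, tpm$gene_id)]
    gene_tpm[is.na(gene_tpm)] <- 0
  }

  a2_vaf <- df$aligner2_alt_count / pmax(1, df$aligner2_depth)

  feats <- tibble(
    vaf = vaf,
    alt_count = df$alt_count,
    depth_total = df$depth_total,
    log_depth = log1p(df$depth_total),
    median_bq_alt = df$median_bq_alt,
    bq_delta = df$median_bq_alt - df$median_bq_ref,
    median_mq_alt = df$median_mq_alt,
    mq_delta = df$median_mq_alt - df$median_mq_ref,
    strand_bias_stat = sb_stat,
    mean_relpos_alt = df$mean_relpos_alt,
    frac_softclip_alt = df$frac_softclip_alt,
    frac_multimap_alt = df$frac_multimap_alt,
    mean_nm_alt = df$mean_nm_alt,
    dist_to_junction = if_else(is.na(df$dist_to_junction) |
                                 df$dist_to_junction < 0,
                               unname(sent["dist_to_junction"]),
                               pmin(df$dist_to_junction,
                                    sent["dist_to_junction"])),
    flank_unevenness = flanking_unevenness(df),
    gc100 = gc_content(genome, df$chrom, df$pos),
    homopolymer_run = as.numeric(homopolymer_run(genome, df$chrom, df$pos)),
    trinuc_context_index = tri_idx,
    subst_class_index = cls_idx,
    is_tc_class = as.numeric(tc),
    editing_site_proximity = unname(edist),
    cluster_density = cdens,
    caller_qual = df$caller_qual %||% rep(NA_real_, nrow(df)),
    aligner2_vaf_delta = vaf - a2_vaf,
    caller2_alt_count = df$caller2_alt_count,
    gene_tpm = log1p(gene_tpm)
  )
  # impute remaining gaps: sentinel where documented, 0 otherwise
  for (cn in names(feats)) {
    v <- feats[[cn]]
    miss <- !is.finite(v)
    if (any(miss)) {
      v[miss] <- if (cn %in% names(sent)) unname(sent[cn]) else 0
      feats[[cn]] <- v
    }
  }
  bind_cols(candidates |> select("sample_id", "chrom", "pos", "ref", "alt"),
            feats[, feature_names()])
}
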