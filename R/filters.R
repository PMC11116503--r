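# The 18-filter rejection stage. Each filter is a named predicate over the
# joined candidate + evidence table; the bank evaluates every enabled filter
# for every candidate and reports both independent rejections (filter applied
# alone) and attributed rejections (first failing filter in canonical order).

#' Canonical filter IDs, in attribution order
#' @return character vector of the 18 filter IDs.
#' @export
filter_ids <- function() {
  c("germline", "depth", "low_alt", "base_quality", "mapping_quality",
    "strand_bias", "multimap", "read_position", "soft_clip", "junction",
    "uneven_coverage", "homopolymer", "cluster", "editing", "population_af",
    "dual_aligner", "dual_caller", "no_evidence")
}

#' Filter-bank configuration
#'
#' All thresholds are exposed so the filter set can be reconciled against any
#' alternative definition. Disabled filters never reject.
#'
#' @param enabled named logical vector over [filter_ids()] (defaults: all on).
#' @param min_depth minimum total read depth at the site (reads).
#' @param min_alt_reads minimum alt-supporting reads.
#' @param min_vaf minimum variant allele fraction.
#' @param min_median_bq minimum median base quality of alt reads (Phred).
#' @param min_median_mq minimum median mapping quality of alt reads.
#' @param max_mean_nm maximum mean per-read mismatch count among alt reads.
#' @param max_strand_bias_p two-sided Fisher-exact p-value floor; the test is
#'   applied only when `alt_count >= strand_bias_min_alt`.
#' @param strand_bias_min_alt minimum alt reads before testing strand bias.
#' @param max_multimap_frac maximum fraction of multimapping alt reads.
#' @param relpos_min,relpos_max accepted range for the mean fractional
#'   position of the variant base within alt reads.
#' @param max_softclip_frac maximum fraction of alt reads soft-clipped within
#'   10 bp of the site.
#' @param max_junction_dist_reject reject sites within this many bp of an
#'   annotated exon boundary.
#' @param min_unevenness_ratio minimum site-depth / flank-depth ratio.
#' @param homopolymer_max_run maximum homopolymer run length near the site.
#' @param cluster_window,cluster_count hyper-editing cluster rule: at least
#'   `cluster_count` same-class T>C/A>G candidates within `cluster_window` bp
#'   all fail.
#' @param editing_window bp tolerance around known editing sites (0 = exact).
#' @param max_population_af maximum population allele frequency (used only
#'   when a population-AF resource is supplied).
#' @param min_aligner2_alt minimum alt reads after second-aligner realignment.
#' @param min_caller2_alt minimum alt reads reported by the second caller.
#' @return an object of class `rnasm_filter_config`.
#' @export
filter_config <- function(enabled = NULL,
                          min_depth = 10,
                          min_alt_reads = 3,
                          min_vaf = 0.05,
                          min_median_bq = 20,
                          min_median_mq = 20,
                          max_mean_nm = 5,
                          max_strand_bias_p = 0.001,
                          strand_bias_min_alt = 5,
                          max_multimap_frac = 0.5,
                          relpos_min = 0.1,
                          relpos_max = 0.9,
                          max_softclip_frac = 0.3,
                          max_junction_dist_reject = 5,
                          min_unevenness_ratio = 0.5,
                          homopolymer_max_run = 6,
                          cluster_window = 150,
                          cluster_count = 3,
                          editing_window = 0,
                          max_population_af = 0.001,
                          min_aligner2_alt = 2,
                          min_caller2_alt = 2) {
  en <- setNames(rep(TRUE, length(filter_ids())), filter_ids())
  if (!is.null(enabled)) {
    unknown <- setdiff(names(enabled), filter_ids())
    if (length(unknown) > 0) {
      abort(sprintf("unknown filter ID(s) in config: %s",
                    paste(unknown, collapse = ", ")))
    }
    en[names(enabled)] <- enabled
  }
  structure(
    list(enabled = en, min_depth = min_depth, min_alt_reads = min_alt_reads,
         min_vaf = min_vaf, min_median_bq = min_median_bq,
         min_median_mq = min_median_mq, max_mean_nm = max_mean_nm,
         max_strand_bias_p = max_strand_bias_p,
         strand_bias_min_alt = strand_bias_min_alt,
         max_multimap_frac = max_multimap_frac,
         relpos_min = relpos_min, relpos_max = relpos_max,
         max_softclip_frac = max_softclip_frac,
         max_junction_dist_reject = max_junction_dist_reject,
         min_unevenness_ratio = min_unevenness_ratio,
         homopolymer_max_run = homopolymer_max_run,
         cluster_window = cluster_window, cluster_count = cluster_count,
         editing_window = editing_window,
         max_population_af = max_population_af,
         min_aligner2_alt = min_aligner2_alt,
         min_caller2_alt = min_caller2_alt),
    class = "rnasm_filter_config")
}

# TRUE where the candidate is an A>G or T>C SNV (pyrimidine-collapsed T>C)
is_tc_class <- function(df) {
  nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    ((df$ref == "A" & df$alt == "G") | (df$ref == "T" & df$alt == "C"))
}

#' Distance to the nearest known RNA-editing site
#' @param editing editing-site tibble (`chrom`, `pos`).
#' @param chrom,pos query vectors.
#' @return numeric distances in bp (Inf when the chromosome has no site).
#' @export
editing_distance <- function(editing, chrom, pos) {
  out <- rep(Inf, length(pos))
  if (nrow(editing) == 0) return(out)
  by_chrom <- lapply(split(editing$pos, editing$chrom), sort)
  for (ch in names(by_chrom)) {
    sel <- which(chrom == ch)
    if (length(sel) == 0) next
    sp <- by_chrom[[ch]]
    i <- findInterval(pos[sel], sp)
    d_lo <- ifelse(i >= 1, pos[sel] - sp[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(sp), sp[pmin(i + 1, length(sp))] - pos[sel], Inf)
    out[sel] <- pmin(abs(d_lo), abs(d_hi))
  }
  out
}

#' Two-sided Fisher exact strand-bias p-values
#' @param ev evidence tibble with the four stranded counts.
#' @return numeric p-value vector (1 where counts are degenerate).
#' @export
strand_bias_p <- function(ev) {
  purrr::pmap_dbl(
    list(ev$ref_fwd, ev$ref_rev, ev$alt_fwd, ev$alt_rev),
    function(rf, rr, af, ar) {
      if (any(is.na(c(rf, rr, af, ar)))) return(1)
      fisher.test(matrix(c(rf, rr, af, ar), nrow = 2))$p.value
    })
}

# each fail_* returns TRUE = reject; NA-valued evidence passes (a candidate
# with no evidence at all is caught by the no_evidence pseudo-filter)
fail_fns <- function() {
  list(
    germline = function(df, res, cfg) {
      if (is.null(res$germline) || nrow(res$germline) == 0) {
        return(rep(FALSE, nrow(df)))
      }
      site_key(df) %in% site_key(res$germline)
    },
    depth = function(df, res, cfg) {
      !is.na(df$depth_total) & df$depth_total < cfg$min_depth
    },
    low_alt = function(df, res, cfg) {
      vaf <- df$alt_count / pmax(1, df$alt_count + df$ref_count)
      !is.na(df$alt_count) &
        (df$alt_count < cfg$min_alt_reads | vaf < cfg$min_vaf)
    },
    base_quality = function(df, res, cfg) {
      !is.na(df$median_bq_alt) & df$median_bq_alt < cfg$min_median_bq
    },
    mapping_quality = function(df, res, cfg) {
      (!is.na(df$median_mq_alt) & df$median_mq_alt < cfg$min_median_mq) |
        (!is.na(df$mean_nm_alt) & df$mean_nm_alt > cfg$max_mean_nm)
    },
    strand_bias = function(df, res, cfg) {
      test <- !is.na(df$alt_count) & df$alt_count >= cfg$strand_bias_min_alt
      out <- rep(FALSE, nrow(df))
      if (any(test)) {
        p <- strand_bias_p(df[test, ])
        out[test] <- p < cfg$max_strand_bias_p
      }
      out
    },
    multimap = function(df, res, cfg) {
      !is.na(df$frac_multimap_alt) &
        df$frac_multimap_alt > cfg$max_multimap_frac
    },
    read_position = function(df, res, cfg) {
      !is.na(df$mean_relpos_alt) &
        (df$mean_relpos_alt < cfg$relpos_min |
           df$mean_relpos_alt > cfg$relpos_max)
    },
    soft_clip = function(df, res, cfg) {
      !is.na(df$frac_softclip_alt) &
        df$frac_softclip_alt > cfg$max_softclip_frac
    },
    junction = function(df, res, cfg) {
      !is.na(df$dist_to_junction) & df$dist_to_junction >= 0 &
        df$dist_to_junction <= cfg$max_junction_dist_reject
    },
    uneven_coverage = function(df, res, cfg) {
      flanking_unevenness(df) < cfg$min_unevenness_ratio
    },
    homopolymer = function(df, res, cfg) {
      if (is.null(res$genome)) return(rep(FALSE, nrow(df)))
      homopolymer_run(res$genome, df$chrom, df$pos) > cfg$homopolymer_max_run
    },
    cluster = function(df, res, cfg) {
      tc <- is_tc_class(df)
      out <- rep(FALSE, nrow(df))
      for (ch in unique(df$chrom[tc])) {
        sel <- which(tc & df$chrom == ch)
        p <- df$pos[sel]
        nnear <- vapply(p, function(x) sum(abs(p - x) <= cfg$cluster_window),
                        integer(1))
        out[sel] <- nnear >= cfg$cluster_count
      }
      out
    },
    editing = function(df, res, cfg) {
      if (is.null(res$editing) || nrow(res$editing) == 0) {
        return(rep(FALSE, nrow(df)))
      }
      is_tc_class(df) &
        editing_distance(res$editing, df$chrom, df$pos) <= cfg$editing_window
    },
    population_af = function(df, res, cfg) {
      if (is.null(res$population_af)) return(rep(FALSE, nrow(df)))
      pa <- res$population_af
      af <- pa$af[match(site_key(df), site_key(pa))]
      !is.na(af) & af > cfg$max_population_af
    },
    dual_aligner = function(df, res, cfg) {
      !is.na(df$aligner2_alt_count) &
        df$aligner2_alt_count < cfg$min_aligner2_alt
    },
    dual_caller = function(df, res, cfg) {
      !is.na(df$caller2_alt_count) &
        df$caller2_alt_count < cfg$min_caller2_alt
    },
    no_evidence = function(df, res, cfg) {
      !df$has_evidence
    }
  )
}

# indels are exempt from the editing and hyper-editing cluster filters
indel_exempt_filters <- function() c("editing", "cluster")

#' Apply the 18-filter bank
#'
#' Joins candidates to their site evidence, evaluates every enabled filter
#' for every candidate and returns the pass set together with a
#' [tidy()]-able report. Outcomes are independent of candidate order.
#'
#' @param candidates candidate tibble ([read_vcf_candidates()]).
#' @param evidence evidence tibble ([read_evidence_table()] /
#'   [summarize_site()]).
#' @param resources named list with optional elements `germline` (tibble of
#'   chrom/pos/ref/alt), `editing` (tibble of chrom/pos), `genome`
#'   (`rnasm_genome`), `genes` (`rnasm_genes`), `population_af` (tibble with
#'   chrom/pos/ref/alt/af).
#' @param config an `rnasm_filter_config`.
#' @return an `rnasm_filter_result` list with elements `calls` (candidates
#'   plus evidence, `pass` flag and `failed_filters` string), `pass`
#'   (pass-set tibble), `report` (`rnasm_filter_report`) and `fail_matrix`
#'   (candidates x filters logical).
#' @export
apply_filter_bank <- function(candidates, evidence, resources = list(),
                              config = filter_config()) {
  stopifnot(inherits(config, "rnasm_filter_config"))
  df <- candidates |>
    left_join(evidence, by = c("chrom", "pos", "ref", "alt")) |>
    mutate(has_evidence = !is.na(.data$depth_total))
  fns <- fail_fns()
  ids <- filter_ids()
  fm <- matrix(FALSE, nrow = nrow(df), ncol = length(ids),
               dimnames = list(NULL, ids))
  inert <- character(0)
  for (id in ids) {
    if (!config$enabled[[id]]) next
    fail <- fns[[id]](df, resources, config)
    if (id %in% c("dual_aligner", "dual_caller") &&
        all(is.na(df[[if (id == "dual_aligner") "aligner2_alt_count"
                      else "caller2_alt_count"]]))) {
      inert <- c(inert, id)
    }
    if (id %in% indel_exempt_filters()) {
      fail <- fail & df$variant_type == "SNV"
    }
    fm[, id] <- fail
  }
  if (length(inert) > 0) {
    inform(sprintf("concordance filter(s) inert (no evidence column): %s",
                   paste(inert, collapse = ", ")))
  }
  pass <- rowSums(fm) == 0
  failed_filters <- apply(fm, 1, function(r) paste(ids[r], collapse = ";"))
  attributed <- apply(fm, 1, function(r) if (any(r)) ids[which(r)[1]]
                      else NA_character_)
  report <- tibble(
    filter = ids,
    enabled = unname(config$enabled[ids]),
    n_evaluated = nrow(df),
    n_rejected_independent = unname(colSums(fm)),
    n_rejected_attributed = as.integer(
      table(factor(attributed, levels = ids))),
    pct_rejected_independent = if (nrow(df) > 0)
      100 * unname(colSums(fm)) / nrow(df) else 0
  )
  report <- structure(report, class = c("rnasm_filter_report", class(report)),
                      n_input = nrow(df), n_pass = sum(pass))
  calls <- df |>
    mutate(pass = pass, failed_filters = failed_filters)
  structure(
    list(calls = calls, pass = calls |> filter(.data$pass),
         report = report, fail_matrix = fm),
    class = "rnasm_filter_result")
}

#' @export
print.rnasm_filter_result <- function(x, ...) {
  cat("<rnasm_filter_result> ", attr(x$report, "n_input"), " candidate(s), ",
      attr(x$report, "n_pass"), " pass\n", sep = "")
  invisible(x)
}

#' @export
tidy.rnasm_filter_report <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.rnasm_filter_report <- function(x, ...) {
  tibble(n_input = attr(x, "n_input"), n_pass = attr(x, "n_pass"),
         n_rejected = attr(x, "n_input") - attr(x, "n_pass"))
}

#' Plot per-filter rejection percentages
#' @param object an `rnasm_filter_report`.
#' @param mode `"independent"` (each filter applied alone) or `"attributed"`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rnasm_filter_report <- function(object, mode = "independent", ...) {
  df <- as_tibble(object)
  df$value <- if (mode == "independent") {
    df$pct_rejected_independent
  } else {
    100 * df$n_rejected_attributed / pmax(1, df$n_evaluated)
  }
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$filter, .data$value), y = .data$value)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = sprintf("%% of candidates rejected (%s)",
                                        mode))
}

# ---- single-filter convenience wrappers ------------------------------------

single_filter <- function(id, df, resources, config) {
  df$has_evidence <- !is.na(df$depth_total %||% NA)
  fail <- fail_fns()[[id]](df, resources, config)
  if (id %in% indel_exempt_filters() && "variant_type" %in% names(df)) {
    fail <- fail & df$variant_type == "SNV"
  }
  ifelse(fail, "fail", "pass")
}

#' Low mutated reads filter
#'
#' Fails sites with fewer than `min_alt_reads` alt reads or a VAF under
#' `min_vaf`.
#'
#' @param ev joined candidate/evidence tibble.
#' @param config an `rnasm_filter_config`.
#' @return character vector `"pass"`/`"fail"`.
#' @export
filter_low_mutated_reads <- function(ev, config = filter_config()) {
  single_filter("low_alt", ev, list(), config)
}

#' Dual-alignment concordance filter
#'
#' The variant must survive realignment by a second aligner with a distinct
#' clipping strategy; sites lacking second-aligner evidence pass (inert).
#'
#' @inheritParams filter_low_mutated_reads
#' @export
filter_dual_alignment <- function(ev, config = filter_config()) {
  single_filter("dual_aligner", ev, list(), config)
}

#' Dual variant-calling concordance filter
#'
#' The variant must be re-observed by an independent pileup-based caller;
#' sites lacking second-caller evidence pass (inert).
#'
#' @inheritParams filter_low_mutated_reads
#' @export
filter_dual_caller <- function(ev, config = filter_config()) {
  single_filter("dual_caller", ev, list(), config)
}

#' Known RNA-editing site filter
#'
#' Fails A>G / T>C SNVs within `editing_window` bp of a known editing site;
#' other substitution classes never fail.
#'
#' @inheritParams filter_low_mutated_reads
#' @param editing editing-site tibble.
#' @export
filter_editing_sites <- function(ev, editing, config = filter_config()) {
  single_filter("editing", ev, list(editing = editing), config)
}

#' Uneven-coverage filter
#'
#' Fails sites whose depth falls below `min_unevenness_ratio` times the
#' median flanking depth (a coverage pit at the variant site).
#'
#' @inheritParams filter_low_mutated_reads
#' @export
filter_uneven_coverage <- function(ev, config = filter_config()) {
  single_filter("uneven_coverage", ev, list(), config)
}

#' Germline filter
#'
#' Fails candidates with an allele-exact match in the matched-normal
#' germline set.
#'
#' @inheritParams filter_low_mutated_reads
#' @param germline germline tibble (`chrom`, `pos`, `ref`, `alt`).
#' @export
filter_germline <- function(ev, germline, config = filter_config()) {
  single_filter("germline", ev, list(germline = germline), config)
}
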