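# Per-site read evidence: the single structure consumed by the filter bank
# and the feature extractor. Evidence can be summarized from alignments
# (summarize_site) or supplied as a precomputed table (read_evidence_table);
# both routes feed identical downstream behaviour.

#' Column names of the evidence table
#'
#' Four site-key columns followed by 22 evidence fields. The aligner2_* and
#' caller2_* columns are optional on ingest; when absent they are filled with
#' NA so concordance filters can run inert.
#'
#' @return character vector of column names.
#' @export
evidence_schema <- function() {
  c("chrom", "pos", "ref", "alt",
    "depth_total", "alt_count", "ref_count",
    "alt_fwd", "alt_rev", "ref_fwd", "ref_rev",
    "median_bq_alt", "median_bq_ref", "median_mq_alt", "median_mq_ref",
    "mean_relpos_alt", "frac_softclip_alt", "frac_multimap_alt",
    "mean_nm_alt", "dist_to_junction",
    "flank_depth_left", "flank_depth_right",
    "aligner2_depth", "aligner2_alt_count", "caller2_alt_count", "dup_frac")
}

evidence_optional_cols <- function() {
  c("aligner2_depth", "aligner2_alt_count", "caller2_alt_count")
}

validate_evidence <- function(ev) {
  num <- setdiff(evidence_schema(), c("chrom", "ref", "alt"))
  for (cn in intersect(num, names(ev))) {
    if (any(!is.na(ev[[cn]]) & ev[[cn]] < 0 &
            cn != "dist_to_junction")) {
      abort(sprintf("negative value in evidence column '%s'", cn))
    }
  }
  if (any(duplicated(site_key(ev)))) abort("duplicate (chrom,pos,ref,alt) key")
  with(ev, {
    if (any(alt_fwd + alt_rev != alt_count)) {
      abort("alt_fwd + alt_rev != alt_count")
    }
    if (any(ref_fwd + ref_rev != ref_count)) {
      abort("ref_fwd + ref_rev != ref_count")
    }
    if (any(alt_count + ref_count > depth_total)) {
      abort("alt_count + ref_count exceeds depth_total")
    }
  })
  fr <- c("frac_softclip_alt", "frac_multimap_alt", "dup_frac")
  for (cn in fr) {
    v <- ev[[cn]]
    if (any(!is.na(v) & (v < 0 | v > 1))) {
      abort(sprintf("'%s' outside [0, 1]", cn))
    }
  }
  invisible(ev)
}

#' Read a precomputed site-evidence table
#'
#' @param path tab-delimited file whose header matches [evidence_schema()];
#'   the second-aligner / second-caller columns may be omitted.
#' @return validated evidence tibble with all schema columns.
#' @export
read_evidence_table <- function(path) {
  ev <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- setdiff(evidence_schema(), evidence_optional_cols())
  assert_columns(ev, required, "evidence table")
  for (cn in setdiff(evidence_optional_cols(), names(ev))) {
    ev[[cn]] <- NA_real_
  }
  unknown <- setdiff(names(ev), evidence_schema())
  if (length(unknown) > 0) {
    warn(sprintf("ignoring unknown evidence column(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  ev <- ev[, evidence_schema()]
  ev$pos <- as.integer(ev$pos)
  validate_evidence(ev)
  as_tibble(ev)
}

#' Write a site-evidence table
#' @param ev evidence tibble.
#' @param path output TSV path.
#' @export
write_evidence_table <- function(ev, path) {
  validate_evidence(ev)
  readr::write_tsv(ev[, evidence_schema()], path, progress = FALSE)
  invisible(path)
}

#' Flanking-coverage unevenness ratio
#'
#' Site depth over the median of the two flank depths; values well below 1
#' indicate a coverage pit at the variant site, a hallmark of misalignment.
#' Sites with missing flank depths return 1 by convention.
#'
#' @param ev evidence tibble (or any tibble with `depth_total`,
#'   `flank_depth_left`, `flank_depth_right`).
#' @return numeric vector of ratios (>= 0).
#' @export
flanking_unevenness <- function(ev) {
  flank <- purrr::map2_dbl(ev$flank_depth_left, ev$flank_depth_right,
                           ~ median(c(.x, .y)))
  out <- ev$depth_total / pmax(1, flank)
  out[is.na(flank)] <- 1
  out
}

# ---- alignment-based summarization -----------------------------------------

parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  list(lens = lens, ops = ops)
}

# walk one read's CIGAR; returns the query index aligned to ref position
# `site` (NA if not aligned there), whether a deletion spans the site,
# whether the exact indel of a candidate is present, and soft-clip geometry
walk_read <- function(start, cigar, site, indel = NULL) {
  cg <- parse_cigar(cigar)
  refpos <- start
  qpos <- 1L
  qidx <- NA_integer_
  del_span <- FALSE
  indel_match <- FALSE
  clip_ref <- integer(0)  # ref coordinate adjacent to each soft clip
  qlen_aligned <- sum(cg$lens[cg$ops %in% c("M", "=", "X", "I", "S")])
  for (i in seq_along(cg$ops)) {
    op <- cg$ops[i]; len <- cg$lens[i]
    if (op %in% c("M", "=", "X")) {
      if (site >= refpos && site <= refpos + len - 1L) {
        qidx <- qpos + (site - refpos)
      }
      refpos <- refpos + len
      qpos <- qpos + len
    } else if (op == "D") {
      if (!is.null(indel) && indel$type == "deletion" &&
          refpos == indel$pos + 1L && len == indel$len) {
        indel_match <- TRUE
      }
      if (site >= refpos && site <= refpos + len - 1L) del_span <- TRUE
      refpos <- refpos + len
    } else if (op == "N") {
      refpos <- refpos + len
    } else if (op == "I") {
      if (!is.null(indel) && indel$type == "insertion" &&
          refpos == indel$pos + 1L && len == indel$len) {
        indel_match <- TRUE
      }
      qpos <- qpos + len
    } else if (op == "S") {
      clip_ref <- c(clip_ref, if (qpos == 1L) refpos - 1L else refpos)
      qpos <- qpos + len
    }
  }
  list(qidx = qidx, del_span = del_span, indel_match = indel_match,
       clip_ref = clip_ref, qlen = qlen_aligned)
}

flank_depths <- function(bam, chrom, pos, flank = 25) {
  chrlen <- Rsamtools::scanBamHeader(bam)[[1]]$targets[chrom]
  left <- IRanges::IRanges(max(1, pos - flank), max(1, pos - 1))
  right <- IRanges::IRanges(min(chrlen, pos + 1), min(chrlen, pos + flank))
  get_med <- function(rng) {
    if (IRanges::start(rng) > IRanges::end(rng)) return(NA_real_)
    p <- Rsamtools::pileup(
      bam,
      scanBamParam = Rsamtools::ScanBamParam(
        which = GenomicRanges::GRanges(chrom, rng)),
      pileupParam = Rsamtools::PileupParam(
        max_depth = 100000, min_base_quality = 0, min_mapq = 0,
        min_nucleotide_depth = 1, distinguish_strands = FALSE,
        distinguish_nucleotides = FALSE, include_deletions = TRUE))
    depth <- rep(0, IRanges::width(rng))
    if (nrow(p) > 0) {
      depth[p$pos - IRanges::start(rng) + 1] <- p$count
    }
    median(depth)
  }
  c(left = get_med(left), right = get_med(right))
}

#' Summarize read evidence at candidate sites from a BAM file
#'
#' Counts follow pileup conventions: bases inside soft-clipped segments never
#' support the variant, duplicate-flagged reads contribute only to
#' `dup_frac`, reads with base quality below `bq_floor` at the site are
#' excluded from allele counts (but remain in `depth_total`), and
#' deletion-spanning reads count toward depth only. Secondary and
#' supplementary alignments are ignored. The second-aligner / second-caller
#' columns are returned as NA (they come from separate inputs, not from this
#' BAM).
#'
#' @param bam path to a coordinate-sorted, indexed BAM.
#' @param candidates candidate tibble from [read_vcf_candidates()].
#' @param genes optional `rnasm_genes` for `dist_to_junction` (-1 otherwise).
#' @param bq_floor base-quality floor for allele counting (Phred, default 10).
#' @param flank flank width in bp for the flanking-depth medians (default 25).
#' @return evidence tibble with one row per candidate, [evidence_schema()]
#'   columns.
#' @export
summarize_site <- function(bam, candidates, genes = NULL, bq_floor = 10,
                           flank = 25) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam))) {
    abort("BAM index (.bai) not found; index the alignment file first")
  }
  header <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  rows <- purrr::pmap(
    list(candidates$chrom, candidates$pos, candidates$ref, candidates$alt,
         candidates$variant_type),
    function(chrom, pos, ref, alt, vtype) {
      if (!chrom %in% names(header)) {
        abort(sprintf("chromosome '%s' absent from BAM header", chrom))
      }
      summarize_one_site(bam, chrom, pos, ref, alt, vtype, genes,
                         bq_floor, flank)
    })
  ev <- bind_rows(rows)
  validate_evidence(ev)
  ev
}

summarize_one_site <- function(bam, chrom, pos, ref, alt, vtype, genes,
                               bq_floor, flank) {
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos)),
    what = c("flag", "strand", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = param)[[1]]
  n_reads <- length(b$pos)
  empty <- tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    depth_total = 0, alt_count = 0, ref_count = 0,
    alt_fwd = 0, alt_rev = 0, ref_fwd = 0, ref_rev = 0,
    median_bq_alt = NA_real_, median_bq_ref = NA_real_,
    median_mq_alt = NA_real_, median_mq_ref = NA_real_,
    mean_relpos_alt = NA_real_, frac_softclip_alt = 0,
    frac_multimap_alt = 0, mean_nm_alt = NA_real_,
    dist_to_junction = if (is.null(genes)) -1 else
      junction_distance(genes, chrom, pos),
    flank_depth_left = NA_real_, flank_depth_right = NA_real_,
    aligner2_depth = NA_real_, aligner2_alt_count = NA_real_,
    caller2_alt_count = NA_real_, dup_frac = 0)
  if (n_reads == 0) return(empty)

  indel <- if (vtype == "insertion") {
    list(type = "insertion", pos = pos, len = nchar(alt) - nchar(ref))
  } else if (vtype == "deletion") {
    list(type = "deletion", pos = pos, len = nchar(ref) - nchar(alt))
  } else NULL

  walks <- purrr::map2(b$pos, b$cigar, walk_read, site = pos, indel = indel)
  covers <- vapply(walks, function(w) !is.na(w$qidx) || w$del_span,
                   logical(1))
  is_dup <- bitwAnd(b$flag, 1024L) > 0
  dup_frac <- if (sum(covers) > 0) mean(is_dup[covers]) else 0
  use <- covers & !is_dup
  depth_total <- sum(use)
  if (depth_total == 0) {
    out <- empty
    out$dup_frac <- dup_frac
    return(out)
  }

  idx <- which(use)
  base <- rep(NA_character_, n_reads)
  bq <- rep(NA_real_, n_reads)
  relpos <- rep(NA_real_, n_reads)
  clip_near <- rep(FALSE, n_reads)
  for (i in idx) {
    w <- walks[[i]]
    if (!is.na(w$qidx)) {
      base[i] <- substr(as.character(b$seq[[i]]), w$qidx, w$qidx)
      bq[i] <- as.integer(charToRaw(substr(as.character(b$qual[[i]]),
                                           w$qidx, w$qidx))) - 33L
      relpos[i] <- w$qidx / w$qlen
    }
    if (length(w$clip_ref) > 0) {
      clip_near[i] <- any(abs(w$clip_ref - pos) <= 10)
    }
  }
  nm <- if (!is.null(b$tag$NM)) as.numeric(b$tag$NM) else rep(NA_real_, n_reads)
  fwd <- b$strand == "+"

  if (vtype == "SNV") {
    is_alt <- use & !is.na(base) & base == alt & !is.na(bq) & bq >= bq_floor
    is_ref <- use & !is.na(base) & base == ref & !is.na(bq) & bq >= bq_floor
  } else {
    im <- vapply(walks, function(w) w$indel_match, logical(1))
    is_alt <- use & im
    is_ref <- use & !im & !is.na(base) & !is.na(bq) & bq >= bq_floor
  }

  fd <- flank_depths(bam, chrom, pos, flank)
  tibble(
    chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
    depth_total = depth_total,
    alt_count = sum(is_alt), ref_count = sum(is_ref),
    alt_fwd = sum(is_alt & fwd), alt_rev = sum(is_alt & !fwd),
    ref_fwd = sum(is_ref & fwd), ref_rev = sum(is_ref & !fwd),
    median_bq_alt = if (any(is_alt)) median(bq[is_alt]) else NA_real_,
    median_bq_ref = if (any(is_ref)) median(bq[is_ref]) else NA_real_,
    median_mq_alt = if (any(is_alt)) median(b$mapq[is_alt]) else NA_real_,
    median_mq_ref = if (any(is_ref)) median(b$mapq[is_ref]) else NA_real_,
    mean_relpos_alt = if (any(is_alt)) mean(relpos[is_alt], na.rm = TRUE)
      else NA_real_,
    frac_softclip_alt = if (any(is_alt)) mean(clip_near[is_alt]) else 0,
    frac_multimap_alt = if (any(is_alt)) mean(b$mapq[is_alt] == 0) else 0,
    mean_nm_alt = if (any(is_alt)) mean(nm[is_alt]) else NA_real_,
    dist_to_junction = if (is.null(genes)) -1 else
      junction_distance(genes, chrom, pos),
    flank_depth_left = unname(fd["left"]),
    flank_depth_right = unname(fd["right"]),
    aligner2_depth = NA_real_, aligner2_alt_count = NA_real_,
    caller2_alt_count = NA_real_,
    dup_frac = dup_frac)
}
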