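# Shared fixtures (built once per test run) and independent oracles.

library(tibble)
library(dplyr)

site_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

.bm_cache <- new.env(parent = emptyenv())

test_benchmark <- function(seed = 7, n_sites = 800, ...) {
  key <- paste("bm", seed, n_sites, ..., sep = "_")
  if (is.null(.bm_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("rnasm_", key))
    .bm_cache[[key]] <- make_benchmark(dir, seed = seed, n_sites = n_sites,
                                       ...)
  }
  .bm_cache[[key]]
}

benchmark_resources <- function(bm) {
  list(
    germline = bm$truth[bm$truth$class == "germline",
                        c("chrom", "pos", "ref", "alt")],
    editing = read_editing_sites(bm$paths[["editing"]]),
    genome = bm$genome,
    genes = bm$genes
  )
}

# tiny two-chromosome genome with known sequence, written from a string
string_genome <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), fa)
  read_genome(fa)
}

# O(n^2) pairwise-concordance AUC oracle (ties count 0.5)
auc_pairwise_oracle <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Independent scalar re-implementation of the 18 filter predicates, applied
# candidate by candidate with plain loops and direct inequalities. Used as
# the brute-force conjunction oracle for the filter bank.
oracle_filter_failures <- function(candidates, evidence, resources, config) {
  ids <- filter_ids()
  gl_keys <- if (!is.null(resources$germline)) {
    paste(resources$germline$chrom, resources$germline$pos,
          resources$germline$ref, resources$germline$alt)
  } else character(0)
  ev_keys <- paste(evidence$chrom, evidence$pos, evidence$ref, evidence$alt)
  ed <- resources$editing
  out <- vector("list", nrow(candidates))
  # precollect T>C-class SNV positions for the cluster rule
  tc_idx <- which(nchar(candidates$ref) == 1 & nchar(candidates$alt) == 1 &
                    ((candidates$ref == "A" & candidates$alt == "G") |
                       (candidates$ref == "T" & candidates$alt == "C")))
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    fails <- character(0)
    j <- match(paste(cd$chrom, cd$pos, cd$ref, cd$alt), ev_keys)
    is_snv <- nchar(cd$ref) == 1 && nchar(cd$alt) == 1
    is_tc <- is_snv && ((cd$ref == "A" && cd$alt == "G") ||
                          (cd$ref == "T" && cd$alt == "C"))
    if (paste(cd$chrom, cd$pos, cd$ref, cd$alt) %in% gl_keys) {
      fails <- c(fails, "germline")
    }
    if (is.na(j)) {
      fails <- c(fails, "no_evidence")
    } else {
      e <- evidence[j, ]
      if (e$depth_total < config$min_depth) fails <- c(fails, "depth")
      vaf <- e$alt_count / max(1, e$alt_count + e$ref_count)
      if (e$alt_count < config$min_alt_reads || vaf < config$min_vaf) {
        fails <- c(fails, "low_alt")
      }
      if (!is.na(e$median_bq_alt) &&
          e$median_bq_alt < config$min_median_bq) {
        fails <- c(fails, "base_quality")
      }
      if ((!is.na(e$median_mq_alt) &&
           e$median_mq_alt < config$min_median_mq) ||
          (!is.na(e$mean_nm_alt) && e$mean_nm_alt > config$max_mean_nm)) {
        fails <- c(fails, "mapping_quality")
      }
      if (e$alt_count >= config$strand_bias_min_alt) {
        p <- stats::fisher.test(matrix(c(e$ref_fwd, e$ref_rev,
                                         e$alt_fwd, e$alt_rev), 2))$p.value
        if (p < config$max_strand_bias_p) fails <- c(fails, "strand_bias")
      }
      if (!is.na(e$frac_multimap_alt) &&
          e$frac_multimap_alt > config$max_multimap_frac) {
        fails <- c(fails, "multimap")
      }
      if (!is.na(e$mean_relpos_alt) &&
          (e$mean_relpos_alt < config$relpos_min ||
             e$mean_relpos_alt > config$relpos_max)) {
        fails <- c(fails, "read_position")
      }
      if (!is.na(e$frac_softclip_alt) &&
          e$frac_softclip_alt > config$max_softclip_frac) {
        fails <- c(fails, "soft_clip")
      }
      if (!is.na(e$dist_to_junction) && e$dist_to_junction >= 0 &&
          e$dist_to_junction <= config$max_junction_dist_reject) {
        fails <- c(fails, "junction")
      }
      flank <- stats::median(c(e$flank_depth_left, e$flank_depth_right))
      ratio <- if (is.na(flank)) 1 else e$depth_total / max(1, flank)
      if (ratio < config$min_unevenness_ratio) {
        fails <- c(fails, "uneven_coverage")
      }
      if (!is.null(resources$genome)) {
        win <- genome_seq(resources$genome, cd$chrom,
                          max(1, cd$pos - 5),
                          min(resources$genome$lengths[[cd$chrom]],
                              cd$pos + 5))
        b <- strsplit(win, "")[[1]]
        run <- 1; best <- 1
        for (k in seq_along(b)[-1]) {
          run <- if (b[k] == b[k - 1]) run + 1 else 1
          best <- max(best, run)
        }
        if (best > config$homopolymer_max_run) {
          fails <- c(fails, "homopolymer")
        }
      }
      if (is_tc) {
        near <- 0
        for (k in tc_idx) {
          if (candidates$chrom[k] == cd$chrom &&
              abs(candidates$pos[k] - cd$pos) <= config$cluster_window) {
            near <- near + 1
          }
        }
        if (near >= config$cluster_count) fails <- c(fails, "cluster")
      }
      if (is_tc && !is.null(ed) && nrow(ed) > 0) {
        d <- Inf
        for (k in seq_len(nrow(ed))) {
          if (ed$chrom[k] == cd$chrom) {
            d <- min(d, abs(ed$pos[k] - cd$pos))
          }
        }
        if (d <= config$editing_window) fails <- c(fails, "editing")
      }
      if (!is.null(resources$population_af)) {
        pk <- paste(resources$population_af$chrom,
                    resources$population_af$pos,
                    resources$population_af$ref,
                    resources$population_af$alt)
        m <- match(paste(cd$chrom, cd$pos, cd$ref, cd$alt), pk)
        if (!is.na(m) &&
            resources$population_af$af[m] > config$max_population_af) {
          fails <- c(fails, "population_af")
        }
      }
      if (!is.na(e$aligner2_alt_count) &&
          e$aligner2_alt_count < config$min_aligner2_alt) {
        fails <- c(fails, "dual_aligner")
      }
      if (!is.na(e$caller2_alt_count) &&
          e$caller2_alt_count < config$min_caller2_alt) {
        fails <- c(fails, "dual_caller")
      }
    }
    fails <- fails[config$enabled[fails]]
    out[[i]] <- fails[order(match(fails, ids))]
  }
  out
}
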