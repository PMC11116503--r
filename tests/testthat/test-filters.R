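make_ev_row <- function(...) {
  base <- tibble::tibble(
    chrom = "chr1", pos = 500L, ref = "C", alt = "T",
    depth_total = 40, alt_count = 10, ref_count = 30,
    alt_fwd = 5, alt_rev = 5, ref_fwd = 15, ref_rev = 15,
    median_bq_alt = 36, median_bq_ref = 36,
    median_mq_alt = 60, median_mq_ref = 60,
    mean_relpos_alt = 0.5, frac_softclip_alt = 0,
    frac_multimap_alt = 0, mean_nm_alt = 1,
    dist_to_junction = -1, flank_depth_left = 40, flank_depth_right = 40,
    aligner2_depth = 40, aligner2_alt_count = 9, caller2_alt_count = 9,
    dup_frac = 0)
  dplyr::mutate(base, ...)
}

test_that("single-filter predicates decide the documented cases", {
  cfg <- filter_config()
  expect_equal(filter_low_mutated_reads(make_ev_row(alt_count = 2,
                                                    alt_fwd = 1,
                                                    alt_rev = 1), cfg),
               "fail")
  expect_equal(filter_low_mutated_reads(
    make_ev_row(alt_count = 5, alt_fwd = 3, alt_rev = 2, ref_count = 20,
                ref_fwd = 10, ref_rev = 10), cfg), "pass")
  expect_equal(filter_dual_alignment(make_ev_row(aligner2_alt_count = 0),
                                     cfg), "fail")
  expect_equal(filter_dual_alignment(make_ev_row(aligner2_alt_count = NA),
                                     cfg), "pass")
  expect_equal(filter_dual_caller(make_ev_row(caller2_alt_count = 0), cfg),
               "fail")
  expect_equal(filter_dual_caller(make_ev_row(caller2_alt_count = 10), cfg),
               "pass")
  expect_equal(filter_uneven_coverage(make_ev_row(), cfg), "pass")
  expect_equal(filter_uneven_coverage(
    make_ev_row(depth_total = 12, alt_count = 6, ref_count = 6,
                alt_fwd = 3, alt_rev = 3, ref_fwd = 3, ref_rev = 3), cfg),
    "fail")

  ed <- tibble::tibble(chrom = "chr1", pos = 500L)
  ag <- make_ev_row(ref = "A", alt = "G", variant_type = "SNV")
  ct <- make_ev_row(ref = "C", alt = "T", variant_type = "SNV")
  expect_equal(filter_editing_sites(ag, ed, cfg), "fail")
  expect_equal(filter_editing_sites(ct, ed, cfg), "pass")

  gl <- tibble::tibble(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  expect_equal(filter_germline(ct, gl, cfg), "fail")
  other_alt <- make_ev_row(ref = "C", alt = "G")
  expect_equal(filter_germline(other_alt, gl, cfg), "pass")
})

test_that("low-mutated-reads decisions match the inequality on a grid", {
  cfg <- filter_config()
  grid <- expand.grid(alt = 0:12, depth = c(5, 20, 60, 120))
  grid <- grid[grid$alt <= grid$depth, ]
  ev <- make_ev_row()[rep(1, nrow(grid)), ]
  ev$alt_count <- grid$alt
  ev$ref_count <- grid$depth - grid$alt
  ev$alt_fwd <- grid$alt; ev$alt_rev <- 0
  ev$ref_fwd <- ev$ref_count; ev$ref_rev <- 0
  ev$depth_total <- grid$depth
  got <- filter_low_mutated_reads(ev, cfg) == "fail"
  want <- grid$alt < 3 | grid$alt / pmax(1, grid$depth) < 0.05
  expect_equal(got, want)
})

test_that("disabled filters never reject and unknown IDs error", {
  bm <- test_benchmark()
  res <- benchmark_resources(bm)
  off <- filter_config(enabled = setNames(rep(FALSE, 18), filter_ids()))
  r <- apply_filter_bank(bm$candidates, bm$evidence, res, off)
  expect_equal(nrow(r$pass), nrow(bm$candidates))
  expect_true(all(as_tibble(r$report)$n_rejected_independent == 0))
  expect_error(filter_config(enabled = c(nonsense = TRUE)), "unknown filter")
})

test_that("filter bank equals the brute-force conjunction oracle", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  res <- benchmark_resources(bm)
  cfg <- filter_config()
  r <- apply_filter_bank(bm$candidates, bm$evidence, res, cfg)
  oracle <- oracle_filter_failures(bm$candidates, bm$evidence, res, cfg)
  oracle_pass <- vapply(oracle, function(f) length(f) == 0, logical(1))
  expect_equal(r$calls$pass, oracle_pass)
  expect_equal(r$calls$failed_filters,
               vapply(oracle, paste, character(1), collapse = ";"))
})

test_that("report satisfies conservation and independence bounds", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  r <- apply_filter_bank(bm$candidates, bm$evidence,
                         benchmark_resources(bm))
  rep <- as_tibble(r$report)
  n_input <- attr(r$report, "n_input")
  n_pass <- attr(r$report, "n_pass")
  expect_equal(n_input, nrow(bm$candidates))
  expect_equal(n_pass + sum(!r$calls$pass), n_input)
  expect_equal(sum(rep$n_rejected_attributed), n_input - n_pass)
  expect_true(all(rep$n_rejected_independent >= rep$n_rejected_attributed))
  # a candidate failing exactly one filter: attributed == independent there
  one <- make_ev_row()
  gl <- tibble::tibble(chrom = "chr1", pos = 500L, ref = "C", alt = "T")
  cand <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = 500L,
                         ref = "C", alt = "T", variant_type = "SNV",
                         caller_qual = 1)
  r1 <- apply_filter_bank(cand, one, list(germline = gl))
  rep1 <- as_tibble(r1$report)
  expect_equal(rep1$n_rejected_attributed[rep1$filter == "germline"], 1L)
  expect_equal(rep1$n_rejected_independent[rep1$filter == "germline"], 1)
  expect_equal(sum(rep1$n_rejected_independent), 1)
})

test_that("outcomes are order-invariant and deterministic", {
  bm <- test_benchmark()
  res <- benchmark_resources(bm)
  r1 <- apply_filter_bank(bm$candidates, bm$evidence, res)
  perm <- sample(nrow(bm$candidates))
  r2 <- apply_filter_bank(bm$candidates[perm, ], bm$evidence, res)
  expect_identical(r1$calls$failed_filters[perm], r2$calls$failed_filters)
  r3 <- apply_filter_bank(bm$candidates, bm$evidence, res)
  expect_identical(r1$fail_matrix, r3$fail_matrix)
})

test_that("tightening any threshold never grows the pass set", {
  bm <- test_benchmark()
  res <- benchmark_resources(bm)
  base_pass <- site_key(apply_filter_bank(bm$candidates, bm$evidence, res,
                                          filter_config())$pass)
  tighter <- list(
    filter_config(min_depth = 20), filter_config(min_alt_reads = 5),
    filter_config(min_vaf = 0.1), filter_config(min_median_bq = 30),
    filter_config(max_softclip_frac = 0.1),
    filter_config(min_unevenness_ratio = 0.8),
    filter_config(max_junction_dist_reject = 20),
    filter_config(min_caller2_alt = 5), filter_config(min_aligner2_alt = 5),
    filter_config(editing_window = 30), filter_config(cluster_count = 2),
    filter_config(homopolymer_max_run = 3))
  for (cfg in tighter) {
    p <- site_key(apply_filter_bank(bm$candidates, bm$evidence, res,
                                    cfg)$pass)
    expect_true(all(p %in% base_pass))
  }
})

test_that("truth classes are intercepted by their designated filters", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  res <- benchmark_resources(bm)
  r <- apply_filter_bank(bm$candidates, bm$evidence, res)
  fm <- r$fail_matrix
  cls <- bm$truth$class
  expect_gte(mean(fm[cls == "rt_error", "dual_caller"]), 0.9)
  art <- cls %in% c("softclip_artifact", "junction_artifact")
  expect_gte(mean(fm[art, "dual_aligner"] | fm[art, "soft_clip"] |
                    fm[art, "junction"]), 0.9)
  expect_equal(mean(fm[cls == "germline", "germline"]), 1.0)
  expect_equal(sum(fm[cls == "somatic", "germline"]), 0L)
  # known editing sites are exactly the coordinate intersection
  known <- bm$truth$known_editing
  expect_true(all(fm[known, "editing"]))
  expect_false(any(fm[!known, "editing"]))
})

test_that("RNA-specific filters raise precision over the DNA-generic set", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  res <- benchmark_resources(bm)
  rna_specific <- c("editing", "cluster", "dual_aligner", "dual_caller",
                    "soft_clip", "junction", "uneven_coverage",
                    "read_position", "multimap", "strand_bias")
  dna_only <- filter_config(
    enabled = setNames(!filter_ids() %in% rna_specific, filter_ids()))
  precision <- function(r) {
    keep <- r$calls$pass
    mean(bm$truth$class[keep] == "somatic")
  }
  p_dna <- precision(apply_filter_bank(bm$candidates, bm$evidence, res,
                                       dna_only))
  p_all <- precision(apply_filter_bank(bm$candidates, bm$evidence, res,
                                       filter_config()))
  expect_gt(p_all, p_dna)
})

test_that("no-evidence candidates are auto-rejected by the pseudo-filter", {
  bm <- test_benchmark()
  cand <- bm$candidates[1:5, ]
  ev <- bm$evidence[2:5, ]
  r <- apply_filter_bank(cand, ev, benchmark_resources(bm))
  expect_true(grepl("no_evidence", r$calls$failed_filters[1]))
  expect_false(r$calls$pass[1])
})
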