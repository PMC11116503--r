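test_that("fixed seeds give byte-identical benchmark files", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  b1 <- make_benchmark(d1, seed = 5, n_sites = 150)
  b2 <- make_benchmark(d2, seed = 5, n_sites = 150)
  for (f in names(b1$paths)) {
    expect_identical(readLines(b1$paths[[f]]), readLines(b2$paths[[f]]),
                     label = f)
  }
  # different seeds -> (almost surely) disjoint somatic site sets
  b3 <- make_benchmark(file.path(tempdir(), "det3"), seed = 6,
                       n_sites = 150)
  k1 <- with(subset(b1$truth, class == "somatic"), paste(chrom, pos))
  k3 <- with(subset(b3$truth, class == "somatic"), paste(chrom, pos))
  expect_lt(length(intersect(k1, k3)), 3)
})

test_that("generated genome and gene models satisfy the index invariants", {
  sim <- simulate_genome(3, n_chrom = 2, chrom_len = 50000, n_genes = 12)
  expect_equal(unname(sim$genome$lengths), c(50000, 50000))
  # gene_model_index validates exon disjointness/strand on construction;
  # writing and re-reading the GTF reproduces the exon table
  fa <- tempfile(fileext = ".fa"); gtf <- tempfile(fileext = ".gtf")
  write_genome_files(sim, fa, gtf)
  genes2 <- read_gene_models(gtf)
  expect_equal(
    dplyr::arrange(genes2$exons, gene_id, start),
    dplyr::arrange(sim$genes$exons, gene_id, start))
  genome2 <- read_genome(fa)
  expect_equal(genome_seq(genome2, "chr1", 1000, 1100),
               genome_seq(sim$genome, "chr1", 1000, 1100))
  expect_error(simulate_genome(1, chrom_len = 500), "at least 1000")
  # zero genes -> empty gene set
  sim0 <- simulate_genome(4, n_genes = 0)
  expect_equal(nrow(sim0$genes$exons), 0)
})

test_that("truth classes respect their placement rules", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  tr <- bm$truth
  dj <- junction_distance(bm$genes, tr$chrom, tr$pos)
  expect_true(all(dj[tr$class == "junction_artifact"] <= 5))
  expect_true(all(dj[tr$class == "junction_artifact"] >= 0))
  expect_true(all(dj[tr$class == "somatic"] > 10 |
                    dj[tr$class == "somatic"] == -1))
  # editing alleles are A>G / T>C and known sites are in the BED
  ed <- tr[tr$class == "editing", ]
  expect_true(all(paste(ed$ref, ed$alt) %in% c("A G", "T C")))
  bed <- read_editing_sites(bm$paths[["editing"]])
  expect_setequal(paste(ed$chrom[ed$known_editing], ed$pos[ed$known_editing]),
                  paste(bed$chrom, bed$pos))
  # all sites unique, one candidate each
  expect_false(any(duplicated(paste(tr$chrom, tr$pos))))
  # germline VCF holds exactly the germline truths
  gl <- read_germline_vcf(bm$paths[["germline"]])
  expect_equal(nrow(gl), sum(tr$class == "germline"))
})

test_that("class counts follow the requested proportions", {
  sim <- simulate_genome(12, chrom_len = 200000, n_genes = 60)
  props <- default_class_proportions()
  tr <- simulate_truth(sim, 12, n_sites = 5000,
                       class_proportions = props)
  counts <- table(factor(tr$truth$class, levels = names(props)))
  gof <- chisq.test(as.integer(counts), p = as.numeric(props))
  expect_gt(gof$p.value, 0.01)
  # degenerate requests
  one <- simulate_truth(sim, 1, n_sites = 50,
                        class_proportions = c(somatic = 1, germline = 0,
                                              editing = 0, rt_error = 0,
                                              softclip_artifact = 0,
                                              junction_artifact = 0))
  expect_true(all(one$truth$class == "somatic"))
  empty <- simulate_truth(sim, 1, n_sites = 0)
  expect_equal(nrow(empty$truth), 0)
  expect_error(simulate_truth(sim, 1, 10,
                              class_proportions = c(somatic = 0.5)),
               "sum to 1")
})

test_that("evidence signatures encode the artifact classes", {
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  ev <- bm$evidence; cls <- bm$truth$class
  expect_true(all(ev$caller2_alt_count[cls == "rt_error"] == 0))
  expect_true(all(ev$frac_softclip_alt[cls == "softclip_artifact"] >= 0.8))
  expect_true(all(ev$aligner2_alt_count[
    cls %in% c("softclip_artifact", "junction_artifact")] == 0))
  expect_true(all(ev$dist_to_junction[cls == "junction_artifact"] <= 5))
  validate_evidence(ev)
})

test_that("evidence invariants hold across seeds", {
  sim <- simulate_genome(30, chrom_len = 60000, n_genes = 20)
  for (seed in 31:38) {
    tr <- simulate_truth(sim, seed, n_sites = 120)
    ev <- simulate_evidence(tr$truth, sim, seed)
    expect_silent(rnasm:::validate_evidence(ev$evidence))
    expect_true(all(ev$evidence$alt_count >= 1))
  }
  expect_error(simulate_evidence(tibble(), sim, 1, mean_depth = 5),
               "at least 10")
})

test_that("an all-somatic benchmark passes the default filter bank", {
  sim <- simulate_genome(11)
  tr <- simulate_truth(sim, 11, n_sites = 400,
                       class_proportions = c(somatic = 1, germline = 0,
                                             editing = 0, rt_error = 0,
                                             softclip_artifact = 0,
                                             junction_artifact = 0))
  ev <- simulate_evidence(tr$truth, sim, 11, mean_depth = 100)
  r <- apply_filter_bank(ev$candidates, ev$evidence,
                         resources = list(genome = sim$genome,
                                          genes = sim$genes))
  expect_gte(nrow(r$pass) / nrow(ev$candidates), 0.95)
})

test_that("a rule-based oracle on generating thresholds is near-perfect", {
  # separability-by-construction: the generating signatures themselves
  # classify the benchmark with precision >= 0.95
  bm <- test_benchmark(seed = 7, n_sites = 1000)
  ev <- bm$evidence
  gl <- site_key(bm$truth[bm$truth$class == "germline", ])
  ed <- read_editing_sites(bm$paths[["editing"]])
  call_somatic <- ev$caller2_alt_count > 0 & ev$aligner2_alt_count > 0 &
    ev$median_bq_alt >= 30 &
    !(site_key(ev) %in% gl) &
    !(rnasm:::is_tc_class(ev) &
        editing_distance(ed, ev$chrom, ev$pos) <= 80)
  precision <- mean(bm$truth$class[call_somatic] == "somatic")
  expect_gte(precision, 0.95)
})
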