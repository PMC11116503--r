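test_that("evidence table round-trips and rejects invariant violations", {
  bm <- test_benchmark()
  path <- tempfile(fileext = ".tsv")
  write_evidence_table(bm$evidence, path)
  back <- read_evidence_table(path)
  expect_equal(back, bm$evidence)

  ev <- bm$evidence[1:3, ]
  ev$alt_fwd[2] <- ev$alt_fwd[2] + 1
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_evidence_table(path), "alt_fwd")

  ev <- bm$evidence[1:3, ]
  ev$depth_total[1] <- -5
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_evidence_table(path), "negative|depth")

  ev <- bm$evidence[c(1, 1), ]
  write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_evidence_table(path), "duplicate")
})

test_that("optional concordance columns are filled with NA sentinels", {
  bm <- test_benchmark()
  ev <- bm$evidence[1:5, setdiff(evidence_schema(),
                                 c("aligner2_depth", "aligner2_alt_count",
                                   "caller2_alt_count"))]
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(ev, path)
  back <- read_evidence_table(path)
  expect_true(all(is.na(back$caller2_alt_count)))
  # and the concordance filters run inert on them
  expect_true(all(filter_dual_caller(back) == "pass"))
  expect_true(all(filter_dual_alignment(back) == "pass"))
})

test_that("flanking unevenness equals the direct formula", {
  ev <- tibble::tibble(depth_total = c(40, 20, 40, 15),
                       flank_depth_left = c(40, 40, 0, NA),
                       flank_depth_right = c(40, 40, 0, NA))
  expect_equal(flanking_unevenness(ev), c(1, 0.5, 40, 1))
  set.seed(5)
  ev <- tibble::tibble(depth_total = sample(1:200, 50, TRUE),
                       flank_depth_left = sample(1:200, 50, TRUE),
                       flank_depth_right = sample(1:200, 50, TRUE))
  manual <- mapply(function(d, l, r) d / max(1, median(c(l, r))),
                   ev$depth_total, ev$flank_depth_left,
                   ev$flank_depth_right)
  expect_equal(flanking_unevenness(ev), unname(manual))
})

test_that("junction distance matches an exhaustive boundary scan", {
  bm <- test_benchmark()
  genes <- bm$genes
  # trivial anchors
  ex1 <- genes$exons[1, ]
  expect_equal(junction_distance(genes, ex1$chrom, ex1$end), 0)
  expect_equal(junction_distance(genes, "chr1", 50), -1)  # intergenic

  set.seed(9)
  pos <- sample.int(90000, 200)
  chrom <- sample(c("chr1", "chr2"), 200, TRUE)
  got <- junction_distance(genes, chrom, pos)
  for (i in seq_len(200)) {
    overl <- genes$genes[genes$genes$chrom == chrom[i] &
                           genes$genes$start <= pos[i] &
                           genes$genes$end >= pos[i], ]
    if (nrow(overl) == 0) {
      expect_identical(got[i], -1)
    } else {
      ex <- genes$exons[genes$exons$gene_id %in% overl$gene_id, ]
      expect_equal(got[i], min(abs(c(ex$start, ex$end) - pos[i])))
    }
  }
})

test_that("summarize_site reproduces constructed pileup counts", {
  sim <- simulate_genome(21, n_chrom = 1, chrom_len = 5000, n_genes = 2)
  pos <- 2500L
  ref <- genome_seq(sim$genome, "chr1", pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  sam <- tempfile(fileext = ".sam")
  simulate_site_reads(sim$genome, "chr1", pos, ref, alt, sam,
                      n_ref = 30, n_alt = 10, n_dup = 4, seed = 2)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  cand <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = pos,
                         ref = ref, alt = alt, variant_type = "SNV",
                         caller_qual = 10)
  ev <- summarize_site(bam, cand, genes = sim$genes)
  expect_equal(ev$depth_total, 40)          # duplicates excluded
  expect_equal(ev$alt_count, 10)
  expect_equal(ev$ref_count, 30)
  expect_equal(ev$alt_fwd + ev$alt_rev, 10)
  expect_equal(ev$dup_frac, 4 / 44)
  expect_equal(ev$median_bq_alt, 35)
  expect_equal(ev$median_mq_alt, 60)
  expect_true(ev$mean_relpos_alt > 0 && ev$mean_relpos_alt < 1)
  expect_true(ev$flank_depth_left > 0)
  expect_true(is.na(ev$caller2_alt_count))
  validate_evidence(ev)
})

test_that("alt bases inside soft-clipped segments never count as support", {
  sim <- simulate_genome(22, n_chrom = 1, chrom_len = 5000, n_genes = 0)
  pos <- 3000L
  ref <- genome_seq(sim$genome, "chr1", pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  sam <- tempfile(fileext = ".sam")
  simulate_site_reads(sim$genome, "chr1", pos, ref, alt, sam,
                      n_ref = 12, n_alt = 0, n_alt_clipped = 6, seed = 3)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  cand <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = pos,
                         ref = ref, alt = alt, variant_type = "SNV",
                         caller_qual = 10)
  ev <- summarize_site(bam, cand)
  expect_equal(ev$alt_count, 0)
  expect_equal(ev$ref_count, 12)
  expect_equal(ev$dist_to_junction, -1)  # no gene models supplied
})

test_that("summarize_site per-read tallies match an independent recount", {
  sim <- simulate_genome(23, n_chrom = 1, chrom_len = 8000, n_genes = 0)
  sam <- tempfile(fileext = ".sam")
  set.seed(41)
  sites <- tibble::tibble(
    pos = as.integer(seq(1000, 7000, length.out = 12)),
    n_ref = sample(5:40, 12, TRUE),
    n_alt = sample(0:15, 12, TRUE))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    ref <- genome_seq(sim$genome, "chr1", p, p)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    sami <- tempfile(fileext = ".sam")
    simulate_site_reads(sim$genome, "chr1", p, ref, alt, sami,
                        n_ref = sites$n_ref[i], n_alt = sites$n_alt[i],
                        seed = 100 + i)
    bam <- Rsamtools::asBam(sami, tempfile(), overwrite = TRUE)
    cand <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = p,
                           ref = ref, alt = alt, variant_type = "SNV",
                           caller_qual = 1)
    ev <- summarize_site(bam, cand)
    # independent recount straight from the SAM text
    lines <- readLines(sami)
    body <- lines[!startsWith(lines, "@")]
    f <- strsplit(body, "\t")
    covered <- vapply(f, function(x) {
      st <- as.integer(x[4]); len <- nchar(x[10])
      grepl("^\\d+M$", x[6]) && p >= st && p <= st + len - 1
    }, logical(1))
    base_at <- vapply(f, function(x) {
      st <- as.integer(x[4])
      substr(x[10], p - st + 1, p - st + 1)
    }, character(1))
    expect_equal(ev$depth_total, sum(covered))
    expect_equal(ev$alt_count, sum(covered & base_at == alt))
    expect_equal(ev$ref_count, sum(covered & base_at == ref))
  }
})

test_that("evidence from alignments and from TSV drive identical filtering", {
  sim <- simulate_genome(24, n_chrom = 1, chrom_len = 5000, n_genes = 0)
  pos <- 2200L
  ref <- genome_seq(sim$genome, "chr1", pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  sam <- tempfile(fileext = ".sam")
  simulate_site_reads(sim$genome, "chr1", pos, ref, alt, sam,
                      n_ref = 25, n_alt = 8, seed = 4)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  cand <- tibble::tibble(sample_id = "s", chrom = "chr1", pos = pos,
                         ref = ref, alt = alt, variant_type = "SNV",
                         caller_qual = 10)
  ev1 <- summarize_site(bam, cand)
  path <- tempfile(fileext = ".tsv")
  write_evidence_table(ev1, path)
  ev2 <- read_evidence_table(path)
  r1 <- apply_filter_bank(cand, ev1, resources = list(genome = sim$genome))
  r2 <- apply_filter_bank(cand, ev2, resources = list(genome = sim$genome))
  expect_identical(r1$fail_matrix, r2$fail_matrix)
  expect_identical(r1$calls$failed_filters, r2$calls$failed_filters)
})
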