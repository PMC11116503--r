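rand_sets <- function(seed, n_pred = 120, n_ref = 100, n_samples = 3) {
  set.seed(seed)
  universe <- tibble(
    sample_id = sample(sprintf("P%d", 1:n_samples), 400, TRUE),
    chrom = sample(c("chr1", "chr2"), 400, TRUE),
    pos = sample.int(1e5, 400),
    ref = sample(c("A", "C", "G", "T"), 400, TRUE)) |>
    mutate(alt = vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))) |>
    distinct(sample_id, chrom, pos, .keep_all = TRUE)
  list(pred = universe[sample(nrow(universe), n_pred), ],
       ref = universe[sample(nrow(universe), n_ref), ],
       universe = universe)
}

deep_depth <- function(df, depth = 50) {
  df |> select(sample_id, chrom, pos) |> mutate(depth = depth)
}

test_that("identical sets give precision and sensitivity 1", {
  s <- rand_sets(1)
  d <- list(rna = deep_depth(s$universe), wxs = deep_depth(s$universe))
  v <- validate_calls(s$pred, s$pred, d)
  expect_equal(v$summary$precision_overall, 1)
  expect_true(all(v$per_patient$precision == 1, na.rm = TRUE))
  expect_true(all(v$per_patient$sensitivity == 1, na.rm = TRUE))
  expect_error(validate_calls(s$pred, s$pred, list()), "depth")
})

test_that("metrics equal brute-force set arithmetic on random sets", {
  for (seed in c(2, 3, 4)) {
    s <- rand_sets(seed)
    d <- list(rna = deep_depth(s$universe), wxs = deep_depth(s$universe))
    v <- validate_calls(s$pred, s$ref, d)
    key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt)
    inter <- sum(key(s$pred) %in% key(s$ref))
    expect_equal(v$summary$n_validated, inter)
    expect_equal(v$summary$precision_overall, inter / nrow(s$pred))
    # per-patient too
    for (p in unique(s$pred$sample_id)) {
      pp <- s$pred[s$pred$sample_id == p, ]
      rr <- s$ref[s$ref$sample_id == p, ]
      row <- v$per_patient[v$per_patient$sample_id == p, ]
      expect_equal(row$n_validated, sum(key(pp) %in% key(rr)))
      if (nrow(rr) > 0) {
        expect_equal(row$sensitivity, mean(key(rr) %in% key(pp)))
      }
    }
  }
})

test_that("the <10-read rule excludes exactly the low-coverage sites", {
  s <- rand_sets(5)
  pred <- s$pred
  # construct platform depths: first 20 predictions under-covered in wxs
  d_rna <- deep_depth(s$universe, 50)
  d_wxs <- deep_depth(s$universe, 50)
  low_keys <- paste(pred$sample_id, pred$chrom, pred$pos)[1:20]
  d_wxs$depth[paste(d_wxs$sample_id, d_wxs$chrom, d_wxs$pos) %in%
                low_keys] <- 8
  v <- validate_calls(pred, s$ref, list(rna = d_rna, wxs = d_wxs))
  expect_equal(v$n_excluded_predictions, 20)
  expect_equal(v$summary$n_predictions_compared, nrow(pred) - 20)
  # a site at exactly the floor stays in
  d_wxs$depth[1] <- 10
  v2 <- validate_calls(pred, s$ref, list(rna = d_rna, wxs = d_wxs))
  expect_lte(v2$n_excluded_predictions, 20)
})

test_that("swapping prediction and reference swaps the metrics", {
  s <- rand_sets(6)
  d <- list(rna = deep_depth(s$universe))
  v1 <- validate_calls(s$pred, s$ref, d)
  v2 <- validate_calls(s$ref, s$pred, d)
  expect_equal(v1$summary$n_validated, v2$summary$n_validated)
  p1 <- v1$per_patient |> arrange(sample_id)
  p2 <- v2$per_patient |> arrange(sample_id)
  expect_equal(p1$precision, p2$sensitivity)
  expect_equal(p1$sensitivity, p2$precision)
})

test_that("metrics are invariant under input permutation", {
  s <- rand_sets(7)
  d <- list(rna = deep_depth(s$universe))
  v1 <- validate_calls(s$pred, s$ref, d)
  v2 <- validate_calls(s$pred[sample(nrow(s$pred)), ],
                       s$ref[sample(nrow(s$ref)), ], d)
  expect_equal(v1$summary, v2$summary)
})

test_that("per-transition FDR handles trivial and empty classes", {
  pred <- tibble(ref = c("C", "C", "T", "A"), alt = c("A", "A", "C", "G"),
                 is_true = c(TRUE, TRUE, TRUE, TRUE))
  f <- fdr_by_transition(pred)
  expect_true(all(f$fdr[f$n_predictions > 0] == 0))
  expect_true(all(is.na(f$fdr[f$n_predictions == 0])))
  pred$is_true[pred$ref == "C"] <- FALSE
  f2 <- fdr_by_transition(pred)
  expect_equal(f2$fdr[f2$subst_class == "C>A"], 1.0)
})

test_that("binned validation recomposes the overall fraction exactly", {
  set.seed(8)
  sites <- tibble(depth = sample(1:200, 500, TRUE),
                  gc = runif(500),
                  validated = runif(500) < 0.7)
  b <- binned_validation(sites, by = "depth")
  w <- sum(b$fraction * b$n, na.rm = TRUE) / sum(b$n)
  expect_equal(w, mean(sites$validated), tolerance = 1e-12)
  # all-validated -> every non-empty bin at 1
  sites$validated <- TRUE
  b2 <- binned_validation(sites, by = "depth")
  expect_true(all(b2$fraction[b2$n > 0] == 1))
  # empty bin flagged, fraction undefined
  sites$depth <- sample(30:49, 500, TRUE)
  b3 <- binned_validation(sites, by = "depth")
  expect_true(is.na(b3$fraction[b3$bin == "[100,Inf]" |
                                  grepl("100", b3$bin)][1]))
  expect_true(all(b3$low_support[b3$n < 5]))
})

test_that("monotone validation probability is recovered across depth bins", {
  set.seed(9)
  n <- 4000
  depth <- sample(1:199, n, TRUE)
  pv <- pmin(0.95, 0.2 + 0.006 * depth)   # rises with depth by construction
  sites <- tibble(depth = depth, validated = runif(n) < pv)
  b <- binned_validation(sites, by = "depth",
                         breaks = c(0, 50, 100, 150, 200))
  expect_true(all(diff(b$fraction) > 0))
})

test_that("SMG input table gates on mean TPM", {
  bm <- test_benchmark()
  tpm <- bm$tpm
  res <- smg_input_table(bm$candidates, bm$genes, tpm, min_tpm = 1)
  expressed <- tpm$gene_id[tpm$tpm >= 1]
  expect_true(all(res$mutations$gene_id %in% expressed))
  expect_setequal(unique(res$mutations$gene_id),
                  intersect(expressed,
                            assign_gene(bm$genes, bm$candidates$chrom,
                                        bm$candidates$pos)))
  # gene below the floor is excluded
  low <- tpm$gene_id[tpm$tpm < 1]
  expect_false(any(res$mutations$gene_id %in% low))
  expect_true(all(res$gene_counts$n_mutations >= 1))
  # with the floor at 0 every mapped gene is retained
  res0 <- smg_input_table(bm$candidates, bm$genes, tpm, min_tpm = 0)
  expect_equal(nrow(res0$mutations),
               nrow(bm$candidates) - res0$n_unmapped)
})
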