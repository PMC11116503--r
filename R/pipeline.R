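# Workflow commands wiring the modules together under a single structured
# config. Every command derives all randomness from the one top-level seed
# and writes a run manifest (config hash, seed, per-stage counts) so any
# output is reproducible from its recorded configuration.

#' Read and validate a run configuration
#'
#' @param config a YAML file path or a named list. Known top-level keys:
#'   `seed`, `outdir`, `paths` (candidates, evidence, genome, gtf, germline,
#'   editing, signatures, tpm, model, labels, calls, references, depths),
#'   `filter` (threshold overrides for [filter_config()], plus `disable`),
#'   `ml` (`threshold`, `folds`), `evaluation` (`min_depth`), `simulate`
#'   (arguments of [make_benchmark()]).
#' @return validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "outdir", "paths", "filter", "ml", "evaluation",
             "simulate")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$outdir)) abort("config needs an 'outdir'")
  config
}

config_filter <- function(config) {
  fc <- config$filter %||% list()
  disable <- fc$disable
  fc$disable <- NULL
  cfg <- do.call(filter_config, fc)
  if (!is.null(disable)) {
    cfg$enabled[disable] <- FALSE
  }
  cfg
}

check_paths_exist <- function(paths) {
  paths <- unlist(paths)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(sprintf("config path(s) do not exist: %s",
                  paste(missing, collapse = ", ")))
  }
}

write_manifest <- function(config, command, counts, outputs) {
  manifest <- list(
    tool = "rnasm",
    version = as.character(utils::packageVersion("rnasm")),
    command = command,
    seed = config$seed,
    config_hash = as.character(rlang::hash(config)),
    counts = counts,
    outputs = as.list(setNames(basename(unlist(outputs)),
                               names(unlist(outputs)))))
  path <- file.path(config$outdir, sprintf("manifest_%s.json", command))
  write_stable_json(manifest, path)
  path
}

load_call_resources <- function(config) {
  p <- config$paths
  need <- c("candidates", "evidence", "genome")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0) {
    abort(sprintf("config paths are missing required entr%s: %s",
                  if (length(missing) > 1) "ies" else "y",
                  paste(missing, collapse = ", ")))
  }
  check_paths_exist(p[intersect(names(p),
                                c("candidates", "evidence", "genome", "gtf",
                                  "germline", "editing", "tpm", "model"))])
  genome <- read_genome(p$genome)
  genes <- if (!is.null(p$gtf)) read_gene_models(p$gtf) else NULL
  list(
    genome = genome, genes = genes,
    germline = if (!is.null(p$germline)) read_germline_vcf(p$germline)
      else NULL,
    editing = if (!is.null(p$editing)) read_editing_sites(p$editing)
      else tibble(chrom = character(), pos = integer()),
    tpm = if (!is.null(p$tpm)) read_tpm_table(p$tpm) else NULL)
}

#' Run the discovery workflow: ingest, filter, classify, annotate, write
#'
#' @param config run configuration (see [read_run_config()]).
#' @param skip_classifier apply only the filter bank even when a model
#'   bundle is configured.
#' @return invisibly, a list with `calls` (annotated tibble), the filter
#'   `result` and the manifest path.
#' @export
run_call <- function(config, skip_classifier = FALSE) {
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- load_call_resources(config)
  sample_id <- config$paths$sample_id %||% "sample"
  candidates <- read_vcf_candidates(config$paths$candidates, sample_id)
  if (!is.null(config$paths$sample_map)) {
    sm <- readr::read_tsv(config$paths$sample_map, show_col_types = FALSE,
                          progress = FALSE)
    mapped <- sm$sample_id[match(site_key(candidates), site_key(sm))]
    candidates$sample_id <- if_else(is.na(mapped), candidates$sample_id,
                                    mapped)
  }
  evidence <- read_evidence_table(config$paths$evidence)
  cfg <- config_filter(config)
  fr <- apply_filter_bank(candidates, evidence,
                          resources = res, config = cfg)
  calls <- fr$calls

  use_model <- !skip_classifier && !is.null(config$paths$model)
  if (use_model) {
    model <- read_model_bundle(config$paths$model)
    pass_idx <- which(calls$pass)
    if (length(pass_idx) > 0) {
      feats <- extract_features(
        calls[pass_idx, names(candidates)], evidence, res$genome,
        res$editing, res$genes, res$tpm)
      sc <- classify(model, feats,
                     threshold = config$ml$threshold %||% 0.5)
      calls$prob_dna <- NA_real_
      calls$prob_dna[pass_idx] <- sc$prob_dna
      calls$pass[pass_idx] <- sc$label == 1
      calls$failed_filters[pass_idx][sc$label == 0] <- "ml_classifier"
    }
  }

  snv <- calls$variant_type == "SNV"
  calls$subst_class <- NA_character_
  calls$subst_class[snv] <- substitution_class(calls$ref[snv],
                                               calls$alt[snv])
  calls$channel <- NA_character_
  if (any(snv)) {
    calls$channel[snv] <- trinucleotide_context(
      res$genome, calls$chrom[snv], calls$pos[snv], calls$ref[snv],
      calls$alt[snv])$channel
  }
  if (!is.null(res$genes)) {
    calls$region <- genic_region(res$genes, calls$chrom, calls$pos)
    calls$gene_id <- assign_gene(res$genes, calls$chrom, calls$pos)
  }

  out_base <- file.path(config$outdir, "calls")
  write_calls(calls, out_base, genome = res$genome)
  readr::write_tsv(as_tibble(fr$report),
                   file.path(config$outdir, "filter_report.tsv"),
                   progress = FALSE)
  write_stable_json(
    list(per_filter = as_tibble(fr$report),
         n_input = attr(fr$report, "n_input"),
         n_pass_filters = attr(fr$report, "n_pass")),
    file.path(config$outdir, "filter_report.json"))
  counts <- list(n_input = nrow(candidates),
                 n_pass_filters = attr(fr$report, "n_pass"),
                 n_final = sum(calls$pass),
                 classifier_applied = use_model)
  manifest <- write_manifest(config, "call", counts,
                             list(calls_vcf = paste0(out_base, ".vcf"),
                                  calls_tsv = paste0(out_base, ".tsv"),
                                  report = "filter_report.tsv"))
  invisible(list(calls = calls, result = fr, manifest = manifest))
}

#' Train the stacking classifier from labelled candidates
#'
#' Expects `paths$labels`: a TSV keyed by `sample_id`, `chrom`, `pos`,
#' `ref`, `alt` with a logical/0-1 `dna_backed` column labelling each
#' candidate as DNA-backed (1) or RNA-only (0).
#'
#' @param config run configuration.
#' @return invisibly, list with the fitted `model`, `cv` table and manifest
#'   path.
#' @export
run_train <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- load_call_resources(config)
  check_paths_exist(config$paths["labels"])
  labels <- readr::read_tsv(config$paths$labels, show_col_types = FALSE,
                            progress = FALSE)
  assert_columns(labels, c("sample_id", "chrom", "pos", "ref", "alt",
                           "dna_backed"), "label table")
  candidates <- read_vcf_candidates(config$paths$candidates,
                                    config$paths$sample_id %||% "sample")
  candidates <- candidates |>
    inner_join(labels |>
                 select("chrom", "pos", "ref", "alt", "dna_backed"),
               by = c("chrom", "pos", "ref", "alt"))
  if (nrow(candidates) == 0) abort("no candidates matched the label table")
  y <- as.integer(candidates$dna_backed)
  if (length(unique(y)) < 2) abort("label column contains a single class")
  evidence <- read_evidence_table(config$paths$evidence)
  feats <- extract_features(candidates |> select(-"dna_backed"), evidence,
                            res$genome, res$editing, res$genes, res$tpm)
  model <- train_classifier(feats, y, seed = config$seed,
                            k = config$ml$folds %||% 5)
  bundle <- file.path(config$outdir, "model_bundle.rds")
  write_model_bundle(model, bundle)
  readr::write_tsv(model$metadata$cv,
                   file.path(config$outdir, "cv_report.tsv"),
                   progress = FALSE)
  counts <- list(n_training = nrow(feats), n_positive = sum(y),
                 best_cv_auc = max(model$metadata$cv$cv_auc))
  manifest <- write_manifest(config, "train", counts,
                             list(model = bundle, cv = "cv_report.tsv"))
  invisible(list(model = model, cv = model$metadata$cv, manifest = manifest))
}

#' Evaluate calls against DNA-derived reference sets
#'
#' @param config run configuration; `paths$calls` (TSV from [run_call()]),
#'   `paths$references` (named list of TSV/VCF reference sets) and
#'   `paths$depths` (named list of depth TSVs) are required.
#' @return invisibly, list with the `rnasm_validation` and manifest path.
#' @export
run_evaluate <- function(config) {
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$paths
  if (is.null(p$references) || length(p$references) == 0) {
    abort("config needs paths$references")
  }
  if (is.null(p$depths) || length(p$depths) == 0) {
    abort("config needs paths$depths (per-platform depth lookups)")
  }
  check_paths_exist(c(p$calls, unlist(p$references), unlist(p$depths)))
  calls <- readr::read_tsv(p$calls, show_col_types = FALSE, progress = FALSE)
  if ("pass" %in% names(calls)) calls <- calls |> filter(.data$pass)
  read_ref <- function(path) {
    if (grepl("\\.vcf(\\.gz)?$", path)) {
      read_vcf_candidates(path) |>
        select("sample_id", "chrom", "pos", "ref", "alt")
    } else {
      readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
        select("sample_id", "chrom", "pos", "ref", "alt")
    }
  }
  references <- purrr::map(p$references, read_ref)
  depths <- purrr::map(p$depths, function(d)
    readr::read_tsv(d, show_col_types = FALSE, progress = FALSE))
  v <- validate_calls(calls, references, depths,
                      min_depth = config$evaluation$min_depth %||% 10)
  readr::write_tsv(v$per_patient,
                   file.path(config$outdir, "validation_per_patient.tsv"),
                   progress = FALSE)
  write_stable_json(
    list(summary = v$summary, overlaps = v$overlaps,
         n_excluded_predictions = v$n_excluded_predictions,
         n_excluded_reference = v$n_excluded_reference),
    file.path(config$outdir, "validation_summary.json"))
  counts <- list(n_compared = v$summary$n_predictions_compared,
                 n_validated = v$summary$n_validated,
                 n_excluded = v$n_excluded_predictions)
  manifest <- write_manifest(config, "evaluate", counts,
                             list(per_patient = "validation_per_patient.tsv",
                                  summary = "validation_summary.json"))
  invisible(list(validation = v, manifest = manifest))
}

#' Spectrum and signature analysis of final calls
#'
#' @param config run configuration; needs `paths$calls`, `paths$genome` and
#'   `paths$signatures`.
#' @param cohort fit one exposure vector for the pooled cohort instead of
#'   per sample.
#' @return invisibly, list with `spectrum`, `exposures`, `assignments` and
#'   manifest path.
#' @export
run_signatures <- function(config, cohort = FALSE) {
  config <- read_run_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- config$paths
  check_paths_exist(c(p$calls, p$genome, p$signatures))
  calls <- readr::read_tsv(p$calls, show_col_types = FALSE,
                           progress = FALSE)
  if ("pass" %in% names(calls)) calls <- calls |> filter(.data$pass)
  genome <- read_genome(p$genome)
  sigs <- read_signature_matrix(p$signatures)
  spectrum <- build_spectrum(calls, genome)
  exposures <- if (cohort) {
    e <- fit_exposures(rowSums(spectrum), sigs)
    tibble(sample_id = "cohort", signature = e$signature,
           exposure = e$exposure)
  } else {
    fit_exposures_cohort(spectrum, sigs)
  }
  snv <- calls |> filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  snv <- snv |>
    mutate(channel = trinucleotide_context(genome, .data$chrom, .data$pos,
                                           .data$ref, .data$alt)$channel)
  assignments <- purrr::map_dfr(unique(snv$sample_id), function(s) {
    exp_s <- exposures |>
      filter(.data$sample_id == if (cohort) "cohort" else s)
    assign_mutations(snv |> filter(.data$sample_id == s),
                     exp_s, sigs)
  })
  readr::write_tsv(tidy(spectrum),
                   file.path(config$outdir, "spectrum.tsv"),
                   progress = FALSE)
  readr::write_tsv(exposures, file.path(config$outdir, "exposures.tsv"),
                   progress = FALSE)
  readr::write_tsv(assignments |>
                     select("sample_id", "chrom", "pos", "ref", "alt",
                            "channel", "signature", "likelihood"),
                   file.path(config$outdir, "assignments.tsv"),
                   progress = FALSE)
  counts <- list(n_snv = sum(spectrum),
                 n_assigned = sum(assignments$signature != "unassigned"))
  manifest <- write_manifest(config, "signatures", counts,
                             list(spectrum = "spectrum.tsv",
                                  exposures = "exposures.tsv",
                                  assignments = "assignments.tsv"))
  invisible(list(spectrum = spectrum, exposures = exposures,
                 assignments = assignments, manifest = manifest))
}

#' Generate the synthetic benchmark via the workflow interface
#'
#' @param config run configuration; `simulate` block passed to
#'   [make_benchmark()].
#' @return invisibly, list with the benchmark objects and manifest path.
#' @export
run_simulate <- function(config) {
  config <- read_run_config(config)
  args <- config$simulate %||% list()
  args$dir <- config$outdir
  args$seed <- config$seed
  bm <- do.call(make_benchmark, args)
  counts <- list(
    n_candidates = nrow(bm$candidates),
    n_genes = nrow(bm$genes$genes),
    class_counts = as.list(table(bm$truth$class)),
    truth_hash = as.character(rlang::hash(bm$truth)))
  manifest <- write_manifest(config, "simulate", counts,
                             list(dir = config$outdir))
  invisible(c(bm, list(manifest = manifest)))
}
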