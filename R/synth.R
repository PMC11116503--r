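# Seeded generator of a miniature genome, gene models, truth-labelled
# variant candidates and site evidence. Evidence-level simulation is the
# default: it exercises every downstream stage without an aligner. The
# defaults below ARE the benchmark conditions; they are config keys so every
# experiment is reproducible from the configuration alone.

#' Default truth-class proportions for the benchmark
#' @return named numeric vector summing to 1.
#' @export
default_class_proportions <- function() {
  c(somatic = 0.45, germline = 0.15, editing = 0.20, rt_error = 0.10,
    softclip_artifact = 0.05, junction_artifact = 0.05)
}

#' Simulate a miniature genome with gene models
#'
#' Base composition alternates between GC-rich and GC-poor 10 kb blocks (so
#' GC-binned analyses see real variation); genes carry 2-8 non-overlapping
#' exons on a random strand.
#'
#' @param seed integer seed (full determinism: fixed seed, identical output).
#' @param n_chrom,chrom_len,n_genes genome dimensions.
#' @return list with `genome` (`rnasm_genome`) and `genes` (`rnasm_genes`).
#' @export
simulate_genome <- function(seed, n_chrom = 2, chrom_len = 100000,
                            n_genes = 40) {
  if (chrom_len < 1000) abort("chrom_len must be at least 1000")
  set.seed(derive_seed(seed, "genome"))
  chroms <- paste0("chr", seq_len(n_chrom))
  seqs <- vapply(chroms, function(ch) {
    block <- 10000
    n_block <- ceiling(chrom_len / block)
    pgc <- rep(c(0.35, 0.60), length.out = n_block)
    paste(vapply(seq_len(n_block), function(b) {
      len <- min(block, chrom_len - (b - 1) * block)
      p <- pgc[b]
      paste(sample(DNA_BASES, len, replace = TRUE,
                   prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
            collapse = "")
    }, character(1)), collapse = "")
  }, character(1))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- chroms
  genome <- structure(
    list(seqs = ss, lengths = setNames(Biostrings::width(ss), chroms)),
    class = "rnasm_genome")

  exon_rows <- list()
  if (n_genes > 0) {
    per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chrom + 1)))
    gi <- 0
    for (ci in seq_len(n_chrom)) {
      ng <- per_chrom[ci]
      if (ng == 0) next
      slot <- floor((chrom_len - 2000) / ng)
      for (g in seq_len(ng)) {
        gi <- gi + 1
        slot_start <- 1000 + (g - 1) * slot
        n_ex <- sample(2:8, 1)
        ex_len <- sample(80:300, n_ex, replace = TRUE)
        in_len <- if (n_ex > 1) sample(200:800, n_ex - 1, replace = TRUE)
          else integer(0)
        need <- sum(ex_len) + sum(in_len)
        while (need > slot - 200 && n_ex > 2) {   # shrink to fit the slot
          n_ex <- n_ex - 1
          ex_len <- ex_len[seq_len(n_ex)]
          in_len <- in_len[seq_len(n_ex - 1)]
          need <- sum(ex_len) + sum(in_len)
        }
        start <- slot_start + sample.int(max(1, slot - need - 100), 1)
        strand <- sample(c("+", "-"), 1)
        s <- start
        for (e in seq_len(n_ex)) {
          exon_rows[[length(exon_rows) + 1]] <- tibble(
            chrom = chroms[ci], start = s, end = s + ex_len[e] - 1,
            strand = strand,
            gene_id = sprintf("g%03d", gi),
            transcript_id = sprintf("g%03d.t1", gi))
          s <- s + ex_len[e] + if (e < n_ex) in_len[e] else 0
        }
      }
    }
  }
  exons <- if (length(exon_rows) > 0) bind_rows(exon_rows) else {
    tibble(chrom = character(), start = integer(), end = integer(),
           strand = character(), gene_id = character(),
           transcript_id = character())
  }
  list(genome = genome, genes = gene_model_index(exons))
}

#' Write a simulated genome to FASTA + GTF
#' @param sim output of [simulate_genome()].
#' @param fasta,gtf output paths.
#' @export
write_genome_files <- function(sim, fasta, gtf) {
  Biostrings::writeXStringSet(sim$genome$seqs, fasta, width = 70)
  con <- file(gtf, "wt")
  on.exit(close(con))
  writeLines("##description: simulated gene models", con)
  ex <- sim$genes$exons
  if (nrow(ex) > 0) {
    by_tx <- ex |> group_by(.data$transcript_id)
    tx <- by_tx |>
      summarise(chrom = first(.data$chrom), start = min(.data$start),
                end = max(.data$end), strand = first(.data$strand),
                gene_id = first(.data$gene_id), .groups = "drop")
    lines <- character(0)
    for (i in seq_len(nrow(tx))) {
      attr_g <- sprintf('gene_id "%s"; transcript_id "%s";',
                        tx$gene_id[i], tx$transcript_id[i])
      lines <- c(lines,
                 sprintf("%s\trnasm\tgene\t%d\t%d\t.\t%s\t.\t%s",
                         tx$chrom[i], tx$start[i], tx$end[i], tx$strand[i],
                         sprintf('gene_id "%s";', tx$gene_id[i])),
                 sprintf("%s\trnasm\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                         tx$chrom[i], tx$start[i], tx$end[i], tx$strand[i],
                         attr_g))
      exi <- ex |> filter(.data$transcript_id == tx$transcript_id[i])
      lines <- c(lines, sprintf(
        "%s\trnasm\texon\t%d\t%d\t.\t%s\t.\t%s",
        exi$chrom, exi$start, exi$end, exi$strand,
        sprintf('gene_id "%s"; transcript_id "%s";',
                exi$gene_id, exi$transcript_id)))
    }
    writeLines(lines, con)
  }
  invisible(c(fasta = fasta, gtf = gtf))
}

# positions at least `margin` bp from every exon boundary of the genome
boundary_distance_ok <- function(genes, chrom, pos, margin = 10) {
  if (nrow(genes$exons) == 0) return(rep(TRUE, length(pos)))
  bp <- genes$exons |>
    tidyr::pivot_longer(c("start", "end"), values_to = "bp")
  ok <- rep(TRUE, length(pos))
  for (ch in unique(chrom)) {
    b <- sort(unique(bp$bp[bp$gene_id %in%
                             genes$exons$gene_id[genes$exons$chrom == ch]]))
    sel <- which(chrom == ch)
    if (length(b) == 0) next
    i <- findInterval(pos[sel], b)
    d_lo <- ifelse(i >= 1, pos[sel] - b[pmax(i, 1)], Inf)
    d_hi <- ifelse(i < length(b), b[pmin(i + 1, length(b))] - pos[sel], Inf)
    ok[sel] <- pmin(abs(d_lo), abs(d_hi)) > margin
  }
  ok
}

#' Simulate a truth-labelled variant manifest
#'
#' Draws truth classes from `class_proportions`, places sites under
#' class-specific constraints (editing in exons on the transcript strand as
#' A>G / T>C pairs of one database-known and one novel site; junction
#' artifacts within 5 bp of exon boundaries; everything else at least 10 bp
#' away so classes are unambiguous) and assigns true VAFs: somatic
#' Beta(2, 5), reverse-transcription errors Beta(1, 20) (low-frequency),
#' editing Beta(3, 3), germline 0.5 or 1.0.
#'
#' @param sim output of [simulate_genome()].
#' @param seed integer seed.
#' @param n_sites number of candidate sites.
#' @param class_proportions named vector over the six truth classes,
#'   summing to 1.
#' @param frac_editing_known fraction of editing sites present in the known
#'   editing database (the rest are novel and must be caught by the
#'   classifier).
#' @param frac_indel fraction of somatic sites emitted as small indels.
#' @param n_samples candidates are split across this many sample IDs.
#' @return list with `truth` (manifest tibble), `germline` (chrom/pos/ref/
#'   alt tibble) and `editing_bed` (known sites tibble: chrom/pos/strand).
#' @export
simulate_truth <- function(sim, seed, n_sites = 2000,
                           class_proportions = default_class_proportions(),
                           frac_editing_known = 0.5,
                           frac_indel = 0.02,
                           n_samples = 4) {
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    abort("class proportions must sum to 1")
  }
  genome <- sim$genome; genes <- sim$genes
  set.seed(derive_seed(seed, "truth"))
  classes <- names(default_class_proportions())
  props <- class_proportions[classes]
  props[is.na(props)] <- 0
  cls_draw <- sample(classes, n_sites, replace = TRUE, prob = props)
  n_by <- table(factor(cls_draw, levels = classes))
  if (n_sites == 0) {
    empty <- tibble(sample_id = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    variant_type = character(), class = character(),
                    true_vaf = double(), known_editing = logical())
    return(list(truth = empty,
                germline = empty[, c("chrom", "pos", "ref", "alt")],
                editing_bed = tibble(chrom = character(), pos = integer(),
                                     strand = character())))
  }

  used <- new.env(hash = TRUE)
  claim <- function(chrom, pos) {
    k <- paste0(chrom, ":", pos)
    if (!is.null(used[[k]])) return(FALSE)
    used[[k]] <- TRUE
    TRUE
  }

  # exonic positions matching the editing-strand base (A on +, T on -)
  exonic_at_pool <- function() {
    ex <- genes$exons
    if (nrow(ex) == 0) return(tibble(chrom = character(), pos = integer(),
                                     strand = character()))
    purrr::pmap_dfr(ex, function(chrom, start, end, strand, ...) {
      s <- genome_seq(genome, chrom, start, end)
      want <- if (strand == "+") "A" else "T"
      rel <- which(strsplit(s, "")[[1]] == want)
      pos <- start + rel - 1
      keep <- pos - start >= 10 & end - pos >= 10 &
        pos > 60 & pos < genome$lengths[chrom] - 60
      tibble(chrom = chrom, pos = pos[keep], strand = strand)
    })
  }

  draw_generic <- function(n) {
    out <- tibble(chrom = character(), pos = integer())
    guard <- 0
    while (nrow(out) < n && guard < 50) {
      guard <- guard + 1
      ch <- sample(names(genome$lengths), n, replace = TRUE)
      p <- vapply(ch, function(c2)
        sample(61:(genome$lengths[c2] - 61), 1), integer(1))
      ok <- boundary_distance_ok(genes, ch, p, margin = 10)
      for (i in which(ok)) {
        if (nrow(out) >= n) break
        if (claim(ch[i], p[i])) {
          out <- bind_rows(out, tibble(chrom = ch[i], pos = p[i]))
        }
      }
    }
    if (nrow(out) < n) abort("could not place all generic sites")
    out
  }

  random_snv <- function(chrom, pos) {
    ref <- genome_seq(genome, chrom, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1),
                  character(1), USE.NAMES = FALSE)
    tibble(chrom = chrom, pos = pos, ref = ref, alt = alt,
           variant_type = "SNV")
  }

  rows <- list()

  # --- editing: pairs of (known anchor, novel partner) inside exons -------
  n_edit <- n_by[["editing"]]
  if (n_edit > 0) {
    pool <- exonic_at_pool()
    pool <- pool[sample.int(nrow(pool)), ]
    anchors <- list(); partners <- list()
    i <- 1
    while (length(anchors) + length(partners) < n_edit && i <= nrow(pool)) {
      a <- pool[i, ]; i <- i + 1
      if (!claim(a$chrom, a$pos)) next
      anchors[[length(anchors) + 1]] <- a
      if (length(anchors) + length(partners) >= n_edit) break
      cand <- pool |>
        filter(.data$chrom == a$chrom, abs(.data$pos - a$pos) >= 20,
               abs(.data$pos - a$pos) <= 80)
      placed <- FALSE
      for (j in seq_len(nrow(cand))) {
        if (claim(cand$chrom[j], cand$pos[j])) {
          partners[[length(partners) + 1]] <- cand[j, ]
          placed <- TRUE
          break
        }
      }
    }
    anchors <- bind_rows(anchors); partners <- bind_rows(partners)
    # split known/novel at frac_editing_known over the anchor set
    edit_sites <- bind_rows(
      anchors |> mutate(known_editing = TRUE),
      partners |> mutate(known_editing = FALSE))
    if (nrow(edit_sites) < n_edit) {
      abort("exon space too small for the requested editing sites")
    }
    target_known <- round(frac_editing_known * n_edit)
    # adjust the known flag count toward the requested fraction
    kn <- which(edit_sites$known_editing)
    if (length(kn) > target_known) {
      edit_sites$known_editing[sample(kn, length(kn) - target_known)] <- FALSE
    }
    edit_rows <- edit_sites |>
      mutate(ref = if_else(.data$strand == "+", "A", "T"),
             alt = if_else(.data$strand == "+", "G", "C"),
             variant_type = "SNV", class = "editing",
             true_vaf = rbeta(n(), 3, 3)) |>
      select(-"strand")
    rows[["editing"]] <- edit_rows
  }

  # --- junction artifacts: within 5 bp of an exon boundary ----------------
  n_junc <- n_by[["junction_artifact"]]
  if (n_junc > 0) {
    bnd <- genes$boundaries |>
      left_join(genes$genes |> select("gene_id", "chrom"), by = "gene_id")
    placed <- list()
    bnd <- bnd[sample.int(nrow(bnd)), ]
    bi <- 0
    max_tries <- 50 * n_junc
    while (length(placed) < n_junc && bi < max_tries) {
      bi <- bi + 1
      b <- bnd[((bi - 1) %% nrow(bnd)) + 1, ]
      off <- sample(-5:5, 1)
      p <- b$bp + off
      if (p < 61 || p > genome$lengths[b$chrom] - 61) next
      jd <- junction_distance(genes, b$chrom, p)
      if (jd < 0 || jd > 5) next   # must sit inside a gene, at the boundary
      if (!claim(b$chrom, p)) next
      placed[[length(placed) + 1]] <- tibble(chrom = b$chrom, pos = p)
    }
    if (length(placed) < n_junc) {
      abort("could not place all junction-artifact sites")
    }
    jp <- bind_rows(placed)
    rows[["junction_artifact"]] <- random_snv(jp$chrom, jp$pos) |>
      mutate(class = "junction_artifact", true_vaf = rbeta(n(), 2, 5),
             known_editing = FALSE)
  }

  # --- remaining classes: generic placement -------------------------------
  for (cl in c("somatic", "germline", "rt_error", "softclip_artifact")) {
    ncl <- n_by[[cl]]
    if (ncl == 0) next
    gp <- draw_generic(ncl)
    r <- random_snv(gp$chrom, gp$pos)
    vaf <- switch(cl,
                  somatic = rbeta(ncl, 2, 5),
                  germline = sample(c(0.5, 1), ncl, replace = TRUE,
                                    prob = c(0.9, 0.1)),
                  rt_error = rbeta(ncl, 1, 20),
                  softclip_artifact = rbeta(ncl, 2, 5))
    r <- r |> mutate(class = cl, true_vaf = vaf, known_editing = FALSE)
    if (cl == "somatic" && frac_indel > 0 && ncl >= 10) {
      n_ind <- max(1, round(frac_indel * ncl))
      idx <- sample.int(ncl, n_ind)
      for (ii in idx) {
        if (runif(1) < 0.5) {   # insertion
          ins <- paste(sample(DNA_BASES, 2, replace = TRUE), collapse = "")
          r$alt[ii] <- paste0(r$ref[ii], ins)
          r$variant_type[ii] <- "insertion"
        } else {                # 2-bp deletion
          r$ref[ii] <- genome_seq(genome, r$chrom[ii], r$pos[ii],
                                  r$pos[ii] + 2)
          r$alt[ii] <- substr(r$ref[ii], 1, 1)
          r$variant_type[ii] <- "deletion"
        }
      }
    }
    rows[[cl]] <- r
  }

  truth <- bind_rows(rows) |>
    mutate(sample_id = sample(sprintf("S%02d", seq_len(n_samples)),
                              n(), replace = TRUE)) |>
    arrange(.data$chrom, .data$pos) |>
    select("sample_id", "chrom", "pos", "ref", "alt", "variant_type",
           "class", "true_vaf", "known_editing")

  list(
    truth = truth,
    germline = truth |> filter(.data$class == "germline") |>
      select("chrom", "pos", "ref", "alt"),
    editing_bed = truth |>
      filter(.data$class == "editing", .data$known_editing) |>
      mutate(strand = if_else(.data$ref == "A", "+", "-")) |>
      select("chrom", "pos", "strand")
  )
}

#' Simulate per-site read evidence for a truth manifest
#'
#' Encodes the class-specific evidence signatures the pipeline must detect:
#' reverse-transcription errors carry low allele counts, low base quality and
#' zero second-caller support; soft-clip artifacts have >= 0.8 of alt reads
#' clipped near the site and zero second-aligner support; junction artifacts
#' sit within 5 bp of an exon boundary with zero second-aligner support;
#' editing, somatic and germline sites carry platform-consistent counts.
#'
#' @param truth manifest from [simulate_truth()].
#' @param sim output of [simulate_genome()].
#' @param seed integer seed.
#' @param mean_depth,dispersion negative-binomial coverage model (mean >= 10).
#' @return list with `candidates` (candidate tibble with caller quality) and
#'   `evidence` (validated evidence tibble).
#' @export
simulate_evidence <- function(truth, sim, seed, mean_depth = 100,
                              dispersion = 10) {
  if (mean_depth < 10) abort("mean_depth must be at least 10")
  genome <- sim$genome; genes <- sim$genes
  set.seed(derive_seed(seed, "evidence"))
  n <- nrow(truth)
  if (n == 0) {
    return(list(candidates = tibble(), evidence = tibble()))
  }
  depth <- pmax(10L, rnbinom(n, mu = mean_depth, size = dispersion))
  # a caller emits a candidate only with a few supporting reads; RT errors
  # are the exception (permissive low-VAF emission is their artifact mode)
  emit_floor <- ifelse(truth$class == "rt_error", 1L, 3L)
  n_alt <- pmin(depth, pmax(emit_floor, rbinom(n, depth, truth$true_vaf)))
  other <- rbinom(n, depth - n_alt, 0.01)
  ref_n <- depth - n_alt - other
  n_alt_fwd <- rbinom(n, n_alt, 0.5)
  n_ref_fwd <- rbinom(n, ref_n, 0.5)
  cls <- truth$class

  bq_alt <- ifelse(cls == "rt_error",
                   pmin(28, pmax(12, round(rnorm(n, 22, 3)))),
                   pmin(40, pmax(30, round(rnorm(n, 36, 2)))))
  bq_ref <- pmin(40, pmax(30, round(rnorm(n, 36, 2))))
  mq_alt <- pmin(60, pmax(50, round(rnorm(n, 60, 2))))
  mq_ref <- pmin(60, pmax(50, round(rnorm(n, 60, 2))))
  relpos <- pmin(0.95, pmax(0.05, rnorm(n, 0.5, 0.12)))
  softclip <- ifelse(cls == "softclip_artifact",
                     runif(n, 0.8, 1), rbeta(n, 1, 30))
  multimap <- rbeta(n, 1, 30)
  nm <- 1 + rpois(n, 0.5)
  djunc <- junction_distance(genes, truth$chrom, truth$pos)
  flank_l <- pmax(1, round(depth * runif(n, 0.9, 1.1)))
  flank_r <- pmax(1, round(depth * runif(n, 0.9, 1.1)))
  a2_depth <- pmax(1, round(depth * runif(n, 0.8, 1.0)))
  a2_alt <- ifelse(cls %in% c("softclip_artifact", "junction_artifact"),
                   0L, rbinom(n, n_alt, 0.9))
  c2_alt <- ifelse(cls == "rt_error", 0L, rbinom(n, n_alt, 0.9))
  dup <- rbeta(n, 1, 40)

  evidence <- tibble(
    chrom = truth$chrom, pos = truth$pos, ref = truth$ref, alt = truth$alt,
    depth_total = as.numeric(depth),
    alt_count = as.numeric(n_alt), ref_count = as.numeric(ref_n),
    alt_fwd = as.numeric(n_alt_fwd), alt_rev = as.numeric(n_alt - n_alt_fwd),
    ref_fwd = as.numeric(n_ref_fwd), ref_rev = as.numeric(ref_n - n_ref_fwd),
    median_bq_alt = as.numeric(bq_alt), median_bq_ref = as.numeric(bq_ref),
    median_mq_alt = as.numeric(mq_alt), median_mq_ref = as.numeric(mq_ref),
    mean_relpos_alt = relpos, frac_softclip_alt = softclip,
    frac_multimap_alt = multimap, mean_nm_alt = as.numeric(nm),
    dist_to_junction = djunc,
    flank_depth_left = as.numeric(flank_l),
    flank_depth_right = as.numeric(flank_r),
    aligner2_depth = as.numeric(a2_depth),
    aligner2_alt_count = as.numeric(a2_alt),
    caller2_alt_count = as.numeric(c2_alt),
    dup_frac = dup)
  validate_evidence(evidence)
  candidates <- truth |>
    select("sample_id", "chrom", "pos", "ref", "alt", "variant_type") |>
    mutate(caller_qual = round(rnorm(n, 30, 5) + n_alt / 4, 2))
  list(candidates = candidates, evidence = evidence)
}

synthetic_signatures <- function() {
  ch <- sbs_channels()
  cls <- rep(subst_classes(), each = 16)
  mk <- function(major_class, w = 0.85) {
    v <- rep((1 - w) / 96, 96)
    v[cls == major_class] <- v[cls == major_class] + w / 16
    # deterministic within-class shape so channels are distinguishable
    shape <- (seq_len(16) %% 4 + 1) / sum(seq_len(16) %% 4 + 1)
    v[cls == major_class] <- (1 - w) / 96 + w * shape
    v / sum(v)
  }
  m <- cbind(SYN_CT = mk("C>T"), SYN_TC = mk("T>C"), SYN_FLAT = rep(1 / 96, 96))
  rownames(m) <- ch
  m
}

#' Generate the full benchmark fixture set
#'
#' One call produces everything the test-suite and documentation walkthrough
#' need: genome FASTA + GTF, germline VCF, known-editing BED, candidate VCF,
#' evidence TSV, truth manifest, per-gene TPM table, a synthetic 3-signature
#' reference matrix, DNA-reference mutation sets (an exome-like and a
#' genome-like platform) and per-platform depth lookups.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed; fixed seed gives byte-identical files.
#' @param n_sites,n_samples,class_proportions,frac_editing_known,mean_depth
#'   passed to the simulators.
#' @param n_chrom,chrom_len,n_genes genome dimensions.
#' @return invisible list with all in-memory objects (`genome`, `genes`,
#'   `truth`, `candidates`, `evidence`, `tpm`, `signatures`, `dna_wxs`,
#'   `dna_wgs`, `depths`) and a named `paths` vector.
#' @export
make_benchmark <- function(dir, seed = 1, n_sites = 2000, n_samples = 4,
                           class_proportions = default_class_proportions(),
                           frac_editing_known = 0.5, mean_depth = 100,
                           n_chrom = 2, chrom_len = 100000, n_genes = 40) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_genome(seed, n_chrom, chrom_len, n_genes)
  tr <- simulate_truth(sim, seed, n_sites, class_proportions,
                       frac_editing_known, n_samples = n_samples)
  ev <- simulate_evidence(tr$truth, sim, seed, mean_depth)

  set.seed(derive_seed(seed, "aux"))
  tpm <- tibble(gene_id = sim$genes$genes$gene_id,
                tpm = round(exp(rnorm(nrow(sim$genes$genes), 1.2, 1.6)), 3))
  sigs <- synthetic_signatures()

  truth <- tr$truth |>
    mutate(dna_backed = .data$class %in% c("somatic", "germline"),
           is_true = .data$class == "somatic")
  dna_wxs <- truth |> filter(.data$class == "somatic") |>
    filter(runif(n()) < 0.95) |>
    select("sample_id", "chrom", "pos", "ref", "alt")
  dna_wgs <- truth |> filter(.data$class == "somatic") |>
    filter(runif(n()) < 0.98) |>
    select("sample_id", "chrom", "pos", "ref", "alt")
  all_sites <- truth |> select("sample_id", "chrom", "pos")
  depths <- list(
    rna = all_sites |> mutate(depth = ev$evidence$depth_total[
      match(paste(truth$chrom, truth$pos),
            paste(ev$evidence$chrom, ev$evidence$pos))]),
    wxs = all_sites |> mutate(depth = rnbinom(n(), mu = 80, size = 8)),
    wgs = all_sites |> mutate(depth = rnbinom(n(), mu = 40, size = 8)))

  paths <- c(
    fasta = file.path(dir, "genome.fa"), gtf = file.path(dir, "genes.gtf"),
    germline = file.path(dir, "germline.vcf"),
    editing = file.path(dir, "editing.bed"),
    candidates = file.path(dir, "candidates.vcf"),
    evidence = file.path(dir, "evidence.tsv"),
    truth = file.path(dir, "truth.tsv"),
    tpm = file.path(dir, "tpm.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    dna_wxs = file.path(dir, "dna_wxs.tsv"),
    dna_wgs = file.path(dir, "dna_wgs.tsv"),
    depth_rna = file.path(dir, "depth_rna.tsv"),
    depth_wxs = file.path(dir, "depth_wxs.tsv"),
    depth_wgs = file.path(dir, "depth_wgs.tsv"))

  write_genome_files(sim, paths["fasta"], paths["gtf"])
  write_vcf(tr$germline, paths["germline"], contigs = sim$genome$lengths)
  readr::write_tsv(
    tr$editing_bed |>
      mutate(start = .data$pos - 1L, end = .data$pos,
             name = ".", score = 0L) |>
      select("chrom", "start", "end", "name", "score", "strand"),
    paths["editing"], col_names = FALSE, progress = FALSE)
  write_vcf(ev$candidates, paths["candidates"],
            contigs = sim$genome$lengths)
  write_evidence_table(ev$evidence, paths["evidence"])
  readr::write_tsv(truth, paths["truth"], progress = FALSE)
  readr::write_tsv(tpm, paths["tpm"], progress = FALSE)
  write_signature_matrix(sigs, paths["signatures"])
  readr::write_tsv(dna_wxs, paths["dna_wxs"], progress = FALSE)
  readr::write_tsv(dna_wgs, paths["dna_wgs"], progress = FALSE)
  readr::write_tsv(depths$rna, paths["depth_rna"], progress = FALSE)
  readr::write_tsv(depths$wxs, paths["depth_wxs"], progress = FALSE)
  readr::write_tsv(depths$wgs, paths["depth_wgs"], progress = FALSE)

  invisible(list(genome = sim$genome, genes = sim$genes, truth = truth,
                 candidates = ev$candidates, evidence = ev$evidence,
                 tpm = tpm, signatures = sigs, dna_wxs = dna_wxs,
                 dna_wgs = dna_wgs, depths = depths, paths = paths,
                 seed = seed))
}

#' Write simulated reads covering one site as SAM (mini alignment fixture)
#'
#' Produces a coordinate-sorted SAM with reads drawn from the reference
#' around a site: `n_ref` matching reads, `n_alt` reads carrying the alt
#' base, optionally `n_alt_clipped` reads whose alt base lies inside a
#' soft-clipped segment (which must therefore never count as support) and
#' `n_dup` duplicate-flagged alt reads. Exists to exercise
#' [summarize_site()]; evidence-level simulation is the package's default.
#'
#' @param genome `rnasm_genome`.
#' @param chrom,pos,ref,alt the site.
#' @param sam_path output SAM path.
#' @param n_ref,n_alt,n_alt_clipped,n_dup read counts.
#' @param read_len,bq,mapq read geometry and qualities.
#' @param seed integer seed.
#' @return `sam_path`, invisibly.
#' @export
simulate_site_reads <- function(genome, chrom, pos, ref, alt, sam_path,
                                n_ref = 20, n_alt = 10, n_alt_clipped = 0,
                                n_dup = 0, read_len = 80, bq = 35,
                                mapq = 60, seed = 1) {
  set.seed(derive_seed(seed, "reads"))
  qual <- strrep(rawToChar(as.raw(bq + 33)), read_len)
  mkread <- function(i, start, cigar, seq, flag) {
    paste(sprintf("r%04d", i), flag, chrom, start, mapq, cigar, "*", 0, 0,
          seq, qual, "NM:i:1", sep = "\t")
  }
  reads <- list()
  idx <- 0
  add_read <- function(is_alt, flag_extra = 0) {
    idx <<- idx + 1
    off <- sample(10:(read_len - 10), 1)
    start <- pos - off + 1
    s <- genome_seq(genome, chrom, start, start + read_len - 1)
    if (is_alt) substr(s, off, off) <- alt
    flag <- sample(c(0, 16), 1) + flag_extra
    reads[[idx]] <<- list(start = start,
                          line = mkread(idx, start,
                                        paste0(read_len, "M"), s, flag))
  }
  for (i in seq_len(n_ref)) add_read(FALSE)
  for (i in seq_len(n_alt)) add_read(TRUE)
  for (i in seq_len(n_dup)) add_read(TRUE, flag_extra = 1024)
  # clipped reads: alignment starts after the site, leading soft clip
  # covers the site and carries the alt base
  for (i in seq_len(n_alt_clipped)) {
    idx <- idx + 1
    clip <- 20
    start <- pos + 5
    s_aln <- genome_seq(genome, chrom, start, start + read_len - clip - 1)
    s_clip <- genome_seq(genome, chrom, start - clip, start - 1)
    coff <- clip - 5  # clip base aligned adjacent covers pos at this offset
    substr(s_clip, coff, coff) <- alt
    reads[[idx]] <- list(start = start, line = mkread(
      idx, start, sprintf("%dS%dM", clip, read_len - clip),
      paste0(s_clip, s_aln), 0))
  }
  ord <- order(vapply(reads, function(r) r$start, numeric(1)))
  con <- file(sam_path, "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome$lengths),
                     as.integer(genome$lengths)), con)
  writeLines(vapply(reads[ord], function(r) r$line, character(1)), con)
  invisible(sam_path)
}
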