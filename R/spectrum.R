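#' The six pyrimidine-collapsed substitution classes
#' @return character vector `c("C>A","C>G","C>T","T>A","T>C","T>G")`.
#' @export
subst_classes <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' The 96 SBS channel labels in COSMIC order
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' base (A, C, G, T), then 3' base, e.g. `A[C>A]A` first.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  unlist(lapply(subst_classes(), function(cl) {
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(f, t3)
      sprintf("%s[%s]%s", f, cl, t3))))
  }))
}

#' Pyrimidine-collapsed substitution class of an SNV
#'
#' Purine-reference substitutions are complemented to their pyrimidine
#' representation, so `A>G` maps to `T>C` and every substitution shares the
#' class of its reverse complement.
#'
#' @param ref,alt single-base character vectors, `ref != alt`.
#' @return character vector of classes from [subst_classes()].
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(nchar(ref) != 1 | nchar(alt) != 1)) abort("SNVs only")
  if (any(ref == alt)) abort("ref == alt")
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, complement_base(ref), ref)
  a <- ifelse(purine, complement_base(alt), alt)
  paste0(r, ">", a)
}

#' Trinucleotide SBS channel of an SNV
#'
#' The channel is the 5' base, the pyrimidine-collapsed substitution and the
#' 3' base; when the reference base is a purine the whole trimer is
#' reverse-complemented together with the substitution (strand collapse).
#'
#' @param genome an `rnasm_genome`.
#' @param chrom,pos,ref,alt SNV vectors; the genome base at `pos` must equal
#'   `ref`.
#' @return tibble with columns `channel` (label) and `channel_index` (0-95,
#'   class-major COSMIC order).
#' @export
trinucleotide_context <- function(genome, chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  len <- genome$lengths[chrom]
  if (any(pos < 2 | pos > len - 1)) {
    abort("position lacks a 5' or 3' neighbour on the chromosome")
  }
  tri <- genome_seq(genome, chrom, pos - 1, pos + 1)
  centre <- substr(tri, 2, 2)
  bad <- centre != ref
  if (any(bad)) {
    abort(sprintf("genome base differs from ref at: %s",
                  paste(utils::head(paste0(chrom[bad], ":", pos[bad]), 5),
                        collapse = ", ")))
  }
  purine <- ref %in% c("A", "G")
  tri[purine] <- revcomp(tri[purine])
  cls <- substitution_class(ref, alt)
  five <- substr(tri, 1, 1)
  three <- substr(tri, 3, 3)
  channel <- sprintf("%s[%s]%s", five, cls, three)
  idx <- (match(cls, subst_classes()) - 1L) * 16L +
    (match(five, DNA_BASES) - 1L) * 4L + (match(three, DNA_BASES) - 1L)
  tibble(channel = channel, channel_index = idx)
}

#' Build per-sample 96-channel mutation spectra
#'
#' Indels are skipped (their count is attached as the `n_skipped_indels`
#' attribute). Channel sums per sample equal the number of SNVs contributed by
#' that sample.
#'
#' @param mutations tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genome an `rnasm_genome` for flanking-base lookup.
#' @return an `rnasm_spectrum`: 96 x n_samples integer matrix (rownames =
#'   channels) with attributes `class_marginal` (6 x n_samples) and
#'   `n_skipped_indels`.
#' @export
build_spectrum <- function(mutations, genome) {
  assert_columns(mutations, c("sample_id", "chrom", "pos", "ref", "alt"),
                 "mutations")
  snv <- mutations |>
    filter(nchar(.data$ref) == 1, nchar(.data$alt) == 1)
  n_skipped <- nrow(mutations) - nrow(snv)
  samples <- sort(unique(mutations$sample_id))
  m <- matrix(0L, nrow = 96, ncol = length(samples),
              dimnames = list(sbs_channels(), samples))
  if (nrow(snv) > 0) {
    ctx <- trinucleotide_context(genome, snv$chrom, snv$pos, snv$ref, snv$alt)
    tab <- table(factor(ctx$channel, levels = sbs_channels()),
                 factor(snv$sample_id, levels = samples))
    m[] <- as.integer(tab)
  }
  cls <- rep(subst_classes(), each = 16)
  marg <- rowsum(m, cls)[subst_classes(), , drop = FALSE]
  structure(m, class = c("rnasm_spectrum", class(m)),
            class_marginal = marg, n_skipped_indels = n_skipped)
}

#' @export
print.rnasm_spectrum <- function(x, ...) {
  cat("<rnasm_spectrum> ", ncol(x), " sample(s), ",
      sum(x), " SNV(s); indels skipped: ",
      attr(x, "n_skipped_indels"), "\n", sep = "")
  invisible(x)
}

#' Tidy a mutation spectrum into long form
#' @param x an `rnasm_spectrum`.
#' @param ... unused.
#' @return tibble with `sample_id`, `channel`, `subst_class`, `count`.
#' @export
tidy.rnasm_spectrum <- function(x, ...) {
  tibble(
    sample_id = rep(colnames(x), each = 96),
    channel = rep(rownames(x), times = ncol(x)),
    subst_class = rep(rep(subst_classes(), each = 16), times = ncol(x)),
    count = as.integer(x)
  )
}

#' Plot a 96-channel spectrum
#' @param object an `rnasm_spectrum`.
#' @param ... unused.
#' @return a ggplot object (facets = samples, bars coloured by class).
#' @exportS3Method ggplot2::autoplot
autoplot.rnasm_spectrum <- function(object, ...) {
  df <- tidy(object) |>
    mutate(channel = factor(.data$channel, levels = sbs_channels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                   fill = .data$subst_class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sample_id, ncol = 1, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank()) +
    ggplot2::labs(x = "SBS channel", y = "SNV count", fill = "class")
}
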