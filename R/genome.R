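#' Load a reference genome from FASTA
#'
#' Wraps a [Biostrings::DNAStringSet] with 1-based inclusive coordinate lookup.
#' Sequence names are taken from the first whitespace-delimited token of each
#' FASTA header and preserved verbatim (no "chr"-prefix aliasing).
#'
#' @param path path to a FASTA file.
#' @return an object of class `rnasm_genome`.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(
    list(seqs = seqs, lengths = setNames(Biostrings::width(seqs), names(seqs))),
    class = "rnasm_genome"
  )
}

#' @export
print.rnasm_genome <- function(x, ...) {
  cat("<rnasm_genome> ", length(x$seqs), " sequence(s), ",
      sum(as.numeric(x$lengths)), " bp total\n", sep = "")
  invisible(x)
}

genome_check_chrom <- function(genome, chrom) {
  bad <- setdiff(unique(chrom), names(genome$lengths))
  if (length(bad) > 0) {
    hint <- if (any(grepl("^chr", names(genome$lengths))) != any(grepl("^chr", bad)))
      " (naming mismatch: check the 'chr' prefix convention of your inputs)" else ""
    abort(sprintf("chromosome(s) not in genome: %s%s",
                  paste(bad, collapse = ", "), hint))
  }
}

#' Extract genome sequence (1-based inclusive)
#'
#' @param genome an `rnasm_genome`.
#' @param chrom,start,end equal-length vectors; coordinates 1-based inclusive.
#' @return character vector of sequences; `nchar` equals `end - start + 1`.
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "rnasm_genome"))
  genome_check_chrom(genome, chrom)
  if (any(start < 1) || any(end > genome$lengths[chrom]) || any(end < start)) {
    abort("requested window outside chromosome bounds")
  }
  unname(as.character(Biostrings::subseq(genome$seqs[chrom],
                                         start = start, end = end)))
}

#' GC fraction of the window around a site
#'
#' The window spans 100 bp centred on the site (50 bases left, the site, 49
#' right), clipped at chromosome ends; N bases are excluded from the
#' denominator.
#'
#' @param genome an `rnasm_genome`.
#' @param chrom,pos vectors of positions (1-based).
#' @param window total window width in bp (default 100).
#' @return numeric vector of GC fractions in \[0, 1\].
#' @export
gc_content <- function(genome, chrom, pos, window = 100) {
  stopifnot(inherits(genome, "rnasm_genome"))
  genome_check_chrom(genome, chrom)
  len <- genome$lengths[chrom]
  if (any(pos < 1) || any(pos > len)) abort("position outside chromosome")
  left <- floor(window / 2)
  right <- window - left - 1
  start <- pmax(1, pos - left)
  end <- pmin(len, pos + right)
  seqs <- genome_seq(genome, chrom, start, end)
  vapply(seqs, function(s) {
    b <- strsplit(toupper(s), "")[[1]]
    b <- b[b %in% DNA_BASES]
    if (length(b) == 0) return(NA_real_)
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Longest homopolymer run near a site
#'
#' Length of the longest single-base run within the window of `flank` bases on
#' each side of the site (11 bp total by default).
#'
#' @inheritParams gc_content
#' @param flank bases examined on each side of the site.
#' @return integer vector of run lengths.
#' @export
homopolymer_run <- function(genome, chrom, pos, flank = 5) {
  stopifnot(inherits(genome, "rnasm_genome"))
  genome_check_chrom(genome, chrom)
  len <- genome$lengths[chrom]
  start <- pmax(1, pos - flank)
  end <- pmin(len, pos + flank)
  seqs <- genome_seq(genome, chrom, start, end)
  vapply(seqs, function(s) {
    r <- rle(strsplit(toupper(s), "")[[1]])
    max(r$lengths)
  }, integer(1), USE.NAMES = FALSE)
}
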