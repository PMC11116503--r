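# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a DNA string (vectorized)
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

complement_base <- function(x) {
  unname(COMPLEMENT[toupper(x)])
}

#' Site key used throughout the package
#' @noRd
site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Lower median: for even n, the lower of the two middle order statistics.
#' @noRd
lower_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  x[floor((n + 1) / 2)]
}

# deterministic integer sub-seed derived from a user seed and a stream label;
# kept below 2^31 so it is a valid R integer
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# write JSON with stable key order and formatting so that run manifests are
# byte-identical across reruns with the same configuration
write_stable_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
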