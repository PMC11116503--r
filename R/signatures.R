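#' Fit signature exposures to a spectrum by non-negative least squares
#'
#' Solves `min ||S e - x||^2, e >= 0` for one 96-channel spectrum against the
#' reference signature matrix, then rescales the exposures to sum to the total
#' mutation count of the spectrum. Supervised refitting against fixed
#' references keeps the fit deterministic; de novo signature discovery is out
#' of scope.
#'
#' @param spectrum numeric 96-vector of channel counts (or a 1-column slice of
#'   an `rnasm_spectrum`).
#' @param sigs 96 x K signature matrix from [read_signature_matrix()].
#' @return an `rnasm_exposures` tibble with columns `signature`, `exposure`,
#'   and attributes `recon_error` (residual L2 norm) and `cosine`
#'   (reconstruction vs spectrum; NA for an all-zero spectrum).
#' @export
fit_exposures <- function(spectrum, sigs) {
  x <- as.numeric(spectrum)
  if (length(x) != nrow(sigs)) abort("spectrum length must match signature rows")
  if (any(x < 0)) abort("spectrum must be nonnegative")
  total <- sum(x)
  if (total == 0) {
    e <- rep(0, ncol(sigs))
    recon <- rep(0, length(x))
  } else {
    fit <- pracma::lsqnonneg(sigs, x)
    # residual reported for the least-squares solution itself; exposures are
    # then rescaled to the total count for interpretability
    recon <- as.numeric(sigs %*% fit$x)
    e <- fit$x
    if (sum(e) > 0) e <- e * total / sum(e)
  }
  cosine <- if (total == 0 || sum(recon) == 0) NA_real_ else {
    sum(recon * x) / sqrt(sum(recon^2) * sum(x^2))
  }
  out <- tibble(signature = colnames(sigs), exposure = e)
  structure(out, class = c("rnasm_exposures", class(out)),
            recon_error = sqrt(sum((recon - x)^2)), cosine = cosine)
}

#' Fit exposures for every sample of a spectrum matrix
#' @param spectrum an `rnasm_spectrum` (96 x samples).
#' @param sigs signature matrix.
#' @return tibble with `sample_id`, `signature`, `exposure`, `recon_error`,
#'   `cosine`.
#' @export
fit_exposures_cohort <- function(spectrum, sigs) {
  purrr::map_dfr(colnames(spectrum), function(s) {
    e <- fit_exposures(spectrum[, s], sigs)
    tibble(sample_id = s, signature = e$signature, exposure = e$exposure,
           recon_error = attr(e, "recon_error"), cosine = attr(e, "cosine"))
  })
}

#' Assign individual mutations to signatures
#'
#' For a mutation in channel c, the likelihood of signature k is the
#' exposure-weighted channel intensity `e_k S[c,k] / sum_j e_j S[c,j]`; the
#' argmax signature is assigned when its likelihood exceeds `threshold`
#' (default 0.75), otherwise the mutation is reported `"unassigned"`.
#'
#' @param mutations tibble of SNVs with `chrom`, `pos`, `ref`, `alt` and a
#'   `channel` column (from [trinucleotide_context()]).
#' @param exposures `rnasm_exposures` for the mutations' sample.
#' @param sigs signature matrix.
#' @param threshold assignment likelihood cut-off.
#' @return the input tibble with `signature` and `likelihood` columns added;
#'   channels with zero total intensity get `signature = "unassigned"` and
#'   `likelihood = NA` (flagged in `zero_intensity`).
#' @export
assign_mutations <- function(mutations, exposures, sigs, threshold = 0.75) {
  assert_columns(mutations, "channel", "mutations")
  e <- setNames(exposures$exposure, exposures$signature)
  e <- e[colnames(sigs)]
  w <- sweep(sigs, 2, e, "*")            # 96 x K intensity
  tot <- rowSums(w)
  lik <- w / ifelse(tot == 0, 1, tot)
  ci <- match(mutations$channel, rownames(sigs))
  if (any(is.na(ci))) abort("unknown channel label in mutations")
  best <- max.col(lik[ci, , drop = FALSE], ties.method = "first")
  best_lik <- lik[cbind(ci, best)]
  zero <- tot[ci] == 0
  mutations |>
    mutate(
      signature = if_else(!zero & best_lik > threshold,
                          colnames(sigs)[best], "unassigned"),
      likelihood = if_else(zero, NA_real_, best_lik),
      zero_intensity = zero
    )
}

#' Per-mutation signature likelihoods (all signatures)
#'
#' @inheritParams assign_mutations
#' @return tibble with one row per mutation x signature and the normalized
#'   likelihood; likelihoods sum to 1 per mutation over signatures with
#'   nonzero exposure.
#' @export
signature_likelihoods <- function(mutations, exposures, sigs) {
  e <- setNames(exposures$exposure, exposures$signature)[colnames(sigs)]
  w <- sweep(sigs, 2, e, "*")
  tot <- rowSums(w)
  lik <- w / ifelse(tot == 0, 1, tot)
  ci <- match(mutations$channel, rownames(sigs))
  tibble(
    row = rep(seq_len(nrow(mutations)), each = ncol(sigs)),
    channel = rep(mutations$channel, each = ncol(sigs)),
    signature = rep(colnames(sigs), times = nrow(mutations)),
    likelihood = as.numeric(t(lik[ci, , drop = FALSE]))
  )
}

#' @export
glance.rnasm_exposures <- function(x, ...) {
  tibble(n_signatures = nrow(x),
         total_exposure = sum(x$exposure),
         recon_error = attr(x, "recon_error"),
         cosine = attr(x, "cosine"))
}

#' Plot fitted signature exposures
#' @param object an `rnasm_exposures`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rnasm_exposures <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$signature,
                                                  -.data$exposure),
                               y = .data$exposure)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "signature", y = "exposure (mutations)")
}
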