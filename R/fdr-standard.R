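#' Estimate the null proportion pi0 from the P-value tail
#'
#' The classical tail-based estimator: under the two-component mixture, P
#' values above a threshold `lambda` are mostly null, so
#' `pi0 = #(P > lambda) / (m * (1 - lambda))`.  Values above 1 (possible
#' under depletion of small P values) are capped at 1; the uncapped value
#' is kept as an attribute for diagnostics.
#'
#' @param pvalues per-gene P values in `[0, 1]`.
#' @param lambda tuning threshold in `(0, 1)`; 0.5 by default.
#' @return estimated null proportion in `[0, 1]`, with attribute
#'   `"uncapped"` carrying the raw ratio.
#' @export
#' @examples
#' estimate_pi0(c(0.8, 0.9, 0.6, 0.7, 0.1, 0.2, 0.01, 0.3, 0.4, 0.45))
estimate_pi0 <- function(pvalues, lambda = 0.5) {
  if (length(pvalues) == 0) abort("empty P-value vector")
  if (lambda <= 0 || lambda >= 1) abort("`lambda` must be in (0, 1)")
  raw <- sum(pvalues > lambda) / (length(pvalues) * (1 - lambda))
  structure(min(raw, 1), uncapped = raw)
}

#' Standard FDR estimate from ordered P values
#'
#' For ordered P values `P_(1) <= ... <= P_(m)` the raw estimate at rank
#' `k` is `m * pi0 * P_(k) / k`; monotonicity is imposed by the cumulative
#' minimum over ranks `>= k`, and the result is capped at 1 and mapped back
#' to the input order.  This estimator takes the uniform null at face value
#' and is therefore conservatively biased when latent subgroup structure
#' narrows the true null.
#'
#' @param pvalues per-gene P values.
#' @param pi0 null proportion in `[0, 1]` (see [estimate_pi0()]).
#' @return per-gene FDR estimates aligned to the input order.
#' @export
#' @examples
#' fdr_standard(c(0.01, 0.011, 0.5), pi0 = 1)
fdr_standard <- function(pvalues, pi0 = estimate_pi0(pvalues)) {
  if (length(pvalues) == 0) abort("empty P-value vector")
  if (pi0 < 0 || pi0 > 1) abort("`pi0` must be in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  raw <- m * as.numeric(pi0) * pvalues[o] / seq_len(m)
  mono <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- pmin(mono, 1)
  out
}
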