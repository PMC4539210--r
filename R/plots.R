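#' Plot a corrected-null fit against the observed histogram
#'
#' Shows the observed statistic histogram (as a density), the baseline
#' `phi0`, and the corrected null `f0_hat`; the narrowing of the corrected
#' null relative to the standard Gaussian is the visual signature of
#' latent-group heterogeneity.
#'
#' @param object a `null_fit` carrying observed counts.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.null_fit <- function(object, ...) {
  m <- sum(object$counts)
  df <- tibble(
    z = rep(object$mid, 3),
    density = c(object$counts / (m * object$delta), object$phi0,
                object$f0_hat),
    component = rep(c("observed", "phi0 (baseline null)",
                      "f0 (corrected null)"), each = length(object$mid))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$density,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "t statistic", y = "density",
                  title = sprintf("Corrected null fit (pi0 = %.2f, b = %.2f)",
                                  object$pi0, object$b)) +
    ggplot2::theme_minimal()
}

#' Compare FDR estimates (and optionally the true FDP) by rank
#'
#' @param fdr_tbl tibble from [fdr_table()] (needs `z` or `p_raw` to order
#'   by, and an `fdr` column).
#' @param standard optional second per-gene FDR vector (e.g. the standard
#'   estimate) aligned to `fdr_tbl`.
#' @param fdp optional per-gene true FDP vector aligned to `fdr_tbl`
#'   (evaluation on simulated data).
#' @param top number of top-ranked genes shown.
#' @return a ggplot object of FDR estimates against significance rank.
#' @export
plot_fdr_curves <- function(fdr_tbl, standard = NULL, fdp = NULL, top = 500) {
  o <- order(abs(fdr_tbl$z), decreasing = TRUE)
  k <- seq_len(min(top, nrow(fdr_tbl)))
  df <- tibble(rank = k, estimate = fdr_tbl$fdr[o][k], curve = "corrected")
  if (!is.null(standard)) {
    df <- bind_rows(df, tibble(rank = k, estimate = standard[o][k],
                               curve = "standard"))
  }
  if (!is.null(fdp)) {
    df <- bind_rows(df, tibble(rank = k, estimate = fdp[o][k],
                               curve = "true FDP"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$estimate,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "significance rank", y = "FDR") +
    ggplot2::theme_minimal()
}

#' Histogram of P values with the uniform reference
#'
#' Depletion below the reference line near 0 is the signature of latent
#' heterogeneity inflating the pooled variance.
#'
#' @param pvalues per-gene P values.
#' @param bins number of histogram bins.
#' @return a ggplot object.
#' @export
plot_pvalue_hist <- function(pvalues, bins = 20) {
  ggplot2::ggplot(tibble(p = pvalues), ggplot2::aes(x = .data$p)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(.data$density)),
                            bins = bins, boundary = 0,
                            fill = "grey70", colour = "white") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "P value", y = "density") +
    ggplot2::theme_minimal()
}
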