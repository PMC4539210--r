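#' Tidy the coefficients of a corrected-null fit
#'
#' @param x a `null_fit` from [fit_mixture_poisson()], [fit_null_model()]
#'   or [fast_null_approximation()].
#' @param ... unused.
#' @return tibble `(term, estimate, std.error)` for the Poisson mixture
#'   coefficients plus the derived quantities `pi0` and `b`.
#' @export
tidy.null_fit <- function(x, ...) {
  bind_rows(
    tibble(term = names(x$beta), estimate = unname(x$beta),
           std.error = unname(x$se)),
    tibble(term = c("pi0", "b"), estimate = c(x$pi0, x$b),
           std.error = NA_real_)
  )
}

#' One-row summary of a corrected-null fit
#'
#' @inheritParams tidy.null_fit
#' @return one-row tibble with `method`, `pi0`, `pi0_raw`, `b`, `null_sd`
#'   (the implied normal-approximation sd `1 - b/2`), `n_bins`, and the
#'   singular-value dominance ratio when a permutation SVD was run.
#' @export
glance.null_fit <- function(x, ...) {
  tibble(
    method = x$method,
    pi0 = x$pi0,
    pi0_raw = x$pi0_raw,
    b = x$b,
    null_sd = 1 - x$b / 2,
    n_bins = length(x$mid),
    sv_ratio = if (!is.null(x$d) && length(x$d) > 1) x$d[1] / x$d[2]
               else NA_real_
  )
}
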