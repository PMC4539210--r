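#' Permutation-null ensemble of statistic histograms
#'
#' Permutes the phenotype labels `K` times; each permutation recomputes all
#' per-gene two-sample t statistics and contributes one histogram count
#' vector on the shared grid.  The ensemble mean estimates the baseline
#' null shape and the centred ensemble carries the null's sampling
#' variation, which is decomposed by [svd_null_decomposition()].
#'
#' @inheritParams two_sample_t
#' @param K number of permutations (default 100).
#' @param edges shared histogram grid.
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @return object of class `perm_null_ensemble`: list with `counts`
#'   (B x K matrix), `mean` (length-B), `centered` (B x K), `edges`, `m`.
#' @export
build_null_ensemble <- function(expr, groups, K = 100,
                                edges = default_edges(), seed = 1,
                                levels = NULL) {
  if (K < 2) abort("`K` must be at least 2")
  check_edges(edges)
  g <- resolve_groups(expr, groups, levels)
  n <- ncol(expr)
  n1 <- length(g$i1)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(K), function(k) {
      idx <- sample.int(n)
      i1 <- idx[seq_len(n1)]
      i2 <- idx[-seq_len(n1)]
      histogram_counts(.tstats(expr, i1, i2)$z, edges)
    }, numeric(length(edges) - 1))
  })
  mean_counts <- rowMeans(counts)
  structure(
    list(counts = counts, mean = mean_counts,
         centered = counts - mean_counts, edges = edges, m = nrow(expr)),
    class = "perm_null_ensemble"
  )
}

#' @export
print.perm_null_ensemble <- function(x, ...) {
  cat(sprintf("<perm_null_ensemble> %d permutations, %d bins, %d genes\n",
              ncol(x$counts), nrow(x$counts), x$m))
  invisible(x)
}

# deterministic fixed-span smoother along the grid
smooth_on_grid <- function(z, v, span = 0.15) {
  lowess(z, v, f = span)$y
}

#' SVD decomposition of the permutation-null histogram variation
#'
#' Singular value decomposition of the centred B x K histogram matrix.
#' The baseline null `phi0` is the ensemble mean rescaled to integrate to 1
#' on the grid; the perturbation predictor `phi1` is the first left
#' singular vector, smoothed along the grid, unit Euclidean norm, with the
#' sign fixed positive at z = 0 so that a positive mixing coefficient `b`
#' encodes a narrower-than-Gaussian null.  Under latent-group
#' heterogeneity the first singular value dominates and `phi1` has the
#' characteristic leptokurtic peak-and-shoulders shape.
#'
#' If the centred matrix is numerically rank 0 (all permutations
#' identical) the parametric forms of [parametric_phi_forms()] are
#' returned instead, with a warning.
#'
#' @param ensemble a [build_null_ensemble()] result.
#' @param span fixed smoothing span for `phi1` (lowess along the grid).
#' @return list with `d` (singular values, non-increasing), `u1` (raw first
#'   singular vector), `phi1` (smoothed, unit norm, sign-fixed), `phi0`,
#'   `edges`.
#' @export
svd_null_decomposition <- function(ensemble, span = 0.15) {
  stopifnot(inherits(ensemble, "perm_null_ensemble"))
  edges <- ensemble$edges
  delta <- bin_width(edges)
  mid <- bin_mids(edges)
  phi0 <- ensemble$mean / (sum(ensemble$mean) * delta)
  s <- svd(ensemble$centered)
  if (s$d[1] <= 1e-10 * max(1, sum(ensemble$mean))) {
    warn("degenerate permutation ensemble (rank 0); using parametric forms")
    par <- parametric_phi_forms(edges)
    phi1 <- par$phi1 / sqrt(sum(par$phi1^2))
    return(list(d = s$d, u1 = rep(0, length(mid)), phi1 = phi1,
                phi0 = phi0, edges = edges))
  }
  u1 <- s$u[, 1]
  phi1 <- smooth_on_grid(mid, u1, span)
  phi1 <- phi1 / sqrt(sum(phi1^2))
  centre <- which.min(abs(mid))
  if (phi1[centre] < 0) {
    phi1 <- -phi1
    u1 <- -u1
  }
  list(d = s$d, u1 = u1, phi1 = phi1, phi0 = phi0, edges = edges)
}

#' Parametric baseline and perturbation densities
#'
#' Known functional forms used by the fast path, avoiding permutations
#' altogether: `phi0` is the standard normal density on the grid and
#' `phi1(z) = ((1 - z^2)/2) * phi0(z)`, the derivative of the N(0, sigma^2)
#' density with respect to sigma at sigma = 1 (up to sign).  With this
#' scaling `phi0 + b * phi1` matches the `N(0, (1 - b/2)^2)` density to
#' first order in `b`, so the fitted `b` directly indexes the narrowing of
#' the null; `phi1` integrates to 0 analytically, so `phi0 + b * phi1`
#' keeps unit mass for any `b`.
#'
#' @param edges histogram grid.
#' @return list with `phi0`, `phi1` (values at bin midpoints) and `edges`.
#' @export
parametric_phi_forms <- function(edges = default_edges()) {
  check_edges(edges)
  mid <- bin_mids(edges)
  delta <- bin_width(edges)
  phi0 <- dnorm(mid)
  phi0 <- phi0 / (sum(phi0) * delta)
  phi1 <- ((1 - mid^2) / 2) * phi0
  list(phi0 = phi0, phi1 = phi1, edges = edges)
}

# Identity-link (mean-scale) Poisson regression by Fisher scoring:
# iterative weighted least squares with weights 1/max(fitted, 1), the
# Poisson variance with a one-count floor.  The mean-scale fit can return
# negative fitted values in the tails when the narrowing coefficient is
# large -- the method's documented instability, handled downstream by the
# |b| < 0.2 check of the fast path and by flooring/renormalising the final
# null density.  glm's IRLS is unusable here: it aborts whenever a
# sign-changing predictor (phi1) drives a fitted mean negative mid-path.
fit_poisson_identity <- function(X, y, eps = 1e-8, maxit = 100,
                                 tol = 1e-12) {
  X <- as.matrix(X)
  keep <- colSums(abs(X)) > 0
  Xk <- X[, keep, drop = FALSE]
  if (ncol(Xk) == 0) abort("all predictors are zero")
  w <- 1 / pmax(y, 1)
  beta <- NULL
  for (it in seq_len(maxit)) {
    fit <- stats::lm.wfit(Xk, y, w)
    new_beta <- fit$coefficients
    new_beta[is.na(new_beta)] <- 0
    if (!is.null(beta) && sum((new_beta - beta)^2) < tol * sum(beta^2 + tol)) {
      beta <- new_beta
      break
    }
    beta <- new_beta
    w <- 1 / pmax(drop(Xk %*% beta), 1)
  }
  if (anyNA(beta) || any(!is.finite(beta))) {
    abort("identity-link Poisson fit did not converge")
  }
  out <- numeric(ncol(X))
  out[keep] <- beta
  mu <- drop(X %*% out)
  se <- rep(NA_real_, ncol(X))
  info <- crossprod(Xk, Xk / pmax(mu, 1))
  V <- tryCatch(solve(info), error = function(e) NULL)
  if (!is.null(V)) se[keep] <- sqrt(pmax(diag(V), 0))
  mu_pos <- pmax(mu, eps)
  list(beta = out, se = se, fitted = mu,
       negll = sum(mu_pos - y * log(mu_pos)))
}

new_null_fit <- function(beta, se, pi0_raw, b, phi0, phi1, f1_hat, f0_hat,
                         edges, method, counts = NULL, d = NULL,
                         extra = list()) {
  structure(
    c(list(
      beta = beta, se = se,
      pi0 = min(max(pi0_raw, 0), 1), pi0_raw = pi0_raw, b = b,
      phi0 = phi0, phi1 = phi1, f1_hat = f1_hat, f0_hat = f0_hat,
      edges = edges, mid = bin_mids(edges), delta = bin_width(edges),
      method = method, counts = counts, d = d
    ), extra),
    class = "null_fit"
  )
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("<null_fit> method=%s  pi0=%.3f  b=%.3f  (%d bins)\n",
              x$method, x$pi0, x$b, length(x$mid)))
  invisible(x)
}

#' Two-step Poisson mixture regression of histogram counts
#'
#' Fits the mixture `f = pi0 * (phi0 + b * phi1) + (1 - pi0) * f1` to the
#' histogram counts of the observed statistics by identity-link Poisson
#' regression with mean `m * delta * f`:
#' 1. fit the reduced model with predictors `phi0`, `phi1` only;
#' 2. smooth the residual counts as a function of z, floor at 0, and divide
#'    by `m * delta` to obtain the alternative component `f1_hat`;
#' 3. refit with the three predictors `phi0`, `phi1`, `f1_hat`.
#'
#' The coefficient of `phi0` estimates `pi0`; the heterogeneity coefficient
#' is `b = beta1 / beta0`; the corrected null density is
#' `f0 = phi0 + b * phi1`, floored at 0 and renormalised so it is always a
#' proper density on the grid.
#'
#' @param y observed histogram counts on the grid.
#' @param phi0,phi1 baseline and perturbation predictors on the same grid
#'   (from [svd_null_decomposition()] or [parametric_phi_forms()]).
#' @param m number of statistics (genes) behind `y`.
#' @param edges histogram grid.
#' @param span fixed smoothing span for the residual smoother.
#' @return object of class `null_fit`; see [tidy.null_fit()] /
#'   [glance.null_fit()].
#' @export
fit_mixture_poisson <- function(y, phi0, phi1, m, edges = default_edges(),
                                span = 0.15) {
  check_edges(edges)
  mid <- bin_mids(edges)
  delta <- bin_width(edges)
  stopifnot(length(y) == length(mid), length(phi0) == length(mid),
            length(phi1) == length(mid))
  X1 <- m * delta * cbind(phi0, phi1)
  step1 <- fit_poisson_identity(X1, y)
  r <- y - step1$fitted
  f1_hat <- pmax(smooth_on_grid(mid, r / (m * delta), span), 0)

  if (max(f1_hat) > 0) {
    X2 <- m * delta * cbind(phi0, phi1, f1_hat)
    step2 <- fit_poisson_identity(X2, y)
    beta <- step2$beta
    se <- step2$se
  } else {
    beta <- c(step1$beta, 0)
    se <- c(step1$se, NA_real_)
  }
  if (beta[1] <= 0) {
    abort(sprintf("degenerate mixture fit: coefficient of phi0 is %.3g <= 0",
                  beta[1]))
  }
  b <- beta[2] / beta[1]
  f0 <- pmax(phi0 + b * phi1, 0)
  f0 <- f0 / (sum(f0) * delta)
  new_null_fit(beta = setNames(beta, c("beta0", "beta1", "beta2")),
               se = setNames(se, c("beta0", "beta1", "beta2")),
               pi0_raw = beta[1], b = b, phi0 = phi0, phi1 = phi1,
               f1_hat = f1_hat, f0_hat = f0, edges = edges,
               method = "poisson-mixture", counts = y)
}

#' Heterogeneity-corrected P values from an estimated null density
#'
#' Two-sided P value for each statistic: the mass of the corrected null
#' density over `{|z| >= |z_obs|}`, evaluated from the piecewise-linear
#' CDF of the grid density with linear interpolation at `|z_obs|`.
#'
#' @param z observed statistics.
#' @param fit a `null_fit` (or any list with `f0_hat` and `edges`).
#' @return P values in `[0, 1]`; statistics beyond the grid get P = 0 with
#'   a warning (all estimated mass is interior).
#' @export
corrected_pvalues <- function(z, fit) {
  tail_fun <- tail_mass_fun(fit$f0_hat, fit$edges)
  if (any(abs(z) > max(fit$edges))) {
    warn("statistics beyond the histogram grid; their corrected P value is 0")
  }
  tail_fun(z)
}

#' Heterogeneity-corrected FDR estimate at a threshold
#'
#' `FDR(c) = m * pi0 * integral of f0_hat over {|z| > c} / #{|z_i| > c}`,
#' capped at 1, and 0 when nothing is rejected (the FDP convention).
#'
#' @param z observed statistics.
#' @param fit a `null_fit` carrying `f0_hat` and `pi0`.
#' @param c rejection threshold on `|z|`.
#' @return scalar FDR estimate in `[0, 1]`.
#' @export
fdr_corrected <- function(z, fit, c) {
  R <- sum(abs(z) > c)
  if (R == 0) return(0)
  tail_fun <- tail_mass_fun(fit$f0_hat, fit$edges)
  min(1, length(z) * fit$pi0 * tail_fun(c) / R)
}

#' Per-gene heterogeneity-corrected FDR curve
#'
#' Evaluates the corrected FDR at each gene's own `|z|` cutoff (rejection
#' region `{|z_i| >= |z|_(k)}`, so the k-th most extreme gene has k
#' rejections) and imposes monotonicity by the cumulative minimum, exactly
#' as the standard estimator does.
#'
#' @inheritParams fdr_corrected
#' @return per-gene FDR estimates aligned to the input order.
#' @export
fdr_corrected_curve <- function(z, fit) {
  m <- length(z)
  tail_fun <- tail_mass_fun(fit$f0_hat, fit$edges)
  o <- order(abs(z), decreasing = TRUE)
  raw <- m * fit$pi0 * tail_fun(abs(z)[o]) / seq_len(m)
  mono <- rev(cummin(rev(raw)))
  out <- numeric(m)
  out[o] <- pmin(mono, 1)
  out
}

#' Centre-weighted distance between histogram count vectors
#'
#' `(y - y*)' Diag(y) (y - y*)`: squared differences weighted by the
#' observed counts, so agreement in the well-populated centre of the
#' histogram matters most.  Used to select permutation curves closest to
#' the observed statistic histogram.
#'
#' @param y observed histogram counts.
#' @param y_star candidate (permutation) histogram counts on the same grid.
#' @return nonnegative scalar.
#' @export
#' @examples
#' weighted_histogram_distance(c(2, 4), c(1, 3))  # 6
weighted_histogram_distance <- function(y, y_star) {
  stopifnot(length(y) == length(y_star))
  sum((y - y_star)^2 * y)
}

#' Fast, stable null-density approximation for batch assessment
#'
#' Avoids the full permutation-SVD machinery where possible:
#' * Path 1 (no permutations): fit the Poisson mixture with the parametric
#'   forms of [parametric_phi_forms()]; when `|b| < b_cutoff` (0.2) the
#'   corrected null is well approximated by `N(0, (1 - b/2)^2)` and that
#'   density is returned directly.
#' * Path 2 (`|b| >= b_cutoff`): run `K` label permutations, rank their
#'   count vectors by [weighted_histogram_distance()] to the observed
#'   histogram, average the `top` closest curves, and rescale to unit mass.
#'   `pi0` is then re-estimated by the tail rule on the corrected P values.
#'
#' @inheritParams build_null_ensemble
#' @param b_cutoff boundary between the normal-approximation and
#'   permutation-curve paths (default 0.2).
#' @param top number of closest permutation curves averaged in path 2.
#' @param lambda tail threshold for the path-2 `pi0` re-estimate.
#' @param force_parametric if `TRUE`, always return the path-1 normal
#'   approximation regardless of `b` (used for the fast prefilter score).
#' @return a `null_fit` with `method` `"parametric-normal"` or
#'   `"permutation-curves"`; path 2 records the selected permutation
#'   indices in `$selected`.
#' @export
fast_null_approximation <- function(expr, groups, edges = default_edges(),
                                    seed = 1, K = 100, b_cutoff = 0.2,
                                    top = 5, lambda = 0.5, levels = NULL,
                                    force_parametric = FALSE) {
  check_edges(edges)
  mid <- bin_mids(edges)
  delta <- bin_width(edges)
  g <- resolve_groups(expr, groups, levels)
  z <- .tstats(expr, g$i1, g$i2)$z
  y <- histogram_counts(z, edges)
  par <- parametric_phi_forms(edges)
  fit <- fit_mixture_poisson(y, par$phi0, par$phi1, m = length(z),
                             edges = edges)
  if (force_parametric || abs(fit$b) < b_cutoff) {
    sd0 <- max(1 - fit$b / 2, 1e-3)
    f0 <- dnorm(mid, sd = sd0)
    f0 <- f0 / (sum(f0) * delta)
    return(new_null_fit(beta = fit$beta, se = fit$se, pi0_raw = fit$pi0_raw,
                        b = fit$b, phi0 = par$phi0, phi1 = par$phi1,
                        f1_hat = fit$f1_hat, f0_hat = f0, edges = edges,
                        method = "parametric-normal", counts = y,
                        extra = list(null_sd = sd0)))
  }
  if (K < top) {
    warn(sprintf("only %d permutation curves available; averaging all of them",
                 K))
    top <- K
  }
  ens <- build_null_ensemble(expr, groups, K = K, edges = edges, seed = seed,
                             levels = levels)
  d <- apply(ens$counts, 2, weighted_histogram_distance, y = y)
  sel <- order(d)[seq_len(top)]
  f0 <- rowMeans(ens$counts[, sel, drop = FALSE])
  f0 <- f0 / (sum(f0) * delta)
  p_corr <- tail_mass_fun(f0, edges)(z)
  pi0 <- estimate_pi0(p_corr, lambda)
  new_null_fit(beta = fit$beta, se = fit$se, pi0_raw = attr(pi0, "uncapped"),
               b = fit$b, phi0 = par$phi0, phi1 = par$phi1,
               f1_hat = fit$f1_hat, f0_hat = f0, edges = edges,
               method = "permutation-curves", counts = y,
               extra = list(selected = sel, distances = d))
}

#' Fit the corrected null model to a cohort
#'
#' Convenience wrapper running the full permutation-SVD engine: build the
#' permutation-null ensemble, decompose it, and fit the two-step Poisson
#' mixture regression to the observed statistic histogram.
#'
#' @inheritParams build_null_ensemble
#' @param span smoothing span for `phi1` and the residual smoother.
#' @return a `null_fit` with the permutation singular values in `$d`.
#' @export
fit_null_model <- function(expr, groups, K = 100, edges = default_edges(),
                           seed = 1, span = 0.15, levels = NULL) {
  g <- resolve_groups(expr, groups, levels)
  z <- .tstats(expr, g$i1, g$i2)$z
  y <- histogram_counts(z, edges)
  ens <- build_null_ensemble(expr, groups, K = K, edges = edges, seed = seed,
                             levels = levels)
  dec <- svd_null_decomposition(ens, span = span)
  fit <- fit_mixture_poisson(y, dec$phi0, dec$phi1, m = length(z),
                             edges = edges, span = span)
  fit$d <- dec$d
  fit
}

#' Per-gene FDR table for a cohort
#'
#' One-call interface producing a tidy per-gene table under one of three
#' engines:
#' * `"standard"` — Gaussian-reference P values, tail-rule `pi0`, standard
#'   FDR estimate (conservatively biased under latent heterogeneity);
#' * `"corrected"` — full permutation-SVD engine ([fit_null_model()]),
#'   corrected P values and FDR curve;
#' * `"fast"` — [fast_null_approximation()] (normal approximation, falling
#'   back to averaged permutation curves when `|b| >= 0.2`).
#'
#' @inheritParams build_null_ensemble
#' @param method FDR engine (see above).
#' @param lambda tail threshold for `pi0`.
#' @param reference P-value reference for the raw statistics.
#' @return tibble `(gene_id, z, p_raw, p_corrected, fdr)` (standard engine
#'   reports `p_corrected = p_raw`), with the fitted `null_fit` (if any) in
#'   attribute `"fit"`.
#' @export
fdr_table <- function(expr, groups, method = c("corrected", "standard", "fast"),
                      K = 100, edges = default_edges(), lambda = 0.5,
                      seed = 1, levels = NULL,
                      reference = c("gaussian", "t")) {
  method <- arg_match(method)
  reference <- arg_match(reference)
  stats <- suppressWarnings(two_sample_t(expr, groups, levels, reference))
  if (method == "standard") {
    pi0 <- estimate_pi0(stats$p, lambda)
    out <- mutate(stats,
                  p_corrected = .data$p,
                  fdr = fdr_standard(.data$p, pi0))
    fit <- NULL
  } else {
    fit <- if (method == "corrected") {
      fit_null_model(expr, groups, K = K, edges = edges, seed = seed,
                     levels = levels)
    } else {
      fast_null_approximation(expr, groups, edges = edges, seed = seed,
                              K = K, lambda = lambda, levels = levels)
    }
    out <- mutate(stats,
                  p_corrected = corrected_pvalues(.data$z, fit),
                  fdr = fdr_corrected_curve(.data$z, fit))
  }
  out <- select(out, "gene_id", "z", p_raw = "p", "p_corrected", "fdr")
  attr(out, "fit") <- fit
  out
}
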