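test_that("permutation ensembles conserve counts and are seed-deterministic", {
  co <- small_cohort(m = 300, n = 30, seed = 61)
  e1 <- build_null_ensemble(co$expr, co$phenotype$group, K = 10, seed = 9)
  e2 <- build_null_ensemble(co$expr, co$phenotype$group, K = 10, seed = 9)
  e3 <- build_null_ensemble(co$expr, co$phenotype$group, K = 10, seed = 10)
  expect_identical(e1$counts, e2$counts)
  expect_false(identical(e1$counts, e3$counts))
  expect_equal(unname(colSums(e1$counts)), rep(300, 10))
  expect_equal(colSums(e1$centered), rep(0, 10), tolerance = 1e-9)
  expect_error(build_null_ensemble(co$expr, co$phenotype$group, K = 1), "K")
})

test_that("the sampling distribution under heterogeneity is taller and
           narrower than the standard Gaussian", {
  co <- simulate_latent_cohort(m = 20000, n = 400, frac_ms_genes = 1,
                               mu = 2, mu0 = 0, seed = 63)
  z <- two_sample_t(co$expr, co$phenotype$group)$z
  y <- histogram_counts(z, default_edges())
  eta <- expected_null_counts(20000, default_edges())
  centre <- 60:61  # the two bins around z = 0
  expect_gt(sum(y[centre]), sum(eta[centre]))
  expect_lt(sd(z), 1)
})

test_that("SVD decomposition recovers a planted rank-1 structure", {
  edges <- default_edges()
  B <- length(edges) - 1
  mid <- (edges[-1] + edges[-(B + 1)]) / 2
  v <- dnorm(mid) - dnorm(mid, sd = 1.2)  # a narrowing-mode shape
  base <- 1000 * dnorm(mid)
  wts <- seq(-2, 2, length.out = 8)
  counts <- sapply(wts, function(w) base + w * 40 * v)
  ens <- structure(list(counts = counts, mean = rowMeans(counts),
                        centered = counts - rowMeans(counts),
                        edges = edges, m = round(sum(base))),
                   class = "perm_null_ensemble")
  dec <- svd_null_decomposition(ens, span = 0.05)
  expect_true(all(diff(dec$d) <= 1e-8))
  expect_gt(dec$d[1] / max(dec$d[2], 1e-12), 1e6)  # exact rank 1
  expect_gt(abs(cor(dec$u1, v)), 0.999)
  # sign convention: positive at the centre of the grid
  expect_gt(dec$phi1[which.min(abs(mid))], 0)
  expect_equal(sum(dec$phi1^2), 1, tolerance = 1e-9)
  expect_equal(sum(dec$phi0) * 0.1, 1, tolerance = 1e-9)
})

test_that("parametric forms have the documented sign structure and match
           the shrunk Gaussian to first order", {
  par <- parametric_phi_forms()
  mid <- (default_edges()[-1] + default_edges()[-121]) / 2
  expect_gt(par$phi1[which.min(abs(mid))], 0)
  expect_true(all(par$phi1[abs(mid) > 1.01] < 0))
  # phi1 integrates to 0, so phi0 + b * phi1 keeps unit mass for any b
  for (b in c(-0.3, 0, 0.1, 0.5)) {
    expect_equal(sum(par$phi0 + b * par$phi1) * 0.1, 1, tolerance = 1e-6)
  }
  gap <- max(abs(par$phi0 + 0.1 * par$phi1 - dnorm(mid, sd = 0.95)))
  expect_lt(gap, 0.003)
})

test_that("the identity-link Poisson fitter agrees with glm on a
           well-conditioned problem", {
  # grid kept inside |z| < 4 so every expected count exceeds one and the
  # two fits share the same Poisson weights
  par <- parametric_phi_forms(default_edges(-4, 4, bins = 80))
  X <- 1e5 * 0.1 * cbind(par$phi0, abs(par$phi1))
  withr::with_seed(65, y <- rpois(80, drop(X %*% c(0.9, 0.3))))
  ours <- camsfdr:::fit_poisson_identity(X, y)
  ref <- suppressWarnings(
    glm(y ~ 0 + X, family = poisson(link = "identity"), start = c(0.9, 0.3)))
  expect_equal(unname(ours$beta), unname(coef(ref)), tolerance = 1e-4)
  expect_equal(unname(ours$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-2)
})

test_that("the mixture regression recovers planted coefficients within 3 SE", {
  par <- parametric_phi_forms()
  m <- 10000
  mu <- m * 0.1 * (0.9 * par$phi0 + 0.05 * par$phi1)
  withr::with_seed(67, {
    hits <- replicate(10, {
      y <- rpois(length(mu), mu)
      s <- camsfdr:::fit_poisson_identity(
        m * 0.1 * cbind(par$phi0, par$phi1), y)
      all(abs(s$beta - c(0.9, 0.05)) <= 3 * s$se)
    })
  })
  expect_gte(sum(hits), 9)
})

test_that("pure-null statistics give b near 0 and pi0 near 1", {
  par <- parametric_phi_forms()
  withr::with_seed(69, {
    fits <- replicate(20, {
      z <- rnorm(10000)
      f <- fit_mixture_poisson(histogram_counts(z, default_edges()),
                               par$phi0, par$phi1, 10000, default_edges())
      c(f$b, f$pi0_raw)
    })
  })
  expect_lt(abs(mean(fits[1, ])), 0.02)
  expect_lt(abs(mean(fits[2, ]) - 1), 0.03)
})

test_that("an all-zero perturbation predictor reduces the fit to scaling", {
  par <- parametric_phi_forms()
  withr::with_seed(71, z <- rnorm(10000))
  f <- fit_mixture_poisson(histogram_counts(z, default_edges()),
                           par$phi0, rep(0, 120), 10000, default_edges())
  expect_equal(f$beta[["beta1"]], 0)
  expect_lt(abs(f$pi0_raw - 1), 0.05)
  # degenerate fits must error rather than return nonsense
  expect_error(
    fit_mixture_poisson(rep(0, 120), par$phi0, par$phi1, 100,
                        default_edges()),
    "beta0|phi0|degenerate")
})

test_that("corrected P values integrate the corrected null tail", {
  par <- parametric_phi_forms()
  fit <- list(f0_hat = par$phi0, edges = default_edges())
  zs <- c(0, 0.5, 1.3, 2.1, 3)
  expect_equal(corrected_pvalues(zs, fit), 2 * pnorm(-abs(zs)),
               tolerance = 1e-3)
  expect_equal(corrected_pvalues(0, fit), 1, tolerance = 1e-9)
  # narrowed null: N(0, 0.9^2) at z = 1.8 is the standard tail at 2
  mid <- (default_edges()[-1] + default_edges()[-121]) / 2
  f09 <- dnorm(mid, sd = 0.9); f09 <- f09 / (sum(f09) * 0.1)
  fit9 <- list(f0_hat = f09, edges = default_edges())
  expect_lt(abs(corrected_pvalues(1.8, fit9) - 2 * pnorm(-2)), 1e-3)
  expect_warning(p_out <- corrected_pvalues(7, fit), "beyond")
  expect_equal(p_out, 0)
})

test_that("corrected FDR reduces to pi0 at c = 0 and matches the standard
           estimator when P values come from its own null", {
  mid <- (default_edges()[-1] + default_edges()[-121]) / 2
  f0 <- dnorm(mid); f0 <- f0 / (sum(f0) * 0.1)
  fit <- structure(list(f0_hat = f0, edges = default_edges(), pi0 = 0.8),
                   class = "null_fit")
  withr::with_seed(73, z <- rnorm(2000))
  expect_equal(fdr_corrected(z, fit, c = 0), 0.8, tolerance = 1e-6)
  expect_equal(fdr_corrected(z, fit, c = 99), 0)
  p <- corrected_pvalues(z, fit)
  expect_equal(fdr_corrected_curve(z, fit), fdr_standard(p, pi0 = 0.8),
               tolerance = 1e-9)
})

test_that("the centre-weighted histogram distance matches hand values and
           preserves selection order under scaling", {
  expect_equal(weighted_histogram_distance(c(2, 4), c(2, 4)), 0)
  expect_equal(weighted_histogram_distance(c(2, 4), c(1, 3)), 6)
  withr::with_seed(75, {
    y <- rpois(30, 20)
    cands <- replicate(8, rpois(30, 20), simplify = FALSE)
    d <- vapply(cands, weighted_histogram_distance, numeric(1), y = y)
    d_scaled <- vapply(cands, function(ys)
      sum((y - ys)^2 * (3 * y)), numeric(1))
    expect_equal(order(d), order(d_scaled))
  })
})

test_that("the fast approximation takes the normal path on homogeneous data
           and the permutation-curve path under strong narrowing", {
  co0 <- simulate_latent_cohort(m = 4000, n = 60, frac_ms_genes = 1,
                                mu = 0, mu0 = 0, seed = 77)
  f0 <- fast_null_approximation(co0$expr, co0$phenotype$group, seed = 1)
  expect_equal(f0$method, "parametric-normal")
  expect_lt(abs(f0$b), 0.2)
  mid <- f0$mid
  expect_lt(max(abs(f0$f0_hat - dnorm(mid, sd = f0$null_sd))), 0.01)

  # mu = 4 narrows the null to sd ~ 0.71, forcing |b| >= 0.2
  co4 <- simulate_latent_cohort(m = 4000, n = 60, frac_ms_genes = 1,
                                mu = 4, mu0 = 0, seed = 79)
  f4 <- fast_null_approximation(co4$expr, co4$phenotype$group, seed = 2,
                                K = 30)
  expect_equal(f4$method, "permutation-curves")
  expect_gte(abs(f4$b), 0.2)
  # the selected curves are exactly the 5 closest by exhaustive scan
  expect_equal(sort(f4$selected), sort(order(f4$distances)[1:5]))
  expect_equal(sum(f4$f0_hat) * f4$delta, 1, tolerance = 1e-9)
  # K below the number of averaged curves warns and uses them all
  expect_warning(
    f3 <- fast_null_approximation(co4$expr, co4$phenotype$group, seed = 3,
                                  K = 3),
    "averaging all")
  expect_equal(length(f3$selected), 3)
})

test_that("corrected null densities are always proper densities", {
  for (s in 1:5) {
    co <- small_cohort(m = 500, n = 40, mu = 2, seed = 80 + s)
    fit <- fit_null_model(co$expr, co$phenotype$group, K = 20, seed = s)
    expect_true(all(fit$f0_hat >= 0))
    expect_equal(sum(fit$f0_hat) * fit$delta, 1, tolerance = 1e-6)
  }
})

test_that("fdr_table exposes all three engines with a tidy per-gene surface", {
  co <- small_cohort(m = 400, n = 40, seed = 91)
  for (meth in c("standard", "fast", "corrected")) {
    tbl <- suppressWarnings(
      fdr_table(co$expr, co$phenotype$group, method = meth, K = 20, seed = 5))
    expect_s3_class(tbl, "tbl_df")
    expect_named(tbl, c("gene_id", "z", "p_raw", "p_corrected", "fdr"))
    expect_true(all(tbl$fdr >= 0 & tbl$fdr <= 1))
    if (meth != "standard") expect_s3_class(attr(tbl, "fit"), "null_fit")
  }
})

test_that("null fits have broom-style tidiers and an autoplot method", {
  co <- small_cohort(m = 400, n = 40, seed = 93)
  fit <- fit_null_model(co$expr, co$phenotype$group, K = 20, seed = 7)
  td <- tidy(fit)
  expect_true(all(c("beta0", "beta1", "beta2", "pi0", "b") %in% td$term))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$sv_ratio > 0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_fdr_curves(tibble::tibble(z = rnorm(50),
                                                 fdr = runif(50))), "ggplot")
  expect_s3_class(plot_pvalue_hist(runif(100)), "ggplot")
})
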