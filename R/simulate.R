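#' Simulate an expression cohort with latent molecular subtypes
#'
#' Generates a genes-by-patients log-expression matrix under a latent-group
#' model: the cohort contains two unobserved molecular subtypes (MS1, MS2)
#' and an observed binary phenotype (relapse yes `RY` / relapse no `RN`).
#' Most genes are *MS-defining*: one subtype is chosen at random (prob 0.5)
#' and patients in it receive a background shift, `N(mu/2, 1)`, while the
#' other subtype's entries are `N(0, 1)`.  The remaining genes are
#' *relapse-related within one subtype*: on top of the background shift in
#' the chosen subtype, an independent signal draw `N(mu0/2, 1)` is added
#' for `RY` patients and `N(-mu0/2, 1)` for `RN` patients (total variance 2
#' inside the affected subtype); the other subtype stays pure `N(0, 1)`.
#'
#' The subtype labels and the differential-expression mask are *latent*:
#' they are stored in the returned object for evaluation (e.g.
#' [true_fdp()], recovery tests) but no analysis function in this package
#' reads them.
#'
#' @param m number of genes.
#' @param n number of patients.
#' @param frac_ms_genes proportion of MS-defining genes in `[0, 1]`; the
#'   remaining `round((1 - frac_ms_genes) * m)` genes are relapse-related.
#' @param mu background (subtype-defining) effect size, `>= 0`.
#' @param mu0 relapse signal effect size, `>= 0`.
#' @param ms_split integer vector of length 2, patients per molecular
#'   subtype; defaults to an even split of `n`.
#' @param ry_fraction fraction of each subtype assigned to the relapse-yes
#'   group (default 0.5, equal group sizes within each subtype).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration and seed.
#' @return an object of class `latent_cohort`: a list with
#'   * `expr` — `m x n` numeric matrix with gene rownames / patient colnames,
#'   * `phenotype` — tibble `(patient_id, group)` with group in `RY`/`RN`,
#'   * `truth` — tibble `(gene_id, is_de, target_ms)` (latent, evaluation only),
#'   * `ms` — tibble `(patient_id, ms)` (latent, evaluation only),
#'   * `config` — the generating parameters.
#' @export
#' @examples
#' cohort <- simulate_latent_cohort(m = 200, n = 20, seed = 1)
#' dim(cohort$expr)
simulate_latent_cohort <- function(m = 10000, n = 60, frac_ms_genes = 0.99,
                                   mu = 2, mu0 = 3, ms_split = NULL,
                                   ry_fraction = 0.5, seed = 1) {
  if (frac_ms_genes < 0 || frac_ms_genes > 1) {
    abort("`frac_ms_genes` must lie in [0, 1]")
  }
  if (mu < 0 || mu0 < 0) abort("`mu` and `mu0` must be nonnegative")
  if (is.null(ms_split)) ms_split <- c(floor(n / 2), n - floor(n / 2))
  ms_split <- as.integer(ms_split)
  if (length(ms_split) != 2 || sum(ms_split) != n || any(ms_split < 1)) {
    abort("`ms_split` must be two positive counts summing to `n`")
  }
  n_ry <- round(ry_fraction * ms_split)
  n_rn <- ms_split - n_ry
  if (any(n_ry < 1) || any(n_rn < 1)) {
    abort("each molecular subtype needs at least one RY and one RN patient")
  }

  gene_id <- sprintf("g%05d", seq_len(m))
  patient_id <- sprintf("p%04d", seq_len(n))
  ms <- rep(1:2, ms_split)
  group <- unlist(map2(n_ry, n_rn, function(y, z) rep(c("RY", "RN"), c(y, z))))

  n_de <- round((1 - frac_ms_genes) * m)

  expr <- withr::with_seed(seed, {
    de_rows <- if (n_de > 0) sample.int(m, n_de) else integer(0)
    target <- sample(1:2, m, replace = TRUE)
    X <- matrix(rnorm(m * n), m, n)
    # background shift mu/2 for entries whose patient is in the gene's target MS
    in_target <- outer(target, ms, "==")
    X <- X + (mu / 2) * in_target
    if (n_de > 0) {
      # independent signal draw inside the target MS only, sign by phenotype
      sig_mean <- ifelse(group == "RY", mu0 / 2, -mu0 / 2)
      S <- matrix(rnorm(n_de * n), n_de, n) +
        matrix(sig_mean, n_de, n, byrow = TRUE)
      X[de_rows, ] <- X[de_rows, ] + S * in_target[de_rows, , drop = FALSE]
    }
    attr(X, "de_rows") <- de_rows
    attr(X, "target") <- target
    X
  })
  de_rows <- attr(expr, "de_rows")
  target <- attr(expr, "target")
  attr(expr, "de_rows") <- NULL
  attr(expr, "target") <- NULL
  dimnames(expr) <- list(gene_id, patient_id)

  is_de <- logical(m)
  is_de[de_rows] <- TRUE

  structure(
    list(
      expr = expr,
      phenotype = tibble(patient_id = patient_id, group = group),
      truth = tibble(gene_id = gene_id, is_de = is_de, target_ms = target),
      ms = tibble(patient_id = patient_id, ms = ms),
      config = list(m = m, n = n, frac_ms_genes = frac_ms_genes, mu = mu,
                    mu0 = mu0, ms_split = ms_split,
                    ry_fraction = ry_fraction, seed = seed)
    ),
    class = "latent_cohort"
  )
}

#' @export
print.latent_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<latent_cohort> %d genes x %d patients (%.0f%% MS-defining, mu=%g, mu0=%g, seed=%d)\n",
    cfg$m, cfg$n, 100 * cfg$frac_ms_genes, cfg$mu, cfg$mu0, cfg$seed))
  cat(sprintf("  phenotype: %d RY / %d RN; subtypes (latent): %d + %d\n",
              sum(x$phenotype$group == "RY"), sum(x$phenotype$group == "RN"),
              cfg$ms_split[1], cfg$ms_split[2]))
  invisible(x)
}

#' Asymptotic null standard deviation of the two-sample t statistic under
#' latent-group heterogeneity
#'
#' For an MS-defining gene with background effect `mu`, each phenotype group
#' mixes the two subtypes half-and-half, which inflates the pooled variance
#' by `1 + mu^2/16` while leaving the numerator variance untouched.  The t
#' statistic is therefore asymptotically `N(0, 1/(1 + mu^2/16))` — narrower
#' than the standard Gaussian reference whenever `mu != 0`, which is what
#' depletes small P values.
#'
#' @param mu background effect size, `>= 0`.
#' @return the asymptotic null standard deviation `1/sqrt(1 + mu^2/16)`.
#' @export
#' @examples
#' theoretical_null_sd(0)  # 1: homogeneous cohort, standard null
#' theoretical_null_sd(2)  # 0.894
theoretical_null_sd <- function(mu) {
  if (any(mu < 0)) abort("`mu` must be nonnegative")
  1 / sqrt(1 + mu^2 / 16)
}

#' True false discovery proportion at a P-value threshold
#'
#' Evaluation-only helper: uses the latent truth mask to compute
#' `V(c)/R(c)`, the realised proportion of rejected genes that are truly
#' non-differentially expressed; defined as 0 when nothing is rejected.
#'
#' @param pvalues per-gene P values.
#' @param de_mask logical, `TRUE` for genes that are truly differentially
#'   expressed.
#' @param c rejection threshold (`P <= c`).
#' @return the false discovery proportion in `[0, 1]`.
#' @export
true_fdp <- function(pvalues, de_mask, c) {
  stopifnot(length(pvalues) == length(de_mask))
  R <- sum(pvalues <= c)
  if (R == 0) return(0)
  sum(pvalues <= c & !de_mask) / R
}

#' Per-rank true false discovery proportion curve
#'
#' Orders genes by P value and reports, at every rank `k`, the proportion of
#' the `k` most significant genes that are truly null.  Used to benchmark
#' FDR estimators against the latent truth.
#'
#' @inheritParams true_fdp
#' @return tibble `(rank, p, fdp)` ordered by increasing P value.
#' @export
fdp_curve <- function(pvalues, de_mask) {
  stopifnot(length(pvalues) == length(de_mask))
  o <- order(pvalues)
  tibble(
    rank = seq_along(pvalues),
    p = pvalues[o],
    fdp = cumsum(!de_mask[o]) / seq_along(pvalues)
  )
}
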