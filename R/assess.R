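#' Count genes below an FDR threshold (N01)
#'
#' The subtype-interestingness score: the number of genes whose corrected
#' FDR estimate falls strictly below `c` (default 0.1).
#'
#' @param fdr per-gene FDR estimates in `[0, 1]`.
#' @param c threshold; strict inequality.
#' @return nonnegative integer count.
#' @export
#' @examples
#' n01(c(0.05, 0.09, 0.2))  # 2
n01 <- function(fdr, c = 0.1) sum(fdr < c)

#' Ratio of observed to expected small P values
#'
#' `Ratio = #(P <= lambda) / (m * lambda)`: the observed count of small P
#' values over its expectation under uniformity.  `Ratio < 1` flags the
#' depletion of small P values that latent-group heterogeneity produces —
#' the situation in which the corrected FDR engine matters.
#'
#' @param pvalues per-gene P values.
#' @param lambda small-P-value cutoff; 0.2 in practice.
#' @return nonnegative scalar; values below 1 indicate depletion.
#' @export
#' @examples
#' ratio_lambda(c(0.15, rep(0.5, 9)))  # 0.5
ratio_lambda <- function(pvalues, lambda = 0.2) {
  if (lambda <= 0 || lambda >= 1) abort("`lambda` must be in (0, 1)")
  sum(pvalues <= lambda) / (length(pvalues) * lambda)
}

# N01 for one label arrangement within a patient subset, by engine.
# "parametric" forces the path-1 normal approximation (the N01_0 score);
# "fast" allows path 2; "svd" runs the full permutation-SVD engine.
.n01_engine <- function(expr_sub, labels, engine, c_fdr, K, seed,
                        edges = default_edges()) {
  fit <- switch(engine,
    parametric = fast_null_approximation(expr_sub, labels, edges = edges,
                                         seed = seed, K = K,
                                         force_parametric = TRUE),
    fast = fast_null_approximation(expr_sub, labels, edges = edges,
                                   seed = seed, K = K),
    svd = fit_null_model(expr_sub, labels, K = K, edges = edges, seed = seed),
    abort(sprintf("unknown engine '%s'", engine))
  )
  g <- resolve_groups(expr_sub, labels)
  z <- .tstats(expr_sub, g$i1, g$i2)$z
  n01(fdr_corrected_curve(z, fit), c_fdr)
}

#' Assess candidate subtypes with heterogeneity-aware FDR scores
#'
#' For each candidate subtype the expression matrix is restricted to the
#' subtype's patients and all-gene two-sample t statistics comparing the
#' phenotype groups *within the subtype* are computed.  The fast
#' normal-approximation score `n01_0` is computed first; subtypes with
#' `n01_0 <= prefilter` are marked skipped (nothing interesting even under
#' the cheap null) and not scored further.  Surviving subtypes get the full
#' `n01` under the requested engine and the small-P-value depletion
#' diagnostic `ratio`.
#'
#' Subtypes in which either phenotype group has fewer than 2 members are
#' discarded with a reason.
#'
#' @param expr genes-by-patients matrix for the whole cohort.
#' @param groups per-patient phenotype labels aligned to `expr` columns.
#' @param subtypes tibble from [enumerate_subtypes()] (needs `subtype_id`,
#'   `patient_ids`, `gene_ids`).
#' @param fdr_threshold FDR cutoff defining N01 (default 0.1).
#' @param ratio_cutoff `lambda` for [ratio_lambda()] (default 0.2).
#' @param prefilter skip threshold on `n01_0` (default 2; set to -1 to
#'   disable).
#' @param engine FDR engine for the full `n01`: `"fast"` (default; normal
#'   approximation with permutation-curve fallback), `"parametric"`, or
#'   `"svd"` (full permutation-SVD fit).
#' @param K permutations for the engines that permute.
#' @param seed integer seed; per-subtype seeds are derived from it.
#' @param edges histogram grid shared by all per-subtype fits.
#' @return tibble: `subtype_id`, `n_genes`, `n_patients`, `n01_0`, `n01`,
#'   `ratio`, `b`, `pi0`, `skipped`, `discarded`, `reason`.
#' @export
assess_subtypes <- function(expr, groups, subtypes, fdr_threshold = 0.1,
                            ratio_cutoff = 0.2, prefilter = 2,
                            engine = c("fast", "parametric", "svd"),
                            K = 100, seed = 1,
                            edges = default_edges()) {
  engine <- arg_match(engine)
  stopifnot(!is.null(colnames(expr)))
  groups <- setNames(as.character(groups), colnames(expr))
  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, nrow(subtypes)))

  rows <- map(seq_len(nrow(subtypes)), function(i) {
    st <- subtypes[i, ]
    pats <- st$patient_ids[[1]]
    if (!all(pats %in% colnames(expr))) {
      abort(sprintf("subtype %s has patients missing from the matrix",
                    st$subtype_id))
    }
    labels <- groups[pats]
    base <- tibble(subtype_id = st$subtype_id,
                   n_genes = length(st$gene_ids[[1]]),
                   n_patients = length(pats),
                   n01_0 = NA_integer_, n01 = NA_integer_,
                   ratio = NA_real_, b = NA_real_, pi0 = NA_real_,
                   skipped = FALSE, discarded = FALSE, reason = NA_character_)
    if (min(table(labels)) < 2 || length(unique(labels)) < 2) {
      base$discarded <- TRUE
      base$reason <- "a phenotype group has fewer than 2 members in the subtype"
      return(base)
    }
    expr_sub <- expr[, pats, drop = FALSE]
    fit0 <- fast_null_approximation(expr_sub, labels, edges = edges,
                                    seed = sub_seeds[i], K = K,
                                    force_parametric = TRUE)
    g <- resolve_groups(expr_sub, labels)
    z <- .tstats(expr_sub, g$i1, g$i2)$z
    base$n01_0 <- n01(fdr_corrected_curve(z, fit0), fdr_threshold)
    base$b <- fit0$b
    base$pi0 <- fit0$pi0
    p_raw <- 2 * pnorm(-abs(z))
    base$ratio <- ratio_lambda(p_raw, ratio_cutoff)
    if (base$n01_0 <= prefilter) {
      base$skipped <- TRUE
      return(base)
    }
    base$n01 <- if (engine == "parametric") {
      base$n01_0
    } else {
      .n01_engine(expr_sub, labels, engine, fdr_threshold, K,
                  sub_seeds[i], edges)
    }
    base
  })
  list_rbind(rows)
}

#' Standardize observed scores against their permutation replicates and
#' stack the reference
#'
#' The calibration core, separated from the permutation machinery so it can
#' be verified directly: each observed score is standardized by the mean
#' and standard deviation of the pooled set (observed value together with
#' its permutation replicates, or the replicates alone); the replicates are
#' standardized the same way and stacked across all subtypes into one
#' reference vector; each P value is the fraction of stacked values at or
#' above the observed standardized score.
#'
#' @param observed numeric vector of observed scores (one per subtype).
#' @param perms list of numeric vectors, the permutation replicates of each
#'   observed score.
#' @param include_observed pool the observed score into its own mean/sd.
#' @return tibble `(z_score, p_value, degenerate)`; a zero-sd pool gives
#'   `p_value = 1` with `degenerate = TRUE`.
#' @export
#' @examples
#' calibrate_scores(10, list(c(4, 5, 6, 25)), include_observed = FALSE)
calibrate_scores <- function(observed, perms, include_observed = TRUE) {
  stopifnot(length(observed) == length(perms))
  std <- map(seq_along(observed), function(i) {
    pool <- if (include_observed) c(observed[i], perms[[i]]) else perms[[i]]
    mu <- mean(pool)
    s <- sd(pool)
    if (!is.finite(s) || s == 0) {
      return(list(z = NA_real_, zperm = numeric(0), degenerate = TRUE))
    }
    list(z = (observed[i] - mu) / s, zperm = (perms[[i]] - mu) / s,
         degenerate = FALSE)
  })
  z_perm <- unlist(map(std, "zperm"))
  K <- length(z_perm)
  tibble(
    z_score = map_dbl(std, "z"),
    p_value = map_dbl(std, function(s) {
      if (s$degenerate || K == 0) 1 else sum(s$z <= z_perm) / K
    }),
    degenerate = map_lgl(std, "degenerate")
  )
}

#' Permutation calibration of N01 with stacked standardized scores
#'
#' High N01 can arise by chance because the clustering search optimises
#' over many candidate subtypes.  For each unskipped subtype the
#' within-subtype phenotype labels are permuted `N_p` times and N01 is
#' recomputed each time.  The observed N01 is standardized against the
#' pooled mean and standard deviation of the observed value together with
#' its permutation replicates; the permutation replicates are standardized
#' the same way, stacked across all subtypes into one reference vector, and
#' each subtype's P value is the fraction of stacked values at or above its
#' standardized score.
#'
#' @param assessments tibble from [assess_subtypes()].
#' @param expr,groups cohort matrix and phenotype labels.
#' @param subtypes the [enumerate_subtypes()] tibble the assessments came
#'   from.
#' @param N_p permutations per subtype (default 50).
#' @param engine N01 engine for the permutation recomputations (default
#'   `"parametric"`, the fast normal-approximation score — calibration of
#'   many subtypes with the full engine would nest permutations).
#' @param include_observed include the observed N01 in the pooled mean/sd
#'   (default `TRUE`); set `FALSE` for a leave-observed-out sensitivity
#'   analysis.
#' @param fdr_threshold FDR cutoff defining N01.
#' @param K permutations inside the FDR engine (only used by non-parametric
#'   engines).
#' @param seed integer seed.
#' @param edges histogram grid shared by all per-subtype fits.
#' @return `assessments` with columns `z_score`, `p_value` and `degenerate`
#'   added (skipped/discarded subtypes keep `NA`).
#' @export
calibrate_n01 <- function(assessments, expr, groups, subtypes, N_p = 50,
                          engine = c("parametric", "fast", "svd"),
                          include_observed = TRUE, fdr_threshold = 0.1,
                          K = 100, seed = 1, edges = default_edges()) {
  engine <- arg_match(engine)
  if (N_p < 2) abort("`N_p` must be at least 2")
  stopifnot(!is.null(colnames(expr)))
  groups <- setNames(as.character(groups), colnames(expr))
  active <- which(!assessments$skipped & !assessments$discarded)
  assessments$z_score <- NA_real_
  assessments$p_value <- NA_real_
  assessments$degenerate <- NA
  if (length(active) == 0) return(assessments)

  sub_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, nrow(assessments)))

  perms <- map(active, function(i) {
    id <- assessments$subtype_id[i]
    st <- subtypes[subtypes$subtype_id == id, ]
    pats <- st$patient_ids[[1]]
    labels <- groups[pats]
    expr_sub <- expr[, pats, drop = FALSE]
    withr::with_seed(sub_seeds[i], {
      map_int(seq_len(N_p), function(k) {
        # group sizes are preserved by label permutation, so both groups
        # keep >= 2 members
        lab_k <- sample(labels)
        .n01_engine(expr_sub, lab_k, engine, fdr_threshold, K,
                    seed = sample.int(.Machine$integer.max, 1),
                    edges = edges)
      })
    })
  })
  cal <- calibrate_scores(assessments$n01[active], perms,
                          include_observed = include_observed)
  assessments$z_score[active] <- cal$z_score
  assessments$p_value[active] <- cal$p_value
  assessments$degenerate[active] <- cal$degenerate
  assessments
}

#' Table-1-style summary of assessed subtypes
#'
#' @param assessments output of [calibrate_n01()] (or [assess_subtypes()]).
#' @return tibble with columns `Subtype_ID`, `Genes_in_clusters`,
#'   `Patients_in_subtype`, `N01`, `P_value`, plus `Ratio` and `Skipped`.
#' @export
subtype_table <- function(assessments) {
  tibble(
    Subtype_ID = assessments$subtype_id,
    Genes_in_clusters = assessments$n_genes,
    Patients_in_subtype = assessments$n_patients,
    N01 = assessments$n01,
    P_value = if ("p_value" %in% names(assessments)) assessments$p_value
              else NA_real_,
    Ratio = assessments$ratio,
    Skipped = assessments$skipped | assessments$discarded
  )
}
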