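test_that("N01 and Ratio follow their counting rules", {
  expect_equal(n01(c(0.05, 0.09, 0.2)), 2)
  expect_equal(n01(c(0.1)), 0)           # strict inequality at the threshold
  expect_equal(n01(rep(0.5, 10)), 0)
  p <- c(0.15, rep(0.5, 9))
  expect_equal(ratio_lambda(p, 0.2), 1 / (10 * 0.2))
  expect_equal(ratio_lambda(rep(0.9, 5), 0.2), 0)
  withr::with_seed(111, {
    expect_lt(abs(ratio_lambda(runif(100000), 0.2) - 1), 0.02)
  })
})

test_that("score calibration reproduces the stacked-permutation P value
           exactly", {
  # one subtype, K = 4 stacked values, exactly one at or above the observed
  cal <- calibrate_scores(10, list(c(4, 5, 6, 25)), include_observed = FALSE)
  expect_equal(cal$p_value, 0.25)
  # observed above every permutation value -> 0; below every one -> 1
  expect_equal(calibrate_scores(99, list(c(1, 2, 3)),
                                include_observed = FALSE)$p_value, 0)
  expect_equal(calibrate_scores(0, list(c(1, 2, 3)),
                                include_observed = FALSE)$p_value, 1)
  # matches a brute-force count over the stacked standardized vector
  withr::with_seed(113, {
    obs <- rpois(3, 10)
    perms <- replicate(3, rpois(7, 10), simplify = FALSE)
    cal2 <- calibrate_scores(obs, perms)
    zp <- unlist(lapply(1:3, function(i) {
      pool <- c(obs[i], perms[[i]])
      (perms[[i]] - mean(pool)) / sd(pool)
    }))
    zi <- vapply(1:3, function(i) {
      pool <- c(obs[i], perms[[i]])
      (obs[i] - mean(pool)) / sd(pool)
    }, numeric(1))
    expect_equal(cal2$z_score, zi)
    expect_equal(cal2$p_value,
                 vapply(zi, function(z) mean(z <= zp), numeric(1)))
  })
  # zero-sd pool is degenerate, not an error
  deg <- calibrate_scores(5, list(c(5, 5, 5)))
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)
})

test_that("subtype assessment prefilters null subtypes and scores planted
           signal", {
  co <- simulate_latent_cohort(m = 600, n = 60, frac_ms_genes = 0.9,
                               mu = 2, mu0 = 3, seed = 115)
  ms1 <- co$ms$patient_id[co$ms$ms == 1]
  other <- setdiff(co$phenotype$patient_id, ms1)[1:25]
  subtypes <- tibble::tibble(
    subtype_id = c("S001", "S002"),
    gene_ids = list(rownames(co$expr)[1:50], rownames(co$expr)[1:50]),
    patient_ids = list(ms1, other)
  )
  a <- assess_subtypes(co$expr, co$phenotype$group, subtypes,
                       engine = "parametric", seed = 3)
  # the pure planted subtype carries the relapse genes: strong N01
  expect_false(a$skipped[1])
  expect_gt(a$n01[1], 10)
  expect_gt(a$ratio[1], 0)
  # a null cohort shows nothing and is prefiltered
  co0 <- simulate_latent_cohort(m = 600, n = 60, frac_ms_genes = 1,
                                mu = 0, mu0 = 0, seed = 117)
  st0 <- tibble::tibble(subtype_id = "S001",
                        gene_ids = list(rownames(co0$expr)[1:50]),
                        patient_ids = list(co0$phenotype$patient_id[1:30]))
  a0 <- assess_subtypes(co0$expr, co0$phenotype$group, st0,
                        engine = "parametric", seed = 5)
  expect_true(a0$skipped[1])
  expect_lte(a0$n01_0[1], 2)
  # disabling the prefilter scores everything
  a1 <- assess_subtypes(co0$expr, co0$phenotype$group, st0,
                        engine = "parametric", prefilter = -1, seed = 5)
  expect_false(a1$skipped[1])
  expect_false(is.na(a1$n01[1]))
})

test_that("subtypes without both phenotype groups are discarded with a
           reason", {
  co <- small_cohort(m = 200, n = 40, seed = 119)
  ry <- co$phenotype$patient_id[co$phenotype$group == "RY"][1:10]
  st <- tibble::tibble(subtype_id = "S001",
                       gene_ids = list(rownames(co$expr)[1:20]),
                       patient_ids = list(ry))
  a <- assess_subtypes(co$expr, co$phenotype$group, st, seed = 1)
  expect_true(a$discarded[1])
  expect_match(a$reason[1], "fewer than 2")
})

test_that("calibration attaches z scores and P values to unskipped
           subtypes only", {
  co <- simulate_latent_cohort(m = 400, n = 60, frac_ms_genes = 0.9,
                               mu = 2, mu0 = 3, seed = 121)
  ms1 <- co$ms$patient_id[co$ms$ms == 1]
  st <- tibble::tibble(subtype_id = c("S001", "S002"),
                       gene_ids = list(rownames(co$expr)[1:30],
                                       rownames(co$expr)[31:60]),
                       patient_ids = list(ms1, co$phenotype$patient_id[16:45]))
  a <- assess_subtypes(co$expr, co$phenotype$group, st,
                       engine = "parametric", seed = 7)
  ac <- calibrate_n01(a, co$expr, co$phenotype$group, st, N_p = 10,
                      engine = "parametric", seed = 9)
  live <- !ac$skipped & !ac$discarded
  expect_true(all(!is.na(ac$p_value[live])))
  expect_true(all(is.na(ac$p_value[!live])))
  expect_true(all(ac$p_value[live] >= 0 & ac$p_value[live] <= 1))
  # a strongly signalled subtype should not look like chance
  expect_lt(ac$p_value[which(ac$subtype_id == "S001")], 0.5)
  tab <- subtype_table(ac)
  expect_named(tab, c("Subtype_ID", "Genes_in_clusters",
                      "Patients_in_subtype", "N01", "P_value", "Ratio",
                      "Skipped"))
})
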