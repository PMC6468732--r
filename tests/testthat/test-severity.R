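test_that("MSSS matches hand-worked rank examples", {
  ref3 <- data.frame(duration_years = 2, edss = c(2, 2, 2))
  expect_equal(compute_msss(ref3, 2, 2), 5)

  ref4 <- data.frame(duration_years = 5, edss = c(1, 2, 2, 4))
  expect_equal(compute_msss(ref4, 5, 2), 5)    # ranks {2,3,4} -> 3/6
  expect_equal(compute_msss(ref4, 5, 4), 7.5)  # ranks {4,5} -> 4.5/6

  # below every reference value in a bin of n: rank 1 -> 10/(n+2)
  refn <- data.frame(duration_years = 1, edss = c(3, 4, 5, 6))
  expect_equal(compute_msss(refn, 1, 0), 10 / 6)
  expect_error(compute_msss(refn, 9, 2), "no reference")
})

test_that("MSSS agrees with the brute-force oracle and stays in (0, 10)", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:25, 1)
    bin <- sample(seq(0, 10, by = 0.5), n, replace = TRUE)
    q <- sample(seq(0, 10, by = 0.5), 1)
    ref <- data.frame(duration_years = 3, edss = bin)
    got <- compute_msss(ref, 3.7, q)
    expect_equal(got, msss_oracle(bin, q))
    expect_gt(got, 0)
    expect_lt(got, 10)
  }
  # monotone in the query EDSS within a bin
  ref <- data.frame(duration_years = 0, edss = c(1, 2, 3.5, 6))
  vals <- vapply(seq(0, 10, 0.5), function(e) compute_msss(ref, 0, e),
                 numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("severity indices are exact arithmetic and antisymmetric", {
  expect_equal(severity_indices(5, 5), c(delta_msss = 0, msss_prime = 0))
  expect_equal(severity_indices(5, 3), c(delta_msss = 2, msss_prime = 10))
  expect_equal(severity_indices(3, 5), c(delta_msss = -2, msss_prime = -6))
  a <- severity_indices(7, 2)
  b <- severity_indices(2, 7)
  expect_equal(a[["delta_msss"]], -b[["delta_msss"]])
})

test_that("patients are classified by strict phase ordering", {
  mk <- function(opn, prot) data.frame(
    patient_id = "P", phase = c("remission", "relapse"),
    opn_nM = opn, prot_nM = prot)
  expect_equal(classify_patient_group(mk(c(40, 120), c(100, 50))), "A")
  expect_equal(classify_patient_group(mk(c(120, 40), c(100, 50))), "B")
  expect_equal(classify_patient_group(mk(c(40, 40), c(100, 50))), "B")
  expect_error(classify_patient_group(
    data.frame(patient_id = "P", phase = "remission", opn_nM = 1,
               prot_nM = 1)), "both")
})

test_that("patient simulation reproduces remission measurements as features", {
  kin <- default_test_kinetics()
  rec <- data.frame(patient_id = "P1",
                    phase = c("remission", "remission", "relapse"),
                    opn_nM = c(0.17, 0.17, 0.52),
                    prot_nM = c(0.0143, 0.0143, 0.009))
  sim <- simulate_patient(rec, kin)
  expect_true(sim$derivable)
  expect_equal(sim$group, "A")
  m <- patient_phase_means(rec)
  expect_equal(sim$features[["opn_f_rem"]], m$opn_rem * 0.5,
               tolerance = 1e-6)
  expect_equal(sim$features[["prot_rem"]], m$prot_rem, tolerance = 1e-6)
  # group-A relapse OPN feature is never below the remission feature
  opn_rem <- sum(sim$features[c("opn_f_rem", "opn_n_rem", "opn_c_rem")])
  opn_rel <- sum(sim$features[c("opn_f_rel", "opn_n_rel", "opn_c_rel")])
  expect_gte(opn_rel, opn_rem)
})

test_that("group-A relapse features dominate remission across a cohort", {
  cfg <- generator_config(seed = 41, n_patients = 10)
  co <- generate_cohort(cfg)
  ft <- cohort_feature_table(co, kinetics = cfg$kinetics)
  a <- ft[ft$group == "A" & ft$derivable, ]
  expect_gt(nrow(a), 0)
  expect_true(all(a$opn_f_rel >= a$opn_f_rem))
  # group-B patients fall back to measured values and are flagged
  b <- ft[ft$group == "B", ]
  expect_true(all(!b$derivable))
  expect_true(all(is.finite(as.matrix(b[, -(1:3)]))))
})

test_that("cross-validated linear model recovers noiseless signal", {
  set.seed(7)
  n <- 50
  x <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  y <- 2 * x[[1]] - x[[3]] + 0.5 * x[[4]]
  fit <- fit_severity_glm(x, y, seed = 2)
  expect_gt(fit$cv_r2, 0.99)
  expect_equal(length(unique(fit$folds)), 10)

  # fold clamping: n = 6 with k = 10 runs leave-one-out without error
  f6 <- fit_severity_glm(x[1:6, ], y[1:6], k_folds = 10, seed = 3)
  expect_equal(sort(unique(f6$folds)), 1:6)
  expect_error(fit_severity_glm(x, rep(1, n)), "constant")
})

test_that("feature-set comparison detects a planted signal", {
  cfg <- generator_config(seed = 4, n_patients = 50,
                          group_b_fraction = 0, severity_noise_sd = 0)
  co <- generate_cohort(cfg)
  ft <- cohort_feature_table(co, kinetics = cfg$kinetics)
  sev <- generate_severity(ft, cfg)
  ev <- evaluate_feature_sets(ft, list(msss = sev$table$msss_relapse),
                              seed = 9)
  r2 <- setNames(ev$cv_r2, ev$feature_set)
  expect_gte(r2[["proteasome_fragments"]], max(r2) - 1e-9)
  expect_equal(min(r2), r2[["opn_only"]])

  # duplicated feature columns leave the fit unchanged
  cols <- severity_feature_sets()$proteasome_fragments
  x <- ft[, cols]
  x2 <- cbind(x, dup = x[[1]])
  f1 <- fit_severity_glm(x, sev$table$msss_relapse, seed = 5)
  f2 <- fit_severity_glm(x2, sev$table$msss_relapse, seed = 5)
  expect_equal(f1$cv_r2, f2$cv_r2, tolerance = 1e-6)

  # a single-feature set equals plain regression R^2 (in-sample)
  f3 <- fit_severity_glm(ft[, "prot_rem", drop = FALSE],
                         sev$table$msss_relapse, seed = 6)
  lmfit <- stats::lm(sev$table$msss_relapse ~ ft$prot_rem)
  expect_equal(f3$in_sample_r2, summary(lmfit)$r.squared)
})

test_that("a group-A model does not transfer to inverted group-B patients", {
  cfg <- generator_config(seed = 8, n_patients = 40,
                          group_b_fraction = 0.25, severity_noise_sd = 0)
  co <- generate_cohort(cfg)
  ft <- cohort_feature_table(co, kinetics = cfg$kinetics)
  sev <- generate_severity(ft, cfg)
  m <- merge(ft, sev$table, by = "patient_id")
  a <- m[m$group == "A", ]
  b <- m[m$group == "B", ]
  cols <- severity_feature_sets()$opn_proteasome_fragments
  fit <- fit_severity_glm(a[, cols], a$msss_relapse, seed = 3)
  pred_b <- apply_model_to_group_b(fit, b[, cols], b$msss_relapse)
  cv_resid <- abs(a$msss_relapse - fit$cv_predictions)
  expect_gt(stats::median(abs(pred_b$residual)),
            stats::median(cv_resid))
  # empty group B gives an empty table; mismatched features error
  expect_equal(nrow(apply_model_to_group_b(fit, b[0, cols])), 0)
  expect_error(apply_model_to_group_b(fit, b[, 1:3]), "mismatch")
})

test_that("cohort statistics recover an exact inverse relationship", {
  opn <- seq(1, 3, length.out = 20)
  prot <- 1 / (0.5 + 2 * opn)
  co <- data.frame(patient_id = rep(1:10, 2),
                   phase = rep(c("remission", "relapse"), each = 10),
                   opn_nM = opn, prot_nM = prot)
  st <- cohort_statistics(co, n_boot = 200, seed = 4)
  expect_equal(st$correlation, 1)
  expect_true(all(abs(st$boot_replicates - 1) < 1e-10, na.rm = TRUE))
  expect_error(
    cohort_statistics(data.frame(patient_id = rep(1:5, 2),
                                 phase = rep(c("remission", "relapse"),
                                             each = 5),
                                 opn_nM = 1, prot_nM = 2)),
    "constant")
})

test_that("severity records assemble MSSS values per patient", {
  ref <- data.frame(duration_years = rep(c(2, 3), each = 5),
                    edss = c(1, 2, 2, 3, 4, 2, 3, 3, 4, 6))
  clin <- data.frame(patient_id = c("P1", "P1"),
                     phase = c("relapse", "remission"),
                     edss = c(4, 2), duration_years = c(2, 3))
  sr <- severity_records(clin, ref)
  expect_equal(sr$msss_relapse, compute_msss(ref, 2, 4))
  expect_equal(sr$msss_remission, compute_msss(ref, 3, 2))
  expect_equal(sr$delta_msss, sr$msss_relapse - sr$msss_remission)
})
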