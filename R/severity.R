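#' Multiple Sclerosis Severity Score from a reference population
#'
#' Ranks a patient's EDSS against the reference assessments with the same
#' (whole-year) disease duration. The query is added to its duration bin,
#' all assessments are ranked ascending by EDSS, the lowest and highest
#' rank of the query's EDSS value are averaged (mid-rank under ties),
#' divided by one plus the augmented bin size, and multiplied by 10,
#' giving a score strictly inside (0, 10).
#'
#' @param reference data.frame with columns `duration_years` (whole
#'   years) and `edss` (0-10 in 0.5 steps) — the normative population.
#' @param duration_years the patient's disease duration; binned by
#'   `floor()`.
#' @param edss the patient's EDSS.
#' @return the MSSS, in (0, 10).
#' @examples
#' ref <- data.frame(duration_years = 2, edss = c(2, 2, 2))
#' compute_msss(ref, 2, 2)  # full tie: 5.0
#' @export
compute_msss <- function(reference, duration_years, edss) {
  stopifnot(is.data.frame(reference),
            all(c("duration_years", "edss") %in% names(reference)))
  if (edss < 0 || edss > 10) stop("EDSS must lie in [0, 10]")
  bin <- reference$edss[floor(reference$duration_years) ==
                          floor(duration_years)]
  if (length(bin) == 0)
    stop("no reference assessments for duration ", floor(duration_years),
         " years")
  aug <- sort(c(bin, edss))
  rks <- which(aug == edss)
  mean(c(min(rks), max(rks))) / (length(aug) + 1) * 10
}

#' Relapse-worsening severity indices
#'
#' `delta_msss = msss_relapse - msss_remission` (positive when the
#' relapse is worse) and `msss_prime = delta_msss * msss_relapse`, which
#' up-weights worsening occurring at high absolute severity.
#'
#' @param msss_relapse,msss_remission MSSS values in [0, 10].
#' @return named vector `c(delta_msss=, msss_prime=)`.
#' @examples
#' severity_indices(5, 3)  # c(2, 10)
#' @export
severity_indices <- function(msss_relapse, msss_remission) {
  stopifnot(msss_relapse >= 0, msss_relapse <= 10,
            msss_remission >= 0, msss_remission <= 10)
  delta <- msss_relapse - msss_remission
  c(delta_msss = delta, msss_prime = delta * msss_relapse)
}

#' Classify a patient's remission-to-relapse pattern
#'
#' Group A patients show the expected circuit behaviour — OPN strictly
#' increases and proteasome strictly decreases from remission to relapse
#' (remission withdrawals averaged). Everyone else (including exact
#' ties) is group B.
#'
#' @param records cohort rows of one patient (columns `phase`, `opn_nM`,
#'   `prot_nM`).
#' @return `"A"` or `"B"`.
#' @export
classify_patient_group <- function(records) {
  phases <- unique(records$phase)
  if (!all(c("remission", "relapse") %in% phases))
    stop("patient needs both remission and relapse records")
  opn_rem <- mean(records$opn_nM[records$phase == "remission"])
  opn_rel <- mean(records$opn_nM[records$phase == "relapse"])
  prot_rem <- mean(records$prot_nM[records$phase == "remission"])
  prot_rel <- mean(records$prot_nM[records$phase == "relapse"])
  if (opn_rel > opn_rem && prot_rel < prot_rem) "A" else "B"
}

#' Simulate one patient and extract circuit features
#'
#' Derives circuit parameters from the patient's own paired measurements
#' (isoform and OPN-FL fractions assumed 0.5 each, as in the per-patient
#' analysis), simulates the circuit through one relapse, and extracts the
#' feature vector used by the severity models: per-species OPN, total
#' proteasome, and standard-/immuno-fragment pools, each at the remission
#' steady state and at the relapse peak, plus isoform-resolved variants
#' and total chemotaxis when an index set is given. Patients whose
#' derivation is inadmissible (group B pattern) are flagged; their
#' features fall back to measured concentrations apportioned by the
#' assumed fractions, with simulation-only features (fragments,
#' chemotaxis) taken from the remission-style split of measured values.
#'
#' @param records cohort rows of one patient (columns `phase`, `opn_nM`,
#'   `prot_nM`).
#' @param kinetics a [kinetic_params()] object.
#' @param ci optional [chemotactic_index_set()] for chemotaxis features.
#' @param schedule relapse schedule for the simulation.
#' @param x_i,x_t assumed fractions (default 0.5 / 0.5).
#' @param t_step output step (h).
#' @return list with `features` (named numeric vector), `group`
#'   (`"A"`/`"B"`), `derivable` (logical), `params` (or `NULL`),
#'   `trajectory` (or `NULL`), `c_tot` (or `NULL`).
#' @export
simulate_patient <- function(records, kinetics, ci = NULL,
                             schedule = relapse_schedule(onset_time = 336,
                                                         t_end = 1680),
                             x_i = 0.5, x_t = 0.5, t_step = 12) {
  group <- classify_patient_group(records)
  m <- patient_phase_means(records)
  pars <- tryCatch(
    derive_circuit_params(m$prot_rem, m$prot_rel, m$opn_rem, m$opn_rel,
                          kinetics, x_i = x_i, x_t = x_t),
    opncircuit_inadmissible = function(e) NULL)

  feature_row <- function(state, ci) {
    f <- c(opn_f = state[["opn_f"]], opn_n = state[["opn_n"]],
           opn_c = state[["opn_c"]],
           prot = state[["p_i"]] + state[["p_s"]],
           frag_s = state[["f_sf"]] + state[["f_sn"]] + state[["f_sc"]],
           frag_i = state[["f_if"]] + state[["f_in"]] + state[["f_ic"]],
           p_i = state[["p_i"]], p_s = state[["p_s"]],
           f_sf = state[["f_sf"]], f_sn = state[["f_sn"]],
           f_sc = state[["f_sc"]], f_if = state[["f_if"]],
           f_in = state[["f_in"]], f_ic = state[["f_ic"]])
    if (!is.null(ci)) {
      st <- as.data.frame(as.list(state))
      st$time_h <- 0
      f <- c(f, c_tot = total_chemotaxis(st, ci)$c_tot[1])
    }
    f
  }

  if (!is.null(pars)) {
    eq <- circuit_equilibrium(pars)
    t_grid <- seq(0, schedule$t_end, by = t_step)
    traj <- simulate_circuit(pars, eq, schedule, t_grid)
    win <- relapse_window(schedule)
    in_win <- traj$time_h >= win[1] & traj$time_h <= win[2]
    peak_idx <- which(in_win)[which.max(
      rowSums(traj[in_win, c("opn_f", "opn_n", "opn_c")]))]
    peak <- as.numeric(traj[peak_idx, state_species()])
    names(peak) <- state_species()
    rem_f <- feature_row(eq, ci)
    rel_f <- feature_row(peak, ci)
    ct <- if (!is.null(ci)) total_chemotaxis(traj, ci) else NULL
  } else {
    # fall back to measured values, split by the assumed fractions
    mk_state <- function(opn_tot, prot) {
      sp <- split_measurements(opn_tot, prot, x_t, x_i)
      circuit_state(p_i = sp$p_i, p_s = sp$p_s, opn_f = sp$opn[["FL"]],
                    opn_n = sp$opn[["N"]], opn_c = sp$opn[["C"]])
    }
    rem_f <- feature_row(mk_state(m$opn_rem, m$prot_rem), ci)
    rel_f <- feature_row(mk_state(m$opn_rel, m$prot_rel), ci)
    traj <- NULL
    ct <- NULL
  }
  names(rem_f) <- paste0(names(rem_f), "_rem")
  names(rel_f) <- paste0(names(rel_f), "_rel")
  list(features = c(rem_f, rel_f), group = group,
       derivable = !is.null(pars), params = pars, trajectory = traj,
       c_tot = ct)
}

#' Feature table for a whole cohort
#'
#' @param cohort cohort data.frame (nM columns present).
#' @param ... passed to [simulate_patient()].
#' @return data.frame, one row per patient, with `patient_id`, `group`,
#'   `derivable` and the feature columns.
#' @export
cohort_feature_table <- function(cohort, ...) {
  ids <- unique(cohort$patient_id)
  rows <- lapply(ids, function(id) {
    sim <- simulate_patient(cohort[cohort$patient_id == id, ], ...)
    cbind(data.frame(patient_id = id, group = sim$group,
                     derivable = sim$derivable),
          as.data.frame(as.list(sim$features)))
  })
  do.call(rbind, rows)
}

#' The nested feature sets of the severity models
#'
#' @param chemotaxis include the chemotaxis-augmented set (requires
#'   `c_tot_*` columns).
#' @return named list of character vectors of feature-column names, from
#'   OPNs-only to the isoform-resolved set.
#' @export
severity_feature_sets <- function(chemotaxis = FALSE) {
  both <- function(x) c(paste0(x, "_rem"), paste0(x, "_rel"))
  sets <- list(
    opn_only = both(c("opn_f", "opn_n", "opn_c")),
    proteasome_fragments = both(c("prot", "frag_s", "frag_i")),
    opn_proteasome_fragments = both(c("opn_f", "opn_n", "opn_c", "prot",
                                      "frag_s", "frag_i")))
  if (chemotaxis) {
    sets$plus_chemotaxis <- c(sets$opn_proteasome_fragments, both("c_tot"))
    sets$isoform_resolved <- c(both(c("opn_f", "opn_n", "opn_c", "p_i",
                                      "p_s", "f_sf", "f_sn", "f_sc",
                                      "f_if", "f_in", "f_ic")),
                               both("c_tot"))
  } else {
    sets$isoform_resolved <- both(c("opn_f", "opn_n", "opn_c", "p_i",
                                    "p_s", "f_sf", "f_sn", "f_sc",
                                    "f_if", "f_in", "f_ic"))
  }
  sets
}

#' Cross-validated Gaussian linear severity model
#'
#' Fits `outcome ~ features` by ordinary least squares and evaluates it
#' by k-fold cross-validation with a seeded random fold assignment
#' (folds are clamped to the sample size, so tiny cohorts get
#' leave-one-out). The cross-validated R-squared is computed on the
#' pooled out-of-fold predictions; the in-sample R-squared is reported
#' alongside. Rank-deficient design matrices (duplicated features) are
#' tolerated.
#'
#' @param features data.frame of feature columns (numeric).
#' @param outcome numeric outcome vector (MSSS, delta-MSSS or
#'   MSSS-prime).
#' @param k_folds requested folds (default 10).
#' @param seed fold-assignment seed.
#' @param folds optional explicit fold assignment (overrides `k_folds`
#'   and `seed`); used to share folds across feature sets.
#' @return object of class `severity_fit`: list with `model` (the full
#'   `lm`), `coefficients`, `cv_r2`, `in_sample_r2`, `cv_predictions`,
#'   `folds`, `feature_names`.
#' @export
fit_severity_glm <- function(features, outcome, k_folds = 10, seed = 1,
                             folds = NULL) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n < 3) stop("need at least 3 patients")
  if (length(outcome) != n) stop("outcome length mismatch")
  if (stats::var(outcome) == 0)
    stop("undefined R-squared: constant outcome")
  if (is.null(folds)) folds <- make_folds(n, k_folds, seed)
  dat <- cbind(features, .y = outcome)
  pred <- rep(NA_real_, n)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit_f <- stats::lm(.y ~ ., data = dat[!hold, , drop = FALSE],
                       singular.ok = TRUE)
    pred[hold] <- suppressWarnings(
      stats::predict(fit_f, newdata = dat[hold, , drop = FALSE]))
  }
  cv_r2 <- 1 - sum((outcome - pred)^2) / sum((outcome - mean(outcome))^2)
  full <- stats::lm(.y ~ ., data = dat, singular.ok = TRUE)
  structure(list(model = full, coefficients = stats::coef(full),
                 cv_r2 = cv_r2,
                 # suppressed: summary.lm warns on noiseless (perfect)
                 # fits, a legitimate case for synthetic outcomes
                 in_sample_r2 = suppressWarnings(summary(full)$r.squared),
                 cv_predictions = pred, folds = folds,
                 feature_names = names(features)),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf(
    "Severity model: %d features, CV R^2 = %.3f (in-sample %.3f)\n",
    length(x$feature_names), x$cv_r2, x$in_sample_r2))
  invisible(x)
}

#' Seeded k-fold assignment with clamping
#' @param n sample size.
#' @param k_folds requested folds; clamped to `n`.
#' @param seed RNG seed.
#' @return integer fold labels of length `n`.
#' @export
make_folds <- function(n, k_folds = 10, seed = 1) {
  k <- min(k_folds, n)
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Compare nested feature sets by cross-validated R-squared
#'
#' Evaluates each nested feature set on each outcome with an identical
#' fold assignment, so differences reflect the feature sets rather than
#' fold noise.
#'
#' @param feature_table output of [cohort_feature_table()] (or any
#'   data.frame holding the feature columns).
#' @param outcomes named list or data.frame of outcome vectors.
#' @param k_folds,seed see [fit_severity_glm()].
#' @param sets named list of feature-column sets (default
#'   [severity_feature_sets()], with chemotaxis sets when the columns
#'   are present).
#' @return data.frame: `feature_set`, `outcome`, `cv_r2`,
#'   `in_sample_r2`, `n_features`.
#' @export
evaluate_feature_sets <- function(feature_table, outcomes, k_folds = 10,
                                  seed = 1, sets = NULL) {
  if (is.null(sets))
    sets <- severity_feature_sets(
      chemotaxis = "c_tot_rem" %in% names(feature_table))
  outcomes <- as.data.frame(outcomes)
  folds <- make_folds(nrow(feature_table), k_folds, seed)
  rows <- list()
  for (s in names(sets)) {
    miss <- setdiff(sets[[s]], names(feature_table))
    if (length(miss))
      stop("feature table lacks columns: ", paste(miss, collapse = ", "))
    for (o in names(outcomes)) {
      fit <- fit_severity_glm(feature_table[, sets[[s]], drop = FALSE],
                              outcomes[[o]], folds = folds)
      rows[[length(rows) + 1]] <- data.frame(
        feature_set = s, outcome = o, cv_r2 = fit$cv_r2,
        in_sample_r2 = fit$in_sample_r2,
        n_features = length(sets[[s]]))
    }
  }
  do.call(rbind, rows)
}

#' Predict severity for held-out (group B) patients
#'
#' Applies a model fitted on group A to the features of group B patients
#' without refitting, returning predictions and residuals. The published
#' pattern is a strong discrepancy: the circuit-based model does not
#' transfer to patients whose phase ordering contradicts the circuit.
#'
#' @param fit a [fit_severity_glm()] result.
#' @param features_b data.frame of group-B features (same columns).
#' @param recorded optional recorded outcome values.
#' @return data.frame with `predicted` (and `recorded`, `residual`).
#' @export
apply_model_to_group_b <- function(fit, features_b, recorded = NULL) {
  stopifnot(inherits(fit, "severity_fit"))
  features_b <- as.data.frame(features_b)
  if (nrow(features_b) == 0)
    return(data.frame(predicted = numeric(0)))
  miss <- setdiff(fit$feature_names, names(features_b))
  if (length(miss))
    stop("feature mismatch: ", paste(miss, collapse = ", "))
  pred <- suppressWarnings(
    stats::predict(fit$model,
                   newdata = features_b[, fit$feature_names,
                                        drop = FALSE]))
  out <- data.frame(predicted = as.numeric(pred))
  if (!is.null(recorded)) {
    out$recorded <- recorded
    out$residual <- out$recorded - out$predicted
  }
  out
}

#' Paired test, inverse correlation and bootstrap CI for a cohort
#'
#' The published cohort statistics: a Wilcoxon signed-rank test of
#' proteasome remission vs relapse (per-patient phase means), the Pearson
#' correlation between OPN and the reciprocal proteasome concentration
#' pooling all withdrawals, and a seeded percentile bootstrap (resampling
#' observations with replacement) for that correlation.
#'
#' @param cohort cohort data.frame (nM columns present).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param conf confidence level of the percentile interval.
#' @return list with `wilcoxon_p`, `correlation`, `boot_ci`
#'   (`c(lower, upper)`), `boot_replicates`, `n_patients`, `n_obs`.
#' @export
cohort_statistics <- function(cohort, n_boot = 1000, seed = 1,
                              conf = 0.95) {
  check_cohort(cohort)
  paired <- patient_phase_means(cohort)
  if (nrow(paired) < 3) stop("need >= 3 paired patients")
  wp <- suppressWarnings(
    stats::wilcox.test(paired$prot_rem, paired$prot_rel,
                       paired = TRUE))$p.value
  x <- cohort$opn_nM
  y <- 1 / cohort$prot_nM
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant measurements")
  rho <- stats::cor(x, y)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(x), replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
    else stats::cor(x[i], y[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(wilcoxon_p = wp, correlation = rho,
       boot_ci = c(lower = ci[1], upper = ci[2]),
       boot_replicates = reps, n_patients = nrow(paired),
       n_obs = length(x))
}

#' Read / write the clinical CSV and derive severity records
#'
#' Clinical columns: `patient_id`, `phase`, `edss`, `duration_years`.
#'
#' @param path CSV path.
#' @return clinical data.frame.
#' @export
read_clinical <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_clinical
#' @param clinical clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE)
  invisible(clinical)
}

#' Severity records (MSSS family) for a clinical table
#'
#' @param clinical clinical data.frame with both phases per patient.
#' @param reference MSSS reference population (see [compute_msss()]).
#' @return data.frame: `patient_id`, `msss_relapse`, `msss_remission`,
#'   `delta_msss`, `msss_prime`.
#' @export
severity_records <- function(clinical, reference) {
  ids <- unique(clinical$patient_id)
  rows <- lapply(ids, function(id) {
    p <- clinical[clinical$patient_id == id, ]
    rel <- p[p$phase == "relapse", ][1, ]
    rem <- p[p$phase == "remission", ][1, ]
    if (any(is.na(rel$edss)) || any(is.na(rem$edss)))
      stop("patient ", id, " lacks a phase")
    ms_rel <- compute_msss(reference, rel$duration_years, rel$edss)
    ms_rem <- compute_msss(reference, rem$duration_years, rem$edss)
    si <- severity_indices(ms_rel, ms_rem)
    data.frame(patient_id = id, msss_relapse = ms_rel,
               msss_remission = ms_rem,
               delta_msss = si[["delta_msss"]],
               msss_prime = si[["msss_prime"]])
  })
  do.call(rbind, rows)
}
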