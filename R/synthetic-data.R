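#' Configuration of the synthetic-data generators
#'
#' Bundles the ground truth and noise structure used to emulate the four
#' input tables of the analysis: the longitudinal serum cohort, the in
#' vitro digestion kinetics, the Boyden-chamber migration assays, the
#' MSSS reference population and the severity outcomes. All generators
#' are byte-deterministic given `seed`.
#'
#' The defaults encode the study conditions: a 16-patient cohort with
#' 1-4 remission withdrawals each and a minority of group-B patients;
#' serum OPN around 10 ng/mL in remission rising ~3-fold in relapse with
#' proteasome around 100 ng/mL falling through OPN-mediated release
#' inhibition (`k_i`); digestion assays at the in vitro concentrations
#' (0.4 ug OPN and 3.5 ug proteasome in 20 uL, i.e. ~571 and ~250 nM)
#' over 0-4 h in duplicate; migration assays at 10 ug/mL OPN with a 20:1
#' proteasome:OPN mass ratio over a 2+20 h window, control counts
#' 87 +/- 7.9; immunoproteasome `kcut` above standard for every OPN
#' species; fragment indices above the parent index for OPN-FL/-C and
#' below it for OPN-N.
#'
#' @param seed master seed.
#' @param n_patients cohort size.
#' @param group_b_fraction fraction with inverted phase ordering.
#' @param opn_rem_ng_ml,prot_rem_ng_ml population remission means.
#' @param patient_sdlog between-patient log-SD of remission OPN.
#' @param noise_sdlog measurement log-SD for OPN and proteasome.
#' @param k_i,gamma,x_i,x_t,k_deg,k_deg3,k_1 ground-truth circuit
#'   constants.
#' @param kinetics ground-truth [kinetic_params()].
#' @param digestion_times,digestion_replicates,digestion_noise_sd,
#'   digestion_p_conc,digestion_opn0 digestion assay design.
#' @param migration_opn0,migration_prot,migration_noise_sd,control_mean,
#'   control_sd,window migration assay design.
#' @param ci_truth named list of ground-truth
#'   [chemotactic_index_set()]s per cell type.
#' @param msss_bin_size,msss_max_duration MSSS reference design.
#' @param severity_noise_sd SD of the severity outcome noise (MSSS
#'   units).
#' @param masses molecular masses for unit conversion (kDa).
#' @return object of class `generator_config` (a list).
#' @export
generator_config <- function(
    seed = 1,
    n_patients = 16,
    group_b_fraction = 0.2,
    opn_rem_ng_ml = 6,
    prot_rem_ng_ml = 10,
    patient_sdlog = 0.15,
    noise_sdlog = c(opn = 0.05, prot = 0.05),
    k_i = 2, gamma = 3, x_i = 0.5, x_t = 0.5,
    k_deg = 2e-4, k_deg3 = 2e-4, k_1 = 1e-4,
    kinetics = kinetic_params(
      kcut = cbind(standard = c(0.4, 0.6, 0.5),
                   immuno = c(1.2, 0.8, 1.5)),
      km = matrix(300, 3, 2)),
    digestion_times = c(0, 0.5, 1, 2, 3, 4), digestion_replicates = 4,
    digestion_noise_sd = 0.05,
    digestion_p_conc = 250, digestion_opn0 = 571,
    migration_opn0 = 285.7, migration_prot = 285.7,
    migration_noise_sd = 5, control_mean = 87, control_sd = 7.9,
    window = c(2, 22),
    ci_truth = default_ci_truth(),
    msss_bin_size = 30, msss_max_duration = 30,
    severity_noise_sd = 0.5,
    masses = default_masses()) {
  stopifnot(n_patients >= 0, group_b_fraction >= 0, group_b_fraction <= 1,
            patient_sdlog >= 0, all(noise_sdlog >= 0),
            digestion_noise_sd >= 0, migration_noise_sd >= 0,
            severity_noise_sd >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

#' Ground-truth chemotactic indices per cell type
#'
#' HUVEC-like defaults with proteasomal processing enhancing OPN-FL and
#' OPN-C chemotaxis (immuno more than standard) and hampering OPN-N;
#' monocytes respond more strongly to unprocessed OPN-FL.
#'
#' @return named list of [chemotactic_index_set()]s.
#' @export
default_ci_truth <- function() {
  frag <- function(s, i) cbind(standard = s, immuno = i)
  list(
    HUVEC = chemotactic_index_set(
      ci_opn = c(FL = 0.009, N = 0.014, C = 0.010),
      ci_frag = frag(c(0.012, 0.007, 0.013), c(0.018, 0.007, 0.020)),
      cell_type = "HUVEC"),
    lymphocyte = chemotactic_index_set(
      ci_opn = c(FL = 0.008, N = 0.012, C = 0.009),
      ci_frag = frag(c(0.011, 0.006, 0.012), c(0.016, 0.006, 0.018)),
      cell_type = "lymphocyte"),
    monocyte = chemotactic_index_set(
      ci_opn = c(FL = 0.015, N = 0.013, C = 0.010),
      ci_frag = frag(c(0.019, 0.007, 0.013), c(0.026, 0.007, 0.019)),
      cell_type = "monocyte"))
}

#' Ground-truth circuit parameters of a generator configuration
#'
#' Built so that the configured population remission measurements are an
#' exact equilibrium: `k_in` from the proteasome balance and the OPN
#' clearances from the per-species residuals.
#'
#' @param config a [generator_config()].
#' @return a [circuit_params()] object.
#' @export
truth_circuit_params <- function(config) {
  opn_rem <- ng_ml_to_nM(config$opn_rem_ng_ml, config$masses[["opn"]])
  prot_rem <- ng_ml_to_nM(config$prot_rem_ng_ml,
                          config$masses[["proteasome"]])
  k_in <- derive_kin(prot_rem, opn_rem, config$k_i, config$k_deg)
  sp <- split_measurements(opn_rem, prot_rem, config$x_t, config$x_i)
  cl <- derive_opn_clearance(config$k_1, config$x_t, sp$opn, sp$p_i,
                             sp$p_s, config$kinetics)
  circuit_params(k_in = k_in, k_i = config$k_i, gamma = config$gamma,
                 k_deg = config$k_deg, k_1 = config$k_1,
                 k_deg_f = cl[["k_deg_f"]], k_deg_n = cl[["k_deg_n"]],
                 k_deg_c = cl[["k_deg_c"]], k_deg3 = config$k_deg3,
                 x_i = config$x_i, x_t = config$x_t,
                 kinetics = config$kinetics)
}

#' Generate a longitudinal serum cohort
#'
#' Per group-A patient: remission OPN log-normal around the population
#' equilibrium, relapse OPN scaled by the equilibrium relapse uplift of
#' the ground-truth circuit, proteasome from the steady-state release
#' balance `p = k_in / (k_deg (1 + k_i opn))`, 1-4 remission
#' withdrawals, and multiplicative log-normal measurement noise on every
#' record. Group-B patients have their noise-free phase values swapped,
#' so only the phase ordering (not the marginal distribution)
#' distinguishes the groups.
#'
#' @param config a [generator_config()].
#' @return cohort data.frame: `patient_id`, `phase`,
#'   `months_from_relapse`, `opn_ng_ml`, `proteasome_ng_ml`, `group`,
#'   plus nM columns.
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed + 101L)
  empty <- data.frame(patient_id = character(0), phase = character(0),
                      months_from_relapse = numeric(0),
                      opn_ng_ml = numeric(0), proteasome_ng_ml = numeric(0),
                      group = character(0))
  if (config$n_patients == 0) return(cohort_to_nM(empty, config$masses))
  truth <- truth_circuit_params(config)
  eq_rem <- circuit_equilibrium(truth, 1)
  eq_rel <- circuit_equilibrium(truth, config$gamma)
  opn_rem_eq <- sum(eq_rem[c("opn_f", "opn_n", "opn_c")])
  uplift <- sum(eq_rel[c("opn_f", "opn_n", "opn_c")]) / opn_rem_eq
  p_of <- function(opn) truth$k_in / (truth$k_deg * (1 + truth$k_i * opn))
  n_b <- round(config$n_patients * config$group_b_fraction)
  groups <- c(rep("B", n_b), rep("A", config$n_patients - n_b))
  rows <- list()
  for (i in seq_len(config$n_patients)) {
    opn_rem <- opn_rem_eq * stats::rlnorm(1, 0, config$patient_sdlog)
    opn_rel <- opn_rem * uplift
    p_rem <- p_of(opn_rem)
    p_rel <- p_of(opn_rel)
    if (groups[i] == "B") {
      tmp <- opn_rem; opn_rem <- opn_rel; opn_rel <- tmp
      tmp <- p_rem; p_rem <- p_rel; p_rel <- tmp
    }
    n_wd <- sample(1:4, 1)
    noisy <- function(x, which)
      x * stats::rlnorm(1, 0, config$noise_sdlog[[which]])
    for (w in seq_len(n_wd)) {
      rows[[length(rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", i), phase = "remission",
        months_from_relapse = stats::runif(1, 1, 8),
        opn_ng_ml = nM_to_ng_ml(noisy(opn_rem, "opn"),
                                config$masses[["opn"]]),
        proteasome_ng_ml = nM_to_ng_ml(noisy(p_rem, "prot"),
                                       config$masses[["proteasome"]]),
        group = groups[i])
    }
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = sprintf("P%02d", i), phase = "relapse",
      months_from_relapse = 0,
      opn_ng_ml = nM_to_ng_ml(noisy(opn_rel, "opn"),
                              config$masses[["opn"]]),
      proteasome_ng_ml = nM_to_ng_ml(noisy(p_rel, "prot"),
                                     config$masses[["proteasome"]]),
      group = groups[i])
  }
  cohort_to_nM(do.call(rbind, rows), config$masses)
}

#' Generate the six in vitro digestion time courses
#'
#' Forward-simulates the Michaelis-Menten depletion under the
#' ground-truth kinetics at the assay concentrations and adds Gaussian
#' noise to the relative substrate remaining (truncated at 0), in
#' duplicate.
#'
#' @param config a [generator_config()].
#' @return list of six [digestion_timecourse()] objects.
#' @export
generate_digestion <- function(config) {
  set.seed(config$seed + 202L)
  out <- list()
  for (sp in opn_species()) for (iso in proteasome_isoforms()) {
    clean <- simulate_digestion(
      config$kinetics$kcut[sp, iso], config$kinetics$km[sp, iso],
      config$digestion_p_conc, config$digestion_opn0,
      config$digestion_times)$relative_remaining
    tt <- rep(config$digestion_times, config$digestion_replicates)
    rr <- rep(seq_len(config$digestion_replicates),
              each = length(config$digestion_times))
    obs <- pmax(rep(clean, config$digestion_replicates) +
                  stats::rnorm(length(tt), 0, config$digestion_noise_sd), 0)
    out[[length(out) + 1]] <- digestion_timecourse(
      sp, iso, config$digestion_p_conc, config$digestion_opn0,
      time_h = tt, replicate = rr, relative_remaining = obs)
  }
  out
}

#' Generate the migration assay table
#'
#' Forward-evaluates the exposure-integral model with the ground-truth
#' indices and kinetics for every (cell type, substrate, isoform)
#' condition, adds Gaussian noise to the percent readouts, and appends
#' control replicates (untreated wells renormalised to their own mean).
#'
#' @param config a [generator_config()].
#' @param replicates readouts per condition.
#' @return migration assay data.frame (see [estimate_index_set()]).
#' @export
generate_migration <- function(config, replicates = 8) {
  set.seed(config$seed + 303L)
  rows <- list()
  for (ct in names(config$ci_truth)) {
    ci <- config$ci_truth[[ct]]
    for (sp in opn_species()) {
      expo <- config$migration_opn0 * diff(config$window)
      expect_none <- 100 + ci$ci_opn[[sp]] * expo
      for (iso in c("none", proteasome_isoforms())) {
        if (iso == "none") {
          mu <- expect_none
          p_nM <- 0
        } else {
          ints <- digestion_integrals(
            config$kinetics$kcut[sp, iso], config$kinetics$km[sp, iso],
            config$migration_prot, config$migration_opn0, config$window)
          mu <- 100 + ci$ci_opn[[sp]] * ints$int_opn +
            ci$ci_frag[sp, iso] * ints$int_f
          p_nM <- config$migration_prot
        }
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = ct, substrate = sp, isoform = iso,
          replicate = seq_len(replicates),
          percent_of_control = pmax(
            mu + stats::rnorm(replicates, 0, config$migration_noise_sd), 0),
          stimulus_nM = config$migration_opn0, proteasome_nM = p_nM)
      }
    }
    counts <- stats::rnorm(replicates, config$control_mean,
                           config$control_sd)
    rows[[length(rows) + 1]] <- data.frame(
      cell_type = ct, substrate = "control", isoform = "none",
      replicate = seq_len(replicates),
      percent_of_control = pmax(100 * counts / config$control_mean, 0),
      stimulus_nM = 0, proteasome_nM = 0)
  }
  do.call(rbind, rows)
}

#' Generate an MSSS reference population
#'
#' EDSS assessments per whole-year disease-duration bin, drawn from a
#' normal distribution whose median increases with duration, snapped to
#' the valid 0.5-step grid and clipped to [0, 10].
#'
#' @param config a [generator_config()].
#' @return data.frame with `duration_years`, `edss`.
#' @export
generate_msss_reference <- function(config) {
  set.seed(config$seed + 404L)
  rows <- lapply(0:(config$msss_max_duration - 1), function(d) {
    e <- stats::rnorm(config$msss_bin_size, 1 + 0.15 * d, 1.5)
    data.frame(duration_years = d,
               edss = pmin(pmax(round(e * 2) / 2, 0), 10))
  })
  do.call(rbind, rows)
}

#' Generate severity outcomes with a planted linear signal
#'
#' The relapse MSSS is a linear combination of the proteasome and
#' fragment circuit features (positive remission coefficients, negative
#' relapse coefficients, scaled by the feature SDs so each carries
#' comparable signal) plus Gaussian noise, clipped to [0, 10]; the
#' remission MSSS subtracts a worsening term driven by the same signal.
#' The clipping fraction is recorded.
#'
#' @param feature_table output of [cohort_feature_table()].
#' @param config a [generator_config()].
#' @param coefficients optional named coefficient vector on the raw
#'   features; the default plants the signal on
#'   `prot/frag_s/frag_i x rem/rel`.
#' @return list with `table` (data.frame: `patient_id`, `msss_relapse`,
#'   `msss_remission`, `delta_msss`, `msss_prime`), `coefficients`,
#'   `clip_fraction`.
#' @export
generate_severity <- function(feature_table, config, coefficients = NULL) {
  set.seed(config$seed + 505L)
  if (is.null(coefficients)) {
    target <- c(prot_rem = 1, frag_s_rem = 1, frag_i_rem = 1,
                prot_rel = -1, frag_s_rel = -1, frag_i_rel = -1)
    sds <- vapply(names(target), function(cn)
      stats::sd(feature_table[[cn]]), numeric(1))
    sds[sds == 0 | !is.finite(sds)] <- 1
    coefficients <- target / sds
  }
  x <- as.matrix(feature_table[, names(coefficients), drop = FALSE])
  raw <- drop(x %*% coefficients)
  z <- if (stats::sd(raw) > 0) (raw - mean(raw)) / stats::sd(raw)
       else raw * 0
  n <- nrow(feature_table)
  clip <- function(v) pmin(pmax(v, 0), 10)
  msss_rel_raw <- 5 + 1.2 * z +
    stats::rnorm(n, 0, config$severity_noise_sd)
  worsen_raw <- 1.5 + 0.8 * z +
    stats::rnorm(n, 0, config$severity_noise_sd / 2)
  msss_rel <- clip(msss_rel_raw)
  msss_rem <- clip(msss_rel - worsen_raw)
  clipped <- mean(msss_rel_raw != msss_rel |
                    (msss_rel - worsen_raw) != msss_rem)
  si <- t(mapply(severity_indices, msss_rel, msss_rem))
  list(table = data.frame(patient_id = feature_table$patient_id,
                          msss_relapse = msss_rel,
                          msss_remission = msss_rem,
                          delta_msss = si[, "delta_msss"],
                          msss_prime = si[, "msss_prime"]),
       coefficients = coefficients, clip_fraction = clipped)
}

#' Generate a complete dataset directory
#'
#' Writes `cohort.csv`, `digestion.csv`, `migration.csv`,
#' `msss_reference.csv`, `severity.csv` and `truth.yaml` (every
#' ground-truth value used) into `dir`. The severity outcomes are
#' planted on the features of the ground-truth-simulated group-A
#' patients.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
generate_dataset <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- generate_cohort(config)
  digestion <- generate_digestion(config)
  migration <- generate_migration(config)
  msss_ref <- generate_msss_reference(config)
  features <- cohort_feature_table(cohort, kinetics = config$kinetics,
                                   x_i = config$x_i, x_t = config$x_t)
  severity <- generate_severity(features, config)
  write_cohort(cohort, file.path(dir, "cohort.csv"))
  write_digestion(digestion, file.path(dir, "digestion.csv"))
  write_migration(migration, file.path(dir, "migration.csv"))
  utils::write.csv(msss_ref, file.path(dir, "msss_reference.csv"),
                   row.names = FALSE)
  utils::write.csv(severity$table, file.path(dir, "severity.csv"),
                   row.names = FALSE)
  truth <- truth_circuit_params(config)
  yaml::write_yaml(list(
    seed = config$seed,
    circuit = list(k_in = truth$k_in, k_i = truth$k_i,
                   gamma = truth$gamma, k_deg = truth$k_deg,
                   k_1 = truth$k_1, k_deg_f = truth$k_deg_f,
                   k_deg_n = truth$k_deg_n, k_deg_c = truth$k_deg_c,
                   k_deg3 = truth$k_deg3, x_i = truth$x_i,
                   x_t = truth$x_t),
    kinetics = list(kcut = as.list(as.data.frame(config$kinetics$kcut)),
                    km = as.list(as.data.frame(config$kinetics$km))),
    ci_truth = lapply(config$ci_truth, function(ci)
      list(ci_opn = as.list(ci$ci_opn),
           ci_frag = as.list(as.data.frame(ci$ci_frag)))),
    severity_coefficients = as.list(severity$coefficients),
    severity_clip_fraction = severity$clip_fraction,
    noise = list(patient_sdlog = config$patient_sdlog,
                 noise_sdlog = as.list(config$noise_sdlog),
                 digestion_noise_sd = config$digestion_noise_sd,
                 migration_noise_sd = config$migration_noise_sd,
                 severity_noise_sd = config$severity_noise_sd)),
    file.path(dir, "truth.yaml"))
  invisible(list(cohort = cohort, digestion = digestion,
                 migration = migration, msss_reference = msss_ref,
                 features = features, severity = severity))
}
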