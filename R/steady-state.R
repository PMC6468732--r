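#' Closed-form circuit parameters from remission/relapse measurements
#'
#' The circuit parameters are identified from paired serum measurements by
#' treating remission as a steady state of the circuit and the relapse as
#' a quasi-steady state with OPN release scaled by `gamma`:
#'
#' * `derive_ki()`: the OPN-mediated inhibition of proteasome release,
#'   `k_i = (p_rel - p_rem) / (p_rem * opn_rem - p_rel * opn_rel)`, from
#'   the proteasome balance in the two phases.
#' * `derive_kin()`: the proteasome release rate that holds the remission
#'   proteasome level constant,
#'   `k_in = p_rem * k_deg * (1 + k_i * opn_rem)`.
#' * `derive_opn_clearance()`: the non-proteasomal OPN clearance of each
#'   species, the residual of production over proteasomal consumption at
#'   the remission level.
#' * `derive_gamma()`: the relapse multiplier on OPN release from the
#'   OPN-FL balance at the relapse quasi-steady state.
#'
#' All concentrations are in nM. Negative results are biologically
#' inadmissible and raise errors of class `opncircuit_inadmissible` (the
#' pattern shown by "group B" patients, whose phase ordering is inverted).
#'
#' @param p_rem,p_rel total extracellular proteasome during remission /
#'   relapse (nM), > 0.
#' @param opn_rem,opn_rel total OPN during remission / relapse (nM), > 0.
#' @return `derive_ki()`: the inhibition coefficient `k_i` (1/nM).
#' @examples
#' derive_ki(p_rem = 100, p_rel = 50, opn_rem = 40, opn_rel = 120)  # 0.025
#' derive_kin(p_rem = 100, opn_rem = 40, k_i = 0.025, k_deg = 2e-4) # 0.04
#' @export
derive_ki <- function(p_rem, p_rel, opn_rem, opn_rel) {
  stopifnot(p_rem > 0, p_rel > 0, opn_rem > 0, opn_rel > 0)
  den <- p_rem * opn_rem - p_rel * opn_rel
  if (den == 0)
    stop_inadmissible("degenerate measurements: p_rem*opn_rem = p_rel*opn_rel")
  ki <- (p_rel - p_rem) / den
  if (ki < 0)
    stop_inadmissible(sprintf(
      "inadmissible k_i = %.4g: phase ordering inconsistent with OPN-inhibited release",
      ki))
  ki
}

#' @rdname derive_ki
#' @param k_i inhibition coefficient (1/nM), >= 0.
#' @param k_deg extracellular proteasome decay rate (1/h).
#' @return `derive_kin()`: the proteasome release rate `k_in` (nM/h).
#' @export
derive_kin <- function(p_rem, opn_rem, k_i, k_deg) {
  stopifnot(p_rem >= 0, opn_rem >= 0, k_i >= 0, k_deg >= 0)
  p_rem * k_deg * (1 + k_i * opn_rem)
}

# total proteasomal Michaelis-Menten consumption rate coefficient (1/h)
# for one OPN species at concentration `opn` given isoform-split levels
mm_rate <- function(kinetics, species, p_i, p_s, opn) {
  kinetics$kcut[species, "immuno"] * p_i / (kinetics$km[species, "immuno"] + opn) +
    kinetics$kcut[species, "standard"] * p_s / (kinetics$km[species, "standard"] + opn)
}

#' @rdname derive_ki
#' @param k_1 OPN release rate (nM/h).
#' @param x_t OPN-FL fraction of OPN production.
#' @param opn_rem_species named vector `c(FL=, N=, C=)` of remission OPN
#'   levels per species (nM).
#' @param p_i_rem,p_s_rem remission proteasome levels by isoform (nM).
#' @param kinetics a [kinetic_params()] object.
#' @return `derive_opn_clearance()`: named vector
#'   `c(k_deg_f=, k_deg_n=, k_deg_c=)` (1/h). Species with zero
#'   production and zero measured level get clearance 0.
#' @export
derive_opn_clearance <- function(k_1, x_t, opn_rem_species,
                                 p_i_rem, p_s_rem, kinetics) {
  stopifnot(all(opn_rem_species >= 0), p_i_rem >= 0, p_s_rem >= 0)
  share <- c(FL = x_t, N = (1 - x_t) / 2, C = (1 - x_t) / 2)
  out <- c(k_deg_f = NA_real_, k_deg_n = NA_real_, k_deg_c = NA_real_)
  for (k in 1:3) {
    sp <- opn_species()[k]
    o <- opn_rem_species[[sp]]
    if (o == 0) {
      if (share[[sp]] * k_1 > 0)
        stop_inadmissible(sprintf(
          "%s: nonzero production with zero remission level", sp))
      out[k] <- 0
      next
    }
    if (share[[sp]] * k_1 == 0)
      stop_inadmissible(sprintf(
        "%s: nonzero remission level but zero production", sp))
    cl <- k_1 * share[[sp]] / o - mm_rate(kinetics, sp, p_i_rem, p_s_rem, o)
    if (cl < 0)
      stop_inadmissible(sprintf(
        "%s: proteasomal consumption exceeds production (clearance %.4g)",
        sp, cl))
    out[k] <- cl
  }
  out
}

#' @rdname derive_ki
#' @param opn_f_rel relapse OPN-FL level (nM).
#' @param p_i_rel,p_s_rel relapse proteasome levels by isoform (nM).
#' @param k_deg_f non-proteasomal OPN-FL clearance (1/h).
#' @return `derive_gamma()`: the relapse multiplier `gamma` (>= 1).
#' @export
derive_gamma <- function(opn_f_rel, p_i_rel, p_s_rel, k_1, x_t,
                         kinetics, k_deg_f) {
  stopifnot(opn_f_rel > 0, p_i_rel >= 0, p_s_rel >= 0)
  if (x_t == 0 || k_1 == 0)
    stop("gamma undefined when OPN-FL production is zero")
  g <- opn_f_rel *
    (mm_rate(kinetics, "FL", p_i_rel, p_s_rel, opn_f_rel) + k_deg_f) /
    (k_1 * x_t)
  if (g < 1)
    stop_inadmissible(sprintf("inadmissible gamma = %.4g < 1", g))
  g
}

#' Split totals into species and isoforms
#'
#' ELISA measures total OPN and total proteasome; the circuit needs
#' per-species and per-isoform levels. Measured totals are apportioned
#' `x_t : (1-x_t)/2 : (1-x_t)/2` to OPN-FL/-N/-C and `x_i : (1-x_i)` to
#' immuno/standard proteasome.
#'
#' @param opn_tot,prot total OPN / proteasome (nM).
#' @param x_t,x_i OPN-FL and immunoproteasome fractions.
#' @return list with `opn` (named FL/N/C) and `p_i`, `p_s`.
#' @export
split_measurements <- function(opn_tot, prot, x_t = 0.5, x_i = 0.5) {
  list(opn = c(FL = opn_tot * x_t,
               N = opn_tot * (1 - x_t) / 2, C = opn_tot * (1 - x_t) / 2),
       p_i = prot * x_i, p_s = prot * (1 - x_i))
}

#' Full closed-form parameter derivation for one (possibly averaged) patient
#'
#' Runs the four derivations in order on paired remission/relapse totals
#' and returns a complete [circuit_params()] object whose remission
#' equilibrium reproduces the input measurements.
#'
#' @inheritParams derive_ki
#' @param kinetics a [kinetic_params()] object.
#' @param x_i,x_t isoform / OPN-FL fractions used to split the totals.
#' @param k_deg,k_deg3,k_1 fixed circuit constants.
#' @return a [circuit_params()] object.
#' @examples
#' kp <- kinetic_params(kcut = 0.5, km = 1000)
#' derive_circuit_params(p_rem = 0.14, p_rel = 0.10,
#'                       opn_rem = 0.3, opn_rel = 0.9, kinetics = kp)
#' @export
derive_circuit_params <- function(p_rem, p_rel, opn_rem, opn_rel, kinetics,
                                  x_i = 0.5, x_t = 0.5,
                                  k_deg = 2e-4, k_deg3 = 2e-4, k_1 = 1e-4) {
  k_i <- derive_ki(p_rem, p_rel, opn_rem, opn_rel)
  k_in <- derive_kin(p_rem, opn_rem, k_i, k_deg)
  rem <- split_measurements(opn_rem, p_rem, x_t, x_i)
  rel <- split_measurements(opn_rel, p_rel, x_t, x_i)
  cl <- derive_opn_clearance(k_1, x_t, rem$opn, rem$p_i, rem$p_s, kinetics)
  gamma <- derive_gamma(rel$opn[["FL"]], rel$p_i, rel$p_s, k_1, x_t,
                        kinetics, cl[["k_deg_f"]])
  circuit_params(k_in = k_in, k_i = k_i, gamma = gamma, k_deg = k_deg,
                 k_1 = k_1, k_deg_f = cl[["k_deg_f"]],
                 k_deg_n = cl[["k_deg_n"]], k_deg_c = cl[["k_deg_c"]],
                 k_deg3 = k_deg3, x_i = x_i, x_t = x_t, kinetics = kinetics)
}

#' Propagate cohort uncertainty into a parameter ensemble
#'
#' Resamples patients with replacement, averages repeated remission
#' withdrawals within each patient, takes phase means across the resampled
#' patients and reruns the closed-form derivations, yielding a
#' distribution over circuit parameters. Draws whose derivations are
#' biologically inadmissible are counted and reported, not silently
#' dropped.
#'
#' @param cohort data.frame with columns `patient_id`, `phase`
#'   (`"remission"`/`"relapse"`), `opn_nM`, `prot_nM` (use
#'   [read_cohort()] / [cohort_to_nM()] for ng/mL input).
#' @param kinetics a [kinetic_params()] object (or a list of draws, one
#'   sampled per bootstrap draw).
#' @param n_draws number of bootstrap draws (default 1000).
#' @param seed RNG seed; the ensemble is deterministic given the seed.
#' @param ... passed to [derive_circuit_params()].
#' @return object of class `param_ensemble`: list with `draws` (list of
#'   [circuit_params()]), `rejected` (count), `reject_reasons`
#'   (character), `n_draws`, `seed`.
#' @export
sample_parameter_distributions <- function(cohort, kinetics,
                                           n_draws = 1000, seed = 1, ...) {
  check_cohort(cohort)
  paired <- patient_phase_means(cohort)
  if (nrow(paired) < 1) stop("no patient has both phases")
  set.seed(seed)
  draws <- vector("list", n_draws)
  reasons <- character(0)
  kin_list <- if (inherits(kinetics, "kinetic_params")) NULL else kinetics
  for (b in seq_len(n_draws)) {
    idx <- sample.int(nrow(paired), replace = TRUE)
    m <- paired[idx, ]
    kin_b <- if (is.null(kin_list)) kinetics
             else kin_list[[sample.int(length(kin_list), 1)]]
    res <- tryCatch(
      derive_circuit_params(p_rem = mean(m$prot_rem),
                            p_rel = mean(m$prot_rel),
                            opn_rem = mean(m$opn_rem),
                            opn_rel = mean(m$opn_rel),
                            kinetics = kin_b, ...),
      opncircuit_inadmissible = function(e) conditionMessage(e))
    if (is.character(res)) reasons <- c(reasons, res) else draws[[b]] <- res
  }
  keep <- !vapply(draws, is.null, logical(1))
  if (!any(keep)) stop("all bootstrap draws were inadmissible")
  structure(list(draws = draws[keep], rejected = sum(!keep),
                 reject_reasons = reasons, n_draws = n_draws, seed = seed),
            class = "param_ensemble")
}

#' @export
print.param_ensemble <- function(x, ...) {
  cat(sprintf(
    "Circuit-parameter ensemble: %d admissible draws (%d rejected of %d)\n",
    length(x$draws), x$rejected, x$n_draws))
  if (length(x$draws)) {
    med <- apply(ensemble_to_matrix(x), 2, stats::median)
    cat("medians:\n"); print(signif(med, 4))
  }
  invisible(x)
}

#' Scalar parameter draws of an ensemble as a matrix
#' @param ensemble a `param_ensemble`.
#' @return numeric matrix, one row per draw, columns `k_in`, `k_i`,
#'   `gamma`, `k_deg_f`, `k_deg_n`, `k_deg_c`.
#' @export
ensemble_to_matrix <- function(ensemble) {
  cols <- c("k_in", "k_i", "gamma", "k_deg_f", "k_deg_n", "k_deg_c")
  t(vapply(ensemble$draws, function(p) unlist(p[cols]), numeric(length(cols))))
}

# ---- cohort table helpers -------------------------------------------------

check_cohort <- function(cohort) {
  need <- c("patient_id", "phase", "opn_nM", "prot_nM")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (!all(cohort$phase %in% c("remission", "relapse")))
    stop("phase must be 'remission' or 'relapse'")
  if (any(cohort$opn_nM <= 0) || any(cohort$prot_nM <= 0))
    stop("concentrations must be > 0")
  invisible(cohort)
}

#' Per-patient phase means of a cohort table
#'
#' Repeated remission withdrawals are averaged within each patient before
#' any derivation; patients lacking either phase are dropped.
#'
#' @param cohort cohort data.frame (see
#'   [sample_parameter_distributions()]).
#' @return data.frame with one row per usable patient: `patient_id`,
#'   `opn_rem`, `opn_rel`, `prot_rem`, `prot_rel`.
#' @export
patient_phase_means <- function(cohort) {
  check_cohort(cohort)
  agg <- stats::aggregate(cbind(opn_nM, prot_nM) ~ patient_id + phase,
                          data = cohort, FUN = mean)
  rem <- agg[agg$phase == "remission", ]
  rel <- agg[agg$phase == "relapse", ]
  m <- merge(rem, rel, by = "patient_id", suffixes = c("_r", "_l"))
  data.frame(patient_id = m$patient_id,
             opn_rem = m$opn_nM_r, opn_rel = m$opn_nM_l,
             prot_rem = m$prot_nM_r, prot_rel = m$prot_nM_l)
}

#' Convert a ng/mL cohort table to nM
#'
#' @param cohort data.frame with `opn_ng_ml` and `proteasome_ng_ml`.
#' @param masses named masses (kDa), see [default_masses()].
#' @return the table with `opn_nM` and `prot_nM` columns added.
#' @export
cohort_to_nM <- function(cohort, masses = default_masses()) {
  cohort$opn_nM <- ng_ml_to_nM(cohort$opn_ng_ml, masses[["opn"]])
  cohort$prot_nM <- ng_ml_to_nM(cohort$proteasome_ng_ml,
                                masses[["proteasome"]])
  cohort
}

#' Read / write the cohort CSV
#'
#' Columns: `patient_id`, `phase`, `months_from_relapse`, `opn_ng_ml`,
#' `proteasome_ng_ml`. Reading adds nM columns.
#'
#' @param path CSV path.
#' @param masses named masses (kDa).
#' @return the cohort data.frame (invisibly for the writer).
#' @export
read_cohort <- function(path, masses = default_masses()) {
  cohort_to_nM(utils::read.csv(path, stringsAsFactors = FALSE), masses)
}

#' @rdname read_cohort
#' @param cohort cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  cols <- intersect(c("patient_id", "phase", "months_from_relapse",
                      "opn_ng_ml", "proteasome_ng_ml", "group"),
                    names(cohort))
  utils::write.csv(cohort[, cols], path, row.names = FALSE)
  invisible(cohort)
}

stop_inadmissible <- function(msg) {
  stop(structure(class = c("opncircuit_inadmissible", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
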