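#' Chemotactic index set
#'
#' Chemotactic indices (relative migration per nM per h) for the three
#' unprocessed OPN species and the six proteasome-generated fragment
#' pools of one cell type. Fragment indices for an isoform may be `NA`
#' when the corresponding migration assays are unavailable.
#'
#' @param ci_opn named vector `c(FL=, N=, C=)`.
#' @param ci_frag 3x2 matrix (species x isoform) of fragment indices.
#' @param cell_type label (`"HUVEC"`, `"lymphocyte"`, `"monocyte"`, ...).
#' @return object of class `chemotactic_index_set`.
#' @export
chemotactic_index_set <- function(ci_opn, ci_frag, cell_type = "HUVEC") {
  stopifnot(all(opn_species() %in% names(ci_opn)))
  ci_frag <- as.matrix(ci_frag)
  if (!all(dim(ci_frag) == c(3, 2)))
    stop("ci_frag must be a 3x2 matrix (species x isoform)")
  dimnames(ci_frag) <- list(opn_species(), proteasome_isoforms())
  if (any(!is.finite(ci_opn))) stop("OPN indices must be finite")
  structure(list(ci_opn = ci_opn[opn_species()], ci_frag = ci_frag,
                 cell_type = cell_type),
            class = "chemotactic_index_set")
}

#' @export
print.chemotactic_index_set <- function(x, ...) {
  cat(sprintf("Chemotactic indices (%s), per nM per h\n", x$cell_type))
  cat("unprocessed OPN:\n"); print(signif(x$ci_opn, 3))
  cat("proteasome-generated fragments:\n"); print(signif(x$ci_frag, 3))
  invisible(x)
}

#' Chemotactic index of an unprocessed OPN species
#'
#' Without proteasome the stimulus concentration is constant over the
#' migration window, so the index is the net relative migration (percent
#' of control minus the 100% baseline) divided by the stimulus exposure
#' `opn0 * window length`.
#'
#' @param percent replicate migration readouts, percent of untreated
#'   control.
#' @param opn0 stimulus concentration (nM), > 0.
#' @param window migration window `c(start, end)` in h (default 2-22 h:
#'   2 h pre-incubation, 20 h migration).
#' @return the chemotactic index (per nM per h).
#' @examples
#' estimate_ci_unprocessed(150, opn0 = 10, window = c(2, 22))  # 0.25
#' @export
estimate_ci_unprocessed <- function(percent, opn0, window = c(2, 22)) {
  if (opn0 <= 0) stop("undefined index: opn0 must be > 0")
  len <- diff(window)
  if (len <= 0) stop("window length must be > 0")
  (mean(percent) - 100) / (opn0 * len)
}

#' Stimulus exposure integrals under proteasomal digestion
#'
#' Integrates the substrate and fragment concentrations of a digestion
#' started at `digestion_start` over the migration window, using the
#' exact Michaelis-Menten depletion curve. By conservation the fragment
#' integral is `opn0 * window length - int_opn`.
#'
#' @inheritParams simulate_digestion
#' @param window integration window `c(start, end)` (h).
#' @param digestion_start time at which enzyme and substrate were mixed
#'   (h); the 2 h pre-incubation protocol corresponds to 0 with a window
#'   starting at 2.
#' @return list with `int_opn` and `int_f` (nM h).
#' @export
digestion_integrals <- function(kcut, km, p_conc, opn0,
                                window = c(2, 22), digestion_start = 0,
                                n_nodes = 4001) {
  stopifnot(window[2] > window[1], window[1] >= digestion_start)
  # composite Simpson on a fine uniform grid: the depletion curve is
  # smooth and monotone but can be near-step for fast kinetics, where
  # adaptive quadrature gives up; the fixed rule is robust and exact to
  # ~1e-8 relative at this resolution
  if (n_nodes %% 2 == 0) n_nodes <- n_nodes + 1
  t <- seq(window[1], window[2], length.out = n_nodes)
  s <- mm_substrate(t - digestion_start, s0 = opn0, v = p_conc * kcut,
                    km = km)
  h <- (window[2] - window[1]) / (n_nodes - 1)
  w <- rep(c(2, 4), length.out = n_nodes)
  w[1] <- w[n_nodes] <- 1
  int_opn <- h / 3 * sum(w * s)
  list(int_opn = int_opn, int_f = opn0 * diff(window) - int_opn)
}

#' Fragment chemotactic index from a processed-OPN migration assay
#'
#' The measured relative migration of cells exposed to
#' proteasome-processed OPN is modelled as the sum of the contributions
#' of the remaining parent and of its fragments, each integrated over the
#' migration window:
#' `net = ci_opn * int(OPN dt) + ci_F * int(F dt)`. Solving for `ci_F`
#' attributes the residual migration to the fragment pool. Applied per
#' posterior kinetic draw this yields an index distribution.
#'
#' @inheritParams estimate_ci_unprocessed
#' @param ci_opn index of the unprocessed parent species.
#' @param kcut,km kinetic draw for this (substrate, isoform) pair.
#' @param p_conc proteasome concentration in the pre-incubation (nM).
#' @param digestion_start see [digestion_integrals()].
#' @return the fragment chemotactic index (per nM per h).
#' @examples
#' # worked example: exponential decay OPN(t) = 10 exp(-0.1 (t - 2)) on
#' # [2, 22] gives int OPN = 86.47, int F = 113.53; with net migration
#' # 100 and ci_opn = 0.25 the fragment index is ~0.690
#' ci_from_integrals(100, 0.25, int_opn = 86.47, int_f = 113.53)
#' @export
estimate_ci_fragments <- function(percent, ci_opn, kcut, km, p_conc, opn0,
                                  window = c(2, 22), digestion_start = 0) {
  ints <- digestion_integrals(kcut, km, p_conc, opn0, window,
                              digestion_start)
  ci_from_integrals(mean(percent) - 100, ci_opn, ints$int_opn, ints$int_f)
}

#' @rdname estimate_ci_fragments
#' @param net_migration net relative migration (percent minus the 100%
#'   control baseline).
#' @param int_opn,int_f parent / fragment exposure integrals (nM h).
#' @export
ci_from_integrals <- function(net_migration, ci_opn, int_opn, int_f) {
  if (int_f <= .Machine$double.eps * (int_opn + int_f))
    stop("singular system: no fragments produced over the window")
  (net_migration - ci_opn * int_opn) / int_f
}

#' Estimate a full chemotactic index set from a migration assay table
#'
#' For one cell type: unprocessed indices from the no-proteasome
#' conditions, then fragment indices per isoform from the processed
#' conditions under a kinetic parameter draw. Missing isoform conditions
#' leave the corresponding fragment indices `NA`.
#'
#' @param assays data.frame with columns `cell_type`, `substrate`,
#'   `isoform` (`"none"`, `"standard"`, `"immuno"`), `replicate`,
#'   `percent_of_control`, `stimulus_nM`, `proteasome_nM`.
#' @param kinetics a [kinetic_params()] object (one draw).
#' @param cell_type which cell type to estimate (default: the only one
#'   present).
#' @param window migration window (h).
#' @return a [chemotactic_index_set()].
#' @export
estimate_index_set <- function(assays, kinetics, cell_type = NULL,
                               window = c(2, 22)) {
  if (nrow(assays) == 0) stop("empty assay table")
  if (is.null(cell_type)) {
    cts <- unique(assays$cell_type)
    if (length(cts) > 1) stop("multiple cell types; specify one")
    cell_type <- cts
  }
  a <- assays[assays$cell_type == cell_type, ]
  if (nrow(a) == 0) stop("no assays for cell type ", cell_type)
  ci_opn <- c(FL = NA_real_, N = NA_real_, C = NA_real_)
  ci_frag <- matrix(NA_real_, 3, 2,
                    dimnames = list(opn_species(), proteasome_isoforms()))
  for (sp in opn_species()) {
    none <- a[a$substrate == sp & a$isoform == "none", ]
    if (nrow(none) == 0)
      stop("missing no-proteasome assay for OPN-", sp)
    ci_opn[sp] <- estimate_ci_unprocessed(none$percent_of_control,
                                          none$stimulus_nM[1], window)
    for (iso in proteasome_isoforms()) {
      proc <- a[a$substrate == sp & a$isoform == iso, ]
      if (nrow(proc) == 0) next
      ci_frag[sp, iso] <- estimate_ci_fragments(
        proc$percent_of_control, ci_opn[sp],
        kcut = kinetics$kcut[sp, iso], km = kinetics$km[sp, iso],
        p_conc = proc$proteasome_nM[1], opn0 = proc$stimulus_nM[1],
        window = window)
    }
  }
  chemotactic_index_set(ci_opn, ci_frag, cell_type)
}

#' Index distributions over posterior kinetic draws
#'
#' @inheritParams estimate_index_set
#' @param kinetic_draws list of [kinetic_params()] draws (see
#'   [kinetics_posterior_draws()]).
#' @return list with `draws` (list of index sets) and `median` (index
#'   set of element-wise medians).
#' @export
estimate_index_distribution <- function(assays, kinetic_draws,
                                        cell_type = NULL,
                                        window = c(2, 22)) {
  sets <- lapply(kinetic_draws, function(k)
    estimate_index_set(assays, k, cell_type, window))
  med_opn <- apply(vapply(sets, `[[`, numeric(3), "ci_opn"), 1,
                   stats::median)
  frag_arr <- vapply(sets, `[[`, matrix(0, 3, 2), "ci_frag")
  med_frag <- apply(frag_arr, c(1, 2), stats::median)
  list(draws = sets,
       median = chemotactic_index_set(med_opn, med_frag,
                                      sets[[1]]$cell_type))
}

#' Total chemotaxis along a trajectory
#'
#' Total chemotaxis is the index-weighted sum of the nine chemotactic
#' species, `C_tot(t) = sum ci_x * x(t)`, decomposed exactly into the
#' OPN-only, standard-fragment and immuno-fragment contributions.
#' `NA` indices contribute zero (their species were never assayed).
#'
#' @param traj a `circuit_trajectory` (or data.frame with the species
#'   columns).
#' @param ci a [chemotactic_index_set()].
#' @return data.frame with `time_h`, `c_tot`, `c_opn`,
#'   `c_frag_standard`, `c_frag_immuno`.
#' @export
total_chemotaxis <- function(traj, ci) {
  stopifnot(inherits(ci, "chemotactic_index_set"))
  z <- function(x) ifelse(is.na(x), 0, x)
  c_opn <- z(ci$ci_opn[["FL"]]) * traj$opn_f +
    z(ci$ci_opn[["N"]]) * traj$opn_n + z(ci$ci_opn[["C"]]) * traj$opn_c
  c_fs <- z(ci$ci_frag["FL", "standard"]) * traj$f_sf +
    z(ci$ci_frag["N", "standard"]) * traj$f_sn +
    z(ci$ci_frag["C", "standard"]) * traj$f_sc
  c_fi <- z(ci$ci_frag["FL", "immuno"]) * traj$f_if +
    z(ci$ci_frag["N", "immuno"]) * traj$f_in +
    z(ci$ci_frag["C", "immuno"]) * traj$f_ic
  data.frame(time_h = traj$time_h, c_tot = c_opn + c_fs + c_fi,
             c_opn = c_opn, c_frag_standard = c_fs, c_frag_immuno = c_fi)
}

#' Relapse-remission chemotaxis surfaces over isoform/thrombin scenarios
#'
#' For every (`x_i`, `x_t`) grid point the circuit parameters are
#' re-derived from the same remission/relapse measurements under that
#' isoform split and OPN-FL fraction, the circuit is simulated through a
#' relapse, and the change in total chemotaxis from the remission
#' baseline to the relapse peak (maximum inside the relapse window) is
#' recorded, together with the fragment-only change and the isoform
#' contribution shares at the peak. Grid points whose derivation is
#' inadmissible are flagged, not fatal.
#'
#' @param measurements list with `p_rem`, `p_rel`, `opn_rem`, `opn_rel`
#'   (nM totals).
#' @param kinetics a [kinetic_params()] object.
#' @param ci a [chemotactic_index_set()].
#' @param x_i_grid,x_t_grid grids in [0, 1].
#' @param schedule a [relapse_schedule()].
#' @param t_step simulation output step (h).
#' @param ... fixed constants passed to [derive_circuit_params()].
#' @return data.frame: `x_i`, `x_t`, `admissible`, `d_ctot`,
#'   `d_ctot_frag`, `share_standard`, `share_immuno` (fragment
#'   contribution shares of the peak `C_tot`).
#' @export
scenario_grid <- function(measurements, kinetics, ci,
                          x_i_grid = seq(0, 1, 0.1),
                          x_t_grid = seq(0.1, 1, 0.1),
                          schedule = relapse_schedule(onset_time = 336,
                                                      t_end = 1680),
                          t_step = 12, ...) {
  stopifnot(all(x_i_grid >= 0 & x_i_grid <= 1),
            all(x_t_grid >= 0 & x_t_grid <= 1))
  win <- relapse_window(schedule)
  t_grid <- seq(0, schedule$t_end, by = t_step)
  out <- expand.grid(x_i = x_i_grid, x_t = x_t_grid)
  out$admissible <- FALSE
  out[c("d_ctot", "d_ctot_frag", "share_standard", "share_immuno")] <- NA_real_
  for (r in seq_len(nrow(out))) {
    pars <- tryCatch(
      derive_circuit_params(measurements$p_rem, measurements$p_rel,
                            measurements$opn_rem, measurements$opn_rel,
                            kinetics, x_i = out$x_i[r], x_t = out$x_t[r],
                            ...),
      opncircuit_inadmissible = function(e) NULL,
      error = function(e) NULL)
    if (is.null(pars)) next
    eq <- circuit_equilibrium(pars)
    traj <- simulate_circuit(pars, eq, schedule, t_grid)
    ct <- total_chemotaxis(traj, ci)
    base <- ct[1, ]
    in_win <- ct$time_h >= win[1] & ct$time_h <= win[2]
    peak <- ct[in_win, ][which.max(ct$c_tot[in_win]), ]
    frag_peak <- peak$c_frag_standard + peak$c_frag_immuno
    frag_base <- base$c_frag_standard + base$c_frag_immuno
    out$admissible[r] <- TRUE
    out$d_ctot[r] <- peak$c_tot - base$c_tot
    out$d_ctot_frag[r] <- frag_peak - frag_base
    out$share_standard[r] <- if (peak$c_tot > 0)
      peak$c_frag_standard / peak$c_tot else 0
    out$share_immuno[r] <- if (peak$c_tot > 0)
      peak$c_frag_immuno / peak$c_tot else 0
  }
  out
}

#' Chemotactic comparison across cell types
#'
#' Estimates a chemotactic index set per cell type from one assay table
#' and, when circuit parameters are supplied, computes the total
#' chemotaxis time course per cell type through a relapse. Cell types
#' lacking immunoproteasome assays get `NA` immuno-fragment indices and
#' are simulated in a standard-proteasome-only scenario (`x_i = 0`).
#'
#' @inheritParams estimate_index_set
#' @param params optional [circuit_params()]; enables the `c_tot` output.
#' @param schedule,t_grid simulation settings when `params` is given.
#' @return list with `indices` (named list of index sets) and `c_tot`
#'   (named list of [total_chemotaxis()] outputs, or `NULL`).
#' @export
cell_type_comparison <- function(assays, kinetics, params = NULL,
                                 schedule = relapse_schedule(onset_time = 336,
                                                             t_end = 1680),
                                 t_grid = seq(0, 1680, by = 12),
                                 window = c(2, 22)) {
  if (nrow(assays) == 0) stop("empty assay table")
  cts <- unique(assays$cell_type)
  indices <- lapply(cts, function(ct)
    estimate_index_set(assays, kinetics, ct, window))
  names(indices) <- cts
  c_tot <- NULL
  if (!is.null(params)) {
    c_tot <- lapply(indices, function(ci) {
      p <- params
      if (any(is.na(ci$ci_frag[, "immuno"]))) {
        p$x_i <- 0  # standard-only scenario
      }
      traj <- simulate_circuit(p, circuit_equilibrium(p), schedule, t_grid)
      total_chemotaxis(traj, ci)
    })
  }
  list(indices = indices, c_tot = c_tot)
}

#' Read / write migration assay CSV
#'
#' Columns: `cell_type`, `substrate`, `isoform`, `replicate`,
#' `percent_of_control`, `stimulus_nM`, `proteasome_nM`.
#'
#' @param path CSV path.
#' @return data.frame of assays.
#' @export
read_migration <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname read_migration
#' @param assays assay data.frame.
#' @export
write_migration <- function(assays, path) {
  utils::write.csv(assays, path, row.names = FALSE)
  invisible(assays)
}
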