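#' Circuit state: concentrations of all eleven species
#'
#' The extracellular circuit tracks two 20S proteasome isoforms
#' (immuno `p_i`, standard `p_s`), three OPN species (`opn_f`, `opn_n`,
#' `opn_c` for OPN-FL, OPN-N, OPN-C) and six proteasome-generated fragment
#' pools, one per (isoform, parent) pair (`f_if`, `f_in`, `f_ic`, `f_sf`,
#' `f_sn`, `f_sc`). All concentrations are in nM.
#'
#' @param p_i,p_s,opn_f,opn_n,opn_c,f_if,f_in,f_ic,f_sf,f_sn,f_sc
#'   non-negative concentrations (nM).
#' @return a named numeric vector of class `circuit_state`.
#' @examples
#' circuit_state(p_i = 0.07, p_s = 0.07, opn_f = 0.15)
#' @export
circuit_state <- function(p_i = 0, p_s = 0, opn_f = 0, opn_n = 0, opn_c = 0,
                          f_if = 0, f_in = 0, f_ic = 0,
                          f_sf = 0, f_sn = 0, f_sc = 0) {
  x <- vapply(list(p_i, p_s, opn_f, opn_n, opn_c,
                   f_if, f_in, f_ic, f_sf, f_sn, f_sc),
              function(v) as.numeric(v)[1], numeric(1))
  names(x) <- state_species()
  if (any(!is.finite(x))) stop("circuit state must be finite")
  if (any(x < 0)) stop("circuit state must be non-negative")
  class(x) <- "circuit_state"
  x
}

#' @rdname circuit_state
#' @return `state_species()` returns the canonical species ordering.
#' @export
state_species <- function() {
  c("p_i", "p_s", "opn_f", "opn_n", "opn_c",
    "f_if", "f_in", "f_ic", "f_sf", "f_sn", "f_sc")
}

#' Circuit parameters
#'
#' Rate constants of the extracellular proteasome-OPN circuit. Proteasomes
#' are released at `k_in` (nM/h), inhibited by total OPN with coefficient
#' `k_i` (1/nM), and cleared at `k_deg` (1/h). OPN is released at `k_1`
#' (nM/h), split `x_t` to OPN-FL and `(1 - x_t)/2` each to OPN-N/-C;
#' during a relapse the release is multiplied by `gamma` (>= 1).
#' Non-proteasomal OPN clearance is `k_deg_f/n/c` (1/h) and fragments are
#' cleared at `k_deg3` (1/h). `x_i` is the immunoproteasome fraction of
#' proteasome release. `kinetics` carries the Michaelis-Menten constants
#' of proteasomal OPN degradation (see [kinetic_params()]).
#'
#' The defaults `k_deg = k_deg3 = 2e-4` and `k_1 = 1e-4` are the fixed
#' constants of the published circuit; all are overridable.
#'
#' @param k_in proteasome release rate (nM/h).
#' @param k_deg extracellular proteasome decay rate (1/h).
#' @param k_i OPN-mediated release-inhibition coefficient (1/nM).
#' @param k_1 OPN release rate (nM/h).
#' @param gamma relapse multiplier on `k_1`, >= 1.
#' @param k_deg_f,k_deg_n,k_deg_c non-proteasomal OPN clearance (1/h).
#' @param k_deg3 fragment clearance rate (1/h).
#' @param x_i immunoproteasome fraction in [0, 1].
#' @param x_t OPN-FL fraction of OPN production in [0, 1].
#' @param kinetics a [kinetic_params()] object.
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(k_in, k_i, gamma = 1,
                           k_deg = 2e-4, k_1 = 1e-4,
                           k_deg_f = 0, k_deg_n = 0, k_deg_c = 0,
                           k_deg3 = 2e-4, x_i = 0.5, x_t = 0.5,
                           kinetics = kinetic_params(0, 1)) {
  rates <- c(k_in = k_in, k_i = k_i, k_deg = k_deg, k_1 = k_1,
             k_deg_f = k_deg_f, k_deg_n = k_deg_n, k_deg_c = k_deg_c,
             k_deg3 = k_deg3)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and >= 0")
  if (!is.finite(gamma) || gamma < 1) stop("gamma must be >= 1")
  if (x_i < 0 || x_i > 1) stop("x_i must lie in [0, 1]")
  if (x_t < 0 || x_t > 1) stop("x_t must lie in [0, 1]")
  if (!inherits(kinetics, "kinetic_params"))
    stop("kinetics must be a kinetic_params object")
  structure(
    list(k_in = k_in, k_i = k_i, k_deg = k_deg, k_1 = k_1, gamma = gamma,
         k_deg_f = k_deg_f, k_deg_n = k_deg_n, k_deg_c = k_deg_c,
         k_deg3 = k_deg3, x_i = x_i, x_t = x_t, kinetics = kinetics),
    class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("Extracellular proteasome-OPN circuit parameters\n")
  cat(sprintf("  k_in = %.4g nM/h, k_i = %.4g 1/nM, k_deg = %.4g 1/h\n",
              x$k_in, x$k_i, x$k_deg))
  cat(sprintf("  k_1 = %.4g nM/h, gamma = %.4g, x_i = %.3g, x_t = %.3g\n",
              x$k_1, x$gamma, x$x_i, x$x_t))
  cat(sprintf("  OPN clearance (FL/N/C): %.4g / %.4g / %.4g 1/h; k_deg3 = %.4g\n",
              x$k_deg_f, x$k_deg_n, x$k_deg_c, x$k_deg3))
  invisible(x)
}

#' Relapse forcing schedule
#'
#' During a relapse the OPN release rate `k_1` rises linearly from its
#' remission value to `gamma * k_1` over `ramp_duration` hours, stays at
#' the plateau for `plateau_duration` hours, and returns instantly to the
#' remission value. The default relapse window is 4 weeks (672 h): a
#' 2-week ramp followed by a 2-week plateau.
#'
#' @param onset_time relapse onset (h).
#' @param ramp_duration linear rise duration (h); 0 gives a step.
#' @param plateau_duration plateau duration (h).
#' @param t_end total simulated span (h), for bookkeeping.
#' @return an object of class `relapse_schedule`.
#' @export
relapse_schedule <- function(onset_time = 672, ramp_duration = 336,
                             plateau_duration = 336, t_end = 2016) {
  d <- c(onset_time = onset_time, ramp_duration = ramp_duration,
         plateau_duration = plateau_duration, t_end = t_end)
  if (any(!is.finite(d)) || any(d < 0))
    stop("schedule durations must be finite and >= 0")
  structure(as.list(d), class = "relapse_schedule")
}

#' @rdname relapse_schedule
#' @param schedule a `relapse_schedule`.
#' @return `relapse_window()` returns `c(start, end)` of the relapse (h).
#' @export
relapse_window <- function(schedule) {
  c(start = schedule$onset_time,
    end = schedule$onset_time + schedule$ramp_duration +
      schedule$plateau_duration)
}

#' Effective relapse multiplier on the OPN release rate
#'
#' @param t time (h); vectorised.
#' @param schedule a [relapse_schedule()], or `NULL` for no relapse.
#' @param gamma relapse multiplier, >= 1.
#' @return the multiplier on `k_1`: 1 outside the relapse window, linear
#'   from 1 to `gamma` on the ramp, `gamma` on the plateau.
#' @examples
#' sch <- relapse_schedule(onset_time = 0)
#' relapse_forcing(c(-1, 168, 400, 700), sch, gamma = 3)
#' @export
relapse_forcing <- function(t, schedule, gamma) {
  stopifnot(all(is.finite(t)), gamma >= 1)
  if (is.null(schedule)) return(rep(gamma, length(t)))
  on <- schedule$onset_time
  ramp <- schedule$ramp_duration
  plateau <- schedule$plateau_duration
  f <- rep(1, length(t))
  if (ramp > 0) {
    in_ramp <- t >= on & t < on + ramp
    f[in_ramp] <- 1 + (gamma - 1) * (t[in_ramp] - on) / ramp
  }
  in_plateau <- t >= on + ramp & t <= on + ramp + plateau
  f[in_plateau] <- gamma
  f
}

#' Right-hand side of the circuit ODE system
#'
#' Time derivatives of the eleven circuit species. Proteasome release is
#' inhibited by total OPN through `1/(1 + k_i * opn_tot)` and split
#' `x_i : (1 - x_i)` between isoforms; each OPN species is produced at
#' `forcing(t) * k_1` times its production share, consumed by both
#' proteasome isoforms through Michaelis-Menten kinetics and cleared
#' non-proteasomally; each (isoform, parent) fragment pool gains what its
#' Michaelis-Menten term consumes and decays at `k_deg3`.
#'
#' @param t time (h).
#' @param state named state vector (see [circuit_state()]).
#' @param params a [circuit_params()] object.
#' @param schedule a [relapse_schedule()] or `NULL` (no relapse).
#' @return named list of derivatives, in `deSolve` convention
#'   (`list(dstate)`).
#' @export
circuit_rhs <- function(t, state, params, schedule = NULL) {
  s <- state
  kin <- params$kinetics
  opn_tot <- s[["opn_f"]] + s[["opn_n"]] + s[["opn_c"]]
  inhib <- 1 / (1 + params$k_i * opn_tot)
  forcing <- if (is.null(schedule)) 1
             else relapse_forcing(t, schedule, params$gamma)

  dp_i <- params$k_in * params$x_i * inhib - s[["p_i"]] * params$k_deg
  dp_s <- params$k_in * (1 - params$x_i) * inhib - s[["p_s"]] * params$k_deg

  opn <- c(FL = s[["opn_f"]], N = s[["opn_n"]], C = s[["opn_c"]])
  share <- c(FL = params$x_t,
             N = (1 - params$x_t) / 2, C = (1 - params$x_t) / 2)
  # per-species Michaelis-Menten consumption rate by each isoform (nM/h)
  mm_i <- kin$kcut[, "immuno"] * s[["p_i"]] * opn / (kin$km[, "immuno"] + opn)
  mm_s <- kin$kcut[, "standard"] * s[["p_s"]] * opn / (kin$km[, "standard"] + opn)
  cl <- c(params$k_deg_f, params$k_deg_n, params$k_deg_c)
  dopn <- forcing * params$k_1 * share - mm_i - mm_s - cl * opn

  dfrag_i <- mm_i - params$k_deg3 * c(s[["f_if"]], s[["f_in"]], s[["f_ic"]])
  dfrag_s <- mm_s - params$k_deg3 * c(s[["f_sf"]], s[["f_sn"]], s[["f_sc"]])

  d <- c(dp_i, dp_s, dopn, dfrag_i, dfrag_s)
  names(d) <- state_species()
  list(d)
}

#' Simulate the circuit over a time grid
#'
#' Integrates the circuit ODEs with the stiff-capable adaptive LSODA
#' solver. Tiny negative excursions (below the clipping threshold, by
#' default the absolute solver tolerance scale) are clipped to zero.
#'
#' @inheritParams circuit_rhs
#' @param init initial [circuit_state()].
#' @param t_grid strictly increasing output times (h).
#' @param rtol,atol relative / absolute solver tolerances.
#' @param clip_tol negatives above `-clip_tol` are set to 0; larger
#'   negative values signal solver trouble and raise an error.
#' @return a `circuit_trajectory`: a data.frame with `time_h` and one
#'   column per species, carrying the params, schedule and tolerances as
#'   attributes.
#' @examples
#' kp <- kinetic_params(kcut = 0.5, km = 1000)
#' pars <- circuit_params(k_in = 3e-5, k_i = 2, gamma = 3, kinetics = kp,
#'                        k_deg_f = 3e-4, k_deg_n = 3e-4, k_deg_c = 3e-4)
#' traj <- simulate_circuit(pars, circuit_state(p_i = 0.07, p_s = 0.07,
#'                          opn_f = 0.1, opn_n = 0.05, opn_c = 0.05),
#'                          relapse_schedule(onset_time = 336),
#'                          t_grid = seq(0, 2016, by = 24))
#' head(traj)
#' @export
simulate_circuit <- function(params, init, schedule = NULL,
                             t_grid = seq(0, 2016, by = 1),
                             rtol = 1e-8, atol = 1e-10, clip_tol = 1e-6) {
  stopifnot(inherits(params, "circuit_params"))
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  y0 <- as.numeric(init)[seq_along(state_species())]
  names(y0) <- state_species()
  if (any(y0 < 0)) stop("initial state must be non-negative")
  sol <- deSolve::lsoda(
    y = y0, times = t_grid,
    func = function(t, y, p) circuit_rhs(t, y, p, schedule),
    parms = params, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop(sprintf("integration failed near t = %.3f h",
                 sol[nrow(sol), "time"]))
  out <- as.data.frame(sol)
  names(out)[1] <- "time_h"
  vals <- as.matrix(out[, state_species()])
  if (any(vals < -clip_tol))
    stop("solution went negative beyond the clipping tolerance")
  vals[vals < 0] <- 0
  out[, state_species()] <- vals
  structure(out, class = c("circuit_trajectory", "data.frame"),
            params = params, schedule = schedule,
            tolerances = c(rtol = rtol, atol = atol, clip = clip_tol))
}

#' Steady state of the circuit at a fixed forcing level
#'
#' Solves the algebraic steady state of the circuit with the OPN release
#' held at `forcing_level * k_1` (1 for remission, `gamma` for the relapse
#' quasi-steady state). The proteasome balance gives `p` in closed form
#' given total OPN; each OPN species then solves a scalar monotone
#' equation; the total is closed by one outer root find.
#'
#' @inheritParams circuit_rhs
#' @param forcing_level multiplier on `k_1` (>= 0).
#' @return a [circuit_state()] at equilibrium.
#' @export
circuit_equilibrium <- function(params, forcing_level = 1) {
  stopifnot(inherits(params, "circuit_params"), forcing_level >= 0)
  kin <- params$kinetics
  share <- c(FL = params$x_t,
             N = (1 - params$x_t) / 2, C = (1 - params$x_t) / 2)
  cl <- c(params$k_deg_f, params$k_deg_n, params$k_deg_c)
  prod <- forcing_level * params$k_1 * share

  p_of <- function(opn_tot) {
    base <- params$k_in / ((1 + params$k_i * opn_tot) * params$k_deg)
    c(i = base * params$x_i, s = base * (1 - params$x_i))
  }
  opn_one <- function(k, p) {
    if (prod[k] == 0) return(0)
    bal <- function(o) {
      mm <- kin$kcut[k, "immuno"] * p[["i"]] / (kin$km[k, "immuno"] + o) +
        kin$kcut[k, "standard"] * p[["s"]] / (kin$km[k, "standard"] + o)
      prod[k] - o * (mm + cl[k])
    }
    hi <- if (cl[k] > 0) prod[k] / cl[k] * 1.0001 + 1e-12 else 1e15
    if (bal(hi) > 0) stop("no finite OPN steady state (clearance too small)")
    stats::uniroot(bal, c(0, hi), tol = 1e-14)$root
  }
  mismatch <- function(opn_tot) {
    p <- p_of(opn_tot)
    sum(vapply(1:3, opn_one, numeric(1), p = p)) - opn_tot
  }
  hi_tot <- sum(prod / pmax(cl, 1e-15)) * 1.001 + 1e-9
  opn_tot <- if (mismatch(0) <= 0) 0 else
    stats::uniroot(mismatch, c(0, hi_tot), tol = 1e-14)$root
  p <- p_of(opn_tot)
  opn <- vapply(1:3, opn_one, numeric(1), p = p)
  mm_i <- kin$kcut[, "immuno"] * p[["i"]] * opn / (kin$km[, "immuno"] + opn)
  mm_s <- kin$kcut[, "standard"] * p[["s"]] * opn / (kin$km[, "standard"] + opn)
  frag_i <- if (params$k_deg3 > 0) mm_i / params$k_deg3 else rep(0, 3)
  frag_s <- if (params$k_deg3 > 0) mm_s / params$k_deg3 else rep(0, 3)
  circuit_state(p_i = p[["i"]], p_s = p[["s"]],
                opn_f = opn[1], opn_n = opn[2], opn_c = opn[3],
                f_if = frag_i[1], f_in = frag_i[2], f_ic = frag_i[3],
                f_sf = frag_s[1], f_sn = frag_s[2], f_sc = frag_s[3])
}

#' Ensemble simulation with uncertainty envelopes
#'
#' Simulates the circuit once per parameter draw (posterior / resampling
#' ensemble) and summarises every species per time point by its median
#' and an interquantile envelope. When a chemotactic index set is
#' supplied, the total chemotaxis along each trajectory is summarised the
#' same way.
#'
#' @param param_samples list of [circuit_params()] draws (>= 1).
#' @param init_samples a single [circuit_state()] or a list with one
#'   state per draw; `NULL` starts each draw at its remission equilibrium.
#' @param schedule a [relapse_schedule()] or `NULL`.
#' @param t_grid output times (h).
#' @param ci optional [chemotactic_index_set()]; adds a `c_tot` summary.
#' @param probs lower/upper envelope quantiles.
#' @param ... passed to [simulate_circuit()].
#' @return list with `summary` (long data.frame: `time_h`, `species`,
#'   `median`, `lo`, `hi`) and `n_samples`.
#' @export
simulate_ensemble <- function(param_samples, init_samples = NULL,
                              schedule = NULL,
                              t_grid = seq(0, 2016, by = 24), ci = NULL,
                              probs = c(0.025, 0.975), ...) {
  if (length(param_samples) == 0) stop("need at least one parameter draw")
  n <- length(param_samples)
  get_init <- function(j) {
    if (is.null(init_samples)) circuit_equilibrium(param_samples[[j]])
    else if (inherits(init_samples, "circuit_state")) init_samples
    else init_samples[[j]]
  }
  species <- state_species()
  extra <- if (!is.null(ci)) "c_tot" else character(0)
  arr <- array(NA_real_, dim = c(length(t_grid), length(species) + length(extra), n),
               dimnames = list(NULL, c(species, extra), NULL))
  for (j in seq_len(n)) {
    traj <- simulate_circuit(param_samples[[j]], get_init(j), schedule,
                             t_grid, ...)
    arr[, species, j] <- as.matrix(traj[, species])
    if (!is.null(ci))
      arr[, "c_tot", j] <- total_chemotaxis(traj, ci)$c_tot
  }
  qs <- apply(arr, c(1, 2), stats::quantile,
              probs = c(probs[1], 0.5, probs[2]), names = FALSE)
  summ <- do.call(rbind, lapply(colnames(arr), function(sp) {
    data.frame(time_h = t_grid, species = sp,
               median = qs[2, , sp], lo = qs[1, , sp], hi = qs[3, , sp])
  }))
  list(summary = summ, n_samples = n)
}

#' Tidy (long) view of a trajectory
#'
#' @param traj a `circuit_trajectory`.
#' @param sample_id optional identifier column value.
#' @return data.frame with columns `time_h`, `species`, `value`
#'   (and `sample_id` if given).
#' @export
trajectory_to_tidy <- function(traj, sample_id = NULL) {
  long <- stats::reshape(
    as.data.frame(traj), direction = "long",
    varying = state_species(), v.names = "value",
    times = state_species(), timevar = "species",
    idvar = "time_h")
  rownames(long) <- NULL
  long <- long[, c("time_h", "species", "value")]
  if (!is.null(sample_id)) long$sample_id <- sample_id
  long[order(long$species, long$time_h), ]
}
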