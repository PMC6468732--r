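test_that("relapse forcing follows the ramp-plateau-return shape", {
  sch <- relapse_schedule(onset_time = 100, ramp_duration = 50,
                          plateau_duration = 50, t_end = 500)
  expect_equal(relapse_forcing(50, sch, 3), 1)
  expect_equal(relapse_forcing(125, sch, 3), 2)  # mid-ramp
  expect_equal(relapse_forcing(175, sch, 3), 3)  # plateau
  expect_equal(relapse_forcing(200.0001, sch, 3), 1)  # instant return

  # brute force over a dense grid: the maximum equals gamma and is
  # attained exactly on the plateau
  tt <- seq(0, 500, by = 0.25)
  f <- relapse_forcing(tt, sch, 3)
  expect_equal(max(f), 3)
  expect_setequal(unique(tt[f == 3] >= 150 & tt[f == 3] <= 200), TRUE)
  expect_error(relapse_schedule(ramp_duration = -1), "durations")
})

test_that("circuit RHS matches the model structure at limit states", {
  kin <- default_test_kinetics()
  pars <- circuit_params(k_in = 1e-3, k_i = 2, gamma = 3, x_i = 0.3,
                         x_t = 0.5, kinetics = kin,
                         k_deg_f = 1e-4, k_deg_n = 1e-4, k_deg_c = 1e-4)
  d0 <- circuit_rhs(0, circuit_state(), pars, NULL)[[1]]
  expect_equal(d0[["p_i"]], 1e-3 * 0.3)
  expect_equal(d0[["p_s"]], 1e-3 * 0.7)
  # all degradation terms vanish at the zero state
  expect_equal(unname(d0[c("f_if", "f_in", "f_ic", "f_sf", "f_sn", "f_sc")]),
               rep(0, 6))
  expect_equal(d0[["opn_f"]], pars$k_1 * 0.5)
  expect_equal(d0[["opn_n"]], pars$k_1 * 0.25)

  # pure immunoproteasome limit: standard pool only decays
  pars_i <- circuit_params(k_in = 1e-3, k_i = 2, x_i = 1, kinetics = kin)
  st <- circuit_state(p_s = 0.4, p_i = 0.1, opn_f = 0.2)
  d <- circuit_rhs(0, st, pars_i, NULL)[[1]]
  expect_equal(d[["p_s"]], -0.4 * pars_i$k_deg)
})

test_that("derived equilibria are fixed points of the RHS", {
  m <- make_archetype_measurements()
  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                default_test_kinetics())
  eq <- circuit_equilibrium(pars)
  d <- circuit_rhs(0, eq, pars, NULL)[[1]]
  scale <- pmax(abs(as.numeric(eq)), 1e-12)
  expect_lt(max(abs(d) / scale), 1e-9)
})

test_that("a steady-state start stays constant over 2000 h", {
  m <- make_archetype_measurements()
  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                default_test_kinetics())
  eq <- circuit_equilibrium(pars)
  traj <- simulate_circuit(pars, eq, schedule = NULL,
                           t_grid = seq(0, 2000, by = 100))
  rel <- abs(sweep(as.matrix(traj[, state_species()]), 2,
                   as.numeric(eq), "/") - 1)
  expect_lt(max(rel), 1e-6)
})

test_that("adaptive solution matches a fixed-step RK4 oracle", {
  kin <- default_test_kinetics()
  pars <- circuit_params(k_in = 1e-3, k_i = 2, gamma = 3, kinetics = kin,
                         k_deg_f = 5e-4, k_deg_n = 5e-4, k_deg_c = 5e-4,
                         k_deg = 0.01, k_1 = 1e-3, k_deg3 = 0.01)
  sch <- relapse_schedule(onset_time = 20, ramp_duration = 40,
                          plateau_duration = 40, t_end = 200)
  init <- circuit_state(p_i = 0.02, p_s = 0.02, opn_f = 0.1,
                        opn_n = 0.05, opn_c = 0.05)
  t_grid <- seq(0, 200, by = 10)
  traj <- simulate_circuit(pars, init, sch, t_grid)
  oracle <- rk4_integrate(
    function(t, y) {
      names(y) <- state_species()
      circuit_rhs(t, y, pars, sch)[[1]]
    },
    as.numeric(init), t_grid, dt = 0.01)
  rel <- abs(as.matrix(traj[, state_species()]) - oracle) /
    pmax(abs(oracle), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("relapse depresses total proteasome inside or after the window", {
  m <- make_archetype_measurements()
  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                default_test_kinetics())
  sch <- relapse_schedule(onset_time = 336, t_end = 2016)
  eq <- circuit_equilibrium(pars)
  traj <- simulate_circuit(pars, eq, sch, seq(0, 2016, by = 12))
  p_tot <- traj$p_i + traj$p_s
  t_min <- traj$time_h[which.min(p_tot)]
  expect_gte(t_min, 336)
  expect_lt(min(p_tot), eq[["p_i"]] + eq[["p_s"]])
})

test_that("total proteasome is independent of x_i under symmetric kinetics", {
  kin_sym <- kinetic_params(kcut = 0.5, km = 300)
  mk <- function(x_i) {
    pars <- circuit_params(k_in = 1e-3, k_i = 2, gamma = 3, x_i = x_i,
                          kinetics = kin_sym, k_deg_f = 5e-4,
                          k_deg_n = 5e-4, k_deg_c = 5e-4)
    init <- circuit_state(p_i = 0.05 * x_i, p_s = 0.05 * (1 - x_i),
                          opn_f = 0.1, opn_n = 0.05, opn_c = 0.05)
    traj <- simulate_circuit(pars, init,
                             relapse_schedule(onset_time = 100,
                                              t_end = 1000),
                             seq(0, 1000, by = 50))
    traj$p_i + traj$p_s
  }
  expect_equal(mk(0.2), mk(0.8), tolerance = 1e-7)
})

test_that("states stay non-negative from non-negative starts", {
  kin <- default_test_kinetics()
  set.seed(42)
  for (r in 1:5) {
    pars <- circuit_params(k_in = 10^runif(1, -4, -2), k_i = runif(1, 0, 5),
                           gamma = runif(1, 1, 5), x_i = runif(1),
                           x_t = runif(1), kinetics = kin,
                           k_deg_f = 10^runif(1, -4, -3),
                           k_deg_n = 10^runif(1, -4, -3),
                           k_deg_c = 10^runif(1, -4, -3))
    init <- circuit_state(p_i = runif(1, 0, 0.1), p_s = runif(1, 0, 0.1),
                          opn_f = runif(1, 0, 0.5), opn_n = runif(1, 0, 0.5),
                          opn_c = runif(1, 0, 0.5))
    traj <- simulate_circuit(pars, init,
                             relapse_schedule(onset_time = 200,
                                              t_end = 1500),
                             seq(0, 1500, by = 50))
    expect_gte(min(as.matrix(traj[, state_species()])), 0)
  }
})

test_that("ensemble envelopes collapse and contain the median", {
  m <- make_archetype_measurements()
  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                default_test_kinetics())
  sch <- relapse_schedule(onset_time = 100, t_end = 800)
  tg <- seq(0, 800, by = 100)
  one <- simulate_ensemble(list(pars), schedule = sch, t_grid = tg)
  expect_equal(one$summary$lo, one$summary$hi)
  expect_equal(one$summary$lo, one$summary$median)

  same <- simulate_ensemble(rep(list(pars), 5), schedule = sch, t_grid = tg)
  expect_equal(same$summary$hi - same$summary$lo, rep(0, nrow(same$summary)))

  perturbed <- lapply(1:20, function(i) {
    p <- pars
    p$k_in <- pars$k_in * (1 + 0.05 * sin(i))
    p
  })
  ens <- simulate_ensemble(perturbed, schedule = sch, t_grid = tg)
  expect_true(all(ens$summary$median >= ens$summary$lo - 1e-12))
  expect_true(all(ens$summary$median <= ens$summary$hi + 1e-12))
  expect_error(simulate_ensemble(list()), "at least one")
})

test_that("trajectories serialise to tidy long format", {
  kin <- default_test_kinetics()
  pars <- circuit_params(k_in = 1e-3, k_i = 2, kinetics = kin,
                         k_deg_f = 5e-4, k_deg_n = 5e-4, k_deg_c = 5e-4)
  traj <- simulate_circuit(pars, circuit_state(p_i = 0.01),
                           t_grid = seq(0, 10, by = 5))
  tidy <- trajectory_to_tidy(traj, sample_id = "a")
  expect_equal(nrow(tidy), 3 * 11)
  expect_named(tidy, c("time_h", "species", "value", "sample_id"))
  expect_equal(tidy$value[tidy$species == "p_i" & tidy$time_h == 0], 0.01)
})

test_that("unit conversion is reciprocal and mass-scaled", {
  expect_equal(ng_ml_to_nM(100, 35), 100 / 35)
  expect_equal(nM_to_ng_ml(ng_ml_to_nM(7, 700), 700), 7)
})
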