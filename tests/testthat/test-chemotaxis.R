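test_that("unprocessed indices follow the exposure closed form", {
  expect_equal(estimate_ci_unprocessed(100, 10), 0)
  expect_equal(estimate_ci_unprocessed(150, 10, c(2, 22)), 0.25)
  expect_equal(estimate_ci_unprocessed(c(140, 160), 10), 0.25)
  expect_error(estimate_ci_unprocessed(150, 0), "opn0")
})

test_that("the exponential worked example reproduces its analytic integrals", {
  # OPN(t) = 10 exp(-0.1 (t-2)) on [2, 22]:
  # int OPN = 10/0.1 (1 - e^-2) = 86.4665; int F = 200 - int OPN = 113.5335
  int_opn <- 10 / 0.1 * (1 - exp(-2))
  int_f <- 10 * 20 - int_opn
  expect_equal(int_opn, 86.4665, tolerance = 1e-5)
  expect_equal(int_f, 113.5335, tolerance = 1e-5)
  ci_f <- ci_from_integrals(100, 0.25, int_opn, int_f)
  expect_equal(ci_f, (100 - 0.25 * int_opn) / int_f)
  expect_equal(signif(ci_f, 4), 0.6904)

  # numeric path: deep first-order kinetics with rate p kcut / KM = 0.1
  ints <- digestion_integrals(kcut = 0.1, km = 1e6, p_conc = 1e6,
                              opn0 = 10, window = c(2, 22),
                              digestion_start = 2)
  expect_equal(ints$int_opn, int_opn, tolerance = 1e-4)
  ci_num <- estimate_ci_fragments(200, 0.25, kcut = 0.1, km = 1e6,
                                  p_conc = 1e6, opn0 = 10,
                                  digestion_start = 2)
  expect_equal(signif(ci_num, 4), 0.6904)
})

test_that("fragment attribution fails cleanly without fragments", {
  expect_error(
    estimate_ci_fragments(150, 0.25, kcut = 0, km = 300, p_conc = 250,
                          opn0 = 571),
    "singular")
})

test_that("indices forward-generated at known truth are recovered", {
  cfg <- generator_config(seed = 12)
  mig <- generate_migration(cfg)
  mig <- mig[mig$substrate != "control", ]
  est <- estimate_index_set(mig, cfg$kinetics, "HUVEC")
  truth <- cfg$ci_truth$HUVEC
  expect_equal(unname(est$ci_opn), unname(truth$ci_opn), tolerance = 0.1)
  expect_equal(unname(est$ci_frag), unname(truth$ci_frag),
               tolerance = 0.10)
})

test_that("total chemotaxis is linear and decomposes exactly", {
  ci <- chemotactic_index_set(ci_opn = c(FL = 0.25, N = 0, C = 0),
                              ci_frag = matrix(0.1, 3, 2))
  zero <- data.frame(time_h = 0, t(setNames(rep(0, 11), state_species())))
  expect_equal(total_chemotaxis(zero, ci)$c_tot, 0)
  single <- zero
  single$opn_f <- 10
  expect_equal(total_chemotaxis(single, ci)$c_tot, 2.5)

  set.seed(3)
  ci_r <- chemotactic_index_set(
    ci_opn = c(FL = runif(1), N = runif(1), C = runif(1)),
    ci_frag = matrix(runif(6), 3, 2))
  a <- data.frame(time_h = 1:4,
                  matrix(runif(44), 4, 11,
                         dimnames = list(NULL, state_species())))
  b <- data.frame(time_h = 1:4,
                  matrix(runif(44), 4, 11,
                         dimnames = list(NULL, state_species())))
  ab <- a
  ab[state_species()] <- a[state_species()] + b[state_species()]
  expect_equal(total_chemotaxis(ab, ci_r)$c_tot,
               total_chemotaxis(a, ci_r)$c_tot +
                 total_chemotaxis(b, ci_r)$c_tot)
  dec <- total_chemotaxis(a, ci_r)
  expect_equal(dec$c_tot,
               dec$c_opn + dec$c_frag_standard + dec$c_frag_immuno)
})

test_that("index estimation is scale-consistent in the first-order regime", {
  # doubling opn0 and halving net migration leaves ci_F unchanged when
  # the exposure integrals scale linearly with opn0
  km <- 1e5
  i1 <- digestion_integrals(0.1, km, 1000, 10, c(2, 22), 2)
  i2 <- digestion_integrals(0.1, km, 1000, 20, c(2, 22), 2)
  ci1 <- ci_from_integrals(100, 0, i1$int_opn, i1$int_f)
  ci2 <- ci_from_integrals(200, 0, i2$int_opn, i2$int_f)
  # exact only in the strict first-order limit; opn0/km ~ 1e-4 here
  expect_equal(ci1, ci2, tolerance = 1e-3)
})

test_that("scenario grid reduces to a single run and honours limits", {
  cfg <- generator_config()
  m <- make_archetype_measurements()
  ci <- cfg$ci_truth$HUVEC
  g <- scenario_grid(m, cfg$kinetics, ci, x_i_grid = 0.5, x_t_grid = 0.5,
                     t_step = 24)
  expect_equal(nrow(g), 1)
  expect_true(g$admissible)

  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                cfg$kinetics, x_i = 0.5, x_t = 0.5)
  sch <- relapse_schedule(onset_time = 336, t_end = 1680)
  traj <- simulate_circuit(pars, circuit_equilibrium(pars), sch,
                           seq(0, 1680, by = 24))
  ct <- total_chemotaxis(traj, ci)
  win <- relapse_window(sch)
  in_win <- ct$time_h >= win[1] & ct$time_h <= win[2]
  expect_equal(g$d_ctot, max(ct$c_tot[in_win]) - ct$c_tot[1])

  # x_t = 1: an OPN-FL-only model, no N/C species anywhere
  g1 <- scenario_grid(m, cfg$kinetics, ci, x_i_grid = c(0, 1),
                      x_t_grid = 1, t_step = 48)
  expect_true(all(g1$admissible))
  pars_fl <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                   cfg$kinetics, x_i = 0, x_t = 1)
  eq_fl <- circuit_equilibrium(pars_fl)
  expect_equal(eq_fl[["opn_n"]], 0)
  expect_equal(eq_fl[["opn_c"]], 0)
})

test_that("cell-type comparison mirrors assay content", {
  cfg <- generator_config(seed = 14)
  mig <- generate_migration(cfg)
  mig <- mig[mig$substrate != "control", ]
  kin <- cfg$kinetics
  expect_error(cell_type_comparison(mig[0, ], kin), "empty")

  # identical assay tables for two cell types -> identical index sets
  a <- mig[mig$cell_type == "HUVEC", ]
  b <- a
  b$cell_type <- "clone"
  res <- cell_type_comparison(rbind(a, b), kin)
  expect_equal(res$indices$HUVEC$ci_opn, res$indices$clone$ci_opn)
  expect_equal(res$indices$HUVEC$ci_frag, res$indices$clone$ci_frag)

  # monocytes respond more to OPN-FL by construction
  full <- cell_type_comparison(mig, kin)
  expect_gt(full$indices$monocyte$ci_opn[["FL"]],
            full$indices$HUVEC$ci_opn[["FL"]])

  # a cell type without immuno assays gets NA immuno indices and a
  # standard-only chemotaxis scenario
  no_imm <- mig[!(mig$cell_type == "lymphocyte" &
                    mig$isoform == "immuno"), ]
  m <- make_archetype_measurements()
  pars <- derive_circuit_params(m$p_rem, m$p_rel, m$opn_rem, m$opn_rel,
                                kin, x_i = 0.5, x_t = 0.5)
  res2 <- cell_type_comparison(no_imm, kin, params = pars,
                               t_grid = seq(0, 1680, by = 120))
  expect_true(all(is.na(res2$indices$lymphocyte$ci_frag[, "immuno"])))
  expect_false(any(is.na(res2$indices$HUVEC$ci_frag)))
  expect_equal(max(abs(res2$c_tot$lymphocyte$c_frag_immuno)), 0)
})
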