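test_that("digestion conserves mass and respects the no-enzyme limit", {
  sim0 <- simulate_digestion(0.5, 300, 0, 571, 0:4)
  expect_equal(sim0$substrate_nM, rep(571, 5))
  expect_equal(sim0$fragment_nM, rep(0, 5))

  sim <- simulate_digestion(0.7, 300, 250, 571, seq(0, 4, by = 0.25))
  expect_lt(max(abs(sim$substrate_nM + sim$fragment_nM - 571)) / 571, 1e-8)
  expect_true(all(diff(sim$substrate_nM) < 0))
})

test_that("dilute substrate decays exponentially (first-order limit)", {
  km <- 1000
  tt <- seq(0, 4, by = 0.2)
  sim <- simulate_digestion(0.5, km, 250, km / 100, tt)
  expo <- exp(-250 * 0.5 / km * tt)
  expect_lt(max(abs(sim$relative_remaining - expo) / expo), 0.01)
})

test_that("the exact depletion curve matches an LSODA oracle", {
  rhs <- function(t, y, p) list(-p$v * y / (p$km + y))
  for (prm in list(c(v = 125, km = 1000, s0 = 571),
                   c(v = 300, km = 50, s0 = 571),
                   c(v = 5, km = 2000, s0 = 20))) {
    tt <- seq(0, 4, by = 0.5)
    ode <- deSolve::lsoda(prm[["s0"]], tt, rhs,
                          list(v = prm[["v"]], km = prm[["km"]]),
                          rtol = 1e-10, atol = 1e-12)
    sim <- simulate_digestion(1, prm[["km"]], prm[["v"]], prm[["s0"]], tt)
    expect_lt(max(abs(ode[, 2] - sim$substrate_nM)) / prm[["s0"]], 1e-7)
  }
})

test_that("digestion likelihood has Gaussian structure and a maximum at truth", {
  tc <- digestion_timecourse("FL", "standard", p_conc = 2, opn0 = 20,
                             time_h = rep(0:4, 2),
                             replicate = rep(1:2, each = 5),
                             relative_remaining = rep(
                               simulate_digestion(2, 10, 2, 20,
                                                  0:4)$relative_remaining,
                               2))
  # zero residuals: doubling sigma lowers the log-likelihood by n log 2
  l1 <- digestion_log_likelihood(2, 10, 0.05, tc)
  l2 <- digestion_log_likelihood(2, 10, 0.10, tc)
  expect_equal(l1 - l2, nrow(tc$data) * log(2))

  # grid search oracle: the generating parameters maximise the likelihood
  grid <- expand.grid(kcut = c(0.5, 1, 2, 4, 8), km = c(2.5, 5, 10, 20, 40))
  ll <- mapply(function(kc, km) digestion_log_likelihood(kc, km, 0.05, tc),
               grid$kcut, grid$km)
  expect_equal(unlist(grid[which.max(ll), ]), c(kcut = 2, km = 10))

  # vacuous data
  empty <- digestion_timecourse("FL", "standard", 2, 20, numeric(0),
                                integer(0), numeric(0))
  expect_equal(digestion_log_likelihood(2, 10, 0.05, empty), 0)
  expect_equal(digestion_log_likelihood(-1, 10, 0.05, tc), -Inf)
})

test_that("random-walk MH samples a standard Gaussian correctly", {
  ch <- metropolis_hastings(function(x) -x^2 / 2, init = 0.5,
                            n_iter = 50000, proposal_scales = 2.4,
                            seed = 17)
  keep <- ch$samples[-(1:1000), 1]
  expect_lt(abs(mean(keep)), 0.05)
  expect_lt(abs(stats::var(keep) - 1), 0.1)
  expect_gt(ch$acceptance_rate, 0.05)
  expect_lt(ch$acceptance_rate, 0.8)
})

test_that("MH chain handles degenerate inputs", {
  ch0 <- metropolis_hastings(function(x) -sum(x^2), c(0, 0), n_iter = 0,
                             proposal_scales = 1, seed = 1)
  expect_equal(nrow(ch0$samples), 1)
  expect_error(
    metropolis_hastings(function(x) -Inf, 0, 10, 1, seed = 1),
    "zero target density")
  a <- metropolis_hastings(function(x) -x^2, 0, 500, 1, seed = 9)
  b <- metropolis_hastings(function(x) -x^2, 0, 500, 1, seed = 9)
  expect_identical(a$samples, b$samples)
})

test_that("noise-free digestion data pin down kcut and KM", {
  clean <- simulate_digestion(2, 10, 2, 20, 0:4)$relative_remaining
  tc <- digestion_timecourse("FL", "standard", 2, 20,
                             time_h = rep(0:4, 2),
                             replicate = rep(1:2, each = 5),
                             relative_remaining = rep(clean, 2))
  fit <- infer_kinetics(tc, n_iter = 20000, burn_in = 5000, seed = 5)
  s <- fit$summary
  expect_equal(s$mode[s$parameter == "kcut"], 2, tolerance = 0.05)
  expect_equal(s$mode[s$parameter == "km"], 10, tolerance = 0.05)
})

test_that("posterior ordering of isoform turnover is stable across seeds", {
  cfg <- generator_config()
  ok <- 0L
  for (s in 1:20) {
    cfg$seed <- 1000 + s
    tcs <- generate_digestion(cfg)
    fl <- Filter(function(tc) tc$substrate == "FL", tcs)
    fit <- infer_kinetics(fl, n_iter = 3000, burn_in = 1000,
                          seed = cfg$seed)
    su <- fit$summary
    med <- function(iso) su$median[su$isoform == iso &
                                     su$parameter == "kcut"]
    ok <- ok + (med("immuno") > med("standard"))
  }
  expect_gte(ok, 19)
})

test_that("identical datasets give statistically indistinguishable posteriors", {
  cfg <- generator_config(seed = 77)
  tc <- generate_digestion(cfg)[[2]]
  f1 <- infer_kinetics(tc, n_iter = 12000, burn_in = 3000, seed = 101)
  f2 <- infer_kinetics(tc, n_iter = 12000, burn_in = 3000, seed = 202)
  # thin to roughly independent draws before comparing distributions
  thin <- function(f) {
    x <- log(f$fits[[1]]$post_burn[, "kcut"])
    x[seq(1, length(x), by = 20)]
  }
  ks <- suppressWarnings(stats::ks.test(thin(f1), thin(f2)))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("decay-free data push kcut to the prior floor", {
  tc <- digestion_timecourse("N", "immuno", 250, 571,
                             time_h = rep(0:4, 2),
                             replicate = rep(1:2, each = 5),
                             relative_remaining = rep(1, 10))
  fit <- infer_kinetics(tc, n_iter = 4000, burn_in = 1000, seed = 8)
  kcut_med <- fit$summary$median[fit$summary$parameter == "kcut"]
  expect_lt(kcut_med, 0.01)
})

test_that("posterior draws cover all pairs and ridge correlation is reported", {
  cfg <- generator_config(seed = 55)
  tcs <- generate_digestion(cfg)
  fit <- infer_kinetics(tcs, n_iter = 2000, burn_in = 500, seed = 56)
  draws <- kinetics_posterior_draws(fit, n_draws = 5, seed = 57)
  expect_length(draws, 5)
  expect_false(any(is.na(draws[[1]]$kcut)))
  expect_true(all(is.finite(vapply(fit$fits, `[[`, numeric(1),
                                   "ridge_correlation"))))
  med <- kinetics_posterior_median(fit)
  expect_s3_class(med, "kinetic_params")
  # digestion CSV round trip
  path <- tempfile(fileext = ".csv")
  write_digestion(tcs, path)
  back <- read_digestion(path)
  expect_length(back, 6)
  expect_equal(back[[1]]$data$relative_remaining,
               tcs[[1]]$data$relative_remaining)
})
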