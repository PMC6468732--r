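# Independent oracles used across the suite. These deliberately avoid the
# package's own solvers: a fixed-step classical Runge-Kutta integrator, a
# brute-force rank-enumeration MSSS, and small closed forms.

# classical 4th-order Runge-Kutta with fixed step; rhs(t, y) -> dy vector
rk4_integrate <- function(rhs, y0, t_grid, dt) {
  out <- matrix(NA_real_, nrow = length(t_grid), ncol = length(y0))
  out[1, ] <- y <- y0
  t <- t_grid[1]
  for (i in 2:length(t_grid)) {
    target <- t_grid[i]
    while (t < target - 1e-12) {
      h <- min(dt, target - t)
      k1 <- rhs(t, y)
      k2 <- rhs(t + h / 2, y + h / 2 * k1)
      k3 <- rhs(t + h / 2, y + h / 2 * k2)
      k4 <- rhs(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  colnames(out) <- names(y0)
  out
}

# brute-force MSSS: augment the bin with the query, enumerate ranks of the
# query EDSS by sorting, average the lowest and highest, normalise
msss_oracle <- function(bin, edss) {
  aug <- sort(c(bin, edss))
  rks <- seq_along(aug)[aug == edss]
  mean(c(min(rks), max(rks))) / (length(aug) + 1) * 10
}

# deterministic small cohort with an exact steady-state structure, built
# from a known parameter set via the package-independent closed forms
make_archetype_measurements <- function() {
  list(p_rem = 10 / 700, p_rel = 10 / 700 * 0.6,
       opn_rem = 6 / 35, opn_rel = 6 / 35 * 3)
}

default_test_kinetics <- function() {
  kinetic_params(kcut = cbind(standard = c(0.4, 0.6, 0.5),
                              immuno = c(1.2, 0.8, 1.5)),
                 km = matrix(300, 3, 2))
}
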