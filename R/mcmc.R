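#' Random-walk Metropolis-Hastings sampler
#'
#' Plain Gaussian random-walk Metropolis-Hastings on a continuous
#' parameter vector. The caller supplies the (unnormalised) log target;
#' for the kinetic parameters this package samples in log-parameter
#' space. The chain is deterministic given the seed.
#'
#' @param log_target function(theta) -> log density (may return `-Inf`).
#' @param init numeric start vector with finite log target.
#' @param n_iter number of proposals (chain has `n_iter + 1` rows).
#' @param proposal_scales per-coordinate SD of the Gaussian proposal
#'   (recycled).
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param wide_fraction probability of proposing from the widened
#'   component (`wide_multiplier * proposal_scales`); the two-component
#'   Gaussian mixture stays symmetric, so acceptance is unchanged, but
#'   the chain can hop between separated modes (e.g. the zero-order and
#'   first-order basins of weakly decaying digestion curves). 0 disables
#'   it.
#' @param wide_multiplier scale factor of the wide component.
#' @return object of class `posterior_chains`: list with `samples`
#'   (matrix, one row per state), `log_post` (trace), `acceptance_rate`,
#'   `n_iter`, `seed`.
#' @examples
#' ch <- metropolis_hastings(function(x) -x^2 / 2, init = 0,
#'                           n_iter = 2000, proposal_scales = 2, seed = 1)
#' mean(ch$samples)
#' @export
metropolis_hastings <- function(log_target, init, n_iter, proposal_scales,
                                seed = NULL, wide_fraction = 0,
                                wide_multiplier = 8) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  scales <- rep_len(proposal_scales, d)
  lp <- log_target(init)
  if (!is.finite(lp)) stop("initial point has zero target density")
  samples <- matrix(NA_real_, nrow = n_iter + 1, ncol = d)
  colnames(samples) <- names(init)
  log_post <- numeric(n_iter + 1)
  samples[1, ] <- init
  log_post[1] <- lp
  cur <- as.numeric(init)
  accepted <- 0L
  for (i in seq_len(n_iter)) {
    s_i <- if (wide_fraction > 0 && stats::runif(1) < wide_fraction)
      scales * wide_multiplier else scales
    prop <- cur + stats::rnorm(d, 0, s_i)
    lp_prop <- log_target(prop)
    # proposals outside the support are rejected without an acceptance draw
    if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
      cur <- prop
      lp <- lp_prop
      accepted <- accepted + 1L
    }
    samples[i + 1, ] <- cur
    log_post[i + 1] <- lp
  }
  structure(list(samples = samples, log_post = log_post,
                 acceptance_rate = if (n_iter > 0) accepted / n_iter else NA_real_,
                 n_iter = n_iter, seed = seed),
            class = "posterior_chains")
}

#' @export
print.posterior_chains <- function(x, ...) {
  cat(sprintf("Metropolis-Hastings chain: %d iterations, acceptance %.1f%%\n",
              x$n_iter, 100 * x$acceptance_rate))
  invisible(x)
}

# Adapt proposal scales toward a target acceptance rate with short pilot
# runs, then return the tuned scales and the last state.
adapt_proposals <- function(log_target, init, scales, target = 0.3,
                            pilot_iter = 400, rounds = 8) {
  cur <- init
  for (r in seq_len(rounds)) {
    ch <- metropolis_hastings(log_target, cur, pilot_iter, scales)
    acc <- ch$acceptance_rate
    cur <- ch$samples[nrow(ch$samples), ]
    if (acc > 0.9 * target && acc < 1.5 * target) break
    # log-linear update, bounded per round
    f <- exp(pmin(pmax(acc - target, -0.25), 0.25) * 4)
    scales <- scales * f
  }
  list(scales = scales, state = cur)
}
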