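#' In vitro digestion time course container
#'
#' One 0-4 h digestion experiment: a single OPN species incubated with a
#' single purified 20S proteasome isoform at constant enzyme
#' concentration, observed as relative substrate remaining (immunoblot
#' quantification, ~1 at t = 0), with replicates.
#'
#' @param substrate one of `"FL"`, `"N"`, `"C"`.
#' @param isoform one of `"standard"`, `"immuno"`.
#' @param p_conc proteasome concentration (nM), constant over the assay.
#' @param opn0 initial substrate concentration (nM).
#' @param time_h observation times (h), starting at 0.
#' @param replicate replicate label per observation.
#' @param relative_remaining observed relative substrate, in [0, ~1.2].
#' @return object of class `digestion_timecourse`.
#' @export
digestion_timecourse <- function(substrate, isoform, p_conc, opn0,
                                 time_h, replicate, relative_remaining) {
  substrate <- match.arg(substrate, opn_species())
  isoform <- match.arg(isoform, proteasome_isoforms())
  stopifnot(p_conc >= 0, opn0 > 0,
            length(time_h) == length(relative_remaining),
            length(time_h) == length(replicate))
  if (any(time_h < 0)) stop("observation times must be >= 0")
  if (any(relative_remaining < 0)) stop("relative substrate must be >= 0")
  structure(list(substrate = substrate, isoform = isoform,
                 p_conc = p_conc, opn0 = opn0,
                 data = data.frame(time_h = time_h, replicate = replicate,
                                   relative_remaining = relative_remaining)),
            class = "digestion_timecourse")
}

#' @export
print.digestion_timecourse <- function(x, ...) {
  cat(sprintf(
    "Digestion time course: OPN-%s x %s proteasome (%g nM enzyme, %g nM substrate, %d obs)\n",
    x$substrate, x$isoform, x$p_conc, x$opn0, nrow(x$data)))
  invisible(x)
}

#' Gaussian log-likelihood of a digestion time course
#'
#' Independent Gaussian observation noise on the relative substrate
#' remaining, with the mean curve given by the exact Michaelis-Menten
#' depletion solution (see [simulate_digestion()]). Replicates are
#' pooled. An empty time course gives 0; a non-finite model curve gives
#' `-Inf` (rejected by the sampler).
#'
#' @param kcut,km Michaelis-Menten parameters for this
#'   (substrate, isoform) pair.
#' @param sigma observation noise SD (relative units), > 0.
#' @param tc a [digestion_timecourse()].
#' @return the log-likelihood (scalar).
#' @export
digestion_log_likelihood <- function(kcut, km, sigma, tc) {
  stopifnot(inherits(tc, "digestion_timecourse"), sigma > 0)
  if (nrow(tc$data) == 0) return(0)
  if (!is.finite(kcut) || !is.finite(km) || kcut < 0 || km <= 0)
    return(-Inf)
  pred <- mm_substrate(tc$data$time_h, s0 = tc$opn0,
                       v = tc$p_conc * kcut, km = km) / tc$opn0
  if (any(!is.finite(pred))) return(-Inf)
  sum(stats::dnorm(tc$data$relative_remaining, pred, sigma, log = TRUE))
}

#' Default priors for the kinetic inference
#'
#' Log-uniform priors: `kcut` in [1e-4, 1e2] 1/h per nM proteasome, `KM`
#' in [1e-2, 1e4] nM, and (when the noise SD is inferred) `sigma` in
#' [1e-3, 1].
#'
#' @return list of `c(lower, upper)` bounds on the natural scale.
#' @export
kinetics_priors <- function() {
  list(kcut = c(1e-4, 1e2), km = c(1e-2, 1e4), sigma = c(1e-3, 1))
}

# log-posterior factory for one time course. The chain runs in
# (log rate0, log KM [, log sigma]) where rate0 = kcut p / (KM + opn0) is
# the initial relative decay rate: the kcut-KM ridge (data that only
# constrain kcut/KM) becomes axis-aligned, so the flat KM direction mixes
# freely. The map (log kcut, log KM) -> (log rate0, log KM) has unit
# Jacobian, so the log-uniform prior is flat here too (within the mapped
# kcut bounds).
make_digestion_log_post <- function(tc, sigma, priors) {
  lr_s <- if (is.null(sigma)) log(priors$sigma) else NULL
  l_km <- log(priors$km)
  l_kc <- log(priors$kcut)
  p <- max(tc$p_conc, 1e-300)
  function(theta) {
    if (theta[2] < l_km[1] || theta[2] > l_km[2]) return(-Inf)
    km <- exp(theta[2])
    l_kcut <- theta[1] + log(km + tc$opn0) - log(p)
    if (l_kcut < l_kc[1] || l_kcut > l_kc[2]) return(-Inf)
    if (is.null(sigma)) {
      if (theta[3] < lr_s[1] || theta[3] > lr_s[2]) return(-Inf)
      sg <- exp(theta[3])
    } else sg <- sigma
    digestion_log_likelihood(exp(l_kcut), km, sg, tc)
  }
}

# convert chain samples from (log rate0, log KM, ...) to kcut/km columns
digestion_chain_to_params <- function(samples, tc) {
  km <- exp(samples[, 2])
  kcut <- exp(samples[, 1]) * (km + tc$opn0) / max(tc$p_conc, 1e-300)
  cbind(kcut = kcut, km = km)
}

#' Infer Michaelis-Menten kinetics from digestion time courses
#'
#' Runs an adapted random-walk Metropolis-Hastings chain in log-parameter
#' space for each (substrate, isoform) time course, pooling replicates
#' under a Gaussian noise model. Acceptance is tuned toward ~30% with
#' short pilot runs before the main chain. Chains whose final acceptance
#' falls outside [0.05, 0.8] are flagged with a warning entry in the
#' result (not fatal). `kcut` and `KM` are strongly ridge-correlated when
#' the data only constrain their ratio (first-order regime); the per-chain
#' posterior correlation is reported so this is visible.
#'
#' @param timecourses list of [digestion_timecourse()] objects (typically
#'   the six species x isoform combinations).
#' @param n_iter main chain length (default 20000).
#' @param burn_in iterations discarded before summarising (default
#'   `n_iter/4`).
#' @param sigma fixed observation noise SD, or `NULL` (default) to infer
#'   it under its log-uniform prior.
#' @param priors prior bounds, see [kinetics_priors()].
#' @param seed RNG seed; one stream per curve derived from it.
#' @return object of class `kinetics_fit`: list with `fits` (per curve:
#'   `chain`, `substrate`, `isoform`, `warnings`, `ridge_correlation`),
#'   `summary` (data.frame: substrate, isoform, parameter, median,
#'   lower95, upper95, mode), `burn_in`, `seed`.
#' @export
infer_kinetics <- function(timecourses, n_iter = 20000, burn_in = NULL,
                           sigma = NULL, priors = kinetics_priors(),
                           seed = 1) {
  if (inherits(timecourses, "digestion_timecourse"))
    timecourses <- list(timecourses)
  if (length(timecourses) == 0) stop("no time courses supplied")
  ok <- vapply(timecourses, function(tc)
    length(unique(tc$data$time_h)) >= 3, logical(1))
  if (!all(ok)) stop("each curve needs at least 3 distinct time points")
  if (is.null(burn_in)) burn_in <- n_iter %/% 4

  fits <- vector("list", length(timecourses))
  rows <- list()
  for (j in seq_along(timecourses)) {
    tc <- timecourses[[j]]
    lp <- make_digestion_log_post(tc, sigma, priors)
    init <- digestion_init(tc, sigma, priors)
    set.seed(seed + 7919L * j)
    ad <- adapt_proposals(lp, init, scales = c(0.1, 0.8, 0.3)[seq_along(init)])
    chain <- metropolis_hastings(lp, ad$state, n_iter, ad$scales,
                                 wide_fraction = 0.1)
    keep <- chain$samples[-seq_len(min(burn_in, nrow(chain$samples) - 1)), ,
                          drop = FALSE]
    kk <- digestion_chain_to_params(keep, tc)
    kcut_s <- kk[, "kcut"]; km_s <- kk[, "km"]
    warn <- character(0)
    if (chain$acceptance_rate < 0.05 || chain$acceptance_rate > 0.8)
      warn <- sprintf("acceptance rate %.2f outside [0.05, 0.8]",
                      chain$acceptance_rate)
    mode_idx <- which.max(chain$log_post)
    modes <- digestion_chain_to_params(
      chain$samples[mode_idx, , drop = FALSE], tc)[1, ]
    q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      substrate = tc$substrate, isoform = tc$isoform,
      parameter = c("kcut", "km"),
      median = c(q(kcut_s)[1], q(km_s)[1]),
      lower95 = c(q(kcut_s)[2], q(km_s)[2]),
      upper95 = c(q(kcut_s)[3], q(km_s)[3]),
      mode = c(modes[["kcut"]], modes[["km"]]))
    fits[[j]] <- list(substrate = tc$substrate, isoform = tc$isoform,
                      chain = chain, warnings = warn,
                      ridge_correlation = stats::cor(keep[, 1], keep[, 2]),
                      post_burn = cbind(kcut = kcut_s, km = km_s))
  }
  structure(list(fits = fits, summary = do.call(rbind, rows),
                 burn_in = burn_in, seed = seed),
            class = "kinetics_fit")
}

# data-informed start in (log rate0, log KM [, log sigma]) space: the
# initial decay rate from a log-linear fit, KM at the substrate scale
digestion_init <- function(tc, sigma, priors) {
  d <- tc$data
  r <- 0.1
  pos <- d$relative_remaining > 1e-3 & d$time_h > 0
  if (sum(pos) >= 2) {
    fit <- stats::lm(log(relative_remaining) ~ time_h, data = d[pos, ])
    r <- max(-stats::coef(fit)[["time_h"]], 1e-3)
  }
  km0 <- min(max(tc$opn0, priors$km[1] * 2), priors$km[2] / 2)
  # keep the implied kcut inside its prior
  kcut0 <- r * (km0 + tc$opn0) / max(tc$p_conc, 1e-300)
  kcut0 <- min(max(kcut0, priors$kcut[1] * 2), priors$kcut[2] / 2)
  r0 <- kcut0 * max(tc$p_conc, 1e-300) / (km0 + tc$opn0)
  init <- c(log_rate0 = log(r0), log_km = log(km0))
  if (is.null(sigma)) init <- c(init, log_sigma = log(0.05))
  init
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Kinetic inference over %d time courses (burn-in %d)\n",
              length(x$fits), x$burn_in))
  print(x$summary, digits = 3, row.names = FALSE)
  warns <- unlist(lapply(x$fits, `[[`, "warnings"))
  if (length(warns)) cat("warnings:", paste(warns, collapse = "; "), "\n")
  invisible(x)
}

#' Draw joint kinetic parameter sets from a fitted posterior
#'
#' Assembles [kinetic_params()] objects by drawing one post-burn-in
#' posterior sample per (substrate, isoform) chain; curves are
#' independent experiments so indices are drawn independently.
#'
#' @param fit a [infer_kinetics()] result covering all six
#'   (substrate, isoform) pairs.
#' @param n_draws number of joint draws.
#' @param seed RNG seed.
#' @return list of `n_draws` [kinetic_params()] objects.
#' @export
kinetics_posterior_draws <- function(fit, n_draws = 100, seed = 1) {
  stopifnot(inherits(fit, "kinetics_fit"))
  set.seed(seed)
  draws <- vector("list", n_draws)
  for (b in seq_len(n_draws)) {
    kcut <- matrix(NA_real_, 3, 2,
                   dimnames = list(opn_species(), proteasome_isoforms()))
    km <- kcut
    for (f in fit$fits) {
      i <- sample.int(nrow(f$post_burn), 1)
      kcut[f$substrate, f$isoform] <- f$post_burn[i, "kcut"]
      km[f$substrate, f$isoform] <- f$post_burn[i, "km"]
    }
    if (any(is.na(kcut)))
      stop("fit does not cover all six (substrate, isoform) pairs")
    draws[[b]] <- kinetic_params(kcut, km)
  }
  draws
}

#' Posterior-median kinetic parameter set
#' @param fit a [infer_kinetics()] result covering all six pairs.
#' @return a [kinetic_params()] object of per-curve posterior medians.
#' @export
kinetics_posterior_median <- function(fit) {
  stopifnot(inherits(fit, "kinetics_fit"))
  kcut <- matrix(NA_real_, 3, 2,
                 dimnames = list(opn_species(), proteasome_isoforms()))
  km <- kcut
  for (f in fit$fits) {
    kcut[f$substrate, f$isoform] <- stats::median(f$post_burn[, "kcut"])
    km[f$substrate, f$isoform] <- stats::median(f$post_burn[, "km"])
  }
  if (any(is.na(kcut))) stop("fit does not cover all six pairs")
  kinetic_params(kcut, km)
}

#' Read / write digestion CSV
#'
#' Columns: `substrate`, `isoform`, `time_h`, `replicate`,
#' `relative_remaining`, `p_conc_nM`, `opn0_nM`.
#'
#' @param path CSV path.
#' @return list of [digestion_timecourse()] objects.
#' @export
read_digestion <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  split_digestion(d)
}

#' @rdname read_digestion
#' @param d digestion data.frame in the CSV layout.
#' @export
split_digestion <- function(d) {
  keys <- unique(d[, c("substrate", "isoform")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- d[d$substrate == keys$substrate[i] & d$isoform == keys$isoform[i], ]
    digestion_timecourse(keys$substrate[i], keys$isoform[i],
                         p_conc = sub$p_conc_nM[1], opn0 = sub$opn0_nM[1],
                         time_h = sub$time_h, replicate = sub$replicate,
                         relative_remaining = sub$relative_remaining)
  })
}

#' @rdname read_digestion
#' @param timecourses list of [digestion_timecourse()] objects.
#' @export
write_digestion <- function(timecourses, path) {
  rows <- lapply(timecourses, function(tc) {
    cbind(substrate = tc$substrate, isoform = tc$isoform, tc$data,
          p_conc_nM = tc$p_conc, opn0_nM = tc$opn0)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(timecourses)
}
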