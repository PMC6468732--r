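#' End-to-end circuit analysis pipeline
#'
#' Orchestrates the stages of the analysis on one output directory:
#'
#' 1. `synth` — generate the synthetic dataset (or use existing input
#'    CSVs in `outdir`).
#' 2. `infer_kinetics` — Metropolis-Hastings inference of the
#'    Michaelis-Menten constants from `digestion.csv`.
#' 3. `derive_params` — bootstrap the cohort into a circuit-parameter
#'    ensemble.
#' 4. `simulate` — ensemble simulation through a relapse with
#'    uncertainty envelopes.
#' 5. `chemotaxis` — chemotactic index estimation per cell type and the
#'    chemotaxis envelope.
#' 6. `severity` — per-patient simulation, feature extraction,
#'    cross-validated severity models and group-B predictions.
#'
#' Every stage writes plain CSV; a JSON manifest lists every artifact
#' with its MD5 checksum and the seeds used, so two runs with the same
#' configuration are byte-identical. With `resume = TRUE` a stage whose
#' outputs already exist is skipped; a failing stage is recorded in the
#' manifest and downstream stages are not run.
#'
#' @param outdir output directory.
#' @param config a [generator_config()]; its `seed` seeds every stage.
#' @param stages subset of the stage names to run (in pipeline order).
#' @param resume skip stages whose outputs already exist.
#' @param mcmc_iter,mcmc_burn main chain length / burn-in per digestion
#'   curve.
#' @param n_kinetic_draws joint posterior kinetic draws carried forward.
#' @param n_param_draws bootstrap draws of the cohort ensemble.
#' @param n_ensemble trajectories in the ensemble simulation.
#' @param schedule relapse schedule used by the simulation stages.
#' @return the manifest (invisibly), a list with per-stage `files`,
#'   `checksums`, `status` and the seed log, also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(outdir,
                         config = generator_config(),
                         stages = pipeline_stages(),
                         resume = FALSE,
                         mcmc_iter = 4000, mcmc_burn = 1000,
                         n_kinetic_draws = 50, n_param_draws = 200,
                         n_ensemble = 50,
                         schedule = relapse_schedule(onset_time = 336,
                                                     t_end = 1680)) {
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  failed <- FALSE

  run_stage <- function(name, outputs, fun) {
    paths <- file.path(outdir, outputs)
    if (failed || !(name %in% stages)) {
      status <- if (failed) "not-run" else "skipped"
    } else if (resume && all(file.exists(paths))) {
      status <- "cached"
    } else {
      status <- tryCatch({ fun(); "ok" },
                         error = function(e) paste("failed:",
                                                   conditionMessage(e)))
      if (startsWith(status, "failed")) failed <<- TRUE
    }
    present <- file.exists(paths)
    manifest$stages[[name]] <<- list(
      status = status, files = outputs[present],
      md5 = unname(tools::md5sum(paths[present])))
    invisible(status)
  }

  run_stage("synth",
            c("cohort.csv", "digestion.csv", "migration.csv",
              "msss_reference.csv", "severity.csv", "truth.yaml"),
            function() generate_dataset(config, outdir))

  run_stage("infer_kinetics",
            c("kinetics_summary.csv", "kinetics_draws.csv"),
            function() {
    tcs <- read_digestion(file.path(outdir, "digestion.csv"))
    fit <- infer_kinetics(tcs, n_iter = mcmc_iter, burn_in = mcmc_burn,
                          seed = config$seed + 11L)
    utils::write.csv(fit$summary,
                     file.path(outdir, "kinetics_summary.csv"),
                     row.names = FALSE)
    draws <- kinetics_posterior_draws(fit, n_kinetic_draws,
                                      seed = config$seed + 12L)
    rows <- do.call(rbind, lapply(seq_along(draws), function(b) {
      k <- draws[[b]]
      data.frame(draw = b,
                 substrate = rep(opn_species(), 2),
                 isoform = rep(proteasome_isoforms(), each = 3),
                 kcut = as.vector(k$kcut), km = as.vector(k$km))
    }))
    utils::write.csv(rows, file.path(outdir, "kinetics_draws.csv"),
                     row.names = FALSE)
  })

  read_kin_draws <- function() {
    d <- utils::read.csv(file.path(outdir, "kinetics_draws.csv"))
    lapply(split(d, d$draw), function(s) {
      kcut <- km <- matrix(NA_real_, 3, 2,
                           dimnames = list(opn_species(),
                                           proteasome_isoforms()))
      for (r in seq_len(nrow(s))) {
        kcut[s$substrate[r], s$isoform[r]] <- s$kcut[r]
        km[s$substrate[r], s$isoform[r]] <- s$km[r]
      }
      kinetic_params(kcut, km)
    })
  }
  median_kinetics <- function() {
    s <- utils::read.csv(file.path(outdir, "kinetics_summary.csv"))
    kcut <- km <- matrix(NA_real_, 3, 2,
                         dimnames = list(opn_species(),
                                         proteasome_isoforms()))
    for (r in seq_len(nrow(s))) {
      m <- s$median[r]
      if (s$parameter[r] == "kcut") kcut[s$substrate[r], s$isoform[r]] <- m
      else km[s$substrate[r], s$isoform[r]] <- m
    }
    kinetic_params(kcut, km)
  }

  run_stage("derive_params", "param_ensemble.csv", function() {
    cohort <- read_cohort(file.path(outdir, "cohort.csv"))
    ens <- sample_parameter_distributions(
      cohort, kinetics = read_kin_draws(), n_draws = n_param_draws,
      seed = config$seed + 21L, x_i = config$x_i, x_t = config$x_t)
    tab <- as.data.frame(ensemble_to_matrix(ens))
    tab$rejected_draws <- ens$rejected
    utils::write.csv(tab, file.path(outdir, "param_ensemble.csv"),
                     row.names = FALSE)
  })

  ensemble_params <- function(n) {
    tab <- utils::read.csv(file.path(outdir, "param_ensemble.csv"))
    kin <- median_kinetics()
    idx <- seq_len(min(n, nrow(tab)))
    lapply(idx, function(i)
      circuit_params(k_in = tab$k_in[i], k_i = tab$k_i[i],
                     gamma = tab$gamma[i], k_deg_f = tab$k_deg_f[i],
                     k_deg_n = tab$k_deg_n[i], k_deg_c = tab$k_deg_c[i],
                     k_deg = config$k_deg, k_1 = config$k_1,
                     k_deg3 = config$k_deg3,
                     x_i = config$x_i, x_t = config$x_t, kinetics = kin))
  }

  run_stage("simulate", "ensemble_summary.csv", function() {
    ens <- simulate_ensemble(ensemble_params(n_ensemble),
                             schedule = schedule,
                             t_grid = seq(0, schedule$t_end, by = 24))
    utils::write.csv(ens$summary,
                     file.path(outdir, "ensemble_summary.csv"),
                     row.names = FALSE)
  })

  run_stage("chemotaxis",
            c("chemotaxis_indices.csv", "chemotaxis_envelope.csv"),
            function() {
    migration <- read_migration(file.path(outdir, "migration.csv"))
    migration <- migration[migration$substrate != "control", ]
    kin_draws <- read_kin_draws()
    rows <- list()
    huvec_ci <- NULL
    for (ct in unique(migration$cell_type)) {
      dist <- estimate_index_distribution(migration, kin_draws, ct,
                                          window = config$window)
      med <- dist$median
      if (ct == "HUVEC") huvec_ci <- med
      rows[[length(rows) + 1]] <- data.frame(
        cell_type = ct,
        species = c(paste0("opn_", c("f", "n", "c")),
                    paste0("frag_", rep(c("s", "i"), each = 3),
                           rep(c("f", "n", "c"), 2))),
        ci = c(med$ci_opn, med$ci_frag[, "standard"],
               med$ci_frag[, "immuno"]))
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(outdir, "chemotaxis_indices.csv"),
                     row.names = FALSE)
    ens <- simulate_ensemble(ensemble_params(n_ensemble),
                             schedule = schedule,
                             t_grid = seq(0, schedule$t_end, by = 24),
                             ci = huvec_ci)
    env <- ens$summary[ens$summary$species == "c_tot", ]
    utils::write.csv(env, file.path(outdir, "chemotaxis_envelope.csv"),
                     row.names = FALSE)
  })

  run_stage("severity",
            c("patient_features.csv", "severity_eval.csv",
              "severity_coefficients.csv", "group_b_predictions.csv"),
            function() {
    cohort <- read_cohort(file.path(outdir, "cohort.csv"))
    sev <- utils::read.csv(file.path(outdir, "severity.csv"))
    feats <- cohort_feature_table(cohort, kinetics = median_kinetics(),
                                  x_i = config$x_i, x_t = config$x_t,
                                  schedule = schedule)
    utils::write.csv(feats, file.path(outdir, "patient_features.csv"),
                     row.names = FALSE)
    m <- merge(feats, sev, by = "patient_id")
    a <- m[m$group == "A", ]
    outcomes <- list(msss = a$msss_relapse, delta_msss = a$delta_msss,
                     msss_prime = a$msss_prime)
    eval_tab <- evaluate_feature_sets(a, outcomes,
                                      seed = config$seed + 31L)
    utils::write.csv(eval_tab, file.path(outdir, "severity_eval.csv"),
                     row.names = FALSE)
    cols <- severity_feature_sets()$opn_proteasome_fragments
    fit <- fit_severity_glm(a[, cols], a$msss_prime,
                            seed = config$seed + 31L)
    utils::write.csv(
      data.frame(term = names(fit$coefficients),
                 estimate = unname(fit$coefficients)),
      file.path(outdir, "severity_coefficients.csv"), row.names = FALSE)
    b <- m[m$group == "B", ]
    pred_b <- if (nrow(b)) apply_model_to_group_b(fit, b[, cols],
                                                  b$msss_prime)
              else data.frame(predicted = numeric(0))
    if (nrow(b)) pred_b <- cbind(patient_id = b$patient_id, pred_b)
    utils::write.csv(pred_b, file.path(outdir, "group_b_predictions.csv"),
                     row.names = FALSE)
  })

  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname run_pipeline
#' @return `pipeline_stages()`: the ordered stage names.
#' @export
pipeline_stages <- function() {
  c("synth", "infer_kinetics", "derive_params", "simulate", "chemotaxis",
    "severity")
}
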