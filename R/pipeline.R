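#' Default pipeline configuration
#'
#' Nested list understood by [run_pipeline()]. The `paper` chain profile
#' (200,000 iterations, 20,000 burn-in, thin 10) is the production setting;
#' `smoke` is a fast end-to-end profile for checks.
#'
#' @param profile `"paper"` or `"smoke"`.
#' @param seed integer seed applied to every stage.
#' @return nested configuration list.
#' @export
pipeline_config <- function(profile = c("smoke", "paper"), seed = 1L) {
  profile <- match.arg(profile)
  chain <- if (profile == "paper") {
    list(n_iterations = 200000L, burn_in = 20000L, thin = 10L)
  } else {
    list(n_iterations = 2000L, burn_in = 500L, thin = 5L)
  }
  sim <- if (profile == "paper") {
    list(n_founders = 400L, n_generations = 2L, n_cgs = 100L,
         cg_mean_size = 20)
  } else {
    list(n_founders = 60L, n_generations = 2L, n_cgs = 12L,
         cg_mean_size = 16)
  }
  list(profile = profile, seed = as.integer(seed), sim = sim, chain = chain,
       edits = list(min_cg_size = 5L, min_progeny = 3L),
       summary = list(k = 5L),
       classify = list(min_progeny = 3L, center = "mean"))
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- pipeline_config(profile = if (!is.null(config$profile))
    config$profile else "smoke",
    seed = if (!is.null(config$seed)) config$seed else 1L)
  for (sec in c("sim", "chain", "edits", "summary", "classify")) {
    if (!is.null(config[[sec]])) base[[sec]] <- utils::modifyList(base[[sec]],
                                                                  config[[sec]])
  }
  if (base$chain$burn_in >= base$chain$n_iterations) {
    stop("invalid config: burn_in must be smaller than n_iterations")
  }
  base
}

#' Run the full simulate-prep-fit-summarize-classify pipeline
#'
#' Executes the five stages in order on a synthetic population, writing all
#' tabular outputs and a JSON run manifest (config, seed, file digests,
#' per-stage wall-clock) to `out_dir`. Deterministic under a fixed seed.
#'
#' @param config nested configuration list (see [pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir output directory, created if absent.
#' @return invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_time <- c()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    stage_time[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    res
  }

  sc <- do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  ped <- tick("simulate", simulate_pedigree(sc))
  sim <- tick("simulate_phenotypes", simulate_phenotypes(ped, sc))
  write_simulation(ped, sim, out_dir)

  ed <- tick("prep", apply_edits(sim$phenotypes,
                                 min_cg_size = cfg$edits$min_cg_size,
                                 min_progeny = cfg$edits$min_progeny))
  utils::write.table(ed$records, file.path(out_dir, "phenotypes_edited.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ed$report, file.path(out_dir, "edit_report.json"),
                       auto_unbox = TRUE)

  rc <- rn_config(n_iterations = cfg$chain$n_iterations,
                  burn_in = cfg$chain$burn_in, thin = cfg$chain$thin,
                  seed = cfg$seed)
  fit <- tick("fit", fit_reaction_norm(ed$records, ped, rc))
  disp <- data.frame(fit$G, sigma2_cg = fit$sigma2_cg,
                     sigma2_pe = fit$sigma2_pe, sigma2_e = fit$sigma2_e)
  utils::write.csv(disp, file.path(out_dir, "dispersion_draws.csv"),
                   row.names = FALSE)
  loc <- data.frame(animal = colnames(fit$a),
                    a_mean = colMeans(fit$a), b_mean = colMeans(fit$b))
  utils::write.csv(loc, file.path(out_dir, "location_posterior_means.csv"),
                   row.names = FALSE)
  utils::write.csv(geweke_table(fit), file.path(out_dir, "geweke.csv"),
                   row.names = FALSE)

  gs <- tick("summarize", gradient_summary(fit, k = cfg$summary$k))
  utils::write.csv(gs$levels, file.path(out_dir, "gradient_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(gs$r_g),
                   file.path(out_dir, "genetic_correlations.csv"))

  sl <- sire_slopes(fit, ed$records, min_progeny = cfg$classify$min_progeny)
  cls <- tick("classify", classify_sires(sl, center = cfg$classify$center))
  utils::write.csv(cls, file.path(out_dir, "sire_classes.csv"),
                   row.names = FALSE)
  pc <- class_percentages(cls)
  utils::write.csv(data.frame(class = names(pc), percent = as.numeric(pc)),
                   file.path(out_dir, "class_percentages.csv"),
                   row.names = FALSE)

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(seed = cfg$seed, profile = cfg$profile, config = cfg,
                   stage_seconds = as.list(stage_time),
                   outputs = as.list(setNames(
                     unname(tools::md5sum(outputs)), basename(outputs))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
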