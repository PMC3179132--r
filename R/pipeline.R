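#' Desk-scale run configuration
#'
#' Bundles the parameters of a full imprint-and-rebind run: mixture
#' composition, thermodynamic state, equilibration length, matrix
#' realization seeds, fugacity ladder and GCMC trial counts. The defaults
#' are a desk-scale preset (a reduced system that runs in minutes); the
#' reference composition of the full model is 10 template / 80 MAA /
#' 200 EGDMA at 298 K and 1 atm.
#'
#' @param system `"MIP_PRZ"` or `"MIP_PMD"` (chooses the template; the
#'   analogue is the other diazine)
#' @param composition named molecule counts
#' @param temperature,pressure ensemble state (K, Pa)
#' @param npt_moves NPT chain length per realization
#' @param seeds matrix-realization seeds
#' @param fugacities fugacity ladder, Pa
#' @param gcmc_trials GCMC trials per isotherm point
#' @param supercell replication factor applied to each quenched matrix
#' @param scale overall composition scale factor (1 = full size)
#' @param out_dir optional output directory for stage artifacts
#' @export
run_config <- function(system = "MIP_PRZ",
                       composition = NULL,
                       temperature = 298, pressure = .const$atm_Pa,
                       npt_moves = 4e5, seeds = 1:3,
                       fugacities = c(1e-4, 1e-3),
                       gcmc_trials = 2e5, supercell = 1L, scale = 0.25,
                       out_dir = NULL) {
  template <- switch(system, MIP_PRZ = "PRZ", MIP_PMD = "PMD",
                     stop("system must be MIP_PRZ or MIP_PMD"))
  analogue <- if (template == "PRZ") "PMD" else "PRZ"
  if (is.null(composition)) {
    composition <- round(c(10, 80, 200) * scale)
    names(composition) <- c(template, "MAA", "EGDMA")
  }
  structure(list(system = system, template = template, analogue = analogue,
                 composition = composition, temperature = temperature,
                 pressure = pressure, npt_moves = npt_moves, seeds = seeds,
                 fugacities = fugacities, gcmc_trials = gcmc_trials,
                 supercell = as.integer(supercell), out_dir = out_dir),
            class = "mip_run_config")
}

#' Run the full imprinting pipeline
#'
#' Executes the three stages of the model: (1) NPT Monte Carlo
#' equilibration of the pre-polymerization mixture for each seed,
#' (2) quench and template removal giving frozen matrix realizations,
#' (3) GCMC rebinding isotherms for the template and its structural
#' analogue, followed by the binding-site census and the selectivity
#' report. Stage artifacts (snapshots as extended XYZ, isotherms and
#' census as CSV, report and provenance as JSON) are written to
#' `config$out_dir` when set; the manifest records completed stages so a
#' failed run keeps its partial artifacts.
#'
#' @param ff a [load_forcefield()] object
#' @param config a [run_config()]
#' @return list of class `mip_pipeline`: `matrices`, `isotherm_template`,
#'   `isotherm_analogue`, `census`, `selectivity`, `manifest`
#' @export
pipeline_run <- function(ff, config = run_config()) {
  manifest <- list(system = config$system, stages = character(0),
                   seeds = config$seeds)
  out <- list(config = config)
  emit <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    if (!is.null(config$out_dir))
      write_provenance(manifest, file.path(config$out_dir, "manifest.json"))
  }
  if (!is.null(config$out_dir))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1-2: mixture equilibration and quench, one matrix per seed
  total_mass <- sum(vapply(names(config$composition), function(s)
    ff$species[[s]]$mass, 1) * config$composition)
  box0 <- (total_mass / .const$N_A / 650 * 1e27)^(1 / 3)  # loose start box
  out$matrices <- lapply(config$seeds, function(s) {
    cfg <- build_initial_configuration(ff, config$composition, box0, seed = s,
                                       overlap_factor = 0.72,
                                       max_attempts = 30000,
                                       temperature = config$temperature,
                                       pressure = config$pressure)
    eq <- equilibrate_npt(cfg, npt_schedule(temperature = config$temperature,
                                            pressure = config$pressure,
                                            n_moves = config$npt_moves,
                                            seed = s))
    m <- quench_and_remove(eq$config, config$template, realization = s)
    if (config$supercell > 1)
      m <- replicate_supercell(m, rep(config$supercell, 3))
    if (!is.null(config$out_dir))
      write_xyz(m, file.path(config$out_dir,
                             sprintf("matrix_%s_r%d.xyz", config$system, s)))
    m
  })
  emit("mixture+quench")

  # stage 3: rebinding isotherms for template and analogue
  iso_t <- isotherm(out$matrices, ff$species[[config$template]],
                    config$fugacities, n_trials = config$gcmc_trials,
                    seed = 10 * config$seeds[1])
  iso_a <- isotherm(out$matrices, ff$species[[config$analogue]],
                    config$fugacities, n_trials = config$gcmc_trials,
                    seed = 20 * config$seeds[1])
  out$isotherm_template <- iso_t
  out$isotherm_analogue <- iso_a
  if (!is.null(config$out_dir)) {
    utils::write.csv(iso_t, file.path(config$out_dir, "isotherm_template.csv"),
                     row.names = FALSE)
    utils::write.csv(iso_a, file.path(config$out_dir, "isotherm_analogue.csv"),
                     row.names = FALSE)
  }
  emit("adsorption")

  # census on the snapshots of the lowest-fugacity template runs
  runs <- attr(iso_t, "runs")
  cfgs <- list()
  for (r in seq_along(runs)) {
    g <- runs[[r]][[1]]
    if (g$final_nmol > 0 || length(g$snapshots))
      cfgs <- c(cfgs, gcmc_configurations(g, out$matrices[[r]],
                                          ff$species[[config$template]]))
  }
  cfgs <- Filter(function(cfg) any(cfg$species == config$template), cfgs)
  out$census <- if (length(cfgs)) site_census(cfgs) else NULL
  if (!is.null(config$out_dir) && !is.null(out$census))
    utils::write.csv(out$census, file.path(config$out_dir, "census.csv"),
                     row.names = FALSE)
  emit("census")

  out$selectivity <- separation_factor(iso_t, iso_a, config$fugacities[1],
                                       temperature = config$temperature,
                                       volume = out$matrices[[1]]$box^3)
  if (!is.null(config$out_dir))
    write_provenance(list(S = out$selectivity$S, f = out$selectivity$f,
                          lower_bound = out$selectivity$lower_bound),
                     file.path(config$out_dir, "selectivity.json"))
  emit("report")
  class(out) <- "mip_pipeline"
  out
}

#' @export
print.mip_pipeline <- function(x, ...) {
  cat("Pipeline", x$config$system, "- stages complete\n")
  cat(sprintf("Template loading at f=%g Pa: %.4g molecules\n",
              x$isotherm_template$f[1], x$isotherm_template$loading[1]))
  print(x$selectivity)
  invisible(x)
}
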