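#' NPT Monte Carlo schedule
#'
#' Move mix and chain length for isothermal-isobaric Metropolis Monte Carlo
#' of the liquid mixture: molecular translations, rigid rotations and
#' torsion rotations for flexible species, plus log-volume moves (one per
#' `vol_every` particle moves). Maximum displacements are auto-tuned to a
#' 30-50% acceptance window during the tuning window only, so the
#' production chain satisfies detailed balance.
#'
#' @param temperature temperature, K
#' @param pressure pressure, Pa
#' @param n_moves total Monte Carlo moves
#' @param vol_every attempt one volume move per this many moves
#'   (`NA` = one per molecule count)
#' @param equil_fraction fraction of the chain treated as equilibration
#'   (step tuning happens only there)
#' @param step_translate,step_rotate,step_torsion,step_lnv initial maximum
#'   displacements (Angstrom / rad / rad / dimensionless)
#' @param sample_every record the density trace every this many moves
#' @param seed RNG seed
#' @export
npt_schedule <- function(temperature = 298, pressure = .const$atm_Pa,
                         n_moves = 2e5, vol_every = NA,
                         equil_fraction = 0.5,
                         step_translate = 0.3, step_rotate = 0.3,
                         step_torsion = 0.4, step_lnv = 0.02,
                         sample_every = 500, seed = 1) {
  stopifnot(temperature > 0, pressure > 0, equil_fraction >= 0,
            equil_fraction <= 1)
  structure(list(temperature = temperature, pressure = pressure,
                 n_moves = n_moves, vol_every = vol_every,
                 equil_fraction = equil_fraction,
                 step_translate = step_translate, step_rotate = step_rotate,
                 step_torsion = step_torsion, step_lnv = step_lnv,
                 sample_every = sample_every, seed = seed),
            class = "mip_npt_schedule")
}

#' Equilibrate a mixture in the NPT ensemble
#'
#' Metropolis Monte Carlo sampling of the isothermal-isobaric ensemble:
#' the stationary distribution is proportional to
#' `V^N exp(-beta U - beta P V)`. Electrostatics use the damped
#' shifted-force pair potential; Lennard-Jones interactions are truncated
#' (at most half the box edge, at most the 14 Angstrom liquid-stage
#' cutoff) with analytic long-tail corrections. Volume moves that would
#' shrink the box below twice the cutoff are rejected, so the cutoff is
#' chosen from the expected equilibrium edge.
#'
#' @param config starting `mip_configuration`
#' @param schedule an [npt_schedule()]
#' @param cutoff LJ/Coulomb cutoff, Angstrom (`NA`: automatic from the
#'   expected liquid density of about 1 kg/L)
#' @param ideal_gas if `TRUE`, all interactions are switched off (test mode)
#' @return list of class `mip_npt`: `config` (final configuration),
#'   `trace` (data.frame with move index, volume, density g/L, energy),
#'   `density`, `density_se` (block standard error), `acceptance`
#' @export
equilibrate_npt <- function(config, schedule = npt_schedule(),
                            cutoff = NA, ideal_gas = FALSE) {
  set.seed(schedule$seed)
  fl <- flat_config(config)
  topo <- config$topologies
  sp_names <- unique(config$species)
  sp_info <- lapply(sp_names, function(s) species_cpp(topo[[s]]))
  mol_sp <- match(config$species, sp_names) - 1L
  total_mass <- sum(fl$mass)
  if (is.na(cutoff)) {
    # expected edge if the liquid lands near 1.05 kg/L
    L_eq <- (total_mass / .const$N_A / 1050 * 1e27)^(1 / 3)
    cutoff <- min(.const$cutoff_mixture, 0.48 * L_eq)
  }
  vol_every <- if (is.na(schedule$vol_every)) max(1L, n_molecules(config))
               else as.integer(schedule$vol_every)
  P_internal <- schedule$pressure * 1e-30 * .const$N_A / 1000  # Pa -> kJ/mol/A^3
  res <- cpp_npt(fl$xyz, sp_info, mol_sp, config$box,
                 schedule$temperature, P_internal,
                 schedule$n_moves, vol_every, cutoff, cutoff,
                 .const$dsf_alpha,
                 schedule$step_translate, schedule$step_rotate,
                 schedule$step_torsion, schedule$step_lnv,
                 schedule$n_moves * schedule$equil_fraction,
                 as.integer(schedule$sample_every), ideal_gas)
  acc <- setNames(res$acc, c("translate", "rotate", "torsion", "volume"))
  ok <- acc[!is.na(acc)]
  if (length(ok) && (any(ok < 0.05) || any(ok > 0.95)))
    warning("pathological acceptance rate(s): ",
            paste(sprintf("%s=%.2f", names(ok), ok), collapse = ", "),
            "; consider adjusting step sizes")
  ns <- vapply(config$coords, nrow, 1L)
  coords <- split_rows(res$xyz, ns)
  out_cfg <- mip_configuration(topo, config$species, coords, box = res$box,
                               temperature = schedule$temperature,
                               pressure = schedule$pressure,
                               provenance = c(config$provenance,
                                              list(npt_seed = schedule$seed,
                                                   n_moves = schedule$n_moves,
                                                   electrostatics = "dsf",
                                                   cutoff = cutoff)))
  dens <- total_mass / .const$N_A / (res$v_trace * 1e-27)
  trace <- data.frame(
    move = seq_along(res$v_trace) * schedule$sample_every,
    volume = res$v_trace, density = dens, energy = res$u_trace)
  prod <- trace[trace$move > schedule$equil_fraction * schedule$n_moves, ]
  est <- block_mean_se(prod$density, nblocks = 5)
  structure(list(config = out_cfg, trace = trace,
                 density = est$mean, density_se = est$se,
                 acceptance = acc, steps = res$steps,
                 stationary = stationarity_ok(prod$density)),
            class = "mip_npt")
}

split_rows <- function(m, ns) {
  off <- c(0L, cumsum(ns))
  lapply(seq_along(ns), function(i) m[(off[i] + 1):off[i + 1], , drop = FALSE])
}

block_mean_se <- function(x, nblocks = 5) {
  if (!length(x)) return(list(mean = NA_real_, se = NA_real_))
  b <- split(x, cut(seq_along(x), nblocks, labels = FALSE))
  bm <- vapply(b, mean, 1)
  list(mean = mean(x), se = sd(bm) / sqrt(length(bm)))
}

# crude stationarity check: first and second half block means agree
# within 3 combined standard errors
stationarity_ok <- function(x) {
  if (length(x) < 10) return(NA)
  h <- length(x) %/% 2
  a <- block_mean_se(x[1:h], 3); b <- block_mean_se(x[(h + 1):length(x)], 3)
  if (!is.finite(a$se) || !is.finite(b$se)) return(NA)
  abs(a$mean - b$mean) <= 3 * sqrt(a$se^2 + b$se^2 + 1e-12)
}

#' @export
print.mip_npt <- function(x, ...) {
  cat(sprintf("NPT Monte Carlo: final box %.2f A, density %.1f +/- %.1f g/L\n",
              x$config$box, x$density, x$density_se))
  cat("Acceptance:", paste(sprintf("%s=%.2f", names(x$acceptance),
                                   x$acceptance), collapse = " "), "\n")
  invisible(x)
}

#' Equilibrate the full mixture over independent repeats
#'
#' Runs [equilibrate_npt()] from independently built initial
#' configurations for several seeds and reports the density averaged with
#' its standard error of the mean, the reporting convention used
#' throughout the package.
#'
#' @param ff force field
#' @param composition named molecule counts
#' @param box_edge initial box edge, Angstrom
#' @param seeds integer vector of seeds (one run each)
#' @param schedule template [npt_schedule()] (its seed is replaced per run)
#' @param ... passed to [equilibrate_npt()]
#' @return list with `runs`, `density` (mean over seeds) and `density_sem`
#' @export
equilibrate_mixture <- function(ff, composition, box_edge,
                                seeds = 1:3, schedule = npt_schedule(), ...) {
  runs <- lapply(seeds, function(s) {
    cfg <- build_initial_configuration(ff, composition, box_edge, seed = s)
    sch <- schedule; sch$seed <- s
    equilibrate_npt(cfg, sch, ...)
  })
  d <- vapply(runs, function(r) r$density, 1)
  list(runs = runs, density = mean(d),
       density_sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_)
}
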