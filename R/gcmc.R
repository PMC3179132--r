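#' Thermodynamic state of the adsorbing species
#'
#' Connects fugacity and chemical potential through the ideal-gas relation
#' `f / (kB T) = (q_rot / Lambda^3) exp(mu / kB T)`, where `Lambda` is the
#' thermal de Broglie wavelength and `q_rot` the classical rigid-rotor
#' rotational partition function (computed from the topology's principal
#' moments of inertia and rotational symmetry number). Exactly one of `f`
#' and `mu` must be given; the other is filled in. `q_rot` cancels from
#' fixed-fugacity GCMC acceptance rules, so it only matters for reporting
#' `mu`.
#'
#' @param adsorbate a `mip_topology` (rigid species)
#' @param temperature temperature, K
#' @param f fugacity, Pa
#' @param mu chemical potential, kJ/mol
#' @return object of class `mip_thermo_state` with `f` (Pa), `mu` (kJ/mol),
#'   `lambda` (m), `q_rot`, `temperature`
#' @export
#' @examples
#' ff <- load_forcefield()
#' st <- fugacity_mu_convert(ff$species$PRZ, 298, f = 0.1)
#' st$mu
fugacity_mu_convert <- function(adsorbate, temperature, f = NULL, mu = NULL) {
  if (is.null(f) == is.null(mu))
    stop("give exactly one of f and mu")
  if (!is.null(f) && f <= 0) stop("fugacity must be positive")
  kT <- .const$kB_SI * temperature                      # J
  m_kg <- adsorbate$mass / 1000 / .const$N_A
  lambda <- .const$h_SI / sqrt(2 * pi * m_kg * kT)      # m
  qrot <- rigid_rotor_qrot(adsorbate, temperature)
  if (is.null(mu)) {
    mu_J <- kT * log(f * lambda^3 / (qrot * kT))
    mu <- mu_J * .const$N_A / 1000                      # kJ/mol
  } else {
    mu_J <- mu * 1000 / .const$N_A
    f <- qrot / lambda^3 * kT * exp(mu_J / kT)
  }
  structure(list(f = f, mu = mu, lambda = lambda, q_rot = qrot,
                 temperature = temperature, adsorbate = adsorbate$name),
            class = "mip_thermo_state")
}

rigid_rotor_qrot <- function(tp, temperature) {
  m <- tp$atoms$mass / 1000 / .const$N_A                # kg
  xyz <- tp$xyz * 1e-10                                 # m
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_along(m)) {
    ri <- r[i, ]
    I <- I + m[i] * (sum(ri^2) * diag(3) - outer(ri, ri))
  }
  Iabc <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  Iabc[Iabc < 1e-60] <- 1e-60
  kT <- .const$kB_SI * temperature
  sqrt(pi) / tp$symmetry_number *
    (8 * pi^2 * kT / .const$h_SI^2)^(3 / 2) * sqrt(prod(Iabc))
}

# ideal-gas number density of the reservoir, 1/A^3
ideal_gas_density <- function(f, temperature)
  f * 1e-30 / (.const$kB_SI * temperature)

#' Build adsorbate-matrix interaction maps
#'
#' Precomputes, on a regular grid over the frozen matrix cell, one
#' Lennard-Jones energy grid per distinct adsorbate atom type (potentials
#' cut at 10.6 Angstrom, no corrections) and one electrostatic potential
#' grid from a standard Ewald summation (multiplied by the atom charge at
#' use time). The maps both bias insertion/deletion trials and provide the
#' adsorbate-matrix energies via periodic trilinear interpolation.
#'
#' @param matrix a `mip_matrix`
#' @param adsorbate a rigid `mip_topology`
#' @param spacing target grid spacing, Angstrom (a warning is issued above
#'   1 Angstrom, where the bias and interpolation quality degrade)
#' @param rc_lj LJ cutoff, Angstrom
#' @param cap upper clamp on stored LJ grid values, kJ/mol
#' @param accuracy Ewald accuracy target
#' @return object of class `mip_energy_map`
#' @export
build_energy_maps <- function(matrix, adsorbate, spacing = 0.4,
                              rc_lj = .const$cutoff_gcmc, cap = 1e5,
                              accuracy = 1e-4) {
  stopifnot(inherits(matrix, "mip_configuration"))
  if (!isTRUE(matrix$frozen)) stop("energy maps need a frozen matrix")
  if (spacing > 1) warning("grid spacing above 1 A degrades the insertion bias")
  fl <- flat_config(matrix)
  L <- matrix$box
  rc_lj <- min(rc_lj, L / 2)   # minimum-image convention
  ngrid <- max(4L, as.integer(ceiling(L / spacing)))
  key <- paste(adsorbate$atoms$sigma, adsorbate$atoms$epsilon)
  types <- match(key, unique(key))
  lj_grids <- lapply(unique(types), function(t) {
    i <- which(types == t)[1]
    cpp_lj_grid(fl$xyz, fl$sigma, fl$epsilon, L, ngrid,
                adsorbate$atoms$sigma[i], adsorbate$atoms$epsilon[i],
                rc_lj, cap)
  })
  phi <- numeric(1)
  if (any(fl$q != 0)) {
    rcut <- min(L / 2, 12)
    s <- sqrt(-log(accuracy))
    alpha <- s / rcut
    kmax <- as.integer(ceiling(s * alpha * L / pi))
    phi <- cpp_ewald_potential_grid(fl$xyz, fl$q, L, ngrid, alpha, rcut, kmax)
  }
  structure(list(lj_grids = lj_grids, type_of_atom = types - 1L, phi = phi,
                 ngrid = ngrid, box = L, spacing = L / ngrid,
                 adsorbate = adsorbate$name, rc_lj = rc_lj),
            class = "mip_energy_map")
}

#' Evaluate maps at arbitrary points (interpolated adsorbate-matrix energy)
#'
#' @param maps a [build_energy_maps()] object
#' @param xyz coordinates of a single adsorbate molecule (n_atoms x 3)
#' @param charges adsorbate charges (e), in topology order
#' @return list with `lj` and `coul` energies, kJ/mol
#' @export
map_energy <- function(maps, xyz, charges) {
  lj <- sum(vapply(seq_len(nrow(xyz)), function(i)
    cpp_interp_grid(maps$lj_grids[[maps$type_of_atom[i] + 1]], maps$box,
                    xyz[i, , drop = FALSE]), 1))
  coul <- 0
  if (length(maps$phi) > 1)
    coul <- sum(charges * cpp_interp_grid(maps$phi, maps$box, xyz))
  list(lj = lj, coul = coul, total = lj + coul)
}

# insertion-bias tables from the combined LJ maps
bias_tables <- function(maps, temperature, cubelet = 2.0, floor_frac = 0.01,
                        t_bias = NULL) {
  ng <- maps$ngrid; L <- maps$box
  ncub <- max(2L, min(ng, as.integer(floor(L / cubelet))))
  umin <- Reduce(pmin, maps$lj_grids)
  # fine node -> cubelet index (0-based, x fastest)
  ix <- as.integer(floor((seq_len(ng) - 1) * ncub / ng))
  cub <- rep(ix, times = ng * ng) +
    ncub * rep(rep(ix, each = ng), times = ng) +
    ncub * ncub * rep(ix, each = ng * ng)
  uc <- tapply(as.vector(umin), cub, min)
  uc <- uc[order(as.integer(names(uc)))]
  Tb <- if (is.null(t_bias)) temperature else t_bias
  w <- exp(-pmin(pmax(uc, -60), 60) / (.const$kB * Tb))
  p <- w / sum(w)
  p <- pmax(p, floor_frac / length(p))
  p <- p / sum(p)
  list(p = as.numeric(p), cum = cumsum(as.numeric(p)), ncub = ncub,
       vcell = (L / ncub)^3)
}

#' Grand canonical Monte Carlo adsorption in a frozen matrix
#'
#' Metropolis GCMC of a rigid adsorbate at fixed fugacity, volume and
#' temperature. Insertions, deletions, translations and rotations are
#' selected with equal probability; insertions are energy-biased towards
#' attractive cubelets of the cell (the exact inverse bias weight enters
#' the acceptance probability, so the sampled distribution is unchanged).
#' Adsorbate-matrix energies come from the interaction maps;
#' adsorbate-adsorbate interactions use LJ plus damped shifted-force
#' Coulomb, both cut at 10.6 Angstrom. The first half of the trials is
#' discarded as equilibration. `interactions = "LJ_only"` switches off all
#' charges (the dispersion-only control).
#'
#' @param matrix a `mip_matrix`
#' @param adsorbate a rigid `mip_topology`
#' @param f fugacity, Pa
#' @param temperature temperature, K
#' @param n_trials number of GCMC trials
#' @param seed RNG seed
#' @param interactions `"both"` or `"LJ_only"`
#' @param maps optional precomputed [build_energy_maps()] (built on the
#'   fly otherwise); must match `matrix` and `adsorbate`
#' @param bias logical: energy-biased insertions?
#' @param step_translate,step_rotate maximum displacements (Angstrom, rad)
#' @param sample_every sampling stride (trials) in the production half
#' @param n_snapshots number of full adsorbate snapshots to keep
#' @param warm_start a previous `mip_gcmc` result to continue from
#' @param rc_aa adsorbate-adsorbate cutoff, Angstrom
#' @return object of class `mip_gcmc` with `loading` (molecules),
#'   `loading_molg` (mol per gram of matrix), `loading_se`, `energy_samples`
#'   (data.frame of per-molecule adsorbate-matrix LJ/Coulomb energies),
#'   `snapshots`, `acceptance`, `n_trace`
#' @export
run_gcmc <- function(matrix, adsorbate, f, temperature = 298,
                     n_trials = 1e6, seed = 1,
                     interactions = c("both", "LJ_only"),
                     maps = NULL, bias = TRUE,
                     step_translate = 1.0, step_rotate = 0.6,
                     sample_every = 1000, n_snapshots = 20,
                     warm_start = NULL, rc_aa = .const$cutoff_gcmc) {
  interactions <- match.arg(interactions)
  stopifnot(inherits(matrix, "mip_configuration"), isTRUE(matrix$frozen))
  if (f <= 0) stop("fugacity must be positive")
  if (is.null(maps)) maps <- build_energy_maps(matrix, adsorbate)
  if (!identical(maps$adsorbate, adsorbate$name) ||
      abs(maps$box - matrix$box) > 1e-9)
    stop("maps do not match this matrix/adsorbate")
  set.seed(seed)
  if (matrix$box < 2 * rc_aa) rc_aa <- matrix$box / 2
  local <- sweep(adsorbate$xyz, 2, colMeans(adsorbate$xyz))  # geometric center
  bt <- if (bias) bias_tables(maps, temperature)
        else list(p = numeric(1), cum = numeric(1), ncub = 1L, vcell = 0)
  init_xyz <- matrix(0, 0, 3); init_n <- 0L
  if (!is.null(warm_start)) {
    init_xyz <- warm_start$final_xyz; init_n <- warm_start$final_nmol
  }
  zz <- ideal_gas_density(f, temperature)
  lj_only <- interactions == "LJ_only"
  res <- cpp_gcmc(maps$lj_grids, maps$type_of_atom,
                  if (lj_only) numeric(1) else maps$phi, matrix$box,
                  local, adsorbate$atoms$sigma, adsorbate$atoms$epsilon,
                  adsorbate$atoms$charge, temperature, zz, n_trials, rc_aa,
                  .const$dsf_alpha, bt$cum, bt$ncub, bt$vcell, bt$p,
                  lj_only, step_translate, step_rotate,
                  as.integer(sample_every), as.integer(n_snapshots),
                  init_xyz, init_n)
  est <- block_mean_se(res$n_trace, 5)
  mass_g <- if (!is.null(matrix$mass_g)) matrix$mass_g else NA_real_
  structure(list(
    loading = res$avg_N, loading_se = est$se,
    loading_molg = res$avg_N / .const$N_A / mass_g,
    loading_molg_se = est$se / .const$N_A / mass_g,
    f = f, temperature = temperature, adsorbate = adsorbate$name,
    interactions = interactions,
    energy_samples = data.frame(lj = res$sample_lj, coul = res$sample_coul,
                                total = res$sample_lj + res$sample_coul),
    snapshots = res$snapshots, n_trace = res$n_trace,
    final_xyz = res$final_xyz, final_nmol = res$final_nmol,
    acceptance = setNames(res$acc, c("insert", "delete", "translate", "rotate")),
    seed = seed, n_trials = n_trials),
    class = "mip_gcmc")
}

#' @export
print.mip_gcmc <- function(x, ...) {
  cat(sprintf("GCMC %s at f = %g Pa, %g trials: <N> = %.4f +/- %.4f\n",
              x$adsorbate, x$f, x$n_trials, x$loading,
              ifelse(is.na(x$loading_se), 0, x$loading_se)))
  if (is.finite(x$loading_molg))
    cat(sprintf("  loading %.3e mol/g (%s)\n", x$loading_molg, x$interactions))
  invisible(x)
}

#' Adsorption isotherm over a fugacity ladder
#'
#' Runs [run_gcmc()] along a strictly increasing fugacity ladder, using the
#' final configuration at each fugacity as the initial configuration for
#' the next, for each matrix realization; loadings are averaged across
#' realizations with the standard error of the mean.
#'
#' @param matrices a `mip_matrix` or list of matrix realizations
#' @param adsorbate a rigid `mip_topology`
#' @param fugacities strictly increasing fugacity ladder, Pa
#' @param n_trials trials per point
#' @param seed base RNG seed (offset per realization and point)
#' @param ... passed to [run_gcmc()]
#' @return data.frame of class `mip_isotherm` with one row per fugacity:
#'   `f`, `loading` (molecules), `loading_molg`, `sem`, plus per-run
#'   results in `attr(, "runs")`
#' @export
isotherm <- function(matrices, adsorbate, fugacities, n_trials = 1e5,
                     seed = 1, ...) {
  if (inherits(matrices, "mip_configuration")) matrices <- list(matrices)
  if (any(diff(fugacities) <= 0)) stop("fugacity ladder must be strictly increasing")
  runs <- list()
  per_real <- lapply(seq_along(matrices), function(r) {
    maps <- build_energy_maps(matrices[[r]], adsorbate)
    warm <- NULL
    out <- vector("list", length(fugacities))
    for (k in seq_along(fugacities)) {
      out[[k]] <- run_gcmc(matrices[[r]], adsorbate, fugacities[k],
                           n_trials = n_trials, maps = maps,
                           seed = seed + 1000 * r + k, warm_start = warm, ...)
      warm <- out[[k]]
    }
    out
  })
  tab <- do.call(rbind, lapply(seq_along(fugacities), function(k) {
    N <- vapply(per_real, function(rr) rr[[k]]$loading, 1)
    Ng <- vapply(per_real, function(rr) rr[[k]]$loading_molg, 1)
    data.frame(f = fugacities[k], loading = mean(N),
               loading_molg = mean(Ng),
               sem = if (length(N) > 1) sd(N) / sqrt(length(N)) else
                 per_real[[1]][[k]]$loading_se)
  }))
  attr(tab, "runs") <- per_real
  attr(tab, "adsorbate") <- adsorbate$name
  class(tab) <- c("mip_isotherm", "data.frame")
  tab
}

#' Reconstruct full configurations from GCMC snapshots
#'
#' Combines the frozen matrix with the adsorbate coordinates stored in a
#' GCMC snapshot so the binding-site classifier can be applied to
#' adsorption configurations.
#'
#' @param result a `mip_gcmc` object with snapshots
#' @param matrix the matrix the run used
#' @param adsorbate the adsorbate topology
#' @return list of `mip_configuration` objects
#' @export
gcmc_configurations <- function(result, matrix, adsorbate) {
  na <- nrow(adsorbate$atoms)
  lapply(result$snapshots, function(sm) {
    nm <- nrow(sm) / na
    coords <- c(matrix$coords,
                if (nm > 0) split_rows(sm, rep(na, nm)) else list())
    species <- c(matrix$species, rep(adsorbate$name, nm))
    topo <- matrix$topologies
    if (is.null(topo[[adsorbate$name]])) topo[[adsorbate$name]] <- adsorbate
    mip_configuration(topo, species, coords, box = matrix$box,
                      temperature = result$temperature)
  })
}
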