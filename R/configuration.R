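#' Create a periodic configuration of molecules
#'
#' A configuration holds a cubic periodic box (edge in Angstrom, `NA` for an
#' isolated, non-periodic system), a vector of species names (one per
#' molecule), a list of per-molecule atom coordinate matrices, and the
#' topology catalogue the molecules refer to. Molecule coordinates are
#' stored unwrapped so molecules stay whole; use [wrap_configuration()] for
#' wrapped output.
#'
#' @param ff a [load_forcefield()] object (or a named topology list)
#' @param species character vector of species names, one per molecule
#' @param coords list of numeric matrices (n_atoms x 3), one per molecule
#' @param box cubic box edge, Angstrom (`NA` = non-periodic)
#' @param temperature,pressure ensemble tags (K, Pa)
#' @param frozen logical: is this an immutable quenched matrix?
#' @param provenance free-form list recorded with the object
#' @return an object of class `mip_configuration`
#' @export
mip_configuration <- function(ff, species = character(), coords = list(),
                              box = NA_real_, temperature = 298, pressure = NA,
                              frozen = FALSE, provenance = list()) {
  topo <- if (inherits(ff, "mip_forcefield")) ff$species else ff
  stopifnot(length(species) == length(coords))
  for (i in seq_along(species)) {
    tp <- topo[[species[i]]]
    if (is.null(tp)) stop("unknown species: ", species[i])
    if (nrow(coords[[i]]) != nrow(tp$atoms))
      stop("molecule ", i, " atom count does not match topology ", species[i])
    if (!all(is.finite(coords[[i]]))) stop("non-finite coordinates in molecule ", i)
  }
  x <- list(box = box, species = species, coords = coords,
            topologies = topo[unique(c(species, names(topo)))],
            temperature = temperature, pressure = pressure,
            frozen = frozen, provenance = provenance)
  class(x) <- "mip_configuration"
  x
}

#' Number of molecules in a configuration
#' @param config a `mip_configuration`
#' @export
n_molecules <- function(config) length(config$species)

#' @export
print.mip_configuration <- function(x, ...) {
  tab <- table(x$species)
  cat(if (isTRUE(x$frozen)) "Frozen matrix" else "Configuration", "-",
      length(x$species), "molecules",
      if (!is.na(x$box)) sprintf("in a %.2f A cubic box", x$box) else "(non-periodic)",
      "\n")
  if (length(tab)) print(tab)
  invisible(x)
}

#' @export
summary.mip_configuration <- function(object, ...) {
  cat("Molecules:", length(object$species), " Atoms:",
      sum(vapply(object$coords, nrow, 1L)), "\n")
  if (!is.na(object$box)) {
    cat(sprintf("Box edge: %.3f A,  density: %.1f g/L\n",
                object$box, density(object)))
  }
  invisible(object)
}

# Flatten a configuration to the arrays the compiled kernels consume.
# Exclusion pairs are intramolecular pairs separated by 1-3 bonds.
flat_config <- function(config) {
  ns <- vapply(config$coords, nrow, 1L)
  natoms <- sum(ns)
  xyz <- if (natoms) do.call(rbind, config$coords) else matrix(numeric(0), 0, 3)
  topo <- config$topologies
  sig <- eps <- q <- mass <- numeric(natoms)
  mol <- integer(natoms)
  excl_i <- excl_j <- integer(0)
  off <- 0L
  # cache per-species exclusion pair lists
  excl_cache <- lapply(topo, function(tp) {
    w <- which(tp$excl == 1L & upper.tri(tp$excl), arr.ind = TRUE)
    w
  })
  for (m in seq_along(config$species)) {
    tp <- topo[[config$species[m]]]
    n <- nrow(tp$atoms)
    idx <- off + seq_len(n)
    sig[idx] <- tp$atoms$sigma
    eps[idx] <- tp$atoms$epsilon
    q[idx] <- tp$atoms$charge
    mass[idx] <- tp$atoms$mass
    mol[idx] <- m
    w <- excl_cache[[config$species[m]]]
    if (nrow(w)) {
      excl_i <- c(excl_i, off + w[, 1])
      excl_j <- c(excl_j, off + w[, 2])
    }
    off <- off + n
  }
  list(xyz = xyz, sigma = sig, epsilon = eps, q = q, mass = mass, mol = mol,
       excl_i = as.integer(excl_i), excl_j = as.integer(excl_j),
       mstart = c(0L, cumsum(ns))[seq_along(ns)], natoms = natoms)
}

# species description list for the compiled MC engines
species_cpp <- function(tp) {
  list(sigma = tp$atoms$sigma, epsilon = tp$atoms$epsilon,
       charge = tp$atoms$charge, mass = tp$atoms$mass,
       rigid = tp$rigid, excl = tp$excl,
       rotatable = if (is.null(tp$rotatable)) list() else
         lapply(tp$rotatable, function(r)
           list(axis = as.integer(unlist(r$axis)),
                moving = as.integer(unlist(r$moving)),
                dihedral = as.integer(unlist(r$dihedral)),
                c = as.numeric(unlist(r$c)))))
}

#' Wrap molecule centers into the primary cell
#'
#' Shifts every molecule by a lattice vector so its center of mass lies in
#' `[0, L)`; atoms within a molecule keep their relative positions, so
#' molecules are never broken across the boundary.
#'
#' @param config a periodic `mip_configuration`
#' @export
wrap_configuration <- function(config) {
  L <- config$box
  if (is.na(L)) return(config)
  config$coords <- lapply(seq_along(config$coords), function(m) {
    xyz <- config$coords[[m]]
    tp <- config$topologies[[config$species[m]]]
    com <- colSums(xyz * tp$atoms$mass) / sum(tp$atoms$mass)
    shift <- -floor(com / L) * L
    sweep(xyz, 2, shift, `+`)
  })
  config
}

#' Mass density of a configuration
#'
#' Total united-atom mass over the box volume, in g/L. Registered as a
#' method for the [stats::density()] generic.
#'
#' @param x a periodic `mip_configuration`
#' @param ... ignored
#' @export
#' @examples
#' ff <- load_forcefield()
#' cfg <- mip_configuration(ff, "PRZ", list(ff$species$PRZ$xyz + 5), box = 10)
#' density(cfg)  # ~133 g/L
density.mip_configuration <- function(x, ...) {
  if (is.na(x$box) || x$box <= 0) stop("density needs a periodic box")
  m <- sum(vapply(x$species, function(s) x$topologies[[s]]$mass, 1))
  v_l <- x$box^3 * 1e-27   # A^3 -> litres
  m / .const$N_A / v_l
}

#' Interaction energy between one group of molecules and the rest
#'
#' Cross LJ + Coulomb energy between the atoms of the selected molecules
#' and all remaining atoms, with the adsorption-stage conventions by
#' default (10.6 Angstrom cutoffs, damped shifted-force Coulomb).
#'
#' @param config a `mip_configuration`
#' @param molecules integer indices of the molecules forming the group
#' @param rc cutoff, Angstrom
#' @param electrostatics `"dsf"` or `"bare"`
#' @return list with `lj`, `coul`, `total` (kJ/mol)
#' @export
group_energy <- function(config, molecules, rc = .const$cutoff_gcmc,
                         electrostatics = c("dsf", "bare")) {
  electrostatics <- match.arg(electrostatics)
  fl <- flat_config(config)
  grp <- fl$mol %in% molecules
  box <- if (is.na(config$box)) -1 else config$box
  cpp_group_energy(fl$xyz, fl$sigma, fl$epsilon, fl$q, grp, box, rc, rc,
                   if (electrostatics == "dsf") 2L else 1L, .const$dsf_alpha)
}
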