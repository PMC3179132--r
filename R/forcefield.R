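#' @useDynLib mipsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats sd setNames aggregate density pnorm runif rnorm approx
#' @importFrom graphics hist
#' @importFrom utils head modifyList
NULL

# Internal physical constants (Angstrom / kJ mol^-1 / elementary charge / K)
.const <- list(
  coulomb_k = 1389.35457644382,  # 1/(4 pi eps0) in kJ A mol^-1 e^-2
  kB        = 0.008314462618,    # molar Boltzmann constant, kJ mol^-1 K^-1
  R         = 8.314462618,       # J mol^-1 K^-1
  kB_SI     = 1.380649e-23,      # J K^-1
  h_SI      = 6.62607015e-34,    # J s
  N_A       = 6.02214076e23,
  atm_Pa    = 101325,
  cutoff_mixture = 14.0,
  cutoff_gcmc    = 10.6,
  dsf_alpha      = 0.2
)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# NeRF placement: new atom bonded to cpos at distance r, with
# angle(new, cpos, bpos) = theta and dihedral(new, cpos, bpos, apos) = phi
place_atom <- function(apos, bpos, cpos, r, theta, phi) {
  bc <- cpos - bpos
  bc <- bc / sqrt(sum(bc^2))
  ab <- bpos - apos
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  cpos + d[1] * bc + d[2] * m + d[3] * n
}

build_geometry <- function(geom, natoms) {
  xyz <- matrix(NA_real_, natoms, 3)
  if (identical(geom$type, "hexagon")) {
    # ideal aromatic hexagon: ring bond length = circumradius
    r <- geom$bond
    ang <- (seq_len(natoms) - 1) * pi / 3
    xyz <- cbind(r * cos(ang), r * sin(ang), rep(0, natoms))
    return(xyz)
  }
  if (!identical(geom$type, "zmat"))
    stop("unknown geometry type: ", geom$type)
  for (entry in geom$zmat) {
    entry <- as.numeric(entry)
    i <- entry[1]
    if (length(entry) == 1) {
      xyz[i, ] <- c(0, 0, 0)
    } else if (length(entry) == 3) {
      xyz[i, ] <- xyz[entry[2], ] + c(entry[3], 0, 0)
    } else if (length(entry) == 5) {
      b <- xyz[entry[2], ]; aref <- xyz[entry[4], ]
      u <- aref - b; u <- u / sqrt(sum(u^2))
      v <- cross3(u, c(0, 0, 1))
      if (sum(v^2) < 1e-8) v <- cross3(u, c(0, 1, 0))
      v <- v / sqrt(sum(v^2))
      th <- entry[5] * pi / 180
      xyz[i, ] <- b + entry[3] * (cos(th) * u + sin(th) * v)
    } else {
      xyz[i, ] <- place_atom(xyz[entry[6], ], xyz[entry[4], ], xyz[entry[2], ],
                             entry[3], entry[5] * pi / 180, entry[7] * pi / 180)
    }
  }
  if (anyNA(xyz)) stop("incomplete z-matrix geometry")
  xyz
}

bond_graph_distances <- function(bonds, n) {
  # BFS shortest path (in bonds) between all atom pairs
  adj <- vector("list", n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (d[s, w] > d[s, v] + 1) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

#' Load the united-atom force field and molecule topologies
#'
#' Reads the packaged parameter file holding Lennard-Jones parameters
#' (sigma printed in nm, converted to Angstrom here), partial charges,
#' united-atom masses, reference geometries, rotatable-bond torsions and
#' functional-group annotations for the four species of the model MIP
#' system: the templates pyrazine (PRZ) and pyrimidine (PMD), the
#' functional monomer methacrylic acid (MAA) and the cross-linker ethylene
#' glycol dimethacrylate (EGDMA). Each table is validated against embedded
#' checksums (net charge and sigma column sum), and every molecule must be
#' exactly charge-neutral.
#'
#' @param path path to a YAML parameter file; defaults to the packaged set
#' @return an object of class `mip_forcefield`: a list with `constants`
#'   and a named list `species` of `mip_topology` objects
#' @export
#' @examples
#' ff <- load_forcefield()
#' names(ff$species)
load_forcefield <- function(path = system.file("extdata", "forcefield.yaml",
                                               package = "mipsim")) {
  raw <- yaml::read_yaml(path)
  const <- modifyList(.const, raw$constants[c("cutoff_mixture", "cutoff_gcmc", "dsf_alpha")])
  species <- lapply(names(raw$species), function(nm) {
    sp <- raw$species[[nm]]
    at <- do.call(rbind, lapply(sp$atoms, function(a)
      data.frame(id = a$id, sigma = a$sigma * 10, epsilon = a$epsilon,
                 charge = a$charge, mass = a$mass, stringsAsFactors = FALSE)))
    qs <- sum(at$charge)
    if (abs(qs - sp$check$charge_sum) > 1e-9 || abs(qs) > 1e-9)
      stop("species ", nm, " fails charge checksum: net charge ", qs)
    if (abs(sum(at$sigma) / 10 - sp$check$sigma_sum) > 1e-9)
      stop("species ", nm, " fails sigma checksum")
    bonds <- do.call(rbind, sp$bonds)
    xyz <- build_geometry(sp$geometry, nrow(at))
    gd <- bond_graph_distances(bonds, nrow(at))
    excl <- (gd <= 3) * 1L   # exclude pairs separated by 1-3 bonds
    topo <- list(name = nm, atoms = at, bonds = bonds, xyz = xyz,
                 rigid = isTRUE(sp$rigid), excl = excl,
                 rotatable = sp$rotatable, functional = sp$functional,
                 symmetry_number = if (is.null(sp$symmetry_number)) 1L
                                   else sp$symmetry_number,
                 mass = sum(at$mass))
    class(topo) <- "mip_topology"
    topo
  })
  names(species) <- names(raw$species)
  ff <- list(constants = const, species = species, version = raw$version)
  class(ff) <- "mip_forcefield"
  ff
}

#' @export
print.mip_forcefield <- function(x, ...) {
  cat("United-atom force field,", length(x$species), "species:\n")
  for (s in x$species)
    cat(sprintf("  %-6s %2d atoms, M = %7.3f g/mol, %s\n", s$name,
                nrow(s$atoms), s$mass, if (s$rigid) "rigid" else "flexible"))
  invisible(x)
}

#' @export
print.mip_topology <- function(x, ...) {
  cat("Molecule", x$name, "-", nrow(x$atoms), "united atoms,",
      if (x$rigid) "rigid" else "flexible", "\n")
  print(x$atoms)
  invisible(x)
}

# Lorentz-Berthelot cross parameters from two atom records
combine_lb <- function(type_i, type_j) {
  list(sigma = (type_i$sigma + type_j$sigma) / 2,
       epsilon = sqrt(type_i$epsilon * type_j$epsilon))
}

#' Lennard-Jones pair energy
#'
#' Evaluates `4 eps [ (sigma/r)^12 - (sigma/r)^6 ]` for a pair of atom
#' types, with Lorentz-Berthelot combining (arithmetic sigma, geometric
#' epsilon, the TraPPE convention). Distances are in Angstrom and energies
#' in kJ/mol. Beyond `cutoff` (if finite) the energy is zero.
#'
#' @param type_i,type_j atom records with `sigma` (Angstrom) and `epsilon`
#'   (kJ/mol) entries, e.g. rows of a topology's `atoms` table
#' @param r interatomic distance(s), Angstrom; must be positive
#' @param cutoff cutoff radius, Angstrom (`Inf` for the full-range potential)
#' @return energy in kJ/mol (vectorized over `r`)
#' @export
lj_energy <- function(type_i, type_j, r, cutoff = Inf) {
  if (any(r <= 0)) stop("distance must be positive")
  p <- combine_lb(type_i, type_j)
  if (p$epsilon == 0 || p$sigma == 0) return(rep(0, length(r)))
  sr6 <- (p$sigma / r)^6
  u <- 4 * p$epsilon * (sr6^2 - sr6)
  u[r >= cutoff] <- 0
  u
}

#' Bare Coulomb pair energy
#'
#' `q_i q_j / (4 pi eps0 r)` in kJ/mol with charges in elementary units and
#' distances in Angstrom.
#'
#' @param q_i,q_j partial charges (e)
#' @param r distance(s), Angstrom; positive
#' @export
coulomb_energy <- function(q_i, q_j, r) {
  if (any(r <= 0)) stop("distance must be positive")
  .const$coulomb_k * q_i * q_j / r
}

#' Damped shifted-force Coulomb pair energy
#'
#' The Fennell-Gezelter pairwise alternative to lattice summation: a
#' complementary-error-function damped Coulomb term shifted so that both the
#' energy and its radial derivative vanish continuously at the cutoff
#' `Rc`. In the `alpha -> 0` limit it reduces to the undamped shifted-force
#' Coulomb potential. Used for adsorbate-adsorbate electrostatics in the
#' adsorption stage (cutoff 10.6 Angstrom).
#'
#' @inheritParams coulomb_energy
#' @param Rc cutoff radius, Angstrom
#' @param alpha damping parameter, 1/Angstrom (non-negative)
#' @export
dsf_coulomb_energy <- function(q_i, q_j, r, Rc = .const$cutoff_gcmc,
                               alpha = .const$dsf_alpha) {
  if (any(r <= 0)) stop("distance must be positive")
  if (alpha < 0) stop("alpha must be non-negative")
  er <- erfc_(alpha * Rc)
  eshift <- er / Rc
  fshift <- er / Rc^2 + 2 * alpha / sqrt(pi) * exp(-alpha^2 * Rc^2) / Rc
  u <- .const$coulomb_k * q_i * q_j * (erfc_(alpha * r) / r - eshift + fshift * (r - Rc))
  u[r >= Rc] <- 0
  u
}

erfc_ <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Ewald electrostatic energy of a periodic configuration
#'
#' Standard Ewald summation (real-space + reciprocal + self + intramolecular
#' exclusion corrections, plus a uniform-background term for non-neutral
#' systems) for a cubic periodic box. The splitting parameter and k-space
#' cutoff are chosen automatically from a relative accuracy target unless
#' given explicitly.
#'
#' @param config a [mip_configuration()]
#' @param accuracy relative accuracy target used to auto-select `alpha`
#'   and `kmax`
#' @param alpha,kmax,rcut optional explicit Ewald parameters
#' @return list with components `real`, `recip`, `self`, `excl`,
#'   `background` and `total` (kJ/mol)
#' @export
ewald_energy <- function(config, accuracy = 1e-4, alpha = NULL, kmax = NULL,
                         rcut = NULL) {
  if (is.na(config$box) || config$box <= 0) stop("Ewald needs a periodic box")
  fl <- flat_config(config)
  L <- config$box
  if (is.null(rcut)) rcut <- L / 2
  s <- sqrt(-log(accuracy))
  if (is.null(alpha)) alpha <- s / rcut
  if (is.null(kmax)) kmax <- ceiling(s * alpha * L / pi)
  res <- cpp_ewald_energy(fl$xyz, fl$q, L, fl$mol, fl$excl_i, fl$excl_j,
                          alpha, rcut, as.integer(kmax))
  if (abs(res$net_charge) > 1e-6)
    warning("system has net charge ", signif(res$net_charge, 4),
            "; uniform background correction applied")
  res
}

#' Total potential energy of a configuration
#'
#' Minimum-image pairwise sum over intermolecular pairs plus intramolecular
#' nonbonded terms beyond the 1-3 bond exclusion rule. The `mixture` scheme
#' uses the liquid-stage conventions (LJ cut at 14 Angstrom with long-tail
#' corrections); the `gcmc` scheme uses the adsorption-stage conventions
#' (LJ and Coulomb cut at 10.6 Angstrom, no corrections). Lennard-Jones and
#' Coulomb contributions are reported separately.
#'
#' @param config a [mip_configuration()]
#' @param scheme `"mixture"` or `"gcmc"`
#' @param components `"both"`, `"LJ"` or `"COUL"`
#' @param electrostatics `"dsf"`, `"ewald"` or `"bare"` (truncated Coulomb)
#' @return list with `lj`, `coul`, `tail` and `total` (kJ/mol)
#' @export
total_energy <- function(config, scheme = c("mixture", "gcmc"),
                         components = c("both", "LJ", "COUL"),
                         electrostatics = c("dsf", "ewald", "bare")) {
  scheme <- match.arg(scheme)
  components <- match.arg(components)
  electrostatics <- match.arg(electrostatics)
  fl <- flat_config(config)
  box <- if (is.na(config$box)) -1 else config$box
  rc <- if (scheme == "mixture") .const$cutoff_mixture else .const$cutoff_gcmc
  if (box > 0 && box < 2 * rc)
    stop("box edge (", box, " A) smaller than twice the cutoff (", rc, " A)")
  tail <- scheme == "mixture"
  want_lj <- components %in% c("both", "LJ")
  want_c <- components %in% c("both", "COUL")
  coul_method <- if (!want_c) 0L else if (electrostatics == "dsf") 2L else 1L
  res <- cpp_energy(fl$xyz, fl$sigma, fl$epsilon, fl$q, fl$mol,
                    fl$excl_i, fl$excl_j, box, rc, rc, coul_method,
                    .const$dsf_alpha, tail && want_lj)
  lj <- if (want_lj) res$lj else 0
  tailu <- if (want_lj) res$tail else 0
  coul <- res$coul
  if (want_c && electrostatics == "ewald" && box > 0) {
    coul <- ewald_energy(config)$total
  }
  if (!want_lj) { lj <- 0; tailu <- 0 }
  list(lj = lj, coul = coul, tail = tailu, total = lj + coul + tailu)
}
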