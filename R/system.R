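#' Build an initial mixture configuration by random insertion
#'
#' Places the requested numbers of molecules at random positions and
#' orientations in a cubic box, rejecting trial placements that bring any
#' atom pair closer than `overlap_factor` times the Lorentz-Berthelot
#' sigma of the pair (atoms with sigma = 0, i.e. the acid hydrogen, are
#' unconstrained). Reproducible for a given seed.
#'
#' @param ff a [load_forcefield()] object
#' @param composition named integer vector of molecule counts,
#'   e.g. `c(PRZ = 10, MAA = 80, EGDMA = 200)`
#' @param box_edge cubic box edge, Angstrom
#' @param seed RNG seed
#' @param overlap_factor hard-overlap threshold as a fraction of sigma_ij
#' @param max_attempts insertion attempts per molecule before giving up
#' @param temperature,pressure ensemble tags stored with the configuration
#' @return a `mip_configuration`
#' @export
#' @examples
#' ff <- load_forcefield()
#' cfg <- build_initial_configuration(ff, c(PRZ = 2, MAA = 3), 25, seed = 1)
#' n_molecules(cfg)
build_initial_configuration <- function(ff, composition, box_edge, seed = 1,
                                        overlap_factor = 0.8, max_attempts = 5000,
                                        temperature = 298,
                                        pressure = .const$atm_Pa) {
  stopifnot(all(composition >= 0), box_edge > 0)
  set.seed(seed)
  # place the bulkiest species first: sequential insertion succeeds at much
  # higher densities when the large cross-linker goes in before the rest
  sizes <- vapply(names(composition), function(s) {
    if (is.null(ff$species[[s]])) stop("unknown species: ", s)
    nrow(ff$species[[s]]$atoms)
  }, 1L)
  composition <- composition[order(-sizes)]
  species <- rep(names(composition), times = composition)
  coords <- vector("list", length(species))
  placed_xyz <- matrix(numeric(0), 0, 3)
  placed_sig <- numeric(0)
  L <- box_edge
  for (m in seq_along(species)) {
    tp <- ff$species[[species[m]]]
    if (is.null(tp)) stop("unknown species: ", species[m])
    local <- sweep(tp$xyz, 2, colSums(tp$xyz * tp$atoms$mass) / sum(tp$atoms$mass))
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      rot <- random_rotation_matrix()
      pos <- runif(3, 0, L)
      cand <- sweep(local %*% t(rot), 2, pos, `+`)
      if (nrow(placed_xyz) == 0) { ok <- TRUE; break }
      # minimum-image distances between candidate atoms and placed atoms
      clash <- FALSE
      for (a in seq_len(nrow(cand))) {
        if (tp$atoms$sigma[a] == 0) next
        d <- sweep(placed_xyz, 2, cand[a, ])
        d <- d - L * round(d / L)
        r2 <- rowSums(d^2)
        thr <- (overlap_factor * (placed_sig + tp$atoms$sigma[a]) / 2)^2
        if (any(r2 < thr & placed_sig > 0)) { clash <- TRUE; break }
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok)
      stop("failed to insert molecule ", m, " (", species[m], ") after ",
           max_attempts, " attempts; try a larger box")
    coords[[m]] <- cand
    placed_xyz <- rbind(placed_xyz, cand)
    placed_sig <- c(placed_sig, tp$atoms$sigma)
  }
  mip_configuration(ff, species, coords, box = L, temperature = temperature,
                    pressure = pressure,
                    provenance = list(seed = seed, builder = "random_insertion",
                                      overlap_factor = overlap_factor))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quench a configuration and remove the template
#'
#' Freezes all molecules in their instantaneous positions, orientations and
#' conformations, removes the listed species, and returns an immutable
#' matrix object. Retained coordinates are bitwise identical to the input.
#'
#' @param config an (equilibrated) `mip_configuration`
#' @param remove character vector of species names to remove
#' @param realization integer tag for the matrix realization (1-3 in the
#'   reference protocol)
#' @return a `mip_matrix` (a frozen `mip_configuration` with a `mass_g`
#'   field, grams per simulation cell)
#' @export
quench_and_remove <- function(config, remove = character(), realization = 1L) {
  missing_sp <- setdiff(remove, unique(config$species))
  if (length(missing_sp))
    warning("species not present, nothing removed: ",
            paste(missing_sp, collapse = ", "))
  keep <- !(config$species %in% remove)
  out <- config
  out$species <- config$species[keep]
  out$coords <- config$coords[keep]
  out$frozen <- TRUE
  out$provenance <- c(config$provenance,
                      list(removed = remove, realization = realization))
  out$mass_g <- sum(vapply(out$species, function(s)
    out$topologies[[s]]$mass, 1)) / .const$N_A
  class(out) <- c("mip_matrix", "mip_configuration")
  out
}

#' Replicate a frozen matrix into a periodic supercell
#'
#' Tiles the cubic cell by integer factors along each axis. With factors
#' `(2, 2, 2)` the atom count grows eightfold and the box edge doubles;
#' the periodic energy per original cell is preserved.
#'
#' @param matrix a `mip_matrix`
#' @param factors integer replication factors, length 3
#' @export
replicate_supercell <- function(matrix, factors = c(2L, 2L, 2L)) {
  stopifnot(inherits(matrix, "mip_matrix"))
  if (any(factors < 1)) stop("replication factors must be positive integers")
  if (all(factors == 1L)) return(matrix)
  if (length(unique(factors)) != 1)
    stop("only isotropic replication of a cubic cell is supported")
  f <- as.integer(factors[1])
  L <- matrix$box
  shifts <- as.matrix(expand.grid(x = 0:(f - 1), y = 0:(f - 1), z = 0:(f - 1))) * L
  species <- rep(matrix$species, times = nrow(shifts))
  coords <- vector("list", 0)
  for (s in seq_len(nrow(shifts)))
    coords <- c(coords, lapply(matrix$coords, function(xyz)
      sweep(xyz, 2, shifts[s, ], `+`)))
  out <- matrix
  out$species <- species
  out$coords <- coords
  out$box <- L * f
  out$mass_g <- matrix$mass_g * f^3
  out$provenance <- c(matrix$provenance, list(supercell = factors))
  out
}
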