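#' Write a configuration as extended XYZ
#'
#' Extended XYZ is the canonical interchange format of the package: one
#' atom per line (`id x y z mol species`) with box, frozen flag and
#' ensemble tags in the comment line. The round trip through
#' [read_xyz()] is lossless to full printed precision (17 significant
#' digits).
#'
#' @param config a `mip_configuration`
#' @param path output file
#' @export
write_xyz <- function(config, path) {
  fl <- flat_config(config)
  n <- fl$natoms
  ids <- unlist(lapply(config$species, function(s)
    config$topologies[[s]]$atoms$id))
  spcol <- rep(config$species, times = vapply(config$coords, nrow, 1L))
  hdr <- sprintf('Box=%s Frozen=%s Temperature=%s Pressure=%s',
                 format(config$box, digits = 17),
                 isTRUE(config$frozen),
                 format(config$temperature), format(config$pressure))
  lines <- c(as.character(n), hdr,
             sprintf("%s %.17g %.17g %.17g %d %s", ids,
                     fl$xyz[, 1], fl$xyz[, 2], fl$xyz[, 3], fl$mol, spcol))
  writeLines(lines, path)
  invisible(path)
}

#' Read an extended XYZ configuration
#'
#' @param path file written by [write_xyz()]
#' @param ff a [load_forcefield()] object (or topology list) supplying the
#'   molecule topologies named in the file
#' @return a `mip_configuration` (a `mip_matrix` when the frozen flag is
#'   set, with its cell mass recomputed)
#' @export
read_xyz <- function(path, ff) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("parse error at line 1: expected an atom count")
  if (length(lines) < n + 2) stop("parse error: file truncated after line ",
                                  length(lines))
  hdr <- lines[2]
  get <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  box <- suppressWarnings(as.numeric(get("Box")))
  frozen <- identical(get("Frozen"), "TRUE")
  temperature <- suppressWarnings(as.numeric(get("Temperature")))
  toks <- if (n > 0) strsplit(lines[3:(n + 2)], " +") else list()
  xyz <- matrix(NA_real_, n, 3)
  mol <- integer(n); spv <- character(n)
  for (i in seq_len(n)) {
    tk <- toks[[i]]
    if (length(tk) != 6)
      stop("parse error at line ", i + 2, ": expected 6 fields, got ",
           length(tk))
    xyz[i, ] <- as.numeric(tk[2:4])
    mol[i] <- as.integer(tk[5])
    spv[i] <- tk[6]
  }
  if (anyNA(xyz)) stop("parse error: non-numeric coordinates")
  species <- spv[!duplicated(mol)]
  coords <- lapply(split.data.frame(xyz, mol), function(m)
    `dimnames<-`(as.matrix(m), NULL))
  cfg <- mip_configuration(ff, species, coords[order(as.integer(names(coords)))],
                           box = box, temperature = temperature,
                           frozen = frozen)
  if (frozen) {
    cfg$mass_g <- sum(vapply(cfg$species, function(s)
      cfg$topologies[[s]]$mass, 1)) / .const$N_A
    class(cfg) <- c("mip_matrix", "mip_configuration")
  }
  cfg
}

#' Export a configuration as PDB (visualization only)
#'
#' Column-formatted HETATM records with a CRYST1 cell; wrapped
#' coordinates. Export-only: use extended XYZ for round trips.
#'
#' @param config a `mip_configuration`
#' @param path output file
#' @export
write_pdb <- function(config, path) {
  cfg <- wrap_configuration(config)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(cfg$box))
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                       cfg$box, cfg$box, cfg$box, 90, 90, 90), con)
  serial <- 0L
  for (m in seq_along(cfg$species)) {
    tp <- cfg$topologies[[cfg$species[m]]]
    for (a in seq_len(nrow(tp$atoms))) {
      serial <- serial + 1L
      el <- substr(gsub("[0-9]", "", tp$atoms$id[a]), 1, 1)
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        serial %% 100000, substr(tp$atoms$id[a], 1, 4),
        substr(cfg$species[m], 1, 3), m %% 10000,
        cfg$coords[[m]][a, 1], cfg$coords[[m]][a, 2], cfg$coords[[m]][a, 3],
        el), con)
    }
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a provenance sidecar
#'
#' JSON record of the seeds, parameters and package version needed to
#' regenerate a numeric artifact.
#'
#' @param info named list
#' @param path output file (conventionally `<artifact>.json`)
#' @export
write_provenance <- function(info, path) {
  info$package_version <- as.character(utils::packageVersion("mipsim"))
  jsonlite::write_json(info, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

# rigid placement helper: translate + rotate reference coordinates so atom
# i lands on target_i and atom j points along target_j - target_i
rigid_map <- function(xyz, i, j, target_i, target_j) {
  a <- xyz[j, ] - xyz[i, ]
  b <- target_j - target_i
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b); s <- sqrt(sum(v^2)); cc <- sum(a * b)
  R <- diag(3)
  if (s > 1e-12) {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
                 byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - cc) / s^2)
  } else if (cc < 0) {
    # antiparallel: rotate pi about any axis orthogonal to a
    w <- cross3(a, c(1, 0, 0))
    if (sum(w^2) < 1e-8) w <- cross3(a, c(0, 1, 0))
    w <- w / sqrt(sum(w^2))
    R <- 2 * outer(w, w) - diag(3)
  }
  sweep(sweep(xyz, 2, xyz[i, ]) %*% t(R), 2, target_i, `+`)
}

#' Deterministic test fixtures
#'
#' Generators for the toy systems the test-suite oracles run on: hand
#' constructed association geometries (classified by construction),
#' a single-well toy matrix with a matching probe adsorbate, an ideal-gas
#' box and a single-site LJ fluid box. Outputs are byte-identical for a
#' given (name, params, seed).
#'
#' @param name one of `"constructed_TM"`, `"constructed_TMX"`,
#'   `"constructed_TX2"`, `"constructed_NONE"`,
#'   `"toy_matrix_single_well"`, `"ideal_gas_box"`, `"lj_fluid_box"`
#' @param params named list overriding generator defaults
#' @param seed RNG seed
#' @param ff force field (loaded if missing)
#' @return a list with at least `config` (or `matrix` plus `probe` for the
#'   toy matrix), plus the resolved parameters
#' @export
make_fixture <- function(name, params = list(), seed = 1,
                         ff = load_forcefield()) {
  gens <- c("constructed_TM", "constructed_TMX", "constructed_TX2",
            "constructed_NONE", "toy_matrix_single_well", "ideal_gas_box",
            "lj_fluid_box")
  if (!name %in% gens)
    stop("unknown fixture '", name, "'; available: ",
         paste(gens, collapse = ", "))
  set.seed(seed)
  switch(name,
    constructed_TM = constructed_complex(ff, m_on = 1, params = params),
    constructed_TMX = constructed_complex(ff, m_on = 1, x_on = 2,
                                          params = params),
    constructed_TX2 = constructed_complex(ff, x_on = c(1, 2), params = params),
    constructed_NONE = constructed_complex(ff, m_on = 1, spoil = TRUE,
                                           params = params),
    toy_matrix_single_well = toy_matrix_single_well(params),
    ideal_gas_box = ideal_gas_box(ff, params, seed),
    lj_fluid_box = lj_fluid_box(params, seed))
}

single_atom_topology <- function(name, id, sigma, epsilon, charge = 0,
                                 mass = 16.04) {
  topo <- list(name = name,
               atoms = data.frame(id = id, sigma = sigma, epsilon = epsilon,
                                  charge = charge, mass = mass,
                                  stringsAsFactors = FALSE),
               bonds = matrix(integer(0), 0, 2),
               xyz = matrix(0, 1, 3), rigid = TRUE,
               excl = matrix(1L, 1, 1), rotatable = NULL, functional = NULL,
               symmetry_number = 1L, mass = mass)
  class(topo) <- "mip_topology"
  topo
}

# template + partners placed to satisfy (or deliberately spoil) the
# conjunctive association criteria; m_on / x_on give nitrogen slots (1 or 2)
constructed_complex <- function(ff, m_on = integer(), x_on = integer(),
                                spoil = FALSE, params = list()) {
  p <- modifyList(list(box = 40, d_nh = 2.3, d_nc = 3.4), params)
  prz <- ff$species$PRZ
  maa <- ff$species$MAA
  egd <- ff$species$EGDMA
  center <- c(p$box / 2, p$box / 2, p$box / 2)
  xt <- sweep(prz$xyz, 2, center, `+`)
  species <- "PRZ"; coords <- list(xt)
  nitro <- prz$functional$nitrogens
  for (slot in seq_len(2)) {
    n <- nitro[slot]
    u <- (xt[n, ] - center); u <- u / sqrt(sum(u^2))
    adj <- prz$functional$adjacent_carbons[[as.character(n)]]
    if (slot %in% m_on) {
      h <- maa$functional$hydrogen; o <- maa$functional$carbonyl_oxygen
      p_h <- xt[n, ] + p$d_nh * u
      r_ho <- sqrt(sum((maa$xyz[h, ] - maa$xyz[o, ])^2))
      dir_o <- if (spoil) u else (xt[adj[1], ] - p_h) / sqrt(sum((xt[adj[1], ] - p_h)^2))
      p_o <- p_h + r_ho * dir_o
      coords <- c(coords, list(rigid_map(maa$xyz, h, o, p_h, p_o)))
      species <- c(species, "MAA")
    }
    if (slot %in% x_on) {
      cs <- egd$functional$carbons[[1]]; os <- egd$functional$oxygens[[1]]
      p_c <- xt[n, ] + p$d_nc * u
      r_co <- sqrt(sum((egd$xyz[cs, ] - egd$xyz[os, ])^2))
      dir_o <- (xt[adj[1], ] - p_c) / sqrt(sum((xt[adj[1], ] - p_c)^2))
      p_o <- p_c + r_co * dir_o
      coords <- c(coords, list(rigid_map(egd$xyz, cs, os, p_c, p_o)))
      species <- c(species, "EGDMA")
    }
  }
  cfg <- mip_configuration(ff, species, coords, box = p$box)
  list(config = cfg, params = p)
}

toy_matrix_single_well <- function(params = list()) {
  # a single small-core deep well at the cell center; the probe's own large
  # core keeps occupancy effectively 0/1/2 so a short grand-partition
  # expansion is exact for the oracle tests
  p <- modifyList(list(box = 12, sigma = 1.0, epsilon = 40.0,
                       probe_sigma = 9.0, probe_epsilon = 0.4), params)
  well <- single_atom_topology("WELL", "W", p$sigma, p$epsilon)
  probe <- single_atom_topology("PROBE", "P", p$probe_sigma, p$probe_epsilon)
  topo <- list(WELL = well, PROBE = probe)
  cfg <- mip_configuration(topo, "WELL",
                           list(matrix(p$box / 2, 1, 3)), box = p$box)
  m <- quench_and_remove(cfg, character(0))
  list(matrix = m, probe = probe, params = p)
}

ideal_gas_box <- function(ff, params = list(), seed = 1) {
  p <- modifyList(list(n = 20, box = 30, species = "PRZ"), params)
  cfg <- build_initial_configuration(
    ff, setNames(p$n, p$species), p$box, seed = seed, overlap_factor = 0)
  list(config = cfg, params = p)
}

lj_fluid_box <- function(params = list(), seed = 1) {
  # TraPPE methane-like single site
  p <- modifyList(list(n = 100, box = 30, sigma = 3.73, epsilon = 1.2305),
                  params)
  tp <- single_atom_topology("CH4", "C", p$sigma, p$epsilon, mass = 16.043)
  set.seed(seed)
  coords <- lapply(seq_len(p$n), function(i) matrix(runif(3, 0, p$box), 1, 3))
  cfg <- mip_configuration(list(CH4 = tp), rep("CH4", p$n), coords,
                           box = p$box)
  list(config = cfg, topology = tp, params = p)
}
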