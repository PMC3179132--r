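#' Association criteria for binding-site classification
#'
#' The conjunctive geometric criteria that define template associations:
#' a monomer (MAA) association requires a template nitrogen within `r_nh`
#' of the MAA acid hydrogen AND a ring carbon flanking that nitrogen
#' within `r_co` of the MAA carbonyl oxygen O4; a cross-linker (EGDMA)
#' association requires the nitrogen within `r_nc` of C7 or C8 AND the
#' flanking carbon within `r_xo` of O5 or O12. All comparisons are strict
#' (a contact exactly at the threshold does not count) and distances use
#' the minimum image. The 2.5 and 4 Angstrom defaults sit at the first
#' minimum of the corresponding atom-atom pair distribution functions.
#'
#' @param r_nh,r_co,r_nc,r_xo threshold distances, Angstrom
#' @param tie_break `"energy"` (partner with the lower template-partner
#'   interaction energy wins when one nitrogen matches both a monomer and
#'   a cross-linker) or `"distance"` (nearest key contact wins)
#' @export
assoc_criteria <- function(r_nh = 2.5, r_co = 4.0, r_nc = 4.0, r_xo = 4.0,
                           tie_break = c("energy", "distance")) {
  list(r_nh = r_nh, r_co = r_co, r_nc = r_nc, r_xo = r_xo,
       tie_break = match.arg(tie_break))
}

min_image_d <- function(a, B, L) {
  # distances from point a (length-3) to matrix of points B
  d <- sweep(B, 2, a)
  if (!is.na(L) && L > 0) d <- d - L * round(d / L)
  sqrt(rowSums(d^2))
}

# full-range minimum-image interaction energy between two molecules
pair_molecule_energy <- function(cfg, i, j) {
  ti <- cfg$topologies[[cfg$species[i]]]
  tj <- cfg$topologies[[cfg$species[j]]]
  xi <- cfg$coords[[i]]; xj <- cfg$coords[[j]]
  L <- if (is.na(cfg$box)) -1 else cfg$box
  u <- 0
  for (a in seq_len(nrow(xi))) {
    r <- min_image_d(xi[a, ], xj, L)
    sij <- (ti$atoms$sigma[a] + tj$atoms$sigma) / 2
    eij <- sqrt(ti$atoms$epsilon[a] * tj$atoms$epsilon)
    sr6 <- ifelse(sij > 0, (sij / r)^6, 0)
    u <- u + sum(4 * eij * (sr6^2 - sr6)) +
      sum(.const$coulomb_k * ti$atoms$charge[a] * tj$atoms$charge / r)
  }
  u
}

#' Detect template associations and classify complexes
#'
#' Applies the conjunctive distance criteria of [assoc_criteria()] to every
#' template molecule (any species annotated with ring nitrogens) in a
#' configuration. Each nitrogen carries at most one association; the
#' per-template label follows from the two nitrogens' states:
#' `TM` (one monomer), `TM2` (both nitrogens to monomers), `TX` (one
#' cross-linker), `TX2` (two cross-linkers), `TMX` (one of each), `NONE`.
#' The labels are mutually exclusive and exhaustive, so there is at most
#' one complex per template molecule.
#'
#' @param config a `mip_configuration` containing template and partner
#'   molecules
#' @param criteria an [assoc_criteria()] list
#' @return data.frame with one row per template molecule: `molecule`,
#'   `species`, `label`, `partner_1`, `partner_2` (molecule indices or NA)
#' @export
detect_associations <- function(config, criteria = assoc_criteria()) {
  known <- c("r_nh", "r_co", "r_nc", "r_xo", "tie_break")
  if (!all(names(criteria) %in% known))
    stop("unknown criteria entries: ",
         paste(setdiff(names(criteria), known), collapse = ", "))
  topo <- config$topologies
  sp <- config$species
  L <- config$box
  is_template <- vapply(sp, function(s) !is.null(topo[[s]]$functional$nitrogens), TRUE)
  is_m <- vapply(sp, function(s) !is.null(topo[[s]]$functional$hydrogen), TRUE)
  is_x <- vapply(sp, function(s) !is.null(topo[[s]]$functional$carbons), TRUE)
  if (!any(is_template)) stop("no template molecules in configuration")
  m_idx <- which(is_m); x_idx <- which(is_x)
  # partner atom coordinates, stacked
  m_h <- do.call(rbind, lapply(m_idx, function(i)
    config$coords[[i]][topo[[sp[i]]]$functional$hydrogen, , drop = FALSE]))
  m_o <- do.call(rbind, lapply(m_idx, function(i)
    config$coords[[i]][topo[[sp[i]]]$functional$carbonyl_oxygen, , drop = FALSE]))
  x_c <- lapply(x_idx, function(i)
    config$coords[[i]][unlist(topo[[sp[i]]]$functional$carbons), , drop = FALSE])
  x_o <- lapply(x_idx, function(i)
    config$coords[[i]][unlist(topo[[sp[i]]]$functional$oxygens), , drop = FALSE])
  out <- NULL
  for (t in which(is_template)) {
    tp <- topo[[sp[t]]]
    xt <- config$coords[[t]]
    per_n <- list()
    for (n in tp$functional$nitrogens) {
      adj <- tp$functional$adjacent_carbons[[as.character(n)]]
      found <- NULL
      # monomer criterion: N...H < r_nh AND flanking C...O4 < r_co
      if (length(m_idx)) {
        dh <- min_image_d(xt[n, ], m_h, L)
        cand <- which(dh < criteria$r_nh)
        for (k in cand) {
          do4 <- min(vapply(adj, function(a)
            min(min_image_d(xt[a, ], m_o[k, , drop = FALSE], L)), 1))
          if (do4 < criteria$r_co)
            found <- rbind(found, data.frame(mol = m_idx[k], kind = "M",
                                             key = dh[k]))
        }
      }
      # cross-linker criterion: N...C7/C8 < r_nc AND flanking C...O5/O12 < r_xo
      for (k in seq_along(x_idx)) {
        dnc <- min(min_image_d(xt[n, ], x_c[[k]], L))
        if (dnc >= criteria$r_nc) next
        dxo <- min(vapply(adj, function(a)
          min(min_image_d(xt[a, ], x_o[[k]], L)), 1))
        if (dxo < criteria$r_xo)
          found <- rbind(found, data.frame(mol = x_idx[k], kind = "X",
                                           key = dnc))
      }
      if (is.null(found)) {
        per_n[[length(per_n) + 1]] <- list(kind = "", mol = NA_integer_)
      } else if (nrow(found) == 1) {
        per_n[[length(per_n) + 1]] <- list(kind = found$kind, mol = found$mol)
      } else {
        score <- if (criteria$tie_break == "energy")
          vapply(found$mol, function(p) pair_molecule_energy(config, t, p), 1)
        else found$key
        b <- which.min(score)
        per_n[[length(per_n) + 1]] <- list(kind = found$kind[b], mol = found$mol[b])
      }
    }
    kinds <- vapply(per_n, `[[`, "", "kind")
    nm <- sum(kinds == "M"); nx <- sum(kinds == "X")
    label <- if (nm == 1 && nx == 0) "TM" else if (nm == 2) "TM2" else
      if (nm == 0 && nx == 1) "TX" else if (nx == 2) "TX2" else
        if (nm == 1 && nx == 1) "TMX" else "NONE"
    out <- rbind(out, data.frame(
      molecule = t, species = sp[t], label = label,
      partner_1 = per_n[[1]]$mol, partner_2 = per_n[[2]]$mol))
  }
  out
}

#' Binding-site census over configurations
#'
#' Label frequencies per template molecule, averaged over the supplied
#' configurations (and hence over realizations) with the standard error of
#' the mean. Because each template carries exactly one label, the per-label
#' means sum to at most one.
#'
#' @param configs a `mip_configuration` or list of them
#' @param criteria an [assoc_criteria()] list
#' @return data.frame of class `mip_site_census`: `label`, `mean`, `sem`
#' @export
site_census <- function(configs, criteria = assoc_criteria()) {
  if (inherits(configs, "mip_configuration")) configs <- list(configs)
  if (!length(configs)) stop("need at least one configuration")
  labels <- c("TM", "TM2", "TX", "TX2", "TMX", "NONE")
  freq <- vapply(configs, function(cfg) {
    a <- detect_associations(cfg, criteria)
    vapply(labels, function(l) mean(a$label == l), 1)
  }, numeric(length(labels)))
  freq <- matrix(freq, nrow = length(labels))
  out <- data.frame(label = labels,
                    mean = rowMeans(freq),
                    sem = apply(freq, 1, function(x)
                      if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_))
  class(out) <- c("mip_site_census", "data.frame")
  out
}

#' Histogram of per-molecule interaction energies
#'
#' Bins per-molecule adsorbate-matrix interaction energies (for example
#' from the `energy_samples` of a GCMC run) into fixed-width bins; the
#' counts integrate to the number of samples.
#'
#' @param samples numeric vector, or a data.frame with `lj`, `coul`,
#'   `total` columns
#' @param component `"TOTAL"`, `"LJ"` or `"COUL"` (for data.frame input)
#' @param bin_width bin width, kJ/mol (positive)
#' @return data.frame of class `mip_energy_histogram`: `mid`, `count`
#' @export
energy_histogram <- function(samples, component = c("TOTAL", "LJ", "COUL"),
                             bin_width = 1) {
  component <- match.arg(component)
  if (bin_width <= 0) stop("bin width must be positive")
  x <- if (is.data.frame(samples))
    samples[[c(TOTAL = "total", LJ = "lj", COUL = "coul")[component]]]
  else samples
  if (!length(x)) stop("no samples")
  lo <- floor(min(x) / bin_width) * bin_width
  hi <- ceiling(max(x) / bin_width) * bin_width
  breaks <- seq(lo, hi + bin_width / 2, by = bin_width)
  h <- hist(x, breaks = breaks, plot = FALSE)
  out <- data.frame(mid = h$mids, count = h$counts)
  attr(out, "component") <- component
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(x)
  attr(out, "mean") <- mean(x)
  class(out) <- c("mip_energy_histogram", "data.frame")
  out
}

#' Atom-atom pair distribution function
#'
#' Radial distribution function between two atom selections, normalized by
#' the ideal-gas shell count, averaged over configurations. Used to locate
#' the first minima that define the association criteria.
#'
#' @param configs a `mip_configuration` or list of them
#' @param species_a,species_b species names
#' @param atom_a,atom_b atom ids (e.g. `"N3"`) or vectors of ids
#' @param dr bin width, Angstrom (positive)
#' @param r_max maximum distance (default: half the box edge)
#' @return data.frame: `r` (bin centers), `g`
#' @export
pair_distribution <- function(configs, species_a, atom_a, species_b, atom_b,
                              dr = 0.1, r_max = NULL) {
  if (dr <= 0) stop("dr must be positive")
  if (inherits(configs, "mip_configuration")) configs <- list(configs)
  L <- configs[[1]]$box
  if (is.null(r_max)) r_max <- L / 2
  breaks <- seq(0, r_max, by = dr)
  counts <- numeric(length(breaks) - 1)
  norm <- 0
  for (cfg in configs) {
    A <- select_atoms(cfg, species_a, atom_a)
    B <- select_atoms(cfg, species_b, atom_b)
    if (!nrow(A$xyz) || !nrow(B$xyz)) next
    same <- identical(species_a, species_b) && identical(atom_a, atom_b)
    for (i in seq_len(nrow(A$xyz))) {
      d <- min_image_d(A$xyz[i, ], B$xyz, cfg$box)
      d <- d[B$mol != A$mol[i]]      # intermolecular only
      d <- d[d < r_max]
      counts <- counts + tabulate(pmin(floor(d / dr) + 1, length(counts)),
                                  nbins = length(counts))
    }
    npairs <- nrow(A$xyz) * nrow(B$xyz) -
      if (same) nrow(A$xyz) else sum(outer(A$mol, B$mol, "=="))
    norm <- norm + npairs / cfg$box^3
  }
  mids <- breaks[-1] - dr / 2
  shell <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
  g <- counts / (norm * shell)
  data.frame(r = mids, g = g)
}

select_atoms <- function(cfg, species, atoms) {
  idx <- which(cfg$species == species)
  tp <- cfg$topologies[[species]]
  ai <- if (is.character(atoms)) match(atoms, tp$atoms$id) else atoms
  if (anyNA(ai)) stop("unknown atom id for species ", species)
  xyz <- do.call(rbind, lapply(idx, function(i)
    cfg$coords[[i]][ai, , drop = FALSE]))
  if (is.null(xyz)) xyz <- matrix(numeric(0), 0, 3)
  list(xyz = xyz, mol = rep(idx, each = length(ai)))
}

#' Separation factor from two isotherms
#'
#' `S(A/B) = N_A(f*) / N_B(f*)`, the ratio of equilibrium loadings at a
#' common fugacity, together with the partition coefficients
#' `K_i = (N_i/V) / B_i` where `B_i` is the ideal-gas reservoir density at
#' `f*`, and the binding free energies `-RT ln K_i`.
#'
#' @param iso_A,iso_B `mip_isotherm` objects (same fugacity ladder point)
#' @param f_star fugacity at which to compare, Pa (must be a ladder point
#'   of both isotherms unless `interpolate = TRUE`)
#' @param temperature temperature, K
#' @param volume cell volume for the K conversion, Angstrom^3 (optional;
#'   K and Delta G are omitted without it)
#' @param interpolate log-linear interpolation between ladder points
#' @return list of class `mip_selectivity`: `S`, `f`, `N_A`, `N_B`,
#'   `lower_bound` flag (set when `N_B = 0`), optionally `K_A`, `K_B`,
#'   `dG_A`, `dG_B` (kJ/mol)
#' @export
separation_factor <- function(iso_A, iso_B, f_star, temperature = 298,
                              volume = NULL, interpolate = FALSE) {
  nA <- loading_at(iso_A, f_star, interpolate)
  nB <- loading_at(iso_B, f_star, interpolate)
  lower <- FALSE
  if (nB == 0) {
    lower <- TRUE
    sB <- iso_B$sem[match_f(iso_B, f_star)]
    nB_eff <- max(sB, .Machine$double.eps, na.rm = TRUE)
    S <- nA / nB_eff
  } else S <- nA / nB
  out <- list(S = S, f = f_star, N_A = nA, N_B = nB, lower_bound = lower,
              adsorbate_A = attr(iso_A, "adsorbate"),
              adsorbate_B = attr(iso_B, "adsorbate"))
  if (!is.null(volume)) {
    B <- ideal_gas_density(f_star, temperature)      # 1/A^3
    out$K_A <- (nA / volume) / B
    out$K_B <- (nB / volume) / B
    out$dG_A <- if (out$K_A > 0) binding_free_energy(out$K_A, temperature)$dG else NA
    out$dG_B <- if (out$K_B > 0) binding_free_energy(out$K_B, temperature)$dG else NA
  }
  class(out) <- "mip_selectivity"
  out
}

match_f <- function(iso, f_star) {
  k <- which(abs(iso$f - f_star) <= 1e-9 * f_star)
  if (!length(k)) stop("f* = ", f_star, " Pa is not a ladder point")
  k[1]
}

loading_at <- function(iso, f_star, interpolate = FALSE) {
  if (!interpolate) return(iso$loading[match_f(iso, f_star)])
  if (f_star < min(iso$f) || f_star > max(iso$f))
    stop("f* outside the isotherm range")
  exp(stats::approx(log(iso$f), log(pmax(iso$loading, 1e-300)),
                    xout = log(f_star))$y)
}

#' @export
print.mip_selectivity <- function(x, ...) {
  cat(sprintf("S(%s/%s) = %.3g at f = %g Pa%s\n",
              x$adsorbate_A, x$adsorbate_B, x$S, x$f,
              if (x$lower_bound) " (lower bound: zero analogue loading)" else ""))
  invisible(x)
}

#' Binding free energy from a partition coefficient
#'
#' `Delta G = -RT ln K` in kJ/mol. The returned record also carries the
#' conventional decomposition slots (translational+rotational, internal
#' rotors, conformational, polar, van der Waals, solvation, vibrational);
#' for rigid templates adsorbed from the gas phase only the
#' translational+rotational and polar terms are active, the others are
#' reported as zero placeholders.
#'
#' @param K partition coefficient (positive)
#' @param temperature temperature, K
#' @export
binding_free_energy <- function(K, temperature = 298) {
  if (any(K <= 0)) stop("K must be positive")
  dG <- -.const$R * temperature * log(K) / 1000
  list(dG = dG, temperature = temperature,
       decomposition = c(trans_rot = NA_real_, rotors = 0, conform = 0,
                         polar = NA_real_, vdW = 0, solv = 0, vib = 0))
}

#' Selectivity implied by a binding free-energy difference
#'
#' Boltzmann relation `S = exp(-ddG / RT)` with `ddG` in kJ/mol; a
#' difference of -15 kJ/mol at 298 K gives a selectivity above 400.
#'
#' @param ddG binding free-energy difference Delta(Delta G), kJ/mol
#' @param temperature temperature, K
#' @export
selectivity_from_dG <- function(ddG, temperature = 298) {
  exp(-ddG * 1000 / (.const$R * temperature))
}

#' Orientational multiplicity of a template
#'
#' Counts the energy-equivalent ordered (nitrogen, flanking ring carbon)
#' binding modes of a template: modes are enumerated from the functional
#' annotation and merged into equal-energy classes by the automorphisms of
#' the charge-labelled molecular graph; `W` is the size of the largest
#' class. Pyrazine has a single class of four modes (`W = 4`); pyrimidine
#' has two classes of two (`W = 2`).
#'
#' @param template a `mip_topology` with annotated nitrogens
#' @return integer `W`, with the orbit decomposition in `attr(, "orbits")`
#' @export
orientational_multiplicity <- function(template) {
  fn <- template$functional
  if (is.null(fn$nitrogens) || !length(fn$nitrogens))
    stop("template has no annotated nitrogen binding sites")
  n <- nrow(template$atoms)
  if (n > 10) stop("automorphism enumeration supports small rigid templates only")
  lab <- paste(round(template$atoms$sigma, 6), template$atoms$epsilon,
               template$atoms$charge)
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(template$bonds))) {
    adj[template$bonds[k, 1], template$bonds[k, 2]] <- TRUE
    adj[template$bonds[k, 2], template$bonds[k, 1]] <- TRUE
  }
  autos <- graph_automorphisms(adj, lab)
  modes <- do.call(rbind, lapply(fn$nitrogens, function(nn)
    cbind(nn, fn$adjacent_carbons[[as.character(nn)]])))
  key <- paste(modes[, 1], modes[, 2])
  orbit <- seq_len(nrow(modes))
  for (p in autos) {
    mapped <- paste(p[modes[, 1]], p[modes[, 2]])
    for (i in seq_len(nrow(modes))) {
      j <- match(mapped[i], key)
      if (!is.na(j)) {
        ri <- orbit[i]; rj <- orbit[j]
        if (ri != rj) orbit[orbit == rj] <- ri
      }
    }
  }
  sizes <- table(orbit)
  W <- as.integer(max(sizes))
  attr(W, "orbits") <- as.integer(sizes)
  W
}

# label- and adjacency-preserving permutations by backtracking
graph_automorphisms <- function(adj, lab) {
  n <- nrow(adj)
  res <- list()
  perm <- integer(n)
  used <- logical(n)
  recur <- function(i) {
    if (i > n) { res[[length(res) + 1]] <<- perm; return(invisible()) }
    for (j in which(!used & lab == lab[i])) {
      ok <- TRUE
      for (k in seq_len(i - 1)) if (adj[i, k] != adj[j, perm[k]]) { ok <- FALSE; break }
      if (ok) {
        perm[i] <<- j; used[j] <<- TRUE
        recur(i + 1)
        used[j] <<- FALSE
      }
    }
  }
  recur(1)
  res
}

#' Entropic free-energy term from orientational multiplicities
#'
#' `-RT ln(W1 / W2)` in kJ/mol: the orientational-entropy advantage of a
#' template with `W1` equivalent binding modes over one with `W2`. For
#' pyrazine (`W = 4`) versus pyrimidine (`W = 2`) at 298 K this is
#' -1.7 kJ/mol.
#'
#' @param W1,W2 positive multiplicities
#' @param temperature temperature, K
#' @export
entropy_term <- function(W1, W2, temperature = 298) {
  if (W1 <= 0 || W2 <= 0) stop("multiplicities must be positive")
  -.const$R * temperature * log(W1 / W2) / 1000
}
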