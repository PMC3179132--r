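#' Simulated annealing of a template-partner dimer
#'
#' Monte Carlo annealing of an isolated pair of molecules (no periodic
#' boundary, full-range potentials): cycles of heating and cooling between
#' `t_high` and `t_low` with translation, rigid-rotation and (for flexible
#' partners) torsion moves. Sampling uses the total energy; the reported
#' complex is the configuration with the lowest intermolecular LJ+Coulomb
#' energy encountered, the quantity that defines complex stability. A
#' center-of-mass tether keeps the pair associated during hot phases.
#'
#' @param ff a [load_forcefield()] object
#' @param template,partner species names (template must be rigid)
#' @param n_cycles number of heat/cool cycles (at least 1)
#' @param t_high,t_low temperature range of a cycle, K
#' @param moves_per_leg Monte Carlo moves per cooling leg
#' @param seed RNG seed
#' @param tether maximum center-of-mass separation, Angstrom
#' @return object of class `mip_anneal`: `e_total`, `e_lj`, `e_coul`
#'   (intermolecular, kJ/mol), `xyz_template`, `xyz_partner`, `distances`
#'   (characteristic contacts, see [complex_metrics()])
#' @export
#' @examples
#' \donttest{
#' ff <- load_forcefield()
#' res <- anneal_dimer(ff, "PRZ", "MAA", n_cycles = 2,
#'                     moves_per_leg = 2000, seed = 1)
#' res$e_total
#' }
anneal_dimer <- function(ff, template, partner, n_cycles = 5,
                         t_high = 500, t_low = 10, moves_per_leg = 2e4,
                         seed = 1, tether = 15) {
  if (t_low >= t_high) stop("schedule requires t_low < t_high")
  if (n_cycles < 1) stop("need at least one annealing cycle")
  tp_t <- ff$species[[template]]
  tp_p <- ff$species[[partner]]
  if (is.null(tp_t) || is.null(tp_p)) stop("unknown species")
  set.seed(seed)
  # start with the partner offset from the template at a random direction
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  xyz_p <- sweep(tp_p$xyz %*% t(random_rotation_matrix()), 2,
                 min(6, 0.7 * tether) * u, `+`)
  xyz_t <- tp_t$xyz
  sp_t <- species_cpp(tp_t); sp_p <- species_cpp(tp_p)
  sched <- anneal_schedule(1, t_high, t_low, moves_per_leg)
  # one engine call per heat/cool cycle; the candidates compared are the
  # frozen configurations at the end of each cooling phase
  cand <- vector("list", n_cycles)
  for (cy in seq_len(n_cycles)) {
    res <- cpp_anneal(sp_t, sp_p, xyz_t, xyz_p, sched, tether)
    cand[[cy]] <- res
    xyz_t <- res$final_xyz_template
    xyz_p <- res$final_xyz_partner
  }
  e_cand <- vapply(cand, function(r) r$final_total, 1)
  best <- cand[[which.min(e_cand)]]
  out <- structure(list(
    template = template, partner = partner,
    e_total = best$final_total, e_lj = best$final_lj,
    e_coul = best$final_coul,
    xyz_template = best$final_xyz_template,
    xyz_partner = best$final_xyz_partner,
    cycle_energies = e_cand,
    trajectory_min = min(vapply(cand, function(r) r$e_total, 1)),
    acceptance = mean(vapply(cand, function(r) r$acceptance, 1)),
    seed = seed,
    schedule = list(n_cycles = n_cycles, t_high = t_high, t_low = t_low,
                    moves_per_leg = moves_per_leg)),
    class = "mip_anneal")
  out$distances <- complex_metrics(out, ff)$distances
  out
}

# stage table: heat leg, geometric cooling ladder, final low-T polish;
# step sizes shrink with sqrt(T) so cold legs refine rather than jump
anneal_schedule <- function(n_cycles, t_high, t_low, moves_per_leg,
                            n_stages = 25) {
  stages <- NULL
  steps <- function(T) c(min(1.0, max(0.04, 0.45 * sqrt(T / 300))),
                         min(0.8, max(0.04, 0.50 * sqrt(T / 300))),
                         min(0.9, max(0.06, 0.60 * sqrt(T / 300))))
  for (cy in seq_len(n_cycles)) {
    stages <- rbind(stages, c(t_high, ceiling(0.3 * moves_per_leg), steps(t_high)))
    ladder <- t_high * (t_low / t_high)^(seq_len(n_stages) / n_stages)
    for (T in ladder)
      stages <- rbind(stages, c(T, ceiling(moves_per_leg / n_stages), steps(T)))
  }
  stages <- rbind(stages,
                  c(t_low / 2, ceiling(moves_per_leg / 2), 0.05, 0.05, 0.08),
                  c(0.5, ceiling(moves_per_leg / 2), 0.02, 0.02, 0.03))
  stages
}

#' @export
print.mip_anneal <- function(x, ...) {
  cat(sprintf("%s-%s complex: E = %.2f kJ/mol (LJ %.2f, Coulomb %.2f)\n",
              x$template, x$partner, x$e_total, x$e_lj, x$e_coul))
  if (!is.null(x$distances)) print(x$distances, row.names = FALSE)
  invisible(x)
}

#' Best-of-seeds annealing
#'
#' Repeats [anneal_dimer()] over several seeds and returns the overall
#' lowest-energy complex together with the seed-to-seed spread of the
#' minima (a reproducibility diagnostic for the global search).
#'
#' @inheritParams anneal_dimer
#' @param seeds integer vector of seeds
#' @param ... passed to [anneal_dimer()]
#' @return the best `mip_anneal` result, with extra fields `seed_energies`
#'   and `spread` (max - min over seeds, kJ/mol)
#' @export
anneal_best <- function(ff, template, partner, seeds = 1:5, ...) {
  runs <- lapply(seeds, function(s) anneal_dimer(ff, template, partner,
                                                 seed = s, ...))
  e <- vapply(runs, function(r) r$e_total, 1)
  best <- runs[[which.min(e)]]
  best$seed_energies <- setNames(e, seeds)
  best$spread <- max(e) - min(e)
  best
}

#' Characteristic distances and energy split of an annealed complex
#'
#' Reports the contact distances that define the association criteria
#' (template nitrogen to MAA acid hydrogen, flanking ring carbon to MAA
#' carbonyl oxygen O4; nitrogen to EGDMA ester-bridge carbon C7/C8 and
#' flanking carbon to carbonyl oxygen O5/O12) together with the
#' LJ/Coulomb decomposition of the complex energy.
#'
#' @param result a `mip_anneal` object
#' @param ff the force field the complex was annealed with
#' @return list with `energies` and a `distances` data.frame
#' @export
complex_metrics <- function(result, ff) {
  tp_t <- ff$species[[result$template]]
  tp_p <- ff$species[[result$partner]]
  xt <- result$xyz_template
  xp <- result$xyz_partner
  fn <- tp_t$functional
  rows <- NULL
  dist1 <- function(a, b) sqrt(sum((a - b)^2))
  for (n in fn$nitrogens) {
    adj <- fn$adjacent_carbons[[as.character(n)]]
    if (!is.null(tp_p$functional$hydrogen)) {
      h <- tp_p$functional$hydrogen
      o <- tp_p$functional$carbonyl_oxygen
      rows <- rbind(rows, data.frame(
        nitrogen = tp_t$atoms$id[n],
        contact = "N...H(MAA)", dist = dist1(xt[n, ], xp[h, ])))
      rows <- rbind(rows, data.frame(
        nitrogen = tp_t$atoms$id[n], contact = "ringC...O4(MAA)",
        dist = min(vapply(adj, function(c) dist1(xt[c, ], xp[o, ]), 1))))
    }
    if (!is.null(tp_p$functional$carbons)) {
      cs <- tp_p$functional$carbons
      os <- tp_p$functional$oxygens
      rows <- rbind(rows, data.frame(
        nitrogen = tp_t$atoms$id[n], contact = "N...C7/C8(X)",
        dist = min(vapply(cs, function(c) dist1(xt[n, ], xp[c, ]), 1))))
      rows <- rbind(rows, data.frame(
        nitrogen = tp_t$atoms$id[n], contact = "ringC...O5/O12(X)",
        dist = min(outer(adj, os, Vectorize(function(a, b)
          dist1(xt[a, ], xp[b, ]))))))
    }
  }
  list(energies = c(lj = result$e_lj, coul = result$e_coul,
                    total = result$e_total),
       distances = rows)
}
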