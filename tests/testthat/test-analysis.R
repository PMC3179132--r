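test_that("constructed geometries classify by construction", {
  tm <- make_fixture("constructed_TM", ff = ff)
  a <- detect_associations(tm$config)
  expect_equal(nrow(a), 1)
  expect_equal(a$label, "TM")

  tmx <- make_fixture("constructed_TMX", ff = ff)
  expect_equal(detect_associations(tmx$config)$label, "TMX")

  tx2 <- make_fixture("constructed_TX2", ff = ff)
  expect_equal(detect_associations(tx2$config)$label, "TX2")

  # conjunction failure: H within 2.5 A but the flanking-carbon/O4 leg
  # violated leaves the template unassociated
  none <- make_fixture("constructed_NONE", ff = ff)
  expect_equal(detect_associations(none$config)$label, "NONE")

  expect_error(detect_associations(tm$config,
                                   c(assoc_criteria(), list(bogus = 1))),
               "unknown criteria")
})

test_that("labels are exclusive, exhaustive and order-invariant", {
  tmx <- make_fixture("constructed_TMX", ff = ff)
  cfg <- tmx$config
  a <- detect_associations(cfg)
  expect_true(all(a$label %in% c("TM", "TM2", "TX", "TX2", "TMX", "NONE")))
  expect_equal(nrow(a), sum(cfg$species %in% c("PRZ", "PMD")))
  # permuting the molecule order never changes the census
  perm <- rev(seq_along(cfg$species))
  cfg_p <- cfg
  cfg_p$species <- cfg$species[perm]
  cfg_p$coords <- cfg$coords[perm]
  c1 <- site_census(cfg); c2 <- site_census(cfg_p)
  expect_equal(c1$mean, c2$mean)
  # a single TM template gives mean 1 for TM and 0 elsewhere
  tm <- make_fixture("constructed_TM", ff = ff)
  ctm <- site_census(tm$config)
  expect_equal(ctm$mean[ctm$label == "TM"], 1)
  expect_equal(sum(ctm$mean), 1)
})

test_that("energy histograms conserve counts and handle degenerate input", {
  x <- c(rep(-5.2, 7))
  h <- energy_histogram(x, bin_width = 1)
  expect_equal(sum(h$count), 7)
  expect_equal(sum(h$count > 0), 1)
  set.seed(1)
  x2 <- rnorm(500, -40, 8)
  h2 <- energy_histogram(x2, bin_width = 2)
  expect_equal(sum(h2$count), 500)
  # integral consistency with the sample mean
  expect_equal(sum(h2$mid * h2$count) / sum(h2$count), mean(x2),
               tolerance = 0.05)
  expect_error(energy_histogram(x, bin_width = 0), "positive")
  df <- data.frame(lj = x2, coul = -x2, total = 0 * x2)
  expect_equal(attr(energy_histogram(df, "LJ"), "n"), 500)
})

test_that("pair distribution normalizes to unity for an ideal gas", {
  set.seed(5)
  A <- atom_species("ID", 0, 0)
  cfgs <- lapply(1:8, function(k) {
    coords <- lapply(1:120, function(i) matrix(runif(3, 0, 24), 1, 3))
    mip_configuration(list(ID = A), rep("ID", 120), coords, box = 24)
  })
  g <- pair_distribution(cfgs, "ID", "I", "ID", "I", dr = 0.5)
  sel <- g$r > 3 & g$r < 11
  expect_equal(mean(g$g[sel]), 1, tolerance = 0.05)
  expect_error(pair_distribution(cfgs, "ID", "I", "ID", "I", dr = 0),
               "positive")
  # hard-core gap: a lattice configuration has g = 0 below first contact
  lat <- as.matrix(expand.grid(x = seq(2, 22, 4), y = seq(2, 22, 4),
                               z = seq(2, 22, 4)))
  cfg_l <- mip_configuration(list(ID = A), rep("ID", nrow(lat)),
                             lapply(seq_len(nrow(lat)),
                                    function(i) matrix(lat[i, ], 1, 3)),
                             box = 24)
  gl <- pair_distribution(cfg_l, "ID", "I", "ID", "I", dr = 0.25)
  expect_true(all(gl$g[gl$r < 3.8] == 0))
})

test_that("separation factors follow the loading ratio with safe bounds", {
  iso <- function(N, sem = 0.01) {
    d <- data.frame(f = c(0.01, 0.1), loading = N, loading_molg = N / 100,
                    sem = sem)
    class(d) <- c("mip_isotherm", "data.frame"); attr(d, "adsorbate") <- "X"
    d
  }
  s1 <- separation_factor(iso(c(4, 8)), iso(c(2, 4)), 0.1)
  expect_equal(s1$S, 2)
  sid <- separation_factor(iso(c(4, 8)), iso(c(4, 8)), 0.01)
  expect_equal(sid$S, 1)
  s0 <- separation_factor(iso(c(4, 8)), iso(c(0, 0)), 0.1)
  expect_true(s0$lower_bound)
  expect_true(is.finite(s0$S))
  expect_error(separation_factor(iso(c(4, 8)), iso(c(2, 4)), 0.5),
               "ladder point")
  # with a volume the report carries K_i and free energies
  sv <- separation_factor(iso(c(4, 8)), iso(c(2, 4)), 0.1, volume = 20000)
  expect_equal(sv$K_A / sv$K_B, 2, tolerance = 1e-10)
  expect_equal(sv$dG_A - sv$dG_B,
               -KB * 298 * log(2), tolerance = 1e-9)
})

test_that("free-energy relations are exact closed forms", {
  expect_equal(binding_free_energy(1, 298)$dG, 0)
  K <- 123.4
  dG <- binding_free_energy(K, 298)$dG
  expect_equal(exp(-dG * 1000 / (8.314462618 * 298)), K, tolerance = 1e-10)
  expect_error(binding_free_energy(-1), "positive")
  # a 15 kJ/mol advantage at 298 K gives a selectivity above 400
  expect_gt(selectivity_from_dG(-15, 298), 400)
  expect_equal(selectivity_from_dG(-15, 298), 425.8, tolerance = 1e-3)
  expect_equal(selectivity_from_dG(0), 1)
})

test_that("orientational multiplicity counts symmetry-equivalent binding modes", {
  W1 <- orientational_multiplicity(ff$species$PRZ)
  W2 <- orientational_multiplicity(ff$species$PMD)
  expect_equal(as.integer(W1), 4)
  expect_equal(as.integer(W2), 2)
  # pyrimidine's four ordered modes split into two equal-energy classes
  expect_setequal(attr(W2, "orbits"), c(2L, 2L))
  expect_error(orientational_multiplicity(ff$species$MAA), "nitrogen")
  expect_equal(entropy_term(4, 2, 298), -1.717, tolerance = 1e-3)
  expect_equal(entropy_term(3, 3, 298), 0)
  expect_error(entropy_term(0, 2), "positive")
})
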