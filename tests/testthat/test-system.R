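test_that("random insertion builds the requested composition reproducibly", {
  comp <- c(PRZ = 2, MAA = 5, EGDMA = 6)
  cfg <- build_initial_configuration(ff, comp, 32, seed = 11)
  expect_equal(n_molecules(cfg), 13)
  expect_equal(as.vector(table(cfg$species)[c("PRZ", "MAA", "EGDMA")]),
               c(2, 5, 6))
  cfg2 <- build_initial_configuration(ff, comp, 32, seed = 11)
  expect_identical(cfg$coords, cfg2$coords)
  # empty composition gives a valid empty configuration
  cfg0 <- build_initial_configuration(ff, c(PRZ = 0), 20, seed = 1)
  expect_equal(n_molecules(cfg0), 0)
  # no intermolecular pair closer than the overlap threshold (minimum image)
  fl <- mipsim:::flat_config(cfg)
  L <- cfg$box
  viol <- 0
  for (i in seq_len(fl$natoms - 1)) {
    if (fl$sigma[i] == 0) next
    j <- (i + 1):fl$natoms
    j <- j[fl$mol[j] != fl$mol[i] & fl$sigma[j] > 0]
    if (!length(j)) next
    d <- sweep(fl$xyz[j, , drop = FALSE], 2, fl$xyz[i, ])
    d <- d - L * round(d / L)
    r <- sqrt(rowSums(d^2))
    viol <- viol + sum(r < 0.8 * (fl$sigma[i] + fl$sigma[j]) / 2 - 1e-9)
  }
  expect_equal(viol, 0)
})

test_that("quench and removal freeze the matrix and keep coordinates bitwise", {
  comp <- c(PRZ = 2, MAA = 4, EGDMA = 5)
  cfg <- build_initial_configuration(ff, comp, 30, seed = 3)
  m <- quench_and_remove(cfg, "PRZ")
  expect_s3_class(m, "mip_matrix")
  expect_true(m$frozen)
  expect_equal(n_molecules(m), 9)
  expect_false("PRZ" %in% m$species)
  # retained coordinates identical to full precision
  keep <- which(cfg$species != "PRZ")
  expect_identical(m$coords, cfg$coords[keep])
  # cell mass from united-atom masses
  expect_equal(m$mass_g, (4 * 86.090 + 5 * 198.218) / N_AVO, tolerance = 1e-6)
  # removing an absent species warns and is a no-op
  expect_warning(m2 <- quench_and_remove(cfg, "PMD"), "not present")
  expect_equal(n_molecules(m2), n_molecules(cfg))
  # removing nothing gives a frozen copy of the input
  m3 <- quench_and_remove(cfg, character(0))
  expect_identical(m3$coords, cfg$coords)
  expect_true(m3$frozen)
})

test_that("supercell replication preserves the periodic energy per cell", {
  cfg <- build_initial_configuration(ff, c(MAA = 6, EGDMA = 6), 24, seed = 5)
  m <- quench_and_remove(cfg, character(0))
  m8 <- replicate_supercell(m, c(2, 2, 2))
  expect_equal(n_molecules(m8), 8 * n_molecules(m))
  expect_equal(m8$box, 2 * m$box)
  expect_equal(m8$mass_g, 8 * m$mass_g)
  e1 <- total_energy(m, scheme = "gcmc")
  e8 <- total_energy(m8, scheme = "gcmc")
  expect_equal(e8$total, 8 * e1$total, tolerance = 1e-6)
  expect_identical(replicate_supercell(m, c(1, 1, 1)), m)
  expect_error(replicate_supercell(m, c(0, 1, 1)), "positive")
})

test_that("wrapping keeps molecules whole and leaves the energy unchanged", {
  cfg <- build_initial_configuration(ff, c(MAA = 5, EGDMA = 4), 26, seed = 8)
  cfg$coords <- lapply(cfg$coords, function(m) m + c(40, -15, 7))
  e0 <- total_energy(cfg, scheme = "gcmc")$total
  w <- wrap_configuration(cfg)
  expect_equal(total_energy(w, scheme = "gcmc")$total, e0, tolerance = 1e-8)
  for (i in seq_along(w$coords)) {
    tp <- w$topologies[[w$species[i]]]
    com <- colSums(w$coords[[i]] * tp$atoms$mass) / sum(tp$atoms$mass)
    expect_true(all(com >= 0 & com < w$box))
    # intramolecular geometry untouched
    expect_equal(as.numeric(dist(w$coords[[i]])),
                 as.numeric(dist(cfg$coords[[i]])), tolerance = 1e-12)
  }
})
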