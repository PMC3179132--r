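test_that("parameter tables load with correct structure and neutrality", {
  expect_setequal(names(ff$species), c("PRZ", "PMD", "MAA", "EGDMA"))
  for (sp in ff$species) {
    expect_equal(sum(sp$atoms$charge), 0, tolerance = 1e-12)
    expect_false(any(duplicated(sp$atoms$id)))
    expect_true(all(sp$atoms$sigma >= 0), info = sp$name)
    expect_true(all(sp$atoms$epsilon >= 0), info = sp$name)
  }
  # both templates carry exactly two ring nitrogens
  for (tname in c("PRZ", "PMD")) {
    ids <- ff$species[[tname]]$atoms$id
    expect_equal(sum(grepl("^N", ids)), 2)
  }
  expect_true(ff$species$PRZ$rigid && ff$species$PMD$rigid)
  expect_false(ff$species$MAA$rigid || ff$species$EGDMA$rigid)
  # bond adjacency is symmetric by construction of the distance matrix
  for (sp in ff$species) expect_equal(sp$excl, t(sp$excl))
})

test_that("Lennard-Jones kernel has the right zero, minimum and cross terms", {
  a <- list(sigma = 3.45, epsilon = 0.233)  # PRZ nitrogen
  b <- list(sigma = 3.02, epsilon = 0.773)  # MAA hydroxyl oxygen
  # like pair: zero at sigma, -eps at the minimum
  expect_equal(lj_energy(a, a, 3.45), 0, tolerance = 1e-12)
  expect_equal(lj_energy(a, a, 2^(1/6) * 3.45), -0.233, tolerance = 1e-12)
  # Lorentz-Berthelot cross pair at its minimum: -sqrt(0.233*0.773)
  scx <- (3.45 + 3.02) / 2
  expect_equal(lj_energy(a, b, 2^(1/6) * scx), -sqrt(0.233 * 0.773),
               tolerance = 1e-12)
  expect_equal(lj_energy(a, b, 2^(1/6) * scx), -0.424, tolerance = 1e-3)
  expect_error(lj_energy(a, b, 0), "positive")
  expect_error(lj_energy(a, b, -1), "positive")
  # strictly negative from sigma out to the cutoff, increasing past the min
  r <- seq(scx * 1.001, 14, length.out = 200)
  u <- lj_energy(a, b, r)
  expect_true(all(u < 0))
  r2 <- seq(2^(1/6) * scx, 14, length.out = 100)
  expect_true(all(diff(lj_energy(a, b, r2)) > 0))
})

test_that("Coulomb kernel matches direct evaluation and symmetry", {
  expect_equal(coulomb_energy(0, 0.5, 1.7), 0)
  expect_equal(coulomb_energy(-0.66, 0.37, 2.0),
               coulomb_energy(0.37, -0.66, 2.0))
  expect_equal(coulomb_energy(-0.66, 0.37, 2.0), -0.66 * 0.37 * COULK / 2,
               tolerance = 1e-12)
  expect_equal(coulomb_energy(-0.66, 0.37, 2.0), -169.6, tolerance = 1e-3)
  expect_error(coulomb_energy(1, 1, 0), "positive")
})

test_that("DSF Coulomb vanishes smoothly at the cutoff", {
  Rc <- 10.6
  expect_equal(dsf_coulomb_energy(1, -1, Rc), 0)
  expect_equal(dsf_coulomb_energy(1, -1, Rc + 0.5), 0)
  # energy and numerical radial derivative both continuous (-> 0) at Rc
  eps <- 1e-5
  expect_lt(abs(dsf_coulomb_energy(1, -1, Rc - eps)), 1e-3)
  du <- (dsf_coulomb_energy(1, -1, Rc - eps) -
           dsf_coulomb_energy(1, -1, Rc - 2 * eps)) / eps
  expect_lt(abs(du), 1e-3)
  # alpha -> 0 limit equals the undamped shifted-force form
  r <- c(2, 5, 8)
  usf <- COULK * 1 * -1 * (1 / r - 1 / Rc + (r - Rc) / Rc^2)
  expect_equal(dsf_coulomb_energy(1, -1, r, Rc, alpha = 1e-8), usf,
               tolerance = 1e-6)
  expect_error(dsf_coulomb_energy(1, 1, 5, alpha = -0.1), "non-negative")
})

test_that("Ewald summation reproduces the rock-salt Madelung constant", {
  a <- 5.64
  na <- rbind(c(0,0,0), c(.5,.5,0), c(.5,0,.5), c(0,.5,.5)) * a
  cl <- rbind(c(.5,0,0), c(0,.5,0), c(0,0,.5), c(.5,.5,.5)) * a
  cfg <- mip_configuration(
    list(NA1 = atom_species("Na", 0, 0, 1), CL1 = atom_species("Cl", 0, 0, -1)),
    c(rep("NA1", 4), rep("CL1", 4)),
    lapply(seq_len(8), function(i) matrix(rbind(na, cl)[i, ], 1, 3)),
    box = a)
  e <- ewald_energy(cfg)
  M <- -e$total * (a / 2) / (COULK * 4)
  expect_equal(M, 1.747565, tolerance = 2e-4)
  # invariance under the splitting parameter
  e2 <- ewald_energy(cfg, alpha = 1.2, kmax = 12)
  expect_equal(e2$total, e$total, tolerance = 1e-4)
})

test_that("Ewald matches a brute-force image sum for a dipole-free system", {
  # two antiparallel +/- dimers: net charge and net dipole both zero, so
  # the shell-by-shell direct sum converges to the Ewald (tinfoil) energy
  L <- 14
  xyz <- rbind(c(3, 3, 3), c(5, 3, 3), c(9, 9, 9), c(7, 9, 9))
  q <- c(1, -1, 1, -1)
  direct <- 0
  for (sx in -5:5) for (sy in -5:5) for (sz in -5:5) {
    sh <- c(sx, sy, sz) * L
    for (i in 1:4) for (j in 1:4) {
      if (all(sh == 0) && i >= j) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ] - sh)^2))
      w <- if (all(sh == 0)) 1 else 0.5
      direct <- direct + w * COULK * q[i] * q[j] / d
    }
  }
  cfg <- mip_configuration(
    list(P1 = atom_species("P", 0, 0, 1), M1 = atom_species("M", 0, 0, -1)),
    c("P1", "M1", "P1", "M1"),
    lapply(1:4, function(i) matrix(xyz[i, ], 1, 3)), box = L)
  e <- ewald_energy(cfg)
  expect_equal(e$total, direct, tolerance = 1e-3)
})

test_that("total_energy reduces to pair kernels and is component-additive", {
  A <- atom_species("A", 3.4, 0.5, 0.25)
  B <- atom_species("B", 3.0, 0.8, -0.25)
  cfg <- mip_configuration(list(A = A, B = B), c("A", "B"),
                           list(matrix(c(10, 10, 10), 1, 3),
                                matrix(c(13.3, 10, 10), 1, 3)), box = 40)
  e <- total_energy(cfg, scheme = "gcmc")
  expect_equal(e$lj, lj_energy(A$atoms, B$atoms, 3.3), tolerance = 1e-10)
  expect_equal(e$coul, dsf_coulomb_energy(0.25, -0.25, 3.3), tolerance = 1e-10)
  # random many-molecule configuration: LJ + COUL runs add up to "both"
  set.seed(42)
  fx <- make_fixture("ideal_gas_box", list(n = 20, box = 40), seed = 7, ff = ff)
  cfg2 <- fx$config
  both <- total_energy(cfg2, scheme = "gcmc")
  lj <- total_energy(cfg2, scheme = "gcmc", components = "LJ")
  cl <- total_energy(cfg2, scheme = "gcmc", components = "COUL")
  expect_equal(both$total, lj$total + cl$total, tolerance = 1e-9)
  expect_error(total_energy(mip_configuration(ff, character(), list(),
                                              box = 15), "mixture"),
               "twice the cutoff")
})

test_that("total_energy is invariant under rigid motion and wrapping", {
  fx <- make_fixture("ideal_gas_box", list(n = 12, box = 35), seed = 3, ff = ff)
  cfg <- fx$config
  e0 <- total_energy(cfg, scheme = "gcmc")$total
  # rigid translation of everything (with wrapping via minimum image)
  cfg_t <- cfg
  cfg_t$coords <- lapply(cfg$coords, function(m) m + 11.3)
  expect_equal(total_energy(cfg_t, scheme = "gcmc")$total, e0,
               tolerance = 1e-8)
  expect_equal(total_energy(wrap_configuration(cfg_t), scheme = "gcmc")$total,
               e0, tolerance = 1e-8)
  # global rotation of a non-periodic copy
  cfg_np <- cfg; cfg_np$box <- NA_real_
  e_np <- total_energy(cfg_np, scheme = "gcmc")$total
  set.seed(9); R <- mipsim:::random_rotation_matrix()
  cfg_r <- cfg_np
  cfg_r$coords <- lapply(cfg_np$coords, function(m) m %*% t(R))
  expect_equal(total_energy(cfg_r, scheme = "gcmc")$total, e_np,
               tolerance = 1e-8)
})
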