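test_that("fugacity-chemical potential conversion round-trips exactly", {
  st <- fugacity_mu_convert(ff$species$PRZ, 298, f = 0.1)
  back <- fugacity_mu_convert(ff$species$PRZ, 298, mu = st$mu)
  expect_equal(back$f, 0.1, tolerance = 1e-12)
  # mu strictly increasing in f
  fs <- 10^seq(-4, 2)
  mus <- vapply(fs, function(f)
    fugacity_mu_convert(ff$species$PRZ, 298, f = f)$mu, 1)
  expect_true(all(diff(mus) > 0))
  expect_error(fugacity_mu_convert(ff$species$PRZ, 298, f = -1), "positive")
  expect_error(fugacity_mu_convert(ff$species$PRZ, 298), "exactly one")
  # independent hand evaluation: Lambda and a rigid-rotor q_rot for PRZ
  m_kg <- 80.090 / 1000 / N_AVO
  kT <- KB_SI * 298
  lam <- 6.62607015e-34 / sqrt(2 * pi * m_kg * kT)
  xyz <- ff$species$PRZ$xyz * 1e-10
  mvec <- ff$species$PRZ$atoms$mass / 1000 / N_AVO
  com <- colSums(xyz * mvec) / sum(mvec)
  rr <- sweep(xyz, 2, com)
  It <- matrix(0, 3, 3)
  for (i in seq_along(mvec))
    It <- It + mvec[i] * (sum(rr[i, ]^2) * diag(3) - outer(rr[i, ], rr[i, ]))
  Ia <- eigen(It, symmetric = TRUE, only.values = TRUE)$values
  qr <- sqrt(pi) / 4 * (8 * pi^2 * kT / 6.62607015e-34^2)^1.5 * sqrt(prod(Ia))
  mu_hand <- kT * log(0.1 * lam^3 / (qr * kT)) * N_AVO / 1000
  expect_equal(st$mu, mu_hand, tolerance = 1e-9)
})

test_that("energy maps reduce to the pair potential and interpolate tightly", {
  fx <- make_fixture("toy_matrix_single_well")
  m <- fx$matrix; probe <- fx$probe
  maps <- build_energy_maps(m, probe, spacing = 0.2)
  wp <- m$coords[[1]][1, ]
  scx <- (fx$params$sigma + fx$params$probe_sigma) / 2
  ecx <- sqrt(fx$params$epsilon * fx$params$probe_epsilon)
  rc_eff <- min(10.6, m$box / 2)
  # on-node values along an axis equal the analytic LJ potential
  h <- maps$spacing
  for (k in c(10, 14, 20, 25)) {
    p <- wp + c(k * h - wp[1] + round((wp[1] - k * h) / m$box) * m$box, 0, 0)
    p <- wp; p[1] <- k * h
    r <- abs(p[1] - wp[1]); r <- min(r, m$box - r)
    u_ref <- if (r < rc_eff) {
      s6 <- (scx / r)^6; 4 * ecx * (s6^2 - s6)
    } else 0
    u_map <- map_energy(maps, matrix(p, 1, 3), 0)$lj
    expect_equal(u_map, u_ref, tolerance = max(1e-6, 1e-6 * abs(u_ref)))
  }
  # off-node probes in the attractive region: |map - direct| <= 0.5 kJ/mol
  set.seed(4)
  for (i in 1:25) {
    p <- wp + runif(3, -1, 1) * 4
    d <- p - wp; d <- d - m$box * round(d / m$box)
    r <- sqrt(sum(d^2))
    if (r < scx * 1.05) next
    u_ref <- if (r < rc_eff) { s6 <- (scx / r)^6; 4 * ecx * (s6^2 - s6) } else 0
    expect_lt(abs(map_energy(maps, matrix(p, 1, 3), 0)$lj - u_ref), 0.5)
  }
  # an empty matrix yields identically zero maps
  topo <- list(WELL = m$topologies$WELL, PROBE = probe)
  m0 <- quench_and_remove(mip_configuration(topo, character(), list(),
                                            box = 12), character(0))
  maps0 <- build_energy_maps(m0, probe, spacing = 0.5)
  expect_true(all(maps0$lj_grids[[1]] == 0))
  expect_warning(build_energy_maps(m, probe, spacing = 1.5), "bias")
})

test_that("GCMC obeys the ideal-gas grand ensemble with and without bias", {
  fx <- make_fixture("toy_matrix_single_well", params = list(epsilon = 0))
  m <- fx$matrix
  probe <- fx$probe; probe$atoms$epsilon <- 0
  maps <- build_energy_maps(m, probe, spacing = 0.3)
  f <- 2e7; Tk <- 298
  nexp <- f * 1e-30 / (KB_SI * Tk) * m$box^3
  r1 <- run_gcmc(m, probe, f, Tk, n_trials = 2e5, seed = 3, bias = FALSE,
                 maps = maps)
  expect_lt(abs(r1$loading - nexp), 3 * r1$loading_se + 0.05 * nexp)
  r2 <- run_gcmc(m, probe, f, Tk, n_trials = 2e5, seed = 4, bias = TRUE,
                 maps = maps)
  expect_lt(abs(r2$loading - nexp), 3 * r2$loading_se + 0.05 * nexp)
})

test_that("single-well GCMC matches exact grand-partition enumeration", {
  fx <- make_fixture("toy_matrix_single_well")
  m <- fx$matrix; probe <- fx$probe
  L <- m$box; Tk <- 298
  well <- m$coords[[1]][1, ]
  rc_eff <- L / 2
  scx <- (fx$params$sigma + fx$params$probe_sigma) / 2
  ecx <- sqrt(fx$params$epsilon * fx$params$probe_epsilon)
  mi <- function(d) d - L * round(d / L)
  bfac <- function(pts) {
    r2 <- mi(pts[, 1] - well[1])^2 + mi(pts[, 2] - well[2])^2 +
      mi(pts[, 3] - well[3])^2
    u <- ifelse(r2 < rc_eff^2,
                4 * ecx * ((scx^2 / r2)^6 - (scx^2 / r2)^3), 0)
    exp(-pmin(u, 200) / (KB * Tk))
  }
  h <- 0.3; g1 <- seq(h / 2, L - h / 2, by = h)
  Z1 <- sum(bfac(as.matrix(expand.grid(g1, g1, g1)))) * h^3
  # coarse pair-correction for the two-particle configurational integral
  hc <- 1.0; g2 <- seq(hc / 2, L - hc / 2, by = hc)
  p2 <- as.matrix(expand.grid(g2, g2, g2))
  bc <- bfac(p2)
  corr <- 0
  for (i in seq_len(nrow(p2))) {
    rr2 <- mi(p2[, 1] - p2[i, 1])^2 + mi(p2[, 2] - p2[i, 2])^2 +
      mi(p2[, 3] - p2[i, 3])^2
    s6 <- (fx$params$probe_sigma^2 / pmax(rr2, 1e-9))^3
    u12 <- ifelse(rr2 < rc_eff^2, 4 * fx$params$probe_epsilon * (s6^2 - s6), 0)
    corr <- corr + bc[i] * sum(bc * (1 - exp(-pmin(u12, 200) / (KB * Tk))))
  }
  Q2 <- (sum(bc)^2 - corr) * hc^6 / 2
  maps <- build_energy_maps(m, probe, spacing = 0.2)
  z <- 3e-4
  nexp <- (z * Z1 + 2 * z^2 * Q2) / (1 + z * Z1 + z^2 * Q2)
  f <- z * KB_SI * Tk * 1e30
  r <- run_gcmc(m, probe, f, Tk, n_trials = 3e5, seed = 5, maps = maps)
  expect_lt(abs(r$loading - nexp), 4 * r$loading_se + 0.05 * nexp)
  # the insertion bias must not change the sampled distribution
  r_nb <- run_gcmc(m, probe, f, Tk, n_trials = 3e5, seed = 6, maps = maps,
                   bias = FALSE)
  expect_lt(abs(r_nb$loading - r$loading),
            4 * sqrt(r$loading_se^2 + r_nb$loading_se^2) + 0.05 * nexp)
  # loading in mol/g is <N> / (N_A m) by construction
  expect_equal(r$loading_molg, r$loading / N_AVO / m$mass_g, tolerance = 1e-12)
})

test_that("isotherm ladders warm-start, reduce and stay analytic for ideal gas", {
  fx <- make_fixture("toy_matrix_single_well", params = list(epsilon = 0))
  m <- fx$matrix
  probe <- fx$probe; probe$atoms$epsilon <- 0
  expect_error(isotherm(m, probe, c(1, 1)), "strictly increasing")
  fs <- c(5e6, 1e7, 2e7)
  iso <- isotherm(m, probe, fs, n_trials = 1.2e5, seed = 2)
  pred <- fs * 1e-30 / (KB_SI * 298) * m$box^3
  expect_equal(iso$loading, pred, tolerance = 0.12)
  # ladder of length 1 reduces to a single run with matching mean
  iso1 <- isotherm(m, probe, fs[1], n_trials = 1.2e5, seed = 2)
  expect_equal(iso1$loading,
               pred[1], tolerance = 0.15)
})
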