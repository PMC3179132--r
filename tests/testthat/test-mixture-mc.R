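test_that("mass density follows the closed-form unit conversion", {
  cfg <- mip_configuration(ff, "PRZ", list(ff$species$PRZ$xyz + 5), box = 10)
  # one 80.09 g/mol molecule in (10 A)^3: hand unit conversion
  expect_equal(density(cfg), 80.090 / N_AVO / 1e-24, tolerance = 1e-4)
  expect_equal(density(cfg), 132.98, tolerance = 1e-3)
  # empty box
  cfg0 <- mip_configuration(ff, character(), list(), box = 10)
  expect_equal(density(cfg0), 0)
  # doubling the edge divides the density by 8
  cfg2 <- cfg; cfg2$box <- 20
  expect_equal(density(cfg2), density(cfg) / 8, tolerance = 1e-12)
})

test_that("NPT sampler reproduces the ideal-gas volume distribution", {
  # all interactions off: <V> = (N + 1) kB T / P
  fx <- make_fixture("ideal_gas_box", list(n = 12, box = 30), seed = 2, ff = ff)
  Tk <- 298; P <- 2e6
  sch <- npt_schedule(temperature = Tk, pressure = P, n_moves = 1.2e5,
                      vol_every = 4, step_lnv = 0.1, sample_every = 50,
                      seed = 4, equil_fraction = 0.4)
  eq <- suppressWarnings(equilibrate_npt(fx$config, sch, ideal_gas = TRUE))
  vexp <- 13 * KB_SI * Tk / P * 1e30
  prod <- eq$trace[eq$trace$move > 0.4 * sch$n_moves, ]
  est <- mipsim:::block_mean_se(prod$volume, 6)
  expect_lt(abs(est$mean - vexp), 4 * est$se + 0.02 * vexp)
})

test_that("NPT density of a dilute LJ fluid matches the virial oracle", {
  # supercritical single-site LJ gas; the exact second-virial quadrature is
  # the independent equation-of-state oracle at this low density
  fx <- make_fixture("lj_fluid_box", list(n = 40, box = 60), seed = 6)
  sig <- 3.73; eps <- 1.2305; Tk <- 1.5 * eps / KB   # T* = 1.5
  # B2 by quadrature (A^3)
  r <- seq(0.35, 30, by = 0.005)
  u <- 4 * eps * ((sig / r)^12 - (sig / r)^6)
  B2 <- -2 * pi * sum((exp(-u / (KB * Tk)) - 1) * r^2) * 0.005
  rho_target <- 0.05 / sig^3                        # rho* = 0.05
  # pressure from the virial series at that density
  P_int <- KB * Tk * (rho_target + B2 * rho_target^2)   # kJ/mol/A^3
  P_Pa <- P_int * 1000 / N_AVO / 1e-30
  cfg <- fx$config
  cfg$temperature <- Tk
  sch <- npt_schedule(temperature = Tk, pressure = P_Pa, n_moves = 2.5e5,
                      vol_every = 8, step_lnv = 0.05, step_translate = 3,
                      sample_every = 100, seed = 9, equil_fraction = 0.5)
  eq <- suppressWarnings(equilibrate_npt(cfg, sch, cutoff = 12))
  prod <- eq$trace[eq$trace$move > 0.5 * sch$n_moves, ]
  rho_sim <- 40 / mean(prod$volume)
  expect_equal(rho_sim, rho_target, tolerance = 0.06)
})

test_that("fixed-temperature sampling is Boltzmann-distributed (detailed balance)", {
  # two single-site LJ atoms at fixed T inside a tether: the radial
  # distribution must follow r^2 exp(-beta u(r)); compare mean separation
  # against direct quadrature
  A <- atom_species("AR", 3.4, 1.0)
  tff <- toy_ff(AR = A)
  Tk <- 180; beta <- 1 / (KB * Tk); tether <- 8
  st <- mipsim:::species_cpp(A)
  set.seed(21)
  xt <- matrix(0, 1, 3); xp <- matrix(c(4, 0, 0), 1, 3)
  rs <- c()
  for (seg in 1:300) {
    r <- mipsim:::cpp_anneal(st, st, xt, xp,
                             matrix(c(Tk, 400, 0.6, 0.3, 0.3), 1), tether)
    xt <- r$final_xyz_template; xp <- r$final_xyz_partner
    if (seg > 50) rs <- c(rs, sqrt(sum((xt - xp)^2)))
  }
  rr <- seq(0.02, tether, by = 0.02)
  u <- 4 * 1.0 * ((3.4 / rr)^12 - (3.4 / rr)^6)
  w <- rr^2 * exp(-beta * pmin(u, 100))
  r_exp <- sum(rr * w) / sum(w)
  expect_equal(mean(rs), r_exp, tolerance = 0.08)
})

test_that("pathological acceptance rates are reported as warnings", {
  fx <- make_fixture("lj_fluid_box", list(n = 15, box = 25), seed = 1)
  sch <- npt_schedule(n_moves = 6000, step_translate = 24,
                      equil_fraction = 0, sample_every = 100, seed = 2)
  expect_warning(equilibrate_npt(fx$config, sch, cutoff = 10),
                 "acceptance")
})
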