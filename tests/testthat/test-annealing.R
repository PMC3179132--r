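test_that("annealing a single-site LJ dimer finds the closed-form minimum", {
  A <- atom_species("AR", 3.4, 1.0)
  tff <- toy_ff(AR = A)
  r <- anneal_dimer(tff, "AR", "AR", n_cycles = 2, moves_per_leg = 6000,
                    t_high = 120, t_low = 2, seed = 1, tether = 5)
  expect_equal(r$e_total, -1.0, tolerance = 5e-3)
  expect_equal(r$e_lj, -1.0, tolerance = 5e-3)
  expect_equal(r$e_coul, 0)
  d <- sqrt(sum((r$xyz_template[1, ] - r$xyz_partner[1, ])^2))
  expect_equal(d, 2^(1 / 6) * 3.4, tolerance = 1e-2)
})

test_that("schedule validation rejects inverted temperature ranges", {
  expect_error(anneal_dimer(ff, "PRZ", "MAA", t_high = 10, t_low = 500),
               "t_low < t_high")
  expect_error(anneal_dimer(ff, "PRZ", "MAA", n_cycles = 0), "at least one")
  expect_error(anneal_dimer(ff, "XX", "MAA"), "unknown species")
})

test_that("template-partner complexes show the expected energetic ordering", {
  # template ordering is preserved for each partner: the pyrazine complex
  # binds more strongly than the pyrimidine one
  rzm <- anneal_best(ff, "PRZ", "MAA", seeds = 1:3, n_cycles = 3,
                     moves_per_leg = 8000)
  rdm <- anneal_best(ff, "PMD", "MAA", seeds = 1:3, n_cycles = 3,
                     moves_per_leg = 8000)
  expect_lt(rzm$e_total, rdm$e_total)
  # energy decomposition is exactly additive
  expect_equal(rzm$e_lj + rzm$e_coul, rzm$e_total, tolerance = 1e-10)
  # the acid hydrogen forms a hydrogen bond with a ring nitrogen by the
  # module's own criterion (N...H < 2.5 A) and the LJ term of the
  # hydrogen-bonded complex is slightly positive (atom overlap)
  dh <- rzm$distances
  expect_lt(min(dh$dist[dh$contact == "N...H(MAA)"]), 2.5)
  expect_gt(rzm$e_lj, 0)
  # seed-to-seed reproducibility of the monomer-complex minimum
  expect_lt(rzm$spread, 1.5)
})

test_that("multi-seed wrapper reports best-of-seeds and spread", {
  r <- anneal_best(ff, "PMD", "MAA", seeds = 1:3, n_cycles = 2,
                   moves_per_leg = 4000)
  expect_equal(length(r$seed_energies), 3)
  expect_equal(r$e_total, min(r$seed_energies), tolerance = 1e-12)
  expect_gte(r$spread, 0)
})

test_that("complex metrics report the characteristic contact distances", {
  r <- anneal_dimer(ff, "PRZ", "EGDMA", n_cycles = 2, moves_per_leg = 6000,
                    seed = 2)
  m <- complex_metrics(r, ff)
  expect_equal(unname(m$energies["total"]),
               unname(m$energies["lj"] + m$energies["coul"]))
  expect_true(all(m$distances$dist > 0))
  expect_setequal(unique(m$distances$contact),
                  c("N...C7/C8(X)", "ringC...O5/O12(X)"))
  # at least one nitrogen is engaged with the ester bridge carbons
  expect_lt(min(m$distances$dist[m$distances$contact == "N...C7/C8(X)"]), 4.5)
})
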