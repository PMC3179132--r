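# loaded once per test run; the parameter tables are validated on load
ff <- load_forcefield()

KB <- 0.008314462618     # kJ/mol/K
COULK <- 1389.35457644382
KB_SI <- 1.380649e-23
N_AVO <- 6.02214076e23

# single-site helper species for reduction tests
atom_species <- function(name, sigma, epsilon, charge = 0, mass = 16) {
  mipsim:::single_atom_topology(name, substr(name, 1, 1), sigma, epsilon,
                                charge, mass)
}

# a minimal force-field wrapper around ad-hoc topologies
toy_ff <- function(...) {
  sp <- list(...)
  structure(list(constants = list(), species = sp),
            class = "mip_forcefield")
}
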