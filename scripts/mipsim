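#!/usr/bin/env Rscript
# Thin command-line front end over the mipsim package.
#
#   mipsim mix      --template PRZ --scale 0.25 --moves 7e5 --seed 1 --out mix.xyz
#   mipsim quench   --in mix.xyz --remove PRZ --out matrix.xyz
#   mipsim adsorb   --matrix matrix.xyz --adsorbate PRZ --fugacities 1e-4,1e-3 \
#                   --trials 2e5 --seed 1 --out isotherm.csv [--lj-only]
#   mipsim anneal   --template PRZ --partner MAA --seeds 5 --out complex.xyz
#   mipsim classify --in snapshot.xyz --out census.csv
#   mipsim gofr     --in snapshot.xyz --a PRZ:N3 --b MAA:H1 --out gofr.csv
#   mipsim report   --template iso_t.csv --analogue iso_a.csv --fstar 1e-4 \
#                   --out report.json

suppressPackageStartupMessages({
  library(optparse)
  library(mipsim)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1) stop("usage: mipsim <mix|quench|adsorb|anneal|classify|gofr|report> ...")
cmd <- argv[1]
rest <- argv[-1]
ff <- load_forcefield()

getopts <- function(spec) parse_args(OptionParser(option_list = spec), rest)

if (cmd == "mix") {
  o <- getopts(list(
    make_option("--template", default = "PRZ"),
    make_option("--scale", type = "double", default = 0.25),
    make_option("--moves", type = "double", default = 7e5),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--box", type = "double", default = NA),
    make_option("--out", default = "mix.xyz")))
  comp <- setNames(round(c(10, 80, 200) * o$scale), c(o$template, "MAA", "EGDMA"))
  mass <- sum(vapply(names(comp), function(s) ff$species[[s]]$mass, 1) * comp)
  box <- if (is.na(o$box)) (mass / 6.02214076e23 / 900 * 1e27)^(1 / 3) else o$box
  cfg <- build_initial_configuration(ff, comp, box, seed = o$seed,
                                     overlap_factor = 0.72, max_attempts = 30000)
  eq <- equilibrate_npt(cfg, npt_schedule(n_moves = o$moves, seed = o$seed))
  print(eq)
  write_xyz(eq$config, o$out)
  utils::write.csv(eq$trace, sub("\\.xyz$", "_trace.csv", o$out), row.names = FALSE)
  write_provenance(list(seed = o$seed, moves = o$moves, density = eq$density,
                        density_se = eq$density_se),
                   paste0(o$out, ".json"))
} else if (cmd == "quench") {
  o <- getopts(list(make_option("--in", dest = "infile"),
                    make_option("--remove", default = "PRZ"),
                    make_option("--supercell", type = "integer", default = 1L),
                    make_option("--out", default = "matrix.xyz")))
  cfg <- read_xyz(o$infile, ff)
  m <- quench_and_remove(cfg, strsplit(o$remove, ",")[[1]])
  if (o$supercell > 1) m <- replicate_supercell(m, rep(o$supercell, 3))
  write_xyz(m, o$out)
  cat("matrix:", n_molecules(m), "molecules,", signif(m$mass_g, 4), "g/cell\n")
} else if (cmd == "adsorb") {
  o <- getopts(list(make_option("--matrix"),
                    make_option("--adsorbate", default = "PRZ"),
                    make_option("--fugacities", default = "1e-4,1e-3"),
                    make_option("--trials", type = "double", default = 2e5),
                    make_option("--seed", type = "integer", default = 1L),
                    make_option("--lj-only", dest = "ljonly", action = "store_true",
                                default = FALSE),
                    make_option("--paper-scale", dest = "paper", action = "store_true",
                                default = FALSE),
                    make_option("--out", default = "isotherm.csv")))
  m <- read_xyz(o$matrix, ff)
  if (o$paper) { m <- replicate_supercell(m, c(2, 2, 2)); o$trials <- 2e7 }
  fs <- as.numeric(strsplit(o$fugacities, ",")[[1]])
  iso <- isotherm(m, ff$species[[o$adsorbate]], fs, n_trials = o$trials,
                  seed = o$seed,
                  interactions = if (o$ljonly) "LJ_only" else "both")
  utils::write.csv(as.data.frame(iso), o$out, row.names = FALSE)
  print(as.data.frame(iso))
  write_provenance(list(seed = o$seed, trials = o$trials, adsorbate = o$adsorbate,
                        lj_only = o$ljonly), paste0(o$out, ".json"))
} else if (cmd == "anneal") {
  o <- getopts(list(make_option("--template", default = "PRZ"),
                    make_option("--partner", default = "MAA"),
                    make_option("--seeds", type = "integer", default = 5L),
                    make_option("--out", default = "complex.xyz")))
  r <- anneal_best(ff, o$template, o$partner, seeds = seq_len(o$seeds))
  print(r)
  cfg <- mip_configuration(ff, c(o$template, o$partner),
                           list(r$xyz_template, r$xyz_partner), box = NA_real_)
  write_xyz(cfg, o$out)
  write_provenance(list(e_total = r$e_total, e_lj = r$e_lj, e_coul = r$e_coul,
                        seeds = o$seeds, spread = r$spread),
                   paste0(o$out, ".json"))
} else if (cmd == "classify") {
  o <- getopts(list(make_option("--in", dest = "infile"),
                    make_option("--out", default = "census.csv")))
  cfg <- read_xyz(o$infile, ff)
  cen <- site_census(cfg)
  utils::write.csv(cen, o$out, row.names = FALSE)
  print(cen)
} else if (cmd == "gofr") {
  o <- getopts(list(make_option("--in", dest = "infile"),
                    make_option("--a", dest = "sa", default = "PRZ:N3"),
                    make_option("--b", dest = "sb", default = "MAA:H1"),
                    make_option("--dr", type = "double", default = 0.1),
                    make_option("--out", default = "gofr.csv")))
  cfg <- read_xyz(o$infile, ff)
  pa <- strsplit(o$sa, ":")[[1]]; pb <- strsplit(o$sb, ":")[[1]]
  g <- pair_distribution(cfg, pa[1], pa[2], pb[1], pb[2], dr = o$dr)
  utils::write.csv(g, o$out, row.names = FALSE)
} else if (cmd == "report") {
  o <- getopts(list(make_option("--template", dest = "iso_t"),
                    make_option("--analogue", dest = "iso_a"),
                    make_option("--fstar", type = "double", default = 1e-4),
                    make_option("--out", default = "report.json")))
  mk <- function(p) { d <- utils::read.csv(p); class(d) <- c("mip_isotherm", "data.frame"); d }
  s <- separation_factor(mk(o$iso_t), mk(o$iso_a), o$fstar)
  print(s)
  write_provenance(list(S = s$S, f = s$f, N_A = s$N_A, N_B = s$N_B,
                        lower_bound = s$lower_bound), o$out)
} else {
  stop("unknown subcommand: ", cmd)
}
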