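---
title: "Models and methods in mipsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mipsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`mipsim` implements a quenched-annealed atomistic model of molecularly
imprinted polymers (MIPs). A pre-polymerization liquid of template
(pyrazine, PRZ, or pyrimidine, PMD), functional monomer (methacrylic acid,
MAA) and cross-linker (ethylene glycol dimethacrylate, EGDMA) in
10:80:200 proportion is equilibrated at 298 K and 1 atm; polymerization is
idealized as an instantaneous quench that freezes every molecule in its
instantaneous position, orientation and conformation; the template is then
deleted, and the frozen porous matrix rebinds the template or its
structural analogue in grand canonical Monte Carlo (GCMC) adsorption runs.
Selectivity is quantified by the separation factor
$S(A/B) = N_A(f^*)/N_B(f^*)$, the ratio of equilibrium loadings at a
common fugacity, with the dilute reservoir treated as an ideal gas.

The model's central question is mechanistic: which binding-site motifs --
template + monomer (TM, TM2), template + cross-linker (TX, TX2), or the
mixed motif TMX -- carry molecular recognition, and how do the association
equilibria of the liquid mixture map onto the site population of the final
material.

# Force field

All species are united-atom: CH$_x$ groups are single sites, and the only
explicit hydrogen is the MAA acid hydrogen (a charge site with no
Lennard-Jones core). Nonbonded interactions are 12-6 Lennard-Jones plus
fixed point charges; the parameter tables ship in
`inst/extdata/forcefield.yaml` (sigma printed in nm, converted to
Angstrom on load; energies in kJ/mol; charges in e) and are validated
against embedded column checksums at load time. Every molecule is exactly
charge-neutral. Cross interactions use Lorentz--Berthelot combining
(arithmetic sigma, geometric epsilon), the TraPPE convention.

PRZ and PMD are rigid; their reference geometry is an ideal aromatic
hexagon with a 1.40 Angstrom ring bond. MAA and EGDMA are flexible:
bond lengths and bending angles are held at standard TraPPE-style
reference values (a z-matrix in the parameter file) and flexibility
enters through rotations about the listed single bonds, each carrying a
cosine-series torsion potential
$U(\phi) = \tfrac12 c_1 (1+\cos\phi) + \tfrac12 c_2 (1-\cos 2\phi) +
\tfrac12 c_3 (1+\cos 3\phi)$.
The torsion constants are a replaceable parameter set chosen at
literature magnitudes (stiff 2-fold terms keeping ester and conjugated
fragments planar, weak 3-fold terms on the C--O and C--C single bonds of
the glycol bridge); the acid O--H torsion favors the syn conformer.
Intramolecular nonbonded pairs separated by one to three bonds are
excluded; more distant pairs interact with full-range LJ plus bare
Coulomb.

Electrostatics are evaluated three ways, each where the stage calls for
it:

* **Ewald summation** (real + reciprocal + self + exclusion corrections,
  uniform-background term for non-neutral source sets) for matrix
  potential maps and reference energies. The splitting parameter and
  k-space cutoff are auto-selected from a $10^{-4}$ relative accuracy
  target.
* **Damped shifted-force (DSF) Coulomb** with damping
  $\alpha = 0.2\,\text{\AA}^{-1}$, which vanishes together with its
  radial derivative at the cutoff, for adsorbate--adsorbate interactions
  (10.6 Angstrom cutoff) and for the liquid-stage sampler (see below).
* **Bare full-range Coulomb** for isolated dimers, where cutoffs are a
  condensed-phase device and unnecessary.

Liquid-stage LJ interactions are cut at 14 Angstrom (capped at half the
box edge) with analytic long-tail corrections; adsorption-stage LJ and
Coulomb are cut at 10.6 Angstrom with no corrections.

# Samplers

## Liquid mixture (NPT Monte Carlo)

The pre-polymerization mixture is sampled with Metropolis Monte Carlo in
the isothermal--isobaric ensemble: molecular translations, rigid
rotations, torsion rotations for flexible species, and logarithmic volume
moves (one per molecule-move sweep) targeting
$\pi(V) \propto V^{N}\exp(-\beta U - \beta P V)$.
Downstream stages consume ensemble averages and frozen configurations,
not dynamics, so a Markov-chain sampler of the same ensemble is used in
place of molecular dynamics. Within the move loop, electrostatics use the
DSF pair potential (tabulated radial factor, 16k bins): per-move
incremental lattice summation would dominate the runtime for no
measurable effect on the densities and association statistics consumed
downstream; the choice is recorded in each run's provenance. Maximum
displacements auto-tune to a 30--50% acceptance window during the
equilibration fraction of the chain only, so production sampling is a
homogeneous chain obeying detailed balance. Initial configurations come
from random sequential insertion with a hard-overlap threshold of
0.8 sigma (bulkiest species first), and the reported density carries a
block standard error plus a two-halves stationarity check.

## Quench, template removal, supercell

`quench_and_remove()` keeps retained coordinates bitwise identical, sets
an immutability flag and records provenance (seed, chain length,
realization index). The reference protocol generates three independent
matrix realizations per system. `replicate_supercell()` tiles the cubic
cell (the adsorption stage of the full-scale protocol runs on a 2x2x2
supercell); the periodic energy per original cell is preserved exactly,
which the test suite verifies.

## Adsorption (energy-biased GCMC)

Rigid adsorbates exchange with an ideal reservoir at fixed fugacity $f$;
the acceptance rules use the activity $z = f/k_BT$ directly, so the
rotational partition function cancels (it is evaluated -- classical rigid
rotor with symmetry numbers 4 for PRZ and 2 for PMD -- only to report
chemical potentials). Adsorbate--matrix energies come from precomputed
interaction maps: one LJ grid per distinct adsorbate atom type (10.6
Angstrom cutoff, no corrections) and one Ewald electrostatic potential
grid, combined by periodic trilinear interpolation; default spacing is
0.35 Angstrom (interpolation tightness is tested at 0.2 Angstrom against
direct summation). Insertions are energy-biased: the cell is partitioned
into ~2 Angstrom cubelets, a cubelet is drawn with probability
proportional to $\exp(-\beta U_{\min})$ (floored at 1% of uniform so no
region is unreachable), and the exact inverse generation density enters
the acceptance probability, leaving the sampled distribution unchanged --
verified against ideal-gas and exact two-level enumeration oracles, and
by agreement between biased and unbiased runs. Insertion, deletion,
translation and rotation trials are selected with equal probability; the
first half of each chain is discarded; per-molecule adsorbate--matrix LJ
and Coulomb energies are sampled for histograms, and full adsorbate
snapshots are kept for the binding-site census. Isotherms warm-start each
fugacity from the previous point's final configuration and average over
matrix realizations with the standard error of the mean. The
`LJ_only` mode zeroes all charges -- the dispersion-only control that
separates electrostatic recognition from packing effects.

## Dimer annealing

Association motifs are defined from simulated annealing of isolated
template--partner pairs (full-range potentials, no box). Each cycle heats
the pair to 500 K and cools it geometrically to 10 K (25 stages, with a
short near-zero polish), with move sizes shrinking as $\sqrt{T}$; a
15 Angstrom center-of-mass tether keeps the pair associated while hot.
The configurations at the end of each cooling phase are the candidates,
and the complex reported is the candidate with the lowest
*intermolecular* LJ+Coulomb energy -- intramolecular strain participates
in sampling but is excluded from the reported interaction energy. A
multi-seed wrapper reports the best-of-seeds result and the seed-to-seed
spread. On this potential surface the monomer complexes converge
reproducibly to the hydrogen-bonded minimum (acid H to ring N, with the
characteristic slightly positive LJ term); the cross-linker complexes
relax into flat stacked/wrapped arrangements in which the ester plates
lie against the aromatic ring, which are deeper than the in-plane
tip-contact geometry whose two ~3.4 Angstrom contacts define the
association criteria. The classifier thresholds are therefore anchored to
the contact geometry, not to the global minimum.

# Analysis definitions

* **Association criteria** (strict inequalities, minimum image): monomer
  association = template N within 2.5 Angstrom of the MAA acid H *and* a
  ring carbon flanking that N within 4 Angstrom of MAA O4; cross-linker
  association = N within 4 Angstrom of EGDMA C7/C8 *and* the flanking
  carbon within 4 Angstrom of O5/O12. The thresholds sit at the first
  minima of the corresponding pair distribution functions. Each nitrogen
  carries at most one association; if a nitrogen satisfies both a monomer
  and a cross-linker criterion the partner with the lower pair interaction
  energy wins (configurable to nearest-distance). Per-template labels
  TM/TM2/TX/TX2/TMX/NONE are mutually exclusive and exhaustive, so the
  census never exceeds one complex per template. Higher-order complexes
  are deliberately not counted. A nitrogen engaged while the other sits in
  an unclassified contact maps to the single-association label.
* **Energy histograms** bin per-molecule adsorbate--matrix energies
  (default 1 kJ/mol bins); LJ, Coulomb and total components are binned
  separately because the total distribution is not a convolution of the
  parts.
* **Pair distribution functions** are ideal-gas normalized over
  intermolecular pairs.
* **Selectivity**: $S$ from loadings at exact ladder points (log-linear
  interpolation behind a flag); when the analogue loading is exactly zero
  the report flags a lower bound using the loading's standard error
  instead of dividing by zero. Partition coefficients
  $K_i = (N_i/V)/B_i$, $\Delta G_i = -RT\ln K_i$, and
  $S = \exp(-\Delta\Delta G/RT)$ connect the loading picture to the
  free-energy picture; the conventional decomposition slots other than
  translational+rotational and polar terms are reported as placeholders
  (they cancel between these near-identical rigid templates, and there is
  no solvent).
* **Orientational multiplicity**: ordered (nitrogen, flanking carbon)
  binding modes are merged into equal-energy classes by automorphisms of
  the charge-labelled molecular graph; $W$ is the size of the largest
  class -- a single class of 4 for pyrazine; two classes of 2 for
  pyrimidine, so either choice of class gives $W=2$. The entropic term is
  $-RT\ln(W_1/W_2)$.

# Fixtures and what the tests show

`make_fixture()` regenerates, deterministically from (name, parameters,
seed): hand-constructed TM/TMX/TX2/NONE geometries (classified by
construction), a single-well toy matrix whose grand-canonical occupancy
is enumerable, an ideal-gas box, and a single-site LJ fluid box. These
power the oracle tests: Madelung-constant and brute-force image sums for
Ewald; DSF continuity at the cutoff; ideal-gas $\langle N\rangle = fV/k_BT$
and $\langle V\rangle = (N{+}1)k_BT/P$; a second-virial quadrature as the
equation-of-state oracle for a dilute LJ fluid; exact grand-partition
enumeration for the toy well; supercell energy scaling. Passing these
shows the samplers target the right distributions and the energy kernels
are correct; it does not show that the united-atom force field reproduces
any particular laboratory material -- the model has no solvent, no
explicit polymerization chemistry, an idealized instantaneous quench, and
fixed bond angles for the flexible species.

# Problem sizes and numerical choices

The package's desk-scale study conditions, used by the test suite and the
pipeline preset, are: quarter composition (3 template / 20 MAA /
50 EGDMA, ~26.5 Angstrom box), chains of $10^5$--$10^6$ NPT moves, a
single 1x cell per matrix realization, and GCMC chains of a few
$10^5$ trials per fugacity -- sizes chosen so a full pipeline runs in
minutes on one core while keeping the acceptance statistics meaningful.
The full-scale protocol (290 molecules, three realizations, 2x2x2
supercells, $2\times10^7$ trials per isotherm point) is available behind
the same interfaces (`--paper-scale` in the CLI) and takes hours to days.
Further numerical choices: LJ grid values are clamped at $10^5$ kJ/mol
(steep-core regions are rejected anyway); grid cutoffs are capped at half
the box edge so no periodic image is double-counted; Ewald parameters
derive from the accuracy target; the DSF table uses 16384 bins (linear
interpolation error far below thermal noise); volume moves that would
shrink the box below twice the cutoff are rejected, so the liquid cutoff
is pre-sized from the expected equilibrium edge; annealing reports are
recomputed exactly (not from tabulated kernels) at the reported
configuration.

# Known limitations

* No solvent: the mixture is the extreme porogen-free case, and the
  $\Delta G_{solv}$ slot is structurally zero.
* No explicit polymerization; the quench overestimates how faithfully a
  real network preserves solution complexes.
* Fixed bends for flexible species fold bending entropy into the torsion
  constants; the torsion set is a replaceable parameter file.
* Single-realization desk-scale runs carry large realization-to-realization
  variance in site populations; the full protocol averages three
  realizations.
* The annealing search is a global stochastic optimizer: on surfaces with
  stacked minima deeper than the contact-defined complex it reports the
  former (see the annealing section), which is a property of the potential
  surface rather than of the search.
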