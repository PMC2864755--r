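---
title: "Models and methods behind designkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind designkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(designkit)
```

# The design model

`designkit` performs fixed-backbone computational protein design: the
backbone of a template structure is held rigid, side chains occupy
discrete rotamers, and sequences are selected to minimize a folding
free energy

$$\Delta G_{fold} = E_{vdw} + E_{coulomb}/\varepsilon +
  s\,\textstyle\sum_i \sigma_i A_i \;-\; \sum_p E^{unf}(X_p),$$

the CASA (Coulomb + Accessible Surface Area) effective energy.  The
van der Waals term uses a united-atom convention: aliphatic hydrogens
are folded into their carbons and only polar hydrogens (O-H, N-H,
S-H) are explicit.  Electrostatics are screened by a uniform
dielectric $\varepsilon = 10$ during design ($\varepsilon = 20$
during structure preparation, where a light conjugate-gradient
relaxation is available via `minimize_structure()`).  Solvation is a
per-atom surface term with class coefficients $\sigma$ of
0.012 kcal/mol/&Aring;&sup2; for carbon and sulfur, $-0.06$ for oxygen and
nitrogen, 0 for hydrogen and $-0.15$ for atoms of ionized groups,
times an overall scale $s$ (default 1).

The unfolded state of each amino-acid type $X$ is an Ala-$X$-Ala
tripeptide: $E^{unf}(X)$ is the minimum CASA energy over a small
catalog of backbone conformations — $(\phi,\psi)$ of
$(-57,-47)$, $(-119,113)$, $(-75,145)$ and $(-180,180)$ — crossed
with the rotamers of $X$.  The catalog is configurable; these four
cover helical, sheet, polyproline-II-like and extended geometry.
An optional per-type correction can be calibrated with
`calibrate_corrections()` so that design reproduces a target
amino-acid composition; corrections default to zero.  Note the sign:
because the correction is *subtracted* together with $E^{unf}$,
raising a type's correction favours that type, so over-represented
types have their correction lowered during calibration.

Native cysteines, glycines and prolines have structural roles
(disulfides, backbone flexibility, backbone geometry) that a rigid
backbone and a tripeptide unfolded model do not describe, so those
positions are frozen: their native side chains are kept at input
coordinates and no position may mutate *into* C, G or P.

## Force-field parameters and rotamers

The shipped parameter set (`default_parameters()`) is a
self-contained united-atom table in the spirit of classic
polar-hydrogen force fields: integral net charges per residue,
element-based Lennard-Jones well depths and radii, and the four
solvation classes above.  It is deliberately simple and fully
documented as a TSV (`inst/extdata/parameters.tsv`); any alternative
table with the same columns can be loaded with `load_parameters()`.
No result in the test-suite depends on specific parameter values —
the tests assert *consistency* properties (matrix fidelity,
symmetry, descent, closed forms), not energies of real proteins.

The built-in rotamer library puts every rotatable $\chi$ on the
staggered $-60/60/180$ grid ($3^k$ rotamers for $k$ dihedrals).
Published libraries can be converted to the TSV dialect and loaded
with `load_rotamer_library()`.  Side chains are built from internal
coordinates (ideal bond lengths and angles) by the
natural-extension-reference-frame construction; placement and
$\chi$-measurement are exact inverses to below $10^{-6}$ degrees,
which the test-suite asserts over the whole library.

Bonded 1-2 and 1-3 atom pairs are excluded from the nonbonded sums
and 1-4 pairs are included at full weight; aromatic rings carry
explicit ring-closure bonds so that ring atoms are correctly
excluded.  Because rings are built as rigid units, their internal
1-4 interactions add a constant per conformation that cancels
between the folded state and the tripeptide reference.

## Surface areas: exact and pairwise

`sasa_exact()` implements the Lee–Richards construction: each atom's
accessible area is $R \int \alpha(z)\,dz$ where $\alpha(z)$ is the
accessible arc of the expanded sphere's circle at height $z$.  The
integral is evaluated by adaptive Gauss–Legendre quadrature in the
latitude variable (which removes the pole singularities), on
intervals split at neighbour-sphere extents and at tangency heights
located by root finding.  When an atom intersects exactly one
neighbour the integral is taken in its closed form (a spherical
cap); a flag forces quadrature so the closed form can be
cross-checked independently.

The energy model does not use the exact areas: following the
contact-area approximation, each atom's area is
$A_i \approx A^{iso}_i - \sum_j b_{ij}$ with $b_{ij}$ the analytic
two-sphere lens area.  This makes the surface energy a sum over
atom (hence residue) pairs — the property that allows the surface
term to live inside a pairwise energy matrix.  Two conventions
coexist deliberately:

* `sasa_pairwise_approx()` reports *areas* and clamps them at zero;
* the energy channels use the *linear* (unclamped) form, because
  only the linear form decomposes exactly into singleton + pairwise
  contributions.  The matrix-fidelity test (matrix route vs direct
  whole-system evaluation, equal to $10^{-3}$ kcal/mol on random
  assignments) is exact precisely because both routes use the linear
  convention.

On random 20-atom clusters with a 3.5 &Aring; minimum separation
(emulating nonbonded heavy-atom packing densities) the pairwise
approximation's summed absolute error is about 11% of the exact
total area; multi-body overlap double-counting is the known cost of
pairwise decomposability, and the test-suite guards the error at
15%.

## The energy matrix and pair relaxation

`build_energy_matrix()` precomputes, for every position, the
singleton energy of each (type, rotamer) state — side-chain/backbone
and intra-side-chain interactions plus the state's surface terms,
minus its unfolded reference — and, for every residue pair within a
cutoff, the interaction energy of each state combination.  The
cutoff is a pseudo-C&beta; distance (C&alpha; for glycine) of 14 &Aring;
by default; entries beyond it are identically zero and unstored, and
enlarging the cutoff never changes entries already present.

With `pair_min_steps > 0`, the pairwise protocol relaxes each side
chain by conjugate-gradient minimization over its Cartesian
coordinates (backbone fixed, pair interactions off), then switches
the pair interaction on and relaxes both side chains again; the
stored entry is the difference between the pair-on energy and the
isolated-side-chain energies at the final geometries.  With
`pair_min_steps = 0` the rigid rotamer geometry is used — this is
the mode in which matrix sums must (and do) reproduce direct
whole-system evaluation, and the default in the desk-scale
configurations because relaxation costs roughly an order of
magnitude more per entry.  Any pair entry above +100 kcal/mol is
stored as computed but flagged in the matrix metadata; no clash
pre-filtering is applied, so the optimizer sees the true landscape.

## Heuristic optimization

A *heuristic cycle* starts from a uniformly random sequence/rotamer
assignment and sweeps positions in ascending order; at each position
the (type, rotamer) state minimizing the total energy given the rest
of the assignment is chosen, ties breaking to the lowest state
index for determinism.  Sweeps repeat until a full pass changes
nothing or `max_passes` (default 50) is reached; the per-position
argmin guarantees a non-increasing energy trajectory.  A design run
is many independent cycles, each with a seed derived from the run
seed and the cycle number, so ensembles are reproducible and
independent of execution order; the `select_k` lowest-energy records
are kept.  On random 3-position × 3-type × 2-rotamer instances,
best-of-25 cycles recovers the exhaustively enumerated global
optimum in ≥95 of 100 instances.

Full-scale studies of this kind run hundreds of thousands of cycles
per backbone; the package defaults to a desk scale of 1000 cycles
and `select_k = min(1000, n_cycles)`, and every test states its own
smaller sizes explicitly.

Variants: `restrained_cycle()` restricts each position to the types
sharing its start type's *flavor* under a reduced alphabet (so a Phe
may become Tyr but never Trp); `rotamer_only_optimize()` fixes the
types and sweeps rotamers only; `sample_from_profile()` draws
sequences independently per column from a profile (preserving
marginals, destroying inter-position correlations);
`random_identity_sequences()` generates batches at a controlled
identity to the template with preserved positions (e.g. conserved
cysteines) kept native.  Together these reproduce the canonical
stability ordering on a toy system — profile-sampled sequences have
the worst (most positive) folding energies, flavor-restrained
optimization recovers part of the gap, and full design is the most
stable — which the acceptance suite asserts on medians over 30
sampled sequences against a 150-cycle design ensemble.

# Ensemble statistics

Reduced alphabets: nine classes
{LVIMC} {FY} {W} {G} {A} {STP} {EDNQ} {KR} {H}
and six classes {LVIMC} {FYW} {G} {ASTP} {EDNQ} {KRH}.  Entropies
and mutual information are computed in these class spaces (or over
the raw 20 types) in *nats*, so the exponentiated entropy $e^{S}$
reads as an effective number of classes (1 = conserved, 9 =
uniform over nine classes).  Gaps are excluded and columns
renormalized; all-gap columns are flagged and dropped from
summaries.  The summary entropy is the arithmetic mean of the
per-column $e^{S_l}$ (a flag switches to $e^{\bar S}$).  Mutual
information uses plug-in counting probabilities with absent types
contributing zero; coarsening the alphabet can only lower it
(data-processing), which the suite checks column-pair-wise.

The similarity of a sequence to an alignment is
$\sum_l \sum_a f_l(a) B(x_l, a)$ with $B$ = BLOSUM62 and a gap score
of $-5$; against a single-sequence alignment this reduces to the
plain pairwise BLOSUM sum.  The overlap between two score samples
is reported as the percentage of one sample at or above the other
sample's minimum; a two-sample histogram overlap coefficient is
available behind a flag, since either convention is defensible and
they answer slightly different questions.

Core positions are defined by relative side-chain accessibility in
the native structure below 20% (configurable), with accessibility
from `sasa_exact()`.

# Profiles and retrieval

PSSMs are half-bit log-odds with pseudocount weight $\beta$:
$p_a = (c_a + \beta q_a)/(N + \beta)$, score $= 2\log_2 p_a/q_a$
against a fixed published background composition; scores are kept
unrounded internally and rounded only in the ASCII export.  Exports
(ASCII layout with consensus, TSV, aligned FASTA of the source
sequences) allow external search tools to consume the profiles.

The internal search scores every database sequence by its best
ungapped window and converts scores to E-values
$E(s) = N \cdot P(S \ge s)$ under a null calibrated on
residue-shuffled copies of the database (20 shuffles per target,
seeded): the survival function is empirical within the observed
null range and extreme-value (exponential-tail) beyond it, with the
tail rate fitted by maximum likelihood to the exceedances over the
top-1% threshold.  On a pure-decoy database this yields at most
about $t$ expected hits at threshold $t$, and on a planted benchmark
(50 true homologues among 950 shuffled decoys) recall is ≥0.9 at
$E \le 0.1$ with ≤5 false positives.  These E-values are
self-calibrated and are not comparable to any external tool's.

The pattern-subset protocol isolates the ensemble subsets matching
each frequent flavor pattern at a set of correlated positions,
queries the database repeatedly with profiles built from 50-sequence
samples of each subset (plus the matching-none subset), and compares
the cumulative union of retrieved targets against a pooled-ensemble
control run with a matched number of queries.  On two-subfamily
planted data the cumulative subset retrieval dominates the pooled
control, because each subfamily's profile is sharper than the
mixture's.

# What the synthetic fixtures do and do not show

`make_structure()` builds ideal-geometry helices, strands and
hairpins with canonical $(\phi,\psi)$, `make_planted_msa()` draws
alignments with specified column distributions, coupled pairs and
subfamily patterns, and `make_search_database()` assembles labelled
homologue/decoy databases.  Everything is deterministic per seed and
regenerated at test time — no binary fixtures are stored.

Passing tests on these fixtures demonstrates that the machinery is
*correct* (energies decompose exactly, optimizers reach optima,
statistics hit closed forms, retrieval is calibrated); it does not
demonstrate that designed sequences for real proteins are
native-like.  Real structures bring crystallographic noise, rotamer
libraries fitted to observed side-chain statistics, calibrated
unfolded-state corrections, and energy functions tuned over decades
— all outside what ideal-geometry toys can probe.  The problem sizes
in the tests (6–8 residues, 3–6 candidate types, hundreds of design
cycles, databases of ~1000 sequences) were chosen as the smallest
systems on which each property is meaningfully exercised.

# Numerical choices

* Tie-breaks in the optimizer go to the lowest state index;
  ensembles sort by energy, then sequence, then rotamer string —
  all orderings are total, hence byte-identical reruns.
* Quadrature in `sasa_exact()` uses embedded 15/31-point
  Gauss–Legendre rules with interval bisection; the area error is
  far below the 15% regression band and the two-body closed form is
  exact.
* The pair-relaxation minimizer is conjugate gradients with analytic
  vdW/Coulomb gradients (verified against finite differences);
  `pair_min_steps` counts CG iterations per stage, 15 by default.
* Seeds: all randomness flows from one integer seed through named
  substreams (`derive_seed()`), kept below $2^{31}$.
* Degenerate inputs fail loudly by design: missing backbone atoms
  name the residue, malformed rotamer TSVs name the line, empty
  columns and empty pattern lists are errors rather than silent
  drops.

# Known limitations

Backbone flexibility, dead-end elimination or other exact search,
generalized-Born/Poisson–Boltzmann solvation, nucleic acids,
ligands, waters, alternate protonation states, MSA construction and
phylogenetic weighting are all out of scope.  The shipped parameter
set is a documented stand-in of the right physical form, not a
validated force field; quantitative claims about real proteins
require loading real tables and libraries through the provided
loaders.
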