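---
title: "Methods: modeling and analyzing supercoiled coiled-coil bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling and analyzing supercoiled coiled-coil bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilbundle)
```

This package bundles the computational machinery behind a structural and
statistical study of a bacterial cell-division coiled coil: a Crick-
parameterized Monte Carlo modeler for supercoiled helical bundles under
distance restraints, a census of polar residues at heptad core positions, a
polarity-conservation analysis over paired alignments, geometry analytics
(superposition RMSD, solvent accessibility, crossing angles, hydrogen
bonds), the cell-length elongation statistic with bootstrap confidence
intervals, and thermal melting-curve fits. Every analysis can be driven
end-to-end from seeded synthetic-data generators with machine-readable
ground truth; the numbered scripts under `analysis/` do exactly that.

## The Crick model of a supercoiled chain

A chain is a minor (alpha) helix of radius $r_0$ and rise $h$ per residue
wound around a superhelical axis of radius $r_1$ and pitch $P$ (signed;
negative = left-handed supercoil). With pitch angle
$\alpha = \arctan(2\pi r_1 / P)$, the rise per residue along the bundle axis
is $d_z = h\cos\alpha$ and the superhelical phase advances by
$\omega_0 = 360^\circ d_z / P$ per residue. The minor helix twists by
$\omega_1$ per residue *relative to the rotating superhelical frame* — the
standard Crick convention; $\omega_1 = 720/7 = 102.857^\circ$ keeps a heptad
repeat facing the bundle axis. `phi1` rotates the minor helix about its own
local axis, `s` translates the chain along the bundle (z) axis, and
`phi_major0` places it around the bundle. Defaults $r_0 = 2.26$ Å and
$h = 1.51$ Å are the canonical alpha-helix values.

Two convention notes, both deliberate:

* **The straight-helix limit.** At $r_1 = 0$ we define $\alpha = 0$ and
  $\omega_0 = 0$, so the chain degenerates *exactly* to an ideal straight
  helix of radius $r_0$, rise $h$, and lab-frame twist $\omega_1$; the pitch
  is irrelevant (and may be omitted) in this limit. Without this definition
  the superhelical frame would keep rotating on a degenerate axis and add
  $\omega_0$ to the lab-frame twist.
* **Twist convention and spacing.** Because $\omega_1$ is relative to the
  rotating frame, the lab-frame twist is $\omega_0 + \omega_1$, and the
  Calpha spacing depends slightly on the supercoil handedness: left-handed
  pitches in the physical range ($|P| \in [80, 250]$ Å, $r_1 \in [3, 9]$ Å)
  give 3.75–3.78 Å at $\omega_1 = 102.857^\circ$, while right-handed
  supercoils pair naturally with the 11/3-repeat twist
  ($\omega_1 \approx 98.2^\circ$) to stay near 3.8 Å. The tests pin the
  generator against an independently coded parametric curve rather than
  against a single nominal spacing.

Full backbones (N, C, O, and Cβ; glycine gets none) are reconstructed from
the Calpha trace by expressing ideal-helix atom offsets in a local
orthonormal frame built at each residue from its two Calpha neighbors. The
offsets are calibrated once against a reference helix built by internal
coordinates (NeRF) at $\phi = -62^\circ$, $\psi = -43^\circ$ with ideal bond
geometry, so reconstruction is exact on ideal helical traces, equivariant
under rigid motion, and a good approximation on gently supercoiled ones.
Chain termini use a screw-transform extrapolation of the trace (estimated
by superposing overlapping Calpha triples), which is exact on helices.
Side chains beyond Cβ are not modeled.

## Energies and the Monte Carlo sampler

The nonbonded model is a reduced CHARMM-like force field over the five
backbone atom classes: Lennard-Jones 12-6 with Lorentz-Berthelot
combination, Coulomb under a distance-dependent dielectric
$\varepsilon(r) = 4r$, both switched smoothly to zero over a 10–12 Å
window, with pairs closer than three bonds excluded. Parameters live in a
flat key-value config (`read_energy_config()`) so the table is replaceable.
Because hydrogens are absent, per-residue charge sums are not neutral; the
electrostatic term is best read as a soft packing bias, not an energy in
physical units.

Distance restraints come in two sigmoidal flavors:

* `type = "upper"` (default): $E(d) = w / (1 + e^{-k(d - d_0)})$ — a soft
  upper bound, zero when the pair is in contact and saturating at the
  penalty $w$ when it is far. This is the natural encoding of a predicted
  contact (e.g. an evolutionary coupling): it says "be close", not "be at
  exactly $d_0$".
* `type = "well"`: the sum of two opposing sigmoids, flat within
  $d_0 \pm \delta$ (`halfwidth`) and rising to $w$ on both sides. Wells
  encode a *known* target distance.

The distinction matters for validation. A one-sided sigmoid centered on the
true distance puts the reference geometry at its inflection point (cost
$w/2$ per restraint), so the restraint term is always lowered by shrinking
every restrained distance — under upper-bound restraints alone the global
optimum is a partly collapsed or rotated state, never the reference. We
verified this directly with exhaustive grid scans over $(r_1, \phi_1)$:
states with all restrained distances pushed below $d_0$ beat the reference
by a wide margin, with or without the nonbonded terms. The synthetic
recovery fixture (`gen_restraint_case()`) therefore samples its targets as
*wells*, which make restraint-only recovery well-posed: the reference is the
(flat-bottomed) global minimum, and a 5000-step annealing run recovers it
to well under 0.1 Å Calpha RMSD from a strongly perturbed start.

`mc_sample()` is a standard Metropolis annealer over the free Crick
parameters: one randomly chosen parameter of one chain per step, Gaussian
proposals, geometric cooling $T_i = T_0\gamma^i$ (defaults $T_0 = 5$,
$\gamma = 0.999$), ties accepted, best state tracked. The schedule carries
optional per-parameter bounds (the physical ranges above) and a
`tie_chains` switch that applies each proposal to all chains simultaneously
— the natural move set for symmetric bundles, and what the recovery fixture
uses. Identical seeds give bit-identical traces.

`apply_c2()` doubles a half-bundle by a two-fold rotation about an axis
(default the bundle axis), relabels the image chains, and reports — but does
not reject — inter-mate clashes. `graft_fragment()` superposes a fragment's
flanking residues onto anchor residues by least squares and splices the
fragment core in, rejecting grafts whose flank RMSD exceeds 1.5 Å.

## Core polarity census and conservation

`heptad_project()` and `polar_frequency()` implement the register census:
the frequency of polar residues (Asp, Glu, His, Arg, Lys, Gln, Asn by
default) at selected register positions, overall and per amino acid,
optionally stratified by oligomer order. Conventions: denominators count
*residues* at the selected positions; residues with register `-` are
excluded; non-standard codes are dropped from numerator and denominator
with a counted warning. The packaged fixture
`ftslb_ecoli_synthetic.tsv` is a constructed (synthetic) E. coli FtsLB
register — the published anchor residues at their published positions,
generic hydrophobics elsewhere — whose five heptads per chain carry six
polar residues at 20 a/d positions: the census returns exactly 30%.

The conservation analysis consumes two aligned FASTA files keyed by shared
taxon ids, anchors the reference's heptad register (conflicting anchors are
an error; reference gap columns carry no register), reduces each pair to a
binary polar/nonpolar pattern over the a/d columns, and summarizes patterns
as a weighted path graph (edge weight = number of pairs following a
transition; flow is conserved at interior columns) plus summary statistics.
Rows with a missing value in a statistic's window are excluded from that
statistic's denominator — a declared convention, since the real analysis'
handling of gapped sequences is not recoverable.

The paired-alignment generator draws each core column as an independent
Bernoulli. Its default probabilities were calibrated once, by a
Poisson-binomial computation, so that the *generating-truth* summaries
equal the three statistics the analysis reports: 71% (at least one polar
among the FtsL-block a/d positions of heptads 1–2), 39% (the (3,3) joint
polar-count class) and 84% (at least five polar core residues). Five
columns are strongly conserved (p = 0.88–0.94), one weakly (p = 0.70), the
rest near zero — the same shape as the real family. What the generator does
*not* emulate: phylogenetic correlation between pairs, column covariation,
indel structure beyond uniform random gaps, and amino-acid composition
beyond the polar/nonpolar split. Passing recovery tests therefore show the
*estimators* are correct, not that real alignments are this clean.

## Structure metrics

* **Superposition** (`kabsch_superpose()`): least-squares rigid fit via SVD
  with reflection correction; degenerate (collinear) selections are
  rejected. Tests cross-check the RMSD against a brute-force quaternion
  optimizer to 1e-6.
* **SASA** (`sasa()`): Shrake-Rupley sphere sampling on a deterministic
  golden-angle spiral lattice, probe 1.4 Å, default 960 points/atom, element
  radii C/N/O/S/H = 1.70/1.55/1.52/1.80/1.20 Å. Deterministic given
  `n_points`; sampling noise on totals is roughly 0.3% at 960 points and
  drops below 0.1% by 6000. Areas of deeply buried atoms are near zero, so
  convergence is judged against each atom's full sphere area.
* **Exposure** (`group_exposure()`): group SASA in context divided by the
  group's SASA with only its own residue(s) present (an isolated-residue
  reference, *not* Gly-X-Gly) — chosen so the fraction isolates occlusion
  by the rest of the structure; stated prominently because published
  exposure percentages rarely name their reference state.
* **Contact area** (`contact_area()`): SASA(A) + SASA(B) − SASA(A∪B) in the
  complex conformation, reported as the *total* buried area (both faces,
  not halved) — also stated prominently, since the halving convention
  varies.
* **Crossing angle** (`crossing_angle()`): each helix axis is the principal
  direction of consecutive four-Calpha midpoints, oriented N→C; the angle is
  measured about the mutual perpendicular at closest approach and folded
  into (−90°, 90°]. Sign convention: right-handed packing is negative; the
  two chains of a canonical left-handed parallel dimer measure about +20°.
* **Hydrogen bonds** (`hydrogen_bonds()`): heavy-atom criterion
  (donor–acceptor ≤ 3.5 Å, N···O=C angle ≥ 120°), appropriate for models
  without hydrogens; an ideal helix yields the complete i→i+4 ladder.

## Phenotype statistics

The elongation statistic is the fraction of cells *strictly longer* than
the 95th percentile of the wild-type length distribution. The percentile is
the linear-interpolation empirical quantile (R's type 7). The threshold is
computed once from the wild type and held fixed while each strain is
bootstrapped (percentile CI, 1000 resamples, seeded): the single-sample
description of the procedure is matched literally, so wild-type threshold
uncertainty is *not* propagated into the mutant CIs. Samples below the
protocol's 500-cell target warn rather than fail. The synthetic generator
uses a lognormal wild type (median 2.93 um, sdlog 0.28 — a right-skewed
positive distribution with a realistic ~30% CV; the family is our choice,
the median matches the reported wild type), an elongated phenotype as a
mixture with a long-cell component, and a small-cell phenotype as a global
down-scaling. Bootstrap coverage, checked over 200 synthetic datasets at
n = 500, sits at 93–95% for a nominal 95% interval.

## Melting curves

`fit_melt()` fits ellipticity-vs-temperature data to a two-state sigmoid
with linear pre- and post-transition baselines,
$y(T) = b_1(T) + [b_2(T) - b_1(T)] / (1 + e^{(T_m - T)/k})$, by
Levenberg-Marquardt least squares with multi-start initialization (Tm
guesses at the 25/50/75% quantiles of the range; best residual wins, ties
to the lowest Tm). No van 't Hoff/thermodynamic parameterization is
attempted — midpoints only, which is the appropriate summary for
irreversible transitions. A fit is flagged `converged = FALSE` (not an
error) when Tm leaves the observed range or the fitted amplitude is below
5% of the signal range (no transition). Noiseless curves are recovered to
±0.01 °C; at 5% noise on a 3 °C-wide transition sampled every 3 °C the
estimator's spread puts ~90% of replicates within 1 °C, which is the
realistic resolution of the protocol.

## Problem sizes and determinism

The shipped analyses and tests use: 2662 synthetic census entries (five
heptads each), 2900 alignment pairs, 5000-step Monte Carlo runs on two
30-residue chains, 200-dataset bootstrap coverage studies at n = 500 with
1000 resamples, and 50-replicate melt-fit studies — sizes chosen to match
the study design they emulate while keeping a full run in minutes on one
core. Every generator takes a seed and emits a truth file; identical seeds
give byte-identical outputs, and all downstream recovery tests consume only
the generated artifacts plus their truth files.

## Known limitations

* The backbone force field is reduced (no hydrogens, no side chains beyond
  Cβ, unscaled 1-4 interactions); it shapes geometry but its absolute
  energies are not physical.
* Register assignment from 3D structures is out of scope — annotations
  arrive with registers assigned.
* The conservation module does not correct for phylogenetic redundancy.
* Antiparallel chain generation is implemented (negated z-progression,
  reversed residue order) but only smoke-tested; the shipped analyses use
  parallel bundles.
* SASA and contact areas carry the sampling tolerances stated above;
  exposure fractions can exceed 1 by ~1% at default density.
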