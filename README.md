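# coilbundle

Modeling and analysis of supercoiled helical bundles (coiled coils), built
around the computational questions raised by the periplasmic coiled-coil
domain of the bacterial cell-division complex FtsLB: how unusual is a
cluster of polar residues buried at the core (a/d) heptad positions, how
conserved is that polarity across species, what bundle geometries are
compatible with coevolution-derived contacts, and how do the resulting
structural phenotypes read out in vivo (cell-length distributions) and in
vitro (thermal melts)?

The package is aimed at structural bioinformaticians and quantitative
microbiologists. It provides:

* **A Crick-parameterized backbone engine.** A chain is a minor helix
  (radius r0 = 2.26 Å, rise h = 1.51 Å per residue) wound around a
  superhelical axis with radius r1, signed pitch P, helical phase phi1 and
  z-shift s; the minor-helix twist omega1 (default 720/7 = 102.857
  degrees) is relative to the rotating superhelical frame. Full backbones
  (N, CA, C, O, CB) are reconstructed with ideal covalent geometry.
* **Metropolis Monte Carlo** over the free Crick parameters under
  sigmoidal distance restraints (one-sided contact bounds or symmetric
  wells) plus reduced CHARMM-like Lennard-Jones/Coulomb terms, with
  simulated-annealing schedules, parameter bounds, and symmetric
  (tied-chain) proposals; C2 symmetrization and fragment grafting assemble
  multi-chain models.
* **Structure analytics**: Kabsch superposition and RMSD traces over
  multi-model PDBs, Shrake-Rupley solvent-accessible surface area, group
  exposure fractions, buried contact areas, signed helix crossing angles
  (right-handed packing negative) and heavy-atom hydrogen-bond detection.
* **Sequence statistics**: a census of polar residues at heptad core
  positions across register-annotated coiled coils (stratified by oligomer
  order), and a conservation analysis that reduces paired alignments to
  binary polar/nonpolar core patterns, path graphs and summary statistics.
* **Phenotype and biophysics statistics**: the elongation statistic (the
  fraction of cells longer than the wild-type 95th percentile) with
  seeded percentile-bootstrap confidence intervals, and sigmoidal
  melting-curve fits reporting transition midpoints (Tm).
* **Seeded synthetic-data generators** for every input, each with a
  machine-readable ground-truth record, so the full pipeline runs and is
  testable without any external downloads.

## Worked example

The polar-residue census on the packaged E. coli FtsLB coiled-coil
register (a constructed fixture carrying the published anchor residues —
FtsB Q39/N43/N50 and FtsL R67/R74/E88 — at their published positions over
five heptads per chain):

```r
library(coilbundle)
ann <- read_annotations(system.file("extdata", "ftslb_ecoli_synthetic.tsv",
                                    package = "coilbundle"))
ft <- polar_frequency(ann, positions = c("a", "d"))
get_frequency(ft)
#> [1] 0.3
```

Six of the 20 core positions are polar — 30%, far above the typical
coiled coil. Compare the synthetic database census (2662 entries,
order-stratified), as run by `analysis/01_polar_census.R`:

```
FtsLB fixture: 30.0% of a/d positions are polar (6 of 20)
  2-stranded: 18.9% polar at a/d (Arg at 'a': 4.4%)
  3-stranded: 14.1% polar at a/d (Arg at 'a': 2.1%)
  4-stranded: 11.7% polar at a/d (Arg at 'a': 1.1%)
  overall: 17.7% polar at a/d
```

Core polarity is common in dimers, rare in four-helix bundles — so a
30%-polar core argues for paired two-stranded geometry over a single
four-chain bundle. The bundle modeler makes the geometric half of that
argument quantitative; `analysis/03_bundle_modeling.R` recovers a known
two-helix coiled coil from distance restraints alone:

```
recovered the reference to 0.028 A Ca RMSD; 100% of 21 restraints within 0.5 A
best parameters: r1 = 4.00 A, P = -141.5 A, phi1 = 15.0 deg (truth: 4.00, -140, 15)
```

and `analysis/05_cell_length_phenotypes.R` shows the division-defect
statistic on synthetic strains:

```
threshold (WT 95th percentile): 4.63 um
elongated mutant: 30% elongated (95% CI 26-33%)
small mutant: median 2.75 um vs WT 2.92 um
```

The numbered scripts under `analysis/` run the whole workflow
(census, conservation paths, bundle modeling, structure metrics,
phenotypes, melting curves) and write their tables under `results/`.

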