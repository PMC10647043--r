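---
title: "Designing photoswitchable ligands: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing photoswitchable ligands: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Azobenzene photoswitches isomerize reversibly between a thermally stable
*trans* (E) and a metastable *cis* (Z) configuration under illumination.
Embedding an azobenzene into a known ligand can put target binding under
optical control: a useful photoswitchable ligand binds its target strongly
in one configuration and weakly in the other, i.e. it shows a large
*isomeric shift* in affinity. Designing such ligands by hand is hard, because
the azobenzene must be placed where isomerization perturbs recognition
without destroying baseline affinity.

`pswdesign` automates the search. It (i) mines well-characterized parent
ligands with curated binding data from a ChEMBL-schema SQLite snapshot,
(ii) enumerates photoswitchable analogs by *azologization* (replacing a
linker or a fused ring with an azo bridge) and *azoextension* (appending a
phenyldiazene), producing explicit E/Z isomer pairs, (iii) prepares ligands
and receptor for docking, and (iv) ranks the designs by a docking-score
based prediction of the isomeric shift, selecting poses by Pareto
multiobjective optimization.

# Transformation rules

All transformations operate on a molecular graph whose perception
(kekulized bond orders, formal charges, aromatic bonds) comes from
OpenBabel; the graph edits and site matching are the package's own, with
atom provenance tracked through every edit (this is what
`map_parent_atoms()` reports). Every emitted SMILES is validated and
canonicalized through OpenBabel.

* **Typical azologization** — two (hetero)aromatic rings joined by a
  two-atom, unbranched, acyclic linker (any linker element among C/N/O/S,
  any bond order); the linker becomes `N=N`. Bibenzyl, stilbene and benzyl
  phenyl ether all collapse to azobenzene. Heavy-atom count is conserved.
* **Atypical azologization** — 0-atom (direct aryl–aryl bond), 1-atom
  (at most a one-atom branch, which is removed with the linker, so
  benzophenone qualifies) and 3-atom linkers (each linker atom may carry
  one terminal extra atom). Linker atoms must be acyclic: the package never
  opens rings, so indane-type bridges are not matched. A linker that is
  already an azo bridge is skipped — transforming it would re-emit the
  parent.
* **Naphthalene-type azologization** — a mono- or disubstituted fused 6-6
  fully aromatic bicycle is replaced by azobenzene and the substituent(s)
  are re-attached *exhaustively over all azobenzene ring positions*; the
  distinct products are kept after canonical-SMILES deduplication. For one
  substituent this yields the three ortho/meta/para products; for two
  distinct substituents exactly 19 distinct placements exist (the orbit
  count of placing two distinguishable substituents on azobenzene's ten
  positions under its order-8 automorphism group), which is also the design
  family size the retrospective H3-receptor case produces. We chose
  exhaustive placement over a fixed position-mapping table because no
  self-consistent distance-preserving table reproduces both the documented
  products and that family size; rule names still encode parent and product
  positions (e.g. `Naphtho_2_6_ABz_3_3p`).
* **Typical azoextension** — a phenyldiazene (`-N=N-C6H5`, 8 heavy atoms)
  is appended at every free aromatic C–H position (exhaustive; symmetry
  duplicates collapse on dedup: benzene gives 1 product, toluene 3).
  Extension is restricted to carbon positions; N–H positions would give
  triazene-type chemistry, a different photoswitch class.
* **Atypical azoextension** — a substituent of at most
  `max_replaced_substituent` heavy atoms (default 1, i.e. halogens and
  hydroxyl; configurable up to 3 — the rule sources differ on this bound)
  on an aromatic carbon is replaced by phenyldiazene.

**E/Z pairs.** Only the newly created azo bond receives stereo assignment;
E is labelled *trans*, Z *cis*. Pre-existing azo bonds keep the geometry
they had in the parent (recovered from the 2D layout, which honors the
input's directional bonds). A design whose new azo bond would sit in a ring
of fewer than 9 atoms is rejected — the geometry cannot exist there.
*Limitation:* tetrahedral stereocenters and non-azo C=C geometry of the
parent are not propagated through the transformation; designs at such
parents are emitted with those centers unspecified.

# Mining and curation

`fetch_activities()` retrieves raw measurements joined with ligand
structures and assay metadata. The default quality rules, all overridable
in `miner_config()`, mirror standard curation for binding data: binding
assays only (`assay_type == "B"`), exact relations (`=`; a permissive mode
keeps `<` upper bounds), units convertible to mol/L, a positive numeric
value, no data-validity flag, duplicate (ligand, assay, value) rows
collapsed, molecular weight in [100, 800] Da and 7–60 heavy atoms. Every
rejection is logged with its violated rule, and filtering is idempotent.

Measurements become `pAffinity = -log10(value in mol/L)`; the median per
(ligand, target, organism) is reported with the measurement count. We
aggregate per organism because affinities for orthologs are not
interchangeable. Ki/Kd/IC50/EC50 are pooled by default (a config switch
restricts to Ki/Kd). Classification uses user thresholds (default 6 and 8,
labels inactive/moderate/active, boundaries inclusive upward), and the
affinity floor (`paffinity_min`, e.g. 8.0) is inclusive.

Diversity selection clusters the ligands hierarchically (complete linkage)
on Tanimoto distance over circular ECFP4 fingerprints (OpenBabel's native
circular fingerprint, radius 2, 4096 bits; name configurable), cuts the
tree at `1 - threshold` and keeps the highest-affinity representative per
cluster (ties: lexicographically smallest id). Because no standard linkage
guarantees that representatives of different clusters stay below the
similarity threshold, a final greedy sweep in decreasing affinity order
drops any representative too similar to one already kept — after it, no two
selected parents exceed the threshold, by construction.

# Preparation

Each isomer is protonated at pH 7.4 with OpenBabel's rule-based pH model
(amines protonated, carboxylic acids deprotonated); the input protonation
state is kept as an alternative variant, capped at `max_variants`. No
installed component enumerates tautomers, so "variants" here are
protonation states; the pairing logic downstream is agnostic to what the
labels denote. Each variant is embedded in 3D and minimized with MMFF94
(default 500 steps). Minimization can rotate an azo bond, so the C–N=N–C
dihedral is checked afterwards (tolerance 30° about 180°/0°); if the
geometry flipped, the pre-minimization embedded structure is kept — an
accepted structure therefore always has the declared isomer geometry, and
the kept energy is never above the embedding energy.

Receptor preparation selects one chain, drops waters/ions/het groups except
an explicit keep list, removes alternate locations and flags residues with
incomplete backbones (no rebuilding is attempted). The docking site is a
sphere centered on the reference ligand's heavy-atom centroid with radius
`max distance + extra_radius` (default 2.0 Å), so the reference is always
contained.

# Docking, pose selection and the shift predictor

Engines are pluggable: anything that maps (receptor, site, ligand,
n_poses) to scored poses. The PLANTS adapter (ChemPLP convention, lower =
better; speed1, 20 ants, 10 poses) is provided for installations that have
the binary; the deterministic mock engine drives all tests. Poses carry
contact metrics computed from heavy-atom distances: contact ≤ 4.0 Å, clash
< 2.5 Å (configurable; clashing pairs also count as contacts), plus the
count of ligand atoms with no contact.

The best pose maximizes contacts and minimizes clashes, uncontacted atoms
and total score in the Pareto sense; among front members the lowest score
wins, then the lowest pose index. The implementation is checked against an
exhaustive dominance oracle on random instances.

The predictor scales the parent's measured affinity by the score ratio:

$$pKi_{pred} = pAffinity_{parent} \times \frac{score}{score_{parent}},
\qquad \Delta pKi = pKi_{pred}(cis) - pKi_{pred}(trans),
\qquad FC = 10^{|\Delta pKi|}.$$

This is a deliberate reconstruction: it uses exactly the three inputs
available (parent score, parent pAffinity, isomer score difference),
reduces to the measured affinity when a variant scores like its parent, and
gives a positive shift when the cis isomer scores better. It is isolated in
`score_to_pki()` so alternative calibrations can be swapped in. Per family,
variant pairs are matched by protonation label (unpaired variants are
dropped), medians across pairs define the consensus, and the active isomer
follows the sign of the median shift — displayed fold-changes are negative
for cis-ON families. The default filter keeps families with at least a
50-fold predicted change (ΔpKi ≥ 1.7, boundary inclusive); it can be
relaxed or disabled.

# Synthetic fixtures and what passing means

`generate_mini_chembl()` emits a seeded, byte-reproducible SQLite snapshot
in the ChEMBL dialect: three targets across two protein classes, six
ligands per target with two measurements each (log-uniform pAffinity in
5–10, units alternating between nM and µM so aggregation must be
unit-invariant), plus dirty records exercising every quality rule. A JSON
manifest of expected post-filter counts is computed during generation from
bookkeeping, not by running the miner, and the tests require the two to
agree. The toy receptor pocket is a 20-residue glycine shell on a spherical
lattice (radius 4.5 Å, placing the shell within contact range of the bound
6-carbon ring ligand at the origin) — sufficient for preparation, site and
metric tests, but not a real protein geometry.

These fixtures emulate schema, dirtiness patterns and determinism, not the
statistics of real ChEMBL data or real binding pockets; passing the suite
demonstrates correctness of the machinery (curation arithmetic,
enumeration, selection, prediction), not predictive accuracy on real
receptors, which additionally depends on the external docking engine.

The default problem sizes (three-target fixture, about a dozen designs per
end-to-end run, 200 random Pareto instances, the five-point recovery grid)
were chosen so each property is exercised across its edge cases while the
whole suite remains quick to run.

One acceptance-style input deserves a flag: the retrospective H3 parent is
shipped as a *synthetic reconstruction* (see
`inst/extdata/chembl476099_synthetic_parent.smi`) carrying the documented
features of that ligand — a 2,6-disubstituted naphthalene core with two
distinct substituents and no other aryl–aryl linker. Any parent with those
features yields the same 19-member design family, which is the property the
enumeration check relies on.

# Numerical choices and degenerate inputs

* Unit conversion covers fM–M; unknown units exclude the record with a
  logged reason rather than failing the run.
* Median aggregation is permutation-invariant; classification of an empty
  record set is an empty record set.
* Dedup keys are OpenBabel canonical SMILES of the flat (stereo-free at the
  new bond) product; dedup is idempotent and order-stable (first seen
  wins, provenance accumulates).
* Pareto ties are broken by score then pose index, making selection
  deterministic for any input order.
* `score_to_pki()` refuses a zero parent score (the scale is undefined
  there).
* Embedding failures skip the variant with a warning; a design whose
  variants all fail is flagged rather than silently dropped.
* All stochastic steps (fixture generation, any sampling in checks) run
  under explicit seeds; the pipeline writes no timestamps, so identical
  inputs give byte-identical reports.

# Known limitations

* Parent stereocenters outside azo bonds are not tracked through
  transformations.
* Tautomer enumeration is limited to protonation states.
* Missing receptor side chains are flagged, not rebuilt.
* Photochemistry (absorption wavelengths, photostationary state, thermal
  half-life) is out of scope by design, as is any scoring-function
  implementation: ChemPLP scores are consumed from the engine, never
  recomputed.
* The ΔpKi formula is a documented reconstruction; absolute fold-change
  predictions inherit its assumptions and the docking engine's noise, so
  they are best read as rankings and isomer-preference calls.
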