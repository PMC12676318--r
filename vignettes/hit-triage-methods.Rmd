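---
title: "Methods: post-docking hit triage with hitfunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-docking hit triage with hitfunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hitfunnel)
```

## The scientific problem

Structure-based virtual screening of a large purchasable library against a
nuclear-receptor target (here, a PPARγ-style ligand-binding domain built by
homology) typically returns hundreds of plausible docked poses. Only a
handful can proceed to molecular-dynamics validation or purchase, so the
screening output must be *triaged*: filtered on drug-likeness, screened for
assay-interference substructures, gated on predicted potency and safety, and
finally ranked by a single defensible criterion.

`hitfunnel` implements that funnel end to end:

1. **Drug-likeness gate** — Lipinski rule-of-five violations plus PAINS and
   Brenk structural-alert screens.
2. **Quadrant filter** — keep compounds at least as potent (docking affinity,
   kcal/mol, more negative is better) *and* at least as safe (predicted rat
   oral LD50, mol/kg, larger is better) as a reference agonist.
3. **Ideal-point ranking** — Euclidean distance to an ideal point in the
   (affinity, LD50) plane.
4. **Orthogonal checks** — pharmacophore match against the reference agonist,
   BOILED-Egg permeability class, homology-model quality, and MD stability
   metrics for the top-ranked complexes.

## The ranking metric

For compound $i$ with affinity $a_i$ and safety $s_i$, and ideal point
$(a^\*, s^\*)$,

$$ d_i = \sqrt{(a_i - a^\*)^2 + (s_i - s^\*)^2}, $$

with compounds sorted by ascending $d_i$ (ties broken by identifier). Two
conventions deserve comment:

* **Mixed units, no rescaling.** The two axes are kcal/mol and mol/kg. The
  published convention computes the distance directly on raw values, so that
  is the default. Because the affinity axis spans a numerically wider range
  than the LD50 axis, affinity dominates the ranking; this is a property of
  the published protocol, not an accident of the implementation. A
  `normalize = TRUE` option z-scores both axes first for users who prefer a
  scale-free metric — it changes the metric only, never the machinery.
* **The ideal point is a parameter.** `ideal_point()` accepts explicit
  coordinates (the published protocol uses the best observed affinity and
  the best observed LD50 across the gated set) or derives them from a data
  set with `from_set`.

```{r ranking}
tab <- read_compound_table(
  system.file("extdata", "table3_hits.csv", package = "hitfunnel"),
  reference_ids = "MCULE-8293284864"
)
kept <- quadrant_filter(tab[!tab$is_reference, ], tab[tab$is_reference, ])
euclidean_rank(kept, ideal_point(affinity_min = -11.1, ld50_max = 2.924))
```

The quadrant thresholds are **inclusive**: a candidate whose affinity exactly
equals the reference affinity passes. This matters in practice — the
lowest-ranked retained compound in the bundled data set ties the reference
at $-8.5$ kcal/mol.

## Drug-likeness and alerts

Lipinski violations are counted with inclusive thresholds (MW ≤ 500,
logP ≤ 5, H-bond donors ≤ 5, acceptors ≤ 10, acceptors counted as all N + O
atoms). `qualitative_pass()` is the conjunction of zero violations (the
`max_lipinski_violations` config relaxes this) and zero PAINS/Brenk alerts.
The bundled alert catalogs (version `compact-1.0`) are deliberately compact,
human-auditable subsets of the published pattern collections — large enough
to catch canonical offenders (nitroaromatics, Michael acceptors,
rhodanines, catechols, …), small enough to review line by line. Users can
supply full catalogs as TSV (`pattern_id`, `smarts`, `description`).

## Pharmacophore model and matching

`build_reference_model()` perceives an 8-feature model from a
thiazolidinedione agonist conformer: head-group H-bond acceptor and donor,
a hydrophobic feature on the ring sulfur, aromatic + hydrophobic features on
each of the two ring centroids, and a hydrophobic feature on the
tertiary-amine methyl carbon. Note the deliberate deviation from generic
hydrophobic perception: the sulfur and methyl features are anchored to
specific atoms of the scaffold because they encode known binding-pocket
contacts, not generic lipophilicity.

Matching is **alignment-free**: a candidate matches if there is an
injective, kind-respecting assignment of model features to perceived
features whose pairwise distances all agree with the model within a
tolerance (default 1.0 Å). Among feasible assignments the one minimizing
the maximum deviation wins. Because only internal distances are compared,
the test is invariant under rigid motion of either structure — no
superposition step can leak error into the decision.

## Pose comparison

`symmetry_rmsd()` minimizes heavy-atom RMSD over all element- and
bond-order-preserving graph automorphisms (benzene has 12; a
para-disubstituted ring has 2), so chemically equivalent atom relabelings
never inflate the RMSD. The default compares poses *in place* (docking
convention); `superpose = TRUE` applies Kabsch superposition first
(conformer convention). The automorphism search is capped at 10,000
mappings to keep the exact search tractable.

## Enrichment validation

`roc_curve()`/`auc()` treat more-negative docking scores as better,
group tied scores, and compute AUC as the tie-corrected Mann–Whitney
statistic. For Gaussian actives/decoys separated by $\delta$ with common
$\sigma$, the expected AUC is $\Phi(\delta/(\sigma\sqrt{2}))$ — the
synthetic generator records this truth so tests can verify convergence.

## Structure quality and MD stability

Sequence identity between target and template uses an overlap alignment
(BLOSUM62, gap open 10 / extend 0.5), identity = matches / aligned columns,
coverage = aligned columns / target length. Backbone φ/ψ dihedrals follow
the standard IUPAC sign convention; consecutive residues with a CA–CA
distance above 4.5 Å are treated as a chain break. Ramachandran
classification uses a coarse bundled polygon map (boundary points take the
more favorable class); it is intended for sanity-checking models, not for
publication-grade validation.

MD metrics: per-frame Kabsch RMSD to a reference frame, per-residue RMSF
about the mean structure, geometric hydrogen-bond counts
(donor–acceptor ≤ 3.5 Å inclusive, optional D–H···A angle criterion), and
interaction-energy summaries. `energy_ratio()` reports
$|E_\text{system}| / |E_\text{reference}|$ rounded to 4 decimals, the
convention used to compare complex stability against a reference complex.

## Synthetic data

Every stage has a paired generator (`gen_compound_table()`,
`gen_score_sets()`, `gen_toy_conformers()`, `gen_trajectory()`,
`gen_sequences()`) that plants a known truth and returns it alongside the
data. Generators draw from per-name derived seed streams and restore the
caller's RNG state. Defaults reproduce the study's problem sizes (hundreds
of compounds, $10^3$–$10^4$ frames, ~270-residue sequences). Limits: the
trajectories are isotropic-noise toys with no correlated dynamics, the
compound tables sample the two axes independently, and the toy conformers
cover only three scaffold archetypes — they validate the *analysis
machinery*, not force fields or docking engines.

## Limitations

* The ranking deliberately mixes units; use `normalize = TRUE` if that is
  not the convention you want.
* Alert catalogs are compact subsets; screen with full published catalogs
  before purchase decisions.
* BOILED-Egg ellipses and the Ramachandran map are fixed published
  parameterizations, bundled as data; they are classification conveniences,
  not re-fits.
* LD50 inputs are predictions (e.g., from QSAR servers); the funnel ranks
  them but cannot audit them.
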