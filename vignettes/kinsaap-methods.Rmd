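---
title: "Methods: contrasting pathogenic and neutral substitutions on a consensus structure"
author: "kinsaap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contrasting pathogenic and neutral substitutions on a consensus structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinsaap)
```

## The analysis model

`kinsaap` compares two classes of unique missense substitutions — pathogenic
deviations (PD) and neutral polymorphisms (SNP) — after projecting all of
them into one structural frame, a consensus model of a protein-family
domain. The underlying assumption is the one that justifies consensus
modelling for families like the protein kinases: the positions that matter
for catalysis, specificity and core packing are conserved across the family,
so substitutions observed in many homologues can be pooled at the level of
model positions. Records are unique under the four-field key
(protein accession, sequence position, native residue, mutant residue), and
only missense changes are analysed; nonsense and synonymous records are
filtered out at load time because their consequences are known (truncation)
or nil.

The pipeline has six stages, each exposed as ordinary functions and
orchestrated by `runAnalysis()`:

1. structure parsing (`readStructure`),
2. solvent accessibility and burial (`computeSasa`, `classifyBuried`),
3. conservation and sequence-to-model mapping (`conservedPositions`,
   `mapMutationsToModel`),
4. structural-effect hypotheses (`classifyEffects`),
5. proximity of each class to feature sets via the Xd statistic
   (`compareClasses`),
6. Fisher-exact composition and effect enrichment (`enrichmentScan`,
   `effectEnrichment`).

## Distances

All proximity analyses use the *minimum heavy-atom distance* between
residues. Functional proximity is largely a side-chain affair (pocket
linings, interfaces), which C-alpha-only distances understate; a `method =
"ca"` mode is available throughout for comparison. Hydrogens are ignored
everywhere, and only the first model of a multi-model PDB file is read,
with alternate locations resolved to the highest-occupancy copy (ties keep
the first record).

## Accessibility and the burial rule

Solvent-accessible surface area follows the probe-rolling construction:
every heavy atom is inflated by the probe radius (1.4 Å, a water molecule),
its sphere is sampled with `n_points` quadrature points, and the accessible
fraction is the fraction of points inside no neighbouring inflated sphere.
The point set is a golden-section spiral — a deterministic, nearly uniform
spherical covering — so areas are bit-reproducible run to run; at the
default 960 points an isolated sphere's area is exact to well under 1 %.
Van der Waals radii are element-based (C 1.70, N 1.55, O 1.52, S 1.80 Å):
at the 16 % burial decision boundary the difference from atom-type-specific
radii sets is immaterial, and the table is user-replaceable through
`sasaParams()`.

Relative accessibility divides a residue's area by its theoretical maximum
in an extended Gly-X-Gly context (the published theoretical maxima of Tien
*et al.* 2013). A residue is **buried** when its relative accessibility is
≤ 0.16 — boundary inclusive, so exactly 16 % counts as buried. The rule is
applied over all heavy atoms of the residue (not side-chain-only), which is
the convention the threshold was calibrated for in the accessibility
literature; both the threshold and the reference table are configurable.

## Conservation

Column conservation is Shannon entropy in bits over the observed residue
frequencies, gaps excluded from the counts; columns with more than 50 %
gaps are never called conserved (too little evidence), and an all-gap
column is an error. A column is conserved when H ≤ 0.5 bits by default —
there is no canonical cutoff for this kind of feature set, so the value is
exposed (`conservation_threshold`) and recorded in the run manifest. The
alignment row whose ungapped sequence equals the model sequence anchors the
column-to-position mapping.

## Mapping mutations onto the model

Each distinct protein sequence is globally aligned to the model sequence
(BLOSUM62, affine gaps: open 10, extend 0.5, via `Biostrings`), replacing a
database BLAST mapping with a deterministic local equivalent. A record maps
only when percent identity over aligned columns is ≥ 95 % — the identity
level at which family-wide sequence-to-model transfer is reliable — and its
position aligns to a non-gap model column; otherwise the record is kept
with an explicit reason (`below identity threshold`, `position not
aligned`). Traceback ties inside the alignment are resolved by the
alignment library's deterministic rules, so mappings are reproducible.

## Structural-effect rules

The effect classifier evaluates a fixed battery of hypotheses per mapped
record and reports a binary vector plus two summaries:
`structurally_explained` (any flag except sequence conservation) and
`explained` (any flag at all). The thresholds are this package's documented
conventions, chosen to be chemically conventional rather than fitted:

| rule | condition | default |
|---|---|---|
| surface hydrophobic | exposed and Δhydropathy ≥ +Δh | Δh = 2.0 (Kyte–Doolittle) |
| core hydrophilic | buried and Δhydropathy ≤ −Δh | Δh = 2.0 |
| buried charge shift | buried and formal charge differs | — |
| disulphide disrupted | native Cys, SG–SG ≤ 2.5 Å, mutant ≠ Cys | 2.5 Å |
| cavity introduced | buried and volume loss ≥ ΔV | ΔV = 40 Å³ |
| clash | buried and volume gain ≥ ΔV | ΔV = 40 Å³ |
| H-bond broken | polar side-chain contact ≤ 3.5 Å and apolar mutant | 3.5 Å |
| from cis-proline | native Pro with \|ω\| ≤ 30° | 30° |
| from glycine | native Gly with φ > −20° | −20° |
| to proline | mutant Pro with φ outside [−90°, −40°] | — |
| binding / interface | heavy atom ≤ 4.0 Å from a ligand atom / another chain | 4.0 Å |
| annotated / conserved | membership in the supplied feature sets | — |

No mutant side chain is modelled: cavity and clash are volume-difference
proxies, and the hydrogen-bond rule asks whether the mutant side chain
retains any donor/acceptor atom, without angular criteria. These are
deliberate simplifications — the geometry of the native structure plus
residue-level chemistry — and are the right resolution for class-level
contrasts, not for per-mutation ΔΔG prediction. Torsion-based rules are
set to FALSE (with a log message) when backbone atoms are missing, as in
pseudo-atom synthetic structures. Histidine is treated as formally neutral
at physiological pH.

## The Xd proximity statistic

For a class of model positions and a feature set, the minimum distance of
every position to the feature is binned in 4 Å bins (first bin closed at
zero so feature members count at distance 0; distances beyond `max_dist`,
60 Å by default, accumulate in the last bin). The observed percentages are
compared with the percentages of *all* model residues (mutated ones
included) through

$$ X_d = \frac{1}{n}\sum_{i=1}^{n} \frac{P_{ic} - P_{ia}}{d_i} $$

with $d_i$ the bin's upper limit. Positive values mean the class sits
closer to the feature than the background. Two conventions deserve note:

* **The bin count n is data-determined.** The distribution ends at the last
  bin occupied by either the observed set or the background; trailing empty
  bins are not part of the distribution. Without this, the statistic's
  magnitude would depend inversely on the arbitrary `max_dist` padding —
  halving the padding would double every Xd. With it, Xd is invariant to
  `max_dist` whenever `max_dist` covers the data (a property the test suite
  checks), and the 1/n normalization can be disabled (`normalize = FALSE`)
  for comparison with un-normalized variants of the statistic.
* **ΔXd orientation.** `compareClasses()` reports
  ΔXd = Xd(class A) − Xd(class B), positive when class A (the PD-like
  class) is the closer one. Published tables sometimes orient the
  difference the other way, printing negative values when the first class
  is closer; `paper_sign = TRUE` emits that orientation. The significance
  call |ΔXd| ≥ 0.75 is unaffected.

The 0.75 threshold is a working convention inherited from prior use of the
statistic, not a calibrated p-value; the package therefore ships a null
calibration (both classes drawn uniformly) in its acceptance checks, which
finds |ΔXd| ≥ 0.75 in far fewer than 10 % of null replicates under default
binning at the study's sample sizes. Mean distances are reported over
*unique* positions by default (several mutations can share a position);
`unique_positions = FALSE` weights positions by their mutation count.

## Enrichment tests

Class-versus-property 2×2 tables (native residue, mutant residue, observed
native→mutant pairs, and each effect flag) are tested with the two-sided
Fisher exact test under the point-probability convention: the p-value sums
all tables with the observed margins whose probability does not exceed the
observed table's (this is `stats::fisher.test`'s definition; the test suite
verifies it against exhaustive hypergeometric enumeration for every table
up to N = 30). A table with a zero row or column carries no information
and returns p = 1 by convention. Raw p-values are reported and flagged at
α = 0.05 by default — the analysis is exploratory and the historical
practice in this setting reports raw values — with an optional
Benjamini–Hochberg mode. Only observed pairs are enumerated in pair mode,
not all 400 ordered pairs. Because the exact test is conservative on
discrete tables, its false-flag rate under a permutation null sits *below*
the nominal α; the acceptance check accordingly bounds the empirical rate
from above rather than expecting it to match α exactly.

## The synthetic generator

`generateBundle()` produces every input the pipeline needs, determined
entirely by a seed:

* **Structure** — either an ideal α-helical trace (rise 1.5 Å, twist 100°,
  Cα radius 2.3 Å, with an interpolated pseudo-backbone and one outward
  side-chain pseudo-atom) or, by default, a *globule*: self-avoiding
  placement (≥ 3.5 Å separation) inside a sphere at ≈ 0.005 residues/Å³,
  each residue a Cα plus a side-chain pseudo-atom. The sequence carries the
  natural amino-acid composition exactly (largest-remainder apportionment,
  shuffled): a protein-family domain has one composition, which should not
  fluctuate between simulated datasets.
* **Feature set** — the `n_features` residues nearest a random anchor
  residue, i.e. a spatial cluster. Real catalytic sites and binding pockets
  are clusters; a uniformly scattered feature set would put every residue
  within a few Ångström of some feature residue and flatten the distance
  distributions the proximity analysis lives on.
* **Mutation classes** — PD positions sampled with probability ∝
  exp(−d/λ) toward the feature set (λ = 2 Å by default; λ = ∞ is the
  uniform limit), SNP positions uniformly; defaults are 62 vs 36 records
  (the structure-mapped shape of the motivating dataset; 130 vs 200 for
  sequence-level studies). Native residues are read off the model sequence.
  Mutant residues follow a genetic-code-aware background: weights
  proportional to the number of single-nucleotide missense paths from the
  native's codons — the right null for polymorphism data, which arises from
  single base changes. The pair enrichment (Leu→Pro at 10-fold by default)
  is planted as a record-level mixture in the PD class, so the PD pair
  frequency is `fold` × the background frequency in expectation regardless
  of how common the pair already is.
* **Alignment** — the model sequence plus `msa_depth − 1` homologue rows;
  planted conserved columns are invariant, all other columns substitute the
  reference residue with probability 0.8 (draws from natural frequencies),
  giving non-conserved column entropies around 3 bits at depth 50. No gaps
  are introduced; gap handling is exercised by dedicated fixtures instead.

What the generator does *not* emulate: real fold topology (no two-lobe
kinase architecture, no secondary-structure packing), correlated
conservation between structure and sequence, gapped alignments, and
ligand-bound het groups (these enter through hand-built fixtures). Passing
tests on synthetic bundles therefore demonstrate that the statistics
recover planted signal under the stated sampling model — not that any
particular biological dataset will show such signal.

## Numerical and degenerate-input choices

* The spiral quadrature uses no random numbers; SASA, distances, alignment
  and classification are bit-deterministic, and all simulation randomness
  flows from explicit seeds (`withSeed` restores the caller's RNG state).
* Distance binning is half-open (d_{i−1}, d_i] with a closed first bin, so
  a boundary value falls in the lower bin and zeros are counted.
* Empty feature sets are errors where a non-empty set is semantically
  required (proximity targets, required features in a run config), and
  empty *computed* sets (e.g. no buried residue in a small model) simply
  drop out of the Xd report.
* Degenerate Fisher tables (zero margin) return p = 1 with a message.
* Unmapped mutation records are carried through with explicit reasons and
  skipped by the effect classifier, mirroring the bookkeeping of mapped
  versus unmapped counts that this kind of study reports.
* The run manifest records every threshold (burial 0.16, ΔXd 0.75, identity
  0.95, binning, α, effect thresholds) even when defaulted; a run is
  reproducible from the manifest alone, and the test suite checks
  byte-identity of replayed reports.

## Problem sizes used in the checks

The acceptance checks run at the study-shaped sizes: 250-residue globules,
a 32-position feature cluster, 62 vs 36 structure-mapped records (130 vs
200 at sequence level), 100 seeded bundles for parameter recovery, 500
uniform-null replicates for the ΔXd calibration, and 200 replicates for
enrichment power. These sizes give the simulation estimates standard
errors of a few percent, which matches the tolerances asserted.

## Known limitations

* Effect rules operate on the native structure only; they cannot see
  mutant-specific rearrangement, and their thresholds are conventions, not
  fitted parameters.
* Conservation uses a single entropy cutoff; no structure-aware
  conservation measure is included.
* The Xd convention (0.75) is inherited, not derived; treat `significant`
  as a screening call, not an inference.
* Composition results at small counts are dominated by the discreteness of
  the exact test; the BH option is available but off by default.
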