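# kinsaap

Structural contrast of pathogenic and neutral single amino-acid
substitutions on a consensus protein model.

## The problem

Families such as the human protein kinases carry hundreds of published
missense substitutions: pathogenic deviations (PD) linked to disease, and
neutral polymorphisms (SNP) observed in healthy individuals. Because the
family shares one domain fold, substitutions from many homologues can be
projected onto a single consensus structure and compared *jointly*: do
pathogenic changes sit closer to catalytic residues, to
specificity-determining (tree-determinant) positions, or to the buried
core? Do they differ in amino-acid composition or in their hypothesized
structural consequences?

`kinsaap` implements that comparative pipeline for R:

* **Structure handling** — PDB parsing (first model, highest-occupancy
  altlocs, ligand groups kept separately) into a `StructureModel` S4 object;
  minimum heavy-atom inter-residue distances.
* **Accessibility** — probe-rolling solvent-accessible surface area
  (Shrake–Rupley with a deterministic golden-spiral quadrature); a residue is
  *buried* when its relative accessibility is ≤ 16 % of the extended
  Gly-X-Gly reference maximum.
* **Conservation and mapping** — Shannon-entropy conservation
  (H = −Σ p<sub>a</sub> log₂ p<sub>a</sub> per alignment column) and transfer
  of each mutation onto the model through global pairwise alignment,
  accepted at ≥ 95 % sequence identity.
* **Structural effects** — the per-mutation binary explanatory vector:
  surface/core hydrophobicity shifts, buried charge shifts, disulphide loss,
  cavities and clashes, broken side-chain hydrogen bonds, torsion-unfavourable
  changes (from cis-proline, from glycine, to proline), annotated/binding/
  interface residues, conserved positions, with the `structurally_explained`
  and `explained` summaries.
* **Proximity (Xd)** — for a mutation class and a feature set, the binned
  distribution of minimum distances is compared with the all-residue
  background through the harmonic deviation

      Xd = (1/n) · Σ_i (P_ic − P_ia) / d_i

  where d_i is the upper limit of bin i (4 Å bins by default), P_ic the
  percentage of the class in that bin and P_ia the background percentage.
  Positive Xd means the class is shifted toward the feature. Two classes are
  called significantly different when |ΔXd| = |Xd(PD) − Xd(SNP)| ≥ 0.75.
* **Enrichment** — two-sided Fisher exact tests contrasting the classes by
  native residue, mutant residue, native→mutant pair, and by each effect
  flag.
* **Synthetic data** — a seeded generator of structures (helix or packed
  globule), alignments, clustered feature sets and two mutation classes with
  a planted distance-decay proximity bias and a planted substitution-pair
  excess, so the whole pipeline is testable offline.

## Worked example

```r
library(kinsaap)

spec   <- syntheticSpec(n_residues = 120, class_sizes = c(40, 30),
                        n_features = 16, seed = 42)
bundle <- generateBundle(spec)
bundle$model
#> StructureModel: 120 residues, 231 heavy atoms, 0 het group(s)
#>   sequence: GTLDKTNVGDKVPENDAEWCESAFESTIGYQGRDSAYLVLAGVTAKASDVPRESQME...

pd  <- bundle$mutations$seq_pos[bundle$mutations$class == "PD"]
snp <- bundle$mutations$seq_pos[bundle$mutations$class == "SNP"]
compareClasses(pd, snp, bundle$feature, bundle$model)
#>     feature n_a n_b mean_dist_a mean_dist_b xd_a   xd_b delta_xd significant
#> 1 catalytic  19  25        1.32        7.64 2.49 -0.191     2.68        TRUE
```

The 40 pathogenic records collapse to 19 unique model positions whose mean
distance to the planted 16-residue site is 1.3 Å, against 7.6 Å for the
neutral class; ΔXd = 2.68 exceeds the 0.75 convention, recovering the
planted proximity bias.

Composition enrichment at sequence-level sample sizes (130 vs 200 records,
Leu→Pro planted at 10-fold):

```r
spec2 <- syntheticSpec(class_sizes = c(130, 200), proximity_lambda = Inf,
                       seed = 42)
scan <- enrichmentScan(generateBundle(spec2)$mutations, modes = "pair")
head(scan, 3)
#>   property  a   b c   d p_two_sided direction flagged
#> 1 pair:L>P 21 109 1 199    1.62e-08        PD    TRUE
#> 2 pair:F>I  2 128 0 200    1.54e-01        PD   FALSE
#> 3 pair:G>E  2 128 0 200    1.54e-01        PD   FALSE
```

A full run (accessibility → conservation → mapping → effects → Xd →
enrichment, with every table and a JSON manifest written to a directory):

```r
res <- runAnalysis(runConfig(synthetic = list(), out_dir = "report", seed = 7))
```

or from the shell, `Rscript inst/cli/kinsaap.R run --config cfg.yaml
--seed 7 --out report`. Each stage is also a subcommand (`generate`, `sasa`,
`map`, `effects`, `xd`, `enrich`).

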