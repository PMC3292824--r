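# barcodegap

Threshold-based DNA-barcode species discrimination for **congeneric**
taxa — the hard case for barcoding, where inter-specific divergence can be
as small as intra-specific noise.

`barcodegap` is for molecular taxonomists and barcoding practitioners who
have, per candidate locus, an aligned multi-FASTA of accession-level
sequences and a sample sheet mapping accessions to species. It answers the
standard question of a barcode-gap study: *what fraction of the species in
this genus does each locus — or each multi-locus combination — actually
discriminate?*

## The statistic

For each scope (a locus, or a concatenation of loci):

1. **Distances.** Pairwise Kimura-2-parameter distances
   *d* = −½ ln(1 − 2*P* − *Q*) − ¼ ln(1 − 2*Q*), with *P* and *Q* the
   transition (A↔G, C↔T) and transversion proportions over the compared
   sites (pairwise deletion by default; p and Jukes–Cantor distances are
   available). Saturated pairs (log argument ≤ 0) are flagged undefined,
   never zeroed.
2. **Representatives.** Each species' accessions are collapsed into one
   majority-rule consensus sequence per locus (ties become IUPAC ambiguity
   codes, which are skipped in distance computation). Inter-specific
   distances use representatives; intra-specific distances always use the
   accession-level sequences (species with a single accession are
   excluded from intra statistics).
3. **Threshold.** τ = the scope's maximum intra-specific distance. Two
   species are *resolved* iff their inter-specific distance is strictly
   greater than τ. With τ = 0 this reduces to counting species pairs with
   a zero distance estimate.
4. **Resolution.** percent = (A − B) × 100 / A, where A = species
   analyzed and B = distinct species involved in at least one unresolved
   pair (each species counted once), reported half-up to two decimals.

Multi-locus scopes use the intersection of species having every member
locus; the concatenated distance pools site counts across members, and the
combination's τ comes from concatenated accession-level sequences.

A ground-truthed simulator (`simulate_genus`) generates congeneric
multi-locus datasets on a star phylogeny with an exact K2P substitution
process — including species pairs sharing identical plastid haplotypes,
the classic failure mode of chloroplast-only barcodes — so the whole
pipeline is testable without downloading sequences.

## Worked example

Simulate a 36-species genus (292 accessions, nuclear ITS plus four
plastid loci, one shared-plastid species pair) and analyze it:

```r
library(barcodegap)

cfg <- simulation_config(seed = 2025)
sim <- simulate_genus(cfg)
report <- analyze_dataset(sim$dataset,
  combos = list(c("matK", "rbcL"), c("matK", "rpoB", "rpoC1"),
                c("matK", "rbcL", "rpoB", "rpoC1")))
resolution_table(report)
```

```
  scope n_species_analyzed_A n_unresolved_pairs n_species_unresolved_B
1   ITS                   36                  0                      0
2  matK                   36                  4                      6
3  rbcL                   36                  5                      7
4  rpoB                   36                 21                      7
5 rpoC1                   36                 79                     15
  n_species_discriminated_C    tau percent_resolution
1                        36 0.0130             100.00
2                        30 0.0038              83.33
3                        29 0.0000              80.56
4                        29 0.0000              80.56
5                        21 0.0000              58.33
```

The nuclear locus resolves all 36 species; each plastid locus leaves
several species pairs at (or below) the threshold, e.g. `rpoC1` has 79
zero-distance pairs involving 15 species, so B = 15 and the resolution is
(36 − 15) × 100 / 36 = 58.33%. Combinations pool sites:

```r
combination_table(report)
```

```
                 scope n_species_analyzed_A n_unresolved_pairs
1            matK+rbcL                   36                  1
2      matK+rpoB+rpoC1                   36                  1
3 matK+rbcL+rpoB+rpoC1                   36                  1
  n_species_unresolved_B n_species_discriminated_C    tau percent_resolution
1                      2                        34 0.0021              94.44
2                      2                        34 0.0017              94.44
3                      2                        34 0.0012              94.44
```

Every all-plastid combination — even all four loci concatenated — stalls
at 94.44%: the one pair sharing identical plastid haplotypes
(`species_01`/`species_02`, visible in `unresolved_pairs_table(report)`)
cannot be separated without the nuclear locus, no matter how many plastid
sites are added.

Real data enter through `run_pipeline()` (or the wrapper script in
`inst/scripts/barcodegap.R`): per-locus aligned FASTA files, a TSV sample
sheet (`accession_id`, `species_label`, `locus_name`, `source_tag`) and an
optional synonym map; rendered reports (`divergence.tsv`,
`resolution.tsv`, `combos.tsv`, `unresolved_pairs.tsv`,
`scope_percent.tsv`, `bundle.json`) land in the output directory.

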