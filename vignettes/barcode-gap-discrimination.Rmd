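---
title: "Barcode-gap species discrimination: model, thresholds and the simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Barcode-gap species discrimination: model, thresholds and the simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodegap)
```

## The problem

A DNA barcode is useful only if inter-specific divergence exceeds
intra-specific divergence — the "barcode gap". For congeneric species the
gap can vanish: plastid loci in particular often carry identical
haplotypes across closely related species, because the chloroplast genome
is uniparentally inherited and evolves slowly. `barcodegap` implements the
classic distance-threshold operationalisation of the gap for a
multi-accession, multi-locus study of one genus, and a simulator that
generates such data with known ground truth.

## Model and procedure

**Distances.** All distances are computed from pairwise site-pattern
counts: among the sites where both sequences carry an unambiguous base
(A/C/G/T), count transitions (A↔G, C↔T) and transversions. The
Kimura-2-parameter distance is

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q),$$

with $P$ and $Q$ the transition and transversion proportions. When a log
argument is non-positive the pair is *saturated*: the distance is
undefined and the pair is flagged, never silently zeroed. p- and
Jukes–Cantor distances are available as diagnostics; at $Q = 2P$ the K2P
distance collapses exactly to Jukes–Cantor with $p = P + Q$, which the
test suite uses as an analytic cross-check (alongside `ape::dist.dna` as
an independent implementation).

**Deletion policy.** Pairwise deletion is the default: each pair skips
only its own unusable sites, preserving signal in datasets with scattered
missing data. Complete deletion (one dataset-wide column mask fixed
before any pair is compared) is available by flag; on real data the two
can shift distance summaries slightly, which is why the choice is
surfaced as a parameter rather than buried.

**Representatives.** Each species' accessions are collapsed, per locus,
into a majority-rule consensus: the strict-majority base wins; a gap wins
only as a strict majority of the column's informative characters; ties
among top-count bases become the minimal IUPAC code covering the tied set
(deterministic and order-invariant; ambiguity codes are later treated as
missing in distances, so a tied column simply drops out of the pairwise
comparison — a conservative choice). A fully missing column becomes `N`.
Inter-specific distances are always computed between representatives;
intra-specific distances always between accession-level sequences, with
singleton species excluded from intra statistics. A 50%-plus consensus is
this package's convention; assembly-software consensus thresholds vary
and are rarely reported.

**Threshold and resolution.** The scope threshold τ is the maximum
intra-specific distance observed in that scope (0 when no conspecific
pair exists). A species pair is resolved iff its inter-specific distance
is *strictly greater* than τ — the boundary case d = τ stays unresolved.
Saturated inter-specific pairs imply divergence far beyond any plausible
τ and are counted resolved, with a warning. Percent resolution is
$(A - B) \times 100 / A$: A species analyzed, B the union of species over
unresolved pairs (a species in several unresolved pairs is counted once).
Percentages are rounded half-up to two decimals, distances reported at
four.

**Multi-locus combinations.** A combination's species set is the
intersection of species having every member locus. Representatives are
concatenated in member order, and the combination distance is the model
distance on pooled site counts — exactly what one gets by running the
concatenated alignment through the engine, and *not* the mean of
per-locus distances (the two differ whenever loci differ in length or
divergence). The combination's τ is computed from concatenated
accession-level sequences (accessions present for all members). The data
give no convention for multi-locus thresholds — observed plastid
intra-divergence is typically zero, making the choice moot there — so the
concatenated-intra convention is this package's documented choice. A
useful consequence, which the tests verify: for τ = 0 scopes the
combination's unresolved set is exactly the intersection of the member
loci's unresolved sets, so combination resolution is monotone — it can
never fall below the best member locus.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `model` | `k2p` | — | the field's standard for barcode distance matrices |
| `deletion` | `pairwise` | — | preserves signal; complete available by flag |
| τ | max intra distance | subst/site | derived, not set by hand; per scope |
| `kappa` (simulator) | 2 | rate ratio | typical plant ts:tv bias |
| rounding | 2 (percent), 4 (distance) | decimals | reporting convention |

## What the simulator emulates — and what it does not

`simulate_genus` places species founders on a **star phylogeny**: every
founder evolves independently from a common ancestor along a branch of
half the configured inter-specific divergence, so every founder pair has
the same expected divergence and expected values are closed-form.
Conspecific accessions evolve from the founder at half the intra-specific
divergence. Evolution is substitution-only (data are born aligned) with
per-site changes drawn from the exact K2P transition-probability matrix
for the branch length, so distance-recovery tests are unbiased at
moderate divergence. Designated capture pairs copy plastid founders
verbatim, reproducing the shared-chloroplast-haplotype failure mode; a
`missing_loci` map reproduces partial locus availability.

The default configuration emulates a congeneric orchid-genus field study:
36 species sampled as 292 accessions (three singletons, the remaining 33
species with 8–9 accessions, i.e. 289 accessions carrying the intra
signal), nuclear ITS (700 bp) plus plastid matK/rbcL/rpoB/rpoC1
(800/600/500/520 bp), per-locus expected inter-specific divergences of
0.1714 (ITS), 0.0126, 0.0061, 0.0077 and 0.0042 substitutions/site —
an order of magnitude of separation between nuclear and plastid signal —
intra-specific divergence 0.003 (ITS) and 0.0005 (matK) with zero for the
other plastid loci, and one plastid-capture pair. These values were fixed
once, from the study design being emulated, and are deliberately not
tuning knobs.

With low plastid divergences over short loci, distinct founders can be
identical *by chance* (at 0.0042 expected substitutions/site over 520 bp,
a founder pair carries ~2 expected differences, so a non-trivial fraction
of pairs coincide). This is realistic — it is exactly why slow plastid
loci resolve congeners poorly — and the simulator's ground truth is
therefore recorded from the **realized** founder haplotypes (which pairs
are identical at which loci), not just the configured capture pairs. The
truth of a combination follows as the intersection of member-locus truth
sets, restricted to species carrying all members.

What the simulator does **not** model: coalescent genealogies within
species, recombination, indels and alignment error, among-site rate
heterogeneity, and divergent paralogous ITS copies or pseudogenes.
Passing tests on simulated data therefore demonstrate the correctness of
the statistics and plumbing under the stated substitution model — not
that any particular real locus will behave this way; real-data results
additionally depend on the upstream alignment, which is out of scope
here (sequences must arrive aligned).

## Numerical choices and degenerate inputs

- Distances are carried at full double precision; rounding happens only
  at reporting.
- Base `round()` rounds half to even; reported figures use
  `round_half_up()` so that, e.g., 29 of 36 species gives 80.56.
- Undefined distances carry a reason (`"saturated"` or
  `"empty overlap"`); matrix entries stay `NA` with a parallel flag mask.
- A locus with no multi-accession species gets τ = 0 with a warning; a
  species whose every inter-distance is undefined counts as resolved,
  with a warning.
- Unresolved pair lists are canonicalised (sorted within and across
  pairs, deduplicated across orderings) so reruns and re-renders are
  byte-identical.
- `pair_list_with_counts()` reconstructs a pair list with a given pair
  count and species-union size (star-plus-extra-edges, or a forest when
  pairs are fewer than species − 1), letting published tallies be
  replayed through `resolution_percent()` without sequences.

## Problem sizes used in the test suite

The shipped tests run the full pipeline on simulated genera of 6–36
species with 2–3 accessions per species and loci of 120–800 bp, plus
10^4-case property fuzzing of the distance closed forms and 10^3-pair
site-counting checks; the whole suite completes in well under a minute.
The stochastic recovery checks (distance and ts:tv ratio against
configured values) use 120–200 replicates and 3-standard-error bands.

## Known limitations

- τ is a per-scope scalar (the global intra maximum), not per species;
  nearest-neighbour or species-specific thresholds are out of scope.
- Tree- or assignment-based discrimination criteria (monophyly, BLAST,
  probabilistic species delimitation) are deliberately not implemented.
- The package consumes pre-aligned loci; no multiple sequence alignment
  is computed.
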