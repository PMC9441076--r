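---
title: "Scanning coding-sequence divergence along a genome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning coding-sequence divergence along a genome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divscan)
```

## The problem

Two lineages that stopped exchanging genes accumulate fixed differences in
their coding sequences.  Comparing many orthologous genes between the two
lineages, anchored on a reference genome, answers three questions at once:
how much divergence has accumulated (t, substitutions per codon), what kind
of selection shaped it (omega = dN/dS per gene), and how divergence is
organised along the genome (scattered genes versus clustered "islands").
Contrasting an early stage (recently separated populations, most genes still
identical) with a late stage (sister species whose genomes have "congealed"
genome-wide) requires every step of this pipeline to behave sensibly at both
extremes — near-zero divergence where most estimates are exactly zero, and
near-saturation where synonymous distances stop being estimable.

## From transcripts to orthologous codon alignments

**Positional classification.**  Orthology is operationalised positionally: a
transcript that aligns once, at one locus, in the reference genome, and whose
partner collection has exactly one transcript at the same locus, is treated
as one member of an orthologous pair.  Everything else is excluded:
transcripts hitting two scaffolds (scaffold paralogs), two disjoint loci on
one scaffold (tandem paralogs), or sharing a locus with another transcript of
the same collection (allelic forms).  Three definitions needed sharpening
into computable rules:

* *"matching exactly the same positions"* (allelic) is relaxed to reciprocal
  locus overlap of at least `overlap_frac` (default 0.9), because real
  alignment coordinates jitter by a few bases.  All members of an allelic
  cluster are excluded from pairing — the conservative reading, since there
  is no principled way to pick one allele — and remain flagged in the
  classification output.
* *"non-overlapping positions"* (tandem) means loci sharing zero bases.
* the exon/uniq split uses a scaffold gap tolerance (`gap_tolerance_bp`,
  default 30): segments that are contiguous on the transcript (within 10 bp)
  but separated by more than the tolerance on the scaffold indicate introns.
  Smaller scaffold gaps are treated as alignment fraying and merged.

Input hit tables may carry several rows per query even when produced with a
best-hit setting; overlapping redundant rows at one locus are reduced to the
best-bitscore chain before classification, so the classifier sees one row
set per locus.

**CDS extraction.**  Each transcript is translated in the six reading frames
and the longest run of codons bounded by stop codons is taken as its CDS; a
start codon is not required, and a sequence end may close one side of a run.
Frames containing no stop codon at all are not trusted — such a run is
returned only as a flagged fallback and removed by the filter, because a
stop-free frame is as consistent with a frameshifted or non-coding sequence
as with a real CDS.  Filters then remove CDSs with gaps or Ns, CDSs shorter
than 300 nt, and optionally CDSs without a protein annotation at
e-value <= 1e-10.  The length and annotation conditions are implemented as
two independent filters, with annotation off by default for synthetic runs
(`require_annotation`), since fully synthetic data has no meaningful protein
database behind it.

**Codon alignments.**  Orthologous CDS pairs are trimmed to their common
in-frame overlap using the genome anchor coordinates rather than re-aligned:
by construction the retained pairs are near-identical over the anchored
region, so coordinate arithmetic is exact and cannot introduce alignment
error.  Pairs whose anchors imply incompatible frames, or whose multi-exon
structures differ, are dropped with a logged reason rather than rescued.

## Pairwise rates

Two counting estimators are provided.  Nei–Gojobori (1986) is the
transparent baseline: synonymous site counts from codon degeneracy fractions
(mutations to stop codons excluded), differences averaged over all
equal-weight minimal pathways between the two observed codons that avoid
stop codons (all six orderings for triple differences), Jukes–Cantor
correction of the difference proportions.  Every pathway computation is
precomputed once for the 61x61 sense-codon pairs and checked in the test
suite against an independent exhaustive enumeration oracle.

The default estimator follows Yang–Nielsen (2000): codon frequencies from
position-specific nucleotide frequencies of the pair (F3x4); the
transition/transversion ratio kappa estimated from fourfold-degenerate and
nondegenerate sites (K80-corrected per class, combined with site-count
weights); site counts weighting each single-nucleotide mutation opportunity
by kappa and the frequency of the target codon; equal-weight pathway
counting of differences (the equal-pathway configuration); and a K80
correction applied per site class, using the transition/transversion
partition within synonymous and within nonsynonymous differences.  With
kappa near 1 and near-uniform codon usage this reduces to the Nei–Gojobori
counts — the test suite asserts agreement of site counts within 5% in that
limit, and parameter recovery (median estimated omega within 25% of truth at
omega = 0.2, t = 0.3, kappa = 2, 300-codon genes) against the simulator.

Degenerate and extreme cases follow fixed conventions: identical pairs give
omega = 0; dN > 0 with dS = 0 resets S·dS to 1 (at least one synonymous
substitution assumed missed by chance), so omega = dN·S; saturated
proportions (no finite distance) yield flags and missing values — sentinel
numbers like 99 are never written to outputs, because sentinel numerics leak
into downstream arithmetic.  When kappa estimation degenerates (no usable
fourfold/nondegenerate variation) it falls back to 1 with a flag.
Per-gene divergence is summarised as t = 3(S·dS + N·dN)/(S + N),
substitutions per codon.  Standard errors (delta method on the corrected
proportions) are reported for information only; inference uses the
bootstrap.

## Testing positive selection

For each gene with omega > 0, codon columns are resampled with replacement
(jointly in both sequences) and dN, dS recomputed per replicate; the
observed D = dN − dS is standardized by the bootstrap standard deviation and
referred to a one-sided normal test.  Two design points:

* The z statistic uses D_obs in the numerator; centering on the replicate
  mean is available (`center = "replicate_mean"`) and numerically
  near-identical since the bootstrap mean of D tracks D_obs.
* Resampling codon columns is exactly a multinomial draw over the
  alignment's distinct codon pairs, so replicates are computed by linear
  tallies over pair counts.  The per-gene nuisance parameters of the
  Yang–Nielsen method — kappa and the F3x4 codon frequencies — are estimated
  once from the observed alignment and held fixed across replicates; sites,
  difference counts and distances are recomputed per replicate.  This keeps
  the replicate distribution centered on the gene's own estimate and makes
  a 1,000-replicate bootstrap over thousands of genes inexpensive.

P-values are adjusted with the Benjamini–Hochberg step-up (the classic
expected-proportion-of-false-positives control; Benjamini–Yekutieli behind a
flag), and a gene is called positively selected when omega > 1 *and*
q < alpha.  Calibration is asserted by simulation: at true omega = 1 the
fraction of genes with p < 0.05 stays at or below 0.10.

## The divergence landscape

Genes are positioned by anchor midpoint along scaffolds of at least 300 kb
(the 400 kb threshold used for display elsewhere is supported via
`min_scaffold_bp`).  A gene is *divergent* when t > 0.1 (`t_div`).  Each
scaffold is assigned a pattern: A (no divergent gene), B (one or two
isolated divergent genes), C (island: a run of at least `min_run = 3`
consecutive divergent genes, or more than `max_isolated = 2` in total).
The original pattern call combined a dispersion index with visual
inspection; the run/allowance rule is an automated, configurable surrogate
for that judgement and is documented as such.

Clustering is quantified with Fisher's index of dispersion s²(d)/mean(d)
over consecutive distances d between divergent genes (sample variance, n−1),
undefined below three divergent genes.  The index-equal-one-means-random
calibration strictly applies to counts in equal windows, not to
inter-gene distances; the index is nevertheless computed on distances, as
printed in the source analysis, and values well above one still indicate
aggregation.  Per-scaffold Pearson correlations between t and omega are
computed for scaffolds with more than 5 informative genes (zero-variance
scaffolds skipped with a flag), and the genome-wide relationship between dN
and dS is summarised by OLS regression.

## The synthetic-data generator

The generator is the package's experimental ground truth, not a fixture: it
draws a genome layout, evolves a transcript pair per gene, and emits the
exact file formats the pipeline consumes, with a truth table.

The codon process is the simplest one whose parameters match the
estimators' targets: continuous-time, single-nucleotide steps among sense
codons, rate proportional to kappa for transitions, multiplied by omega for
nonsynonymous changes, stop codons inaccessible; ancestors are uniform draws
over sense codons; each descendant evolves t/2 (pairwise estimators measure
only the total path length).  Rates are normalised so that one unit of time
produces one expected substitution per codon over a uniform codon
distribution; as composition drifts away from uniform the realised rate
changes slightly, a bias the tests bound at well under 10% of t.
Simulation is a vectorised Gillespie over codon sites.

Regime defaults encode the two stages being contrasted:

* **early** — 58% of genes with t = 0; non-zero divergence from a gamma
  distribution with mode ~0.025 and overall mean t ~0.016 substitutions per
  codon; an omega mixture with mean ~0.13 and a small omega > 1 component;
  one configured island (3 consecutive genes at t = 0.5) mirroring the
  single island-bearing scaffold seen in early-stage data.
* **late** — 0.4% identical genes; divergence centered at 1.1 substitutions
  per codon (sd 0.15, plus a 3% mid-range component), so that ~96% of genes
  exceed t = 0.75; an omega mixture with mean ~0.18 including a
  "frozen-protein" class near zero.  At these divergences a minority of
  genes saturate and are flagged rather than estimated — as happens in real
  late-stage comparisons.

The printed late-stage location "0.2 per codon" in the source material is
inconsistent with its own statement that 96% of genes diverge by more than
25% of sites (t > 0.75 per codon); the generator follows the
per-synonymous-site reading, which reproduces the printed marginal
fractions.

Complications (scaffold paralog, tandem duplicate, allelic variant,
intron-split anchor) are mutually exclusive per gene so truth labels stay
unambiguous, are assigned to one random side, and are generated at the
definitions' extremes (disjoint scaffolds, byte-identical loci, intron gaps
far above the tolerance); classifier recovery on such bundles is asserted at
100%.  What the generator does *not* emulate — indels and alignment error,
codon-usage bias, within-population polymorphism, assembly artefacts —
bounds what passing tests show about real data: they validate the
estimators and the pipeline logic, not robustness to upstream noise.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use regime runs of ~500 genes on
24 scaffolds, 300-codon genes, 200 bootstrap replicates (the pipeline
default is 1,000), and 500-gene Monte-Carlo batches for recovery and
calibration — sizes chosen so the whole suite re-runs in minutes on one core
while keeping binomial error well inside the asserted tolerances.  Every
stochastic step is seed-controlled: a configuration plus seed reproduces the
input bundle byte-for-byte, and pipeline reruns produce byte-identical
summary files.  Known limitations: no gap handling in alignments (gapped
CDSs are excluded, not realigned); saturated genes are excluded rather than
rescued by likelihood methods; the pattern classifier is a rule-based
surrogate for visual inspection; and the bootstrap holds per-gene kappa and
codon frequencies fixed across replicates.
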