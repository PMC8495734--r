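---
title: "Genotype-specific mutation profiling at a selectable reporter locus"
author: "canprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-specific mutation profiling at a selectable reporter locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canprofiler)
```

## The experimental design this package analyses

Mutational processes leave characteristic fingerprints: the proportions of
substitution types, the sequence contexts they favour, and the positions of
a gene they hit. A classic way to read those fingerprints in budding yeast
is selection at *CAN1*, the arginine permease: inactivating mutations make
cells resistant to the toxic analogue canavanine, so plating on canavanine
selects exactly the cells carrying a *CAN1* mutation. Pooling ~2,000
resistant colonies per culture and deep-sequencing the 1,773 bp locus
(~16,000x) turns each pool into a dense sample of the genotype's mutation
spectrum: the frequency of a variant in the pool is, to first order, the
fraction of colonies that carry it.

`canprofiler` implements the downstream half of that design. It consumes
one VCF of low-frequency variant calls per pooled sample, plus a reference
locus and a sample sheet, and produces per-genotype mutation profiles:

1. **Classification** — every (ref, alt) pair is assigned to one of 14
   classes: 6 strand-collapsed SNV classes (`CG>AT` ... `TA>GC`),
   single-base A/T and G/C insertions and deletions, complex (>1 bp)
   in/dels, dinucleotide MNVs, and replacements (in/dels whose retained
   base is also changed, e.g. `AAC>G`).
2. **Background filtering** — an empirical filter learned from *permissive*
   pools (grown without selection), whose calls are almost entirely
   PCR/sequencing error.
3. **Profiles** — per-genotype aggregation over biological replicates:
   unique counts, replicate fractions, summed and averaged frequencies,
   high-frequency (>5%) and jackpot (>25% in one replicate) variants.
4. **Context spectra** — 96-category trinucleotide spectra normalised by
   reference triplet occurrence, with genotype-by-genotype correlations.
5. **Clustering and motifs** — hierarchical clustering of the
   replicate-fraction matrix and positional information-content models of
   the sequence around each variant class.

A pooled-colony simulator generates complete synthetic experiments with
known ground truth, so every stage is testable without sequencing data.

## The permissive filter

Permissive pools carry no selection, yet their calls are far above what
spontaneous mutation would produce; they measure the noise floor of the
amplification and sequencing pipeline. The filter has two parts:

* a **global floor**: the mean called frequency over all unique-variant
  observations in the permissive samples (each variant called in each
  permissive sample contributes one observation). On simulated data at the
  default background model this comes out near 0.1% — about one supporting
  read per thousand.
* **position-specific maxima**: some positions are systematically noisy in
  every sample. For each position (or, optionally, each position+variant
  key) the threshold is raised to the highest frequency ever observed there
  in a permissive sample.

A selected-sample variant is retained iff its frequency is at least
`max(floor, position_max)`. The comparison is "remove strictly below":
a call exactly at the threshold survives, because the rule is phrased as
removing what occurs *below* the permissive level. Removals are logged with
their reason (`global` vs `positional`) in the filtered sample's metadata.

Two ambiguities had to be resolved and are exposed as options:

* the floor could be a pooled-observation mean or a mean of per-sample
  means; the pooled mean is the default (`computeGlobalFloor(method=)`).
* position keying could be per-position (default; the threshold at a
  position applies to any allele there) or per-variant
  (`keying_mode = "position_variant"`). Both are tested.

## Profile statistics and their boundaries

* **Replicate fraction** — a unique variant seen in 4 of 4 biological
  replicates scores 1; in 3 of 6, 0.5. This is the entry of the clustering
  matrix, chosen over raw frequency because frequency is dominated by when
  a mutation happened during growth, not whether the genotype favours it.
* **Mean frequency** — averaged over the replicates where the variant was
  observed (zeros excluded); a mean-with-zeros column is also provided
  since either convention is defensible.
* **High vs low frequency** — strict `> 5%` on the observed mean; exactly
  5% is low.
* **Jackpots** — strict `> 25%` in *exactly one* replicate. A mutation that
  fixes in the culture at generation *g* of growth ends up in `2^-g` of the
  final colonies, so anything that arose in the first two generations
  crosses 25%; seeing the same variant above 25% in several replicates is
  instead a systematic hotspot. The strict boundary follows the "above
  25%" phrasing of the rule; the simulator plants jackpots as
  `round(2^-g * n_colonies)` colonies *on top of* at least one regular
  occurrence, so a planted generation-2 jackpot sits strictly above the
  boundary and is always flaggable.

## Trinucleotide context

The sequenced strand is unknowable, so every SNV is collapsed to a
pyrimidine-reference representation before context assignment: the 3 bp
window around a purine reference is reverse-complemented. That yields 16
flank combinations x 6 substitutions = 96 categories. Context counting uses
presence per replicate (not frequency), averaged over all biological
replicates of the genotype; the normalised spectrum divides each category
by the number of times its triplet occurs in the reference locus, computed
by a sliding window in which every interior position contributes its
pyrimidine-collapsed triplet (the 32 counts always sum to L-2). Categories
whose triplet never occurs are reported as `NA`, never divided. Both
Pearson (default) and Spearman correlations over the 96-vectors are
available, with the method recorded on the output.

## Clustering and motifs

Rows of the replicate-fraction matrix are clustered with `stats::hclust`
(euclidean or correlation distance; complete, average or Ward linkage),
with rows pre-sorted by variant key so tie-breaking is deterministic, and
exported as Newick. A row-sum cutoff is available for dropping sparse rows;
note that on the raw fraction scale row sums are non-negative, so a
negative published cutoff can only refer to a standardised matrix — the
default here is raw scale with cutoff 0 (keep everything) and a
`scale = "zscore"` option for standardised cutoffs.

Motif models take the reference window 6 bases either side of each variant
(13 bp, variant indexed 0; in/dels anchored at the first affected base),
build a position frequency matrix per variant class, and report
per-position information content `2 - H` bits, where `H` is the Shannon
entropy of the column: 2 bits for an invariant column, 0 for a uniform one.
Windows running off the locus are excluded with a warning. Windows are not
strand-collapsed by default, so e.g. C-run and G-run deletion contexts stay
distinguishable.

## What the simulator emulates — and what it does not

Each simulated genotype owns a fixed **site pool**: ~300 distinct
(pos, ref, alt) variants, allocated to classes proportionally to the
genotype's class-spectrum weights and shared across its biological
replicates. This matches the few hundred unique variants per genotype that
selected pools show in practice, and it is load-bearing: with 2,000
colonies spread over ~300 sites a typical true variant is carried by ~7
colonies (~0.35% of reads), comfortably above the ~0.1% background floor.
Spreading the same colonies uniformly over all 1,771 eligible positions
would leave most true variants at 1-2 colonies — *below* the floor — and no
empirical filter could see them; biologically, inactivating mutations are
in fact concentrated at susceptible positions. Four pool sites per genotype
are promoted to **hot sites** (sampling weight x10-40), reproducing the
systematic >5% high-frequency variants that selected data show and
guaranteeing the existence of true variants above 1%.

Each colony draws one variant from the pool; a binomial share (default 5%)
draws a second, which is why total variant frequency can exceed 100%. With
probability 0.1 per replicate one variant becomes a jackpot at generation
g in {1,2,3}. Called frequencies are binomially thinned at 16,000x depth.

Background is a fixed per-experiment table of ~90 error-prone sites with
log-normal per-site rates around 0.1% of reads (so permissive totals land
near the ~9% that unselected pools show), ~70% CG>TA class bias, and 3 hot
positions whose systematically elevated rates are what the
position-specific filter learns. Selected samples are emitted as two
technical replicates (independent amplification and sequencing of the same
pooled preparation) and merged by observed-mean; permissive samples as
one. This asymmetry matters for filter efficacy: against the max of 16
permissive draws, a single iid selected draw survives ~1/17 of the time
(~94% removal at best), while the mean of two technical replicates has
half the variance and rarely reaches the permissive maximum, giving the
>=97% removal the acceptance checks measure.

The simulator does **not** emulate read-level errors, alignment artifacts,
primer dropout over the amplicon tiles, the caller's significance
machinery, or a full Luria-Delbrück jackpot-size distribution (jackpot
frequencies are the deterministic `2^-g` growth values). Passing tests on
simulated data therefore demonstrate the correctness of the downstream
arithmetic and the filter's behaviour under the modelled noise — not
robustness to upstream artefacts the model excludes.

## Numerical and design choices

* Coordinates are 1-based genomic throughout the interface; indels are
  stored anchor-trimmed (a single G deletion is `(pos_of_G, "G", "")`).
* Frequency source precedence when reading VCFs: allele-fraction INFO
  field, then alt-supporting reads / depth, then error — caller dialects
  differ on this and both are covered.
* Technical-replicate merge: union of keys, mean over the replicates where
  the variant was observed (mean-with-zeros available). Observed-mean
  avoids halving a variant that one amplification missed.
* Equal-length substitutions longer than 2 bp are replacements; MNVs are
  dinucleotide only. MNVs and replacements are excluded from SNV collapse
  and context analysis.
* Pearson is the default spectrum correlation (Spearman available);
  zero-variance spectra yield `NA` with a warning rather than a number.
* All empty-input cases degrade explicitly: empty samples give zero
  spectra with a warning, all-identical clustering rows merge at height 0,
  an all-removing row cutoff is an error with a diagnostic.

## Problem sizes used by the test suite

The suite simulates experiments at the design scale — 4 genotypes x 4
biological replicates x 2,000 colonies at 16,000x depth with background on
— once through the full file-based pipeline and across ten further seeds in
memory, checking that class spectra are recovered within total-variation
distance 0.05, that >=95% of background-only keys are removed, and that
every true variant at >=1% frequency survives the filter. Oracle checks run
brute-force re-implementations: 1,000 random filter scenarios, 1,000
random-sequence triplet counts, and exhaustive pairwise agglomeration
against `hclust` on matrices of up to 6 rows.

## Limitations

The filter is empirical: it can only remove what permissive sampling has
seen, so with few permissive samples rare background keys leak through and
genuinely low-frequency biology below the floor is invisible by
construction. Unique-variant counts saturate: once every pool site has been
observed, deeper sequencing adds frequency resolution, not new keys.
Context spectra use the supplied locus as the triplet denominator — the
choice of amplicon span (with or without flanks) changes the
normalisation. None of the statistics test significance; the profiles are
descriptive, as in the experimental design they mirror.
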