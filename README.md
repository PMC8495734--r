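# canprofiler

Genotype-specific mutation profiles from pooled reporter-gene deep
sequencing.

## The problem

Mutational processes — environmental exposures, replication-fidelity
defects, skewed dNTP pools — leave fingerprints in *which* mutations occur,
*where*, and in *what sequence context*. A sensitive way to read those
fingerprints in *Saccharomyces cerevisiae* is selection at the *CAN1*
arginine-permease reporter: inactivating mutations confer canavanine
resistance, so pooling ~2,000 resistant colonies per culture and
deep-sequencing the 1,773 bp locus at ~16,000x yields thousands of
selected mutations per sample, with each variant's read frequency
approximating the fraction of colonies that carry it.

`canprofiler` is the downstream analysis for that design. It consumes one
VCF of low-frequency variant calls per pooled sample (plus a reference
FASTA and a sample sheet) and produces background-filtered, per-genotype
mutation profiles. It is aimed at groups running reporter-selection deep
sequencing in yeast or adapting the approach to other loci.

## What it computes

* **Variant classes** — each (ref, alt) pair maps to one of 14 classes:
  the six strand-collapsed SNV classes written pyrimidine-first
  (`CG>AT` means C→A or its complement G→T), single-base A/T and G/C
  in/dels, complex in/dels, dinucleotide MNVs, and replacements
  (e.g. `AAC>G`).
* **Permissive filter** — from unselected ("permissive") control pools,
  whose calls measure PCR/sequencing background: a variant *v* in a
  selected sample is retained iff

  `freq(v) >= max(floor, max_permissive_freq(pos(v)))`

  where `floor` is the mean frequency over all permissive variant
  observations (≈0.1% ≙ 1 supporting read per 1,000) and the second term
  is the position-specific permissive maximum.
* **Profiles** — per genotype over biological replicates: unique counts,
  replicate fractions (seen in 4/4 replicates → 1; 3/6 → 0.5), summed and
  mean frequencies, total variant frequency
  `100 × Σ_v freq(v)` (values >100% mean multiple mutations per colony),
  high-frequency variants (mean > 5%) and jackpots (> 25% in exactly one
  replicate — a mutation that fixed within the first ~2 generations of
  growth reaches `2^-g ≥ 25%` of colonies).
* **Trinucleotide spectra** — each unique SNV in its 96-category
  pyrimidine-centred context, averaged over replicates and normalised by
  the triplet's occurrence count in the locus; Pearson/Spearman
  correlations between genotype spectra.
* **Clustering & motifs** — hierarchical clustering of the
  variants × genotypes replicate-fraction matrix (Newick export), and
  per-class position frequency matrices with information content in bits
  over a 13 bp window centred on the variant.
* **Simulator** — a pooled-colony experiment generator (selected +
  permissive pools, jackpots, background with CG>TA bias and hot
  positions, binomial thinning at depth) that emits VCFs, a sample sheet
  and ground truth, so the whole pipeline can be validated end to end.

## Worked example

Simulate a two-genotype experiment, learn the filter from the permissive
pools, and profile the mutant genotype:

```r
library(canprofiler)

locus <- syntheticLocus(seed = 7)      # 1,773 bp synthetic reporter
specs <- list(
  genotypeSpec("RNR1"),
  genotypeSpec("rnr1_mut",
               class_weights = c("CG>AT" = 0.35, "del_GC" = 0.35,
                                 "CG>TA" = 0.2, del_AT = 0.1)))
ex <- emitExperiment(specs, backgroundModel(), locus, "simdata", seed = 42)

samples  <- loadExperiment(ex$sheet)   # reads VCFs, merges tech replicates
perm     <- Filter(function(s) condition(s) == "permissive", samples)
sel      <- Filter(function(s) condition(s) == "selected",  samples)

(thr <- buildThresholds(perm))
#> ThresholdSet: global floor 0.1047%, 90 position threshold(s)

filtered <- lapply(sel, applyFilter, thresholds = thr)
round(vapply(filtered, totalVariantFrequency, numeric(1)), 1)
#> [1] 102.2 103.7 105.0 103.7 102.8 154.8 104.3 104.9
```

The learned floor sits at ~0.1%, the level at which one background call is
expected per 1,000 reads. Filtered selected pools have total variant
frequencies just above 100% — every colony carries at least one reporter
mutation, and ~5% carry two; the 154.8% replicate contains a jackpot.

```r
prof <- buildProfile(Filter(function(s) genotype(s) == "rnr1_mut", filtered))
prof
#> MutationProfile 'rnr1_mut': 306 unique variants over 4 biological replicates

round(classSpectrum(prof, "total_variants"), 3)
#>       CG>AT       CG>TA       CG>GC       TA>AT       TA>CG       TA>GC
#>       0.343       0.216       0.000       0.000       0.000       0.000
#>      ins_AT      ins_GC ins_complex      del_AT      del_GC del_complex
#>       0.000       0.000       0.000       0.098       0.343       0.000
#>         MNV replacement
#>       0.000       0.000
```

The unique-count class spectrum recovers the simulated weights
(0.35 / 0.2 / 0.35 / 0.1). High-frequency and jackpot variants:

```r
head(partitionByFrequency(prof)$high[, c("pos", "ref", "alt", "class",
     "replicate_fraction", "freq_mean_observed")], 4)
#>       pos ref alt  class replicate_fraction freq_mean_observed
#> 93  32571   G     del_GC                  1         0.09579688
#> 252 33506   G   A  CG>TA                  1         0.12843750
#> 276 33593   G   A  CG>TA                  1         0.07482031

flagJackpots(prof)
#> [1] "33506:G:A"
```

`33506:G:A` is both a systematically susceptible site (present in 4/4
replicates) and, in one replicate, a jackpot that crossed 25%. Context
spectra separate the genotypes:

```r
prof_wt <- buildProfile(Filter(function(s) genotype(s) == "RNR1", filtered))
sp <- lapply(list(prof_wt, prof), trinucSpectrum, locus = locus)
round(spectrumCorrelation(sp[[1]], sp[[2]]), 3)
#> [1] 0.529
```

`runPipeline()` chains all stages and writes TSV artifacts (thresholds,
filtered samples, profiles with flags, 96-context spectra and correlation
matrix, fraction matrix + Newick dendrogram, motif PFMs); a thin
command-line wrapper lives at `inst/cli/canprofiler.R`
(`simulate | run | filter | profile | trinuc | cluster | motif`).

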