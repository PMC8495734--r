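#' @import methods
#' @importFrom S4Vectors metadata
NULL

## Column layout shared by every variant table in the package. `ref`/`alt`
## are stored anchor-trimmed, so a single-base deletion of G is (pos_of_G,
## "G", "") and a pure insertion is (pos, "", "A").
.variant_cols <- c("chrom", "pos", "ref", "alt", "frequency", "depth")

.empty_variants <- function() {
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), frequency = numeric(), depth = integer(),
               stringsAsFactors = FALSE)
}

.check_variants_df <- function(v) {
    msg <- character()
    if (!is.data.frame(v)) return("variants must be a data.frame")
    missing <- setdiff(.variant_cols, names(v))
    if (length(missing))
        return(paste("variants lacks columns:", paste(missing, collapse = ", ")))
    if (nrow(v)) {
        if (any(v$ref == v$alt))
            msg <- c(msg, "ref == alt for some variant")
        if (any(v$ref == "" & v$alt == ""))
            msg <- c(msg, "ref and alt both empty for some variant")
        if (any(v$frequency < 0 | v$frequency > 1))
            msg <- c(msg, "frequency outside [0, 1]")
        bad <- grepl("[^ACGT]", v$ref) | grepl("[^ACGT]", v$alt)
        if (any(bad))
            msg <- c(msg, "non-ACGT characters in ref/alt")
    }
    msg
}

#' Reference locus
#'
#' A contiguous stretch of genome (here the 1,773 bp \emph{CAN1} reporter
#' plus flanks) held as a \code{DNAString} with the genomic coordinate of its
#' first base, so that printed genomic positions map directly onto the
#' sequence. Coordinates are 1-based and inclusive throughout the interface.
#'
#' @slot name locus name.
#' @slot sequence a \code{\link[Biostrings]{DNAString}} over A/C/G/T.
#' @slot offset 1-based genomic coordinate of the first base.
#' @slot chrom chromosome name used in VCF records.
#'
#' @exportClass ReferenceLocus
setClass("ReferenceLocus",
    representation(name = "character", sequence = "DNAString",
                   offset = "integer", chrom = "character"))

setValidity("ReferenceLocus", function(object) {
    msg <- character()
    if (length(object@sequence) == 0L)
        msg <- c(msg, "sequence is empty")
    s <- as.character(object@sequence)
    bad <- regmatches(s, gregexpr("[^ACGT]", s))[[1]]
    if (length(bad))
        msg <- c(msg, paste0("sequence contains non-ACGT characters: ",
                             paste(unique(bad), collapse = ", ")))
    if (length(object@offset) != 1L || is.na(object@offset) || object@offset < 1L)
        msg <- c(msg, "offset must be a single positive integer")
    if (length(msg)) msg else TRUE
})

#' Pooled-colony sequencing sample
#'
#' One sequencing replicate of a pool of ~2,000 colonies: either a
#' \emph{selected} pool (canavanine-resistant colonies, each carrying at
#' least one reporter-inactivating variant) or a \emph{permissive} pool
#' (grown without selection, used to estimate PCR/sequencing background).
#' Variants are one row per called ALT allele, anchor-trimmed.
#'
#' @slot sampleId unique sample identifier.
#' @slot genotype strain genotype label (e.g. \code{rnr1Y285A}).
#' @slot bioReplicate,techReplicate replicate labels.
#' @slot condition \code{"selected"} or \code{"permissive"}.
#' @slot totalReads total reads sequenced for the sample.
#' @slot variants data.frame with columns chrom, pos, ref, alt, frequency, depth.
#' @slot metadata free-form list (filter logs, provenance).
#'
#' @exportClass PooledSample
setClass("PooledSample",
    representation(sampleId = "character", genotype = "character",
                   bioReplicate = "character", techReplicate = "character",
                   condition = "character", totalReads = "integer",
                   variants = "data.frame", metadata = "list"),
    prototype(variants = .empty_variants(), metadata = list()))

setValidity("PooledSample", function(object) {
    msg <- .check_variants_df(object@variants)
    if (!object@condition %in% c("selected", "permissive"))
        msg <- c(msg, "condition must be 'selected' or 'permissive'")
    if (length(object@totalReads) != 1L || is.na(object@totalReads) ||
        object@totalReads < 1L)
        msg <- c(msg, "totalReads must be a single positive integer")
    v <- object@variants
    if (nrow(v) && anyDuplicated(paste(v$pos, v$ref, v$alt)))
        msg <- c(msg, "duplicate (pos, ref, alt) within sample")
    if (length(msg)) msg else TRUE
})

#' Permissive-filter thresholds
#'
#' The empirical background filter learned from permissive samples: a global
#' frequency floor (the mean called frequency over all permissive variant
#' observations; 0.109\% in the original study) plus per-key maxima for
#' positions where background is systematically elevated. The effective
#' threshold for a variant is \code{max(globalFloor, positionMax[key])} and a
#' variant is retained iff its frequency is >= that threshold.
#'
#' @slot globalFloor global frequency floor (fraction).
#' @slot positionMax data.frame with pos (and ref/alt when keyed per variant)
#'   and max_freq.
#' @slot keyingMode \code{"position"} (threshold applies to any variant at
#'   the position) or \code{"position_variant"}.
#'
#' @exportClass ThresholdSet
setClass("ThresholdSet",
    representation(globalFloor = "numeric", positionMax = "data.frame",
                   keyingMode = "character"))

setValidity("ThresholdSet", function(object) {
    msg <- character()
    if (length(object@globalFloor) != 1L || object@globalFloor < 0)
        msg <- c(msg, "globalFloor must be a single non-negative number")
    if (!object@keyingMode %in% c("position", "position_variant"))
        msg <- c(msg, "keyingMode must be 'position' or 'position_variant'")
    pm <- object@positionMax
    need <- if (identical(object@keyingMode, "position")) c("pos", "max_freq")
            else c("pos", "ref", "alt", "max_freq")
    if (!all(need %in% names(pm)))
        msg <- c(msg, paste("positionMax lacks columns:",
                            paste(setdiff(need, names(pm)), collapse = ", ")))
    else if (nrow(pm) && any(pm$max_freq < 0))
        msg <- c(msg, "negative max_freq")
    if (length(msg)) msg else TRUE
})

#' Genotype-level mutation profile
#'
#' Aggregation of the filtered biological replicates of one genotype.
#' Each unique variant key (pos, ref, alt) carries its replicate count,
#' replicate fraction (count / n replicates, the clustering matrix entry),
#' summed frequency across replicates, and mean frequency over the
#' replicates in which it was observed.
#'
#' @slot genotype genotype label.
#' @slot nReplicates number of biological replicates aggregated.
#' @slot replicateIds biological replicate labels, in column order of
#'   \code{freqMatrix}.
#' @slot variantStats per-key statistics (one row per unique variant).
#' @slot freqMatrix keys x replicates matrix of called frequencies
#'   (0 where not called).
#'
#' @exportClass MutationProfile
setClass("MutationProfile",
    representation(genotype = "character", nReplicates = "integer",
                   replicateIds = "character", variantStats = "data.frame",
                   freqMatrix = "matrix"))

setValidity("MutationProfile", function(object) {
    msg <- character()
    vs <- object@variantStats
    if (nrow(vs) != nrow(object@freqMatrix))
        msg <- c(msg, "variantStats and freqMatrix disagree on key count")
    if (ncol(object@freqMatrix) != object@nReplicates)
        msg <- c(msg, "freqMatrix has wrong number of replicate columns")
    if (nrow(vs)) {
        if (any(vs$replicate_count < 1L) ||
            any(vs$replicate_count > object@nReplicates))
            msg <- c(msg, "replicate_count outside (0, nReplicates]")
        if (any(abs(vs$replicate_fraction -
                    vs$replicate_count / object@nReplicates) > 1e-12))
            msg <- c(msg, "replicate_fraction inconsistent with replicate_count")
    }
    if (length(msg)) msg else TRUE
})

#' Trinucleotide-context SNV spectrum
#'
#' The 96-category spectrum of unique SNVs in pyrimidine-centred triplet
#' context for one genotype: per-replicate presence counts averaged over
#' biological replicates (\code{avgCount}), optionally divided by the number
#' of times each triplet occurs in the reference locus (\code{normalized};
#' NA where the triplet is absent from the locus).
#'
#' @slot genotype genotype label.
#' @slot avgCount named 96-vector of average unique-SNV counts.
#' @slot normalized named 96-vector normalised by reference triplet counts.
#' @slot tripletCounts named 32-vector of pyrimidine-centred triplet counts
#'   in the reference locus.
#'
#' @exportClass TrinucSpectrum
setClass("TrinucSpectrum",
    representation(genotype = "character", avgCount = "numeric",
                   normalized = "numeric", tripletCounts = "numeric"))

setValidity("TrinucSpectrum", function(object) {
    msg <- character()
    if (length(object@avgCount) != 96L)
        msg <- c(msg, "avgCount must have 96 entries")
    if (length(object@normalized) != 96L)
        msg <- c(msg, "normalized must have 96 entries")
    if (length(object@tripletCounts) != 32L)
        msg <- c(msg, "tripletCounts must have 32 entries")
    if (any(object@avgCount < 0))
        msg <- c(msg, "negative avgCount")
    if (any(is.infinite(object@normalized)))
        msg <- c(msg, "normalized values must be finite or NA")
    if (length(msg)) msg else TRUE
})

#' Simulator genotype specification
#'
#' Parameters of one simulated genotype: the class spectrum its colonies
#' draw reporter-inactivating variants from, optional trinucleotide-context
#' weights for the SNV share, pool size, replicate count, the probability a
#' colony carries a second variant, and the jackpot model (a mutation fixed
#' at generation g of the culture reaches 2^-g of final colonies).
#'
#' @slot name genotype label.
#' @slot classWeights named non-negative weights over the 14 variant classes;
#'   normalised internally.
#' @slot contextWeights optional named non-negative 96-vector steering SNV
#'   placement by trinucleotide context; length-0 means uniform over sites.
#' @slot nSites size of the genotype's variant-site pool: the distinct
#'   (pos, ref, alt) variants its colonies draw from, allocated to classes
#'   proportionally to \code{classWeights} and fixed once per genotype (so
#'   biological replicates share systematic, genotype-specific variants).
#' @slot nHotSites number of pool sites promoted to genotype-specific
#'   susceptible positions whose sampling weight is multiplied by a factor
#'   drawn uniformly from \code{hotRange} — the source of systematic
#'   high-frequency (>5\%) variants.
#' @slot hotRange length-2 numeric, the weight-multiplier range for hot
#'   sites.
#' @slot nColonies colonies pooled per biological replicate.
#' @slot nBioReplicates biological replicates.
#' @slot multiMutationRate probability a colony carries a second variant.
#' @slot jackpotProb per-replicate probability of one jackpot event.
#' @slot jackpotGenerations candidate generations g for jackpots (frequency
#'   2^-g), sampled uniformly.
#'
#' @exportClass GenotypeSpec
setClass("GenotypeSpec",
    representation(name = "character", classWeights = "numeric",
                   contextWeights = "numeric", nSites = "integer",
                   nHotSites = "integer", hotRange = "numeric",
                   nColonies = "integer",
                   nBioReplicates = "integer", multiMutationRate = "numeric",
                   jackpotProb = "numeric", jackpotGenerations = "integer"))

setValidity("GenotypeSpec", function(object) {
    msg <- character()
    if (any(object@classWeights < 0) || sum(object@classWeights) <= 0)
        msg <- c(msg, "classWeights must be non-negative with positive sum")
    if (!all(names(object@classWeights) %in% variantClassNames()))
        msg <- c(msg, "classWeights names must be variant class names")
    if (length(object@contextWeights) &&
        length(object@contextWeights) != 96L)
        msg <- c(msg, "contextWeights must be empty or length 96")
    if (object@nSites < length(object@classWeights))
        msg <- c(msg, "nSites must be at least the number of active classes")
    if (object@nHotSites > object@nSites)
        msg <- c(msg, "nHotSites cannot exceed nSites")
    if (length(object@hotRange) != 2L || any(object@hotRange < 1))
        msg <- c(msg, "hotRange must be two multipliers >= 1")
    if (object@nColonies < 1L) msg <- c(msg, "nColonies must be >= 1")
    if (object@nBioReplicates < 1L) msg <- c(msg, "nBioReplicates must be >= 1")
    if (object@multiMutationRate < 0 || object@multiMutationRate > 1)
        msg <- c(msg, "multiMutationRate must be in [0, 1]")
    if (object@jackpotProb < 0 || object@jackpotProb > 1)
        msg <- c(msg, "jackpotProb must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Simulator background-error model
#'
#' PCR/sequencing background as observed in permissive pools: a set of
#' error-prone (position, variant) sites with per-site rates drawn once per
#' experiment from a log-normal around \code{meanRate}, an SNV class bias
#' (defaults to ~70\% CG>TA, the signature of the amplification polymerase),
#' a few hot positions with systematically elevated rates shared across all
#' samples, and the sequencing depth used for binomial thinning of called
#' frequencies.
#'
#' @slot meanRate mean per-site background frequency (fraction of reads).
#' @slot sdLog log-scale standard deviation of per-site rates.
#' @slot snvBias named non-negative weights over the 6 SNV classes.
#' @slot nSites number of background-prone sites on the locus.
#' @slot nHotPositions number of sites given systematically elevated rates.
#' @slot hotMultiplier rate multiplier at hot sites.
#' @slot depth sequencing depth (reads) per sample.
#'
#' @exportClass BackgroundModel
setClass("BackgroundModel",
    representation(meanRate = "numeric", sdLog = "numeric",
                   snvBias = "numeric", nSites = "integer",
                   nHotPositions = "integer", hotMultiplier = "numeric",
                   depth = "integer"))

setValidity("BackgroundModel", function(object) {
    msg <- character()
    if (object@meanRate < 0 || object@meanRate > 1)
        msg <- c(msg, "meanRate must be in [0, 1]")
    if (any(object@snvBias < 0) || sum(object@snvBias) <= 0)
        msg <- c(msg, "snvBias must be non-negative with positive sum")
    if (!all(names(object@snvBias) %in% snvClassNames()))
        msg <- c(msg, "snvBias names must be SNV class names")
    if (object@depth < 1L) msg <- c(msg, "depth must be >= 1")
    if (object@nHotPositions > object@nSites)
        msg <- c(msg, "nHotPositions cannot exceed nSites")
    if (length(msg)) msg else TRUE
})
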