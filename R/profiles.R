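## Genotype-level aggregation of filtered biological replicates.

#' @rdname MutationProfile-accessors
#' @export
setGeneric("variantStats", function(x) standardGeneric("variantStats"))

#' Accessors for MutationProfile
#'
#' @param x a \code{MutationProfile}.
#' @return \code{variantStats}: per-unique-variant statistics;
#'   \code{freqMatrix}: keys x replicates frequency matrix;
#'   \code{nReplicates}: number of biological replicates.
#' @name MutationProfile-accessors
#' @aliases variantStats
#' @export
setMethod("variantStats", "MutationProfile", function(x) x@variantStats)

#' @rdname MutationProfile-accessors
#' @export
freqMatrix <- function(x) x@freqMatrix

#' @rdname MutationProfile-accessors
#' @export
nReplicates <- function(x) x@nReplicates

setMethod("show", "MutationProfile", function(object) {
    cat("MutationProfile '", object@genotype, "': ",
        nrow(object@variantStats), " unique variants over ",
        object@nReplicates, " biological replicates\n", sep = "")
})

#' Build a genotype mutation profile from filtered replicates
#'
#' Aggregates the biological replicates of one genotype over unique variant
#' keys (pos, ref, alt). Each key is counted once per replicate in which it
#' was called (\emph{unique counts}); the replicate fraction
#' (count / n replicates) is the entry later used for clustering; the
#' summed frequency preserves the \emph{sum of frequencies} view; the mean
#' frequency is by default taken over the replicates where the variant was
#' observed (zeros excluded), with a mean-over-all alternative in the
#' \code{freq_mean_all} column.
#'
#' @param samples list of \code{PooledSample} of one genotype, technical
#'   replicates already merged.
#' @param genotype optional genotype label override (defaults to the
#'   samples' shared genotype).
#' @return a \code{\link{MutationProfile}}; rows ordered by (pos, ref, alt).
#' @export
buildProfile <- function(samples, genotype = NULL) {
    samples <- .as_sample_list(samples)
    if (length(samples) == 0L) stop("no samples supplied")
    gts <- unique(vapply(samples, canprofiler::genotype, character(1)))
    if (is.null(genotype)) {
        if (length(gts) != 1L)
            stop("samples mix genotypes: ", paste(gts, collapse = ", "))
        genotype <- gts
    }
    reps <- vapply(samples, bioReplicate, character(1))
    if (anyDuplicated(reps))
        reps <- make.unique(reps)
    n_rep <- length(samples)
    vs_all <- do.call(rbind, lapply(seq_along(samples), function(i) {
        v <- variants(samples[[i]])
        if (nrow(v)) cbind(v, .rep = i) else cbind(v, .rep = integer())
    }))
    if (is.null(vs_all) || nrow(vs_all) == 0L) {
        stats <- data.frame(pos = integer(), ref = character(),
                            alt = character(), class = character(),
                            replicate_count = integer(),
                            replicate_fraction = numeric(),
                            freq_sum = numeric(),
                            freq_mean_observed = numeric(),
                            freq_mean_all = numeric())
        fm <- matrix(0, 0, n_rep, dimnames = list(NULL, reps))
        return(new("MutationProfile", genotype = genotype,
                   nReplicates = as.integer(n_rep), replicateIds = reps,
                   variantStats = stats, freqMatrix = fm))
    }
    o <- order(vs_all$pos, vs_all$ref, vs_all$alt)
    vs_all <- vs_all[o, , drop = FALSE]
    k <- variantKey(vs_all$pos, vs_all$ref, vs_all$alt)
    uk <- unique(k)
    first <- match(uk, k)
    fm <- matrix(0, nrow = length(uk), ncol = n_rep,
                 dimnames = list(uk, reps))
    fm[cbind(match(k, uk), vs_all$.rep)] <- vs_all$frequency
    rep_count <- as.integer(rowSums(fm > 0))
    stats <- data.frame(
        pos = vs_all$pos[first], ref = vs_all$ref[first],
        alt = vs_all$alt[first],
        class = classifyVariant(vs_all$ref[first], vs_all$alt[first]),
        replicate_count = rep_count,
        replicate_fraction = rep_count / n_rep,
        freq_sum = rowSums(fm),
        freq_mean_observed = rowSums(fm) / rep_count,
        freq_mean_all = rowSums(fm) / n_rep,
        row.names = NULL)
    new("MutationProfile", genotype = genotype,
        nReplicates = as.integer(n_rep), replicateIds = reps,
        variantStats = stats, freqMatrix = fm)
}

#' Partition a profile's variants by mean frequency
#'
#' High-frequency variants are those whose mean observed frequency is
#' strictly above the cutoff (default 5\%); the rest are low-frequency.
#'
#' @param profile a \code{MutationProfile}.
#' @param high_cutoff frequency fraction (default 0.05).
#' @return list with data.frames \code{high} and \code{low}.
#' @export
partitionByFrequency <- function(profile, high_cutoff = 0.05) {
    vs <- variantStats(profile)
    hi <- vs$freq_mean_observed > high_cutoff
    list(high = vs[hi, , drop = FALSE], low = vs[!hi, , drop = FALSE])
}

#' Flag jackpot variants
#'
#' A jackpot is a unique variant whose called frequency exceeds the cutoff
#' (default 25\%) in exactly one biological replicate — the signature of a
#' mutation that arose within the first couple of generations of the
#' culture (a mutation fixed at generation g reaches 2^-g of final
#' colonies). Variants above the cutoff in several replicates are
#' systematic high-frequency variants, not jackpots.
#'
#' @param profile a \code{MutationProfile}.
#' @param jackpot_cutoff frequency fraction (default 0.25, strict >).
#' @return character vector of jackpot variant keys ("pos:ref:alt").
#' @export
flagJackpots <- function(profile, jackpot_cutoff = 0.25) {
    fm <- freqMatrix(profile)
    if (!nrow(fm)) return(character())
    n_above <- rowSums(fm > jackpot_cutoff)
    rownames(fm)[n_above == 1L]
}

#' Count unique variants per genotype and overall
#'
#' @param profiles list of \code{MutationProfile} (or one).
#' @return data.frame with one row per genotype plus a \code{"combined"}
#'   row counting the union of keys.
#' @export
countUniqueVariants <- function(profiles) {
    if (is(profiles, "MutationProfile")) profiles <- list(profiles)
    keys <- lapply(profiles, function(p) rownames(freqMatrix(p)))
    gts <- vapply(profiles, genotype, character(1))
    data.frame(genotype = c(gts, "combined"),
               n_unique = c(lengths(keys),
                            length(unique(unlist(keys)))))
}

#' Per-variant presence across genotypes
#'
#' Binary presence matrix of unique variant keys across genotype profiles,
#' plus the tally of keys present in exactly k genotypes.
#'
#' @param profiles list of >= 2 \code{MutationProfile}.
#' @return list: \code{presence} (keys x genotypes 0/1 matrix) and
#'   \code{k_table} (named count of keys present in exactly k genotypes).
#' @export
genotypeOverlap <- function(profiles) {
    if (length(profiles) < 2L) stop("need >= 2 genotype profiles")
    keys <- lapply(profiles, function(p) rownames(freqMatrix(p)))
    gts <- vapply(profiles, genotype, character(1))
    all_keys <- sort(unique(unlist(keys)))
    presence <- vapply(keys, function(k) as.integer(all_keys %in% k),
                       integer(length(all_keys)))
    presence <- matrix(presence, nrow = length(all_keys),
                       dimnames = list(all_keys, gts))
    k_counts <- rowSums(presence)
    k_table <- table(factor(k_counts, levels = seq_along(profiles)))
    list(presence = presence, k_table = k_table)
}
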