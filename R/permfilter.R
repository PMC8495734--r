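## Empirical background filter learned from permissive (unselected) pools.
## Background here is dominated by PCR/sequencing error: low-frequency calls
## (~0.1% of reads) with a strong CG>TA bias, plus a few positions with
## systematically elevated rates shared across genotypes.

#' Global background floor from permissive samples
#'
#' The mean called frequency over all unique-variant observations in the
#' permissive samples: each variant called in each permissive sample
#' contributes one observation (pooled-observation mean; the study's fitted
#' value was 0.109\%). \code{mean_of_means} instead averages per-sample
#' means, exposed because the original computation is ambiguous on this
#' point.
#'
#' @param permissive_samples list of permissive \code{PooledSample}.
#' @param method \code{"pooled"} (default) or \code{"mean_of_means"}.
#' @return the floor as a frequency fraction.
#' @export
computeGlobalFloor <- function(permissive_samples,
                               method = c("pooled", "mean_of_means")) {
    method <- match.arg(method)
    permissive_samples <- .as_sample_list(permissive_samples)
    if (length(permissive_samples) == 0L)
        stop("no permissive samples: supply a configured floor instead ",
             "(buildThresholds(floor = <fraction>))")
    per <- lapply(permissive_samples, function(s) variants(s)$frequency)
    if (method == "pooled") mean(unlist(per))
    else mean(vapply(per, mean, numeric(1)))
}

#' Position-specific background maxima from permissive samples
#'
#' For each key (position, or position + variant), the highest frequency at
#' which background was ever called in a permissive sample. Positions never
#' seen in permissive data are absent: their effective threshold is the
#' global floor.
#'
#' @inheritParams computeGlobalFloor
#' @param keying_mode \code{"position"}: one threshold per position,
#'   applying to any variant there (the default, reading the filter rule
#'   literally); \code{"position_variant"}: per-variant thresholds.
#' @return data.frame of keys and \code{max_freq}.
#' @export
computePositionMax <- function(permissive_samples,
                               keying_mode = c("position",
                                               "position_variant")) {
    keying_mode <- match.arg(keying_mode)
    permissive_samples <- .as_sample_list(permissive_samples)
    vs <- do.call(rbind, lapply(permissive_samples, variants))
    if (is.null(vs) || nrow(vs) == 0L) {
        out <- if (keying_mode == "position")
            data.frame(pos = integer(), max_freq = numeric())
        else data.frame(pos = integer(), ref = character(),
                        alt = character(), max_freq = numeric())
        return(out)
    }
    if (keying_mode == "position") {
        mx <- tapply(vs$frequency, vs$pos, max)
        out <- data.frame(pos = as.integer(names(mx)),
                          max_freq = as.numeric(mx))
    } else {
        k <- variantKey(vs$pos, vs$ref, vs$alt)
        uk <- unique(k)
        first <- match(uk, k)
        mx <- vapply(split(vs$frequency, factor(k, levels = uk)),
                     max, numeric(1))
        out <- data.frame(pos = vs$pos[first], ref = vs$ref[first],
                          alt = vs$alt[first], max_freq = as.numeric(mx))
    }
    out[order(out$pos), , drop = FALSE]
}

#' Build the permissive filter
#'
#' Combines the global floor and the position-specific maxima into a
#' \code{\link{ThresholdSet}}. A fixed floor (e.g. the published 0.00109)
#' can be supplied to reproduce a previous filter without permissive data.
#'
#' @inheritParams computePositionMax
#' @param floor \code{"auto"} to compute from the permissive samples, or a
#'   numeric fraction.
#' @param floor_method passed to \code{\link{computeGlobalFloor}}.
#' @return a \code{ThresholdSet}.
#' @export
buildThresholds <- function(permissive_samples = list(), floor = "auto",
                            keying_mode = c("position", "position_variant"),
                            floor_method = "pooled") {
    keying_mode <- match.arg(keying_mode)
    gf <- if (identical(floor, "auto"))
        computeGlobalFloor(permissive_samples, floor_method)
    else as.numeric(floor)
    pm <- computePositionMax(permissive_samples, keying_mode)
    new("ThresholdSet", globalFloor = gf, positionMax = pm,
        keyingMode = keying_mode)
}

setMethod("show", "ThresholdSet", function(object) {
    cat("ThresholdSet: global floor ",
        format(100 * object@globalFloor, digits = 4), "%, ",
        nrow(object@positionMax), " ", object@keyingMode,
        " threshold(s)\n", sep = "")
})

#' Effective threshold for variant keys
#'
#' @param thresholds a \code{ThresholdSet}.
#' @param pos,ref,alt variant key components (ref/alt ignored under
#'   position keying).
#' @return numeric vector: \code{max(globalFloor, positionMax[key])}.
#' @export
effectiveThreshold <- function(thresholds, pos, ref = "", alt = "") {
    pm <- thresholds@positionMax
    key <- if (thresholds@keyingMode == "position") as.character(pos)
           else variantKey(pos, ref, alt)
    pkey <- if (thresholds@keyingMode == "position") as.character(pm$pos)
            else variantKey(pm$pos, pm$ref, pm$alt)
    posmax <- pm$max_freq[match(key, pkey)]
    posmax[is.na(posmax)] <- 0
    pmax(thresholds@globalFloor, posmax)
}

#' Apply the permissive filter to a sample
#'
#' Retains exactly the variants whose called frequency is at or above the
#' effective threshold at their key (a variant occurring \emph{below} the
#' threshold is removed; equality is retained). Removed variants are logged
#' in the returned sample's metadata with the removal reason
#' (\code{"global"} vs \code{"positional"}). The input is not mutated.
#'
#' @param sample a \code{PooledSample} (normally selected; applying to a
#'   permissive sample is allowed for diagnostics).
#' @param thresholds a \code{ThresholdSet}.
#' @return filtered \code{PooledSample}; \code{metadata(x)$removed} holds
#'   the removed rows with their threshold and reason.
#' @export
applyFilter <- function(sample, thresholds) {
    v <- variants(sample)
    thr <- if (nrow(v))
        effectiveThreshold(thresholds, v$pos, v$ref, v$alt) else numeric()
    keep <- v$frequency >= thr
    removed <- v[!keep, , drop = FALSE]
    if (nrow(removed)) {
        removed$threshold <- thr[!keep]
        posmax_part <- thr[!keep] > thresholds@globalFloor
        removed$reason <- ifelse(posmax_part, "positional", "global")
    } else {
        removed$threshold <- numeric()
        removed$reason <- character()
    }
    out <- pooledSample(sampleId(sample), genotype(sample),
                        bioReplicate(sample), techReplicate(sample),
                        condition(sample), totalReads(sample),
                        v[keep, , drop = FALSE])
    out@metadata <- c(sample@metadata,
                      list(removed = removed,
                           n_in = nrow(v), n_out = sum(keep)))
    out
}

#' Total variant frequency of a sample, in percent
#'
#' The sum of variant-supporting reads over all called variants divided by
#' the sample's total reads, equivalently 100 x the sum of called
#' frequencies when all variants share the sample depth. Values above 100\%
#' indicate colonies carrying more than one mutation in the reporter.
#'
#' @param sample a \code{PooledSample} with positive \code{totalReads}.
#' @return percentage (may exceed 100).
#' @export
totalVariantFrequency <- function(sample) {
    if (totalReads(sample) <= 0L) stop("total_reads must be positive")
    100 * sum(variants(sample)$frequency)
}

.as_sample_list <- function(x) {
    if (is(x, "PooledSample")) list(x)
    else if (is.list(x)) x
    else stop("expected a PooledSample or a list of them")
}
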