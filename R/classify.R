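## Variant classification: the 14 serialized classes are the 6 strand-
## collapsed SNV classes plus single-base and complex in/dels, MNVs and
## replacements.

.SNV_CLASSES <- c("CG>AT", "CG>TA", "CG>GC", "TA>AT", "TA>CG", "TA>GC")
.OTHER_CLASSES <- c("ins_AT", "ins_GC", "ins_complex",
                    "del_AT", "del_GC", "del_complex",
                    "MNV", "replacement")

#' Serialized variant class names
#'
#' The 14 variant classes used throughout: the 6 strand-collapsed SNV
#' classes (pyrimidine reference written first, so \code{CG>AT} covers both
#' C>A and its complement G>T), single-base A/T and G/C insertions and
#' deletions, complex (>1 base) insertions and deletions, dinucleotide MNVs,
#' and replacements (complex in/dels whose retained base is also changed,
#' e.g. AAC>G or C>AT).
#'
#' @return character vector of the 14 class names, SNV classes first.
#' @export
variantClassNames <- function() c(.SNV_CLASSES, .OTHER_CLASSES)

#' @rdname variantClassNames
#' @export
snvClassNames <- function() .SNV_CLASSES

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a character DNA string (vectorized)
#' @noRd
.revcomp <- function(x) {
    vapply(x, function(s) {
        if (!nzchar(s)) return("")
        paste(rev(.COMP[strsplit(s, "")[[1]]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

#' Collapse a single-base substitution to its strand-symmetric SNV class
#'
#' Sequencing of a double-stranded amplicon cannot tell which strand
#' mutated: a C>A call is the same event as G>T on the other strand. All 12
#' ordered substitutions are therefore collapsed to 6 classes written with
#' the pyrimidine reference first (\code{CG>AT} etc.); purine-reference
#' substitutions are mapped through complementation.
#'
#' @param ref_base,alt_base single bases in A/C/G/T (vectorized, recycled).
#' @return character vector of SNV class names (see \code{snvClassNames}).
#' @examples
#' collapseSnv("C", "A")  # "CG>AT"
#' collapseSnv("G", "T")  # "CG>AT"
#' @export
collapseSnv <- function(ref_base, alt_base) {
    n <- max(length(ref_base), length(alt_base))
    ref_base <- rep_len(toupper(ref_base), n)
    alt_base <- rep_len(toupper(alt_base), n)
    if (any(nchar(ref_base) != 1L | nchar(alt_base) != 1L))
        stop("collapseSnv expects single bases")
    if (any(!ref_base %in% names(.COMP)) || any(!alt_base %in% names(.COMP)))
        stop("non-DNA base in substitution")
    if (any(ref_base == alt_base))
        stop("ref and alt base are identical")
    pur <- ref_base %in% c("A", "G")
    r <- ifelse(pur, .COMP[ref_base], ref_base)
    a <- ifelse(pur, .COMP[alt_base], alt_base)
    paste0(r, .COMP[r], ">", a, .COMP[a])
}

#' Classify a variant by its (ref, alt) allele pair
#'
#' Assigns every anchor-trimmed (ref, alt) pair to exactly one variant
#' class: single-base substitutions are collapsed to the 6 strand-symmetric
#' SNV classes; dinucleotide substitutions are MNVs; pure single-base
#' insertions/deletions are classed by the inserted/deleted base (A/T vs
#' G/C); pure multi-base in/dels are complex; everything else (unequal
#' lengths with both alleles non-empty, or equal length > 2) is a
#' replacement.
#'
#' @param ref,alt reference and alternate allele strings over A/C/G/T; an
#'   empty string denotes a pure insertion (\code{ref}) or deletion
#'   (\code{alt}). Vectorized.
#' @return character vector of class names (see \code{variantClassNames}).
#' @examples
#' classifyVariant("CC", "AT")   # MNV
#' classifyVariant("AAC", "G")   # replacement
#' classifyVariant("G", "")      # del_GC
#' @export
classifyVariant <- function(ref, alt) {
    n <- max(length(ref), length(alt))
    ref <- rep_len(toupper(ref), n)
    alt <- rep_len(toupper(alt), n)
    if (any(grepl("[^ACGT]", ref)) || any(grepl("[^ACGT]", alt)))
        stop("non-DNA characters in ref/alt")
    if (any(ref == "" & alt == ""))
        stop("ref and alt cannot both be empty")
    if (any(ref == alt))
        stop("ref == alt is not a variant")
    lr <- nchar(ref); la <- nchar(alt)
    out <- character(n)
    snv <- lr == 1L & la == 1L
    if (any(snv)) out[snv] <- collapseSnv(ref[snv], alt[snv])
    out[lr == 2L & la == 2L] <- "MNV"
    del1 <- la == 0L & lr == 1L
    out[del1 & ref %in% c("A", "T")] <- "del_AT"
    out[del1 & ref %in% c("G", "C")] <- "del_GC"
    ins1 <- lr == 0L & la == 1L
    out[ins1 & alt %in% c("A", "T")] <- "ins_AT"
    ins1g <- ins1 & alt %in% c("G", "C")
    out[ins1g] <- "ins_GC"
    out[la == 0L & lr > 1L] <- "del_complex"
    out[lr == 0L & la > 1L] <- "ins_complex"
    out[out == ""] <- "replacement"
    out
}

#' Class spectrum of a sample or profile
#'
#' Tabulates classified variants into the 14-class spectrum under one of
#' three normalisations: \code{per_class_total} normalises within each class
#' family (the 6 SNV classes sum to 1, the 3 insertion classes sum to 1, the
#' 3 deletion classes sum to 1, MNV+replacement sum to 1 — matching spectra
#' "normalised to total SNVs / deletions / insertions");
#' \code{total_variants} normalises over all classes; \code{per_read} sums
#' called frequencies per class (already read-normalised, so no further
#' division).
#'
#' @param x a \code{PooledSample}, \code{MutationProfile}, or data.frame
#'   with ref/alt (and, for \code{per_read}, frequency) columns.
#' @param normalization one of \code{"per_class_total"},
#'   \code{"total_variants"}, \code{"per_read"}.
#' @param weight \code{"unique"} counts each unique variant once;
#'   \code{"frequency"} weights by called frequency (for profiles, the
#'   summed frequency across replicates).
#' @return named numeric vector over \code{variantClassNames()}.
#' @export
classSpectrum <- function(x,
                          normalization = c("per_class_total",
                                            "total_variants", "per_read"),
                          weight = c("unique", "frequency")) {
    normalization <- match.arg(normalization)
    weight <- match.arg(weight)
    v <- if (is(x, "PooledSample")) variants(x)
         else if (is(x, "MutationProfile")) {
             vs <- variantStats(x)
             if (nrow(vs)) data.frame(ref = vs$ref, alt = vs$alt,
                                      frequency = vs$freq_sum)
             else .empty_variants()
         } else x
    classes <- variantClassNames()
    out <- setNames(numeric(length(classes)), classes)
    if (!nrow(v)) {
        warning("empty input: all-zero class spectrum")
        return(out)
    }
    cls <- classifyVariant(v$ref, v$alt)
    need_freq <- weight == "frequency" || normalization == "per_read"
    if (need_freq && is.null(v$frequency))
        stop("frequency-weighted spectrum needs a 'frequency' column ",
             "(for profile tables use freq_sum as frequency)")
    w <- if (need_freq) v$frequency else rep(1, nrow(v))
    agg <- tapply(w, factor(cls, levels = classes), sum, default = 0)
    out[] <- as.numeric(agg)
    if (normalization == "per_read") return(out)
    if (normalization == "total_variants") return(out / sum(out))
    families <- list(.SNV_CLASSES,
                     c("ins_AT", "ins_GC", "ins_complex"),
                     c("del_AT", "del_GC", "del_complex"),
                     c("MNV", "replacement"))
    for (fam in families) {
        tot <- sum(out[fam])
        if (tot > 0) out[fam] <- out[fam] / tot
    }
    out
}
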