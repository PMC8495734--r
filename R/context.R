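## Trinucleotide-context spectra: every unique SNV is categorised by the
## bases immediately 5' and 3' of it, with the central base collapsed to a
## pyrimidine (the sequenced strand is unknowable), giving 16 flank
## combinations x 6 substitutions = 96 categories.

.BASES <- c("A", "C", "G", "T")

#' The 32 pyrimidine-centred triplets and the 96 context categories
#'
#' \code{tripletLabels} enumerates the 32 triplets with a C or T centre;
#' \code{trinucContextLabels} the 96 substitution-in-context categories,
#' written \code{X[C>A]Y}, substitution-major then 5' then 3' flank.
#'
#' @return character vector of labels.
#' @export
tripletLabels <- function() {
    as.vector(vapply(c("C", "T"), function(ctr)
        as.vector(outer(.BASES, .BASES,
                        function(u, d) paste0(u, ctr, d))),
        character(16)))
}

#' @rdname tripletLabels
#' @export
trinucContextLabels <- function() {
    subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    unlist(lapply(subs, function(s) {
        ctr <- substr(s, 1, 1)
        as.vector(outer(.BASES, .BASES, function(u, d)
            paste0(u, "[", s, "]", d)))
    }))
}

#' Trinucleotide context of an SNV
#'
#' Takes the 3 bp window around the variant position on the reference
#' locus; when the reference base is a purine, window and substitution are
#' reverse-complemented so the central base is always a pyrimidine.
#' Positions on the locus boundary have no complete window and return NA
#' with a warning; a reference-base mismatch is an error.
#'
#' @param locus a \code{ReferenceLocus}.
#' @param pos genomic position(s) of the SNV (vectorized).
#' @param ref_base,alt_base single-base alleles.
#' @return data.frame with \code{triplet} (pyrimidine-centred),
#'   \code{substitution} (e.g. "C>T") and \code{label} ("G[C>T]C");
#'   NA rows for boundary positions.
#' @export
tripletContext <- function(locus, pos, ref_base, alt_base) {
    n <- max(length(pos), length(ref_base), length(alt_base))
    pos <- rep_len(as.integer(pos), n)
    ref_base <- rep_len(toupper(ref_base), n)
    alt_base <- rep_len(toupper(alt_base), n)
    sp <- locusSpan(locus)
    ok <- pos > sp[1] & pos < sp[2]
    if (any(!ok))
        warning(sum(!ok), " SNV(s) at the locus boundary excluded from ",
                "context analysis")
    out <- data.frame(triplet = rep(NA_character_, n),
                      substitution = rep(NA_character_, n),
                      label = rep(NA_character_, n))
    if (!any(ok)) return(out)
    obs <- locusBase(locus, pos[ok])
    if (any(obs != ref_base[ok]))
        stop("reference base mismatch at position(s) ",
             paste(pos[ok][obs != ref_base[ok]], collapse = ", "))
    win <- locusBase(locus, pos[ok] - 1L, width = 3L)
    r <- ref_base[ok]; a <- alt_base[ok]
    pur <- r %in% c("A", "G")
    win[pur] <- .revcomp(win[pur])
    r[pur] <- .COMP[r[pur]]
    a[pur] <- .COMP[a[pur]]
    out$triplet[ok] <- win
    out$substitution[ok] <- paste0(r, ">", a)
    out$label[ok] <- paste0(substr(win, 1, 1), "[", r, ">", a, "]",
                            substr(win, 3, 3))
    out
}

#' Count pyrimidine-centred triplets along the reference
#'
#' Sliding 3 bp window over the locus: each interior position contributes
#' one count — its triplet as-is when the centre is C/T, otherwise the
#' reverse complement. The counts always sum to locus length - 2.
#'
#' @param locus a \code{ReferenceLocus} (length >= 3).
#' @return named 32-vector over \code{tripletLabels()}.
#' @export
countReferenceTriplets <- function(locus) {
    L <- locusLength(locus)
    if (L < 3L) stop("locus shorter than 3 bp")
    s <- locusSequence(locus)
    i <- 2:(L - 1L)
    win <- substring(s, i - 1L, i + 1L)
    ctr <- substr(win, 2, 2)
    pur <- ctr %in% c("A", "G")
    win[pur] <- .revcomp(win[pur])
    counts <- table(factor(win, levels = tripletLabels()))
    setNames(as.numeric(counts), tripletLabels())
}

#' Trinucleotide-context spectrum of a genotype
#'
#' Per biological replicate, counts the unique SNVs falling in each of the
#' 96 categories (presence only — frequency is deliberately ignored, which
#' also keeps jackpots from dominating), then averages the per-replicate
#' counts over all replicates of the genotype. The normalised spectrum
#' divides each category's average by the number of times its triplet
#' occurs in the reference locus; categories whose triplet is absent are
#' NA, never infinite.
#'
#' @param profile a \code{MutationProfile} built from filtered replicates.
#' @param locus the \code{ReferenceLocus}.
#' @param frequency_weighted weight contexts by called frequency instead of
#'   presence (non-standard extension; default off).
#' @return a \code{\link{TrinucSpectrum}}.
#' @export
trinucSpectrum <- function(profile, locus, frequency_weighted = FALSE) {
    vs <- variantStats(profile)
    fm <- freqMatrix(profile)
    trip <- countReferenceTriplets(locus)
    labels <- trinucContextLabels()
    avg <- setNames(numeric(96), labels)
    is_snv <- nchar(vs$ref) == 1L & nchar(vs$alt) == 1L
    if (any(is_snv)) {
        ctx <- tripletContext(locus, vs$pos[is_snv], vs$ref[is_snv],
                              vs$alt[is_snv])
        keep <- !is.na(ctx$label)
        if (any(keep)) {
            w <- fm[which(is_snv)[keep], , drop = FALSE]
            w <- if (frequency_weighted) w else (w > 0) * 1
            per_ctx <- rowsum(rowSums(w), ctx$label[keep])
            avg[rownames(per_ctx)] <- per_ctx[, 1] / nReplicates(profile)
        }
    }
    trip_of <- function(lab)
        paste0(substr(lab, 1, 1), substr(lab, 3, 3), substr(lab, 7, 7))
    denom <- trip[trip_of(labels)]
    normalized <- ifelse(denom > 0, avg / denom, NA_real_)
    new("TrinucSpectrum", genotype = genotype(profile),
        avgCount = avg, normalized = setNames(normalized, labels),
        tripletCounts = trip)
}

setMethod("show", "TrinucSpectrum", function(object) {
    cat("TrinucSpectrum '", object@genotype, "': ",
        sum(object@avgCount > 0), "/96 categories occupied, ",
        "total avg count ", format(sum(object@avgCount), digits = 4),
        "\n", sep = "")
})

#' @rdname trinucSpectrum
#' @param x a \code{TrinucSpectrum}.
#' @param mode \code{"avg_count"} or \code{"normalized"}.
#' @return \code{spectrumValues}: the named 96-vector in the chosen mode.
#' @export
spectrumValues <- function(x, mode = c("avg_count", "normalized")) {
    mode <- match.arg(mode)
    if (mode == "avg_count") x@avgCount else x@normalized
}

#' Correlation between two context spectra
#'
#' Correlation over the 96-vectors of two genotypes' spectra, used to
#' quantify how similar two mutational signatures are. Pearson is the
#' default; Spearman is provided. A zero-variance spectrum has no defined
#' correlation and yields NA with a warning.
#'
#' @param a,b \code{TrinucSpectrum} objects (same locus and mode).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @param mode which 96-vector to correlate.
#' @return correlation coefficient in [-1, 1], or NA.
#' @export
spectrumCorrelation <- function(a, b, method = c("pearson", "spearman"),
                                mode = c("avg_count", "normalized")) {
    method <- match.arg(method)
    mode <- match.arg(mode)
    va <- spectrumValues(a, mode); vb <- spectrumValues(b, mode)
    keep <- !is.na(va) & !is.na(vb)
    va <- va[keep]; vb <- vb[keep]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
        warning("zero-variance spectrum: correlation undefined")
        return(NA_real_)
    }
    stats::cor(va, vb, method = method)
}

#' @rdname spectrumCorrelation
#' @param spectra list of >= 2 \code{TrinucSpectrum}.
#' @return \code{spectrumCorrelationMatrix}: genotype x genotype matrix.
#' @export
spectrumCorrelationMatrix <- function(spectra,
                                      method = c("pearson", "spearman"),
                                      mode = c("avg_count", "normalized")) {
    method <- match.arg(method); mode <- match.arg(mode)
    gts <- vapply(spectra, genotype, character(1))
    n <- length(spectra)
    m <- matrix(NA_real_, n, n, dimnames = list(gts, gts))
    for (i in seq_len(n)) for (j in seq_len(n))
        m[i, j] <- if (i == j) 1 else
            suppressWarnings(spectrumCorrelation(spectra[[i]], spectra[[j]],
                                                 method, mode))
    attr(m, "method") <- method
    attr(m, "mode") <- mode
    m
}
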