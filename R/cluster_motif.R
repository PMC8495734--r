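## Genotype-comparison layer: unique variants condensed to the fraction of
## biological replicates in which they occur, clustered across genotypes,
## and per-class motif models over windows around the variants.

#' Replicate-fraction matrix across genotypes
#'
#' Rows are the union of unique variant keys over the supplied genotype
#' profiles, columns are genotypes, entries are the fraction of that
#' genotype's biological replicates in which the variant was called (0 when
#' absent). Row metadata carries pos/ref/alt/class.
#'
#' @param profiles list of >= 2 \code{MutationProfile}.
#' @return list: \code{matrix} (keys x genotypes) and \code{row_meta}
#'   data.frame aligned to the rows.
#' @export
buildFractionMatrix <- function(profiles) {
    if (length(profiles) < 2L) stop("need >= 2 genotype profiles")
    if (all(vapply(profiles, function(p) nrow(variantStats(p)) == 0L,
                   logical(1))))
        stop("all profiles are empty")
    gts <- vapply(profiles, genotype, character(1))
    metas <- do.call(rbind, lapply(profiles, function(p)
        variantStats(p)[, c("pos", "ref", "alt", "class")]))
    keys_all <- unlist(lapply(profiles, function(p)
        rownames(freqMatrix(p))))
    o <- order(metas$pos, metas$ref, metas$alt)
    metas <- metas[o, , drop = FALSE]
    keys_all <- keys_all[o]
    first <- !duplicated(keys_all)
    row_meta <- metas[first, , drop = FALSE]
    keys <- keys_all[first]
    rownames(row_meta) <- keys
    m <- matrix(0, nrow = length(keys), ncol = length(gts),
                dimnames = list(keys, gts))
    for (i in seq_along(profiles)) {
        p <- profiles[[i]]
        m[rownames(freqMatrix(p)), i] <-
            variantStats(p)$replicate_fraction
    }
    list(matrix = m, row_meta = row_meta)
}

#' Filter matrix rows by row sum
#'
#' Retains rows whose sum, on the chosen scale, is strictly above
#' \code{min_row_sum}. The default (raw scale, cutoff 0) keeps every row:
#' replicate fractions are non-negative, so a negative published cutoff can
#' only refer to a standardised matrix — \code{scale = "zscore"} with
#' \code{min_row_sum = -2} approximates that behaviour.
#'
#' @param fm result of \code{\link{buildFractionMatrix}} (or a bare matrix).
#' @param min_row_sum retain rows with row sum > this value.
#' @param scale \code{"raw"} or \code{"zscore"} (rows standardised before
#'   summing; constant rows get z-scores of 0).
#' @return same shape as the input, rows subset.
#' @export
filterRows <- function(fm, min_row_sum = 0, scale = c("raw", "zscore")) {
    scale <- match.arg(scale)
    m <- if (is.list(fm)) fm$matrix else fm
    ms <- if (scale == "raw") m else {
        mu <- rowMeans(m)
        sdv <- apply(m, 1, stats::sd)
        z <- (m - mu) / ifelse(sdv > 0, sdv, 1)
        z[sdv == 0, ] <- 0
        z
    }
    keep <- rowSums(ms) > min_row_sum
    if (!any(keep))
        stop("row-sum cutoff ", min_row_sum, " (", scale,
             ") removes every row; largest row sum is ",
             format(max(rowSums(ms)), digits = 4))
    if (is.list(fm))
        list(matrix = m[keep, , drop = FALSE],
             row_meta = fm$row_meta[keep, , drop = FALSE])
    else m[keep, , drop = FALSE]
}

#' Hierarchical clustering of the replicate-fraction matrix
#'
#' Agglomerative clustering of rows (unique variants), optionally also of
#' columns (genotypes), with deterministic input order: rows are pre-sorted
#' by key so hclust's tie-breaking is reproducible. Correlation distance is
#' 1 - Pearson r between rows; constant rows are assigned distance 1 to
#' everything (correlation undefined).
#'
#' @param fm result of \code{\link{buildFractionMatrix}} or a bare matrix.
#' @param distance \code{"euclidean"} or \code{"correlation"}.
#' @param linkage \code{"complete"}, \code{"average"} or \code{"ward"}
#'   (ward.D2).
#' @param k optional number of flat clusters to cut.
#' @param cluster_columns also cluster the genotype columns.
#' @return list: \code{row_hclust}, \code{row_order} (leaf order of keys),
#'   \code{clusters} (named vector when \code{k} given), and
#'   \code{col_hclust} when requested.
#' @export
clusterRows <- function(fm, distance = c("euclidean", "correlation"),
                        linkage = c("complete", "average", "ward"),
                        k = NULL, cluster_columns = FALSE) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    m <- if (is.list(fm)) fm$matrix else fm
    if (nrow(m) < 2L) stop("need >= 2 rows to cluster")
    m <- m[order(rownames(m)), , drop = FALSE]
    method <- c(complete = "complete", average = "average",
                ward = "ward.D2")[[linkage]]
    d <- .row_dist(m, distance)
    hc <- stats::hclust(d, method = method)
    out <- list(row_hclust = hc, row_order = rownames(m)[hc$order])
    if (!is.null(k))
        out$clusters <- stats::cutree(hc, k = k)
    if (cluster_columns && ncol(m) >= 2L)
        out$col_hclust <- stats::hclust(.row_dist(t(m), distance),
                                        method = method)
    out
}

.row_dist <- function(m, distance) {
    if (distance == "euclidean") return(stats::dist(m))
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[is.na(cc)] <- 0   # constant rows: undefined correlation -> distance 1
    d <- 1 - cc
    diag(d) <- 0
    stats::as.dist(d)
}

#' Write a row dendrogram as Newick
#'
#' @param clustering result of \code{\link{clusterRows}}.
#' @param path output file.
#' @export
writeDendrogram <- function(clustering, path) {
    ape::write.tree(ape::as.phylo(clustering$row_hclust), file = path)
    invisible(path)
}

#' Extract aligned sequence windows around variants
#'
#' For each variant, the reference window of \code{half_width} bases either
#' side of the variant position (13 bp at the default 6), with the variant
#' position indexed 0. In/dels are anchored at the first deleted/inserted
#' base's position. Variants whose window would run off the locus are
#' excluded with a warning.
#'
#' @param variants data.frame with pos/ref/alt (e.g. a profile's
#'   \code{variantStats} or a fraction-matrix \code{row_meta}), or a
#'   \code{MutationProfile}.
#' @param locus the \code{ReferenceLocus}.
#' @param half_width bases either side of the variant (default 6).
#' @param class restrict to one variant class (e.g. \code{"del_GC"}).
#' @return list of per-class character vectors of windows (all classes when
#'   \code{class} is NULL; a single vector when \code{class} is given).
#' @export
extractWindows <- function(variants, locus, half_width = 6L, class = NULL) {
    if (is(variants, "MutationProfile")) variants <- variantStats(variants)
    v <- as.data.frame(variants)
    if (!"class" %in% names(v))
        v$class <- classifyVariant(v$ref, v$alt)
    if (!is.null(class)) v <- v[v$class %in% class, , drop = FALSE]
    sp <- locusSpan(locus)
    ok <- v$pos - half_width >= sp[1] & v$pos + half_width <= sp[2]
    if (any(!ok))
        warning(sum(!ok), " variant(s) within ", half_width,
                " bp of the locus end excluded from motif windows")
    v <- v[ok, , drop = FALSE]
    win <- if (nrow(v))
        locusBase(locus, v$pos - half_width, width = 2L * half_width + 1L)
    else character()
    if (!is.null(class)) return(win)
    split(win, v$class)
}

#' Position frequency matrix and information content of aligned windows
#'
#' Builds the motif model the sequence-logo way: a position frequency
#' matrix over A/C/G/T (columns are window positions -w..+w, each summing
#' to 1), and per-position information content 2 - H bits, where H is the
#' Shannon entropy of the column distribution. All-identical columns carry
#' 2 bits, uniform columns 0.
#'
#' @param windows character vector of equal-length windows.
#' @param pseudocount added per base per position before normalising
#'   (default 0).
#' @return list: \code{pfm} (4 x width matrix, colnames -w..+w),
#'   \code{information} (bits per position), \code{n} windows used.
#' @export
motifModel <- function(windows, pseudocount = 0) {
    if (length(windows) < 1L) stop("no windows supplied")
    wdt <- unique(nchar(windows))
    if (length(wdt) != 1L) stop("windows have unequal lengths")
    half <- (wdt - 1L) %/% 2L
    chars <- matrix(unlist(strsplit(windows, "")), nrow = length(windows),
                    byrow = TRUE)
    counts <- apply(chars, 2, function(col)
        table(factor(col, levels = .BASES)))
    counts <- counts + pseudocount
    pfm <- sweep(counts, 2, colSums(counts), "/")
    dimnames(pfm) <- list(.BASES, as.character(seq_len(wdt) - half - 1L))
    h <- apply(pfm, 2, function(p) {
        p <- p[p > 0]
        -sum(p * log2(p))
    })
    list(pfm = pfm, information = 2 - h, n = length(windows))
}
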