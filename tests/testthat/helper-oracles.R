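# Independent oracles, deliberately naive: these re-derive expected results
# by direct enumeration so the implementation can be checked against them.

# Brute-force permissive filter: rescan every variant against the raw
# permissive observations.
oracle_filter <- function(sample_df, perm_dfs, floor,
                          keying = c("position", "position_variant")) {
    keying <- match.arg(keying)
    keep <- logical(nrow(sample_df))
    for (i in seq_len(nrow(sample_df))) {
        v <- sample_df[i, ]
        mx <- 0
        for (p in perm_dfs) {
            hit <- if (keying == "position") p$pos == v$pos
                   else p$pos == v$pos & p$ref == v$ref & p$alt == v$alt
            if (any(hit)) mx <- max(mx, p$frequency[hit])
        }
        keep[i] <- v$frequency >= max(floor, mx)
    }
    keep
}

# Brute-force agglomerative clustering: repeatedly merge the closest pair
# under the requested linkage, tracking merge heights and memberships.
oracle_hclust <- function(m, distance = c("euclidean", "correlation"),
                          linkage = c("complete", "average")) {
    distance <- match.arg(distance)
    linkage <- match.arg(linkage)
    n <- nrow(m)
    pd <- function(i, j) {
        if (distance == "euclidean") sqrt(sum((m[i, ] - m[j, ])^2))
        else {
            r <- suppressWarnings(stats::cor(m[i, ], m[j, ]))
            if (is.na(r)) r <- 0
            1 - r
        }
    }
    d0 <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) d0[i, j] <- pd(i, j)
    clusters <- as.list(seq_len(n))
    heights <- numeric(0)
    members <- list()
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bh <- Inf
        for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
            if (a >= b) next
            ds <- d0[clusters[[a]], clusters[[b]], drop = FALSE]
            h <- if (linkage == "complete") max(ds) else mean(ds)
            if (h < bh - 1e-12) { bh <- h; best <- c(a, b) }
        }
        merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
        heights <- c(heights, bh)
        members[[length(members) + 1L]] <- merged
        clusters[[best[1]]] <- merged
        clusters[[best[2]]] <- NULL
    }
    list(heights = heights, members = members)
}

# Brute-force pyrimidine-centred triplet counting over a plain string.
oracle_triplet_counts <- function(seq) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- function(s) paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    counts <- integer(0)
    for (i in 2:(nchar(seq) - 1L)) {
        w <- substr(seq, i - 1L, i + 1L)
        if (substr(w, 2, 2) %in% c("A", "G")) w <- rc(w)
        counts[w] <- if (is.na(counts[w])) 1L else counts[w] + 1L
    }
    counts
}

# Shannon entropy in bits of a base-count column.
oracle_column_bits <- function(bases) {
    p <- table(factor(bases, levels = c("A", "C", "G", "T")))
    p <- p / sum(p)
    p <- p[p > 0]
    2 + sum(p * log2(p))
}
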