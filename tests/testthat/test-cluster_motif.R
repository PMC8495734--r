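prof_from_keys <- function(keys_freqs, genotype, n_rep) {
    # keys_freqs: list bio_rep -> data.frame(pos, ref, alt, frequency)
    samples <- lapply(seq_len(n_rep), function(i) {
        df <- keys_freqs[[i]]
        if (is.null(df) || nrow(df) == 0)
            pooledSample(paste0(genotype, i), genotype,
                         bio_rep = as.character(i))
        else make_sample(df$pos, df$ref, df$alt, df$frequency,
                         sample_id = paste0(genotype, i),
                         genotype = genotype, bio_rep = as.character(i))
    })
    buildProfile(samples, genotype = genotype)
}

test_that("fraction matrix entries are replicate fractions with zeros", {
    key <- data.frame(pos = 101, ref = "C", alt = "A", frequency = 0.1)
    a <- prof_from_keys(list(key, key, key, key), "A", 4)      # 4/4
    b <- prof_from_keys(list(key, key, key, NULL, NULL, NULL), "B", 6) # 3/6
    c_ <- prof_from_keys(list(
        data.frame(pos = 105, ref = "G", alt = "", frequency = 0.2),
        NULL, NULL, NULL), "C", 4)
    fm <- buildFractionMatrix(list(a, b, c_))
    expect_equal(unname(fm$matrix["101:C:A", ]), c(1, 0.5, 0))
    expect_equal(unname(fm$matrix["105:G:", ]), c(0, 0, 0.25))
    expect_equal(fm$row_meta["105:G:", "class"], "del_GC")
    expect_error(buildFractionMatrix(list(a)), ">= 2")
    e1 <- prof_from_keys(list(NULL), "E1", 1)
    e2 <- prof_from_keys(list(NULL), "E2", 1)
    expect_error(buildFractionMatrix(list(e1, e2)), "empty")
})

test_that("row filtering applies a strict row-sum cutoff", {
    m <- matrix(c(1, 0.5, 0, 0,
                  0.25, 0, 0, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("k1", "k2"), paste0("g", 1:4)))
    kept <- filterRows(m, min_row_sum = 0.75)
    expect_equal(rownames(kept), "k1")          # sum 1.5 retained
    expect_equal(rownames(filterRows(m, -Inf)), c("k1", "k2"))
    expect_error(filterRows(m, 10), "every row")
    # z-score scale with the -2 cutoff keeps rows (z-scores sum to ~0)
    expect_equal(nrow(filterRows(m, -2, scale = "zscore")), 2L)
})

test_that("clustering matches brute-force agglomeration on small matrices", {
    set.seed(31)
    for (i in 1:12) {
        n <- sample(3:6, 1)
        m <- matrix(runif(n * 4), nrow = n,
                    dimnames = list(paste0("k", seq_len(n)),
                                    paste0("g", 1:4)))
        for (dist_kind in c("euclidean", "correlation"))
            for (link in c("complete", "average")) {
                got <- clusterRows(m, dist_kind, link)
                want <- oracle_hclust(m, dist_kind, link)
                expect_equal(got$row_hclust$height, want$heights,
                             tolerance = 1e-10)
                # memberships agree at every cut
                for (k in 2:(n - 1)) {
                    ct <- cutree(got$row_hclust, k = k)
                    # oracle memberships after n-k merges
                    oracle_groups <- want$members[seq_len(n - k)]
                    # compare partitions via co-membership matrices
                    co_got <- outer(ct, ct, "==")
                    grp <- seq_len(n)
                    for (mm in oracle_groups) grp[mm] <- min(grp[mm])
                    co_want <- outer(grp, grp, "==")
                    expect_equal(unname(co_got), unname(co_want))
                }
            }
    }
})

test_that("identical rows merge at distance zero, ties are deterministic", {
    m <- matrix(c(1, 0, 1, 0,
                  1, 0, 1, 0,
                  0, 1, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("a", "b", "c"), paste0("g", 1:4)))
    cl <- clusterRows(m)
    expect_equal(cl$row_hclust$height[1], 0)
    cl2 <- clusterRows(m[c(3, 1, 2), ])
    expect_equal(cl$row_order, cl2$row_order)  # input order irrelevant
    expect_error(clusterRows(m[1, , drop = FALSE]), ">= 2")
})

test_that("row clustering is invariant to genotype column order", {
    set.seed(37)
    m <- matrix(runif(24), nrow = 6,
                dimnames = list(paste0("k", 1:6), paste0("g", 1:4)))
    for (dist_kind in c("euclidean", "correlation")) {
        c1 <- clusterRows(m, dist_kind, k = 3)
        c2 <- clusterRows(m[, c(3, 1, 4, 2)], dist_kind, k = 3)
        expect_equal(c1$row_hclust$height, c2$row_hclust$height)
        expect_equal(c1$clusters, c2$clusters)
    }
    # aliased genotype columns: the implementation still matches the
    # brute-force agglomeration oracle on the widened matrix
    m2 <- cbind(m, g4b = m[, 4])
    got <- clusterRows(m2, "correlation", "complete")
    want <- oracle_hclust(m2, "correlation", "complete")
    expect_equal(got$row_hclust$height, want$heights, tolerance = 1e-10)
})

test_that("dendrograms export as Newick", {
    m <- matrix(runif(12), nrow = 3,
                dimnames = list(c("a", "b", "c"), paste0("g", 1:4)))
    cl <- clusterRows(m)
    f <- tempfile(fileext = ".nwk")
    writeDendrogram(cl, f)
    tree <- ape::read.tree(f)
    expect_setequal(tree$tip.label, c("a", "b", "c"))
})

test_that("windows are centred on the variant with the reference at 0", {
    s <- paste(rep("ACGT", 10), collapse = "")
    locus <- make_locus(s, offset = 500)
    v <- data.frame(pos = c(509, 502), ref = c("C", "C"), alt = c("T", ""))
    expect_warning(win <- extractWindows(v, locus), "excluded")
    expect_length(win, 1L)  # only one class survives (the SNV at 509)
    w <- win[["CG>TA"]]
    expect_equal(nchar(w), 13L)
    expect_equal(substr(w, 7, 7), "C")  # index 0 carries the reference base
    expect_equal(w, locusBase(locus, 503, width = 13))
    # class subsetting
    v2 <- data.frame(pos = c(509, 513), ref = c("C", "C"), alt = c("T", ""))
    dels <- extractWindows(v2, locus, class = "del_GC")
    expect_length(dels, 1L)
    expect_equal(substr(dels, 7, 7), "C")
})

test_that("motif models follow the entropy arithmetic", {
    same <- rep("ACGTACGTACGTA", 5)
    mm <- motifModel(same)
    expect_equal(unname(colSums(mm$pfm)), rep(1, 13))
    expect_equal(unname(mm$information), rep(2, 13))
    expect_equal(colnames(mm$pfm)[1], "-6")
    expect_equal(colnames(mm$pfm)[7], "0")

    uniform <- c("A", "C", "G", "T")
    mu <- motifModel(uniform)
    expect_equal(unname(mu$information), 0)

    half <- c("C", "C", "T", "T")
    mh <- motifModel(half)
    expect_equal(unname(mh$information), 1)
    expect_equal(unname(mh$information),
                 oracle_column_bits(half), tolerance = 1e-12)

    # duplicate windows leave the PFM unchanged
    mix <- c("ACG", "ACG", "CGT")
    expect_equal(motifModel(mix)$pfm, motifModel(c(mix, mix))$pfm)

    expect_error(motifModel(character()), "no windows")
    expect_error(motifModel(c("AC", "ACG")), "unequal")

    # pseudocounts keep columns normalised
    mp <- motifModel(c("A", "A"), pseudocount = 1)
    expect_equal(sum(mp$pfm[, 1]), 1)
    expect_equal(mp$pfm["A", 1], 3 / 6)
})
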