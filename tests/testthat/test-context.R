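test_that("exactly 96 context categories and 32 triplets enumerate", {
    labs <- trinucContextLabels()
    expect_length(labs, 96L)
    expect_length(unique(labs), 96L)
    trips <- tripletLabels()
    expect_length(trips, 32L)
    expect_length(unique(trips), 32L)
    # 16 flank combinations per central pyrimidine
    ctr <- substr(trips, 2, 2)
    expect_equal(as.vector(table(ctr)[c("C", "T")]), c(16L, 16L))
    expect_true(all(ctr %in% c("C", "T")))
})

test_that("triplet context collapses purine references by strand", {
    # ...G C C... with C>T stays as-is; ...A G G... with G>A flips to CCT
    locus <- make_locus("TGCCAGGAT", offset = 200)
    fwd <- tripletContext(locus, 202, "C", "T")   # window GCC
    expect_equal(fwd$triplet, "GCC")
    expect_equal(fwd$label, "G[C>T]C")
    rev <- tripletContext(locus, 205, "G", "A")   # window AGG -> CCT
    expect_equal(rev$triplet, "CCT")
    expect_equal(rev$label, "C[C>T]T")
    expect_error(tripletContext(locus, 202, "G", "T"), "mismatch")
    expect_warning(b <- tripletContext(locus, 200, "T", "A"), "boundary")
    expect_true(is.na(b$label))
})

test_that("context categorisation is strand-symmetric everywhere", {
    set.seed(7)
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    rc <- function(x) paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
    locus <- make_locus(s, offset = 1)
    locus_rc <- make_locus(rc(s), offset = 1)
    for (pos in sample(2:59, 15)) {
        ref <- substr(s, pos, pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        a <- tripletContext(locus, pos, ref, alt)
        # same substitution seen from the complementary strand
        pos2 <- 60 - pos + 1
        b <- tripletContext(locus_rc, pos2, comp[[ref]], comp[[alt]])
        expect_equal(a$label, b$label)
    }
})

test_that("reference triplet counts match hand enumeration", {
    # "ACGTA": windows ACG (C centre), CGT (G centre -> ACG), GTA (T centre)
    locus <- make_locus("ACGTA", offset = 1)
    counts <- countReferenceTriplets(locus)
    expect_equal(unname(counts["ACG"]), 2)
    expect_equal(unname(counts["GTA"]), 1)
    expect_equal(sum(counts), 3)

    # homopolymer: both A-centred windows reverse-complement to TTT
    locus2 <- make_locus("AAAA", offset = 1)
    counts2 <- countReferenceTriplets(locus2)
    expect_equal(unname(counts2["TTT"]), 2)
    expect_equal(sum(counts2), 2)

    expect_error(countReferenceTriplets(make_locus("AC", offset = 1)),
                 "shorter")
})

test_that("triplet counts sum to L-2 and match the brute-force oracle", {
    set.seed(19)
    for (i in 1:25) {
        L <- sample(3:120, 1)
        s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                   collapse = "")
        counts <- countReferenceTriplets(make_locus(s, offset = 1))
        expect_equal(sum(counts), L - 2)
        brute <- oracle_triplet_counts(s)
        expect_equal(counts[names(brute)], brute[names(brute)],
                     ignore_attr = TRUE)
        expect_equal(sum(counts[setdiff(names(counts), names(brute))]), 0)
    }
})

test_that("context spectra average presence over replicates", {
    # locus with a known number of GCC triplets, counted by hand below
    s <- "TTGCCATTGCCATTGCCATTGCCATT"   # GCC occurs 4 times (centres C)
    locus <- make_locus(s, offset = 301)
    # rep 1 carries one C>T in GCC context (position 304 = first GCC centre),
    # rep 2 carries nothing
    r1 <- make_sample(304, "C", "T", 0.02, bio_rep = "1")
    r2 <- pooledSample("s2", "WT", bio_rep = "2")
    prof <- buildProfile(list(r1, r2))
    sp <- trinucSpectrum(prof, locus)
    expect_equal(unname(spectrumValues(sp)["G[C>T]C"]), 0.5)
    expect_equal(unname(sp@tripletCounts["GCC"]), 4)
    expect_equal(unname(spectrumValues(sp, "normalized")["G[C>T]C"]),
                 0.5 / 4)
    # categories absent from the reference are NA, never infinite
    absent <- names(sp@tripletCounts)[sp@tripletCounts == 0]
    if (length(absent)) {
        lab_of <- trinucContextLabels()
        trip_of <- paste0(substr(lab_of, 1, 1), substr(lab_of, 3, 3),
                          substr(lab_of, 7, 7))
        expect_true(all(is.na(spectrumValues(sp, "normalized")[
            trip_of %in% absent])))
    }
    # empty profile -> zero vector
    sp0 <- trinucSpectrum(buildProfile(list(r2)), locus)
    expect_true(all(spectrumValues(sp0) == 0))
})

test_that("spectrum averages are invariant to replicate duplication", {
    locus <- syntheticLocus(seed = 2)
    set.seed(23)
    pos <- sample(31980:33700, 12)
    base <- vapply(pos, function(p) locusBase(locus, p), character(1))
    alt <- vapply(base, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    r1 <- make_sample(pos, base, alt, runif(12, 0.01, 0.2), bio_rep = "1")
    r2 <- make_sample(pos[1:5], base[1:5], alt[1:5], runif(5, 0.01, 0.2),
                      bio_rep = "2")
    p12 <- buildProfile(list(r1, r2))
    p1212 <- buildProfile(list(r1, r2,
                               make_sample(pos, base, alt, runif(12),
                                           bio_rep = "3"),
                               make_sample(pos[1:5], base[1:5], alt[1:5],
                                           runif(5), bio_rep = "4")))
    s12 <- trinucSpectrum(p12, locus)
    s1212 <- trinucSpectrum(p1212, locus)
    expect_equal(spectrumValues(s12), spectrumValues(s1212))
})

test_that("spectrum correlations match the direct formula", {
    locus <- syntheticLocus(seed = 2)
    mk <- function(n, seed, gt) {
        set.seed(seed)
        pos <- sample(31980:33700, n)
        base <- vapply(pos, function(p) locusBase(locus, p), character(1))
        alt <- vapply(base, function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
        buildProfile(list(make_sample(pos, base, alt, runif(n, 0.01, 0.2),
                                      genotype = gt)), genotype = gt)
    }
    a <- trinucSpectrum(mk(40, 3, "a"), locus)
    b <- trinucSpectrum(mk(40, 4, "b"), locus)
    expect_equal(spectrumCorrelation(a, a), 1)
    va <- spectrumValues(a); vb <- spectrumValues(b)
    manual <- sum((va - mean(va)) * (vb - mean(vb))) /
        sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
    expect_equal(spectrumCorrelation(a, b), manual)
    expect_equal(spectrumCorrelation(a, b, method = "spearman"),
                 cor(rank(va), rank(vb)))

    m <- spectrumCorrelationMatrix(list(a, b))
    expect_equal(dim(m), c(2L, 2L))
    expect_equal(m[1, 2], m[2, 1])

    empty <- trinucSpectrum(buildProfile(list(pooledSample("e", "e"))),
                            locus)
    expect_warning(r0 <- spectrumCorrelation(a, empty), "zero-variance")
    expect_true(is.na(r0))
})
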