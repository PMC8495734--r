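reps_of <- function(freqs_by_rep, pos = 101, ref = "C", alt = "A",
                    genotype = "WT") {
    # freqs_by_rep: list, one numeric (possibly length 0) per replicate
    lapply(seq_along(freqs_by_rep), function(i) {
        f <- freqs_by_rep[[i]]
        if (length(f) == 0)
            pooledSample(paste0("s", i), genotype, bio_rep = as.character(i))
        else make_sample(pos[seq_along(f)], ref[seq_along(f)],
                         alt[seq_along(f)], f,
                         sample_id = paste0("s", i), genotype = genotype,
                         bio_rep = as.character(i))
    })
}

test_that("replicate fractions score presence per biological replicate", {
    p4 <- buildProfile(reps_of(list(0.1, 0.2, 0.3, 0.4)))
    expect_equal(variantStats(p4)$replicate_fraction, 1)   # 4/4 -> 1

    p6 <- buildProfile(reps_of(list(0.1, 0.2, 0.3, numeric(), numeric(),
                                    numeric())))
    expect_equal(variantStats(p6)$replicate_fraction, 0.5) # 3/6 -> 0.5
})

test_that("profile frequency statistics follow the stated arithmetic", {
    p <- buildProfile(reps_of(list(0.02, 0.04, numeric())))
    vs <- variantStats(p)
    expect_equal(vs$replicate_count, 2L)
    expect_equal(vs$replicate_fraction, 2 / 3)
    expect_equal(vs$freq_sum, 0.06)
    expect_equal(vs$freq_mean_observed, 0.03)
    expect_equal(vs$freq_mean_all, 0.02)
    expect_error(buildProfile(list()), "no samples")
})

test_that("profiles are permutation-invariant and conserve counts", {
    set.seed(5)
    samples <- lapply(1:4, function(i) {
        n <- sample(3:8, 1)
        make_sample(sample(101:140, n), "C", "A", runif(n, 0, 0.3),
                    sample_id = paste0("s", i), bio_rep = as.character(i))
    })
    p1 <- buildProfile(samples)
    p2 <- buildProfile(rev(samples))
    expect_equal(variantStats(p1), variantStats(p2))
    # conservation: sum of replicate_counts == total calls across replicates
    expect_equal(sum(variantStats(p1)$replicate_count),
                 sum(vapply(samples, function(s) nrow(variants(s)),
                            integer(1))))
})

test_that("high/low partition uses a strict 5% boundary", {
    p <- buildProfile(reps_of(list(c(0.06, 0.05, 0.01),
                                   c(0.06, 0.05, 0.01)),
                              pos = c(101, 105, 110),
                              ref = c("C", "C", "C"),
                              alt = c("A", "A", "A")))
    parts <- partitionByFrequency(p)
    expect_equal(parts$high$pos, 101)          # mean 6% -> high
    expect_true(105 %in% parts$low$pos)        # mean exactly 5% -> low
    expect_true(110 %in% parts$low$pos)

    all_low <- buildProfile(reps_of(list(0.01, 0.02)))
    expect_equal(nrow(partitionByFrequency(all_low)$high), 0L)
})

test_that("jackpots are >25% in exactly one replicate", {
    one <- buildProfile(reps_of(list(0.30, numeric(), numeric())))
    expect_equal(length(flagJackpots(one)), 1L)

    two <- buildProfile(reps_of(list(0.30, 0.30, numeric())))
    expect_equal(length(flagJackpots(two)), 0L)  # systematic, not jackpot

    low <- buildProfile(reps_of(list(0.10, numeric(), numeric())))
    expect_equal(length(flagJackpots(low)), 0L)

    # jackpot set never overlaps variants above cutoff in >= 2 replicates
    set.seed(9)
    samples <- lapply(1:4, function(i)
        make_sample(101:115, "C", "A", runif(15, 0, 0.6),
                    sample_id = paste0("s", i), bio_rep = as.character(i)))
    p <- buildProfile(samples)
    jp <- flagJackpots(p)
    fm <- freqMatrix(p)
    systematic <- rownames(fm)[rowSums(fm > 0.25) >= 2]
    expect_length(intersect(jp, systematic), 0)
})

test_that("unique-variant counting and overlap match set arithmetic", {
    a <- buildProfile(reps_of(list(c(0.1, 0.1, 0.1)),
                              pos = c(101, 102, 103),
                              ref = c("C", "C", "C"),
                              alt = c("A", "A", "A")), genotype = "A")
    b <- buildProfile(reps_of(list(c(0.1, 0.1, 0.1)),
                              pos = c(103, 104, 105),
                              ref = c("C", "C", "C"),
                              alt = c("A", "A", "A")), genotype = "B")
    counts <- countUniqueVariants(list(a, b))
    expect_equal(counts$n_unique[counts$genotype == "combined"], 5L)

    ov <- genotypeOverlap(list(a, b))
    expect_equal(unname(ov$k_table["2"]), 1L)   # the shared key
    expect_equal(unname(ov$k_table["1"]), 4L)
    expect_equal(unname(ov$presence["103:C:A", ]), c(1L, 1L))
})

test_that("overlap counts match a brute-force intersection oracle", {
    set.seed(13)
    profs <- lapply(1:4, function(g) {
        pos <- sample(101:130, 10)
        buildProfile(list(make_sample(pos, "C", "A", runif(10, 0, 0.2),
                                      genotype = paste0("g", g))),
                     genotype = paste0("g", g))
    })
    ov <- genotypeOverlap(profs)
    keysets <- lapply(profs, function(p) rownames(freqMatrix(p)))
    all_keys <- unique(unlist(keysets))
    brute <- table(factor(vapply(all_keys, function(k)
        sum(vapply(keysets, function(ks) k %in% ks, logical(1))),
        numeric(1)), levels = 1:4))
    expect_equal(as.vector(ov$k_table), as.vector(brute))
})
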