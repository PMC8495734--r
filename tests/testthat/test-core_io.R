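test_that("readReference maps genomic offsets onto the sequence", {
    f <- write_fasta("ACGTACGT")
    locus <- readReference(f, offset = 100, chrom = "chrV")
    expect_equal(locusLength(locus), 8L)
    expect_equal(locusBase(locus, 100), "A")
    expect_equal(locusBase(locus, 103), "T")
    expect_equal(locusSpan(locus), c(100L, 107L))
    expect_error(locusBase(locus, 99), "outside")
    expect_error(locusBase(locus, 108), "outside")
})

test_that("readReference rejects non-ACGT sequence, naming the position", {
    f <- write_fasta("ACGNACGT")
    expect_error(readReference(f, 1, "chrV"), "position 4")
    lc <- write_fasta("acgt")
    expect_equal(locusSequence(readReference(lc, 1, "chrV")), "ACGT")
})

test_that("multi-record FASTA needs a selector", {
    f <- tempfile(fileext = ".fa")
    writeLines(c(">a", "ACGT", ">b", "GGCC"), f)
    expect_error(readReference(f, 1, "chrV"), "select one")
    expect_equal(locusSequence(readReference(f, 1, "chrV", name = "b")),
                 "GGCC")
})

test_that("the synthetic reporter locus has the 1,773 bp layout", {
    locus <- syntheticLocus()
    expect_equal(locusLength(locus), 1773L)
    expect_equal(locusSpan(locus), c(31971L, 33743L))
})

test_that("readVcfSample maps fields and normalizes anchored indels", {
    f <- write_vcf_text(c(
        "chrV\t32058\t.\tC\tA\t.\tPASS\tAF=0.004;DP=16000",
        "chrV\t32100\t.\tAC\tA\t.\tPASS\tAF=0.01;DP=15000",
        "chrV\t32150\t.\tA\tAG\t.\tPASS\tAF=0.02;DP=15000",
        "chrV\t32200\t.\tC\tA,T\t.\tPASS\tAF=0.002,0.003;DP=16000"))
    s <- readVcfSample(f, "s1", "WT")
    v <- variants(s)
    expect_equal(nrow(v), 5L)
    snv <- v[v$pos == 32058, ]
    expect_equal(c(snv$ref, snv$alt), c("C", "A"))
    expect_equal(snv$frequency, 0.004)
    del <- v[v$pos == 32101, ]              # anchored AC>A
    expect_equal(c(del$ref, del$alt), c("C", ""))
    ins <- v[v$pos == 32151, ]              # anchored A>AG
    expect_equal(c(ins$ref, ins$alt), c("", "G"))
    multi <- v[v$pos == 32200, ]
    expect_equal(nrow(multi), 2L)
    expect_setequal(multi$alt, c("A", "T"))
    expect_equal(sort(multi$frequency), c(0.002, 0.003))
})

test_that("a VCF without frequency or counts fails loudly", {
    f <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chrV,length=600000>",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                 "chrV\t32058\t.\tC\tA\t.\tPASS\t."), f)
    expect_error(readVcfSample(f, "s1", "WT"), "allele-fraction")
})

test_that("technical replicate merge averages observed frequencies", {
    a <- make_sample(c(101, 102), c("C", "G"), c("A", ""),
                     c(0.004, 0.01), tech_rep = "1")
    b <- make_sample(101, "C", "A", 0.006, tech_rep = "2")
    m <- mergeTechnicalReplicates(list(a, b))
    v <- variants(m)
    expect_equal(v$frequency[v$pos == 101], 0.005)   # mean over observed
    expect_equal(v$frequency[v$pos == 102], 0.01)    # singleton unchanged
    expect_equal(totalReads(m), 32000L)

    mz <- mergeTechnicalReplicates(list(a, b), policy = "mean_with_zeros")
    expect_equal(variants(mz)$frequency[variants(mz)$pos == 102], 0.005)

    expect_identical(variants(mergeTechnicalReplicates(list(a))),
                     variants(a))
})

test_that("technical merge is permutation-invariant and type-safe", {
    a <- make_sample(c(101, 103), c("C", "T"), c("A", "G"), c(0.1, 0.2))
    b <- make_sample(c(103, 105), c("T", "A"), c("G", ""), c(0.4, 0.3),
                     tech_rep = "2")
    m1 <- variants(mergeTechnicalReplicates(list(a, b)))
    m2 <- variants(mergeTechnicalReplicates(list(b, a)))
    expect_equal(m1, m2)

    other <- make_sample(101, "C", "A", 0.1, genotype = "mut")
    expect_error(mergeTechnicalReplicates(list(a, other)), "mix")
})

test_that("variant tables round-trip and sort deterministically", {
    s <- make_sample(c(105, 101, 105), c("C", "G", "C"),
                     c("T", "", "A"), c(0.123456, 0.2, 0.05))
    f <- tempfile(fileext = ".tsv")
    writeVariantTable(s, f)
    df <- readVariantTable(f)
    expect_equal(df$pos, c(101L, 105L, 105L))
    expect_equal(df$alt, c("", "A", "T"))      # alt breaks the tie
    back <- make_variants(df$pos, df$ref, df$alt, df$frequency)
    orig <- variants(s)
    expect_equal(back[, c("pos", "ref", "alt")],
                 orig[, c("pos", "ref", "alt")])
    expect_equal(back$frequency, orig$frequency, tolerance = 1e-6)

    empty <- pooledSample("e", "WT")
    f2 <- tempfile(fileext = ".tsv")
    writeVariantTable(empty, f2)
    expect_equal(nrow(readVariantTable(f2)), 0L)
})

test_that("simulator VCFs round-trip through the VCF reader", {
    locus <- syntheticLocus(seed = 3)
    spec <- genotypeSpec("g", n_bio_replicates = 1L, n_colonies = 200L,
                         n_sites = 50L)
    tr <- simulateSelectedPool(spec, locus, seed = 5)[[1]]
    d <- withr::local_tempdir()
    ex <- emitExperiment(list(spec), backgroundModel(n_sites = 10L),
                         locus, d, seed = 5)
    sheet <- readSampleSheet(ex$sheet)
    s <- readVcfSample(sheet$file[1], "x", "g")
    v <- variants(s)
    expect_gt(nrow(v), 0)
    # every called allele matches the reference where it claims to
    expect_equal(nrow(validateVariants(s, locus)), 0L)
})

test_that("sample sheets are validated", {
    d <- withr::local_tempdir()
    vcf <- write_vcf_text("chrV\t32058\t.\tC\tA\t.\tPASS\tAF=0.004;DP=16000")
    file.copy(vcf, file.path(d, "a.vcf"))
    sheet <- data.frame(file = "a.vcf", sample_id = "s1", genotype = "WT",
                        bio_rep = 1, tech_rep = 1, condition = "selected",
                        total_reads = 16000)
    p <- file.path(d, "samples.tsv")
    write.table(sheet, p, sep = "\t", quote = FALSE, row.names = FALSE)
    out <- readSampleSheet(p)
    expect_true(file.exists(out$file[1]))

    sheet$file <- "missing.vcf"
    write.table(sheet, p, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readSampleSheet(p), "missing")

    sheet2 <- rbind(sheet, sheet)
    sheet2$file <- "a.vcf"
    write.table(sheet2, p, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readSampleSheet(p), "duplicate")
})

test_that("variants outside the locus span are rejected at validation", {
    locus <- make_locus("ACGTACGT", offset = 100)
    s <- make_sample(200, "C", "A", 0.1)
    expect_error(validateVariants(s, locus), "span")
    ok <- make_sample(101, "C", "A", 0.1)
    expect_equal(nrow(validateVariants(ok, locus)), 0L)
    bad <- make_sample(101, "G", "A", 0.1)   # locus has C at 101
    mism <- validateVariants(bad, locus)
    expect_equal(mism$expected, "C")
})
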