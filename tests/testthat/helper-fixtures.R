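# Fixtures are built in code: small loci with known content, toy samples,
# and VCF text written through the package's own emitter or by hand.

make_locus <- function(seq, offset = 100L, chrom = "chrV",
                       name = "toy") {
    methods::new("ReferenceLocus", name = name,
                 sequence = Biostrings::DNAString(seq),
                 offset = as.integer(offset), chrom = chrom)
}

make_variants <- function(pos, ref, alt, frequency,
                          depth = 16000L, chrom = "chrV") {
    n <- length(pos)
    data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
               ref = rep_len(ref, n), alt = rep_len(alt, n),
               frequency = rep_len(frequency, n),
               depth = as.integer(rep_len(depth, n)),
               stringsAsFactors = FALSE)
}

make_sample <- function(pos, ref, alt, frequency, sample_id = "s1",
                        genotype = "WT", bio_rep = "1", tech_rep = "1",
                        condition = "selected", total_reads = 16000L) {
    pooledSample(sample_id, genotype, bio_rep, tech_rep, condition,
                 total_reads,
                 make_variants(pos, ref, alt, frequency))
}

write_fasta <- function(seq, name = "toy") {
    f <- tempfile(fileext = ".fa")
    writeLines(c(paste0(">", name), seq), f)
    f
}

write_vcf_text <- function(records, chrom = "chrV") {
    f <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        paste0("##contig=<ID=", chrom, ",length=600000>"),
        "##INFO=<ID=AF,Number=A,Type=Float,Description=\"AF\">",
        "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        records), f)
    f
}
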