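#' @importFrom Biostrings readDNAStringSet DNAString reverseComplement
#' @importFrom VariantAnnotation readVcf expand info ref alt
#' @importFrom GenomicRanges start seqnames
#' @importFrom utils read.delim write.table
NULL

#' Canonical key of a unique variant
#'
#' Unique variants are identified throughout by the string
#' \code{"pos:ref:alt"} (anchor-trimmed alleles, so a single-base G
#' deletion at 32658 is \code{"32658:G:"}).
#'
#' @param pos,ref,alt variant fields (vectorized).
#' @return character vector of keys.
#' @export
variantKey <- function(pos, ref, alt) paste(pos, ref, alt, sep = ":")

## ---- ReferenceLocus ----------------------------------------------------

#' Read a reference locus from FASTA
#'
#' Loads the reporter locus (e.g. the CAN1 amplicon) and anchors it at its
#' genomic offset so VCF positions printed in genomic coordinates map onto
#' the sequence. The sequence is uppercased and must be pure A/C/G/T.
#'
#' @param fasta_path path to a FASTA file.
#' @param offset 1-based genomic coordinate of the first base.
#' @param chrom chromosome name matching the VCF records.
#' @param name record name to select when the FASTA holds several records.
#' @return a \code{\link{ReferenceLocus}}.
#' @export
readReference <- function(fasta_path, offset, chrom, name = NULL) {
    seqs <- readDNAStringSet(fasta_path)
    if (length(seqs) == 0L)
        stop("no records in FASTA: ", fasta_path)
    if (length(seqs) > 1L) {
        if (is.null(name))
            stop("FASTA has ", length(seqs),
                 " records; select one with `name`")
        if (!name %in% names(seqs))
            stop("no FASTA record named '", name, "'")
        seqs <- seqs[name]
    }
    s <- toupper(as.character(seqs[[1]]))
    bad <- regexpr("[^ACGT]", s)
    if (bad > 0)
        stop("non-ACGT character '", substr(s, bad, bad),
             "' at sequence position ", bad, " in ", fasta_path)
    new("ReferenceLocus",
        name = if (is.null(name)) names(seqs)[1] else name,
        sequence = DNAString(s), offset = as.integer(offset),
        chrom = as.character(chrom))
}

#' @rdname readReference
#' @param x,locus a \code{ReferenceLocus}.
#' @export
locusLength <- function(x) length(x@sequence)

#' @rdname readReference
#' @export
locusOffset <- function(x) x@offset

#' @rdname readReference
#' @export
locusChrom <- function(x) x@chrom

#' @rdname readReference
#' @export
locusSequence <- function(x) as.character(x@sequence)

#' @rdname readReference
#' @param pos genomic position(s), 1-based.
#' @param width number of bases to return starting at \code{pos}.
#' @return \code{locusBase}: the reference base(s) at genomic position(s).
#' @export
locusBase <- function(locus, pos, width = 1L) {
    i <- pos - locus@offset + 1L
    if (any(i < 1L | i + width - 1L > locusLength(locus)))
        stop("position outside the reference locus span")
    s <- locusSequence(locus)
    substring(s, i, i + width - 1L)
}

#' Genomic span of a reference locus
#' @param locus a \code{ReferenceLocus}.
#' @return integer vector \code{c(first, last)} of genomic coordinates.
#' @export
locusSpan <- function(locus)
    c(locus@offset, locus@offset + locusLength(locus) - 1L)

setMethod("show", "ReferenceLocus", function(object) {
    sp <- locusSpan(object)
    cat("ReferenceLocus '", object@name, "': ", locusLength(object),
        " bp on ", object@chrom, ":", sp[1], "-", sp[2], "\n", sep = "")
})

## ---- PooledSample accessors --------------------------------------------

#' @rdname PooledSample-accessors
#' @export
setGeneric("variants", function(x) standardGeneric("variants"))

#' Accessors for PooledSample
#'
#' @param x a \code{PooledSample}.
#' @return \code{variants}: the variant data.frame; the others return the
#'   corresponding scalar slot.
#' @name PooledSample-accessors
#' @aliases variants
#' @export
setMethod("variants", "PooledSample", function(x) x@variants)

#' @rdname PooledSample-accessors
#' @export
sampleId <- function(x) x@sampleId

#' @rdname PooledSample-accessors
#' @export
genotype <- function(x) x@genotype

#' @rdname PooledSample-accessors
#' @export
condition <- function(x) x@condition

#' @rdname PooledSample-accessors
#' @export
totalReads <- function(x) x@totalReads

#' @rdname PooledSample-accessors
#' @export
bioReplicate <- function(x) x@bioReplicate

#' @rdname PooledSample-accessors
#' @export
techReplicate <- function(x) x@techReplicate

setMethod("show", "PooledSample", function(object) {
    cat("PooledSample '", object@sampleId, "' (", object@genotype, ", ",
        object@condition, ", bio ", object@bioReplicate, "/tech ",
        object@techReplicate, "): ", nrow(object@variants), " variants, ",
        object@totalReads, " reads\n", sep = "")
})

#' Construct a PooledSample
#'
#' @param sample_id,genotype,bio_rep,tech_rep,condition,total_reads sample
#'   metadata (see \code{\link{PooledSample}}).
#' @param variants data.frame with columns chrom, pos, ref, alt, frequency,
#'   depth (anchor-trimmed alleles).
#' @return a \code{PooledSample}.
#' @export
pooledSample <- function(sample_id, genotype, bio_rep = "1", tech_rep = "1",
                         condition = c("selected", "permissive"),
                         total_reads = 16000L, variants = .empty_variants()) {
    condition <- match.arg(condition)
    v <- as.data.frame(variants)[, .variant_cols]
    v$pos <- as.integer(v$pos)
    v$depth <- as.integer(v$depth)
    o <- order(v$pos, v$ref, v$alt)
    v <- v[o, , drop = FALSE]
    rownames(v) <- NULL
    new("PooledSample", sampleId = as.character(sample_id),
        genotype = as.character(genotype),
        bioReplicate = as.character(bio_rep),
        techReplicate = as.character(tech_rep), condition = condition,
        totalReads = as.integer(total_reads), variants = v,
        metadata = list())
}

## ---- VCF ----------------------------------------------------------------

#' Left-trim the shared anchor base(s) from VCF-style alleles
#'
#' VCF anchors indels on a shared leading base; this package stores alleles
#' anchor-trimmed so a single-base G deletion is (pos_of_G, "G", "").
#' @noRd
.anchor_trim <- function(pos, ref, alt) {
    repeat {
        sh <- nchar(ref) > 0L & nchar(alt) > 0L &
              substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &
              !(ref == alt)  # guard; ref==alt rejected upstream
        if (!any(sh)) break
        pos[sh] <- pos[sh] + 1L
        ref[sh] <- substring(ref[sh], 2L)
        alt[sh] <- substring(alt[sh], 2L)
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' Read one pooled sample from a low-frequency variant caller VCF
#'
#' Reads a VCF 4.x file (site-only records or a single sample column),
#' producing one variant per ALT allele. Frequencies are taken from an
#' allele-fraction INFO field when present (default \code{AF}); otherwise
#' from alt-supporting reads (\code{alt_count_field}) divided by depth;
#' otherwise the load fails. Indels are left-normalised by trimming the
#' shared anchor base.
#'
#' @param vcf_path path to the VCF.
#' @param sample_id,genotype,bio_rep,tech_rep,condition,total_reads sample
#'   metadata for the resulting \code{PooledSample}.
#' @param freq_field INFO field holding the per-ALT allele fraction.
#' @param depth_field INFO field holding read depth.
#' @param alt_count_field INFO field holding alt-supporting read counts,
#'   used as fallback frequency source (\code{alt_count / depth}).
#' @return a \code{PooledSample}.
#' @export
readVcfSample <- function(vcf_path, sample_id, genotype,
                          bio_rep = "1", tech_rep = "1",
                          condition = "selected", total_reads = 16000L,
                          freq_field = "AF", depth_field = "DP",
                          alt_count_field = "AO") {
    vcf <- tryCatch(suppressWarnings(readVcf(vcf_path)),
                    error = function(e)
                        stop("malformed VCF '", vcf_path, "': ",
                             conditionMessage(e)))
    vcf <- expand(vcf)
    n <- length(vcf)
    if (n == 0L)
        return(pooledSample(sample_id, genotype, bio_rep, tech_rep,
                            condition, total_reads))
    inf <- info(vcf)
    depth <- if (depth_field %in% names(inf))
        as.integer(inf[[depth_field]]) else rep(NA_integer_, n)
    freq <- if (freq_field %in% names(inf)) {
        as.numeric(inf[[freq_field]])
    } else if (alt_count_field %in% names(inf) && !all(is.na(depth))) {
        as.numeric(inf[[alt_count_field]]) / depth
    } else {
        stop("VCF '", vcf_path, "' carries neither a '", freq_field,
             "' allele-fraction field nor '", alt_count_field,
             "'+'", depth_field, "' counts")
    }
    if (any(is.na(freq)))
        stop("missing frequency for ", sum(is.na(freq)),
             " record(s) in '", vcf_path, "'")
    tr <- .anchor_trim(as.integer(start(rowRanges(vcf))),
                       as.character(ref(vcf)), as.character(alt(vcf)))
    v <- data.frame(chrom = as.character(seqnames(rowRanges(vcf))),
                    pos = tr$pos, ref = tr$ref, alt = tr$alt,
                    frequency = freq,
                    depth = ifelse(is.na(depth), 0L, depth),
                    stringsAsFactors = FALSE)
    pooledSample(sample_id, genotype, bio_rep, tech_rep, condition,
                 total_reads, v)
}

## ---- sample sheet -------------------------------------------------------

.SHEET_COLS <- c("file", "sample_id", "genotype", "bio_rep", "tech_rep",
                 "condition", "total_reads")

#' Read a sample sheet
#'
#' Tab-separated with header
#' \code{file sample_id genotype bio_rep tech_rep condition total_reads};
#' VCF paths are resolved relative to the sheet's directory. Sample ids
#' must be unique and every referenced file must exist.
#'
#' @param path path to the TSV sample sheet.
#' @return data.frame with the sheet rows, file paths resolved.
#' @export
readSampleSheet <- function(path) {
    sheet <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
    missing <- setdiff(.SHEET_COLS, names(sheet))
    if (length(missing))
        stop("sample sheet lacks columns: ", paste(missing, collapse = ", "))
    if (anyDuplicated(sheet$sample_id))
        stop("duplicate sample_id in sample sheet")
    base <- dirname(normalizePath(path))
    abs <- ifelse(grepl("^/", sheet$file), sheet$file,
                  file.path(base, sheet$file))
    gone <- !file.exists(abs)
    if (any(gone))
        stop("sample sheet references missing file(s): ",
             paste(sheet$file[gone], collapse = ", "))
    sheet$file <- abs
    sheet$total_reads <- as.integer(sheet$total_reads)
    sheet
}

#' Load an experiment: sample sheet + VCFs, technical replicates merged
#'
#' Reads every VCF referenced by the sheet and merges technical replicates
#' of the same (genotype, biological replicate, condition) group.
#'
#' @param sheet a sample sheet path or the data.frame from
#'   \code{\link{readSampleSheet}}.
#' @param ... passed to \code{\link{readVcfSample}} (frequency field etc.).
#' @return list of \code{PooledSample}, one per biological replicate.
#' @export
loadExperiment <- function(sheet, ...) {
    if (is.character(sheet)) sheet <- readSampleSheet(sheet)
    samples <- lapply(seq_len(nrow(sheet)), function(i) {
        r <- sheet[i, ]
        readVcfSample(r$file, r$sample_id, r$genotype, r$bio_rep,
                      r$tech_rep, r$condition, r$total_reads, ...)
    })
    grp <- vapply(samples, function(s)
        paste(genotype(s), bioReplicate(s), condition(s), sep = "\r"),
        character(1))
    unname(lapply(split(samples, grp), mergeTechnicalReplicates))
}

## ---- technical replicate merge ------------------------------------------

#' Merge technical replicates of one pooled sample
#'
#' Technical replicates are independent amplifications/sequencing runs of
#' the same pooled genomic preparation. The merge takes the union of
#' variant keys; the merged frequency is by default the mean over the
#' technical replicates in which the variant was called
#' (\code{"observed_mean"}), or the mean over all replicates with zeros for
#' absences (\code{"mean_with_zeros"}). Total reads are summed; depth is
#' summed over observing replicates.
#'
#' @param samples list of \code{PooledSample} sharing genotype, biological
#'   replicate and condition.
#' @param policy frequency merge policy.
#' @return a single merged \code{PooledSample}.
#' @export
mergeTechnicalReplicates <- function(samples,
                                     policy = c("observed_mean",
                                                "mean_with_zeros")) {
    policy <- match.arg(policy)
    if (is(samples, "PooledSample")) return(samples)
    stopifnot(length(samples) >= 1L)
    if (length(samples) == 1L) return(samples[[1]])
    key3 <- vapply(samples, function(s)
        paste(genotype(s), bioReplicate(s), condition(s), sep = "\r"),
        character(1))
    if (length(unique(key3)) != 1L)
        stop("technical replicates mix genotype/bio replicate/condition")
    vs <- do.call(rbind, lapply(samples, variants))
    if (nrow(vs) == 0L) {
        merged <- vs
    } else {
        k <- variantKey(vs$pos, vs$ref, vs$alt)
        uk <- unique(k)
        merged <- vs[match(uk, k), , drop = FALSE]
        by_key <- split(seq_along(k), factor(k, levels = uk))
        sum_f <- vapply(by_key, function(i) sum(vs$frequency[i]), numeric(1))
        denom <- if (policy == "observed_mean")
            lengths(by_key) else rep(length(samples), length(uk))
        merged$frequency <- sum_f / denom
        merged$depth <- vapply(by_key, function(i)
            as.integer(sum(vs$depth[i])), integer(1))
    }
    s1 <- samples[[1]]
    pooledSample(paste0(genotype(s1), "_", bioReplicate(s1), "_",
                        condition(s1)),
                 genotype(s1), bioReplicate(s1), "merged", condition(s1),
                 sum(vapply(samples, totalReads, integer(1))), merged)
}

## ---- tabular output -----------------------------------------------------

#' Write a deterministic variant table (TSV)
#'
#' One row per variant, sorted by (pos, ref, alt), with `#`-prefixed
#' provenance header lines. Accepts a \code{PooledSample}, a list of them,
#' or a \code{MutationProfile}.
#'
#' @param x object to serialise.
#' @param path output path.
#' @param provenance extra character lines to record in the header.
#' @return the written data.frame, invisibly.
#' @export
writeVariantTable <- function(x, path, provenance = character()) {
    sample_table <- function(s) {
        v <- variants(s)
        cbind(v,
              class = if (nrow(v)) classifyVariant(v$ref, v$alt)
                      else character(),
              genotype = rep(genotype(s), nrow(v)),
              replicate = rep(bioReplicate(s), nrow(v)),
              condition = rep(condition(s), nrow(v)),
              sample_id = rep(sampleId(s), nrow(v)))
    }
    df <- if (is(x, "PooledSample")) {
        sample_table(x)
    } else if (is.list(x) && all(vapply(x, is, logical(1), "PooledSample"))) {
        do.call(rbind, lapply(x, sample_table))
    } else if (is(x, "MutationProfile")) {
        variantStats(x)
    } else as.data.frame(x)
    if (all(c("pos", "ref", "alt") %in% names(df)))
        df <- df[order(df$pos, df$ref, df$alt), , drop = FALSE]
    rownames(df) <- NULL
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(c(paste0("# canprofiler ",
                        as.character(utils::packageVersion("canprofiler"))),
                 paste0("# ", provenance)), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}

#' Read back a variant table written by \code{writeVariantTable}
#' @param path TSV path.
#' @return data.frame.
#' @export
readVariantTable <- function(path) {
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    for (col in c("ref", "alt"))
        if (col %in% names(df)) df[[col]][is.na(df[[col]])] <- ""
    df
}

## ---- validation ----------------------------------------------------------

#' Check loaded variants against the reference locus
#'
#' Verifies that every variant's ref allele matches the locus sequence at
#' its position (pure insertions carry no ref and are skipped). Mismatches
#' are reported, never dropped.
#'
#' @param sample a \code{PooledSample}.
#' @param locus the \code{ReferenceLocus}.
#' @return data.frame of mismatching rows (zero rows when all match) with
#'   an added \code{expected} column.
#' @export
validateVariants <- function(sample, locus) {
    v <- variants(sample)
    v$expected <- NA_character_
    has_ref <- nchar(v$ref) > 0L
    sp <- locusSpan(locus)
    if (any(v$pos < sp[1] | v$pos > sp[2]))
        stop("variant position outside the reference locus span")
    if (any(has_ref))
        v$expected[has_ref] <- locusBase(locus, v$pos[has_ref],
                                         width = nchar(v$ref[has_ref]))
    bad <- has_ref & v$expected != v$ref
    v[bad, , drop = FALSE]
}
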