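## Synthetic pooled-colony experiment generator. Emulates the experimental
## design end to end: selected pools of ~2,000 canavanine-resistant colonies
## per biological replicate, each colony carrying at least one
## reporter-inactivating variant drawn from a genotype-specific class
## spectrum (optionally steered by trinucleotide context); occasional
## jackpot events from mutations arising at generation g of the culture
## (2^-g of final colonies); permissive pools carrying only PCR/sequencing
## background with a strong CG>TA bias at per-site rates around 0.1%; and
## binomial thinning of all called frequencies at the sequencing depth.

.DEFAULT_CLASS_WEIGHTS <- c(
    "CG>AT" = 0.15, "CG>TA" = 0.25, "CG>GC" = 0.04,
    "TA>AT" = 0.05, "TA>CG" = 0.10, "TA>GC" = 0.05,
    ins_AT = 0.02, ins_GC = 0.01, ins_complex = 0.005,
    del_AT = 0.06, del_GC = 0.20, del_complex = 0.02,
    MNV = 0.015, replacement = 0.02)

#' Construct a simulator genotype specification
#'
#' Defaults follow the study design: ~2,000 colonies pooled per replicate,
#' 4 biological replicates per genotype, sequencing-era class spectrum with
#' SNVs and G/C deletions dominating, a 5\% chance a colony carries a
#' second reporter variant, and a 10\% per-replicate chance of one jackpot
#' event at generation 1-3.
#'
#' @param name genotype label.
#' @param class_weights named non-negative weights over (a subset of) the
#'   14 variant classes; normalised internally.
#' @param context_weights optional named 96-vector over
#'   \code{trinucContextLabels()} steering SNV placement.
#' @param n_sites size of the genotype's variant-site pool (distinct
#'   (pos, ref, alt) variants available to its colonies), allocated to
#'   classes by weight. The default 300 matches the few hundred unique
#'   variants observed per genotype in selected pools; it is what makes
#'   most true variants sit at several colonies (~0.3\% and up) rather
#'   than at background level.
#' @param n_hot_sites pool sites promoted to genotype-specific susceptible
#'   positions (systematic high-frequency variants, reaching ~3-15\% of
#'   colonies at the defaults).
#' @param hot_range sampling-weight multiplier range for hot sites.
#' @param n_colonies colonies per biological replicate.
#' @param n_bio_replicates biological replicates.
#' @param multi_mutation_rate probability of a second variant per colony.
#' @param jackpot_prob per-replicate probability of a jackpot event.
#' @param jackpot_generations candidate generations (frequency 2^-g).
#' @return a \code{\link{GenotypeSpec}}.
#' @export
genotypeSpec <- function(name, class_weights = .DEFAULT_CLASS_WEIGHTS,
                         context_weights = numeric(0), n_sites = 300L,
                         n_hot_sites = 4L, hot_range = c(10, 40),
                         n_colonies = 2000L, n_bio_replicates = 4L,
                         multi_mutation_rate = 0.05, jackpot_prob = 0.1,
                         jackpot_generations = 1:3) {
    w <- class_weights[class_weights > 0]
    if (length(context_weights) == 96L && is.null(names(context_weights)))
        names(context_weights) <- trinucContextLabels()
    new("GenotypeSpec", name = as.character(name),
        classWeights = w / sum(w),
        contextWeights = context_weights,
        nSites = as.integer(n_sites),
        nHotSites = as.integer(n_hot_sites),
        hotRange = as.numeric(hot_range),
        nColonies = as.integer(n_colonies),
        nBioReplicates = as.integer(n_bio_replicates),
        multiMutationRate = multi_mutation_rate,
        jackpotProb = jackpot_prob,
        jackpotGenerations = as.integer(jackpot_generations))
}

setMethod("show", "GenotypeSpec", function(object) {
    cat("GenotypeSpec '", object@name, "': ", object@nColonies,
        " colonies x ", object@nBioReplicates, " replicates, ",
        length(object@classWeights), " active classes\n", sep = "")
})

#' Construct a simulator background-error model
#'
#' Defaults anchor to what permissive pools show: per-site rates around
#' 0.1\% of reads, ~70\% of background SNVs being CG>TA (the amplification
#' polymerase's signature), a few hot positions with systematically
#' elevated rates, and 16,000x depth. The default 90 sites put a permissive
#' sample's total variant frequency near 9\%, the level observed in
#' unselected pools.
#'
#' @param mean_rate mean per-site background frequency.
#' @param sd_log log-normal sd of per-site rates.
#' @param snv_bias named weights over the 6 SNV classes.
#' @param n_sites number of background-prone sites.
#' @param n_hot_positions sites with systematically elevated rates.
#' @param hot_multiplier rate multiplier at hot sites.
#' @param depth sequencing depth per sample.
#' @return a \code{\link{BackgroundModel}}.
#' @export
backgroundModel <- function(mean_rate = 0.001, sd_log = 0.5,
                            snv_bias = c("CG>TA" = 0.70, "CG>AT" = 0.06,
                                         "CG>GC" = 0.06, "TA>AT" = 0.06,
                                         "TA>CG" = 0.06, "TA>GC" = 0.06),
                            n_sites = 90L, n_hot_positions = 3L,
                            hot_multiplier = 5, depth = 16000L) {
    new("BackgroundModel", meanRate = mean_rate, sdLog = sd_log,
        snvBias = snv_bias / sum(snv_bias), nSites = as.integer(n_sites),
        nHotPositions = as.integer(n_hot_positions),
        hotMultiplier = hot_multiplier, depth = as.integer(depth))
}

setMethod("show", "BackgroundModel", function(object) {
    cat("BackgroundModel: ", object@nSites, " sites, mean rate ",
        format(100 * object@meanRate, digits = 3), "%, ",
        object@nHotPositions, " hot, depth ", object@depth, "x\n",
        sep = "")
})

## ---- site machinery ------------------------------------------------------

## Positions usable for each base / triplet, genomic coordinates, interior
## only (so context analysis always has a full window).
.site_pools <- function(locus) {
    sp <- locusSpan(locus)
    pos <- (sp[1] + 1L):(sp[2] - 1L)
    s <- locusSequence(locus)
    i <- 2:(locusLength(locus) - 1L)
    base <- substring(s, i, i)
    win <- substring(s, i - 1L, i + 1L)
    pur <- base %in% c("A", "G")
    win[pur] <- .revcomp(win[pur])
    list(pos = pos, base = base,
         by_base = split(pos, base),
         by_context = split(pos, win),
         span = sp)
}

## Map an SNV class + actual reference base to the alt base.
## Classes are written pyrimidine-first: "CG>AT" is C>A on the pyrimidine
## strand and G>T on the complement.
.snv_alt <- function(class, base) {
    pyr_ref <- substr(class, 1, 1)   # C or T
    pyr_alt <- substr(class, 4, 4)
    ifelse(base == pyr_ref, pyr_alt, .COMP[pyr_alt])
}

## Bases compatible with an SNV class (the pyrimidine and its complement).
.snv_bases <- function(class) {
    b <- substr(class, 1, 1)
    c(b, unname(.COMP[b]))
}

## Realize one concrete (pos, ref, alt) for a sampled variant class.
.realize_variant <- function(class, pools, locus, spec = NULL) {
    pick <- function(v) if (length(v) == 1L) v else sample(v, 1L)
    if (class %in% snvClassNames()) {
        cw <- if (!is.null(spec)) spec@contextWeights else numeric(0)
        if (length(cw)) {
            labs <- trinucContextLabels()
            sub <- paste0(substr(class, 1, 1), ">", substr(class, 4, 4))
            idx <- grepl(paste0("[", sub, "]"), labs, fixed = TRUE)
            w <- cw[labs[idx]]
            lab <- sample(labs[idx], 1L, prob = w + 1e-12)
            trip_fwd <- paste0(substr(lab, 1, 1), substr(lab, 3, 3),
                               substr(lab, 7, 7))
            cand <- pools$by_context[[trip_fwd]]
            if (is.null(cand) || length(cand) == 0L)
                cand <- unlist(pools$by_base[.snv_bases(class)])
            p <- pick(cand)
        } else {
            p <- pick(unlist(pools$by_base[.snv_bases(class)]))
        }
        b <- locusBase(locus, p)
        return(list(pos = p, ref = b, alt = unname(.snv_alt(class, b))))
    }
    switch(class,
        del_AT = { p <- pick(unlist(pools$by_base[c("A", "T")]))
                   list(pos = p, ref = locusBase(locus, p), alt = "") },
        del_GC = { p <- pick(unlist(pools$by_base[c("G", "C")]))
                   list(pos = p, ref = locusBase(locus, p), alt = "") },
        ins_AT = { p <- pick(pools$pos)
                   list(pos = p, ref = "", alt = pick(c("A", "T"))) },
        ins_GC = { p <- pick(pools$pos)
                   list(pos = p, ref = "", alt = pick(c("G", "C"))) },
        del_complex = {
            len <- pick(2:3)
            p <- pick(pools$pos[pools$pos + len - 1L <= pools$span[2] - 1L])
            list(pos = p, ref = locusBase(locus, p, width = len), alt = "")
        },
        ins_complex = {
            p <- pick(pools$pos)
            list(pos = p, ref = "",
                 alt = paste(sample(.BASES, pick(2:3), replace = TRUE),
                             collapse = ""))
        },
        MNV = {
            p <- pick(pools$pos[pools$pos + 1L <= pools$span[2] - 1L])
            r <- locusBase(locus, p, width = 2L)
            a1 <- pick(setdiff(.BASES, substr(r, 1, 1)))
            a2 <- pick(setdiff(.BASES, substr(r, 2, 2)))
            list(pos = p, ref = r, alt = paste0(a1, a2))
        },
        replacement = {
            p <- pick(pools$pos)
            r <- locusBase(locus, p)
            a1 <- pick(setdiff(.BASES, r))
            list(pos = p, ref = r, alt = paste0(a1, pick(.BASES)))
        },
        stop("unknown variant class: ", class))
}

## ---- selected pools -------------------------------------------------------

#' Draw a genotype's variant-site pool
#'
#' Realises the fixed set of distinct (pos, ref, alt) variants a genotype's
#' colonies draw from: \code{nSites} sites allocated to the active classes
#' proportionally to their weights (at least one per class), SNV placement
#' optionally steered by the context weights. The pool is drawn once per
#' genotype and shared by its biological replicates — the source of the
#' systematic, genotype-specific variants the downstream clustering keys
#' on.
#'
#' @param spec a \code{\link{GenotypeSpec}}.
#' @param locus the \code{ReferenceLocus}.
#' @param seed optional integer seed.
#' @return data.frame (pos, ref, alt, class, weight, hot) — \code{weight}
#'   is the per-site colony sampling weight, \code{hot} marks susceptible
#'   high-frequency sites.
#' @export
drawSitePool <- function(spec, locus, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pools <- .site_pools(locus)
    if (length(pools$pos) == 0L) stop("no eligible sites on the locus")
    alloc <- pmax(round(spec@classWeights * spec@nSites), 1L)
    out <- list()
    for (cl in names(alloc)) {
        seen <- character()
        sites <- list()
        tries <- 0L
        while (length(sites) < alloc[[cl]] && tries < 50L * alloc[[cl]]) {
            tries <- tries + 1L
            v <- .realize_variant(cl, pools, locus, spec)
            k <- variantKey(v$pos, v$ref, v$alt)
            if (k %in% seen) next
            seen <- c(seen, k)
            sites[[length(sites) + 1L]] <- v
        }
        df <- data.frame(
            pos = vapply(sites, `[[`, integer(1), "pos"),
            ref = vapply(sites, `[[`, character(1), "ref"),
            alt = vapply(sites, `[[`, character(1), "alt"))
        df$class <- cl
        df$weight <- spec@classWeights[[cl]] / nrow(df)
        out[[cl]] <- df
    }
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out$hot <- FALSE
    if (spec@nHotSites > 0L) {
        hi <- sample.int(nrow(out), min(spec@nHotSites, nrow(out)),
                         prob = out$weight)
        out$weight[hi] <- out$weight[hi] *
            stats::runif(length(hi), spec@hotRange[1], spec@hotRange[2])
        out$hot[hi] <- TRUE
    }
    out
}

#' Simulate the true variant content of selected pools
#'
#' Per biological replicate: every colony draws one variant from the
#' genotype's site pool (class proportions follow the genotype's class
#' spectrum), a binomial share of colonies draws a second one, and with
#' probability \code{jackpotProb} one variant is promoted to a jackpot —
#' its colony count raised by \code{round(2^-g * n_colonies)} for a
#' generation g drawn from \code{jackpotGenerations}, on top of its regular
#' occurrences (so a g = 2 jackpot sits strictly above 25\%). True
#' frequencies are colony counts over \code{n_colonies}.
#'
#' @param spec a \code{\link{GenotypeSpec}}.
#' @param locus the \code{ReferenceLocus}.
#' @param seed optional integer seed for reproducibility.
#' @param site_pool optional pre-drawn pool from \code{\link{drawSitePool}};
#'   drawn internally when NULL.
#' @return list of per-replicate data.frames (pos, ref, alt, class, count,
#'   frequency, jackpot_generation — NA when not a jackpot).
#' @export
simulateSelectedPool <- function(spec, locus, seed = NULL,
                                 site_pool = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(site_pool)) site_pool <- drawSitePool(spec, locus)
    lapply(seq_len(spec@nBioReplicates), function(rep_i) {
        n_extra <- stats::rbinom(1L, spec@nColonies, spec@multiMutationRate)
        n_draw <- spec@nColonies + n_extra
        idx <- sample.int(nrow(site_pool), n_draw, replace = TRUE,
                          prob = site_pool$weight)
        counts <- tabulate(idx, nbins = nrow(site_pool))
        out <- site_pool[counts > 0L,
                         c("pos", "ref", "alt", "class"), drop = FALSE]
        out$count <- counts[counts > 0L]
        out$jackpot_generation <- NA_integer_
        if (stats::runif(1) < spec@jackpotProb && nrow(out) > 0L) {
            g <- if (length(spec@jackpotGenerations) == 1L)
                spec@jackpotGenerations
            else sample(spec@jackpotGenerations, 1L)
            i <- sample.int(nrow(out), 1L)
            out$count[i] <- out$count[i] +
                as.integer(round(2^(-g) * spec@nColonies))
            out$jackpot_generation[i] <- g
        }
        out$frequency <- out$count / spec@nColonies
        o <- order(out$pos, out$ref, out$alt)
        rownames(out) <- NULL
        out[o, c("pos", "ref", "alt", "class", "count", "frequency",
                 "jackpot_generation")]
    })
}

## ---- background ----------------------------------------------------------

#' Draw the experiment's background error sites
#'
#' Realises the background model once per experiment: \code{nSites}
#' distinct positions each receive one error variant (class by the SNV
#' bias, allele fixed by the reference base) and a per-site rate drawn
#' log-normally around \code{meanRate}; \code{nHotPositions} of them are
#' multiplied by \code{hotMultiplier}. All samples of the experiment share
#' this table, which is what makes position-specific maxima learnable by
#' the permissive filter.
#'
#' @param model a \code{\link{BackgroundModel}}.
#' @param locus the \code{ReferenceLocus}.
#' @param seed optional integer seed.
#' @return data.frame (pos, ref, alt, class, rate, hot).
#' @export
drawBackgroundSites <- function(model, locus, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    pools <- .site_pools(locus)
    n <- min(model@nSites, length(pools$pos))
    # class first (so emitted class proportions follow the bias), then a
    # distinct position with a compatible reference base
    cls <- sample(names(model@snvBias), n, replace = TRUE,
                  prob = model@snvBias)
    is_cg <- substr(cls, 1, 1) == "C"
    pool_cg <- c(pools$by_base$C, pools$by_base$G)
    pool_ta <- c(pools$by_base$T, pools$by_base$A)
    pos <- integer(n)
    pos[is_cg] <- sample(pool_cg, sum(is_cg))
    pos[!is_cg] <- sample(pool_ta, sum(!is_cg))
    o <- order(pos)
    pos <- pos[o]; cls <- cls[o]
    base <- vapply(pos, function(p) locusBase(locus, p), character(1))
    alt <- unname(.snv_alt(cls, base))
    meanlog <- log(model@meanRate) - model@sdLog^2 / 2
    rate <- stats::rlnorm(n, meanlog, model@sdLog)
    hot <- rep(FALSE, n)
    if (model@nHotPositions > 0L) {
        hi <- sample.int(n, model@nHotPositions)
        rate[hi] <- rate[hi] * model@hotMultiplier
        hot[hi] <- TRUE
    }
    data.frame(pos = pos, ref = base, alt = alt, class = cls,
               rate = pmin(rate, 1), hot = hot)
}

#' Simulate one permissive (background-only) sample
#'
#' Each background site emits a binomial number of supporting reads at the
#' model depth; sites with at least one read are called, at frequency
#' reads / depth. A zero-rate model yields an empty table.
#'
#' @inheritParams drawBackgroundSites
#' @param sites optional pre-drawn site table (from
#'   \code{\link{drawBackgroundSites}}); drawn internally when NULL.
#' @return data.frame (chrom, pos, ref, alt, frequency, depth).
#' @export
simulatePermissivePool <- function(model, locus, seed = NULL, sites = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(sites)) sites <- drawBackgroundSites(model, locus)
    reads <- stats::rbinom(nrow(sites), model@depth, sites$rate)
    keep <- reads >= 1L
    data.frame(chrom = rep(locusChrom(locus), sum(keep)),
               pos = sites$pos[keep],
               ref = sites$ref[keep], alt = sites$alt[keep],
               frequency = reads[keep] / model@depth,
               depth = rep(model@depth, sum(keep)),
               stringsAsFactors = FALSE)
}

## ---- VCF + experiment emission -------------------------------------------

## Minimal deterministic site-only VCF 4.2 writer. Alleles arrive
## anchor-trimmed; indels are re-anchored on the preceding reference base
## as the format requires.
.write_vcf <- function(df, path, locus, depth) {
    sp <- locusSpan(locus)
    pos <- df$pos; ref <- df$ref; alt <- df$alt
    indel <- nchar(ref) == 0L | nchar(alt) == 0L
    if (any(indel)) {
        anchor <- locusBase(locus, pos[indel] - 1L)
        ref[indel] <- paste0(anchor, ref[indel])
        alt[indel] <- paste0(anchor, alt[indel])
        pos[indel] <- pos[indel] - 1L
    }
    o <- order(pos, ref, alt)
    lines <- c(
        "##fileformat=VCFv4.2",
        "##source=canprofiler-simulator",
        paste0("##contig=<ID=", locusChrom(locus), ",length=",
               sp[2] + 1000L, ">"),
        paste0("##INFO=<ID=AF,Number=A,Type=Float,",
               "Description=\"Allele frequency\">"),
        paste0("##INFO=<ID=DP,Number=1,Type=Integer,",
               "Description=\"Read depth\">"),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
        if (nrow(df)) sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%.8g;DP=%d",
                              locusChrom(locus), pos[o], ref[o], alt[o],
                              df$frequency[o], depth))
    writeLines(lines, path)
    invisible(path)
}

## Binomially thin true frequencies to called frequencies at given depth.
.thin_calls <- function(df, depth, chrom) {
    reads <- stats::rbinom(nrow(df), depth, pmin(df$frequency, 1))
    keep <- reads >= 1L
    data.frame(chrom = chrom, pos = df$pos[keep], ref = df$ref[keep],
               alt = df$alt[keep], frequency = reads[keep] / depth,
               depth = rep(depth, sum(keep)), stringsAsFactors = FALSE)
}

## Add background reads onto a selected sample's calls (frequencies add
## per key).
.add_background <- function(calls, bg_calls) {
    if (nrow(bg_calls) == 0L) return(calls)
    both <- rbind(calls, bg_calls)
    k <- variantKey(both$pos, both$ref, both$alt)
    uk <- unique(k)
    out <- both[match(uk, k), , drop = FALSE]
    out$frequency <- vapply(split(both$frequency,
                                  factor(k, levels = uk)), sum, numeric(1))
    out[order(out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Emit a full synthetic experiment to disk
#'
#' Writes one VCF per sample (selected: true colony variants plus
#' background, frequencies added per key; permissive: background only), a
#' sample sheet consumable by \code{\link{loadExperiment}}, a ground-truth
#' table of planted variants, and the realised background site table.
#' Identical (specs, seed) give byte-identical outputs.
#'
#' @param specs list of \code{\link{GenotypeSpec}}.
#' @param background a \code{\link{BackgroundModel}}.
#' @param locus the \code{ReferenceLocus}.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling the whole experiment.
#' @param n_permissive_per_genotype permissive replicates per genotype.
#' @param n_tech_selected technical replicates (independent amplification
#'   and sequencing of the same pooled preparation) per selected biological
#'   replicate. The default 2 mirrors the re-sequencing of selected pools
#'   as a reproducibility check; merging them by mean halves the noise on
#'   selected background calls, which is what lets the permissive
#'   position-max filter catch them.
#' @param n_tech_permissive technical replicates per permissive sample.
#' @return invisibly, a list with the sheet path, truth table and
#'   background sites.
#' @export
emitExperiment <- function(specs, background, locus, out_dir, seed = 1L,
                           n_permissive_per_genotype = 4L,
                           n_tech_selected = 2L,
                           n_tech_permissive = 1L) {
    if (length(specs) == 0L) stop("need at least one genotype spec")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    set.seed(seed)
    sites <- drawBackgroundSites(background, locus)
    depth <- background@depth
    chrom <- locusChrom(locus)
    sheet <- list(); truth <- list()
    for (spec in specs) {
        true_reps <- simulateSelectedPool(spec, locus)
        for (b in seq_along(true_reps)) {
            tr <- true_reps[[b]]
            truth[[length(truth) + 1L]] <-
                cbind(genotype = spec@name, bio_rep = b, tr)
            for (t in seq_len(n_tech_selected)) {
                calls <- .thin_calls(tr, depth, chrom)
                bg <- simulatePermissivePool(background, locus,
                                             sites = sites)
                calls <- .add_background(calls, bg)
                sid <- sprintf("%s_sel_b%d_t%d", spec@name, b, t)
                f <- file.path(out_dir, paste0(sid, ".vcf"))
                .write_vcf(calls, f, locus, depth)
                sheet[[length(sheet) + 1L]] <- data.frame(
                    file = basename(f), sample_id = sid,
                    genotype = spec@name, bio_rep = as.character(b),
                    tech_rep = as.character(t), condition = "selected",
                    total_reads = depth)
            }
        }
        for (b in seq_len(n_permissive_per_genotype)) {
            for (t in seq_len(n_tech_permissive)) {
                bg <- simulatePermissivePool(background, locus,
                                             sites = sites)
                sid <- sprintf("%s_perm_b%d_t%d", spec@name, b, t)
                f <- file.path(out_dir, paste0(sid, ".vcf"))
                .write_vcf(bg, f, locus, depth)
                sheet[[length(sheet) + 1L]] <- data.frame(
                    file = basename(f), sample_id = sid,
                    genotype = spec@name, bio_rep = as.character(b),
                    tech_rep = as.character(t), condition = "permissive",
                    total_reads = depth)
            }
        }
    }
    sheet <- do.call(rbind, sheet)
    truth <- do.call(rbind, truth)
    sheet_path <- file.path(out_dir, "samples.tsv")
    write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sites, file.path(out_dir, "background_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(list(sheet = sheet_path, truth = truth, sites = sites))
}

#' A synthetic reference locus for examples and simulation
#'
#' Generates a random-sequence stand-in for the 1,773 bp reporter amplicon
#' (flagged synthetic: it shares the length, coordinate layout and GC
#' content class of the real locus, not its sequence).
#'
#' @param length locus length in bp.
#' @param offset genomic coordinate of the first base.
#' @param chrom chromosome name.
#' @param seed integer seed.
#' @param gc target GC fraction.
#' @return a \code{\link{ReferenceLocus}}.
#' @export
syntheticLocus <- function(length = 1773L, offset = 31971L, chrom = "chrV",
                           seed = 1L, gc = 0.4) {
    set.seed(seed)
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    s <- paste(sample(names(p), length, replace = TRUE, prob = p),
               collapse = "")
    new("ReferenceLocus", name = "synthetic_reporter",
        sequence = Biostrings::DNAString(s), offset = as.integer(offset),
        chrom = chrom)
}
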