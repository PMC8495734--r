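# In-memory simulated experiment (no VCF round-trip): the same generative
# process as emitExperiment, assembled from the exported simulator pieces.
# Used where many seeds are run and file I/O would dominate.
simulate_experiment_mem <- function(specs, bg, locus, seed,
                                    n_perm_per_genotype = 4L,
                                    n_tech_selected = 2L) {
    set.seed(seed)
    sites <- drawBackgroundSites(bg, locus)
    chrom <- locusChrom(locus)
    thin <- function(df) {
        reads <- rbinom(nrow(df), bg@depth, pmin(df$frequency, 1))
        keep <- reads >= 1L
        data.frame(chrom = rep(chrom, sum(keep)), pos = df$pos[keep],
                   ref = df$ref[keep], alt = df$alt[keep],
                   frequency = reads[keep] / bg@depth,
                   depth = rep(bg@depth, sum(keep)))
    }
    add_bg <- function(calls, bgc) {
        both <- rbind(calls, bgc)
        k <- paste(both$pos, both$ref, both$alt)
        uk <- unique(k)
        out <- both[match(uk, k), , drop = FALSE]
        out$frequency <- vapply(split(both$frequency,
                                      factor(k, levels = uk)),
                                sum, numeric(1))
        out
    }
    samples <- list(); truth <- list()
    for (spec in specs) {
        reps <- simulateSelectedPool(spec, locus)
        for (b in seq_along(reps)) {
            truth[[length(truth) + 1L]] <-
                cbind(genotype = spec@name, bio_rep = b, reps[[b]])
            techs <- lapply(seq_len(n_tech_selected), function(t) {
                calls <- add_bg(thin(reps[[b]]),
                                simulatePermissivePool(bg, locus,
                                                       sites = sites))
                pooledSample(sprintf("%s_s%d_%d", spec@name, b, t),
                             spec@name, as.character(b), as.character(t),
                             "selected", bg@depth, calls)
            })
            samples[[length(samples) + 1L]] <-
                mergeTechnicalReplicates(techs)
        }
        for (b in seq_len(n_perm_per_genotype)) {
            calls <- simulatePermissivePool(bg, locus, sites = sites)
            samples[[length(samples) + 1L]] <-
                pooledSample(sprintf("%s_p%d", spec@name, b), spec@name,
                             as.character(b), "1", "permissive",
                             bg@depth, calls)
        }
    }
    list(samples = samples, truth = do.call(rbind, truth), sites = sites)
}

# Filter efficacy and class-spectrum recovery for a simulated experiment.
score_experiment <- function(samples, truth, sites, specs) {
    perm <- Filter(function(s) condition(s) == "permissive", samples)
    sel <- Filter(function(s) condition(s) == "selected", samples)
    thr <- buildThresholds(perm)
    bg_keys <- variantKey(sites$pos, sites$ref, sites$alt)
    removed <- total_bg <- kept1 <- total1 <- 0
    filtered <- list()
    for (s in sel) {
        f <- applyFilter(s, thr)
        filtered[[length(filtered) + 1L]] <- f
        tk <- truth[truth$genotype == genotype(s) &
                    truth$bio_rep == as.integer(bioReplicate(s)), ]
        true_keys <- variantKey(tk$pos, tk$ref, tk$alt)
        vin <- variants(s); vout <- variants(f)
        kin <- variantKey(vin$pos, vin$ref, vin$alt)
        kout <- variantKey(vout$pos, vout$ref, vout$alt)
        bg_only <- setdiff(intersect(kin, bg_keys), true_keys)
        total_bg <- total_bg + length(bg_only)
        removed <- removed + sum(!bg_only %in% kout)
        t1 <- intersect(true_keys[tk$frequency >= 0.01], kin)
        total1 <- total1 + length(t1)
        kept1 <- kept1 + sum(t1 %in% kout)
    }
    profiles <- lapply(split(filtered,
                             vapply(filtered, genotype, character(1))),
                       buildProfile)
    tvd <- vapply(specs, function(spec) {
        obs <- classSpectrum(profiles[[spec@name]], "total_variants")
        want <- setNames(numeric(14), variantClassNames())
        want[names(spec@classWeights)] <- spec@classWeights
        0.5 * sum(abs(obs - want))
    }, numeric(1))
    list(removal = removed / total_bg, retention = kept1 / max(total1, 1),
         n_true_high = total1, tvd = tvd, profiles = profiles,
         thresholds = thr)
}

study_specs <- function() list(
    genotypeSpec("WT"),
    genotypeSpec("mutA",
                 class_weights = c("CG>AT" = 0.35, "del_GC" = 0.35,
                                   "CG>TA" = 0.2, del_AT = 0.1)),
    genotypeSpec("mutB",
                 class_weights = c("CG>TA" = 0.3, del_AT = 0.3,
                                   "TA>CG" = 0.3, ins_AT = 0.1)),
    genotypeSpec("mutC",
                 class_weights = c("CG>AT" = 0.5, "del_GC" = 0.4,
                                   MNV = 0.05, replacement = 0.05)))
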