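## Orchestration: load -> filter -> profile -> trinucleotide spectra ->
## clustering -> motifs, with plain-table artifacts at every stage.

.default_config <- function() list(
    reference = list(fasta = NULL, offset = NULL, chrom = NULL, name = NULL),
    sample_sheet = NULL,
    out_dir = "canprofiler_run",
    freq_field = "AF",
    filter = list(floor = "auto", keying = "position"),
    profile = list(high_cutoff = 0.05, jackpot_cutoff = 0.25),
    trinuc = list(method = "pearson", mode = "normalized"),
    cluster = list(distance = "euclidean", linkage = "complete",
                   row_sum_scale = "raw", min_row_sum = 0, k = 3),
    motif = list(classes = c("del_GC", "CG>AT"), half_width = 6,
                 pseudocount = 0))

#' Read a pipeline configuration
#'
#' Merges a YAML file (or list) over the package defaults. Defaults carry
#' the study's fixed constants: 5\% high-frequency cutoff, 25\% jackpot
#' cutoff, 6-base motif half-width, position-keyed permissive filter with
#' an automatically computed floor.
#'
#' @param config path to a YAML file, or a list of overrides, or NULL.
#' @return full configuration list.
#' @export
readRunConfig <- function(config = NULL) {
    base <- .default_config()
    user <- if (is.null(config)) list()
            else if (is.character(config)) yaml::read_yaml(config)
            else config
    merge2 <- function(a, b) {
        for (nm in names(b))
            a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
                merge2(a[[nm]], b[[nm]]) else b[[nm]]
        a
    }
    cfg <- merge2(base, user)
    stopifnot(cfg$profile$high_cutoff > 0, cfg$profile$high_cutoff < 1,
              cfg$profile$jackpot_cutoff > 0, cfg$profile$jackpot_cutoff < 1,
              cfg$motif$half_width >= 1)
    cfg
}

#' Run the full analysis pipeline
#'
#' Loads the experiment, learns the permissive filter, filters the selected
#' samples, builds per-genotype profiles (with high/low-frequency partition
#' and jackpot flags), trinucleotide-context spectra and their correlation
#' matrix, the replicate-fraction clustering, and per-class motif models —
#' writing a TSV artifact set under \code{out_dir} and logging counts in
#' and out of every filtering stage.
#'
#' @param config configuration (see \code{\link{readRunConfig}}); must
#'   provide \code{reference} and \code{sample_sheet}. A pre-built
#'   \code{ReferenceLocus} can be passed via \code{locus}.
#' @param locus optional \code{ReferenceLocus}, overriding
#'   \code{config$reference}.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with thresholds, filtered samples, profiles,
#'   spectra, correlation matrix, clustering and motif models.
#' @export
runPipeline <- function(config, locus = NULL, quiet = FALSE) {
    cfg <- readRunConfig(config)
    say <- function(...) if (!quiet) message(...)
    if (is.null(locus)) {
        r <- cfg$reference
        locus <- readReference(r$fasta, r$offset, r$chrom, r$name)
    }
    out <- cfg$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    prov <- paste0("config: high=", cfg$profile$high_cutoff,
                   " jackpot=", cfg$profile$jackpot_cutoff,
                   " keying=", cfg$filter$keying)

    samples <- loadExperiment(cfg$sample_sheet, freq_field = cfg$freq_field)
    say("loaded ", length(samples), " biological replicates")
    perm <- Filter(function(s) condition(s) == "permissive", samples)
    sel <- Filter(function(s) condition(s) == "selected", samples)
    for (s in sel) {
        mism <- validateVariants(s, locus)
        if (nrow(mism))
            say("NOTE: ", nrow(mism), " ref-mismatch variant(s) in ",
                sampleId(s))
    }

    thresholds <- buildThresholds(perm, floor = cfg$filter$floor,
                                  keying_mode = cfg$filter$keying)
    pm <- thresholds@positionMax
    writeVariantTable(
        cbind(pm, global_floor = thresholds@globalFloor),
        file.path(out, "thresholds.tsv"), prov)

    filt_dir <- file.path(out, "filtered")
    dir.create(filt_dir, showWarnings = FALSE)
    filtered <- lapply(sel, function(s) {
        fs <- applyFilter(s, thresholds)
        say("filter ", sampleId(s), ": ", fs@metadata$n_in, " -> ",
            fs@metadata$n_out, " variants")
        writeVariantTable(fs, file.path(filt_dir,
                                        paste0(sampleId(fs), ".tsv")), prov)
        fs
    })

    gts <- unique(vapply(filtered, genotype, character(1)))
    prof_dir <- file.path(out, "profiles")
    dir.create(prof_dir, showWarnings = FALSE)
    profiles <- lapply(gts, function(g) {
        p <- buildProfile(Filter(function(s) genotype(s) == g, filtered))
        vs <- variantStats(p)
        jp <- flagJackpots(p, cfg$profile$jackpot_cutoff)
        vs$jackpot_flag <- rownames(freqMatrix(p)) %in% jp
        vs$high_low_flag <- ifelse(
            vs$freq_mean_observed > cfg$profile$high_cutoff, "high", "low")
        writeVariantTable(vs, file.path(prof_dir, paste0(g, ".tsv")), prov)
        p
    })
    names(profiles) <- gts
    if (length(profiles) >= 2L) {
        ov <- genotypeOverlap(profiles)
        write.table(cbind(key = rownames(ov$presence), ov$presence),
                    file.path(prof_dir, "overlap.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
    }

    trinuc_dir <- file.path(out, "trinuc")
    dir.create(trinuc_dir, showWarnings = FALSE)
    spectra <- lapply(profiles, trinucSpectrum, locus = locus)
    for (sp in spectra)
        write.table(
            data.frame(context = trinucContextLabels(),
                       avg_count = sp@avgCount,
                       normalized = sp@normalized),
            file.path(trinuc_dir, paste0(genotype(sp), ".tsv")),
            sep = "\t", quote = FALSE, row.names = FALSE)
    cormat <- if (length(spectra) >= 2L) {
        cm <- spectrumCorrelationMatrix(spectra,
                                        method = cfg$trinuc$method,
                                        mode = cfg$trinuc$mode)
        write.table(cbind(genotype = rownames(cm), as.data.frame(cm)),
                    file.path(trinuc_dir, "correlations.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        cm
    } else NULL

    clustering <- NULL
    if (length(profiles) >= 2L) {
        clu_dir <- file.path(out, "cluster")
        dir.create(clu_dir, showWarnings = FALSE)
        fm <- buildFractionMatrix(profiles)
        fm <- filterRows(fm, cfg$cluster$min_row_sum,
                         cfg$cluster$row_sum_scale)
        say("clustering ", nrow(fm$matrix), " unique variants x ",
            ncol(fm$matrix), " genotypes")
        if (nrow(fm$matrix) >= 2L) {
            clustering <- clusterRows(fm, cfg$cluster$distance,
                                      cfg$cluster$linkage,
                                      k = min(cfg$cluster$k,
                                              nrow(fm$matrix)))
            write.table(cbind(key = rownames(fm$matrix), fm$row_meta,
                              fm$matrix),
                        file.path(clu_dir, "fraction_matrix.tsv"),
                        sep = "\t", quote = FALSE, row.names = FALSE)
            writeDendrogram(clustering,
                            file.path(clu_dir, "row_dendrogram.nwk"))
            write.table(data.frame(key = names(clustering$clusters),
                                   cluster = clustering$clusters),
                        file.path(clu_dir, "clusters.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
        }
        clustering$fraction_matrix <- fm
    }

    motif_dir <- file.path(out, "motifs")
    dir.create(motif_dir, showWarnings = FALSE)
    all_stats <- do.call(rbind, lapply(profiles, variantStats))
    motifs <- list()
    for (cl in cfg$motif$classes) {
        win <- withCallingHandlers(
            extractWindows(all_stats, locus,
                           half_width = cfg$motif$half_width, class = cl),
            warning = function(w) {
                say("motif ", cl, ": ", conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        if (length(win) == 0L) { say("no windows for class ", cl); next }
        mm <- motifModel(win, cfg$motif$pseudocount)
        motifs[[cl]] <- mm
        safe <- gsub("[^A-Za-z_]", "_", cl)
        write.table(data.frame(base = rownames(mm$pfm), mm$pfm,
                               check.names = FALSE),
                    file.path(motif_dir, paste0(safe, "_pfm.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        write.table(data.frame(position = colnames(mm$pfm),
                               bits = mm$information),
                    file.path(motif_dir, paste0(safe, "_information.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }

    invisible(list(config = cfg, locus = locus, thresholds = thresholds,
                   permissive = perm, filtered = filtered,
                   profiles = profiles, spectra = spectra,
                   correlations = cormat, clustering = clustering,
                   motifs = motifs))
}
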