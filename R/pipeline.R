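#' Run the pipeline stages from a configuration
#'
#' Command-oriented front end tying the stages into the published workflow:
#' \describe{
#'   \item{simulate}{write a synthetic community (genomes, reads, truth,
#'     family model) under \code{out_dir}}
#'   \item{build-graph}{reads -> condensed string graph (GFA) + verified
#'     contig FASTA}
#'   \item{merge}{string graph + contigs -> hybrid graph GFA + merge report}
#'   \item{search}{reads + models -> per-read assignment and per-family
#'     abundance tables + homologous-path FASTA (templates, not genes)}
#'   \item{evaluate}{assignments + truth -> metric table}
#'   \item{all}{simulate, then the full chain, in one output directory}
#' }
#' Each run writes \code{manifest.yaml} (configuration echo incl. seed) so
#' re-runs are bit-identical. Unknown configuration keys are rejected.
#'
#' @param command One of the commands above.
#' @param config Named list or path to a YAML file; see
#'   \code{defaultRunConfig()} for keys and defaults.
#' @param overrides Named list applied on top of \code{config}.
#' @return Invisibly, a list of the main in-memory results per stage.
#' @export
runPipeline <- function(command = c("all", "simulate", "build-graph",
                                    "merge", "search", "evaluate"),
                        config = list(), overrides = list()) {
    command <- match.arg(command)
    if (is.character(config)) config <- yaml::read_yaml(config)
    cfg <- defaultRunConfig()
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown) > 0L)
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
    cfg[names(overrides)] <- overrides
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(cfg, file.path(cfg$out_dir, "manifest.yaml"))
    # family and community draw from distinct streams so planted
    # backgrounds never replay the family's consensus
    simConf <- SimConfig(n_genomes = cfg$n_genomes,
                         genome_len = cfg$genome_len,
                         instances_per_genome = cfg$instances_per_genome,
                         read_len = cfg$read_len, error_rate = cfg$error_rate,
                         coverage = cfg$coverage,
                         abundance_mode = cfg$abundance_mode,
                         stagger_ratio = cfg$stagger_ratio,
                         seed = cfg$seed + 90001L)
    sgParams <- StringGraphParams(min_overlap = cfg$min_overlap)
    dbgParams <- DeBruijnParams(k = cfg$k,
                                min_kmer_count = cfg$min_kmer_count)
    mergeParams <- MergeParams(min_score = cfg$min_score,
                               min_aln_len = cfg$min_aln_len)
    searchParams <- SearchParams(
        anchor_threshold = cfg$anchor_threshold,
        extension_slack = cfg$extension_slack,
        identity_cutoff = cfg$identity_cutoff,
        read_cover_frac = cfg$read_cover_frac)
    res <- list()
    if (command %in% c("simulate", "all")) {
        fam <- simulateFamily(L = cfg$family_L, seed = cfg$seed)
        writeProfileModel(fam$model, file.path(cfg$out_dir, "family.pm.yml"))
        planted <- plantGenomes(fam$model, simConf)
        ab <- if (cfg$abundance_mode == "staggered")
            staggeredAbundances(cfg$n_genomes, cfg$stagger_ratio)
        else rep(1 / cfg$n_genomes, cfg$n_genomes)
        reads <- simulateReads(planted$genomes, ab, simConf)
        writeSimulation(list(genomes = planted$genomes,
                             truth = planted$truth, reads = reads),
                        cfg$out_dir, simConf)
        res$sim <- list(model = fam$model, planted = planted, reads = reads)
    }
    if (command == "simulate") return(invisible(res))
    reads <- if (!is.null(res$sim)) res$sim$reads else {
        if (is.null(cfg$reads) || is.na(cfg$reads)) NULL
        else readSequences(cfg$reads, cfg$reads_format)
    }
    needBuild <- command %in% c("build-graph", "all") ||
        (command %in% c("merge", "search") && is.null(cfg$asqg))
    if (needBuild && is.null(reads))
        stop("config key 'reads' required")
    if (needBuild) {
        ov <- findReadOverlaps(reads, sgParams)
        sg <- condense(buildStringGraph(reads, ov, sgParams))
        dbg <- buildDeBruijnGraph(reads, dbgParams)
        contigs <- verifyContigs(extractContigs(dbg), reads)
        writeGFA(sg, file.path(cfg$out_dir, "string_graph.gfa"))
        writeContigs(contigs[contigs$verified %in% TRUE, , drop = FALSE],
                     file.path(cfg$out_dir, "contigs.fasta"))
        res$sg <- sg; res$contigs <- contigs
    }
    if (command == "build-graph") return(invisible(res))
    if (command %in% c("merge", "search", "all")) {
        sg <- res$sg %||% {
            if (!is.null(cfg$asqg)) condense(readASQG(cfg$asqg))
            else stop("config key 'asqg' required for merge without reads")
        }
        contigs <- res$contigs %||% {
            ct <- readContigs(cfg$contigs)
            if (!is.null(reads)) verifyContigs(ct, reads)
            else { ct$verified <- TRUE; ct }  # externally verified set
        }
        rec <- recruitAlignments(sg, terminalEdges(sg), contigs, mergeParams)
        hybrid <- condense(mergeGraphs(sg, contigs, rec, mergeParams))
        writeGFA(hybrid, file.path(cfg$out_dir, "hybrid_graph.gfa"))
        utils::write.table(hybrid@meta$mergeReport,
                           file.path(cfg$out_dir, "merge_report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$hybrid <- hybrid
    }
    if (command == "merge") return(invisible(res))
    if (command %in% c("search", "all")) {
        models <- if (!is.null(res$sim)) list(res$sim$model) else {
            if (is.null(cfg$models)) stop("config key 'models' required")
            lapply(cfg$models, readProfileModel)
        }
        found <- searchFamilies(reads, models, searchParams,
                                hybrid = res$hybrid)
        asn <- do.call(rbind, lapply(found, function(fr)
            if (nrow(fr$read_assignments) > 0L)
                cbind(fr$read_assignments, family_id = fr$family_id)
            else NULL))
        if (is.null(asn))
            asn <- data.frame(read_id = character(), path_id = character(),
                              score = numeric(), family_id = character(),
                              stringsAsFactors = FALSE)
        utils::write.table(asn, file.path(cfg$out_dir, "assignments.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        ab <- data.frame(family_id = names(found),
                         abundance = vapply(found, `[[`, 0, "abundance"))
        utils::write.table(ab, file.path(cfg$out_dir, "abundance.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        for (fr in found)
            if (nrow(fr$homologous_paths) > 0L)
                writeSequences(stats::setNames(fr$homologous_paths$seq,
                                               fr$homologous_paths$path_id),
                               file.path(cfg$out_dir,
                                         sprintf("paths_%s.fasta",
                                                 fr$family_id)), "fasta")
        res$search <- found
    }
    if (command == "search") return(invisible(res))
    if (command %in% c("evaluate", "all")) {
        if (command == "evaluate") {
            asn <- utils::read.delim(file.path(cfg$out_dir,
                                               "assignments.tsv"),
                                     stringsAsFactors = FALSE)
            truthIv <- readIntervals(file.path(cfg$out_dir, "truth.tsv"))
            readTruth <- utils::read.delim(
                file.path(cfg$out_dir, "read_truth.tsv"),
                stringsAsFactors = FALSE)
            readTruth$length <- readTruth$end - readTruth$start
            truthLabels <- labelGroundTruth(readTruth, truthIv,
                                            EvalParams(cfg$truth_cover_frac))
            predicted <- split(asn$read_id, asn$family_id)
        } else {
            truthLabels <- labelGroundTruth(res$sim$reads, res$sim$planted$truth,
                                            EvalParams(cfg$truth_cover_frac))
            predicted <- lapply(res$search, function(fr)
                fr$read_assignments$read_id)
        }
        metrics <- scorePredictions(predicted, truthLabels)
        utils::write.table(metrics, file.path(cfg$out_dir, "metrics.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res$metrics <- metrics
    }
    invisible(res)
}

#' @rdname runPipeline
#' @export
defaultRunConfig <- function() {
    list(out_dir = "graphrna_out", seed = 1L,
         reads = NULL, reads_format = "fastq", asqg = NULL, contigs = NULL,
         models = NULL,
         n_genomes = 5L, genome_len = 1500L, instances_per_genome = 4L,
         read_len = 100L, error_rate = 0.01, coverage = 10,
         abundance_mode = "uniform", stagger_ratio = 2, family_L = 150L,
         min_overlap = 45L, k = 21L, min_kmer_count = 1L,
         min_score = 45, min_aln_len = 100L,
         anchor_threshold = NULL, extension_slack = 0.10,
         identity_cutoff = 0.95, read_cover_frac = 0.60,
         truth_cover_frac = 0.60)
}
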