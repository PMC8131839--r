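#' Configuration for the synthetic community simulator
#'
#' Defaults follow the benchmark regime the pipeline targets: 100 nt reads
#' with a 1\% per-base substitution error rate, paired-end fragments, and
#' either uniform or geometrically staggered genome abundances.
#'
#' @param n_genomes Number of genomes.
#' @param genome_len Genome length in bases (recycled across genomes).
#' @param instances_per_genome Planted family instances per genome
#'   (recycled).
#' @param read_len Read length (default 100).
#' @param error_rate Per-base substitution probability (default 0.01);
#'   indels are not modelled so exact-overlap assembly stays exercisable.
#' @param coverage Expected mean sequencing depth; determines the fragment
#'   count unless \code{n_reads} is given.
#' @param n_reads Total read count override (reads, not fragments).
#' @param insert_mean,insert_sd Fragment-length distribution (clamped
#'   normal).
#' @param paired Emit read pairs from fragment ends (mate on the opposite
#'   strand), named \code{<id>/1} and \code{<id>/2}.
#' @param abundance_mode \code{"uniform"} or \code{"staggered"}.
#' @param stagger_ratio Fold-change between consecutive genome abundances.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return A validated list of class \code{SimConfig}.
#' @export
SimConfig <- function(n_genomes = 5L, genome_len = 1500L,
                      instances_per_genome = 4L, read_len = 100L,
                      error_rate = 0.01, coverage = 10, n_reads = NULL,
                      insert_mean = 220, insert_sd = 30, paired = TRUE,
                      abundance_mode = c("uniform", "staggered"),
                      stagger_ratio = 2, seed = 1L) {
    abundance_mode <- match.arg(abundance_mode)
    stopifnot(error_rate >= 0, error_rate < 1, read_len >= 1,
              all(read_len <= genome_len), n_genomes >= 1,
              abundance_mode != "staggered" || stagger_ratio > 1)
    structure(list(n_genomes = as.integer(n_genomes),
                   genome_len = as.integer(genome_len),
                   instances_per_genome = as.integer(instances_per_genome),
                   read_len = as.integer(read_len), error_rate = error_rate,
                   coverage = coverage, n_reads = n_reads,
                   insert_mean = insert_mean, insert_sd = insert_sd,
                   paired = isTRUE(paired), abundance_mode = abundance_mode,
                   stagger_ratio = stagger_ratio, seed = as.integer(seed)),
              class = "SimConfig")
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({ if (!is.null(old)) assign(".Random.seed", old, globalenv()) })
    set.seed(seed)
    force(expr)
}

.randomSeq <- function(n) paste0(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

#' Simulate a toy ncRNA family alignment and model
#'
#' Generates a conserved consensus with one hairpin stem, derives alignment
#' rows by per-column substitution, and builds the profile model. The
#' gathering threshold follows the curated-database convention — set so
#' that every known member of the family passes — applied to this
#' synthetic family's member population: the lowest model-global score
#' among \code{nMembers} sequences drawn from the model (scaled by
#' \code{ga_frac}). Sequences covering only part of the consensus score
#' well below it in model-global mode.
#'
#' @param L Consensus length.
#' @param stemLen Number of base pairs in the single hairpin stem.
#' @param nRows Alignment rows.
#' @param mutRate Per-column substitution rate between rows.
#' @param ga_frac Multiplier on the lowest member score (default 1: the
#'   threshold sits exactly at the weakest member).
#' @param nMembers Number of member draws defining the threshold.
#' @param seed Integer seed.
#' @param familyId Family identifier.
#' @return List: \code{model} (\linkS4class{ProfileModel}), \code{sto} (the
#'   alignment list as from [readStockholm()]).
#' @export
simulateFamily <- function(L = 150L, stemLen = 18L, nRows = 10L,
                           mutRate = 0.05, ga_frac = 1, nMembers = 50L,
                           seed = 1L, familyId = "toyfam") {
    stopifnot(L >= 4L * stemLen %/% 2L, stemLen >= 1L)
    .withSeed(seed, {
        loopStart <- (L - 2L * stemLen) %/% 2L + stemLen
        cons <- strsplit(.randomSeq(L), "")[[1]]
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ssc <- rep(".", L)
        stem5 <- seq(loopStart - stemLen + 1L, loopStart)
        loopLen <- 6L
        stem3 <- seq(loopStart + loopLen + 1L, loopStart + loopLen + stemLen)
        stopifnot(max(stem3) <= L)
        cons[stem3] <- comp[cons[rev(stem5)]]
        ssc[stem5] <- "<"; ssc[stem3] <- ">"
        rows <- vapply(seq_len(nRows), function(i) {
            r <- cons
            mut <- stats::runif(L) < mutRate
            r[mut] <- vapply(which(mut), function(q)
                sample(setdiff(.BASES, r[q]), 1L), "")
            # keep the stem paired: re-complement the 3' side
            r[stem3] <- comp[r[rev(stem5)]]
            paste0(r, collapse = "")
        }, "")
        names(rows) <- sprintf("row%02d", seq_len(nRows))
        sto <- list(aln = rows, ss_cons = paste0(ssc, collapse = ""),
                    ga = NA_real_)
        model <- buildProfileModel(sto, familyId = familyId, ga = 0)
        members <- vapply(seq_len(nMembers), function(i)
            sampleFromModel(model, seed = seed * 1000L + i), "")
        sc <- vapply(members, function(s)
            alignModel(model, s, mode = "global_in_model")$score, numeric(1))
        gaThreshold(model) <- ga_frac * min(sc)
        list(model = model, sto = sto)
    })
}

#' Plant family instances into random background genomes
#'
#' Backgrounds are i.i.d. uniform over \{A,C,G,T\}; per genome, the
#' configured number of model-sampled instances is inserted (replacing
#' background) at non-overlapping uniform positions on random strands, and
#' each insertion is recorded as a truth interval.
#'
#' @param models A \linkS4class{ProfileModel} or list of them, cycled over
#'   instances.
#' @param config A [SimConfig()] list.
#' @param seed Seed (defaults to \code{config$seed}).
#' @return List: \code{genomes} (named character), \code{truth}
#'   (interval \code{data.frame}).
#' @export
plantGenomes <- function(models, config = SimConfig(), seed = config$seed) {
    if (methods::is(models, "ProfileModel")) models <- list(models)
    .withSeed(seed, {
        glens <- rep_len(config$genome_len, config$n_genomes)
        ninst <- rep_len(config$instances_per_genome, config$n_genomes)
        genomes <- character(config$n_genomes)
        names(genomes) <- sprintf("g%02d", seq_len(config$n_genomes))
        truth <- list()
        mi <- 0L
        for (gi in seq_len(config$n_genomes)) {
            glen <- glens[gi]
            g <- strsplit(.randomSeq(glen), "")[[1]]
            occupied <- integer(0)
            for (ii in seq_len(ninst[gi])) {
                mi <- mi + 1L
                model <- models[[(mi - 1L) %% length(models) + 1L]]
                inst <- sampleFromModel(model)
                ilen <- nchar(inst)
                if (ilen > glen) stop("genome_len smaller than an instance")
                ok <- FALSE
                for (try in seq_len(200L)) {
                    s <- sample.int(glen - ilen + 1L, 1L) - 1L
                    if (!any(seq(s + 1L, s + ilen) %in% occupied)) {
                        ok <- TRUE
                        break
                    }
                }
                if (!ok) stop("could not place instance without overlap")
                strand <- sample(c("+", "-"), 1L)
                placed <- if (strand == "+") inst else revComp(inst)
                g[seq(s + 1L, s + ilen)] <- strsplit(placed, "")[[1]]
                occupied <- c(occupied, seq(s + 1L, s + ilen))
                truth[[length(truth) + 1L]] <- data.frame(
                    genome_id = names(genomes)[gi], start = s, end = s + ilen,
                    strand = strand, family_id = model@familyId,
                    stringsAsFactors = FALSE)
            }
            genomes[gi] <- paste0(g, collapse = "")
        }
        truthDf <- if (length(truth)) do.call(rbind, truth) else
            data.frame(genome_id = character(), start = integer(),
                       end = integer(), strand = character(),
                       family_id = character(), stringsAsFactors = FALSE)
        list(genomes = genomes, truth = truthDf)
    })
}

#' Geometrically staggered abundance fractions
#'
#' \code{abundance_i} proportional to \code{ratio^(n-1-i)} (the first genome
#' is the most abundant), normalised to sum 1.
#'
#' @param n Number of genomes.
#' @param ratio Fold-change between consecutive genomes (> 1).
#' @return Numeric vector of length \code{n} summing to 1.
#' @examples
#' staggeredAbundances(3, 2)  # 4/7, 2/7, 1/7
#' @export
staggeredAbundances <- function(n, ratio) {
    stopifnot(n >= 1, ratio > 1)
    w <- ratio^seq(n - 1, 0)
    w / sum(w)
}

#' Simulate error-bearing (paired-end) reads with truth intervals
#'
#' Fragments are drawn from genomes with probability proportional to
#' abundance x genome length; fragment length is a clamped normal; paired
#' reads come from the two fragment ends with the mate on the opposite
#' strand. Substitution errors are i.i.d. per base (uniform over the three
#' alternatives). Each read records its source interval for ground-truth
#' labelling.
#'
#' @param genomes Named character vector.
#' @param abundances Abundance fractions summing to 1.
#' @param config A [SimConfig()] list.
#' @param seed Seed (defaults to \code{config$seed + 1}).
#' @return A named \code{DNAStringSet} with metadata columns
#'   \code{mate_id}, \code{genome_id}, \code{start}, \code{end},
#'   \code{strand}.
#' @export
simulateReads <- function(genomes, abundances, config = SimConfig(),
                          seed = config$seed + 1L) {
    stopifnot(abs(sum(abundances) - 1) < 1e-8,
              length(abundances) == length(genomes))
    .withSeed(seed, {
        glens <- nchar(genomes)
        rl <- config$read_len
        nFrag <- if (!is.null(config$n_reads)) {
            as.integer(ceiling(config$n_reads / (if (config$paired) 2L else 1L)))
        } else {
            as.integer(round(config$coverage * sum(glens) /
                             (rl * (if (config$paired) 2L else 1L))))
        }
        w <- abundances * glens
        gidx <- sample.int(length(genomes), nFrag, replace = TRUE,
                           prob = w / sum(w))
        ids <- character(); seqs <- character(); mates <- character()
        gsrc <- character(); starts <- integer(); ends <- integer()
        strands <- character()
        emit <- function(id, seq, mate, g, s, e, st) {
            ids <<- c(ids, id); seqs <<- c(seqs, seq)
            mates <<- c(mates, mate); gsrc <<- c(gsrc, g)
            starts <<- c(starts, s); ends <<- c(ends, e)
            strands <<- c(strands, st)
        }
        addErrors <- function(s) {
            if (config$error_rate == 0) return(s)
            v <- strsplit(s, "")[[1]]
            mut <- stats::runif(length(v)) < config$error_rate
            if (any(mut))
                v[mut] <- vapply(which(mut), function(q)
                    sample(setdiff(.BASES, v[q]), 1L), "")
            paste0(v, collapse = "")
        }
        for (fi in seq_len(nFrag)) {
            gi <- gidx[fi]
            glen <- glens[gi]
            flen <- max(rl, min(glen,
                round(stats::rnorm(1, config$insert_mean, config$insert_sd))))
            fs <- sample.int(glen - flen + 1L, 1L) - 1L  # 0-based
            fstrand <- sample(c("+", "-"), 1L)
            gseq <- genomes[[gi]]
            if (config$paired) {
                # R1 from the fragment's 5' end on fstrand, R2 from the
                # other end on the opposite strand
                if (fstrand == "+") {
                    s1 <- fs; e1 <- fs + rl
                    s2 <- fs + flen - rl; e2 <- fs + flen
                    r1 <- substr(gseq, s1 + 1L, e1)
                    r2 <- revComp(substr(gseq, s2 + 1L, e2))
                    st1 <- "+"; st2 <- "-"
                } else {
                    s1 <- fs + flen - rl; e1 <- fs + flen
                    s2 <- fs; e2 <- fs + rl
                    r1 <- revComp(substr(gseq, s1 + 1L, e1))
                    r2 <- substr(gseq, s2 + 1L, e2)
                    st1 <- "-"; st2 <- "+"
                }
                base <- sprintf("r%06d", fi)
                emit(paste0(base, "/1"), addErrors(r1), paste0(base, "/2"),
                     names(genomes)[gi], s1, e1, st1)
                emit(paste0(base, "/2"), addErrors(r2), paste0(base, "/1"),
                     names(genomes)[gi], s2, e2, st2)
            } else {
                s1 <- fs; e1 <- fs + rl
                r1 <- substr(gseq, s1 + 1L, e1)
                if (fstrand == "-") r1 <- revComp(r1)
                emit(sprintf("r%06d", fi), addErrors(r1), NA_character_,
                     names(genomes)[gi], s1, e1, fstrand)
            }
        }
        reads <- Biostrings::DNAStringSet(seqs)
        names(reads) <- ids
        S4Vectors::mcols(reads) <- S4Vectors::DataFrame(
            mate_id = mates, genome_id = gsrc, start = starts, end = ends,
            strand = strands)
        reads
    })
}

#' Write a simulated dataset to disk
#'
#' Emits genome FASTA, reads (paired FASTQ \code{_1}/\code{_2} or a single
#' FASTQ), the truth-interval TSV, and a YAML manifest echoing the
#' configuration and seed for bit-identical re-runs.
#'
#' @param sim List with \code{genomes}, \code{truth} (from
#'   [plantGenomes()]) and \code{reads} (from [simulateReads()]).
#' @param dir Output directory (created if needed).
#' @param config The [SimConfig()] used.
#' @return Named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir, config) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(genomes = file.path(dir, "genomes.fasta"),
               truth = file.path(dir, "truth.tsv"),
               manifest = file.path(dir, "manifest.yaml"))
    writeSequences(sim$genomes, paths[["genomes"]], "fasta")
    writeIntervals(sim$truth, paths[["truth"]])
    reads <- sim$reads
    if (config$paired) {
        r1 <- reads[grepl("/1$", names(reads))]
        r2 <- reads[grepl("/2$", names(reads))]
        paths[["reads_1"]] <- file.path(dir, "reads_1.fastq")
        paths[["reads_2"]] <- file.path(dir, "reads_2.fastq")
        writeSequences(r1, paths[["reads_1"]], "fastq")
        writeSequences(r2, paths[["reads_2"]], "fastq")
    } else {
        paths[["reads"]] <- file.path(dir, "reads.fastq")
        writeSequences(reads, paths[["reads"]], "fastq")
    }
    truthCols <- S4Vectors::mcols(reads)
    utils::write.table(
        data.frame(read_id = names(reads), genome_id = truthCols$genome_id,
                   start = truthCols$start, end = truthCols$end,
                   strand = truthCols$strand, stringsAsFactors = FALSE),
        file.path(dir, "read_truth.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    paths[["read_truth"]] <- file.path(dir, "read_truth.tsv")
    yaml::write_yaml(unclass(config), paths[["manifest"]])
    invisible(paths)
}

#' Simulate a tiling read set with an engineered coverage dip
#'
#' Generates a random genome and error-free reads tiling it densely, except
#' at one engineered junction near the middle where the two flanking reads
#' overlap by only \code{dip_overlap} bases. With \code{min_overlap}
#' above \code{dip_overlap} the string graph necessarily splits into two
#' components there, while a de Bruijn graph with \code{k - 1 <=
#' dip_overlap} still bridges the junction, so the merged hybrid graph can
#' spell the genome. This is the canonical demonstration of why the two
#' graphs are merged.
#'
#' @param seed Integer seed.
#' @param genome_range Genome length range (sampled uniformly).
#' @param read_len Read length.
#' @param step Tiling step (true adjacent overlaps are
#'   \code{read_len - step}).
#' @param dip_overlap Overlap at the engineered junction.
#' @return List: \code{genome}, named \code{reads} (character), and the
#'   junction coordinate \code{dip_at}.
#' @export
simulateCoverageDip <- function(seed = 1L, genome_range = c(300L, 500L),
                                read_len = 80L, step = 40L,
                                dip_overlap = 16L) {
    .withSeed(seed, {
        glen <- sample(seq(genome_range[1L], genome_range[2L]), 1L)
        genome <- .randomSeq(glen)
        dip <- glen %/% 2L
        starts <- seq(1L, glen - read_len + 1L, by = step)
        ends <- starts + read_len - 1L
        iL <- max(which(ends <= dip + step))
        eL <- ends[iL]
        sR <- eL - dip_overlap + 1L
        startsR <- seq(sR, glen - read_len + 1L, by = step)
        if (max(startsR) + read_len - 1L < glen)
            startsR <- c(startsR, glen - read_len + 1L)
        starts <- c(starts[seq_len(iL)], startsR)
        reads <- substring(genome, starts, starts + read_len - 1L)
        names(reads) <- sprintf("r%02d", seq_along(reads))
        list(genome = genome, reads = reads, dip_at = eL)
    })
}
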