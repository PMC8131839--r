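test_that("planting is deterministic and records exact truth intervals", {
    fam <- smallFamily(seed = 81)
    cfg <- SimConfig(n_genomes = 2, genome_len = 400,
                     instances_per_genome = 2, seed = 810001)
    p1 <- plantGenomes(fam$model, cfg)
    p2 <- plantGenomes(fam$model, cfg)
    expect_identical(p1, p2)
    expect_equal(nrow(p1$truth), 4L)
    for (i in seq_len(nrow(p1$truth))) {
        tr <- p1$truth[i, ]
        planted <- substr(p1$genomes[[tr$genome_id]], tr$start + 1L, tr$end)
        expect_equal(nchar(planted), fam$model@L)
        # the planted strand carries a genuine high-scoring family instance
        expect_gte(alignModel(fam$model, planted)$score,
                   0.85 * gaThreshold(fam$model))
    }
    # zero instances: pure background with empty truth
    cfg0 <- SimConfig(n_genomes = 1, genome_len = 300,
                      instances_per_genome = 0, seed = 820001)
    p0 <- plantGenomes(fam$model, cfg0)
    expect_equal(nrow(p0$truth), 0L)
})

test_that("staggered abundances are geometric and normalised", {
    expect_equal(staggeredAbundances(3, 2), c(4, 2, 1) / 7)
    expect_equal(staggeredAbundances(1, 2), 1)
    for (n in c(2, 5, 9)) expect_equal(sum(staggeredAbundances(n, 1.7)), 1)
})

test_that("read simulation: determinism, error rate, abundance, mates", {
    fam <- smallFamily(seed = 83)
    cfg <- SimConfig(n_genomes = 2, genome_len = 1200,
                     instances_per_genome = 0, error_rate = 0.01,
                     coverage = 10, seed = 830001)
    pl <- plantGenomes(fam$model, cfg)
    r1 <- simulateReads(pl$genomes, c(0.5, 0.5), cfg)
    r2 <- simulateReads(pl$genomes, c(0.5, 0.5), cfg)
    expect_identical(as.character(r1), as.character(r2))
    # error-free reads are exact substrings of their source interval
    cfg0 <- SimConfig(n_genomes = 2, genome_len = 1200,
                      instances_per_genome = 0, error_rate = 0,
                      coverage = 4, seed = 840001)
    r0 <- simulateReads(pl$genomes, c(0.5, 0.5), cfg0)
    mc <- S4Vectors::mcols(r0)
    for (i in seq_along(r0)) {
        src <- substr(pl$genomes[[mc$genome_id[i]]], mc$start[i] + 1L,
                      mc$end[i])
        got <- as.character(r0[[i]])
        expect_true(got == src || got == revComp(src))
    }
    # mates cross-link and sit on opposite strands
    expect_true(all(mc$mate_id[match(mc$mate_id, names(r0))] == names(r0)))
    m1 <- match(mc$mate_id, names(r0))
    expect_true(all(mc$strand != mc$strand[m1]))
    # substitution count within 3 binomial SDs of the expectation
    nb <- sum(Biostrings::width(r1))
    exp_err <- nb * 0.01
    obs <- 0L
    mc1 <- S4Vectors::mcols(r1)
    for (i in seq_along(r1)) {
        src <- substr(pl$genomes[[mc1$genome_id[i]]], mc1$start[i] + 1L,
                      mc1$end[i])
        if (mc1$strand[i] == "-") src <- revComp(src)
        obs <- obs + sum(strsplit(as.character(r1[[i]]), "")[[1]] !=
                         strsplit(src, "")[[1]])
    }
    expect_lt(abs(obs - exp_err), 3 * sqrt(nb * 0.01 * 0.99) + 1)
    # degenerate abundances: all reads from genome 1
    rA <- simulateReads(pl$genomes, c(1, 0), cfg0)
    expect_true(all(S4Vectors::mcols(rA)$genome_id == names(pl$genomes)[1]))
    # abundance-weighted sampling matches expectation within 3 SDs
    cfgN <- SimConfig(n_genomes = 2, genome_len = 1200,
                      instances_per_genome = 0, error_rate = 0,
                      n_reads = 10000, seed = 850001)
    rN <- simulateReads(pl$genomes, c(0.8, 0.2), cfgN)
    n1 <- sum(S4Vectors::mcols(rN)$genome_id == names(pl$genomes)[1])
    expect_lt(abs(n1 / length(rN) - 0.8), 3 * sqrt(0.8 * 0.2 / length(rN)))
})

test_that("simulated truth labels agree with direct geometry", {
    fam <- smallFamily(seed = 86)
    cfg <- SimConfig(n_genomes = 2, genome_len = 600,
                     instances_per_genome = 2, error_rate = 0.01,
                     coverage = 8, seed = 860001)
    pl <- plantGenomes(fam$model, cfg)
    reads <- simulateReads(pl$genomes, c(0.5, 0.5), cfg)
    lab <- labelGroundTruth(reads, pl$truth)
    mc <- S4Vectors::mcols(reads)
    # independent overlap computation
    expected <- character()
    for (i in seq_along(reads)) {
        rl <- mc$end[i] - mc$start[i]
        for (j in seq_len(nrow(pl$truth))) {
            tr <- pl$truth[j, ]
            if (tr$genome_id != mc$genome_id[i]) next
            ov <- min(mc$end[i], tr$end) - max(mc$start[i], tr$start)
            if (ov > 0.6 * rl) expected <- c(expected, names(reads)[i])
        }
    }
    expect_setequal(lab[[fam$model@familyId]], unique(expected))
})

test_that("simulation writer emits the documented artifact set", {
    fam <- smallFamily(seed = 87)
    cfg <- SimConfig(n_genomes = 1, genome_len = 400,
                     instances_per_genome = 1, coverage = 4, seed = 870001)
    pl <- plantGenomes(fam$model, cfg)
    reads <- simulateReads(pl$genomes, 1, cfg)
    d <- tempfile()
    paths <- writeSimulation(list(genomes = pl$genomes, truth = pl$truth,
                                  reads = reads), d, cfg)
    expect_true(all(file.exists(paths)))
    back <- readSequences(paths[["reads_1"]], "fastq")
    expect_equal(length(back) + length(readSequences(paths[["reads_2"]],
                                                     "fastq")),
                 length(reads))
    tv <- readIntervals(paths[["truth"]])
    expect_equal(nrow(tv), 1L)
})

test_that("the coverage-dip generator engineers the intended junction", {
    for (seed in c(91, 92)) {
        fx <- simulateCoverageDip(seed)
        expect_identical(fx, simulateCoverageDip(seed))
        # every read is an exact genome substring
        for (r in fx$reads) expect_true(grepl(r, fx$genome, fixed = TRUE))
        # the two dip-flanking reads overlap by exactly 16
        sgp <- StringGraphParams(min_overlap = 20)
        sg <- condense(buildStringGraph(fx$reads,
                                        findReadOverlaps(fx$reads, sgp),
                                        sgp))
        expect_gte(nSegs(sg), 2L)
    }
})
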