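test_that("maximal suffix-prefix overlaps match a brute-force scan", {
    ov <- findReadOverlaps(c(r1 = "ACGTACGT", r2 = "TACGTTTT"),
                           StringGraphParams(min_overlap = 4))
    expect_equal(nrow(ov$overlaps), 1L)
    expect_equal(ov$overlaps$length, 5L)
    expect_equal(ov$overlaps$from, "r1")

    # reverse-complement duplicate is absorbed as a containment
    ov2 <- findReadOverlaps(c(a = "AAAA", b = "TTTT"),
                            StringGraphParams(min_overlap = 4))
    expect_equal(nrow(ov2$overlaps), 0L)
    expect_equal(ov2$containments$contained, "b")
    expect_equal(ov2$containments$orient, "-")

    # identical sequences: one read absorbed
    ov3 <- findReadOverlaps(c(a = "ACGT", b = "ACGT"),
                            StringGraphParams(min_overlap = 4))
    expect_equal(ov3$containments$contained, "b")

    # brute force over random read sets: every reported overlap is real and
    # maximal; every real overlap >= min_overlap is reported
    set.seed(7)
    for (trial in 1:5) {
        g <- randSeq(120)
        reads <- tileReads(g, 30, sample(10:20, 1))
        p <- StringGraphParams(min_overlap = 5, use_revcomp = FALSE)
        ov <- findReadOverlaps(reads, p)$overlaps
        brute <- list()
        for (a in names(reads)) for (b in names(reads)) {
            if (a == b) next
            sa <- reads[[a]]; sb <- reads[[b]]
            lmax <- min(nchar(sa), nchar(sb)) - 1L
            for (l in lmax:5) {
                if (substr(sa, nchar(sa) - l + 1, nchar(sa)) ==
                    substr(sb, 1, l)) {
                    brute[[paste(a, b)]] <- l
                    break
                }
            }
        }
        got <- setNames(ov$length, paste(ov$from, ov$to))
        ctd <- findReadOverlaps(reads, p)$containments$contained
        bruteFree <- brute[!vapply(strsplit(names(brute), " "), function(ab)
            any(ab %in% ctd), logical(1))]
        expect_setequal(names(got), names(bruteFree))
        for (k in names(got)) expect_equal(unname(got[[k]]), bruteFree[[k]])
    }
})

test_that("string graph of chained reads condenses to the genome", {
    set.seed(11)
    g <- randSeq(60)
    reads <- c(r1 = substr(g, 1, 30), r2 = substr(g, 16, 45),
               r3 = substr(g, 31, 60))
    p <- StringGraphParams(min_overlap = 10)
    sg <- buildStringGraph(reads, findReadOverlaps(reads, p), p)
    expect_equal(nSegs(sg), 3L)
    expect_equal(nrow(segLinks(sg)), 2L)
    cg <- condense(sg)
    expect_equal(nSegs(cg), 1L)
    expect_true(as.character(segSeqs(cg))[[1]] %in% c(g, revComp(g)))
    # all three reads are members of the unitig
    expect_setequal(segMembers(cg)[[1]]$read_id, names(reads))
    # single read stays an isolated edge
    one <- buildStringGraph(c(x = "ACGTTGCA"),
                            findReadOverlaps(c(x = "ACGTTGCA"), p), p)
    expect_equal(nSegs(one), 1L)
    expect_equal(nrow(segLinks(one)), 0L)
})

test_that("transitive reduction preserves spelled maximal walks", {
    set.seed(13)
    for (trial in 1:6) {
        g <- randSeq(sample(80:140, 1))
        reads <- tileReads(g, 40, sample(8:14, 1))
        if (length(reads) > 10) reads <- reads[1:10]
        p0 <- StringGraphParams(min_overlap = 8,
                                do_transitive_reduction = FALSE)
        p1 <- StringGraphParams(min_overlap = 8,
                                do_transitive_reduction = TRUE)
        ov <- findReadOverlaps(reads, p0)
        g0 <- buildStringGraph(reads, ov, p0)
        g1 <- buildStringGraph(reads, ov, p1)
        expect_lte(nrow(segLinks(g1)), nrow(segLinks(g0)))
        spell <- function(gr) {
            w <- allWalks(gr, maxDepth = length(reads))
            sort(unique(vapply(w, function(x)
                spellWalk(gr, x$seg, x$orient), "")))
        }
        # maximal walks of the reduced graph spell the same genome
        expect_true(spellsSequence(g1, g) || spellsSequence(g1, revComp(g)))
        # reduced spellings are a subset of unreduced ones
        expect_true(all(spell(g1) %in% spell(g0)))
    }
})

test_that("condensation is idempotent and stops at branches", {
    # branch: two reads extend the same prefix differently
    reads <- c(a = "AAACCCGGGTT", b = "GGGTTACACAC", c = "GGGTTGTGTGT")
    p <- StringGraphParams(min_overlap = 5, use_revcomp = FALSE)
    sg <- buildStringGraph(reads, findReadOverlaps(reads, p), p)
    cg <- condense(sg)
    expect_equal(nSegs(cg), 3L)  # branch prevents merging
    cg2 <- condense(cg)
    expect_equal(nSegs(cg2), nSegs(cg))
    expect_setequal(unname(as.character(segSeqs(cg2))),
                    unname(as.character(segSeqs(cg))))
})

test_that("terminal edges report which end is open; cycles have none", {
    g <- AssemblyGraph(c(a = "ACGTAC", b = "TACGGA", c = "GGACCT"),
        data.frame(from = c("a", "b"), from_orient = "+",
                   to = c("b", "c"), to_orient = "+", ovl = 3L))
    te <- terminalEdges(g)
    expect_setequal(te$seg_id, c("a", "c"))
    expect_equal(te$open_end[te$seg_id == "a"], "head")
    expect_equal(te$open_end[te$seg_id == "c"], "tail")
    # isolated edge: both ends open
    iso <- AssemblyGraph(c(z = "ACGT"))
    expect_equal(terminalEdges(iso)$open_end, "both")
    # a 3-cycle has no open ends
    cyc <- AssemblyGraph(c(a = "AACC", b = "CCGG", c = "GGAA"),
        data.frame(from = c("a", "b", "c"), from_orient = "+",
                   to = c("b", "c", "a"), to_orient = "+", ovl = 2L))
    expect_equal(nrow(terminalEdges(cyc)), 0L)
})

test_that("error-free tiling reads condense to a single genome edge", {
    set.seed(17)
    for (trial in 1:5) {
        g <- randSeq(sample(150:300, 1))
        reads <- tileReads(g, 50, 25)
        p <- StringGraphParams(min_overlap = 20)
        cg <- condense(buildStringGraph(reads, findReadOverlaps(reads, p), p))
        expect_true(spellsSequence(cg, g))
    }
})

test_that("ASQG import and GFA export round-trip graph structure", {
    asqg <- tempfile(fileext = ".asqg")
    writeLines(c("HT\tVN:i:1",
                 "VT\tr1\tACGTACGT",
                 "VT\tr2\tTACGTTTT",
                 "ED\tr1 r2 3 7 8 0 4 8 0 0"), asqg)
    g <- readASQG(asqg)
    expect_equal(nSegs(g), 2L)
    expect_equal(segLinks(g)$ovl, 5L)
    expect_equal(spellWalk(g, c("r1", "r2")), "ACGTACGTTTT")
    gfa <- tempfile(fileext = ".gfa")
    writeGFA(g, gfa)
    lines <- readLines(gfa)
    expect_equal(sum(startsWith(lines, "S")), 2L)
    expect_equal(sum(startsWith(lines, "L")), 1L)
    expect_true(any(grepl("5M", lines)))
})

test_that("miniature two-graph toy: overlap graph splits where k-mers connect", {
    fx <- figToyReads()
    p <- StringGraphParams(min_overlap = 4)
    sg <- condense(buildStringGraph(fx$reads, findReadOverlaps(fx$reads, p),
                                    p))
    # sub-minimum overlaps leave the string graph unable to spell the genome
    expect_false(spellsSequence(sg, fx$genome))
    # the 3-mer graph of the same reads still contains a spelling walk
    dbg <- buildDeBruijnGraph(fx$reads,
                              DeBruijnParams(k = 3, use_revcomp = FALSE))
    expect_true(spellsSequence(dbg, fx$genome))
})
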