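test_that("k-mer graph construction matches hand enumeration", {
    # without strand folding: ACGTA at k=3 is the path ACG -> CGT -> GTA
    g <- buildDeBruijnGraph(c(r1 = "ACGTA"),
                            DeBruijnParams(k = 3, use_revcomp = FALSE))
    expect_setequal(as.character(segSeqs(g)), c("ACG", "CGT", "GTA"))
    expect_equal(nrow(segLinks(g)), 2L)
    expect_true(spellsSequence(g, "ACGTA"))

    # homopolymer read: a self-loop on vertex AA
    h <- buildDeBruijnGraph(c(r1 = "AAAA"),
                            DeBruijnParams(k = 3, use_revcomp = FALSE))
    expect_equal(nSegs(h), 1L)
    lk <- segLinks(h)
    expect_equal(lk$from, lk$to)

    # reads sharing an internal k-mer form one branched graph
    b <- buildDeBruijnGraph(c(r1 = "AACGTT", r2 = "GACGTA"),
                            DeBruijnParams(k = 4, use_revcomp = FALSE))
    pre <- substr(as.character(segSeqs(b)), 1, 3)
    expect_true(any(duplicated(pre)) ||
                any(duplicated(substr(as.character(segSeqs(b)), 2, 4))))

    # multiplicity filter removes singletons
    f <- buildDeBruijnGraph(c(r1 = "ACGTACGT", r2 = "ACGTAAAA"),
                            DeBruijnParams(k = 5, min_kmer_count = 2,
                                           use_revcomp = FALSE))
    expect_equal(unname(as.character(segSeqs(f))), "ACGTA")
})

test_that("k-mer accounting: sum of contig lengths minus (k-1) equals k-mer count", {
    set.seed(5)
    for (trial in 1:5) {
        g <- randSeq(200)
        reads <- tileReads(g, 40, 15)
        k <- 13
        dbg <- buildDeBruijnGraph(reads, DeBruijnParams(k = k))
        ct <- extractContigs(dbg)
        expect_equal(sum(nchar(ct$seq) - (k - 1)), nSegs(dbg))
        expect_true(all(nchar(ct$seq) >= k))
    }
})

test_that("full tiling coverage with unique k-mers yields the genome contig", {
    set.seed(6)
    g <- randSeq(250)
    reads <- tileReads(g, 50, 20)
    ct <- extractContigs(buildDeBruijnGraph(reads, DeBruijnParams(k = 15)))
    expect_equal(nrow(ct), 1L)
    expect_true(ct$seq %in% c(g, revComp(g)))
})

test_that("verification flags coverage holes and respects chimeric junctions", {
    # a contig equal to a read is verified
    ct <- data.frame(contig_id = "c1", seq = "ACGTACGTACGT", verified = NA)
    expect_true(verifyContigs(ct, c(r = "ACGTACGTACGT"))$verified)
    # empty read set: unverified
    expect_false(verifyContigs(ct, character(0))$verified)
    # chimeric junction: two reads share k-1 = 4 bases; the spelled contig
    # crosses a junction no single read covers
    r1 <- "AAATTCCGG"; r2 <- "CCGGTTAAA"
    dbg <- buildDeBruijnGraph(c(a = r1, b = r2),
                              DeBruijnParams(k = 5, use_revcomp = FALSE))
    ct2 <- extractContigs(dbg)
    chim <- ct2[nchar(ct2$seq) == 14, , drop = FALSE]
    expect_equal(nrow(chim), 1L)  # spells r1 + r2 without shared genome
    v <- verifyContigs(chim, c(a = r1, b = r2), max_mismatch_frac = 0)
    # junction base(s) between the reads are covered by both clipped reads
    # here, so construct the uncovered case explicitly: coverage counting
    # is checked against brute force instead
    cov <- integer(nchar(chim$seq))
    for (r in c(r1, r2, revComp(r1), revComp(r2))) {
        for (s in seq_len(nchar(chim$seq) - nchar(r) + 1)) {
            if (substr(chim$seq, s, s + nchar(r) - 1) == r)
                cov[s:(s + nchar(r) - 1)] <- cov[s:(s + nchar(r) - 1)] + 1
        }
        for (l in seq_len(nchar(r) - 1)) {
            if (substr(chim$seq, 1, l) ==
                substr(r, nchar(r) - l + 1, nchar(r)))
                cov[1:l] <- cov[1:l] + 1
            if (substr(chim$seq, nchar(chim$seq) - l + 1,
                       nchar(chim$seq)) == substr(r, 1, l))
                cov[(nchar(chim$seq) - l + 1):nchar(chim$seq)] <-
                    cov[(nchar(chim$seq) - l + 1):nchar(chim$seq)] + 1
        }
    }
    expect_equal(unname(v$verified), all(cov > 0))
})

test_that("mismatch-tolerant verification covers error-bearing reads", {
    set.seed(8)
    g <- randSeq(300)
    reads <- tileReads(g, 60, 20)
    # plant one substitution in every read
    mut <- vapply(reads, function(r) {
        p <- sample(10:50, 1)
        substr(r, p, p) <- sample(setdiff(BASES, substr(r, p, p)), 1)
        r
    }, "")
    names(mut) <- names(reads)
    ct <- data.frame(contig_id = "c1", seq = g, verified = NA)
    expect_false(verifyContigs(ct, mut, max_mismatch_frac = 0)$verified)
    expect_true(verifyContigs(ct, mut, max_mismatch_frac = 0.05)$verified)
})
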