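test_that("recruitment applies the three acceptance rules inclusively", {
    set.seed(51)
    contig <- randSeq(400)
    # terminal whose open tail end matches contig[101..200] exactly
    goodTail <- paste0(randSeq(0), substr(contig, 101, 200))
    g <- AssemblyGraph(c(t1 = goodTail))
    te <- terminalEdges(g)
    ct <- data.frame(contig_id = "c1", seq = contig, verified = TRUE)
    rec <- recruitAlignments(g, te, ct, MergeParams())
    # exact 100-base alignment: score 100 >= 45, length 100 >= 100, flush
    expect_true(nrow(rec) >= 1)
    expect_true(all(rec$score >= 45 & rec$aln_len >= 100))

    # score 45 at length 50 is rejected (length rule)
    short <- substr(contig, 101, 150)
    g2 <- AssemblyGraph(c(t2 = short))
    rec2 <- recruitAlignments(g2, terminalEdges(g2), ct, MergeParams())
    expect_equal(nrow(rec2), 0L)

    # clipping at the open end is rejected even at high score
    clipped <- paste0(substr(contig, 101, 220), "GGGGGGGGGG")
    mism <- paste0("GGGGGGGGGG", substr(contig, 101, 220))
    gg <- AssemblyGraph(c(tc = clipped, tm = mism))
    # make both ends of each segment open (isolated): tc aligns flush at
    # its head but clipped at its tail; tm the reverse
    rec3 <- recruitAlignments(gg, terminalEdges(gg), ct, MergeParams())
    for (i in seq_len(nrow(rec3))) {
        r <- rec3[i, ]
        # the recruited end must correspond to the flush side
        expect_true((r$seg_id == "tc" && r$end == "L" && r$orientation == "+") ||
                    (r$seg_id == "tc" && r$end == "R" && r$orientation == "-") ||
                    (r$seg_id == "tm" && r$end == "R" && r$orientation == "+") ||
                    (r$seg_id == "tm" && r$end == "L" && r$orientation == "-"))
    }

    # boundary case: score exactly 45 with aligned length exactly 100 is
    # retained (inclusive thresholds). Build a 100-base end region whose
    # interior carries enough mismatches to score 45 while local alignment
    # keeps the full span: 11 mismatches spread every 8 bases score
    # 89 - 44 = 45.
    qry <- substr(contig, 101, 200)
    pos <- seq(8, 88, by = 8)
    for (p in pos) substr(qry, p, p) <- setdiff(BASES, substr(qry, p, p))[1]
    a <- localAlign(qry, contig, MergeParams(), both_strands = FALSE)
    expect_equal(a$score, 45)
    expect_equal(a$query_span, c(0, 100))
    g4 <- AssemblyGraph(c(t4 = qry))
    rec4 <- recruitAlignments(g4, terminalEdges(g4), ct, MergeParams())
    expect_true(nrow(rec4) >= 1)
    expect_true(any(rec4$score == 45 & rec4$aln_len == 100))
})

test_that("merge actions: connect, extend, isolate; originals untouched", {
    set.seed(52)
    genome <- randSeq(500)
    left <- substr(genome, 1, 180)
    right <- substr(genome, 321, 500)
    sg <- AssemblyGraph(c(L = left, R = right), graphType = "string")
    contig <- substr(genome, 51, 450)
    ct <- data.frame(contig_id = "c1", seq = contig, verified = TRUE)
    rec <- recruitAlignments(sg, terminalEdges(sg), ct, MergeParams())
    hy <- mergeGraphs(sg, ct, rec, MergeParams())
    rep <- hy@meta$mergeReport
    expect_true("connect" %in% rep$action)
    # pre-existing labels survive verbatim
    expect_true(all(c(left, right) %in% as.character(segSeqs(hy))))
    # the hybrid graph now spells the stretch the string graph could not
    expect_true(spellsSequence(hy, genome))
    expect_false(spellsSequence(sg, genome))

    # a contig matching only one open end extends it with its overhang
    overhang <- paste0(substr(genome, 381, 500), randSeq(80))
    ct2 <- data.frame(contig_id = "c2", seq = overhang, verified = TRUE)
    rec2 <- recruitAlignments(sg, terminalEdges(sg), ct2, MergeParams())
    hy2 <- mergeGraphs(sg, ct2, rec2, MergeParams())
    expect_true("extend" %in% hy2@meta$mergeReport$action)
    expect_true(spellsSequence(hy2, paste0(right, substr(overhang, 121, 200))))

    # an unrelated contig is retained isolated
    lone <- randSeq(150)
    ct3 <- data.frame(contig_id = "c3", seq = lone, verified = TRUE)
    rec3 <- recruitAlignments(sg, terminalEdges(sg), ct3, MergeParams())
    hy3 <- mergeGraphs(sg, ct3, rec3, MergeParams())
    expect_equal(hy3@meta$mergeReport$action, "isolate")
    expect_true(lone %in% as.character(segSeqs(hy3)))

    # unverified contigs never participate
    ct4 <- data.frame(contig_id = "c4", seq = contig, verified = FALSE)
    rec4 <- recruitAlignments(sg, terminalEdges(sg), ct4, MergeParams())
    expect_equal(nrow(rec4), 0L)
    hy4 <- mergeGraphs(sg, ct4, rec4, MergeParams())
    expect_equal(nSegs(hy4), 2L)
})

test_that("zero-length connecting interval yields a direct junction", {
    set.seed(53)
    genome <- randSeq(400)
    left <- substr(genome, 1, 200)
    right <- substr(genome, 201, 400)
    sg <- AssemblyGraph(c(L = left, R = right), graphType = "string")
    ct <- data.frame(contig_id = "c1", seq = substr(genome, 81, 320),
                     verified = TRUE)
    rec <- recruitAlignments(sg, terminalEdges(sg), ct, MergeParams())
    hy <- mergeGraphs(sg, ct, rec, MergeParams())
    expect_true(spellsSequence(hy, genome))
    # no connector segment was needed: adjacent spans joined directly
    expect_equal(nSegs(hy), 2L)
})

test_that("string graph stays a label-subgraph of the hybrid over random dips", {
    for (seed in 1:5) {
        fx <- simulateCoverageDip(seed)
        sgp <- StringGraphParams(min_overlap = 20)
        sg <- condense(buildStringGraph(fx$reads,
                                        findReadOverlaps(fx$reads, sgp), sgp))
        ct <- verifyContigs(extractContigs(buildDeBruijnGraph(
            fx$reads, DeBruijnParams(k = 15))), fx$reads)
        rec <- recruitAlignments(sg, terminalEdges(sg), ct, MergeParams())
        hy <- mergeGraphs(sg, ct, rec, MergeParams())
        expect_true(all(as.character(segSeqs(sg)) %in%
                        as.character(segSeqs(hy))))
        lk1 <- segLinks(sg); lk2 <- segLinks(hy)
        key <- function(l) paste(l$from, l$from_orient, l$to, l$to_orient,
                                 l$ovl)
        expect_true(all(key(lk1) %in% key(lk2)))
    }
})
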