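test_that("SCFG alignment equals exhaustive parse maximisation (small cases)", {
    set.seed(31)
    for (trial in 1:8) {
        L <- sample(3:8, 1)
        nRows <- 6
        cons <- randSeq(L)
        rows <- vapply(seq_len(nRows), function(i) {
            v <- strsplit(cons, "")[[1]]
            mut <- runif(L) < 0.2
            v[mut] <- sample(BASES, sum(mut), replace = TRUE)
            paste0(v, collapse = "")
        }, "")
        names(rows) <- paste0("r", seq_len(nRows))
        # random nested structure: an outer pair plus (if room) an inner one
        ss <- rep(".", L)
        if (L >= 4 && trial %% 2 == 0) { ss[1] <- "<"; ss[L] <- ">" }
        if (L >= 7 && trial %% 3 == 0) { ss[2] <- "("; ss[4] <- ")" }
        m <- buildProfileModel(list(aln = rows,
                                    ss_cons = paste0(ss, collapse = ""),
                                    ga = 0))
        for (tl in c(1, 4, sample(5:12, 1))) {
            tgt <- randSeq(tl)
            for (mode in c("local_in_model", "global_in_model")) {
                expect_equal(alignModel(m, tgt, mode = mode)$score,
                             oracleModelScore(m, tgt, mode = mode),
                             tolerance = 1e-9,
                             info = paste("trial", trial, "mode", mode))
            }
        }
    }
})

test_that("multiloop structures (bifurcation) score like the oracle", {
    sto <- list(aln = c(a = "GGAACCGGTTCC", b = "GGAACCGGTTCC",
                        c = "GGATCCGGATCC"),
                ss_cons = "<<..>><<..>>", ga = 0)
    m <- buildProfileModel(sto)
    set.seed(32)
    for (i in 1:6) {
        tgt <- if (i <= 2) "GGAACCGGTTCC" else randSeq(sample(4:12, 1))
        for (mode in c("local_in_model", "global_in_model"))
            expect_equal(alignModel(m, tgt, mode = mode)$score,
                         oracleModelScore(m, tgt, mode = mode),
                         tolerance = 1e-9)
    }
})

test_that("score is invariant under target reverse complement", {
    fam <- smallFamily(seed = 41)
    set.seed(410001)
    for (i in 1:5) {
        tgt <- paste0(randSeq(10), sampleFromModel(fam$model, seed = i),
                      randSeq(10))
        h1 <- alignModel(fam$model, tgt)
        h2 <- alignModel(fam$model, revComp(tgt))
        expect_equal(h1$score, h2$score, tolerance = 1e-9)
        expect_false(h1$strand == h2$strand)
        # spans map to the same forward interval
        expect_equal(h1$seq_span,
                     c(nchar(tgt) - h2$seq_span[2],
                       nchar(tgt) - h2$seq_span[1]))
    }
})

test_that("a pair-free model reduces to profile alignment", {
    set.seed(43)
    rows <- vapply(1:8, function(i) randSeq(10), "")
    names(rows) <- paste0("r", 1:8)
    m <- buildProfileModel(list(aln = rows, ss_cons = strrep(".", 10),
                                ga = 0))
    # independent oracle: plain profile DP with linear gaps (global in
    # model, local in target, one strand)
    profDP <- function(model, tt) {
        L <- model@L; T <- nchar(tt)
        tb <- match(strsplit(tt, "")[[1]], BASES)
        best <- -Inf
        for (x in 0:T) {
            # D[i][y]: cols 1..i consumed, target x..y used, y varies
            D <- matrix(-Inf, L + 1, T + 1)
            D[1, (x:T) + 1] <- model@insertPenalty * ((x:T) - x)
            for (i in seq_len(L)) {
                for (y in x:T) {
                    o <- D[i, y + 1] + model@gapPenalty
                    if (y > x) {
                        o <- max(o, D[i, y] + model@singleEmit[tb[y], i])
                        o <- max(o, D[i + 1, y] + model@insertPenalty)
                    }
                    D[i + 1, y + 1] <- o
                }
            }
            best <- max(best, max(D[L + 1, ]))
        }
        best
    }
    for (i in 1:4) {
        tgt <- randSeq(sample(6:14, 1))
        expect_equal(alignModel(m, tgt, mode = "global_in_model")$score,
                     max(profDP(m, tgt), profDP(m, revComp(tgt))),
                     tolerance = 1e-9)
    }
})

test_that("model-sampled sequences outscore length-matched background", {
    fam <- smallFamily(seed = 44)
    set.seed(987654)
    sScores <- vapply(1:40, function(i)
        alignModel(fam$model, sampleFromModel(fam$model, seed = i))$score,
        numeric(1))
    bScores <- vapply(1:40, function(i)
        alignModel(fam$model, randSeq(fam$model@L))$score, numeric(1))
    expect_gt(mean(sScores), mean(bScores))
    expect_gt(min(sScores), mean(bScores))
})

test_that("edge scanning reports planted hits with correct spans", {
    fam <- smallFamily(seed = 45)
    model <- fam$model
    set.seed(456789)
    inst <- sampleFromModel(model, seed = 9)
    gdata <- c(e1 = paste0(randSeq(40), inst, randSeq(40)),
               e2 = randSeq(100),
               e3 = paste0(randSeq(30),
                           revComp(substr(inst, 1, nchar(inst) %/% 2)),
                           randSeq(30)))
    g <- AssemblyGraph(gdata)
    hits <- scanEdges(model, g, threshold = 0.4 * gaThreshold(model))
    expect_true("e1" %in% hits$seg_id)
    full <- hits[hits$seg_id == "e1", ]
    expect_equal(full$m_start, 0L)
    expect_equal(full$m_end, model@L)
    expect_lt(abs(full$s_start - 40), 6)
    # half-planted edge, if detected, is found on the minus strand
    if ("e3" %in% hits$seg_id)
        expect_equal(hits$strand[hits$seg_id == "e3"], "-")
    # unrelated edge stays silent at a high threshold
    none <- scanEdges(model, AssemblyGraph(c(x = randSeq(150))),
                      threshold = gaThreshold(model))
    expect_equal(nrow(none), 0L)
})
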