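# Shared fixtures built in code at test time.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste0(sample(BASES, n, replace = TRUE), collapse = "")

# small, well-conserved hairpin family for search tests (cheap to scan,
# with a clear member/background score margin)
smallFamily <- function(seed = 3L, L = 60L) {
    simulateFamily(L = L, stemLen = 8L, nRows = 20L, mutRate = 0.03,
                   seed = seed, familyId = "fam")
}

# error-free reads tiling a genome with constant step
tileReads <- function(genome, read_len, step) {
    starts <- seq(1L, nchar(genome) - read_len + 1L, by = step)
    if (max(starts) + read_len - 1L < nchar(genome))
        starts <- c(starts, nchar(genome) - read_len + 1L)
    reads <- substring(genome, starts, starts + read_len - 1L)
    names(reads) <- sprintf("t%03d", seq_along(reads))
    reads
}

# a literal miniature of the two-graphs toy: six short reads joined only
# by overlaps below min_overlap, so the string graph splits while every
# genome 3-mer stays covered
figToyReads <- function() {
    genome <- "GATTACAGGCTTGCAACTTCCAGTCAGATCGTAAG"
    starts <- c(1, 6, 11, 17, 23, 28)
    lens <- c(8, 8, 9, 9, 8, 8)
    reads <- substring(genome, starts, starts + lens - 1)
    names(reads) <- sprintf("f%d", seq_along(reads))
    list(genome = genome, reads = reads)
}

# tiny hybrid-search fixture: genome with one planted instance; variants add
# a coverage dip or an exact repeat to shape the graph
searchFixture <- function(seed, kind = c("plain", "dip", "repeat"),
                          fam = smallFamily()) {
    kind <- match.arg(kind)
    set.seed(seed)
    model <- fam$model
    inst <- sampleFromModel(model, seed = seed + 500L)
    glen <- 220L
    g <- randSeq(glen)
    at <- sample(40:(glen - nchar(inst) - 40), 1)
    substr(g, at + 1L, at + nchar(inst)) <- inst
    if (kind == "repeat") {
        rep40 <- randSeq(30L)
        substr(g, 5L, 34L) <- rep40
        substr(g, glen - 33L, glen - 4L) <- rep40
    }
    if (kind == "dip") {
        reads <- character(); starts <- integer()
        pos <- 1L
        dipDone <- FALSE
        while (pos <= glen - 45L + 1L) {
            starts <- c(starts, pos)
            nxt <- pos + 22L
            if (!dipDone && pos + 45L > glen %/% 2L) {
                nxt <- pos + 45L - 10L  # overlap 10 < min_overlap
                dipDone <- TRUE
            }
            pos <- nxt
        }
        starts <- unique(c(starts, glen - 45L + 1L))
        reads <- substring(g, starts, pmin(starts + 44L, glen))
        names(reads) <- sprintf("t%03d", seq_along(reads))
    } else {
        reads <- tileReads(g, 45L, 22L)
    }
    list(genome = g, reads = reads, model = model,
         instance_at = c(at, at + nchar(inst)))
}

# small-parameter profiles for toy graphs
toySG <- StringGraphParams(min_overlap = 20, do_transitive_reduction = TRUE)
toyDBG <- DeBruijnParams(k = 11, min_kmer_count = 1)
toyMerge <- MergeParams(min_score = 20, min_aln_len = 20, max_query_tail = 200)
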