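# Independent reference implementations used to check the package's
# dynamic programs and heuristics.

# --- local alignment -------------------------------------------------------
# Top-down memoised recursion over alignment endings; state M = last column
# is a substitution, E = gap in query (consumes target), F = gap in target.
# Gap of length g costs gap_open + g * gap_extend (first base pays both).
oracleLocalAlign <- function(q, t, match = 1, mismatch = -4, gap_open = -6,
                             gap_extend = -1) {
    n <- nchar(q); m <- nchar(t)
    qs <- strsplit(q, "")[[1]]; ts <- strsplit(t, "")[[1]]
    memo <- new.env(parent = emptyenv())
    M <- function(i, j) {
        if (i == 0 || j == 0) return(-Inf)
        key <- paste0("M", i, ",", j)
        v <- memo[[key]]
        if (!is.null(v)) return(v)
        s <- if (qs[i] == ts[j] && qs[i] != "N") match else mismatch
        v <- s + max(0, M(i - 1, j - 1), E(i - 1, j - 1), F(i - 1, j - 1))
        memo[[key]] <- v
        v
    }
    E <- function(i, j) {
        if (j == 0) return(-Inf)
        key <- paste0("E", i, ",", j)
        v <- memo[[key]]
        if (!is.null(v)) return(v)
        v <- max(M(i, j - 1) + gap_open + gap_extend,
                 E(i, j - 1) + gap_extend)
        memo[[key]] <- v
        v
    }
    F <- function(i, j) {
        if (i == 0) return(-Inf)
        key <- paste0("F", i, ",", j)
        v <- memo[[key]]
        if (!is.null(v)) return(v)
        v <- max(M(i - 1, j) + gap_open + gap_extend,
                 F(i - 1, j) + gap_extend)
        memo[[key]] <- v
        v
    }
    best <- 0
    for (i in seq_len(n)) for (j in seq_len(m))
        best <- max(best, M(i, j))
    best
}

# --- model alignment -------------------------------------------------------
# Memoised recursion over (model interval, target interval) following the
# grammar definition directly (no guide-tree compilation). Peeling
# precedence must match the engine: left column unpaired; ends paired
# together; right column unpaired; otherwise bifurcate at the left
# column's partner.
oracleModelScore <- function(model, target,
                             mode = c("local_in_model", "global_in_model")) {
    mode <- match.arg(mode)
    L <- model@L
    partner <- integer(L)
    pr <- model@pairs
    pairRow <- integer(L)
    if (nrow(pr) > 0L) {
        partner[pr[, 1]] <- pr[, 2]
        partner[pr[, 2]] <- pr[, 1]
        pairRow[pr[, 1]] <- seq_len(nrow(pr))
    }
    gp <- model@gapPenalty; ip <- model@insertPenalty
    oneStrand <- function(tt) {
        T <- nchar(tt)
        tb <- match(strsplit(tt, "")[[1]], BASES)  # NA for N
        eS <- function(c, p) {
            if (is.na(tb[p])) return(-2)
            model@singleEmit[tb[p], c]
        }
        eP <- function(c, p1, p2) {
            if (is.na(tb[p1]) || is.na(tb[p2])) return(-4)
            model@pairEmit[(tb[p1] - 1) * 4 + tb[p2], pairRow[c]]
        }
        memo <- new.env(parent = emptyenv())
        sc <- function(i, j, x, y) {  # model cols i..j, target (x, y], 0-based
            if (i > j) return(ip * (y - x))
            key <- paste(i, j, x, y)
            v <- memo[[key]]
            if (!is.null(v)) return(v)
            opts <- numeric()
            if (partner[i] == 0) {
                opts <- c(opts, gp + sc(i + 1, j, x, y))
                if (y > x) opts <- c(opts,
                    eS(i, x + 1) + sc(i + 1, j, x + 1, y),
                    ip + sc(i, j, x + 1, y))
            } else if (partner[i] == j) {
                opts <- c(opts, 2 * gp + sc(i + 1, j - 1, x, y))
                if (y - x >= 2) opts <- c(opts,
                    eP(i, x + 1, y) + sc(i + 1, j - 1, x + 1, y - 1))
                if (y > x) opts <- c(opts,
                    ip + sc(i, j, x + 1, y), ip + sc(i, j, x, y - 1))
            } else if (partner[j] == 0) {
                opts <- c(opts, gp + sc(i, j - 1, x, y))
                if (y > x) opts <- c(opts,
                    eS(j, y) + sc(i, j - 1, x, y - 1),
                    ip + sc(i, j, x, y - 1))
            } else {
                k <- partner[i]
                for (m in x:y)
                    opts <- c(opts, sc(i, k, x, m) + sc(k + 1, j, m, y))
            }
            v <- max(opts)
            memo[[key]] <- v
            v
        }
        if (mode == "global_in_model") {
            best <- -Inf
            for (x in 0:T) for (y in x:T)
                best <- max(best, sc(1, L, x, y))
            return(best)
        }
        # structural subtree intervals, by the same peeling rules
        ivals <- new.env(parent = emptyenv())
        peel <- function(i, j) {
            if (i > j) return(invisible(NULL))
            key <- paste(i, j)
            if (!is.null(ivals[[key]])) return(invisible(NULL))
            ivals[[key]] <- c(i, j)
            if (partner[i] == 0) peel(i + 1, j)
            else if (partner[i] == j) peel(i + 1, j - 1)
            else if (partner[j] == 0) peel(i, j - 1)
            else { peel(i, partner[i]); peel(partner[i] + 1, j) }
        }
        peel(1, L)
        best <- -Inf
        for (key in ls(ivals)) {
            ij <- ivals[[key]]
            for (x in 0:(T - 1)) for (y in (x + 1):T)
                best <- max(best, sc(ij[1], ij[2], x, y))
        }
        best
    }
    max(oneStrand(toupper(target)), oneStrand(revComp(toupper(target))))
}

# --- exhaustive graph search ----------------------------------------------
# Enumerate ALL walks up to maxDepth, classify their spelled sequences at
# the gathering threshold, and assign reads with the same rule as the
# package. An admissible length bound (no aligned base can contribute more
# than the best emission unit) prunes walks that provably cannot reach the
# threshold.
oracleAssignReads <- function(hybrid, model, reads, params) {
    walks <- allWalks(hybrid, params$max_path_depth)
    seqs <- unique(vapply(walks, function(w)
        spellWalk(hybrid, w$seg, w$orient), ""))
    maxUnit <- max(model@singleEmit, 0)
    if (nrow(model@pairs) > 0L) maxUnit <- max(maxUnit, model@pairEmit / 2)
    seqs <- seqs[nchar(seqs) * maxUnit >= gaThreshold(model)]
    paths <- lapply(seqs, function(s) list(seq = s))
    hom <- classifyPaths(paths, model)
    assignReads(hom, reads, params, familyId = model@familyId)
}
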