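# Compile a ProfileModel into a guide tree for the CYK engine. Interval
# decomposition precedence (mirrored by the exhaustive test oracle):
# left column unpaired -> MATL; ends paired together -> MATP; right column
# unpaired -> MATR; otherwise the left column pairs inside, -> BIF at its
# partner. Node types: 0 MATL, 1 MATR, 2 MATP, 3 BIF, 4 END, 5 ROOT.
# Appending each node after its children makes 1..n a postorder.
.compileModel <- function(model, nScore = -2) {
    L <- model@L
    partner <- integer(L)
    pr <- model@pairs
    if (nrow(pr) > 0L) {
        partner[pr[, 1L]] <- pr[, 2L]
        partner[pr[, 2L]] <- pr[, 1L]
    }
    pairRow <- integer(L)
    if (nrow(pr) > 0L) pairRow[pr[, 1L]] <- seq_len(nrow(pr))
    env <- new.env()
    env$type <- integer(); env$c1 <- integer(); env$c2 <- integer()
    env$minCol <- integer(); env$maxCol <- integer()
    env$sE <- list(); env$pE <- list()
    zeroS <- rep(0, 5); zeroP <- rep(0, 25)
    singleFor <- function(col) c(model@singleEmit[, col], nScore)
    pairFor <- function(col) {
        e <- matrix(nScore * 2, 5L, 5L)
        e[1:4, 1:4] <- matrix(model@pairEmit[, pairRow[col]], 4L, 4L,
                              byrow = TRUE)
        as.vector(t(e))  # row-major: index b1 * 5 + b2
    }
    add <- function(type, c1, c2, minc, maxc, sE, pE) {
        env$type <- c(env$type, type)
        env$c1 <- c(env$c1, c1); env$c2 <- c(env$c2, c2)
        env$minCol <- c(env$minCol, minc); env$maxCol <- c(env$maxCol, maxc)
        env$sE[[length(env$sE) + 1L]] <- sE
        env$pE[[length(env$pE) + 1L]] <- pE
        length(env$type)
    }
    comp <- function(i, j) {
        if (i > j) return(add(4L, 0L, 0L, 0L, -1L, zeroS, zeroP))
        if (partner[i] == 0L) {
            w <- comp(i + 1L, j)
            add(0L, w, 0L, i, j, singleFor(i), zeroP)
        } else if (partner[i] == j) {
            w <- comp(i + 1L, j - 1L)
            add(2L, w, 0L, i, j, zeroS, pairFor(i))
        } else if (partner[j] == 0L) {
            w <- comp(i, j - 1L)
            add(1L, w, 0L, i, j, singleFor(j), zeroP)
        } else {
            k <- partner[i]
            u <- comp(i, k)
            w <- comp(k + 1L, j)
            add(3L, u, w, i, j, zeroS, zeroP)
        }
    }
    rootChild <- comp(1L, L)
    root <- add(5L, rootChild, 0L, 1L, L, zeroS, zeroP)
    list(type = env$type, c1 = env$c1, c2 = env$c2,
         minCol = env$minCol, maxCol = env$maxCol,
         singleE = matrix(unlist(env$sE), nrow = 5L),
         pairE = matrix(unlist(env$pE), nrow = 25L),
         postorder = seq_along(env$type), root = root)
}

# number of consensus columns in each node's subtree (0 for END)
.nodeNcols <- function(cm) {
    ifelse(cm$maxCol >= cm$minCol & cm$minCol > 0L,
           cm$maxCol - cm$minCol + 1L, 0L)
}

#' Align a profile model to a target sequence
#'
#' CYK-style dynamic programming over the model's nested pair structure.
#' Paired columns emit two target bases scored jointly; unpaired columns
#' emit one; deleted columns and inserted bases pay the model's linear
#' penalties. The alignment is always local in the target. In
#' \code{"global_in_model"} mode every consensus column must be accounted
#' for (aligned or deleted); \code{"local_in_model"} additionally allows
#' truncating the columns outside any structural subtree at no cost, which
#' is what a partial hit on a graph edge looks like. Both target strands
#' are scored and the better one reported.
#'
#' Targets longer than \code{maxWindow} are scanned in half-overlapping
#' windows and the best window hit is reported, so very long unitigs do not
#' inflate the cubic dynamic program.
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param target Nucleotide string (length >= 1).
#' @param mode \code{"local_in_model"} or \code{"global_in_model"}.
#' @param maxWindow Window cap in bases; default \code{max(250, 2.5 * L)}.
#' @return List of class \code{ModelHit}: \code{score}, \code{seq_span}
#'   (0-based half-open, forward-strand coordinates of \code{target}),
#'   \code{model_span} (0-based half-open consensus columns), \code{strand},
#'   \code{mode}.
#' @examples
#' sto <- list(aln = c(a = "GGGAAACCC", b = "GGGAAACCC"),
#'             ss_cons = "<<<...>>>", ga = NA)
#' m <- buildProfileModel(sto, "toy", ga = 5)
#' alignModel(m, "GGGAAACCC")$score
#' @export
alignModel <- function(model, target, mode = c("local_in_model",
                                               "global_in_model"),
                       maxWindow = NULL) {
    mode <- match.arg(mode)
    stopifnot(methods::is(model, "ProfileModel"), nchar(target) >= 1L)
    .alignModelCompiled(model, .compileModel(model), target, mode, maxWindow)
}

# worker sharing one compiled guide tree across many targets
.alignModelCompiled <- function(model, cm, target, mode, maxWindow = NULL) {
    target <- toupper(target)
    ncols <- .nodeNcols(cm)
    W <- as.integer(maxWindow %||% max(250, ceiling(2.5 * model@L)))
    tlen <- nchar(target)
    starts <- if (tlen <= W) 0L else {
        s <- seq(0L, tlen - W, by = max(1L, W %/% 2L))
        unique(c(s, tlen - W))
    }
    best <- NULL
    for (strand in c("+", "-")) {
        tt <- if (strand == "+") target else revComp(target)
        for (s0 in starts) {
            win <- substr(tt, s0 + 1L, min(tlen, s0 + W))
            r <- cpp_cm_align(cm$type, cm$c1, cm$c2, cm$singleE, cm$pairE,
                             model@gapPenalty, model@insertPenalty,
                             ncols, cm$postorder, win,
                             mode == "local_in_model")
            if (is.null(best) || r$score > best$score) {
                best <- r
                best$strand <- strand
                best$offset <- s0
            }
        }
    }
    x <- best$offset + best$x
    y <- best$offset + best$y
    span <- if (best$strand == "+") c(x, y) else c(tlen - y, tlen - x)
    v <- best$node
    structure(list(score = best$score, seq_span = span,
                   model_span = c(cm$minCol[v] - 1L, cm$maxCol[v]),
                   strand = best$strand, mode = mode), class = "ModelHit")
}

# 5 x L ungapped-profile scores for the filter stage: unpaired columns use
# their emissions, paired columns the log-odds of their pair-marginal base
# distribution
.scanProfile <- function(model, nScore = -2) {
    L <- model@L
    prof <- rbind(model@singleEmit, rep(nScore, L))
    if (nrow(model@pairs) > 0L) for (pi in seq_len(nrow(model@pairs))) {
        joint <- (rep(model@nullFreq, each = 4L) *
                  rep(model@nullFreq, times = 4L)) * 2^model@pairEmit[, pi]
        joint <- matrix(joint / sum(joint), 4L, 4L, byrow = TRUE)
        i <- model@pairs[pi, 1L]; j <- model@pairs[pi, 2L]
        prof[, i] <- c(log2(rowSums(joint) / model@nullFreq), nScore)
        prof[, j] <- c(log2(colSums(joint) / model@nullFreq), nScore)
    }
    prof
}

#' Scan graph edges for model hits (anchors)
#'
#' Aligns the model to every segment label in model-local mode (both
#' strands) and reports each edge whose best hit reaches the threshold.
#' These are the anchors from which path extension starts.
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param graph An \linkS4class{AssemblyGraph} (condensed).
#' @param threshold Minimum hit score.
#' @param filter_frac Edges are pre-screened with a cheap structure-free
#'   profile alignment and skipped when that score stays below
#'   \code{filter_frac * threshold}; the generous margin makes the filter
#'   lose essentially nothing while avoiding the cubic dynamic program on
#'   unrelated edges (the same role HMM filters play in covariance-model
#'   search pipelines). Set to 0 to disable.
#' @return \code{data.frame(seg_id, score, strand, s_start, s_end, m_start,
#'   m_end)}; spans 0-based half-open, sequence span on the segment's
#'   stored orientation.
#' @export
scanEdges <- function(model, graph, threshold, filter_frac = 0.5) {
    ids <- names(segSeqs(graph))
    rows <- list()
    seqs <- as.character(segSeqs(graph))
    cm <- .compileModel(model)
    prof <- .scanProfile(model)
    # admissible bound: every aligned base contributes at most the best
    # single emission or half the best pair emission, so short segments
    # that cannot reach the threshold are skipped without alignment
    maxUnit <- max(model@singleEmit, 0)
    if (nrow(model@pairs) > 0L) maxUnit <- max(maxUnit, model@pairEmit / 2)
    for (id in ids) {
        if (nchar(seqs[[id]]) * maxUnit < threshold) next
        if (filter_frac > 0) {
            fsc <- max(cpp_profile_sw(prof, seqs[[id]], -3),
                       cpp_profile_sw(prof, revComp(seqs[[id]]), -3))
            if (fsc < filter_frac * threshold) next
        }
        hit <- .alignModelCompiled(model, cm, seqs[[id]],
                                   mode = "local_in_model")
        if (hit$score >= threshold)
            rows[[length(rows) + 1L]] <- data.frame(
                seg_id = id, score = hit$score, strand = hit$strand,
                s_start = hit$seq_span[1L], s_end = hit$seq_span[2L],
                m_start = hit$model_span[1L], m_end = hit$model_span[2L],
                stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(seg_id = character(), score = numeric(),
                          strand = character(), s_start = integer(),
                          s_end = integer(), m_start = integer(),
                          m_end = integer(), stringsAsFactors = FALSE))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
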