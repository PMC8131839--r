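#' Align terminal edges to verified contigs and apply the acceptance rules
#'
#' Each open end of each terminal edge of the condensed string graph is
#' locally aligned (both orientations) to every verified contig. An
#' alignment is recruited when its score is at least \code{min_score}, its
#' aligned query length at least \code{min_aln_len}, and the open end is
#' flush (no unaligned query overhang at the end with degree 0); thresholds
#' are inclusive. Only the \code{max_query_tail} bases nearest the open end
#' take part in the alignment.
#'
#' @param graph The condensed string \linkS4class{AssemblyGraph}.
#' @param terminals Output of [terminalEdges()] on \code{graph}.
#' @param contigs Contig table from [verifyContigs()]; only rows with
#'   \code{verified == TRUE} are used.
#' @param params A [MergeParams()] list.
#' @return \code{data.frame} with one row per recruited alignment:
#'   \code{contig_id}, \code{seg_id}, \code{end} ("L"/"R" on the segment's
#'   stored orientation), \code{orientation} (query strand along the
#'   contig), \code{score}, \code{aln_len}, \code{q_start}, \code{q_end},
#'   \code{t_start}, \code{t_end}, and \code{direction} ("right"/"left":
#'   which way along the contig the open end faces).
#' @export
recruitAlignments <- function(graph, terminals, contigs,
                              params = MergeParams()) {
    contigs <- contigs[contigs$verified %in% TRUE, , drop = FALSE]
    out <- list()
    if (nrow(terminals) == 0L || nrow(contigs) == 0L)
        return(.emptyRecruits())
    seqs <- as.character(segSeqs(graph))
    seedLen <- 12L
    contigSeeds <- lapply(contigs$seq, function(s) .seedSet(s, seedLen))
    for (ti in seq_len(nrow(terminals))) {
        seg <- terminals$seg_id[ti]
        E <- seqs[[seg]]
        ends <- c(if (terminals$left_open[ti]) "L",
                  if (terminals$right_open[ti]) "R")
        for (end in ends) {
            if (end == "R") {
                qs <- max(1L, nchar(E) - params$max_query_tail + 1L)
                portion <- substr(E, qs, nchar(E))
            } else {
                portion <- substr(E, 1L, params$max_query_tail)
            }
            pseeds <- if (nchar(portion) >= 3L * seedLen)
                .seedSet(paste(portion, revComp(portion)), seedLen) else NULL
            for (ci in seq_len(nrow(contigs))) {
                if (!is.null(pseeds) &&
                    !any(pseeds %in% contigSeeds[[ci]])) next
                a <- localAlign(portion, contigs$seq[ci], params,
                                both_strands = TRUE)
                alnLen <- a$query_span[2L] - a$query_span[1L]
                if (a$score < params$min_score ||
                    alnLen < params$min_aln_len) next
                # open-end flush check on the oriented query
                openAtRight <- (end == "R") == (a$orientation == "+")
                clipped <- if (openAtRight) a$clipped_tail else a$clipped_head
                if (clipped) next
                out[[length(out) + 1L]] <- data.frame(
                    contig_id = contigs$contig_id[ci], seg_id = seg,
                    end = end, orientation = a$orientation,
                    score = a$score, aln_len = alnLen,
                    q_start = a$query_span[1L], q_end = a$query_span[2L],
                    t_start = a$target_span[1L], t_end = a$target_span[2L],
                    direction = if (openAtRight) "right" else "left",
                    stringsAsFactors = FALSE)
            }
        }
    }
    if (length(out) == 0L) return(.emptyRecruits())
    res <- do.call(rbind, out)
    # best alignment per (segment end, contig)
    key <- paste(res$contig_id, res$seg_id, res$end)
    res <- res[order(key, -res$score), , drop = FALSE]
    res <- res[!duplicated(paste(res$contig_id, res$seg_id, res$end)), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

.emptyRecruits <- function() {
    data.frame(contig_id = character(), seg_id = character(),
               end = character(), orientation = character(),
               score = numeric(), aln_len = integer(), q_start = integer(),
               q_end = integer(), t_start = integer(), t_end = integer(),
               direction = character(), stringsAsFactors = FALSE)
}

.seedSet <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Merge the string graph with verified contigs into the hybrid graph
#'
#' Per verified contig: with two or more recruited alignments, every
#' compatible ordered pair (a right-facing open end upstream of a
#' left-facing open end, non-overlapping contig spans) is connected through
#' the intervening contig interval; with exactly one alignment, the open end
#' is extended by the contig overhang beyond the aligned span; with none,
#' the contig is retained as an isolated segment. Pre-existing string-graph
#' segments and links are never altered: connectors and extensions are new
#' segments attached with overlap-0 links, so the string graph remains a
#' subgraph of the hybrid graph. A zero-length connecting interval becomes a
#' direct link.
#'
#' @param graph The condensed string \linkS4class{AssemblyGraph}.
#' @param contigs Contig table from [verifyContigs()].
#' @param recruits Output of [recruitAlignments()].
#' @param params A [MergeParams()] list.
#' @return A hybrid \linkS4class{AssemblyGraph}; \code{meta$mergeReport}
#'   records one row per action (\code{connect}, \code{extend},
#'   \code{isolate}).
#' @export
mergeGraphs <- function(graph, contigs, recruits, params = MergeParams()) {
    contigs <- contigs[contigs$verified %in% TRUE, , drop = FALSE]
    seqs <- as.character(segSeqs(graph))
    members <- segMembers(graph)
    links <- segLinks(graph)
    report <- list()
    nSkipped <- 0L
    addSeg <- function(id, seq) {
        seqs[[id]] <<- seq
        members[[id]] <<- data.frame(read_id = character(),
                                     offset = integer(), orient = character(),
                                     stringsAsFactors = FALSE)
    }
    addLink <- function(from, fo, to, to_or, ovl = 0L) {
        links <<- rbind(links, data.frame(from = from, from_orient = fo,
                                          to = to, to_orient = to_or,
                                          ovl = ovl, stringsAsFactors = FALSE))
    }
    for (ci in seq_len(nrow(contigs))) {
        cid <- contigs$contig_id[ci]
        cseq <- contigs$seq[ci]
        rec <- recruits[recruits$contig_id == cid, , drop = FALSE]
        if (nrow(rec) == 0L) {
            addSeg(cid, cseq)
            report[[length(report) + 1L]] <- data.frame(
                contig_id = cid, action = "isolate", detail = "",
                stringsAsFactors = FALSE)
        } else if (nrow(rec) == 1L) {
            r <- rec[1L, ]
            if (r$direction == "right") {
                over <- substr(cseq, r$t_end + 1L, nchar(cseq))
                if (nchar(over) > 0L) {
                    oid <- sprintf("%s_ext1", cid)
                    addSeg(oid, over)
                    addLink(r$seg_id, r$orientation, oid, "+")
                }
            } else {
                over <- substr(cseq, 1L, r$t_start)
                if (nchar(over) > 0L) {
                    oid <- sprintf("%s_ext1", cid)
                    addSeg(oid, over)
                    addLink(oid, "+", r$seg_id, r$orientation)
                }
            }
            report[[length(report) + 1L]] <- data.frame(
                contig_id = cid, action = "extend",
                detail = sprintf("%s:%s", r$seg_id, r$end),
                stringsAsFactors = FALSE)
        } else {
            nj <- 0L
            up <- rec[rec$direction == "right", , drop = FALSE]
            dn <- rec[rec$direction == "left", , drop = FALSE]
            # bypass-safe reduction: a pair is redundant when a fully
            # interposed segment (left entry and right exit both recruited
            # between the two spans) already carries a connecting walk
            bypassed <- function(a, b) {
                cand <- intersect(up$seg_id, dn$seg_id)
                cand <- setdiff(cand, c(a$seg_id, b$seg_id))
                for (s in cand) {
                    ls <- dn[dn$seg_id == s, , drop = FALSE]
                    rs <- up[up$seg_id == s, , drop = FALSE]
                    if (any(a$t_end <= ls$t_start) &&
                        any(rs$t_end <= b$t_start)) return(TRUE)
                }
                FALSE
            }
            for (i in seq_len(nrow(up))) for (j in seq_len(nrow(dn))) {
                a <- up[i, ]; b <- dn[j, ]
                if (a$seg_id == b$seg_id && a$end == b$end) next
                if (a$t_start >= b$t_start) next  # wrong order along contig
                if (bypassed(a, b)) next
                if (a$t_end > b$t_start) {
                    # alignment spans overlap: the terminals share sequence
                    # at the junction; join them directly with that overlap
                    o <- a$t_end - b$t_start
                    sa <- .orientedSeqChar(segSeqs(graph), a$seg_id,
                                           a$orientation)
                    sb <- .orientedSeqChar(segSeqs(graph), b$seg_id,
                                           b$orientation)
                    if (o >= min(nchar(sa), nchar(sb)) ||
                        substr(sa, nchar(sa) - o + 1L, nchar(sa)) !=
                            substr(sb, 1L, o)) {
                        nSkipped <- nSkipped + 1L
                        next
                    }
                    nj <- nj + 1L
                    addLink(a$seg_id, a$orientation, b$seg_id, b$orientation,
                            ovl = o)
                    report[[length(report) + 1L]] <- data.frame(
                        contig_id = cid, action = "connect",
                        detail = sprintf("%s:%s->%s:%s ovl %d", a$seg_id,
                                         a$end, b$seg_id, b$end, o),
                        stringsAsFactors = FALSE)
                    next
                }
                gap <- substr(cseq, a$t_end + 1L, b$t_start)
                nj <- nj + 1L
                if (nchar(gap) == 0L) {
                    addLink(a$seg_id, a$orientation, b$seg_id, b$orientation)
                } else {
                    jid <- sprintf("%s_j%d", cid, nj)
                    addSeg(jid, gap)
                    addLink(a$seg_id, a$orientation, jid, "+")
                    addLink(jid, "+", b$seg_id, b$orientation)
                }
                report[[length(report) + 1L]] <- data.frame(
                    contig_id = cid, action = "connect",
                    detail = sprintf("%s:%s->%s:%s [%d,%d)", a$seg_id, a$end,
                                     b$seg_id, b$end, a$t_end, b$t_start),
                    stringsAsFactors = FALSE)
            }
            if (nj == 0L)
                report[[length(report) + 1L]] <- data.frame(
                    contig_id = cid, action = "connect",
                    detail = "no compatible pair", stringsAsFactors = FALSE)
        }
    }
    if (nSkipped > 0L)
        warning(nSkipped,
                " orientation/sequence-inconsistent pair(s) skipped")
    rep <- if (length(report)) do.call(rbind, report) else
        data.frame(contig_id = character(), action = character(),
                   detail = character(), stringsAsFactors = FALSE)
    meta <- graph@meta
    meta$mergeReport <- rep
    meta$mergeParams <- params
    AssemblyGraph(seqs, links, members, graphType = "hybrid", meta = meta)
}
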