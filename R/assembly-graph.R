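#' Accessors for AssemblyGraph
#'
#' \code{segSeqs} returns the segment labels as a
#' \link[Biostrings]{DNAStringSet}; \code{segLinks} the canonical link table;
#' \code{segMembers} the constituent-read tables; \code{nSegs} the number of
#' segments; \code{graphType} the provenance tag.
#'
#' @param x An \linkS4class{AssemblyGraph}.
#' @return See the individual descriptions.
#' @name segSeqs
#' @aliases segSeqs,AssemblyGraph-method segLinks,AssemblyGraph-method
#'   segMembers,AssemblyGraph-method nSegs,AssemblyGraph-method
#'   graphType,AssemblyGraph-method
NULL

#' @rdname segSeqs
#' @export
setMethod("segSeqs", "AssemblyGraph", function(x) x@seqs)

#' @rdname segSeqs
#' @export
setMethod("segLinks", "AssemblyGraph", function(x) x@links)

#' @rdname segSeqs
#' @export
setMethod("segMembers", "AssemblyGraph", function(x) x@members)

#' @rdname segSeqs
#' @export
setMethod("nSegs", "AssemblyGraph", function(x) length(x@seqs))

#' @rdname segSeqs
#' @export
setMethod("graphType", "AssemblyGraph", function(x) x@graphType)

setMethod("show", "AssemblyGraph", function(object) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("AssemblyGraph (%s): %d segments, %d links, %d bp total\n",
                object@graphType, length(object@seqs), nrow(object@links),
                sum(w)))
    if (length(w) > 0L)
        cat(sprintf("  segment lengths: min %d / median %g / max %d\n",
                    min(w), stats::median(w), max(w)))
    invisible(NULL)
})

# degree bookkeeping on the doubled link table ------------------------------

# out-links of oriented segment (seg, orient)
.outLinks <- function(dl, seg, orient) {
    dl[dl$from == seg & dl$from_orient == orient, , drop = FALSE]
}

.inLinks <- function(dl, seg, orient) {
    dl[dl$to == seg & dl$to_orient == orient, , drop = FALSE]
}

# named degree vectors keyed "seg\torient"
.degreeTables <- function(g) {
    dl <- .doubledLinks(g)
    ids <- names(g@seqs)
    keys <- c(paste0(ids, "\t+"), paste0(ids, "\t-"))
    outd <- stats::setNames(integer(length(keys)), keys)
    ind <- outd
    if (nrow(dl) > 0L) {
        to <- table(paste0(dl$from, "\t", dl$from_orient))
        ti <- table(paste0(dl$to, "\t", dl$to_orient))
        outd[names(to)] <- as.integer(to)
        ind[names(ti)] <- as.integer(ti)
    }
    list(out = outd, "in" = ind, doubled = dl)
}

#' Spell the sequence of a walk
#'
#' Concatenates the oriented labels of consecutive segments, trimming the
#' link overlap at each junction. Every consecutive pair must be joined by a
#' link (original or implied complement).
#'
#' @param g An \linkS4class{AssemblyGraph}.
#' @param segs Character vector of segment ids along the walk.
#' @param orients Character vector of orientations ("+"/"-"), recycled if
#'   length 1.
#' @return A single character string.
#' @examples
#' g <- AssemblyGraph(c(a = "ACGTAC", b = "TACGGA"),
#'     data.frame(from = "a", from_orient = "+", to = "b", to_orient = "+",
#'                ovl = 3))
#' spellWalk(g, c("a", "b"))  # "ACGTACGGA"
#' @export
spellWalk <- function(g, segs, orients = "+") {
    stopifnot(methods::is(g, "AssemblyGraph"), length(segs) >= 1L)
    orients <- rep_len(orients, length(segs))
    dl <- .doubledLinks(g)
    out <- .orientedSeqChar(g@seqs, segs[1L], orients[1L])
    if (length(segs) > 1L) {
        for (i in seq(2L, length(segs))) {
            hit <- dl[dl$from == segs[i - 1L] & dl$from_orient == orients[i - 1L] &
                      dl$to == segs[i] & dl$to_orient == orients[i], , drop = FALSE]
            if (nrow(hit) == 0L)
                stop(sprintf("no link from (%s,%s) to (%s,%s)",
                             segs[i - 1L], orients[i - 1L], segs[i], orients[i]))
            ovl <- max(hit$ovl)  # maximal-overlap join if parallel links exist
            s <- .orientedSeqChar(g@seqs, segs[i], orients[i])
            out <- paste0(out, substr(s, ovl + 1L, nchar(s)))
        }
    }
    out
}

#' Condense unbranched paths into unitig segments
#'
#' Every maximal chain of segments whose internal junctions have exactly one
#' incoming and one outgoing oriented link is replaced by a single segment
#' spelling the chain; constituent-read tables are concatenated with shifted
#' offsets. Cycles condense to a single self-linked segment. The set of
#' spelled sequences of maximal walks is unchanged, and the operation is
#' idempotent.
#'
#' @param x An \linkS4class{AssemblyGraph}.
#' @param ... Unused.
#' @return A condensed \linkS4class{AssemblyGraph}.
#' @rdname condense
#' @export
setMethod("condense", "AssemblyGraph", function(x, ...) {
    ids <- names(x@seqs)
    if (length(ids) == 0L) return(x)
    deg <- .degreeTables(x)
    dl <- deg$doubled
    keyOf <- function(s, o) paste0(s, "\t", o)
    # mergeable joins: unique out at (a,oa), unique in at (b,ob), a != b
    mrg <- dl[dl$from != dl$to &
              deg$out[keyOf(dl$from, dl$from_orient)] == 1L &
              deg$`in`[keyOf(dl$to, dl$to_orient)] == 1L, , drop = FALSE]
    nxt <- new.env(parent = emptyenv())
    prv <- new.env(parent = emptyenv())
    if (nrow(mrg) > 0L) for (i in seq_len(nrow(mrg))) {
        assign(keyOf(mrg$from[i], mrg$from_orient[i]),
               list(seg = mrg$to[i], orient = mrg$to_orient[i], ovl = mrg$ovl[i]),
               envir = nxt)
        assign(keyOf(mrg$to[i], mrg$to_orient[i]),
               list(seg = mrg$from[i], orient = mrg$from_orient[i]),
               envir = prv)
    }
    visited <- new.env(parent = emptyenv())
    chains <- list()
    for (s in ids) {
        if (!is.null(visited[[s]])) next
        # walk backwards from (s, +) to the chain start (or around a cycle)
        cs <- s; co <- "+"; isCycle <- FALSE
        repeat {
            p <- prv[[keyOf(cs, co)]]
            if (is.null(p)) break
            if (p$seg == s && p$orient == "+") { isCycle <- TRUE; break }
            cs <- p$seg; co <- p$orient
        }
        segs <- cs; ors <- co; ovls <- integer()
        visited[[cs]] <- TRUE
        cur <- list(seg = cs, orient = co)
        repeat {
            nx <- nxt[[keyOf(cur$seg, cur$orient)]]
            if (is.null(nx) || !is.null(visited[[nx$seg]])) break
            segs <- c(segs, nx$seg); ors <- c(ors, nx$orient)
            ovls <- c(ovls, nx$ovl)
            visited[[nx$seg]] <- TRUE
            cur <- list(seg = nx$seg, orient = nx$orient)
        }
        closing <- NA_integer_
        if (isCycle) {
            nx <- nxt[[keyOf(cur$seg, cur$orient)]]
            if (!is.null(nx) && nx$seg == segs[1L] && nx$orient == ors[1L])
                closing <- nx$ovl
        }
        chains[[length(chains) + 1L]] <- list(segs = segs, orients = ors,
                                              ovls = ovls, closing = closing)
    }
    # build merged segments; the unitig prefix must not collide with names
    # from an earlier condensation round
    prefix <- "u"
    while (any(grepl(paste0("^", prefix, "[0-9]+$"), ids)))
        prefix <- paste0("u", prefix)
    newSeqs <- character(length(chains))
    newMembers <- vector("list", length(chains))
    newIds <- character(length(chains))
    segMap <- new.env(parent = emptyenv())  # seg -> list(new, orientInNew)
    for (ci in seq_along(chains)) {
        ch <- chains[[ci]]
        nid <- if (length(ch$segs) == 1L) ch$segs[1L]
               else sprintf("%s%04d", prefix, ci)
        newIds[ci] <- nid
        parts <- .orientedSeqChar(x@seqs, ch$segs, ch$orients)
        seq <- parts[1L]
        off <- 0L
        offs <- integer(length(parts)); offs[1L] <- 0L
        if (length(parts) > 1L) for (i in seq(2L, length(parts))) {
            off <- nchar(seq) - ch$ovls[i - 1L]
            offs[i] <- off
            seq <- paste0(seq, substr(parts[i], ch$ovls[i - 1L] + 1L,
                                      nchar(parts[i])))
        }
        newSeqs[ci] <- seq
        mem <- do.call(rbind, lapply(seq_along(ch$segs), function(i) {
            m <- x@members[[ch$segs[i]]]
            if (is.null(m) || nrow(m) == 0L) return(NULL)
            slen <- nchar(parts[i])
            if (ch$orients[i] == "-") {
                rl <- .memberReadLens(x, m)
                m <- data.frame(read_id = m$read_id,
                                offset = slen - (m$offset + rl),
                                orient = .flipOrient(m$orient),
                                stringsAsFactors = FALSE)
            }
            m$offset <- m$offset + offs[i]
            m
        }))
        if (is.null(mem)) mem <- data.frame(read_id = character(),
                                            offset = integer(),
                                            orient = character(),
                                            stringsAsFactors = FALSE)
        newMembers[[ci]] <- mem
        for (i in seq_along(ch$segs))
            assign(ch$segs[i], list(new = nid, orient = ch$orients[i]),
                   envir = segMap)
    }
    names(newMembers) <- newIds
    # remap non-merged links; drop links internal to a chain
    mergedKey <- if (nrow(mrg) > 0L)
        paste(mrg$from, mrg$from_orient, mrg$to, mrg$to_orient, mrg$ovl)
    else character()
    keep <- x@links
    if (nrow(keep) > 0L) {
        dkey <- paste(keep$from, keep$from_orient, keep$to, keep$to_orient,
                      keep$ovl)
        ckey <- paste(keep$to, .flipOrient(keep$to_orient), keep$from,
                      .flipOrient(keep$from_orient), keep$ovl)
        keep <- keep[!(dkey %in% mergedKey | ckey %in% mergedKey), ,
                     drop = FALSE]
    }
    remap <- function(seg, orient) {
        m <- mget(seg, envir = segMap)
        data.frame(seg = vapply(m, `[[`, "", "new"),
                   orient = ifelse(orient == vapply(m, `[[`, "", "orient"),
                                   "+", "-"),
                   stringsAsFactors = FALSE)
    }
    newLinks <- .emptyLinks()
    if (nrow(keep) > 0L) {
        f <- remap(keep$from, keep$from_orient)
        t <- remap(keep$to, keep$to_orient)
        newLinks <- data.frame(from = f$seg, from_orient = f$orient,
                               to = t$seg, to_orient = t$orient,
                               ovl = keep$ovl, stringsAsFactors = FALSE)
    }
    # closing links of condensed cycles
    for (ci in seq_along(chains)) {
        cl <- chains[[ci]]$closing
        if (!is.na(cl))
            newLinks <- rbind(newLinks,
                data.frame(from = newIds[ci], from_orient = "+",
                           to = newIds[ci], to_orient = "+", ovl = cl,
                           stringsAsFactors = FALSE))
    }
    AssemblyGraph(stats::setNames(newSeqs, newIds), newLinks, newMembers,
                  graphType = x@graphType, meta = x@meta)
})

# member read lengths: from the graph's recorded read lengths when known,
# else 0 (offsets on flipped segments then stay approximate)
.memberReadLens <- function(g, m) {
    lens <- g@meta$read_lengths
    if (!is.null(lens) && all(m$read_id %in% names(lens)))
        return(as.integer(lens[m$read_id]))
    rep(0L, nrow(m))
}

#' Terminal (open-ended) edges of an assembly graph
#'
#' A segment end is open when no oriented link attaches to it. Isolated
#' segments report both ends open. Ends are reported on the segment's stored
#' (+) orientation: \code{left_open} means no link enters the segment read
#' left-to-right, \code{right_open} means no link leaves it.
#'
#' @param x A condensed \linkS4class{AssemblyGraph}.
#' @param ... Unused.
#' @return \code{data.frame(seg_id, left_open, right_open, open_end)} with
#'   \code{open_end} in \code{"head"}, \code{"tail"}, \code{"both"}; one row
#'   per segment having at least one open end.
#' @rdname terminalEdges
#' @export
setMethod("terminalEdges", "AssemblyGraph", function(x, ...) {
    ids <- names(x@seqs)
    deg <- .degreeTables(x)
    leftOpen <- deg$`in`[paste0(ids, "\t+")] == 0L
    rightOpen <- deg$out[paste0(ids, "\t+")] == 0L
    out <- data.frame(seg_id = ids, left_open = unname(leftOpen),
                      right_open = unname(rightOpen),
                      stringsAsFactors = FALSE)
    out <- out[out$left_open | out$right_open, , drop = FALSE]
    out$open_end <- ifelse(out$left_open & out$right_open, "both",
                           ifelse(out$left_open, "head", "tail"))
    rownames(out) <- NULL
    out
})

#' Does some walk of the graph spell a given sequence?
#'
#' Depth-first search over oriented segments for a walk whose spelled
#' sequence equals \code{target} exactly.
#'
#' @param g An \linkS4class{AssemblyGraph}.
#' @param target Character; the sequence to spell.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
spellsSequence <- function(g, target) {
    stopifnot(methods::is(g, "AssemblyGraph"), nchar(target) >= 1L)
    target <- toupper(target)
    tlen <- nchar(target)
    dl <- .doubledLinks(g)
    ids <- names(g@seqs)
    failed <- new.env(parent = emptyenv())
    dfs <- function(seg, orient, pos) {
        # pos bases of target already spelled, ending at this segment's end
        if (pos == tlen) return(TRUE)
        key <- paste0(seg, "\t", orient, "\t", pos)
        if (!is.null(failed[[key]])) return(FALSE)
        out <- .outLinks(dl, seg, orient)
        if (nrow(out) > 0L) for (i in seq_len(nrow(out))) {
            s <- .orientedSeqChar(g@seqs, out$to[i], out$to_orient[i])
            contrib <- nchar(s) - out$ovl[i]
            if (contrib > 0L && pos + contrib <= tlen &&
                substr(s, out$ovl[i] + 1L, nchar(s)) ==
                    substr(target, pos + 1L, pos + contrib)) {
                if (dfs(out$to[i], out$to_orient[i], pos + contrib))
                    return(TRUE)
            }
        }
        failed[[key]] <- TRUE
        FALSE
    }
    for (seg in ids) for (orient in c("+", "-")) {
        s <- .orientedSeqChar(g@seqs, seg, orient)
        if (nchar(s) <= tlen && s == substr(target, 1L, nchar(s))) {
            if (dfs(seg, orient, nchar(s))) return(TRUE)
        }
    }
    FALSE
}

#' Enumerate all walks of a graph up to a depth
#'
#' Exhaustive depth-first enumeration of all oriented walks with at most
#' \code{maxDepth} segments. Intended for exact, small-graph computations
#' against which heuristic search results can be compared; the number of
#' walks grows exponentially.
#'
#' @param g An \linkS4class{AssemblyGraph}.
#' @param maxDepth Maximum number of segments per walk.
#' @return A list of \code{data.frame(seg, orient)} walks.
#' @export
allWalks <- function(g, maxDepth = 5L) {
    dl <- .doubledLinks(g)
    walks <- list()
    grow <- function(segs, orients) {
        walks[[length(walks) + 1L]] <<- data.frame(seg = segs,
                                                   orient = orients,
                                                   stringsAsFactors = FALSE)
        if (length(segs) >= maxDepth) return(invisible(NULL))
        last <- length(segs)
        out <- .outLinks(dl, segs[last], orients[last])
        if (nrow(out) > 0L) for (i in seq_len(nrow(out)))
            grow(c(segs, out$to[i]), c(orients, out$to_orient[i]))
        invisible(NULL)
    }
    for (seg in names(g@seqs)) for (orient in c("+", "-"))
        grow(seg, orient)
    walks
}
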