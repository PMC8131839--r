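#' Parameters for string-graph construction
#'
#' @param min_overlap Minimum exact suffix-prefix overlap, in bases. The
#'   default 45 suits 100 nt reads; toy fixtures use much smaller values.
#' @param use_revcomp Consider both read orientations (bidirected graph).
#' @param do_transitive_reduction Remove overlaps implied by two-step chains.
#' @return A validated parameter list of class \code{StringGraphParams}.
#' @export
StringGraphParams <- function(min_overlap = 45L, use_revcomp = TRUE,
                              do_transitive_reduction = TRUE) {
    min_overlap <- as.integer(min_overlap)
    stopifnot(min_overlap >= 1L, is.logical(use_revcomp),
              is.logical(do_transitive_reduction))
    structure(list(min_overlap = min_overlap, use_revcomp = use_revcomp,
                   do_transitive_reduction = do_transitive_reduction),
              class = "StringGraphParams")
}

#' Find exact suffix-prefix overlaps between reads
#'
#' Reports every maximal exact suffix-prefix overlap of length >=
#' \code{min_overlap} between distinct reads, in both orientations when
#' \code{use_revcomp}. A read fully contained in (or identical to) another is
#' reported in the \code{containments} table instead and is treated as
#' absorbed by graph construction. \code{N} bases never match, so they cannot
#' extend an overlap.
#'
#' @param reads Named \code{DNAStringSet} (or named character vector).
#' @param params A [StringGraphParams()] list.
#' @return List with elements \code{overlaps}
#'   (\code{data.frame(from, to, to_orient, length)}: suffix of \code{from}
#'   read in + orientation equals prefix of \code{to} read in
#'   \code{to_orient}) and \code{containments}
#'   (\code{data.frame(container, contained, orient, offset)}).
#' @examples
#' ov <- findReadOverlaps(c(r1 = "ACGTACGT", r2 = "TACGTTTT"),
#'                        StringGraphParams(min_overlap = 4))
#' ov$overlaps$length  # 5
#' @export
findReadOverlaps <- function(reads, params = StringGraphParams()) {
    nm <- names(reads)
    if (is.null(nm) || anyDuplicated(nm)) stop("reads must be uniquely named")
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    res <- cpp_find_overlaps(unname(seqs), params$min_overlap,
                             params$use_revcomp)
    ov <- res$overlaps
    ct <- res$containments
    overlaps <- data.frame(from = nm[ov$from], to = nm[ov$to],
                           to_orient = ifelse(ov$to_orient == 0L, "+", "-"),
                           length = ov$length, stringsAsFactors = FALSE)
    containments <- data.frame(container = nm[ct$container],
                               contained = nm[ct$contained],
                               orient = ifelse(ct$orient == 0L, "+", "-"),
                               offset = ct$offset, stringsAsFactors = FALSE)
    # a read contained in several others is absorbed once (first container)
    containments <- containments[!duplicated(containments$contained), ,
                                 drop = FALSE]
    list(overlaps = overlaps, containments = containments)
}

#' Build the string graph from reads and overlaps
#'
#' One segment per surviving (non-absorbed) read; links from the maximal
#' overlaps. With \code{do_transitive_reduction} an overlap A->C is removed
#' when overlaps A->B and B->C imply it (the two-step walk places C at the
#' same offset with the same orientation). Absorbed reads are recorded as
#' members of their container's segment so that read assignment still counts
#' them.
#'
#' @param reads Named \code{DNAStringSet} or character vector.
#' @param overlaps Result of [findReadOverlaps()] on the same reads.
#' @param params The [StringGraphParams()] used.
#' @return An \linkS4class{AssemblyGraph} of type \code{"string"} (not yet
#'   condensed; see [condense()]).
#' @export
buildStringGraph <- function(reads, overlaps, params = StringGraphParams()) {
    nm <- names(reads)
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    names(seqs) <- nm
    ct <- overlaps$containments
    # resolve containment chains (a contained read's container may itself be
    # absorbed)
    finalContainer <- stats::setNames(nm, nm)
    if (nrow(ct) > 0L) {
        cmap <- stats::setNames(ct$container, ct$contained)
        for (r in ct$contained) {
            cur <- r
            seen <- character()
            while (cur %in% names(cmap) && !(cur %in% seen)) {
                seen <- c(seen, cur)
                cur <- cmap[[cur]]
            }
            finalContainer[[r]] <- cur
        }
    }
    surviving <- nm[!(nm %in% ct$contained)]
    if (length(surviving) == 0L) stop("all reads absorbed; no graph")
    # member tables: each surviving read plus its absorbed reads; offsets for
    # directly contained reads are exact, chained containments fall back to
    # the container's offset
    members <- lapply(stats::setNames(surviving, surviving), function(id) {
        kids <- names(finalContainer)[finalContainer == id]
        kids <- setdiff(kids, id)
        m <- data.frame(read_id = id, offset = 0L, orient = "+",
                        stringsAsFactors = FALSE)
        if (length(kids) > 0L) {
            direct <- ct[ct$contained %in% kids & ct$container == id, ,
                         drop = FALSE]
            indirect <- setdiff(kids, direct$contained)
            m <- rbind(m,
                data.frame(read_id = direct$contained, offset = direct$offset,
                           orient = direct$orient, stringsAsFactors = FALSE))
            if (length(indirect) > 0L)
                m <- rbind(m, data.frame(read_id = indirect, offset = 0L,
                                         orient = "+",
                                         stringsAsFactors = FALSE))
        }
        m
    })
    ov <- overlaps$overlaps
    ov <- ov[ov$from %in% surviving & ov$to %in% surviving, , drop = FALSE]
    if (params$do_transitive_reduction && nrow(ov) > 0L)
        ov <- .transitiveReduce(ov, stats::setNames(nchar(seqs), nm))
    links <- if (nrow(ov) > 0L)
        data.frame(from = ov$from, from_orient = "+", to = ov$to,
                   to_orient = ov$to_orient, ovl = ov$length,
                   stringsAsFactors = FALSE)
    else .emptyLinks()
    AssemblyGraph(seqs[surviving], links, members, graphType = "string",
                  meta = list(params = params,
                              read_lengths = nchar(seqs),
                              absorbed = ct))
}

# Remove overlap A->C when overlaps A->B and B->C imply it: following the
# two-step walk, C starts at offset (lenA - pAB) + (lenB - pBC) from A, so
# the implied direct overlap is pAB + pBC - lenB, and orientations compose.
.transitiveReduce <- function(ov, readLens) {
    # doubled, oriented view: rows (from, fo, to, to_orient, length)
    d1 <- data.frame(from = ov$from, fo = "+", to = ov$to, to_or = ov$to_orient,
                     len = ov$length, stringsAsFactors = FALSE)
    d2 <- data.frame(from = ov$to, fo = .flipOrient(ov$to_orient), to = ov$from,
                     to_or = "-", len = ov$length, stringsAsFactors = FALSE)
    dd <- rbind(d1, d2)
    key <- function(f, fo, t, to, l) paste(f, fo, t, to, l)
    have <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(dd)))
        have[[key(dd$from[i], dd$fo[i], dd$to[i], dd$to_or[i], dd$len[i])]] <- TRUE
    removed <- new.env(parent = emptyenv())
    byFrom <- split(seq_len(nrow(dd)), paste(dd$from, dd$fo))
    for (grp in byFrom) {
        if (length(grp) < 2L) next
        for (i in grp) {
            # A -> B
            b <- dd$to[i]; bo <- dd$to_or[i]; pAB <- dd$len[i]
            outB <- byFrom[[paste(b, bo)]]
            if (is.null(outB)) next
            for (j in outB) {
                cseg <- dd$to[j]; co <- dd$to_or[j]; pBC <- dd$len[j]
                if (cseg == dd$from[i]) next
                r <- pAB + pBC - readLens[[b]]
                if (r <= 0L) next
                k <- key(dd$from[i], dd$fo[i], cseg, co, r)
                if (!is.null(have[[k]])) removed[[k]] <- TRUE
            }
        }
    }
    # map removals back to the (+-anchored) overlap rows, including via the
    # complement representation
    drop <- vapply(seq_len(nrow(ov)), function(i) {
        k1 <- paste(ov$from[i], "+", ov$to[i], ov$to_orient[i], ov$length[i])
        k2 <- paste(ov$to[i], .flipOrient(ov$to_orient[i]), ov$from[i], "-",
                    ov$length[i])
        !is.null(removed[[k1]]) || !is.null(removed[[k2]])
    }, logical(1))
    ov[!drop, , drop = FALSE]
}
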