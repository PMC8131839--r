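#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Bidirected assembly graph with sequence-labelled edges
#'
#' The common container for string graphs, de Bruijn graphs and the hybrid
#' graph produced by merging them. Following GFA1 semantics, each *segment*
#' is a sequence-labelled edge of the assembly graph (a read, a k-mer, a
#' condensed unitig, or a contig-derived connector), stored in one canonical
#' orientation; every segment is implicitly also present as its reverse
#' complement. A *link* joins the end of one oriented segment to the start of
#' another with an exact overlap of \code{ovl} bases, so the spelled sequence
#' of any walk is well defined: consecutive labels are concatenated after
#' trimming the overlap. The complement of every link is implied.
#'
#' @slot seqs A named \link[Biostrings]{DNAStringSet}, one entry per segment.
#' @slot links A \code{data.frame} with columns \code{from},
#'   \code{from_orient}, \code{to}, \code{to_orient}, \code{ovl}; canonical
#'   rows only (the implied reverse-complement link is not stored).
#' @slot members Named list, one entry per segment: a \code{data.frame} with
#'   columns \code{read_id}, \code{offset}, \code{orient} recording the
#'   constituent reads laid along the segment (offset is 0-based on the
#'   segment's stored orientation).
#' @slot graphType One of \code{"string"}, \code{"debruijn"},
#'   \code{"hybrid"}.
#' @slot meta Free-form list of provenance (parameters, merge report, k-mer
#'   counts).
#'
#' @seealso [buildStringGraph()], [buildDeBruijnGraph()], [mergeGraphs()],
#'   [condense()], [terminalEdges()], [spellWalk()]
#' @export
setClass("AssemblyGraph",
    representation(seqs = "DNAStringSet", links = "data.frame",
                   members = "list", graphType = "character", meta = "list"))

.LINK_COLS <- c("from", "from_orient", "to", "to_orient", "ovl")

setValidity("AssemblyGraph", function(object) {
    msg <- character()
    ids <- names(object@seqs)
    if (length(object@seqs) > 0L) {
        if (is.null(ids) || anyDuplicated(ids) || any(ids == ""))
            msg <- c(msg, "segment names must be unique and nonempty")
        if (any(Biostrings::width(object@seqs) == 0L))
            msg <- c(msg, "every segment label must be nonempty")
    }
    lk <- object@links
    if (!all(.LINK_COLS %in% colnames(lk)))
        msg <- c(msg, "links must have columns from/from_orient/to/to_orient/ovl")
    if (nrow(lk) > 0L && length(msg) == 0L) {
        if (!all(c(lk$from, lk$to) %in% ids))
            msg <- c(msg, "links reference unknown segments")
        if (!all(c(lk$from_orient, lk$to_orient) %in% c("+", "-")))
            msg <- c(msg, "link orientations must be '+' or '-'")
        w <- stats::setNames(Biostrings::width(object@seqs), ids)
        if (length(msg) == 0L && any(lk$ovl < 0L | lk$ovl >= pmin(w[lk$from], w[lk$to])))
            msg <- c(msg, "link overlap must be in [0, min(segment lengths))")
        if (length(msg) == 0L && !all(.linksConsistent(object@seqs, lk)))
            msg <- c(msg, "link overlap sequences disagree with segment labels")
    }
    if (length(msg)) msg else TRUE
})

# suffix(ovl) of the oriented 'from' label must equal prefix(ovl) of the
# oriented 'to' label
.linksConsistent <- function(seqs, lk) {
    if (nrow(lk) == 0L) return(logical(0))
    keep <- lk$ovl > 0L
    out <- rep(TRUE, nrow(lk))
    if (!any(keep)) return(out)
    lk <- lk[keep, , drop = FALSE]
    fs <- .orientedSeqChar(seqs, lk$from, lk$from_orient)
    ts <- .orientedSeqChar(seqs, lk$to, lk$to_orient)
    suf <- substr(fs, nchar(fs) - lk$ovl + 1L, nchar(fs))
    pre <- substr(ts, 1L, lk$ovl)
    out[keep] <- suf == pre
    out
}

.orientedSeqChar <- function(seqs, id, orient) {
    s <- as.character(seqs[id])
    flip <- orient == "-"
    if (any(flip))
        s[flip] <- as.character(
            Biostrings::reverseComplement(Biostrings::DNAStringSet(s[flip])))
    unname(s)
}

#' Construct an AssemblyGraph
#'
#' @param seqs Named character vector or \code{DNAStringSet} of segment
#'   labels.
#' @param links \code{data.frame} of links (see the class documentation);
#'   rows are canonicalised and deduplicated, so either or both of a
#'   link/complement pair may be supplied.
#' @param members Optional named list of constituent-read tables; defaults to
#'   each segment being its own sole member.
#' @param graphType Graph provenance tag.
#' @param meta Free-form metadata list.
#' @return An \linkS4class{AssemblyGraph}.
#' @examples
#' g <- AssemblyGraph(c(a = "ACGTAC", b = "TACGGA"),
#'     data.frame(from = "a", from_orient = "+", to = "b", to_orient = "+",
#'                ovl = 3))
#' nSegs(g)
#' @export
AssemblyGraph <- function(seqs, links = .emptyLinks(), members = NULL,
                          graphType = "string", meta = list()) {
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- Biostrings::DNAStringSet(toupper(seqs))
    links <- .canonLinks(links)
    if (is.null(members))
        members <- lapply(stats::setNames(names(seqs), names(seqs)), function(id)
            data.frame(read_id = id, offset = 0L, orient = "+",
                       stringsAsFactors = FALSE))
    methods::new("AssemblyGraph", seqs = seqs, links = links,
                 members = members, graphType = graphType, meta = meta)
}

.emptyLinks <- function() {
    data.frame(from = character(), from_orient = character(),
               to = character(), to_orient = character(), ovl = integer(),
               stringsAsFactors = FALSE)
}

.flipOrient <- function(o) ifelse(o == "+", "-", "+")

# keep the lexicographically smaller of link/complement, then deduplicate
.canonLinks <- function(lk) {
    if (nrow(lk) == 0L) return(.emptyLinks())
    lk <- lk[, .LINK_COLS]
    lk$ovl <- as.integer(lk$ovl)
    key <- paste(lk$from, lk$from_orient, lk$to, lk$to_orient, lk$ovl)
    ckey <- paste(lk$to, .flipOrient(lk$to_orient), lk$from,
                  .flipOrient(lk$from_orient), lk$ovl)
    flip <- ckey < key
    if (any(flip)) {
        tmp <- lk[flip, , drop = FALSE]
        lk[flip, ] <- data.frame(from = tmp$to,
                                 from_orient = .flipOrient(tmp$to_orient),
                                 to = tmp$from,
                                 to_orient = .flipOrient(tmp$from_orient),
                                 ovl = tmp$ovl, stringsAsFactors = FALSE)
        key[flip] <- ckey[flip]
    }
    lk <- lk[!duplicated(key), , drop = FALSE]
    rownames(lk) <- NULL
    lk
}

# canonical links plus their complements (deduplicated for palindromic links)
.doubledLinks <- function(g) {
    lk <- g@links
    if (nrow(lk) == 0L) return(lk)
    comp <- data.frame(from = lk$to, from_orient = .flipOrient(lk$to_orient),
                       to = lk$from, to_orient = .flipOrient(lk$from_orient),
                       ovl = lk$ovl, stringsAsFactors = FALSE)
    all <- rbind(lk, comp)
    key <- paste(all$from, all$from_orient, all$to, all$to_orient, all$ovl)
    all <- all[!duplicated(key), , drop = FALSE]
    rownames(all) <- NULL
    all
}

#' Structure-aware profile model of an ncRNA family
#'
#' A simplified covariance model: an ordered set of consensus columns, a
#' nested set of base-paired column pairs, and log-odds emission scores (log2
#' against a background base distribution). Paired columns emit two bases
#' jointly (16-cell table); unpaired columns emit one base. Deleted consensus
#' columns and inserted target bases are linearly penalised. The gathering
#' threshold is the family-specific score above which a sequence is accepted
#' as a homolog.
#'
#' @slot familyId Family identifier.
#' @slot L Number of consensus columns.
#' @slot pairs Integer matrix with columns \code{i}, \code{j} (1-based
#'   consensus column indices, \code{i < j}), nested and disjoint.
#' @slot singleEmit 4 x L matrix (rows A, C, G, T) of log-odds scores;
#'   columns belonging to a pair are ignored.
#' @slot pairEmit 16 x P matrix (row order A/A, A/C, ..., T/T) for the paired
#'   columns, one column per row of \code{pairs}.
#' @slot gapPenalty Score for deleting one consensus column (negative).
#' @slot insertPenalty Score per inserted target base (negative).
#' @slot gaThreshold Gathering score threshold (bits).
#' @slot nullFreq Background base frequencies (A, C, G, T).
#' @seealso [buildProfileModel()], [alignModel()], [scanEdges()],
#'   [sampleFromModel()]
#' @export
setClass("ProfileModel",
    representation(familyId = "character", L = "integer", pairs = "matrix",
                   singleEmit = "matrix", pairEmit = "matrix",
                   gapPenalty = "numeric", insertPenalty = "numeric",
                   gaThreshold = "numeric", nullFreq = "numeric"))

setValidity("ProfileModel", function(object) {
    msg <- character()
    L <- object@L
    p <- object@pairs
    if (length(L) != 1L || is.na(L) || L < 1L) msg <- c(msg, "L must be >= 1")
    if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
    if (nrow(p) > 0L && length(msg) == 0L) {
        if (any(p < 1L | p > L)) msg <- c(msg, "pair columns out of range")
        if (any(p[, 1L] >= p[, 2L])) msg <- c(msg, "pairs must satisfy i < j")
        if (anyDuplicated(as.vector(p)))
            msg <- c(msg, "a column may belong to at most one pair")
        # nestedness: no crossing pairs
        if (nrow(p) > 1L) {
            for (a in seq_len(nrow(p) - 1L)) for (b in seq(a + 1L, nrow(p))) {
                i <- p[a, 1L]; j <- p[a, 2L]; k <- p[b, 1L]; l <- p[b, 2L]
                crossing <- (i < k & k < j & j < l) | (k < i & i < l & l < j)
                if (crossing) { msg <- c(msg, "pair set must be nested"); break }
            }
        }
    }
    if (!identical(dim(object@singleEmit), c(4L, L)))
        msg <- c(msg, "singleEmit must be 4 x L")
    if (!identical(dim(object@pairEmit), c(16L, nrow(p))))
        msg <- c(msg, "pairEmit must be 16 x nrow(pairs)")
    if (!is.finite(object@gaThreshold)) msg <- c(msg, "gaThreshold must be finite")
    if (any(!is.finite(object@singleEmit)) || any(!is.finite(object@pairEmit)))
        msg <- c(msg, "emission scores must be finite")
    if (length(object@nullFreq) != 4L || abs(sum(object@nullFreq) - 1) > 1e-6)
        msg <- c(msg, "nullFreq must be 4 frequencies summing to 1")
    if (length(msg)) msg else TRUE
})
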