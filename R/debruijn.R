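#' Parameters for de Bruijn graph construction
#'
#' @param k k-mer length in bases (2..31). Default 21 for realistic reads;
#'   the classic toy illustration uses 3.
#' @param min_kmer_count Minimum k-mer multiplicity; k-mers seen fewer times
#'   are dropped. Default 1 (no abundance filtering) so that low-abundance
#'   families are not lost; error-prone data benefit from 2.
#' @param use_revcomp Fold k-mers onto their canonical (lexicographically
#'   smaller) strand.
#' @return A validated parameter list of class \code{DeBruijnParams}.
#' @export
DeBruijnParams <- function(k = 21L, min_kmer_count = 1L, use_revcomp = TRUE) {
    k <- as.integer(k); min_kmer_count <- as.integer(min_kmer_count)
    stopifnot(k >= 2L, k <= 31L, min_kmer_count >= 1L)
    structure(list(k = k, min_kmer_count = min_kmer_count,
                   use_revcomp = use_revcomp), class = "DeBruijnParams")
}

#' Build the de Bruijn graph from reads
#'
#' Vertices are (k-1)-mers; each surviving k-mer is one sequence-labelled
#' segment, linked to its successors with an overlap of k-1. Reads shorter
#' than k are skipped (their count is recorded in the graph metadata);
#' k-mers containing N are never formed. No topological simplification (tip
#' clipping, bubble popping) is performed: preserving low-coverage structure
#' is the point of searching the graph rather than contigs.
#'
#' @param reads Named \code{DNAStringSet} or character vector.
#' @param params A [DeBruijnParams()] list.
#' @return An \linkS4class{AssemblyGraph} of type \code{"debruijn"}; k-mer
#'   multiplicities are kept in \code{metadata} (\code{meta$counts}).
#' @examples
#' g <- buildDeBruijnGraph(c(r1 = "ACGTA"), DeBruijnParams(k = 3))
#' nSegs(g)  # ACG, CGT, GTA
#' @export
buildDeBruijnGraph <- function(reads, params = DeBruijnParams()) {
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    k <- params$k
    nShort <- sum(nchar(seqs) < k)
    tab <- cpp_count_kmers(unname(seqs), k, params$use_revcomp)
    tab <- tab[tab$count >= params$min_kmer_count, , drop = FALSE]
    if (nrow(tab) == 0L)
        return(AssemblyGraph(Biostrings::DNAStringSet(), members = list(),
                             graphType = "debruijn",
                             meta = list(params = params, n_short = nShort)))
    ids <- sprintf("k%06d", seq_len(nrow(tab)))
    kmers <- tab$kmer
    # oriented k-mers: canonical (+) and, with strand folding, complement (-)
    oriKmer <- kmers; oriOr <- rep("+", length(kmers)); oriIdx <- seq_along(kmers)
    if (params$use_revcomp) {
        rc <- revComp(kmers)
        notPal <- rc != kmers
        oriKmer <- c(oriKmer, rc[notPal])
        oriOr <- c(oriOr, rep("-", sum(notPal)))
        oriIdx <- c(oriIdx, which(notPal))
    }
    pre <- substr(oriKmer, 1L, k - 1L)
    suf <- substr(oriKmer, 2L, k)
    byPre <- split(seq_along(oriKmer), pre)
    sel <- byPre[suf]
    nsucc <- lengths(sel)
    fromIdx <- rep(seq_along(oriKmer), nsucc)
    succIdx <- unlist(sel, use.names = FALSE)
    links <- .emptyLinks()
    if (length(succIdx) > 0L)
        links <- data.frame(from = ids[oriIdx[fromIdx]],
                            from_orient = oriOr[fromIdx],
                            to = ids[oriIdx[succIdx]],
                            to_orient = oriOr[succIdx],
                            ovl = k - 1L, stringsAsFactors = FALSE)
    members <- lapply(stats::setNames(ids, ids), function(id)
        data.frame(read_id = character(), offset = integer(),
                   orient = character(), stringsAsFactors = FALSE))
    AssemblyGraph(stats::setNames(kmers, ids), links, members,
                  graphType = "debruijn",
                  meta = list(params = params, n_short = nShort,
                              counts = stats::setNames(tab$count, ids)))
}

#' Extract maximal non-branching contigs from a de Bruijn graph
#'
#' Condenses the graph and spells each resulting segment; every surviving
#' k-mer appears in exactly one contig.
#'
#' @param graph A de Bruijn \linkS4class{AssemblyGraph}.
#' @return \code{data.frame(contig_id, seq, verified)} with \code{verified}
#'   set to \code{NA} (see [verifyContigs()]).
#' @export
extractContigs <- function(graph) {
    stopifnot(methods::is(graph, "AssemblyGraph"))
    cg <- condense(graph)
    if (nSegs(cg) == 0L)
        return(data.frame(contig_id = character(), seq = character(),
                          verified = logical(), stringsAsFactors = FALSE))
    data.frame(contig_id = sprintf("c%04d", seq_len(nSegs(cg))),
               seq = unname(as.character(segSeqs(cg))),
               verified = NA, stringsAsFactors = FALSE)
}

#' Flag contigs without coverage holes
#'
#' A contig is verified when every base is covered by at least one read
#' placement; reads may be clipped only at the contig ends. Placements are
#' seed-anchored ungapped alignments accepting up to
#' \code{max_mismatch_frac} mismatches, mirroring how a read mapper (rather
#' than an exact matcher) would establish coverage on error-bearing data.
#' Chimeric junctions spelled by k-mer chaining but crossed by no single
#' read leave a zero-coverage position and fail verification. Unverified
#' contigs are kept but excluded from graph merging.
#'
#' @param contigs Output of [extractContigs()].
#' @param reads The read set the graph was built from.
#' @param max_mismatch_frac Mismatch tolerance of a placement (default
#'   0.05; use 0 for exact coverage).
#' @param seed_k Exact seed length anchoring candidate placements; reads
#'   shorter than this are matched exactly.
#' @return The contig \code{data.frame} with \code{verified} filled in.
#' @export
verifyContigs <- function(contigs, reads, max_mismatch_frac = 0.05,
                          seed_k = 15L) {
    if (nrow(contigs) == 0L) return(contigs)
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    if (length(seqs) == 0L) {
        contigs$verified <- FALSE
        return(contigs)
    }
    contigs$verified <- as.logical(cpp_verify_contigs(
        contigs$seq, unname(seqs), max_mismatch_frac, as.integer(seed_k)))
    contigs
}
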