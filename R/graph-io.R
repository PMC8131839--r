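#' Export an assembly graph as GFA1
#'
#' Segments become \code{S} lines, links become \code{L} lines with an
#' \code{<ovl>M} overlap CIGAR.
#'
#' @param graph An \linkS4class{AssemblyGraph}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeGFA <- function(graph, path) {
    seqs <- as.character(segSeqs(graph))
    s <- sprintf("S\t%s\t%s", names(seqs), unname(seqs))
    lk <- segLinks(graph)
    l <- if (nrow(lk) > 0L)
        sprintf("L\t%s\t%s\t%s\t%s\t%dM", lk$from, lk$from_orient, lk$to,
                lk$to_orient, lk$ovl)
    else character()
    writeLines(c("H\tVN:Z:1.0", s, l), path)
    invisible(path)
}

#' Import an externally built string graph from ASQG-like text
#'
#' Reads \code{VT} (vertex: id, sequence) and \code{ED} (edge: the standard
#' 10-field overlap record \code{id1 id2 s1 e1 l1 s2 e2 l2 rc nd}) records.
#' Only proper suffix-prefix overlaps are imported; containment records are
#' skipped with a warning.
#'
#' @param path ASQG(-like) file (plain text or gzip).
#' @return An \linkS4class{AssemblyGraph} of type \code{"string"}.
#' @export
readASQG <- function(path) {
    lines <- readLines(path)
    vt <- lines[startsWith(lines, "VT")]
    ed <- lines[startsWith(lines, "ED")]
    if (length(vt) == 0L) stop("no VT records in ", path)
    vf <- strsplit(vt, "\t")
    ids <- vapply(vf, `[[`, "", 2L)
    seqs <- toupper(vapply(vf, `[[`, "", 3L))
    names(seqs) <- ids
    links <- .emptyLinks()
    nContain <- 0L
    if (length(ed) > 0L) {
        rows <- list()
        for (e in ed) {
            f <- strsplit(sub("^ED\\s+", "", e), "\\s+")[[1]]
            id1 <- f[1]; id2 <- f[2]
            s1 <- as.integer(f[3]); e1 <- as.integer(f[4])
            l1 <- as.integer(f[5])
            s2 <- as.integer(f[6]); e2 <- as.integer(f[7])
            l2 <- as.integer(f[8])
            rc <- as.integer(f[9])
            ovl <- e1 - s1 + 1L
            full1 <- s1 == 0L && e1 == l1 - 1L
            full2 <- s2 == 0L && e2 == l2 - 1L
            if (full1 || full2) { nContain <- nContain + 1L; next }
            # overlap at the end of read1 -> read1 precedes read2
            if (e1 == l1 - 1L) {
                from <- id1; fo <- "+"
                to <- id2; to_or <- if (rc == 1L) "-" else "+"
            } else {
                from <- id2; fo <- if (rc == 1L) "-" else "+"
                to <- id1; to_or <- "+"
            }
            rows[[length(rows) + 1L]] <- data.frame(
                from = from, from_orient = fo, to = to, to_orient = to_or,
                ovl = ovl, stringsAsFactors = FALSE)
        }
        if (length(rows) > 0L) links <- do.call(rbind, rows)
    }
    if (nContain > 0L)
        warning(nContain, " containment ED records skipped")
    AssemblyGraph(seqs, links, graphType = "string",
                  meta = list(source = path,
                              read_lengths = stats::setNames(nchar(seqs),
                                                             ids)))
}

#' Read or write contigs as FASTA
#'
#' Interchange with externally produced contigs (verification flags are
#' reset to \code{NA} on read).
#'
#' @param contigs Contig \code{data.frame} (see [extractContigs()]).
#' @param path FASTA file.
#' @return \code{writeContigs}: \code{path} invisibly; \code{readContigs}:
#'   a contig \code{data.frame}.
#' @export
writeContigs <- function(contigs, path) {
    writeSequences(stats::setNames(contigs$seq, contigs$contig_id), path,
                   "fasta")
}

#' @rdname writeContigs
#' @export
readContigs <- function(path) {
    x <- readSequences(path, "fasta")
    data.frame(contig_id = names(x), seq = as.character(x), verified = NA,
               stringsAsFactors = FALSE)
}
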