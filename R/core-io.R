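#' Read short-read sequences from FASTA or FASTQ
#'
#' Records are returned as a named \link[Biostrings]{DNAStringSet} in file
#' order, uppercased. Mate pairing is inferred from \code{/1} / \code{/2}
#' name suffixes or from a whitespace-separated \code{1:...} / \code{2:...}
#' comment field; paired records are cross-linked through the \code{mate_id}
#' metadata column. Plain-gzip input is handled transparently.
#'
#' @param path Input file.
#' @param format \code{"fasta"} or \code{"fastq"}; FASTQ qualities are parsed
#'   by the reader and discarded.
#' @return A \code{DNAStringSet} with metadata columns \code{mate_id} (NA
#'   when unpaired) and placeholder truth columns \code{genome_id},
#'   \code{start}, \code{end}, \code{strand} (all NA; filled by the
#'   simulator or by mapping).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "acgt"), fa)
#' readSequences(fa, "fasta")
#' @export
readSequences <- function(path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    x <- Biostrings::readDNAStringSet(path, format = format)
    nm <- sub("\\s.*$", "", names(x))
    comment <- sub("^\\S+\\s*", "", names(x))
    mate <- rep(NA_character_, length(x))
    suff <- regmatches(nm, regexpr("/[12]$", nm))
    hasSuff <- grepl("/[12]$", nm)
    if (any(hasSuff)) {
        base <- sub("/[12]$", "", nm)
        mateName <- ifelse(suff == "/1", paste0(base, "/2"), paste0(base, "/1"))
        mate[hasSuff] <- ifelse(mateName[hasSuff] %in% nm, mateName[hasSuff],
                                NA_character_)
    }
    # whitespace-mate convention (Illumina "name 1:..." / "name 2:..."):
    # mates share the bare name; disambiguate with /1 /2 and cross-link
    casava <- grepl("^[12]:", comment) & !hasSuff
    dupd <- casava & nm %in% nm[duplicated(nm[casava])]
    if (any(dupd)) {
        tag <- substr(comment, 1L, 1L)
        newNm <- ifelse(dupd, paste0(nm, "/", tag), nm)
        mate[dupd] <- paste0(nm[dupd], "/", ifelse(tag[dupd] == "1", "2", "1"))
        nm <- newNm
        mate[dupd][!(mate[dupd] %in% nm)] <- NA_character_
    }
    seqs <- Biostrings::DNAStringSet(toupper(x))
    names(seqs) <- nm
    if (anyDuplicated(nm)) stop("duplicate read identifiers after pairing")
    n <- length(seqs)
    S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
        mate_id = mate, genome_id = rep(NA_character_, n),
        start = rep(NA_integer_, n), end = rep(NA_integer_, n),
        strand = rep(NA_character_, n))
    seqs
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs A named \code{DNAStringSet} (or named character vector).
#' @param path Output file.
#' @param format \code{"fasta"} or \code{"fastq"} (constant maximum quality
#'   is written, as the pipeline is quality-agnostic).
#' @return \code{path}, invisibly.
#' @export
writeSequences <- function(seqs, path, format = c("fasta", "fastq")) {
    format <- match.arg(format)
    if (!methods::is(seqs, "DNAStringSet"))
        seqs <- Biostrings::DNAStringSet(seqs)
    if (format == "fasta") {
        Biostrings::writeXStringSet(seqs, path)
    } else {
        q <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
        Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = q)
    }
    invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' Alphabet \{A, C, G, T, N\}; N maps to N. An involution that preserves
#' length.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revComp("AAC")   # "GTT"
#' revComp("ACGT")  # "ACGT"
#' @export
revComp <- function(seq) {
    if (any(grepl("[^ACGTN]", seq)))
        stop("sequence contains characters outside {A,C,G,T,N}")
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Read or write genomic interval annotations
#'
#' Tab-separated files with columns \code{genome_id}, \code{start},
#' \code{end}, \code{strand}, \code{family_id}; coordinates are 0-based
#' half-open throughout the package.
#'
#' @param path File path.
#' @return For \code{readIntervals}, a \code{data.frame} with the five
#'   columns above.
#' @export
readIntervals <- function(path) {
    x <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("genome_id", "start", "end", "strand", "family_id")
    if (!all(need %in% colnames(x)))
        stop("interval file must have columns: ", paste(need, collapse = ", "))
    if (any(x$start < 0L | x$start >= x$end))
        stop("intervals must satisfy 0 <= start < end")
    x[, need]
}

#' @rdname readIntervals
#' @param intervals \code{data.frame} of intervals to write.
#' @export
writeIntervals <- function(intervals, path) {
    utils::write.table(intervals, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
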