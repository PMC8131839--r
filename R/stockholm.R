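#' Read a Stockholm alignment with consensus structure
#'
#' Minimal Stockholm 1.0 reader sufficient for family model building:
#' sequence rows (interleaved blocks supported), the \code{#=GC SS_cons}
#' consensus-structure line, and the \code{#=GF GA} gathering threshold.
#'
#' @param path Stockholm file.
#' @return List with \code{aln} (named character vector of aligned rows,
#'   uppercase, U converted to T), \code{ss_cons} (character), and \code{ga}
#'   (numeric or NA).
#' @export
readStockholm <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    aln <- list()
    ss <- character()
    ga <- NA_real_
    for (ln in lines) {
        if (grepl("^# STOCKHOLM", ln) || ln == "//") next
        if (grepl("^#=GF\\s+GA\\s", ln)) {
            ga <- as.numeric(strsplit(trimws(ln), "\\s+")[[1]][3])
        } else if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
            ss <- c(ss, strsplit(trimws(ln), "\\s+")[[1]][3])
        } else if (!grepl("^#", ln)) {
            f <- strsplit(trimws(ln), "\\s+")[[1]]
            if (length(f) != 2L)
                stop("malformed Stockholm sequence line: ", ln)
            aln[[f[1]]] <- paste0(aln[[f[1]]] %||% "", f[2])
        }
    }
    if (length(aln) == 0L) stop("no sequence rows in ", path)
    if (length(ss) == 0L) stop("missing #=GC SS_cons line in ", path)
    rows <- toupper(unlist(aln))
    rows <- chartr("U", "T", rows)
    ssc <- paste0(ss, collapse = "")
    if (length(unique(nchar(rows))) != 1L || nchar(ssc) != nchar(rows[1]))
        stop("alignment rows and SS_cons have unequal lengths")
    list(aln = rows, ss_cons = ssc, ga = ga)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
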