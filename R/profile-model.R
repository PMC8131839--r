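.BASES <- c("A", "C", "G", "T")
.GAPCH <- c("-", ".", "_", "~", ",")

#' Build a structure-aware profile model from a Stockholm alignment
#'
#' Consensus columns are alignment columns with at most 50\% gaps. Base
#' pairs come from matching brackets in \code{SS_cons} (all WUSS bracket
#' types; pseudoknot letters are rejected), restricted to pairs whose two
#' columns are both consensus; a pair with only one consensus column
#' degrades to an unpaired column. Emission scores are Laplace-smoothed
#' log2 odds against the background: for unpaired columns
#' \code{log2(((count + pc) / (rows + 4 pc)) / null)}, and analogously over
#' the 16 base combinations for paired columns.
#'
#' @param x A file path or the list returned by [readStockholm()].
#' @param familyId Family identifier (defaults to the file base name).
#' @param ga Gathering threshold; used when the alignment has no
#'   \code{#=GF GA} line (an error if neither is available).
#' @param gapPenalty,insertPenalty Linear penalties (bits) for deleting a
#'   consensus column / inserting a target base.
#' @param pseudocount Laplace pseudocount for emission counts.
#' @param nullFreq Background base frequencies.
#' @return A \linkS4class{ProfileModel}.
#' @export
buildProfileModel <- function(x, familyId = NULL, ga = NULL,
                              gapPenalty = -2, insertPenalty = -2,
                              pseudocount = 1, nullFreq = rep(0.25, 4)) {
    if (is.character(x) && length(x) == 1L) {
        if (is.null(familyId))
            familyId <- sub("\\.[^.]*$", "", basename(x))
        x <- readStockholm(x)
    }
    if (is.null(familyId)) familyId <- "family"
    rows <- x$aln
    ss <- x$ss_cons
    n <- length(rows)
    if (n < 2L) stop("alignment must have at least 2 rows")
    mat <- do.call(rbind, strsplit(rows, ""))
    isGap <- matrix(mat %in% .GAPCH, nrow = n)
    gapFrac <- colMeans(isGap)
    consensus <- which(gapFrac <= 0.5)
    L <- length(consensus)
    if (L == 0L) stop("no consensus columns (all columns >50% gaps)")
    colMap <- match(seq_len(ncol(mat)), consensus)  # original -> consensus idx

    pairsAll <- .matchBrackets(ss)
    keep <- !is.na(colMap[pairsAll[, 1L]]) & !is.na(colMap[pairsAll[, 2L]])
    pairs <- cbind(colMap[pairsAll[keep, 1L]], colMap[pairsAll[keep, 2L]])
    if (nrow(pairs) > 0L) colnames(pairs) <- c("i", "j")
    pairedCols <- as.vector(pairs)

    null4 <- nullFreq / sum(nullFreq)
    singleEmit <- matrix(0, 4L, L, dimnames = list(.BASES, NULL))
    for (ci in seq_len(L)) {
        col <- mat[, consensus[ci]]
        cnt <- vapply(.BASES, function(b) sum(col == b), numeric(1))
        singleEmit[, ci] <- log2(((cnt + pseudocount) /
                                  (n + 4 * pseudocount)) / null4)
    }
    pairEmit <- matrix(0, 16L, max(1L, nrow(pairs)))[, seq_len(nrow(pairs)),
                                                     drop = FALSE]
    if (nrow(pairs) > 0L) {
        combos <- expand.grid(b2 = .BASES, b1 = .BASES)[, c("b1", "b2")]
        nullPair <- null4[match(combos$b1, .BASES)] *
                    null4[match(combos$b2, .BASES)]
        for (pi in seq_len(nrow(pairs))) {
            ci <- consensus[pairs[pi, 1L]]; cj <- consensus[pairs[pi, 2L]]
            b1 <- mat[, ci]; b2 <- mat[, cj]
            cnt <- vapply(seq_len(16L), function(q)
                sum(b1 == combos$b1[q] & b2 == combos$b2[q]), numeric(1))
            pairEmit[, pi] <- log2(((cnt + pseudocount) /
                                    (n + 16 * pseudocount)) / nullPair)
        }
    }
    gaVal <- if (!is.na(x$ga)) x$ga else ga
    if (is.null(gaVal))
        stop("no #=GF GA line in the alignment; supply ga=")
    methods::new("ProfileModel", familyId = familyId, L = L,
                 pairs = matrix(as.integer(pairs), ncol = 2L,
                                dimnames = list(NULL, c("i", "j"))),
                 singleEmit = singleEmit, pairEmit = pairEmit,
                 gapPenalty = gapPenalty, insertPenalty = insertPenalty,
                 gaThreshold = as.numeric(gaVal), nullFreq = null4)
}

# bracket matching over all WUSS bracket families; crossing pairs (between
# bracket families) surface later via the class validity check
.matchBrackets <- function(ss) {
    chars <- strsplit(ss, "")[[1]]
    if (any(grepl("[A-Za-z]", chars)))
        stop("pseudoknot letters in SS_cons are not supported")
    openers <- c("<" = ">", "(" = ")", "[" = "]", "{" = "}")
    out <- matrix(integer(), ncol = 2L)
    for (op in names(openers)) {
        cl <- openers[[op]]
        stack <- integer()
        for (i in seq_along(chars)) {
            if (chars[i] == op) stack <- c(stack, i)
            else if (chars[i] == cl) {
                if (length(stack) == 0L)
                    stop("unbalanced SS_cons: unmatched '", cl, "'")
                out <- rbind(out, c(stack[length(stack)], i))
                stack <- stack[-length(stack)]
            }
        }
        if (length(stack) > 0L)
            stop("unbalanced SS_cons: unmatched '", op, "'")
    }
    out[order(out[, 1L]), , drop = FALSE]
}

#' @rdname gaThreshold
#' @param x A \linkS4class{ProfileModel}.
#' @param value Replacement gathering threshold.
#' @export
setMethod("gaThreshold", "ProfileModel", function(x) x@gaThreshold)

#' Gathering threshold of a profile model
#'
#' @rdname gaThreshold
#' @export
setMethod("gaThreshold<-", "ProfileModel", function(x, value) {
    x@gaThreshold <- as.numeric(value)
    methods::validObject(x)
    x
})

setMethod("show", "ProfileModel", function(object) {
    cat(sprintf(
        "ProfileModel '%s': %d consensus columns, %d base pairs, GA = %.2f\n",
        object@familyId, object@L, nrow(object@pairs), object@gaThreshold))
    invisible(NULL)
})

#' Sample a sequence from a profile model
#'
#' Draws one base per unpaired consensus column and one jointly distributed
#' base pair per paired columns, from the emission distributions implied by
#' the log-odds scores (probability proportional to null * 2^score).
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param seed Optional integer; when given, sampling is deterministic and
#'   the caller's RNG state is untouched.
#' @return A nucleotide string of length \code{L}.
#' @export
sampleFromModel <- function(model, seed = NULL) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (!is.null(old)) assign(".Random.seed", old, globalenv())
        })
        set.seed(seed)
    }
    L <- model@L
    out <- character(L)
    paired <- if (nrow(model@pairs)) as.vector(model@pairs) else integer()
    for (ci in setdiff(seq_len(L), paired)) {
        p <- model@nullFreq * 2^model@singleEmit[, ci]
        out[ci] <- sample(.BASES, 1L, prob = p / sum(p))
    }
    if (nrow(model@pairs) > 0L) for (pi in seq_len(nrow(model@pairs))) {
        # row order of pairEmit is b1-major (A/A, A/C, ..., T/T)
        nullPair <- rep(model@nullFreq, each = 4L) *
                    rep(model@nullFreq, times = 4L)
        p <- nullPair * 2^model@pairEmit[, pi]
        q <- sample.int(16L, 1L, prob = p / sum(p))
        out[model@pairs[pi, 1L]] <- .BASES[(q - 1L) %/% 4L + 1L]
        out[model@pairs[pi, 2L]] <- .BASES[(q - 1L) %% 4L + 1L]
    }
    paste0(out, collapse = "")
}

#' Write or read a profile model as flat text
#'
#' YAML serialisation of all model fields, so externally built models can be
#' supplied and models can be reused across pipeline stages.
#'
#' @param model A \linkS4class{ProfileModel}.
#' @param path File path.
#' @return \code{writeProfileModel}: \code{path}, invisibly;
#'   \code{readProfileModel}: a \linkS4class{ProfileModel}.
#' @export
writeProfileModel <- function(model, path) {
    obj <- list(family_id = model@familyId, L = model@L,
                pairs_i = as.integer(model@pairs[, 1L]),
                pairs_j = as.integer(model@pairs[, 2L]),
                single_emit = as.numeric(model@singleEmit),
                pair_emit = as.numeric(model@pairEmit),
                gap_penalty = model@gapPenalty,
                insert_penalty = model@insertPenalty,
                ga_threshold = model@gaThreshold,
                null_freq = as.numeric(model@nullFreq))
    yaml::write_yaml(obj, path, precision = 12L)
    invisible(path)
}

#' @rdname writeProfileModel
#' @export
readProfileModel <- function(path) {
    o <- yaml::read_yaml(path)
    L <- as.integer(o$L)
    np <- length(o$pairs_i)
    methods::new("ProfileModel", familyId = o$family_id, L = L,
                 pairs = matrix(as.integer(c(o$pairs_i, o$pairs_j)),
                                ncol = 2L, dimnames = list(NULL, c("i", "j"))),
                 singleEmit = matrix(as.numeric(o$single_emit), 4L, L,
                                     dimnames = list(.BASES, NULL)),
                 pairEmit = matrix(as.numeric(o$pair_emit), 16L, np),
                 gapPenalty = o$gap_penalty, insertPenalty = o$insert_penalty,
                 gaThreshold = o$ga_threshold,
                 nullFreq = as.numeric(o$null_freq))
}
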