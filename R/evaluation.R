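#' Parameters for ground-truth labelling
#'
#' @param truth_cover_frac Fraction of a read's length that must fall
#'   inside an annotated family interval for the read to be ground-truth
#'   positive; strict inequality (default 0.60, i.e. ">60\% of their total
#'   lengths").
#' @return A validated list of class \code{EvalParams}.
#' @export
EvalParams <- function(truth_cover_frac = 0.60) {
    stopifnot(truth_cover_frac > 0, truth_cover_frac < 1)
    structure(list(truth_cover_frac = truth_cover_frac),
              class = "EvalParams")
}

#' Label ground-truth family membership of reads
#'
#' A read is labelled with family F when the overlap between its source
#' interval and an F-annotated interval strictly exceeds
#' \code{truth_cover_frac} of the read's length. Reads without a source
#' interval are background.
#'
#' @param reads \code{DNAStringSet} whose metadata columns carry the truth
#'   source interval (\code{genome_id}, \code{start}, \code{end}), as
#'   produced by [simulateReads()], or a \code{data.frame} with columns
#'   \code{read_id}, \code{genome_id}, \code{start}, \code{end},
#'   \code{length}.
#' @param annotations Interval \code{data.frame} (see [readIntervals()]).
#' @param params An [EvalParams()] list.
#' @return Named list: for each family id, the character vector of positive
#'   read ids.
#' @export
labelGroundTruth <- function(reads, annotations, params = EvalParams()) {
    if (methods::is(reads, "DNAStringSet")) {
        mc <- S4Vectors::mcols(reads)
        tab <- data.frame(read_id = names(reads),
                          genome_id = mc$genome_id,
                          start = mc$start, end = mc$end,
                          length = Biostrings::width(reads),
                          stringsAsFactors = FALSE)
    } else tab <- reads
    fams <- unique(annotations$family_id)
    out <- stats::setNames(vector("list", length(fams)), fams)
    has <- !is.na(tab$genome_id)
    for (f in fams) {
        ann <- annotations[annotations$family_id == f, , drop = FALSE]
        pos <- character()
        if (nrow(ann) > 0L && any(has)) {
            t2 <- tab[has, , drop = FALSE]
            rr <- IRanges::IRanges(start = t2$start + 1L, end = t2$end)
            ar <- IRanges::IRanges(start = ann$start + 1L, end = ann$end)
            ho <- IRanges::findOverlaps(rr, ar)
            if (length(ho) > 0L) {
                ovl <- IRanges::width(IRanges::pintersect(
                    rr[S4Vectors::queryHits(ho)],
                    ar[S4Vectors::subjectHits(ho)]))
                sameGenome <- t2$genome_id[S4Vectors::queryHits(ho)] ==
                              ann$genome_id[S4Vectors::subjectHits(ho)]
                qualify <- sameGenome &
                    ovl > params$truth_cover_frac *
                          t2$length[S4Vectors::queryHits(ho)]
                pos <- unique(t2$read_id[S4Vectors::queryHits(ho)[qualify]])
            }
        }
        out[[f]] <- pos
    }
    out
}

#' Confusion counts and derived metrics per family
#'
#' TP = predicted and true, FP = predicted only, FN = true only; recall =
#' TP/(TP+FN), precision = TP/(TP+FP), F = harmonic mean. Undefined
#' precision or recall (empty denominator) is reported as 0 with the
#' \code{degenerate} flag set. The unweighted arithmetic mean across
#' families is appended as row \code{"mean"}.
#'
#' @param predicted Named list: per family, character vector of predicted
#'   read ids.
#' @param truth Named list from [labelGroundTruth()] (same family set).
#' @return \code{data.frame(family_id, TP, FP, FN, recall, precision,
#'   f_score, degenerate)}.
#' @export
scorePredictions <- function(predicted, truth) {
    fams <- union(names(truth), names(predicted))
    rows <- lapply(fams, function(f) {
        p <- unique(predicted[[f]] %||% character())
        t <- unique(truth[[f]] %||% character())
        TP <- length(intersect(p, t))
        FP <- length(setdiff(p, t))
        FN <- length(setdiff(t, p))
        degenerate <- (TP + FN) == 0L || (TP + FP) == 0L
        recall <- if (TP + FN > 0L) TP / (TP + FN) else 0
        precision <- if (TP + FP > 0L) TP / (TP + FP) else 0
        f_score <- if (recall + precision > 0) {
            2 * recall * precision / (recall + precision)
        } else 0
        data.frame(family_id = f, TP = TP, FP = FP, FN = FN, recall = recall,
                   precision = precision, f_score = f_score,
                   degenerate = degenerate, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    mean_row <- data.frame(family_id = "mean", TP = NA_integer_,
                           FP = NA_integer_, FN = NA_integer_,
                           recall = mean(out$recall),
                           precision = mean(out$precision),
                           f_score = mean(out$f_score), degenerate = NA,
                           stringsAsFactors = FALSE)
    rbind(out, mean_row)
}

#' Area under the extrapolated precision-recall ROC curve
#'
#' Points are sorted by recall, duplicate recalls averaged, the curve
#' extrapolated to (recall 0, precision 1) and (recall 1, precision 0),
#' and integrated over recall by the trapezoid rule.
#'
#' @param points \code{data.frame} with columns \code{recall} and
#'   \code{precision} (one point per stringency cutoff).
#' @return The area, in [0, 1].
#' @examples
#' rocAuc(data.frame(recall = 0.5, precision = 0.5))  # 0.5
#' @export
rocAuc <- function(points) {
    stopifnot(nrow(points) >= 1L,
              all(points$recall >= 0 & points$recall <= 1),
              all(points$precision >= 0 & points$precision <= 1))
    agg <- stats::aggregate(precision ~ recall, data = points, FUN = mean)
    agg <- agg[order(agg$recall), , drop = FALSE]
    # extrapolation endpoints; segments at duplicate recall have zero width
    r <- c(0, agg$recall, 1)
    p <- c(1, agg$precision, 0)
    sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Sweep stringency cutoffs into ROC points
#'
#' Re-classifies and re-assigns at each threshold (paths and anchors are
#' computed once at the loosest threshold; classification and read
#' assignment are repeated per cutoff, which is what a stringency sweep
#' varies), then scores against the truth labels.
#'
#' @param reads Read set.
#' @param model A \linkS4class{ProfileModel}.
#' @param hybrid Condensed hybrid graph for \code{reads}.
#' @param truth Truth labels for the model's family
#'   ([labelGroundTruth()] output element).
#' @param thresholds Numeric vector of classification cutoffs.
#' @param params A [SearchParams()] list.
#' @return \code{data.frame(threshold, recall, precision)}.
#' @export
rocSweep <- function(reads, model, hybrid, truth,
                     thresholds, params = SearchParams()) {
    params$anchor_threshold <- params$anchor_threshold %||%
        (0.4 * min(thresholds))
    anchors <- findAnchors(hybrid, model, params)
    paths <- list()
    if (nrow(anchors) > 0L) for (ai in seq_len(nrow(anchors))) {
        budgets <- extensionBudget(anchors[ai, ], model, params)
        paths <- c(paths, enumeratePaths(hybrid, anchors[ai, ], budgets,
                                         params))
    }
    paths <- dedupePaths(paths, params)
    rows <- lapply(thresholds, function(th) {
        hom <- classifyPaths(paths, model, threshold = th)
        res <- assignReads(hom, reads, params, familyId = model@familyId)
        sc <- scorePredictions(
            stats::setNames(list(res$read_assignments$read_id),
                            model@familyId),
            stats::setNames(list(truth), model@familyId))
        sc <- sc[sc$family_id == model@familyId, ]
        data.frame(threshold = th, recall = sc$recall,
                   precision = sc$precision)
    })
    do.call(rbind, rows)
}
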