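#' Parameters for anchor-based graph search
#'
#' @param anchor_threshold Minimum edge-hit score for an anchor; default
#'   \code{NULL} means 0.4 x the model's gathering threshold.
#' @param extension_slack Fractional budget slack added to the unaligned
#'   model prefix/suffix lengths (default 0.10, "10\% for potential gaps").
#' @param identity_cutoff Redundancy-clustering identity over the shorter
#'   sequence (default 0.95).
#' @param max_paths_per_anchor Path-explosion cap per anchor (logged when
#'   hit).
#' @param max_path_depth Maximum number of edges per candidate path.
#' @param read_cover_frac Fraction of a read's length that must align
#'   inside a homologous path's model-aligned region for assignment
#'   (strict >, mirroring the >60\% ground-truth rule).
#' @return A validated parameter list of class \code{SearchParams}.
#' @export
SearchParams <- function(anchor_threshold = NULL, extension_slack = 0.10,
                         identity_cutoff = 0.95, max_paths_per_anchor = 1000L,
                         max_path_depth = 20L, read_cover_frac = 0.60) {
    stopifnot(extension_slack > 0, extension_slack < 1,
              identity_cutoff > 0, identity_cutoff <= 1,
              max_paths_per_anchor >= 1L, max_path_depth >= 1L,
              read_cover_frac > 0, read_cover_frac < 1)
    structure(list(anchor_threshold = anchor_threshold,
                   extension_slack = extension_slack,
                   identity_cutoff = identity_cutoff,
                   max_paths_per_anchor = as.integer(max_paths_per_anchor),
                   max_path_depth = as.integer(max_path_depth),
                   read_cover_frac = read_cover_frac),
              class = "SearchParams")
}

.anchorThreshold <- function(params, model) {
    params$anchor_threshold %||% (0.4 * gaThreshold(model))
}

#' Detect anchor edges for a model
#'
#' Thin wrapper over [scanEdges()] at the anchor threshold.
#'
#' @param hybrid A condensed hybrid \linkS4class{AssemblyGraph}.
#' @param model A \linkS4class{ProfileModel}.
#' @param params A [SearchParams()] list.
#' @return The [scanEdges()] hit table.
#' @export
findAnchors <- function(hybrid, model, params = SearchParams()) {
    scanEdges(model, hybrid, .anchorThreshold(params, model))
}

#' Extension budget from the unaligned model prefix and suffix
#'
#' \code{left = ceil(prefix * (1 + slack))} where \code{prefix} is the
#' number of consensus columns before the hit's model span, and analogously
#' for the suffix.
#'
#' @param hit A hit row (needs \code{m_start}, \code{m_end}) or a
#'   \code{ModelHit}.
#' @param model The \linkS4class{ProfileModel} the hit refers to.
#' @param params A [SearchParams()] list.
#' @return \code{c(left, right)} in bases.
#' @examples
#' h <- list(m_start = 20, m_end = 80)
#' # L = 100: both unaligned lengths are 20 -> ceil(22) each side
#' @export
extensionBudget <- function(hit, model, params = SearchParams()) {
    ms <- if (!is.null(hit$m_start)) hit$m_start else hit$model_span[1L]
    me <- if (!is.null(hit$m_end)) hit$m_end else hit$model_span[2L]
    pre <- ms
    suf <- model@L - me
    c(left = as.integer(ceiling(pre * (1 + params$extension_slack))),
      right = as.integer(ceiling(suf * (1 + params$extension_slack))))
}

#' Enumerate candidate paths by budgeted anchor extension
#'
#' Depth-first extension of the anchor edge in both directions, spelling at
#' most \code{budgets[1]} extra bases upstream of the hit strand's 5' end
#' and \code{budgets[2]} downstream; a partial final edge is truncated to
#' the budget. Every distinct maximal extension combination yields one
#' path, plus the unextended anchor itself. Enumeration honours
#' \code{max_path_depth} and stops at \code{max_paths_per_anchor} (with a
#' warning).
#'
#' @param hybrid A condensed hybrid \linkS4class{AssemblyGraph}.
#' @param anchor One row of the [findAnchors()] table.
#' @param budgets \code{c(left, right)} from [extensionBudget()].
#' @param params A [SearchParams()] list.
#' @return List of candidate paths: each has \code{segs}, \code{orients},
#'   \code{seq}, \code{anchor}.
#' @export
enumeratePaths <- function(hybrid, anchor, budgets, params = SearchParams()) {
    dl <- .doubledLinks(hybrid)
    ao <- anchor$strand  # orient the anchor so the hit reads on '+'
    # directional DFS: returns list of chains (possibly empty chain)
    extend <- function(seg, orient, budget, forward) {
        res <- list(list(segs = character(), orients = character(),
                         bases = 0L))
        if (budget <= 0L) return(res)
        rec <- function(seg, orient, got, segs, orients, depth) {
            nb <- if (forward) .outLinks(dl, seg, orient)
                  else .inLinks(dl, seg, orient)
            extended <- FALSE
            if (nrow(nb) > 0L && depth < params$max_path_depth)
                for (i in seq_len(nrow(nb))) {
                    if (length(res) >= params$max_paths_per_anchor) break
                    ns <- if (forward) nb$to[i] else nb$from[i]
                    no <- if (forward) nb$to_orient[i] else nb$from_orient[i]
                    contrib <- nchar(seqs[[ns]]) - nb$ovl[i]
                    if (contrib <= 0L) next
                    extended <- TRUE
                    got2 <- got + contrib
                    segs2 <- if (forward) c(segs, ns) else c(ns, segs)
                    ors2 <- if (forward) c(orients, no) else c(no, orients)
                    if (got2 >= budget) {
                        res[[length(res) + 1L]] <<- list(segs = segs2,
                                                         orients = ors2,
                                                         bases = got2)
                    } else {
                        rec(ns, no, got2, segs2, ors2, depth + 1L)
                    }
                }
            if (!extended && length(segs) > 0L)
                res[[length(res) + 1L]] <<- list(segs = segs, orients = orients,
                                                 bases = got)
            invisible(NULL)
        }
        rec(seg, orient, 0L, character(), character(), 0L)
        res
    }
    seqs <- as.character(segSeqs(hybrid))
    lefts <- extend(anchor$seg_id, ao, budgets[1L], forward = FALSE)
    rights <- extend(anchor$seg_id, ao, budgets[2L], forward = TRUE)
    paths <- list()
    truncated <- FALSE
    for (lf in lefts) for (rt in rights) {
        if (length(paths) >= params$max_paths_per_anchor) {
            truncated <- TRUE
            break
        }
        segs <- c(lf$segs, anchor$seg_id, rt$segs)
        orients <- c(lf$orients, ao, rt$orients)
        seq <- spellWalk(hybrid, segs, orients)
        ltrim <- max(0L, lf$bases - budgets[1L])
        rtrim <- max(0L, rt$bases - budgets[2L])
        seq <- substr(seq, ltrim + 1L, nchar(seq) - rtrim)
        paths[[length(paths) + 1L]] <- list(segs = segs, orients = orients,
                                            seq = seq, anchor = anchor)
    }
    if (truncated)
        warning("path enumeration truncated at max_paths_per_anchor")
    paths
}

#' Remove redundant candidate paths by greedy identity clustering
#'
#' Paths are sorted by length (descending); each path joins the first
#' cluster whose representative shares at least \code{identity_cutoff}
#' identity over the shorter sequence (containment-style, either strand),
#' otherwise it founds a new cluster. Cluster representatives are returned.
#'
#' @param paths List of candidate paths (from [enumeratePaths()]).
#' @param params A [SearchParams()] list.
#' @return The nonredundant sublist.
#' @export
dedupePaths <- function(paths, params = SearchParams()) {
    if (length(paths) <= 1L) return(paths)
    # collapse byte-identical sequences first
    seqs <- vapply(paths, `[[`, "", "seq")
    paths <- paths[!duplicated(seqs)]
    ord <- order(-vapply(paths, function(p) nchar(p$seq), integer(1)))
    reps <- list()
    repSeeds <- list()
    k <- 12L
    for (i in ord) {
        s <- paths[[i]]$seq
        sSeeds <- .seedSet(s, k)
        dup <- FALSE
        for (ri in seq_along(reps)) {
            r <- reps[[ri]]$seq
            # fast containment (identity 1 over the shorter sequence)
            if (grepl(s, r, fixed = TRUE) ||
                grepl(revComp(s), r, fixed = TRUE)) {
                dup <- TRUE
                break
            }
            # high identity needs long exact runs, hence many shared seeds;
            # a generous margin below the cutoff's expectation is safe
            if (length(sSeeds) > 4L &&
                mean(sSeeds %in% repSeeds[[ri]]) < 0.3) next
            if (.seqIdentity(s, r) >= params$identity_cutoff) {
                dup <- TRUE
                break
            }
        }
        if (!dup) {
            reps[[length(reps) + 1L]] <- paths[[i]]
            repSeeds[[length(reps)]] <- .seedSet(paste(s, revComp(s)), k)
        }
    }
    reps
}

# identity over the shorter sequence: matched bases in the best local
# alignment (either strand), unit match scoring
.seqIdentity <- function(a, b) {
    if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
    if (nchar(a) == 0L) return(0)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
    nm <- 0L
    for (q in c(a, revComp(a))) {
        al <- Biostrings::pairwiseAlignment(q, b, type = "local",
                                            substitutionMatrix = mat,
                                            gapOpening = 2, gapExtension = 1)
        nm <- max(nm, Biostrings::nmatch(al))
    }
    nm / nchar(a)
}

#' Classify nonredundant paths against the model
#'
#' Realigns each path in model-global mode (local in target) and keeps
#' those whose score reaches the gathering threshold: the homologous paths,
#' which serve as read-classification templates (not as assembled genes).
#'
#' @param paths Nonredundant path list.
#' @param model A \linkS4class{ProfileModel}.
#' @param threshold Score cutoff; defaults to the model's gathering
#'   threshold.
#' @return \code{data.frame(path_id, seq, score, s_start, s_end)} plus the
#'   path list as attribute \code{"paths"}; \code{s_start}/\code{s_end}
#'   delimit the model-aligned region on the path.
#' @export
classifyPaths <- function(paths, model, threshold = gaThreshold(model)) {
    rows <- list()
    kept <- list()
    cm <- .compileModel(model)
    for (i in seq_along(paths)) {
        hit <- .alignModelCompiled(model, cm, paths[[i]]$seq,
                                   mode = "global_in_model")
        if (hit$score >= threshold) {
            kept[[length(kept) + 1L]] <- paths[[i]]
            rows[[length(rows) + 1L]] <- data.frame(
                path_id = sprintf("p%04d", length(kept)),
                seq = paths[[i]]$seq, score = hit$score,
                s_start = hit$seq_span[1L], s_end = hit$seq_span[2L],
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(path_id = character(), seq = character(),
                   score = numeric(), s_start = integer(),
                   s_end = integer(), stringsAsFactors = FALSE)
    attr(out, "paths") <- kept
    out
}

#' Assign reads to homologous paths and quantify the family
#'
#' A read is assigned when it aligns (local alignment, merge scoring, both
#' strands) to some homologous path with strictly more than
#' \code{read_cover_frac} of its length falling inside the path's
#' model-aligned region. Each read is assigned to at most one path per
#' family (best qualifying score); family abundance is the assigned-read
#' count.
#'
#' @param homologous Output of [classifyPaths()].
#' @param reads The full input read set (named \code{DNAStringSet} or
#'   character), including reads absorbed during graph construction.
#' @param params A [SearchParams()] list.
#' @param familyId Family identifier for the result.
#' @param mergeParams Alignment scoring ([MergeParams()]).
#' @return List of class \code{FamilyResult}: \code{family_id},
#'   \code{homologous_paths}, \code{read_assignments}
#'   (\code{data.frame(read_id, path_id, score)}), \code{abundance}.
#' @export
assignReads <- function(homologous, reads, params = SearchParams(),
                        familyId = "family", mergeParams = MergeParams()) {
    nm <- names(reads)
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    rows <- list()
    if (nrow(homologous) > 0L) {
        seedLen <- 12L
        useSeeds <- min(nchar(seqs)) >= 3L * seedLen
        pathSeeds <- if (useSeeds)
            lapply(homologous$seq, function(s)
                .seedSet(paste(s, revComp(s)), seedLen))
        for (ri in seq_along(seqs)) {
            rseq <- seqs[[ri]]
            rlen <- nchar(rseq)
            best <- NULL
            rseeds <- if (useSeeds) .seedSet(rseq, seedLen)
            for (pi in seq_len(nrow(homologous))) {
                if (useSeeds && !any(rseeds %in% pathSeeds[[pi]])) next
                a <- localAlign(rseq, homologous$seq[pi], mergeParams,
                                both_strands = TRUE)
                inRegion <- min(a$target_span[2L], homologous$s_end[pi]) -
                            max(a$target_span[1L], homologous$s_start[pi])
                if (inRegion <= 0L) next
                if (inRegion / rlen <= params$read_cover_frac) next
                if (is.null(best) || a$score > best$score)
                    best <- list(score = a$score,
                                 path_id = homologous$path_id[pi])
            }
            if (!is.null(best))
                rows[[length(rows) + 1L]] <- data.frame(
                    read_id = nm[ri], path_id = best$path_id,
                    score = best$score, stringsAsFactors = FALSE)
        }
    }
    asn <- if (length(rows)) do.call(rbind, rows) else
        data.frame(read_id = character(), path_id = character(),
                   score = numeric(), stringsAsFactors = FALSE)
    structure(list(family_id = familyId, homologous_paths = homologous,
                   read_assignments = asn, abundance = nrow(asn)),
              class = "FamilyResult")
}

#' Build the hybrid assembly graph from reads
#'
#' Convenience pipeline for stage one: string graph (overlaps, transitive
#' reduction, condensation), de Bruijn graph, contig extraction and
#' verification, then merging.
#'
#' @param reads Named \code{DNAStringSet} or character vector.
#' @param sgParams,dbgParams,mergeParams Stage parameter lists.
#' @return The condensed hybrid \linkS4class{AssemblyGraph}.
#' @export
buildHybridGraph <- function(reads, sgParams = StringGraphParams(),
                             dbgParams = DeBruijnParams(),
                             mergeParams = MergeParams()) {
    ov <- findReadOverlaps(reads, sgParams)
    sg <- condense(buildStringGraph(reads, ov, sgParams))
    dbg <- buildDeBruijnGraph(reads, dbgParams)
    contigs <- verifyContigs(extractContigs(dbg), reads)
    rec <- recruitAlignments(sg, terminalEdges(sg), contigs, mergeParams)
    condense(mergeGraphs(sg, contigs, rec, mergeParams))
}

#' End-to-end family search over the hybrid graph
#'
#' Builds the hybrid graph once (or reuses a supplied one), then for each
#' model: anchors, budgeted extension, redundancy removal, gathering-
#' threshold classification, and read assignment.
#'
#' @param reads Named \code{DNAStringSet} or character vector.
#' @param models A \linkS4class{ProfileModel} or list of them.
#' @param params A [SearchParams()] list.
#' @param sgParams,dbgParams,mergeParams Stage parameters (ignored when
#'   \code{hybrid} is supplied).
#' @param hybrid Optional prebuilt condensed hybrid graph.
#' @return Named list of \code{FamilyResult}, one per model.
#' @export
searchFamilies <- function(reads, models, params = SearchParams(),
                           sgParams = StringGraphParams(),
                           dbgParams = DeBruijnParams(),
                           mergeParams = MergeParams(), hybrid = NULL) {
    if (methods::is(models, "ProfileModel")) models <- list(models)
    if (length(models) == 0L) return(list())
    if (is.null(hybrid))
        hybrid <- buildHybridGraph(reads, sgParams, dbgParams, mergeParams)
    out <- list()
    for (model in models) {
        anchors <- findAnchors(hybrid, model, params)
        paths <- list()
        if (nrow(anchors) > 0L) for (ai in seq_len(nrow(anchors))) {
            anchor <- anchors[ai, ]
            budgets <- extensionBudget(anchor, model, params)
            paths <- c(paths, enumeratePaths(hybrid, anchor, budgets, params))
        }
        paths <- dedupePaths(paths, params)
        homologous <- classifyPaths(paths, model)
        out[[model@familyId]] <- assignReads(homologous, reads, params,
                                             familyId = model@familyId)
    }
    out
}

#' Read-based classification baseline
#'
#' Aligns the model directly to each unassembled read (model-local mode,
#' both strands) and predicts the reads reaching the threshold. This is the
#' strategy the graph search is designed to outperform when family
#' instances are split across reads.
#'
#' @param reads Named \code{DNAStringSet} or character vector.
#' @param model A \linkS4class{ProfileModel}.
#' @param threshold Score cutoff; defaults to the gathering threshold.
#' @return \code{data.frame(read_id, score, predicted)}.
#' @export
classifyReads <- function(reads, model, threshold = gaThreshold(model)) {
    nm <- names(reads)
    seqs <- if (methods::is(reads, "DNAStringSet")) as.character(reads)
            else toupper(as.character(reads))
    cm <- .compileModel(model)
    score <- vapply(seqs, function(s)
        .alignModelCompiled(model, cm, s, mode = "local_in_model")$score,
        numeric(1))
    data.frame(read_id = nm, score = unname(score),
               predicted = unname(score >= threshold),
               stringsAsFactors = FALSE)
}
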