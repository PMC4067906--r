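## Objective: maximum over features (and condition pairs) of the absolute
## standardized difference between condition means, in units of the pooled
## SD of the full candidate pool (a stable denominator across iterations).
.matchObjective <- function(means) {
    k <- nrow(means)
    worst <- 0
    for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k)) {
        worst <- max(worst, max(abs(means[a, ] - means[b, ])))
    }
    worst
}

.pairwiseSmd <- function(means) {
    k <- nrow(means)
    pairs <- utils::combn(seq_len(k), 2L)
    smd <- apply(pairs, 2L, function(p) means[p[1], ] - means[p[2], ])
    smd <- matrix(smd, nrow = ncol(means),
                  dimnames = list(colnames(means),
                                  apply(pairs, 2L, function(p)
                                      paste(rownames(means)[p],
                                            collapse = " - "))))
    smd
}

#' Select condition subsets of images matched on chosen features
#'
#' Operationalizes stimulus-set matching: from a candidate pool labeled by
#' condition (e.g. high vs. low caloric density), pick \code{subsetSize}
#' images per condition so that the selected sets are balanced on features
#' unrelated to the manipulation (total calories, color contribution,
#' complexity, ...). Features are standardized by the pooled SD of the full
#' candidate pool and optionally weighted; the objective is the maximum
#' absolute standardized mean difference across features and condition
#' pairs, so no single feature can remain badly unbalanced.
#'
#' Two-condition problems small enough to enumerate (combination-pair count
#' at most \code{enumLimit}) are solved exactly by exhaustive search over
#' all subset pairs; the max-over-features objective has needle-like global
#' optima that local search cannot reliably reach, while enumeration at
#' desk scale costs well under a second. Larger problems use
#' best-improving pairwise-swap hill-climbing (monotone descent, with a
#' sum-of-squares tie-break on plateaus) from \code{nStarts} seeded random
#' starts, each followed by \code{nKicks} perturbation-and-redescend
#' cycles, keeping the best end point. Either way the result is
#' deterministic given the seed.
#'
#' @param candidates data.frame with an \code{image_id} column, a condition
#'   label column, and numeric feature columns.
#' @param features character vector of feature column names.
#' @param subsetSize images to select per condition, >= 1.
#' @param groupCol name of the condition label column (default
#'   \code{"condition"}).
#' @param weights optional positive weights, one per feature.
#' @param maxStdDiff tolerance in pooled-SD units the result is checked
#'   against (default 0.2).
#' @param seed integer seed for the random starts.
#' @param nStarts number of random restarts of the heuristic (default 8).
#' @param nKicks perturbation-and-redescend cycles per start (default 20).
#' @param maxSweeps cap on swap sweeps per descent (default 200).
#' @param enumLimit exhaustive-search budget: two-condition problems with
#'   \code{choose(nA, k) * choose(nB, k)} at most this are solved exactly
#'   (default 5e5; set 0 to force the heuristic).
#' @return A [MatchResult-class]: per-condition selections, per-feature
#'   standardized differences, attained objective and whether the tolerance
#'   was met.
#' @export
#' @examples
#' set.seed(7)
#' pool <- data.frame(image_id = sprintf("im%02d", 1:24),
#'                    condition = rep(c("high", "low"), each = 12),
#'                    kcal = rnorm(24, 200, 50), size = runif(24))
#' matchStimulusSets(pool, features = c("kcal", "size"), subsetSize = 6)
matchStimulusSets <- function(candidates, features, subsetSize,
                              groupCol = "condition", weights = NULL,
                              maxStdDiff = 0.2, seed = 1L, nStarts = 8L,
                              nKicks = 20L, maxSweeps = 200L,
                              enumLimit = 5e5) {
    stopifnot(is.data.frame(candidates), "image_id" %in% names(candidates),
              groupCol %in% names(candidates))
    if (subsetSize < 1L)
        stop("subsetSize must be >= 1")
    if (maxStdDiff <= 0)
        stop("maxStdDiff must be > 0")
    missingF <- setdiff(features, names(candidates))
    if (length(missingF))
        stop("feature column(s) absent: ", paste(missingF, collapse = ", "))
    if (is.null(weights))
        weights <- rep(1, length(features))
    if (length(weights) != length(features) || any(weights <= 0))
        stop("weights must be positive, one per feature")

    X <- as.matrix(candidates[features])
    if (!is.numeric(X) || anyNA(X))
        stop("features must be numeric and complete")
    pooledSd <- apply(X, 2L, stats::sd)
    constant <- pooledSd == 0
    if (any(constant)) {
        warning("all-constant feature(s) excluded: ",
                paste(features[constant], collapse = ", "))
        if (all(constant))
            stop("no non-constant features left to match on")
        X <- X[, !constant, drop = FALSE]
        weights <- weights[!constant]
        pooledSd <- pooledSd[!constant]
        features <- features[!constant]
    }
    Z <- sweep(sweep(X, 2L, pooledSd, "/"), 2L, weights, "*")
    colnames(Z) <- features

    grp <- as.character(candidates[[groupCol]])
    levs <- sort(unique(grp))
    idxByGroup <- split(seq_len(nrow(candidates)), grp)[levs]
    short <- vapply(idxByGroup, length, 1L) < subsetSize
    if (any(short))
        stop("condition(s) with fewer than subsetSize candidates: ",
             paste(levs[short], collapse = ", "))

    groupMeans <- function(sel) {
        m <- vapply(sel, function(ix)
            colMeans(Z[ix, , drop = FALSE]), numeric(ncol(Z)))
        m <- t(matrix(m, nrow = ncol(Z)))  # conditions x features
        dimnames(m) <- list(levs, colnames(Z))
        m
    }

    finish <- function(sel) {
        means <- groupMeans(sel)
        obj <- .matchObjective(means)
        selected <- data.frame(
            condition = rep(levs, each = subsetSize),
            image_id = as.character(candidates$image_id[unlist(sel)]),
            stringsAsFactors = FALSE)
        new("MatchResult", selected = selected, smd = .pairwiseSmd(means),
            objective = obj, met = obj <= maxStdDiff,
            seed = as.integer(seed))
    }

    # exact branch: enumerate all subset pairs of a small 2-condition pool
    if (length(levs) == 2L) {
        nPairs <- choose(length(idxByGroup[[1]]), subsetSize) *
            choose(length(idxByGroup[[2]]), subsetSize)
        if (is.finite(nPairs) && nPairs <= enumLimit) {
            combA <- utils::combn(idxByGroup[[1]], subsetSize)
            combB <- utils::combn(idxByGroup[[2]], subsetSize)
            mA <- apply(combA, 2L, function(ix)
                colMeans(Z[ix, , drop = FALSE]))
            mB <- apply(combB, 2L, function(ix)
                colMeans(Z[ix, , drop = FALSE]))
            mA <- matrix(mA, nrow = ncol(Z))
            mB <- matrix(mB, nrow = ncol(Z))
            bestObj <- Inf; bestA <- 1L; bestB <- 1L
            for (i in seq_len(ncol(mA))) {
                d <- abs(mB - mA[, i])
                worst <- d[1L, ]
                for (r in seq_len(nrow(d))[-1L])
                    worst <- pmax(worst, d[r, ])
                j <- which.min(worst)
                if (worst[j] < bestObj) {
                    bestObj <- worst[j]; bestA <- i; bestB <- j
                }
            }
            return(finish(list(combA[, bestA], combB[, bestB])))
        }
    }
    ## Sum of squared pairwise mean differences: a smooth secondary
    ## criterion that breaks plateaus of the max objective, so descent can
    ## cross regions where no single swap improves the worst feature.
    secondary <- function(means) {
        k <- nrow(means); s <- 0
        for (a in seq_len(k - 1L)) for (b in seq.int(a + 1L, k))
            s <- s + sum((means[a, ] - means[b, ])^2)
        s
    }
    descend <- function(sel) {
        means <- groupMeans(sel)
        obj <- .matchObjective(means)
        sec <- secondary(means)
        eps <- 1e-15
        for (sweep_i in seq_len(maxSweeps)) {
            improved <- FALSE
            for (g in seq_along(levs)) {
                pool <- setdiff(idxByGroup[[g]], sel[[g]])
                if (length(pool) == 0L) next
                bestSwap <- NULL; bestMeans <- NULL
                bestObj <- obj; bestSec <- sec
                for (outIx in sel[[g]]) for (inIx in pool) {
                    trialMeans <- means
                    trialMeans[g, ] <- means[g, ] +
                        (Z[inIx, ] - Z[outIx, ]) / subsetSize
                    trialObj <- .matchObjective(trialMeans)
                    if (trialObj > obj + eps || trialObj > bestObj + eps)
                        next
                    trialSec <- secondary(trialMeans)
                    if (trialObj < bestObj - eps ||
                        (trialObj <= bestObj + eps &&
                         trialSec < bestSec - eps)) {
                        bestObj <- trialObj; bestSec <- trialSec
                        bestSwap <- c(outIx, inIx)
                        bestMeans <- trialMeans
                    }
                }
                if (!is.null(bestSwap) &&
                    (bestObj < obj - eps || bestSec < sec - eps)) {
                    sel[[g]] <- c(setdiff(sel[[g]], bestSwap[1]),
                                  bestSwap[2])
                    means <- bestMeans
                    obj <- bestObj; sec <- bestSec
                    improved <- TRUE
                }
            }
            if (!improved) break
        }
        list(sel = sel, obj = .matchObjective(groupMeans(sel)))
    }

    kick <- function(sel) {
        for (g in seq_along(levs)) {
            pool <- setdiff(idxByGroup[[g]], sel[[g]])
            if (length(pool) == 0L) next
            out <- sel[[g]][sample.int(length(sel[[g]]), 1L)]
            inn <- pool[sample.int(length(pool), 1L)]
            sel[[g]] <- c(setdiff(sel[[g]], out), inn)
        }
        sel
    }

    set.seed(seed)
    forced <- all(vapply(idxByGroup, length, 1L) == subsetSize)
    best <- NULL
    for (start in seq_len(if (forced) 1L else max(1L, nStarts))) {
        sel0 <- lapply(idxByGroup, function(ix)
            if (length(ix) == subsetSize) ix else sample(ix, subsetSize))
        cand <- descend(sel0)
        if (is.null(best) || cand$obj < best$obj) best <- cand
        if (!forced) {
            for (k in seq_len(max(0L, nKicks))) {
                cand <- descend(kick(best$sel))
                if (cand$obj < best$obj) best <- cand
            }
        }
    }
    finish(best$sel)
}

#' @rdname matchStimulusSets
#' @param result a [MatchResult-class].
#' @export
matchSelection <- function(result) {
    stopifnot(is(result, "MatchResult"))
    result@selected
}

#' @rdname matchStimulusSets
#' @export
matchObjective <- function(result) {
    stopifnot(is(result, "MatchResult"))
    result@objective
}

#' @rdname matchStimulusSets
#' @export
matchSmd <- function(result) {
    stopifnot(is(result, "MatchResult"))
    result@smd
}
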