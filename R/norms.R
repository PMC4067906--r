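.VAS_SCALES <- c("complexity_vas", "valence_vas", "arousal_vas",
                 "palatability_vas", "desire_vas")
.DICHOTOMOUS <- c("familiarity", "recognizability")
.FOOD_ONLY_SCALES <- c("palatability_vas", "desire_vas")

.checkRatings <- function(ratings) {
    need <- c("participant_id", "image_id", .DICHOTOMOUS, .VAS_SCALES)
    missingCols <- setdiff(need, names(ratings))
    if (length(missingCols))
        stop("ratings table lacks column(s): ",
             paste(missingCols, collapse = ", "))
    vas <- unlist(ratings[.VAS_SCALES], use.names = FALSE)
    if (any(!is.na(vas) & (vas < 1 | vas > 100)))
        stop("VAS values must lie in [1, 100]")
    invisible(TRUE)
}

#' Apply the minimum-food-images inclusion rule
#'
#' Retains only participants who completed all applicable ratings (both
#' dichotomous items and every VAS scale, including palatability and desire
#' to eat) for at least \code{minFoodImages} food images. This mirrors the
#' usual normative-survey inclusion rule of requiring complete rating sets
#' on at least 3 food images.
#'
#' @param ratings ratings data.frame (one row per participant x image).
#' @param foodImages character vector of the image_ids that depict food.
#' @param minFoodImages integer >= 0; default 3.
#' @return The ratings restricted to retained participants.
#' @export
filterParticipants <- function(ratings, foodImages, minFoodImages = 3L) {
    .checkRatings(ratings)
    if (minFoodImages < 0)
        stop("minFoodImages must be >= 0")
    if (minFoodImages == 0)
        return(ratings)
    food <- ratings[ratings$image_id %in% foodImages, , drop = FALSE]
    complete <- stats::complete.cases(
        food[c(.DICHOTOMOUS, .VAS_SCALES)])
    nComplete <- table(factor(food$participant_id[complete],
                              levels = unique(ratings$participant_id)))
    keep <- names(nComplete)[nComplete >= minFoodImages]
    ratings[ratings$participant_id %in% keep, , drop = FALSE]
}

.summarizeCell <- function(sub, subgroupLabel) {
    out <- list()
    for (sc in .VAS_SCALES) {
        v <- sub[[sc]]
        v <- v[!is.na(v)]
        if (length(v) == 0L) next
        out[[sc]] <- data.frame(scale = sc, mean = mean(v),
                                sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
                                n = length(v))
    }
    for (sc in .DICHOTOMOUS) {
        v <- sub[[sc]]
        v <- v[!is.na(v)]
        if (length(v) == 0L) next
        pct <- 100 * as.numeric(v)
        out[[sc]] <- data.frame(scale = sc, mean = mean(pct),
                                sd = if (length(v) > 1L) stats::sd(pct) else NA_real_,
                                n = length(v))
    }
    if (length(out) == 0L) return(NULL)
    res <- do.call(rbind, out)
    res$subgroup <- subgroupLabel
    res
}

#' Aggregate ratings into per-image normative summaries
#'
#' Computes, per image, mean / SD / number of raters for every VAS scale and
#' percent-yes for the dichotomous familiarity and recognizability items —
#' overall, plus one block per level of each requested participant subgroup
#' factor (e.g. \code{"gender"}, \code{"diet_style"}), labeled
#' \code{factor=level}. Participants lacking a value on a factor are dropped
#' from that stratification only (with a message); aggregation is
#' permutation-invariant over record order.
#'
#' @param ratings ratings data.frame.
#' @param profiles participant data.frame (needed when subgroup factors are
#'   requested), keyed by \code{participant_id}.
#' @param subgroupFactors character vector of profile column names.
#' @return Long data.frame: \code{image_id, subgroup, scale, mean, sd, n};
#'   dichotomous rows carry percent-yes in \code{mean}.
#' @export
aggregateRatings <- function(ratings, profiles = NULL,
                             subgroupFactors = character()) {
    .checkRatings(ratings)
    if (length(subgroupFactors)) {
        if (is.null(profiles))
            stop("subgroup aggregation requires a profiles table")
        bad <- setdiff(subgroupFactors, names(profiles))
        if (length(bad))
            stop("subgroup factor(s) absent from profiles: ",
                 paste(bad, collapse = ", "))
    }
    blocks <- list()
    byImage <- split(ratings, ratings$image_id)
    blocks[["all"]] <- do.call(rbind, Map(function(sub, id) {
        res <- .summarizeCell(sub, "all")
        if (!is.null(res)) res$image_id <- id
        res
    }, byImage, names(byImage)))
    for (f in subgroupFactors) {
        val <- profiles[[f]][match(ratings$participant_id,
                                   profiles$participant_id)]
        nMissing <- length(unique(ratings$participant_id[is.na(val)]))
        if (nMissing > 0)
            message(nMissing, " participant(s) lack '", f,
                    "'; dropped from that stratification")
        sub <- ratings[!is.na(val), , drop = FALSE]
        subVal <- val[!is.na(val)]
        for (lev in sort(unique(subVal))) {
            lab <- paste0(f, "=", lev)
            cells <- split(sub[subVal == lev, , drop = FALSE],
                           sub$image_id[subVal == lev])
            blocks[[lab]] <- do.call(rbind, Map(function(s, id) {
                res <- .summarizeCell(s, lab)
                if (!is.null(res)) res$image_id <- id
                res
            }, cells, names(cells)))
        }
    }
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out[c("image_id", "subgroup", "scale", "mean", "sd", "n")]
}

#' Paired contrast between two image categories
#'
#' For each participant, averages their ratings on one scale within each of
#' two image groups (e.g. high- vs. low-calorie foods), then runs a paired
#' Student t-test over participants on those two means
#' (\code{df = n - 1}). Both common paired effect-size conventions are
#' reported: \code{d_z = t / sqrt(n)} (SD of the difference scores) and
#' \code{d_av} (mean difference over the average of the two group SDs), so
#' either can be reconciled with published values. The difference is taken
#' as first minus second group in alphabetical label order.
#'
#' @param ratings ratings data.frame.
#' @param imageLabels data.frame with columns \code{image_id} and
#'   \code{label} (exactly two label levels), or a named vector of labels.
#' @param scale one of the VAS scale columns.
#' @return One-row data.frame: group labels and per-group mean/SD (over
#'   participant means), \code{n}, \code{t}, \code{df}, \code{p},
#'   \code{d_z}, \code{d_av}.
#' @export
categoryContrast <- function(ratings, imageLabels, scale) {
    .checkRatings(ratings)
    stopifnot(scale %in% .VAS_SCALES)
    if (!is.data.frame(imageLabels))
        imageLabels <- data.frame(image_id = names(imageLabels),
                                  label = unname(imageLabels),
                                  stringsAsFactors = FALSE)
    levs <- sort(unique(imageLabels$label))
    if (length(levs) != 2L)
        stop("imageLabels must define exactly two groups, got: ",
             paste(levs, collapse = ", "))
    lab <- imageLabels$label[match(ratings$image_id, imageLabels$image_id)]
    keep <- !is.na(lab) & !is.na(ratings[[scale]])
    sub <- ratings[keep, , drop = FALSE]
    lab <- lab[keep]
    pm <- tapply(sub[[scale]], list(sub$participant_id, lab), mean)
    pm <- pm[stats::complete.cases(pm), , drop = FALSE]
    n <- nrow(pm)
    if (n < 2L)
        stop("paired contrast needs >= 2 participants rating both groups")
    a <- pm[, levs[1]]; b <- pm[, levs[2]]
    d <- a - b
    if (stats::sd(d) == 0) {
        if (mean(d) != 0)
            stop("difference scores are constant and non-zero; ",
                 "the paired t statistic is undefined")
        tStat <- 0; pVal <- 1; dz <- 0
    } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        tStat <- unname(tt$statistic); pVal <- tt$p.value
        dz <- mean(d) / stats::sd(d)
    }
    sdAvg <- (stats::sd(a) + stats::sd(b)) / 2
    data.frame(group_a = levs[1], group_b = levs[2],
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               n = n, t = tStat,
               df = n - 1L, p = pVal,
               d_z = dz,
               d_av = if (sdAvg > 0) mean(d) / sdAvg else 0,
               stringsAsFactors = FALSE)
}

#' Correlate a participant covariate with mean ratings
#'
#' Averages each participant's ratings on one scale over an image subset and
#' correlates those means with a participant covariate (e.g. hunger with
#' desire to eat).
#'
#' @param ratings ratings data.frame.
#' @param profiles participant data.frame containing the covariate.
#' @param covariate name of the profile column.
#' @param scale one of the VAS scale columns.
#' @param imageSubset optional character vector of image_ids; default all.
#' @return List with \code{r}, \code{n} (participants) and \code{p}.
#' @export
covariateCorrelation <- function(ratings, profiles, covariate, scale,
                                 imageSubset = NULL) {
    .checkRatings(ratings)
    stopifnot(scale %in% .VAS_SCALES)
    if (!covariate %in% names(profiles))
        stop("covariate '", covariate, "' absent from profiles")
    sub <- ratings
    if (!is.null(imageSubset))
        sub <- sub[sub$image_id %in% imageSubset, , drop = FALSE]
    sub <- sub[!is.na(sub[[scale]]), , drop = FALSE]
    pm <- tapply(sub[[scale]], sub$participant_id, mean)
    cov <- profiles[[covariate]][match(names(pm), profiles$participant_id)]
    keep <- !is.na(cov)
    pm <- pm[keep]; cov <- cov[keep]
    if (length(pm) < 3L)
        stop("correlation needs >= 3 participants")
    if (stats::sd(cov) == 0)
        stop("correlation undefined: constant covariate")
    ct <- stats::cor.test(cov, pm)
    list(r = unname(ct$estimate), n = length(pm), p = ct$p.value)
}

#' Average pre- and post-survey hunger
#'
#' Arithmetic mean of the hunger ratings taken before and after the survey
#' (1--100 scale). When only one is present the available value is used and
#' flagged; when both are missing, \code{NA} propagates.
#'
#' @param profiles participant data.frame with \code{hunger_pre} and
#'   \code{hunger_post}.
#' @return The profiles with columns \code{hunger} (the average) and
#'   \code{hunger_single_source} (logical flag) added.
#' @export
#' @examples
#' hungerAverage(data.frame(participant_id = "p1", hunger_pre = 20,
#'                          hunger_post = 40))$hunger  # 30
hungerAverage <- function(profiles) {
    stopifnot(all(c("hunger_pre", "hunger_post") %in% names(profiles)))
    pre <- profiles$hunger_pre; post <- profiles$hunger_post
    profiles$hunger <- rowMeans(cbind(pre, post), na.rm = TRUE)
    profiles$hunger[is.na(pre) & is.na(post)] <- NA_real_
    profiles$hunger_single_source <- xor(is.na(pre), is.na(post))
    profiles
}

#' Read / write the ratings, participants and norms CSVs
#'
#' CSV round-trips for the survey tables. Ratings columns:
#' \code{participant_id, image_id, familiarity, recognizability,
#' complexity_vas, valence_vas, arousal_vas, palatability_vas, desire_vas}
#' (food-only scales empty for non-food images). The participants CSV
#' mirrors the participant profile fields; the norms CSV holds
#' \code{image_id, subgroup, scale, mean, sd, n}.
#'
#' @param path CSV file path.
#' @param x table to write.
#' @return Readers return a data.frame; writers invisibly return \code{path}.
#' @name survey-csv
NULL

#' @rdname survey-csv
#' @export
readRatingsCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df$familiarity <- as.logical(df$familiarity)
    df$recognizability <- as.logical(df$recognizability)
    .checkRatings(df)
    df
}

#' @rdname survey-csv
#' @export
writeRatingsCsv <- function(x, path) {
    .checkRatings(x)
    cols <- c("participant_id", "image_id", .DICHOTOMOUS, .VAS_SCALES)
    utils::write.csv(x[cols], path, row.names = FALSE, quote = FALSE,
                     na = "")
    invisible(path)
}

#' @rdname survey-csv
#' @export
readParticipantsCsv <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname survey-csv
#' @export
writeParticipantsCsv <- function(x, path) {
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}

#' @rdname survey-csv
#' @export
writeNormsCsv <- function(x, path) {
    stopifnot(all(c("image_id", "subgroup", "scale", "mean", "sd", "n")
                  %in% names(x)))
    utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "")
    invisible(path)
}
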