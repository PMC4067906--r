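.grayValue <- function(fill) sum(.GRAY_WEIGHTS * fill)

#' Generate a parametric stimulus image with analytic ground truth
#'
#' Deterministic generator of geometric stimuli on a white canvas, emulating
#' the standardized figure-ground composition of stimulus-database
#' photographs (colored object, pure-white background, default canvas
#' 600 x 450 px). Alongside the image it returns ground truth computed
#' analytically from the parameters — object pixel set, exact size fraction,
#' exact mean/SD of object gray values, grating frequency — so downstream
#' metrics can be verified against closed forms rather than against the
#' image itself.
#'
#' Shapes: \code{"square"} (uniform fill), \code{"disk"} (uniform fill),
#' \code{"checkerboard"} (a square of \code{cells x cells} alternating
#' \code{fill} and \code{altFill} cells — internal texture for edge-count
#' monotonicity checks), \code{"grating"} (full-frame horizontal sinusoidal
#' luminance with \code{cycles} cycles per image width, amplitude 100 around
#' mid-gray), and \code{"composite"} (a square and a disk side by side, two
#' separate outlines).
#'
#' @param shape one of square, disk, checkerboard, grating, composite.
#' @param fill object color, numeric RGB triple in [0, 255].
#' @param side square side length (also the checkerboard side), pixels.
#' @param radius disk radius, pixels.
#' @param cells checkerboard cells per side; must divide \code{side}.
#' @param cycles grating frequency, cycles per image width.
#' @param altFill second checkerboard color.
#' @param position top-left pixel of the square / disk bounding box as
#'   \code{c(x, y)} (1-based); default centered.
#' @param canvas \code{c(width, height)} in pixels, default \code{c(600,
#'   450)}, the stimulus-database standard.
#' @param seed integer; kept for interface symmetry (all shapes are
#'   deterministic).
#' @return List with \code{image} (an [RGBImage-class]) and \code{truth}:
#'   \code{objectFlags} (logical matrix), \code{sizeFraction},
#'   \code{grayMean}, \code{graySD} (population SD), \code{brightness}
#'   (255 - grayMean), \code{colorProps}, and \code{gratingCycles} (NA
#'   unless a grating).
#' @export
#' @examples
#' fx <- generateImage(shape = "square", side = 100, fill = c(0, 0, 0))
#' fx$truth$sizeFraction  # 10000 / 270000
generateImage <- function(shape = c("square", "disk", "checkerboard",
                                    "grating", "composite"),
                          fill = c(0, 0, 0), side = 100, radius = 50,
                          cells = 4L, cycles = 8, altFill = c(255, 0, 0),
                          position = NULL, canvas = c(600L, 450L),
                          seed = 1L) {
    shape <- match.arg(shape)
    w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
    stopifnot(w >= 1L, h >= 1L, length(fill) == 3L,
              all(fill >= 0 & fill <= 255))
    px <- array(255, dim = c(h, w, 3L))
    flags <- matrix(FALSE, h, w)
    grayMean <- NA_real_; graySD <- NA_real_
    colorProps <- NULL; gratingCycles <- NA_real_

    placeBox <- function(extent) {
        if (is.null(position))
            c(x = (w - extent) %/% 2L, y = (h - extent) %/% 2L)
        else
            c(x = as.integer(position[1]) - 1L,
              y = as.integer(position[2]) - 1L)
    }
    checkFit <- function(off, extent) {
        if (off["x"] < 0L || off["y"] < 0L ||
            off["x"] + extent > w || off["y"] + extent > h)
            stop("object does not fit inside the canvas")
    }
    fillRect <- function(px, off, extent, col) {
        for (ch in 1:3)
            px[off["y"] + seq_len(extent), off["x"] + seq_len(extent), ch] <-
                col[ch]
        px
    }

    if (shape == "square") {
        s <- as.integer(side)
        off <- placeBox(s); checkFit(off, s)
        px <- fillRect(px, off, s, fill)
        flags[off["y"] + seq_len(s), off["x"] + seq_len(s)] <- TRUE
        grayMean <- .grayValue(fill); graySD <- 0
        colorProps <- if (sum(fill) > 0) fill / sum(fill) else rep(1 / 3, 3)
    } else if (shape == "disk") {
        r <- as.integer(radius)
        off <- placeBox(2L * r); checkFit(off, 2L * r)
        cy <- off["y"] + r + 0.5; cx <- off["x"] + r + 0.5
        d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
        flags <- d2 <= r^2
        for (ch in 1:3) {
            plane <- px[, , ch]; plane[flags] <- fill[ch]
            px[, , ch] <- plane
        }
        grayMean <- .grayValue(fill); graySD <- 0
        colorProps <- if (sum(fill) > 0) fill / sum(fill) else rep(1 / 3, 3)
    } else if (shape == "checkerboard") {
        s <- as.integer(side); k <- as.integer(cells)
        if (s %% k != 0L)
            stop("side must be a multiple of cells")
        cell <- s %/% k
        off <- placeBox(s); checkFit(off, s)
        parity <- outer(rep(seq_len(k) - 1L, each = cell),
                        rep(seq_len(k) - 1L, each = cell), "+") %% 2L
        for (ch in 1:3) {
            block <- ifelse(parity == 0L, fill[ch], altFill[ch])
            px[off["y"] + seq_len(s), off["x"] + seq_len(s), ch] <- block
        }
        flags[off["y"] + seq_len(s), off["x"] + seq_len(s)] <- TRUE
        nA <- ceiling(k^2 / 2) * cell^2   # fill-colored pixels
        nB <- s^2 - nA
        gA <- .grayValue(fill); gB <- .grayValue(altFill)
        pA <- nA / s^2; pB <- nB / s^2
        grayMean <- pA * gA + pB * gB
        graySD <- abs(gA - gB) * sqrt(pA * pB)
        chSums <- pA * fill + pB * altFill
        colorProps <- if (sum(chSums) > 0) chSums / sum(chSums)
                      else rep(1 / 3, 3)
    } else if (shape == "grating") {
        rowVals <- round(127.5 + 100 * sin(2 * pi * cycles *
                                           (seq_len(w) - 1L) / w))
        for (ch in 1:3)
            px[, , ch] <- matrix(rowVals, h, w, byrow = TRUE)
        flags[] <- TRUE
        grayMean <- mean(rowVals)
        graySD <- sqrt(mean((rowVals - grayMean)^2))
        colorProps <- rep(1 / 3, 3)
        gratingCycles <- cycles
    } else {  # composite: square left, disk right, separated outlines
        s <- as.integer(side); r <- as.integer(radius)
        offS <- c(x = w %/% 4L - s %/% 2L, y = (h - s) %/% 2L)
        offD <- c(x = 3L * (w %/% 4L) - r, y = (h - 2L * r) %/% 2L)
        checkFit(offS, s); checkFit(offD, 2L * r)
        px <- fillRect(px, offS, s, fill)
        flags[offS["y"] + seq_len(s), offS["x"] + seq_len(s)] <- TRUE
        cy <- offD["y"] + r + 0.5; cx <- offD["x"] + r + 0.5
        d2 <- outer((seq_len(h) - cy)^2, (seq_len(w) - cx)^2, "+")
        disk <- d2 <= r^2
        for (ch in 1:3) {
            plane <- px[, , ch]; plane[disk] <- altFill[ch]
            px[, , ch] <- plane
        }
        flags <- flags | disk
        nS <- s^2; nD <- sum(disk); n <- nS + nD
        gS <- .grayValue(fill); gD <- .grayValue(altFill)
        grayMean <- (nS * gS + nD * gD) / n
        graySD <- sqrt((nS * (gS - grayMean)^2 + nD * (gD - grayMean)^2) / n)
        chSums <- nS * fill + nD * altFill
        colorProps <- if (sum(chSums) > 0) chSums / sum(chSums)
                      else rep(1 / 3, 3)
    }

    truth <- list(shape = shape, objectFlags = flags,
                  sizeFraction = sum(flags) / (h * w),
                  grayMean = grayMean, graySD = graySD,
                  brightness = 255 - grayMean,
                  colorProps = c(red_prop = colorProps[1],
                                 green_prop = colorProps[2],
                                 blue_prop = colorProps[3]),
                  gratingCycles = gratingCycles)
    list(image = rgbImage(px), truth = truth)
}

#' The survey design of a large multi-sample normative study
#'
#' Four participant samples with their sizes and per-rater random-subset
#' sizes (non-food / food images): a distance-university sample (n = 638,
#' 40/80), a German-speaking mailing-list sample (n = 831, 25/40), a US
#' crowdsourcing sample (n = 496, 17/35), and a children/youth sample
#' (n = 23, 5/35), rating pools of 568 food and 315 non-food images.
#'
#' @return data.frame with columns \code{sample}, \code{n},
#'   \code{nonfood_per_rater}, \code{food_per_rater}.
#' @export
defaultSurveySamples <- function() {
    data.frame(
        sample = c("unihagen", "german_speaking", "us", "children_youth"),
        n = c(638L, 831L, 496L, 23L),
        nonfood_per_rater = c(40L, 25L, 17L, 5L),
        food_per_rater = c(80L, 40L, 35L, 35L),
        stringsAsFactors = FALSE)
}

.truncRoundVas <- function(x) pmin(pmax(round(x), 1), 100)

#' Simulate a normative rating survey
#'
#' Emulates the design of a multi-sample online rating study: each simulated
#' participant rates an independent uniform random subset of the food images
#' and of the non-food images on 100-point VAS scales (complexity, valence,
#' arousal, plus palatability and desire to eat for food only) and on the
#' dichotomous familiarity / recognizability items. VAS responses are drawn
#' as latent per-image means plus Gaussian noise, rounded to integers and
#' clamped to [1, 100]. Known subgroup effects are injected and returned as
#' generative truth so recovery can be tested: a gender shift on desire to
#' eat, a vegetarian/vegan shift on meat-image palatability, and a linear
#' hunger slope on desire to eat.
#'
#' @param nFoodImages,nNonFoodImages image pool sizes (defaults 568 / 315).
#' @param samples data.frame as returned by [defaultSurveySamples()]; sizes
#'   default to the four-sample design of the emulated study.
#' @param latentMeans optional numeric matrix (images x the five VAS
#'   scales); drawn from realistic ranges when NULL.
#' @param noiseSd response noise SD in VAS points (default 20, the order of
#'   between-rater SDs seen in normative food-image data).
#' @param genderDesireShift additive shift on desire for female raters
#'   (default -8.3, the female minus male desire difference reported for
#'   normative food ratings).
#' @param vegMeatShift additive shift on meat-image palatability for
#'   vegetarian/vegan raters (default -36.5, vegetarian minus omnivore).
#' @param hungerDesireSlope desire points per hunger point (default 0.3).
#' @param pMeat fraction of food images depicting meat (default 0.111).
#' @param pFemale,dietProbs participant composition (defaults 0.8 female;
#'   omnivore/vegetarian/vegan 0.78/0.18/0.04).
#' @param completion probability that any given participant x image rating
#'   is completed (default 1).
#' @param seed integer seed; the whole simulation is a pure function of
#'   (spec, seed).
#' @return List: \code{ratings} (one row per completed participant x
#'   image), \code{participants} (profiles with demographics, diet, hunger),
#'   and \code{truth} (latent means, injected effects, meat/food/non-food
#'   ids, expected raters per image at full completion).
#' @export
simulateSurvey <- function(nFoodImages = 568L, nNonFoodImages = 315L,
                           samples = defaultSurveySamples(),
                           latentMeans = NULL, noiseSd = 20,
                           genderDesireShift = -8.3, vegMeatShift = -36.5,
                           hungerDesireSlope = 0.3, pMeat = 0.111,
                           pFemale = 0.8,
                           dietProbs = c(omnivore = 0.78,
                                         vegetarian = 0.18, vegan = 0.04),
                           completion = 1, seed = 1L) {
    stopifnot(nFoodImages >= 1L, nNonFoodImages >= 1L,
              completion >= 0, completion <= 1)
    if (any(samples$food_per_rater > nFoodImages) ||
        any(samples$nonfood_per_rater > nNonFoodImages))
        stop("per-rater subset sizes must not exceed the pool sizes")
    set.seed(seed)
    foodIds <- sprintf("food_%04d", seq_len(nFoodImages))
    nonfoodIds <- sprintf("nonfood_%04d", seq_len(nNonFoodImages))
    allIds <- c(foodIds, nonfoodIds)
    nMeat <- round(pMeat * nFoodImages)
    meatIds <- foodIds[seq_len(nMeat)]

    if (is.null(latentMeans)) {
        latentMeans <- cbind(
            complexity_vas = stats::runif(length(allIds), 20, 80),
            valence_vas = stats::runif(length(allIds), 30, 80),
            arousal_vas = stats::runif(length(allIds), 10, 70),
            palatability_vas = stats::runif(length(allIds), 30, 85),
            desire_vas = stats::runif(length(allIds), 10, 70))
        rownames(latentMeans) <- allIds
    }
    stopifnot(identical(sort(rownames(latentMeans)), sort(allIds)),
              all(.VAS_SCALES %in% colnames(latentMeans)))
    pFamiliar <- stats::runif(length(allIds), 0.85, 1)
    pRecognizable <- stats::runif(length(allIds), 0.85, 1)
    names(pFamiliar) <- names(pRecognizable) <- allIds

    nTotal <- sum(samples$n)
    participants <- data.frame(
        participant_id = sprintf("p%05d", seq_len(nTotal)),
        sample = rep(samples$sample, samples$n),
        age = round(pmax(11, stats::rnorm(nTotal, 29, 11))),
        gender = ifelse(stats::runif(nTotal) < pFemale, "female", "male"),
        bmi = round(pmax(13, stats::rnorm(nTotal, 23.5, 4.5)), 1),
        diet_style = sample(names(dietProbs), nTotal, replace = TRUE,
                            prob = dietProbs),
        currently_dieting = stats::runif(nTotal) < 0.136,
        hunger_pre = .truncRoundVas(stats::rnorm(nTotal, 28.5, 25.4)),
        hunger_post = .truncRoundVas(stats::rnorm(nTotal, 28.5, 25.4)),
        stringsAsFactors = FALSE)
    nFoodPer <- rep(samples$food_per_rater, samples$n)
    nNonfoodPer <- rep(samples$nonfood_per_rater, samples$n)

    ratedIds <- unlist(lapply(seq_len(nTotal), function(i) c(
        foodIds[sample.int(nFoodImages, nFoodPer[i])],
        nonfoodIds[sample.int(nNonFoodImages, nNonfoodPer[i])])))
    pid <- rep(participants$participant_id, nFoodPer + nNonfoodPer)
    isFood <- ratedIds %in% foodIds

    n <- length(ratedIds)
    base <- latentMeans[ratedIds, .VAS_SCALES, drop = FALSE]
    female <- participants$gender[match(pid, participants$participant_id)] ==
        "female"
    veg <- participants$diet_style[match(pid,
        participants$participant_id)] %in% c("vegetarian", "vegan")
    hunger <- rowMeans(participants[match(pid, participants$participant_id),
                                    c("hunger_pre", "hunger_post")])
    base[, "desire_vas"] <- base[, "desire_vas"] +
        genderDesireShift * female +
        hungerDesireSlope * (hunger - mean(hunger))
    base[, "palatability_vas"] <- base[, "palatability_vas"] +
        vegMeatShift * (veg & ratedIds %in% meatIds)
    noise <- if (noiseSd > 0)
        matrix(stats::rnorm(n * length(.VAS_SCALES), 0, noiseSd), n)
    else matrix(0, n, length(.VAS_SCALES))
    vas <- .truncRoundVas(base + noise)

    ratings <- data.frame(
        participant_id = pid, image_id = ratedIds,
        familiarity = stats::runif(n) < pFamiliar[ratedIds],
        recognizability = stats::runif(n) < pRecognizable[ratedIds],
        complexity_vas = vas[, "complexity_vas"],
        valence_vas = vas[, "valence_vas"],
        arousal_vas = vas[, "arousal_vas"],
        palatability_vas = ifelse(isFood, vas[, "palatability_vas"], NA),
        desire_vas = ifelse(isFood, vas[, "desire_vas"], NA),
        stringsAsFactors = FALSE)
    if (completion < 1)
        ratings <- ratings[stats::runif(n) < completion, , drop = FALSE]

    truth <- list(
        latentMeans = latentMeans, foodIds = foodIds,
        nonfoodIds = nonfoodIds, meatIds = meatIds,
        effects = list(genderDesireShift = genderDesireShift,
                       vegMeatShift = vegMeatShift,
                       hungerDesireSlope = hungerDesireSlope),
        noiseSd = noiseSd, completion = completion, samples = samples,
        expectedRatersPerFoodImage =
            sum(samples$n * samples$food_per_rater) / nFoodImages,
        expectedRatersPerNonFoodImage =
            sum(samples$n * samples$nonfood_per_rater) / nNonFoodImages)
    list(ratings = ratings, participants = participants, truth = truth)
}

#' Generate a synthetic nutrition metadata table
#'
#' Draws macronutrients per 100 g from realistic ranges (protein 0--30 g,
#' carbohydrate 0--70 g, fat 0--40 g), sets caloric density by the Atwater
#' factors (4 kcal/g protein and carbohydrate, 9 kcal/g fat) plus Gaussian
#' noise floored at 0, and assigns category / sweet-savory / processing
#' labels with the proportions observed in a large food-image database
#' (fruit 13.3%, vegetable 20.7%, chocolate 11.4%, meat 11.1%, fish 2.3%,
#' nuts 1.8%, beverage 1.6%, other 37.8%; sweet 42.8% / savory 38.8% /
#' unclassifiable 18.4%; processed 32.0% / whole 66.7% / unclassifiable
#' 1.3%). Pure function of \code{(n, noiseSd, seed)}.
#'
#' @param nItems number of food records, >= 1.
#' @param noiseSd SD of the kcal noise around the Atwater value (default 10
#'   kcal/100 g); 0 makes the Atwater identity exact.
#' @param nNonFood additional non-food records with empty nutrition fields.
#' @param seed integer seed.
#' @return data.frame with the canonical nutrition columns (see
#'   [writeNutritionCsv()]) plus per-portion totals.
#' @export
generateNutrition <- function(nItems, noiseSd = 10, nNonFood = 0L,
                              seed = 1L) {
    stopifnot(nItems >= 1L, noiseSd >= 0, nNonFood >= 0L)
    set.seed(seed)
    protein <- stats::runif(nItems, 0, 30)
    carb <- stats::runif(nItems, 0, 70)
    fat <- stats::runif(nItems, 0, 40)
    kcal <- pmax(0, 4 * protein + 4 * carb + 9 * fat +
                     if (noiseSd > 0) stats::rnorm(nItems, 0, noiseSd)
                     else 0)
    food <- data.frame(
        image_id = sprintf("food_%04d", seq_len(nItems)),
        is_food = TRUE,
        category = sample(c("fruit", "vegetable", "chocolate", "meat",
                            "fish", "nuts", "beverage", "other"),
                          nItems, replace = TRUE,
                          prob = c(0.133, 0.207, 0.114, 0.111, 0.023,
                                   0.018, 0.016, 0.378)),
        sweet_savory = sample(c("sweet", "savory", "unclassifiable"),
                              nItems, replace = TRUE,
                              prob = c(0.428, 0.388, 0.184)),
        processing = sample(c("processed", "whole", "unclassifiable"),
                            nItems, replace = TRUE,
                            prob = c(0.320, 0.667, 0.013)),
        kcal_per_100g = kcal,
        protein_per_100g = protein,
        carb_per_100g = carb,
        fat_per_100g = fat,
        portion_grams = stats::runif(nItems, 20, 400),
        item_count = sample.int(10L, nItems, replace = TRUE),
        stringsAsFactors = FALSE)
    food <- portionTotals(food)
    if (nNonFood > 0L) {
        nonfood <- data.frame(
            image_id = sprintf("nonfood_%04d", seq_len(nNonFood)),
            is_food = FALSE, category = "other",
            sweet_savory = "unclassifiable", processing = "unclassifiable",
            kcal_per_100g = NA_real_, protein_per_100g = NA_real_,
            carb_per_100g = NA_real_, fat_per_100g = NA_real_,
            portion_grams = NA_real_, item_count = NA_integer_,
            total_kcal = NA_real_, total_protein_g = NA_real_,
            total_carb_g = NA_real_, total_fat_g = NA_real_,
            stringsAsFactors = FALSE)
        food <- rbind(food, nonfood)
    }
    food
}
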