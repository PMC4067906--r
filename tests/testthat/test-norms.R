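# Build a ratings row block by hand; food images carry all five VAS scales.
mkRatings <- function(pid, imgs, value = 50, palat = value, desire = value,
                      fam = TRUE, rec = TRUE) {
    data.frame(participant_id = pid, image_id = imgs,
               familiarity = fam, recognizability = rec,
               complexity_vas = value, valence_vas = value,
               arousal_vas = value,
               palatability_vas = palat, desire_vas = desire,
               stringsAsFactors = FALSE)
}

test_that("the minimum-food-images inclusion rule counts complete sets only", {
    foodIds <- sprintf("food_%04d", 1:10)
    full3 <- mkRatings("pFull", foodIds[1:3])
    partial <- rbind(mkRatings("pPart", foodIds[1:2]),
                     mkRatings("pPart", foodIds[3:7], palat = NA))
    ratings <- rbind(full3, partial)
    kept <- filterParticipants(ratings, foodIds, 3)
    expect_identical(unique(kept$participant_id), "pFull")
    expect_identical(filterParticipants(ratings, foodIds, 0), ratings)
    # non-food rows never count toward the rule
    nf <- mkRatings("pNF", sprintf("nonfood_%04d", 1:5))
    expect_identical(nrow(filterParticipants(nf, foodIds, 3)), 0L)
})

test_that("aggregation reports mean/SD/n and percent-yes per image", {
    r <- rbind(mkRatings("p1", "food_0001", value = 10),
               mkRatings("p2", "food_0001", value = 20),
               mkRatings("p3", "food_0001", value = 30, fam = FALSE))
    norms <- aggregateRatings(r)
    val <- norms[norms$scale == "valence_vas", ]
    expect_equal(val$mean, 20)
    expect_equal(val$n, 3)
    fam <- norms[norms$scale == "familiarity", ]
    expect_equal(fam$mean, 200 / 3, tolerance = 1e-9)
    # permutation invariance
    norms2 <- aggregateRatings(r[c(3, 1, 2), ])
    expect_equal(norms, norms2)
})

test_that("subgroup blocks partition the raters", {
    svy <- simulateSurvey(nFoodImages = 10, nNonFoodImages = 4,
                          samples = tinySamples(30, 2, 5), seed = 61)
    norms <- aggregateRatings(svy$ratings, svy$participants, "gender")
    one <- norms[norms$scale == "valence_vas", ]
    byImg <- split(one, one$image_id)
    for (blk in byImg) {
        overall <- blk$n[blk$subgroup == "all"]
        expect_equal(sum(blk$n[blk$subgroup != "all"]), overall)
    }
    expect_error(aggregateRatings(svy$ratings, svy$participants, "shoe"),
                 "absent")
})

test_that("a zero-noise survey reproduces its latent means exactly", {
    ids <- surveyImageIds(8, 3)
    svy <- simulateSurvey(nFoodImages = 8, nNonFoodImages = 3,
                          samples = tinySamples(25, 2, 5),
                          latentMeans = flatLatents(ids, 37),
                          noiseSd = 0, genderDesireShift = 0,
                          vegMeatShift = 0, hungerDesireSlope = 0,
                          seed = 62)
    norms <- aggregateRatings(svy$ratings)
    vas <- norms[grepl("_vas$", norms$scale), ]
    expect_true(all(vas$mean == 37))
    expect_true(all(vas$sd[vas$n > 1] == 0))
})

test_that("the paired category contrast handles identity and recovers d_z", {
    labels <- data.frame(image_id = c("food_0001", "food_0002",
                                      "food_0003", "food_0004"),
                         label = c("a", "a", "b", "b"))
    # identical per-participant group means -> t = 0, d = 0
    same <- rbind(mkRatings("p1", labels$image_id, value = 40),
                  mkRatings("p2", labels$image_id, value = 60))
    res <- categoryContrast(same, labels, "valence_vas")
    expect_equal(res$t, 0)
    expect_equal(res$d_z, 0)
    expect_equal(res$p, 1)
    expect_equal(res$df, 1)

    # a real difference: d_z must equal t / sqrt(n)
    set.seed(63)
    rows <- do.call(rbind, lapply(1:12, function(i) {
        r <- mkRatings(sprintf("p%02d", i), labels$image_id)
        r$valence_vas <- round(stats::runif(4, 20, 80))
        r
    }))
    res2 <- categoryContrast(rows, labels, "valence_vas")
    expect_equal(res2$d_z, res2$t / sqrt(res2$n), tolerance = 1e-12)
    expect_equal(res2$df, res2$n - 1)

    # no participant spanning both groups -> domain error
    onesided <- mkRatings("p1", labels$image_id[1:2])
    expect_error(categoryContrast(onesided, labels, "valence_vas"),
                 ">= 2 participants")
})

test_that("covariate correlation hits r = 1 on aligned data and guards", {
    imgs <- sprintf("food_%04d", 1:3)
    r <- do.call(rbind, lapply(1:6, function(i)
        mkRatings(sprintf("p%d", i), imgs, value = 10 * i)))
    profiles <- data.frame(participant_id = sprintf("p%d", 1:6),
                           drive = 10 * (1:6))
    out <- covariateCorrelation(r, profiles, "drive", "desire_vas")
    expect_equal(out$r, 1, tolerance = 1e-12)
    expect_equal(out$n, 6)
    profiles$flat <- 5
    expect_error(covariateCorrelation(r, profiles, "flat", "desire_vas"),
                 "constant")
})

test_that("hunger averaging handles missing sources", {
    p <- data.frame(participant_id = c("a", "b", "c", "d"),
                    hunger_pre = c(20, 50, NA, 1),
                    hunger_post = c(40, NA, NA, 100))
    out <- hungerAverage(p)
    expect_equal(out$hunger, c(30, 50, NA, 50.5))
    expect_identical(out$hunger_single_source, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("injected subgroup effects are recovered from simulated surveys", {
    ids <- surveyImageIds(20, 2)
    svy <- simulateSurvey(nFoodImages = 20, nNonFoodImages = 2,
                          samples = tinySamples(400, 1, 10),
                          latentMeans = flatLatents(ids, 65),
                          noiseSd = 10, genderDesireShift = -8,
                          vegMeatShift = -30, hungerDesireSlope = 0,
                          pMeat = 0.3, seed = 64)
    r <- svy$ratings; p <- svy$participants
    veg <- p$participant_id[p$diet_style %in% c("vegetarian", "vegan")]
    meat <- r[r$image_id %in% svy$truth$meatIds, ]
    isVeg <- meat$participant_id %in% veg
    est <- mean(meat$palatability_vas[isVeg]) -
        mean(meat$palatability_vas[!isVeg])
    se <- sqrt(stats::var(meat$palatability_vas[isVeg]) / sum(isVeg) +
               stats::var(meat$palatability_vas[!isVeg]) / sum(!isVeg))
    expect_lt(abs(est - (-30)), 3 * se + 0.5)

    food <- r[r$image_id %in% svy$truth$foodIds, ]
    isF <- p$gender[match(food$participant_id, p$participant_id)] == "female"
    gest <- mean(food$desire_vas[isF]) - mean(food$desire_vas[!isF])
    gse <- sqrt(stats::var(food$desire_vas[isF]) / sum(isF) +
                stats::var(food$desire_vas[!isF]) / sum(!isF))
    expect_lt(abs(gest - (-8)), 3 * gse + 0.5)
})

test_that("the hunger slope propagates into the desire correlation", {
    ids <- surveyImageIds(16, 2)
    svy <- simulateSurvey(nFoodImages = 16, nNonFoodImages = 2,
                          samples = tinySamples(500, 1, 8),
                          latentMeans = flatLatents(ids, 40),
                          noiseSd = 10, genderDesireShift = 0,
                          vegMeatShift = 0, hungerDesireSlope = 0.3,
                          seed = 65)
    p <- hungerAverage(svy$participants)
    food <- svy$ratings[svy$ratings$image_id %in% svy$truth$foodIds, ]
    pm <- tapply(food$desire_vas, food$participant_id, mean)
    hun <- p$hunger[match(names(pm), p$participant_id)]
    fit <- stats::lm(pm ~ hun)
    ci <- stats::confint(fit, "hun", level = 0.99)
    expect_gt(0.3, ci[1])
    expect_lt(0.3, ci[2])
    out <- covariateCorrelation(svy$ratings, p, "hunger", "desire_vas",
                                imageSubset = svy$truth$foodIds)
    # attenuation: r = s*sd_h / sqrt(s^2 sd_h^2 + noise^2 / k)
    sdh <- stats::sd(hun)
    rTheory <- 0.3 * sdh / sqrt(0.3^2 * sdh^2 + 10^2 / 8)
    expect_equal(out$r, rTheory, tolerance = 0.1)
})

test_that("raters per image match the design expectation at full completion", {
    svy <- simulateSurvey(nFoodImages = 30, nNonFoodImages = 10,
                          samples = tinySamples(120, 4, 9), seed = 66)
    food <- svy$ratings[svy$ratings$image_id %in% svy$truth$foodIds, ]
    perImage <- table(food$image_id)
    expect_equal(length(perImage), 30L)
    expected <- svy$truth$expectedRatersPerFoodImage
    expect_equal(expected, 120 * 9 / 30)
    expect_equal(mean(perImage), expected, tolerance = 1e-12)
    # binomial spread around the expectation
    se <- sqrt(120 * (9 / 30) * (1 - 9 / 30))
    expect_lt(max(abs(perImage - expected)), 5 * se)
})

test_that("ratings CSV round-trips including empty food-only fields", {
    svy <- simulateSurvey(nFoodImages = 5, nNonFoodImages = 4,
                          samples = tinySamples(8, 3, 3), seed = 67)
    f <- tempfile(fileext = ".csv")
    writeRatingsCsv(svy$ratings, f)
    back <- readRatingsCsv(f)
    expect_equal(back$palatability_vas, svy$ratings$palatability_vas)
    expect_identical(back$familiarity, svy$ratings$familiarity)
    expect_true(all(is.na(
        back$desire_vas[!back$image_id %in% svy$truth$foodIds])))
})
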