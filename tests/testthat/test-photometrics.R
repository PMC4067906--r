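test_that("color contribution matches closed forms on simple objects", {
    sq <- function(fill) generateImage(shape = "square", side = 10,
                                       fill = fill, canvas = c(30, 30))
    img <- sq(c(200, 0, 0))$image
    cc <- colorContribution(img, computeMask(img))
    expect_equal(unname(cc), c(1, 0, 0))

    for (c0 in c(40, 128, 249)) {  # achromatic objects split evenly
        img <- sq(c(c0, c0, c0))$image
        cc <- colorContribution(img, computeMask(img))
        expect_equal(unname(cc), rep(1 / 3, 3), tolerance = 1e-12)
    }

    # two-pixel object {(255,0,0), (0,255,0)}: channel sums 255/255/0
    px <- array(255, dim = c(1, 3, 3))
    px[1, 1, ] <- c(255, 0, 0)
    px[1, 2, ] <- c(0, 255, 0)
    img <- rgbImage(px)
    cc <- colorContribution(img, computeMask(img))
    expect_equal(unname(cc), c(0.5, 0.5, 0))
})

test_that("color proportions are invariant to uniform channel rescaling", {
    set.seed(31)
    base <- array(stats::runif(20 * 20 * 3, 0, 120), dim = c(20, 20, 3))
    m <- uniformMask(20, 20)
    cc1 <- colorContribution(rgbImage(base), m)
    for (a in c(0.25, 0.5, 2)) {
        cc2 <- colorContribution(rgbImage(base * a), m)
        expect_equal(cc1, cc2, tolerance = 1e-12)
    }
})

test_that("object size is the non-white pixel fraction", {
    expect_identical(objectSize(uniformMask(5, 8)), 1)
    expect_identical(objectSize(uniformMask(5, 8, FALSE)), 0)
    fx <- generateImage(shape = "square", side = 100, fill = c(0, 0, 0))
    expect_equal(objectSize(computeMask(fx$image)), 10000 / 270000)
})

test_that("brightness is 255 minus mean object luminance", {
    black <- generateImage(shape = "square", side = 20, fill = c(0, 0, 0),
                           canvas = c(50, 50))
    g <- toGrayscale(black$image)
    m <- computeMask(black$image)
    expect_equal(objectBrightness(g, m), 255)

    g200 <- grayImage(matrix(200, 10, 10))
    expect_equal(objectBrightness(g200, uniformMask(10, 10)), 55)
    g255 <- grayImage(matrix(255, 10, 10))
    expect_equal(objectBrightness(g255, uniformMask(10, 10)), 0)
})

test_that("contrast is the population SD of object luminance", {
    u <- grayImage(matrix(137.2, 6, 6))
    expect_equal(objectContrast(u, uniformMask(6, 6)), 0)

    two <- grayImage(matrix(c(0, 255), 1, 2))
    expect_equal(objectContrast(two, uniformMask(1, 2)), 127.5)

    # half 0 / half 255 at any size: same distribution, same SD
    for (n in c(4, 20, 100)) {
        half <- grayImage(matrix(rep(c(0, 255), n / 2), 1, n))
        expect_equal(objectContrast(half, uniformMask(1, n)), 127.5)
    }

    # n-1 divisor matches stats::sd
    set.seed(32)
    v <- stats::runif(24, 0, 255)
    g <- grayImage(matrix(v, 4, 6))
    expect_equal(objectContrast(g, uniformMask(4, 6), divisor = "n-1"),
                 stats::sd(v))
})

test_that("brightness and contrast ignore background padding", {
    fx1 <- generateImage(shape = "checkerboard", side = 40, cells = 4,
                         fill = c(20, 60, 100), altFill = c(240, 200, 160),
                         canvas = c(60, 60))
    fx2 <- generateImage(shape = "checkerboard", side = 40, cells = 4,
                         fill = c(20, 60, 100), altFill = c(240, 200, 160),
                         canvas = c(200, 150))
    for (fx in list(fx1, fx2)) {
        g <- toGrayscale(fx$image)
        m <- computeMask(fx$image)
        expect_equal(objectBrightness(g, m), fx1$truth$brightness,
                     tolerance = 1e-12)
        expect_equal(objectContrast(g, m), fx1$truth$graySD,
                     tolerance = 1e-12)
    }
})

test_that("all four metrics match analytic ground truth on generated objects", {
    set.seed(33)
    shapes <- c("square", "disk", "checkerboard", "composite")
    for (i in 1:12) {
        shape <- shapes[(i - 1) %% 4 + 1]
        fill <- sample(0:220, 3, replace = TRUE)
        alt <- sample(0:220, 3, replace = TRUE)
        fx <- generateImage(shape = shape, fill = fill, altFill = alt,
                            side = sample(c(24, 48, 96), 1),
                            radius = sample(c(12, 25, 40), 1),
                            cells = sample(c(2, 4, 6), 1),
                            canvas = c(240, 200))
        g <- toGrayscale(fx$image)
        m <- computeMask(fx$image)
        expect_equal(objectSize(m), fx$truth$sizeFraction,
                     tolerance = 1e-12)
        expect_equal(objectBrightness(g, m), fx$truth$brightness,
                     tolerance = 1e-9)
        expect_equal(objectContrast(g, m), fx$truth$graySD,
                     tolerance = 1e-9)
        expect_equal(unname(colorContribution(fx$image, m)),
                     unname(fx$truth$colorProps), tolerance = 1e-9)
    }
})

test_that("empty masks raise domain errors", {
    img <- rgbImage(array(255, dim = c(4, 4, 3)))
    g <- toGrayscale(img)
    m <- computeMask(img)
    expect_error(colorContribution(img, m), "no object pixels")
    expect_error(objectBrightness(g, m), "no object pixels")
    expect_error(objectContrast(g, m), "no object pixels")
})
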