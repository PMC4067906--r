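test_that("PNG round-trip preserves pixel values exactly", {
    canvas <- generateImage(shape = "square", side = 4, fill = c(30, 99, 201),
                            canvas = c(16, 12))
    f <- tempfile(fileext = ".png")
    writeStimulus(canvas$image, f)
    back <- loadImage(f)
    expect_s4_class(back, "RGBImage")
    expect_equal(unclass(back), unclass(canvas$image))

    # all-white canvas and a single saturated pixel
    white <- rgbImage(array(255, dim = c(12, 16, 3)))
    px <- unclass(white); px[1, 1, ] <- c(255, 0, 0)
    one <- rgbImage(px)
    f2 <- tempfile(fileext = ".png")
    writeStimulus(one, f2)
    back2 <- loadImage(f2)
    expect_equal(as.numeric(back2[1, 1, ]), c(255, 0, 0))
    expect_true(all(back2[2:12, , ] == 255))
})

test_that("JPEG quality-95 round-trip stays within +/-6 per channel", {
    # achromatic content: codec error is luma-only and small even at edges
    fx <- generateImage(shape = "checkerboard", side = 48, cells = 4,
                        fill = c(60, 60, 60), altFill = c(190, 190, 190),
                        canvas = c(96, 64))
    fp <- tempfile(fileext = ".png")
    fj <- tempfile(fileext = ".jpg")
    writeStimulus(fx$image, fp)
    writeStimulus(fx$image, fj, quality = 0.95)
    pngPx <- unclass(loadImage(fp))
    jpgPx <- unclass(loadImage(fj))
    expect_lte(max(abs(pngPx - jpgPx)), 6)
    # the default white threshold tolerates the ringing: the object mask
    # recovered from the lossy file matches the generator exactly
    mJpg <- computeMask(loadImage(fj), 250L)
    expect_identical(maskFlags(mJpg), fx$truth$objectFlags)
})

test_that("BMP files decode to the same pixels as the source array", {
    fx <- generateImage(shape = "disk", radius = 5, fill = c(10, 200, 60),
                        canvas = c(20, 15))
    f <- tempfile(fileext = ".bmp")
    writeBmp24(unclass(fx$image), f)
    back <- loadImage(f)
    expect_equal(unclass(back), unclass(fx$image))
})

test_that("grayscale conversion applies the printed weights without quantization", {
    gray1 <- function(rgb) {
        img <- rgbImage(array(rgb, dim = c(1, 1, 3)))
        as.numeric(toGrayscale(img))
    }
    expect_identical(gray1(c(255, 0, 0)), 255 * 0.2989)  # 76.2195
    expect_identical(gray1(c(0, 255, 0)), 255 * 0.5870)
    expect_identical(gray1(c(0, 0, 255)), 255 * 0.1140)
    expect_identical(gray1(c(0, 0, 0)), 0)
    expect_equal(gray1(c(255, 255, 255)), 254.9745)

    # linearity: gray(a * p) = a * gray(p)
    set.seed(11)
    for (i in 1:25) {
        p <- stats::runif(3, 0, 120)
        a <- stats::runif(1, 0, 2)
        expect_equal(gray1(a * p), a * gray1(p), tolerance = 1e-12)
    }
})

test_that("grayscale-only files are promoted to three channels with a warning", {
    g <- matrix(stats::runif(12 * 10), 12, 10)
    f <- tempfile(fileext = ".png")
    png::writePNG(g, f)
    expect_warning(img <- loadImage(f), "promoted")
    expect_equal(img[, , 1], img[, , 2])
    expect_equal(img[, , 2], img[, , 3])
})

test_that("alpha channels are composited over pure white", {
    rgba <- array(0, dim = c(5, 5, 4))
    rgba[, , 1] <- 1          # pure red object
    rgba[, , 4] <- 0          # fully transparent
    rgba[1, 1, 4] <- 1        # except one opaque pixel
    f <- tempfile(fileext = ".png")
    png::writePNG(rgba, f)
    img <- loadImage(f)
    expect_equal(as.numeric(img[1, 1, ]), c(255, 0, 0))
    expect_equal(as.numeric(img[3, 3, ]), c(255, 255, 255))  # transparent -> white
})

test_that("mask thresholding flags non-white pixels and records the threshold", {
    white <- rgbImage(array(255, dim = c(10, 10, 3)))
    m <- computeMask(white, 250L)
    expect_identical(objectCount(m), 0L)
    expect_identical(whiteThreshold(m), 250L)

    fx <- generateImage(shape = "square", side = 100, fill = c(0, 0, 0))
    expect_identical(objectCount(computeMask(fx$image, 250L)), 10000L)

    # boundary: one channel below the threshold makes the pixel non-white
    px <- array(255, dim = c(1, 2, 3))
    px[1, 1, ] <- c(250, 250, 249)
    m2 <- computeMask(rgbImage(px), 250L)
    expect_identical(unname(maskFlags(m2)[1, ]), c(TRUE, FALSE))
})

test_that("raising the white threshold never decreases the object count", {
    set.seed(21)
    px <- array(sample(0:255, 40 * 30 * 3, replace = TRUE),
                dim = c(30, 40, 3))
    img <- rgbImage(px)
    counts <- vapply(seq(0L, 255L, by = 15L),
                     function(t) objectCount(computeMask(img, t)), 1L)
    expect_true(all(diff(counts) >= 0))
})

test_that("mask recovery from lossless files matches the generator exactly", {
    for (shape in c("square", "disk", "composite")) {
        fx <- generateImage(shape = shape, side = 40, radius = 18,
                            fill = c(120, 40, 200), canvas = c(160, 120))
        f <- tempfile(fileext = ".png")
        writeStimulus(fx$image, f)
        m <- computeMask(loadImage(f))
        expect_identical(maskFlags(m), fx$truth$objectFlags)
    }
})

test_that("invalid images and parameters are rejected", {
    expect_error(loadImage(tempfile(fileext = ".png")), "cannot read")
    expect_error(rgbImage(array(300, dim = c(2, 2, 3))), "255")
    expect_error(computeMask(rgbImage(array(0, dim = c(2, 2, 3))), 300),
                 "whiteThreshold")
    bad <- tempfile(fileext = ".png")
    writeLines("not an image", bad)
    expect_error(loadImage(bad), "cannot decode")
})
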