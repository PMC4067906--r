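#' Proportional RGB channel contribution of the object
#'
#' Sums each channel over the non-white pixels and divides by the grand sum
#' across the three channels, so the three proportions add to 1. Computed as
#' proportion-of-sums rather than mean of per-pixel proportions: the two
#' agree on uniform objects, and proportion-of-sums stays well-conditioned on
#' near-black pixels. A red object (e.g. a tomato) yields a dominant red
#' proportion.
#'
#' @param img an [RGBImage-class].
#' @param mask an [ObjectMask-class] for the same image.
#' @return Named numeric of length 3: \code{red_prop}, \code{green_prop},
#'   \code{blue_prop}.
#' @export
#' @examples
#' img <- generateImage(shape = "square", side = 10, fill = c(200, 0, 0),
#'                      canvas = c(30, 30))
#' colorContribution(img$image, computeMask(img$image))  # (1, 0, 0)
colorContribution <- function(img, mask) {
    stopifnot(is(img, "RGBImage"), is(mask, "ObjectMask"))
    .checkSameDim(img, mask)
    f <- mask@flags
    if (!any(f))
        stop("no object pixels: mask is empty")
    sums <- c(sum(.channel(img, 1)[f]), sum(.channel(img, 2)[f]),
              sum(.channel(img, 3)[f]))
    total <- sum(sums)
    if (total == 0)  # all-black object: channels contribute equally
        return(c(red_prop = 1 / 3, green_prop = 1 / 3, blue_prop = 1 / 3))
    c(red_prop = sums[1], green_prop = sums[2], blue_prop = sums[3]) / total
}

#' Object size as a fraction of the frame
#'
#' Proportion of non-white pixels relative to the total number of pixels.
#'
#' @param mask an [ObjectMask-class].
#' @return Fraction in [0, 1].
#' @export
objectSize <- function(mask) {
    stopifnot(is(mask, "ObjectMask"))
    sum(mask@flags) / length(mask@flags)
}

#' Object brightness relative to the white background
#'
#' Difference between the white background level (255) and the mean luminance
#' of the non-white pixels: very dark objects on the white background score
#' highest, i.e. the scale runs with object salience.
#'
#' @param gray a [GrayImage-class].
#' @param mask an [ObjectMask-class] for the same image.
#' @return Value on the 0--255 scale.
#' @export
objectBrightness <- function(gray, mask) {
    stopifnot(is(gray, "GrayImage"), is(mask, "ObjectMask"))
    .checkSameDim(gray, mask)
    if (!any(mask@flags))
        stop("no object pixels: mask is empty")
    255 - mean(gray[mask@flags])
}

#' Within-object luminance contrast
#'
#' Standard deviation of luminance across the non-white pixels. A perfectly
#' uniform object has contrast 0; an object spanning near-black to near-white
#' (a dark chocolate bar on a white plate) scores high. The default is the
#' population SD (divisor n); set \code{divisor = "n-1"} for the sample SD.
#'
#' @param gray a [GrayImage-class].
#' @param mask an [ObjectMask-class] for the same image.
#' @param divisor \code{"n"} (population SD, default) or \code{"n-1"}.
#' @return SD on the 0--255 scale, >= 0.
#' @export
#' @examples
#' g <- grayImage(matrix(c(0, 255), 1, 2))
#' m <- new("ObjectMask", flags = matrix(TRUE, 1, 2), whiteThreshold = 250L)
#' objectContrast(g, m)  # 127.5
objectContrast <- function(gray, mask, divisor = c("n", "n-1")) {
    stopifnot(is(gray, "GrayImage"), is(mask, "ObjectMask"))
    divisor <- match.arg(divisor)
    .checkSameDim(gray, mask)
    n <- sum(mask@flags)
    if (n == 0L)
        stop("no object pixels: mask is empty")
    v <- gray[mask@flags]
    ss <- sum((v - mean(v))^2)
    den <- if (divisor == "n") n else n - 1L
    if (den == 0L)
        stop("contrast with divisor n-1 needs at least 2 object pixels")
    sqrt(ss / den)
}

.checkSameDim <- function(a, b) {
    if (imgHeight(a) != imgHeight(b) || imgWidth(a) != imgWidth(b))
        stop("image and mask dimensions differ")
    invisible(TRUE)
}
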