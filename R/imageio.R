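#' Construct an RGBImage from a numeric array
#'
#' @param pixels numeric array \code{height x width x 3}, channel order red,
#'   green, blue, values in [0, 255].
#' @return An [RGBImage-class].
#' @export
#' @examples
#' px <- array(255, dim = c(2, 2, 3))
#' rgbImage(px)
rgbImage <- function(pixels) {
    if (is.matrix(pixels))
        pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
    new("RGBImage", pixels)
}

#' Construct a GrayImage from a numeric matrix
#'
#' @param values numeric matrix of luminance values in [0, 255].
#' @return A [GrayImage-class].
#' @export
grayImage <- function(values) new("GrayImage", values)

## Minimal reader for uncompressed 24/32-bit BMP (BITMAPINFOHEADER, BI_RGB).
## Returns height x width x {3,4} array in [0,1], channels RGB(A).
.readBMP <- function(path) {
    raw <- readBin(path, "raw", file.info(path)$size)
    if (length(raw) < 54L || rawToChar(raw[1:2]) != "BM")
        stop("not a BMP file: ", path)
    u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
    s32 <- function(off) {
        v <- u32(off); if (v >= 2^31) v - 2^32 else v
    }
    dataOffset <- u32(10L)
    width <- s32(18L)
    height <- s32(22L)
    bpp <- sum(as.integer(raw[28L + 1:2]) * 256^(0:1))
    compression <- u32(30L)
    if (compression != 0L || !(bpp %in% c(24L, 32L)))
        stop("unsupported BMP variant (need uncompressed 24- or 32-bit): ",
             path)
    flip <- height > 0
    height <- abs(height)
    nch <- bpp %/% 8L
    rowSize <- ((bpp * width + 31L) %/% 32L) * 4L
    px <- array(0, dim = c(height, width, if (nch == 4L) 4L else 3L))
    for (r in seq_len(height)) {
        off <- dataOffset + (r - 1L) * rowSize
        row <- as.integer(raw[off + seq_len(nch * width)])
        rowm <- matrix(row, nrow = nch)  # BGR(A) order
        y <- if (flip) height - r + 1L else r
        px[y, , 1] <- rowm[3, ]
        px[y, , 2] <- rowm[2, ]
        px[y, , 3] <- rowm[1, ]
        if (nch == 4L) px[y, , 4] <- rowm[4, ]
    }
    px / 255
}

#' Load a stimulus image from disk
#'
#' Reads a PNG, JPEG or (uncompressed 24/32-bit) BMP file and returns an
#' [RGBImage-class] on the 0--255 scale. Grayscale-only files are promoted to
#' three identical channels with a warning; an alpha channel is composited
#' over pure white first, matching the white-background convention of
#' standardized stimulus databases.
#'
#' @param path path to the image file; format inferred from the extension.
#' @return An [RGBImage-class].
#' @export
#' @examples
#' img <- generateImage(shape = "square", side = 8, canvas = c(24, 24))
#' f <- tempfile(fileext = ".png")
#' writeStimulus(img$image, f)
#' loadImage(f)
loadImage <- function(path) {
    if (!file.exists(path))
        stop("cannot read image file: ", path)
    ext <- tolower(tools::file_ext(path))
    px <- tryCatch(
        switch(ext,
            png = png::readPNG(path),
            jpg = ,
            jpeg = jpeg::readJPEG(path),
            bmp = .readBMP(path),
            stop("unsupported image format '", ext, "': ", path)),
        error = function(e) stop("cannot decode image file ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (is.matrix(px)) {
        warning("grayscale-only file promoted to 3 identical channels: ",
                path)
        px <- array(rep(px, 3L), dim = c(dim(px), 3L))
    } else if (dim(px)[3] == 2L) {  # gray + alpha
        warning("grayscale-only file promoted to 3 identical channels: ",
                path)
        a <- px[, , 2]
        g <- px[, , 1] * a + (1 - a)
        px <- array(rep(g, 3L), dim = c(dim(g), 3L))
    }
    if (dim(px)[3] == 4L) {  # composite alpha over white
        a <- px[, , 4]
        px <- px[, , 1:3] * as.vector(a) + (1 - as.vector(a))
    }
    rgbImage(round(px[, , 1:3, drop = FALSE] * 255))
}

#' Write a stimulus image to disk
#'
#' Writes an [RGBImage-class] as PNG (lossless, the default so fixture masks
#' round-trip exactly) or JPEG.
#'
#' @param img an [RGBImage-class].
#' @param path output path; format from the extension (png, jpg/jpeg).
#' @param quality JPEG quality in (0, 1], ignored for PNG.
#' @return Invisibly, \code{path}.
#' @export
writeStimulus <- function(img, path, quality = 0.95) {
    stopifnot(is(img, "RGBImage"))
    px <- unclass(img) / 255
    ext <- tolower(tools::file_ext(path))
    switch(ext,
        png = png::writePNG(px, path),
        jpg = ,
        jpeg = jpeg::writeJPEG(px, path, quality = quality),
        stop("unsupported output format '", ext, "'"))
    invisible(path)
}

## Luminance weights: standard NTSC/ITU-R 601 coefficients.
.GRAY_WEIGHTS <- c(red = 0.2989, green = 0.5870, blue = 0.1140)

## One channel of an RGB array as a matrix (robust to 1-pixel-high images,
## where plain [ , , k] indexing would drop dimensions).
.channel <- function(img, k) {
    m <- img[, , k, drop = FALSE]
    dim(m) <- dim(img)[1:2]
    m
}

#' Convert a color image to gray values
#'
#' Luminance is the weighted channel sum 0.2989 R + 0.5870 G + 0.1140 B,
#' which discards hue and saturation while retaining luminance. Output values
#' stay fractional on the 0--255 scale; nothing is rounded.
#'
#' @param img an [RGBImage-class].
#' @return A [GrayImage-class] of the same dimensions.
#' @export
#' @examples
#' g <- toGrayscale(rgbImage(array(c(255, 0, 0), dim = c(1, 1, 3))))
#' g[1, 1]  # 255 * 0.2989 = 76.2195
toGrayscale <- function(img) {
    stopifnot(is(img, "RGBImage"))
    w <- .GRAY_WEIGHTS
    grayImage(w[1] * .channel(img, 1) + w[2] * .channel(img, 2) +
              w[3] * .channel(img, 3))
}

#' Derive the non-white object mask
#'
#' A pixel is background ("white") iff all three channels are at or above
#' \code{whiteThreshold}; every other pixel belongs to the depicted object.
#' The default threshold 250 tolerates JPEG ringing near the white background
#' while keeping near-white objects (e.g. whipped cream) in the mask.
#'
#' @param img an [RGBImage-class].
#' @param whiteThreshold integer in [0, 255]; default 250.
#' @return An [ObjectMask-class] recording the threshold used.
#' @export
#' @examples
#' img <- generateImage(shape = "square", side = 10, canvas = c(30, 20))
#' objectCount(computeMask(img$image))  # 100
computeMask <- function(img, whiteThreshold = 250L) {
    stopifnot(is(img, "RGBImage"))
    wt <- as.integer(whiteThreshold)
    if (length(wt) != 1L || is.na(wt) || wt < 0L || wt > 255L)
        stop("whiteThreshold must be a single integer in [0, 255]")
    white <- .channel(img, 1) >= wt & .channel(img, 2) >= wt &
        .channel(img, 3) >= wt
    new("ObjectMask", flags = !white, whiteThreshold = wt)
}
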