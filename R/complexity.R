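## Shift a matrix by (dy, dx) with replicate (clamped) border padding:
## result[i, j] = m[clamp(i + dy), clamp(j + dx)].
.shiftPad <- function(m, dy, dx) {
    h <- nrow(m); w <- ncol(m)
    m[pmin.int(pmax.int(seq_len(h) + dy, 1L), h),
      pmin.int(pmax.int(seq_len(w) + dx, 1L), w), drop = FALSE]
}

## Separable Gaussian smoothing, replicate padding, kernel radius 3*sigma.
.gaussianBlur <- function(m, sigma) {
    r <- max(1L, as.integer(ceiling(3 * sigma)))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * .shiftPad(m, 0L, i - r - 1L)
    m <- out
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * .shiftPad(m, i - r - 1L, 0L)
    out
}

## 8-neighborhood dilation of a logical matrix (border-safe).
.dilate8 <- function(b) {
    out <- b
    for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        out <- out | .shiftPad(b, dy, dx)
    }
    out
}

#' Canny edge detection
#'
#' Standard Canny pipeline: Gaussian smoothing, Sobel gradient magnitude and
#' orientation, non-maximum suppression along the gradient direction, and
#' hysteresis thresholding (weak pixels survive only when 8-connected to a
#' strong pixel). The hysteresis thresholds are fractions of the
#' gradient-magnitude range, so results are invariant to linear rescaling of
#' the luminance values. Parameters are recorded in the returned map.
#'
#' @param gray a [GrayImage-class].
#' @param sigma Gaussian smoothing width in pixels, > 0 (default 1.0).
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude, 0 <= low < high <= 1 (defaults 0.1 and 0.2).
#' @return An [EdgeMap-class].
#' @export
#' @examples
#' img <- generateImage(shape = "square", side = 40, canvas = c(100, 100))
#' e <- detectEdges(toGrayscale(img$image))
#' edgeCount(e)  # roughly the square's perimeter
detectEdges <- function(gray, sigma = 1.0, low = 0.1, high = 0.2) {
    stopifnot(is(gray, "GrayImage"))
    if (sigma <= 0)
        stop("sigma must be > 0")
    if (low < 0 || high > 1 || low >= high)
        stop("hysteresis thresholds must satisfy 0 <= low < high <= 1")
    edgeMap <- function(flags) new("EdgeMap", flags = flags, sigma = sigma,
                                   low = low, high = high)
    g <- .gaussianBlur(unclass(gray), sigma)
    # Sobel gradients; x runs along columns, y along rows
    gx <- (.shiftPad(g, -1L, 1L) + 2 * .shiftPad(g, 0L, 1L) +
           .shiftPad(g, 1L, 1L)) -
          (.shiftPad(g, -1L, -1L) + 2 * .shiftPad(g, 0L, -1L) +
           .shiftPad(g, 1L, -1L))
    gy <- (.shiftPad(g, 1L, -1L) + 2 * .shiftPad(g, 1L, 0L) +
           .shiftPad(g, 1L, 1L)) -
          (.shiftPad(g, -1L, -1L) + 2 * .shiftPad(g, -1L, 0L) +
           .shiftPad(g, -1L, 1L))
    mag <- sqrt(gx^2 + gy^2)
    magMax <- max(mag)
    if (magMax == 0)
        return(edgeMap(matrix(FALSE, nrow(gray), ncol(gray))))
    # Non-maximum suppression: compare against the two neighbors along the
    # gradient direction, quantized to 4 sectors. Plateau ties are broken
    # asymmetrically (strict > toward the +gradient neighbor) so a symmetric
    # step edge yields a single-pixel line.
    ang <- atan2(gy, gx) * 180 / pi
    ang[ang < 0] <- ang[ang < 0] + 180
    offs <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
    sector <- findInterval(ang, c(22.5, 67.5, 112.5, 157.5)) %% 4L + 1L
    nPlus <- nMinus <- mag
    for (s in 1:4) {
        sel <- sector == s
        o <- offs[[s]]
        nPlus[sel] <- .shiftPad(mag, o[1], o[2])[sel]
        nMinus[sel] <- .shiftPad(mag, -o[1], -o[2])[sel]
    }
    nms <- mag
    nms[!(mag > nPlus & mag >= nMinus)] <- 0
    strong <- nms >= high * magMax
    weak <- nms >= low * magMax
    # grow strong seeds through 8-connected weak pixels to a fixpoint
    repeat {
        grown <- weak & .dilate8(strong)
        if (identical(grown, strong)) break
        strong <- grown
    }
    edgeMap(strong)
}

#' Image complexity from edge density
#'
#' Images showing multiple objects or multi-component objects carry more
#' outline pixels than single homogeneous objects; complexity is the
#' proportion of outline pixels within the frame.
#'
#' @param edges an [EdgeMap-class].
#' @return Fraction in [0, 1]: \code{edgeCount / (height * width)}.
#' @export
edgeComplexity <- function(edges) {
    stopifnot(is(edges, "EdgeMap"))
    sum(edges@flags) / length(edges@flags)
}

#' Size-normalized image complexity
#'
#' Complexity divided by object size, i.e. outline pixels per object pixel,
#' so that larger objects are not trivially scored as more complex. The
#' strict-literal variant divides the outline proportion by the raw
#' non-white pixel count instead (a frame-size-dependent quantity); the
#' default, dimensionally consistent reading divides proportion by
#' proportion. Note that under either reading a uniformly magnified object
#' still scales as 1/side (perimeter grows linearly, area quadratically).
#'
#' @param edges an [EdgeMap-class].
#' @param mask an [ObjectMask-class] for the same image.
#' @param strictLiteral logical; if TRUE use
#'   \code{edgeCount / (frameArea * objectCount)}.
#' @return Non-negative ratio; equals \code{edgeComplexity(edges) /
#'   objectSize(mask)} when \code{strictLiteral = FALSE}.
#' @export
normalizedComplexity <- function(edges, mask, strictLiteral = FALSE) {
    stopifnot(is(edges, "EdgeMap"), is(mask, "ObjectMask"))
    .checkSameDim(edges, mask)
    n <- sum(mask@flags)
    if (n == 0L)
        stop("no object pixels: mask is empty")
    if (strictLiteral)
        sum(edges@flags) / (length(edges@flags) * n)
    else
        sum(edges@flags) / n
}
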