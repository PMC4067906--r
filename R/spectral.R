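#' Centered 2D power spectrum
#'
#' Squared modulus of the two-dimensional discrete Fourier transform of the
#' luminance raster, shifted so the DC (zero-frequency) coefficient sits at
#' the center bin \code{(floor(h/2)+1, floor(w/2)+1)}. The transform runs on
#' the full frame, white background included, with no windowing or padding.
#' The unnormalized DFT convention is used, so total power obeys Parseval's
#' identity \code{sum(P) = N * sum(x^2)} with \code{N = h * w}.
#'
#' @param gray a [GrayImage-class].
#' @return Numeric matrix of spectral power, same dimensions as the input.
#' @export
#' @examples
#' p <- powerSpectrum2D(grayImage(matrix(100, 8, 8)))
#' sum(p > 0)  # constant image: all power in the DC bin
powerSpectrum2D <- function(gray) {
    stopifnot(is(gray, "GrayImage"))
    p <- Mod(stats::fft(unclass(gray)))^2
    .fftshift2(p)
}

## Move the DC bin from [1,1] to the center (floor(d/2)+1 in each dimension).
.fftshift2 <- function(m) {
    idx <- function(n) {
        cut <- n - n %/% 2L
        c(seq.int(cut + 1L, length.out = n %/% 2L), seq_len(cut))
    }
    m[idx(nrow(m)), idx(ncol(m)), drop = FALSE]
}

.dcIndex <- function(h, w) c(h %/% 2 + 1L, w %/% 2 + 1L)

#' Radial average of a 2D power spectrum
#'
#' Collapses a centered 2D power spectrum into a one-dimensional function of
#' spatial frequency: each coefficient is assigned to the bin given by its
#' integer-rounded Euclidean distance from the DC bin, and a bin's value is
#' the mean power of its members. Bins beyond
#' \code{floor(min(height, width)/2)} (frequencies not supported in every
#' direction) are discarded. Radial binning is orientation-blind: rotating a
#' grating by 90 degrees leaves the result unchanged.
#'
#' @param power2d centered power matrix from [powerSpectrum2D()].
#' @return A [RadialSpectrum-class] with bins 0..maxRadius.
#' @export
radialAverage <- function(power2d) {
    stopifnot(is.matrix(power2d), all(power2d >= 0))
    h <- nrow(power2d); w <- ncol(power2d)
    dc <- .dcIndex(h, w)
    r <- sqrt(outer((seq_len(h) - dc[1])^2, (seq_len(w) - dc[2])^2, "+"))
    bin <- as.integer(round(r))
    maxR <- min(h, w) %/% 2L
    keep <- bin <= maxR
    sums <- rowsum(as.vector(power2d)[keep], bin[keep])
    counts <- tabulate(bin[keep] + 1L, nbins = maxR + 1L)
    pw <- numeric(maxR + 1L)
    pw[as.integer(rownames(sums)) + 1L] <- sums
    pw <- pw / counts
    new("RadialSpectrum", frequencies = 0:maxR, power = pw)
}

#' Median spectral power
#'
#' Summarizes an image's spatial-frequency content as the median of the
#' radially averaged power values. The DC bin is excluded by default —
#' including it would tie the statistic to mean luminance rather than
#' spatial structure — and can be brought back with \code{includeDC = TRUE}.
#' Applied to a [GrayImage-class], the whole pipeline (2D FFT, radial
#' average, median) runs in one call; \code{mode = "all_coefficients"} takes
#' the median over all raw 2D power coefficients instead of the radial bins.
#'
#' @param x a [RadialSpectrum-class] or a [GrayImage-class].
#' @param includeDC logical; include the zero-frequency bin (default FALSE).
#' @param mode for GrayImage input: \code{"radial_bins"} (default) or
#'   \code{"all_coefficients"}.
#' @param ... passed between methods.
#' @return Non-negative scalar; 0 iff the image is constant.
#' @name medianPower
#' @export
#' @examples
#' g <- generateImage(shape = "grating", cycles = 8, canvas = c(64, 64))
#' medianPower(toGrayscale(g$image))
setMethod("medianPower", "RadialSpectrum", function(x, includeDC = FALSE) {
    p <- x@power
    if (!includeDC) p <- p[-1L]
    if (length(p) == 0L)
        stop("spectrum has no non-DC bins")
    stats::median(p)
})

#' @rdname medianPower
#' @export
setMethod("medianPower", "GrayImage",
    function(x, mode = c("radial_bins", "all_coefficients"),
             includeDC = FALSE) {
    mode <- match.arg(mode)
    p2d <- powerSpectrum2D(x)
    if (mode == "radial_bins")
        return(medianPower(radialAverage(p2d), includeDC = includeDC))
    dc <- .dcIndex(nrow(p2d), ncol(p2d))
    v <- as.vector(p2d)
    if (!includeDC)
        v <- v[-((dc[2] - 1L) * nrow(p2d) + dc[1])]
    stats::median(v)
})
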