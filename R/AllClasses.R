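#' @import methods
NULL

#' RGBImage: a color stimulus raster
#'
#' A three-channel raster holding integer-valued intensities on the 0--255
#' scale, stored as a numeric array with dimensions \code{height x width x 3}
#' and channel order red, green, blue. Stimulus-database photographs are
#' nominally 600 x 450 px (sRGB), but any size is accepted.
#'
#' @slot .Data numeric array, \code{height x width x 3}, values in [0, 255].
#' @seealso [loadImage()], [toGrayscale()], [computeMask()], [generateImage()]
#' @export
setClass("RGBImage", contains = "array", validity = function(object) {
    d <- dim(object)
    if (length(d) != 3L || d[3] != 3L)
        return("pixel array must be height x width x 3")
    if (d[1] < 1L || d[2] < 1L)
        return("height and width must be >= 1")
    if (anyNA(object))
        return("pixel values must not be NA")
    r <- range(object)
    if (r[1] < 0 || r[2] > 255)
        return("channel values must lie in [0, 255]")
    TRUE
})

#' GrayImage: luminance raster on the 0--255 scale
#'
#' Single-channel luminance values obtained from an [RGBImage-class] by the
#' weighted channel sum 0.2989 R + 0.5870 G + 0.1140 B. Values are kept
#' fractional (no integer quantization) so downstream means and standard
#' deviations are exact.
#'
#' @slot .Data numeric matrix, \code{height x width}, values in [0, 255].
#' @seealso [toGrayscale()]
#' @export
setClass("GrayImage", contains = "matrix", validity = function(object) {
    if (anyNA(object))
        return("luminance values must not be NA")
    r <- range(object)
    if (r[1] < 0 || r[2] > 255)
        return("luminance values must lie in [0, 255]")
    TRUE
})

#' ObjectMask: the non-white (object) pixels of a stimulus
#'
#' Boolean raster flagging object pixels: a pixel counts as background
#' ("white") iff all three channels are >= the white threshold used to build
#' the mask; the mask flags the complement. The threshold is recorded so
#' results are reproducible.
#'
#' @slot flags logical matrix, TRUE = object (non-white) pixel.
#' @slot whiteThreshold integer in [0, 255] used to build the mask.
#' @seealso [computeMask()], [objectCount()], [objectSize()]
#' @export
setClass("ObjectMask",
    representation(flags = "matrix", whiteThreshold = "integer"),
    validity = function(object) {
        if (!is.logical(object@flags))
            return("flags must be a logical matrix")
        if (anyNA(object@flags))
            return("flags must not contain NA")
        wt <- object@whiteThreshold
        if (length(wt) != 1L || is.na(wt) || wt < 0L || wt > 255L)
            return("whiteThreshold must be a single integer in [0, 255]")
        TRUE
    })

#' EdgeMap: Canny outline pixels of a stimulus
#'
#' Boolean raster of detected outline pixels, together with the detector
#' parameters (Gaussian sigma and the hysteresis thresholds expressed as
#' fractions of the gradient-magnitude range) so runs are reproducible.
#'
#' @slot flags logical matrix, TRUE = outline pixel.
#' @slot sigma numeric, Gaussian smoothing width in pixels.
#' @slot low,high numeric hysteresis thresholds in (0, 1], low < high.
#' @seealso [detectEdges()], [edgeComplexity()], [normalizedComplexity()]
#' @export
setClass("EdgeMap",
    representation(flags = "matrix", sigma = "numeric",
                   low = "numeric", high = "numeric"),
    validity = function(object) {
        if (!is.logical(object@flags))
            return("flags must be a logical matrix")
        if (object@sigma <= 0)
            return("sigma must be > 0")
        if (object@low < 0 || object@high > 1 || object@low >= object@high)
            return("need 0 <= low < high <= 1")
        TRUE
    })

#' RadialSpectrum: radially averaged 2D power spectrum
#'
#' One-dimensional power spectrum obtained by collapsing a centered 2D power
#' spectrum over integer-rounded distance from the DC bin. Bin b holds the
#' mean power of all coefficients at rounded radius b; radii beyond
#' \code{floor(min(height, width) / 2)} are discarded.
#'
#' @slot frequencies integer radii, 0..maxRadius (cycles per image).
#' @slot power mean spectral power per radial bin, >= 0.
#' @seealso [radialAverage()], [medianPower()]
#' @export
setClass("RadialSpectrum",
    representation(frequencies = "integer", power = "numeric"),
    validity = function(object) {
        if (length(object@frequencies) != length(object@power))
            return("frequencies and power must have equal length")
        if (length(object@power) < 1L)
            return("spectrum must have at least the DC bin")
        if (!identical(object@frequencies,
                       seq_len(length(object@frequencies)) - 1L))
            return("frequencies must be 0..maxRadius")
        if (any(object@power < 0))
            return("power must be non-negative")
        TRUE
    })

#' MatchResult: outcome of matched stimulus-set selection
#'
#' @slot selected data.frame with columns \code{condition} and
#'   \code{image_id}: the chosen, disjoint condition subsets.
#' @slot smd numeric matrix of standardized mean differences
#'   (features x condition pairs), denominated in the pooled SD of the full
#'   candidate pool.
#' @slot objective numeric, max absolute standardized difference attained.
#' @slot met logical, whether the requested tolerance was met.
#' @slot seed integer seed that produced the selection.
#' @seealso [matchStimulusSets()]
#' @export
setClass("MatchResult",
    representation(selected = "data.frame", smd = "matrix",
                   objective = "numeric", met = "logical", seed = "integer"))
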