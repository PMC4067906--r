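#' Image and mask accessors
#'
#' Dimension and count accessors for the raster classes. \code{imgHeight} /
#' \code{imgWidth} give pixel dimensions; \code{objectCount} the number of
#' non-white pixels in an [ObjectMask-class]; \code{edgeCount} the number of
#' outline pixels in an [EdgeMap-class]; \code{whiteThreshold} the threshold
#' an [ObjectMask-class] was built with; \code{maskFlags} / \code{edgeFlags}
#' the underlying logical matrices.
#'
#' @param x an object of one of the raster classes.
#' @return An integer scalar (dimensions, counts, threshold) or a logical
#'   matrix (flag accessors).
#' @name raster-accessors
#' @aliases imgHeight imgWidth objectCount edgeCount whiteThreshold
#'   maskFlags edgeFlags
#' @examples
#' img <- generateImage(shape = "square", side = 20, canvas = c(60, 40))
#' m <- computeMask(img$image)
#' objectCount(m)
#' imgWidth(img$image)
NULL

#' @rdname raster-accessors
#' @export
setGeneric("imgHeight", function(x) standardGeneric("imgHeight"))
#' @rdname raster-accessors
#' @export
setGeneric("imgWidth", function(x) standardGeneric("imgWidth"))
#' @rdname raster-accessors
#' @export
setGeneric("objectCount", function(x) standardGeneric("objectCount"))
#' @rdname raster-accessors
#' @export
setGeneric("edgeCount", function(x) standardGeneric("edgeCount"))
#' @rdname raster-accessors
#' @export
setGeneric("whiteThreshold", function(x) standardGeneric("whiteThreshold"))
#' @rdname raster-accessors
#' @export
setGeneric("maskFlags", function(x) standardGeneric("maskFlags"))
#' @rdname raster-accessors
#' @export
setGeneric("edgeFlags", function(x) standardGeneric("edgeFlags"))

#' @rdname medianPower
#' @export
setGeneric("medianPower", function(x, ...) standardGeneric("medianPower"))

setMethod("imgHeight", "RGBImage", function(x) dim(x)[1])
setMethod("imgWidth", "RGBImage", function(x) dim(x)[2])
setMethod("imgHeight", "GrayImage", function(x) nrow(x))
setMethod("imgWidth", "GrayImage", function(x) ncol(x))
setMethod("imgHeight", "ObjectMask", function(x) nrow(x@flags))
setMethod("imgWidth", "ObjectMask", function(x) ncol(x@flags))
setMethod("imgHeight", "EdgeMap", function(x) nrow(x@flags))
setMethod("imgWidth", "EdgeMap", function(x) ncol(x@flags))

setMethod("objectCount", "ObjectMask", function(x) sum(x@flags))
setMethod("edgeCount", "EdgeMap", function(x) sum(x@flags))
setMethod("whiteThreshold", "ObjectMask", function(x) x@whiteThreshold)
setMethod("maskFlags", "ObjectMask", function(x) x@flags)
setMethod("edgeFlags", "EdgeMap", function(x) x@flags)

setMethod("show", "RGBImage", function(object) {
    d <- dim(object)
    cat(sprintf("RGBImage: %d x %d px, 3 channels (RGB), range [%g, %g]\n",
                d[1], d[2], min(object), max(object)))
})

setMethod("show", "GrayImage", function(object) {
    cat(sprintf("GrayImage: %d x %d px, luminance range [%.3f, %.3f]\n",
                nrow(object), ncol(object), min(object), max(object)))
})

setMethod("show", "ObjectMask", function(object) {
    cat(sprintf(
        "ObjectMask: %d x %d px, %d object pixels (%.2f%%), whiteThreshold %d\n",
        nrow(object@flags), ncol(object@flags), sum(object@flags),
        100 * mean(object@flags), object@whiteThreshold))
})

setMethod("show", "EdgeMap", function(object) {
    cat(sprintf(
        "EdgeMap: %d x %d px, %d outline pixels (sigma %.2f, thresholds %.2f/%.2f)\n",
        nrow(object@flags), ncol(object@flags), sum(object@flags),
        object@sigma, object@low, object@high))
})

setMethod("show", "RadialSpectrum", function(object) {
    cat(sprintf("RadialSpectrum: %d bins (radius 0..%d), median power %.4g\n",
                length(object@power), length(object@power) - 1L,
                medianPower(object)))
})

setMethod("show", "MatchResult", function(object) {
    k <- table(object@selected$condition)
    cat(sprintf(
        "MatchResult: %s; max |SMD| = %.4f (%s)\n",
        paste(sprintf("%s: %d images", names(k), as.integer(k)),
              collapse = ", "),
        object@objective,
        if (object@met) "tolerance met" else "tolerance NOT met"))
})
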