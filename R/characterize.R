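#' Run configuration for the characterization pipeline
#'
#' Bundles every tunable parameter of the image-characterization pipeline
#' with its default, validates the constraints, and is echoed into every
#' output artifact so runs are reproducible.
#'
#' @param whiteThreshold integer in [0, 255]; channels at or above it count
#'   as white background (default 250).
#' @param cannySigma Gaussian smoothing width in pixels (default 1.0).
#' @param cannyLow,cannyHigh hysteresis thresholds as fractions of the
#'   gradient-magnitude range (defaults 0.1 / 0.2).
#' @param sdDivisor \code{"n"} (population SD, default) or \code{"n-1"} for
#'   the within-object contrast.
#' @param medianMode \code{"radial_bins"} (default) or
#'   \code{"all_coefficients"} for the median spectral power.
#' @param strictLiteralNormalizedComplexity logical; divide the outline
#'   proportion by the raw object pixel count instead of the size fraction
#'   (default FALSE).
#' @param seed integer seed recorded with the run.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
runConfig <- function(whiteThreshold = 250L, cannySigma = 1.0,
                      cannyLow = 0.1, cannyHigh = 0.2,
                      sdDivisor = c("n", "n-1"),
                      medianMode = c("radial_bins", "all_coefficients"),
                      strictLiteralNormalizedComplexity = FALSE,
                      seed = 1L) {
    sdDivisor <- match.arg(sdDivisor)
    medianMode <- match.arg(medianMode)
    whiteThreshold <- as.integer(whiteThreshold)
    if (whiteThreshold < 0L || whiteThreshold > 255L)
        stop("whiteThreshold must lie in [0, 255]")
    if (cannySigma <= 0)
        stop("cannySigma must be > 0")
    if (cannyLow < 0 || cannyHigh > 1 || cannyLow >= cannyHigh)
        stop("need 0 <= cannyLow < cannyHigh <= 1")
    structure(list(whiteThreshold = whiteThreshold,
                   cannySigma = cannySigma, cannyLow = cannyLow,
                   cannyHigh = cannyHigh, sdDivisor = sdDivisor,
                   medianMode = medianMode,
                   strictLiteralNormalizedComplexity =
                       isTRUE(strictLiteralNormalizedComplexity),
                   seed = as.integer(seed)),
              class = "RunConfig")
}

.configEcho <- function(config) {
    data.frame(white_threshold = config$whiteThreshold,
               canny_sigma = config$cannySigma,
               canny_low = config$cannyLow,
               canny_high = config$cannyHigh,
               sd_divisor = config$sdDivisor,
               median_mode = config$medianMode,
               strict_literal_normalized_complexity =
                   config$strictLiteralNormalizedComplexity)
}

#' Characterize one stimulus image
#'
#' Computes the full physical-appearance metric vector for one image: RGB
#' channel contributions, object size, brightness, within-object contrast,
#' median spectral power, and raw plus size-normalized edge complexity.
#' Images with an empty object mask (all-white) get \code{NA} for every
#' object-dependent metric.
#'
#' @param img an [RGBImage-class] or a file path.
#' @param config a [runConfig()] list.
#' @param imageId identifier for the output row; defaults to the filename
#'   stem when \code{img} is a path.
#' @return One-row data.frame: \code{image_id, width, height, red_prop,
#'   green_prop, blue_prop, size, brightness, contrast, median_power,
#'   complexity, normalized_complexity} plus config echo columns.
#' @export
#' @examples
#' fx <- generateImage(shape = "square", side = 40, canvas = c(120, 90))
#' characterizeImage(fx$image, imageId = "sq40")
characterizeImage <- function(img, config = runConfig(), imageId = NULL) {
    stopifnot(inherits(config, "RunConfig"))
    if (is.character(img)) {
        if (is.null(imageId))
            imageId <- tools::file_path_sans_ext(basename(img))
        img <- loadImage(img)
    }
    if (is.null(imageId))
        imageId <- "image"
    stopifnot(is(img, "RGBImage"))
    gray <- toGrayscale(img)
    mask <- computeMask(img, config$whiteThreshold)
    edges <- detectEdges(gray, sigma = config$cannySigma,
                         low = config$cannyLow, high = config$cannyHigh)
    n <- objectCount(mask)
    if (n > 0L) {
        cc <- colorContribution(img, mask)
        bright <- objectBrightness(gray, mask)
        contr <- objectContrast(gray, mask, divisor = config$sdDivisor)
        normC <- normalizedComplexity(
            edges, mask,
            strictLiteral = config$strictLiteralNormalizedComplexity)
    } else {
        warning("image '", imageId,
                "' has no object pixels; object metrics set to NA")
        cc <- c(red_prop = NA_real_, green_prop = NA_real_,
                blue_prop = NA_real_)
        bright <- contr <- normC <- NA_real_
    }
    row <- data.frame(
        image_id = imageId,
        width = imgWidth(img), height = imgHeight(img),
        red_prop = unname(cc[1]), green_prop = unname(cc[2]),
        blue_prop = unname(cc[3]),
        size = objectSize(mask), brightness = bright, contrast = contr,
        median_power = medianPower(gray, mode = config$medianMode),
        complexity = edgeComplexity(edges),
        normalized_complexity = normC,
        stringsAsFactors = FALSE)
    cbind(row, .configEcho(config))
}

#' Characterize every image in a directory
#'
#' Applies [characterizeImage()] to every PNG/JPEG/BMP file in a directory,
#' one row per image, sorted by \code{image_id} (the filename stem).
#' Undecodable files are skipped with a warning; duplicate stems across
#' files are an error. Optionally writes the metrics CSV (UTF-8, comma
#' separator, "." decimal mark, empty fields for missing values); two runs
#' with identical inputs and config produce byte-identical output.
#'
#' @param inputDir directory containing at least one decodable image.
#' @param config a [runConfig()] list.
#' @param outputCsv optional path for the metrics CSV.
#' @return data.frame of metric rows (invisibly when \code{outputCsv} is
#'   given). The number of skipped files is attached as attribute
#'   \code{"n_skipped"}.
#' @export
characterizeDirectory <- function(inputDir, config = runConfig(),
                                  outputCsv = NULL) {
    files <- list.files(inputDir, pattern = "\\.(png|jpe?g|bmp)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L)
        stop("no decodable images found in ", inputDir)
    ids <- tools::file_path_sans_ext(basename(files))
    if (anyDuplicated(ids))
        stop("duplicate image ids (filename stems): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    rows <- list()
    skipped <- 0L
    for (i in seq_along(files)) {
        rows[[ids[i]]] <- tryCatch(
            characterizeImage(files[i], config, imageId = ids[i]),
            error = function(e) {
                warning("skipping '", files[i], "': ",
                        conditionMessage(e), call. = FALSE)
                NULL
            })
        if (is.null(rows[[ids[i]]])) skipped <- skipped + 1L
    }
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows) == 0L)
        stop("no image in ", inputDir, " could be decoded")
    out <- do.call(rbind, rows[order(names(rows))])
    rownames(out) <- NULL
    attr(out, "n_skipped") <- skipped
    if (!is.null(outputCsv)) {
        utils::write.csv(out, outputCsv, row.names = FALSE, quote = FALSE,
                         na = "")
        return(invisible(out))
    }
    out
}
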