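# Shared test helpers: tiny constructors, an independent BMP writer, the
# scikit-image Canny oracle, and a compact survey design for simulations.

uniformMask <- function(h, w, value = TRUE, threshold = 250L) {
    new("ObjectMask", flags = matrix(value, h, w),
        whiteThreshold = as.integer(threshold))
}

# Minimal uncompressed 24-bit BMP writer (bottom-up rows, BGR order),
# independent of the package's reader.
writeBmp24 <- function(px, path) {  # px: h x w x 3 array, 0..255
    h <- dim(px)[1]; w <- dim(px)[2]
    rowSize <- ((24 * w + 31) %/% 32) * 4
    dataSize <- rowSize * h
    u32 <- function(x) writeBin(as.integer(x), con, size = 4,
                                endian = "little")
    u16 <- function(x) writeBin(as.integer(x), con, size = 2,
                                endian = "little")
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("BM"), con)
    u32(54 + dataSize); u32(0); u32(54)          # file size, reserved, offset
    u32(40); u32(w); u32(h); u16(1); u16(24)     # info header
    u32(0); u32(dataSize); u32(2835); u32(2835); u32(0); u32(0)
    pad <- as.raw(rep(0, rowSize - 3 * w))
    for (r in seq(h, 1)) {                       # bottom-up
        row <- rbind(px[r, , 3], px[r, , 2], px[r, , 1])  # BGR
        writeBin(as.raw(as.integer(row)), con)
        if (length(pad)) writeBin(pad, con)
    }
    invisible(path)
}

# Edge count from scikit-image's Canny on a PNG written to disk; the
# independent reference implementation for the edge detector.
skimageCannyCount <- function(pngPath, sigma = 1.0) {
    script <- sprintf(paste0(
        "import numpy as np; from skimage.io import imread; ",
        "from skimage.feature import canny; ",
        "img = imread(r'%s'); ",
        "g = (0.2989*img[:,:,0]+0.5870*img[:,:,1]+0.1140*img[:,:,2])/255.0; ",
        "print(int(canny(g, sigma=%f, low_threshold=0.1, ",
        "high_threshold=0.2).sum()))"), pngPath, sigma)
    out <- suppressWarnings(
        tryCatch(system2("python", c("-c", shQuote(script)),
                         stdout = TRUE, stderr = FALSE),
                 error = function(e) character()))
    if (length(out) == 0 || is.na(suppressWarnings(as.integer(out[1]))))
        return(NA_integer_)
    as.integer(out[1])
}

# Small survey design used throughout the simulation tests.
tinySamples <- function(n = 40L, nonfood = 2L, food = 8L) {
    data.frame(sample = "test", n = as.integer(n),
               nonfood_per_rater = as.integer(nonfood),
               food_per_rater = as.integer(food),
               stringsAsFactors = FALSE)
}

# Latent means with a single constant value per scale (integer, so the
# zero-noise survey reproduces them exactly after rounding).
flatLatents <- function(ids, value = 50) {
    m <- matrix(value, nrow = length(ids), ncol = 5,
                dimnames = list(ids, c("complexity_vas", "valence_vas",
                                       "arousal_vas", "palatability_vas",
                                       "desire_vas")))
    m
}

surveyImageIds <- function(nFood, nNonFood) {
    c(sprintf("food_%04d", seq_len(nFood)),
      sprintf("nonfood_%04d", seq_len(nNonFood)))
}

# Independent exhaustive search over all subset pairs (two conditions
# labeled "a" and "b"): the matching oracle.
bruteForceObjective <- function(pool, features, k) {
    X <- as.matrix(pool[features])
    Z <- sweep(X, 2, apply(X, 2, stats::sd), "/")
    ia <- which(pool$condition == "a")
    ib <- which(pool$condition == "b")
    ca <- utils::combn(ia, k); cb <- utils::combn(ib, k)
    ma <- apply(ca, 2, function(ix) colMeans(Z[ix, , drop = FALSE]))
    mb <- apply(cb, 2, function(ix) colMeans(Z[ix, , drop = FALSE]))
    ma <- matrix(ma, nrow = length(features))
    mb <- matrix(mb, nrow = length(features))
    best <- Inf
    for (i in seq_len(ncol(ma))) {
        d <- abs(mb - ma[, i])
        best <- min(best, min(apply(d, 2, max)))
    }
    best
}
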