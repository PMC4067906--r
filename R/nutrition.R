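## Canonical column order for the nutrition CSV contract.
.NUTRITION_COLS <- c("image_id", "is_food", "category", "sweet_savory",
                     "processing", "kcal_per_100g", "protein_per_100g",
                     "carb_per_100g", "fat_per_100g", "portion_grams",
                     "item_count", "total_kcal")

#' Per-portion nutrient totals
#'
#' Converts per-100 g nutrient values into totals for the depicted portion:
#' each total equals the per-100 g value times \code{portion_grams / 100}.
#' A missing portion mass propagates as \code{NA} (flagged unavailable,
#' never treated as zero); a non-positive portion mass is an error.
#'
#' @param records data.frame with columns \code{kcal_per_100g},
#'   \code{protein_per_100g}, \code{carb_per_100g}, \code{fat_per_100g},
#'   \code{portion_grams}.
#' @return The input with columns \code{total_kcal}, \code{total_protein_g},
#'   \code{total_carb_g}, \code{total_fat_g} added (or overwritten).
#' @export
#' @examples
#' portionTotals(data.frame(kcal_per_100g = 250, protein_per_100g = 9,
#'                          carb_per_100g = 50, fat_per_100g = 2,
#'                          portion_grams = 17.6))$total_kcal  # 44
portionTotals <- function(records) {
    need <- c("kcal_per_100g", "protein_per_100g", "carb_per_100g",
              "fat_per_100g", "portion_grams")
    missingCols <- setdiff(need, names(records))
    if (length(missingCols))
        stop("missing nutrition columns: ",
             paste(missingCols, collapse = ", "))
    pg <- records$portion_grams
    if (any(!is.na(pg) & pg <= 0))
        stop("portion_grams must be > 0 (or NA when unavailable)")
    scale <- pg / 100
    records$total_kcal <- records$kcal_per_100g * scale
    records$total_protein_g <- records$protein_per_100g * scale
    records$total_carb_g <- records$carb_per_100g * scale
    records$total_fat_g <- records$fat_per_100g * scale
    records
}

#' High/low caloric-density median split
#'
#' Splits food records at the median caloric density (kcal per 100 g):
#' density at or below the median is labeled \code{"low"}, above it
#' \code{"high"}. Ties at the median deterministically go to \code{"low"};
#' the median of an even count is the mean of the central order statistics.
#' Non-food records and records with missing density are excluded (with a
#' message giving the count).
#'
#' @param records data.frame with columns \code{image_id},
#'   \code{kcal_per_100g} and (optionally) logical \code{is_food}; when
#'   \code{is_food} is absent all records count as food.
#' @return A list with \code{median_density} (kcal/100 g) and \code{labels},
#'   a data.frame of \code{image_id}, \code{kcal_per_100g},
#'   \code{calorie_split} (\code{"high"}/\code{"low"}).
#' @export
#' @examples
#' medianSplit(data.frame(image_id = letters[1:4],
#'                        kcal_per_100g = c(100, 200, 300, 400)))
medianSplit <- function(records) {
    stopifnot(all(c("image_id", "kcal_per_100g") %in% names(records)))
    food <- if ("is_food" %in% names(records))
        records[records$is_food %in% TRUE, ] else records
    dropped <- sum(is.na(food$kcal_per_100g))
    if (dropped > 0)
        message(dropped, " food record(s) lack kcal_per_100g; excluded ",
                "from the split")
    food <- food[!is.na(food$kcal_per_100g), ]
    if (nrow(food) < 2L)
        stop("median split needs >= 2 food records with kcal_per_100g")
    med <- stats::median(food$kcal_per_100g)
    lab <- ifelse(food$kcal_per_100g > med, "high", "low")
    if (all(lab == "low"))
        warning("all caloric densities at or below the median; ",
                "'high' group is empty")
    list(median_density = med,
         labels = data.frame(image_id = food$image_id,
                             kcal_per_100g = food$kcal_per_100g,
                             calorie_split = lab,
                             stringsAsFactors = FALSE))
}

#' Between-coder agreement for double-coded metadata
#'
#' Pearson correlation between two coders' estimates of the same quantity
#' (e.g. kcal per 100 g over a double-coded subsample), the cross-validation
#' statistic for human-estimated nutrition metadata.
#'
#' @param coderA,coderB numeric vectors of equal length >= 3, neither
#'   constant.
#' @return Pearson r.
#' @export
coderAgreement <- function(coderA, coderB) {
    if (length(coderA) != length(coderB))
        stop("coder vectors must have equal length")
    keep <- !is.na(coderA) & !is.na(coderB)
    a <- coderA[keep]; b <- coderB[keep]
    if (length(a) < 3L)
        stop("agreement needs >= 3 complete pairs")
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("correlation undefined: constant coder values")
    stats::cor(a, b)
}

#' Read / write the nutrition metadata CSV
#'
#' Round-trips the nutrition table with the canonical header
#' \code{image_id, is_food, category, sweet_savory, processing,
#' kcal_per_100g, protein_per_100g, carb_per_100g, fat_per_100g,
#' portion_grams, item_count, total_kcal} (UTF-8, comma separator, "."
#' decimal mark, empty fields for missing values).
#'
#' @param path CSV file path.
#' @param records data.frame with (at least) the canonical columns.
#' @return \code{readNutritionCsv}: the table as a data.frame;
#'   \code{writeNutritionCsv}: invisibly, \code{path}.
#' @export
readNutritionCsv <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    missingCols <- setdiff(.NUTRITION_COLS, names(df))
    if (length(missingCols))
        stop("nutrition CSV ", path, " lacks column(s): ",
             paste(missingCols, collapse = ", "))
    df$is_food <- as.logical(df$is_food)
    df
}

#' @rdname readNutritionCsv
#' @export
writeNutritionCsv <- function(records, path) {
    missingCols <- setdiff(.NUTRITION_COLS, names(records))
    if (length(missingCols))
        stop("nutrition table lacks column(s): ",
             paste(missingCols, collapse = ", "))
    utils::write.csv(records[.NUTRITION_COLS], path, row.names = FALSE,
                     quote = FALSE, na = "")
    invisible(path)
}
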