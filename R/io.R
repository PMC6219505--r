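# Plain-text interchange: tab-separated tables for features/outcomes/
# results, CSV + JSON sidecar for point patterns.

#' Write a feature matrix as tab-separated text
#'
#' One header line; first column `sample_id`; a `#kinds` comment line
#' records the per-feature kind tags.
#'
#' @param features a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  kinds <- feature_kinds(features)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kinds\t", paste(kinds, collapse = "\t")), con)
  df <- data.frame(sample_id = rownames(features),
                   unclass_matrix(features), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path input path.
#' @return a [feature_matrix()].
#' @export
read_feature_matrix <- function(path) {
  first <- readLines(path, n = 1)
  kinds <- NULL
  if (startsWith(first, "#kinds\t")) {
    kinds <- strsplit(sub("^#kinds\t", "", first), "\t")[[1]]
  }
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  feature_matrix(m, kinds %||% "mutation")
}

#' Write survival outcomes as tab-separated text
#' @param outcomes a [survival_outcome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  df <- as.data.frame(outcomes)
  df$endpoint <- attr(outcomes, "endpoint")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival outcomes written by [write_outcomes()]
#' @param path input path.
#' @return a [survival_outcome()].
#' @export
read_outcomes <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  survival_outcome(df$time, df$event,
                   endpoint = unique(df$endpoint)[1] %||% "OS",
                   sample_ids = df$sample_id)
}

#' Write a point pattern as CSV with a JSON geometry sidecar
#'
#' Coordinates go to `<path>` (columns `x`, `y`, micrometers); field
#' dimensions, units and magnification go to `<path>.json`.
#'
#' @param pattern a [point_pattern()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  write.table(data.frame(x = pattern$x, y = pattern$y), path, sep = ",",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(field_width = pattern$field_width,
         field_height = pattern$field_height,
         units = "um", sample_id = pattern$sample_id,
         magnification = pattern$magnification),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a point pattern written by [write_point_pattern()]
#' @param path CSV path (expects the `<path>.json` sidecar).
#' @return a [point_pattern()].
#' @export
read_point_pattern <- function(path) {
  df <- read.table(path, header = TRUE, sep = ",")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  point_pattern(df$x, df$y, side$field_width, side$field_height,
                sample_id = side$sample_id %||% NA_character_,
                magnification = side$magnification %||% "20x")
}
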