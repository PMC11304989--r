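#' Candidate and annotation tables
#'
#' Candidate lists and nodule annotations travel as comma-separated tables in
#' the LUNA16 dialect: columns `seriesuid, coordX, coordY, coordZ` plus either
#' a `class` column (`0`/`1`, candidates), an optional `probability` column,
#' or a `diameter_mm` column (annotations). Coordinates are world mm.
#' Readers preserve row order; writers round-trip bit-stably through
#' [readr::read_csv()] / [readr::write_csv()].
#'
#' @param path Path to a CSV file.
#' @return `read_candidates()`: a tibble with columns `seriesuid`, `coordX`,
#'   `coordY`, `coordZ`, `label` (factor `negative`/`positive`/`unknown`) and,
#'   when present in the file, `score`. `read_annotations()`: a tibble with
#'   `seriesuid`, `coordX`, `coordY`, `coordZ`, `diameter_mm` and, when
#'   present, `agreement`.
#' @name candidate_tables
NULL

candidate_coord_cols <- c("seriesuid", "coordX", "coordY", "coordZ")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("table ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' @rdname candidate_tables
#' @export
read_candidates <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, candidate_coord_cols, path)
  out <- tibble::tibble(
    seriesuid = as.character(df$seriesuid),
    coordX = as.numeric(df$coordX),
    coordY = as.numeric(df$coordY),
    coordZ = as.numeric(df$coordZ)
  )
  out$label <- if ("class" %in% names(df)) {
    candidate_label(ifelse(df$class == 1, "positive", "negative"))
  } else {
    candidate_label(rep("unknown", nrow(df)))
  }
  score_col <- intersect(c("probability", "score"), names(df))
  if (length(score_col) > 0L) {
    score <- as.numeric(df[[score_col[1]]])
    if (any(!is.na(score) & (score < 0 | score > 1))) {
      stop("candidate scores must lie in [0, 1]: ", path, call. = FALSE)
    }
    out$score <- score
  }
  out
}

#' @rdname candidate_tables
#' @param candidates A candidate tibble as returned by [read_candidates()] or
#'   [propose_candidates()].
#' @export
write_candidates <- function(candidates, path) {
  check_columns(candidates, candidate_coord_cols, "`candidates`")
  out <- candidates[candidate_coord_cols]
  if ("label" %in% names(candidates) &&
      !all(candidates$label == "unknown")) {
    out$class <- as.integer(candidates$label == "positive")
  }
  if ("score" %in% names(candidates)) out$probability <- candidates$score
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname candidate_tables
#' @export
read_annotations <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c(candidate_coord_cols, "diameter_mm"), path)
  if (any(df$diameter_mm <= 0)) {
    stop("annotation diameters must be positive: ", path, call. = FALSE)
  }
  out <- tibble::tibble(
    seriesuid = as.character(df$seriesuid),
    coordX = as.numeric(df$coordX),
    coordY = as.numeric(df$coordY),
    coordZ = as.numeric(df$coordZ),
    diameter_mm = as.numeric(df$diameter_mm)
  )
  if ("agreement" %in% names(df)) out$agreement <- as.integer(df$agreement)
  out
}

#' @rdname candidate_tables
#' @param annotations An annotation tibble.
#' @export
write_annotations <- function(annotations, path) {
  check_columns(annotations, c(candidate_coord_cols, "diameter_mm"),
                "`annotations`")
  keep <- intersect(c(candidate_coord_cols, "diameter_mm", "agreement"),
                    names(annotations))
  readr::write_csv(annotations[keep], path, progress = FALSE)
  invisible(path)
}

candidate_label <- function(x) {
  factor(x, levels = c("negative", "positive", "unknown"))
}
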