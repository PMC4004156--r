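#' Read and validate a ratings file
#'
#' Ratings files are UTF-8, header-first CSV with columns
#' `photo_id, rater_id, task_id, question_id, answer_type, answer` and
#' an optional `timestamp` (ISO 8601). `answer_type` is one of
#' `binary`, `categorical`, `numeric`, `crop`; binary answers must be
#' `present`/`absent`; numeric answers must parse to a nonnegative
#' price (a leading `$` and thousands separators are tolerated).
#'
#' @param path CSV file path.
#' @param strict if `TRUE` (default) any malformed row aborts with a
#'   line-numbered diagnostic; if `FALSE` malformed rows are skipped and
#'   their count reported via `message()`.
#' @return ratings data frame (all id columns character; `answer` kept
#'   as character — use [parse_price()] for numeric answers).
#' @export
read_ratings <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("photo_id", "rater_id", "task_id", "question_id",
                "answer_type", "answer")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_pc("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"timestamp" %in% names(df)) df$timestamp <- NA_character_
  df$timestamp[df$timestamp == ""] <- NA_character_

  bad <- character(0)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  ok_type <- df$answer_type %in% c("binary", "categorical", "numeric", "crop")
  bad_binary <- df$answer_type == "binary" &
    !df$answer %in% c("present", "absent")
  price <- parse_price(df$answer)
  bad_numeric <- df$answer_type == "numeric" & (is.na(price) | price < 0)
  empty_id <- df$photo_id == "" | df$rater_id == "" | df$question_id == ""
  problems <- !ok_type | bad_binary | bad_numeric | empty_id
  if (any(problems)) {
    why <- ifelse(!ok_type, "unknown answer_type",
           ifelse(bad_binary, "binary answer not present/absent",
           ifelse(bad_numeric, "invalid price", "empty identifier")))
    diag <- sprintf("line %d: %s", line[problems], why[problems])
    if (strict)
      stop_pc("malformed ratings file:\n  ", paste(diag, collapse = "\n  "))
    message(sum(problems), " malformed row(s) skipped:\n  ",
            paste(utils::head(diag, 10), collapse = "\n  "))
    df <- df[!problems, , drop = FALSE]
    rownames(df) <- NULL
  }
  df[, c(required, "timestamp")]
}

#' Write a ratings file
#' @param ratings ratings data frame (see [read_ratings()] for the schema).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Read a crop-box file
#'
#' Columns: `photo_id, rater_id, task_id, tag, x0, y0, x1, y1`;
#' coordinates are pixels with origin top-left and half-open
#' `[x0, x1) x [y0, y1)` extents.
#'
#' @inheritParams read_ratings
#' @return crops data frame with numeric coordinates.
#' @export
read_crops <- function(path, strict = TRUE) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("photo_id", "rater_id", "task_id", "tag",
                "x0", "y0", "x1", "y1")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_pc("missing required column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in c("x0", "y0", "x1", "y1"))
    df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  line <- seq_len(nrow(df)) + 1L
  problems <- is.na(df$x0) | is.na(df$y0) | is.na(df$x1) | is.na(df$y1) |
    df$x0 >= df$x1 | df$y0 >= df$y1 | df$x0 < 0 | df$y0 < 0
  if (any(problems)) {
    diag <- sprintf("line %d: invalid box", line[problems])
    if (strict)
      stop_pc("malformed crops file:\n  ", paste(diag, collapse = "\n  "))
    message(sum(problems), " malformed row(s) skipped")
    df <- df[!problems, , drop = FALSE]
    rownames(df) <- NULL
  }
  df[, required]
}

#' Write a crop-box file
#' @param crops crops data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crops <- function(crops, path) {
  utils::write.csv(crops, path, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard file
#'
#' Columns: `photo_id, feature_id, truth` where truth is
#' `present`/`absent` for binary features, a label for categorical
#' ones, or a decimal price.
#'
#' @param path CSV file path.
#' @return gold data frame (character columns).
#' @export
read_gold <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("photo_id", "feature_id", "truth")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_pc("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df[, required]
}

#' Write a gold-standard file
#' @param gold gold data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  utils::write.csv(gold, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to a directory
#'
#' Writes `gold.csv`, `photos.csv`, `gold_crops.csv`, `raters.csv` and a
#' `manifest.json` echoing the full configuration (seed included), so a
#' study directory is reproducible byte for byte from its manifest.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "photo_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gold(study$gold, file.path(dir, "gold.csv"))
  utils::write.csv(study$photos, file.path(dir, "photos.csv"),
                   row.names = FALSE)
  utils::write.csv(study$gold_crops, file.path(dir, "gold_crops.csv"),
                   row.names = FALSE)
  utils::write.csv(study$raters, file.path(dir, "raters.csv"),
                   row.names = FALSE)
  cfg <- unclass(study$config)
  cfg$features <- as.list(cfg$features)
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
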