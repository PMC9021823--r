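#' Construct and validate a cohort of performance occasions
#'
#' A cohort is a long-format data frame with one row per
#' (participant, occasion): identifier columns `participant_id` and
#' `occasion_id`, a `phase` column (`"recalled"` for the retrospective
#' occasions the zones are estimated from, `"predicted"` for the upcoming
#' jury), the three subscale intensities `ca`, `sa`, `sc` (integers, 9--36),
#' and a performance `score` (1--100).
#'
#' Raw inputs may instead carry 27 item columns `item_01..item_27` (scored
#' through `item_key`) and/or judge columns `judge_1..judge_N` (N >= 3,
#' aggregated by [aggregate_judges()]). When both judge columns and a `score`
#' column are present the judges win; a discrepancy greater than 0.5 points
#' raises a warning. Missing values are rejected -- no imputation.
#'
#' @param data data frame in the schema above.
#' @param item_key optional 27-element item-to-subscale key (see
#'   [read_item_key()]), required when item columns are used.
#' @return A validated data frame of class `izof_cohort` with columns
#'   `participant_id`, `occasion_id`, `phase`, `ca`, `sa`, `sc`, `score`
#'   (judge columns, if supplied, are retained after them). Row order is
#'   preserved.
#' @export
as_cohort <- function(data, item_key = NULL) {
  if (!is.data.frame(data))
    stop_izof("cohort input must be a data frame", class = "izof_schema_error")
  data <- as.data.frame(data, stringsAsFactors = FALSE)

  for (col in c("participant_id", "occasion_id", "phase"))
    if (!col %in% names(data))
      stop_izof("missing required column '", col, "'",
                class = "izof_schema_error")

  item_cols <- grep("^item_[0-9]{2}$", names(data), value = TRUE)
  judge_cols <- grep("^judge_[0-9]+$", names(data), value = TRUE)

  if (!all(SUBSCALES %in% names(data))) {
    if (length(item_cols) != 27)
      stop_izof("missing required columns 'ca', 'sa', 'sc' (or 27 item_* ",
                "columns)", class = "izof_schema_error")
    if (is.null(item_key))
      stop_izof("item columns present but no item_key supplied",
                class = "izof_config_error")
    item_cols <- item_cols[order(item_cols)]
    totals <- score_items(data[item_cols], key = item_key)
    data[SUBSCALES] <- totals
  }

  if (!"score" %in% names(data) && length(judge_cols) == 0)
    stop_izof("missing required column 'score' (or judge_* columns)",
              class = "izof_schema_error")
  if (length(judge_cols) > 0) {
    if (length(judge_cols) < 3)
      stop_izof("judge columns present but fewer than 3 judges",
                class = "izof_panel_error")
    judge_cols <- judge_cols[order(as.integer(sub("judge_", "", judge_cols)))]
    agg <- vapply(seq_len(nrow(data)), function(i)
      aggregate_judges(as.numeric(data[i, judge_cols])), numeric(1))
    if ("score" %in% names(data)) {
      off <- which(abs(data$score - agg) > 0.5)
      if (length(off))
        warning("score column disagrees with trimmed judge aggregate by more ",
                "than 0.5 at row(s) ", paste(off, collapse = ", "),
                "; judge columns take precedence", call. = FALSE)
    }
    data$score <- agg
  }

  data$phase <- as.character(data$phase)
  bad_phase <- which(!data$phase %in% c("recalled", "predicted"))
  if (length(bad_phase))
    stop_izof("phase must be 'recalled' or 'predicted' (row(s) ",
              paste(bad_phase, collapse = ", "), ")",
              class = "izof_validation_error")

  for (col in SUBSCALES) {
    v <- data[[col]]
    bad <- which(!is.finite(v) | v < 9 | v > 36 | v != floor(v))
    if (length(bad))
      stop_izof("column '", col, "' outside the 9-36 instrument range (or ",
                "non-integer/missing) at row(s) ",
                paste(bad, collapse = ", "), class = "izof_validation_error")
    data[[col]] <- as.numeric(v)
  }
  bad <- which(!is.finite(data$score) | data$score < 1 | data$score > 100)
  if (length(bad))
    stop_izof("column 'score' outside 1-100 (or missing) at row(s) ",
              paste(bad, collapse = ", "), class = "izof_validation_error")

  keyv <- paste(data$participant_id, data$occasion_id, sep = "\r")
  dup <- which(duplicated(keyv))
  if (length(dup))
    stop_izof("duplicate (participant_id, occasion_id) at row(s) ",
              paste(dup, collapse = ", "), class = "izof_uniqueness_error")

  # Zone estimability: anyone with a predicted occasion needs >= 2 recalled.
  pred_ids <- unique(data$participant_id[data$phase == "predicted"])
  n_rec <- table(data$participant_id[data$phase == "recalled"])
  short <- pred_ids[!(pred_ids %in% names(n_rec)) |
                      n_rec[as.character(pred_ids)] < 2]
  short <- short[!is.na(short)]
  if (length(short))
    stop_izof("participant(s) with predicted occasions but fewer than 2 ",
              "recalled occasions: ", paste(short, collapse = ", "),
              class = "izof_estimability_error")

  front <- c("participant_id", "occasion_id", "phase", SUBSCALES, "score")
  data <- data[c(front, setdiff(names(data), front))]
  class(data) <- c("izof_cohort", "data.frame")
  data
}

#' Read a cohort CSV
#'
#' Reads a long-format cohort file (see [as_cohort()] for the schema) and
#' validates it. Item columns are scored through `item_key`; judge columns
#' are trim-aggregated into `score`.
#'
#' @param path path to a CSV file.
#' @param item_key optional item key (character vector or path to a JSON/YAML
#'   key file).
#' @return An `izof_cohort` data frame.
#' @export
read_cohort <- function(path, item_key = NULL) {
  if (!file.exists(path))
    stop_izof("cohort file not found: ", path, class = "izof_io_error")
  if (is.character(item_key) && length(item_key) == 1 && file.exists(item_key))
    item_key <- read_item_key(item_key)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df, item_key = item_key)
}

#' Write analysis report tables to CSV
#'
#' Writes each table in a named list to `<dir>/<name>.csv` with stable
#' column order. Numeric values are written at full precision so a
#' write-then-read round trip reproduces them.
#'
#' @param tables named list of data frames (e.g. the components of an
#'   [izof()] fit: zones, classification report, combination table).
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written (character(0) for an empty list).
#' @export
write_report <- function(tables, dir) {
  stopifnot(is.list(tables))
  if (length(tables) == 0) return(invisible(character(0)))
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop_izof("tables must be a named list", class = "izof_io_error")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_izof("cannot create output directory: ", dir,
                       class = "izof_io_error")
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
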