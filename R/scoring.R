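#' Score CSAI-2 item responses into subscale totals
#'
#' Converts a vector of 27 item ratings (each 1--4) into the three subscale
#' totals -- cognitive anxiety (`ca`), somatic anxiety (`sa`) and
#' self-confidence (`sc`) -- by summing the nine items assigned to each
#' subscale. Totals therefore lie in 9--36 by construction.
#'
#' The published CSAI-2 item key is not bundled; the assignment of items to
#' subscales is supplied by the user, either as a character vector or via
#' [read_item_key()].
#'
#' @param items integer vector of length 27, each element in 1--4. A matrix
#'   or data frame with 27 columns scores each row.
#' @param key character vector of length 27 with values `"ca"`, `"sa"`,
#'   `"sc"`, exactly nine of each; element `i` names the subscale of item `i`.
#' @return A named numeric vector `c(ca=, sa=, sc=)`, or a data frame with
#'   those columns when `items` has multiple rows.
#' @examples
#' key <- rep(c("ca", "sa", "sc"), each = 9)
#' score_items(rep(1L, 27), key)   # minimum: all subscales 9
#' score_items(rep(4L, 27), key)   # maximum: all subscales 36
#' @seealso [aggregate_judges()], [read_item_key()]
#' @export
score_items <- function(items, key) {
  validate_item_key(key)
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 27)
      stop_izof("item matrix must have 27 columns, got ", ncol(items),
                class = "izof_validation_error")
    out <- t(apply(items, 1, score_items, key = key))
    return(as.data.frame(out))
  }
  if (length(items) != 27)
    stop_izof("expected 27 item responses, got ", length(items),
              class = "izof_validation_error")
  bad <- which(!is.finite(items) | items < 1 | items > 4 | items != floor(items))
  if (length(bad))
    stop_izof("item response out of the 1-4 range at item(s) ",
              paste(bad, collapse = ", "), class = "izof_validation_error")
  vapply(SUBSCALES, function(s) sum(items[key == s]), numeric(1))
}

validate_item_key <- function(key) {
  if (length(key) != 27 || !all(key %in% SUBSCALES))
    stop_izof("item key must assign each of 27 items to one of 'ca', 'sa', 'sc'",
              class = "izof_config_error")
  tab <- table(factor(key, levels = SUBSCALES))
  if (!all(tab == 9))
    stop_izof("item key must assign exactly 9 items per subscale (got ",
              paste(names(tab), tab, sep = "=", collapse = ", "), ")",
              class = "izof_config_error")
  invisible(key)
}

#' Read an item-to-subscale key from JSON or YAML
#'
#' The key file maps each of the 27 CSAI-2 items to exactly one subscale,
#' nine items per subscale. Accepted layouts: a list/mapping
#' `{"ca": [1,4,...], "sa": [...], "sc": [...]}` of item indices, or a
#' 27-element array of subscale names in item order.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return character vector of length 27 suitable for [score_items()].
#' @export
read_item_key <- function(path) {
  if (!file.exists(path))
    stop_izof("item key file not found: ", path, class = "izof_io_error")
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  key <- if (is.list(raw) && all(SUBSCALES %in% names(raw))) {
    out <- character(27)
    for (s in SUBSCALES) {
      idx <- as.integer(unlist(raw[[s]]))
      if (any(is.na(idx)) || any(idx < 1 | idx > 27))
        stop_izof("item key for '", s, "' has indices outside 1-27",
                  class = "izof_config_error")
      out[idx] <- s
    }
    if (any(out == ""))
      stop_izof("item key leaves some of the 27 items unassigned",
                class = "izof_config_error")
    out
  } else {
    tolower(as.character(unlist(raw)))
  }
  validate_item_key(key)
  key
}

#' Aggregate a judge panel into one performance score
#'
#' Implements the trimmed panel rule used for jury grading: one occurrence of
#' the highest score and one of the lowest are removed and the remaining
#' scores are averaged. With the default seven-judge panel this keeps five
#' scores. Ties are trimmed one-per-end: sorting the panel and dropping the
#' first and last element.
#'
#' @param scores integer vector of at least 3 judge scores, each in 1--100.
#' @return The trimmed mean as a single numeric value. It always lies within
#'   the range of the retained (second-smallest to second-largest) scores.
#' @examples
#' aggregate_judges(c(85, 88, 90, 92, 95, 80, 99))  # drops 99 and 80 -> 90
#' aggregate_judges(c(90, 90, 90, 90, 90, 100, 100)) # drops one 100, one 90 -> 92
#' @export
aggregate_judges <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 3)
    stop_izof("judge panel needs at least 3 scores (one must remain after ",
              "trimming the highest and lowest)", class = "izof_panel_error")
  if (any(!is.finite(scores) | scores < 1 | scores > 100))
    stop_izof("judge scores must lie in 1-100", class = "izof_validation_error")
  s <- sort(scores)
  mean(s[-c(1L, length(s))])
}
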