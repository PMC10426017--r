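#' Score ranges of the three democracy index conventions
#'
#' @param convention one of `"polity2"` (-10 autocracy to 10 democracy),
#'   `"vanhanen"` (0 to 50), `"freedom-house"` (combined reversed scale,
#'   0 not free to 12 free).
#' @return numeric length-2 vector `c(min, max)`.
#' @export
democracy_range <- function(convention) {
  switch(convention,
    "polity2" = c(-10, 10),
    "vanhanen" = c(0, 50),
    "freedom-house" = c(0, 12),
    stop(sprintf("unknown index convention: %s", convention))
  )
}

#' Validate a democracy panel
#'
#' Checks a long-format country-year-score table against one of the three
#' index conventions: scores must lie inside the convention's range (special
#' interregnum codes such as -66/-77/-88 are not valid polity2 values and are
#' rejected — inputs must be the revised combined measure with these resolved
#' upstream) and no country-year may appear twice. For Freedom House panels an
#' optional `status` column ("free", "partly free", "not free") is retained
#' for democratic classification.
#'
#' @param df data frame with columns `country`, `year`, `score`, and
#'   optionally `status`.
#' @param convention index convention, see [democracy_range()].
#' @return the validated panel, class `democracy_panel`, with attribute
#'   `convention`.
#' @export
as_democracy_panel <- function(df, convention) {
  rng <- democracy_range(convention)
  req <- c("country", "year", "score")
  if (!all(req %in% names(df))) stop("panel needs columns country, year, score")
  df$country <- as.character(df$country)
  df$year <- as.integer(df$year)
  bad <- which(!is.finite(df$score) | df$score < rng[1] | df$score > rng[2])
  if (length(bad) > 0L) {
    stop(sprintf("score outside %s range [%g, %g] at row(s): %s",
                 convention, rng[1], rng[2],
                 paste(utils::head(bad, 10), collapse = ", ")))
  }
  key <- paste(df$country, df$year)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate country-year at row(s): %s",
                 paste(utils::head(which(duplicated(key)), 10), collapse = ", ")))
  }
  df <- df[order(df$country, df$year), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "convention") <- convention
  class(df) <- c("democracy_panel", "data.frame")
  df
}

#' @rdname as_democracy_panel
#' @param path CSV path.
#' @export
read_panel <- function(path, convention) {
  as_democracy_panel(utils::read.csv(path, stringsAsFactors = FALSE), convention)
}

#' Write a democracy panel to CSV
#'
#' @param panel a `democracy_panel`.
#' @param path CSV path.
#' @return `path` invisibly.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  invisible(path)
}

#' Extract one year of a panel as a named score vector
#'
#' Each year's cross-section is a separate analysis; split or merged nations
#' carry distinct codes and appear only in the years they existed.
#'
#' @param panel a `democracy_panel`.
#' @param year the year to slice.
#' @return named numeric vector of scores (names are country codes), with
#'   attributes `year` and `convention`.
#' @export
year_slice <- function(panel, year) {
  rows <- panel$year == year
  if (!any(rows)) stop(sprintf("no records for year %s", year))
  out <- stats::setNames(panel$score[rows], panel$country[rows])
  attr(out, "year") <- as.integer(year)
  attr(out, "convention") <- attr(panel, "convention")
  out
}

#' Classify a nation-year as democratic
#'
#' A nation counts as democratic when its Polity score exceeds 0, its Vanhanen
#' index exceeds 5, or its Freedom House status is "free" or "partly free".
#' Both thresholds are strict inequalities, so boundary scores (Polity 0,
#' Vanhanen 5) are non-democratic.
#'
#' @param score numeric score(s) under the convention.
#' @param convention index convention.
#' @param status Freedom House status labels, required when
#'   `convention = "freedom-house"`.
#' @return logical vector.
#' @export
classify_democratic <- function(score, convention, status = NULL) {
  switch(convention,
    "polity2" = score > 0,
    "vanhanen" = score > 5,
    "freedom-house" = {
      if (is.null(status)) stop("freedom-house classification needs 'status' labels")
      tolower(trimws(status)) %in% c("free", "partly free", "partly-free")
    },
    stop(sprintf("unknown index convention: %s", convention))
  )
}

#' Share of democracies per year
#'
#' Applies [classify_democratic()] to every record and reports, per year, the
#' percentage of sampled nations classified as democratic.
#'
#' @param panel a `democracy_panel` (with a `status` column when the
#'   convention is `"freedom-house"`).
#' @return data frame with columns `year`, `n`, `percent_democratic`.
#' @export
percent_democratic <- function(panel) {
  conv <- attr(panel, "convention")
  dem <- classify_democratic(panel$score, conv, status = panel$status)
  agg <- stats::aggregate(dem, by = list(year = panel$year),
                          FUN = function(z) c(n = length(z), pct = 100 * mean(z)))
  data.frame(year = agg$year, n = agg$x[, "n"], percent_democratic = agg$x[, "pct"])
}
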