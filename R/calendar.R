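#' Build an alternating summer/winter season calendar
#'
#' Divides each study year into two operationally defined seasons: a summer
#' occasion running from the spring arrival boundary to the autumn departure
#' boundary, and a winter occasion running from the autumn boundary to the
#' next spring boundary. For `Y` years the calendar has `2Y - 1` occasions
#' (the final year contributes only its summer), alternating
#' summer, winter, summer, ... and both starting and ending with a summer.
#'
#' Occasion windows are half-open on the right: a date equal to the next
#' occasion's start belongs to the next occasion, so every date inside the
#' calendar maps to exactly one occasion. The stored `end` is the last day of
#' the occasion (the day before the next start).
#'
#' @param years Integer vector of consecutive calendar years (e.g.
#'   `2009:2016`).
#' @param summer_start Summer start boundary: a `"MM-DD"` string applied to
#'   every year, or a `Date` vector with one entry per year. Default 2 March,
#'   the mean first spring arrival of a migrant.
#' @param winter_start Winter start boundary, same forms. Default 3 November,
#'   the mean last autumn departure.
#' @param first_start Optional `Date` overriding the start of the very first
#'   occasion (e.g. the date of the first capture in the first field season).
#' @return A data frame of class `season_calendar` with columns `label`,
#'   `type` (`"summer"`/`"winter"`), `start`, `end` (both `Date`).
#' @examples
#' cal <- build_season_calendar(2009:2016,
#'                              first_start = as.Date("2009-04-23"))
#' nrow(cal)    # 15 occasions: 8 summers, 7 winters
#' @export
build_season_calendar <- function(years,
                                  summer_start = "03-02",
                                  winter_start = "11-03",
                                  first_start = NULL) {
  years <- as.integer(years)
  if (length(years) < 1L) stop("need at least one year")
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("'years' must be consecutive calendar years")

  ss <- .boundary_dates(summer_start, years)
  ws <- .boundary_dates(winter_start, years)
  if (any(ws <= ss))
    stop("winter start must fall after summer start within each year")

  ny <- length(years)
  starts <- as.Date(character(0))
  labels <- character(0)
  types <- character(0)
  for (k in seq_len(ny)) {
    y <- years[k]
    starts <- c(starts, ss[k])
    labels <- c(labels, sprintf("summer-%d", y))
    types <- c(types, "summer")
    if (k < ny) {
      starts <- c(starts, ws[k])
      labels <- c(labels, sprintf("winter-%d/%02d", y, (y + 1L) %% 100L))
      types <- c(types, "winter")
    }
  }
  # terminal summer ends where its winter would have begun; give a single-year
  # calendar the same summer span
  ends <- c(starts[-1L] - 1L, ws[ny] - 1L)

  if (!is.null(first_start)) {
    first_start <- as.Date(first_start)
    if (first_start >= ends[1L])
      stop("'first_start' must precede the end of the first occasion")
    starts[1L] <- first_start
  }
  if (any(starts[-1L] <= starts[-length(starts)]))
    stop("season boundaries are not strictly increasing")

  cal <- data.frame(label = labels, type = types,
                    start = starts, end = ends,
                    stringsAsFactors = FALSE)
  class(cal) <- c("season_calendar", "data.frame")
  cal
}

.boundary_dates <- function(x, years) {
  if (inherits(x, "Date")) {
    if (length(x) == 1L) stop("Date boundaries must give one date per year")
    if (length(x) != length(years))
      stop("boundary dates must have one entry per year")
    return(x)
  }
  if (is.character(x)) {
    if (length(x) == 1L) x <- rep(x, length(years))
    if (length(x) != length(years))
      stop("boundary strings must be length 1 or one per year")
    return(as.Date(sprintf("%d-%s", years, x)))
  }
  stop("season boundary must be 'MM-DD' strings or a Date vector")
}

#' Map dates to calendar occasions
#'
#' @param calendar A `season_calendar`.
#' @param dates A `Date` vector (or coercible).
#' @return Integer occasion indices; `NA` for dates outside the calendar.
#' @export
occasion_of_date <- function(calendar, dates) {
  stopifnot(inherits(calendar, "season_calendar"))
  dates <- as.Date(dates)
  idx <- findInterval(as.numeric(dates), as.numeric(calendar$start))
  idx[idx == 0L] <- NA_integer_
  last <- nrow(calendar)
  idx[!is.na(idx) & idx == last & dates > calendar$end[last]] <- NA_integer_
  idx
}

#' Season years covered by a calendar
#' @param calendar A `season_calendar`.
#' @return Integer vector of calendar years with a summer occasion.
#' @keywords internal
calendar_years <- function(calendar) {
  as.integer(sub("^summer-", "",
                 calendar$label[calendar$type == "summer"]))
}

#' Read/write a season calendar as CSV
#'
#' @param calendar A `season_calendar`.
#' @param path File path.
#' @return `read_season_calendar` returns a `season_calendar`.
#' @export
write_season_calendar <- function(calendar, path) {
  stopifnot(inherits(calendar, "season_calendar"))
  utils::write.csv(as.data.frame(calendar), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_season_calendar
#' @export
read_season_calendar <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start <- as.Date(d$start)
  d$end <- as.Date(d$end)
  class(d) <- c("season_calendar", "data.frame")
  d
}
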