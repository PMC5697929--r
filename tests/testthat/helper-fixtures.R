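# shared fixture builders

default_calendar <- function(first_start = NULL)
  build_season_calendar(2009:2016, first_start = first_start)

# encounter history straight from 0/1 rows, with uniform covariates unless
# overridden
history_from_rows <- function(rows, calendar = NULL) {
  mat <- do.call(rbind, lapply(rows, function(r)
    as.integer(strsplit(r, "")[[1L]])))
  rownames(mat) <- sprintf("b%02d", seq_along(rows))
  if (is.null(calendar)) {
    ny <- ceiling((ncol(mat) + 1L) / 2L)
    calendar <- build_season_calendar(2009:(2008L + ny))
  }
  if (nrow(calendar) > ncol(mat)) {
    calendar <- calendar[seq_len(ncol(mat)), ]
    class(calendar) <- c("season_calendar", "data.frame")
  }
  encounter_history(mat, calendar)
}

covariates_for <- function(history, strategy = "resident", sex = "female",
                           age = "adult") {
  n <- nrow(history$matrix)
  data.frame(id = rownames(history$matrix),
             sex = rep_len(sex, n), age = rep_len(age, n),
             strategy = rep_len(strategy, n),
             first_occasion = history$first_occasion,
             stringsAsFactors = FALSE)
}

# dated record stream for one synthetic individual
records_of <- function(id, dates, events = "detection") {
  dates <- as.Date(dates)
  data.frame(id = rep_len(id, length(dates)), date = dates,
             event = rep_len(events, length(dates)),
             stringsAsFactors = FALSE)
}

daily_presence <- function(id, from, to, by = 3L)
  records_of(id, seq(as.Date(from), as.Date(to), by = by))
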