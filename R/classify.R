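#' Classify the migratory strategy of one individual
#'
#' Applies the record-based classification rules to one individual's dated
#' detection stream, year by year, then reconciles the yearly labels:
#' \itemize{
#'   \item \strong{migrant}: a `nocturnal_departure` event during the autumn
#'     (September--November) followed by at least `min_absence_days` without
#'     a detection;
#'   \item \strong{resident}: detections continuing at least to the residency
#'     cutoff (30 November) with no gap of `min_absence_days` or more before
#'     it, and no qualifying departure;
#'   \item \strong{winter_departer}: a nocturnal departure after the cutoff
#'     but before the following spring;
#'   \item \strong{undetermined}: records that end before the cutoff without
#'     a departure (tag failure, dispersal or death cannot be told apart).
#' }
#' A bird whose yearly labels mix migrant and resident is a
#' \strong{switcher}. Classification is idempotent and insensitive to record
#' order (records are sorted internally).
#'
#' @param records Data frame `id`, `date`, `event` for a single individual
#'   (an empty frame yields `undetermined` with reason `no_records`).
#' @param calendar A `season_calendar` covering the record dates.
#' @param min_absence_days Minimum continuous absence (days) that separates a
#'   migration or winter departure from an ordinary detection gap.
#' @param residency_cutoff `"MM-DD"` date through which presence must extend
#'   for a resident year.
#' @return A list with `strategy`, `reason`, and `years` (data frame of
#'   per-year labels with supporting departure/last-detection dates).
#' @export
classify_strategy <- function(records, calendar,
                              min_absence_days = 14L,
                              residency_cutoff = "11-30") {
  stopifnot(inherits(calendar, "season_calendar"))
  if (nrow(records) == 0L)
    return(list(strategy = "undetermined", reason = "no_records",
                years = .empty_year_table()))
  if (length(unique(records$id)) > 1L)
    stop("classify_strategy() expects records for a single individual; ",
         "use classify_strategies() for a multi-individual table")
  records <- records[order(as.Date(records$date)), , drop = FALSE]
  det_dates <- as.Date(records$date[records$event == "detection"])
  dep_dates <- as.Date(records$date[records$event == "nocturnal_departure"])
  if (length(det_dates) == 0L)
    return(list(strategy = "undetermined", reason = "no_detections",
                years = .empty_year_table()))

  years <- calendar_years(calendar)
  yr_label <- character(0); yr_year <- integer(0)
  yr_dep <- as.Date(character(0)); yr_last <- as.Date(character(0))

  for (y in years) {
    # the bird-year spans the summer of y and the following winter
    span_lo <- min(calendar$start[calendar$label == sprintf("summer-%d", y)])
    wlab <- sprintf("winter-%d/%02d", y, (y + 1L) %% 100L)
    span_hi <- if (wlab %in% calendar$label)
      calendar$end[calendar$label == wlab] else
      calendar$end[calendar$label == sprintf("summer-%d", y)]
    det_y <- det_dates[det_dates >= span_lo & det_dates <= span_hi]
    dep_y <- dep_dates[dep_dates >= span_lo & dep_dates <= span_hi]
    if (length(det_y) == 0L && length(dep_y) == 0L) next

    cutoff <- as.Date(sprintf("%d-%s", y, residency_cutoff))
    autumn_lo <- as.Date(sprintf("%d-09-01", y))
    label <- "undetermined"
    dep_used <- as.Date(NA)

    absent_after <- function(d)
      !any(det_y > d & det_y <= d + min_absence_days)
    aut_dep <- dep_y[dep_y >= autumn_lo & dep_y <= cutoff]
    aut_dep <- aut_dep[vapply(aut_dep, absent_after, logical(1L))]
    win_dep <- dep_y[dep_y > cutoff]
    win_dep <- win_dep[vapply(win_dep, absent_after, logical(1L))]

    if (length(aut_dep) > 0L) {
      label <- "migrant"; dep_used <- aut_dep[1L]
    } else if (length(det_y) > 0L) {
      upto <- det_y[det_y <= min(max(det_y), cutoff)]
      gaps_ok <- length(upto) > 0L &&
        (length(upto) == 1L || max(diff(upto)) < min_absence_days)
      present_through <- max(det_y) >= cutoff
      if (present_through && gaps_ok) {
        if (length(win_dep) > 0L) {
          label <- "winter_departer"; dep_used <- win_dep[1L]
        } else {
          label <- "resident"
        }
      }
    }
    yr_year <- c(yr_year, y); yr_label <- c(yr_label, label)
    yr_dep <- c(yr_dep, dep_used)
    yr_last <- c(yr_last, if (length(det_y) > 0L) max(det_y) else as.Date(NA))
  }

  yrs <- data.frame(year = yr_year, label = yr_label,
                    departure = yr_dep, last_detection = yr_last,
                    stringsAsFactors = FALSE)
  lab <- yrs$label[yrs$label != "undetermined"]
  strategy <-
    if (all(c("migrant", "resident") %in% lab)) "switcher"
    else if ("winter_departer" %in% lab) "winter_departer"
    else if ("migrant" %in% lab) "migrant"
    else if ("resident" %in% lab) "resident"
    else "undetermined"
  reason <- switch(strategy,
                   undetermined = "records_end_before_cutoff",
                   switcher = "conflicting_year_labels",
                   NA_character_)
  list(strategy = strategy, reason = reason, years = yrs)
}

.empty_year_table <- function()
  data.frame(year = integer(0), label = character(0),
             departure = as.Date(character(0)),
             last_detection = as.Date(character(0)))

#' Classify every individual in a record table
#'
#' @inheritParams classify_strategy
#' @param records Data frame `id`, `date`, `event` for any number of
#'   individuals.
#' @return Data frame `id`, `strategy`, `reason`, one row per individual.
#' @export
classify_strategies <- function(records, calendar,
                                min_absence_days = 14L,
                                residency_cutoff = "11-30") {
  by_id <- split(records, as.character(records$id))
  ids <- names(by_id)
  res <- lapply(by_id, classify_strategy, calendar = calendar,
                min_absence_days = min_absence_days,
                residency_cutoff = residency_cutoff)
  data.frame(id = ids,
             strategy = vapply(res, `[[`, character(1L), "strategy"),
             reason = vapply(res, function(r)
               if (is.na(r$reason)) "" else r$reason, character(1L)),
             stringsAsFactors = FALSE)
}

#' Apply the study's exclusion filters
#'
#' Removes individuals that cannot enter the survival analysis: strategy
#' undetermined, winter departers, strategy switchers, and juveniles whose
#' sex could not be determined. The tally of exclusions partitions the input
#' together with the included set.
#'
#' @param individuals Data frame with at least `id`, `strategy`, `sex`,
#'   `age`; `sex` may be `NA` (undetermined).
#' @return List with `included` (the retained rows, strategies all
#'   resident/migrant), `tally` (named integer vector over reasons
#'   `undetermined`, `winter_departer`, `switcher`, `unsexed_juvenile`), and
#'   `n_input`.
#' @export
apply_exclusion_filters <- function(individuals) {
  req <- c("id", "strategy", "sex", "age")
  stopifnot(all(req %in% names(individuals)))
  reasons <- c("undetermined", "winter_departer", "switcher",
               "unsexed_juvenile")
  tally <- stats::setNames(integer(length(reasons)), reasons)
  if (nrow(individuals) == 0L)
    return(list(included = individuals, tally = tally, n_input = 0L))

  excl <- rep(NA_character_, nrow(individuals))
  strat <- as.character(individuals$strategy)
  excl[strat %in% c("undetermined", "winter_departer", "switcher")] <-
    strat[strat %in% c("undetermined", "winter_departer", "switcher")]
  unsexed_juv <- is.na(excl) & individuals$age == "juvenile" &
    (is.na(individuals$sex) | individuals$sex == "")
  excl[unsexed_juv] <- "unsexed_juvenile"

  tab <- table(factor(excl, levels = reasons))
  tally[] <- as.integer(tab)
  included <- individuals[is.na(excl), , drop = FALSE]
  rownames(included) <- NULL
  stopifnot(nrow(included) + sum(tally) == nrow(individuals))
  list(included = included, tally = tally, n_input = nrow(individuals))
}

#' Write an exclusion report as TSV
#' @param filtered Output of [apply_exclusion_filters()].
#' @param path File path.
#' @export
write_exclusion_report <- function(filtered, path) {
  d <- data.frame(reason = c(names(filtered$tally), "included", "total"),
                  n = c(as.integer(filtered$tally),
                        nrow(filtered$included), filtered$n_input))
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
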