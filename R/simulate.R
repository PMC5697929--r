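#' Simulate a partially migratory cohort
#'
#' Generates the data the downstream analysis assumes: each individual enters
#' the study at a drawn first-capture occasion with a guaranteed detection
#' there (the likelihood conditions on first capture), survives each
#' following inter-occasion interval with the season- and
#' strategy-appropriate Bernoulli probability, and, while alive, is detected
#' at each later occasion with the strategy-appropriate probability. Dead
#' individuals are never detected. Winter and summer intervals are single
#' survival draws regardless of their calendar length: the target quantity is
#' per-season, not per-day, survival.
#'
#' Strategy is fixed for life. Optionally, `n_switchers` individuals that
#' alternate strategy between years and `n_winter_departers` individuals that
#' leave only in mid-winter are planted (with resident demographic rates) to
#' exercise the classification and exclusion filters; their truth labels are
#' `"switcher"` and `"winter_departer"`.
#'
#' @param config A [simulation_config()].
#' @return A list with components
#'   \describe{
#'     \item{history}{an [encounter_history()] (zero rows if the cohort is
#'       empty);}
#'     \item{covariates}{data frame `id`, `sex`, `age`, `strategy`,
#'       `first_occasion`;}
#'     \item{truth}{list with `alive` (logical individuals x occasions
#'       matrix of true states from first capture onward) and
#'       `death_interval` (index of the interval in which the individual
#'       died, `NA` if it outlived the study).}
#'   }
#'   All output is deterministic given `config$seed`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .simulate_population_impl(config)
}

.simulate_population_impl <- function(config) {
  cal <- build_season_calendar(
    config$start_year + seq_len(config$years) - 1L,
    summer_start = config$phenology$summer_start,
    winter_start = config$phenology$winter_start)
  T_occ <- nrow(cal)

  n_res <- config$n_residents
  n_mig <- config$n_migrants
  n_sw <- config$n_switchers
  n_wd <- config$n_winter_departers
  n <- n_res + n_mig + n_sw + n_wd

  strategy <- rep(c("resident", "migrant", "switcher", "winter_departer"),
                  times = c(n_res, n_mig, n_sw, n_wd))
  ids <- sprintf("%s%04d", c("R", "M", "S", "W")[match(
    strategy, c("resident", "migrant", "switcher", "winter_departer"))],
    unlist(lapply(c(n_res, n_mig, n_sw, n_wd), seq_len)))

  if (n == 0L) {
    hist <- encounter_history(
      matrix(integer(0), 0L, T_occ, dimnames = list(NULL, cal$label)), cal)
    return(list(history = hist,
                covariates = data.frame(id = character(0),
                                        sex = character(0),
                                        age = character(0),
                                        strategy = character(0),
                                        first_occasion = integer(0)),
                truth = list(alive = matrix(FALSE, 0L, T_occ),
                             death_interval = integer(0))))
  }

  # demographic rates: planted switchers/winter-departers behave like
  # residents for survival and detection
  like_res <- strategy != "migrant"
  p_fem <- ifelse(like_res, config$sex_ratio_resident,
                  config$sex_ratio_migrant)
  p_juv <- ifelse(like_res, config$juv_fraction_resident,
                  config$juv_fraction_migrant)
  sex <- ifelse(stats::runif(n) < p_fem, "female", "male")
  age <- ifelse(stats::runif(n) < p_juv, "juvenile", "adult")

  f <- sample.int(T_occ, n, replace = TRUE, prob = config$entry_weights)

  phi_winter <- ifelse(like_res, config$phi_winter_resident,
                       config$phi_winter_migrant)
  phi_summer <- ifelse(like_res, config$phi_summer,
                       config$phi_summer_migrant)
  p_det <- ifelse(like_res, config$p_resident, config$p_migrant)

  alive <- matrix(FALSE, n, T_occ, dimnames = list(ids, cal$label))
  y <- matrix(0L, n, T_occ, dimnames = list(ids, cal$label))
  alive[cbind(seq_len(n), f)] <- TRUE
  y[cbind(seq_len(n), f)] <- 1L

  for (t in seq_len(T_occ - 1L)) {
    at_risk <- which(alive[, t] & f <= t)
    if (length(at_risk) > 0L) {
      phi_t <- if (cal$type[t] == "summer") phi_summer[at_risk]
               else phi_winter[at_risk]
      surv <- stats::rbinom(length(at_risk), 1L, phi_t) == 1L
      alive[at_risk[surv], t + 1L] <- TRUE
    }
    obs_pool <- which(alive[, t + 1L] & f <= t)
    if (length(obs_pool) > 0L)
      y[obs_pool, t + 1L] <-
        stats::rbinom(length(obs_pool), 1L, p_det[obs_pool])
  }

  last_alive <- apply(alive, 1L, function(a) max(which(a)))
  death_interval <- ifelse(last_alive < T_occ, last_alive, NA_integer_)

  list(history = encounter_history(y, cal),
       covariates = data.frame(id = ids, sex = sex, age = age,
                               strategy = strategy, first_occasion = f,
                               stringsAsFactors = FALSE),
       truth = list(alive = alive,
                    death_interval = as.integer(death_interval)))
}

#' Simulate dated detection records
#'
#' Emits the raw dated record stream underlying the encounter matrix that
#' [simulate_population()] produces for the same configuration, so the
#' classification and matrix-building stages can be tested end to end.
#' For every occasion in which the matrix has a detection, residents (and
#' resident-behaving planted birds) get presence records every
#' `visit_interval` days across the occasion window; migrants get summer
#' records from their drawn spring-arrival date to the night of their drawn
#' autumn departure (truncated normal within 19 Sep--12 Nov), a
#' `nocturnal_departure` event on the departure date, and, when detected in
#' winter, a single away-site record. Planted winter-departers depart every
#' mid-winter after a `nocturnal_departure` event in December. Occasions with
#' no detection in the matrix produce no records, so rebuilding the matrix
#' from the records reproduces it exactly.
#'
#' @param config A [simulation_config()].
#' @return A data frame `id`, `date`, `event`
#'   (`event` in `detection`/`nocturnal_departure`), sorted by id and date,
#'   with the matching [simulate_population()] output attached as attribute
#'   `"population"`. Deterministic given `config$seed`.
#' @export
simulate_detection_records <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pop <- .simulate_population_impl(config)
  y <- pop$history$matrix
  cal <- pop$history$calendar
  cov <- pop$covariates
  n <- nrow(y)
  phen <- config$phenology
  years <- calendar_years(cal)

  chunks <- vector("list", 4096L); n_chunks <- 0L
  add <- function(id, dates, event) {
    k <- length(dates)
    if (k == 0L) return(invisible(NULL))
    n_chunks <<- n_chunks + 1L
    if (n_chunks > length(chunks))
      length(chunks) <<- 2L * n_chunks
    chunks[[n_chunks]] <<- list(id = rep(id, k), date = dates,
                                event = rep(event, k))
    invisible(NULL)
  }
  summer_idx <- which(cal$type == "summer")
  year_of_occ <- as.integer(format(cal$start, "%Y"))

  for (i in seq_len(n)) {
    strat <- cov$strategy[i]
    id <- cov$id[i]
    # per-year phenology draws, indexed by calendar year
    dep <- stats::setNames(
      .rtruncnorm(length(years),
                  .mmdd(phen$departure_mean, years),
                  phen$departure_sd,
                  .mmdd(phen$departure_window[1L], years),
                  .mmdd(phen$departure_window[2L], years)),
      years)
    arr <- stats::setNames(
      .rtruncnorm(length(years),
                  .mmdd(phen$arrival_mean, years),
                  phen$arrival_sd,
                  .mmdd(phen$arrival_window[1L], years),
                  .mmdd(phen$arrival_window[2L], years)),
      years)
    wd_dep <- stats::setNames(
      cal$start[pmin(summer_idx + 1L, nrow(cal))] + 28L +
        sample.int(28L, length(summer_idx), replace = TRUE),
      year_of_occ[summer_idx])

    for (t in which(y[i, ] == 1L)) {
      s <- cal$start[t]; e <- cal$end[t]
      yr <- as.character(year_of_occ[t])
      migrant_year <- strat == "migrant" ||
        (strat == "switcher" && (match(year_of_occ[t], years) %% 2L == 0L))
      if (cal$type[t] == "summer") {
        if (migrant_year) {
          from <- max(s, arr[[yr]])
          to <- min(e, dep[[yr]] - 1L)
          add(id, seq(from, to, by = config$visit_interval), "detection")
          add(id, dep[[yr]], "nocturnal_departure")
        } else {
          add(id, seq(s, e, by = config$visit_interval), "detection")
        }
      } else {  # winter occasion; label year is the preceding summer's
        yr <- as.character(year_of_occ[t - 1L])
        if (migrant_year) {
          from <- max(s, dep[[yr]] + config$min_record_gap)
          add(id, from + sample.int(max(as.integer(e - from), 1L), 1L) - 1L,
              "detection")
        } else if (strat == "winter_departer") {
          d <- wd_dep[[yr]]
          add(id, seq(s, min(e, d - 1L), by = config$visit_interval),
              "detection")
          add(id, d, "nocturnal_departure")
        } else {
          add(id, seq(s, e, by = config$visit_interval), "detection")
        }
      }
    }
  }

  if (n_chunks == 0L) {
    rec <- data.frame(id = character(0), date = as.Date(character(0)),
                      event = character(0), stringsAsFactors = FALSE)
    attr(rec, "population") <- pop
    return(rec)
  }
  chunks <- chunks[seq_len(n_chunks)]
  rec <- data.frame(
    id = unlist(lapply(chunks, `[[`, "id"), use.names = FALSE),
    date = as.Date(unlist(lapply(chunks, function(ch)
      as.numeric(ch$date)), use.names = FALSE), origin = "1970-01-01"),
    event = unlist(lapply(chunks, `[[`, "event"), use.names = FALSE),
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$id, rec$date, rec$event), , drop = FALSE]
  rownames(rec) <- NULL
  attr(rec, "population") <- pop
  rec
}

#' Write detection records as CSV (`id,date,event`)
#' @param records Record data frame.
#' @param path File path.
#' @return `read_detection_records` returns the record data frame.
#' @export
write_detection_records <- function(records, path) {
  utils::write.csv(records[, c("id", "date", "event")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_detection_records
#' @export
read_detection_records <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

# "MM-DD" + year vector -> Date vector
.mmdd <- function(mmdd, years) as.Date(sprintf("%d-%s", years, mmdd))

# truncated-normal dates by rejection with a clamp fallback; sd in days
.rtruncnorm <- function(k, mean_date, sd, lo, hi) {
  x <- mean_date + round(stats::rnorm(k, 0, sd))
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) > 0L && tries < 50L) {
    x[bad] <- mean_date[bad] + round(stats::rnorm(length(bad), 0, sd))
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  x <- pmax(pmin(x, hi), lo)
  x
}
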