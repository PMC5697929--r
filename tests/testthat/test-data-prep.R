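cal <- build_season_calendar(2009:2016)

test_that("an autumn nocturnal departure with spring return is a migrant", {
  rec <- rbind(daily_presence("m1", "2010-04-01", "2010-10-15"),
               records_of("m1", "2010-10-16", "nocturnal_departure"),
               daily_presence("m1", "2011-03-14", "2011-10-10"))
  out <- classify_strategy(rec, cal)
  expect_equal(out$strategy, "migrant")
  expect_equal(out$years$label[out$years$year == 2010], "migrant")
  expect_equal(out$years$departure[out$years$year == 2010],
               as.Date("2010-10-16"))
})

test_that("continuous presence through 30 November is a resident", {
  rec <- daily_presence("r1", "2010-04-01", "2011-02-20")
  out <- classify_strategy(rec, cal)
  expect_equal(out$strategy, "resident")
})

test_that("a December departure is a winter departer", {
  rec <- rbind(daily_presence("w1", "2010-04-01", "2010-12-19"),
               records_of("w1", "2010-12-20", "nocturnal_departure"))
  out <- classify_strategy(rec, cal)
  expect_equal(out$strategy, "winter_departer")
})

test_that("conflicting year labels make a switcher", {
  rec <- rbind(daily_presence("s1", "2010-04-01", "2010-10-15"),
               records_of("s1", "2010-10-16", "nocturnal_departure"),
               daily_presence("s1", "2011-03-14", "2012-02-20"))
  out <- classify_strategy(rec, cal)
  expect_equal(out$strategy, "switcher")
  expect_setequal(out$years$label, c("migrant", "resident"))
})

test_that("insufficient records are undetermined with a reason", {
  expect_equal(classify_strategy(records_of("u0", character(0))[0, ],
                                 cal)$strategy, "undetermined")
  expect_equal(classify_strategy(records_of("u0", character(0))[0, ],
                                 cal)$reason, "no_records")
  # records ending before the cutoff
  out <- classify_strategy(daily_presence("u1", "2010-04-01", "2010-09-10"),
                           cal)
  expect_equal(out$strategy, "undetermined")
  expect_equal(out$reason, "records_end_before_cutoff")
  # a long unexplained absence before the cutoff is not residency
  rec <- rbind(daily_presence("u2", "2010-04-01", "2010-09-01"),
               daily_presence("u2", "2010-11-25", "2010-12-15"))
  expect_equal(classify_strategy(rec, cal)$strategy, "undetermined")
})

test_that("classification is idempotent and order-insensitive", {
  rec <- rbind(daily_presence("m1", "2010-04-01", "2010-10-15"),
               records_of("m1", "2010-10-16", "nocturnal_departure"),
               daily_presence("m1", "2011-03-14", "2011-11-30"))
  base <- classify_strategy(rec, cal)
  set.seed(1)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(classify_strategy(shuffled, cal), base)
  expect_equal(classify_strategy(rec, cal), base)
})

test_that("exclusion filters reproduce the study arithmetic", {
  # plant the published tallies: 469 birds, 158 undetermined, 11 winter
  # departers, 11 switchers, 27 unsexed juveniles; 192 residents and 70
  # migrants remain
  plant <- data.frame(
    id = sprintf("x%03d", 1:469),
    strategy = rep(c("undetermined", "winter_departer", "switcher",
                     "resident", "resident", "migrant"),
                   times = c(158, 11, 11, 27, 192, 70)),
    sex = c(rep("female", 158 + 11 + 11), rep(NA_character_, 27),
            rep(c("female", "male"), length.out = 192),
            rep(c("female", "male"), length.out = 70)),
    age = c(rep("adult", 158 + 11 + 11), rep("juvenile", 27),
            rep("adult", 192 + 70)),
    stringsAsFactors = FALSE)
  out <- apply_exclusion_filters(plant)
  expect_equal(out$tally,
               c(undetermined = 158L, winter_departer = 11L,
                 switcher = 11L, unsexed_juvenile = 27L))
  expect_equal(nrow(out$included), 262L)
  expect_equal(sum(out$included$strategy == "resident"), 192L)
  expect_equal(sum(out$included$strategy == "migrant"), 70L)
  # the tally partitions the input
  expect_equal(nrow(out$included) + sum(out$tally), out$n_input)
})

test_that("filters are the identity when nothing applies, and tolerate
           empty input", {
  ok <- data.frame(id = c("a", "b"), strategy = c("resident", "migrant"),
                   sex = c("female", "male"), age = c("adult", "juvenile"),
                   stringsAsFactors = FALSE)
  out <- apply_exclusion_filters(ok)
  expect_equal(out$included, ok)
  expect_true(all(out$tally == 0L))
  empty <- apply_exclusion_filters(ok[0, ])
  expect_equal(nrow(empty$included), 0L)
  expect_true(all(empty$tally == 0L))
})

test_that("exclusion tallies match planted generator truth exactly", {
  cfg <- simulation_config(n_residents = 25, n_migrants = 15,
                           n_switchers = 6, n_winter_departers = 4,
                           phi_summer = 1, phi_winter_resident = 1,
                           phi_winter_migrant = 1, p_resident = 1,
                           p_migrant = 1,
                           entry_weights = c(1, rep(0, 14)), seed = 13)
  rec <- simulate_detection_records(cfg)
  pop <- attr(rec, "population")
  cl <- classify_strategies(rec, pop$history$calendar)
  indiv <- merge(cl, pop$covariates[, c("id", "sex", "age")], by = "id")
  out <- apply_exclusion_filters(indiv)
  expect_equal(unname(out$tally["switcher"]), 6L)
  expect_equal(unname(out$tally["winter_departer"]), 4L)
  expect_equal(nrow(out$included), 40L)
})

test_that("the encounter matrix honors occasion windows and boundaries", {
  # one detection per occasion -> all-ones row
  rec <- records_of("a1", cal$start + 1L)
  eh <- build_encounter_matrix(rec, cal)
  expect_true(all(eh$matrix == 1L))
  # a detection on a boundary start date belongs to the starting occasion
  rec2 <- records_of("a2", as.Date(c("2009-11-03", "2010-03-02")))
  eh2 <- build_encounter_matrix(rec2, cal)
  expect_equal(which(eh2$matrix[1L, ] == 1L), c(2L, 3L),
               ignore_attr = TRUE)
  # out-of-range detections warn and are counted
  rec3 <- rbind(records_of("a3", "2008-06-01"),
                records_of("a3", "2009-06-01"))
  expect_warning(eh3 <- build_encounter_matrix(rec3, cal), "dropped")
  expect_equal(attr(eh3, "n_dropped"), 1L)
  expect_equal(sum(eh3$matrix), 1L)
  # departure events never create detections
  rec4 <- rbind(records_of("a4", "2009-06-01"),
                records_of("a4", "2009-10-16", "nocturnal_departure"))
  expect_equal(sum(build_encounter_matrix(rec4, cal)$matrix), 1L)
})

test_that("encounter histories validate their invariants", {
  m <- matrix(c(1L, 0L, 0L, 1L), 2, 2)
  cal2 <- build_season_calendar(2009)
  expect_error(encounter_history(m, cal2), "calendar has 1 occasions")
  cal3 <- build_season_calendar(2009:2010)[1:2, ]
  class(cal3) <- c("season_calendar", "data.frame")
  m2 <- rbind(c(1L, 0L), c(0L, 0L))
  expect_error(encounter_history(m2, cal3), "at least one detection")
  m3 <- rbind(c(2L, 0L))
  expect_error(encounter_history(m3, cal3), "0 or 1")
})

test_that("encounter CSV round-trips with covariates", {
  pop <- simulate_population(simulation_config(n_residents = 12,
                                               n_migrants = 8, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_encounter_csv(pop$history, pop$covariates, path)
  back <- read_encounter_csv(path, pop$history$calendar)
  expect_identical(back$history$matrix, pop$history$matrix)
  expect_equal(back$covariates$strategy, pop$covariates$strategy)
  expect_equal(back$history$first_occasion,
               pop$covariates$first_occasion)
})

test_that("full preparation round-trips simulator output for any seed", {
  for (seed in c(8, 123)) {
    cfg <- simulation_config(n_residents = 50, n_migrants = 30,
                             seed = seed)
    rec <- simulate_detection_records(cfg)
    pop <- attr(rec, "population")
    cl <- classify_strategies(rec, pop$history$calendar)
    truth <- pop$covariates$strategy[match(cl$id, pop$covariates$id)]
    # no bird is assigned the wrong determinate strategy
    determinate <- cl$strategy %in% c("resident", "migrant")
    expect_true(all(cl$strategy[determinate] == truth[determinate]))
    # matrix rebuilt from records equals the simulator's matrix
    eh <- build_encounter_matrix(rec, pop$history$calendar,
                                 ids = pop$covariates$id)
    expect_identical(eh$matrix, pop$history$matrix)
  }
})
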