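test_that("configuration validation enforces the documented invariants", {
  expect_error(simulation_config(phi_summer = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(n_residents = -1), "non-negative")
  expect_error(simulation_config(years = 0), "at least one")
  expect_error(simulation_config(entry_weights = rep(1, 3)),
               "one weight per occasion")
  cfg <- simulation_config(entry_weights = c(2, rep(0, 14)))
  expect_equal(cfg$entry_weights, c(1, rep(0, 14)))
  # default entry weights: summers only, none at the terminal occasion
  w <- simulation_config()$entry_weights
  expect_equal(sum(w), 1)
  expect_true(all(w[seq(2, 14, by = 2)] == 0))
  expect_equal(w[15L], 0)
  # additive default for migrant summer survival
  expect_equal(simulation_config()$phi_summer_migrant,
               plogis(qlogis(0.89) + qlogis(0.73) - qlogis(0.57)))
  expect_equal(simulation_config(phi_summer_migrant = 0.89,
                                 seed = 1)$phi_summer_migrant, 0.89)
})

test_that("deterministic degenerate cohorts behave as advertised", {
  # no mortality, perfect detection, entry at occasion 1: all-ones rows
  cfg <- simulation_config(n_residents = 10, n_migrants = 5,
                           phi_summer = 1, phi_winter_resident = 1,
                           phi_winter_migrant = 1,
                           p_resident = 1, p_migrant = 1,
                           entry_weights = c(1, rep(0, 14)), seed = 9)
  pop <- simulate_population(cfg)
  expect_true(all(pop$history$matrix == 1L))
  expect_true(all(pop$truth$alive))

  # no survival: exactly one detection, at first capture
  cfg0 <- simulation_config(n_residents = 10, n_migrants = 5,
                            phi_summer = 0, phi_winter_resident = 0,
                            phi_winter_migrant = 0, seed = 9)
  pop0 <- simulate_population(cfg0)
  expect_true(all(rowSums(pop0$history$matrix) == 1L))
  expect_equal(pop0$truth$death_interval, pop0$covariates$first_occasion)
})

test_that("zero individuals give an empty matrix with a valid calendar", {
  cfg <- simulation_config(n_residents = 0, n_migrants = 0, seed = 1)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop$history$matrix), 0L)
  expect_equal(ncol(pop$history$matrix), 15L)
  expect_equal(nrow(pop$covariates), 0L)
})

test_that("conditioning and death constraints hold for any seed", {
  for (seed in c(2, 17, 301)) {
    pop <- simulate_population(simulation_config(
      n_residents = 80, n_migrants = 40, seed = seed))
    y <- pop$history$matrix
    f <- pop$covariates$first_occasion
    # first-capture column is 1 for every individual
    expect_true(all(y[cbind(seq_len(nrow(y)), f)] == 1L))
    # no detection after true death, and no detection before entry
    expect_true(all(y[!pop$truth$alive] == 0L))
    before_entry <- col(y) < f[row(y)]
    expect_true(all(y[before_entry] == 0L))
    # truth log consistent: alive exactly from entry until death interval
    d <- pop$truth$death_interval
    last <- ifelse(is.na(d), ncol(y), d)
    expect_true(all(pop$truth$alive[cbind(seq_len(nrow(y)), last)]))
  }
})

test_that("true-state survival frequency matches the winter rate", {
  # one winter interval: entry at the first winter occasion (occasion 2)
  w <- c(0, 1, rep(0, 12), 0)
  cfg <- simulation_config(n_residents = 0, n_migrants = 20000,
                           entry_weights = w, seed = 77)
  pop <- simulate_population(cfg)
  alive_next <- pop$truth$alive[, 3L]
  frac <- mean(alive_next)
  se <- sqrt(0.73 * 0.27 / 20000)
  expect_lt(abs(frac - 0.73), 3 * se)
})

test_that("empirical detection frequency matches the per-occasion rate", {
  cfg <- simulation_config(n_residents = 20000, n_migrants = 0,
                           entry_weights = c(1, rep(0, 14)), seed = 78)
  pop <- simulate_population(cfg)
  at_risk <- pop$truth$alive[, -1L]
  detected <- pop$history$matrix[, -1L] == 1L
  frac <- sum(detected[at_risk]) / sum(at_risk)
  se <- sqrt(0.74 * 0.26 / sum(at_risk))
  expect_lt(abs(frac - 0.74), 3 * se)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_residents = 30, n_migrants = 20,
                           n_switchers = 2, n_winter_departers = 2,
                           seed = 5)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  expect_identical(simulate_detection_records(cfg),
                   simulate_detection_records(cfg))
})

test_that("detection records reproduce the encounter matrix exactly", {
  for (seed in c(4, 99)) {
    cfg <- simulation_config(n_residents = 40, n_migrants = 25,
                             seed = seed)
    rec <- simulate_detection_records(cfg)
    pop <- attr(rec, "population")
    rebuilt <- build_encounter_matrix(rec, pop$history$calendar,
                                      ids = rownames(pop$history$matrix))
    expect_identical(rebuilt$matrix, pop$history$matrix)
    expect_identical(pop$history$matrix,
                     simulate_population(cfg)$history$matrix)
  }
})

test_that("record streams carry the migratory phenology", {
  cfg <- simulation_config(n_residents = 10, n_migrants = 10,
                           p_resident = 1, p_migrant = 1, seed = 21)
  rec <- simulate_detection_records(cfg)
  pop <- attr(rec, "population")
  cal <- pop$history$calendar

  # a resident alive through its first winter is recorded on every sampled
  # day through 30 November
  res_ids <- pop$covariates$id[pop$covariates$strategy == "resident"]
  f <- pop$covariates$first_occasion
  alive_w <- vapply(seq_len(nrow(pop$truth$alive)), function(i)
    f[i] < 15L && pop$truth$alive[i, f[i] + 1L], logical(1L))
  i <- which(pop$covariates$id %in% res_ids & alive_w)[1L]
  id <- pop$covariates$id[i]
  yr <- as.integer(format(cal$start[f[i]], "%Y"))
  r <- rec[rec$id == id & rec$event == "detection", ]
  upto <- r$date[r$date <= as.Date(sprintf("%d-11-30", yr))]
  expect_gte(max(upto), as.Date(sprintf("%d-11-28", yr)))
  expect_lte(max(diff(sort(upto))), cfg$visit_interval)

  # every migrant departure is nocturnal, inside 19 Sep - 12 Nov, and after
  # the last preceding autumn detection
  deps <- rec[rec$event == "nocturnal_departure" &
                rec$id %in% pop$covariates$id[
                  pop$covariates$strategy == "migrant"], ]
  expect_gt(nrow(deps), 0L)
  md <- as.integer(format(deps$date, "%m%d"))
  expect_true(all(md >= 919L & md <= 1112L))
  for (k in seq_len(nrow(deps))) {
    det <- rec[rec$id == deps$id[k] & rec$event == "detection", ]
    yr <- as.integer(format(deps$date[k], "%Y"))
    aut <- det$date[det$date >= as.Date(sprintf("%d-06-01", yr)) &
                      det$date <= as.Date(sprintf("%d-11-30", yr))]
    if (length(aut) > 0L) expect_lt(max(aut), deps$date[k])
  }
})
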