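small_pop <- function(seed = 10, n_res = 120, n_mig = 60)
  simulate_population(simulation_config(n_residents = n_res,
                                        n_migrants = n_mig, seed = seed))

test_that("with perfect detection the survival MLE is the observed
           interval-survival fraction", {
  cfg <- simulation_config(n_residents = 150, n_migrants = 0,
                           phi_summer = 0.8, phi_winter_resident = 0.8,
                           phi_winter_migrant = 0.8, p_resident = 1,
                           seed = 31)
  pop <- simulate_population(cfg)
  # with p = 1 the history pins down each death interval, so the MLE of a
  # constant phi is survived transitions / at-risk transitions
  y <- pop$history$matrix
  f <- pop$covariates$first_occasion
  last <- apply(y == 1L, 1L, function(r) max(which(r)))
  survived <- sum(last - f)
  died <- sum(last < ncol(y))
  at_risk <- survived + died
  fit <- fit_cmr("Phi[.].P[.]", pop$history, pop$covariates)
  expect_true(fit$boundary)  # p is estimated at its upper boundary
  expect_equal(plogis(fit$coefficients[["phi_intercept"]]),
               survived / at_risk, tolerance = 1e-4)
})

test_that("never-redetected data raise the boundary diagnostic", {
  cal <- default_calendar()
  y <- matrix(0L, 20, 15)
  y[cbind(1:20, rep(c(1L, 3L), 10))] <- 1L
  rownames(y) <- sprintf("s%02d", 1:20)
  h <- encounter_history(y, cal)
  fit <- fit_cmr("Phi[.].P[.]", h, covariates_for(h))
  expect_true(fit$boundary)
})

test_that("pooling identical histories leaves the fit unchanged", {
  pop <- small_pop(seed = 44, n_res = 60, n_mig = 40)
  fit <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates)
  expect_lt(fit$n_pooled, fit$n_individuals)
  # unpooled likelihood at the pooled optimum agrees with the optimum
  d_full <- build_design("Phi[season+migr].P[migr]", pop$covariates,
                         pop$history$calendar)
  expect_equal(hmm_loglik(fit$coefficients, pop$history, d_full),
               fit$loglik, tolerance = 1e-8)
})

test_that("adding a term never increases the minimized deviance along
           nesting chains", {
  pop <- small_pop(seed = 12)
  chains <- list(
    c("Phi[.].P[migr]", "Phi[season].P[migr]", "Phi[season+migr].P[migr]",
      "Phi[season+migr+sex].P[migr]"),
    c("Phi[.].P[.]", "Phi[.].P[migr]"),
    c("Phi[season].P[season]", "Phi[season+migr].P[season]"))
  for (chain in chains) {
    dev <- vapply(chain, function(s)
      fit_cmr(s, pop$history, pop$covariates)$deviance, numeric(1))
    expect_true(all(diff(dev) <= 1e-4), info = paste(chain, collapse = " "))
  }
})

test_that("rank-deficient designs abort the fit naming the columns", {
  pop <- simulate_population(simulation_config(n_residents = 40,
                                               n_migrants = 0, seed = 2))
  expect_error(fit_cmr("Phi[migr].P[.]", pop$history, pop$covariates),
               "phi_strategy_migrant")
})

test_that("degenerate inputs are rejected up front", {
  cal <- default_calendar()
  h_empty <- encounter_history(
    matrix(integer(0), 0, 15, dimnames = list(NULL, cal$label)), cal)
  expect_error(fit_cmr("Phi[.].P[.]", h_empty,
                       covariates_for(h_empty)), "at least one")
  y <- matrix(0L, 2, 15); y[, 15] <- 1L
  rownames(y) <- c("a", "b")
  h_last <- encounter_history(y, cal)
  expect_error(fit_cmr("Phi[.].P[.]", h_last, covariates_for(h_last)),
               "post-entry")
})

test_that("fits are deterministic and stable across extra starts", {
  pop <- small_pop(seed = 77, n_res = 80, n_mig = 50)
  f1 <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates)
  f2 <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates)
  expect_identical(f1$coefficients, f2$coefficients)
  f3 <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates,
                options = list(n_starts = 8L, start_seed = 99L))
  expect_equal(f3$coefficients, f1$coefficients, tolerance = 1e-5)
})

test_that("rate predictions back-transform the requested cell", {
  pop <- small_pop(seed = 21)
  fit <- fit_cmr("Phi[season+migr].P[migr]", pop$history, pop$covariates)
  b <- fit$coefficients
  pr <- predict_rates(fit, list(season = "winter", strategy = "migrant"))
  expect_equal(pr$estimate,
               plogis(b[["phi_intercept"]] + b[["phi_season_winter"]] +
                        b[["phi_strategy_migrant"]]))
  # reference cell: factors omitted sit at reference levels
  ref <- predict_rates(fit, list())
  expect_equal(ref$estimate, plogis(b[["phi_intercept"]]))
  # intervals are inside [0,1], asymmetric, and contain the estimate
  expect_true(pr$lower > 0 && pr$upper < 1)
  expect_true(pr$lower < pr$estimate && pr$estimate < pr$upper)
  expect_false(isTRUE(all.equal(pr$estimate - pr$lower,
                                pr$upper - pr$estimate)))
  # naming a factor outside the sub-model errors
  expect_error(predict_rates(fit, list(sex = "male")), "not in the")
  expect_error(predict_rates(fit, list(season = "winter"), type = "p"),
               "not in the")
})

test_that("an intercept coefficient of zero predicts a rate of one half,
           and zero variance collapses the interval", {
  cal <- default_calendar()
  h <- history_from_rows(strrep("1", 15), cal)
  fit <- fit_cmr("Phi[.].P[.]", h, covariates_for(h),
                 options = list(hessian = FALSE, n_starts = 1L))
  fit$coefficients[] <- 0
  fit$vcov[] <- 0
  pr <- predict_rates(fit, list())
  expect_equal(pr$estimate, 0.5)
  expect_equal(pr$lower, 0.5)
  expect_equal(pr$upper, 0.5)
})
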