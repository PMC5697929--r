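#' Fit a capture-recapture model by maximum likelihood
#'
#' Maximizes the hidden-Markov likelihood over the logit-scale coefficients
#' by quasi-Newton (BFGS) iteration from several seeded starting points,
#' keeping the best optimum (ties broken by smaller coefficient norm). The
#' coefficient covariance is the inverse observed Hessian at the optimum.
#' Identical (history, covariate, entry) rows are pooled into weighted
#' pseudo-individuals before optimization, which leaves the likelihood
#' unchanged and makes large simulated cohorts cheap.
#'
#' @param spec A `cmr_model_spec` or model string.
#' @param history An `encounter_history`.
#' @param covariates Covariates (`id`, `sex`, `age`, `strategy`,
#'   `first_occasion`) in matrix row order.
#' @param options List: `n_starts` (default 5), `start_seed` (default 1),
#'   `maxit` (default 500), `reltol` (default 1e-10), `start_spread`
#'   (uniform half-width of the random starts on the logit scale, default
#'   1.5), `hessian` (default `TRUE`), `boundary_tol` (default 1e-4).
#' @return A `cmr_fit`: `coefficients`, `vcov`, `loglik`, `deviance`
#'   (`-2 loglik`, conditional on first capture, no saturated-model offset),
#'   `K`, `spec`, `n_individuals`, `n_pooled`, `convergence` (per-start
#'   codes), `boundary` flag, and the pooled `design`/`history`.
#' @export
fit_cmr <- function(spec, history, covariates, options = list()) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  opt <- utils::modifyList(list(n_starts = 5L, start_seed = 1L,
                                maxit = 500L, reltol = 1e-10,
                                start_spread = 1.5, hessian = TRUE,
                                boundary_tol = 1e-4), options)
  stopifnot(inherits(history, "encounter_history"))
  if (nrow(history$matrix) < 1L)
    stop("need at least one individual to fit")
  if (all(history$first_occasion == ncol(history$matrix)))
    stop("no individual has a post-entry occasion; nothing to estimate")

  pooled <- .pool_histories(history, covariates)
  design <- build_design(spec, pooled$covariates, history$calendar,
                         weights = pooled$weights)
  check_design_rank(design)
  K <- ncol(design$phi) + ncol(design$p)
  negll <- function(beta) -hmm_loglik(beta, pooled$history, design)

  best <- NULL
  codes <- integer(0)
  for (j in seq_len(opt$n_starts)) {
    start <- if (j == 1L) numeric(K) else {
      set.seed(opt$start_seed + j)
      stats::runif(K, -opt$start_spread, opt$start_spread)
    }
    res <- tryCatch(
      stats::optim(start, negll, method = "BFGS",
                   control = list(maxit = opt$maxit,
                                  reltol = opt$reltol)),
      error = function(e) NULL)
    if (is.null(res)) { codes <- c(codes, NA_integer_); next }
    codes <- c(codes, res$convergence)
    better <- is.null(best) ||
      res$value < best$value - 1e-9 ||
      (abs(res$value - best$value) <= 1e-9 &&
         sum(res$par^2) < sum(best$par^2))
    if (better) best <- res
  }
  if (is.null(best) || !any(codes == 0L, na.rm = TRUE)) {
    e <- simpleError(
      "optimizer failed to converge from any starting point")
    e$best_so_far <- best
    stop(e)
  }

  beta <- best$par
  names(beta) <- c(colnames(design$phi), colnames(design$p))
  vc <- matrix(NA_real_, K, K, dimnames = list(names(beta), names(beta)))
  if (isTRUE(opt$hessian)) {
    H <- tryCatch(stats::optimHess(beta, negll), error = function(e) NULL)
    if (!is.null(H)) {
      vc_try <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vc_try)) {
        vc <- (vc_try + t(vc_try)) / 2
        dimnames(vc) <- list(names(beta), names(beta))
      }
    }
  }

  rates <- .link_rates(beta, design)
  used_phi <- rep(design$first_occasion, ncol(rates$phi)) <=
    rep(seq_len(ncol(rates$phi)), each = design$n)
  used_p <- rep(design$first_occasion, ncol(rates$p)) <
    rep(seq_len(ncol(rates$p)), each = design$n)
  used_rates <- c(rates$phi[matrix(used_phi, design$n)],
                  rates$p[matrix(used_p, design$n)])
  boundary <- any(used_rates < opt$boundary_tol |
                    used_rates > 1 - opt$boundary_tol)

  structure(list(coefficients = beta, vcov = vc,
                 loglik = -best$value, deviance = 2 * best$value,
                 K = K, spec = design$spec,
                 n_individuals = nrow(history$matrix),
                 n_pooled = design$n,
                 convergence = codes, boundary = boundary,
                 design = design, history = pooled$history),
            class = "cmr_fit")
}

# collapse identical (history row, covariates, entry) patterns
.pool_histories <- function(history, covariates) {
  y <- history$matrix
  key <- paste(apply(y, 1L, paste, collapse = ""),
               covariates$sex, covariates$age, covariates$strategy,
               sep = "|")
  idx <- !duplicated(key)
  w <- as.numeric(table(key)[key[idx]])
  ph <- encounter_history(y[idx, , drop = FALSE], history$calendar)
  list(history = ph,
       covariates = covariates[idx, , drop = FALSE],
       weights = w)
}

#' @export
print.cmr_fit <- function(x, ...) {
  cat("Capture-recapture fit:", format(x$spec), "\n")
  cat(sprintf("  K = %d, logLik = %.3f, deviance = %.3f, n = %d%s\n",
              x$K, x$loglik, x$deviance, x$n_individuals,
              if (x$boundary) "  [boundary solution]" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
logLik.cmr_fit <- function(object, ...) {
  structure(object$loglik, df = object$K, class = "logLik")
}

#' @export
coef.cmr_fit <- function(object, ...) object$coefficients

#' @export
vcov.cmr_fit <- function(object, ...) object$vcov

#' Back-transformed rate and Wald confidence interval for a covariate cell
#'
#' Evaluates the fitted survival or detection probability for a combination
#' of factor levels: the cell's linear predictor is inverse-logit
#' transformed, and the 95% interval is the inverse logit of
#' `predictor +/- 1.96 SE` with the standard error taken on the link scale
#' (`sqrt(x' V x)`), which yields the usual asymmetric interval inside
#' [0, 1]. Factors in the model but absent from `cell` sit at their
#' reference level (summer, resident, female, adult, first time level);
#' naming a factor the model does not contain is an error.
#'
#' @param fit A `cmr_fit`.
#' @param cell Named list/vector of factor levels, e.g.
#'   `list(season = "winter", strategy = "migrant")`.
#' @param type `"phi"` (survival, default) or `"p"` (detection).
#' @param level Confidence level (default 0.95).
#' @return One-row data frame `estimate`, `lower`, `upper`, `se_link`.
#' @export
predict_rates <- function(fit, cell = list(), type = c("phi", "p"),
                          level = 0.95) {
  stopifnot(inherits(fit, "cmr_fit"))
  type <- match.arg(type)
  cell <- as.list(cell)
  terms <- if (type == "phi") fit$spec$phi_terms else fit$spec$p_terms
  prefix <- paste0(type, "_")
  cols <- names(fit$coefficients)[startsWith(names(fit$coefficients),
                                             prefix)]
  term_of <- c(season = "season", strategy = "migr", migr = "migr",
               sex = "sex", age = "age", t = "t")
  unknown <- setdiff(names(cell), names(term_of))
  if (length(unknown) > 0L)
    stop("unknown factor(s) in cell: ", paste(unknown, collapse = ", "))
  not_in_model <- names(cell)[!term_of[names(cell)] %in% terms]
  if (length(not_in_model) > 0L)
    stop("cell references factor(s) not in the ", type, " sub-model: ",
         paste(not_in_model, collapse = ", "))

  x <- stats::setNames(numeric(length(cols)), cols)
  x[paste0(prefix, "intercept")] <- 1
  dummy_on <- list(season = c("winter", paste0(prefix, "season_winter")),
                   strategy = c("migrant", paste0(prefix,
                                                  "strategy_migrant")),
                   migr = c("migrant", paste0(prefix, "strategy_migrant")),
                   sex = c("male", paste0(prefix, "sex_male")),
                   age = c("juvenile", paste0(prefix, "age_juvenile")))
  for (nm in names(cell)) {
    if (nm == "t") {
      tcol <- paste0(prefix, "t", cell[[nm]])
      if (tcol %in% cols) x[tcol] <- 1
      next
    }
    d <- dummy_on[[nm]]
    if (identical(as.character(cell[[nm]]), d[1L])) x[d[2L]] <- 1
  }

  beta <- fit$coefficients[cols]
  eta <- sum(x * beta)
  V <- fit$vcov[cols, cols, drop = FALSE]
  se <- if (all(is.finite(V))) sqrt(max(drop(t(x) %*% V %*% x), 0))
        else NA_real_
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(estimate = stats::plogis(eta),
             lower = stats::plogis(eta - z * se),
             upper = stats::plogis(eta + z * se),
             se_link = se)
}
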