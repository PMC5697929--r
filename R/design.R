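#' Build survival and detection design matrices
#'
#' Realizes a model specification as logit-scale design matrices. Survival
#' rows are (individual, interval) cells for every interval `t -> t+1`;
#' an interval carries the season type of the occasion it leaves, so survival
#' "through summer" links a summer occasion to the following winter occasion.
#' Detection rows are (individual, occasion) cells. Treatment coding with
#' reference levels summer, resident, female, adult (and the first
#' interval/occasion for time effects); any full-rank coding is equivalent on
#' the rate scale.
#'
#' Rows are laid out individual-fastest: entry `(i, t)` is row
#' `i + (t - 1) * n`. The full grid is built for all individuals; the
#' likelihood masks cells before each individual's first capture. An
#' individual first captured at the final occasion simply contributes no
#' used survival rows.
#'
#' @param spec A `cmr_model_spec` or model string.
#' @param covariates Covariate data frame (`id`, `sex`, `age`, `strategy`,
#'   `first_occasion`) for the individuals, in matrix row order.
#' @param calendar The `season_calendar` of the encounter history.
#' @param weights Optional per-individual multiplicities (pooled histories);
#'   default 1.
#' @return A list of class `cmr_design`: `phi`/`p` (design matrices with
#'   column labels), `n`, `n_occasions`, `first_occasion`, `weights`,
#'   `spec`.
#' @export
build_design <- function(spec, covariates, calendar, weights = NULL) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  stopifnot(inherits(spec, "cmr_model_spec"),
            inherits(calendar, "season_calendar"))
  need <- c("sex", "age", "strategy", "first_occasion")
  stopifnot(all(need %in% names(covariates)))
  n <- nrow(covariates)
  T_occ <- nrow(calendar)
  if (T_occ < 2L) stop("need at least two occasions to define survival")
  if (any(!covariates$strategy %in% c("resident", "migrant")))
    stop("design covariates require strategy resident/migrant only; ",
         "run apply_exclusion_filters() first")
  if (any(is.na(covariates$sex)) || any(is.na(covariates$age)))
    stop("sex and age must be complete for included individuals")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))

  migr <- as.numeric(covariates$strategy == "migrant")
  male <- as.numeric(covariates$sex == "male")
  juv <- as.numeric(covariates$age == "juvenile")
  winter <- as.numeric(calendar$type == "winter")

  col_for <- function(term, grid_t, n_rows, level_count) {
    switch(term,
      season = matrix(winter[grid_t], ncol = 1L,
                      dimnames = list(NULL, "season_winter")),
      migr = matrix(rep(migr, level_count), ncol = 1L,
                    dimnames = list(NULL, "strategy_migrant")),
      sex = matrix(rep(male, level_count), ncol = 1L,
                   dimnames = list(NULL, "sex_male")),
      age = matrix(rep(juv, level_count), ncol = 1L,
                   dimnames = list(NULL, "age_juvenile")),
      t = {
        lv <- sort(unique(grid_t))[-1L]
        m <- vapply(lv, function(l) as.numeric(grid_t == l),
                    numeric(n_rows))
        colnames(m) <- paste0("t", lv)
        m
      },
      stop("unhandled term ", term))
  }

  make_X <- function(terms, times, prefix) {
    n_rows <- n * length(times)
    grid_t <- rep(times, each = n)
    X <- matrix(1, nrow = n_rows, ncol = 1L,
                dimnames = list(NULL, paste0(prefix, "_intercept")))
    for (tm in terms) {
      cols <- col_for(tm, grid_t, n_rows, length(times))
      colnames(cols) <- paste0(prefix, "_", colnames(cols))
      X <- cbind(X, cols)
    }
    X
  }

  Xphi <- make_X(spec$phi_terms, seq_len(T_occ - 1L), "phi")
  Xp <- make_X(spec$p_terms, seq_len(T_occ), "p")

  structure(list(phi = Xphi, p = Xp, n = n, n_occasions = T_occ,
                 first_occasion = as.integer(covariates$first_occasion),
                 weights = as.numeric(weights), spec = spec),
            class = "cmr_design")
}

#' Check the identifiability (column rank) of a design on its used rows
#'
#' Restricts each design matrix to the rows the conditional likelihood
#' actually uses (post-entry cells) and reports rank deficiency, naming the
#' confounded columns.
#'
#' @param design A `cmr_design`.
#' @return Invisibly `TRUE`; raises an error on rank deficiency.
#' @export
check_design_rank <- function(design) {
  stopifnot(inherits(design, "cmr_design"))
  n <- design$n; T_occ <- design$n_occasions
  f <- design$first_occasion
  use_phi <- which(rep(seq_len(T_occ - 1L), each = n) >= rep(f, T_occ - 1L))
  use_p <- which(rep(seq_len(T_occ), each = n) > rep(f, T_occ))
  for (part in list(list(X = design$phi, rows = use_phi, what = "survival"),
                    list(X = design$p, rows = use_p, what = "detection"))) {
    X <- part$X[part$rows, , drop = FALSE]
    if (nrow(X) == 0L) next
    qd <- qr(X)
    if (qd$rank < ncol(X)) {
      dropped <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]]
      stop("rank-deficient ", part$what, " design; confounded column(s): ",
           paste(dropped, collapse = ", "))
    }
  }
  invisible(TRUE)
}
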