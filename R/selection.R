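#' Small-sample-corrected (quasi-)Akaike information criterion
#'
#' `QAICc = deviance / c_hat + 2K + 2K(K+1) / (n_eff - K - 1)`, where the
#' deviance is `-2 loglik`. With `c_hat = 1` this is AICc; `c_hat > 1`
#' discounts the deviance for overdispersion.
#'
#' @param loglik Maximized log-likelihood.
#' @param K Number of estimated coefficients.
#' @param n_eff Effective sample size.
#' @param c_hat Overdispersion factor (>= 1, default 1).
#' @return QAICc value.
#' @export
qaicc <- function(loglik, K, n_eff, c_hat = 1) {
  stopifnot(is.finite(loglik), K >= 1, c_hat >= 1)
  if (n_eff <= K + 1)
    stop("small-sample correction undefined: n_eff (", n_eff,
         ") must exceed K + 1 (", K + 1, ")")
  (-2 * loglik) / c_hat + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Akaike weights from criterion differences
#'
#' @param delta Vector of criterion differences from the best model
#'   (`min(delta)` is shifted to 0 if needed).
#' @return Weights `exp(-delta/2)` normalized to sum to 1.
#' @export
akaike_weights <- function(delta) {
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Rank fitted models by QAICc
#'
#' Builds the model-comparison table: QAICc per fit, differences from the
#' best model, Akaike weights, parameter counts and deviances, sorted by
#' ascending QAICc (ties broken by fewer parameters, then input order). The
#' `n_eff` and `c_hat` in force are stored as attributes.
#'
#' @param fits List of `cmr_fit` objects.
#' @param n_eff Effective sample size; default the number of individuals in
#'   the first fit (set it to the number of release events to use that
#'   convention instead).
#' @param c_hat Overdispersion factor (default 1).
#' @return Data frame of class `model_table`: `model`, `K`, `QAICc`,
#'   `delta`, `weight`, `deviance`.
#' @export
rank_models <- function(fits, n_eff = NULL, c_hat = 1) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1L), "cmr_fit")))
  if (is.null(n_eff)) n_eff <- fits[[1L]]$n_individuals
  q <- vapply(fits, function(f) qaicc(f$loglik, f$K, n_eff, c_hat),
              numeric(1L))
  K <- vapply(fits, `[[`, numeric(1L), "K")
  ord <- order(q, K, seq_along(fits))
  tab <- data.frame(
    model = vapply(fits, function(f) format(f$spec), character(1L))[ord],
    K = as.integer(K[ord]),
    QAICc = q[ord],
    delta = q[ord] - min(q),
    weight = akaike_weights(q[ord] - min(q)),
    deviance = vapply(fits, `[[`, numeric(1L), "deviance")[ord],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "n_eff") <- n_eff
  attr(tab, "c_hat") <- c_hat
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Write a model table as TSV
#'
#' Mirrors the familiar comparison-table layout; the header comment records
#' the `n_eff` and `c_hat` conventions used.
#'
#' @param table A `model_table`.
#' @param path File path.
#' @export
write_model_table <- function(table, path) {
  stopifnot(inherits(table, "model_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_eff = %s, c_hat = %s",
                     attr(table, "n_eff"), attr(table, "c_hat")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
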