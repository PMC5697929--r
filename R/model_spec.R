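# Model mini-language: "Phi[season + migr].P[migr]" (the Greek letter is
# accepted on input). Terms are additive two-level factors; "." alone means
# intercept-only. "juv" and "ad" jointly stand for the age-at-capture factor.

.phi_factors <- c("season", "migr", "sex", "age", "t")
.p_factors <- c("migr", "season", "t")

#' Parse a model-specification string
#'
#' The notation names the factors entering the survival (Phi) and detection
#' (P) linear predictors, e.g. `"Phi[season + migr].P[migr]"`. Recognized
#' factor tokens (case-insensitive): `season` (summer/winter), `migr`
#' (resident/migrant), `sex` (female/male), `age` or its level pair
#' `juv`/`ad` (adult/juvenile at capture), `t` (fully time-dependent), and
#' `.` for an intercept-only sub-model. Detection accepts `migr`, `season`,
#' `t`, `.`. Effects are additive; interactions are not part of the language.
#' `format()` canonicalizes, and `parse_model_spec(format(x))` round-trips.
#'
#' @param text Model string.
#' @return An object of class `cmr_model_spec` with `phi_terms` and
#'   `p_terms` character vectors (empty = intercept-only).
#' @examples
#' spec <- parse_model_spec("Phi[season + migr].P[migr]")
#' format(spec)
#' count_parameters(spec)
#' @export
parse_model_spec <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(
    "^\\s*(Φ|[Pp]hi)\\s*\\[([^]]*)\\]\\s*\\.\\s*[Pp]\\s*\\[([^]]*)\\]\\s*$",
    text))[[1L]]
  if (length(m) == 0L)
    stop("cannot parse model string: ", text,
         " (expected \"Phi[...].P[...]\")")
  spec <- structure(list(phi_terms = .parse_terms(m[3L], .phi_factors),
                         p_terms = .parse_terms(m[4L], .p_factors)),
                    class = "cmr_model_spec")
  spec
}

.parse_terms <- function(txt, allowed) {
  toks <- trimws(strsplit(txt, "+", fixed = TRUE)[[1L]])
  toks <- sub("\\.+$", "", toks)      # Table-style trailing periods: "migr."
  toks <- tolower(toks[toks != ""])
  if (length(toks) == 0L) return(character(0))
  mapped <- vapply(toks, function(tk) {
    switch(tk,
           "season" = "season",
           "migr" = , "migration" = , "strategy" = "migr",
           "sex" = "sex",
           "age" = , "juv" = , "ad" = "age",
           "t" = , "time" = , "occasion" = "t",
           stop("unknown factor token '", tk, "' in model string"))
  }, character(1L))
  terms <- unique(unname(mapped))
  bad <- setdiff(terms, allowed)
  if (length(bad) > 0L)
    stop("factor(s) not allowed in this sub-model: ",
         paste(bad, collapse = ", "))
  terms[order(match(terms, allowed))]
}

#' @export
format.cmr_model_spec <- function(x, ...) {
  fmt <- function(terms) if (length(terms) == 0L) "." else
    paste(terms, collapse = "+")
  sprintf("Phi[%s].P[%s]", fmt(x$phi_terms), fmt(x$p_terms))
}

#' @export
print.cmr_model_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Number of estimated coefficients of a model specification
#'
#' One intercept per sub-model plus one coefficient per additional two-level
#' factor; the time factor (`t`) adds one coefficient per non-reference
#' interval (survival) or occasion (detection) and therefore needs
#' `n_occasions`. Equals the design-matrix column count of [build_design()].
#'
#' @param spec A `cmr_model_spec` (or string, parsed on the fly).
#' @param n_occasions Number of occasions; required only when `t` appears.
#' @return Integer coefficient count K.
#' @export
count_parameters <- function(spec, n_occasions = NULL) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  stopifnot(inherits(spec, "cmr_model_spec"))
  count_one <- function(terms, n_levels_t) {
    k <- 1L
    for (tm in terms)
      k <- k + if (tm == "t") n_levels_t - 1L else 1L
    k
  }
  needs_t <- "t" %in% c(spec$phi_terms, spec$p_terms)
  if (needs_t && is.null(n_occasions))
    stop("n_occasions is required for time-dependent specifications")
  count_one(spec$phi_terms,
            if (needs_t) n_occasions - 1L else NA_integer_) +
    count_one(spec$p_terms,
              if (needs_t) n_occasions - 1L else NA_integer_)
}

#' The candidate model set of the analysis
#'
#' The 15 distinct additive formulas combining season, migratory strategy,
#' sex and age effects on survival with strategy, season or constant
#' detection.
#'
#' @return Character vector of model strings.
#' @export
candidate_model_set <- function() {
  c("Phi[season+migr].P[migr]",
    "Phi[season+migr+sex].P[migr]",
    "Phi[season].P[migr]",
    "Phi[season+age].P[migr]",
    "Phi[migr].P[migr]",
    "Phi[.].P[migr]",
    "Phi[sex].P[migr]",
    "Phi[season+migr].P[season]",
    "Phi[season].P[season]",
    "Phi[season+migr+sex].P[season]",
    "Phi[season+sex].P[.]",
    "Phi[season+migr].P[.]",
    "Phi[season+age].P[.]",
    "Phi[season+migr+sex].P[.]",
    "Phi[.].P[season]")
}
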