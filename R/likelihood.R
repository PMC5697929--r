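#' Hidden-Markov capture-recapture log-likelihood
#'
#' Conditional-on-first-capture log-likelihood of the two-state (alive/dead)
#' hidden Markov model: from its first capture, an individual transitions
#' alive -> alive with the interval's survival probability and alive -> dead
#' with its complement (dead is absorbing); an alive individual is detected
#' at an occasion with that occasion's detection probability and a dead one
#' never. The initial state at first capture is alive with probability 1.
#' The forward pass is vectorized across individuals; per-individual forward
#' masses are summed (with multiplicities for pooled histories).
#'
#' @param coefficients Numeric vector, survival coefficients followed by
#'   detection coefficients (lengths = design column counts), on the logit
#'   scale.
#' @param history An `encounter_history` (row order matching the design).
#' @param design A `cmr_design` from [build_design()].
#' @return The total log-likelihood (scalar).
#' @export
hmm_loglik <- function(coefficients, history, design) {
  stopifnot(inherits(history, "encounter_history"),
            inherits(design, "cmr_design"))
  kphi <- ncol(design$phi); kp <- ncol(design$p)
  if (length(coefficients) != kphi + kp)
    stop("expected ", kphi + kp, " coefficients, got ",
         length(coefficients))
  rates <- .link_rates(coefficients, design)
  .forward_two_state(history$matrix, design$first_occasion,
                     rates$phi, rates$p, design$weights)
}

.link_rates <- function(coefficients, design) {
  kphi <- ncol(design$phi)
  eta_phi <- drop(design$phi %*% coefficients[seq_len(kphi)])
  eta_p <- drop(design$p %*% coefficients[-seq_len(kphi)])
  if (any(!is.finite(eta_phi)) || any(!is.finite(eta_p)))
    stop("non-finite linear predictor")
  n <- design$n
  list(phi = matrix(stats::plogis(eta_phi), n, design$n_occasions - 1L),
       p = matrix(stats::plogis(eta_p), n, design$n_occasions))
}

# vectorized forward pass over states {alive, dead}
.forward_two_state <- function(y, f, phi, p, w) {
  n <- nrow(y); T_occ <- ncol(y)
  if (n == 0L) return(0)
  aA <- as.numeric(f == 1L)  # mass alive at current occasion
  aD <- numeric(n)
  for (t in seq_len(T_occ - 1L)) {
    act <- f <= t
    if (any(act)) {
      s <- phi[act, t]
      obs <- y[act, t + 1L] == 1L
      pp <- p[act, t + 1L]
      aliveA <- aA[act] * s * ifelse(obs, pp, 1 - pp)
      deadA <- ifelse(obs, 0, aD[act] + aA[act] * (1 - s))
      aA[act] <- aliveA
      aD[act] <- deadA
    }
    enter <- f == t + 1L
    aA[enter] <- 1
    aD[enter] <- 0
  }
  ll <- log(aA + aD)
  sum(w * ll)
}

#' Generic finite-state forward-algorithm log-likelihood
#'
#' Single-sequence forward algorithm over an arbitrary finite hidden-state
#' space with probabilistic event emission (the multi-event generalization
#' of capture-recapture: observed events map stochastically onto underlying
#' states). The packaged survival model is the two-state special case; a
#' multi-state configuration is a matter of supplying larger arrays.
#'
#' @param init Initial state distribution at the first occasion (length S).
#' @param trans S x S x (T-1) array; `trans[a, b, t]` is the probability of
#'   moving from state `a` at occasion `t` to state `b` at occasion `t+1`.
#' @param emit S x E x T array; `emit[a, e, t]` is the probability of
#'   observing event `e` in state `a` at occasion `t`.
#' @param events Integer event codes per occasion (length T); the first
#'   occasion's event is typically conditioned on via `init`.
#' @param condition_first Logical; if `TRUE` (default) the first occasion's
#'   emission is not scored (the model conditions on the first capture).
#' @return Log-likelihood of the event sequence.
#' @export
forward_loglik <- function(init, trans, emit, events,
                           condition_first = TRUE) {
  S <- length(init)
  T_occ <- length(events)
  stopifnot(dim(trans)[1L] == S, dim(trans)[2L] == S,
            dim(trans)[3L] == T_occ - 1L,
            dim(emit)[1L] == S, dim(emit)[3L] == T_occ)
  alpha <- init
  if (!condition_first) alpha <- alpha * emit[, events[1L], 1L]
  for (t in seq_len(T_occ - 1L)) {
    alpha <- drop(alpha %*% trans[, , t]) * emit[, events[t + 1L], t + 1L]
  }
  log(sum(alpha))
}

#' Closed-form Cormack-Jolly-Seber log-likelihood (oracle)
#'
#' Independent check of the forward algorithm on the two-state model: the
#' classical closed-form CJS product over each history -- survival and
#' detection/non-detection terms between first and last capture, times the
#' terminal-absence probability chi computed by backward recursion
#' `chi_t = (1 - phi_t) + phi_t (1 - p_{t+1}) chi_{t+1}`. Intended for small
#' instances; it shares no code with [hmm_loglik()].
#'
#' @param phi Interval survival: matrix n x (T-1), or a vector over
#'   intervals recycled to all individuals.
#' @param p Occasion detection: matrix n x T, or a vector over occasions.
#' @param history An `encounter_history`.
#' @return Total log-likelihood.
#' @export
cjs_loglik_oracle <- function(phi, p, history) {
  stopifnot(inherits(history, "encounter_history"))
  y <- history$matrix
  n <- nrow(y); T_occ <- ncol(y)
  if (is.null(dim(phi))) phi <- matrix(phi, n, T_occ - 1L, byrow = TRUE)
  if (is.null(dim(p))) p <- matrix(p, n, T_occ, byrow = TRUE)
  total <- 0
  for (i in seq_len(n)) {
    f <- history$first_occasion[i]
    detected <- which(y[i, ] == 1L)
    L <- max(detected)
    lik <- 1
    if (L > f) {
      for (t in f:(L - 1L)) {
        lik <- lik * phi[i, t] *
          (if (y[i, t + 1L] == 1L) p[i, t + 1L] else 1 - p[i, t + 1L])
      }
    }
    chi <- 1
    if (L < T_occ) {
      for (t in (T_occ - 1L):L) {
        chi <- (1 - phi[i, t]) + phi[i, t] * (1 - p[i, t + 1L]) * chi
      }
    }
    total <- total + log(lik * chi)
  }
  total
}
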