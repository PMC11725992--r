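#' Parameters of the piecewise-linear serial-history model
#'
#' The descriptive model represents the influence of each past stimulus on the
#' current psychometric midpoint as a sum of linear ramp components, each
#' defined by an initial one-back weight `w` and the number of stimuli `m`
#' over which that weight decays to zero. Separate component sets apply when
#' the judged test is high or low contrast; a single `gamma > 0` scales down
#' the influence of low-contrast past stimuli (a low-contrast adaptor carries
#' weight `w / gamma`). With three components per contrast the model has
#' 3 x 2 x 2 + 1 = 13 free parameters.
#'
#' Because the midpoint recursion feeds each shift back into later history
#' terms, stable dynamics require the influence weights (times
#' `k_norm = 2 ln(9)/k`) to stay well below 1; see
#' [default_linear_params()] for a stable repulsion-dominated setting.
#'
#' @param w_high,w_low Numeric vectors of initial weights (dimensionless;
#'   negative = repulsive, positive = attractive), one per component.
#' @param m_high,m_low Positive integer vectors, same lengths as the weights:
#'   number of past stimuli over which each component decays to zero.
#' @param gamma Relative strength of a high- versus a low-contrast adaptor
#'   (> 0).
#' @return An object of class `linear_params`.
#' @export
#' @examples
#' lp <- linear_params(w_high = c(-0.05, -0.002, 5e-4), m_high = c(2, 50, 300),
#'                     w_low = c(-0.025, -0.001, 3e-4), m_low = c(2, 60, 350),
#'                     gamma = 2.56)
#' n_free_params(lp)
linear_params <- function(w_high, m_high, w_low, m_low, gamma = 1) {
  m_high <- as.integer(m_high); m_low <- as.integer(m_low)
  if (length(w_high) != length(m_high) || length(w_low) != length(m_low))
    stop("weights and decay lengths must have matching lengths")
  if (any(m_high < 1L) || any(m_low < 1L))
    stop("decay lengths m must be positive integers")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  structure(list(w_high = as.numeric(w_high), m_high = m_high,
                 w_low = as.numeric(w_low), m_low = m_low,
                 gamma = gamma), class = "linear_params")
}

#' Default linear-model parameters
#'
#' Three components per contrast with the qualitative structure recovered by
#' the descriptive model: a strong short repulsive component, a weaker
#' medium-timescale repulsive component, and a weak long-timescale attractive
#' component; low-contrast test components are weaker on the repulsive side.
#' Weight magnitudes are chosen so that steady-state midpoint shifts under
#' the bimodal adaptor blocks stay in the one-to-two degree range typical of
#' orientation aftereffects, keeping the midpoint recursion stable.
#'
#' @param gamma Adaptor-contrast strength ratio; default 2.56.
#' @return A [linear_params()] object.
#' @export
default_linear_params <- function(gamma = 2.56) {
  linear_params(
    w_high = c(-0.050, -0.0020, 5e-4), m_high = c(2L, 50L, 300L),
    w_low  = c(-0.025, -0.0010, 3e-4), m_low  = c(2L, 60L, 350L),
    gamma = gamma
  )
}

#' @export
print.linear_params <- function(x, ...) {
  cat("Linear serial-history model (", n_free_params(x), " free parameters)\n",
      sep = "")
  cat("  high-contrast tests: w =", paste(signif(x$w_high, 3), collapse = ", "),
      "; m =", paste(x$m_high, collapse = ", "), "\n")
  cat("  low-contrast tests:  w =", paste(signif(x$w_low, 3), collapse = ", "),
      "; m =", paste(x$m_low, collapse = ", "), "\n")
  cat("  gamma =", signif(x$gamma, 4), "\n")
  invisible(x)
}

#' Number of free parameters of a model-parameter object
#'
#' @param params A `linear_params` or `observer_params` object.
#' @return Integer count of free parameters (13 for the three-component
#'   linear model; 6 for the contrast-variant observer, 4 for the
#'   contrast-invariant one).
#' @export
n_free_params <- function(params) UseMethod("n_free_params")

#' @export
n_free_params.linear_params <- function(params) {
  2L * (length(params$w_high) + length(params$w_low)) + 1L
}

# one ramp component evaluated at lags 1..S: w * (1 - (i-1)/m), zero beyond m
component_ramp <- function(w, m, S) {
  i <- seq_len(S)
  ifelse(i <= m, w * (1 - (i - 1) / m), 0)
}

#' Influence function over past-stimulus lags
#'
#' Sums the linear ramp components for the given test contrast into the
#' weight sequence `F_1..F_S`: the influence of the stimulus `i` positions
#' back on the current midpoint. The adaptor-contrast factor (1 or
#' `1/gamma`) is not included here; it multiplies each past stimulus
#' individually in [midpoint_shift()].
#'
#' @param params A [linear_params()].
#' @param test_contrast `"high"` or `"low"`: contrast of the judged test.
#' @param S Number of lags to evaluate (defaults to the largest `m`).
#' @return Numeric vector `F` of length `S`; zero for lags beyond the largest
#'   component.
#' @export
#' @examples
#' lp <- linear_params(w_high = -0.2, m_high = 3, w_low = -0.1, m_low = 3)
#' influence_function(lp, "high", S = 4)  # -0.2, -0.1333, -0.0667, 0
influence_function <- function(params, test_contrast = c("high", "low"),
                               S = NULL) {
  test_contrast <- match.arg(test_contrast)
  w <- if (test_contrast == "high") params$w_high else params$w_low
  m <- if (test_contrast == "high") params$m_high else params$m_low
  if (is.null(S)) S <- max(m)
  Reduce(`+`, lapply(seq_along(w), function(j) component_ramp(w[j], m[j], S)))
}

#' Midpoint shift induced by the stimulus history
#'
#' Computes the horizontal displacement of the psychometric function from a
#' history of past stimuli: `shift = k_norm * sum_i s_i (c_{s-i} - theta_{s-i})
#' F_i`, where `k_norm = 2 ln(9) / k` normalises across participants, `F` is
#' the [influence_function()] for the judged test's contrast, and `s_i` is 1
#' for a high-contrast past stimulus and `1/gamma` for a low-contrast one.
#' A positive shift moves the midpoint counterclockwise, i.e. repels
#' subsequent percepts away from a counterclockwise adaptor.
#'
#' @param history A data.frame with one row per past stimulus, most recent
#'   first (lag 1 first), columns `orientation` (deg), `midpoint` (deg, the
#'   midpoint of the function at that stimulus's time) and `contrast_level`
#'   (`"high"`/`"low"`). May have zero rows.
#' @param params A [linear_params()].
#' @param test_contrast `"high"` or `"low"`: contrast of the judged test.
#' @param k Psychometric slope for the judged test's contrast, 1/deg.
#' @return Shift in degrees (0 for an empty history).
#' @export
midpoint_shift <- function(history, params, test_contrast = c("high", "low"),
                           k) {
  test_contrast <- match.arg(test_contrast)
  n <- nrow(history)
  if (n == 0L) return(0)
  stopifnot(k > 0)
  Fi <- influence_function(params, test_contrast, S = n)
  s <- ifelse(history$contrast_level == "high", 1, 1 / params$gamma)
  (2 * log(9) / k) * sum(s * (history$midpoint - history$orientation) * Fi)
}

#' Psychometric response probability
#'
#' Logistic probability of judging a test "orange" (counterclockwise of the
#' reference): `p = 1 / (1 + exp(-k (theta - c)))` with slope `k` chosen by
#' the test's contrast and midpoint `c`.
#'
#' @param theta Test orientation, degrees.
#' @param contrast `"high"` or `"low"`.
#' @param midpoint Current psychometric midpoint, degrees.
#' @param profile A [participant_profile()] supplying `k_high`/`k_low`.
#' @return Probability in `[0, 1]` (vectorised over `theta`).
#' @export
response_probability <- function(theta, contrast = c("high", "low"),
                                 midpoint, profile) {
  contrast <- match.arg(contrast)
  k <- if (contrast == "high") profile$k_high else profile$k_low
  plogis(k * (theta - midpoint))
}

# classify event contrasts as high/low relative to the profile's two levels
contrast_level <- function(contrast, profile) {
  thr <- (profile$high_contrast + profile$low_contrast) / 2
  ifelse(contrast >= thr, 1L, 0L)
}

#' Sequential prediction of test-response probabilities (linear model)
#'
#' Runs the serial-history model causally through an ordered session: for
#' every stimulus the current midpoint of each psychometric function (high-
#' and low-contrast) is computed from the accrued history of
#' `(midpoint - orientation)` terms, stored, and used for subsequent shifts;
#' every test event gets the logistic probability of an "orange" response at
#' its shifted midpoint. Test stimuli enter the history like adaptors.
#'
#' @param events Session data.frame (rows ordered by `index`).
#' @param profile A [participant_profile()].
#' @param params A [linear_params()].
#' @param trace If `TRUE`, attach the per-stimulus midpoint tracks as
#'   attributes `midpoint_high` / `midpoint_low`.
#' @return Numeric vector, one element per event row: probability of "orange"
#'   for tests, `NA` for adaptors.
#' @export
sequential_predict <- function(events, profile, params, trace = FALSE) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(params, "linear_params"))
  if (is.unsorted(events$index, strictly = TRUE))
    stop("events must be ordered by index")
  hl <- contrast_level(events$contrast, profile)
  res <- linear_predict_cpp(
    events$orientation, hl, as.integer(events$role == "test"),
    profile$c0, profile$k_high, profile$k_low,
    params$w_high, params$m_high, params$w_low, params$m_low, params$gamma
  )
  p <- res$p
  if (trace) {
    attr(p, "midpoint_high") <- res$c_high
    attr(p, "midpoint_low") <- res$c_low
  }
  p
}

# shared NLL kernel: clipped Bernoulli negative log likelihood
bernoulli_nll <- function(p, r, eps = 1e-9) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(r * log(p) + (1 - r) * log(1 - p))
}

#' Negative log likelihood of a cohort under the linear model
#'
#' Sums, over all participants and all responded tests, the Bernoulli
#' negative log likelihood of the observed responses under
#' [sequential_predict()]. Probabilities are clipped to `[1e-9, 1 - 1e-9]`.
#'
#' @param sessions A cohort: list of `list(profile, events)`, with responses
#'   present on every test event.
#' @param params A [linear_params()].
#' @return Scalar negative log likelihood.
#' @export
linear_nll <- function(sessions, params) {
  tot <- 0
  for (s in sessions) {
    it <- s$events$role == "test"
    r <- s$events$response[it]
    if (anyNA(r)) stop("all test events must carry a response")
    p <- sequential_predict(s$events, s$profile, params)[it]
    tot <- tot + bernoulli_nll(p, r)
  }
  tot
}

# pack/unpack continuous parameters (weights and log gamma) given fixed m
lin_pack <- function(params) c(params$w_high, params$w_low, log(params$gamma))
lin_unpack <- function(par, m_high, m_low) {
  nh <- length(m_high); nl <- length(m_low)
  linear_params(w_high = par[seq_len(nh)], m_high = m_high,
                w_low = par[nh + seq_len(nl)], m_low = m_low,
                gamma = exp(par[nh + nl + 1L]))
}

# continuous optimisation of (w, gamma) at fixed integer m; divergent
# parameter regions (midpoint recursion blowing up) get a large finite NLL
lin_fit_continuous <- function(sessions, m_high, m_low, start, maxit) {
  obj <- function(par) {
    v <- linear_nll(sessions, lin_unpack(par, m_high, m_low))
    if (!is.finite(v)) 1e10 else v
  }
  nw <- length(start) - 1L
  fit <- optim(start, obj, method = "L-BFGS-B",
               lower = c(rep(-1, nw), log(1e-3)),
               upper = c(rep(1, nw), log(1e3)),
               control = list(maxit = maxit,
                              parscale = c(rep(0.02, nw), 1)))
  list(par = fit$par, nll = fit$value, converged = fit$convergence == 0L)
}

#' Fit the linear serial-history model to a cohort
#'
#' Maximum-likelihood fit of the component weights and `gamma` across all
#' participants jointly, by bounded quasi-Newton optimisation from multiple
#' starts. The integer decay lengths `m` are handled by a nested coordinate
#' search: each `m` in turn is moved across a multiplicative candidate grid
#' with the continuous parameters re-optimised at every candidate, for
#' `m_rounds` sweeps; ties prefer the smaller `m`. Set `m_rounds = 0` to fit
#' with `m` fixed at the initial values.
#'
#' @param sessions A cohort with responses on all test events.
#' @param init Initial [linear_params()]; defaults to
#'   [default_linear_params()].
#' @param starts Number of optimisation starts (the initial point plus
#'   `starts - 1` perturbations). Default 3.
#' @param m_rounds Rounds of coordinate search over the integer `m`s.
#'   Default 0 (fixed timescales).
#' @param m_grid Candidate values for each `m` during the search.
#' @param maxit Iteration cap per continuous optimisation.
#' @param seed Seed for the start perturbations.
#' @return A list of class `linear_fit`: `params`, `nll`, `n_params`,
#'   `n_obs`, `converged`, `nll_trace` (best NLL after each stage).
#' @export
fit_linear <- function(sessions, init = default_linear_params(), starts = 3L,
                       m_rounds = 0L,
                       m_grid = c(1L, 2L, 3L, 5L, 8L, 12L, 20L, 35L, 60L,
                                  100L, 180L, 300L, 500L),
                       maxit = 200L, seed = 1L) {
  if (length(sessions) < 1L) stop("need at least one session with responses")
  m_high <- init$m_high; m_low <- init$m_low
  base <- lin_pack(init)
  # perturbation scales: weights live around 1e-2, log gamma around 1
  sdv <- c(rep(0.02, length(base) - 1L), 0.7)
  perturb <- withr::with_seed(seed, lapply(seq_len(max(starts - 1L, 0L)),
    function(i) base + rnorm(length(base), 0, sdv)))
  trace <- numeric(0)
  best <- NULL
  for (st in c(list(base), perturb)) {
    f <- lin_fit_continuous(sessions, m_high, m_low, st, maxit)
    if (is.null(best) || f$nll < best$nll) best <- f
    trace <- c(trace, best$nll)
  }
  # nested coordinate search over each integer m
  if (m_rounds > 0L) {
    for (round in seq_len(m_rounds)) {
      for (slot in seq_len(length(m_high) + length(m_low))) {
        for (cand in sort(m_grid)) {
          mh <- m_high; ml <- m_low
          if (slot <= length(m_high)) mh[slot] <- cand
          else ml[slot - length(m_high)] <- cand
          cur <- if (slot <= length(m_high)) m_high[slot]
                 else m_low[slot - length(m_high)]
          if (cand == cur) next
          f <- lin_fit_continuous(sessions, mh, ml, best$par, maxit)
          # strict improvement required, so ties keep the smaller earlier m
          if (f$nll < best$nll - 1e-6) {
            best <- f; m_high <- mh; m_low <- ml
          }
        }
        trace <- c(trace, best$nll)
      }
    }
  }
  params <- lin_unpack(best$par, m_high, m_low)
  n_obs <- sum(vapply(sessions, function(s) sum(s$events$role == "test"), 0L))
  structure(list(params = params, nll = best$nll,
                 n_params = n_free_params(params), n_obs = n_obs,
                 converged = best$converged, nll_trace = trace),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("Linear model fit: NLL = %.2f over %d responses (%d params%s)\n",
              x$nll, x$n_obs, x$n_params,
              if (x$converged) "" else "; optimizer did not report convergence"))
  print(x$params)
  invisible(x)
}
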