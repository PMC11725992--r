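#' Orientation grid
#'
#' Evenly spaced discretisation of one full 180-degree orientation period, on
#' which all likelihoods, priors, posteriors and the reference distribution
#' live. Orientation is treated as 180-degree periodic; circular densities
#' are evaluated in double-angle space (`angle = 2 theta`) and mapped back to
#' degrees for reporting.
#'
#' @param resolution Grid step in degrees; must divide 180. Default 0.25
#'   (720 points).
#' @return Object of class `orientation_grid` with elements `values`
#'   (degrees, in `[-90, 90)`), `resolution`, `n`.
#' @export
orientation_grid <- function(resolution = 0.25) {
  if (resolution <= 0 || abs(180 / resolution - round(180 / resolution)) > 1e-9)
    stop("resolution must be a positive divisor of 180")
  values <- seq(-90, 90 - resolution, by = resolution)
  structure(list(values = values, resolution = resolution,
                 n = length(values)), class = "orientation_grid")
}

#' von Mises probability mass on an orientation grid
#'
#' Evaluates a von Mises density in double-angle space at the grid
#' orientations and normalises it to sum to 1.
#'
#' @param grid An [orientation_grid()].
#' @param mu Mean orientation, degrees.
#' @param kappa Concentration (double-angle space), `> 0`.
#' @return Numeric probability vector over `grid$values`.
#' @export
von_mises_mass <- function(grid, mu, kappa) {
  stopifnot(inherits(grid, "orientation_grid"), kappa > 0)
  w <- exp(kappa * (cos(2 * (grid$values - mu) * pi / 180) - 1))
  w / sum(w)
}

#' Bank of orientation-tuned channels
#'
#' `N` von Mises channels with preferred orientations equally spread over the
#' 180-degree period, each normalised to peak response 1 at maximum contrast,
#' and a per-channel gain (maximum response) initialised at 1.
#'
#' @param n_channels Number of channels. Default 60.
#' @param kappa_phi Tuning concentration at maximum contrast (double-angle
#'   space).
#' @param grid An [orientation_grid()].
#' @return Object of class `channel_bank`: `mu` (preferred orientations,
#'   degrees), `kappa_phi`, `gains` (all 1), `grid`, and `log_phi`, the
#'   `grid$n x n_channels` matrix of log tuning curves.
#' @export
channel_bank <- function(n_channels = 60L, kappa_phi = 4,
                         grid = orientation_grid()) {
  stopifnot(n_channels >= 2L, kappa_phi > 0)
  mu <- -90 + 180 / n_channels * (seq_len(n_channels) - 1L)
  log_phi <- sapply(mu, function(m)
    kappa_phi * (cos(2 * (grid$values - m) * pi / 180) - 1))
  structure(list(mu = mu, kappa_phi = kappa_phi,
                 gains = rep(1, n_channels), grid = grid,
                 log_phi = log_phi), class = "channel_bank")
}

#' Physiological channel presets
#'
#' Named presets of channel constants (tuning concentration at maximum
#' contrast and the contrast-response semi-saturation and exponent) for
#' visual areas V1, V2 and V5/MT, shipped as
#' `inst/extdata/channel_presets.json`. Entries flagged in the file's
#' `placeholder` field are synthetic stand-in values, not transcribed
#' physiological estimates; no result in this package depends on them.
#'
#' @param name `"V1"`, `"V2"` or `"V5"`; omit to get the full list.
#' @return A list with `kappa_phi`, `c50`, `c_exp` (and the placeholder
#'   flags), or the named list of all presets.
#' @export
observer_preset <- function(name = NULL) {
  path <- system.file("extdata", "channel_presets.json", package = "serialdep")
  presets <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  presets <- presets[names(presets) != "_comment"]
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) stop("unknown preset: ", name)
  presets[[name]]
}

#' Observer model parameters
#'
#' Bundles the channel-bank constants (from a named preset or given
#' explicitly) with the free parameters of the adaptive Bayesian observer:
#' `alpha` (gain reduction per unit channel activation, in `[0, 1)`), `beta`
#' (gain recovery, 1/s), `tau` (prior integration rate per stimulus, in
#' `[0, 1]`), `omega` (response accumulation for a 300 ms presentation), and,
#' for the contrast-variant (CV) tuning-width variant, `w50` and `eps_exp`
#' (semi-saturation and exponent of the tuning-width contrast function). The
#' CV observer has 6 free parameters; the contrast-invariant (CI) variant
#' ignores `w50`/`eps_exp` and has 4.
#'
#' @param alpha,beta,tau,omega Free adaptation/integration parameters.
#' @param w50,eps_exp Tuning-width saturation parameters (CV variant only).
#' @param preset Preset name passed to [observer_preset()], or `NULL` when
#'   `kappa_phi`, `c50`, `c_exp` are given directly.
#' @param variant `"CV"` or `"CI"`.
#' @param kappa_phi,c50,c_exp Channel constants; default from the preset.
#' @param n_channels,grid_resolution Discretisation settings.
#' @return Object of class `observer_params`.
#' @export
#' @examples
#' op <- observer_params()
#' n_free_params(op)
observer_params <- function(alpha = 0.12, beta = 0.02, tau = 0.008,
                            omega = 2.5, w50 = 0.12, eps_exp = 2.31,
                            preset = "V5", variant = c("CV", "CI"),
                            kappa_phi = NULL, c50 = NULL, c_exp = NULL,
                            n_channels = 60L, grid_resolution = 0.25) {
  variant <- match.arg(variant)
  if (!is.null(preset)) {
    pr <- observer_preset(preset)
    if (is.null(kappa_phi)) kappa_phi <- pr$kappa_phi
    if (is.null(c50)) c50 <- pr$c50
    if (is.null(c_exp)) c_exp <- pr$c_exp
  }
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, tau >= 0, tau <= 1, omega > 0,
            w50 > 0, eps_exp > 0, kappa_phi > 0, c50 > 0, c_exp > 0)
  structure(list(alpha = alpha, beta = beta, tau = tau, omega = omega,
                 w50 = w50, eps_exp = eps_exp, preset = preset,
                 variant = variant, kappa_phi = kappa_phi, c50 = c50,
                 c_exp = c_exp, n_channels = as.integer(n_channels),
                 grid_resolution = grid_resolution),
            class = "observer_params")
}

#' @export
n_free_params.observer_params <- function(params) {
  if (params$variant == "CV") 6L else 4L
}

#' @export
print.observer_params <- function(x, ...) {
  cat(sprintf(
    "Bayesian observer (%s-%s, %d free params): alpha=%.3g beta=%.3g tau=%.3g omega=%.3g",
    if (is.null(x$preset)) "custom" else x$preset, x$variant,
    n_free_params(x), x$alpha, x$beta, x$tau, x$omega))
  if (x$variant == "CV") cat(sprintf(" w50=%.3g eps=%.3g", x$w50, x$eps_exp))
  cat("\n")
  invisible(x)
}

# rescaled Naka-Rushton gain: 1 at contrast 1
contrast_gain <- function(contrast, c50, c_exp) {
  (contrast^c_exp / (c50^c_exp + contrast^c_exp)) / (1 / (c50^c_exp + 1))
}

# tuning concentration at a given contrast (CV rescaled to kappa_phi at c = 1)
contrast_kappa <- function(contrast, params) {
  if (params$variant == "CI") return(params$kappa_phi)
  s <- contrast^params$eps_exp /
    (params$w50^params$eps_exp + contrast^params$eps_exp)
  params$kappa_phi * s / (1 / (params$w50^params$eps_exp + 1))
}

#' Channel responses to a stimulus
#'
#' Response of every channel to an oriented stimulus: the contrast-gain
#' function times the channel's von Mises tuning curve (peak-normalised to 1)
#' evaluated at the stimulus orientation, with tuning concentration either
#' fixed (`CI`) or contrast-dependent (`CV`). Both contrast functions are
#' rescaled so that contrast 1 reproduces the maximum-contrast tuning curve
#' exactly.
#'
#' @param theta Stimulus orientation, degrees.
#' @param contrast Michelson contrast in `(0, 1]`.
#' @param bank A [channel_bank()].
#' @param params An [observer_params()].
#' @return Numeric vector of per-channel responses in `[0, 1]`.
#' @export
channel_response <- function(theta, contrast, bank, params) {
  if (contrast <= 0) stop("contrast must be positive")
  g <- contrast_gain(contrast, params$c50, params$c_exp)
  kc <- contrast_kappa(contrast, params)
  g * exp(kc * (cos(2 * (theta - bank$mu) * pi / 180) - 1))
}

#' Encode the orientation likelihood from channel responses
#'
#' Log mass on the grid is `omega_s * sum_i m_i n_i log phi_i`, exponentiated
#' and normalised: each channel votes with its log tuning curve, weighted by
#' its (gain-scaled) response, and `omega_s` accumulates evidence with
#' presentation duration, sharpening the likelihood. All-zero responses give
#' a uniform distribution.
#'
#' The decoding tuning curve is the channel's tuning at the stimulus's
#' contrast: when `kappa_c` (from [channel_response()]'s width function)
#' differs from the bank's maximum-contrast `kappa_phi`, the log tuning
#' curves scale by `kappa_c / kappa_phi`, so a low-contrast stimulus yields a
#' proportionally broader likelihood. With the contrast-invariant variant (or
#' `kappa_c` omitted) this reduces to the maximum-contrast decoder.
#'
#' @param responses Per-channel response vector from [channel_response()].
#' @param bank A [channel_bank()] (supplies gains and log tuning curves).
#' @param omega_s Accumulation parameter for this presentation.
#' @param kappa_c Tuning concentration at the stimulus's contrast; default
#'   `bank$kappa_phi`.
#' @return Probability vector over the bank's grid.
#' @export
encode_likelihood <- function(responses, bank, omega_s,
                              kappa_c = bank$kappa_phi) {
  stopifnot(length(responses) == length(bank$mu), omega_s >= 0, kappa_c > 0)
  ll <- omega_s * (kappa_c / bank$kappa_phi) *
    as.vector(bank$log_phi %*% (bank$gains * responses))
  w <- exp(ll - max(ll))
  w / sum(w)
}

#' Adapt channel gains after a presentation
#'
#' Each channel's maximum response is reduced in proportion to its activation
#' by the stimulus: `m_i <- m_i (1 - alpha n_i)`. Repeated identical
#' presentations therefore reduce the gain geometrically (self-constrained,
#' never reaching 0).
#'
#' @param bank A [channel_bank()].
#' @param responses Per-channel responses in `[0, 1]`.
#' @param alpha Gain-reduction rate in `[0, 1)`.
#' @return The bank with updated gains.
#' @export
apply_adaptation <- function(bank, responses, alpha) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  stopifnot(all(responses >= 0), all(responses <= 1))
  bank$gains <- bank$gains * (1 - alpha * responses)
  bank
}

#' Recover channel gains over stimulus-free time
#'
#' Gains regress linearly toward their initial value 1:
#' `m_i <- m_i (1 - min(beta dt, 1)) + min(beta dt, 1)`; `beta dt >= 1` is
#' full recovery.
#'
#' @param bank A [channel_bank()].
#' @param beta Recovery constant, 1/s.
#' @param dt Elapsed time, seconds (`>= 0`).
#' @return The bank with updated gains.
#' @export
recover_gains <- function(bank, beta, dt) {
  if (dt < 0) stop("dt must be non-negative")
  r <- min(beta * dt, 1)
  bank$gains <- bank$gains * (1 - r) + r
  bank
}

#' Update the slow orientation prior
#'
#' Convex combination `(1 - tau) prior + tau posterior`; with the small `tau`
#' values typical of the model the prior changes noticeably only over
#' hundreds of presentations.
#'
#' @param prior,posterior Probability vectors on the same grid.
#' @param tau Integration rate in `[0, 1]`.
#' @return Updated (normalised) prior.
#' @export
update_prior <- function(prior, posterior, tau) {
  if (tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  stopifnot(length(prior) == length(posterior))
  (1 - tau) * prior + tau * posterior
}

#' Combine likelihood and prior into the posterior
#'
#' Pointwise product, renormalised.
#'
#' @param likelihood,prior Probability vectors on the same grid.
#' @return Posterior probability vector.
#' @export
compute_posterior <- function(likelihood, prior) {
  stopifnot(length(likelihood) == length(prior))
  w <- likelihood * prior
  z <- sum(w)
  if (z <= 0) stop("posterior has zero total mass")
  w / z
}

# circular mean (degrees) of a probability mass on the grid
circular_mean_deg <- function(mass, grid) {
  a <- 2 * grid$values * pi / 180
  atan2(sum(mass * sin(a)), sum(mass * cos(a))) * 180 / pi / 2
}

# For each grid index, the reference ROC statistic C(x) - ref(x)/2 where C is
# the reference CDF along the grid ordered counterclockwise from mu (the
# reference circular mean): P(X > Y) + P(X = Y)/2 = sum_x post(x) stat(x).
reference_stat <- function(reference, grid, mu = NULL) {
  if (is.null(mu)) mu <- circular_mean_deg(reference, grid)
  d <- ((grid$values - mu + 90) %% 180) - 90
  o <- order(d)
  stat <- numeric(grid$n)
  stat[o] <- cumsum(reference[o]) - reference[o] / 2
  stat
}

#' Decision probability from posterior versus reference
#'
#' Probability that the stimulus is judged counterclockwise ("orange") of the
#' reference: the ROC area between the posterior and the reference
#' distribution, computed on the shared grid as `P(X > Y) + P(X = Y)/2` with
#' `X ~ posterior`, `Y ~ reference`, the grid linearised (unwrapped) around
#' the reference circular mean. Identical distributions give exactly 0.5.
#'
#' @param posterior,reference Probability vectors on `grid`.
#' @param grid An [orientation_grid()].
#' @return Probability in `[0, 1]`.
#' @export
decision_probability <- function(posterior, reference, grid) {
  if (length(posterior) != length(reference) ||
      length(posterior) != grid$n)
    stop("posterior and reference must live on the same grid")
  sum(posterior * reference_stat(reference, grid))
}

#' Simulate the Bayesian observer through a session
#'
#' Runs the full observer causally over an ordered stimulus stream. Per
#' stimulus: gains recover with the time since the previous stimulus offset;
#' channel responses and the orientation likelihood (with current gains and
#' `omega_s = omega * duration / 0.3`) are computed; the posterior combines
#' the likelihood with the slowly integrated prior (initialised uniform); for
#' test stimuli the "orange" response probability is the ROC area between
#' posterior and the participant's fixed reference distribution
#' `V(mu_ref, kappa_ref)`; finally gains adapt and the prior updates. The
#' current stimulus is perceived with pre-adaptation gains.
#'
#' @param events Ordered session data.frame with onsets.
#' @param profile A [participant_profile()] (supplies the reference).
#' @param params An [observer_params()].
#' @param trace If `TRUE`, also return the per-stimulus gain trace and the
#'   likelihood/posterior mode orientations.
#' @return A list: `p` (probability per event row, `NA` on adaptors),
#'   `final_gains`, `final_prior`, `grid`, and when `trace = TRUE` also
#'   `gain_trace` (stimuli x channels), `lik_mode`, `post_mode` (degrees).
#' @export
simulate_observer <- function(events, profile, params, trace = FALSE) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(params, "observer_params"))
  if (is.unsorted(events$index, strictly = TRUE))
    stop("events must be ordered by index")
  if (anyNA(events$onset) || is.unsorted(events$onset, strictly = TRUE))
    stop("events must carry strictly increasing onsets")
  grid <- orientation_grid(params$grid_resolution)
  bank <- channel_bank(params$n_channels, params$kappa_phi, grid)
  reference <- von_mises_mass(grid, profile$mu_ref, profile$kappa_ref)
  rs <- reference_stat(reference, grid, mu = profile$mu_ref)
  res <- observer_simulate_cpp(
    events$orientation, events$contrast, events$duration, events$onset,
    as.integer(events$role == "test"), bank$mu, params$kappa_phi,
    params$c50, params$c_exp, params$w50, params$eps_exp,
    as.integer(params$variant == "CV"), params$alpha, params$beta,
    params$tau, params$omega, bank$log_phi, rs, trace
  )
  out <- list(p = res$p, final_gains = res$gains, final_prior = res$prior,
              grid = grid)
  if (trace) {
    out$gain_trace <- res$gain_trace
    out$lik_mode <- grid$values[res$lik_mode]
    out$post_mode <- grid$values[res$post_mode]
  }
  out
}

#' Negative log likelihood of a cohort under the observer model
#'
#' Same contract and clipping as [linear_nll()], with probabilities from
#' [simulate_observer()].
#'
#' @param sessions A cohort with responses on all test events.
#' @param params An [observer_params()].
#' @return Scalar negative log likelihood.
#' @export
observer_nll <- function(sessions, params) {
  tot <- 0
  for (s in sessions) {
    it <- s$events$role == "test"
    r <- s$events$response[it]
    if (anyNA(r)) stop("all test events must carry a response")
    p <- simulate_observer(s$events, s$profile, params)$p[it]
    tot <- tot + bernoulli_nll(p, r)
  }
  tot
}

# transforms keeping free parameters in their domains during optimisation
obs_free_names <- function(variant)
  c("alpha", "beta", "tau", "omega",
    if (variant == "CV") c("w50", "eps_exp"))
obs_to_unconstrained <- function(v, name)
  switch(name, alpha = qlogis(v), tau = qlogis(v), log(v))
obs_from_unconstrained <- function(u, name)
  switch(name, alpha = plogis(u), tau = plogis(u), exp(u))

#' Fit the Bayesian observer to a cohort
#'
#' Maximum-likelihood fit of the observer's free parameters (`alpha`, `beta`,
#' `tau`, `omega`, plus `w50`, `eps_exp` for the CV variant) by bounded
#' quasi-Newton optimisation in transformed space, from the initial point and
#' optional perturbed restarts. Parameters named in `fixed` are held at their
#' initial values (useful for profile fits and recovery studies); the
#' reported `n_params` is the variant's declared free-parameter count.
#'
#' @param sessions A cohort with responses on all test events.
#' @param init Initial [observer_params()].
#' @param fixed Character vector of free-parameter names to hold fixed.
#' @param starts Number of optimisation starts. Default 1.
#' @param maxit Iteration cap per start. Default 100.
#' @param seed Seed for start perturbations.
#' @return A list of class `observer_fit`: `params`, `nll`, `n_params`,
#'   `n_obs`, `converged`, `nll_trace`.
#' @export
fit_observer <- function(sessions, init = observer_params(), fixed = character(),
                         starts = 1L, maxit = 100L, seed = 1L) {
  if (length(sessions) < 1L) stop("need at least one session with responses")
  free <- setdiff(obs_free_names(init$variant), fixed)
  if (length(free) == 0L) stop("no free parameters left to fit")
  base <- vapply(free, function(nm) obs_to_unconstrained(init[[nm]], nm), 0)
  make_params <- function(par) {
    p <- init
    for (j in seq_along(free))
      p[[free[j]]] <- obs_from_unconstrained(par[j], free[j])
    p
  }
  obj <- function(par) observer_nll(sessions, make_params(par))
  perturb <- withr::with_seed(seed, lapply(seq_len(max(starts - 1L, 0L)),
    function(i) base + rnorm(length(base), 0, 0.3)))
  best <- NULL; trace <- numeric(0)
  for (st in c(list(base), perturb)) {
    fit <- optim(st, obj, method = "L-BFGS-B", lower = -12, upper = 12,
                 control = list(maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
    trace <- c(trace, best$value)
  }
  params <- make_params(best$par)
  n_obs <- sum(vapply(sessions, function(s) sum(s$events$role == "test"), 0L))
  structure(list(params = params, nll = best$value,
                 n_params = n_free_params(params), n_obs = n_obs,
                 converged = best$convergence == 0L, nll_trace = trace,
                 fitted_names = free),
            class = "observer_fit")
}

#' @export
print.observer_fit <- function(x, ...) {
  cat(sprintf("Observer fit: NLL = %.2f over %d responses (%d params)\n",
              x$nll, x$n_obs, x$n_params))
  print(x$params)
  invisible(x)
}

#' Presentation duration equivalent to a contrast reduction
#'
#' Computes the duration at which a high-contrast presentation produces
#' exactly the same orientation likelihood (for a fresh, unadapted bank and
#' in the absence of serial effects) as a reference-duration presentation at
#' a lower contrast. With log-linear von Mises tuning the encoded likelihood
#' is itself von Mises with concentration proportional to
#' `omega_s * gain * kappa_c * |population vector|`, so matching reduces to a
#' duration rescaling. Although the instantaneous likelihoods match, the
#' sequential predictions differ, because channel adaptation depends on the
#' per-presentation responses (contrast) but not on duration.
#'
#' @param contrast The lower contrast to be matched.
#' @param params An [observer_params()].
#' @param high_contrast Contrast of the substituted stimulus. Default 0.5.
#' @param duration Reference duration in seconds. Default 0.3.
#' @return Matched duration in seconds (shorter than `duration`).
#' @export
matched_duration <- function(contrast, params, high_contrast = 0.5,
                             duration = 0.3) {
  bank <- channel_bank(params$n_channels, params$kappa_phi,
                       orientation_grid(params$grid_resolution))
  conc <- function(cc) {
    n <- channel_response(0, cc, bank, params)
    a <- 2 * bank$mu * pi / 180
    contrast_kappa(cc, params) * sqrt(sum(n * cos(a))^2 + sum(n * sin(a))^2)
  }
  duration * conc(contrast) / conc(high_contrast)
}
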