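#' Session design for the adaptor/test paradigm
#'
#' Describes one experimental session of the three-block design: a stream of
#' briefly presented oriented Gabors ("adaptors") with interleaved test
#' stimuli cued for a 2AFC judgement against a fixed reference. The adaptor
#' orientation distribution changes at each third of the session (blocks i,
#' ii, iii): unimodal around the participant's PSE in block i, bimodal with
#' modes `bimodal_offset` degrees either side of the PSE afterwards, with the
#' block-ii distribution depending on the participant's group (see
#' [generate_session()]).
#'
#' @param n_stimuli Total number of stimuli per session. Must be divisible by
#'   3 (blocks) and by 240 (balanced test sets). Default 2160.
#' @param cue_period A response cue appears at every `cue_period`-th stimulus,
#'   plus once at a uniformly random position strictly inside each cycle.
#'   Default 12, giving `n_stimuli / cue_period * 2` tests per session.
#' @param responses_per_set Number of tests per 240-stimulus span; must be
#'   divisible by 4 so the four test types balance. Default 40.
#' @param adaptor_sd Standard deviation of adaptor orientations around each
#'   mode, degrees. Default 3.
#' @param bimodal_offset Distance of the bimodal modes from the PSE, degrees.
#'   Default 15.
#' @param test_offset Test orientations are `PSE +/- test_offset` degrees.
#'   Default 3.
#' @param groupB_ratio Odds of the counterclockwise over the clockwise mode in
#'   Group B's block-ii distribution. Default 3 (i.e. 3:1).
#' @param duration Stimulus duration, seconds. Default 0.300.
#' @param isi Inter-stimulus interval, seconds. Default 0.900.
#' @param response_pause Extra pause after each response, seconds, before the
#'   next stimulus. Default 1.5.
#' @return An object of class `session_design`.
#' @export
#' @examples
#' d <- session_design()
#' d$n_stimuli / d$cue_period * 2  # number of tests per session
session_design <- function(n_stimuli = 2160L, cue_period = 12L,
                           responses_per_set = 40L, adaptor_sd = 3,
                           bimodal_offset = 15, test_offset = 3,
                           groupB_ratio = 3, duration = 0.300, isi = 0.900,
                           response_pause = 1.5) {
  n_stimuli <- as.integer(n_stimuli)
  cue_period <- as.integer(cue_period)
  if (n_stimuli %% 3L != 0L)
    stop("n_stimuli must be divisible by 3 (three blocks)")
  if (n_stimuli %% 240L != 0L)
    stop("n_stimuli must be divisible by 240 (balanced test sets)")
  if (240L %% cue_period != 0L)
    stop("cue_period must divide 240")
  if (responses_per_set %% 4L != 0L)
    stop("responses_per_set must be divisible by 4 (test types balanced)")
  if (cue_period < 2L) stop("cue_period must be at least 2")
  stopifnot(adaptor_sd > 0, bimodal_offset > 0, test_offset > 0,
            groupB_ratio > 0, duration > 0, isi >= 0, response_pause >= 0)
  structure(list(
    n_stimuli = n_stimuli, cue_period = cue_period,
    responses_per_set = as.integer(responses_per_set),
    adaptor_sd = adaptor_sd, bimodal_offset = bimodal_offset,
    test_offset = test_offset, groupB_ratio = groupB_ratio,
    duration = duration, isi = isi, response_pause = response_pause
  ), class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design:", x$n_stimuli, "stimuli,",
      x$n_stimuli %/% x$cue_period * 2L, "tests,",
      "blocks of", x$n_stimuli %/% 3L, "\n")
  invisible(x)
}

default_sampling_ranges <- function() {
  list(
    c0_mean = 0, c0_sd = 0.5,          # Phase-1 PSE measurement error, deg
    k_high_range = c(0.5, 1.0),        # logistic slope, 1/deg
    k_low_frac_range = c(0.35, 0.7),   # k_low as a fraction of k_high
    mu_ref_sd = 0.25,                  # Phase-1 PSE estimation error, deg
    kappa_ref_range = c(100, 200),     # reference concentration (double angle)
    p_low_contrast_10 = 9 / 24         # fraction of participants at 10% low contrast
  )
}

#' Sample a synthetic participant profile
#'
#' Draws the per-participant baseline psychometric parameters that in the real
#' experiment come from adaptive staircases: the baseline midpoint `c0` (the
#' measured PSE, expressed relative to the reference and therefore near 0),
#' logistic slopes at high and low contrast (with `k_high >= k_low`), and the
#' mean and concentration of the participant's internal reference
#' distribution.
#'
#' @param group One of `"A"`, `"B"`, `"C"`.
#' @param design A [session_design()].
#' @param seed Integer seed; the draw is deterministic given the seed and does
#'   not disturb the global RNG state.
#' @param ranges Optional list overriding elements of the default sampling
#'   ranges (see `serialdep:::default_sampling_ranges`).
#' @param participant_id Optional label; generated from the seed if missing.
#' @return An object of class `participant_profile`.
#' @export
#' @examples
#' p <- sample_participant("A", session_design(), seed = 1)
#' p$k_high >= p$k_low
sample_participant <- function(group, design = session_design(), seed = NULL,
                               ranges = list(), participant_id = NULL) {
  if (!is.character(group) || length(group) != 1L || !group %in% c("A", "B", "C"))
    stop("group must be one of 'A', 'B', 'C'")
  rg <- utils::modifyList(default_sampling_ranges(), ranges)
  draw <- function() {
    c0 <- rnorm(1, rg$c0_mean, rg$c0_sd)
    k_high <- runif(1, rg$k_high_range[1], rg$k_high_range[2])
    k_low <- k_high * runif(1, rg$k_low_frac_range[1], rg$k_low_frac_range[2])
    mu_ref <- c0 + rnorm(1, 0, rg$mu_ref_sd)
    kappa_ref <- runif(1, rg$kappa_ref_range[1], rg$kappa_ref_range[2])
    low_contrast <- if (runif(1) < rg$p_low_contrast_10) 0.10 else 0.08
    list(c0 = c0, k_high = k_high, k_low = k_low, mu_ref = mu_ref,
         kappa_ref = kappa_ref, low_contrast = low_contrast)
  }
  v <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (is.null(participant_id))
    participant_id <- sprintf("%s%s", group, if (is.null(seed)) "x" else seed)
  participant_profile(
    participant_id = participant_id, group = group, c0 = v$c0,
    k_high = v$k_high, k_low = v$k_low, mu_ref = v$mu_ref,
    kappa_ref = v$kappa_ref, low_contrast = v$low_contrast
  )
}

#' Construct a participant profile
#'
#' @param participant_id Opaque label.
#' @param group One of `"A"`, `"B"`, `"C"`.
#' @param c0 Baseline psychometric midpoint (measured PSE), degrees relative
#'   to the reference.
#' @param k_high,k_low Logistic slopes at high/low contrast, 1/degrees; both
#'   positive.
#' @param mu_ref,kappa_ref Mean (degrees) and concentration (double-angle
#'   space, dimensionless) of the internal reference distribution.
#' @param low_contrast,high_contrast Michelson contrasts of the low- and
#'   high-contrast stimuli; `0 < low_contrast < high_contrast <= 1`.
#' @return An object of class `participant_profile`.
#' @export
participant_profile <- function(participant_id, group, c0, k_high, k_low,
                                mu_ref = c0, kappa_ref = 150,
                                low_contrast = 0.08, high_contrast = 0.50) {
  if (!group %in% c("A", "B", "C")) stop("group must be one of 'A', 'B', 'C'")
  stopifnot(k_high > 0, k_low > 0, kappa_ref > 0,
            low_contrast > 0, low_contrast < high_contrast, high_contrast <= 1)
  structure(list(
    participant_id = as.character(participant_id), group = group, c0 = c0,
    k_high = k_high, k_low = k_low, mu_ref = mu_ref, kappa_ref = kappa_ref,
    low_contrast = low_contrast, high_contrast = high_contrast
  ), class = "participant_profile")
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf(
    "Participant %s (group %s): c0 = %.2f deg, k = %.2f/%.2f, contrasts %g/%g\n",
    x$participant_id, x$group, x$c0, x$k_high, x$k_low,
    x$high_contrast, x$low_contrast))
  invisible(x)
}

# Block label (i/ii/iii) for 1-based stimulus positions.
block_of <- function(pos, n_stimuli) {
  third <- n_stimuli %/% 3L
  findInterval(pos, c(1L, third + 1L, 2L * third + 1L))
}

#' Generate one synthetic session
#'
#' Builds the full ordered stimulus stream for one participant. Response cues
#' appear at every `cue_period`-th stimulus plus once at a uniformly random
#' position strictly inside each cycle; the stimulus at a cue position is a
#' test (orientation `c0 +/- test_offset`, contrast per test type) and also
#' acts as an adaptor for subsequent history. Within every 240-stimulus span
#' the four test types (HC+, LC+, HC-, LC-) each occur exactly
#' `responses_per_set / 4` times in randomized order.
#'
#' Adaptor orientations follow the block distributions: block i is
#' `N(c0, adaptor_sd)`; blocks ii and iii are two-mode Gaussian mixtures with
#' modes at `c0 +/- bimodal_offset`. In block ii the mixture is balanced for
#' Groups A and C and favours the counterclockwise mode `groupB_ratio`:1 for
#' Group B; for Group C, block-ii adaptors clockwise of the PSE
#' (orientation < c0) are shown at the participant's low contrast. All other
#' adaptors are high contrast. Onsets advance by `duration + isi`, plus
#' `response_pause` after each test.
#'
#' @param profile A [participant_profile()].
#' @param design A [session_design()].
#' @param seed Integer seed; identical (profile, design, seed) give an
#'   identical session.
#' @return A data.frame of stimulus events with columns `index` (0-based),
#'   `onset` (s), `orientation` (deg, relative to the reference), `contrast`,
#'   `duration` (s), `role` (`"adaptor"`/`"test"`), `test_type` (`"none"`,
#'   `"HC+"`, `"LC+"`, `"HC-"`, `"LC-"`), `response` (NA until simulated).
#' @export
#' @examples
#' p <- sample_participant("B", seed = 1)
#' ev <- generate_session(p, session_design(), seed = 2)
#' table(ev$role)
generate_session <- function(profile, design = session_design(), seed = NULL) {
  stopifnot(inherits(profile, "participant_profile"),
            inherits(design, "session_design"))
  build <- function() {
    n <- design$n_stimuli
    cp <- design$cue_period
    n_cycles <- n %/% cp
    fixed <- seq(cp, n, by = cp)
    # one extra cue uniformly among the cp - 1 positions strictly inside each cycle
    extra <- (seq_len(n_cycles) - 1L) * cp +
      sample.int(cp - 1L, n_cycles, replace = TRUE)
    test_pos <- sort(c(fixed, extra))

    # balanced randomized test types within each 240-stimulus span
    types <- c("HC+", "LC+", "HC-", "LC-")
    per_type <- design$responses_per_set %/% 4L
    n_spans <- n %/% 240L
    test_type <- unlist(lapply(seq_len(n_spans), function(s)
      sample(rep(types, per_type))), use.names = FALSE)

    orientation <- numeric(n)
    contrast <- rep(profile$high_contrast, n)
    block <- block_of(seq_len(n), n)

    # adaptor orientations per block/group
    is_test <- logical(n); is_test[test_pos] <- TRUE
    ad <- which(!is_test)
    b <- block[ad]
    m <- length(ad)
    side <- numeric(m)                       # +1 CCW mode, -1 CW mode
    p_ccw <- rep(0.5, m)
    if (profile$group == "B")
      p_ccw[b == 2L] <- design$groupB_ratio / (design$groupB_ratio + 1)
    side <- ifelse(runif(m) < p_ccw, 1, -1)
    mode <- ifelse(b == 1L, 0, side * design$bimodal_offset)
    orientation[ad] <- profile$c0 + mode + rnorm(m, 0, design$adaptor_sd)
    if (profile$group == "C") {
      lc <- ad[b == 2L & orientation[ad] < profile$c0]
      contrast[lc] <- profile$low_contrast
    }

    # tests
    sign_t <- ifelse(grepl("\\+", test_type), 1, -1)
    orientation[test_pos] <- profile$c0 + sign_t * design$test_offset
    contrast[test_pos] <- ifelse(grepl("^HC", test_type),
                                 profile$high_contrast, profile$low_contrast)

    step <- design$duration + design$isi + ifelse(is_test, design$response_pause, 0)
    onset <- c(0, cumsum(step)[-n])

    tt <- rep("none", n); tt[test_pos] <- test_type
    data.frame(
      index = 0:(n - 1L), onset = onset, orientation = orientation,
      contrast = contrast, duration = design$duration,
      role = ifelse(is_test, "test", "adaptor"), test_type = tt,
      response = NA_integer_, stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Generate a cohort of synthetic participants with sessions
#'
#' @param design A [session_design()].
#' @param n_per_group Named integer vector of group sizes, default
#'   `c(A = 8, B = 8, C = 8)`.
#' @param seed Integer master seed; per-participant seeds are derived from it.
#' @param ranges Sampling-range overrides passed to [sample_participant()].
#' @return A list of class `cohort`; each element is `list(profile, events)`.
#' @export
generate_cohort <- function(design = session_design(),
                            n_per_group = c(A = 8L, B = 8L, C = 8L),
                            seed = 1L, ranges = list()) {
  groups <- rep(names(n_per_group), n_per_group)
  n <- length(groups)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * n))
  cohort <- lapply(seq_len(n), function(i) {
    prof <- sample_participant(groups[i], design, seed = seeds[i],
                               ranges = ranges,
                               participant_id = sprintf("P%02d%s", i, groups[i]))
    list(profile = prof,
         events = generate_session(prof, design, seed = seeds[n + i]))
  })
  structure(cohort, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("Cohort of", length(x), "participants (",
    paste(vapply(x, function(s) s$profile$group, ""), collapse = ""), ")\n")
  invisible(x)
}

#' Simulate binary responses for the test events of a session
#'
#' Fills the `response` column of the test events with Bernoulli draws from a
#' response model's probabilities of answering "orange" (counterclockwise).
#'
#' @param events A session data.frame from [generate_session()].
#' @param model Either a numeric vector of probabilities aligned with the rows
#'   of `events` (NA on adaptor rows), or a function `f(events)` returning
#'   such a vector, e.g. a wrapped [sequential_predict()] or
#'   [simulate_observer()].
#' @param seed Integer seed for the Bernoulli draws.
#' @return `events` with `response` filled on test rows (0 = "blue",
#'   1 = "orange"); adaptor rows unchanged.
#' @export
simulate_responses <- function(events, model, seed = NULL) {
  p <- if (is.function(model)) model(events) else model
  if (!is.numeric(p) || length(p) != nrow(events))
    stop("model must supply one probability per event row")
  it <- events$role == "test"
  pt <- p[it]
  if (anyNA(pt) || any(pt < 0 | pt > 1))
    stop("model produced probabilities outside [0, 1] for test events")
  draw <- function() rbinom(length(pt), 1L, pt)
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  events$response[it] <- r
  events
}
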