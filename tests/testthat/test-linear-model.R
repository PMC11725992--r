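test_that("influence function evaluates the ramp components", {
  lp <- linear_params(w_high = -0.2, m_high = 3, w_low = -0.1, m_low = 3)
  expect_equal(influence_function(lp, "high", S = 5),
               c(-0.2, -0.2 * 2 / 3, -0.2 / 3, 0, 0), tolerance = 1e-12)
  # zero beyond m for any component
  lp2 <- linear_params(w_high = c(-0.2, 0.05), m_high = c(3, 6),
                       w_low = -0.1, m_low = 2)
  expect_true(all(influence_function(lp2, "high", S = 10)[7:10] == 0))
  # two components sum elementwise
  a <- linear_params(w_high = -0.2, m_high = 3, w_low = 0, m_low = 1)
  b <- linear_params(w_high = 0.05, m_high = 6, w_low = 0, m_low = 1)
  expect_equal(influence_function(lp2, "high", S = 8),
               influence_function(a, "high", S = 8) +
                 influence_function(b, "high", S = 8), tolerance = 1e-12)
  expect_error(linear_params(w_high = -0.2, m_high = 0, w_low = 0, m_low = 1),
               "positive")
})

test_that("midpoint shift follows the history arithmetic", {
  lp <- linear_params(w_high = -0.2, m_high = 3, w_low = -0.2, m_low = 3,
                      gamma = 2)
  empty <- data.frame(orientation = numeric(0), midpoint = numeric(0),
                      contrast_level = character(0))
  expect_identical(midpoint_shift(empty, lp, "high", k = 1), 0)

  # one high-contrast stimulus 10 deg counterclockwise of the midpoint
  h1 <- data.frame(orientation = 10, midpoint = 0, contrast_level = "high")
  expect_equal(midpoint_shift(h1, lp, "high", k = 1), 8.7888983,
               tolerance = 1e-6)
  # the same stimulus at low contrast is halved by gamma = 2
  h2 <- data.frame(orientation = 10, midpoint = 0, contrast_level = "low")
  expect_equal(midpoint_shift(h2, lp, "high", k = 1), 4.3944492,
               tolerance = 1e-6)
  # beyond the largest m the stimulus no longer contributes
  h3 <- data.frame(orientation = c(0, 0, 0, 10), midpoint = rep(0, 4),
                   contrast_level = rep("high", 4))
  expect_identical(midpoint_shift(h3, lp, "high", k = 1), 0)
})

test_that("the psychometric function is the contrast-matched logistic", {
  prof <- canonical_profile("A")
  expect_equal(response_probability(0.3, "high", 0.3, prof), 0.5)
  expect_equal(response_probability(log(9) / prof$k_high, "high", 0, prof),
               0.9, tolerance = 1e-12)
  expect_equal(response_probability(log(9) / prof$k_low, "low", 0, prof),
               0.9, tolerance = 1e-12)
  steep <- participant_profile("s", "A", 0, k_high = 500, k_low = 250)
  expect_equal(response_probability(1, "high", 0, steep), 1, tolerance = 1e-8)
})

test_that("sequential prediction reduces to the static logistic at zero weights", {
  d <- session_design(n_stimuli = 240L)
  prof <- canonical_profile("A")
  ev <- generate_session(prof, d, seed = 21)
  lp0 <- linear_params(w_high = c(0, 0), m_high = c(2, 50),
                       w_low = c(0, 0), m_low = c(2, 50), gamma = 1.5)
  p <- sequential_predict(ev, prof, lp0)
  it <- ev$role == "test"
  k <- ifelse(grepl("^HC", ev$test_type[it]), prof$k_high, prof$k_low)
  expect_equal(p[it], plogis(k * (ev$orientation[it] - prof$c0)),
               tolerance = 1e-12)
  expect_true(all(is.na(p[!it])))
})

test_that("sequential prediction matches the R operation-level composition", {
  # independent route: influence_function + midpoint_shift + logistic,
  # tracked causally per contrast in plain R
  d <- session_design(n_stimuli = 240L)
  prof <- sample_participant("B", d, seed = 22)
  ev <- generate_session(prof, d, seed = 23)
  lp <- default_linear_params()
  hl <- ifelse(ev$contrast >= (prof$high_contrast + prof$low_contrast) / 2,
               "high", "low")
  n <- nrow(ev)
  ch <- cl <- numeric(n)
  p_ref <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    hist_idx <- rev(seq_len(t - 1L))
    hh <- data.frame(orientation = ev$orientation[hist_idx],
                     midpoint = ch[hist_idx], contrast_level = hl[hist_idx])
    llh <- data.frame(orientation = ev$orientation[hist_idx],
                      midpoint = cl[hist_idx], contrast_level = hl[hist_idx])
    ch[t] <- prof$c0 + midpoint_shift(hh, lp, "high", prof$k_high)
    cl[t] <- prof$c0 + midpoint_shift(llh, lp, "low", prof$k_low)
    if (ev$role[t] == "test") {
      ctr <- if (hl[t] == "high") "high" else "low"
      mid <- if (hl[t] == "high") ch[t] else cl[t]
      p_ref[t] <- response_probability(ev$orientation[t], ctr, mid, prof)
    }
  }
  p <- sequential_predict(ev, prof, lp, trace = TRUE)
  expect_equal(as.numeric(p), p_ref, tolerance = 1e-9)
  expect_equal(attr(p, "midpoint_high"), ch, tolerance = 1e-9)
})

test_that("negative weights repel and positive weights attract", {
  prof <- canonical_profile("A")
  base <- toy <- serialdep:::toy_stream(prof, c(10, 3), 2L)
  base$orientation[1] <- 0   # neutral history at the midpoint
  rep_p <- linear_params(w_high = -0.1, m_high = 3, w_low = -0.1, m_low = 3)
  att_p <- linear_params(w_high = 0.1, m_high = 3, w_low = 0.1, m_low = 3)
  p_rep <- sequential_predict(toy, prof, rep_p)[2]
  p_att <- sequential_predict(toy, prof, att_p)[2]
  p_neu <- sequential_predict(base, prof, rep_p)[2]
  # CCW adaptor at +10: repulsion makes a CCW test less likely "orange"
  expect_lt(p_rep, p_neu)
  expect_gt(p_att, p_neu)
})

test_that("cohort NLL matches the per-trial oracle and is order-invariant", {
  fx <- make_fixture("toy-20-trials", seed = 31)
  lp <- default_linear_params()
  s <- fx$cohort[[1]]
  it <- s$events$role == "test"
  p <- sequential_predict(s$events, s$profile, lp)[it]
  expect_equal(linear_nll(fx$cohort, lp),
               nll_oracle(p, s$events$response[it]), tolerance = 1e-10)

  # all-0.5 predictions give R ln 2
  nm <- make_fixture("null-model", seed = 32)
  lp0 <- linear_params(w_high = c(0, 0, 0), m_high = c(2, 50, 300),
                       w_low = c(0, 0, 0), m_low = c(2, 60, 350))
  expect_equal(linear_nll(nm$cohort, lp0), nm$expected$null_nll,
               tolerance = 1e-12)

  d <- session_design(n_stimuli = 240L)
  cohort <- generate_cohort(d, c(A = 1L, B = 1L, C = 1L), seed = 33)
  cohort <- lapply(cohort, function(s) {
    s$events <- simulate_responses(
      s$events, sequential_predict(s$events, s$profile, lp), seed = 34)
    s
  })
  expect_equal(linear_nll(cohort, lp), linear_nll(rev(cohort), lp),
               tolerance = 1e-12)
  # unanswered tests are an error
  cohort[[1]]$events$response[which(cohort[[1]]$events$role == "test")[1]] <- NA
  expect_error(linear_nll(cohort, lp), "response")
})

test_that("fitting improves the likelihood and recovers a null truth", {
  d <- session_design(n_stimuli = 720L)
  lp0 <- linear_params(w_high = c(0, 0), m_high = c(2, 50),
                       w_low = c(0, 0), m_low = c(2, 50), gamma = 1)
  cohort <- generate_cohort(d, c(A = 1L, B = 1L, C = 1L), seed = 41)
  cohort <- lapply(cohort, function(s) {
    s$events <- simulate_responses(
      s$events, sequential_predict(s$events, s$profile, lp0), seed = 42)
    s
  })
  init <- linear_params(w_high = c(-0.02, -0.02), m_high = c(2, 50),
                        w_low = c(-0.02, -0.02), m_low = c(2, 50), gamma = 1)
  fit <- fit_linear(cohort, init = init, starts = 2, maxit = 300)
  expect_lte(fit$nll, linear_nll(cohort, init))
  # best-so-far NLL never increases across optimisation stages
  expect_true(all(diff(fit$nll_trace) <= 1e-9))
  # null truth: small recovered weights, NLL close to the zero-weight NLL
  # (ML overfit gain is about chi^2_df / 2, df = 5 continuous parameters)
  expect_lt(max(abs(c(fit$params$w_high, fit$params$w_low))), 0.02)
  expect_lt(linear_nll(cohort, lp0) - fit$nll, 8)
  expect_equal(fit$n_params, 9L)  # 2 components per contrast
})

test_that("the nested search over integer timescales only improves the fit", {
  d <- session_design(n_stimuli = 240L)
  lp <- linear_params(w_high = c(-0.05, 0.005), m_high = c(2, 20),
                      w_low = c(-0.02, 0.005), m_low = c(2, 20), gamma = 2)
  cohort <- generate_cohort(d, c(B = 2L), seed = 43)
  cohort <- lapply(cohort, function(s) {
    s$events <- simulate_responses(
      s$events, sequential_predict(s$events, s$profile, lp), seed = 44)
    s
  })
  init <- linear_params(w_high = c(-0.02, 0), m_high = c(5, 20),
                        w_low = c(-0.02, 0), m_low = c(5, 20), gamma = 1)
  f0 <- fit_linear(cohort, init = init, starts = 1, maxit = 150)
  f1 <- fit_linear(cohort, init = init, starts = 1, maxit = 150,
                   m_rounds = 1, m_grid = c(1L, 2L, 5L, 20L))
  expect_lte(f1$nll, f0$nll + 1e-6)
  expect_true(all(diff(f1$nll_trace) <= 1e-9))
})
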