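# Independent per-trial negative log likelihood: plain loop over responses.
nll_oracle <- function(p, r, eps = 1e-9) {
  tot <- 0
  for (i in seq_along(p)) {
    pi <- min(max(p[i], eps), 1 - eps)
    tot <- tot - (r[i] * log(pi) + (1 - r[i]) * log(1 - pi))
  }
  tot
}

# Monte-Carlo oracle for P(X > Y) + P(X = Y)/2 with X ~ posterior,
# Y ~ reference, on the grid linearised around the reference circular mean.
auc_mc_oracle <- function(posterior, reference, grid, n = 4e6, seed = 99) {
  mu <- serialdep:::circular_mean_deg(reference, grid)
  d <- ((grid$values - mu + 90) %% 180) - 90
  withr::with_seed(seed, {
    x <- sample(d, n, replace = TRUE, prob = posterior)
    y <- sample(d, n, replace = TRUE, prob = reference)
    mean(x > y) + 0.5 * mean(x == y)
  })
}

# Step-by-step composition of the exported observer operations; independent
# route against the compiled sequential core.
observer_compose_R <- function(events, profile, params) {
  grid <- orientation_grid(params$grid_resolution)
  bank <- channel_bank(params$n_channels, params$kappa_phi, grid)
  reference <- von_mises_mass(grid, profile$mu_ref, profile$kappa_ref)
  prior <- rep(1 / grid$n, grid$n)
  p <- rep(NA_real_, nrow(events))
  for (t in seq_len(nrow(events))) {
    if (t > 1) {
      dt <- events$onset[t] - events$onset[t - 1] - events$duration[t - 1]
      bank <- recover_gains(bank, params$beta, max(dt, 0))
    }
    n <- channel_response(events$orientation[t], events$contrast[t], bank, params)
    kc <- serialdep:::contrast_kappa(events$contrast[t], params)
    lik <- encode_likelihood(n, bank, params$omega * events$duration[t] / 0.3,
                             kappa_c = kc)
    post <- compute_posterior(lik, prior)
    if (events$role[t] == "test")
      p[t] <- decision_probability(post, reference, grid)
    bank <- apply_adaptation(bank, n, params$alpha)
    prior <- update_prior(prior, post, params$tau)
  }
  p
}

# Circular mean of a probability mass, in degrees (orientation space).
grid_mean <- function(mass, grid) serialdep:::circular_mean_deg(mass, grid)

# Canonical noiseless participant for mechanism checks.
canonical_profile <- function(group = "C") {
  participant_profile("canon", group, c0 = 0, k_high = 0.8, k_low = 0.4,
                      mu_ref = 0, kappa_ref = 150, low_contrast = 0.08)
}

# PSE from the response probabilities at the two test orientations +off/-off,
# by inverting the two-point logistic.
pse_two_point <- function(p_plus, p_minus, off = 3) {
  lp <- qlogis(p_plus); lm <- qlogis(p_minus)
  -off * (lp + lm) / (lp - lm)
}

# Block label (1, 2, 3) for a default-design event table.
block_index <- function(events, design = session_design()) {
  third <- design$n_stimuli %/% 3L
  findInterval(events$index, c(0, third, 2L * third))
}

# Per-contrast PSE shift from block i to block ii of a simulated session,
# using model probabilities (no response noise).
block_shift <- function(events, p, contrast = "HC", design = session_design()) {
  blk <- block_index(events, design)
  avg <- function(b, ty) mean(p[events$role == "test" & blk == b &
                                  events$test_type == ty])
  pse_two_point(avg(2, paste0(contrast, "+")), avg(2, paste0(contrast, "-")),
                design$test_offset) -
    pse_two_point(avg(1, paste0(contrast, "+")), avg(1, paste0(contrast, "-")),
                  design$test_offset)
}
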