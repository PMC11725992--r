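op_default <- observer_params()
grid_default <- orientation_grid()
bank_default <- channel_bank(op_default$n_channels, op_default$kappa_phi,
                             grid_default)

test_that("channel responses follow the contrast gain and tuning width", {
  op_ci <- observer_params(variant = "CI")
  # at maximum contrast the preferred channel responds at its ceiling
  n1 <- channel_response(bank_default$mu[10], 1, bank_default, op_ci)
  expect_equal(max(n1), 1, tolerance = 1e-12)
  expect_equal(which.max(n1), 10L)
  # at the semi-saturation contrast the peak is (c50^e + 1)/2 of the c = 1
  # peak (half the unrescaled saturation asymptote)
  n50 <- channel_response(bank_default$mu[10], op_ci$c50, bank_default, op_ci)
  expect_equal(max(n50) / max(n1), (op_ci$c50^op_ci$c_exp + 1) / 2,
               tolerance = 1e-10)
  # responses vanish with contrast
  n0 <- channel_response(bank_default$mu[10], 1e-6, bank_default, op_ci)
  expect_lt(max(n0), 1e-10)
  expect_error(channel_response(0, 0, bank_default, op_ci), "contrast")
  expect_error(channel_response(0, -0.5, bank_default, op_ci), "contrast")

  # CV variant widens the response profile across channels at low contrast
  nH <- channel_response(0, 0.5, bank_default, op_default)
  nL <- channel_response(0, 0.08, bank_default, op_default)
  width <- function(n) sum(n > max(n) / 2)
  expect_gt(width(nL), width(nH))
  expect_true(all(nH >= 0 & nH <= 1) && all(nL >= 0 & nL <= 1))
})

test_that("likelihood encoding peaks at the stimulus and degenerates correctly", {
  n <- channel_response(12, 1, bank_default, op_default)
  lik <- encode_likelihood(n, bank_default, op_default$omega)
  expect_equal(grid_default$values[which.max(lik)], 12, tolerance = 0.25)
  expect_equal(sum(lik), 1, tolerance = 1e-12)
  # zero accumulation or a silent bank gives a uniform distribution
  expect_equal(encode_likelihood(n, bank_default, 0),
               rep(1 / grid_default$n, grid_default$n), tolerance = 1e-12)
  expect_equal(encode_likelihood(rep(0, 60), bank_default, op_default$omega),
               rep(1 / grid_default$n, grid_default$n), tolerance = 1e-12)
})

test_that("adaptation reduces gains geometrically and is self-constrained", {
  b <- bank_default
  expect_identical(apply_adaptation(b, rep(0, 60), 0.3)$gains, b$gains)
  b1 <- apply_adaptation(b, rep(1, 60), 0.2)
  expect_equal(b1$gains, rep(0.8, 60), tolerance = 1e-12)

  n <- channel_response(0, 0.5, b, op_default)
  bt <- b
  for (t in 1:30) {
    prev <- bt$gains
    bt <- apply_adaptation(bt, n, op_default$alpha)
    expect_true(all(bt$gains <= prev + 1e-15))
    expect_true(all(bt$gains > 0))
  }
  expect_equal(bt$gains, (1 - op_default$alpha * n)^30, tolerance = 1e-9)
  expect_error(apply_adaptation(b, n, 1), "alpha")
})

test_that("gain recovery is linear toward one and capped at full recovery", {
  b <- bank_default
  b$gains <- rep(0.5, 60)
  expect_equal(recover_gains(b, beta = 0.5, dt = 1)$gains, rep(0.75, 60))
  expect_equal(recover_gains(b, beta = 2, dt = 1)$gains, rep(1, 60))
  expect_equal(recover_gains(b, beta = 0.5, dt = 0)$gains, rep(0.5, 60))
  expect_error(recover_gains(b, beta = 0.5, dt = -1), "dt")
})

test_that("prior updating is the convex combination of prior and posterior", {
  pr <- von_mises_mass(grid_default, 0, 5)
  po <- von_mises_mass(grid_default, 20, 8)
  expect_equal(update_prior(pr, po, 0), pr)
  expect_equal(update_prior(pr, po, 1), po)
  mixed <- update_prior(pr, po, 0.3)
  expect_equal(sum(mixed), 1, tolerance = 1e-12)
  expect_equal(mixed, 0.7 * pr + 0.3 * po, tolerance = 1e-15)
  expect_error(update_prior(pr, po, 1.2), "tau")
})

test_that("posterior combination multiplies and renormalises", {
  lik <- von_mises_mass(grid_default, 5, 10)
  expect_equal(compute_posterior(lik, rep(1 / grid_default$n, grid_default$n)),
               lik, tolerance = 1e-12)
  # product of two equal von Mises masses doubles the concentration
  post <- compute_posterior(lik, lik)
  expect_equal(post, von_mises_mass(grid_default, 5, 20), tolerance = 1e-12)
  zero <- rep(0, grid_default$n)
  expect_error(compute_posterior(lik, zero), "zero")
})

test_that("decision probability is a grid ROC area with exact symmetry", {
  ref <- von_mises_mass(grid_default, 0, 150)
  expect_equal(decision_probability(ref, ref, grid_default), 0.5,
               tolerance = 1e-12)
  # all posterior mass counterclockwise of all reference mass
  d1 <- d2 <- rep(0, grid_default$n)
  d1[which(grid_default$values == 10)] <- 1
  d2[which(grid_default$values == -10)] <- 1
  expect_equal(decision_probability(d1, d2, grid_default), 1)
  expect_equal(decision_probability(d2, d1, grid_default), 0)
  expect_error(decision_probability(d1[-1], d2, grid_default), "grid")

  # Monte-Carlo oracle agreement
  post <- von_mises_mass(grid_default, 2.4, 60)
  expect_lt(abs(decision_probability(post, ref, grid_default) -
                  auc_mc_oracle(post, ref, grid_default)), 1e-3)
  wide <- von_mises_mass(grid_default, -1.3, 15)
  expect_lt(abs(decision_probability(wide, ref, grid_default) -
                  auc_mc_oracle(wide, ref, grid_default)), 1e-3)
})

test_that("an adapted bank repels the likelihood away from the adaptor", {
  b <- bank_default
  for (i in 1:5)
    b <- apply_adaptation(b, channel_response(-5.66, 0.5, b, op_default),
                          op_default$alpha)
  for (ct in c(0.5, 0.08)) {
    n <- channel_response(0, ct, bank_default, op_default)
    kc <- serialdep:::contrast_kappa(ct, op_default)
    m0 <- grid_mean(encode_likelihood(n, bank_default, op_default$omega,
                                      kappa_c = kc), grid_default)
    m1 <- grid_mean(encode_likelihood(n, b, op_default$omega, kappa_c = kc),
                    grid_default)
    # adaptor clockwise of the test: the likelihood moves counterclockwise
    expect_gt(m1, m0 + 0.05)
  }
})

test_that("a peaked prior pulls wide low-contrast likelihoods hardest", {
  prior <- 0.8 * rep(1 / grid_default$n, grid_default$n) +
    0.2 * von_mises_mass(grid_default, 15, 2)
  pull <- sapply(c(0.5, 0.08), function(ct) {
    n <- channel_response(0, ct, bank_default, op_default)
    kc <- serialdep:::contrast_kappa(ct, op_default)
    lik <- encode_likelihood(n, bank_default, op_default$omega, kappa_c = kc)
    grid_mean(compute_posterior(lik, prior), grid_default) -
      grid_mean(lik, grid_default)
  })
  expect_gt(pull[2], pull[1])   # low contrast pulled further toward the prior
  expect_gt(pull[1], 0)
})
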