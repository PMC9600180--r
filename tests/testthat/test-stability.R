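test_that("impulse response honors its closed forms", {
  p0 <- stability_params(0, 0, -1, 1)
  expect_equal(impulse_response(seq(0, 5, 0.5), p0), rep(0, 11))
  p1 <- stability_params(3.2, -0.7, -1.1, 0.9)
  expect_equal(impulse_response(0, p1), 0)
  # pure relaxation: D = 0, A = 1, phi2 = 1 -> 1 - exp(-t)
  p2 <- stability_params(0, 1, -1, 1)
  expect_equal(impulse_response(1, p2), 1 - exp(-1))
  expect_equal(impulse_response(1, p2), 0.6321, tolerance = 1e-4)
  # asymptote: x(t) -> A for decaying impulse and positive relaxation rate
  expect_equal(impulse_response(60, p1), p1$A, tolerance = 1e-8)
  # overdamped form also starts at zero and is continuous at phi1 == phi2
  expect_equal(impulse_response(0, p1, form = "overdamped"), 0)
  pa <- stability_params(2, 0.5, -1, -1 + 1e-9)
  pb <- stability_params(2, 0.5, -1, -1)
  t <- seq(0, 4, 0.5)
  expect_equal(impulse_response(t, pa, form = "overdamped"),
               impulse_response(t, pb, form = "overdamped"), tolerance = 1e-5)
})

test_that("trajectory simulation is exact in the noiseless limit and calibrated in noise", {
  p <- stability_params(3, 0.5, -1.2, 1.1)
  t <- seq(0, 5, length.out = 12)
  tr0 <- simulate_diversity_trajectory(p, t, sigma = 0, n_rep = 3, seed = 1)
  mu <- impulse_response(t, p)
  for (r in 1:3) expect_equal(unname(tr0$displacements[r, ]), mu)
  # determinism
  tr1 <- simulate_diversity_trajectory(p, t, 0.05, 4, seed = 5)
  tr2 <- simulate_diversity_trajectory(p, t, 0.05, 4, seed = 5)
  expect_identical(tr1$displacements, tr2$displacements)
  # Monte-Carlo noise variance check over 1000 draws
  trn <- simulate_diversity_trajectory(p, t, sigma = 0.3, n_rep = 1000, seed = 2)
  resid <- sweep(trn$displacements, 2, mu)
  expect_equal(var(as.vector(resid)), 0.09, tolerance = 0.015)
  expect_error(simulate_diversity_trajectory(p, numeric(0), 0.1, 2), "non-empty")
  expect_error(simulate_diversity_trajectory(p, c(1, 0.5), 0.1, 2), "increasing")
})

test_that("the fit recovers parameters from near-noiseless dense data", {
  p <- stability_params(4.0, 0.8, -1.3, 1.4)
  t <- seq(0, 5, length.out = 40)
  traj <- simulate_diversity_trajectory(p, t, sigma = 0.005, n_rep = 4, seed = 3)
  fit <- fit_stability_model(traj, fit_config(seed = 4))
  med <- apply(fit$samples, 2, median)
  expect_equal(med[["D"]], p$D, tolerance = 0.02 * p$D)
  expect_equal(med[["A"]], p$A, tolerance = 0.02 * abs(p$A))
  expect_equal(med[["phi1"]], p$phi1, tolerance = 0.02 * abs(p$phi1))
  expect_equal(med[["phi2"]], p$phi2, tolerance = 0.05 * abs(p$phi2))
  # prior-support containment
  expect_true(all(fit$samples[, "D"] >= 0 & fit$samples[, "D"] <= 10))
  expect_true(all(abs(fit$samples[, c("A", "phi1", "phi2")]) <= 2))
  expect_true(all(fit$samples[, "sigma"] > 0))
})

test_that("null data give a posterior hugging zero displacement", {
  p <- stability_params(0, 0, -1, 1)
  t <- seq(0, 5, length.out = 15)
  traj <- simulate_diversity_trajectory(p, t, sigma = 0.05, n_rep = 4, seed = 6)
  fit <- fit_stability_model(traj, fit_config(seed = 7))
  s <- posterior_summary(fit)
  expect_lt(s$lower[s$parameter == "D"], 0.3)   # D CI reaches near the boundary
  expect_true(s$lower[s$parameter == "A"] < 0 & s$upper[s$parameter == "A"] > 0)
})

test_that("doubling the noise widens every credible interval", {
  p <- stability_params(3.63, 0.70, -1.46, 1.69)
  t <- seq(0, 5, length.out = 25)
  tr_lo <- simulate_diversity_trajectory(p, t, 0.05, 4, seed = 8)
  tr_hi <- list(times = t,
                displacements = sweep(2 * sweep(tr_lo$displacements, 2,
                                                impulse_response(t, p)), 2,
                                      -impulse_response(t, p)))
  # same noise draws scaled x2 around the same curve, matched seeds
  f_lo <- fit_stability_model(tr_lo, fit_config(seed = 9))
  f_hi <- fit_stability_model(tr_hi, fit_config(seed = 9))
  w <- function(f) {
    s <- posterior_summary(f)
    setNames(s$upper - s$lower, s$parameter)
  }
  expect_true(all(w(f_hi)[c("D", "A", "phi1", "phi2")] >
                    w(f_lo)[c("D", "A", "phi1", "phi2")]))
})

test_that("replicate order does not change the posterior", {
  p <- stability_params(2, 0.5, -1, 1)
  t <- seq(0, 4, length.out = 10)
  traj <- simulate_diversity_trajectory(p, t, 0.1, 4, seed = 10)
  perm <- traj
  perm$displacements <- traj$displacements[c(3, 1, 4, 2), ]
  cfg <- fit_config(n_steps = 2000, burn_in = 500, seed = 11)
  f1 <- fit_stability_model(traj, cfg)
  f2 <- fit_stability_model(perm, cfg)
  expect_identical(f1$samples, f2$samples)
})

test_that("posterior summaries equal independently recomputed percentiles", {
  set.seed(12)
  fake <- structure(list(samples = cbind(D = rgamma(5000, 4), A = rnorm(5000),
                                         phi1 = -runif(5000), phi2 = runif(5000),
                                         sigma = rexp(5000))),
                    class = "stability_fit")
  s <- posterior_summary(fake)
  for (k in seq_len(5)) {
    q <- quantile(fake$samples[, k], c(0.025, 0.5, 0.975), names = FALSE)
    expect_equal(unlist(s[k, c("lower", "median", "upper")], use.names = FALSE),
                 q[c(1, 2, 3)])
  }
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
  expect_error(posterior_summary(structure(list(samples = fake$samples[0, ]),
                                           class = "stability_fit")), "empty")
})

test_that("posterior skewness behaves like moment skewness", {
  set.seed(13)
  sym <- structure(list(samples = cbind(A = rnorm(2e4))), class = "stability_fit")
  expect_equal(posterior_skewness(sym, "A"), 0, tolerance = 0.06)
  expo <- structure(list(samples = cbind(A = rexp(4e4))), class = "stability_fit")
  expect_equal(posterior_skewness(expo, "A"), 2, tolerance = 0.15)
  neg <- structure(list(samples = cbind(A = -expo$samples[, "A"])),
                   class = "stability_fit")
  expect_equal(posterior_skewness(neg, "A"), -posterior_skewness(expo, "A"))
  flat <- structure(list(samples = cbind(A = rep(1, 10))), class = "stability_fit")
  expect_true(is.na(posterior_skewness(flat, "A")))
})

test_that("ensemble sampler reproduces a known Gaussian target", {
  lp <- function(th) -0.5 * rowSums(th^2)
  init <- matrix(rnorm(32 * 2, 0, 0.1), 32, 2)
  ch <- ensemble_mcmc(lp, init, 3000, seed = 14)
  draws <- matrix(ch[1001:3000, , ], ncol = 2)
  expect_equal(colMeans(draws), c(0, 0), tolerance = 0.08)
  expect_equal(apply(draws, 2, sd), c(1, 1), tolerance = 0.08)
  expect_identical(ch, ensemble_mcmc(lp, init, 3000, seed = 14))
})
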