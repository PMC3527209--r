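test_that("emission histograms normalize and place mass where constructed", {
  set.seed(31)
  nw <- 50; na <- 8; nc <- 5
  mom_mean <- runif(nw, 0.008, 0.012)
  mom_sd <- runif(nw, 0.0005, 0.002)
  afr <- mom_mean + mom_sd * matrix(rnorm(nw * na), nw)
  colnames(afr) <- paste0("a", 1:na)
  # cosmopolitan self-divergence shifted about -3 SD
  cos <- mom_mean - 3 * mom_sd + 0.3 * mom_sd * matrix(rnorm(nw * nc), nw)
  colnames(cos) <- paste0("c", 1:nc)
  mom <- window_moments(afr)
  em <- build_emission_model(afr, cos, mom)
  expect_equal(sum(em$non_admixed), 1, tolerance = 1e-12)
  expect_equal(sum(em$admixed), 1, tolerance = 1e-12)
  expect_true(all(em$non_admixed >= 0) && all(em$admixed >= 0))
  # admixed mass concentrated in negative bins
  neg <- seq_len(em$n_bins / 2)
  expect_gt(sum(em$admixed[neg]), 0.9)
  expect_lt(sum(em$non_admixed[neg]), 0.75)
  # a value equal to the window mean lands in bin [0, 0.1)
  cfgd <- hmm_config()
  b0 <- cosmotracts:::.z_bin(0, cfgd)
  expect_equal(b0, em$n_bins / 2 + 1)
})

test_that("likelihood lookup floors the admixed state and clamps tails", {
  afr <- matrix(rep(c(0.01, 0.011, 0.009, 0.0095, 0.0105), 30), 30, 5,
                byrow = TRUE)
  colnames(afr) <- paste0("a", 1:5)
  cos <- matrix(rep(c(0.002, 0.0021, 0.0022), 30), 30, 3, byrow = TRUE)
  colnames(cos) <- paste0("c", 1:3)
  mom <- window_moments(afr)
  em <- build_emission_model(afr, cos, mom)
  # a z landing where admixed mass is zero gets the 0.005 floor
  lik <- window_likelihoods(rep(0.01, 30), em)
  expect_true(all(lik[, "admixed"] == 0.005))
  # missing windows are uninformative
  lik2 <- window_likelihoods(c(NA, 0.01, rep(0.01, 28)), em)
  expect_equal(unname(lik2[1, ]), c(1, 1))
  # values beyond +-5 SD clamp into terminal bins instead of erroring
  lik3 <- window_likelihoods(c(rep(0.01, 29), 10), em)
  expect_true(all(is.finite(lik3)))
  # window-count mismatch errors
  expect_error(window_likelihoods(rep(0.01, 4), em), "mismatch")
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(33)
  worst <- 0
  for (case in 1:30) {
    n <- sample(1:12, 1)
    lik <- matrix(runif(2 * n, 0.001, 1), n, 2)
    tau <- runif(1, 0.001, 0.4)
    p0 <- runif(1, 0.02, 0.95)
    fb <- forward_backward(lik, hmm_config(tau = tau, p0 = p0))
    expect_equal(fb$posterior, enum_posterior(lik, tau, p0),
                 tolerance = 1e-10)
    worst <- max(worst, max(abs(fb$posterior -
                                  enum_posterior(lik, tau, p0))))
  }
  expect_lt(worst, 1e-10)

  # single window with equal likelihoods returns the prior
  fb1 <- forward_backward(matrix(c(0.5, 0.5), 1), hmm_config(p0 = 0.3))
  expect_equal(fb1$posterior, 0.3)

  # tau -> 0 with uniform likelihoods: posterior constant across windows
  fbu <- forward_backward(matrix(1, 10, 2), hmm_config(tau = 1e-9, p0 = .2))
  expect_equal(fbu$posterior, rep(0.2, 10), tolerance = 1e-6)

  # posterior pair sums to one by construction; monotonicity in the
  # admixed likelihoods
  lik <- matrix(runif(20, 0.1, 1), 10, 2)
  base <- forward_backward(lik, hmm_config())$posterior
  lik2 <- lik; lik2[, 2] <- lik2[, 2] * 3
  up <- forward_backward(lik2, hmm_config())$posterior
  expect_true(all(up >= base - 1e-12))
})

test_that("tract calling finds runs, buffers them, and measures cM", {
  w <- build_windows(seq(50, 950, by = 100), K = 1, arm_length = 1000)
  nw <- w$n_windows
  post <- rep(0, nw)
  expect_equal(nrow(call_tracts(post, w)), 0L)

  post[5:8] <- 0.9
  map <- recombination_map("2L", pos = c(0, 1000),
                           rate = c(2e6, 2e6))  # 1 cM/bp adjusted
  tr <- call_tracts(post, w, map = map, genome = "q")
  expect_equal(tr$win_from, 5L)
  expect_equal(tr$win_to, 8L)
  expect_equal(tr$buf_start, w$start[4])
  expect_equal(tr$buf_end, w$end[9])
  expect_equal(tr$cm, (w$end[8] - w$start[5]) * 1)
  expect_equal(tr$mean_posterior, 0.9)

  # runs at the arm edge clip their buffer
  post2 <- rep(0, nw); post2[1:2] <- 1
  tr2 <- call_tracts(post2, w)
  expect_equal(tr2$buf_start, w$start[1])

  # threshold is strict: exactly 0.5 is not admixed
  post3 <- rep(0.5, nw)
  expect_equal(nrow(call_tracts(post3, w)), 0L)
})

test_that("depth correction rescales divergence multiplicatively", {
  expect_equal(depth_correction(0.01, 0.01), 1)
  expect_equal(depth_correction(0.009, 0.01), 1 / 0.9)
  expect_error(depth_correction(0, 0.01), "positive")
  # scaling commutes with windowing: scale-then-mean == mean-then-scale
  d <- runif(20, 0.001, 0.01)
  f <- depth_correction(0.008, 0.01)
  expect_equal(mean(d * f), mean(d) * f)
})

test_that("intermediate posterior fraction counts the open interval", {
  expect_equal(classify_probability_quality(c(0, 1, 1, 0)), 0)
  expect_equal(classify_probability_quality(c(0.5, 1.0)), 0.5)
  expect_equal(classify_probability_quality(list(c(0.04, 0.06),
                                                 c(0.96, 0.5))), 0.5)
  expect_error(classify_probability_quality(numeric(0)), "no posteriors")
})

test_that("age-matched transition probability behaves sensibly", {
  # short windows, recent admixture: tiny switch rate
  expect_lt(tau_from_age(100, 1e-5), 0.001)
  # old admixture saturates near 2 p0 (1 - p0)
  expect_equal(tau_from_age(1e6, 0.01), 2 * 0.1 * 0.9, tolerance = 1e-3)
  expect_lte(tau_from_age(1e9, 1), 0.45)
})
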