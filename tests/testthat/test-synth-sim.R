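# Small, fast simulation checks; the full-scale recovery runs live in
# test-acceptance.R.
small_model <- function(L = 3e4, ...) {
  demographic_model(L = L, n_african = 6L, n_cosmopolitan = 8L, ...)
}

test_that("coalescent panels honour the model's qualitative structure", {
  hs <- simulate_panels(small_model(), seed = 1)
  expect_s3_class(hs, "HaplotypeSet")
  expect_equal(n_genomes(hs), 6 + 8 + 6)   # panel + panel + donors
  expect_equal(seq_length(hs), 3e4)
  roles <- table(hs$meta$role)
  expect_equal(unname(roles["african_panel"]), 6)
  expect_equal(unname(roles["cosmopolitan_panel"]), 8)

  # theta = 0: all sequences identical
  hs0 <- simulate_panels(small_model(theta = 0), seed = 2)
  expect_true(all(hs0$seq == hs0$seq[, 1]))

  # bottleneck signature: cosmopolitan diversity below African-cosmopolitan
  # divergence in (nearly) every replicate
  wins <- 0
  for (s in 1:8) {
    h <- simulate_panels(small_model(), seed = 100 + s)
    afr <- h$meta$genome_id[h$meta$role == "african_panel"]
    cos <- h$meta$genome_id[h$meta$role == "cosmopolitan_panel"]
    pc <- attr(windowed_pi(subset_genomes(h, cos), window = 3e4),
               "arm_value")
    dac <- attr(dxy(subset_genomes(h, afr), subset_genomes(h, cos),
                    window = 3e4), "arm_value")
    if (pc < dac) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("African diversity matches the coalescent epoch-model expectation", {
  # pairwise coalescence: rate 2 per 4N time unit until the ancestral size
  # change at 0.0145, then 2 / 0.2; E[pi] = 2 theta E[T]
  a <- 0.0145; th <- 0.0376
  ET <- (1 - exp(-2 * a)) / 2 + exp(-2 * a) * (a - a + 0.2 / 2)
  expected <- 2 * th * ET
  reps <- vapply(1:6, function(s) {
    h <- simulate_panels(small_model(L = 5e4), seed = 200 + s)
    afr <- h$meta$genome_id[h$meta$role == "african_panel"]
    attr(windowed_pi(subset_genomes(h, afr), window = 5e4), "arm_value")
  }, numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - expected), 4 * se + 0.05 * expected)
})

test_that("migrant-tract simulation obeys its boundary cases", {
  # m = 0: no tracts
  tr0 <- simulate_migrant_tracts(N = 200, m = 0, g = 10, morgans = 1,
                                 n_haplotypes = 20, seed = 1)
  expect_equal(sum(vapply(tr0$tracts, nrow, 1L)), 0L)
  expect_equal(tr0$admixture, rep(0, 20))

  # forced migrants at g = 1: whole-chromosome tracts
  tr1 <- simulate_migrant_tracts(N = 100, m = 1, g = 1, morgans = 1,
                                 n_haplotypes = 10, seed = 2)
  expect_true(all(tr1$admixture == 1))
  expect_true(all(vapply(tr1$tracts, nrow, 1L) == 1L))

  # seeded reproducibility
  a <- simulate_migrant_tracts(N = 500, m = 0.1, g = 50, morgans = 0.5,
                               n_haplotypes = 10, seed = 9)
  b <- simulate_migrant_tracts(N = 500, m = 0.1, g = 50, morgans = 0.5,
                               n_haplotypes = 10, seed = 9)
  expect_identical(a$tracts, b$tracts)
})

test_that("tract lengths follow the 1/g exponential law after a pulse", {
  g <- 50
  lens <- lapply(1:10, function(r) {
    tr <- simulate_migrant_tracts(N = 5000, m = 0.01, g = g, morgans = 4,
                                  n_haplotypes = 50, seed = 130 + r,
                                  model = "pulse")
    unique(tract_lengths(tr, interior_only = TRUE))
  })
  pooled <- unlist(lens)
  expect_gt(length(pooled), 600)
  rep_means <- vapply(lens, mean, numeric(1))
  se <- sd(rep_means) / sqrt(length(rep_means))
  expect_lt(abs(mean(rep_means) - 1 / g), 4 * se + 0.02 / g)
  # interior tract lengths approximate Exp(g (1 - m)): boundaries fall
  # between migrant and native backgrounds at rate g (1 - m) per Morgan
  D <- suppressWarnings(ks.test(pooled, "pexp",
                                rate = g * (1 - 0.01)))$statistic
  expect_lt(D, 0.05)
})

test_that("splicing changes bases only inside truth intervals", {
  hs <- simulate_panels(small_model(), seed = 31)
  african <- hs$meta$genome_id[hs$meta$role == "african_panel"]
  donors <- hs$meta$genome_id[hs$meta$population == "DON"]

  # empty truth: identity
  tr0 <- simulate_migrant_tracts(N = 100, m = 0, g = 5, morgans = 0.1,
                                 n_haplotypes = 6, seed = 1, L = 3e4)
  sp0 <- splice_admixture(hs, tr0)
  expect_identical(sp0$hs$seq, hs$seq)

  # full-length tract: output equals donor
  tr_full <- tr0
  tr_full$tracts[[1]] <- cbind(start = 0, end = 0.1, bp_start = 0,
                               bp_end = 3e4)
  spf <- splice_admixture(hs, tr_full)
  expect_identical(spf$hs$seq[, african[1]], hs$seq[, donors[1]])

  # random tracts: positionwise equality against an oracle mask
  set.seed(41)
  iv <- sort(sample(0:3e4, 6))
  trr <- tr0
  trr$tracts[[2]] <- cbind(start = 0, end = 0,
                           bp_start = iv[c(1, 3, 5)],
                           bp_end = iv[c(2, 4, 6)])
  spr <- splice_admixture(hs, trr)
  inside <- logical(3e4)
  for (k in 1:3) inside[(iv[2 * k - 1] + 1):iv[2 * k]] <- TRUE
  out <- spr$hs$seq[, african[2]]
  expect_identical(out[inside], hs$seq[inside, donors[2]])
  expect_identical(out[!inside], hs$seq[!inside, african[2]])

  # interval beyond L errors
  trb <- tr0
  trb$tracts[[1]] <- cbind(start = 0, end = 1, bp_start = 10,
                           bp_end = 3e4 + 5)
  expect_error(splice_admixture(hs, trb), "beyond")
})

test_that("call scoring labels windows by majority-bp and scores edges", {
  w <- build_windows(seq(500, 9500, by = 1000), K = 1, arm_length = 1e4)
  truth <- list(tracts = list(cbind(start = 0, end = 1,
                                    bp_start = 2600, bp_end = 5400)),
                g = 10L, morgans = 1, L = 1e4, model = "pulse",
                admixture = 0.28)
  class(truth) <- "TractTruth"
  # windows 4 and 5 span [3500,4500),[4500,5500): >50% inside the tract?
  calls <- data.frame(genome = "q", arm = "arm", win_from = 3L, win_to = 5L,
                      start = 0, end = 0, buf_start = 0, buf_end = 0,
                      cm = NA, mean_posterior = 1)
  ev <- evaluate_calls(calls, truth, w, genomes = "q")
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$fpr, 0)   # window 5's span is majority-in

  # perfect and empty calls
  ev0 <- evaluate_calls(calls[0, ], truth, w, genomes = "q")
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$fpr, 0)

  # one-window shift gives boundary error 1
  shifted <- transform(calls, win_from = 4L, win_to = 6L)
  evs <- evaluate_calls(shifted, truth, w, genomes = "q")
  expect_equal(evs$boundary_error, 1)
})
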