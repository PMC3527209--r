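test_that("windowed diversity matches hand enumeration", {
  hs <- haplotype_set(c(a = "ACGT", b = "ACGA", c = "ACCA"))
  pw <- windowed_pi(hs, window = 4)
  expect_equal(pw$value, (1 + 2 + 1) / 3 / 4)

  same <- haplotype_set(c(a = "ACGT", b = "ACGT"))
  expect_equal(windowed_pi(same, window = 4)$value, 0)

  allN <- haplotype_set(c(a = "NNNN", b = "NNNN"))
  expect_true(is.na(windowed_pi(allN, window = 4)$value))
})

test_that("relative diversity weights by reference coverage", {
  mk <- function(vals, w) {
    out <- data.frame(arm = "2L", start = seq_along(vals) - 1,
                      end = seq_along(vals), value = vals, weight = w)
    class(out) <- c("WindowStat", "data.frame"); out
  }
  # pop identical to ref: ratio 1 everywhere
  r1 <- relative_pi(mk(c(0.01, 0.02), c(5, 5)), mk(c(0.01, 0.02), c(5, 5)))
  expect_equal(r1$arm_value, 1)
  # pop at exactly half of ref
  r2 <- relative_pi(mk(c(0.005, 0.01), c(5, 5)), mk(c(0.01, 0.02), c(5, 5)))
  expect_equal(r2$arm_value, 0.5)
  # heterogeneous windows against a hand-weighted computation
  pop <- mk(c(0.010, 0.030, 0.020), c(9, 9, 9))
  ref <- mk(c(0.020, 0.020, 0.010), c(100, 300, 600))
  hand <- sum(c(0.5, 1.5, 2.0) * c(100, 300, 600)) / 1000
  expect_equal(relative_pi(pop, ref)$arm_value, hand)
  # zero-diversity reference windows are skipped with a warning
  expect_warning(r4 <- relative_pi(mk(c(0.01, 0.01), c(1, 1)),
                                   mk(c(0, 0.01), c(1, 1))), "zero")
  expect_equal(r4$arm_value, 1)
  # genome-wide value is the unweighted arm mean
  expect_equal(genomewide_relative_pi(c(1, 0.5)), 0.75)
})

test_that("pi, dxy, fst, and LD match brute force on random fixtures", {
  set.seed(55)
  worst <- 0
  for (rep in 1:12) {
    na <- sample(4:10, 1); nb <- sample(4:10, 1); L <- 300
    ma <- rand_haps(na, L, poly = 0.08, miss = 0.08)
    mb <- rand_haps(nb, L, poly = 0.08, miss = 0.08)
    hsa <- chr_to_hs(ma); hsb <- chr_to_hs(mb)

    expect_equal(windowed_pi(hsa, window = L)$value, oracle_pi(ma)$pi,
                 tolerance = 1e-12)
    expect_equal(dxy(hsa, hsb, window = L)$value, oracle_dxy(ma, mb)$dxy,
                 tolerance = 1e-12)
    fst <- hudson_fst(hsa, hsb, window = L)$value
    ofst <- oracle_fst(ma, mb)
    if (!is.na(ofst)) expect_equal(fst, ofst, tolerance = 1e-12)
  }

  # populations fixed for different alleles: F_ST = 1
  fa <- chr_to_hs(matrix("A", 50, 4, dimnames = list(NULL, paste0("a", 1:4))))
  fb <- chr_to_hs(matrix("T", 50, 4, dimnames = list(NULL, paste0("b", 1:4))))
  expect_equal(hudson_fst(fa, fb, window = 50)$value, 1)

  # two fixed haplotypes differing at 1 site in 100
  h1 <- paste0(c(rep("A", 99), "T"), collapse = "")
  h2 <- paste0(rep("A", 100), collapse = "")
  expect_equal(dxy(haplotype_set(c(x = h1)), haplotype_set(c(y = h2)),
                   window = 100)$value, 0.01)
})

test_that("directional LD has the right sign and magnitude", {
  # minor alleles coupled: AB/ab/ab/ab (rows = sites, columns = haplotypes)
  m <- cbind(h1 = c("A", "A"), h2 = c("T", "T"), h3 = c("T", "T"),
             h4 = c("T", "T"))
  ld <- ld_stats(chr_to_hs(m), exclude_singletons = FALSE)
  expect_equal(ld$pairs$rw, 1)

  # repulsion: Ab/aB/ab/ab
  m2 <- cbind(h1 = c("A", "T"), h2 = c("T", "A"), h3 = c("T", "T"),
              h4 = c("T", "T"))
  ld2 <- ld_stats(chr_to_hs(m2), exclude_singletons = FALSE)
  expect_lt(ld2$pairs$rw, 0)
  expect_equal(ld2$pairs$rw, as.numeric(oracle_rw(m2[1, ], m2[2, ])))

  # random pairs match the 2x2-table oracle: enumerate the same biallelic
  # sites and check every reported pair against the oracle value
  set.seed(66)
  m3 <- rand_haps(16, 120, poly = 0.3, miss = 0.05)
  ld3 <- ld_stats(chr_to_hs(m3), exclude_singletons = FALSE,
                  dist_breaks = c(0, 120))
  vt <- call_variants(chr_to_hs(m3))
  keep <- vapply(seq_along(vt$pos), function(i) {
    al <- m3[vt$pos[i] + 1, ]
    length(unique(al[al != "N"])) == 2
  }, logical(1))
  pos <- vt$pos[keep]
  site_rows <- pos + 1
  pr <- ld3$pairs
  ok <- 0
  for (i in seq_along(pos)) for (j in seq_along(pos)) {
    if (j <= i || pos[j] - pos[i] > 120) next
    orw <- oracle_rw(m3[site_rows[i], ], m3[site_rows[j], ])
    if (is.na(orw)) next
    ok <- ok + 1
    hit <- which(pr$dist == pos[j] - pos[i])
    if (isTRUE(attr(orw, "ambiguous_sign"))) {
      expect_true(any(abs(abs(pr$rw[hit]) - abs(orw)) < 1e-12))
    } else {
      expect_true(any(abs(pr$rw[hit] - orw) < 1e-12))
    }
  }
  expect_gte(ok, 10)
})

test_that("folded SFS counts classes and matches the neutral expectation", {
  e18 <- expected_neutral_folded(18)
  expect_equal(sum(e18), 1)
  expect_equal(unname(e18[1]), 0.3078, tolerance = 5e-4)
  expect_equal(unname(expected_neutral_folded(2)), 1)
  e4 <- expected_neutral_folded(4)
  expect_equal(unname(e4), c(1 + 1 / 3, 1 / 2) / (1 + 1 / 3 + 1 / 2))

  # counting: 6 haplotypes, planted frequencies
  m <- matrix("A", 10, 6, dimnames = list(NULL, paste0("h", 1:6)))
  m[1, 1] <- "T"                        # singleton
  m[2, 1:2] <- "T"                      # doubleton
  m[3, 1:3] <- "T"                      # tripleton (n/2 class)
  m[4, 1:5] <- "T"                      # folded singleton
  m[5, 1] <- "N"                        # missing call: site dropped
  m[5, 2:3] <- "T"
  sfs <- folded_sfs(chr_to_hs(m), paste0("h", 1:6))
  expect_equal(unname(sfs$counts), c(2, 1, 1))
})

test_that("depth adjustment follows the regression-ratio closed form", {
  fit <- list(intercept = 0.002, slope = 1e-5)
  da <- depth_adjust(0.01, pop_depth = 30, ref_depth = 60, fit = fit)
  expect_equal(da$factor, (0.002 + 6e-4) / (0.002 + 3e-4))
  expect_equal(depth_adjust(0.01, 50, 50, fit)$factor, 1)
  # lm-fitted version agrees with the closed form
  d <- c(20, 40, 60, 80); y <- 0.002 + 1e-5 * d + c(0, 0, 0, 0)
  da2 <- depth_adjust(1, 20, 80, lm(y ~ d))
  expect_equal(da2$factor, (0.002 + 8e-4) / (0.002 + 2e-4))
})

test_that("bootstrap ratio test is seeded, reproducible, and sane", {
  set.seed(77)
  m <- rand_haps(16, 4000, poly = 0.05, miss = 0.02)
  a <- chr_to_hs(m[, 1:8]); b <- chr_to_hs(m[, 9:16])
  d_win <- dxy(a, b, window = 400)
  pi_win <- windowed_pi(b, window = 400)
  r1 <- dzi_pi_ratio(d_win, pi_win, n_windows = 10, reps = 2000, seed = 5)
  r2 <- dzi_pi_ratio(d_win, pi_win, n_windows = 10, reps = 2000, seed = 5)
  expect_identical(r1, r2)
  expect_gt(r1$ratio, 0.8); expect_lt(r1$ratio, 1.25)
  expect_warning(dzi_pi_ratio(d_win, pi_win, n_windows = 10, reps = 10,
                              seed = 1), "unstable")
})
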