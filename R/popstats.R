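## Windowed diversity and differentiation statistics, bootstrap
## diversity-ratio test, folded SFS, and linkage disequilibrium.

## Per-site pair-difference and called-pair counts within one population.
## Returns site vectors: pd (differing pairs), np (called pairs), k (calls).
.site_pair_stats <- function(m) {
  cnt <- base_counts(m)
  k <- rowSums(cnt)
  np <- k * (k - 1) / 2
  pd <- (k * (k - 1) - rowSums(cnt * (cnt - 1))) / 2
  list(pd = pd, np = np, k = k)
}

#' Windowed nucleotide diversity
#'
#' Per window, the mean pairwise difference per comparable site with
#' pairwise deletion per site: each site with at least two non-`N` calls
#' contributes its fraction of differing called pairs, and the window
#' value is the average over such sites.  The window weight is the number
#' of contributing sites, and the arm-wide value is the weight-weighted
#' mean.
#'
#' @param hs a `HaplotypeSet` (>= 2 genomes) for one population.
#' @param window window size in bp (default 1e5); alternatively pass
#'   explicit `breaks`.
#' @param breaks optional 0-based window breakpoints (overrides `window`).
#' @return data frame of class `WindowStat`: `arm`, `start`, `end`,
#'   `value`, `weight`; attribute `arm_value` holds the weighted mean.
#' @export
windowed_pi <- function(hs, window = 1e5, breaks = NULL) {
  stopifnot(n_genomes(hs) >= 2L)
  st <- .site_pair_stats(hs$seq)
  .windowed_ratio(st$pd / pmax(st$np, 1), st$np >= 1, seq_length(hs),
                  hs$arm, window, breaks)
}

## shared windowing helper: per-site values + usable mask -> window means
.windowed_ratio <- function(site_val, usable, L, arm, window, breaks) {
  if (is.null(breaks)) breaks <- c(seq(0, L - 1, by = window), L)
  starts <- breaks[-length(breaks)]; ends <- breaks[-1L]
  v <- ifelse(usable, site_val, 0)
  cs <- cumsum(v); cn <- cumsum(usable)
  at <- function(x, i) ifelse(i > 0, x[pmax(i, 1L)], 0)
  tot <- at(cs, ends) - at(cs, starts)
  n <- at(cn, ends) - at(cn, starts)
  out <- data.frame(arm = arm, start = starts, end = ends,
                    value = ifelse(n > 0, tot / pmax(n, 1), NA_real_),
                    weight = n, stringsAsFactors = FALSE)
  attr(out, "arm_value") <-
    if (any(n > 0)) sum(tot) / sum(n) else NA_real_
  class(out) <- c("WindowStat", "data.frame")
  out
}

#' Relative nucleotide diversity against a reference population
#'
#' Per-window ratio of the population's diversity to the reference's,
#' aggregated with the *reference* coverage weights, making the statistic
#' robust to masked blocks coinciding with unusually diverse regions.
#' Windows where the reference diversity is zero are skipped with a
#' warning.  Genome-wide values are the unweighted mean of per-arm values.
#'
#' @param pi_pop,pi_ref `WindowStat` frames from [windowed_pi()] on
#'   identical windows.
#' @return list with `windows` (data frame with `ratio`), `arm_value`
#'   (weighted mean ratio).
#' @export
relative_pi <- function(pi_pop, pi_ref) {
  stopifnot(nrow(pi_pop) == nrow(pi_ref),
            all(pi_pop$start == pi_ref$start))
  ok <- !is.na(pi_pop$value) & !is.na(pi_ref$value) & pi_ref$weight > 0
  zero <- ok & pi_ref$value == 0
  if (any(zero)) {
    warning(sum(zero), " window(s) with zero reference diversity skipped")
    ok <- ok & !zero
  }
  ratio <- ifelse(ok, pi_pop$value / pi_ref$value, NA_real_)
  win <- data.frame(arm = pi_pop$arm, start = pi_pop$start,
                    end = pi_pop$end, ratio = ratio,
                    weight = pi_ref$weight, stringsAsFactors = FALSE)
  list(windows = win,
       arm_value = sum(ratio[ok] * pi_ref$weight[ok]) /
         sum(pi_ref$weight[ok]))
}

#' Genome-wide relative diversity from per-arm values
#' @param arm_values numeric vector of per-arm relative diversities.
#' @return unweighted mean.
#' @export
genomewide_relative_pi <- function(arm_values) mean(arm_values, na.rm = TRUE)

## per-site between-population stats for two raw matrices
.site_between_stats <- function(ma, mb) {
  ca <- base_counts(ma); cb <- base_counts(mb)
  ka <- rowSums(ca); kb <- rowSums(cb)
  np <- ka * kb
  pd <- np - rowSums(ca * cb)
  list(pd = pd, np = np, ka = ka, kb = kb)
}

#' Windowed between-population divergence (D_xy)
#'
#' Mean per-site nucleotide difference over all between-population pairs,
#' with pairwise deletion per site; weighting as in [windowed_pi()].
#'
#' @param hsA,hsB `HaplotypeSet`s of the two populations on the same
#'   coordinate system.
#' @inheritParams windowed_pi
#' @return `WindowStat` data frame with attribute `arm_value`.
#' @export
dxy <- function(hsA, hsB, window = 1e5, breaks = NULL) {
  stopifnot(seq_length(hsA) == seq_length(hsB))
  st <- .site_between_stats(hsA$seq, hsB$seq)
  .windowed_ratio(st$pd / pmax(st$np, 1), st$np >= 1, seq_length(hsA),
                  hsA$arm, window, breaks)
}

#' Windowed Hudson F_ST
#'
#' `F_ST = 1 - Hw / Hb`, where `Hw` is the unweighted mean of the two
#' within-population diversities (sample-size-corrected per-site pairwise
#' diversity) and `Hb` the between-population divergence, both averaged
#' over the window's usable sites.  The two populations are weighted
#' equally regardless of sample size.  Windows with `Hb = 0` are missing;
#' negative estimates are reported as computed.
#'
#' @inheritParams dxy
#' @return `WindowStat` data frame (`value` = F_ST, `weight` = usable
#'   sites, plus `hw`, `hb`); attribute `arm_value` is
#'   `1 - sum(Hw)/sum(Hb)` over the arm.
#' @export
hudson_fst <- function(hsA, hsB, window = 1e5, breaks = NULL) {
  stopifnot(n_genomes(hsA) >= 2L, n_genomes(hsB) >= 2L,
            seq_length(hsA) == seq_length(hsB))
  sa <- .site_pair_stats(hsA$seq)
  sb <- .site_pair_stats(hsB$seq)
  ab <- .site_between_stats(hsA$seq, hsB$seq)
  usable <- sa$np >= 1 & sb$np >= 1 & ab$np >= 1
  hw_site <- (sa$pd / pmax(sa$np, 1) + sb$pd / pmax(sb$np, 1)) / 2
  hb_site <- ab$pd / pmax(ab$np, 1)
  L <- seq_length(hsA)
  if (is.null(breaks)) breaks <- c(seq(0, L - 1, by = window), L)
  starts <- breaks[-length(breaks)]; ends <- breaks[-1L]
  at <- function(x, i) ifelse(i > 0, x[pmax(i, 1L)], 0)
  wsum <- function(v) {
    cs <- cumsum(ifelse(usable, v, 0)); at(cs, ends) - at(cs, starts)
  }
  hw <- wsum(hw_site); hb <- wsum(hb_site); n <- wsum(rep(1, L))
  fst <- ifelse(n > 0 & hb > 0, 1 - hw / hb, NA_real_)
  out <- data.frame(arm = hsA$arm, start = starts, end = ends,
                    value = fst, weight = n,
                    hw = ifelse(n > 0, hw / pmax(n, 1), NA_real_),
                    hb = ifelse(n > 0, hb / pmax(n, 1), NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "arm_value") <- if (sum(hb) > 0) 1 - sum(hw) / sum(hb)
  else NA_real_
  class(out) <- c("WindowStat", "data.frame")
  out
}

#' Bootstrap test of the divergence-to-diversity ratio
#'
#' Tests whether a population carries diversity not present in a maximally
#' diverse reference: the ratio of the population's mean divergence from
#' the reference (`D`) to the reference's own diversity, with window
#' bootstrap.  Windows are resampled with replacement (`n_windows` draws
#' per replicate, 667 by default, matching the number of mid-chromosomal
#' 100-kb windows); the P value is the fraction of replicates with ratio
#' below one.
#'
#' @param d_win `WindowStat` frame of between-population divergence
#'   ([dxy()] of population vs reference).
#' @param pi_win `WindowStat` frame of reference diversity on the same
#'   windows.
#' @param n_windows windows drawn per replicate (default 667).
#' @param reps bootstrap replicates (default 1e4; the full-scale analysis
#'   uses 1e6).
#' @param seed integer seed.
#' @param depth_factor optional multiplicative depth correction applied
#'   to the ratio (see [depth_adjust()]).
#' @return list with `ratio`, `p_value`, `reps`.
#' @export
dzi_pi_ratio <- function(d_win, pi_win, n_windows = 667L, reps = 1e4,
                         seed = 1L, depth_factor = 1) {
  stopifnot(nrow(d_win) == nrow(pi_win))
  if (reps < 1000) warning("fewer than 1000 replicates: unstable P value")
  ok <- !is.na(d_win$value) & !is.na(pi_win$value) & pi_win$weight > 0
  dv <- d_win$value[ok] * d_win$weight[ok]
  dw <- d_win$weight[ok]
  pv <- pi_win$value[ok] * pi_win$weight[ok]
  pw <- pi_win$weight[ok]
  nw <- sum(ok)
  if (!nw) stop("no usable windows")
  ratio <- (sum(dv) / sum(dw)) / (sum(pv) / sum(pw)) * depth_factor
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(nw, n_windows * reps, replace = TRUE),
                nrow = reps)
  rsum <- function(v) {
    mm <- matrix(v[idx], nrow = reps)
    rowSums(mm)
  }
  rratio <- (rsum(dv) / rsum(dw)) / (rsum(pv) / rsum(pw)) * depth_factor
  list(ratio = ratio, p_value = mean(rratio < 1), reps = reps)
}

#' Depth-based correction factor for divergence summaries
#'
#' From a linear regression of per-genome sequencing depth against
#' divergence from a reference, the predicted divergence at the reference
#' population's mean depth and at the target population's mean depth give
#' a multiplicative correction `predicted(ref) / predicted(pop)`.
#'
#' @param observed observed summary value(s).
#' @param pop_depth,ref_depth mean sequencing depths.
#' @param fit an `lm` fit of divergence on depth, or a list/vector with
#'   `intercept` and `slope`.
#' @return list with `corrected`, `factor`.
#' @export
depth_adjust <- function(observed, pop_depth, ref_depth, fit) {
  if (inherits(fit, "lm")) {
    b <- coef(fit)[1L]; s <- coef(fit)[2L]
  } else {
    b <- fit[["intercept"]]; s <- fit[["slope"]]
  }
  fac <- (b + s * ref_depth) / (b + s * pop_depth)
  list(corrected = observed * fac, factor = unname(fac))
}

#' Folded site frequency spectrum of a panel
#'
#' Counts minor-allele classes `i = 1..floor(n/2)` over sites where all
#' `n` panel genomes are called (fixed-n filtering); sites that are
#' monomorphic within the panel are ignored.  Sites with more than two
#' alleles contribute their minor count over all non-major alleles.
#'
#' @param hs a `HaplotypeSet` (or raw matrix).
#' @param panel genome ids (all must be called at a site for it to
#'   count); `n = length(panel)`.
#' @param sites optional `IntervalSet` restricting the analysed positions
#'   (e.g. short-intron sites).
#' @return object of class `SFS`: list with `n`, `counts` (named vector
#'   over classes 1..n/2) and `n_sites`.
#' @export
folded_sfs <- function(hs, panel, sites = NULL) {
  m <- if (inherits(hs, "HaplotypeSet")) hs$seq else hs
  m <- m[, panel, drop = FALSE]
  if (!is.null(sites)) {
    idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e), sites$start,
                         sites$end, SIMPLIFY = FALSE), use.names = FALSE)
    m <- m[idx, , drop = FALSE]
  }
  n <- length(panel)
  stopifnot(n >= 2L)
  cnt <- base_counts(m)
  full <- rowSums(cnt) == n
  major <- apply(cnt, 1L, max)
  minor <- n - major
  seg <- full & minor >= 1L
  counts <- tabulate(pmin(minor[seg], n - minor[seg]), nbins = n %/% 2L)
  names(counts) <- seq_len(n %/% 2L)
  structure(list(n = n, counts = counts, n_sites = sum(seg)),
            class = "SFS")
}

#' Neutral-equilibrium expectation of the folded SFS
#'
#' Class probabilities for minor-allele count `i` under the standard
#' neutral coalescent: proportional to `1/i + 1/(n-i)`, halved when
#' `i = n - i`, normalized over `i = 1..floor(n/2)`.  At `n = 18` the
#' singleton class is 0.3078 (the 31% null expectation).
#'
#' @param n sample size (>= 2).
#' @return named numeric vector of class probabilities summing to one.
#' @export
expected_neutral_folded <- function(n) {
  stopifnot(n >= 2)
  i <- seq_len(n %/% 2)
  w <- (1 / i + 1 / (n - i)) / (1 + (i == n - i))
  setNames(w / sum(w), i)
}

#' @export
print.SFS <- function(x, ...) {
  cat("Folded SFS: n = ", x$n, ", ", x$n_sites, " segregating site(s); ",
      "singletons ", round(100 * x$counts[1L] / max(1, sum(x$counts)), 1),
      "%\n", sep = "")
  invisible(x)
}

#' Linkage disequilibrium: r-squared and directional r_omega
#'
#' For pairs of biallelic sites, `r` is the correlation of minor-allele
#' indicators over haplotypes called at both sites (pairwise deletion for
#' `N`); `r_omega` is this signed correlation (positive when minor
#' alleles co-occur on the same haplotype, i.e. coupling), and
#' `r^2` its square.  Pairs where either site is monomorphic after
#' deletion are skipped; singleton sites can be excluded.
#'
#' @param hs a `HaplotypeSet` (or raw matrix).
#' @param vt optional precomputed [call_variants()]; biallelic sites only
#'   are used.
#' @param max_pairs cap on the number of site pairs per distance bin
#'   evaluation (pairs are enumerated up to `max_dist`).
#' @param max_dist maximum pair distance in bp (default 10 kb).
#' @param dist_breaks distance bin breakpoints in bp.
#' @param exclude_singletons drop sites whose minor-allele count is 1
#'   (default `TRUE`).
#' @return list with `pairs` (per-pair `dist`, `r2`, `rw`) and `bins`
#'   (per-bin mean `r2`, mean `rw`, mean positive and negative `rw`,
#'   pair count).
#' @export
ld_stats <- function(hs, vt = NULL, max_pairs = 2e5, max_dist = 1e4,
                     dist_breaks = c(0, 100, 250, 500, 1000, 2500, 5000,
                                     1e4),
                     exclude_singletons = TRUE) {
  if (is.null(vt)) vt <- call_variants(hs)
  m <- vt$alleles
  cnt <- base_counts(m)
  biallelic <- rowSums(cnt > 0L) == 2L
  n_called <- rowSums(cnt)
  minor <- n_called - apply(cnt, 1L, max)
  keep <- biallelic & (!exclude_singletons | minor >= 2L)
  m <- m[keep, , drop = FALSE]
  pos <- vt$pos[keep]
  cnt <- cnt[keep, , drop = FALSE]
  ns <- nrow(m)
  if (ns < 2L) stop("fewer than two usable sites")
  ## minor-allele indicator with NA for missing
  minor_base <- .BASES[apply(cnt, 1L, which.min4)]
  ind <- matrix(NA_real_, ns, ncol(m))
  for (s in seq_len(ns)) {
    row <- m[s, ]
    v <- as.numeric(row == minor_base[s])
    v[row == .RAW_N] <- NA
    ind[s, ] <- v
  }
  ## enumerate pairs within max_dist
  p1 <- integer(0); p2 <- integer(0)
  for (i in seq_len(ns - 1L)) {
    j <- which(pos > pos[i] & pos - pos[i] <= max_dist)
    j <- j[j > i]
    if (length(j)) { p1 <- c(p1, rep(i, length(j))); p2 <- c(p2, j) }
    if (length(p1) >= max_pairs) break
  }
  if (length(p1) > max_pairs) { p1 <- p1[seq_len(max_pairs)]
    p2 <- p2[seq_len(max_pairs)] }
  rw <- vapply(seq_along(p1), function(k) {
    x <- ind[p1[k], ]; y <- ind[p2[k], ]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L || !sd(x) || !sd(y)) return(NA_real_)
    ## re-fold to minor allele within the complete haplotypes
    if (mean(x) > 0.5) x <- 1 - x
    if (mean(y) > 0.5) y <- 1 - y
    cor(x, y)
  }, numeric(1))
  dist <- pos[p2] - pos[p1]
  ok <- !is.na(rw)
  pairs <- data.frame(dist = dist[ok], r2 = rw[ok]^2, rw = rw[ok])
  bin <- cut(pairs$dist, dist_breaks, include.lowest = TRUE)
  agg <- function(f) tapply(seq_len(nrow(pairs)), bin, function(ii)
    f(pairs[ii, , drop = FALSE]))
  bins <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_r2 = as.numeric(agg(function(p) mean(p$r2))),
    mean_rw = as.numeric(agg(function(p) mean(p$rw))),
    mean_rw_pos = as.numeric(agg(function(p)
      if (any(p$rw > 0)) mean(p$rw[p$rw > 0]) else NA_real_)),
    mean_rw_neg = as.numeric(agg(function(p)
      if (any(p$rw < 0)) mean(p$rw[p$rw < 0]) else NA_real_)))
  list(pairs = pairs, bins = bins)
}

## index of the least-frequent *present* base (for minor-base lookup)
which.min4 <- function(v) {
  v2 <- ifelse(v > 0, v, Inf)
  which.min(v2)
}
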