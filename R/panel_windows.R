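## Variant columns, panel non-singleton SNPs, SNP-count windows, and
## per-window pairwise divergence profiles with their moments.

#' Call variant columns of a HaplotypeSet
#'
#' A site is variant iff at least two distinct non-`N` bases occur among
#' the genomes; `N` is missing data.  Returns per-site base counts so that
#' downstream panel filters can be recomputed without rescanning the
#' sequences.
#'
#' @param hs a `HaplotypeSet` with at least two genomes.
#' @return an object of class `VariantTable`: list with `arm`, `pos`
#'   (0-based site positions, strictly increasing), `alleles` (raw matrix
#'   sites x genomes) and `n_genomes`.
#' @export
call_variants <- function(hs) {
  stopifnot(n_genomes(hs) >= 2L)
  m <- hs$seq
  cnt <- base_counts(m)
  nalleles <- rowSums(cnt > 0L)
  keep <- which(nalleles >= 2L)
  structure(list(arm = hs$arm, pos = keep - 1L,
                 alleles = m[keep, , drop = FALSE],
                 n_genomes = ncol(m)),
            class = "VariantTable")
}

#' @export
print.VariantTable <- function(x, ...) {
  cat("VariantTable: arm ", x$arm, ", ", length(x$pos), " variant site(s), ",
      x$n_genomes, " genome(s)\n", sep = "")
  invisible(x)
}

## per-site counts of A,C,G,T over a raw matrix (positions x genomes)
base_counts <- function(m) {
  cbind(A = rowSums(m == .BASES[1L]),
        C = rowSums(m == .BASES[2L]),
        G = rowSums(m == .BASES[3L]),
        T = rowSums(m == .BASES[4L]))
}

#' Panel non-singleton SNP positions
#'
#' Restricts a `VariantTable` to sites that are polymorphic within the
#' given panel with a panel minor-allele count of at least `min_minor`
#' (2 by default, i.e. non-singleton), counted over non-missing panel
#' calls.  These sites are the windowing currency for the admixture HMM
#' and the outlier scans.
#'
#' @param vt a [call_variants()] result.
#' @param panel genome ids defining the panel.
#' @param min_minor minimum panel minor-allele count (default 2).
#' @return numeric vector of 0-based site positions.
#' @export
nonsingleton_sites <- function(vt, panel, min_minor = 2L) {
  if (!length(panel)) stop("empty panel")
  idx <- match(panel, colnames(vt$alleles))
  if (anyNA(idx)) stop("panel ids absent from variant table")
  cnt <- base_counts(vt$alleles[, idx, drop = FALSE])
  ord <- apply(cnt, 1L, sort, decreasing = TRUE)   # 4 x sites
  minor <- colSums(ord[-1L, , drop = FALSE])       # all but the major allele
  vt$pos[ord[2L, ] > 0L & minor >= min_minor]
}

#' Build SNP-count windows along an arm
#'
#' Consecutive blocks of `K` panel SNPs.  Window bp spans are
#' `[first SNP, next window's first SNP)`, with the first window extended
#' to the arm start and the last to the arm end, so spans partition the
#' arm exactly.  A trailing remainder of fewer than `K` SNPs is merged
#' into the final window.
#'
#' @param sites ascending 0-based SNP positions.
#' @param K SNPs per window.
#' @param arm_length arm length in bp.
#' @param arm arm label.
#' @return an object of class `WindowSet`: data-frame-like list with
#'   `start`, `end`, `n_snps` per window plus `arm`, `K`.
#' @export
build_windows <- function(sites, K, arm_length, arm = "arm") {
  stopifnot(K >= 1L)
  n <- length(sites)
  if (!n) stop("no sites to window")
  if (is.unsorted(sites, strictly = TRUE)) stop("sites must be ascending")
  nw <- max(1L, n %/% K)
  first <- sites[(seq_len(nw) - 1L) * K + 1L]
  start <- c(0, first[-1L])
  end <- c(first[-1L], arm_length)
  n_snps <- c(rep(K, nw - 1L), n - (nw - 1L) * K)
  structure(list(arm = arm, start = start, end = end, n_snps = n_snps,
                 K = K, arm_length = arm_length, n_windows = nw),
            class = "WindowSet")
}

#' @export
print.WindowSet <- function(x, ...) {
  cat("WindowSet: arm ", x$arm, ", ", x$n_windows, " window(s) of K = ",
      x$K, " SNPs, median span ", round(median(x$end - x$start)), " bp\n",
      sep = "")
  invisible(x)
}

#' @export
as.data.frame.WindowSet <- function(x, ...) {
  data.frame(arm = x$arm, window = seq_len(x$n_windows), start = x$start,
             end = x$end, n_snps = x$n_snps)
}

#' Pairwise divergence between two haploid sequences
#'
#' Counts differences over comparable sites (both bases not `N`).
#'
#' @param a,b raw vectors (or single characters strings) of equal length.
#' @param start,end optional 0-based half-open sub-interval.
#' @return list with `diffs`, `n_sites` (comparable sites) and `d`
#'   (`diffs / n_sites`; `NA` if no comparable site).
#' @export
pairwise_divergence <- function(a, b, start = NULL, end = NULL) {
  if (is.character(a)) a <- charToRaw(a)
  if (is.character(b)) b <- charToRaw(b)
  stopifnot(length(a) == length(b))
  if (!is.null(start)) {
    stopifnot(start >= 0, end <= length(a), start < end)
    a <- a[(start + 1L):end]; b <- b[(start + 1L):end]
  }
  comp <- a != .RAW_N & b != .RAW_N
  diffs <- sum(comp & (a != b))
  n <- sum(comp)
  list(diffs = diffs, n_sites = n, d = if (n) diffs / n else NA_real_)
}

## Per-window difference and comparable-site counts for one pair of raw
## vectors, over the windows' bp breakpoints.  Vectorized workhorse.
pair_window_counts <- function(a, b, start, end) {
  comp <- a != .RAW_N & b != .RAW_N
  dif <- comp & (a != b)
  cs <- cumsum(dif); cn <- cumsum(comp)
  at <- function(v, i) ifelse(i > 0, v[pmax(i, 1L)], 0)
  list(diffs = at(cs, end) - at(cs, start),
       n_sites = at(cn, end) - at(cn, start))
}

#' Per-window divergence profile of a query genome against a panel
#'
#' For each window, the mean over panel members of the per-pair divergence
#' per comparable site; pairs with fewer than `min_sites` comparable sites
#' in a window are dropped, and the window value is missing when no pair
#' remains.  If the query belongs to the panel it is excluded from its own
#' comparisons (leave-one-out), which is how the cosmopolitan
#' self-comparison profiles are formed.
#'
#' @param hs `HaplotypeSet` containing query and panel.
#' @param query genome id.
#' @param panel character vector of panel genome ids.
#' @param windows a [build_windows()] result.
#' @param min_sites minimum comparable sites per pair per window
#'   (default 100).
#' @return an object of class `DivergenceProfile`: list with `genome`,
#'   `d` (per-window mean divergence, `NA` where missing), `n_sites`
#'   (mean comparable sites over used pairs).
#' @export
divergence_profile <- function(hs, query, panel, windows, min_sites = 100L) {
  panel <- setdiff(panel, query)
  if (!length(panel)) stop("panel empty after excluding query")
  q <- hs$seq[, query]
  nw <- windows$n_windows
  ## bp breakpoints as site indices (1-based cumulative positions)
  s <- as.integer(windows$start); e <- as.integer(windows$end)
  dsum <- matrix(0, nw, length(panel))
  nsum <- matrix(0, nw, length(panel))
  for (j in seq_along(panel)) {
    pc <- pair_window_counts(q, hs$seq[, panel[j]], s, e)
    dsum[, j] <- pc$diffs
    nsum[, j] <- pc$n_sites
  }
  ok <- nsum >= min_sites
  dmat <- ifelse(ok, dsum / nsum, NA)
  d <- rowMeans(dmat, na.rm = TRUE)
  d[!rowSums(ok)] <- NA_real_
  structure(list(genome = query, d = d,
                 n_sites = rowMeans(ifelse(ok, nsum, NA), na.rm = TRUE)),
            class = "DivergenceProfile")
}

#' Divergence profiles for many queries at once
#'
#' @inheritParams divergence_profile
#' @param queries genome ids; each is profiled against `panel` (with
#'   leave-one-out when the query is a panel member).
#' @return matrix windows x queries of per-window mean divergence.
#' @export
divergence_profiles <- function(hs, queries, panel, windows,
                                min_sites = 100L) {
  out <- vapply(queries, function(q)
    divergence_profile(hs, q, panel, windows, min_sites)$d,
    numeric(windows$n_windows))
  matrix(out, nrow = windows$n_windows, ncol = length(queries),
         dimnames = list(NULL, queries))
}

#' Per-window moments of the African-panel divergence distribution
#'
#' Sample mean and SD (n-1 denominator) over African panel members of
#' their per-window divergence from the cosmopolitan panel.  Windows with
#' fewer than two non-missing values or zero SD are flagged degenerate
#' (kept, not dropped); degenerate windows emit uninformative likelihoods
#' downstream.
#'
#' @param profiles windows x members matrix from [divergence_profiles()].
#' @return object of class `WindowMoments`: list with `mean`, `sd`,
#'   `degenerate` (logical), `n` per window.
#' @export
window_moments <- function(profiles) {
  n <- rowSums(!is.na(profiles))
  mu <- rowMeans(profiles, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  sdv <- apply(profiles, 1L, sd, na.rm = TRUE)
  degenerate <- n < 2L | is.na(sdv) | sdv == 0
  structure(list(mean = mu, sd = sdv, degenerate = degenerate, n = n),
            class = "WindowMoments")
}

#' Genome-wide mean divergence of each genome from the rest of a panel
#'
#' Whole-arm average pairwise divergence of each listed genome from the
#' remaining panel members (leave-one-out), used both for the depth
#' correction proxy and for summary tables.
#'
#' @param hs a `HaplotypeSet`.
#' @param ids genome ids to evaluate.
#' @param panel panel ids (defaults to `ids`).
#' @return named numeric vector of mean divergences.
#' @export
panel_self_divergence <- function(hs, ids, panel = ids) {
  vapply(ids, function(g) {
    others <- setdiff(panel, g)
    ds <- vapply(others, function(o)
      pairwise_divergence(hs$seq[, g], hs$seq[, o])$d, numeric(1))
    mean(ds, na.rm = TRUE)
  }, numeric(1))
}
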