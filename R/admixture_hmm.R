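## Two-state admixture HMM: empirical emission histograms over standardized
## divergence, per-window state likelihoods, forward-backward posterior
## decoding, tract calling, and iterative refinement of the African panel.

#' HMM configuration
#'
#' @param tau per-window state-switch probability of the symmetric
#'   transition matrix (stay `1 - tau`).
#' @param p0 initial prior probability of the admixed state.
#' @param floor minimum admixture likelihood applied at lookup, damping
#'   the influence of any single unusual window (default 0.005).
#' @param floor_admixed_only apply the floor to the admixed state only
#'   (default `TRUE`, so that windows falling in empty non-admixed bins
#'   carry unbounded evidence for admixture; set `FALSE` to floor both
#'   states, trading sensitivity to short tracts for robustness).
#' @param threshold posterior probability above which a window is called
#'   admixed (default 0.5).
#' @param rounds refinement rounds (default 3).
#' @param bin_width emission histogram bin width in SDs (default 0.1).
#' @param z_range standardized values beyond +/- this many SDs fall into
#'   the terminal bins (default 5).
#' @return a list of class `HMMConfig`.
#' @export
hmm_config <- function(tau = 0.005, p0 = 0.1, floor = 0.005,
                       floor_admixed_only = TRUE, threshold = 0.5,
                       rounds = 3L, bin_width = 0.1, z_range = 5) {
  stopifnot(tau > 0, tau < 1, p0 > 0, p0 < 1, floor >= 0, threshold > 0,
            threshold < 1, rounds >= 1, bin_width > 0, z_range > 0)
  structure(list(tau = tau, p0 = p0, floor = floor,
                 floor_admixed_only = floor_admixed_only,
                 threshold = threshold, rounds = as.integer(rounds),
                 bin_width = bin_width, z_range = z_range),
            class = "HMMConfig")
}

#' Transition probability matched to an expected admixture age
#'
#' The per-window state-switch probability implied by tract structure of
#' age `g`: ancestry breakpoints accrue at rate `g` per Morgan, so the
#' probability that adjacent windows differ in state is approximately
#' `2 p0 (1 - p0) (1 - exp(-g * w))` for window genetic length `w` and
#' stationary admixed fraction `p0`.  Useful when the admixture age of
#' interest is roughly known (e.g. in validation runs); capped into
#' (1e-6, 0.45).
#'
#' @param g generations since admixture.
#' @param window_morgans genetic length of one window in Morgans.
#' @param p0 admixed fraction.
#' @return switch probability.
#' @export
tau_from_age <- function(g, window_morgans, p0 = 0.1) {
  min(max(2 * p0 * (1 - p0) * (1 - exp(-g * window_morgans)), 1e-6), 0.45)
}

## bin index of standardized value z under a config (clamped tails)
.z_bin <- function(z, cfg) {
  nb <- 2L * as.integer(round(cfg$z_range / cfg$bin_width))
  i <- floor(z / cfg$bin_width) + nb / 2L + 1L
  pmin(pmax(i, 1L), nb)
}

#' Build the empirical emission model for one arm
#'
#' The non-admixed state pools, over all windows and all African panel
#' members, the divergence of each member from the cosmopolitan panel,
#' standardized by that window's mean and SD of the same quantity.  The
#' admixed state pools the leave-one-out self-divergence of each
#' cosmopolitan panel member, standardized by the *same* (African-panel)
#' window moments.  Both are binned at `bin_width` SDs and normalized to
#' sum to one; the likelihood floor is applied at lookup, not here.
#'
#' @param african_profiles windows x members matrix of African-panel
#'   divergence from the cosmopolitan panel ([divergence_profiles()]).
#' @param cosmopolitan_profiles windows x members matrix of leave-one-out
#'   cosmopolitan self-divergence.
#' @param moments [window_moments()] of `african_profiles`.
#' @param cfg an [hmm_config()].
#' @return object of class `EmissionModel`: normalized histograms
#'   `non_admixed`, `admixed` over the shared bin grid, plus `moments`
#'   and `cfg`.
#' @export
build_emission_model <- function(african_profiles, cosmopolitan_profiles,
                                 moments, cfg = hmm_config()) {
  usable <- !moments$degenerate
  if (!any(usable)) stop("all windows degenerate; cannot build emissions")
  if (mean(usable) < 0.5)
    warning("more than half of windows degenerate; emissions may be poor")
  nb <- 2L * as.integer(round(cfg$z_range / cfg$bin_width))
  pool <- function(profiles) {
    z <- (profiles - moments$mean) / moments$sd
    z <- z[usable, , drop = FALSE]
    z <- z[!is.na(z)]
    if (!length(z)) stop("no usable standardized values")
    tabulate(.z_bin(z, cfg), nbins = nb) / length(z)
  }
  structure(list(non_admixed = pool(african_profiles),
                 admixed = pool(cosmopolitan_profiles),
                 moments = moments, cfg = cfg, n_bins = nb),
            class = "EmissionModel")
}

#' @export
print.EmissionModel <- function(x, ...) {
  mid <- function(h) sum(h * (seq_along(h) - 0.5 - x$n_bins / 2)) * x$cfg$bin_width
  cat("EmissionModel: ", x$n_bins, " bins of ", x$cfg$bin_width,
      " SD; state means ", round(mid(x$non_admixed), 2), " (non-admixed), ",
      round(mid(x$admixed), 2), " (admixed) SD\n", sep = "")
  invisible(x)
}

#' Depth correction factor for a query genome
#'
#' Sequencing depth depresses observed divergence; as a proxy for quality
#' effects, a genome's average divergence from the rest of the African
#' panel (`d_self`) is compared to the panel average, and its divergence
#' from the cosmopolitan panel is multiplied by
#' `panel_mean / d_self` before standardization.  Computed per arm.
#'
#' @param d_self query genome's mean divergence from the rest of the
#'   African panel on this arm.
#' @param panel_mean African panel average of the same quantity.
#' @return multiplicative correction factor.
#' @export
depth_correction <- function(d_self, panel_mean) {
  if (any(d_self <= 0)) stop("query self-divergence must be positive")
  panel_mean / d_self
}

#' Per-window state likelihoods for a query profile
#'
#' Standardizes the query's per-window divergence with the model's window
#' moments, looks up the histogram mass of each state's emission bin, and
#' floors likelihoods at `cfg$floor`.  Windows with missing divergence or
#' degenerate moments emit `(1, 1)` (uninformative).
#'
#' @param d per-window query divergence from the cosmopolitan panel
#'   (optionally depth-corrected).
#' @param model an [build_emission_model()] result.
#' @return matrix windows x 2 (`non_admixed`, `admixed`).
#' @export
window_likelihoods <- function(d, model) {
  mom <- model$moments
  if (length(d) != length(mom$mean))
    stop("window count mismatch between profile and model")
  cfg <- model$cfg
  lik <- matrix(1, length(d), 2L,
                dimnames = list(NULL, c("non_admixed", "admixed")))
  ok <- !is.na(d) & !mom$degenerate
  if (any(ok)) {
    z <- (d[ok] - mom$mean[ok]) / mom$sd[ok]
    b <- .z_bin(z, cfg)
    l0 <- model$non_admixed[b]
    l1 <- model$admixed[b]
    ## bins never seen in either pool carry no information
    void <- l0 == 0 & l1 == 0
    l1 <- pmax(l1, cfg$floor)
    if (!cfg$floor_admixed_only) l0 <- pmax(l0, cfg$floor)
    l0[void] <- 1; l1[void] <- 1
    lik[ok, 1L] <- l0
    lik[ok, 2L] <- l1
  }
  lik
}

#' Forward-backward posterior decoding of the two-state chain
#'
#' Exact marginal posterior probabilities of the admixed state under a
#' symmetric transition matrix (stay `1 - tau`, switch `tau`) and initial
#' distribution `(1 - p0, p0)`, with per-window scaling against
#' underflow.
#'
#' @param lik windows x 2 likelihood matrix (`non_admixed`, `admixed`).
#' @param cfg an [hmm_config()].
#' @return object of class `PosteriorTrack`: list with `posterior`
#'   (admixed-state probability per window), `lik`, and `loglik` of the
#'   observation sequence.
#' @export
forward_backward <- function(lik, cfg = hmm_config()) {
  lik <- as.matrix(lik)
  n <- nrow(lik)
  stopifnot(n >= 1L, ncol(lik) == 2L)
  A <- matrix(c(1 - cfg$tau, cfg$tau, cfg$tau, 1 - cfg$tau), 2L, 2L)
  init <- c(1 - cfg$p0, cfg$p0)
  fwd <- matrix(0, n, 2L)
  scl <- numeric(n)
  a <- init * lik[1L, ]
  scl[1L] <- sum(a)
  fwd[1L, ] <- a / scl[1L]
  if (n > 1L) for (t in 2:n) {
    a <- (fwd[t - 1L, ] %*% A) * lik[t, ]
    scl[t] <- sum(a)
    fwd[t, ] <- a / scl[t]
  }
  bwd <- matrix(0, n, 2L)
  bwd[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    b <- A %*% (lik[t + 1L, ] * bwd[t + 1L, ])
    bwd[t, ] <- b / scl[t + 1L]
  }
  g <- fwd * bwd
  g <- g / rowSums(g)
  structure(list(posterior = g[, 2L], lik = lik, loglik = sum(log(scl))),
            class = "PosteriorTrack")
}

#' Call admixture tracts from a posterior track
#'
#' Maximal runs of windows with admixed-state posterior above the
#' threshold become tracts.  Each tract records its core window span, the
#' buffered bp span (one extra window each side, clipped to the arm; used
#' for masking), the genetic length of the *core* span (buffers excluded),
#' and the mean core posterior.
#'
#' @param track a [forward_backward()] result (or numeric posteriors).
#' @param windows the [build_windows()] window set.
#' @param map optional [recombination_map()] for cM lengths.
#' @param genome genome id recorded on the tracts.
#' @param threshold posterior threshold (default 0.5).
#' @return data frame of tracts: `genome`, `arm`, `win_from`, `win_to`
#'   (1-based window indices), `start`, `end` (core bp span),
#'   `buf_start`, `buf_end` (buffered bp span), `cm` (core genetic
#'   length; `NA` without a map), `mean_posterior`.
#' @export
call_tracts <- function(track, windows, map = NULL, genome = NA_character_,
                        threshold = 0.5) {
  post <- if (inherits(track, "PosteriorTrack")) track$posterior else track
  stopifnot(length(post) == windows$n_windows)
  hit <- !is.na(post) & post > threshold
  r <- rle(hit)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(genome = character(), arm = character(),
                    win_from = integer(), win_to = integer(),
                    start = numeric(), end = numeric(),
                    buf_start = numeric(), buf_end = numeric(),
                    cm = numeric(), mean_posterior = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(keep)) return(out)
  wf <- starts[keep]; wt <- ends[keep]
  bs <- pmax(wf - 1L, 1L); be <- pmin(wt + 1L, windows$n_windows)
  core_start <- windows$start[wf]; core_end <- windows$end[wt]
  cm <- if (is.null(map)) NA_real_ else cm_length(map, core_start, core_end)
  data.frame(genome = genome, arm = windows$arm, win_from = wf, win_to = wt,
             start = core_start, end = core_end,
             buf_start = windows$start[bs], buf_end = windows$end[be],
             cm = cm,
             mean_posterior = vapply(seq_along(wf), function(i)
               mean(post[wf[i]:wt[i]]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Fraction of intermediate posterior probabilities
#'
#' Diagnostic for posterior calibration: the fraction of window
#' posteriors strictly between `lo` and `hi` (default 0.05 and 0.95).  A
#' well-separated model leaves this fraction small.
#'
#' @param tracks a `PosteriorTrack`, numeric vector, or list of either.
#' @param lo,hi interval bounds.
#' @return fraction in `(lo, hi)`.
#' @export
classify_probability_quality <- function(tracks, lo = 0.05, hi = 0.95) {
  if (inherits(tracks, "PosteriorTrack") || is.numeric(tracks))
    tracks <- list(tracks)
  p <- unlist(lapply(tracks, function(t)
    if (inherits(t, "PosteriorTrack")) t$posterior else t))
  p <- p[!is.na(p)]
  if (!length(p)) stop("no posteriors")
  mean(p > lo & p < hi)
}

## mask buffered tract spans from their genomes in one pass (single copy)
.mask_tracts <- function(hs, tr) {
  if (is.null(tr) || !nrow(tr)) return(hs)
  m <- hs$seq
  for (g in unique(tr$genome)) {
    rows <- tr[tr$genome == g, , drop = FALSE]
    idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e),
                         rows$buf_start, rows$buf_end, SIMPLIFY = FALSE),
                  use.names = FALSE)
    m[unique(idx), g] <- .RAW_N
  }
  hs$seq <- m
  hs
}

#' Iteratively refine the African panel and emission model
#'
#' Round 1 builds emissions from the (IBD-masked) raw panel, decodes every
#' panel member over the full arm, and masks the buffered spans of its
#' called tracts from the panel copy used to build emissions.  Round 2
#' rebuilds emissions from the masked panel and re-masks from its calls;
#' the round-3 (final-round) model is returned for final calling.  With an
#' admixture-free panel no masking occurs and all rounds coincide.
#'
#' @param hs `HaplotypeSet` holding African and cosmopolitan panels (an
#'   IBD-masked copy may be supplied via `emission_hs` for emissions
#'   construction while likelihoods use the full sequences in `hs`).
#' @param african,cosmopolitan genome id vectors (disjoint).
#' @param windows a [build_windows()] result.
#' @param cfg an [hmm_config()]; `cfg$rounds` rounds are run.
#' @param emission_hs optional masked copy used only to build emissions.
#' @param min_sites passed to [divergence_profiles()].
#' @return list with `model` (final `EmissionModel`), `models` and
#'   `tracts` per round, `tracks` (final-round `PosteriorTrack`s for the
#'   panel), and `masked_panel` (the panel `HaplotypeSet` with final
#'   admixture masks applied).
#' @export
refine_panel <- function(hs, african, cosmopolitan, windows,
                         cfg = hmm_config(), emission_hs = NULL,
                         min_sites = 100L) {
  stopifnot(!length(intersect(african, cosmopolitan)))
  if (is.null(emission_hs)) emission_hs <- hs
  ## cosmopolitan leave-one-out profiles are fixed across rounds
  cos_prof <- divergence_profiles(hs, cosmopolitan, cosmopolitan, windows,
                                  min_sites)
  ## full-arm profiles used for decoding do not change across rounds
  afr_prof_full <- divergence_profiles(hs, african, cosmopolitan,
                                       windows, min_sites)
  panel_hs <- emission_hs
  models <- list(); tracts_by_round <- list(); tracks <- NULL
  for (round in seq_len(cfg$rounds)) {
    afr_prof_panel <- if (round == 1L && identical(panel_hs, hs))
      afr_prof_full
    else divergence_profiles(panel_hs, african, cosmopolitan, windows,
                             min_sites)
    mom <- window_moments(afr_prof_panel)
    if (mean(mom$n >= 2L) < 0.5)
      stop("fewer than 2 unmasked panel members in >50% of windows")
    model <- build_emission_model(afr_prof_panel, cos_prof, mom, cfg)
    models[[round]] <- model
    tracks <- lapply(african, function(g) {
      forward_backward(window_likelihoods(afr_prof_full[, g], model), cfg)
    })
    names(tracks) <- african
    tr <- do.call(rbind, lapply(african, function(g)
      call_tracts(tracks[[g]], windows, genome = g,
                  threshold = cfg$threshold)))
    tracts_by_round[[round]] <- tr
    if (round < cfg$rounds)
      panel_hs <- .mask_tracts(emission_hs, tr)
  }
  list(model = models[[cfg$rounds]], models = models,
       tracts = tracts_by_round, tracks = tracks,
       profiles = afr_prof_full,
       masked_panel = .mask_tracts(emission_hs, tracts_by_round[[cfg$rounds]]))
}
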