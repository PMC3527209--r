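## Central fitting function: full admixture-detection pipeline for one
## chromosome arm, returning a classed fit with the usual accessors.

#' Detect cosmopolitan admixture tracts in African genomes
#'
#' Fits the two-state divergence HMM to one chromosome arm: builds
#' SNP-count windows from the African panel's non-singleton SNPs,
#' iteratively refines the panel and its empirical emission model
#' (masking called admixture between rounds), then decodes every query
#' genome with the final-round model and calls tracts.
#'
#' @param hs a `HaplotypeSet` containing the African panel, the
#'   cosmopolitan panel and any additional query genomes (roles in
#'   `hs$meta$role`); supply an IBD-masked copy via `emission_hs` if IBD
#'   masking should apply to emissions construction only.
#' @param K non-singleton SNPs per window (default 1000, giving ~50 kb
#'   windows at Rwandan diversity; validation runs on simulated data use
#'   smaller K to reach the ~10 kb validation window scale).
#' @param cfg an [hmm_config()].
#' @param queries genome ids to decode (default: African panel plus any
#'   `query`-role genomes not in the cosmopolitan panel).
#' @param map optional [recombination_map()] for tract cM lengths.
#' @param depth_correct multiply each query's divergence profile by the
#'   per-arm depth proxy factor ([depth_correction()]) before
#'   standardization.
#' @param emission_hs optional masked `HaplotypeSet` for emissions.
#' @param min_sites minimum comparable sites per pair per window.
#' @return object of class `admixture_fit` with components `windows`,
#'   `model` (final `EmissionModel`), `refinement` (models/tracts per
#'   round), `tracks` (per query `PosteriorTrack`), `tracts` (data
#'   frame), `proportions` (per-genome core and buffered admixture
#'   fractions), `cfg`, `arm`.
#' @export
detect_admixture <- function(hs, K = 1000L, cfg = hmm_config(),
                             queries = NULL, map = NULL,
                             depth_correct = FALSE, emission_hs = NULL,
                             min_sites = 100L) {
  african <- hs$meta$genome_id[hs$meta$role == "african_panel"]
  cosmo <- hs$meta$genome_id[hs$meta$role == "cosmopolitan_panel"]
  if (length(african) < 2L || length(cosmo) < 2L)
    stop("need at least two genomes in each panel")
  if (is.null(queries))
    queries <- union(african,
                     hs$meta$genome_id[hs$meta$role == "query"])
  vt <- call_variants(subset_genomes(hs, african))
  sites <- nonsingleton_sites(vt, african)
  windows <- build_windows(sites, K, seq_length(hs), arm = hs$arm)
  ref <- refine_panel(hs, african, cosmo, windows, cfg,
                      emission_hs = emission_hs, min_sites = min_sites)
  ## decode the queries with the final model (panel profiles are reused)
  extra <- setdiff(queries, colnames(ref$profiles))
  prof <- ref$profiles[, intersect(queries, colnames(ref$profiles)),
                       drop = FALSE]
  if (length(extra))
    prof <- cbind(prof, divergence_profiles(hs, extra, cosmo, windows,
                                            min_sites))
  prof <- prof[, queries, drop = FALSE]
  dfac <- setNames(rep(1, length(queries)), queries)
  if (depth_correct) {
    d_self <- panel_self_divergence(hs, queries, african)
    panel_mean <- mean(panel_self_divergence(hs, african, african))
    dfac <- depth_correction(d_self, panel_mean)
  }
  tracks <- lapply(queries, function(g)
    forward_backward(window_likelihoods(prof[, g] * dfac[g], ref$model),
                     cfg))
  names(tracks) <- queries
  tracts <- do.call(rbind, lapply(queries, function(g)
    call_tracts(tracks[[g]], windows, map = map, genome = g,
                threshold = cfg$threshold)))
  L <- seq_length(hs)
  span <- function(from, to) sum(to - from)
  proportions <- data.frame(
    genome = queries,
    core = vapply(queries, function(g) {
      tr <- tracts[tracts$genome == g, , drop = FALSE]
      span(tr$start, tr$end) / L
    }, numeric(1)),
    buffered = vapply(queries, function(g) {
      tr <- tracts[tracts$genome == g, , drop = FALSE]
      span(tr$buf_start, tr$buf_end) / L
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(windows = windows, model = ref$model, refinement = ref,
                 tracks = tracks, tracts = tracts,
                 proportions = proportions, cfg = cfg, arm = hs$arm,
                 queries = queries, map = map),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("Cosmopolitan admixture HMM fit\n")
  cat("  arm: ", x$arm, "  windows: ", x$windows$n_windows,
      " (K = ", x$windows$K, " SNPs)\n", sep = "")
  cat("  queries: ", length(x$queries), "  tracts called: ",
      if (is.null(x$tracts)) 0L else nrow(x$tracts), "\n", sep = "")
  cat("  mean core admixture proportion: ",
      signif(mean(x$proportions$core), 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, ...) {
  interm <- classify_probability_quality(object$tracks)
  out <- list(arm = object$arm, n_windows = object$windows$n_windows,
              proportions = object$proportions,
              intermediate_posterior_fraction = interm,
              n_tracts = if (is.null(object$tracts)) 0L
              else nrow(object$tracts),
              mean_tract_cm = if (!is.null(object$tracts) &&
                                  nrow(object$tracts))
                mean(object$tracts$cm) else NA_real_)
  class(out) <- "summary.admixture_fit"
  out
}

#' @export
print.summary.admixture_fit <- function(x, ...) {
  cat("Admixture fit summary (arm ", x$arm, ", ", x$n_windows,
      " windows)\n", sep = "")
  cat("  tracts: ", x$n_tracts,
      if (!is.na(x$mean_tract_cm))
        paste0(" (mean core length ", signif(x$mean_tract_cm, 3), " cM)"),
      "\n", sep = "")
  cat("  intermediate posteriors (0.05, 0.95): ",
      signif(100 * x$intermediate_posterior_fraction, 3), "%\n", sep = "")
  cat("  per-genome core admixture proportion:\n")
  pr <- x$proportions
  print(data.frame(genome = pr$genome, core = signif(pr$core, 3),
                   buffered = signif(pr$buffered, 3)), row.names = FALSE)
  invisible(x)
}

#' Posterior admixture probabilities of a fit
#' @param object an `admixture_fit`.
#' @param ... unused.
#' @return matrix windows x queries of admixed-state posteriors.
#' @export
posterior <- function(object, ...) UseMethod("posterior")

#' @rdname posterior
#' @export
posterior.admixture_fit <- function(object, ...) {
  nw <- object$windows$n_windows
  matrix(vapply(object$tracks, function(t) t$posterior, numeric(nw)),
         nrow = nw, dimnames = list(NULL, names(object$tracks)))
}

#' Called tracts of a fit
#' @param object an `admixture_fit`.
#' @return data frame of tracts ([call_tracts()] columns).
#' @export
tracts <- function(object) UseMethod("tracts")

#' @rdname tracts
#' @export
tracts.admixture_fit <- function(object) object$tracts

#' @export
coef.admixture_fit <- function(object, ...) {
  setNames(object$proportions$core, object$proportions$genome)
}

#' Plot posterior admixture probability along the arm
#'
#' One panel per plotted genome: admixed-state posterior per window
#' against window midpoint, with called core tracts shaded.
#'
#' @param x an `admixture_fit`.
#' @param genomes genome ids to plot (default first 4 queries).
#' @param ... passed to [graphics::plot()].
#' @export
plot.admixture_fit <- function(x, genomes = NULL, ...) {
  if (is.null(genomes)) genomes <- head(x$queries, 4L)
  mid <- (x$windows$start + x$windows$end) / 2
  old <- graphics::par(mfrow = c(length(genomes), 1L),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (g in genomes) {
    graphics::plot(mid, x$tracks[[g]]$posterior, type = "l",
                   ylim = c(0, 1), xlab = "position (bp)",
                   ylab = "P(admixed)", main = g, ...)
    tr <- x$tracts[x$tracts$genome == g, , drop = FALSE]
    if (!is.null(tr) && nrow(tr))
      graphics::rect(tr$start, 0, tr$end, 1, border = NA,
                     col = grDevices::adjustcolor("firebrick", 0.2))
    graphics::abline(h = x$cfg$threshold, lty = 3)
  }
  invisible(x)
}

#' Tract report table in 1-based closed coordinates
#'
#' Export form of the called tracts: positions start at 1 and both the
#' first and last included bp are reported (the convention of the
#' published supplementary tables), with cM lengths and mean posteriors.
#'
#' @param fit an `admixture_fit` (or a [call_tracts()] data frame).
#' @return data frame.
#' @export
tract_table <- function(fit) {
  tr <- if (inherits(fit, "admixture_fit")) fit$tracts else fit
  if (is.null(tr) || !nrow(tr))
    return(data.frame(genome = character(), arm = character(),
                      start = numeric(), end = numeric(),
                      buf_start = numeric(), buf_end = numeric(),
                      cm = numeric(), mean_posterior = numeric()))
  data.frame(genome = tr$genome, arm = tr$arm,
             start = tr$start + 1, end = tr$end,
             buf_start = tr$buf_start + 1, buf_end = tr$buf_end,
             cm = tr$cm, mean_posterior = tr$mean_posterior,
             stringsAsFactors = FALSE)
}
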