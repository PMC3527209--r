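## Synthetic data: coalescent panel simulation under the African /
## cosmopolitan bottleneck model, forward Wright-Fisher migrant-tract
## simulation, splicing of donor tracts into African haplotypes, and
## evaluation of calls against the tract truth.

#' Demographic model for panel simulation
#'
#' Two-population model in ms-style scaled units (time in 4*N0
#' generations, sizes relative to N0): an African population of size N0
#' and a cosmopolitan population at `cosmo_size`*N0 that crashed to
#' `crash_size`*N0 at `crash_time` (the out-of-Africa bottleneck), merging
#' into the African lineage at `join_time`; the ancestral population
#' changes to `ancestral_size`*N0 at `ancestral_time`.  Defaults follow a
#' published autosomal model for D. melanogaster.
#'
#' @param theta population mutation rate per site (default 0.0376).
#' @param rho population crossover rate per site (default 0.171).
#' @param gc_ratio gene conversion initiation rate as a multiple of the
#'   crossover rate (default 5; set 0 to disable).
#' @param gc_tract mean gene-conversion tract length in bp (default 86.5).
#' @param n_african,n_cosmopolitan haploid sample sizes (27 and 36; the
#'   cosmopolitan sample includes one donor haplotype per African
#'   haplotype, leaving `n_cosmopolitan - n_african` panel members).
#' @param L sequence length in bp (default 1e7, scalable down).
#' @param cosmo_size,crash_size,crash_time,join_time,ancestral_time,ancestral_size
#'   epoch parameters (see description).
#' @param n0 reference population size used to de-scale rates for the
#'   simulation engine (results are invariant to it).
#' @return list of class `DemographicModel`.
#' @export
demographic_model <- function(theta = 0.0376, rho = 0.171, gc_ratio = 5,
                              gc_tract = 86.5, n_african = 27L,
                              n_cosmopolitan = 36L, L = 1e7,
                              cosmo_size = 0.183, crash_size = 0.000377,
                              crash_time = 0.0037281, join_time = 0.00381,
                              ancestral_time = 0.0145,
                              ancestral_size = 0.2, n0 = 1e6) {
  stopifnot(theta >= 0, rho >= 0, crash_time < join_time,
            join_time < ancestral_time, n_african > 0, n_cosmopolitan > 0)
  structure(as.list(environment()), class = "DemographicModel")
}

#' Simulate African and cosmopolitan panels plus donor haplotypes
#'
#' Runs a coalescent simulation of the two-population model (via the
#' bundled msprime helper script), drops mutations onto a monomorphic
#' `A` background with a random alternative base per site, and returns a
#' `HaplotypeSet` holding the African panel (`AFR*`, role
#' `african_panel`), the cosmopolitan panel (`COS*`,
#' `cosmopolitan_panel`) and one donor haplotype per African haplotype
#' (`DON*`, role `donor`), taken from the extra cosmopolitan samples.
#' Gene conversion is disabled by default for `L <= 1e6` (flagged by a
#' message) to keep small validation runs fast.
#'
#' @param model a [demographic_model()].
#' @param seed integer seed (drives both the coalescent engine and the
#'   base assignment).
#' @param gene_conversion override the L-based default.
#' @param python python interpreter (default `"python"` on the PATH).
#' @return a `HaplotypeSet`.
#' @export
simulate_panels <- function(model = demographic_model(), seed = 1L,
                            gene_conversion = NULL, python = "python") {
  stopifnot(inherits(model, "DemographicModel"))
  if (is.null(gene_conversion)) gene_conversion <- model$L > 1e6
  if (!gene_conversion && model$gc_ratio > 0 && model$L > 1e6)
    message("gene conversion disabled")
  script <- system.file("python", "simulate_panels.py",
                        package = "cosmotracts", mustWork = TRUE)
  out <- tempfile(fileext = ".tsv")
  on.exit(unlink(out))
  n_cos_total <- model$n_cosmopolitan + model$n_african   # panel + donors
  args <- c(script,
            "--length", format(model$L, scientific = FALSE),
            "--n-african", model$n_african,
            "--n-cosmopolitan", n_cos_total,
            "--theta", model$theta, "--rho", model$rho,
            "--gc-ratio", if (gene_conversion) model$gc_ratio else 0,
            "--gc-tract", model$gc_tract,
            "--cosmo-size", model$cosmo_size,
            "--crash-size", model$crash_size,
            "--crash-time", model$crash_time,
            "--join-time", model$join_time,
            "--ancestral-time", model$ancestral_time,
            "--ancestral-size", model$ancestral_size,
            "--n0", format(model$n0, scientific = FALSE),
            "--seed", as.integer(seed) %% 100000L + 1L,
            "--out", out)
  status <- system2(python, args, stdout = FALSE, stderr = "")
  if (status != 0L) stop("coalescent simulation failed (python/msprime)")
  sites <- if (file.size(out) > 0)
    read.delim(out, header = FALSE,
               colClasses = c("numeric", "character"))
  else data.frame(V1 = numeric(0), V2 = character(0))
  n_hap <- model$n_african + n_cos_total
  L <- as.integer(model$L)
  m <- matrix(charToRaw(strrep("A", L)), nrow = L, ncol = n_hap)
  if (nrow(sites)) {
    ## collapse recurrent hits at the same discrete position
    keep <- !duplicated(sites[[1L]])
    sites <- sites[keep, , drop = FALSE]
    pos <- as.integer(sites[[1L]]) + 1L
    set.seed(as.integer(seed))
    alt <- sample(c("C", "G", "T"), length(pos), replace = TRUE)
    gm <- matrix(unlist(strsplit(sites[[2L]], "")) == "1",
                 nrow = n_hap)               # haplotypes x sites
    for (b in c("C", "G", "T")) {
      sel <- which(alt == b)
      if (!length(sel)) next
      hit <- which(gm[, sel, drop = FALSE], arr.ind = TRUE)
      m[cbind(pos[sel][hit[, 2L]], hit[, 1L])] <- charToRaw(b)
    }
  }
  ids <- c(sprintf("AFR%02d", seq_len(model$n_african)),
           sprintf("COS%02d", seq_len(model$n_cosmopolitan)),
           sprintf("DON%02d", seq_len(model$n_african)))
  colnames(m) <- ids
  meta <- data.frame(
    genome_id = ids,
    population = c(rep("AFR", model$n_african),
                   rep("COS", model$n_cosmopolitan),
                   rep("DON", model$n_african)),
    depth = 100,
    role = c(rep("african_panel", model$n_african),
             rep("cosmopolitan_panel", model$n_cosmopolitan),
             rep("donor", model$n_african)),
    stringsAsFactors = FALSE)
  haplotype_set(m, meta, arm = "sim")
}

#' Simulate migrant-ancestry tracts by forward Wright-Fisher simulation
#'
#' Chromosomes are simulated as breakpoint lists in a haploid
#' Wright-Fisher population of size `N`; recombination is Poisson with
#' mean `morgans` crossovers per meiosis at uniform map positions.  Under
#' the pulse model (default) a fraction `m` of the founding population is
#' migrant `g` generations before sampling, giving the classical
#' exponential tract-length law with mean `1/g` Morgans; under the
#' continuous model each offspring is an unrecombined migrant with
#' probability `m` every generation.
#'
#' @param N haploid population size.
#' @param m migrant fraction (pulse) or per-generation migration rate
#'   (continuous).
#' @param g generations since the admixture pulse / onset.
#' @param morgans genetic map length of the simulated chromosome.
#' @param n_haplotypes number of haplotypes sampled (without replacement).
#' @param seed integer seed.
#' @param model `"pulse"` or `"continuous"`.
#' @param L physical length in bp; tract coordinates are also reported in
#'   bp under a uniform map when given.
#' @return object of class `TractTruth`: list with `tracts` (per sampled
#'   haplotype a matrix of migrant intervals, columns `start`,`end`, in
#'   Morgans plus bp columns when `L` is given), `g`, `morgans`, `L`, and
#'   `admixture` (realized migrant fraction per haplotype).
#' @export
simulate_migrant_tracts <- function(N = 1000L, m = 0.1, g = 100L,
                                    morgans = 0.05, n_haplotypes = 30L,
                                    seed = 1L, model = c("pulse",
                                                         "continuous"),
                                    L = NULL) {
  model <- match.arg(model)
  stopifnot(g >= 1, m >= 0, m <= 1, morgans > 0)
  set.seed(as.integer(seed))
  raw <- .wf_tracts_cpp(as.integer(N), m, as.integer(g), morgans,
                        as.integer(n_haplotypes), model == "pulse")
  tracts <- lapply(raw, function(mat) {
    if (!is.null(L) && nrow(mat)) {
      mat <- cbind(mat, bp_start = floor(mat[, "start"] / morgans * L),
                   bp_end = ceiling(mat[, "end"] / morgans * L))
    } else if (!is.null(L)) {
      mat <- cbind(mat, bp_start = numeric(0), bp_end = numeric(0))
    }
    mat
  })
  adm <- vapply(tracts, function(mat)
    if (nrow(mat)) sum(mat[, "end"] - mat[, "start"]) / morgans else 0,
    numeric(1))
  structure(list(tracts = tracts, g = as.integer(g), morgans = morgans,
                 L = L, model = model, admixture = adm),
            class = "TractTruth")
}

#' @export
print.TractTruth <- function(x, ...) {
  nt <- sum(vapply(x$tracts, nrow, integer(1)))
  cat("TractTruth: ", length(x$tracts), " haplotype(s), ", nt,
      " migrant tract(s), g = ", x$g, ", mean admixture ",
      round(mean(x$admixture), 3), "\n", sep = "")
  invisible(x)
}

#' Pooled migrant tract lengths (in Morgans)
#' @param truth a `TractTruth`.
#' @param interior_only drop tracts touching either chromosome end (they
#'   are right-censored by the map edge).
#' @return numeric vector of tract lengths.
#' @export
tract_lengths <- function(truth, interior_only = FALSE) {
  len <- lapply(truth$tracts, function(mat) {
    if (!nrow(mat)) return(numeric(0))
    l <- mat[, "end"] - mat[, "start"]
    if (interior_only)
      l <- l[mat[, "start"] > 0 & mat[, "end"] < truth$morgans]
    l
  })
  unlist(len, use.names = FALSE)
}

#' Splice donor tracts into African haplotypes
#'
#' Within each haplotype's truth intervals, the African haplotype's bases
#' are replaced by its dedicated donor's; elsewhere it is unchanged.
#' Haplotype `i` of the truth is spliced into the `i`-th African genome
#' using the `i`-th donor genome.
#'
#' @param hs [simulate_panels()] output (or any `HaplotypeSet`).
#' @param truth a [simulate_migrant_tracts()] result with bp coordinates.
#' @param african,donors genome id vectors, same length, at least as long
#'   as `truth$tracts`; defaults select by metadata role/population.
#' @return list with `hs` (the admixed `HaplotypeSet`) and `truth`.
#' @export
splice_admixture <- function(hs, truth, african = NULL, donors = NULL) {
  if (is.null(african))
    african <- hs$meta$genome_id[hs$meta$role == "african_panel"]
  if (is.null(donors))
    donors <- hs$meta$genome_id[hs$meta$population == "DON"]
  nh <- length(truth$tracts)
  stopifnot(nh <= length(african), nh <= length(donors))
  L <- seq_length(hs)
  for (i in seq_len(nh)) {
    mat <- truth$tracts[[i]]
    if (!nrow(mat)) next
    if (any(mat[, "bp_end"] > L)) stop("truth interval beyond sequence end")
    for (k in seq_len(nrow(mat))) {
      s <- mat[k, "bp_start"]; e <- mat[k, "bp_end"]
      if (e <= s) next
      idx <- (s + 1L):e
      hs$seq[idx, african[i]] <- hs$seq[idx, donors[i]]
    }
  }
  list(hs = hs, truth = truth)
}

#' Simulate an admixed validation data set
#'
#' Convenience harness tying the pieces together: coalescent panels under
#' the demographic model, forward Wright-Fisher migrant tracts under
#' continuous migration at `m = admixture / g` per generation
#' (approximating the target total admixture proportion), and splicing of
#' donor tracts into the African haplotypes.  The tract simulator uses
#' the genetic length implied by the model's crossover rate
#' (`rho * L / (4 * n0)` Morgans).
#'
#' @param model a [demographic_model()].
#' @param g generations since the onset of admixture.
#' @param admixture target total admixture proportion (default 0.1).
#' @param N forward-simulation haploid population size (default 5000).
#' @param seed integer seed.
#' @return list with `hs` (admixed `HaplotypeSet`), `truth`
#'   (`TractTruth`), `african` (query/panel ids), and `panels` (the
#'   un-spliced `HaplotypeSet`).
#' @export
simulate_validation <- function(model = demographic_model(L = 1e6),
                                g = 100L, admixture = 0.1, N = 5000L,
                                seed = 1L) {
  panels <- simulate_panels(model, seed = seed)
  morgans <- model$rho * model$L / (4 * model$n0)
  truth <- simulate_migrant_tracts(N = N, m = admixture / g, g = g,
                                   morgans = morgans,
                                   n_haplotypes = model$n_african,
                                   seed = seed + 1L, model = "continuous",
                                   L = model$L)
  sp <- splice_admixture(panels, truth)
  list(hs = sp$hs, truth = truth,
       african = panels$meta$genome_id[panels$meta$role == "african_panel"],
       panels = panels)
}

#' Run the detection fit on a simulated validation data set and score it
#'
#' Fits [detect_admixture()] to a [simulate_validation()] result with
#' windows sized to the validation window scale (`window_bp`, default
#' 10 kb: `K` is set to the panel SNP density times `window_bp`) and the
#' transition probability matched to the admixture age via
#' [tau_from_age()], then scores the calls with [evaluate_calls()].
#'
#' @param sim a [simulate_validation()] result.
#' @param g the admixture age used for `tau` (the one the data were
#'   simulated under).
#' @param window_bp target window size in bp (default 1e4).
#' @param ... passed to [detect_admixture()].
#' @return list with `fit`, `eval`, `windows`.
#' @export
validate_detection <- function(sim, g, window_bp = 1e4, ...) {
  hs <- sim$hs
  L <- seq_length(hs)
  vt <- call_variants(subset_genomes(hs, sim$african))
  sites <- nonsingleton_sites(vt, sim$african)
  K <- max(20L, round(length(sites) / (L / window_bp)))
  wm <- sim$truth$morgans * window_bp / L
  cfg <- hmm_config(tau = tau_from_age(g, wm))
  fit <- detect_admixture(hs, K = K, cfg = cfg, ...)
  ev <- evaluate_calls(fit$tracts, sim$truth, fit$windows, sim$african)
  list(fit = fit, eval = ev, windows = fit$windows)
}

#' Label windows by truth-admixture and score calls against them
#'
#' A window is truth-admixed for a haplotype when more than half of its bp
#' lie inside that haplotype's migrant tracts.  Sensitivity and
#' false-positive rate are computed over all (haplotype, window) cells on
#' the core (unbuffered) calls; the boundary error is the mean absolute
#' window offset between each called tract edge and the nearest truth
#' edge of the same haplotype.
#'
#' @param tracts data frame of called tracts ([call_tracts()] rows,
#'   possibly several genomes).
#' @param truth a `TractTruth` with bp coordinates.
#' @param windows a [build_windows()] result.
#' @param genomes genome ids corresponding to `truth$tracts`, in order.
#' @return list with `sensitivity`, `fpr`, `boundary_error` (windows; NA
#'   when no tract is called), and the per-cell confusion counts.
#' @export
evaluate_calls <- function(tracts, truth, windows, genomes) {
  nh <- length(truth$tracts)
  stopifnot(nh == length(genomes))
  nw <- windows$n_windows
  truth_mat <- matrix(FALSE, nw, nh)
  for (i in seq_len(nh)) {
    mat <- truth$tracts[[i]]
    if (!nrow(mat)) next
    ov <- numeric(nw)
    for (k in seq_len(nrow(mat)))
      ov <- ov + pmax(0, pmin(windows$end, mat[k, "bp_end"]) -
                        pmax(windows$start, mat[k, "bp_start"]))
    truth_mat[, i] <- ov > 0.5 * (windows$end - windows$start)
  }
  call_mat <- matrix(FALSE, nw, nh)
  berr <- numeric(0)
  for (i in seq_len(nh)) {
    tr <- tracts[tracts$genome == genomes[i], , drop = FALSE]
    if (!nrow(tr)) next
    for (k in seq_len(nrow(tr)))
      call_mat[tr$win_from[k]:tr$win_to[k], i] <- TRUE
    truth_edges <- which(diff(c(FALSE, truth_mat[, i], FALSE)) != 0)
    if (length(truth_edges)) {
      call_edges <- c(tr$win_from, tr$win_to + 1L)
      berr <- c(berr, vapply(call_edges, function(e)
        min(abs(e - truth_edges)), numeric(1)))
    }
  }
  tp <- sum(call_mat & truth_mat); fn <- sum(!call_mat & truth_mat)
  fp <- sum(call_mat & !truth_mat); tn <- sum(!call_mat & !truth_mat)
  list(sensitivity = if (tp + fn) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn) fp / (fp + tn) else NA_real_,
       boundary_error = if (length(berr)) mean(berr) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}
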