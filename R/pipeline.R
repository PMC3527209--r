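## Pipeline driver and config handling for the command-line entry point.

.CONFIG_DEFAULTS <- list(
  mode = "simulate",            # "simulate" or "detect"
  out_dir = "cosmotracts_out",
  seed = 1L,
  ## simulate mode
  L = 1e6, g = 100L, admixture = 0.1, morgans = NULL, wf_n = 1000L,
  ## detect mode inputs
  fasta = NULL, metadata = NULL, arm = "arm", recomb_map = NULL,
  ## windowing / HMM
  K = 1000L, tau = 0.005, p0 = 0.1, floor = 0.005, threshold = 0.5,
  rounds = 3L, min_sites = 100L, depth_correct = FALSE,
  ## IBD
  ibd_window = 5e5, ibd_step = 1e5, ibd_max_div = 5e-4,
  ibd_total_limit = 5e6, ibd_single_limit = 5e6, ibd_buffer = 1e5,
  run_ibd = FALSE)

#' Resolve a run configuration
#'
#' Fills defaults and rejects unknown keys.  `config` may be a named list
#' or the path of a JSON file.
#'
#' @param config named list or JSON path.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .CONFIG_DEFAULTS
  cfg[names(config)] <- config
  if (!cfg$mode %in% c("simulate", "detect"))
    stop("mode must be 'simulate' or 'detect'")
  if (cfg$mode == "detect" && (is.null(cfg$fasta) || is.null(cfg$metadata)))
    stop("detect mode requires 'fasta' and 'metadata' paths")
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the admixture-detection pipeline
#'
#' Simulate mode generates panels under the demographic model, splices
#' migrant tracts of known location into the African haplotypes, runs the
#' full detection fit and scores the calls, writing all artifacts (and a
#' metrics JSON) to `out_dir`.  Detect mode reads FASTA + metadata,
#' optionally applies IBD masking, and runs the fit.  Deterministic given
#' the seed.
#'
#' @param config a [run_config()], named list, or JSON path.
#' @return invisibly, a list with the fit and (simulate mode) metrics.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.txt")
  resolved <- unclass(cfg)
  writeLines(c(
    paste0("cosmotracts ",
           as.character(utils::packageVersion("cosmotracts"))),
    paste0("R ", R.version.string),
    paste0("config_hash ", .config_hash(resolved)),
    paste0(names(resolved), " = ",
           vapply(resolved, function(v)
             paste(format(v), collapse = ","), character(1)))),
    log_path)
  hcfg <- hmm_config(tau = cfg$tau, p0 = cfg$p0, floor = cfg$floor,
                     threshold = cfg$threshold, rounds = cfg$rounds)
  metrics <- NULL
  if (cfg$mode == "simulate") {
    model <- demographic_model(L = cfg$L)
    sim <- simulate_validation(model, g = cfg$g,
                               admixture = cfg$admixture, N = cfg$wf_n,
                               seed = cfg$seed)
    val <- validate_detection(sim, g = cfg$g, min_sites = cfg$min_sites)
    fit <- val$fit
    ev <- val$eval
    metrics <- list(sensitivity = ev$sensitivity, fpr = ev$fpr,
                    boundary_error_windows = ev$boundary_error,
                    intermediate_posterior_fraction =
                      classify_probability_quality(fit$tracks),
                    g = cfg$g, L = cfg$L)
    jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    write_haplotype_set(sim$hs, file.path(cfg$out_dir, "admixed.fasta"))
  } else {
    meta <- cfg$metadata
    hs <- read_haplotype_set(cfg$fasta, meta, arm = cfg$arm)
    emission_hs <- NULL
    if (isTRUE(cfg$run_ibd)) {
      segs <- scan_ibd(hs, window = cfg$ibd_window, step = cfg$ibd_step,
                       max_div = cfg$ibd_max_div)
      flagged <- classify_relatedness(segs, meta = hs$meta,
                                      total_limit = cfg$ibd_total_limit,
                                      single_limit = cfg$ibd_single_limit)
      emission_hs <- mask_relatedness(hs, segs, flagged,
                                      buffer = cfg$ibd_buffer)
      write_haplotype_set(emission_hs,
                          file.path(cfg$out_dir, "ibd_masked.fasta"))
    }
    map <- if (!is.null(cfg$recomb_map))
      read_recombination_map(cfg$recomb_map, cfg$arm) else NULL
    fit <- detect_admixture(hs, K = cfg$K, cfg = hcfg, map = map,
                            depth_correct = cfg$depth_correct,
                            emission_hs = emission_hs,
                            min_sites = cfg$min_sites)
  }
  ## common artifacts
  wdf <- as.data.frame(fit$windows)
  write_bed(data.frame(arm = wdf$arm, start = wdf$start, end = wdf$end),
            file.path(cfg$out_dir, "windows.bed"))
  post <- posterior(fit)
  post_tab <- cbind(wdf[, c("arm", "start", "end")],
                    as.data.frame(round(post, 6)))
  write.table(post_tab, file.path(cfg$out_dir, "posteriors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  tt <- tract_table(fit)
  write.table(tt, file.path(cfg$out_dir, "tracts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(fit$tracts) && nrow(fit$tracts))
    write_bed(data.frame(arm = fit$tracts$arm, start = fit$tracts$start,
                         end = fit$tracts$end),
              file.path(cfg$out_dir, "tracts.bed"),
              names = fit$tracts$genome)
  write.table(fit$proportions,
              file.path(cfg$out_dir, "admixture_proportions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fit = fit, metrics = metrics, config = cfg))
}

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)),
    collapse = ";", sep = "=")
  ## tiny FNV-1a style hash; avoids external digest dependency
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(s)) h <- (bitwXor(as.integer(h), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
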