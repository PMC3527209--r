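## Windowed outlier detection, region merging, nearest-exon assignment and
## GO permutation enrichment.

#' Evaluate a statistic in SNP-count windows along an arm
#'
#' Windows hold `K` panel SNPs and advance by `offset` SNPs (overlapping
#' when `offset < K`, as in differentiation scans; `offset = K` gives
#' non-overlapping windows).  The statistic is a user function of the
#' window's site indices and bp span.
#'
#' @param sites ascending 0-based panel SNP positions.
#' @param stat_fun `function(site_idx, start, end)` returning one number;
#'   `site_idx` indexes into `sites`, and `[start, end]` is the bp span
#'   of the window's first and last SNP.
#' @param K SNPs per window (default 100).
#' @param offset SNP offset between window starts (default 20).
#' @param arm arm label.
#' @return data frame: `arm`, `window`, `start`, `end`, `value`.
#' @export
scan_windows <- function(sites, stat_fun, K = 100L, offset = 20L,
                         arm = "arm") {
  n <- length(sites)
  if (n < K) stop("fewer sites than one window")
  starts <- seq.int(1L, n - K + 1L, by = offset)
  vals <- vapply(starts, function(s) {
    idx <- s:(s + K - 1L)
    stat_fun(idx, sites[idx[1L]], sites[idx[K]])
  }, numeric(1))
  data.frame(arm = arm, window = seq_along(starts),
             start = sites[starts], end = sites[starts + K - 1L],
             value = vals, stringsAsFactors = FALSE)
}

#' Call outlier regions from windowed statistics
#'
#' Windows strictly above the arm-wise `1 - q` quantile are outliers.
#' Outlier windows with at most `max_gap` intervening non-outlier windows
#' (counted in non-overlapping window equivalents, `K / offset` steps
#' for overlapping windows) are merged into one region.  The region
#' center is the midpoint of its most extreme window.
#'
#' @param stats data frame from [scan_windows()] (one arm).
#' @param q upper tail fraction (0.025 for differentiation scans, 0.05
#'   for non-overlapping scans).
#' @param max_gap maximum intervening non-outlier windows (default 2).
#' @param step_equiv window-index steps per non-overlapping window
#'   equivalent (`K / offset`; 1 for non-overlapping windows).
#' @return data frame of regions: `arm`, `win_from`, `win_to`, `start`,
#'   `end`, `peak_value`, `center` (bp midpoint of the most extreme
#'   window), `n_outlier_windows`.
#' @export
call_outliers <- function(stats, q = 0.025, max_gap = 2L, step_equiv = 1L) {
  stats <- stats[order(stats$window), , drop = FALSE]
  rownames(stats) <- NULL
  if (nrow(stats) < 40L)
    warning("fewer than 40 windows; quantile threshold unstable")
  thr <- quantile(stats$value, 1 - q, na.rm = TRUE, names = FALSE)
  hit <- which(!is.na(stats$value) & stats$value > thr)
  if (!length(hit))
    return(data.frame(arm = character(), win_from = integer(),
                      win_to = integer(), start = numeric(),
                      end = numeric(), peak_value = numeric(),
                      center = numeric(), n_outlier_windows = integer(),
                      stringsAsFactors = FALSE))
  gap_limit <- (max_gap + 1L) * step_equiv
  brk <- c(0L, which(diff(hit) > gap_limit), length(hit))
  out <- lapply(seq_len(length(brk) - 1L), function(i) {
    members <- hit[(brk[i] + 1L):brk[i + 1L]]
    peak <- members[which.max(stats$value[members])]
    data.frame(arm = stats$arm[1L], win_from = members[1L],
               win_to = members[length(members)],
               start = stats$start[members[1L]],
               end = stats$end[members[length(members)]],
               peak_value = stats$value[peak],
               center = (stats$start[peak] + stats$end[peak]) / 2,
               n_outlier_windows = length(members),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign the nearest exon's gene to each outlier region
#'
#' The gene whose nearest exon edge minimizes the distance to the region
#' center; distance 0 when the center falls inside an exon.  Exact ties
#' are broken by the lexicographically smaller gene id (with a message).
#'
#' @param regions data frame with `arm` and `center` ([call_outliers()]).
#' @param annotation GFF3 path or data frame ([read_annotation()]) with
#'   exon records carrying gene ids.
#' @return `regions` with added `gene` and `distance` columns (`NA` when
#'   the arm has no exon annotation).
#' @export
nearest_exon <- function(regions, annotation) {
  ann <- read_annotation(annotation)
  ann <- ann[ann$type == "exon", , drop = FALSE]
  regions$gene <- NA_character_
  regions$distance <- NA_real_
  for (i in seq_len(nrow(regions))) {
    ex <- ann[ann$seqid == regions$arm[i], , drop = FALSE]
    if (!nrow(ex)) next
    ctr <- regions$center[i]
    dist <- ifelse(ctr >= ex$start & ctr <= ex$end, 0,
                   pmin(abs(ctr - ex$start), abs(ctr - ex$end)))
    best <- which(dist == min(dist))
    if (length(best) > 1L) {
      genes <- sort(ex$gene_id[best])
      if (length(unique(genes)) > 1L)
        message("nearest-exon tie at region ", i, ": picking ", genes[1L])
      regions$gene[i] <- genes[1L]
    } else {
      regions$gene[i] <- ex$gene_id[best]
    }
    regions$distance[i] <- min(dist)
  }
  regions
}

#' GO category enrichment among outlier-region genes by permutation
#'
#' For each category, the observed statistic is the number of unique
#' genes nearest to an outlier region center.  The null distribution
#' reassigns every region center to a uniformly drawn analysis window (of
#' the same arm) and recomputes the statistic, which accounts for gene
#' length via the number of windows a gene is nearest to.  `P` is the
#' fraction of permutations with a count at least the observed one.
#'
#' @param regions [nearest_exon()]-annotated regions (`arm`, `gene`).
#' @param go_map data frame with columns `gene` and `category`.
#' @param window_genes data frame with `arm` and `gene`: the nearest gene
#'   of every analysis window (the permutation universe).
#' @param n_perm permutations (default 10000).
#' @param seed integer seed.
#' @return data frame per category: `category`, `n_outlier_genes`,
#'   `n_category_genes`, `p_value`.
#' @export
go_enrichment <- function(regions, go_map, window_genes, n_perm = 10000L,
                          seed = 1L) {
  if (!nrow(go_map)) stop("empty GO map")
  cats <- split(unique(go_map[, c("gene", "category")])$gene,
                unique(go_map[, c("gene", "category")])$category)
  obs_genes <- unique(regions$gene[!is.na(regions$gene)])
  obs <- vapply(cats, function(g) sum(obs_genes %in% g), integer(1))
  set.seed(as.integer(seed))
  arms <- regions$arm
  pool <- split(window_genes$gene, window_genes$arm)
  exceed <- integer(length(cats))
  nr <- nrow(regions)
  for (p in seq_len(n_perm)) {
    perm_genes <- unique(vapply(seq_len(nr), function(i) {
      cand <- pool[[arms[i]]]
      cand[sample.int(length(cand), 1L)]
    }, character(1)))
    cnt <- vapply(cats, function(g) sum(perm_genes %in% g), integer(1))
    exceed <- exceed + (cnt >= obs)
  }
  data.frame(category = names(cats),
             n_outlier_genes = unname(obs),
             n_category_genes = lengths(cats),
             p_value = unname(exceed / n_perm),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of admixture peaks with differentiation outlier regions
#'
#' Counts admixture peaks having an outlier region overlapping them or
#' within `slack` bp, and evaluates significance by re-placing region
#' centers uniformly among the analysis windows of their arm (region
#' widths preserved).
#'
#' @param peaks data frame with `arm`, `start`, `end` (admixture peaks).
#' @param regions data frame with `arm`, `start`, `end`
#'   ([call_outliers()] output).
#' @param windows data frame with `arm`, `start`, `end` of all analysis
#'   windows (permutation universe).
#' @param slack maximum distance in bp (default 1e5).
#' @param n_perm permutations.
#' @param seed integer seed.
#' @return list with `overlap` (observed count), `p_value`, `n_perm`.
#' @export
admixture_fst_overlap <- function(peaks, regions, windows, slack = 1e5,
                                  n_perm = 1000L, seed = 1L) {
  count_overlap <- function(reg) {
    hits <- vapply(seq_len(nrow(peaks)), function(i) {
      r <- reg[reg$arm == peaks$arm[i], , drop = FALSE]
      if (!nrow(r)) return(FALSE)
      any(r$start - slack <= peaks$end[i] & r$end + slack >= peaks$start[i])
    }, logical(1))
    sum(hits)
  }
  obs <- count_overlap(regions)
  set.seed(as.integer(seed))
  wins <- split(windows, windows$arm)
  width <- regions$end - regions$start
  exceed <- 0L
  for (p in seq_len(n_perm)) {
    perm <- regions
    for (i in seq_len(nrow(perm))) {
      w <- wins[[perm$arm[i]]]
      k <- sample.int(nrow(w), 1L)
      ctr <- (w$start[k] + w$end[k]) / 2
      perm$start[i] <- ctr - width[i] / 2
      perm$end[i] <- ctr + width[i] / 2
    }
    if (count_overlap(perm) >= obs) exceed <- exceed + 1L
  }
  list(overlap = obs, p_value = exceed / n_perm, n_perm = n_perm)
}
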