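## Identity-by-descent detection between genome pairs and relatedness
## masking.

#' Scan genome pairs for identity-by-descent segments
#'
#' Slides windows (500 kb by default, advanced in 100 kb steps) across the
#' arm for every genome pair and flags windows whose pairwise divergence is
#' below `max_div` (fewer than 0.0005 differences per comparable site).
#' Overlapping or adjacent flagged windows are merged into maximal
#' segments.  Windows where fewer than `min_frac` of sites are comparable
#' are skipped.
#'
#' @param hs a `HaplotypeSet` (>= 2 genomes).
#' @param window,step window and step size in bp.
#' @param max_div divergence threshold defining identity.
#' @param min_frac minimum comparable-site fraction per window.
#' @param pairs optional 2-column matrix of genome-id pairs to scan
#'   (default all pairs).
#' @return data frame of segments: `genome1`, `genome2`, `arm`, `start`,
#'   `end` (0-based half-open, merged maximal spans).
#' @export
scan_ibd <- function(hs, window = 5e5, step = 1e5, max_div = 5e-4,
                     min_frac = 0.1, pairs = NULL) {
  ids <- colnames(hs$seq)
  stopifnot(length(ids) >= 2L)
  if (is.null(pairs)) {
    pairs <- t(combn(ids, 2L))
  }
  L <- seq_length(hs)
  starts <- seq(0, max(0, L - window), by = step)
  ends <- pmin(starts + window, L)
  segs <- list()
  for (k in seq_len(nrow(pairs))) {
    g1 <- pairs[k, 1L]; g2 <- pairs[k, 2L]
    pc <- pair_window_counts(hs$seq[, g1], hs$seq[, g2],
                             as.integer(starts), as.integer(ends))
    usable <- pc$n_sites >= min_frac * (ends - starts)
    hit <- usable & (pc$diffs / pmax(pc$n_sites, 1L)) < max_div
    if (!any(hit)) next
    iv <- interval_set(hs$arm, starts[hit], ends[hit])   # merges overlaps
    segs[[length(segs) + 1L]] <-
      data.frame(genome1 = g1, genome2 = g2, arm = hs$arm,
                 start = iv$start, end = iv$end, stringsAsFactors = FALSE)
  }
  if (!length(segs))
    return(data.frame(genome1 = character(), genome2 = character(),
                      arm = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, segs)
}

#' Classify genome pairs as related from their IBD segments
#'
#' A within-population pair is flagged for masking when more than
#' `total_limit` (5 Mb) of summed genome-wide IBD lies outside recurrent
#' IBD regions, or when any single segment larger than `single_limit`
#' (5 Mb) overlaps a recurrent region.  For each flagged pair one genome
#' is designated for masking: the one with lower mean sequencing depth,
#' ties broken lexicographically by id.
#'
#' @param segments data frame from [scan_ibd()] (possibly several arms
#'   row-bound; within-population pairs only).
#' @param recurrent named list of `IntervalSet`s per arm delimiting
#'   recurrent IBD regions (default none).
#' @param meta metadata data frame with `genome_id` and `depth`, used to
#'   designate the genome to mask.
#' @param total_limit,single_limit thresholds in bp (defaults 5 Mb).
#' @return data frame with one row per flagged pair: `genome1`,
#'   `genome2`, `outside_bp`, `max_overlap_bp`, `masked_genome`.
#' @export
classify_relatedness <- function(segments, recurrent = list(), meta = NULL,
                                 total_limit = 5e6, single_limit = 5e6) {
  empty <- data.frame(genome1 = character(), genome2 = character(),
                      outside_bp = numeric(), max_overlap_bp = numeric(),
                      masked_genome = character(), stringsAsFactors = FALSE)
  if (!nrow(segments)) return(empty)
  key <- paste(segments$genome1, segments$genome2, sep = "\r")
  out <- lapply(split(segments, key), function(sg) {
    outside <- 0; biggest_overlapping <- 0
    for (i in seq_len(nrow(sg))) {
      len <- sg$end[i] - sg$start[i]
      rec <- recurrent[[sg$arm[i]]]
      ov <- 0
      if (!is.null(rec) && length(rec$start)) {
        ov <- sum(pmax(0, pmin(sg$end[i], rec$end) -
                         pmax(sg$start[i], rec$start)))
      }
      outside <- outside + (len - ov)
      if (ov > 0 && len > single_limit)
        biggest_overlapping <- max(biggest_overlapping, len)
    }
    flagged <- outside > total_limit || biggest_overlapping > single_limit
    if (!flagged) return(NULL)
    g <- c(sg$genome1[1L], sg$genome2[1L])
    if (!is.null(meta)) {
      dep <- meta$depth[match(g, meta$genome_id)]
      masked <- g[order(dep, g)][1L]
    } else {
      masked <- sort(g)[1L]
    }
    data.frame(genome1 = g[1L], genome2 = g[2L], outside_bp = outside,
               max_overlap_bp = biggest_overlapping,
               masked_genome = masked, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out
}

#' Mask IBD segments of related pairs from one genome of each pair
#'
#' For each flagged pair, all of the pair's IBD segments on this arm
#' (including those inside recurrent regions) are extended by `buffer` bp
#' on both sides (IBD may extend between window increments), clipped to
#' the arm, and masked to `N` in the designated genome only.
#'
#' @param hs a `HaplotypeSet`.
#' @param segments [scan_ibd()] output.
#' @param flagged [classify_relatedness()] output.
#' @param buffer bp added to each side of every segment (default 100 kb).
#' @return the masked `HaplotypeSet`.
#' @export
mask_relatedness <- function(hs, segments, flagged, buffer = 1e5) {
  if (!nrow(flagged)) return(hs)
  L <- seq_length(hs)
  for (i in seq_len(nrow(flagged))) {
    sg <- segments[segments$genome1 == flagged$genome1[i] &
                     segments$genome2 == flagged$genome2[i] &
                     segments$arm == hs$arm, , drop = FALSE]
    if (!nrow(sg)) next
    hs <- apply_mask(hs, interval_set(hs$arm,
                                      pmax(0, sg$start - buffer),
                                      pmin(L, sg$end + buffer),
                                      genome = flagged$masked_genome[i]))
  }
  hs
}
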