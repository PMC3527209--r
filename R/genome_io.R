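## Haploid consensus sequence I/O, interval masks, recombination maps and
## analysis-region definitions.
##
## Coordinates are 0-based half-open internally; exported report tables are
## 1-based closed (see `tract_table()`), exported BED is 0-based half-open.

#' Haploid consensus sequence set for one chromosome arm
#'
#' Container for aligned haploid consensus sequences sharing one reference
#' coordinate system, together with per-genome metadata.  Sequences are held
#' as a raw byte matrix (positions x genomes) over the alphabet `A,C,G,T,N`,
#' which keeps whole-arm pairwise comparisons fast and memory-light.
#'
#' @param sequences named character vector of equal-length sequences, or a
#'   raw matrix (positions x genomes) with column names.
#' @param meta data frame with columns `genome_id`, `population`, `depth`
#'   (mean sequencing depth, x-coverage) and `role` (one of
#'   `"african_panel"`, `"cosmopolitan_panel"`, `"query"`).  Missing
#'   metadata for any sequence is an error.
#' @param arm chromosome-arm label (e.g. `"2L"`).
#' @return An object of class `HaplotypeSet` with elements `arm`, `seq`
#'   (raw matrix) and `meta`.
#' @export
haplotype_set <- function(sequences, meta = NULL, arm = "arm") {
  if (is.matrix(sequences) && is.raw(sequences)) {
    m <- sequences
  } else {
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
      stop("sequences must have unique names (genome ids)")
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[lens != lens[1L]]
      stop("sequence length mismatch for genome(s): ",
           paste(bad, collapse = ", "))
    }
    m <- vapply(sequences, function(s) charToRaw(toupper(s)),
                raw(lens[1L]))
    if (length(sequences) == 1L) m <- matrix(m, ncol = 1L,
                                             dimnames = list(NULL, names(sequences)))
  }
  ## anything outside A,C,G,T becomes N
  m[!(m %in% .BASES[1:4])] <- .RAW_N
  ids <- colnames(m)
  if (is.null(meta)) {
    meta <- data.frame(genome_id = ids, population = "pop",
                       depth = NA_real_, role = "query",
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("genome_id", "population", "depth", "role")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(ids, meta$genome_id)
  if (length(absent))
    stop("missing metadata for genome(s): ", paste(absent, collapse = ", "))
  meta <- meta[match(ids, meta$genome_id), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(arm = arm, seq = m, meta = meta), class = "HaplotypeSet")
}

#' @export
print.HaplotypeSet <- function(x, ...) {
  cat("HaplotypeSet: arm ", x$arm, ", ", ncol(x$seq), " genome(s) x ",
      nrow(x$seq), " bp\n", sep = "")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(table(x$meta$population)),
                    table(x$meta$population)), collapse = ", "), "\n")
  invisible(x)
}

#' Number of genomes and sequence length of a HaplotypeSet
#' @param hs a `HaplotypeSet`.
#' @return integer.
#' @export
n_genomes <- function(hs) ncol(hs$seq)

#' @rdname n_genomes
#' @export
seq_length <- function(hs) nrow(hs$seq)

#' Subset a HaplotypeSet by genome id
#' @param hs a `HaplotypeSet`.
#' @param ids genome ids to keep.
#' @return a `HaplotypeSet`.
#' @export
subset_genomes <- function(hs, ids) {
  stopifnot(all(ids %in% colnames(hs$seq)))
  haplotype_set(hs$seq[, ids, drop = FALSE],
                hs$meta[match(ids, hs$meta$genome_id), , drop = FALSE],
                arm = hs$arm)
}

#' Read aligned haploid consensus sequences from FASTA
#'
#' Reads one or more FASTA files (record id = genome id), upper-cases the
#' sequences, maps any symbol outside `A,C,G,T` to `N`, verifies that all
#' sequences have equal length, and attaches metadata.
#'
#' @param fasta character vector of FASTA file paths.
#' @param meta metadata data frame or path to a TSV with columns
#'   `genome_id`, `population`, `depth`, `role`.
#' @param arm chromosome-arm label.
#' @return a [haplotype_set()].
#' @export
read_haplotype_set <- function(fasta, meta, arm = "arm") {
  recs <- do.call(c, lapply(fasta, Biostrings::readDNAStringSet))
  seqs <- as.character(recs)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(meta) && length(meta) == 1L)
    meta <- read.delim(meta, stringsAsFactors = FALSE)
  haplotype_set(seqs, meta, arm = arm)
}

#' Write a HaplotypeSet to FASTA
#' @param hs a `HaplotypeSet`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_haplotype_set <- function(hs, path) {
  seqs <- apply(hs$seq, 2L, rawToChar)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Genomic interval set
#'
#' Sorted, merged 0-based half-open intervals on one arm, optionally scoped
#' to a single genome (e.g. per-genome masks).  Overlapping or touching
#' intervals are merged on construction.
#'
#' @param arm chromosome-arm label.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param genome optional genome id scope.
#' @return an object of class `IntervalSet` with `start`/`end` vectors.
#' @export
interval_set <- function(arm = "arm", start = integer(), end = integer(),
                         genome = NULL) {
  stopifnot(length(start) == length(end))
  if (length(start) && any(start >= end)) stop("need start < end")
  if (length(start)) {
    ir <- IRanges::reduce(IRanges::IRanges(start = start + 1, end = end))
    start <- IRanges::start(ir) - 1L
    end <- IRanges::end(ir)
  }
  structure(list(arm = arm, start = as.numeric(start), end = as.numeric(end),
                 genome = genome), class = "IntervalSet")
}

#' @export
print.IntervalSet <- function(x, ...) {
  cat("IntervalSet: arm ", x$arm, ", ", length(x$start), " interval(s), ",
      sum(x$end - x$start), " bp", if (!is.null(x$genome))
        paste0(", genome ", x$genome), "\n", sep = "")
  invisible(x)
}

#' Total length of an IntervalSet in bp
#' @param x an `IntervalSet`.
#' @return numeric total span.
#' @export
interval_width <- function(x) sum(x$end - x$start)

#' Apply an interval mask to a HaplotypeSet
#'
#' Sets masked positions to `N`.  If the mask carries a genome scope only
#' that genome is masked, otherwise all genomes are.  Masking is idempotent
#' and never un-masks.
#'
#' @param hs a `HaplotypeSet`.
#' @param mask an `IntervalSet` (or list of them) within the sequence span.
#' @return the masked `HaplotypeSet`.
#' @export
apply_mask <- function(hs, mask) {
  masks <- if (inherits(mask, "IntervalSet")) list(mask) else mask
  L <- seq_length(hs)
  for (mk in masks) {
    if (!length(mk$start)) next
    if (any(mk$start < 0) || any(mk$end > L))
      stop("mask interval out of range [0, ", L, ")")
    idx <- unlist(mapply(function(s, e) seq.int(s + 1L, e), mk$start, mk$end,
                         SIMPLIFY = FALSE), use.names = FALSE)
    if (is.null(mk$genome)) {
      hs$seq[idx, ] <- .RAW_N
    } else {
      stopifnot(mk$genome %in% colnames(hs$seq))
      hs$seq[idx, mk$genome] <- .RAW_N
    }
  }
  hs
}

#' Recombination map for one chromosome arm
#'
#' Piecewise-linear cumulative genetic map built from local rates.  The
#' sex-averaged arm adjustment (map distances multiplied by 1/2 on autosomes
#' and 2/3 on the X, reflecting absence of crossing-over in males) is
#' applied at construction when `adjust = TRUE`.
#'
#' @param arm arm label; arms whose name starts with `"X"` take the 2/3
#'   factor, all others 1/2.
#' @param pos ascending bp positions (knots), 0-based.
#' @param rate local rate in cM/Mb on the interval starting at each knot
#'   (last value unused); give either `rate` or `cum`.
#' @param cum cumulative cM at each knot (already adjusted if
#'   `adjust = FALSE` semantics are wanted).
#' @param adjust apply the arm adjustment factor to rates (default `TRUE`).
#' @return an object of class `RecombinationMap` with knot positions and
#'   cumulative (adjusted) cM.
#' @export
recombination_map <- function(arm, pos, rate = NULL, cum = NULL,
                              adjust = TRUE) {
  stopifnot(!is.unsorted(pos, strictly = TRUE))
  fac <- if (adjust) arm_adjustment(arm) else 1
  if (is.null(cum)) {
    stopifnot(!is.null(rate), length(rate) == length(pos))
    span <- diff(pos) / 1e6
    cum <- c(0, cumsum(rate[-length(rate)] * span)) * fac
  } else {
    cum <- cum * fac
  }
  if (is.unsorted(cum)) stop("cumulative cM must be non-decreasing")
  structure(list(arm = arm, pos = as.numeric(pos), cum = as.numeric(cum),
                 factor = fac), class = "RecombinationMap")
}

#' @rdname recombination_map
#' @export
arm_adjustment <- function(arm) if (startsWith(arm, "X")) 2 / 3 else 1 / 2

#' Read a recombination map TSV (columns arm, pos, cM_per_Mb)
#' @param path TSV path.
#' @param arm arm to extract.
#' @param adjust apply the arm adjustment factor (default `TRUE`).
#' @return a [recombination_map()].
#' @export
read_recombination_map <- function(path, arm, adjust = TRUE) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[tab$arm == arm, , drop = FALSE]
  if (!nrow(tab)) stop("no map rows for arm ", arm)
  recombination_map(arm, tab$pos, rate = tab$cM_per_Mb, adjust = adjust)
}

#' Genetic length of a physical span
#'
#' Linear interpolation of the cumulative (arm-adjusted) genetic map.
#'
#' @param map a [recombination_map()].
#' @param start,end bp span, 0-based half-open, within map support.
#' @return genetic length in cM.
#' @export
cm_length <- function(map, start, end) {
  if (any(start > end)) stop("need start <= end")
  lo <- map$pos[1L]; hi <- map$pos[length(map$pos)]
  if (any(start < lo) || any(end > hi))
    stop("query outside map support [", lo, ", ", hi, "]")
  at <- function(x) approx(map$pos, map$cum, xout = x, ties = "ordered")$y
  at(end) - at(start)
}

## Mid-chromosomal high-recombination intervals used for most diversity
## analyses (0-based half-open; the source table is 1-based closed).
.MID_CHROMOSOMAL <- list(
  X  = c(2222391L - 1L, 20054556L),
  `2L` = c(464654L - 1L, 15063839L),
  `2R` = c(9551429L - 1L, 20635011L),
  `3L` = c(1979673L - 1L, 12286842L),
  `3R` = c(12949344L - 1L, 25978664L))

#' Mid-chromosomal analysis regions
#'
#' The five major-arm intervals of higher recombination (excluding
#' centromere- and telomere-proximal spans below 2e-8 crossovers/bp/gen)
#' used for diversity and differentiation analyses.
#'
#' @param arm optional single arm; default returns all five.
#' @return a named list of `IntervalSet`s (or one `IntervalSet`).
#' @export
mid_chromosomal_regions <- function(arm = NULL) {
  mk <- function(a) interval_set(a, .MID_CHROMOSOMAL[[a]][1L],
                                 .MID_CHROMOSOMAL[[a]][2L])
  if (!is.null(arm)) {
    if (!arm %in% names(.MID_CHROMOSOMAL)) stop("unknown arm ", arm)
    return(mk(arm))
  }
  setNames(lapply(names(.MID_CHROMOSOMAL), mk), names(.MID_CHROMOSOMAL))
}

#' Derive the analysis region of an arm from its recombination map
#'
#' Finds the single maximal run of map intervals whose adjusted local rate
#' meets the low/high recombination threshold (2e-8 crossovers/bp/gen,
#' i.e. 1 cM/Mb after arm adjustment on autosomes); narrow rate valleys
#' shorter than `min_gap` bp inside the run are ignored.
#'
#' @param map a [recombination_map()].
#' @param threshold_cm_mb adjusted-rate threshold in cM/Mb (default
#'   `2e-8 * 1e8 * arm factor`).
#' @param min_gap ignore sub-threshold valleys shorter than this (bp).
#' @return an `IntervalSet` with the single analysis interval.
#' @export
analysis_region_from_map <- function(map, threshold_cm_mb = NULL,
                                     min_gap = 5e5) {
  if (is.null(threshold_cm_mb)) threshold_cm_mb <- 2 * map$factor
  pos <- map$pos
  rate <- diff(map$cum) / (diff(pos) / 1e6)   # adjusted cM/Mb per interval
  hi <- rate >= threshold_cm_mb
  ## close short valleys
  r <- rle(hi)
  len_bp <- vapply(seq_along(r$lengths), function(i) {
    j <- sum(r$lengths[seq_len(i)])
    pos[j + 1L] - pos[j + 1L - r$lengths[i]]
  }, numeric(1))
  r$values[!r$values & len_bp < min_gap] <- TRUE
  hi <- inverse.rle(r)
  if (!any(hi)) stop("no interval above recombination threshold")
  r2 <- rle(hi)
  ends <- cumsum(r2$lengths); starts <- ends - r2$lengths + 1L
  runs <- which(r2$values)
  spans <- pos[ends[runs] + 1L] - pos[starts[runs]]
  k <- runs[which.max(spans)]
  interval_set(map$arm, pos[starts[k]], pos[ends[k] + 1L])
}

#' Extract short-intron neutral reference sites
#'
#' Returns the positions of bp 8..30 (counted 1-based from the 5' end of
#' the intron on its annotated strand) of introns at most `max_len` bp
#' long: the classic near-neutral site class in Drosophila.
#'
#' @param annotation GFF3 path, or a data frame with columns `seqid`,
#'   `type`, `start`, `end` (1-based closed, as in GFF3) and `strand`.
#' @param arm arm (seqid) to extract.
#' @param max_len maximum intron length (default 65 bp).
#' @param from,to 1-based offsets of the retained block within the intron
#'   (defaults 8 and 30).
#' @return an `IntervalSet` of the retained sites (0-based half-open).
#' @export
extract_short_intron_sites <- function(annotation, arm, max_len = 65,
                                       from = 8, to = 30) {
  ann <- read_annotation(annotation)
  ann <- ann[ann$type == "intron" & ann$seqid == arm, , drop = FALSE]
  bad <- is.na(ann$start) | is.na(ann$end) | ann$end < ann$start |
    !(ann$strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " malformed intron record(s) skipped")
    ann <- ann[!bad, , drop = FALSE]
  }
  len <- ann$end - ann$start + 1
  ann <- ann[len <= max_len & len >= to, , drop = FALSE]
  if (!nrow(ann)) return(interval_set(arm))
  plus <- ann$strand == "+"
  s1 <- ifelse(plus, ann$start + from - 1, ann$end - to + 1)   # 1-based
  e1 <- ifelse(plus, ann$start + to - 1, ann$end - from + 1)
  interval_set(arm, start = s1 - 1, end = e1)
}

#' Read a GFF3 annotation into a plain data frame
#'
#' Minimal GFF3 reader retaining `seqid`, `type`, `start`, `end`, `strand`
#' and a `gene_id` extracted from the attribute column (first of
#' `gene_id`, `Parent`, `ID` present).  Data frames pass through
#' unchanged (after column checks), so all annotation-consuming functions
#' accept either form.
#'
#' @param annotation GFF3 path or data frame.
#' @return data frame.
#' @export
read_annotation <- function(annotation) {
  if (is.data.frame(annotation)) {
    need <- c("seqid", "type", "start", "end", "strand")
    stopifnot(all(need %in% names(annotation)))
    if (is.null(annotation$gene_id)) annotation$gene_id <- NA_character_
    return(annotation)
  }
  tab <- read.delim(annotation, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("seqid", "source", "type", "start", "end",
                                  "score", "strand", "phase", "attributes"))
  att <- tab$attributes
  pick <- function(key) {
    hit <- regexpr(paste0("(?:^|;)", key, "=[^;]*"), att, perl = TRUE)
    val <- rep(NA_character_, length(att))
    ok <- hit > 0L
    val[ok] <- sub(paste0("^;?", key, "="), "", regmatches(att, hit))
    val
  }
  gid <- pick("gene_id")
  gid <- ifelse(is.na(gid), pick("Parent"), gid)
  gid <- ifelse(is.na(gid), pick("ID"), gid)
  data.frame(seqid = as.character(tab$seqid), type = tab$type,
             start = tab$start, end = tab$end, strand = tab$strand,
             gene_id = gid, stringsAsFactors = FALSE)
}

#' Write an IntervalSet (or tract list) as BED
#' @param x an `IntervalSet` or a data frame with `arm`, `start`, `end`.
#' @param path output path.
#' @param names optional name column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, names = NULL) {
  if (inherits(x, "IntervalSet"))
    x <- data.frame(arm = x$arm, start = x$start, end = x$end)
  df <- data.frame(x$arm, format(x$start, scientific = FALSE, trim = TRUE),
                   format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(names)) df$name <- names
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
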