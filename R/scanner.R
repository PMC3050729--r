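# PBM-mapping: moving average of W overlapping octamer E-scores along a
# sequence, probe scoring and thresholded site calling.
#
# A window of W overlapping octamers spans W + 7 bases; its score is the
# mean of the W octamer E-scores.  W = 7 is the default (the largest number
# of overlapping octamers that still share at least one common base); the
# homeodomain default threshold is 0.37.  Nuclear-receptor-class factors
# such as Hnf4a use W = 6 and a lower threshold.

#' Scan configuration
#'
#' @param window Number of overlapping octamers averaged per window
#'   (default 7).
#' @param threshold Minimum moving average for a site call (default 0.37).
#' @param skip_masked If TRUE, windows overlapping soft-masked (lowercase)
#'   sequence are excluded.  Default FALSE: raw genome sequence is scanned
#'   as-is.
#' @return A `scan_config` list.
#' @export
scan_config <- function(window = 7L, threshold = 0.37, skip_masked = FALSE) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be a positive integer")
  if (threshold < -0.5 || threshold > 0.5)
    stop("threshold must lie in [-0.5, 0.5]")
  structure(list(window = window, threshold = threshold,
                 skip_masked = isTRUE(skip_masked)),
            class = "scan_config")
}

#' Moving-average E-score profile of one sequence
#'
#' Window i (0-based start i) covers octamers starting at i .. i + W - 1
#' and spans W + 7 bases; its score is the mean of those W E-scores,
#' computed with a vectorized moving sum.  Windows containing any
#' unscoreable octamer (non-ACGT base) are masked; with
#' `cfg$skip_masked`, windows touching soft-masked bases are masked too.
#'
#' @param seq Character scalar DNA sequence (length >= window + 7).
#' @param array A `dense_score_array` from [build_dense_array()].
#' @param cfg A [scan_config()].
#' @param softmask Optional logical vector (per base) of soft-mask flags.
#' @param seq_name Label carried on the profile.
#' @return A `scan_profile`: list with `seq_name`, `window_start` (0-based
#'   integer vector), `score` (NA where masked) and `valid`.
#' @export
score_profile <- function(seq, array, cfg = scan_config(), softmask = NULL,
                          seq_name = "seq") {
  W <- cfg$window
  L <- nchar(seq)
  if (L < W + 7L)
    stop("no scoreable window: sequence length ", L,
         " < minimum length ", W + 7L)
  codes <- octamer_codes(seq)                  # length L - 7
  e <- unclass(array)[codes + 1L]
  bad <- is.na(e)
  e0 <- ifelse(bad, 0, e)
  wsum <- stats::filter(e0, rep(1, W), sides = 1)   # sum ending at i
  wbad <- stats::filter(as.numeric(bad), rep(1, W), sides = 1)
  n_win <- L - W - 6L                          # window starts 0 .. L-W-7
  idx <- seq.int(W, length(e))                 # window starting at i ends at i+W-1
  score <- as.numeric(wsum[idx]) / W
  valid <- as.numeric(wbad[idx]) == 0
  if (cfg$skip_masked && !is.null(softmask)) {
    msum <- stats::filter(as.numeric(softmask), rep(1, W + 7L), sides = 1)
    valid <- valid & as.numeric(msum[seq.int(W + 7L, L)]) == 0
  }
  score[!valid] <- NA_real_
  structure(list(seq_name = seq_name,
                 window_start = 0:(n_win - 1L),
                 score = score, valid = valid,
                 window = W, threshold = cfg$threshold),
            class = "scan_profile")
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("PBM-mapping profile of %s: %d windows (W=%d), %d valid\n",
              x$seq_name, length(x$score), x$window, sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  score range [%.5f, %.5f], max at window start %d\n",
                min(x$score, na.rm = TRUE), max(x$score, na.rm = TRUE),
                x$window_start[which.max(x$score)]))
  invisible(x)
}

#' Score a probe: max single E-score and PBM-mapping score
#'
#' `max_escore` is the maximum single-octamer E-score anywhere on the
#' probe; `pbm_mapping_score` is the maximum W-octamer moving average.  A
#' mean of W values never exceeds their max, so
#' `pbm_mapping_score <= max_escore` always.  If the probe is shorter than
#' W + 7 (no full window) the mapping score is NA and flagged.
#'
#' @inheritParams score_profile
#' @return A `probe_score` list: `max_escore`, `pbm_mapping_score`,
#'   `best_octamer`, `best_window_start`, `has_window`.
#' @export
score_probe <- function(seq, array, cfg = scan_config()) {
  L <- nchar(seq)
  if (L < 8L) stop("probe shorter than 8 bases")
  codes <- octamer_codes(seq)
  e <- unclass(array)[codes + 1L]
  if (all(is.na(e)))
    stop("no scoreable octamer in probe (ambiguity codes throughout)")
  imax <- which.max(e)                          # leftmost max wins
  res <- list(max_escore = e[imax],
              best_octamer = substr(toupper(seq), imax, imax + 7L),
              pbm_mapping_score = NA_real_,
              best_window_start = NA_integer_,
              has_window = FALSE)
  if (L >= cfg$window + 7L) {
    prof <- score_profile(seq, array, cfg)
    if (any(prof$valid)) {
      j <- which.max(prof$score)
      res$pbm_mapping_score <- prof$score[j]
      res$best_window_start <- prof$window_start[j]
      res$has_window <- TRUE
    }
  }
  structure(res, class = "probe_score")
}

#' @export
print.probe_score <- function(x, ...) {
  cat(sprintf("max E-score = %.5f (octamer %s)\n", x$max_escore, x$best_octamer))
  if (x$has_window)
    cat(sprintf("PBM-mapping score = %.5f (window start %d)\n",
                x$pbm_mapping_score, x$best_window_start))
  else cat("PBM-mapping score = NA (no full window on probe)\n")
  invisible(x)
}

#' Call binding sites on sequences
#'
#' Maximal runs of valid windows with moving average strictly above the
#' threshold are merged into one site per run; the site interval covers
#' all bases of all its windows (first window start to last window start
#' + W + 7, 0-based half-open).  Sites are sorted by (sequence, start).
#'
#' @param records A `dna_records` list, named character vector, or single
#'   string.
#' @param array A `dense_score_array`.
#' @param cfg A [scan_config()].
#' @param chunk_size Optional: score each sequence in chunks of about this
#'   many window starts (identical output to whole-sequence scanning;
#'   bounds memory on chromosome-scale input).
#' @return A `predicted_sites` data.frame: seq_name, start, end,
#'   peak_score, peak_octamer, n_windows; attributes record window and
#'   threshold.
#' @export
call_sites <- function(records, array, cfg = scan_config(),
                       chunk_size = NULL) {
  records <- as_dna_records(records)
  out <- list()
  for (nm in names(records)) {
    rec <- records[[nm]]
    L <- nchar(rec$sequence)
    if (L < cfg$window + 7L) next
    if (is.null(chunk_size)) {
      prof <- score_profile(rec$sequence, array, cfg,
                            softmask = rec$softmask, seq_name = nm)
      score <- prof$score
      valid <- prof$valid
    } else {
      # chunked scan: each chunk recomputes a block of window starts from
      # the W+6 extra bases it needs; concatenation covers each start once
      n_win <- L - cfg$window - 6L
      score <- numeric(n_win); valid <- logical(n_win)
      cs <- as.integer(chunk_size)
      for (s0 in seq.int(0L, n_win - 1L, by = cs)) {
        s1 <- min(s0 + cs - 1L, n_win - 1L)
        sub <- substr(rec$sequence, s0 + 1L, s1 + cfg$window + 7L)
        subm <- rec$softmask[(s0 + 1L):(s1 + cfg$window + 7L)]
        p <- score_profile(sub, array, cfg, softmask = subm, seq_name = nm)
        score[(s0 + 1L):(s1 + 1L)] <- p$score
        valid[(s0 + 1L):(s1 + 1L)] <- p$valid
      }
    }
    above <- valid & !is.na(score) & score > cfg$threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (k in runs) {
      w0 <- starts[k] - 1L                 # 0-based first window start
      w1 <- ends[k] - 1L
      seg_scores <- score[starts[k]:ends[k]]
      pk <- which.max(seg_scores)          # leftmost max
      # peak octamer: max single E-score among octamer starts inside the site
      ostart <- w0 + 1L
      oend <- w1 + cfg$window              # last octamer start (1-based)
      ocodes <- octamer_codes(substr(rec$sequence, ostart, oend + 7L))
      oe <- unclass(array)[ocodes + 1L]
      oi <- which.max(oe)
      out[[length(out) + 1L]] <- data.frame(
        seq_name = nm, start = w0, end = w1 + cfg$window + 7L,
        peak_score = seg_scores[pk],
        peak_octamer = substr(rec$sequence, ostart + oi - 1L, ostart + oi + 6L),
        n_windows = w1 - w0 + 1L,
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_name = character(), start = integer(), end = integer(),
               peak_score = numeric(), peak_octamer = character(),
               n_windows = integer(), stringsAsFactors = FALSE)
  sites <- sites[order(sites$seq_name, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("predicted_sites", "data.frame"),
            window = cfg$window, threshold = cfg$threshold)
}

#' Call sites inside defined regions of a genome
#'
#' Each region is scanned independently and site coordinates are lifted
#' back to the parent sequence.  Regions on the minus strand are scanned
#' as-is: E-score reverse-complement symmetry makes the score strandless.
#' Sites whose genomic interval is reported for more than one region are
#' flagged `multi_region`.
#'
#' @param records Genome sequences (`dna_records` or named character).
#' @param regions data.frame with columns chrom, start, end (0-based
#'   half-open) and optionally name, strand (see [read_bed()]).
#' @param array A `dense_score_array`.
#' @param cfg A [scan_config()].
#' @return A `predicted_sites` data.frame with extra columns `region` and
#'   `multi_region`.
#' @export
scan_regions <- function(records, regions, array, cfg = scan_config()) {
  records <- as_dna_records(records)
  if (is.null(regions$name)) regions$name <- paste0("region", seq_len(nrow(regions)))
  out <- list()
  for (i in seq_len(nrow(regions))) {
    chrom <- regions$chrom[i]
    if (!chrom %in% names(records))
      stop("region ", regions$name[i], ": unknown sequence ", sQuote(chrom))
    L <- nchar(records[[chrom]]$sequence)
    if (regions$start[i] < 0 || regions$end[i] > L)
      stop("region ", regions$name[i], " [", regions$start[i], ",",
           regions$end[i], ") out of bounds for ", chrom, " (length ", L, ")")
    sub <- list(sequence = substr(records[[chrom]]$sequence,
                                  regions$start[i] + 1L, regions$end[i]),
                softmask = records[[chrom]]$softmask[
                  (regions$start[i] + 1L):regions$end[i]])
    recs <- structure(stats::setNames(list(sub), chrom), class = "dna_records")
    s <- call_sites(recs, array, cfg)
    if (nrow(s) == 0L) next
    s$start <- s$start + regions$start[i]
    s$end <- s$end + regions$start[i]
    s$region <- regions$name[i]
    out[[length(out) + 1L]] <- as.data.frame(s)
  }
  sites <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_name = character(), start = integer(), end = integer(),
               peak_score = numeric(), peak_octamer = character(),
               n_windows = integer(), region = character(),
               stringsAsFactors = FALSE)
  key <- paste(sites$seq_name, sites$start, sites$end)
  sites$multi_region <- key %in% key[duplicated(key)]
  sites <- sites[order(sites$seq_name, sites$start), , drop = FALSE]
  rownames(sites) <- NULL
  structure(sites, class = c("predicted_sites", "data.frame"),
            window = cfg$window, threshold = cfg$threshold)
}

#' Build promoter regions around transcription start sites
#'
#' Strand-aware: for a plus-strand TSS at p the region is
#' `[p - upstream, p + downstream)`; for minus strand
#' `[p - downstream, p + upstream)`.  Defaults follow the regulatory-region
#' convention of 2.5 kb upstream to 1 kb downstream.
#'
#' @param tss data.frame with columns gene, chrom, pos (0-based TSS
#'   coordinate) and strand ("+"/"-").
#' @param upstream,downstream Extents in bp.
#' @param seq_lengths Optional named vector to clip regions to sequence
#'   bounds.
#' @return Regions data.frame (chrom, start, end, name, strand).
#' @export
promoter_regions <- function(tss, upstream = 2500L, downstream = 1000L,
                             seq_lengths = NULL) {
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)))
  minus <- tss$strand == "-"
  start <- ifelse(minus, tss$pos - downstream, tss$pos - upstream)
  end <- ifelse(minus, tss$pos + upstream, tss$pos + downstream)
  start <- pmax(start, 0L)
  if (!is.null(seq_lengths))
    end <- pmin(end, unname(seq_lengths[tss$chrom]))
  data.frame(chrom = tss$chrom, start = as.integer(start),
             end = as.integer(end), name = tss$gene, strand = tss$strand,
             stringsAsFactors = FALSE)
}
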