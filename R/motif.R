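# Core-motif analytics: top-octamer census, first-position histograms,
# dual-core orientation classes, and TSS-proximity enrichment.
#
# A "core" is a short invariant tetramer inside the binding motif (AAGT is
# the canonical homeodomain core for Nkx2.2-class factors; GAGT the
# low-affinity alternative).  An octamer "contains" a core if the core or
# its reverse complement occurs anywhere in it, so both strands are
# inspected at once.

#' Which octamers contain a core
#'
#' @param core A 4-mer (any k-mer works).
#' @param count_revcomp Also match the reverse complement of the core.
#' @return Logical vector over all 65,536 octamers in code order.
#' @export
octamers_with_core <- function(core, count_revcomp = TRUE) {
  octs <- all_octamers()
  hit <- grepl(core, octs, fixed = TRUE)
  if (count_revcomp) {
    rc <- reverse_complement(core)
    if (rc != core) hit <- hit | grepl(rc, octs, fixed = TRUE)
  }
  hit
}

#' Census of core sequences among top-scoring octamers
#'
#' Octamers with E-score above `cutoff` are selected (each
#' octamer/reverse-complement pair counted once) and assigned to the first
#' core in `cores` they contain, in order — so with the default
#' `c("AAGT", "GAGT")` an octamer containing both counts as AAGT.  Group
#' mean E-scores are computed over *all* octamers containing each core,
#' with the mean over all 65,536 octamers as baseline, and each group is
#' compared to the all-octamer background by a one-sided Welch t-test.
#'
#' @param table An [escore_table].
#' @param cutoff Top-octamer selection threshold (default 0.45).
#' @param cores Ordered character vector of core 4-mers (precedence order).
#' @param count_revcomp Match cores on either strand (default TRUE).
#' @return A `core_census` list: `n_top`, `counts` (per core plus
#'   `neither`), `means` (per core, over all containing octamers),
#'   `mean_all`, `p_values`, `cutoff`, `cores`.
#' @export
core_census <- function(table, cutoff = 0.45, cores = c("AAGT", "GAGT"),
                        count_revcomp = TRUE) {
  stopifnot(inherits(table, "escore_table"))
  if (cutoff < -0.5 || cutoff > 0.5) stop("cutoff must lie in [-0.5, 0.5]")
  if (any(nchar(cores) != 4L | grepl("[^ACGT]", cores)))
    stop("cores must be ACGT 4-mers")
  v <- unname(table$scores)
  codes <- 0:65535
  rc <- revcomp_codes()
  canon <- codes <= rc[codes + 1L]
  top <- canon & v > cutoff
  n_top <- sum(top)
  if (n_top == 0L) warning("no octamers above cutoff ", cutoff)

  contains <- lapply(cores, octamers_with_core, count_revcomp = count_revcomp)
  names(contains) <- cores

  counts <- integer(length(cores))
  names(counts) <- cores
  unassigned <- top
  for (co in cores) {
    hit <- unassigned & contains[[co]]
    counts[co] <- sum(hit)
    unassigned <- unassigned & !hit
  }
  n_neither <- sum(unassigned)

  means <- vapply(cores, function(co) mean(v[contains[[co]]]), numeric(1))
  p_values <- vapply(cores, function(co) {
    if (n_top == 0L || sum(contains[[co]]) < 2L) return(NA_real_)
    stats::t.test(v[contains[[co]]], v, alternative = "greater")$p.value
  }, numeric(1))

  structure(list(n_top = n_top,
                 counts = c(counts, neither = n_neither),
                 means = means, mean_all = mean(v),
                 p_values = p_values, cutoff = cutoff, cores = cores),
            class = "core_census")
}

#' @export
print.core_census <- function(x, ...) {
  cat(sprintf("Core census at E-score cutoff %.2f: %d top octamer pairs\n",
              x$cutoff, x$n_top))
  for (co in x$cores)
    cat(sprintf("  %s: %d above cutoff (%.0f%%), mean E-score %.3f, P = %.3g\n",
                co, x$counts[co],
                if (x$n_top > 0) 100 * x$counts[co] / x$n_top else 0,
                x$means[co], x$p_values[co]))
  cat(sprintf("  neither: %d;  mean over all octamers %.3f\n",
              x$counts["neither"], x$mean_all))
  invisible(x)
}

#' First-position core histogram
#'
#' Bins all octamer E-scores into bins of `bin_width` spanning
#' `[-0.5, 0.5]` (left-closed; top bin right-closed) and reports, per bin,
#' the fraction of octamers containing each first-position variant
#' `X + suffix` for X in A/C/G/T (reverse-complement-aware).  Fractions
#' across the four variants need not sum to 1: an octamer can contain
#' several cores.
#'
#' @param table An [escore_table].
#' @param suffix 3-mer core suffix (default "AGT").
#' @param bin_width Bin width; must divide 1.0 evenly (default 0.10).
#' @param count_revcomp Match cores on either strand.
#' @return A `core_histogram` list: `bin_edges`, `bin_n` (octamers per
#'   bin), `fractions` (bins x 4 matrix), `empty` (logical per bin).
#' @export
first_position_histogram <- function(table, suffix = "AGT", bin_width = 0.10,
                                     count_revcomp = TRUE) {
  stopifnot(inherits(table, "escore_table"))
  if (nchar(suffix) != 3L || grepl("[^ACGT]", suffix))
    stop("suffix must be an ACGT 3-mer")
  nb <- 1 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 1.0 evenly")
  nb <- as.integer(round(nb))
  edges <- seq(-0.5, 0.5, length.out = nb + 1L)
  v <- unname(table$scores)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bases <- c("A", "C", "G", "T")
  frac <- matrix(0, nrow = nb, ncol = 4L,
                 dimnames = list(NULL, paste0(bases, suffix)))
  bin_n <- tabulate(bin, nbins = nb)
  for (j in seq_along(bases)) {
    hit <- octamers_with_core(paste0(bases[j], suffix), count_revcomp)
    hits_per_bin <- tabulate(bin[hit], nbins = nb)
    frac[, j] <- ifelse(bin_n > 0, hits_per_bin / bin_n, 0)
  }
  structure(list(bin_edges = edges, bin_n = bin_n, fractions = frac,
                 empty = bin_n == 0L, suffix = suffix),
            class = "core_histogram")
}

#' @export
print.core_histogram <- function(x, ...) {
  cat("E-score histogram of X", x$suffix, " core content (fractions per bin)\n",
      sep = "")
  df <- data.frame(bin = sprintf("[%.2f,%.2f%s", utils::head(x$bin_edges, -1),
                                 x$bin_edges[-1],
                                 c(rep(")", length(x$bin_n) - 1), "]")),
                   n = x$bin_n, round(x$fractions, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Enumerate dual-core octamers
#'
#' An octamer is dual-core when its two disjoint tetramer halves
#' (positions 1-4 and 5-8) are each a configured core or a core's reverse
#' complement.  Content class is `identical` (both halves from the same
#' underlying core) or `mixed`; orientation is `inline` (both forward or
#' both reverse-complement) or `revcomp` (one of each).
#'
#' @param table An [escore_table].
#' @param cores Core 4-mers (default `c("AAGT", "GAGT")`).
#' @return data.frame: octamer, left_core, left_orient, right_core,
#'   right_orient, content, orientation, escore; one row per octamer in
#'   code order.
#' @export
dual_core_scan <- function(table, cores = c("AAGT", "GAGT")) {
  stopifnot(inherits(table, "escore_table"))
  forms <- data.frame(seq = c(cores, reverse_complement(cores)),
                      core = rep(cores, 2),
                      orient = rep(c("fwd", "rc"), each = length(cores)),
                      stringsAsFactors = FALSE)
  forms <- forms[!duplicated(forms$seq), ]   # palindromic core: fwd wins
  octs <- all_octamers()
  left <- substr(octs, 1L, 4L)
  right <- substr(octs, 5L, 8L)
  li <- match(left, forms$seq)
  ri <- match(right, forms$seq)
  keep <- !is.na(li) & !is.na(ri)
  li <- li[keep]; ri <- ri[keep]
  df <- data.frame(
    octamer = octs[keep],
    left_core = forms$core[li], left_orient = forms$orient[li],
    right_core = forms$core[ri], right_orient = forms$orient[ri],
    stringsAsFactors = FALSE)
  df$content <- ifelse(df$left_core == df$right_core, "identical", "mixed")
  df$orientation <- ifelse(df$left_orient == df$right_orient,
                           "inline", "revcomp")
  df$escore <- unname(table$scores[df$octamer])
  df
}

#' Signed distance from each TSS to its nearest site
#'
#' Distance is measured from the TSS to the site midpoint, strand-aware:
#' negative means upstream of the TSS.  Genes whose chromosome carries no
#' site get NA.
#'
#' @param sites A `predicted_sites` data.frame (or any data.frame with
#'   seq_name, start, end).
#' @param tss data.frame with columns gene, chrom, pos, strand.
#' @return Named numeric vector of signed distances, one per gene.
#' @export
nearest_tss_distance <- function(sites, tss) {
  stopifnot(all(c("gene", "chrom", "pos", "strand") %in% names(tss)))
  mid <- (sites$start + sites$end) / 2
  out <- vapply(seq_len(nrow(tss)), function(i) {
    on <- sites$seq_name == tss$chrom[i]
    if (!any(on)) return(NA_real_)
    d <- mid[on] - tss$pos[i]
    if (tss$strand[i] == "-") d <- -d
    d[which.min(abs(d))]
  }, numeric(1))
  stats::setNames(out, tss$gene)
}

#' TSS-proximity enrichment between two gene sets
#'
#' Builds the 2x2 table (gene has / has no site within the window) x
#' (set A / set B) and applies Fisher's exact test.  The window is
#' upstream-only by default: a gene counts as "near" when its nearest-site
#' distance d satisfies `-window <= d <= 0`.
#'
#' @param dist_a,dist_b Per-gene nearest-site distances (from
#'   [nearest_tss_distance()]); NA means no site.
#' @param window Window size in bp (default 500).
#' @param upstream_only If FALSE, use `|d| <= window` instead.
#' @return A `tss_enrichment` list: `table` (2x2), `odds_ratio`, `p_value`,
#'   `window`.
#' @export
tss_proximity_enrichment <- function(dist_a, dist_b, window = 500,
                                     upstream_only = TRUE) {
  if (length(dist_a) == 0L || length(dist_b) == 0L)
    stop("empty gene set")
  near <- function(d) !is.na(d) &
    (if (upstream_only) d >= -window & d <= 0 else abs(d) <= window)
  tab <- matrix(c(sum(near(dist_a)), sum(!near(dist_a)),
                  sum(near(dist_b)), sum(!near(dist_b))),
                nrow = 2, dimnames = list(c("near", "far"), c("A", "B")))
  ft <- stats::fisher.test(tab)
  structure(list(table = tab, odds_ratio = unname(ft$estimate),
                 p_value = ft$p.value, window = window),
            class = "tss_enrichment")
}

#' @export
print.tss_enrichment <- function(x, ...) {
  cat(sprintf("TSS-proximity enrichment (window %g bp)\n", x$window))
  print(x$table)
  cat(sprintf("  odds ratio %.3g, Fisher P = %.4g\n", x$odds_ratio, x$p_value))
  invisible(x)
}
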