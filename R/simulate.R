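# Synthetic-data generators with ground-truth manifests.
#
# The table generator emulates the structure of homeodomain PBM data: a
# planted primary 4-bp core (strong), a secondary core (weaker), additive
# per-position flank effects plus one pairwise interdependency term (so
# flank contributions are not purely additive), optional Gaussian noise,
# and exact reverse-complement symmetry imposed after noise by mirroring
# the lexicographically smaller member of each octamer pair.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic E-score table with planted cores
#'
#' Noiseless score of an octamer: `primary_weight` if it contains the
#' primary core on either strand (precedence), else `secondary_weight` if
#' it contains the secondary core, else `background_mean`; plus a
#' position-dependent flank term and one pairwise interaction
#' (`interaction_weight` added when the first base is T and the last is
#' G), so base contributions are neither independent nor purely additive.
#' The flank term is deterministic: position i has a favored base
#' contributing `+flank_amplitude * w[i]` (others `-flank_amplitude *
#' w[i] / 3`, zero mean per position), with edge positions weighted most —
#' flanking sequence matters more than the motif interior, as in real PBM
#' data.  Gaussian noise of sd `noise_sd` is then added to the canonical
#' member of each octamer/reverse-complement pair and mirrored (exact
#' symmetry survives the noise), and scores are clipped to `[-0.5, 0.5]`.
#'
#' @param primary_core,secondary_core Core 4-mers (secondary may be NULL).
#' @param primary_weight,secondary_weight Core base scores
#'   (secondary < primary).
#' @param background_mean Baseline for core-free octamers.
#' @param flank_amplitude Scale of per-position effects.
#' @param interaction_weight Size of the pairwise interdependency term.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @param seed RNG seed; generation is deterministic given the seed.
#' @param tf_name Label on the emitted table.
#' @return List: `table` (an [escore_table]) and `manifest` (data.frame
#'   octamer, noiseless, escore in code order; `noiseless` is already
#'   symmetrized so it predicts every downstream census exactly at
#'   noise 0).
#' @export
make_table <- function(primary_core = "AAGT", primary_weight = 0.42,
                       secondary_core = "GAGT", secondary_weight = 0.30,
                       background_mean = -0.05, flank_amplitude = 0.012,
                       interaction_weight = 0.015, noise_sd = 0,
                       seed = 1L, tf_name = "synthetic") {
  if (!is.null(secondary_core) && secondary_weight >= primary_weight)
    stop("secondary_weight must be below primary_weight")
  with_seed(seed, {
    D <- octamer_digit_matrix()
    favored <- match(c("T", "C", "A", "G", "T", "G", "G", "C"),
                     c("A", "C", "G", "T")) - 1L
    wpos <- c(1, 0.8, 0.6, 0.5, 0.5, 0.6, 0.8, 1)
    flank <- numeric(65536L)
    for (i in 1:8)
      flank <- flank + flank_amplitude * wpos[i] *
        ifelse(D[, i] == favored[i], 1, -1 / 3)
    flank <- flank + interaction_weight * (D[, 1] == 3L & D[, 8] == 2L)

    base <- rep(background_mean, 65536L)
    if (!is.null(secondary_core))
      base[octamers_with_core(secondary_core)] <- secondary_weight
    base[octamers_with_core(primary_core)] <- primary_weight
    noiseless <- base + flank
    if (any(noiseless < -0.5 | noiseless > 0.5))
      stop("spec produces noiseless scores outside [-0.5, 0.5]; ",
           "reduce weights or flank effects")
    if (max(noiseless[octamers_with_core(primary_core)]) <= 0.45)
      stop("primary-core weight too low: no octamer exceeds 0.45")

    rc <- revcomp_codes()
    canon_of <- pmin(0:65535, rc) + 1L       # index of canonical member
    noiseless <- noiseless[canon_of]         # symmetrize noiseless scores
    final <- noiseless
    if (noise_sd > 0) {
      noise <- stats::rnorm(65536L, 0, noise_sd)
      final <- noiseless + noise[canon_of]
      final <- pmin(pmax(final, -0.5), 0.5)
    }
    octs <- all_octamers()
    list(table = escore_table(stats::setNames(final, octs), tf_name = tf_name,
                              source = sprintf("make_table(seed=%d)", seed)),
         manifest = data.frame(octamer = octs, noiseless = noiseless,
                               escore = final, stringsAsFactors = FALSE))
  })
}

# direct window mean used internally by the generators (kept separate from
# the scanner so generator guarantees do not depend on the code under test)
naive_window_means <- function(seq, scores_by_code, W) {
  codes <- octamer_codes(seq)
  e <- scores_by_code[codes + 1L]
  n <- length(e) - W + 1L
  vapply(seq_len(n), function(i) mean(e[i:(i + W - 1L)]), numeric(1))
}

# Hill-climb a sequence of length `len` whose maximum W-window mean hits
# `target` (for len = W+7 there is a single window, so max = mean).
climb_segment <- function(scores_by_code, W, target, core = NULL, tol = 0.008,
                          restarts = 30L, iters = 400L, len = W + 7L) {
  bases <- c("A", "C", "G", "T")
  obj <- function(s) abs(max(naive_window_means(s, scores_by_code, W)) - target)
  for (r in seq_len(restarts)) {
    s <- paste(sample(bases, len, replace = TRUE), collapse = "")
    if (!is.null(core)) {                  # seed a core near the middle
      at <- sample(3:(len - 5L), 1L)
      substr(s, at, at + 3L) <- core
    }
    cur <- obj(s)
    for (it in seq_len(iters)) {
      if (cur <= tol) return(list(seq = s, achieved = max(naive_window_means(
        s, scores_by_code, W)), error = cur))
      improved <- FALSE
      for (pos in sample(len)) {
        for (b in bases[bases != substr(s, pos, pos)]) {
          s2 <- s
          substr(s2, pos, pos) <- b
          v <- obj(s2)
          if (v < cur) { s <- s2; cur <- v; improved <- TRUE; break }
        }
        if (improved) break
      }
      if (!improved) break
    }
    if (cur <= tol) return(list(seq = s, achieved = max(naive_window_means(
      s, scores_by_code, W)), error = cur))
  }
  NULL
}

#' Generate a genome with planted binding sites
#'
#' Background sequence is drawn from an order-0 model at the given GC
#' content and rejection-sampled until no background window reaches
#' `threshold - margin`.  Each planted site is a (window + 7)-mer built by
#' hill-climbing single-base mutations until its window average is within
#' 0.008 of the target score.  After planting, the whole genome is
#' re-validated: every above-threshold window must overlap a
#' supra-threshold planted segment and every supra-threshold segment must
#' contain one; on violation the background is regenerated.
#'
#' @param table An [escore_table] the genome is planted against.
#' @param length Genome length in bp (default 10000).
#' @param n_sites Number of planted sites (ignored when `site_scores`
#'   given).
#' @param site_scores Target window averages; default `n_sites` values
#'   from `threshold + margin` upward in steps of 0.004.  Values below the
#'   threshold are allowed (planted decoys that must not be called).
#' @param window,threshold Scan parameters the plant is calibrated to.
#' @param margin Safety margin separating background from calls
#'   (default 0.04).
#' @param gc GC content of the background (default 0.41).
#' @param min_sep Minimum bp between planted segments (default 50).
#' @param core Optional core 4-mer used to seed segment construction
#'   (default: taken from the table's best octamer).
#' @param seed RNG seed.
#' @param seq_name Name of the emitted sequence.
#' @return List: `records` (a `dna_records` of one sequence), `manifest`
#'   (data.frame start, end, target_score, achieved_score, supra), and
#'   the generation parameters.
#' @export
make_genome <- function(table, length = 10000L, n_sites = 5L,
                        site_scores = NULL, window = 7L, threshold = 0.37,
                        margin = 0.04, gc = 0.41, min_sep = 50L,
                        core = NULL, seed = 1L, seq_name = "chr_syn") {
  stopifnot(inherits(table, "escore_table"))
  v <- unname(table$scores)
  W <- as.integer(window)
  seg_len <- W + 7L
  if (is.null(site_scores))
    site_scores <- threshold + margin + 0.004 * (seq_len(n_sites) - 1L)
  n_sites <- length(site_scores)
  with_seed(seed, {
    if (is.null(core)) {
      top <- all_octamers()[which.max(v)]
      core <- substr(top, 3L, 6L)
    }
    # placements, evenly spaced with jitter
    span <- length - 200L
    if (n_sites > 0 && span / max(n_sites, 1) < seg_len + min_sep)
      stop("genome too short for ", n_sites, " sites ", min_sep, " bp apart")
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    # Sub-threshold decoys must stay sub-threshold in context: a core at the
    # segment edge can otherwise lift a junction window over the threshold
    # for any background.  Reject such segments against random embeddings.
    build_seg <- function(tg) {
      for (k in 1:15) {
        s <- climb_segment(v, W, tg, core = core)
        if (is.null(s)) next
        if (tg > threshold) return(s)
        ok <- TRUE
        for (j in 1:3) {
          ctx <- paste0(
            paste(sample(names(probs), 20, TRUE, probs), collapse = ""),
            s$seq,
            paste(sample(names(probs), 20, TRUE, probs), collapse = ""))
          if (max(naive_window_means(ctx, v, W)) > threshold - 0.002) {
            ok <- FALSE
            break
          }
        }
        if (ok) return(s)
      }
      stop("unsatisfiable site score ", tg, " for this table")
    }
    for (attempt in 1:20) {
      segs <- lapply(site_scores, build_seg)
      bg <- sample(names(probs), length, replace = TRUE, prob = probs)
      genome <- paste(bg, collapse = "")
      # clean the background of near-threshold windows
      ok_bg <- FALSE
      for (it in 1:200) {
        wm <- naive_window_means(genome, v, W)
        hot <- which(wm > threshold - margin)
        if (!length(hot)) { ok_bg <- TRUE; break }
        for (h in hot) {
          repl <- paste(sample(names(probs), seg_len, replace = TRUE,
                               prob = probs), collapse = "")
          substr(genome, h, h + seg_len - 1L) <- repl
        }
      }
      if (!ok_bg) next
      if (n_sites > 0) {
        at <- round(seq(100, length - 100 - seg_len, length.out = n_sites))
        at <- as.integer(at + sample(-10:10, n_sites, replace = TRUE))
        if (n_sites > 1 && any(diff(at) < seg_len + min_sep)) next
        for (k in seq_len(n_sites))
          substr(genome, at[k] + 1L, at[k] + seg_len) <- segs[[k]]$seq
      } else at <- integer(0)
      # validate: calls must coincide with supra-threshold plants
      wm <- naive_window_means(genome, v, W)
      above <- which(wm > threshold) - 1L          # 0-based window starts
      supra <- site_scores > threshold
      cover <- rep(FALSE, max(length(above), 0L))
      ok <- TRUE
      if (length(above)) {
        win_lo <- above; win_hi <- above + seg_len  # window spans, half-open
        hit <- rep(FALSE, length(above))
        for (k in which(supra)) {
          ov <- win_hi > at[k] & win_lo < at[k] + seg_len
          hit <- hit | ov
        }
        if (!all(hit)) ok <- FALSE
      }
      for (k in seq_len(n_sites)) {
        w_in <- wm[at[k] + 1L]                      # the segment's own window
        if (supra[k] && !(w_in > threshold)) ok <- FALSE
        if (!supra[k]) {
          ov <- length(above) &&
            any(above + seg_len > at[k] & above < at[k] + seg_len)
          if (isTRUE(ov)) ok <- FALSE
        }
      }
      if (!ok) next
      manifest <- data.frame(
        start = at, end = at + seg_len,
        target_score = site_scores,
        achieved_score = vapply(segs, function(s) s$achieved, numeric(1)),
        supra = supra)
      recs <- structure(stats::setNames(list(list(
        sequence = genome, softmask = rep(FALSE, length))), seq_name),
        class = "dna_records")
      return(list(records = recs, manifest = manifest, window = W,
                  threshold = threshold, margin = margin, seed = seed))
    }
    stop("could not generate a clean background after bounded retries")
  })
}

#' Generate a probe set with known affinity model
#'
#' Each probe is hill-climbed so its maximum W-window moving average hits
#' one of `n_probes` evenly spaced targets, so measured scores span a wide
#' range.  The
#' measured probe score x (maximum W-window average) generates fraction
#' bound F = a*x + b (plus optional Gaussian noise, clipped to [0, 1]) and
#' Kd = z(1 - F*)/F* from the noiseless occupancy F* (times optional
#' log-normal noise).
#'
#' @param table An [escore_table].
#' @param n_probes Number of probes (default 24).
#' @param a,b,z Generating affinity parameters (occupancy a*x+b must stay
#'   inside (0, 1) over the score range).
#' @param noise_sd Noise level: additive sd on F, and sd of log-normal
#'   multiplicative noise on Kd.
#' @param window Window size the affinity is generated from (default 7:
#'   probes built this way make W = 7 the true predictor in a sweep).
#' @param probe_len Probe length (default 36).
#' @param score_range Target range of probe scores (default c(0.05, 0.40));
#'   must span at least 0.3.
#' @param seed RNG seed.
#' @return List: `probes` (data.frame name, sequence, fraction_bound, kd),
#'   `manifest` (adds score, fraction_bound_true, kd_true), `params`.
#' @export
make_probe_set <- function(table, n_probes = 24L, a = 0.8, b = 0.1, z = 2.0,
                           noise_sd = 0, window = 7L, probe_len = 36L,
                           score_range = c(0.05, 0.40), seed = 1L) {
  stopifnot(inherits(table, "escore_table"))
  if (diff(score_range) < 0.3)
    stop("score_range must span at least 0.3 for a meaningful fit")
  v <- unname(table$scores)
  arr <- build_dense_array(table)
  W <- as.integer(window)
  cfg <- scan_config(window = W, threshold = 0.37)
  with_seed(seed, {
    targets <- seq(score_range[1], score_range[2], length.out = n_probes)
    top <- all_octamers()[which.max(v)]
    core <- substr(top, 3L, 6L)
    probes <- lapply(seq_len(n_probes), function(i) {
      # climb the whole probe so its maximum window mean hits the target
      seg <- climb_segment(v, W, targets[i], core = core, len = probe_len)
      if (is.null(seg))
        stop("could not build probe with target score ", targets[i])
      x <- score_probe(seg$seq, arr, cfg)$pbm_mapping_score
      list(seq = seg$seq, score = x)
    })
    x <- vapply(probes, `[[`, numeric(1), "score")
    if (max(x) - min(x) < 0.3)
      stop("insufficient probe score spread: ", round(max(x) - min(x), 3))
    occ <- a * x + b
    if (any(occ <= 0 | occ >= 1))
      stop("affinity model leaves occupancy (0, 1) over the score range")
    fb_true <- occ
    kd_true <- z * (1 - occ) / occ
    fb <- fb_true
    kd <- kd_true
    if (noise_sd > 0) {
      fb <- pmin(pmax(fb_true + stats::rnorm(n_probes, 0, noise_sd), 1e-6), 1)
      kd <- kd_true * exp(stats::rnorm(n_probes, 0, noise_sd))
    }
    nm <- sprintf("probe_%02d", seq_len(n_probes))
    list(probes = data.frame(name = nm,
                             sequence = vapply(probes, `[[`, character(1), "seq"),
                             fraction_bound = fb, kd = kd,
                             stringsAsFactors = FALSE),
         manifest = data.frame(name = nm, score = x,
                               fraction_bound_true = fb_true,
                               kd_true = kd_true, stringsAsFactors = FALSE),
         params = list(a = a, b = b, z = z, window = W, noise_sd = noise_sd,
                       seed = seed))
  })
}
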