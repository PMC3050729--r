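# Log-odds PWM scanning (the comparison scorer; matrix construction is
# external input).

#' Maximum log-odds PWM score of a sequence
#'
#' Counts are converted to per-position frequencies and scored as
#' `log((f + p*bg) / (bg * (1 + p)))` summed over the window, where `p` is
#' the pseudocount fraction and `bg` the background frequency of the base.
#' The maximum is taken over every offset on both strands.
#'
#' @param seq DNA string, length >= matrix width.
#' @param pwm A `pwm_matrix` from [read_transfac_matrix()].
#' @param pseudocount Nonnegative pseudocount fraction (default 0.01).
#' @param background Per-base background frequencies (A,C,G,T), positive,
#'   summing to 1.
#' @param details If TRUE also return best offset/strand and the per-window
#'   score vectors.
#' @return Numeric max score, or a list when `details = TRUE`.
#' @export
pwm_log_odds_score <- function(seq, pwm, pseudocount = 0.01,
                               background = rep(0.25, 4), details = FALSE) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  if (pseudocount < 0) stop("pseudocount must be nonnegative")
  if (any(background <= 0) || abs(sum(background) - 1) > 1e-9)
    stop("background must be positive and sum to 1")
  W <- pwm$width
  if (nchar(seq) < W)
    stop("sequence shorter than matrix width ", W)
  f <- pwm$counts / rowSums(pwm$counts)
  if (pseudocount == 0 && any(f == 0))
    stop("zero frequency with zero pseudocount gives -Inf; ",
         "supply a positive pseudocount")
  lo <- log(sweep(f, 2, pseudocount * background, `+`)) -
    log(matrix(background * (1 + pseudocount), W, 4, byrow = TRUE))

  score_strand <- function(s) {
    b <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
               c("A", "C", "G", "T"))
    n <- length(b) - W + 1L
    vapply(seq_len(n), function(i) {
      d <- b[i:(i + W - 1L)]
      if (anyNA(d)) return(-Inf)          # ambiguity: window unscoreable
      sum(lo[cbind(seq_len(W), d)])
    }, numeric(1))
  }
  fwd <- score_strand(seq)
  rev <- score_strand(reverse_complement(toupper(seq)))
  best <- max(fwd, rev)
  if (!is.finite(best)) stop("no scoreable window for PWM (ambiguity codes)")
  if (!details) return(best)
  list(score = best, forward = fwd, reverse = rev,
       strand = if (max(fwd) >= max(rev)) "+" else "-")
}

#' Consensus sequence of a PWM
#'
#' @param pwm A `pwm_matrix`.
#' @return Character scalar: the per-position argmax base (leftmost wins
#'   ties).
#' @export
pwm_consensus <- function(pwm) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  paste(c("A", "C", "G", "T")[apply(pwm$counts, 1, which.max)], collapse = "")
}
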