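# Octamer encoding and dense E-score lookup.
#
# Octamers are packed 2 bits/base (A=0, C=1, G=2, T=3, leftmost base most
# significant), giving codes 0..65535 that index a dense score array.

.pbm <- new.env(parent = emptyenv())

#' All 65,536 octamers in code order
#'
#' Returns the character vector of every A/C/G/T 8-mer, ordered by its
#' integer code (see [encode_octamer()]).  Cached after first call.
#'
#' @return Character vector of length 65,536.
#' @export
all_octamers <- function() {
  if (is.null(.pbm$octamers)) {
    b <- c("A", "C", "G", "T")
    g <- expand.grid(b, b, b, b, b, b, b, b, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; the first column must be
    # the least significant digit, so paste right-to-left
    .pbm$octamers <- do.call(paste0, rev(g))
  }
  .pbm$octamers
}

#' @keywords internal
octamer_digit_matrix <- function() {
  if (is.null(.pbm$digits)) {
    codes <- 0:65535
    m <- matrix(0L, nrow = 65536L, ncol = 8L)
    x <- codes
    for (i in 8:1) {          # least significant digit is the rightmost base
      m[, i] <- x %% 4L
      x <- x %/% 4L
    }
    .pbm$digits <- m
  }
  .pbm$digits
}

#' Reverse-complement codes for all octamers
#'
#' Integer vector `v` such that `v[code + 1]` is the code of the reverse
#' complement of the octamer with the given code.
#'
#' @return Integer vector of length 65,536.
#' @export
revcomp_codes <- function() {
  if (is.null(.pbm$rc)) {
    x <- 0:65535
    r <- integer(65536L)
    for (k in 1:8) {          # digit k (from the right) is base 9-k; its
      d <- x %% 4L            # complement becomes the k-th base from the left
      x <- x %/% 4L
      r <- r * 4L + (3L - d)
    }
    .pbm$rc <- r
  }
  .pbm$rc
}

#' Encode an 8-mer as an integer code
#'
#' @param s Character scalar: an 8-mer over A/C/G/T (case-insensitive).
#' @return Integer in `[0, 65535]`.  An ambiguity code (any non-ACGT
#'   character) signals an error: such octamers are unscoreable and callers
#'   mask the corresponding window.
#' @examples
#' encode_octamer("AAAAAAAA")  # 0
#' encode_octamer("TTTTTTTT")  # 65535
#' @export
encode_octamer <- function(s) {
  if (!is.character(s) || length(s) != 1L || nchar(s) != 8L)
    stop("octamer must be a single 8-character string")
  b <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  if (anyNA(b))
    stop("unscoreable octamer: non-ACGT base in ", sQuote(s))
  sum((b - 1L) * 4^(7:0))
}

#' Decode an integer octamer code
#'
#' @param code Integer in `[0, 65535]`.
#' @return The 8-mer string.
#' @export
decode_octamer <- function(code) {
  if (any(code < 0 | code > 65535)) stop("octamer code out of range")
  all_octamers()[code + 1L]
}

#' Reverse complement of a DNA string
#'
#' Case is preserved (soft-masked lowercase stays lowercase).
#'
#' @param s Character vector of DNA strings over A/C/G/T (either case).
#' @return Reverse-complemented strings.
#' @examples
#' reverse_complement("AAGT")  # "ACTT"
#' reverse_complement("ACGT")  # palindrome: "ACGT"
#' @export
reverse_complement <- function(s) {
  if (any(grepl("[^ACGTacgt]", s)))
    stop("reverse_complement: non-ACGT base in input")
  comp <- chartr("ACGTacgt", "TGCAtgca", s)
  vapply(comp, function(x)
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Per-position octamer codes along a sequence
#'
#' For a sequence of length L returns an integer vector of length L - 7
#' whose i-th entry is the code of the octamer starting at position i
#' (1-based), or NA where the octamer contains a non-ACGT base.
#'
#' @param seq Character scalar DNA sequence.
#' @return Integer vector with NAs at unscoreable positions.
#' @keywords internal
octamer_codes <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L < 8L) return(integer(0))
  b <- match(chars, c("A", "C", "G", "T")) - 1L
  bad <- is.na(b)
  b[bad] <- 0L
  # code of the octamer ending at position i: sum_{k=0..7} 4^k * b[i-k]
  y <- stats::filter(b, 4^(0:7), sides = 1)
  nbad <- stats::filter(as.numeric(bad), rep(1, 8), sides = 1)
  codes <- as.integer(round(y[8:L]))
  codes[nbad[8:L] > 0] <- NA_integer_
  codes
}

#' Build the dense score array backing the scanner
#'
#' Converts an [escore_table] into a bare numeric vector of length 65,536
#' indexed by octamer code + 1, and re-checks totality, range and
#' reverse-complement symmetry so no invalid array reaches the scanner.
#'
#' @param table An `escore_table`.
#' @return Numeric vector of length 65,536 (class `dense_score_array`).
#' @export
build_dense_array <- function(table) {
  stopifnot(inherits(table, "escore_table"))
  v <- unname(table$scores[all_octamers()])
  if (anyNA(v))
    stop("incomplete E-score table: ", sum(is.na(v)), " octamers missing")
  if (any(v < -0.5 | v > 0.5))
    stop("E-score out of [-0.5, 0.5] in table")
  rc <- revcomp_codes()
  if (any(abs(v - v[rc + 1L]) > 1e-12))
    stop("E-score table violates reverse-complement symmetry")
  structure(v, class = "dense_score_array")
}
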