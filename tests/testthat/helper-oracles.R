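# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's fast paths: profiles are
# recomputed by substring extraction and named-map lookup, never through
# octamer codes or the dense array.

# A random reverse-complement-symmetric total table (independent of
# make_table): uniform scores on [-0.5, 0.5], mirrored over strand pairs.
random_symmetric_table <- function(seed) {
  set.seed(seed)
  v <- runif(65536, -0.5, 0.5)
  octs <- all_octamers()
  rc <- revcomp_codes()
  canon <- pmin(0:65535, rc) + 1L
  v <- v[canon]
  escore_table(setNames(v, octs), tf_name = paste0("rand", seed),
               source = "helper")
}

# A constant table (every octamer scores `value`).
uniform_table <- function(value = 0.2) {
  escore_table(setNames(rep(value, 65536), all_octamers()),
               tf_name = "uniform", source = "helper")
}

# Naive O(L*W) profile: mean of W octamer scores looked up by substring.
oracle_profile <- function(seq, table, W) {
  seq <- toupper(seq)
  L <- nchar(seq)
  n_win <- L - W - 6L
  vapply(seq_len(n_win), function(i) {
    octs <- vapply(0:(W - 1L), function(k) substr(seq, i + k, i + k + 7L),
                   character(1))
    if (any(grepl("[^ACGT]", octs))) return(NA_real_)
    mean(unname(table$scores[octs]))
  }, numeric(1))
}

# Brute-force probe scores by substring lookup.
oracle_probe <- function(seq, table, W) {
  seq <- toupper(seq)
  L <- nchar(seq)
  octs <- vapply(seq_len(L - 7L), function(i) substr(seq, i, i + 7L),
                 character(1))
  ok <- !grepl("[^ACGT]", octs)
  list(max_escore = max(unname(table$scores[octs[ok]])),
       pbm_mapping_score = if (L >= W + 7L)
         max(oracle_profile(seq, table, W), na.rm = TRUE) else NA_real_)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Two-sided Fisher p-value by exhaustive hypergeometric enumeration for a
# 2x2 table [[a, b], [c, d]] with fixed margins.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # col-1 total
  x <- max(0, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p0 <- dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
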