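# FASTA, BED and TRANSFAC readers/writers.

#' Read FASTA sequences, keeping the soft-mask
#'
#' Parsing is done by Biostrings; case is preserved on input so lowercase
#' (soft-masked) runs are recorded as a per-position mask, then sequences
#' are uppercased.  IUPAC ambiguity codes are accepted (the scanner masks
#' any window containing one).
#'
#' @param path FASTA file.
#' @return A named list of records, each `list(sequence =, softmask =)`
#'   where `softmask` is a logical vector over positions; class
#'   `dna_records`.
#' @export
read_fasta <- function(path) {
  ss <- tryCatch(Biostrings::readBStringSet(path), error = function(e)
    stop("empty or malformed FASTA file: ", path, " (", conditionMessage(e), ")",
         call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate FASTA record name: ", sQuote(nm[duplicated(nm)][1]))
  recs <- lapply(seq_along(ss), function(i) {
    s <- as.character(ss[[i]])
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    list(sequence = toupper(s),
         softmask = chars %in% c("a", "c", "g", "t", "n"))
  })
  names(recs) <- nm
  structure(recs, class = "dna_records")
}

#' Write FASTA sequences
#'
#' @param records A `dna_records` list, or a named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as_dna_records(records)
  seqs <- vapply(records, `[[`, character(1), "sequence")
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(records)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @keywords internal
as_dna_records <- function(x) {
  if (inherits(x, "dna_records")) return(x)
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    recs <- lapply(unname(x), function(s)
      list(sequence = toupper(s), softmask = rep(FALSE, nchar(s))))
    names(recs) <- names(x)
    return(structure(recs, class = "dna_records"))
  }
  if (is.list(x)) {           # already record-shaped, just stamp the class
    recs <- lapply(x, function(r) {
      if (is.character(r)) list(sequence = toupper(r),
                                softmask = rep(FALSE, nchar(r)))
      else r
    })
    return(structure(recs, class = "dna_records"))
  }
  stop("cannot interpret input as DNA records")
}

#' Write predicted sites as BED6
#'
#' Coordinates are 0-based half-open.  The BED score column maps the peak
#' moving average linearly from `[threshold, 0.5]` onto 0..1000; names are
#' `<tf>_<rank>` with rank 1 the highest-scoring site.  Strand is `"."`:
#' E-score reverse-complement symmetry makes calls strandless.  A header
#' comment records the threshold and window actually used.
#'
#' @param sites A `predicted_sites` data.frame from [call_sites()].
#' @param path Output path.
#' @param tf_name Label used in site names (default: attribute on `sites`
#'   or "TF").
#' @param threshold,window Scan parameters for the header/score scaling
#'   (defaults: attributes stored on `sites`).
#' @return `path`, invisibly.
#' @export
write_bed <- function(sites, path, tf_name = NULL, threshold = NULL,
                      window = NULL) {
  tf_name <- tf_name %||% attr(sites, "tf_name") %||% "TF"
  threshold <- threshold %||% attr(sites, "threshold") %||% 0.37
  window <- window %||% attr(sites, "window") %||% 7L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pbmscan sites tf=%s window=%d threshold=%g",
                     tf_name, as.integer(window), threshold), con)
  if (nrow(sites) == 0L) return(invisible(path))
  if (any(sites$start >= sites$end)) stop("site with start >= end")
  ord <- order(sites$seq_name, sites$start)
  sites <- sites[ord, , drop = FALSE]
  rank <- rank(-sites$peak_score, ties.method = "first")
  bedscore <- round(1000 * (sites$peak_score - threshold) / (0.5 - threshold))
  bedscore <- pmin(pmax(bedscore, 0), 1000)
  df <- data.frame(sites$seq_name, sites$start, sites$end,
                   paste0(tf_name, "_", rank), as.integer(bedscore), ".")
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of regions
#'
#' Minimal BED3+ reader: chrom, start, end and optional name/score/strand
#' columns; `#` and `track`/`browser` lines skipped.
#'
#' @param path BED file.
#' @return data.frame with columns chrom, start, end, name, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|track\\b|browser\\b|$)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character()))
  f <- strsplit(lines, "\t")
  n <- lengths(f)
  if (any(n < 3L)) stop("BED line with fewer than 3 fields")
  df <- data.frame(
    chrom = vapply(f, `[`, character(1), 1L),
    start = as.integer(vapply(f, `[`, character(1), 2L)),
    end = as.integer(vapply(f, `[`, character(1), 3L)),
    name = ifelse(n >= 4L, vapply(f, function(x) x[4], character(1)), NA),
    strand = ifelse(n >= 6L, vapply(f, function(x) x[6], character(1)), "."))
  df$name[is.na(df$name)] <- paste0("region", which(is.na(df$name)))
  if (any(df$start >= df$end)) stop("BED region with start >= end")
  df
}

#' Read a TRANSFAC-format count matrix
#'
#' Parses the flat TRANSFAC block: a `P0` (or `PO`) header line naming the
#' base columns, followed by numbered position rows of per-base counts or
#' frequencies.
#'
#' @param path File path.
#' @return A `pwm_matrix`: list with `counts` (width x 4 matrix, columns
#'   A/C/G/T), `width`, `id`.
#' @export
read_transfac_matrix <- function(path) {
  lines <- readLines(path)
  id <- sub("^(ID|NA)\\s+", "", grep("^(ID|NA)\\s", lines, value = TRUE)[1])
  if (is.na(id)) id <- "PWM"
  hdr <- grep("^P[O0]\\s", lines)
  if (length(hdr) == 0L) stop("no P0 header line in TRANSFAC file")
  cols <- strsplit(trimws(sub("^P[O0]", "", lines[hdr[1]])), "\\s+")[[1]]
  if (!setequal(toupper(cols), c("A", "C", "G", "T")))
    stop("TRANSFAC P0 header must name columns A C G T; got: ",
         paste(cols, collapse = " "))
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  rows <- grep("^\\s*[0-9]+\\s", body, value = TRUE)
  if (length(rows) == 0L) stop("no position rows in TRANSFAC file")
  parsed <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(parsed)
  if (any(nf < 5L)) stop("ragged TRANSFAC row: position ",
                         parsed[[which(nf < 5L)[1]]][1])
  counts <- t(vapply(parsed, function(p) as.numeric(p[2:5]), numeric(4)))
  if (anyNA(counts)) stop("non-numeric count in TRANSFAC matrix")
  if (any(counts < 0)) stop("negative count in TRANSFAC matrix")
  colnames(counts) <- toupper(cols)
  counts <- counts[, c("A", "C", "G", "T"), drop = FALSE]
  structure(list(counts = counts, width = nrow(counts), id = id),
            class = "pwm_matrix")
}

#' Write a TRANSFAC-format count matrix
#'
#' @param pwm A `pwm_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transfac_matrix <- function(pwm, path) {
  stopifnot(inherits(pwm, "pwm_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ID", pwm$id), "P0      A      C      G      T"), con)
  for (i in seq_len(pwm$width)) {
    writeLines(sprintf("%02d %6g %6g %6g %6g", i,
                       pwm$counts[i, "A"], pwm$counts[i, "C"],
                       pwm$counts[i, "G"], pwm$counts[i, "T"]), con)
  }
  writeLines("XX", con)
  invisible(path)
}

#' @export
print.pwm_matrix <- function(x, ...) {
  cat("TRANSFAC matrix", x$id, "- width", x$width, "\n")
  print(x$counts)
  invisible(x)
}
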