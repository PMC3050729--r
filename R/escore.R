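# The E-score table: a total, reverse-complement-symmetric map from every
# octamer to its PBM enrichment score in [-0.5, 0.5].

#' Construct an E-score table
#'
#' @param scores Named numeric vector giving an E-score for every one of the
#'   65,536 octamers (names are 8-mers over ACGT; order is irrelevant).
#' @param tf_name Transcription factor label.
#' @param source Provenance string (file path or generator description).
#' @return An object of class `escore_table` with fields `scores` (named,
#'   in code order), `tf_name` and `source`.
#' @export
escore_table <- function(scores, tf_name = "TF", source = "in-memory") {
  octs <- all_octamers()
  if (is.null(names(scores)) || !all(octs %in% names(scores))) {
    missing <- if (is.null(names(scores))) 65536L else sum(!(octs %in% names(scores)))
    stop("incomplete E-score table: ", missing, " octamers missing")
  }
  v <- scores[octs]
  if (anyNA(v)) stop("incomplete E-score table: ", sum(is.na(v)), " octamers missing")
  if (any(v < -0.5 | v > 0.5)) stop("E-score out of range [-0.5, 0.5]")
  rc <- revcomp_codes()
  if (any(abs(unname(v) - unname(v)[rc + 1L]) > 1e-12))
    stop("E-score table violates reverse-complement symmetry")
  structure(list(scores = v, tf_name = tf_name, source = source),
            class = "escore_table")
}

#' @export
print.escore_table <- function(x, ...) {
  cat("E-score table for", x$tf_name, "\n")
  cat("  source:", x$source, "\n")
  cat(sprintf("  65536 octamers, score range [%.5f, %.5f], mean %.5f\n",
              min(x$scores), max(x$scores), mean(x$scores)))
  invisible(x)
}

#' Read a UniPROBE-style 8-mer E-score table
#'
#' Accepts whitespace/tab-delimited text with at least three columns:
#' octamer, reverse-complement octamer, E-score.  A fourth (e.g. median
#' intensity) and further columns are ignored; published PBM downloads vary.
#' Lines starting with `#` are comments.  Each listed row fills both the
#' octamer and its reverse complement (mirror-fill), so a canonical
#' 32,896-row file yields a total table.
#'
#' @param path File path.
#' @param tf_name Label stored on the table (defaults to the file name).
#' @param strict_symmetry If TRUE, conflicting scores for an
#'   octamer/reverse-complement pair are an error; otherwise they are
#'   averaged with a warning (tolerates rounding in third-party files).
#' @return An [escore_table].
#' @export
read_escore_table <- function(path, tf_name = NULL, strict_symmetry = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty E-score table: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("line ", lineno[which(nf < 3L)[1]], ": expected >= 3 columns")
  oct <- toupper(vapply(fields, `[`, character(1), 1L))
  esc <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))

  bad <- nchar(oct) != 8L | grepl("[^ACGT]", oct)
  if (any(bad))
    stop("line ", lineno[which(bad)[1]], ": malformed octamer ",
         sQuote(vapply(fields, `[`, character(1), 1L)[which(bad)[1]]))
  if (anyNA(esc))
    stop("line ", lineno[which(is.na(esc))[1]], ": non-numeric E-score")
  if (any(esc < -0.5 | esc > 0.5))
    stop("line ", lineno[which(esc < -0.5 | esc > 0.5)[1]],
         ": E-score outside [-0.5, 0.5]")

  code <- vapply(fields, function(f) encode_octamer(f[1]), numeric(1))
  rc <- revcomp_codes()
  canon <- pmin(code, rc[code + 1L])   # one representative per strand pair

  # detect conflicting duplicates within the file
  first <- !duplicated(canon)
  ref <- esc[first][match(canon, canon[first])]
  conflict <- abs(esc - ref) > 0
  if (any(conflict)) {
    if (strict_symmetry)
      stop("line ", lineno[which(conflict)[1]],
           ": conflicting E-scores for octamer/reverse-complement pair ",
           sQuote(oct[which(conflict)[1]]))
    warning("averaging conflicting scores for ",
            length(unique(canon[conflict])), " octamer pair(s)")
    esc <- ave(esc, canon, FUN = mean)
  }

  v <- rep(NA_real_, 65536L)
  v[canon + 1L] <- esc
  v[rc[canon + 1L] + 1L] <- esc       # mirror-fill
  if (anyNA(v))
    stop("incomplete E-score table: ", sum(is.na(v)),
         " octamers missing after mirror-fill")
  names(v) <- all_octamers()
  escore_table(v, tf_name = tf_name %||% sub("\\.[^.]*$", "", basename(path)),
               source = path)
}

#' Write an E-score table
#'
#' Writes the canonical 32,896 rows (one per octamer/reverse-complement
#' pair, lexicographically smaller member first) as
#' `octamer<TAB>revcomp<TAB>escore`.
#'
#' @param table An [escore_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_escore_table <- function(table, path) {
  stopifnot(inherits(table, "escore_table"))
  rc <- revcomp_codes()
  codes <- 0:65535
  canon <- codes[codes <= rc[codes + 1L]]
  octs <- all_octamers()
  df <- data.frame(octamer = octs[canon + 1L],
                   revcomp = octs[rc[canon + 1L] + 1L],
                   escore = unname(table$scores[canon + 1L]))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# 8-mer E-score table for %s", table$tf_name), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TSV of binding measurements
#'
#' Expects a header with columns `name`, `sequence`, and at least one of
#' `fraction_bound` (in `[0,1]`) and `kd` (positive, concentration units).
#'
#' @param path File path.
#' @return data.frame with those columns (absent measurement columns are NA).
#' @export
read_measurements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "sequence")
  if (!all(need %in% names(df)))
    stop("measurement table must have columns 'name' and 'sequence'")
  if (!("fraction_bound" %in% names(df))) df$fraction_bound <- NA_real_
  if (!("kd" %in% names(df))) df$kd <- NA_real_
  df$sequence <- toupper(df$sequence)
  if (any(grepl("[^ACGT]", df$sequence)))
    stop("measurement sequences must be over A/C/G/T")
  if (all(is.na(df$fraction_bound) & is.na(df$kd)))
    stop("each probe needs fraction_bound or kd; none found")
  ok_fb <- is.na(df$fraction_bound) | (df$fraction_bound >= 0 & df$fraction_bound <= 1)
  if (!all(ok_fb)) stop("fraction_bound outside [0, 1]")
  if (!all(is.na(df$kd) | df$kd > 0)) stop("kd must be positive")
  df[, c("name", "sequence", "fraction_bound", "kd")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
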