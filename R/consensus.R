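ALN_ALPHABET <- c("A", "C", "G", "T", "U", "N", "-")

#' Build an Alignment object from equal-length sequences
#'
#' @param seqs named character vector of aligned sequences over
#'   \code{A,C,G,T,U,N,-} (case-insensitive; \code{.} is read as a gap).
#'   T and U are kept as written but treated as the same symbol by
#'   \code{\link{column_consensus}}.
#' @return an object of class \code{Alignment} with elements \code{ids},
#'   \code{seqs} and \code{length} (number of columns).
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("aligned sequences must be named")
  seqs <- chartr(".", "-", toupper(seqs))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged alignment: record '%s' has %d columns, expected %d",
                 names(seqs)[bad], widths[bad], widths[1]))
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  illegal <- setdiff(chars, ALN_ALPHABET)
  if (length(illegal))
    stop("illegal alignment character(s): ", paste(illegal, collapse = ", "))
  structure(list(ids = names(seqs), seqs = unname(seqs),
                 length = unname(widths[1])), class = "Alignment")
}

#' @export
print.Alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d records x %d columns\n", length(x$ids), x$length))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' @param path file path.
#' @param dialect \code{"aligned-fasta"} or \code{"clustal"}; interleaved
#'   Clustal blocks are concatenated.
#' @return an \code{Alignment}.
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*$", "", names(set))
  } else {
    m <- tryCatch(Biostrings::readRNAMultipleAlignment(path, format = "clustal"),
                  error = function(e)
                    Biostrings::readDNAMultipleAlignment(path, format = "clustal"))
    seqs <- as.character(m)
  }
  as_alignment(seqs)
}

#' Write a multiple sequence alignment
#'
#' @param aln an \code{Alignment}.
#' @param path output path.
#' @param dialect \code{"aligned-fasta"} or \code{"clustal"} (interleaved,
#'   60-column blocks).
#' @return \code{path}, invisibly.
#' @export
write_alignment <- function(aln, path, dialect = c("aligned-fasta", "clustal")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(aln, "Alignment"))
  if (dialect == "aligned-fasta") {
    set <- Biostrings::BStringSet(aln$seqs)
    names(set) <- aln$ids
    Biostrings::writeXStringSet(set, path)
  } else {
    width <- 60L
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("CLUSTAL W multiple sequence alignment", "", ""), con)
    pad <- max(nchar(aln$ids)) + 6L
    for (from in seq(1L, aln$length, by = width)) {
      to <- min(from + width - 1L, aln$length)
      writeLines(sprintf("%-*s%s", pad, aln$ids,
                         substr(aln$seqs, from, to)), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Per-column consensus symbols of an alignment
#'
#' Applies the positional-frequency rule used to define "common sequences":
#' in each column, count each nucleotide (T and U pooled); if a unique modal
#' base reaches the threshold fraction it becomes the consensus symbol, if two
#' or more bases tie for the maximum at or above the threshold the column is
#' marked \code{"+"} (displayed but never part of an extracted run), and
#' otherwise the column has no consensus.
#'
#' @param aln an \code{Alignment}.
#' @param min_frac minimum base fraction, inclusive (default 0.10).
#' @param count_gaps if \code{TRUE} (default) gaps and \code{N} count in the
#'   denominator (per-column fractions are taken over all rows, as in Jalview
#'   consensus percentages); if \code{FALSE} fractions are over non-gap rows.
#' @return data.frame with one row per column: \code{column} (0-based),
#'   \code{symbol} (\code{A/C/G/U}, \code{"+"} or \code{NA}) and
#'   \code{frequency} of the modal base.
#' @export
column_consensus <- function(aln, min_frac = 0.10, count_gaps = TRUE) {
  stopifnot(inherits(aln, "Alignment"))
  if (!length(aln$ids)) stop("empty alignment")
  if (!is.numeric(min_frac) || min_frac <= 0 || min_frac > 1)
    stop("'min_frac' must be in (0, 1]")
  mat <- do.call(rbind, strsplit(chartr("T", "U", aln$seqs), ""))
  bases <- c("A", "C", "G", "U")
  symbol <- rep(NA_character_, aln$length)
  freq <- rep(NA_real_, aln$length)
  for (j in seq_len(aln$length)) {
    col <- mat[, j]
    counts <- vapply(bases, function(b) sum(col == b), 0L)
    denom <- if (count_gaps) length(col) else sum(col %in% bases)
    if (denom == 0L || all(counts == 0L)) next
    f <- counts / denom
    fmax <- max(f)
    freq[j] <- fmax
    if (fmax + 1e-12 < min_frac) next
    modal <- bases[f == fmax]
    symbol[j] <- if (length(modal) == 1L) modal else "+"
  }
  data.frame(column = seq_len(aln$length) - 1L, symbol = symbol,
             frequency = freq, stringsAsFactors = FALSE)
}

#' Extract consensus runs ("common sequences")
#'
#' Maximal stretches of consecutive consensus columns whose symbol is a base
#' (not \code{"+"}, not absent), of at least \code{min_run_length} columns,
#' reported left to right with 0-based half-open coordinates.
#'
#' @param consensus data.frame from \code{\link{column_consensus}} (or any
#'   data.frame with \code{symbol} and \code{frequency} columns in column
#'   order).
#' @param min_run_length minimum run length in columns (default 10).
#' @return data.frame with columns \code{index}, \code{sequence} (RNA
#'   alphabet), \code{length}, \code{complement} (reverse complement),
#'   \code{start_col}, \code{end_col} (0-based half-open); the per-column
#'   modal-base frequencies of each run are kept in the list column
#'   \code{column_frequency}.
#' @export
extract_runs <- function(consensus, min_run_length = 10L) {
  stopifnot(is.data.frame(consensus), all(c("symbol", "frequency") %in% names(consensus)))
  if (min_run_length < 1) stop("'min_run_length' must be >= 1")
  is_base <- !is.na(consensus$symbol) & consensus$symbol %in% c("A", "C", "G", "U", "T")
  r <- rle(is_base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_run_length)
  seqs <- vapply(keep, function(k) {
    chartr("T", "U", paste(consensus$symbol[starts[k]:ends[k]], collapse = ""))
  }, "")
  out <- data.frame(
    index = seq_along(keep),
    sequence = seqs,
    length = r$lengths[keep],
    complement = if (length(keep)) reverse_complement(seqs) else character(),
    start_col = starts[keep] - 1L,
    end_col = ends[keep],
    stringsAsFactors = FALSE)
  out$column_frequency <- lapply(keep, function(k)
    consensus$frequency[starts[k]:ends[k]])
  out
}

#' Reverse complement of a nucleotide sequence
#'
#' Reverses the sequence and complements each base (A with U or T, C with G);
#' the output alphabet (RNA vs DNA) matches the input, and \code{N} maps to
#' \code{N}.
#'
#' @param s character vector of sequences over \code{A,C,G,U,N} or
#'   \code{A,C,G,T,N} (case-insensitive; a sequence mixing T and U is
#'   rejected).
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(s) {
  vapply(s, function(x) {
    xu <- toupper(x)
    chars <- strsplit(xu, "")[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T", "U", "N"))
    if (length(bad))
      stop(sprintf("invalid character '%s' at position %d", chars[bad[1]], bad[1]))
    if (any(chars == "T") && any(chars == "U"))
      stop("sequence mixes T and U; alphabet must be pure DNA or RNA")
    comp <- if (any(chars == "T")) chartr("ACGTN", "TGCAN", xu)
            else chartr("ACGUN", "UGCAN", xu)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Find common sequences in an alignment
#'
#' Convenience wrapper chaining \code{\link{column_consensus}} and
#' \code{\link{extract_runs}}.
#'
#' @inheritParams column_consensus
#' @inheritParams extract_runs
#' @return the run table of \code{\link{extract_runs}}, with the full
#'   consensus table attached as \code{attr(, "consensus")}.
#' @export
find_common_sequences <- function(aln, min_frac = 0.10, min_run_length = 10L,
                                  count_gaps = TRUE) {
  cons <- column_consensus(aln, min_frac = min_frac, count_gaps = count_gaps)
  runs <- extract_runs(cons, min_run_length = min_run_length)
  attr(runs, "consensus") <- cons
  runs
}
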