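#' Exhaustive approximate scan of a transcript database
#'
#' Slides the motif (typically the reverse complement of a common lncRNA
#' sequence) along the sense strand of every transcript and reports every
#' full-length ungapped window whose identity -- (motif length - mismatches) /
#' motif length, with U and T equivalent -- reaches the threshold. Unlike a
#' heuristic seed-based search, the scan is exhaustive, so no qualifying
#' window is ever missed. Transcripts shorter than the motif are skipped
#' silently; windows overhanging a transcript end are not scored.
#'
#' @param motif RNA or DNA string of length >= 1.
#' @param db transcript database data.frame with columns
#'   \code{transcript_id}, \code{gene_symbol}, \code{description},
#'   \code{sequence} (see \code{\link{read_transcript_fasta}}).
#' @param min_identity minimum identity fraction, inclusive (default 0.85, so
#'   e.g. one mismatch is allowed in a 12-mer but two are not).
#' @return data.frame of hits: \code{transcript_id}, \code{gene_symbol},
#'   \code{description}, \code{offset} (0-based position in the transcript),
#'   \code{identity}, \code{matched_span}, and \code{is_best} marking the
#'   best-identity (first on tie) window per transcript.
#' @export
scan_database <- function(motif, db, min_identity = 0.85) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) >= 1L)
  if (min_identity <= 0 || min_identity > 1)
    stop("'min_identity' must be in (0, 1]")
  motif_dna <- chartr("Uu", "Tt", toupper(motif))
  L <- nchar(motif_dna)
  max_mm <- floor(L * (1 - min_identity) + 1e-9)
  empty <- data.frame(transcript_id = character(), gene_symbol = character(),
                      description = character(), offset = integer(),
                      identity = numeric(), matched_span = character(),
                      is_best = logical(), stringsAsFactors = FALSE)
  wide <- nchar(db$sequence) >= L
  if (!any(wide)) return(empty)
  dbw <- db[wide, , drop = FALSE]
  subject <- Biostrings::DNAStringSet(chartr("Uu", "Tt", toupper(dbw$sequence)))
  hits_by_tx <- Biostrings::vmatchPattern(motif_dna, subject,
                                          max.mismatch = max_mm)
  rows <- list()
  pattern_chars <- strsplit(motif_dna, "")[[1]]
  for (i in seq_along(hits_by_tx)) {
    starts <- Biostrings::start(hits_by_tx[[i]])
    ends <- Biostrings::end(hits_by_tx[[i]])
    ok <- starts >= 1L & ends <= nchar(dbw$sequence[i])
    starts <- starts[ok]
    if (!length(starts)) next
    spans <- substring(chartr("Uu", "Tt", toupper(dbw$sequence[i])),
                       starts, starts + L - 1L)
    mm <- vapply(spans, function(s)
      sum(strsplit(s, "")[[1]] != pattern_chars), 0L, USE.NAMES = FALSE)
    identity <- (L - mm) / L
    keep <- identity >= min_identity - 1e-12
    if (!any(keep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = dbw$transcript_id[i],
      gene_symbol = dbw$gene_symbol[i],
      description = dbw$description[i],
      offset = starts[keep] - 1L,
      identity = identity[keep],
      matched_span = spans[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$transcript_id, -hits$identity, hits$offset), ]
  hits$is_best <- !duplicated(hits$transcript_id)
  rownames(hits) <- NULL
  hits
}

#' Drop hits whose transcript description matches an exclusion pattern
#'
#' Mirrors the rule of excluding entries labeled as other than curated mRNA
#' (e.g. "PREDICTED" model transcripts or "cDNA" clones) from the match set.
#' Matching is case-sensitive fixed-substring by default.
#'
#' @param hits hit data.frame from \code{\link{scan_database}}.
#' @param exclude_patterns character vector of substrings; a hit is dropped
#'   when its description contains any of them. An empty vector is the
#'   identity.
#' @return the filtered hit data.frame.
#' @export
filter_headers <- function(hits, exclude_patterns = c("PREDICTED", "cDNA")) {
  stopifnot(is.data.frame(hits))
  if (!length(exclude_patterns) || !nrow(hits)) return(hits)
  drop <- Reduce(`|`, lapply(exclude_patterns, function(p)
    grepl(p, hits$description, fixed = TRUE)))
  hits[!drop, , drop = FALSE]
}

#' Keep hits whose gene is on an expression whitelist
#'
#' The whitelist stands in for confirmation of expression in the cerebral
#' cortex; matching is case-insensitive on gene symbols.
#'
#' @param hits hit data.frame.
#' @param whitelist character vector of gene symbols; an empty whitelist
#'   drops every hit with a warning.
#' @return the filtered hit data.frame.
#' @export
filter_whitelist <- function(hits, whitelist) {
  stopifnot(is.data.frame(hits))
  if (!length(whitelist)) {
    warning("empty whitelist: all hits dropped")
    return(hits[0, , drop = FALSE])
  }
  hits[toupper(hits$gene_symbol) %in% toupper(whitelist), , drop = FALSE]
}

n_genes <- function(hits) length(unique(toupper(hits$gene_symbol)))

#' Tabulate per-motif match counts along the filter chain
#'
#' @param hits_raw,hits_header,hits_whitelist named lists of hit data.frames
#'   (one element per motif, in motif order) after the scan, after the header
#'   filter, and after the whitelist filter.
#' @return data.frame with one row per motif -- \code{motif_index},
#'   \code{n_transcripts}, \code{n_genes}, \code{n_genes_after_header},
#'   \code{n_genes_after_whitelist} -- plus a \code{Total} row in which gene
#'   counts are de-duplicated across motifs; the plain (with-duplicates)
#'   column sums are attached as \code{attr(, "totals_with_duplicates")}.
#' @export
summarize_matches <- function(hits_raw, hits_header, hits_whitelist) {
  stopifnot(length(hits_raw) == length(hits_header),
            length(hits_raw) == length(hits_whitelist))
  n <- length(hits_raw)
  per <- data.frame(
    motif_index = seq_len(n),
    n_transcripts = vapply(hits_raw, function(h) length(unique(h$transcript_id)), 0L),
    n_genes = vapply(hits_raw, n_genes, 0L),
    n_genes_after_header = vapply(hits_header, n_genes, 0L),
    n_genes_after_whitelist = vapply(hits_whitelist, n_genes, 0L))
  dedup <- function(hlist) length(unique(toupper(
    unlist(lapply(hlist, function(h) h$gene_symbol), use.names = FALSE))))
  total <- data.frame(
    motif_index = NA_integer_,
    n_transcripts = length(unique(unlist(lapply(hits_raw, function(h) h$transcript_id)))),
    n_genes = dedup(hits_raw),
    n_genes_after_header = dedup(hits_header),
    n_genes_after_whitelist = dedup(hits_whitelist))
  out <- rbind(per, total)
  rownames(out) <- c(paste0("motif_", seq_len(n)), "Total")
  attr(out, "totals_with_duplicates") <- colSums(per[-1])
  out
}

#' Scan, filter and tabulate complements of common sequences
#'
#' Runs \code{\link{scan_database}} for the complement of every common
#' sequence, applies the header and whitelist filters, and tabulates the
#' match counts.
#'
#' @param common_sequences run table from
#'   \code{\link{find_common_sequences}} (uses the \code{complement} column).
#' @param db transcript database data.frame.
#' @param whitelist character vector of gene symbols (or \code{NULL} to skip
#'   the whitelist stage).
#' @param exclude_patterns description substrings to exclude.
#' @param min_identity identity threshold for the scan.
#' @return list with \code{hits} (per-motif list of surviving hit frames),
#'   \code{hits_raw}, \code{hits_header}, \code{summary} (from
#'   \code{\link{summarize_matches}}) and \code{genes} (per-motif list of
#'   surviving gene symbols, upper-cased).
#' @export
match_complements <- function(common_sequences, db, whitelist = NULL,
                              exclude_patterns = c("PREDICTED", "cDNA"),
                              min_identity = 0.85) {
  stopifnot(is.data.frame(common_sequences),
            "complement" %in% names(common_sequences))
  raw <- lapply(common_sequences$complement, scan_database, db = db,
                min_identity = min_identity)
  header <- lapply(raw, filter_headers, exclude_patterns = exclude_patterns)
  final <- if (is.null(whitelist)) header
           else lapply(header, filter_whitelist, whitelist = whitelist)
  list(hits = final, hits_raw = raw, hits_header = header,
       summary = summarize_matches(raw, header, final),
       genes = lapply(final, function(h) unique(toupper(h$gene_symbol))))
}
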