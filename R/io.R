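#' Read a probe-level expression table
#'
#' The TSV dialect written by the synthetic-data generator (and expected from
#' any externally exported dataset): columns \code{probe_id}, \code{biotype},
#' \code{conf_<sample>} confidence columns and \code{<sample>} intensity
#' columns, one row per probe. Sample condition labels are taken from a
#' \code{# condition:} header line or supplied explicitly.
#'
#' @param path path to the TSV file.
#' @param condition optional named character vector of per-sample condition
#'   labels; overrides the header line if both are present.
#' @return an \code{\link{expression_matrix}}.
#' @export
read_expression_tsv <- function(path, condition = NULL) {
  lines <- readLines(path)
  header_line <- grep("^# condition:", lines, value = TRUE)
  if (is.null(condition) && length(header_line)) {
    spec <- strsplit(sub("^# condition:\\s*", "", header_line[1]), ",")[[1]]
    kv <- strsplit(trimws(spec), "=")
    condition <- vapply(kv, `[`, "", 2)
    names(condition) <- vapply(kv, `[`, "", 1)
  }
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"probe_id" %in% names(df)) stop("expression TSV lacks a 'probe_id' column")
  dup <- df$probe_id[duplicated(df$probe_id)]
  if (length(dup))
    stop("duplicated probe id(s) at row(s) ",
         paste(which(df$probe_id %in% dup), collapse = ", "), ": ",
         paste(unique(dup), collapse = ", "))
  conf_cols <- grep("^conf_", names(df), value = TRUE)
  samples <- sub("^conf_", "", conf_cols)
  if (!length(samples))
    samples <- setdiff(names(df), c("probe_id", "biotype"))
  missing_s <- setdiff(samples, names(df))
  if (length(missing_s))
    stop("missing intensity column(s): ", paste(missing_s, collapse = ", "))
  for (s in samples) {
    v <- suppressWarnings(as.numeric(df[[s]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop(sprintf("non-numeric intensity in column '%s', row %d (value '%s')",
                   s, bad[1], df[[s]][bad[1]]))
    df[[s]] <- v
  }
  intens <- as.matrix(df[samples])
  rownames(intens) <- df$probe_id
  conf <- NULL
  if (length(conf_cols)) {
    conf <- as.matrix(df[conf_cols])
    storage.mode(conf) <- "integer"
    dimnames(conf) <- dimnames(intens)
  }
  biotype <- NULL
  if ("biotype" %in% names(df)) {
    biotype <- df$biotype
    names(biotype) <- df$probe_id
  }
  if (is.null(condition))
    stop("no condition labels: supply 'condition' or a '# condition:' header")
  expression_matrix(intens, condition, confidence = conf, biotype = biotype)
}

#' Write a probe-level expression table
#'
#' @param m an \code{ExpressionMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  samples <- colnames(m$intensities)
  df <- data.frame(probe_id = rownames(m$intensities),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(m$biotype)) df$biotype <- unname(m$biotype)
  if (!is.null(m$confidence))
    for (s in samples) df[[paste0("conf_", s)]] <- m$confidence[, s]
  for (s in samples) df[[s]] <- m$intensities[, s]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# condition: ",
                    paste(samples, m$condition[samples], sep = "=", collapse = ",")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript database FASTA
#'
#' Headers follow \code{>transcript_id|gene_symbol|description}; a header
#' without pipes yields an empty gene symbol and description.
#'
#' @param path FASTA file path.
#' @return data.frame with columns \code{transcript_id}, \code{gene_symbol},
#'   \code{description}, \code{sequence}.
#' @export
read_transcript_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  data.frame(
    transcript_id = vapply(parts, `[`, "", 1),
    gene_symbol   = vapply(parts, function(p) if (length(p) >= 2) p[2] else "", ""),
    description   = vapply(parts, function(p)
      if (length(p) >= 3) paste(p[-(1:2)], collapse = "|") else "", ""),
    sequence      = unname(toupper(as.character(set))),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a transcript database FASTA
#'
#' @param db data.frame as returned by \code{\link{read_transcript_fasta}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_transcript_fasta <- function(db, path) {
  set <- Biostrings::BStringSet(db$sequence)
  names(set) <- paste(db$transcript_id, db$gene_symbol, db$description, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a gene whitelist (one symbol per line)
#'
#' Used to represent genes with confirmed expression in the cerebral cortex.
#' Symbols are upper-cased; blank lines and \code{#} comments are ignored.
#'
#' @param path text file path.
#' @return character vector of gene symbols.
#' @export
read_whitelist <- function(path) {
  lines <- trimws(readLines(path))
  toupper(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' Write a gene whitelist
#' @param genes character vector of gene symbols.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_whitelist <- function(genes, path) {
  writeLines(toupper(genes), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member gene symbols, all
#' tab-separated. Gene symbols are upper-cased and de-duplicated within a
#' term; terms with an empty gene list are skipped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (term id -> gene set), with the
#'   per-term descriptions in \code{attr(, "description")}.
#' @export
read_gmt <- function(path) {
  fields <- strsplit(readLines(path), "\t", fixed = TRUE)
  fields <- fields[vapply(fields, function(f) any(nzchar(f)), TRUE)]
  sets <- list(); desc <- character()
  for (f in fields) {
    genes <- unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])]))
    if (length(f) < 3L || !length(genes)) { next }
    sets[[f[1]]] <- genes
    desc[f[1]] <- f[2]
  }
  n_skipped <- length(fields) - length(sets)
  if (n_skipped > 0)
    warning(n_skipped, " term(s) with a blank gene list skipped")
  attr(sets, "description") <- desc
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors (term id -> gene set).
#' @param path output path.
#' @param description optional named character vector of term descriptions.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && nm %in% names(description))
      description[[nm]] else "na"
    paste(c(nm, d, toupper(sets[[nm]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
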