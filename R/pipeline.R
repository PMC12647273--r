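#' Run the full screening pipeline
#'
#' Executes the five analysis stages in order -- preprocessing, PCA
#' selection, consensus-motif extraction, complement matching, term
#' enrichment -- on in-memory inputs, and assembles a funnel report of the
#' probe and gene counts at every stage (the analogue of the dataset-level
#' counts a user re-analyzing the deposited accession would compare against).
#'
#' @param expr an \code{\link{expression_matrix}}.
#' @param alignment an \code{Alignment} holding one aligned sequence per
#'   probe (only the selected probes' rows are used for consensus
#'   extraction); pass an externally computed alignment here when one is
#'   available.
#' @param db transcript database data.frame
#'   (see \code{\link{read_transcript_fasta}}).
#' @param whitelist character vector of cortex-expressed gene symbols, or
#'   \code{NULL} to skip that filter.
#' @param gmt named list of annotation categories (each a term -> gene-set
#'   list), or \code{NULL} to skip enrichment.
#' @param k number of top-ranked probes to extract (default 100).
#' @param min_conf,keep_biotype,outlier_k,outlier_require,low_expr_threshold,low_expr_mode
#'   preprocessing parameters (see \code{\link{preprocess_expression}}).
#' @param min_frac,min_run_length consensus parameters
#'   (see \code{\link{find_common_sequences}}).
#' @param min_identity complement-scan identity threshold.
#' @param exclude_patterns description substrings excluded from matches.
#' @param min_fold,max_fdr,ease enrichment parameters
#'   (see \code{\link{enrich_gene_list}}).
#' @param out_dir optional directory; when given, every stage's tables are
#'   written there as TSV/FASTA.
#' @return list of class \code{PipelineResult} with elements
#'   \code{preprocess}, \code{pca}, \code{selection}, \code{cluster},
#'   \code{common_sequences}, \code{match}, \code{enrichment} (per-motif
#'   results), \code{enriched_terms} (union over motifs) and \code{funnel}
#'   (stage-count data.frame).
#' @export
run_pipeline <- function(expr, alignment, db, whitelist = NULL, gmt = NULL,
                         k = 100L,
                         min_conf = 2L, keep_biotype = "lncRNA",
                         outlier_k = 1.0, outlier_require = "all",
                         low_expr_threshold = 100, low_expr_mode = "any",
                         min_frac = 0.10, min_run_length = 10L,
                         min_identity = 0.85,
                         exclude_patterns = c("PREDICTED", "cDNA"),
                         min_fold = 2.0, max_fdr = 0.05, ease = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(alignment, "Alignment"))

  pp <- preprocess_expression(expr, min_conf = min_conf,
                              keep_biotype = keep_biotype,
                              outlier_k = outlier_k,
                              outlier_require = outlier_require,
                              low_expr_threshold = low_expr_threshold,
                              low_expr_mode = low_expr_mode)
  pca <- run_pca(pp$z)
  sel <- select_component(pca, severity_of(pp$expr))
  sel <- select_top(pca, sel, k = k)
  clus <- cluster_order(pp$z[sel$selected_probe_ids, , drop = FALSE])

  aln_ids <- intersect(sel$selected_probe_ids, alignment$ids)
  if (!length(aln_ids))
    stop("stage consensus_motif failed: no selected probe has an aligned sequence")
  sub_aln <- as_alignment(stats::setNames(
    alignment$seqs[match(aln_ids, alignment$ids)], aln_ids))
  runs <- find_common_sequences(sub_aln, min_frac = min_frac,
                                min_run_length = min_run_length)

  match <- NULL; enrichment <- list(); enriched_terms <- character()
  if (nrow(runs)) {
    match <- match_complements(runs, db, whitelist = whitelist,
                               exclude_patterns = exclude_patterns,
                               min_identity = min_identity)
    if (!is.null(gmt)) {
      catalog <- annotation_catalog(gmt, background = toupper(db$gene_symbol))
      for (m in seq_len(nrow(runs))) {
        genes <- match$genes[[m]]
        if (!length(genes)) next
        enrichment[[m]] <- enrich_gene_list(genes, catalog,
                                            min_fold = min_fold,
                                            max_fdr = max_fdr, ease = ease)
        enriched_terms <- union(enriched_terms,
                                enrichment[[m]]$enriched$term)
      }
    }
  }

  funnel <- pp$reports
  funnel <- rbind(funnel, data.frame(
    stage = c("pca_top_k", "common_sequences", "matched_genes",
              "matched_genes_after_header", "matched_genes_after_whitelist",
              "enriched_terms"),
    probes_in = NA_real_,
    probes_out = c(length(sel$selected_probe_ids), nrow(runs),
                   if (is.null(match)) c(0, 0, 0) else unlist(
                     match$summary["Total", c("n_genes",
                                              "n_genes_after_header",
                                              "n_genes_after_whitelist")]),
                   length(enriched_terms))))
  rownames(funnel) <- NULL

  res <- structure(list(preprocess = pp, pca = pca, selection = sel,
                        cluster = clus, common_sequences = runs,
                        match = match, enrichment = enrichment,
                        enriched_terms = sort(enriched_terms),
                        funnel = funnel), class = "PipelineResult")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("Screening pipeline result\n")
  cat("-------------------------\n")
  f <- x$funnel
  for (i in seq_len(nrow(f)))
    cat(sprintf("  %-32s %s%s\n", f$stage[i],
                if (is.na(f$probes_in[i])) "" else paste0(f$probes_in[i], " -> "),
                f$probes_out[i]))
  if (length(x$enriched_terms))
    cat("enriched terms:", paste(x$enriched_terms, collapse = ", "), "\n")
  invisible(x)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res$funnel, "funnel.tsv")
  wt(res$preprocess$reports, "filter_reports.tsv")
  wt(data.frame(component = seq_along(res$pca$contribution_ratios),
                contribution_ratio = res$pca$contribution_ratios),
     "contribution_ratios.tsv")
  loading_df <- data.frame(component = rownames(res$pca$loadings),
                           res$pca$loadings, check.names = FALSE)
  wt(loading_df, "loadings.tsv")
  wt(data.frame(rank = seq_along(res$selection$selected_probe_ids),
                probe_id = res$selection$selected_probe_ids,
                score = res$selection$selected_scores),
     "selected_probes.tsv")
  runs <- res$common_sequences
  wt(runs[setdiff(names(runs), "column_frequency")], "common_sequences.tsv")
  if (!is.null(res$match)) {
    wt(cbind(motif_index = rep(seq_along(res$match$hits),
                               vapply(res$match$hits, nrow, 0L)),
             do.call(rbind, res$match$hits)), "hits.tsv")
    wt(cbind(row = rownames(res$match$summary), res$match$summary),
       "match_summary.tsv")
  }
  if (length(res$enrichment)) {
    all_rows <- do.call(rbind, lapply(seq_along(res$enrichment), function(m)
      if (is.null(res$enrichment[[m]])) NULL
      else cbind(motif_index = m, res$enrichment[[m]]$rows)))
    wt(all_rows, "enrichment.tsv")
  }
  invisible(out_dir)
}

#' Run the pipeline on a freshly generated synthetic study
#'
#' Generates a synthetic study with \code{\link{simulate_study}} and runs
#' \code{\link{run_pipeline}} on it with \code{k = n_suppressive}. The
#' consensus threshold defaults to 0.90 here rather than the 0.10 used for
#' externally aligned input: the synthetic alignment is gapless with full
#' column occupancy, so every column trivially carries a modal base above
#' 0.10, and near-unanimity is the faithful analogue of the original rule
#' (see the methods vignette).
#'
#' @param seed master seed for the generators.
#' @param n_probes,n_suppressive,effect_size,noise_sd,corruption generator
#'   settings (see \code{\link{simulate_study}}).
#' @param min_frac consensus threshold for the gapless synthetic alignment
#'   (default 0.90).
#' @param ... further arguments passed to \code{\link{run_pipeline}}.
#' @return list with \code{result} (a \code{PipelineResult}), \code{truth}
#'   and \code{inputs} (the generated study).
#' @export
run_synthetic_study <- function(seed = 1L, n_probes = 1000L,
                                n_suppressive = 50L, effect_size = 1.25,
                                noise_sd = 0.25, corruption = 0,
                                min_frac = 0.90, ...) {
  study <- simulate_study(seed = seed, n_probes = n_probes,
                          n_suppressive = n_suppressive,
                          effect_size = effect_size, noise_sd = noise_sd,
                          corruption = corruption)
  res <- run_pipeline(study$expr, study$alignment, study$db,
                      whitelist = study$whitelist, gmt = study$gmt,
                      k = n_suppressive, min_frac = min_frac, ...)
  list(result = res, truth = study$truth, inputs = study)
}

#' Validate pipeline input files before any computation
#'
#' Checks formats, alphabets and dimension consistency of the on-disk inputs
#' and returns one problem entry (file, cause) per defect found; an empty
#' data.frame means all supplied inputs parse cleanly.
#'
#' @param expression_tsv,alignment_fasta,transcript_fasta,whitelist_txt,gmt_file
#'   paths to the individual inputs; \code{NULL} entries are skipped.
#' @return data.frame with columns \code{file} and \code{problem}.
#' @export
validate_inputs <- function(expression_tsv = NULL, alignment_fasta = NULL,
                            transcript_fasta = NULL, whitelist_txt = NULL,
                            gmt_file = NULL) {
  problems <- list()
  note <- function(file, problem)
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, problem = problem, stringsAsFactors = FALSE)
  check <- function(path, reader) {
    if (is.null(path)) return()
    if (!file.exists(path)) { note(path, "file does not exist"); return() }
    tryCatch(withCallingHandlers(reader(path),
                                 warning = function(w) invokeRestart("muffleWarning")),
             error = function(e) note(path, conditionMessage(e)))
  }
  check(expression_tsv, read_expression_tsv)
  check(alignment_fasta, function(p) read_alignment(p, "aligned-fasta"))
  check(transcript_fasta, function(p) {
    db <- read_transcript_fasta(p)
    bad <- grepl("[^ACGTUN]", db$sequence)
    if (any(bad))
      stop("illegal sequence character(s) in record '",
           db$transcript_id[which(bad)[1]], "'")
    db
  })
  check(whitelist_txt, read_whitelist)
  check(gmt_file, read_gmt)
  if (!length(problems))
    return(data.frame(file = character(), problem = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, problems)
}
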