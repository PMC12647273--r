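#' Assemble an annotation catalog
#'
#' @param categories named list of categories, each a named list (or GMT list
#'   from \code{\link{read_gmt}}) mapping term id to a character vector of
#'   gene symbols.
#' @param background character vector of background (population) gene
#'   symbols; defaults to the union of all annotated genes. Annotated genes
#'   absent from a supplied background are added with a message, preserving
#'   the invariant that every annotated gene is in the background.
#' @return object of class \code{AnnotationCatalog}: list with
#'   \code{categories} (gene sets upper-cased, empty terms dropped) and
#'   \code{background}.
#' @export
annotation_catalog <- function(categories, background = NULL) {
  stopifnot(is.list(categories), !is.null(names(categories)))
  categories <- lapply(categories, function(cat) {
    cat <- lapply(cat, function(g) unique(toupper(g)))
    cat[vapply(cat, length, 0L) > 0]
  })
  annotated <- unique(toupper(unlist(categories, use.names = FALSE)))
  if (is.null(background)) {
    background <- annotated
  } else {
    background <- unique(toupper(background))
    extra <- setdiff(annotated, background)
    if (length(extra)) {
      message(length(extra), " annotated gene(s) added to the background")
      background <- union(background, extra)
    }
  }
  structure(list(categories = categories, background = background),
            class = "AnnotationCatalog")
}

#' Contingency counts for one term
#'
#' Computes the four counts underlying fold enrichment with the semantics of
#' per-category annotation totals: \code{PT} is the number of background
#' genes with at least one annotation in the category, \code{PH} the
#' background genes annotated to the term, \code{LT} the list genes with at
#' least one annotation in the category, and \code{LH} the list genes
#' annotated to the term. Gene symbols are matched case-insensitively.
#'
#' @param gene_list character vector of gene symbols.
#' @param catalog an \code{AnnotationCatalog}.
#' @param category category name.
#' @param term term id within the category.
#' @return named integer vector \code{c(LH, LT, PH, PT)}.
#' @export
build_contingency <- function(gene_list, catalog, category, term) {
  stopifnot(inherits(catalog, "AnnotationCatalog"))
  cat_sets <- catalog$categories[[category]]
  if (is.null(cat_sets)) stop("unknown category: ", category)
  term_genes <- cat_sets[[term]]
  if (is.null(term_genes)) stop("unknown term: ", term)
  annotated <- unique(unlist(cat_sets, use.names = FALSE))
  genes <- unique(toupper(gene_list))
  pop_annotated <- intersect(catalog$background, annotated)
  list_annotated <- intersect(genes, pop_annotated)
  c(LH = length(intersect(list_annotated, term_genes)),
    LT = length(list_annotated),
    PH = length(intersect(pop_annotated, term_genes)),
    PT = length(pop_annotated))
}

#' Fold enrichment
#'
#' The ratio of the list hit rate to the population hit rate,
#' \code{(LH/LT) / (PH/PT)}, computed exactly from the integer counts.
#'
#' @param LH,LT,PH,PT list hits, list total, population hits, population
#'   total (vectorized).
#' @return numeric fold-enrichment value(s).
#' @export
fold_enrichment <- function(LH, LT, PH, PT) {
  if (any(LT == 0) || any(PH == 0) || any(PT == 0))
    stop("fold enrichment undefined for LT, PH or PT equal to 0")
  (LH / LT) / (PH / PT)
}

#' One-sided hypergeometric enrichment p-value
#'
#' Upper-tail probability of observing at least \code{LH} term hits when
#' \code{LT} genes are drawn from a population of \code{PT} genes containing
#' \code{PH} term members. With \code{ease = TRUE} the observed hit count is
#' first reduced by one (floored at zero) -- the conservative EASE-score
#' variant popularized by DAVID.
#'
#' @param LH,LT,PH,PT contingency counts (vectorized).
#' @param ease logical; apply the EASE adjustment (default \code{TRUE}).
#' @return p-value(s) in [0, 1].
#' @export
enrichment_pvalue <- function(LH, LT, PH, PT, ease = TRUE) {
  x <- if (ease) pmax(LH - 1, 0) else LH
  stats::phyper(x - 1, PH, PT - PH, LT, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity, one
#' value per input p-value (order preserved).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted values (q-values).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Keep significantly enriched rows
#'
#' @param rows data.frame with \code{fold} and \code{fdr} columns.
#' @param min_fold minimum fold enrichment, inclusive (default 2.0).
#' @param max_fdr maximum FDR, inclusive (default 0.05).
#' @return the surviving rows, sorted by fold enrichment descending.
#' @export
filter_enriched <- function(rows, min_fold = 2.0, max_fdr = 0.05) {
  stopifnot(is.data.frame(rows), all(c("fold", "fdr") %in% names(rows)))
  keep <- rows$fold >= min_fold & rows$fdr <= max_fdr
  out <- rows[keep, , drop = FALSE]
  out[order(-out$fold), , drop = FALSE]
}

#' Term-enrichment analysis of a gene list
#'
#' Scores every term of every category against the gene list: contingency
#' counts, fold enrichment, one-sided hypergeometric p-value (EASE variant by
#' default) and Benjamini-Hochberg FDR computed within each category (terms
#' of one category form one multiple-testing family). Terms with \code{LT =
#' 0} or \code{PH = 0} are skipped with a message.
#'
#' @param gene_list character vector of gene symbols.
#' @param catalog an \code{AnnotationCatalog}.
#' @param min_fold,max_fdr significance filter bounds (both inclusive).
#' @param ease logical; EASE-adjusted p-values (default \code{TRUE}).
#' @return list with \code{rows} (all scored terms: \code{category},
#'   \code{term}, \code{LH}, \code{LT}, \code{PH}, \code{PT}, \code{fold},
#'   \code{p}, \code{fdr}) and \code{enriched} (the filtered, fold-sorted
#'   subset).
#' @export
enrich_gene_list <- function(gene_list, catalog, min_fold = 2.0,
                             max_fdr = 0.05, ease = TRUE) {
  stopifnot(inherits(catalog, "AnnotationCatalog"))
  genes <- unique(toupper(gene_list))
  all_rows <- list()
  for (category in names(catalog$categories)) {
    cat_sets <- catalog$categories[[category]]
    annotated <- unique(unlist(cat_sets, use.names = FALSE))
    pop_annotated <- intersect(catalog$background, annotated)
    list_annotated <- intersect(genes, pop_annotated)
    LT <- length(list_annotated)
    PT <- length(pop_annotated)
    LH <- vapply(cat_sets, function(g) length(intersect(list_annotated, g)), 0L)
    PH <- vapply(cat_sets, function(g) length(intersect(pop_annotated, g)), 0L)
    usable <- LT > 0 & PH > 0
    if (any(!usable))
      message("category ", category, ": ", sum(!usable),
              " term(s) skipped (LT = 0 or PH = 0)")
    if (!any(usable)) next
    rows <- data.frame(category = category, term = names(cat_sets)[usable],
                       LH = LH[usable], LT = LT, PH = PH[usable], PT = PT,
                       stringsAsFactors = FALSE, row.names = NULL)
    rows$fold <- fold_enrichment(rows$LH, rows$LT, rows$PH, rows$PT)
    rows$p <- enrichment_pvalue(rows$LH, rows$LT, rows$PH, rows$PT, ease = ease)
    rows$fdr <- bh_fdr(rows$p)
    all_rows[[category]] <- rows
  }
  rows <- if (length(all_rows)) do.call(rbind, all_rows)
          else data.frame(category = character(), term = character(),
                          LH = integer(), LT = integer(), PH = integer(),
                          PT = integer(), fold = numeric(), p = numeric(),
                          fdr = numeric(), stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  list(rows = rows, enriched = filter_enriched(rows, min_fold, max_fdr))
}
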