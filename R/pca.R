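#' Principal component analysis over probes
#'
#' Probes are the observations and samples the variables: the
#' sample-by-sample (population) covariance of the probe rows is
#' eigendecomposed, the contribution ratio of component j is its eigenvalue
#' divided by the trace, loadings are the (unit-norm) eigenvectors -- one
#' weight per sample -- and scores are the projections of the (uncentered)
#' probe rows onto the loading vectors. With all components kept, scores times
#' loadings reconstructs the input exactly, since the loading vectors form an
#' orthonormal basis of the sample space.
#'
#' @param z standardized probe x sample matrix (rows Z-scored; see
#'   \code{\link{zscore_rows}}).
#' @return an object of class \code{PCAResult}: list with
#'   \code{contribution_ratios}, \code{loadings} (component x sample),
#'   \code{scores} (probe x component), \code{probe_ids}, \code{sample_ids}.
#' @export
run_pca <- function(z) {
  stopifnot(is.matrix(z), is.numeric(z))
  if (nrow(z) < 2 || ncol(z) < 2)
    stop("need at least 2 probes and 2 samples")
  if (all(z == 0)) stop("all-zero matrix has no principal components")
  # rows are already Z-scored; no further centering across samples is applied,
  # so this is the second-moment matrix of the standardized probe rows
  covm <- crossprod(z) / nrow(z)
  eig <- eigen(covm, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  vectors <- eig$vectors
  # deterministic orientation: largest-magnitude entry of each loading positive
  for (j in seq_len(ncol(vectors))) {
    pivot <- which.max(abs(vectors[, j]))
    if (vectors[pivot, j] < 0) vectors[, j] <- -vectors[, j]
  }
  loadings <- t(vectors)
  dimnames(loadings) <- list(paste0("PC", seq_len(nrow(loadings))), colnames(z))
  scores <- z %*% vectors
  dimnames(scores) <- list(rownames(z), rownames(loadings))
  structure(list(contribution_ratios = values / sum(values),
                 loadings = loadings, scores = scores,
                 probe_ids = rownames(z), sample_ids = colnames(z)),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d probes, %d samples, %d components\n",
              length(x$probe_ids), length(x$sample_ids),
              length(x$contribution_ratios)))
  cat("contribution ratios:",
      paste(sprintf("%.3f", utils::head(x$contribution_ratios, 4)),
            collapse = ", "), "...\n")
  invisible(x)
}

#' Choose the lesion-discriminating component
#'
#' Selects the component whose loading vector has the largest absolute
#' Spearman rank correlation with the ordinal lesion severity of the samples,
#' and orients it so that low-severity (control/weak) samples carry positive
#' loadings -- the sign convention under which probes suppressed by the lesion
#' receive high scores. Ties in absolute correlation resolve to the lowest
#' component index with a message.
#'
#' @param p a \code{PCAResult}.
#' @param severity named numeric vector of per-sample severity ranks (see
#'   \code{\link{severity_of}}).
#' @return list of class \code{SelectionResult} with \code{component_index},
#'   \code{orientation} (+1/-1) and \code{severity_correlation} (of the
#'   oriented loadings).
#' @export
select_component <- function(p, severity) {
  stopifnot(inherits(p, "PCAResult"))
  missing <- setdiff(p$sample_ids, names(severity))
  if (length(missing))
    stop("severity undefined for sample(s): ", paste(missing, collapse = ", "))
  sev <- severity[p$sample_ids]
  if (stats::sd(sev) == 0)
    stop("severity is constant across samples: no discriminating axis exists")
  cors <- apply(p$loadings, 1, function(l)
    suppressWarnings(stats::cor(l, sev, method = "spearman")))
  cors[is.na(cors)] <- 0
  best_abs <- max(abs(cors))
  ties <- which(abs(abs(cors) - best_abs) < 1e-12)
  if (length(ties) > 1)
    message("tie in |severity correlation| between components ",
            paste(ties, collapse = ", "), "; lowest index chosen")
  idx <- ties[1]
  orientation <- if (cors[idx] > 0) -1 else 1
  structure(list(component_index = unname(idx),
                 orientation = orientation,
                 severity_correlation = unname(orientation * cors[idx])),
            class = "SelectionResult")
}

#' Top-k probes by oriented component score
#'
#' Sorts probes by the oriented score of the selected component, descending,
#' and returns the top k; ties in score are broken by probe id (lexicographic)
#' with a message.
#'
#' @param p a \code{PCAResult}.
#' @param sel a \code{SelectionResult} from \code{\link{select_component}}.
#' @param k number of probes to extract (default 100); \code{k} larger than
#'   the probe count returns all probes with a warning.
#' @return the \code{SelectionResult} extended with \code{k},
#'   \code{selected_probe_ids} (rank order) and \code{selected_scores}.
#' @export
select_top <- function(p, sel, k = 100L) {
  stopifnot(inherits(p, "PCAResult"), inherits(sel, "SelectionResult"))
  if (k < 1) stop("'k' must be >= 1")
  score <- sel$orientation * p$scores[, sel$component_index]
  if (k > length(score)) {
    warning("k = ", k, " exceeds the ", length(score),
            " probes available; returning all")
    k <- length(score)
  }
  ord <- order(-score, p$probe_ids)
  topk <- ord[seq_len(k)]
  if (k < length(score) && score[ord[k]] == score[ord[k + 1]])
    message("score tie at rank ", k, " broken by probe id")
  sel$k <- as.integer(k)
  sel$selected_probe_ids <- p$probe_ids[topk]
  sel$selected_scores <- unname(score[topk])
  sel$full_ranking <- p$probe_ids[ord]
  sel
}

#' Hierarchical-clustering leaf orders for a heatmap
#'
#' Agglomerative clustering of probes (rows) and samples (columns) on
#' Euclidean distances, for display of the selected probe subset.
#'
#' @param z standardized probe x sample matrix (at least 2 probes).
#' @param linkage agglomeration method passed to \code{\link[stats]{hclust}}
#'   (default \code{"average"}).
#' @return list with \code{probe_order} and \code{sample_order} (leaf-order
#'   id vectors) and the two \code{hclust} objects (\code{probe_hclust},
#'   \code{sample_hclust}) carrying the linkage heights.
#' @export
cluster_order <- function(z, linkage = "average") {
  stopifnot(is.matrix(z), nrow(z) >= 2)
  hr <- stats::hclust(stats::dist(z), method = linkage)
  hc <- if (ncol(z) >= 2)
    stats::hclust(stats::dist(t(z)), method = linkage) else NULL
  list(probe_order = rownames(z)[hr$order],
       sample_order = if (is.null(hc)) colnames(z) else colnames(z)[hc$order],
       probe_hclust = hr, sample_hclust = hc)
}
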