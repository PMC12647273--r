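#' Probe-level expression container
#'
#' Bundles the probe-by-sample intensity matrix with the per-probe/per-sample
#' quantification-confidence scores, per-probe biotype labels and per-sample
#' lesion-condition labels used throughout the screening pipeline.
#'
#' @param intensities numeric matrix, probes in rows, samples in columns; must
#'   carry row and column dimnames and be strictly positive.
#' @param condition named character vector mapping each sample id to one of
#'   the lesion conditions (by default \code{"severe"}, \code{"moderate"},
#'   \code{"weak"}, \code{"control"}).
#' @param confidence optional integer matrix with the same dimensions as
#'   \code{intensities}, values in \{0, 1, 2\} (2 = highest quantification
#'   confidence on the array platform).
#' @param biotype optional named character vector mapping each probe id to a
#'   transcript biotype label (e.g. \code{"lncRNA"}).
#'
#' @return An object of class \code{ExpressionMatrix}: a list with elements
#'   \code{intensities}, \code{confidence}, \code{biotype}, \code{condition}.
#' @export
expression_matrix <- function(intensities, condition,
                              confidence = NULL, biotype = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("'intensities' must be a numeric matrix")
  if (is.null(rownames(intensities)) || is.null(colnames(intensities)))
    stop("'intensities' must have probe rownames and sample colnames")
  if (anyDuplicated(rownames(intensities)))
    stop("duplicate probe ids in 'intensities'")
  if (any(!is.finite(intensities)) || any(intensities <= 0))
    stop("'intensities' must be strictly positive and finite")
  samples <- colnames(intensities)
  if (!all(samples %in% names(condition)))
    stop("every sample needs a condition label; missing: ",
         paste(setdiff(samples, names(condition)), collapse = ", "))
  condition <- condition[samples]
  if (!is.null(confidence)) {
    if (!is.matrix(confidence) || !identical(dim(confidence), dim(intensities)))
      stop("'confidence' must be a matrix with the same dimensions as 'intensities'")
    if (!all(confidence %in% 0:2))
      stop("'confidence' values must be 0, 1 or 2")
    dimnames(confidence) <- dimnames(intensities)
  }
  if (!is.null(biotype)) {
    if (!all(rownames(intensities) %in% names(biotype)))
      stop("every probe needs a biotype label")
    biotype <- biotype[rownames(intensities)]
  }
  structure(list(intensities = intensities, confidence = confidence,
                 biotype = biotype, condition = condition),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$intensities), ncol(x$intensities)))
  cat("conditions:", paste(sprintf("%s=%d", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  cat("confidence scores:", if (is.null(x$confidence)) "absent" else "present",
      "| biotype labels:", if (is.null(x$biotype)) "absent" else "present", "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$intensities)

#' Subset an ExpressionMatrix to a set of probes
#'
#' @param m an \code{ExpressionMatrix}.
#' @param probe_ids character vector of probe ids to keep (order preserved as
#'   given).
#' @return the subsetted \code{ExpressionMatrix}.
#' @export
subset_probes <- function(m, probe_ids) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  missing <- setdiff(probe_ids, rownames(m$intensities))
  if (length(missing))
    stop("unknown probe ids: ", paste(utils::head(missing, 5), collapse = ", "))
  structure(list(
    intensities = m$intensities[probe_ids, , drop = FALSE],
    confidence  = if (is.null(m$confidence)) NULL
                  else m$confidence[probe_ids, , drop = FALSE],
    biotype     = if (is.null(m$biotype)) NULL else m$biotype[probe_ids],
    condition   = m$condition), class = "ExpressionMatrix")
}

#' Ordinal lesion severity of each sample
#'
#' Encodes the four lesion conditions as an ordinal covariate
#' (control = 0, weak = 1, moderate = 2, severe = 3).
#'
#' @param condition named character vector of per-sample condition labels, or
#'   an \code{ExpressionMatrix}.
#' @return named numeric vector of severity ranks, one per sample.
#' @export
severity_of <- function(condition) {
  if (inherits(condition, "ExpressionMatrix")) condition <- condition$condition
  levels <- c(control = 0, weak = 1, moderate = 2, severe = 3)
  unknown <- setdiff(unique(condition), names(levels))
  if (length(unknown))
    stop("unknown condition labels: ", paste(unknown, collapse = ", "))
  out <- levels[condition]
  names(out) <- names(condition)
  out
}

# Run code with a local, restorable RNG state so generators are pure in seed.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
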