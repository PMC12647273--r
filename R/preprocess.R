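filter_report <- function(stage, probes_in, removed_ids) {
  list(stage = stage, probes_in = probes_in,
       probes_out = probes_in - length(removed_ids),
       removed_ids = removed_ids)
}

apply_removal <- function(m, stage, removed_ids) {
  report <- filter_report(stage, nrow(m$intensities), removed_ids)
  keep <- setdiff(rownames(m$intensities), removed_ids)
  list(expr = subset_probes(m, keep), report = report)
}

#' Quantification-confidence filter
#'
#' Retains exactly the probes having at least one sample whose confidence
#' score (0/1/2 platform scale, 2 = highest) reaches \code{min_level}.
#'
#' @param m an \code{ExpressionMatrix} with a confidence matrix.
#' @param min_level minimum score required in at least one sample (default 2).
#' @return list with elements \code{expr} (filtered matrix) and \code{report}
#'   (stage name, probes in/out, removed ids).
#' @export
filter_confidence <- function(m, min_level = 2L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$confidence))
    stop("no confidence matrix present; to run without confidence scores, ",
         "disable the confidence stage explicitly")
  ok <- apply(m$confidence >= min_level, 1, any)
  apply_removal(m, "confidence", rownames(m$intensities)[!ok])
}

#' Biotype filter
#'
#' Retains probes whose biotype equals \code{keep} (case-insensitive exact
#' match). Probes with labels other than \code{keep} -- including unknown
#' labels -- are removed and summarized in a message.
#'
#' @param m an \code{ExpressionMatrix} with biotype labels.
#' @param keep biotype label to retain (default \code{"lncRNA"}).
#' @return list with \code{expr} and \code{report}.
#' @export
filter_biotype <- function(m, keep = "lncRNA") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (is.null(m$biotype)) stop("no biotype labels present")
  ok <- toupper(m$biotype) == toupper(keep)
  removed <- rownames(m$intensities)[!ok]
  if (length(removed)) {
    other <- table(m$biotype[removed])
    message("biotype filter removed ", length(removed), " probe(s): ",
            paste(sprintf("%s=%d", names(other), other), collapse = ", "))
  }
  apply_removal(m, "biotype", removed)
}

#' Replicate-outlier filter
#'
#' For each probe and each within-condition replicate pair, the absolute
#' intensity difference \code{d} is computed; per comparison, the mean and
#' standard deviation of \code{d} across all probes define a tolerance band
#' \code{mean +/- k_sd * sd}. A probe is removed when its \code{d} falls
#' outside the band in all comparisons (\code{require = "all"}, default) or in
#' at least one (\code{require = "any"}). Comparisons with a degenerate
#' \code{sd(d) = 0} remove nothing, and conditions with a single sample are
#' skipped with a warning.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param k_sd width of the tolerance band in pooled standard deviations
#'   (default 1).
#' @param require \code{"all"} or \code{"any"}: the quantifier over
#'   comparisons for calling a probe an outlier.
#' @return list with \code{expr} and \code{report}.
#' @export
filter_replicate_outliers <- function(m, k_sd = 1.0, require = c("all", "any")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  require <- match.arg(require)
  if (k_sd <= 0) stop("'k_sd' must be positive")
  conds <- unique(m$condition)
  outlier <- NULL
  for (cond in conds) {
    samples <- names(m$condition)[m$condition == cond]
    if (length(samples) < 2) {
      warning("condition '", cond, "' has a single sample; comparison skipped")
      next
    }
    pairs <- utils::combn(samples, 2, simplify = FALSE)
    for (p in pairs) {
      d <- abs(m$intensities[, p[1]] - m$intensities[, p[2]])
      mu <- mean(d)
      sdd <- stats::sd(d)
      out <- if (is.na(sdd) || sdd == 0) rep(FALSE, length(d))
             else d < mu - k_sd * sdd | d > mu + k_sd * sdd
      outlier <- if (is.null(outlier)) matrix(out, ncol = 1)
                 else cbind(outlier, out)
    }
  }
  if (is.null(outlier))
    return(apply_removal(m, "replicate_outlier", character()))
  flag <- if (require == "all") apply(outlier, 1, all) else apply(outlier, 1, any)
  apply_removal(m, "replicate_outlier", rownames(m$intensities)[flag])
}

#' Low-expression filter
#'
#' Removes weakly expressed probes: with \code{mode = "any"} (the default,
#' literal reading of "intensity less than the threshold in any sample") a
#' probe is removed when at least one sample is strictly below the threshold;
#' with \code{mode = "all"} only probes below the threshold in every sample
#' are removed.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param threshold positive intensity threshold (default 100); the rule is a
#'   strict "less than", so an intensity exactly at the threshold survives.
#' @param mode \code{"any"} or \code{"all"}.
#' @return list with \code{expr} and \code{report}.
#' @export
filter_low_expression <- function(m, threshold = 100, mode = c("any", "all")) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  low <- m$intensities < threshold
  flag <- if (mode == "any") apply(low, 1, any) else apply(low, 1, all)
  apply_removal(m, "low_expression", rownames(m$intensities)[flag])
}

#' Per-probe Z-score standardization
#'
#' Standardizes each probe row to mean 0 and (population, divisor N) standard
#' deviation 1: \code{x = (I - mean(I)) / sd_pop(I)}. Rows with zero variance
#' cannot be standardized and are removed with a message, never emitted as
#' \code{NaN}.
#'
#' @param m an \code{ExpressionMatrix} or a plain numeric matrix with
#'   dimnames.
#' @param sd_divisor \code{"n"} (population, default) or \code{"n-1"}
#'   (sample); the choice rescales rows by a constant and changes no
#'   downstream rank ordering.
#' @return list with \code{z} (the standardized probe x sample matrix) and
#'   \code{removed_ids} (zero-variance rows dropped).
#' @export
zscore_rows <- function(m, sd_divisor = c("n", "n-1")) {
  sd_divisor <- match.arg(sd_divisor)
  x <- if (inherits(m, "ExpressionMatrix")) m$intensities else m
  stopifnot(is.matrix(x), is.numeric(x))
  mu <- rowMeans(x)
  centered <- x - mu
  n <- ncol(x)
  ss <- rowSums(centered^2)
  sdv <- sqrt(ss / if (sd_divisor == "n") n else n - 1)
  zero <- sdv == 0
  if (any(zero))
    message("zscore: removed ", sum(zero), " zero-variance row(s): ",
            paste(utils::head(rownames(x)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
  z <- centered[!zero, , drop = FALSE] / sdv[!zero]
  list(z = z, removed_ids = rownames(x)[zero])
}

#' Run the full preprocessing chain
#'
#' Applies the four filters in their fixed order -- confidence, biotype,
#' replicate outlier, low expression -- followed by per-probe Z-score
#' standardization, and records a telescoping chain of per-stage filter
#' reports.
#'
#' @param m an \code{ExpressionMatrix}.
#' @param min_conf minimum confidence level (see
#'   \code{\link{filter_confidence}}); \code{NULL} disables the stage.
#' @param keep_biotype biotype to retain; \code{NULL} disables the stage.
#' @param outlier_k,outlier_require replicate-outlier parameters
#'   (see \code{\link{filter_replicate_outliers}}); \code{outlier_k = NULL}
#'   disables the stage.
#' @param low_expr_threshold,low_expr_mode low-expression parameters
#'   (see \code{\link{filter_low_expression}}); \code{low_expr_threshold =
#'   NULL} disables the stage.
#' @param sd_divisor standard-deviation convention for the Z-score.
#' @return list with \code{expr} (filtered \code{ExpressionMatrix}), \code{z}
#'   (standardized matrix), \code{reports} (data.frame: stage, probes_in,
#'   probes_out) and \code{removed} (named list of removed ids per stage).
#' @export
preprocess_expression <- function(m, min_conf = 2L, keep_biotype = "lncRNA",
                                  outlier_k = 1.0, outlier_require = "all",
                                  low_expr_threshold = 100,
                                  low_expr_mode = "any",
                                  sd_divisor = "n") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  reports <- list()
  removed <- list()
  step <- function(res) {
    reports[[res$report$stage]] <<- res$report
    removed[[res$report$stage]] <<- res$report$removed_ids
    res$expr
  }
  if (!is.null(min_conf)) m <- step(filter_confidence(m, min_conf))
  if (!is.null(keep_biotype)) m <- step(filter_biotype(m, keep_biotype))
  if (!is.null(outlier_k))
    m <- step(filter_replicate_outliers(m, outlier_k, outlier_require))
  if (!is.null(low_expr_threshold))
    m <- step(filter_low_expression(m, low_expr_threshold, low_expr_mode))
  zs <- zscore_rows(m, sd_divisor = sd_divisor)
  reports[["zscore"]] <- filter_report("zscore", nrow(m$intensities),
                                       zs$removed_ids)
  removed[["zscore"]] <- zs$removed_ids
  if (length(zs$removed_ids))
    m <- subset_probes(m, setdiff(rownames(m$intensities), zs$removed_ids))
  report_df <- data.frame(
    stage = vapply(reports, `[[`, "", "stage"),
    probes_in = vapply(reports, `[[`, 0, "probes_in"),
    probes_out = vapply(reports, `[[`, 0, "probes_out"),
    row.names = NULL, stringsAsFactors = FALSE)
  list(expr = m, z = zs$z, reports = report_df, removed = removed)
}
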