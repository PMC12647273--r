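#' Default planted common sequences
#'
#' Two of the consensus subsequences reported for the lesion-suppressive
#' lncRNA set, reused as the default planted motifs of the generator so that
#' the synthetic alignment exercises realistic motif lengths (12 and 11 nt).
#'
#' @return data.frame with columns \code{sequence} (RNA alphabet) and
#'   \code{start_col} (0-based planted alignment column).
#' @export
default_planted_motifs <- function() {
  data.frame(sequence = c("UUCUUUCACAUA", "AUCAUCUUUCC"),
             start_col = c(5L, 35L), stringsAsFactors = FALSE)
}

check_positive <- function(value, name, strict = TRUE) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      (strict && value <= 0) || (!strict && value < 0))
    stop("'", name, "' must be a ", if (strict) "positive" else "non-negative",
         " number")
  value
}

random_rna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), length, replace = TRUE), collapse = ""),
    "")
}

#' Generate a synthetic 8-sample expression matrix with planted signal
#'
#' Emulates the study design: two samples each of severe, moderate and weak
#' lesions plus two controls, with a planted subset of "suppressive" lncRNA
#' probes whose expected intensity decreases monotonically with lesion
#' severity. The suppressive mean intensity is linear in the ordinal severity
#' (control = 0 ... severe = 3): \code{base_intensity * (1 - delta *
#' severity)} with the per-step fractional drop \code{delta = effect_size *
#' noise_sd} (so \code{effect_size} measures the planted signal in units of
#' the noise); background probes are severity-independent. Every intensity is
#' multiplied by log-normal noise \code{exp(N(0, noise_sd))} and clipped at a
#' small positive floor. Configurable fractions of background probes are
#' planted to fail each preprocessing filter: confidence never reaching 2, a
#' non-lncRNA biotype, an aberrant within-condition replicate difference, and
#' intensities below the low-expression threshold.
#'
#' @param n_probes number of probes (default 1000).
#' @param n_suppressive number of planted suppressive probes (default 50).
#' @param base_intensity median background intensity (default 20000, keeping
#'   suppressed probes well above the intensity-100 filter at the default
#'   effect).
#' @param effect_size planted per-step signal in units of \code{noise_sd}
#'   (default 1.25, i.e. 5 times the default noise); \code{effect_size *
#'   noise_sd} must stay below 1/3 so the severe-sample mean remains
#'   positive.
#' @param noise_sd standard deviation of the multiplicative log-normal noise
#'   (default 0.25).
#' @param conf_fail_frac,other_biotype_frac,outlier_frac,low_expr_frac
#'   fractions of background probes planted to fail, respectively, the
#'   confidence, biotype, replicate-outlier and low-expression filters
#'   (defaults 0.05, 0.10, 0.02, 0.03; the four planted sets are disjoint).
#' @param seed integer seed; all randomness flows from it.
#' @return list with \code{expr} (an \code{\link{expression_matrix}}) and
#'   \code{truth} (class \code{SyntheticTruth}: \code{suppressive_probe_ids},
#'   placeholders for downstream plantings, the per-filter planted failure
#'   ids in \code{planted_fail}, and \code{seed}).
#' @export
simulate_expression <- function(n_probes = 1000L, n_suppressive = 50L,
                                base_intensity = 20000, effect_size = 1.25,
                                noise_sd = 0.25, conf_fail_frac = 0.05,
                                other_biotype_frac = 0.10,
                                outlier_frac = 0.02, low_expr_frac = 0.03,
                                seed = 1L) {
  check_positive(n_probes, "n_probes")
  check_positive(n_suppressive, "n_suppressive")
  check_positive(base_intensity, "base_intensity")
  check_positive(effect_size, "effect_size", strict = FALSE)
  check_positive(noise_sd, "noise_sd", strict = FALSE)
  if (n_suppressive > n_probes)
    stop("'n_suppressive' cannot exceed 'n_probes'")
  delta <- effect_size * noise_sd
  if (3 * delta >= 1)
    stop("'effect_size' too large: effect_size * noise_sd must be < 1/3 ",
         "for the severe-sample mean to stay positive")
  with_seed(seed, {
    conditions <- rep(c("control", "weak", "moderate", "severe"), each = 2)
    samples <- paste(conditions, rep(1:2, 4), sep = "_")
    condition <- stats::setNames(conditions, samples)
    severity <- severity_of(condition)
    probe_ids <- sprintf("PROBE_%05d", seq_len(n_probes))
    suppressive <- sort(sample(probe_ids, n_suppressive))
    is_supp <- probe_ids %in% suppressive

    mu <- matrix(base_intensity, n_probes, 8,
                 dimnames = list(probe_ids, samples))
    mu[is_supp, ] <- base_intensity *
      (1 - delta * matrix(severity, sum(is_supp), 8, byrow = TRUE))
    intens <- mu * exp(matrix(stats::rnorm(n_probes * 8, 0, noise_sd),
                              n_probes, 8))

    background <- setdiff(probe_ids, suppressive)
    n_bg <- length(background)
    pick <- function(pool, frac) {
      n <- min(length(pool), round(frac * n_bg))
      if (n < 1) character() else sort(sample(pool, n))
    }
    fail_conf <- pick(background, conf_fail_frac)
    pool <- setdiff(background, fail_conf)
    fail_bio <- pick(pool, other_biotype_frac)
    pool <- setdiff(pool, fail_bio)
    fail_out <- pick(pool, outlier_frac)
    pool <- setdiff(pool, fail_out)
    fail_low <- pick(pool, low_expr_frac)

    # planted low-expression probes: scale well below the intensity-100 floor
    intens[fail_low, ] <- intens[fail_low, ] * (50 / base_intensity)
    # planted replicate outliers: inflate the second replicate of every pair
    rep2 <- samples[endsWith(samples, "_2")]
    intens[fail_out, rep2] <- intens[fail_out, rep2] * 8
    intens <- pmax(intens, 1e-3)

    conf <- matrix(sample(0:2, n_probes * 8, replace = TRUE,
                          prob = c(0.1, 0.2, 0.7)),
                   n_probes, 8, dimnames = dimnames(intens))
    no2 <- rowSums(conf == 2) == 0
    conf[no2 & !probe_ids %in% fail_conf, 1] <- 2L
    conf[fail_conf, ] <- pmin(conf[fail_conf, ], 1L)

    biotype <- stats::setNames(rep("lncRNA", n_probes), probe_ids)
    biotype[fail_bio] <- sample(c("mRNA", "miRNA", "snoRNA"),
                                length(fail_bio), replace = TRUE)

    truth <- structure(list(
      suppressive_probe_ids = suppressive,
      planted_motifs = NULL,
      planted_target_transcripts = NULL,
      enriched_terms = NULL,
      planted_fail = list(confidence = fail_conf, biotype = fail_bio,
                          replicate_outlier = fail_out,
                          low_expression = fail_low),
      seed = as.integer(seed)), class = "SyntheticTruth")
    list(expr = expression_matrix(intens, condition, confidence = conf,
                                  biotype = biotype),
         truth = truth)
  })
}

#' @export
print.SyntheticTruth <- function(x, ...) {
  cat(sprintf("SyntheticTruth (seed %d): %d suppressive probes, %d planted motif(s), %d enriched term(s)\n",
              x$seed, length(x$suppressive_probe_ids),
              if (is.null(x$planted_motifs)) 0L else nrow(x$planted_motifs),
              length(x$enriched_terms)))
  invisible(x)
}

#' Generate pre-aligned probe sequences with planted motifs
#'
#' Produces one gapless sequence of equal length per probe (an implicit
#' trivial alignment, standing in for an externally computed multiple
#' alignment). Every suppressive probe carries each planted motif at its
#' planted column, with an optional per-base corruption probability;
#' background probes are uniform random RNA.
#'
#' @param probe_ids character vector of all probe ids to generate sequences
#'   for.
#' @param truth a \code{SyntheticTruth} (identifies the suppressive probes;
#'   updated with the planted motifs on return).
#' @param motifs data.frame with columns \code{sequence} (RNA) and
#'   \code{start_col} (0-based), as \code{\link{default_planted_motifs}}.
#' @param probe_length columns of the alignment (default 60); every motif
#'   must fit, i.e. \code{start_col + nchar(sequence) <= probe_length}.
#' @param corruption per-base probability that a planted motif base is
#'   replaced by a random different base (default 0).
#' @param seed integer seed.
#' @return list with \code{alignment} (an \code{\link{as_alignment}} object)
#'   and the updated \code{truth}.
#' @export
simulate_probe_sequences <- function(probe_ids, truth,
                                     motifs = default_planted_motifs(),
                                     probe_length = 60L, corruption = 0,
                                     seed = truth$seed + 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"), is.data.frame(motifs))
  check_positive(probe_length, "probe_length")
  if (corruption < 0 || corruption > 1) stop("'corruption' must be in [0, 1]")
  if (any(nchar(motifs$sequence) < 10))
    stop("every planted motif must be at least 10 nt long")
  over <- motifs$start_col + nchar(motifs$sequence) > probe_length
  if (any(over))
    stop("motif '", motifs$sequence[which(over)[1]],
         "' exceeds the probe bounds (probe_length = ", probe_length, ")")
  with_seed(seed, {
    seqs <- random_rna(length(probe_ids), probe_length)
    names(seqs) <- probe_ids
    supp <- intersect(probe_ids, truth$suppressive_probe_ids)
    for (id in supp) {
      chars <- strsplit(seqs[[id]], "")[[1]]
      for (k in seq_len(nrow(motifs))) {
        mchars <- strsplit(motifs$sequence[k], "")[[1]]
        if (corruption > 0) {
          hit <- stats::runif(length(mchars)) < corruption
          mchars[hit] <- vapply(mchars[hit], function(b)
            sample(setdiff(c("A", "C", "G", "U"), b), 1L), "")
        }
        chars[motifs$start_col[k] + seq_along(mchars)] <- mchars
      }
      seqs[[id]] <- paste(chars, collapse = "")
    }
    truth$planted_motifs <- motifs
    list(alignment = as_alignment(seqs), truth = truth)
  })
}

embed_motif <- function(sequence, insert, n_mismatch = 0L) {
  ins <- strsplit(insert, "")[[1]]
  if (n_mismatch > 0L) {
    pos <- sample(length(ins), n_mismatch)
    ins[pos] <- vapply(ins[pos], function(b)
      sample(setdiff(c("A", "C", "G", "U"), b), 1L), "")
  }
  offset <- sample(nchar(sequence) - length(ins), 1L)
  paste0(substr(sequence, 1, offset),
         paste(ins, collapse = ""),
         substr(sequence, offset + length(ins) + 1L, nchar(sequence)))
}

#' Generate a decoy mRNA database, whitelist and annotation sets
#'
#' For each planted motif, target transcripts embedding the motif's reverse
#' complement (a configurable fraction with one mismatch, the rest exact) are
#' mixed into a database of decoy transcripts verified, by exhaustive scan at
#' generation time, to contain no complement at the identity threshold.
#' Headers follow \code{transcript_id|gene_symbol|description}; a fraction of
#' decoy descriptions are marked \code{"PREDICTED"} or \code{"cDNA"} so the
#' header filter has work to do. The whitelist covers a configurable fraction
#' of target genes plus most decoy genes, and the annotation catalog plants
#' one enriched term per motif (the motif's target genes) among random
#' background terms.
#'
#' @param truth a \code{SyntheticTruth} with planted motifs (updated with
#'   target transcripts and enriched terms on return).
#' @param n_decoys number of decoy transcripts (default 300); 0 triggers a
#'   warning since enrichment against an all-target background is vacuous.
#' @param n_targets_per_motif target transcripts per motif (default 15).
#' @param mismatch_frac fraction of targets embedded with one mismatch
#'   (default 0.3).
#' @param predicted_frac fraction of decoy descriptions marked PREDICTED/cDNA
#'   (default 0.15).
#' @param whitelist_coverage fraction of target genes on the whitelist
#'   (default 1).
#' @param decoy_whitelist_frac fraction of decoy genes on the whitelist
#'   (default 0.8).
#' @param n_background_terms random background terms in the catalog (default
#'   20, sizes 5-15 genes).
#' @param transcript_length decoy/target transcript length (default 500).
#' @param min_identity identity threshold used for the decoy cleanliness
#'   check (default 0.85).
#' @param seed integer seed.
#' @return list with \code{db} (transcript data.frame), \code{whitelist},
#'   \code{gmt} (named list of categories, here one category \code{"SYNTH"}
#'   of term gene sets), and the updated \code{truth}.
#' @export
simulate_mrna_db <- function(truth, n_decoys = 300L, n_targets_per_motif = 15L,
                             mismatch_frac = 0.3, predicted_frac = 0.15,
                             whitelist_coverage = 1.0,
                             decoy_whitelist_frac = 0.8,
                             n_background_terms = 20L,
                             transcript_length = 500L,
                             min_identity = 0.85,
                             seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  if (is.null(truth$planted_motifs))
    stop("truth carries no planted motifs; run simulate_probe_sequences() first")
  if (n_decoys == 0)
    warning("n_decoys = 0: enrichment statistics over an all-target ",
            "background are uninformative")
  complements <- reverse_complement(truth$planted_motifs$sequence)
  with_seed(seed, {
    n_motifs <- nrow(truth$planted_motifs)
    targets <- list(); target_map <- list()
    for (k in seq_len(n_motifs)) {
      n_mm <- round(mismatch_frac * n_targets_per_motif)
      ids <- sprintf("TX_T%d_%03d", k, seq_len(n_targets_per_motif))
      seqs <- random_rna(n_targets_per_motif, transcript_length)
      for (i in seq_len(n_targets_per_motif))
        seqs[i] <- embed_motif(seqs[i], complements[k],
                               n_mismatch = if (i <= n_mm) 1L else 0L)
      targets[[k]] <- data.frame(
        transcript_id = ids,
        gene_symbol = sprintf("TG%d_%03d", k, seq_len(n_targets_per_motif)),
        description = "Mus musculus synthetic target transcript, mRNA",
        sequence = seqs, stringsAsFactors = FALSE)
      target_map[[k]] <- ids
    }
    decoys <- data.frame(
      transcript_id = sprintf("TX_D%04d", seq_len(n_decoys)),
      gene_symbol = sprintf("DG%04d", seq_len(n_decoys)),
      description = rep("Mus musculus synthetic decoy transcript, mRNA",
                        n_decoys),
      sequence = random_rna(n_decoys, transcript_length),
      stringsAsFactors = FALSE)
    # exhaustive cleanliness check: resample decoys matching any complement
    repeat {
      dirty <- rep(FALSE, nrow(decoys))
      for (comp in complements) {
        hits <- scan_database(comp, decoys, min_identity = min_identity)
        dirty[decoys$transcript_id %in% hits$transcript_id] <- TRUE
      }
      if (!any(dirty)) break
      decoys$sequence[dirty] <- random_rna(sum(dirty), transcript_length)
    }
    if (n_decoys > 0 && predicted_frac > 0) {
      n_pred <- round(predicted_frac * n_decoys)
      marked <- sample(seq_len(n_decoys), n_pred)
      half <- marked[seq_len(ceiling(n_pred / 2))]
      decoys$description[half] <-
        "PREDICTED: Mus musculus synthetic model transcript"
      decoys$description[setdiff(marked, half)] <-
        "Mus musculus synthetic cDNA clone"
    }
    db <- rbind(do.call(rbind, targets), decoys)

    target_genes <- lapply(targets, function(t) t$gene_symbol)
    wl_targets <- unlist(lapply(target_genes, function(g) {
      n <- round(whitelist_coverage * length(g))
      if (n < 1) character() else sort(sample(g, n))
    }), use.names = FALSE)
    wl_decoys <- if (n_decoys > 0) {
      n <- round(decoy_whitelist_frac * n_decoys)
      if (n < 1) character() else sort(sample(decoys$gene_symbol, n))
    } else character()
    whitelist <- toupper(c(wl_targets, wl_decoys))

    all_genes <- toupper(db$gene_symbol)
    sets <- list()
    for (k in seq_len(n_motifs))
      sets[[sprintf("TERM_PLANTED_%d", k)]] <- toupper(target_genes[[k]])
    for (b in seq_len(n_background_terms))
      sets[[sprintf("TERM_BG_%02d", b)]] <-
        sample(all_genes, sample(5:15, 1L))
    truth$planted_target_transcripts <- target_map
    truth$enriched_terms <- sprintf("TERM_PLANTED_%d", seq_len(n_motifs))
    list(db = db, whitelist = whitelist, gmt = list(SYNTH = sets),
         truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Chains the three generators with sub-seeds derived from one master seed
#' and returns every input the pipeline needs plus the planted truth.
#'
#' @param seed master integer seed.
#' @param n_probes,n_suppressive,effect_size,noise_sd see
#'   \code{\link{simulate_expression}}.
#' @param corruption see \code{\link{simulate_probe_sequences}}.
#' @param ... further arguments passed to \code{\link{simulate_mrna_db}}.
#' @return list with \code{expr}, \code{alignment}, \code{db},
#'   \code{whitelist}, \code{gmt}, \code{truth}.
#' @export
simulate_study <- function(seed = 1L, n_probes = 1000L, n_suppressive = 50L,
                           effect_size = 1.25, noise_sd = 0.25, corruption = 0,
                           ...) {
  ex <- simulate_expression(n_probes = n_probes, n_suppressive = n_suppressive,
                            effect_size = effect_size, noise_sd = noise_sd,
                            seed = seed)
  sq <- simulate_probe_sequences(rownames(ex$expr$intensities), ex$truth,
                                 corruption = corruption, seed = seed + 1L)
  db <- simulate_mrna_db(sq$truth, seed = seed + 2L, ...)
  list(expr = ex$expr, alignment = sq$alignment, db = db$db,
       whitelist = db$whitelist, gmt = db$gmt, truth = db$truth)
}
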