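# Independent brute-force oracles, kept deliberately naive and separate from
# the implementation paths they check.

# All maximal intervals of consecutive base symbols, enumerated by walking
# every start/end pair.
oracle_runs <- function(symbols, min_len) {
  is_base <- !is.na(symbols) & symbols %in% c("A", "C", "G", "U", "T")
  n <- length(symbols)
  out <- list()
  for (s in seq_len(n)) {
    for (e in s:n) {
      if (!all(is_base[s:e])) next
      maximal <- (s == 1 || !is_base[s - 1]) && (e == n || !is_base[e + 1])
      if (maximal && e - s + 1 >= min_len)
        out[[length(out) + 1]] <- data.frame(start = s - 1L, end = e)
    }
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  unique(do.call(rbind, out))
}

# Naive Hamming scan: every window, character-by-character comparison.
oracle_scan <- function(motif, transcript, min_identity) {
  motif <- chartr("U", "T", toupper(motif))
  transcript <- chartr("U", "T", toupper(transcript))
  L <- nchar(motif)
  mchars <- strsplit(motif, "")[[1]]
  tchars <- strsplit(transcript, "")[[1]]
  hits <- data.frame(offset = integer(), identity = numeric())
  if (length(tchars) < L) return(hits)
  for (off in 0:(length(tchars) - L)) {
    mm <- sum(tchars[off + seq_len(L)] != mchars)
    id <- (L - mm) / L
    if (id >= min_identity - 1e-12)
      hits <- rbind(hits, data.frame(offset = off, identity = id))
  }
  hits
}

# Hypergeometric upper tail by direct enumeration of point masses from
# log-factorials (never calls phyper/dhyper).
oracle_hyper_tail <- function(LH, LT, PH, PT) {
  lchoose2 <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)
  xs <- LH:min(PH, LT)
  xs <- xs[xs >= max(0, PH + LT - PT)]
  if (!length(xs)) return(0)
  sum(exp(lchoose2(PH, xs) + lchoose2(PT - PH, LT - xs) - lchoose2(PT, LT)))
}

# Small toy expression matrix builder for filter tests: 8 samples, 2 per
# condition, intensities supplied row-wise.
toy_expr <- function(rows, confidence = NULL, biotype = NULL) {
  samples <- paste(rep(c("control", "weak", "moderate", "severe"), each = 2),
                   rep(1:2, 4), sep = "_")
  condition <- stats::setNames(
    rep(c("control", "weak", "moderate", "severe"), each = 2), samples)
  m <- do.call(rbind, rows)
  dimnames(m) <- list(names(rows), samples)
  if (is.null(biotype))
    biotype <- stats::setNames(rep("lncRNA", nrow(m)), rownames(m))
  expression_matrix(m, condition, confidence = confidence, biotype = biotype)
}

random_symbol_list <- function(n) {
  sample(c("A", "C", "G", "U", "+", NA), n, replace = TRUE,
         prob = c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1))
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
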