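aln_of <- function(...) {
  seqs <- c(...)
  names(seqs) <- paste0("seq", seq_along(seqs))
  as_alignment(seqs)
}

test_that("alignment construction validates shape and alphabet", {
  a <- aln_of("ACGU-", "AC-UU", "ACGUA")
  expect_equal(a$length, 5)
  expect_length(a$ids, 3)
  expect_error(aln_of(strrep("A", 60), strrep("A", 59)), "ragged.*59")
  expect_error(aln_of("ACGX"), "illegal")
})

test_that("column consensus applies the modal-base threshold and tie rules", {
  # all-A column -> A at frequency 1
  a <- aln_of("A", "A", "A", "A", "A", "A", "A", "A", "A", "A")
  cc <- column_consensus(a)
  expect_identical(cc$symbol, "A")
  expect_equal(cc$frequency, 1.0)

  # 5 A vs 5 G: a tie at the maximum gives "+", excluded from runs
  a2 <- aln_of("A", "A", "A", "A", "A", "G", "G", "G", "G", "G")
  cc2 <- column_consensus(a2)
  expect_identical(cc2$symbol, "+")

  # unique mode at exactly the 10% threshold is inclusive: one A among gaps
  a3 <- aln_of("A", "-", "-", "-", "-", "-", "-", "-", "-", "-")
  cc3 <- column_consensus(a3)
  expect_identical(cc3$symbol, "A")
  expect_equal(cc3$frequency, 0.1)
  # and just below the threshold there is no consensus
  expect_true(is.na(column_consensus(a3, min_frac = 0.11)$symbol))

  # gaps count in the denominator by default, not with count_gaps = FALSE
  a4 <- aln_of("A", "A", "-", "-", "-", "-", "-", "-", "-", "-")
  expect_equal(column_consensus(a4, min_frac = 0.5)$frequency, 0.2)
  cc4 <- column_consensus(a4, min_frac = 0.5, count_gaps = FALSE)
  expect_identical(cc4$symbol, "A")
  expect_equal(cc4$frequency, 1.0)

  # T and U are pooled
  a5 <- aln_of("T", "U", "T", "U")
  cc5 <- column_consensus(a5)
  expect_identical(cc5$symbol, "U")
  expect_equal(cc5$frequency, 1.0)
})

test_that("run extraction reports maximal qualifying runs in half-open coordinates", {
  symbols_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[ch == "."] <- NA
    ch
  }
  cons <- function(sym) data.frame(symbol = sym, frequency = 1,
                                   stringsAsFactors = FALSE)

  # a 12-column run is reported with its sequence in the RNA alphabet
  r1 <- extract_runs(cons(symbols_of("..UUCUUUCACAUA..")))
  expect_equal(nrow(r1), 1)
  expect_identical(r1$sequence, "UUCUUUCACAUA")
  expect_equal(r1$length, 12)
  expect_equal(r1$start_col, 2)
  expect_equal(r1$end_col, 14)

  # a 9-column run is below the default minimum length
  expect_equal(nrow(extract_runs(cons(symbols_of(".ACGUACGUA.")))), 0)

  # a 25-column run split by one "+" at the 13th column gives two 12-runs
  sym <- symbols_of(strrep("A", 25))
  sym[13] <- "+"
  r3 <- extract_runs(cons(sym))
  expect_equal(r3$length, c(12, 12))
  expect_equal(r3$start_col, c(0, 13))
  expect_equal(r3$end_col, c(12, 25))
})

test_that("identical gapless sequences give one run covering all columns at frequency 1", {
  s <- "ACGUACGUACGUACG"
  a <- as_alignment(stats::setNames(rep(s, 7), paste0("p", 1:7)))
  runs <- find_common_sequences(a, min_frac = 0.10)
  expect_equal(nrow(runs), 1)
  expect_identical(runs$sequence, s)
  expect_equal(runs$start_col, 0)
  expect_equal(runs$end_col, nchar(s))
  expect_true(all(runs$column_frequency[[1]] == 1))
})

test_that("run extraction matches brute-force enumeration and thresholds are monotone", {
  set.seed(19)
  for (i in 1:20) {
    sym <- random_symbol_list(sample(10:100, 1))
    min_len <- sample(c(3, 5, 10), 1)
    got <- extract_runs(data.frame(symbol = sym, frequency = 1), min_len)
    want <- oracle_runs(sym, min_len)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start_col, want$start)
      expect_equal(got$end_col, want$end)
    }
  }

  # raising min_frac never lengthens a run: each high-threshold run is
  # contained in a low-threshold run
  for (i in 1:10) {
    seqs <- vapply(1:8, function(j) random_seq(40, c("A", "C", "G", "U")), "")
    names(seqs) <- paste0("s", 1:8)
    a <- as_alignment(seqs)
    lo <- find_common_sequences(a, min_frac = 0.3, min_run_length = 3)
    hi <- find_common_sequences(a, min_frac = 0.6, min_run_length = 3)
    for (r in seq_len(nrow(hi))) {
      contained <- any(lo$start_col <= hi$start_col[r] &
                       lo$end_col >= hi$end_col[r])
      expect_true(contained)
    }
  }
})

test_that("reverse complement is the biological reverse complement and an involution", {
  expect_identical(reverse_complement("UUCUUUCACAUA"), "UAUGUGAAAGAA")
  expect_identical(reverse_complement("AUCAUCUUUCC"), "GGAAAGAUGAU")
  # DNA input stays DNA; N maps to N
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  expect_error(reverse_complement("ACGB"), "invalid character 'B' at position 4")
  expect_error(reverse_complement("ACUT"), "mixes T and U")

  set.seed(23)
  for (i in 1:25) {
    s <- random_seq(sample(5:40, 1), c("A", "C", "G", "U", "N"))
    expect_identical(reverse_complement(reverse_complement(s)), s)
    # independent oracle: Biostrings reverse complement on the RNA alphabet
    expect_identical(reverse_complement(s),
                     as.character(Biostrings::reverseComplement(
                       Biostrings::RNAString(s))))
  }
})

test_that("alignment io round-trips through both dialects", {
  seqs <- stats::setNames(
    c("ACGU-ACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACG",
      "ACGUAACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACG-ACGUACGUACG",
      "AC-UAACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACG"),
    c("probe_a", "probe_b", "probe_c"))
  a <- as_alignment(seqs)

  fa <- tempfile(fileext = ".fasta")
  write_alignment(a, fa, "aligned-fasta")
  expect_equal(read_alignment(fa, "aligned-fasta"), a)

  # interleaved Clustal blocks concatenate back to the same alignment
  cl <- tempfile(fileext = ".aln")
  write_alignment(a, cl, "clustal")
  b <- read_alignment(cl, "clustal")
  expect_identical(toupper(b$seqs), a$seqs)
  expect_identical(b$ids, a$ids)
})
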