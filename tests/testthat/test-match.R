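toy_db <- function(seqs, genes = NULL, desc = NULL) {
  n <- length(seqs)
  data.frame(transcript_id = sprintf("TX%02d", seq_len(n)),
             gene_symbol = if (is.null(genes)) sprintf("G%02d", seq_len(n)) else genes,
             description = if (is.null(desc)) rep("Mus musculus test mRNA", n) else desc,
             sequence = seqs, stringsAsFactors = FALSE)
}

test_that("exact and near matches are scored by Hamming identity with U/T equivalence", {
  flank <- strrep("C", 30)
  motif <- "GGAAAGAUGAU"                       # 11-mer, RNA alphabet
  exact_dna <- "GGAAAGATGAT"
  one_mm <- "GGAAAGATGAA"                      # 1 mismatch at the end
  db <- toy_db(c(paste0(flank, exact_dna, flank),
                 paste0(flank, one_mm, flank)))
  hits <- scan_database(motif, db, min_identity = 0.85)
  expect_setequal(hits$transcript_id, c("TX01", "TX02"))
  h1 <- hits[hits$transcript_id == "TX01", ]
  expect_equal(h1$offset, 30)
  expect_equal(h1$identity, 1.0)
  expect_identical(h1$matched_span, exact_dna)
  h2 <- hits[hits$transcript_id == "TX02", ]
  expect_equal(h2$identity, 10 / 11, tolerance = 1e-12)

  # a 12-mer with 1 mismatch (11/12 ~ 0.917) is kept at 0.85, with 2
  # mismatches in an 11-mer (9/11 ~ 0.818) it is not
  m12 <- "GGAAAGAUGAUC"
  db12 <- toy_db(paste0(flank, "GGAAAGATGACC", flank))   # 1 mm vs m12
  expect_equal(nrow(scan_database(m12, db12, 0.85)), 1)
  two_mm <- "GGAAAGATGCC"                                 # 2 mm vs motif
  db2 <- toy_db(paste0(flank, two_mm, flank))
  expect_equal(nrow(scan_database(motif, db2, 0.85)), 0)

  # transcripts shorter than the motif are skipped silently
  expect_equal(nrow(scan_database(motif, toy_db("ACGT"), 0.85)), 0)
})

test_that("the scan agrees with a naive Hamming oracle on random inputs", {
  set.seed(31)
  for (i in 1:50) {
    L <- sample(11:15, 1)
    motif <- random_seq(L, c("A", "C", "G", "U"))
    tx <- random_seq(sample(200:400, 1))
    db <- toy_db(tx)
    for (thr in c(0.85, 1.0)) {
      got <- scan_database(motif, db, thr)
      want <- oracle_scan(motif, tx, thr)
      expect_equal(nrow(got), nrow(want))
      if (nrow(want)) {
        expect_equal(sort(got$offset), sort(want$offset))
        expect_equal(got$identity[order(got$offset)],
                     want$identity[order(want$offset)], tolerance = 1e-12)
      }
    }
  }
})

test_that("identity threshold 1.0 reproduces exact substring search", {
  set.seed(37)
  motif <- "AUGGCAUGGCAU"
  motif_dna <- chartr("U", "T", motif)
  for (i in 1:10) {
    tx <- paste0(random_seq(100), motif_dna, random_seq(50), motif_dna,
                 random_seq(30))
    got <- scan_database(motif, toy_db(tx), min_identity = 1.0)
    naive <- as.integer(gregexpr(motif_dna, tx, fixed = TRUE)[[1]]) - 1L
    expect_equal(sort(got$offset), sort(naive))
    expect_true(all(got$identity == 1))
  }
})

test_that("header exclusion is case-sensitive substring matching", {
  hits <- data.frame(
    transcript_id = c("a", "b", "c", "d"),
    gene_symbol = c("GFAP", "AQP4", "VIM", "S100B"),
    description = c("PREDICTED: Mus musculus some model",
                    "Mus musculus Gfap mRNA",
                    "Mus musculus cDNA clone",
                    "Mus musculus predicted-like mRNA"),   # lower case survives
    offset = 0L, identity = 1, matched_span = "A", is_best = TRUE,
    stringsAsFactors = FALSE)
  out <- filter_headers(hits)
  expect_setequal(out$transcript_id, c("b", "d"))
  expect_identical(filter_headers(hits, character()), hits)
})

test_that("whitelist filter is case-insensitive and warns when empty", {
  hits <- data.frame(gene_symbol = c("Gfap", "AQP4", "Vim"),
                     transcript_id = c("a", "b", "c"),
                     description = "x", stringsAsFactors = FALSE)
  out <- filter_whitelist(hits, c("gfap", "VIM"))
  expect_setequal(out$gene_symbol, c("Gfap", "Vim"))
  expect_warning(none <- filter_whitelist(hits, character()), "empty whitelist")
  expect_equal(nrow(none), 0)
})

test_that("header and whitelist filters commute on random hit sets", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:30, 1)
    hits <- data.frame(
      transcript_id = sprintf("t%02d", seq_len(n)),
      gene_symbol = sample(sprintf("G%02d", 1:15), n, replace = TRUE),
      description = sample(c("Mus musculus mRNA", "PREDICTED: model",
                             "Mus musculus cDNA clone"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    wl <- sample(sprintf("G%02d", 1:15), 8)
    a <- filter_whitelist(filter_headers(hits), wl)
    b <- filter_headers(filter_whitelist(hits, wl))
    expect_identical(a[order(a$transcript_id), ], b[order(b$transcript_id), ])
  }
})

test_that("match summaries count genes with the de-duplicated total", {
  h <- function(genes) data.frame(
    transcript_id = sprintf("t_%s_%d", genes, seq_along(genes)),
    gene_symbol = genes, description = rep("d", length(genes)),
    stringsAsFactors = FALSE)
  raw <- list(h(c("A", "B")), h(c("B", "C")))
  s <- summarize_matches(raw, raw, raw)
  expect_equal(s["Total", "n_genes"], 3)                # A, B, C de-duplicated
  expect_equal(attr(s, "totals_with_duplicates")[["n_genes"]], 4)
  # no hits at all: zeros
  s0 <- summarize_matches(list(h(character())), list(h(character())),
                          list(h(character())))
  expect_true(all(s0[, -1] == 0))
})

test_that("planted targets are recovered with whitelist set arithmetic", {
  ex <- simulate_expression(n_probes = 50, n_suppressive = 5, seed = 8)
  sq <- simulate_probe_sequences(rownames(ex$expr$intensities), ex$truth,
                                 seed = 9)
  gen <- simulate_mrna_db(sq$truth, n_decoys = 100, whitelist_coverage = 0.6,
                          seed = 10)
  runs <- data.frame(
    sequence = gen$truth$planted_motifs$sequence,
    complement = reverse_complement(gen$truth$planted_motifs$sequence),
    stringsAsFactors = FALSE)
  mm <- match_complements(runs, gen$db, whitelist = gen$whitelist)
  for (k in seq_len(nrow(runs))) {
    planted_tx <- gen$truth$planted_target_transcripts[[k]]
    # every planted target transcript is found by the raw scan
    expect_true(all(planted_tx %in% mm$hits_raw[[k]]$transcript_id))
    # after whitelisting, surviving target genes = planted genes on the list
    planted_genes <- toupper(gen$db$gene_symbol[gen$db$transcript_id %in% planted_tx])
    expect_setequal(intersect(mm$genes[[k]], planted_genes),
                    intersect(planted_genes, gen$whitelist))
  }
})
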