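test_that("read_fasta normalizes, splits headers, and enforces the alphabet", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">y some description", "acgu"), f)
  recs <- read_fasta(f)
  expect_equal(recs[[1]]$sequence, "ACGU")
  expect_equal(nchar(recs[[1]]$sequence), 4L)
  expect_equal(recs[[2]]$transcript_id, "y")
  expect_equal(recs[[2]]$sequence, "ACGU")

  writeLines(c(">z", "ACGX"), f)
  expect_error(read_fasta(f, "strict"), "position 4")
  masked <- read_fasta(f, "mask_n")
  expect_equal(masked[[1]]$sequence, "ACGN")

  writeLines(c("no header line", "ACGU"), f)
  expect_error(read_fasta(f), "parse error")
})

test_that("write_fasta / read_fasta round-trips normalized records", {
  recs <- list(utr_record("t1", "ACGUACGU", gene_id = "g1", species = "human"),
               utr_record("t2", "UUUUNAAA", alphabet_policy = "mask_n"))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, f)
  back <- read_fasta(f, "mask_n")
  expect_equal(lapply(back, `[[`, "sequence"), lapply(recs, `[[`, "sequence"))
  expect_equal(back[[1]]$gene_id, "g1")
})

test_that("tile_windows follows the 100/50 scheme with an end-anchored tail", {
  mk <- function(n) utr_record("u", strrep("A", n))
  w1 <- tile_windows(mk(100), 100, 50)
  expect_equal(nrow(w1), 1L)
  expect_equal(c(w1$start, w1$end), c(0L, 100L))

  w2 <- tile_windows(mk(150), 100, 50)
  expect_equal(w2$start, c(0L, 50L))
  expect_equal(w2$end, c(100L, 150L))

  w3 <- tile_windows(mk(1131), 100, 50)
  expect_equal(nrow(w3), 22L)
  expect_equal(w3$start[21], 1000L)
  expect_equal(c(w3$start[22], w3$end[22]), c(1031L, 1131L))

  # short UTR: single full-length window
  w4 <- tile_windows(mk(60), 100, 50)
  expect_equal(c(w4$start, w4$end), c(0L, 60L))
})

test_that("window tiling covers every position with unique starts", {
  set.seed(11)
  for (n in sample(30:1500, 25)) {
    w <- tile_windows(utr_record("u", strrep("C", n)), 100, 50)
    covered <- rep(FALSE, n)
    for (r in seq_len(nrow(w))) covered[(w$start[r] + 1):w$end[r]] <- TRUE
    expect_true(all(covered))
    expect_false(anyDuplicated(w$start) > 0)
    expect_equal(w$sequence,
                 substring(strrep("C", n), w$start + 1, w$end))
  }
})

test_that("MAF round-trip preserves blocks; invariants are enforced", {
  blocks <- list(data.frame(
    src = c("human.tx1", "mouse.tx1"),
    species = c("human", "mouse"), chrom = "tx1",
    start = c(0L, 5L), size = c(8L, 8L), strand = "+",
    src_size = c(8L, 20L),
    text = c("ACGUACGU", "ACGUACGU"), stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(blocks, f)
  back <- read_maf(f, reference = "human")
  expect_equal(length(back), 1L)
  expect_equal(back[[1]]$text, blocks[[1]]$text)
  expect_equal(back[[1]]$start, blocks[[1]]$start)

  writeLines(c("a", "s human.tx1 0 4 + 4 ACGU", "s mouse.tx1 0 3 + 3 ACG"), f)
  expect_error(read_maf(f, "human"), "unequal gapped length")

  writeLines(c("a", "s mouse.tx1 0 4 + 4 ACGU"), f)
  expect_warning(out <- read_maf(f, "human"), "skipped")
  expect_length(out, 0L)

  writeLines(c("a", "s human.tx1 zero 4 + 4 ACGU"), f)
  expect_error(read_maf(f, "human"), "malformed")
})

test_that("synthetic MAF written by the generator re-reads identically", {
  sim <- gen_ortholog_alignment(gen_background(120, seed = 5),
                                background_rate = 0.2, parent_id = "tx9",
                                seed = 6)
  f <- withr::local_tempfile(fileext = ".maf")
  write_maf(list(sim$block), f)
  back <- read_maf(f, "human")
  expect_equal(back[[1]]$text, sim$block$text)
  expect_equal(gsub("-", "", back[[1]]$text), gsub("-", "", sim$block$text))
})

test_that("slice_alignment reproduces the motif footprint on the reference", {
  seq <- "GGGAGCUGCUAUGCAGCUCCC"
  motif <- scan_motifs(seq, motif_descriptor("CDE"), parent_id = "tx1")[[1]]
  block <- data.frame(
    src = c("human.tx1", "mouse.tx1"), species = c("human", "mouse"),
    chrom = "tx1", start = 0L, size = nchar(seq), strand = "+",
    src_size = nchar(seq), text = seq, stringsAsFactors = FALSE)
  sl <- slice_alignment(list(block), motif, flank = 0L)
  expect_equal(gsub("-", "", sl$rows[["human"]]), motif_sequence(motif))

  # motif spanning two adjacent blocks equals slicing one concatenated block
  b1 <- block; b1$size <- 10L; b1$text <- substr(seq, 1, 10)
  b2 <- block; b2$start <- 10L; b2$size <- nchar(seq) - 10L
  b2$text <- substr(seq, 11, nchar(seq))
  sl2 <- slice_alignment(list(b1, b2), motif, flank = 2L)
  sl1 <- slice_alignment(list(block), motif, flank = 2L)
  expect_equal(sl2$rows, sl1$rows)

  # footprint outside all blocks -> coverage error
  b3 <- block; b3$start <- 100L
  expect_error(slice_alignment(list(b3), motif), "coverage error")
})

test_that("slice reference ungapping equals the scanner motif on synthetic data", {
  ds <- gen_dataset(n_genes = 12, n_cde = 5, n_ade = 2, utr_length = 300,
                    seed = 99)
  desc <- list(CDE = motif_descriptor("CDE"), ADE = motif_descriptor("ADE"))
  for (i in seq_len(nrow(ds$truth_motifs))) {
    tr <- ds$truth_motifs[i, ]
    rec <- ds$records[[which(vapply(ds$records, `[[`, character(1),
                                    "transcript_id") == tr$parent_id)]]
    motifs <- scan_motifs(rec$sequence, desc[[tr$motif_class]],
                          parent_id = tr$parent_id)
    m <- Filter(function(x) x$five_start == tr$five_start, motifs)[[1]]
    sl <- slice_alignment(ds$blocks, m)
    fp <- slice_footprint(sl, m)
    expect_equal(gsub("-", "", fp$rows[["human"]]), motif_sequence(m))
  }
})

test_that("window score table reader validates columns and range", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(transcript_id = "t", start = 0L, end = 100L, score = 0.95)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_window_scores(f)$score, 0.95)
  df$score <- 1.4
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_window_scores(f), "\\[0,1\\]")
})

test_that("BED6 output is half-open with a 1000*p_fold score", {
  motif <- scan_motifs("AGCUGCUAUGCAGCU", motif_descriptor("CDE"), "tx7")[[1]]
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed6(list(motif), p_fold = 0.55, path = f)
  bed <- read.delim(f, header = FALSE)
  expect_equal(bed$V2, 0L)
  expect_equal(bed$V3, 15L)
  expect_equal(bed$V5, 550L)
  expect_equal(bed$V6, "+")
})
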