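test_that("constructed CDE/ADE examples scan as specified", {
  cde <- motif_descriptor("CDE")

  m <- scan_motifs("AGCUGCUAUGCAGCU", cde)
  expect_length(m, 1L)
  expect_equal(m[[1]]$five_start, 0L)
  expect_equal(m[[1]]$stem_len, 6L)
  expect_equal(m[[1]]$loop_seq, "UAU")

  expect_length(scan_motifs("AGCUGCAAUGCAGCU", cde), 0L)  # AAU fails YRN

  # apical U.G wobble: excluded unless allow_wobble
  expect_length(scan_motifs("AGCUGUUAUGCAGCU", cde), 0L)
  expect_length(scan_motifs("AGCUGUUAUGCAGCU",
                            motif_descriptor("CDE", allow_wobble = TRUE)), 1L)

  # maximality: nested 6-bp version suppressed in favor of the 7-bp stem
  m7 <- scan_motifs("UAGCUGCUAUGCAGCUA", cde)
  expect_length(m7, 1L)
  expect_equal(m7[[1]]$stem_len, 7L)
  expect_equal(loop_closing_pair(m7[[1]]), c(five = "C", three = "G"))

  ade <- scan_motifs("AGCUGCGUUCUAGCAGCU", motif_descriptor("ADE"))
  expect_length(ade, 1L)
  expect_equal(ade[[1]]$stem_len, 6L)
  expect_equal(ade[[1]]$loop_seq, "GUUCUA")
})

test_that("a stem extendable beyond stem_max is capped, or rejected on demand", {
  # 9 pairable positions around the loop; consensus caps the stem at 8
  hp <- paste0("GGAGCUGCU", "UAU", "AGCAGCUCC")
  m <- scan_motifs(hp, motif_descriptor("CDE"))
  expect_equal(vapply(m, `[[`, integer(1), "stem_len"), 8L)
  expect_length(scan_motifs(hp, motif_descriptor("CDE", reject_extendable = TRUE)),
                0L)
})

test_that("N never pairs and never matches a consensus letter", {
  expect_length(scan_motifs("AGCUGCNAUGCAGCU", motif_descriptor("CDE")), 0L)
  expect_length(scan_motifs("NGCUGCUAUGCAGCN", motif_descriptor("CDE")), 0L)
  m <- scan_motifs("ANCUGCUAUGCAGNU", motif_descriptor("CDE"))
  expect_length(m, 0L)  # N inside the stem blocks the 6-bp requirement
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(20181)
  descs <- list(motif_descriptor("CDE"),
                motif_descriptor("CDE", allow_wobble = TRUE),
                motif_descriptor("ADE"),
                motif_descriptor("CDE", reject_extendable = TRUE))
  for (i in 1:150) {
    s <- random_rna(sample(25:80, 1))
    d <- descs[[(i %% length(descs)) + 1]]
    got <- scan_as_df(scan_motifs(s, d))
    want <- brute_force_scan(s, d)
    expect_equal(got, want, info = s)
  }
})

test_that("no scanned motif violates the hairpin invariants", {
  set.seed(77)
  n_motifs <- 0
  for (i in 1:60) {
    s <- random_rna(120)
    if (i %% 2 == 0) {  # guarantee motif-bearing inputs as well
      cls <- if (i %% 4 == 0) "ADE" else "CDE"
      s <- plant_motif(s, plant_spec(cls, stem_len = sample(6:8, 1)))$sequence
    }
    for (d in list(motif_descriptor("CDE"), motif_descriptor("ADE"))) {
      for (m in scan_motifs(s, d)) {
        n_motifs <- n_motifs + 1
        expect_equal(m$three_end - m$five_start,
                     2L * m$stem_len + nchar(m$loop_seq))
        expect_equal(motif_sequence(m),
                     substr(s, m$five_start + 1, m$three_end))
        a5 <- strsplit(m$arm5, "")[[1]]
        a3 <- strsplit(m$arm3, "")[[1]]
        for (k in seq_len(m$stem_len)) {
          expect_true(can_pair(a5[k], a3[m$stem_len + 1 - k],
                               allow_wobble = d$allow_wobble))
        }
        expect_true(matches_iupac(m$loop_seq, d$loop_consensus))
        cp <- loop_closing_pair(m)
        expect_true(can_pair(cp[["five"]], cp[["three"]],
                             allow_wobble = d$allow_wobble))
      }
    }
  }
  expect_gt(n_motifs, 20)
})

test_that("palindromic constructs scan identically in reverse", {
  # footprint is its own reverse; the match count must not change
  pal <- "AGCUGCUAUAGCAGCU"  # arm5 AGCUGC, loop UAU? build explicitly instead:
  hp <- paste0("AGCUGC", "UAU", "GCAGCU")
  rev_s <- paste(rev(strsplit(hp, "")[[1]]), collapse = "")
  d <- motif_descriptor("CDE")
  expect_length(scan_motifs(hp, d), length(scan_motifs(rev_s, d)))
})

test_that("planted motifs are recovered at their exact footprint", {
  set.seed(303)
  for (i in 1:40) {
    cls <- if (i %% 4 == 0) "ADE" else "CDE"
    spec <- plant_spec(cls, stem_len = sample(6:8, 1),
                       purine_stack = i %% 3 == 0)
    res <- plant_motif(gen_background(200), spec)
    found <- scan_motifs(res$sequence, motif_descriptor(cls), "bg")
    hit <- Filter(function(m) m$five_start == res$motif$five_start &&
                    m$three_end == res$motif$three_end, found)
    expect_length(hit, 1L)
  }
})

test_that("closing pair polarity follows the 5' base", {
  m_cg <- scan_motifs("AGCUGCUAUGCAGCU", motif_descriptor("CDE"))[[1]]
  expect_equal(closing_pair_polarity(m_cg), "Y-R")  # C is a pyrimidine
  hp <- paste0("GCGCGA", "UAU", "UUCGCGC")  # closing pair A-U
  m_au <- scan_motifs(substr(hp, 1, 15), motif_descriptor("CDE"))
  hp2 <- paste0("GCGCGA", "UAU", "UCGCGC")
  m_au <- scan_motifs(hp2, motif_descriptor("CDE"))[[1]]
  expect_equal(loop_closing_pair(m_au), c(five = "A", three = "U"))
  expect_equal(closing_pair_polarity(m_au), "R-Y")
})
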