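# The human reference motif used throughout: AGCUGC UAU GCAGCU
# (stem pairs outermost->apical: A-U, G-C, C-G, U-A, G-C, C-G; loop UAU).

ref_motif <- function() scan_motifs("AGCUGCUAUGCAGCU",
                                    motif_descriptor("CDE"), "tx")[[1]]

test_that("single-species verdicts cover the published change categories", {
  m <- ref_motif()
  d <- motif_descriptor("CDE")
  hseq <- motif_sequence(m)

  expect_equal(classify_species(m, hseq, d)$status, "identical")

  # compensatory change: outermost pair A-U -> G-C (positions 1 and 15)
  sp <- hseq
  substr(sp, 1, 1) <- "G"; substr(sp, 15, 15) <- "C"
  v <- classify_species(m, sp, d)
  expect_equal(v$status, "tolerated")
  expect_equal(v$changes, "compensatory_pair")

  # loop UAU -> CAU still matches YRN
  sp <- hseq; substr(sp, 7, 7) <- "C"
  v <- classify_species(m, sp, d)
  expect_equal(v$status, "tolerated")
  expect_equal(v$changes, "loop_motif_preserving")

  # single-arm change creating a wobble: apical pair C-G -> U-G (position 6)
  sp <- hseq; substr(sp, 6, 6) <- "U"
  v <- classify_species(m, sp, d)
  expect_equal(v$status, "tolerated")
  expect_equal(v$changes, "wobble_pair")

  # loop UAU -> AAU violates (A is not a pyrimidine)
  sp <- hseq; substr(sp, 7, 7) <- "A"
  expect_equal(classify_species(m, sp, d)$status, "violated")

  # breaking an apical-core pair violates
  sp <- hseq; substr(sp, 6, 6) <- "A"  # apical C-G -> A-G
  expect_equal(classify_species(m, sp, d)$status, "violated")

  # all-gap row is absent
  expect_equal(classify_species(m, strrep("-", 15), d)$status, "absent")

  # gaps inside the loop violate
  sp <- hseq; substr(sp, 8, 8) <- "-"
  expect_equal(classify_species(m, sp, d)$status, "violated")
})

test_that("a 7-bp stem may lose its outermost pair (rule: only 6 bp conserved)", {
  s <- "UAGCUGCUAUGCAGCUA"
  m <- scan_motifs(s, motif_descriptor("CDE"))[[1]]
  expect_equal(m$stem_len, 7L)
  d <- motif_descriptor("CDE")
  sp <- motif_sequence(m)
  substr(sp, 1, 1) <- "C"  # outermost U-A -> C-A: lost, but 6 apical remain
  v <- classify_species(m, sp, d)
  expect_equal(v$status, "tolerated")
  expect_equal(v$changes, "stem_length_change")

  # under a 6-bp stem the same loss hits the required core
  m6 <- ref_motif()
  sp6 <- motif_sequence(m6)
  substr(sp6, 1, 1) <- "C"
  expect_equal(classify_species(m6, sp6, d)$status, "violated")
})

test_that("classify_motif aggregates species with the required-species policy", {
  m <- ref_motif()
  d <- motif_descriptor("CDE")
  sl <- identity_slice(m)
  expect_true(classify_motif(m, sl, d)$conserved)

  # one violated species breaks conservation
  sl2 <- mutate_row(sl, "mouse", 7, "A")
  expect_false(classify_motif(m, sl2, d)$conserved)

  # absent species: strict vs ignore_absent
  sl3 <- sl
  sl3$rows <- sl3$rows[names(sl3$rows) != "cow"]
  expect_false(classify_motif(m, sl3, d, policy = "strict")$conserved)
  expect_true(classify_motif(m, sl3, d, policy = "ignore_absent")$conserved)
  expect_equal(classify_motif(m, sl3, d)$per_species$cow$status, "absent")
})

test_that("verdicts are deterministic and monotone under reversion", {
  set.seed(88)
  d <- motif_descriptor("CDE")
  m <- ref_motif()
  hseq <- motif_sequence(m)
  for (i in 1:40) {
    sp <- strsplit(hseq, "")[[1]]
    nmut <- sample(1:4, 1)
    pos <- sample(15, nmut)
    sp[pos] <- sample(c("A", "C", "G", "U"), nmut, replace = TRUE)
    sps <- paste(sp, collapse = "")
    v1 <- classify_species(m, sps, d)
    v2 <- classify_species(m, sps, d)
    expect_identical(v1, v2)
    # reverting one changed position toward human never turns tolerated
    # into violated
    if (v1$status == "tolerated") {
      for (p in pos) {
        sp2 <- sp; sp2[p] <- substr(hseq, p, p)
        v3 <- classify_species(m, paste(sp2, collapse = ""), d)
        expect_true(v3$status %in% c("identical", "tolerated"))
      }
    }
  }
})

test_that("the classifier recovers generator truth labels exactly", {
  set.seed(3141)
  desc <- list(CDE = motif_descriptor("CDE"), ADE = motif_descriptor("ADE"))
  n_checked <- 0
  for (rep in 1:40) {
    cls <- if (rep %% 5 == 0) "ADE" else "CDE"
    spec <- plant_spec(cls, stem_len = sample(6:8, 1),
                       intended_conserved = rep %% 2 == 0)
    res <- plant_motif(gen_background(120), spec)
    sim <- gen_ortholog_alignment(res$sequence, list(res$motif),
                                  spec$intended_conserved,
                                  background_rate = 0.1, parent_id = "plant")
    sl <- slice_alignment(list(sim$block), res$motif)
    call <- classify_motif(res$motif, sl, desc[[cls]])
    expect_equal(call$conserved, spec$intended_conserved,
                 info = paste(rep, motif_sequence(res$motif)))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 40)
})

test_that("the ADE engine only differs in the loop consensus", {
  s <- "AGCUGCGUUCUAGCAGCU"
  m <- scan_motifs(s, motif_descriptor("ADE"))[[1]]
  d <- motif_descriptor("ADE")
  hseq <- motif_sequence(m)
  # GUUCUA -> GUUUUA stays within GUUYUA
  sp <- hseq; substr(sp, 10, 10) <- "U"
  v <- classify_species(m, sp, d)
  expect_equal(v$status, "tolerated")
  expect_equal(v$changes, "loop_motif_preserving")
  # GUUCUA -> AUUCUA violates
  sp2 <- hseq; substr(sp2, 7, 7) <- "A"
  expect_equal(classify_species(m, sp2, d)$status, "violated")
  # stem rules are shared: compensatory still tolerated
  sp3 <- hseq; substr(sp3, 1, 1) <- "G"; substr(sp3, 18, 18) <- "C"
  expect_equal(classify_species(m, sp3, d)$status, "tolerated")
})
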