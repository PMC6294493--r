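# The dynamic programs are validated against two independent routes: the
# exhaustive enumerator (with the R loop-decomposition energy evaluator)
# and closed forms read off the parameter table.

test_that("trivial sequences have Z = 1 and no pairs", {
  m <- energy_model()
  r <- partition_function("AAAA", m)
  expect_equal(r$Z, 1)
  expect_true(all(r$pair_prob == 0))
  expect_equal(r$mfe_structure, "....")
  expect_equal(r$mfe_energy, 0)

  # ACGU: the only complementary pair would close a 2-nt loop
  r2 <- partition_function("ACGU", m)
  expect_equal(r2$Z, 1)
  expect_true(all(r2$pair_prob == 0))
})

test_that("GAAAC follows the two-state closed form from the parameter table", {
  m <- energy_model("turner2004")
  dg <- m$hairpin[3]  # G-C closing pair: no terminal AU penalty
  w <- exp(-dg / m$RT)
  r <- partition_function("GAAAC", m)
  expect_equal(r$Z, 1 + w, tolerance = 1e-12)
  expect_equal(r$pair_prob[1, 5], w / (1 + w), tolerance = 1e-12)

  motif <- list(motif_id = "hp", five_start = 0L, three_end = 5L, stem_len = 1L)
  p <- motif_fold_probability("GAAAC", motif, m)
  expect_equal(p$p_fold, w / (1 + w), tolerance = 1e-12)

  # with an A-U closing pair the terminal penalty appears at both loops the
  # lone helix borders (hairpin side and exterior side)
  dg_au <- m$hairpin[3] + 2 * m$terminal_au
  w_au <- exp(-dg_au / m$RT)
  r_au <- partition_function("AAAAU", m)
  expect_equal(r_au$Z, 1 + w_au, tolerance = 1e-12)
})

test_that("enumeration is complete: counts match the independent counter", {
  mu <- energy_model("uniform-test")
  set.seed(5)
  for (s in c("AAAA", "GAAAC", "AGCUGCUAUGCAGCU",
              replicate(10, random_rna(sample(6:14, 1))))) {
    en <- enumerate_structures(s, mu)
    expect_equal(nrow(en), count_structures(s, mu), info = s)
    expect_false(anyDuplicated(en$structure) > 0)
  }
  expect_equal(nrow(enumerate_structures("AAAA", mu)), 1L)
  expect_equal(nrow(enumerate_structures("GAAAC", mu)), 2L)
  expect_error(enumerate_structures(random_rna(30), mu), "cap")
})

test_that("Z, pair probabilities and MFE agree with enumeration", {
  set.seed(101)
  for (ps in c("uniform-test", "turner2004")) {
    m <- energy_model(ps)
    for (i in 1:25) {
      s <- random_rna(sample(6:15, 1))
      en <- enumerate_structures(s, m)
      Zo <- sum(en$weight)
      r <- partition_function(s, m)
      expect_equal(r$Z, Zo, tolerance = 1e-9)
      pp <- enum_pair_probs(nchar(s), en)
      expect_lt(max(abs(r$pair_prob - pp)), 1e-9)
      expect_lte(r$mfe_energy, min(en$energy) + 1e-9)
      expect_equal(structure_energy(s, r$mfe_structure, m), r$mfe_energy,
                   tolerance = 1e-6)
      # row sums of the pair matrix are occupancy probabilities
      expect_true(all(rowSums(r$pair_prob) <= 1 + 1e-9))
    }
  }
})

test_that("motif p_fold equals the enumeration ratio and obeys bounds", {
  set.seed(202)
  for (ps in c("uniform-test", "turner2004")) {
    m <- energy_model(ps)
    tested <- 0
    while (tested < 12) {
      s <- random_rna(sample(13:18, 1))
      motifs <- scan_motifs(s, motif_descriptor("CDE", stem_min = 2,
                                                stem_max = 5))
      if (!length(motifs)) next
      en <- enumerate_structures(s, m)
      r <- partition_function(s, m)
      for (mo in motifs) {
        p <- motif_fold_probability(s, mo, m)$p_fold
        expect_equal(p, enum_pfold(en, mo), tolerance = 1e-9)
        # the motif event is a sub-event of the apical pair forming
        ai <- mo$five_start + mo$stem_len
        bi <- mo$three_end - mo$stem_len + 1
        expect_lte(p, r$pair_prob[ai, bi] + 1e-9)
        tested <- tested + 1
      }
    }
  }
})

test_that("uniform-test p_fold is rational with the structure count as denominator", {
  mu <- energy_model("uniform-test")
  s <- "AGCUGCUAUGCAGCU"
  motif <- scan_motifs(s, motif_descriptor("CDE"))[[1]]
  p <- motif_fold_probability(s, motif, mu)$p_fold
  n_total <- count_structures(s, mu)
  expect_equal(round(p * n_total), p * n_total, tolerance = 1e-9)
  # and matches the enumeration ratio exactly
  en <- enumerate_structures(s, mu)
  expect_equal(p, enum_pfold(en, motif), tolerance = 1e-12)
})

test_that("p_fold is 0 for stems illegal under the model and dilutes in context", {
  m <- energy_model()
  # C-C cannot pair under any rule
  motif <- list(motif_id = "bad", five_start = 0L, three_end = 11L,
                stem_len = 4L)
  expect_equal(motif_fold_probability("CAGCUAUGCUC", motif, m)$p_fold, 0)

  # context whose added bases cannot pair with anything leaves p_fold
  # exactly unchanged (an enclosing helix, by contrast, may legitimately
  # *stabilize* the motif, so a blanket monotone-dilution bound does not
  # hold under a stacking energy model)
  hp <- "GCGCGCCGCGCGCGC"  # G/C-only CDE: poly-A flanks are inert
  motif2 <- scan_motifs(hp, motif_descriptor("CDE"))[[1]]
  expect_equal(motif2$stem_len, 6L)
  p_bare <- motif_fold_probability(hp, motif2, m)$p_fold
  ctx <- paste0(strrep("A", 15), hp, strrep("A", 15))
  shifted <- motif2
  shifted$five_start <- motif2$five_start + 15L
  shifted$three_end <- motif2$three_end + 15L
  p_inert <- motif_fold_probability(ctx, shifted, m)$p_fold
  expect_equal(p_inert, p_bare, tolerance = 1e-9)
})

test_that("batch and single-motif p_fold agree; windowing is honored", {
  m <- energy_model()
  set.seed(31)
  s <- gen_background(260)
  spec <- plant_spec("CDE", stem_len = 6)
  res <- plant_motif(s, spec)
  motifs <- scan_motifs(res$sequence, motif_descriptor("CDE"))
  batch <- motif_fold_probabilities(res$sequence, motifs, m)
  singles <- vapply(motifs, function(mo)
    motif_fold_probability(res$sequence, mo, m)$p_fold, numeric(1))
  expect_equal(batch, singles, tolerance = 1e-12)

  long_ctx <- paste0(strrep("A", 1200), res$sequence, strrep("A", 1200))
  mo <- motifs[[1]]
  mo$five_start <- mo$five_start + 1200L
  mo$three_end <- mo$three_end + 1200L
  p <- motif_fold_probability(long_ctx, mo, m, max_context = 1500,
                              window_size = 1000)
  expect_equal(p$context_end - p$context_start, 1000L)
  expect_gte(p$p_fold, 0)
  expect_error(motif_fold_probability(res$sequence,
                                      list(motif_id = "x", five_start = 0L,
                                           three_end = 10000L, stem_len = 6L),
                                      m),
               "bounds|footprint")
})

test_that("MFE traceback is deterministic and self-consistent", {
  m <- energy_model()
  set.seed(404)
  for (i in 1:20) {
    s <- random_rna(sample(20:60, 1))
    a <- mfe_structure(s, m)
    b <- mfe_structure(s, m)
    expect_identical(a, b)
    expect_equal(structure_energy(s, a$structure, m), a$energy,
                 tolerance = 1e-6)
    expect_lte(a$energy, 0)
  }
})

test_that("N positions are unpairable but tolerated", {
  m <- energy_model()
  r <- partition_function("GANNNAAAC", m)
  expect_gte(r$Z, 1)
  hp <- "AGCUGCUAUGCAGCU"
  masked <- sub("^A", "N", hp)
  rn <- partition_function(masked, m)
  expect_true(all(rn$pair_prob[1, ] == 0))
})
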