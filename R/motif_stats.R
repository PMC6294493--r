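# Composition and enrichment statistics over scanned motifs: per-position
# loop composition, Pearson's chi-square, the loop-position-2 x closing-pair
# polarity co-occurrence, AU-rich stems, 3' purine stacks, and the
# conserved-vs-non-conserved folding probability comparison.

#' Per-position nucleotide composition of motif loops
#'
#' @param motifs list of `hairpin_motif` (all sharing one loop length).
#' @param conserved logical vector, one flag per motif.
#' @return list with `all` and `conserved`: 4 x L count matrices (rows
#'   A/C/G/U, columns 1-based loop positions, 5' to 3').
#' @export
loop_composition <- function(motifs, conserved = rep(FALSE, length(motifs))) {
  stopifnot(length(conserved) == length(motifs))
  loops <- vapply(motifs, `[[`, character(1), "loop_seq")
  L <- unique(nchar(loops))
  if (length(L) > 1L) stop("motifs have mixed loop lengths", call. = FALSE)
  if (!length(motifs)) stop("no motifs supplied", call. = FALSE)
  count <- function(lp) {
    m <- matrix(0L, 4L, L, dimnames = list(RNA_BASES, seq_len(L)))
    for (s in lp) {
      cc <- seq_chars(s)
      for (k in seq_len(L)) {
        if (cc[k] %in% RNA_BASES) m[cc[k], k] <- m[cc[k], k] + 1L
      }
    }
    m
  }
  list(all = count(loops), conserved = count(loops[conserved]))
}

#' Pearson's chi-square test of independence
#'
#' Classic form, `X^2 = sum (O - E)^2 / E` with expectations from the
#' row/column margins and no continuity correction; p-value from the
#' chi-square distribution with `(r-1)(c-1)` degrees of freedom.  Tables
#' with any expected count below 5 trigger a warning suggesting the
#' permutation oracle.
#'
#' @param counts non-negative integer matrix, at least 2 x 2.
#' @return list of class `chi_square_result`: `statistic`, `df`, `p_value`,
#'   `expected`, `observed`.
#' @export
pearson_chi_square <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) >= 2L, ncol(counts) >= 2L, all(counts >= 0))
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  if (any(rs == 0) || any(cs == 0)) {
    stop("degenerate table: a row or column margin is zero", call. = FALSE)
  }
  expected <- outer(rs, cs) / n
  if (any(expected < 5)) {
    warning("expected counts below 5; consider a permutation test",
            call. = FALSE)
  }
  stat <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 expected = expected, observed = counts),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Co-occurrence of the loop position-2 purine with closing-pair polarity
#'
#' Builds the 2 x 2 table of A/G at triloop position 2 against Y-R vs R-Y
#' closing-pair polarity, restricted to conserved CDE motifs, and tests
#' independence with Pearson's chi-square.
#'
#' @param motifs list of CDE `hairpin_motif` (triloops).
#' @param conserved logical vector, one flag per motif.
#' @return list with `table` (2 x 2 counts) and `test`
#'   (a `chi_square_result`, or NULL if the table is degenerate).
#' @export
closing_pair_cooccurrence <- function(motifs, conserved) {
  stopifnot(length(conserved) == length(motifs))
  keep <- which(conserved)
  tab <- matrix(0L, 2L, 2L, dimnames = list(c("A", "G"), c("Y-R", "R-Y")))
  for (i in keep) {
    m <- motifs[[i]]
    if (nchar(m$loop_seq) != 3L) stop("co-occurrence expects triloop motifs",
                                      call. = FALSE)
    p2 <- substr(m$loop_seq, 2L, 2L)
    if (!p2 %in% c("A", "G")) next
    tab[p2, closing_pair_polarity(m)] <- tab[p2, closing_pair_polarity(m)] + 1L
  }
  test <- tryCatch(suppressWarnings(pearson_chi_square(tab)),
                   error = function(e) NULL)
  list(table = tab, test = test)
}

#' AU content of a motif stem
#'
#' @param motif a `hairpin_motif`.
#' @return list with `fraction` (share of stem pairs made of A and U) and
#'   `au_rich` (strictly greater than 0.5).
#' @export
stem_au_fraction <- function(motif) {
  a5 <- seq_chars(motif$arm5)
  a3 <- rev(seq_chars(motif$arm3))
  au <- sum(a5 %in% c("A", "U") & a3 %in% c("A", "U"))
  frac <- au / motif$stem_len
  list(fraction = frac, au_rich = frac > 0.5)
}

#' Purine stack on the 3' stem arm
#'
#' @param motif a `hairpin_motif`.
#' @return `TRUE` iff the 3' arm carries at least three consecutive purines.
#' @export
purine_stack_3p <- function(motif) {
  grepl("[AG]{3}", motif$arm3)
}

#' Compare folding probabilities of conserved vs non-conserved motifs
#'
#' Two-sided Wilcoxon-Mann-Whitney rank-sum test (p_fold is bounded and
#' skewed, so a rank test is the defensible default); group medians are
#' reported alongside.
#'
#' @param conserved_p,non_conserved_p numeric vectors of p_fold values.
#' @return list: `statistic` (W), `p_value`, `median_conserved`,
#'   `median_non_conserved`, `n_conserved`, `n_non_conserved`.
#' @export
fold_prob_comparison <- function(conserved_p, non_conserved_p) {
  if (!length(conserved_p) || !length(non_conserved_p)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(conserved_p, non_conserved_p,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_conserved = stats::median(conserved_p),
       median_non_conserved = stats::median(non_conserved_p),
       n_conserved = length(conserved_p),
       n_non_conserved = length(non_conserved_p))
}

#' Permutation oracle for a contingency-table chi-square p-value
#'
#' Monte-Carlo p-value under fixed margins (tables drawn with
#' [stats::r2dtable()]), used in tests as the independent check on the
#' asymptotic chi-square p.
#'
#' @param counts contingency matrix.
#' @param n_perm number of sampled tables.
#' @return Monte-Carlo p-value (with the +1 correction).
#' @export
chi_square_permutation_p <- function(counts, n_perm = 1e5) {
  counts <- as.matrix(counts)
  obs <- pearson_chi_square(counts)$statistic
  rs <- rowSums(counts); cs <- colSums(counts); n <- sum(counts)
  expected <- outer(rs, cs) / n
  tabs <- stats::r2dtable(n_perm, rs, cs)
  stats_perm <- vapply(tabs, function(tt) sum((tt - expected)^2 / expected),
                       numeric(1))
  (1 + sum(stats_perm >= obs - 1e-12)) / (n_perm + 1)
}
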