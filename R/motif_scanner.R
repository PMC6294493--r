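# Combinatorial CDE/ADE hairpin scanner: pure consensus matching, no
# thermodynamics.  A CDE is a 6-8 bp perfect stem capped by a YRN triloop;
# an ADE the same stem capped by a GUUYUA hexaloop.  Wobble pairs are
# excluded from the search by default (they are tolerated later, in
# conservation assessment -- the two modules deliberately use different
# pairing predicates).

#' Describe a hairpin motif class to scan for
#'
#' @param motif_class `"CDE"` (YRN triloop) or `"ADE"` (GUUYUA hexaloop).
#' @param stem_min,stem_max stem length bounds in base pairs (default 6-8).
#' @param loop_consensus IUPAC string; defaults to the class consensus.
#' @param allow_wobble allow G·U pairs in the stem during scanning
#'   (default `FALSE`).
#' @param reject_extendable if `TRUE`, drop hairpins whose stem could extend
#'   beyond `stem_max`; default caps them at `stem_max` instead.
#' @return object of class `motif_descriptor`.
#' @export
motif_descriptor <- function(motif_class = c("CDE", "ADE"),
                             stem_min = 6L, stem_max = 8L,
                             loop_consensus = NULL,
                             allow_wobble = FALSE,
                             reject_extendable = FALSE) {
  motif_class <- match.arg(motif_class)
  if (is.null(loop_consensus)) {
    loop_consensus <- if (motif_class == "CDE") "YRN" else "GUUYUA"
  }
  stopifnot(stem_min >= 1L, stem_min <= stem_max,
            nchar(loop_consensus) == (if (motif_class == "CDE") 3L else 6L))
  structure(list(
    motif_class = motif_class,
    stem_min = as.integer(stem_min),
    stem_max = as.integer(stem_max),
    loop_consensus = loop_consensus,
    allow_wobble = isTRUE(allow_wobble),
    reject_extendable = isTRUE(reject_extendable)
  ), class = "motif_descriptor")
}

new_hairpin_motif <- function(parent_id, motif_class, five_start, stem_len,
                              loop_seq, arm5, arm3) {
  loop_len <- nchar(loop_seq)
  three_end <- five_start + 2L * stem_len + loop_len
  structure(list(
    motif_id = sprintf("%s|%s|%d-%d", parent_id, motif_class, five_start, three_end),
    parent_id = parent_id,
    motif_class = motif_class,
    five_start = as.integer(five_start),
    stem_len = as.integer(stem_len),
    loop_seq = loop_seq,
    arm5 = arm5,
    arm3 = arm3,
    three_end = as.integer(three_end)
  ), class = "hairpin_motif")
}

#' Scan a sequence for consensus hairpin motifs
#'
#' Enumerates every maximal match: for each loop register where a hairpin
#' with stem length in `[stem_min, stem_max]` and a consensus-matching loop
#' exists, only the longest extendable stem (capped at `stem_max`) is
#' reported.  Overlapping matches at different registers are all reported.
#' Output is sorted by `five_start`, then `stem_len` descending.
#'
#' @param seq RNA/DNA string (normalized internally; `N` never pairs and
#'   never satisfies a consensus letter).
#' @param descriptor a [motif_descriptor()].
#' @param parent_id identifier recorded in each motif.
#' @return list of `hairpin_motif` objects (empty list when nothing matches).
#' @export
scan_motifs <- function(seq, descriptor = motif_descriptor("CDE"),
                        parent_id = "seq") {
  s <- normalize_rna(seq, "mask_n", id = parent_id)
  ch <- seq_chars(s)
  n <- length(ch)
  L <- nchar(descriptor$loop_consensus)
  out <- list()
  if (n < 2L * descriptor$stem_min + L) return(out)
  for (p in seq_len(n - L + 1L)) {  # 1-based loop start
    loop <- substr(s, p, p + L - 1L)
    if (!matches_iupac(loop, descriptor$loop_consensus)) next
    k <- 1L
    while (p - k >= 1L && p + L - 1L + k <= n &&
           can_pair(ch[p - k], ch[p + L - 1L + k], descriptor$allow_wobble)) {
      k <- k + 1L
    }
    max_ext <- k - 1L
    if (max_ext < descriptor$stem_min) next
    if (descriptor$reject_extendable && max_ext > descriptor$stem_max) next
    stem_len <- min(max_ext, descriptor$stem_max)
    five_start <- (p - 1L) - stem_len  # 0-based
    arm5 <- substr(s, p - stem_len, p - 1L)
    arm3 <- substr(s, p + L, p + L + stem_len - 1L)
    out[[length(out) + 1L]] <- new_hairpin_motif(
      parent_id, descriptor$motif_class, five_start, stem_len, loop, arm5, arm3)
  }
  ord <- order(vapply(out, `[[`, integer(1), "five_start"),
               -vapply(out, `[[`, integer(1), "stem_len"))
  out[ord]
}

#' The base pair closing the hairpin loop
#'
#' @param motif a `hairpin_motif`.
#' @return named character vector `c(five = ..., three = ...)`: the apical
#'   stem pair (5' base, 3' base) directly adjacent to the loop.
#' @export
loop_closing_pair <- function(motif) {
  c(five = substr(motif$arm5, motif$stem_len, motif$stem_len),
    three = substr(motif$arm3, 1L, 1L))
}

#' Closing-pair polarity
#'
#' `"Y-R"` when the 5' partner of the loop-closing pair is a pyrimidine,
#' `"R-Y"` when it is a purine.
#' @param motif a `hairpin_motif`.
#' @return `"Y-R"` or `"R-Y"`.
#' @export
closing_pair_polarity <- function(motif) {
  cp <- loop_closing_pair(motif)
  if (is_pyrimidine(cp[["five"]])) "Y-R" else "R-Y"
}

#' Convert a list of motifs to a data.frame
#' @param motifs list of `hairpin_motif` objects.
#' @return data.frame with one row per motif.
#' @export
motif_table <- function(motifs) {
  if (!length(motifs)) {
    return(data.frame(motif_id = character(), parent_id = character(),
                      motif_class = character(), five_start = integer(),
                      three_end = integer(), stem_len = integer(),
                      loop_seq = character(), arm5 = character(),
                      arm3 = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(motifs, function(m) {
    data.frame(motif_id = m$motif_id, parent_id = m$parent_id,
               motif_class = m$motif_class, five_start = m$five_start,
               three_end = m$three_end, stem_len = m$stem_len,
               loop_seq = m$loop_seq, arm5 = m$arm5, arm3 = m$arm3,
               stringsAsFactors = FALSE)
  }))
}

#' Full motif footprint sequence (arm5 + loop + arm3)
#' @param motif a `hairpin_motif`.
#' @return RNA string.
#' @export
motif_sequence <- function(motif) {
  paste0(motif$arm5, motif$loop_seq, motif$arm3)
}

#' @export
print.hairpin_motif <- function(x, ...) {
  cat(sprintf("<%s %s: [%d,%d), stem %d bp, loop %s, closing %s-%s>\n",
              x$motif_class, x$motif_id, x$five_start, x$three_end,
              x$stem_len, x$loop_seq,
              loop_closing_pair(x)[["five"]], loop_closing_pair(x)[["three"]]))
  invisible(x)
}
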