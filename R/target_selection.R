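# Per-gene aggregation: the high-confidence filter (conserved, p_fold > 5%,
# U at triloop position 3, 1-2 CDEs per gene), tandem-element detection, and
# the wet-lab candidate-window selection criteria.

#' High-confidence CDE qualification
#'
#' A CDE qualifies iff it is conserved, its folding probability strictly
#' exceeds 5%, and the triloop carries U at position 3.  Vectorized.
#'
#' @param conserved logical.
#' @param p_fold numeric in `[0,1]`.
#' @param loop_seq triloop strings.
#' @return logical vector.
#' @export
qualify_cde <- function(conserved, p_fold, loop_seq) {
  conserved & (p_fold > 0.05) & (substr(loop_seq, 3L, 3L) == "U")
}

#' Group closely spaced motifs into tandem elements
#'
#' Single-linkage grouping: two motifs join when their footprints are
#' separated by at most `max_gap` nt (overlapping footprints count as
#' separation 0); groups of size >= 2 are reported.  Invariant under input
#' order.
#'
#' @param motifs data.frame with columns `motif_id`, `five_start`,
#'   `three_end` (one gene).
#' @param max_gap maximum separation in nt (default 50).
#' @return list of character vectors of motif ids.
#' @export
detect_tandem <- function(motifs, max_gap = 50L) {
  if (!nrow(motifs)) return(list())
  o <- order(motifs$five_start, motifs$three_end)
  m <- motifs[o, , drop = FALSE]
  group <- integer(nrow(m))
  group[1L] <- 1L
  reach <- m$three_end[1L]
  for (i in seq_len(nrow(m))[-1L]) {
    gap <- m$five_start[i] - reach
    group[i] <- if (gap <= max_gap) group[i - 1L] else group[i - 1L] + 1L
    reach <- max(reach, m$three_end[i])
  }
  out <- split(m$motif_id, group)
  unname(out[vapply(out, length, integer(1)) >= 2L])
}

#' Assemble per-gene target records
#'
#' @param annotations data.frame with one row per motif: `gene_id`,
#'   `motif_id`, `motif_class` ("CDE"/"ADE"), `five_start`, `three_end`,
#'   `loop_seq`, `p_fold`, `conserved`.
#' @param policy `"one_to_two"` (high confidence iff the gene has 1-2
#'   qualifying CDEs; default) or `"at_least_one"`.
#' @param tandem_max_gap passed to [detect_tandem()].
#' @return list of `target_record` objects: `gene_id`, `motifs` (the rows),
#'   `n_cde`, `n_ade`, `n_qualifying`, `high_confidence`, `ade_target`,
#'   `tandem_groups`.
#' @export
assemble_targets <- function(annotations,
                             policy = c("one_to_two", "at_least_one"),
                             tandem_max_gap = 50L) {
  policy <- match.arg(policy)
  if (!nrow(annotations)) return(list())
  lapply(split(annotations, annotations$gene_id), function(g) {
    is_cde <- g$motif_class == "CDE"
    qual <- sum(qualify_cde(g$conserved, g$p_fold, g$loop_seq) & is_cde)
    hc <- if (policy == "one_to_two") qual >= 1L && qual <= 2L else qual >= 1L
    structure(list(
      gene_id = g$gene_id[1L],
      motifs = g,
      n_cde = sum(is_cde),
      n_ade = sum(!is_cde),
      n_qualifying = qual,
      high_confidence = hc,
      ade_target = any(!is_cde),
      tandem_groups = detect_tandem(g[is_cde, , drop = FALSE],
                                    max_gap = tandem_max_gap)
    ), class = "target_record")
  })
}

#' @export
print.target_record <- function(x, ...) {
  cat(sprintf("<target_record %s: %d CDE / %d ADE, %d qualifying, %s%s>\n",
              x$gene_id, x$n_cde, x$n_ade, x$n_qualifying,
              if (x$high_confidence) "high-confidence" else "not high-confidence",
              if (length(x$tandem_groups)) sprintf(", %d tandem group(s)",
                                                   length(x$tandem_groups)) else ""))
  invisible(x)
}

#' Tabulate target records
#' @param records list of `target_record`.
#' @return data.frame with one row per gene.
#' @export
targets_table <- function(records) {
  if (!length(records)) {
    return(data.frame(gene_id = character(), n_cde = integer(),
                      n_ade = integer(), n_qualifying = integer(),
                      high_confidence = logical(), ade_target = logical(),
                      n_tandem_groups = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(records, function(r) {
    data.frame(gene_id = r$gene_id, n_cde = r$n_cde, n_ade = r$n_ade,
               n_qualifying = r$n_qualifying,
               high_confidence = r$high_confidence, ade_target = r$ade_target,
               n_tandem_groups = length(r$tandem_groups),
               stringsAsFactors = FALSE)
  }))
}

#' Select candidate windows for an experimental screen
#'
#' Keeps windows with an external conserved-structure score > 0.9 whose
#' parent UTR is 500-1500 nt long, then resolves overlaps greedily by
#' descending score (ties by parent id, then coordinate), so that no two
#' selected windows on the same UTR overlap.
#'
#' @param windows data.frame with `parent_id`, `start`, `end`, `score`.
#' @param utr_lengths named integer vector: parent id -> UTR length.
#' @param min_score score threshold (default 0.9, strict).
#' @param length_range allowed UTR length range (default `c(500, 1500)`).
#' @return the selected rows of `windows`, ordered by parent then start.
#' @export
select_screen_windows <- function(windows, utr_lengths, min_score = 0.9,
                                  length_range = c(500L, 1500L)) {
  if (any(is.na(windows$score))) {
    stop("windows lack scores; supply the external screen output ",
         "(see read_window_scores)", call. = FALSE)
  }
  len <- utr_lengths[windows$parent_id]
  if (any(is.na(len))) stop("missing UTR length for some windows", call. = FALSE)
  cand <- windows[windows$score > min_score &
                    len >= length_range[1L] & len <= length_range[2L], ,
                  drop = FALSE]
  if (!nrow(cand)) return(cand)
  cand <- cand[order(-cand$score, cand$parent_id, cand$start), , drop = FALSE]
  sel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(sel)) {
      prev <- cand[sel, , drop = FALSE]
      same <- prev$parent_id == cand$parent_id[i]
      if (any(same & prev$start < cand$end[i] & cand$start[i] < prev$end)) {
        ok <- FALSE
      }
    }
    sel[i] <- ok
  }
  out <- cand[sel, , drop = FALSE]
  out[order(out$parent_id, out$start), , drop = FALSE]
}
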