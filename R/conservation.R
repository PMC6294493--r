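# Structure-aware conservation classification.  A motif counts as conserved
# in a species when its ortholog is either identical or carries only
# tolerated changes: (i) loop changes that still match the loop consensus,
# (ii) stem-length changes leaving >= 6 loop-proximal pairs, (iii)
# compensatory pair changes, (iv) wobble-creating changes.  Unlike the
# scanner, the conservation pairing predicate accepts G.U wobbles.

TOLERATED_CATEGORIES <- c("loop_motif_preserving", "stem_length_change",
                          "compensatory_pair", "wobble_pair")

#' Classify one species' ortholog of a human motif
#'
#' @param human_motif a `hairpin_motif`.
#' @param species_seq gapped ortholog sequence over the motif footprint
#'   columns (same columns as `human_gapped`).
#' @param descriptor the [motif_descriptor()] used for the scan (supplies
#'   the loop consensus).
#' @param human_gapped gapped reference row over the same columns; defaults
#'   to the ungapped motif sequence (no insertion columns).
#' @param conserved_core `"apical"` (the 6 loop-proximal pairs must form;
#'   default) or `"any6"` (any 6 stem pairs may carry the structure).
#' @return verdict record: list with `status` in
#'   identical/tolerated/violated/absent and `changes`, a character vector
#'   of change categories.
#' @export
classify_species <- function(human_motif, species_seq, descriptor,
                             human_gapped = NULL,
                             conserved_core = c("apical", "any6")) {
  conserved_core <- match.arg(conserved_core)
  hseq <- motif_sequence(human_motif)
  if (is.null(human_gapped)) human_gapped <- hseq
  verdict <- function(status, changes = character()) {
    list(status = status, changes = unique(changes))
  }
  if (is.null(species_seq) || !nzchar(gsub("-", "", species_seq))) {
    return(verdict("absent"))
  }
  hg <- seq_chars(human_gapped)
  sg <- seq_chars(toupper(chartr("Tt", "Uu", species_seq)))
  if (length(hg) != length(sg)) {
    stop("species row and reference row must share alignment columns",
         call. = FALSE)
  }
  # insertion relative to the human motif -> not a defined change category
  if (any(hg == "-" & sg != "-")) return(verdict("violated"))
  spos <- sg[hg != "-"]           # one character per motif position ('-' = deleted)
  hpos <- seq_chars(hseq)
  stopifnot(length(spos) == length(hpos))
  if (identical(spos, hpos)) return(verdict("identical"))

  m <- human_motif$stem_len
  L <- nchar(human_motif$loop_seq)
  loop_idx <- (m + 1L):(m + L)
  sloop <- spos[loop_idx]
  changes <- character()
  if (any(sloop == "-")) return(verdict("violated"))
  if (!matches_iupac(paste(sloop, collapse = ""), descriptor$loop_consensus)) {
    return(verdict("violated"))
  }
  if (!identical(sloop, hpos[loop_idx])) changes <- c(changes, "loop_motif_preserving")

  required_min <- 6L
  formed <- logical(m)
  lost <- logical(m)
  for (k in seq_len(m)) {      # k = 1 outermost, k = m apical
    i5 <- k
    i3 <- 2L * m + L - k + 1L
    a <- spos[i5]; b <- spos[i3]
    if (a == "-" || b == "-") {
      lost[k] <- TRUE
      next
    }
    if (can_pair(a, b, allow_wobble = TRUE)) {
      formed[k] <- TRUE
      if (a != hpos[i5] || b != hpos[i3]) {
        changes <- c(changes,
                     if (is_wobble_pair(a, b)) "wobble_pair" else "compensatory_pair")
      }
    } else {
      lost[k] <- TRUE
    }
  }
  if (conserved_core == "apical") {
    core <- (m - required_min + 1L):m
    if (!all(formed[core])) return(verdict("violated"))
  } else {
    if (sum(formed) < required_min) return(verdict("violated"))
  }
  if (any(lost)) changes <- c(changes, "stem_length_change")
  verdict("tolerated", changes)
}

#' Classify conservation of a motif across all required species
#'
#' @param motif a `hairpin_motif`.
#' @param slice an `alignment_slice` covering the motif footprint (it is
#'   restricted to the footprint columns internally).
#' @param descriptor the [motif_descriptor()] of the scan.
#' @param required_species species that must be non-violating (default the
#'   four non-human mammals of the five-way comparison).
#' @param policy `"strict"` (a species absent from the alignment makes the
#'   motif not conserved) or `"ignore_absent"` (absent species are dropped;
#'   a motif with all species absent is not conserved).
#' @param conserved_core see [classify_species()].
#' @return object of class `conservation_call`: `motif_id`, `per_species`
#'   (named list of verdict records), `conserved` (logical).
#' @export
classify_motif <- function(motif, slice, descriptor,
                           required_species = c("chimp", "mouse", "dog", "cow"),
                           policy = c("strict", "ignore_absent"),
                           conserved_core = c("apical", "any6")) {
  policy <- match.arg(policy)
  conserved_core <- match.arg(conserved_core)
  fp <- slice_footprint(slice, motif)
  ref_ungapped <- gsub("-", "", fp$rows[[fp$reference]])
  if (!identical(ref_ungapped, motif_sequence(motif))) {
    stop("slice reference row does not reproduce the motif footprint sequence",
         call. = FALSE)
  }
  per <- lapply(required_species, function(sp) {
    if (!sp %in% names(fp$rows)) return(list(status = "absent",
                                             changes = character()))
    classify_species(motif, fp$rows[[sp]], descriptor,
                     human_gapped = fp$rows[[fp$reference]],
                     conserved_core = conserved_core)
  })
  names(per) <- required_species
  status <- vapply(per, `[[`, character(1), "status")
  conserved <- if (policy == "strict") {
    all(status %in% c("identical", "tolerated"))
  } else {
    kept <- status[status != "absent"]
    length(kept) > 0L && all(kept %in% c("identical", "tolerated"))
  }
  structure(list(motif_id = motif$motif_id, per_species = per,
                 conserved = conserved),
            class = "conservation_call")
}

#' @export
print.conservation_call <- function(x, ...) {
  st <- vapply(x$per_species, `[[`, character(1), "status")
  cat(sprintf("<conservation_call %s: %s -> %s>\n", x$motif_id,
              paste(sprintf("%s=%s", names(st), st), collapse = ", "),
              if (x$conserved) "conserved" else "not conserved"))
  invisible(x)
}

#' Tabulate conservation calls
#'
#' One row per motif, one column per species
#' (`status[:category1+category2]`), and a final `conserved` flag.
#' @param calls list of `conservation_call` objects.
#' @return data.frame.
#' @export
conservation_table <- function(calls) {
  if (!length(calls)) {
    return(data.frame(motif_id = character(), conserved = logical(),
                      stringsAsFactors = FALSE))
  }
  species <- names(calls[[1L]]$per_species)
  rows <- lapply(calls, function(cl) {
    cells <- vapply(cl$per_species, function(v) {
      if (length(v$changes)) paste0(v$status, ":", paste(v$changes, collapse = "+"))
      else v$status
    }, character(1))
    df <- data.frame(motif_id = cl$motif_id, stringsAsFactors = FALSE)
    for (sp in species) df[[sp]] <- cells[[sp]]
    df$conserved <- cl$conserved
    df
  })
  do.call(rbind, rows)
}
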