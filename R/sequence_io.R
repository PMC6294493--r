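# Format plumbing: FASTA records, UTR windowing, MAF alignment blocks,
# alignment slicing over motif footprints, window-score tables, BED6 output.
# Coordinates are 0-based half-open everywhere inside the package; MAF's own
# conventions are converted at the parser boundary.

#' Construct a 3'UTR record
#'
#' @param transcript_id,gene_id,species identifiers; `gene_id` defaults to
#'   the transcript id.
#' @param sequence nucleotide string (normalized to RNA).
#' @param alphabet_policy `"strict"` rejects characters outside A/C/G/U/T/N;
#'   `"mask_n"` masks them to `N`.
#' @return object of class `utr_record`.
#' @export
utr_record <- function(transcript_id, sequence, gene_id = transcript_id,
                       species = "human",
                       alphabet_policy = c("strict", "mask_n")) {
  seqn <- normalize_rna(sequence, match.arg(alphabet_policy), id = transcript_id)
  stopifnot(nchar(seqn) >= 1L)
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 species = species, sequence = seqn),
            class = "utr_record")
}

#' @export
print.utr_record <- function(x, ...) {
  cat(sprintf("<utr_record %s (gene %s, %s): %d nt>\n", x$transcript_id,
              x$gene_id, x$species, nchar(x$sequence)))
  invisible(x)
}

#' Read a FASTA file into UTR records
#'
#' The header token before the first whitespace becomes the transcript id;
#' optional `gene=` and `species=` header fields are honored.  T is mapped
#' to U and case is folded.
#'
#' @param path FASTA file.
#' @param alphabet_policy `"strict"` (reject non-ACGUNT, naming record and
#'   position) or `"mask_n"`.
#' @return list of [utr_record()] objects.
#' @export
read_fasta <- function(path, alphabet_policy = c("strict", "mask_n")) {
  alphabet_policy <- match.arg(alphabet_policy)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    toks <- strsplit(header, "\\s+")[[1L]]
    tid <- toks[1L]
    field <- function(key, default) {
      hit <- grep(paste0("^", key, "="), toks, value = TRUE)
      if (length(hit)) sub(paste0("^", key, "="), "", hit[1L]) else default
    }
    utr_record(tid, as.character(set[[i]]),
               gene_id = field("gene", tid),
               species = field("species", "human"),
               alphabet_policy = alphabet_policy)
  })
}

#' Write UTR records to FASTA
#'
#' Inverse of [read_fasta()] on normalized records.
#' @param records list of [utr_record()].
#' @param path output file.
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    c(sprintf(">%s gene=%s species=%s", r$transcript_id, r$gene_id, r$species),
      r$sequence)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Tile a UTR into overlapping analysis windows
#'
#' Windows start at 0, `step`, 2*`step`, ... while `start + width` fits; if
#' the tail would otherwise be unscanned, one final end-anchored window
#' `[length - width, length)` is appended.  A UTR no longer than `width`
#' yields the single window `[0, length)`.
#'
#' @param utr a [utr_record()].
#' @param width window width in nt (default 100).
#' @param step step size in nt (default 50).
#' @return data.frame with columns `parent_id`, `start`, `end`, `sequence`,
#'   `score` (NA; filled from an external conserved-structure screen).
#' @export
tile_windows <- function(utr, width = 100L, step = 50L) {
  stopifnot(width >= 1L, step >= 1L, step <= width)
  n <- nchar(utr$sequence)
  if (n <= width) {
    starts <- 0L
    ends <- n
  } else {
    starts <- seq.int(0L, n - width, by = step)
    if (max(starts) + width < n) starts <- c(starts, n - width)
    ends <- starts + width
  }
  data.frame(
    parent_id = utr$transcript_id,
    start = as.integer(starts),
    end = as.integer(ends),
    sequence = substring(utr$sequence, starts + 1L, ends),
    score = NA_real_,
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------- MAF -------

split_src <- function(src) {
  dot <- regexpr(".", src, fixed = TRUE)
  if (dot > 0L) {
    c(species = substr(src, 1L, dot - 1L), chrom = substr(src, dot + 1L, nchar(src)))
  } else c(species = src, chrom = "")
}

#' Read a MAF (Multiz-style) multiple alignment file
#'
#' No pre-installed R package parses MAF, so this is a purpose-built reader
#' for the `a`/`s` line subset.  Row order and per-row start/size/strand/
#' srcSize metadata are preserved; the `##maf` header is optional.  Blocks
#' lacking the reference species are skipped with a warning; rows of
#' unequal gapped length or malformed `s` lines are a parse error.
#'
#' @param path MAF file.
#' @param reference species label that must be present in every kept block
#'   (the part of `src` before the first dot).
#' @return list of blocks; each block is a data.frame with columns `src`,
#'   `species`, `chrom`, `start`, `size`, `strand`, `src_size`, `text`.
#' @export
read_maf <- function(path, reference = "human") {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || !nrow(cur)) return(invisible(NULL))
    widths <- nchar(cur$text)
    if (length(unique(widths)) != 1L) {
      stop("MAF parse error: rows of unequal gapped length in block ending near '",
           cur$src[nrow(cur)], "'", call. = FALSE)
    }
    if (!reference %in% cur$species) {
      warning("MAF block without reference species '", reference, "' skipped",
              call. = FALSE)
      return(invisible(NULL))
    }
    blocks[[length(blocks) + 1L]] <<- cur
    invisible(NULL)
  }
  for (ln in lines) {
    if (grepl("^a(\\s|$)", ln)) {
      flush(cur)
      cur <- data.frame(src = character(), species = character(),
                        chrom = character(), start = integer(),
                        size = integer(), strand = character(),
                        src_size = integer(), text = character(),
                        stringsAsFactors = FALSE)
    } else if (grepl("^s\\s", ln)) {
      if (is.null(cur)) stop("MAF parse error: 's' line before any 'a' line",
                             call. = FALSE)
      tk <- strsplit(trimws(ln), "\\s+")[[1L]]
      if (length(tk) != 7L || is.na(suppressWarnings(as.integer(tk[3L])))) {
        stop("MAF parse error: malformed s line: ", ln, call. = FALSE)
      }
      sp <- split_src(tk[2L])
      cur <- rbind(cur, data.frame(
        src = tk[2L], species = sp[["species"]], chrom = sp[["chrom"]],
        start = as.integer(tk[3L]), size = as.integer(tk[4L]),
        strand = tk[5L], src_size = as.integer(tk[6L]),
        text = toupper(chartr("Tt", "Uu", tk[7L])),
        stringsAsFactors = FALSE))
    }
  }
  flush(cur)
  blocks
}

#' Write alignment blocks to MAF
#' @param blocks list of block data.frames as returned by [read_maf()].
#' @param path output file.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  for (b in blocks) {
    writeLines("a", con)
    for (r in seq_len(nrow(b))) {
      writeLines(sprintf("s %s %d %d %s %d %s", b$src[r], b$start[r],
                         b$size[r], b$strand[r], b$src_size[r], b$text[r]), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Slice a multi-species alignment over a motif footprint
#'
#' Extracts the alignment columns covering `[five_start, three_end)` of the
#' motif (reference ungapped coordinates) plus up to `flank` reference
#' nucleotides on each side (trimmed to available coverage).  Reference-row
#' gap columns inside the interval are retained.  Species absent from a
#' covering block contribute all-gap rows for that stretch.
#'
#' @param blocks list of MAF blocks ([read_maf()]).
#' @param motif a `hairpin_motif`; its `parent_id` must match the reference
#'   row's chrom part when one is present.
#' @param flank nt of reference context on each side (default 0).
#' @param reference reference species label (default `"human"`).
#' @return object of class `alignment_slice`: `motif_id`, `rows` (named
#'   character vector species -> gapped sequence), `reference`, `ref_start`,
#'   `ref_end`, `absent` (species absent from all covering blocks is simply
#'   not in `rows`; partial absence appears as gaps).
#' @export
slice_alignment <- function(blocks, motif, flank = 0L, reference = "human") {
  lo_want <- max(0L, motif$five_start - flank)
  hi_want <- motif$three_end + flank
  keep <- list()  # per covering block: ref coords + column range
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    r <- which(b$species == reference)[1L]
    if (is.na(r)) next
    if (nzchar(b$chrom[r]) && b$chrom[r] != motif$parent_id) next
    chars <- seq_chars(b$text[r])
    nongap <- chars != "-"
    coords <- integer(length(chars))
    coords[nongap] <- b$start[r] + seq_len(sum(nongap)) - 1L
    coords[!nongap] <- NA_integer_
    cols <- which(!is.na(coords) & coords >= lo_want & coords < hi_want)
    if (!length(cols)) next
    keep[[length(keep) + 1L]] <- list(block = b, refrow = r, coords = coords,
                                      cols = range(cols))
  }
  if (!length(keep)) {
    stop(sprintf("alignment coverage error: footprint [%d,%d) of motif %s not covered",
                 motif$five_start, motif$three_end, motif$motif_id), call. = FALSE)
  }
  ord <- order(vapply(keep, function(k) k$coords[k$cols[1L]], integer(1)))
  keep <- keep[ord]
  covered <- sort(unique(unlist(lapply(keep, function(k) {
    cc <- k$coords[k$cols[1L]:k$cols[2L]]
    cc[!is.na(cc)]
  }))))
  need <- seq.int(motif$five_start, motif$three_end - 1L)
  missing <- setdiff(need, covered)
  if (length(missing)) {
    stop(sprintf("alignment coverage error: positions [%d,%d] of motif %s uncovered",
                 min(missing), max(missing), motif$motif_id), call. = FALSE)
  }
  species <- unique(unlist(lapply(keep, function(k) k$block$species)))
  rows <- stats::setNames(rep("", length(species)), species)
  for (k in keep) {
    rng <- k$cols[1L]:k$cols[2L]
    width <- length(rng)
    for (sp in species) {
      r <- which(k$block$species == sp)[1L]
      piece <- if (is.na(r)) strrep("-", width)
               else paste(seq_chars(k$block$text[r])[rng], collapse = "")
      rows[sp] <- paste0(rows[sp], piece)
    }
  }
  covered_in <- covered[covered >= lo_want & covered < hi_want]
  structure(list(
    motif_id = motif$motif_id,
    rows = rows,
    reference = reference,
    ref_start = min(covered_in),
    ref_end = max(covered_in) + 1L
  ), class = "alignment_slice")
}

#' Restrict an alignment slice to the exact motif footprint columns
#'
#' @param slice an `alignment_slice`.
#' @param motif the `hairpin_motif` the slice was cut for.
#' @return `alignment_slice` whose reference row ungaps to exactly the motif
#'   footprint sequence.
#' @export
slice_footprint <- function(slice, motif) {
  ref <- seq_chars(slice$rows[[slice$reference]])
  nongap <- ref != "-"
  coords <- integer(length(ref))
  coords[nongap] <- slice$ref_start + seq_len(sum(nongap)) - 1L
  coords[!nongap] <- NA_integer_
  inside <- !is.na(coords) & coords >= motif$five_start & coords < motif$three_end
  # retain reference-gap columns between footprint columns
  idx <- which(inside)
  cols <- seq.int(min(idx), max(idx))
  rows <- vapply(slice$rows, function(s) paste(seq_chars(s)[cols], collapse = ""),
                 character(1))
  structure(list(motif_id = slice$motif_id, rows = rows,
                 reference = slice$reference,
                 ref_start = motif$five_start, ref_end = motif$three_end),
            class = "alignment_slice")
}

# ------------------------------------------------------------- tables -------

#' Read an external conserved-structure window score table
#'
#' Tab-delimited with columns `transcript_id`, `start`, `end`, `score`
#' (probability in `[0,1]` from an external fold-and-align screen).
#' @param path file path.
#' @return data.frame.
#' @export
read_window_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("transcript_id", "start", "end", "score")
  if (!all(req %in% names(df))) {
    stop("window score table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE)) {
    stop("window scores must lie in [0,1]", call. = FALSE)
  }
  df
}

#' Write motifs to BED6
#'
#' chromStart/chromEnd are the half-open footprint; name is the motif id;
#' score is `round(1000 * p_fold)`; strand is `+` (sense-strand mRNA).
#'
#' @param motifs list of `hairpin_motif`.
#' @param p_fold numeric vector of folding probabilities (same order);
#'   missing values score 0.
#' @param path output file.
#' @export
write_bed6 <- function(motifs, p_fold = NULL, path) {
  tab <- motif_table(motifs)
  score <- if (is.null(p_fold)) rep(0, nrow(tab)) else round(1000 * p_fold)
  score[is.na(score)] <- 0
  bed <- data.frame(chrom = tab$parent_id, chromStart = tab$five_start,
                    chromEnd = tab$three_end, name = tab$motif_id,
                    score = as.integer(score), strand = "+",
                    stringsAsFactors = FALSE)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
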