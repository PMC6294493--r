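# Synthetic data generator: background UTRs, planted CDE/ADE hairpins with
# configurable stem composition, and five-species ortholog alignments whose
# motif-footprint substitutions are drawn from the tolerated or violating
# change categories, with ground-truth labels.  Everything is reproducible
# from (config, seed).

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate an iid background RNA sequence
#'
#' @param length nt (0 allowed).
#' @param composition named probabilities for A/C/G/U.
#' @param seed optional integer; the result is deterministic given the seed.
#' @return RNA string.
#' @export
gen_background <- function(length,
                           composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                           seed = NULL) {
  stopifnot(length >= 0, all(names(composition) == RNA_BASES))
  with_seed(seed, {
    if (length == 0L) return("")
    paste(sample(RNA_BASES, length, replace = TRUE, prob = composition),
          collapse = "")
  })
}

WC_PAIRS <- c("AU", "UA", "CG", "GC")

sample_cde_loop <- function(p3_u = 0.7) {
  paste0(sample(c("C", "U"), 1L),
         sample(c("A", "G"), 1L, prob = c(0.7, 0.3)),
         sample(RNA_BASES, 1L, prob = c((1 - p3_u) / 3, (1 - p3_u) / 3,
                                        (1 - p3_u) / 3, p3_u)))
}

sample_ade_loop <- function() paste0("GUU", sample(c("C", "U"), 1L), "UA")

# pairs as a character vector, element k = pair at stem position k
# (k = 1 outermost, k = stem_len apical), "XY" = (5' base, 3' base)
sample_stem_pairs <- function(stem_len, au_fraction = NULL,
                              purine_stack = FALSE) {
  if (is.null(au_fraction)) {
    pairs <- sample(WC_PAIRS, stem_len, replace = TRUE)
  } else {
    n_au <- round(au_fraction * stem_len)
    type <- sample(c(rep(TRUE, n_au), rep(FALSE, stem_len - n_au)))
    pairs <- ifelse(type, sample(c("AU", "UA"), stem_len, replace = TRUE),
                    sample(c("CG", "GC"), stem_len, replace = TRUE))
  }
  if (purine_stack && stem_len >= 3L) {
    run <- sample.int(stem_len - 2L, 1L)
    for (k in run:(run + 2L)) {
      # force the 3' base of this pair to a purine, keeping the pair type
      pairs[k] <- if (substr(pairs[k], 1L, 1L) %in% c("A", "U")) "UA" else "CG"
    }
  }
  pairs
}

#' Specify a hairpin to plant
#'
#' Unset fields are sampled at plant time: the loop from the class consensus
#' (triloop position 3 skewed toward U, matching the conservation-derived
#' loop preference), the stem from uniform Watson-Crick pairs.
#'
#' @param motif_class `"CDE"` or `"ADE"`.
#' @param stem_len 6-8.
#' @param loop_seq optional consensus-conforming loop.
#' @param stem_pairs optional character vector of pairs (`"XY"` = 5',3'),
#'   outermost first.
#' @param au_fraction optional target AU share of stem pairs.
#' @param purine_stack force >= 3 consecutive purines on the 3' arm.
#' @param position 0-based footprint start or `"random"`.
#' @param intended_conserved ground-truth conservation label.
#' @return object of class `plant_spec`.
#' @export
plant_spec <- function(motif_class = c("CDE", "ADE"), stem_len = 6L,
                       loop_seq = NULL, stem_pairs = NULL,
                       au_fraction = NULL, purine_stack = FALSE,
                       position = "random", intended_conserved = TRUE) {
  motif_class <- match.arg(motif_class)
  stopifnot(stem_len >= 1L)
  if (!is.null(loop_seq)) {
    cons <- if (motif_class == "CDE") "YRN" else "GUUYUA"
    if (!matches_iupac(loop_seq, cons)) {
      stop("loop_seq does not match the ", motif_class, " consensus ", cons,
           call. = FALSE)
    }
  }
  if (!is.null(stem_pairs) && !all(stem_pairs %in% WC_PAIRS)) {
    stop("stem_pairs must be Watson-Crick", call. = FALSE)
  }
  structure(list(motif_class = motif_class, stem_len = as.integer(stem_len),
                 loop_seq = loop_seq, stem_pairs = stem_pairs,
                 au_fraction = au_fraction, purine_stack = isTRUE(purine_stack),
                 position = position,
                 intended_conserved = isTRUE(intended_conserved)),
            class = "plant_spec")
}

build_hairpin <- function(spec) {
  loop <- spec$loop_seq %||% (if (spec$motif_class == "CDE") sample_cde_loop()
                              else sample_ade_loop())
  pairs <- spec$stem_pairs %||% sample_stem_pairs(spec$stem_len,
                                                  spec$au_fraction,
                                                  spec$purine_stack)
  arm5 <- paste(substr(pairs, 1L, 1L), collapse = "")
  arm3 <- paste(rev(substr(pairs, 2L, 2L)), collapse = "")
  list(arm5 = arm5, loop = loop, arm3 = arm3,
       text = paste0(arm5, loop, arm3), pairs = pairs)
}

#' Plant a hairpin motif into a background sequence
#'
#' The hairpin text replaces the background at the footprint; the flanking
#' bases are resampled (bounded retries) so they cannot pair (even as a
#' wobble), which guarantees the planted stem length is exactly as
#' specified and the scanner reports the planted footprint.
#'
#' @param background RNA string.
#' @param spec a [plant_spec()].
#' @param seed optional integer.
#' @param max_retries flank resampling attempts before giving up.
#' @return list: `sequence` (modified background), `motif` (the planted
#'   `hairpin_motif` with coordinates in the returned sequence).
#' @export
plant_motif <- function(background, spec, seed = NULL, max_retries = 20L) {
  with_seed(seed, {
    n <- nchar(background)
    hp <- build_hairpin(spec)
    len <- nchar(hp$text)
    if (len > n) stop("background too short for the planted hairpin",
                      call. = FALSE)
    pos0 <- if (identical(spec$position, "random")) {
      sample.int(n - len + 1L, 1L) - 1L
    } else as.integer(spec$position)
    if (pos0 < 0L || pos0 + len > n) stop("plant position out of range",
                                          call. = FALSE)
    desc <- motif_descriptor(spec$motif_class)
    ch <- seq_chars(background)
    ch[(pos0 + 1L):(pos0 + len)] <- seq_chars(hp$text)
    for (try in seq_len(max_retries)) {
      if (pos0 >= 1L) ch[pos0] <- sample(RNA_BASES, 1L)
      if (pos0 + len < n) {
        left <- if (pos0 >= 1L) ch[pos0] else "A"
        ok3 <- RNA_BASES[!can_pair(left, RNA_BASES, allow_wobble = TRUE)]
        ch[pos0 + len + 1L] <- sample(ok3, 1L)
      }
      seqn <- paste(ch, collapse = "")
      found <- scan_motifs(seqn, desc, parent_id = "plant")
      hit <- Filter(function(m) m$five_start == pos0 &&
                      m$three_end == pos0 + len, found)
      if (length(hit)) {
        m <- hit[[1L]]
        return(list(sequence = seqn, motif = m))
      }
    }
    stop("plant_motif: retries exhausted (over-constrained spec)", call. = FALSE)
  })
}

# ---------------------------------------------------------------------------
# Ortholog simulation
# ---------------------------------------------------------------------------

VIOLATING_CATEGORIES <- c("loop_violation", "stem_break")

stem_site_indices <- function(m, L, k) {
  c(i5 = k, i3 = 2L * m + L - k + 1L)
}

apply_change <- function(chars, motif, category, site = NULL) {
  m <- motif$stem_len
  L <- nchar(motif$loop_seq)
  cons <- if (motif$motif_class == "CDE") "YRN" else "GUUYUA"
  cons_ch <- seq_chars(cons)
  if (category == "loop_motif_preserving") {
    ks <- if (is.null(site)) sample(seq_len(L)) else site
    for (k in ks) {
      alt <- setdiff(IUPAC_SETS[[cons_ch[k]]], chars[m + k])
      if (length(alt)) {
        chars[m + k] <- if (length(alt) == 1L) alt else sample(alt, 1L)
        break
      }
    }
  } else if (category == "compensatory_pair") {
    k <- site %||% sample.int(m, 1L)
    ii <- stem_site_indices(m, L, k)
    cur <- paste0(chars[ii["i5"]], chars[ii["i3"]])
    alt <- setdiff(WC_PAIRS, cur)
    p <- sample(alt, 1L)
    chars[ii["i5"]] <- substr(p, 1L, 1L)
    chars[ii["i3"]] <- substr(p, 2L, 2L)
  } else if (category == "wobble_pair") {
    ks <- if (is.null(site)) sample(seq_len(m)) else site
    for (k in ks) {
      ii <- stem_site_indices(m, L, k)
      cur <- paste0(chars[ii["i5"]], chars[ii["i3"]])
      route <- switch(cur, AU = c("i5", "G"), UA = c("i3", "G"),
                      CG = c("i5", "U"), GC = c("i3", "U"), NULL)
      if (!is.null(route)) {
        chars[ii[route[1L]]] <- route[2L]
        break
      }
    }
  } else if (category == "stem_length_change") {
    if (m <= 6L) stop("stem_length_change needs a stem longer than 6 bp",
                      call. = FALSE)
    k <- site %||% sample.int(m - 6L, 1L)  # outermost dispensable pairs
    ii <- stem_site_indices(m, L, k)
    b <- chars[ii["i3"]]
    alt <- setdiff(RNA_BASES[!can_pair(RNA_BASES, b, allow_wobble = TRUE)],
                   chars[ii["i5"]])
    chars[ii["i5"]] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  } else if (category == "loop_violation") {
    if (motif$motif_class == "CDE") {
      chars[m + 2L] <- sample(c("C", "U"), 1L)  # purine position -> pyrimidine
    } else {
      chars[m + 1L] <- sample(c("A", "C", "U"), 1L)  # G position
    }
  } else if (category == "stem_break") {
    k <- site %||% m  # apical pair: always in the required core
    ii <- stem_site_indices(m, L, k)
    b <- chars[ii["i3"]]
    alt <- setdiff(RNA_BASES[!can_pair(RNA_BASES, b, allow_wobble = TRUE)],
                   chars[ii["i5"]])
    chars[ii["i5"]] <- if (length(alt) == 1L) alt else sample(alt, 1L)
  } else stop("unknown change category: ", category, call. = FALSE)
  chars
}

sample_tolerated_plan <- function(motif, n_changes) {
  pool <- c("loop_motif_preserving", "compensatory_pair", "wobble_pair")
  if (motif$stem_len > 6L) pool <- c(pool, "stem_length_change")
  if (n_changes == 0L) return(character())
  sample(pool, n_changes, replace = FALSE)
}

#' Simulate a five-species ortholog alignment with labeled changes
#'
#' Non-motif sites mutate iid at `background_rate` per species; motif
#' footprint sites change only according to the per-species change plans.
#' Plans for `intended_conserved = TRUE` motifs draw only tolerated
#' categories; plans for `FALSE` motifs include at least one violating
#' change.  No indels are introduced (in-motif gaps are violations by rule,
#' so the default simulation is substitution-only).
#'
#' @param human_seq RNA string (the reference UTR).
#' @param motifs list of `hairpin_motif` planted in `human_seq`.
#' @param intended_conserved logical vector, one label per motif.
#' @param species non-reference species names.
#' @param background_rate per-site substitution probability outside motifs.
#' @param parent_id sequence name used in MAF src fields.
#' @param seed optional integer.
#' @return list: `block` (MAF block data.frame, reference row first),
#'   `species_seqs` (named character), `plans` (per motif x species list of
#'   categories applied).
#' @export
gen_ortholog_alignment <- function(human_seq, motifs = list(),
                                   intended_conserved = logical(0),
                                   species = c("chimp", "mouse", "dog", "cow"),
                                   background_rate = 0.1,
                                   parent_id = "utr", seed = NULL) {
  stopifnot(length(motifs) == length(intended_conserved))
  with_seed(seed, {
    n <- nchar(human_seq)
    hch <- seq_chars(human_seq)
    in_motif <- rep(FALSE, n)
    for (m in motifs) in_motif[(m$five_start + 1L):m$three_end] <- TRUE
    plans <- lapply(motifs, function(m) stats::setNames(
      vector("list", length(species)), species))
    species_seqs <- stats::setNames(character(length(species)), species)
    for (sp in species) {
      ch <- hch
      mut <- which(!in_motif & stats::runif(n) < background_rate)
      for (i in mut) ch[i] <- sample(setdiff(RNA_BASES, ch[i]), 1L)
      for (mi in seq_along(motifs)) {
        m <- motifs[[mi]]
        fp <- (m$five_start + 1L):m$three_end
        mchars <- ch[fp]
        cats <- sample_tolerated_plan(m, sample(0:2, 1L))
        for (cat in cats) mchars <- apply_change(mchars, m, cat)
        plans[[mi]][[sp]] <- cats
        ch[fp] <- mchars
      }
      species_seqs[sp] <- paste(ch, collapse = "")
    }
    # for non-conserved motifs, add one violating change in one species
    for (mi in seq_along(motifs)) {
      if (intended_conserved[mi]) next
      m <- motifs[[mi]]
      sp <- sample(species, 1L)
      cat <- sample(VIOLATING_CATEGORIES, 1L)
      fp <- (m$five_start + 1L):m$three_end
      ch <- seq_chars(species_seqs[sp])
      ch[fp] <- apply_change(ch[fp], m, cat)
      species_seqs[sp] <- paste(ch, collapse = "")
      plans[[mi]][[sp]] <- c(plans[[mi]][[sp]], cat)
    }
    rows <- data.frame(
      src = paste0(c("human", species), ".", parent_id),
      species = c("human", species),
      chrom = parent_id,
      start = 0L, size = n, strand = "+", src_size = n,
      text = c(human_seq, unname(species_seqs)),
      stringsAsFactors = FALSE
    )
    list(block = rows, species_seqs = species_seqs, plans = plans)
  })
}

#' Generate a full synthetic dataset (FASTA + MAF + ground truth)
#'
#' Plants `n_cde` CDEs and `n_ade` ADEs into distinct genes out of
#' `n_genes` iid background UTRs, simulates the five-species alignment for
#' every gene, and (optionally) writes FASTA, MAF, truth tables and a
#' parameter manifest to `dir`.  Fully reproducible from (arguments, seed).
#'
#' @param n_genes number of genes (default 500).
#' @param n_cde,n_ade planted element counts (defaults 100 / 20).
#' @param conserved_fraction share of plants with `intended_conserved = TRUE`.
#' @param utr_length background UTR length in nt (default 600; inside the
#'   500-1500 nt band used for screen-window selection).
#' @param composition background base probabilities.
#' @param background_rate per-site ortholog substitution rate outside motifs.
#' @param purine_stack_prob share of plants forced to carry a 3' purine stack.
#' @param seed integer (required: the dataset is its seed).
#' @param dir optional output directory; created if needed.
#' @return list: `records` (utr_record list), `blocks` (MAF blocks),
#'   `truth_motifs` (data.frame), `truth_genes` (data.frame), `paths`
#'   (when written), `params`.
#' @export
gen_dataset <- function(n_genes = 500L, n_cde = 100L, n_ade = 20L,
                        conserved_fraction = 0.5, utr_length = 600L,
                        composition = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25),
                        background_rate = 0.1, purine_stack_prob = 0.3,
                        seed, dir = NULL) {
  stopifnot(n_cde + n_ade <= n_genes)
  params <- list(n_genes = n_genes, n_cde = n_cde, n_ade = n_ade,
                 conserved_fraction = conserved_fraction,
                 utr_length = utr_length, composition = as.list(composition),
                 background_rate = background_rate,
                 purine_stack_prob = purine_stack_prob, seed = seed)
  with_seed(seed, {
    gene_ids <- sprintf("gene%04d", seq_len(n_genes))
    tx_ids <- sprintf("tx%04d", seq_len(n_genes))
    seqs <- vapply(seq_len(n_genes), function(i)
      gen_background(utr_length, composition), character(1))
    plant_idx <- sample.int(n_genes, n_cde + n_ade)
    classes <- c(rep("CDE", n_cde), rep("ADE", n_ade))
    conserved_lab <- stats::runif(n_cde + n_ade) < conserved_fraction
    truth <- list()
    motifs_by_gene <- stats::setNames(vector("list", n_genes), tx_ids)
    for (p in seq_along(plant_idx)) {
      g <- plant_idx[p]
      spec <- plant_spec(classes[p], stem_len = sample(6:8, 1L),
                         purine_stack = stats::runif(1) < purine_stack_prob,
                         intended_conserved = conserved_lab[p])
      planted <- plant_motif(seqs[g], spec)
      seqs[g] <- planted$sequence
      m <- planted$motif
      m$parent_id <- tx_ids[g]
      m$motif_id <- sprintf("%s|%s|%d-%d", tx_ids[g], m$motif_class,
                            m$five_start, m$three_end)
      motifs_by_gene[[tx_ids[g]]] <- c(motifs_by_gene[[tx_ids[g]]], list(m))
      truth[[p]] <- data.frame(
        parent_id = tx_ids[g], gene_id = gene_ids[g],
        motif_class = classes[p],
        five_start = m$five_start, three_end = m$three_end,
        stem_len = m$stem_len, loop_seq = m$loop_seq,
        intended_conserved = conserved_lab[p], stringsAsFactors = FALSE)
    }
    truth_motifs <- if (length(truth)) do.call(rbind, truth) else
      data.frame(parent_id = character(), gene_id = character(),
                 motif_class = character(), five_start = integer(),
                 three_end = integer(), stem_len = integer(),
                 loop_seq = character(), intended_conserved = logical(),
                 stringsAsFactors = FALSE)
    blocks <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      ms <- motifs_by_gene[[tx_ids[g]]] %||% list()
      lab <- vapply(ms, function(m) {
        truth_motifs$intended_conserved[truth_motifs$parent_id == tx_ids[g] &
                                          truth_motifs$five_start == m$five_start]
      }, logical(1))
      sim <- gen_ortholog_alignment(seqs[g], ms, lab,
                                    background_rate = background_rate,
                                    parent_id = tx_ids[g])
      blocks[[g]] <- sim$block
    }
    records <- lapply(seq_len(n_genes), function(g)
      utr_record(tx_ids[g], seqs[g], gene_id = gene_ids[g]))
    truth_genes <- data.frame(
      gene_id = gene_ids, transcript_id = tx_ids,
      n_planted_cde = vapply(tx_ids, function(t)
        sum(truth_motifs$parent_id == t & truth_motifs$motif_class == "CDE"),
        integer(1)),
      n_planted_ade = vapply(tx_ids, function(t)
        sum(truth_motifs$parent_id == t & truth_motifs$motif_class == "ADE"),
        integer(1)),
      n_conserved_u3_cde = vapply(tx_ids, function(t)
        sum(truth_motifs$parent_id == t & truth_motifs$motif_class == "CDE" &
              truth_motifs$intended_conserved &
              substr(truth_motifs$loop_seq, 3L, 3L) == "U"), integer(1)),
      stringsAsFactors = FALSE, row.names = NULL)
    paths <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        fasta = file.path(dir, "utrs.fa"),
        maf = file.path(dir, "alignments.maf"),
        truth_motifs = file.path(dir, "truth_motifs.tsv"),
        truth_genes = file.path(dir, "truth_genes.tsv"),
        manifest = file.path(dir, "manifest.json")
      )
      write_fasta(records, paths$fasta)
      write_maf(blocks, paths$maf)
      utils::write.table(truth_motifs, paths$truth_motifs, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(truth_genes, paths$truth_genes, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      jsonlite::write_json(params, paths$manifest, auto_unbox = TRUE,
                           pretty = TRUE)
    }
    list(records = records, blocks = blocks, truth_motifs = truth_motifs,
         truth_genes = truth_genes, paths = paths, params = params)
  })
}
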