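# Thermodynamic ensemble interface: partition function, base-pair
# probabilities, MFE, exact motif formation probability, and the exhaustive
# enumeration oracle.  The dynamic programs live in src/thermo.cpp; the
# enumeration and the loop-decomposition energy evaluator are independent R
# implementations used to cross-check them.

#' Partition function, pair probabilities and MFE of an RNA sequence
#'
#' Computes the Boltzmann ensemble of pseudoknot-free secondary structures
#' (hairpin loops >= `model$min_hairpin`) under the nearest-neighbor model:
#' the partition function Z (empty structure has energy 0, so Z >= 1), the
#' base-pair probability matrix from the inside-outside decomposition, and
#' the minimum free energy structure.  Computations are scaled per
#' nucleotide, so kilobase contexts do not overflow; `logZ` is always
#' finite while `Z` itself may overflow to `Inf` for long stable sequences.
#'
#' @param seq RNA/DNA string; normalized internally ('N' positions never pair).
#' @param model an [energy_model()].
#' @param sequence_id identifier carried into the result.
#' @param pair_probs logical; set `FALSE` to skip the outside pass.
#' @return an object of class `ensemble_result` with elements `sequence_id`,
#'   `sequence`, `Z`, `logZ`, `pair_prob` (n x n symmetric matrix or NULL),
#'   `mfe_structure`, `mfe_energy`.
#' @export
partition_function <- function(seq, model = energy_model(), sequence_id = "seq",
                               pair_probs = TRUE) {
  s <- normalize_rna(seq, "mask_n")
  stopifnot(nchar(s) >= 1L)
  res <- cpp_partition(encode_seq(s), model$compiled, isTRUE(pair_probs))
  structure(list(
    sequence_id = sequence_id,
    sequence = s,
    Z = exp(res$logZ),
    logZ = res$logZ,
    pair_prob = res$pair_prob,
    mfe_structure = res$mfe_structure,
    mfe_energy = res$mfe_energy,
    parameter_set = model$parameter_set
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result '%s' (%d nt, %s): logZ = %.4f, MFE = %.2f kcal/mol>\n%s\n",
              x$sequence_id, nchar(x$sequence), x$parameter_set, x$logZ,
              x$mfe_energy, x$mfe_structure))
  invisible(x)
}

#' Minimum free energy structure
#'
#' @inheritParams partition_function
#' @return list with `structure` (dot-bracket) and `energy` (kcal/mol).
#'   The empty structure (energy 0) is part of the ensemble, so the MFE is
#'   never positive.
#' @export
mfe_structure <- function(seq, model = energy_model()) {
  s <- normalize_rna(seq, "mask_n")
  res <- cpp_mfe(encode_seq(s), model$compiled)
  list(structure = res$structure, energy = res$energy)
}

#' Exact formation probability of a hairpin motif in context
#'
#' The motif event is: every stem pair of the motif is formed and the apical
#' pair closes a hairpin whose loop is exactly the motif's loop nucleotides
#' (unpaired); anything may happen outside the footprint, including
#' enclosing helices.  Computed exactly as a ratio of the constrained to the
#' unconstrained partition function (the motif footprint is frozen as a
#' rigid element in the constrained run).
#'
#' If the full context exceeds `max_context` nt, folding is restricted to a
#' window of `window_size` nt centered on the motif (clamped to the
#' sequence); the window used is reported in the result.
#'
#' @param context RNA string the motif lives in.
#' @param motif a `hairpin_motif` (see [scan_motifs()]) with coordinates
#'   relative to `context`.
#' @param model an [energy_model()].
#' @param context_id identifier for reporting.
#' @param max_context fold the whole context when its length is <= this.
#' @param window_size centered window used beyond `max_context`.
#' @return list of class `motif_probability`: `motif_id`, `context_id`,
#'   `p_fold`, `context_start`, `context_end`.
#' @export
motif_fold_probability <- function(context, motif, model = energy_model(),
                                   context_id = "context",
                                   max_context = 1500L, window_size = 1000L) {
  s <- normalize_rna(context, "mask_n")
  n <- nchar(s)
  if (motif$five_start < 0L || motif$three_end > n) {
    stop("motif footprint outside context bounds", call. = FALSE)
  }
  if (n <= max_context) {
    cs <- 0L; ce <- n
  } else {
    mid <- (motif$five_start + motif$three_end) %/% 2L
    cs <- max(0L, mid - window_size %/% 2L)
    ce <- min(n, cs + window_size)
    cs <- max(0L, ce - window_size)
    if (motif$five_start < cs || motif$three_end > ce) {
      stop("motif footprint larger than the folding window", call. = FALSE)
    }
  }
  sub <- substr(s, cs + 1L, ce)
  p <- cpp_pfold(encode_seq(sub), model$compiled,
                 motif$five_start - cs, motif$three_end - 1L - cs,
                 motif$stem_len)
  structure(list(
    motif_id = motif$motif_id %||% "motif",
    context_id = context_id,
    p_fold = p,
    context_start = cs,
    context_end = ce
  ), class = "motif_probability")
}

#' Folding probabilities for several motifs sharing one context
#'
#' Batch form of [motif_fold_probability()]: the unconstrained ensemble of
#' the context is computed once and reused for every motif.  All motifs are
#' folded in the full context (no windowing), so use this for contexts
#' within the full-UTR folding limit.
#'
#' @param context RNA string.
#' @param motifs list of `hairpin_motif` with coordinates in `context`.
#' @param model an [energy_model()].
#' @return numeric vector of p_fold values, one per motif.
#' @export
motif_fold_probabilities <- function(context, motifs, model = energy_model()) {
  if (!length(motifs)) return(numeric(0))
  s <- normalize_rna(context, "mask_n")
  coords <- t(vapply(motifs, function(m)
    c(m$five_start, m$three_end - 1L, m$stem_len), integer(3)))
  cpp_pfold_multi(encode_seq(s), model$compiled, coords)
}

# ----------------------------------------------------------------------------
# Exhaustive enumeration oracle
# ----------------------------------------------------------------------------

#' Enumerate every pseudoknot-free structure of a short sequence
#'
#' Validation oracle: lists each structure (hairpin loops >=
#' `model$min_hairpin`, pairs legal under the model) exactly once, with its
#' loop-decomposition free energy and Boltzmann weight.  Refuses sequences
#' longer than `cap` to bound the exponential enumeration.
#'
#' @inheritParams partition_function
#' @param cap maximum sequence length (default 22).
#' @return data.frame with columns `structure`, `energy`, `weight`.
#' @export
enumerate_structures <- function(seq, model = energy_model(), cap = 22L) {
  s <- normalize_rna(seq, "mask_n")
  n <- nchar(s)
  if (n > cap) {
    stop(sprintf("sequence length %d exceeds enumeration cap %d", n, cap),
         call. = FALSE)
  }
  ch <- seq_chars(s)
  mh <- model$min_hairpin
  ok <- function(a, b) model_can_pair(model, ch[a], ch[b])
  memo <- new.env(parent = emptyenv())
  # list of integer pair matrices (2 x k), positions 1-based
  structs <- function(i, j) {
    if (i > j) return(list(matrix(integer(), 2)))
    key <- paste0(i, ",", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- structs(i + 1L, j)  # i unpaired
    if (i + mh + 1L <= j) {
      for (l in seq.int(i + mh + 1L, j)) {
        if (!ok(i, l)) next
        inner <- structs(i + 1L, l - 1L)
        outer <- structs(l + 1L, j)
        for (si in inner) for (so in outer) {
          out[[length(out) + 1L]] <- cbind(c(i, l), si, so)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  all <- structs(1L, n)
  db <- vapply(all, function(p) {
    x <- rep(".", n)
    if (ncol(p)) { x[p[1L, ]] <- "("; x[p[2L, ]] <- ")" }
    paste(x, collapse = "")
  }, character(1))
  energy <- vapply(db, function(d) structure_energy(s, d, model), numeric(1),
                   USE.NAMES = FALSE)
  weight <- exp(-energy / model$RT)
  data.frame(structure = db, energy = energy, weight = weight,
             stringsAsFactors = FALSE)
}

#' Dot-bracket string to partner vector
#' @param db dot-bracket string.
#' @return integer vector, `partner[i]` = 1-based partner of position i or NA.
#' @export
parse_dotbracket <- function(db) {
  ch <- seq_chars(db)
  partner <- rep(NA_integer_, length(ch))
  stack <- integer()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[j] <- i
      partner[i] <- j
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket", call. = FALSE)
  partner
}

model_loop_tab <- function(model, tab, L) {
  if (L <= 30L) return(tab[L])
  tab[30L] + model$js_coef * log(L / 30)
}

#' Free energy of a given secondary structure (loop decomposition)
#'
#' Independent R implementation of the nearest-neighbor energy rules used by
#' the dynamic programs; serves as the oracle route in tests.
#'
#' @param seq RNA string.
#' @param db dot-bracket structure of the same length.
#' @param model an [energy_model()].
#' @return free energy in kcal/mol.
#' @export
structure_energy <- function(seq, db, model = energy_model()) {
  s <- seq_chars(normalize_rna(seq, "mask_n"))
  stopifnot(length(s) == nchar(db))
  partner <- parse_dotbracket(db)
  au <- function(i, j) {
    if (paste0(s[i], s[j]) %in% c("AU", "UA", "GU", "UG")) model$terminal_au else 0
  }
  pair_str <- function(i, j) paste0(s[i], s[j])
  stack_e <- function(i, j, k, l) model$stack[pair_str(i, j), pair_str(k, l)]
  children_of <- function(a, b) {
    kids <- list()
    k <- a
    while (k <= b) {
      if (!is.na(partner[k]) && partner[k] > k) {
        kids[[length(kids) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else k <- k + 1L
    }
    kids
  }
  e <- 0
  opens <- which(!is.na(partner) & partner > seq_along(s))
  for (i in opens) {
    j <- partner[i]
    kids <- children_of(i + 1L, j - 1L)
    if (length(kids) == 0L) {
      e <- e + model_loop_tab(model, model$hairpin, j - i - 1L) + au(i, j)
    } else if (length(kids) == 1L) {
      k <- kids[[1L]][1L]; l <- kids[[1L]][2L]
      n1 <- k - i - 1L; n2 <- j - l - 1L
      if (n1 == 0L && n2 == 0L) {
        e <- e + stack_e(i, j, k, l)
      } else if (n1 == 0L || n2 == 0L) {
        if (n1 + n2 == 1L) {
          e <- e + model$bulge[1L] + stack_e(i, j, k, l)
        } else {
          e <- e + model_loop_tab(model, model$bulge, n1 + n2) + au(i, j) + au(k, l)
        }
      } else {
        asym <- min(model$asym_max, model$asym_coef * abs(n1 - n2))
        e <- e + model_loop_tab(model, model$internal, n1 + n2) + asym +
          au(i, j) + au(k, l)
      }
    } else {
      unpaired <- (j - i - 1L) - sum(vapply(kids, function(p) p[2L] - p[1L] + 1L,
                                            integer(1)))
      e <- e + model$ml_closing + model$ml_branch + au(i, j) +
        model$ml_unpaired * unpaired +
        sum(vapply(kids, function(p) model$ml_branch + au(p[1L], p[2L]),
                   numeric(1)))
    }
  }
  for (p in children_of(1L, length(s))) e <- e + au(p[1L], p[2L])
  e
}
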