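# Independent oracles used across the suite.  These deliberately share no
# code with the implementation paths they check.

# Brute-force hairpin scan: test every (five_start, stem_len) pair directly
# against the sequence, then keep the largest stem per loop register.
brute_force_scan <- function(seq, descriptor) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  L <- nchar(descriptor$loop_consensus)
  cons <- strsplit(descriptor$loop_consensus, "")[[1]]
  iupac <- list(A = "A", C = "C", G = "G", U = "U",
                R = c("A", "G"), Y = c("C", "U"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "U"))
  pair_set <- c("AU", "UA", "CG", "GC")
  if (descriptor$allow_wobble) pair_set <- c(pair_set, "GU", "UG")
  hits <- list()
  for (fs in 0:(n - 1)) {
    for (k in descriptor$stem_min:descriptor$stem_max) {
      te <- fs + 2 * k + L
      if (te > n) next
      idx5 <- (fs + 1):(fs + k)
      idx3 <- (fs + k + L + 1):(fs + 2 * k + L)
      pairs_ok <- all(paste0(ch[idx5], rev(ch[idx3])) %in% pair_set)
      if (!pairs_ok) next
      loop <- ch[(fs + k + 1):(fs + k + L)]
      loop_ok <- all(vapply(seq_len(L), function(t)
        loop[t] %in% iupac[[cons[t]]], logical(1)))
      if (!loop_ok) next
      hits[[length(hits) + 1]] <- c(register = fs + k, five_start = fs,
                                    stem_len = k)
    }
  }
  if (!length(hits)) return(data.frame(five_start = integer(),
                                       stem_len = integer()))
  h <- as.data.frame(do.call(rbind, hits))
  # per register keep the largest stem (<= stem_max)
  out <- do.call(rbind, lapply(split(h, h$register), function(g)
    g[which.max(g$stem_len), c("five_start", "stem_len")]))
  if (descriptor$reject_extendable) {
    keep <- vapply(seq_len(nrow(out)), function(r) {
      fs <- out$five_start[r]; k <- out$stem_len[r]
      if (k < descriptor$stem_max) return(TRUE)  # maximality implies no extension
      i5 <- fs; i3 <- fs + 2 * k + L + 1
      if (i5 < 1 || i3 > n) return(TRUE)
      !(paste0(ch[i5], ch[i3]) %in% pair_set)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  out <- out[order(out$five_start, -out$stem_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

scan_as_df <- function(motifs) {
  if (!length(motifs)) return(data.frame(five_start = integer(),
                                         stem_len = integer()))
  data.frame(five_start = vapply(motifs, `[[`, integer(1), "five_start"),
             stem_len = vapply(motifs, `[[`, integer(1), "stem_len"))
}

# Independent count of pseudoknot-free pair sets (loops >= mh), memoized.
count_structures <- function(seq, model) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  mh <- model$min_hairpin
  memo <- new.env(parent = emptyenv())
  cnt <- function(i, j) {
    if (i >= j) return(1)
    key <- paste0(i, ":", j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    total <- cnt(i + 1, j)
    if (i + mh + 1 <= j) {
      for (l in seq.int(i + mh + 1, j)) {
        if (model_can_pair(model, ch[i], ch[l])) {
          total <- total + cnt(i + 1, l - 1) * cnt(l + 1, j)
        }
      }
    }
    memo[[key]] <- total
    total
  }
  if (n < mh + 2) return(1)
  cnt(1, n)
}

# Pair-probability matrix and motif fold probabilities from an enumeration
# data.frame (single parse per structure).
enum_pair_probs <- function(seqlen, enum) {
  Z <- sum(enum$weight)
  mat <- matrix(0, seqlen, seqlen)
  partners <- lapply(enum$structure, parse_dotbracket)
  for (s in seq_along(partners)) {
    p <- partners[[s]]
    op <- which(!is.na(p) & p > seq_along(p))
    for (i in op) {
      mat[i, p[i]] <- mat[i, p[i]] + enum$weight[s]
      mat[p[i], i] <- mat[p[i], i] + enum$weight[s]
    }
  }
  mat / Z
}

enum_pfold <- function(enum, motif) {
  Z <- sum(enum$weight)
  a <- motif$five_start + 1; b <- motif$three_end; sl <- motif$stem_len
  w <- 0
  for (s in seq_len(nrow(enum))) {
    p <- parse_dotbracket(enum$structure[s])
    ok <- TRUE
    for (k in 0:(sl - 1)) {
      if (is.na(p[a + k]) || p[a + k] != b - k) { ok <- FALSE; break }
    }
    if (ok) {
      loop <- (a + sl):(b - sl)
      ok <- all(is.na(p[loop]))
    }
    if (ok) w <- w + enum$weight[s]
  }
  w / Z
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                                collapse = "")

# small identity alignment slice for a motif (all species equal to human)
identity_slice <- function(motif, species = c("chimp", "mouse", "dog", "cow")) {
  seqs <- stats::setNames(rep(motif_sequence(motif), length(species) + 1),
                          c("human", species))
  structure(list(motif_id = motif$motif_id, rows = seqs, reference = "human",
                 ref_start = motif$five_start, ref_end = motif$three_end),
            class = "alignment_slice")
}

# mutate one motif position in a slice row (1-based within footprint)
mutate_row <- function(slice, species, pos, base) {
  s <- strsplit(slice$rows[[species]], "")[[1]]
  s[pos] <- base
  slice$rows[[species]] <- paste(s, collapse = "")
  slice
}
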