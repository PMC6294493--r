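# Shared sequence utilities: alphabet normalization, pairing predicates,
# IUPAC consensus matching.  All coordinates in the package are 0-based,
# half-open; conversion to 1-based R indexing happens locally.

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and maps T to U. Under `strict` policy any character outside
#' A/C/G/U/N/T aborts with the offending record position; under `mask_n`
#' such characters are replaced by `N` (which can never pair and never
#' matches a consensus letter).
#'
#' @param x character scalar, nucleotide sequence (DNA or RNA).
#' @param alphabet_policy `"strict"` or `"mask_n"`.
#' @param id identifier used in error messages.
#' @return normalized RNA string over A/C/G/U/N.
#' @export
normalize_rna <- function(x, alphabet_policy = c("strict", "mask_n"), id = "sequence") {
  alphabet_policy <- match.arg(alphabet_policy)
  stopifnot(is.character(x), length(x) == 1L)
  s <- chartr("t", "u", toupper(x))
  s <- chartr("T", "U", s)
  bad <- regexpr("[^ACGUN]", s)
  if (bad > 0L) {
    if (alphabet_policy == "strict") {
      stop(sprintf("record '%s': invalid character '%s' at position %d",
                   id, substr(s, bad, bad), bad), call. = FALSE)
    }
    s <- gsub("[^ACGUN]", "N", s)
  }
  s
}

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

#' Test whether two bases can pair
#'
#' @param a,b single upper-case RNA bases (vectorized).
#' @param allow_wobble logical; if `TRUE`, G·U and U·G count as pairs in
#'   addition to Watson-Crick. `N` never pairs.
#' @return logical vector.
#' @export
can_pair <- function(a, b, allow_wobble = FALSE) {
  wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
        (a == "C" & b == "G") | (a == "G" & b == "C")
  if (!allow_wobble) return(wc)
  wc | (a == "G" & b == "U") | (a == "U" & b == "G")
}

is_wobble_pair <- function(a, b) (a == "G" & b == "U") | (a == "U" & b == "G")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U", T = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Match a sequence against an IUPAC consensus
#'
#' Position-wise membership test; an `N` *base* in the query matches no
#' consensus letter (unknown bases cannot be claimed to fit a motif).
#'
#' @param seq RNA string.
#' @param consensus IUPAC string of the same length.
#' @return logical scalar.
#' @export
matches_iupac <- function(seq, consensus) {
  if (nchar(seq) != nchar(consensus)) return(FALSE)
  sc <- seq_chars(seq)
  cc <- seq_chars(consensus)
  for (k in seq_along(sc)) {
    set <- IUPAC_SETS[[cc[k]]]
    if (is.null(set)) stop("unknown IUPAC letter: ", cc[k], call. = FALSE)
    if (sc[k] == "N" || !(sc[k] %in% set)) return(FALSE)
  }
  TRUE
}

#' Reverse-complement an RNA string (Watson-Crick)
#' @param s RNA string.
#' @return RNA string.
#' @export
rna_revcomp <- function(s) {
  paste(rev(seq_chars(chartr("ACGU", "UGCA", s))), collapse = "")
}

wc_partner <- function(b) chartr("ACGU", "UGCA", b)

is_purine <- function(b) b %in% c("A", "G")
is_pyrimidine <- function(b) b %in% c("C", "U")

`%||%` <- function(a, b) if (is.null(a)) b else a
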