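# SYNTHETIC stand-ins for published reference sequences.
#
# The package's worked examples refer to real 3'UTRs (a 1131-nt UTR carrying
# a tandem CDE, and UTRs of known Roquin targets).  Those sequences cannot
# be redistributed or fetched at build time, so the functions below
# construct synthetic stand-ins from their published *verbal* descriptions:
# element sizes, stem compositions, loop sequences, closing pairs, AU
# content.  They are NOT the real sequences; every identifier says so.
# Construction choices were fixed before any folding probability was
# computed and are not tuned to reproduce published numbers.

hairpin_text <- function(pairs, loop) {
  arm5 <- paste(substr(pairs, 1L, 1L), collapse = "")
  arm3 <- paste(rev(substr(pairs, 2L, 2L)), collapse = "")
  paste0(arm5, loop, arm3)
}

#' Synthetic stand-in for the UCP3-like tandem-CDE 3'UTR
#'
#' A 1131-nt synthetic UTR containing a 64-nt repressive element with two
#' tandem CDEs built from the published description: CDEI has a 6-bp stem
#' of A-U pairs only with a UAU triloop and an A-U closing pair; CDEII has
#' a 6-bp mixed stem with an A-U closing pair and a purine stack on the 3'
#' arm; the element is ~72% AU; the two footprints are 10 nt apart.  The
#' rest of the UTR is AU-rich iid background (fixed seed).
#'
#' @return list: `record` (a [utr_record()]), `element_start` (0-based),
#'   `cde1`, `cde2` (0-based half-open footprints as length-2 integers).
#' @export
ucp3_synthetic_utr <- function() {
  cde1 <- hairpin_text(c("UA", "AU", "UA", "AU", "UA", "AU"), "UAU")
  cde2 <- hairpin_text(c("UA", "CG", "CG", "UA", "GC", "AU"), "UAU")
  element <- paste0("ACCAUCUC", cde1, "AUUCCAUAAC", cde2,
                    "CAUCAAUUCUUAUUCA")
  stopifnot(nchar(element) == 64L)
  bg <- gen_background(1131L,
                       composition = c(A = 0.35, C = 0.15, G = 0.15, U = 0.35),
                       seed = 20181008L)
  e0 <- 500L
  seqn <- paste0(substr(bg, 1L, e0), element, substr(bg, e0 + 65L, 1131L))
  stopifnot(nchar(seqn) == 1131L)
  rec <- utr_record("UCP3-SYNTHETIC-STANDIN", seqn, gene_id = "UCP3_synthetic")
  list(record = rec,
       element_start = e0,
       cde1 = c(e0 + 8L, e0 + 23L),
       cde2 = c(e0 + 33L, e0 + 48L))
}

#' Synthetic stand-ins for known-CDE 3'UTRs
#'
#' Three ~800-nt synthetic UTRs each carrying one CDE-like hairpin built
#' from published verbal descriptions of known Roquin-bound CDEs (YRY-type
#' triloop, Y-R pairs in the apical stem, a 3' purine stack for the
#' TNF-like element; mixed stems for the others).  Not the real sequences.
#'
#' @return list of lists: `record`, `cde` (0-based half-open footprint).
#' @export
known_cde_synthetic_utrs <- function() {
  designs <- list(
    TNF_like  = list(pairs = c("GC", "AU", "GC", "UA", "CG", "UA"),
                     loop = "UAU", seed = 1001L),
    Ox40_like = list(pairs = c("AU", "GC", "UA", "AU", "CG", "UA"),
                     loop = "CAU", seed = 1002L),
    ICOS_like = list(pairs = c("UA", "AU", "CG", "AU", "GC", "CG"),
                     loop = "UAU", seed = 1003L)
  )
  lapply(names(designs), function(nm) {
    d <- designs[[nm]]
    hp <- hairpin_text(d$pairs, d$loop)
    bg <- gen_background(800L,
                         composition = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                         seed = d$seed)
    e0 <- 400L
    # non-pairing flanks so the planted stem length is exact
    seqn <- paste0(substr(bg, 1L, e0 - 1L), "C", hp, "C",
                   substr(bg, e0 + nchar(hp) + 2L, 800L))
    stopifnot(nchar(seqn) == 800L)
    list(record = utr_record(paste0(nm, "-SYNTHETIC-STANDIN"), seqn,
                             gene_id = paste0(nm, "_synthetic")),
         cde = c(e0, e0 + nchar(hp)))
  }) |> stats::setNames(names(designs))
}
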