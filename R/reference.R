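#' Synthetic mitogenome reference in rCRS coordinates
#'
#' Returns a deterministic, synthetic 16,569-bp nucleotide sequence used as
#' the default reference throughout the package. It is coordinate-compatible
#' with rCRS numbering (positions 1--16,569; control region 16,024--16,569
#' and 1--576) and has a realistic human-mtDNA base composition, but it is
#' *not* the revised Cambridge Reference Sequence itself: analyses of real
#' data should pass the genuine rCRS through the `reference` argument of the
#' scoring functions. The synthetic sequence is generated by a fixed linear
#' congruential stream, so it is identical across machines and sessions and
#' independent of R's random number generator state.
#'
#' @return A single upper-case character string of length 16,569.
#' @examples
#' nchar(mito_reference())
#' substr(mito_reference(), 1, 20)
#' @export
mito_reference <- function() {
  if (!is.null(.mf_cache$reference)) return(.mf_cache$reference)
  n <- 16569L
  # fixed LCG (Numerical Recipes constants), seeded once; not R's RNG
  state <- 20160213
  draws <- numeric(n)
  a <- 1664525; cmod <- 2^32; cc <- 1013904223
  for (i in seq_len(n)) {
    state <- (a * state + cc) %% cmod
    draws[i] <- state / cmod
  }
  # human mtDNA L-strand composition: A .309, C .313, G .131, T .247
  cuts <- cumsum(c(A = 0.309, C = 0.313, G = 0.131, T = 0.247))
  bases <- c("A", "C", "G", "T")[findInterval(draws, c(0, cuts[-4])) ]
  .mf_cache$reference <- paste(bases, collapse = "")
  .mf_cache$reference
}

#' Mitochondrial gene map (rCRS coordinates)
#'
#' The standard human mitogenome annotation used for functional
#' classification of variants: protein-coding genes, rRNAs, tRNAs and the
#' control region, with 1-based closed intervals on rCRS numbering and the
#' coding strand (`"+"` heavy-strand numbering direction, `"-"` for ND6 and
#' the light-strand tRNAs). Overlapping genes (ATP8/ATP6, ND4L/ND4) are both
#' listed; classification uses the first matching row.
#'
#' @return A data frame with columns `gene`, `type`
#'   (`protein`/`rRNA`/`tRNA`/`control`), `start`, `end`, `strand`.
#' @examples
#' head(mito_gene_map())
#' @export
mito_gene_map <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
gene type start end strand
CR_a control 1 576 +
TRNF tRNA 577 647 +
RNR1 rRNA 648 1601 +
TRNV tRNA 1602 1670 +
RNR2 rRNA 1671 3229 +
TRNL1 tRNA 3230 3304 +
ND1 protein 3307 4262 +
TRNI tRNA 4263 4331 +
TRNQ tRNA 4329 4400 -
TRNM tRNA 4402 4469 +
ND2 protein 4470 5511 +
TRNW tRNA 5512 5579 +
TRNA tRNA 5587 5655 -
TRNN tRNA 5657 5729 -
TRNC tRNA 5761 5826 -
TRNY tRNA 5826 5891 -
CO1 protein 5904 7445 +
TRNS1 tRNA 7446 7514 -
TRND tRNA 7518 7585 +
CO2 protein 7586 8269 +
TRNK tRNA 8295 8364 +
ATP8 protein 8366 8572 +
ATP6 protein 8527 9207 +
CO3 protein 9207 9990 +
TRNG tRNA 9991 10058 +
ND3 protein 10059 10404 +
TRNR tRNA 10405 10469 +
ND4L protein 10470 10766 +
ND4 protein 10760 12137 +
TRNH tRNA 12138 12206 +
TRNS2 tRNA 12207 12265 +
TRNL2 tRNA 12266 12336 +
ND5 protein 12337 14148 +
ND6 protein 14149 14673 -
TRNE tRNA 14674 14742 -
CYB protein 14747 15887 +
TRNT tRNA 15888 15953 +
TRNP tRNA 15956 16023 -
CR_b control 16024 16569 +
")
  df
}

# vertebrate mitochondrial genetic code, as a named vector codon -> AA
.mito_code <- function() {
  if (is.null(.mf_cache$code)) {
    gc2 <- Biostrings::getGeneticCode("2")  # Vertebrate Mitochondrial
    .mf_cache$code <- gc2
  }
  .mf_cache$code
}

.complement <- function(x) {
  chartr("ACGTRYKMBDHVacgtrykmbdhv", "TGCAYRMKVHDBtgcayrmkvhdb", x)
}

.rev_comp <- function(x) {
  paste(rev(strsplit(.complement(x), "", fixed = TRUE)[[1]]), collapse = "")
}
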