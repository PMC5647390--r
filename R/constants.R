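# Internal scoring constants shared by the alignment engine.

#' @importFrom utils data
NULL

## Fixed residue order used throughout the engine; integer codes 1..20
## index rows/columns of the substitution matrix and PSSM columns.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## BLOSUM62 restricted to the 20 standard residues, in AA20 order.
## Evaluated at install time from the matrix shipped with Biostrings.
BLOSUM62_20 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  storage.mode(m) <- "double"
  m
})

## Robinson & Robinson amino-acid background frequencies (the background
## model BLAST uses for BLOSUM-series matrices), in AA20 order.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

## Karlin-Altschul parameters for gapped BLOSUM62 with gap penalties
## 11/1 (the values BLAST applies to this scoring scheme). The engine's
## alignments are gapped, so the gapped constants keep E <= 0.1
## meaning what it says; the ungapped pair (0.3176, 0.134) understates
## E for gapped scores and admits chance hits well past the nominal
## threshold.
KA_LAMBDA <- 0.267
KA_K <- 0.041

## Bacterial/plastid genetic code (NCBI translation table 11).
GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Encode a protein string as integer codes 1..20 (AA20 order).
## Non-standard residues raise a validation error.
aa_encode <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  idx <- match(ch, AA20)
  if (anyNA(idx)) {
    bad <- unique(ch[is.na(idx)])
    stop("non-standard amino-acid residue(s): ", paste(bad, collapse = ", "))
  }
  idx
}

aa_decode <- function(idx) paste(AA20[idx], collapse = "")
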