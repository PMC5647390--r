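# Naive six-frame ORF detection with alternative start codons, the
# longest-variant rule, and bacterial (table 11) translation.

#' Find open reading frames in a contig set
#'
#' Scans all six reading frames for ORFs: a qualifying start codon
#' followed in-frame by a stop codon (TAA/TAG/TGA) with no intervening
#' stop. Per (strand, frame, stop position) only the longest variant --
#' the most upstream qualifying start after the previous in-frame stop --
#' is returned, and every reported ORF spans at least `min_orf_len_nt`
#' nucleotides measured start through stop codon inclusive. ORFs whose
#' span contains an N are skipped. Alternative start codons (ATA, ATC,
#' ATT, CTG, GTG, TTG by default) are honoured and rendered as Met at the
#' initiator position.
#'
#' @param contigs a `DNAStringSet` from [readAssembly()] or
#'   [makeContigSet()].
#' @param config a [PipelineConfig-class].
#' @return A `GRanges` (1-based inclusive coordinates on the forward
#'   strand of the stored contig, strand flag for orientation) ordered by
#'   (contig, strand, start) with metadata columns `orf_id`, `strain_id`,
#'   `protein` (stop excluded, initial residue M), `start_codon`,
#'   `nt_len`.
#' @examples
#' ctg <- makeContigSet(paste0("ATG", strrep("GCT", 32), "TAA"),
#'                      "c1", "strainA")
#' findOrfs(ctg, pipelineConfig())
#' @export
findOrfs <- function(contigs, config = pipelineConfig()) {
  stopifnot(is(config, "PipelineConfig"))
  res <- list()
  strains <- S4Vectors::mcols(contigs)$strain_id
  if (is.null(strains)) strains <- rep("", length(contigs))
  for (k in seq_along(contigs)) {
    cid <- names(contigs)[k]
    fwd <- as.character(contigs[[k]])
    L <- nchar(fwd)
    rev <- as.character(reverseComplement(contigs[[k]]))
    plus <- .scanStrand(fwd, config)
    minus <- .scanStrand(rev, config)
    if (nrow(plus)) {
      plus$strand <- "+"
    }
    if (nrow(minus)) {
      ## map coordinates on the reverse complement back to the forward
      ## strand of the stored contig
      s <- L - minus$end + 1L
      e <- L - minus$start + 1L
      minus$start <- s
      minus$end <- e
      minus$strand <- "-"
    }
    both <- rbind(plus, minus)
    if (nrow(both) == 0L) next
    both$contig_id <- cid
    both$strain_id <- strains[k]
    res[[length(res) + 1L]] <- both
  }
  if (length(res) == 0L) return(.emptyOrfGRanges())
  df <- do.call(rbind, res)
  df <- df[order(df$contig_id, df$strand, df$start), , drop = FALSE]
  gr <- GRanges(df$contig_id, IRanges(df$start, df$end),
                strand = df$strand)
  mcols(gr) <- DataFrame(
    orf_id = paste(df$strain_id, df$contig_id, df$strand, df$start,
                   df$end, sep = "|"),
    strain_id = df$strain_id, protein = df$protein,
    start_codon = df$start_codon, nt_len = df$end - df$start + 1L)
  gr
}

.emptyOrfGRanges <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(orf_id = character(), strain_id = character(),
                         protein = character(), start_codon = character(),
                         nt_len = integer())
  gr
}

## Scan the three forward frames of one strand's sequence. Returns a
## data.frame with 1-based inclusive start/end on that strand, protein,
## and start codon.
.scanStrand <- function(seq, config) {
  L <- nchar(seq)
  out <- list()
  min_cod <- ceiling(config@min_orf_len_nt / 3)
  for (f in 0:2) {
    n_cod <- (L - f) %/% 3L
    if (n_cod < min_cod) next
    pos1 <- f + 3L * (seq_len(n_cod) - 1L) + 1L
    codons <- substring(seq, pos1, pos1 + 2L)
    is_stop <- codons %in% STOP_CODONS
    stop_idx <- which(is_stop)
    if (length(stop_idx) == 0L) next
    start_idx <- which(codons %in% config@start_codons)
    if (length(start_idx) == 0L) next
    has_n <- grepl("N", codons, fixed = TRUE)
    cum_n <- cumsum(has_n)
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    ## most upstream qualifying start strictly after the previous stop
    cand <- findInterval(prev_stop, start_idx) + 1L
    for (t in seq_along(stop_idx)) {
      if (cand[t] > length(start_idx)) next
      a <- start_idx[cand[t]]
      s <- stop_idx[t]
      if (a >= s) next
      nt_len <- 3L * (s - a + 1L)
      if (nt_len < config@min_orf_len_nt) next
      n_inside <- cum_n[s] - if (a > 1L) cum_n[a - 1L] else 0L
      if (n_inside > 0L) next
      orf_nt <- substr(seq, pos1[a], pos1[s] + 2L)
      prot <- translateOrf(orf_nt, config@translation_table)
      out[[length(out) + 1L]] <- data.frame(
        start = pos1[a], end = pos1[s] + 2L, protein = prot,
        start_codon = codons[a], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      protein = character(), start_codon = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Translate an ORF nucleotide sequence
#'
#' Translates with the bacterial genetic code (NCBI table 11 by default).
#' The initiator codon is rendered as M regardless of identity -- the
#' table-11 convention for alternative starts -- internal codons follow
#' the table, and the trailing stop codon is dropped.
#'
#' @param orf_nt DNA string whose length is divisible by 3 and whose
#'   final codon is a stop.
#' @param table NCBI genetic code id (default 11).
#' @return The protein string (no stop symbol, initial residue M).
#' @examples
#' translateOrf("TTGAAATAA")  # "MK": TTG initiator reads as Met
#' @export
translateOrf <- function(orf_nt, table = 11L) {
  orf_nt <- toupper(orf_nt)
  n <- nchar(orf_nt)
  if (n %% 3L != 0L) stop("ORF length must be divisible by 3")
  code <- if (table == 11L) GENETIC_CODE_11 else
    getGeneticCode(as.character(table))
  pos <- seq(1L, n, by = 3L)
  codons <- substring(orf_nt, pos, pos + 2L)
  last <- codons[length(codons)]
  if (!last %in% STOP_CODONS)
    stop("final codon must be a stop codon, got ", last)
  body <- codons[-length(codons)]
  aa <- unname(code[body])
  if (anyNA(aa))
    stop("untranslatable codon(s): ",
         paste(unique(body[is.na(aa)]), collapse = ", "))
  if (any(aa == "*"))
    stop("internal stop codon at codon ", which(aa == "*")[1],
         " contradicts the ORF definition")
  aa[1] <- "M"
  paste(aa, collapse = "")
}
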