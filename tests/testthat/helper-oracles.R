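# Independent brute-force oracles used to validate the alignment engine
# and the ORF finder. These are deliberately simple, loop-based
# implementations that share no code with the package internals.

ORACLE_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62[ORACLE_AA, ORACLE_AA]
})

## Plain-R Gotoh local alignment with traceback. A gap of length L costs
## open + L * ext. Returns score and per-column identity/similarity
## counts (gap columns count toward length only).
oracle_sw <- function(q, s, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  m <- length(qc); n <- length(sc)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    F_[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F_[i, j + 1] - ext)
    sub <- oracle_blosum62[qc[i], sc[j]]
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                           F_[i + 1, j + 1])
  }
  best <- max(H)
  idx <- which(H == best, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  pos <- idx[1, ] # earliest maximal cell in row-major order
  i <- pos[1] - 1; j <- pos[2] - 1
  n_id <- 0; n_pos <- 0; aln_len <- 0
  state <- "H"
  while (i > 0 && j > 0) {
    if (state == "H") {
      h <- H[i + 1, j + 1]
      if (h == 0) break
      sub <- oracle_blosum62[qc[i], sc[j]]
      if (h == H[i, j] + sub) {
        aln_len <- aln_len + 1
        if (qc[i] == sc[j]) n_id <- n_id + 1
        if (sub > 0) n_pos <- n_pos + 1
        i <- i - 1; j <- j - 1
      } else if (h == E[i + 1, j + 1]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      aln_len <- aln_len + 1
      if (E[i + 1, j + 1] == H[i + 1, j] - open - ext) state <- "H"
      j <- j - 1
    } else {
      aln_len <- aln_len + 1
      if (F_[i + 1, j + 1] == H[i, j + 1] - open - ext) state <- "H"
      i <- i - 1
    }
  }
  list(score = best, n_id = n_id, n_pos = n_pos, aln_len = aln_len)
}

## Plain-R local profile alignment (score only).
oracle_profile_score <- function(weights, s, open = 11, ext = 1) {
  sc <- strsplit(s, "")[[1]]
  m <- nrow(weights); n <- length(sc)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F_ <- matrix(NEG, m + 1, n + 1)
  for (i in 1:m) for (j in 1:n) {
    E[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, E[i + 1, j] - ext)
    F_[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, F_[i, j + 1] - ext)
    sub <- weights[i, match(sc[j], ORACLE_AA)]
    H[i + 1, j + 1] <- max(0, H[i, j] + sub, E[i + 1, j + 1],
                           F_[i + 1, j + 1])
  }
  max(H)
}

## Brute-force six-frame ORF enumeration: every position is tested as a
## start codon directly; the in-frame scan reports the first stop. The
## longest-variant rule is applied afterwards by grouping on (strand,
## frame, stop).
oracle_orfs <- function(seq, min_len = 100,
                        starts = c("ATA", "ATC", "ATG", "ATT", "CTG",
                                   "GTG", "TTG")) {
  revcomp <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  scan <- function(sq) {
    L <- nchar(sq)
    out <- NULL
    for (p in 1:max(L - 5, 1)) {
      if (!substr(sq, p, p + 2) %in% starts) next
      q <- p + 3
      while (q + 2 <= L) {
        codon <- substr(sq, q, q + 2)
        if (codon %in% stops) {
          len <- q + 2 - p + 1
          orf <- substr(sq, p, q + 2)
          if (len >= min_len && !grepl("N", orf))
            out <- rbind(out, data.frame(start = p, end = q + 2,
                                         len = len))
          break
        }
        q <- q + 3
      }
    }
    out
  }
  longest_variants <- function(df) {
    if (is.null(df)) return(NULL)
    df$frame <- df$start %% 3
    keep <- do.call(rbind, lapply(split(df, paste(df$frame, df$end)),
                                  function(g) g[which.min(g$start), ]))
    keep
  }
  fwd <- longest_variants(scan(seq))
  if (!is.null(fwd)) fwd$strand <- "+"
  L <- nchar(seq)
  rev_ <- longest_variants(scan(revcomp(seq)))
  if (!is.null(rev_)) {
    s2 <- L - rev_$end + 1
    e2 <- L - rev_$start + 1
    rev_$start <- s2
    rev_$end <- e2
    rev_$strand <- "-"
  }
  out <- rbind(fwd, rev_)
  if (is.null(out)) return(data.frame(start = integer(), end = integer(),
                                      strand = character()))
  out[order(out$strand, out$start, out$end),
      c("start", "end", "strand")]
}

random_protein_chr <- function(len) {
  paste(c("M", sample(ORACLE_AA, len - 1, replace = TRUE)),
        collapse = "")
}

random_dna <- function(len, gc = 0.33) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
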