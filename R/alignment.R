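# Alignment engine: exact local alignment, E-value estimation, PSSM
# construction and search, identity/coverage clustering. This is the
# computational substrate shared by all five TA search strategies.

#' @useDynLib taMiner, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Internal: batch Smith-Waterman of one encoded query against a list of
## encoded subjects; returns the raw stats matrix from the C++ core.
.alignBatch <- function(q_int, subj_int_list, gap_open, gap_extend) {
  .C_sw_batch(q_int, subj_int_list, BLOSUM62_20, gap_open, gap_extend)
}

#' Optimal local alignment of two protein sequences
#'
#' Computes the exact Smith-Waterman local alignment under BLOSUM62 with
#' affine gap penalties (a gap of length L costs `gap_open + L *
#' gap_extend`). Identity and similarity are fractions of aligned columns:
#' gap columns count toward the alignment length but never toward identity
#' or similarity (the BLAST "Identities"/"Positives" convention).
#'
#' @param query,subject protein sequences (standard 20-letter alphabet).
#' @param query_id,subject_id identifiers carried into the result.
#' @param gap_open,gap_extend affine gap penalties (defaults 11 and 1,
#'   the BLAST defaults for BLOSUM62).
#' @param db_residues,db_seq_count database size used for the E-value
#'   estimate; defaults to the subject alone.
#' @return A one-row `data.frame` with columns `query_id`, `subject_id`,
#'   `score`, `identity`, `similarity`, `aln_len`, `len_ratio` (subject
#'   length / query length), and `evalue`. The aligned column index pairs
#'   are attached as attributes `qcols`/`scols` (0 marks a gap) together
#'   with `qstart`/`qend`/`sstart`/`send`, for use by [buildPssm()].
#' @examples
#' alignPair("HEAGAWGHEE", "HEAGAWGHEE")$identity
#' @export
alignPair <- function(query, subject, query_id = "query",
                      subject_id = "subject", gap_open = 11,
                      gap_extend = 1, db_residues = nchar(subject),
                      db_seq_count = 1L) {
  if (!nzchar(query) || !nzchar(subject))
    stop("query and subject must be non-empty protein sequences")
  qi <- aa_encode(query)
  si <- aa_encode(subject)
  a <- .C_sw_align(qi, si, BLOSUM62_20, gap_open, gap_extend)
  aln_len <- a$aln_len
  res <- data.frame(
    query_id = query_id, subject_id = subject_id, score = a$score,
    identity = if (aln_len > 0) a$n_id / aln_len else 0,
    similarity = if (aln_len > 0) a$n_pos / aln_len else 0,
    aln_len = aln_len,
    len_ratio = nchar(subject) / nchar(query),
    evalue = estimateEvalue(a$score, nchar(query), db_residues,
                            db_seq_count),
    stringsAsFactors = FALSE)
  attr(res, "qcols") <- a$qcols
  attr(res, "scols") <- a$scols
  attr(res, "qstart") <- a$qstart
  attr(res, "qend") <- a$qend
  attr(res, "sstart") <- a$sstart
  attr(res, "send") <- a$send
  attr(res, "subject_seq") <- subject
  res
}

#' Karlin-Altschul E-value estimate
#'
#' Expected number of chance local alignments scoring at least `score`,
#' `E = K * m * n * exp(-lambda * S)`, with the gapped BLOSUM62 (gap
#' 11/1) constants lambda = 0.267 and K = 0.041 as documented defaults
#' -- the parameters matching the engine's actual scoring scheme. The
#' estimate is a permissive pre-filter ahead of the decisive similarity
#' and arrangement criteria, not a full composition-adjusted BLAST
#' statistic.
#'
#' @param score alignment score (>= 0), half-bit BLOSUM62 units.
#' @param query_len query length m in residues.
#' @param db_residues total database residues n.
#' @param db_seq_count number of database sequences (kept for interface
#'   completeness; the ungapped estimate does not use it).
#' @param lambda,K Karlin-Altschul parameters.
#' @return The E-value, strictly decreasing in `score` and linear in
#'   `db_residues`.
#' @export
estimateEvalue <- function(score, query_len, db_residues,
                           db_seq_count = 1L, lambda = KA_LAMBDA,
                           K = KA_K) {
  stopifnot(all(score >= 0))
  K * query_len * db_residues * exp(-lambda * score)
}

#' Build a PSSM from a seed and its aligned hits
#'
#' Constructs a position-specific score matrix anchored on the seed
#' coordinates. Observed residue frequencies per seed position (the seed
#' residue plus every hit residue aligned to it) are smoothed with a
#' background-proportional pseudocount of total mass 1 -- so the
#' background's weight decays as alignment depth grows -- and converted to
#' half-bit log-odds against the Robinson-Robinson background. Seed
#' positions covered by no hit fall back to the BLOSUM62 row of the seed
#' residue, keeping scores on the familiar substitution-matrix scale.
#'
#' @param seed the anchor protein sequence.
#' @param hits a list of results from [alignPair()] in which `seed` was
#'   the query (their aligned-column attributes are required).
#' @param profile_id identifier for the resulting profile.
#' @param role optional role annotation ("toxin"/"antitoxin").
#' @return A [PSSMProfile-class] of length `nchar(seed)`.
#' @export
buildPssm <- function(seed, hits, profile_id = "pssm", role = "") {
  if (length(hits) == 0L)
    stop("no hits supplied; use alignPair() directly for a single pair")
  L <- nchar(seed)
  seed_int <- aa_encode(seed)
  counts <- matrix(0, nrow = L, ncol = 20L)
  depth <- integer(L)
  for (h in hits) {
    qc <- attr(h, "qcols")
    sc <- attr(h, "scols")
    ss <- attr(h, "subject_seq")
    if (is.null(qc) || is.null(ss))
      stop("hits must carry alignment columns from alignPair()")
    s_int <- aa_encode(ss)
    keep <- qc > 0L & sc > 0L
    qp <- qc[keep]
    sa <- s_int[sc[keep]]
    for (t in seq_along(qp)) counts[qp[t], sa[t]] <- counts[qp[t], sa[t]] + 1
    depth[unique(qp)] <- depth[unique(qp)] + 1L
  }
  ## seed contributes one observation at every position
  counts[cbind(seq_len(L), seed_int)] <- counts[cbind(seq_len(L), seed_int)] + 1
  w <- matrix(0, nrow = L, ncol = 20L, dimnames = list(NULL, AA20))
  bg <- AA_BACKGROUND
  for (i in seq_len(L)) {
    if (depth[i] == 0L) {
      w[i, ] <- BLOSUM62_20[seed_int[i], ]
    } else {
      n_i <- sum(counts[i, ])
      freq <- (counts[i, ] + bg) / (n_i + 1)
      w[i, ] <- 2 * log2(freq / bg)
    }
  }
  new("PSSMProfile", profile_id = profile_id, weights = w,
      source_alignment_size = length(hits) + 1L, role = role)
}

#' Search a PSSM against protein sequences
#'
#' Local alignment of the profile against each subject using the
#' per-position profile scores with affine gaps. `profile_coverage` is the
#' fraction of profile positions present in the alignment; `similarity`
#' is the fraction of *profile positions* aligned with a positive score
#' (the profile analogue of BLAST "Positives", anchored on the profile so
#' that a short spurious local match cannot masquerade as a near-perfect
#' homologue); `identity` the fraction of profile positions where the
#' subject residue is the profile's top-scoring residue.
#'
#' @param profile a [PSSMProfile-class].
#' @param subjects named character vector of protein sequences.
#' @param gap_open,gap_extend affine gap penalties.
#' @param evalue_max report only hits at or below this E-value
#'   (default `Inf`: report all).
#' @param db_residues database size for E-values (default: total subject
#'   residues).
#' @return A `data.frame` with one row per reported hit: `profile_id`,
#'   `subject_id`, `score`, `evalue`, `profile_coverage`, `similarity`,
#'   `identity`, `aln_len`, `len_ratio` (subject length / profile length),
#'   `sstart`, `send`.
#' @export
searchPssm <- function(profile, subjects, gap_open = 11, gap_extend = 1,
                       evalue_max = Inf,
                       db_residues = sum(nchar(subjects))) {
  stopifnot(is(profile, "PSSMProfile"))
  if (length(subjects) == 0L) return(.emptyProfileHits())
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  enc <- lapply(unname(subjects), aa_encode)
  m <- .C_profile_batch(profile@weights, enc, gap_open, gap_extend)
  L <- nrow(profile@weights)
  ev <- estimateEvalue(m[, "score"], L, db_residues)
  out <- data.frame(
    profile_id = profile@profile_id,
    subject_id = names(subjects),
    score = m[, "score"],
    evalue = ev,
    profile_coverage = m[, "n_prof"] / L,
    similarity = m[, "n_pos"] / L,
    identity = m[, "n_best"] / L,
    aln_len = as.integer(m[, "aln_len"]),
    len_ratio = nchar(subjects) / L,
    sstart = as.integer(m[, "sstart"]),
    send = as.integer(m[, "send"]),
    stringsAsFactors = FALSE, row.names = NULL)
  out[out$evalue <= evalue_max, , drop = FALSE]
}

.emptyProfileHits <- function() {
  data.frame(profile_id = character(), subject_id = character(),
             score = numeric(), evalue = numeric(),
             profile_coverage = numeric(), similarity = numeric(),
             identity = numeric(), aln_len = integer(),
             len_ratio = numeric(), sstart = integer(), send = integer(),
             stringsAsFactors = FALSE)
}

#' Single-linkage protein clustering by identity and coverage
#'
#' blastclust-style clustering: two proteins are linked when their local
#' alignment identity reaches `identity_threshold` and the aligned region
#' spans at least `coverage_threshold` of the longer sequence. Clusters
#' are the connected components of the link graph (single linkage), with
#' deterministic ids taken from the lexicographically smallest member.
#'
#' @param proteins named character vector of protein sequences (>= 1).
#' @param coverage_threshold length coverage of the longer sequence
#'   (default 0.55).
#' @param identity_threshold aligned-column identity (default 0.60).
#' @param gap_open,gap_extend affine gap penalties.
#' @return A `data.frame` with one row per cluster: `cluster_id`,
#'   `representative_id` (member with maximal summed similarity to its
#'   co-members) and list-column `members`. Clusters partition the input.
#' @export
clusterProteins <- function(proteins, coverage_threshold = 0.55,
                            identity_threshold = 0.60, gap_open = 11,
                            gap_extend = 1) {
  if (length(proteins) < 1L) stop("need at least one protein")
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must carry unique names")
  ids <- names(proteins)
  n <- length(proteins)
  enc <- lapply(unname(proteins), aa_encode)
  lens <- nchar(proteins)
  edge_a <- integer(0); edge_b <- integer(0)
  sim <- matrix(0, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      stats <- .C_sw_batch(enc[[i]], enc[(i + 1L):n], BLOSUM62_20,
                           gap_open, gap_extend)
      for (r in seq_len(nrow(stats))) {
        j <- i + r
        al <- stats[r, "aln_len"]
        if (al == 0) next
        idf <- stats[r, "n_id"] / al
        sim[i, j] <- sim[j, i] <- stats[r, "n_pos"] / al
        ## span on the longer of the two sequences
        span <- if (lens[i] >= lens[j])
          stats[r, "qend"] - stats[r, "qstart"] + 1
        else stats[r, "send"] - stats[r, "sstart"] + 1
        cov <- span / max(lens[i], lens[j])
        if (idf >= identity_threshold && cov >= coverage_threshold) {
          edge_a <- c(edge_a, i); edge_b <- c(edge_b, j)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edge_a))
    g <- igraph::add_edges(g, rbind(edge_a, edge_b))
  comp <- igraph::components(g)$membership
  out <- lapply(split(seq_len(n), comp), function(members) {
    mem_ids <- sort(ids[members])
    rep_id <- if (length(members) == 1L) mem_ids[1] else {
      sums <- rowSums(sim[members, members, drop = FALSE])
      ord <- order(-sums, ids[members])
      ids[members][ord[1]]
    }
    list(cluster_id = mem_ids[1], representative_id = rep_id,
         members = mem_ids)
  })
  out <- out[order(vapply(out, `[[`, "", "cluster_id"))]
  data.frame(
    cluster_id = vapply(out, `[[`, "", "cluster_id"),
    representative_id = vapply(out, `[[`, "", "representative_id"),
    members = I(lapply(out, `[[`, "members")),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read and write PSSM fixture files
#'
#' Plain-text profile format: each profile starts with a header line
#' `>profile_id<TAB>role<TAB>source_alignment_size`, followed by a column
#' header naming the 20 residues and one whitespace-separated row of 20
#' scores per profile position.
#'
#' @param path file path.
#' @return `readPssmSet` returns a named list of [PSSMProfile-class]
#'   objects; `writePssmSet` invisibly returns `path`.
#' @export
readPssmSet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no profile headers found in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  profiles <- list()
  for (k in seq_along(starts)) {
    hdr <- strsplit(sub("^>", "", lines[starts[k]]), "\t")[[1]]
    body <- lines[(starts[k] + 1L):ends[k]]
    body <- body[!grepl("^pos\\b|^#", body)]
    w <- do.call(rbind, lapply(strsplit(trimws(body), "[ \t]+"),
                               function(x) as.numeric(x)))
    if (ncol(w) == 21L) w <- w[, -1, drop = FALSE] # leading position index
    colnames(w) <- AA20
    profiles[[hdr[1]]] <- new("PSSMProfile", profile_id = hdr[1],
                              weights = w,
                              source_alignment_size =
                                as.integer(hdr[3] %||% "1"),
                              role = hdr[2] %||% "")
  }
  profiles
}

#' @rdname readPssmSet
#' @param profiles a list of [PSSMProfile-class] objects.
#' @export
writePssmSet <- function(profiles, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in profiles) {
    stopifnot(is(p, "PSSMProfile"))
    writeLines(sprintf(">%s\t%s\t%d", p@profile_id,
                       if (length(p@role)) p@role else "",
                       p@source_alignment_size), con)
    writeLines(paste(c("pos", AA20), collapse = " "), con)
    for (i in seq_len(nrow(p@weights)))
      writeLines(paste(c(i, formatC(p@weights[i, ], format = "g",
                                    digits = 8)), collapse = " "), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a
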