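# The five TA-discovery strategies: conservative iterative cascade,
# extensive single-pass, PSI-style iterative PSSM refinement, RPS-style
# domain-profile scan, and DELTA-style profile-mediated search, together
# with the operon arrangement predicate and the inclusion criteria that
# turn alignment hits into accepted loci.

#' Define a seed query set
#'
#' @param toxins,antitoxins named character vectors of protein sequences.
#' @return A `data.frame` with columns `seed_id`, `role`, `protein`.
#' @export
seedSet <- function(toxins, antitoxins) {
  stopifnot(length(toxins) >= 1L, length(antitoxins) >= 1L,
            !is.null(names(toxins)), !is.null(names(antitoxins)))
  data.frame(
    seed_id = c(names(toxins), names(antitoxins)),
    role = rep(c("toxin", "antitoxin"), c(length(toxins),
                                          length(antitoxins))),
    protein = c(unname(toxins), unname(antitoxins)),
    stringsAsFactors = FALSE)
}

## Flat ORF table used internally by the strategies.
.orfTable <- function(orfs) {
  mc <- S4Vectors::mcols(orfs)
  data.frame(orf_id = mc$orf_id, strain_id = mc$strain_id,
             contig_id = as.character(GenomicRanges::seqnames(orfs)),
             strand = as.character(BiocGenerics::strand(orfs)),
             start = BiocGenerics::start(orfs),
             end = BiocGenerics::end(orfs),
             protein = mc$protein, plen = nchar(mc$protein),
             stringsAsFactors = FALSE)
}

#' Test the canonical TA operon arrangement
#'
#' TRUE when the two ORFs lie on the same contig and (by default) the same
#' strand, the putative antitoxin precedes the putative toxin in coding
#' orientation, and the intergenic distance -- end of the upstream gene to
#' start of the downstream gene along the coding direction -- is below
#' `max_gap_nt` (default: overlapping or less than 100 bp apart).
#'
#' @param orf_a,orf_b single-row ORF `GRanges` (as produced by
#'   [findOrfs()]); `orf_a` is the candidate upstream (antitoxin) gene.
#' @param config a [PipelineConfig-class].
#' @return Logical scalar (vectorised over parallel inputs).
#' @export
isTaArrangement <- function(orf_a, orf_b, config = pipelineConfig()) {
  same_contig <- as.character(GenomicRanges::seqnames(orf_a)) ==
    as.character(GenomicRanges::seqnames(orf_b))
  sa <- as.character(BiocGenerics::strand(orf_a))
  sb <- as.character(BiocGenerics::strand(orf_b))
  same_strand <- sa == sb
  gap <- ifelse(sa == "-",
                BiocGenerics::start(orf_a) - BiocGenerics::end(orf_b) - 1L,
                BiocGenerics::start(orf_b) - BiocGenerics::end(orf_a) - 1L)
  ordered_ok <- ifelse(sa == "-",
                       BiocGenerics::end(orf_b) <= BiocGenerics::end(orf_a),
                       BiocGenerics::start(orf_b) >=
                         BiocGenerics::start(orf_a))
  ok <- same_contig & gap < config@max_gap_nt & ordered_ok
  if (config@require_same_strand) ok <- ok & same_strand
  ok
}

## All arrangement-satisfying adjacent ORF pairs, oriented upstream (U) ->
## downstream (D) in coding orientation. gap_nt < max_gap_nt (negative =
## overlap).
.adjacentPairs <- function(ot, config) {
  res <- list()
  grp <- split(seq_len(nrow(ot)),
               paste(ot$contig_id, ot$strand, sep = "\r"))
  for (idx in grp) {
    sub <- ot[idx, , drop = FALSE]
    o <- order(sub$start, sub$end)
    sub <- sub[o, , drop = FALSE]
    idx <- idx[o]
    n <- length(idx)
    if (n < 2L) next
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        gap <- sub$start[j] - sub$end[i] - 1L
        if (gap >= config@max_gap_nt) break
        if (sub$strand[i] == "+") {
          u <- idx[i]; d <- idx[j]
        } else {
          u <- idx[j]; d <- idx[i]
        }
        res[[length(res) + 1L]] <- c(u, d, gap)
      }
    }
  }
  if (length(res) == 0L)
    return(data.frame(u = integer(), d = integer(), gap_nt = integer()))
  m <- do.call(rbind, res)
  data.frame(u = m[, 1], d = m[, 2], gap_nt = m[, 3])
}

## Pairwise sequence search of queries against per-strain ORF databases.
## Returns hits at E <= blastp_evalue. `ratio_window` optionally skips
## subjects whose length ratio falls outside it -- used by the cascade,
## where out-of-ratio hits can never contribute evidence under the
## decision rules, so the restriction cannot change the accepted set.
.searchHits <- function(ot, queries, config, ratio_window = NULL) {
  if (nrow(queries) == 0L || nrow(ot) == 0L) return(.emptySeqHits())
  res <- list()
  for (strain in unique(ot$strain_id)) {
    rows <- which(ot$strain_id == strain)
    enc <- lapply(ot$protein[rows], aa_encode)
    db_res <- sum(ot$plen[rows])
    for (qi in seq_len(nrow(queries))) {
      q <- queries$protein[qi]
      sub_rows <- rows
      sub_enc <- enc
      if (!is.null(ratio_window)) {
        ok <- ot$plen[rows] / nchar(q) >= ratio_window[1] &
          ot$plen[rows] / nchar(q) <= ratio_window[2]
        sub_rows <- rows[ok]
        sub_enc <- enc[ok]
        if (length(sub_rows) == 0L) next
      }
      stats <- .C_sw_batch(aa_encode(q), sub_enc, BLOSUM62_20,
                           config@gap_open, config@gap_extend)
      ev <- estimateEvalue(stats[, "score"], nchar(q), db_res,
                           length(rows))
      ## a reportable hit must be a credible homology alignment: the
      ## aligned span covers at least the clustering coverage
      ## threshold of the longer protein (the blastclust coverage
      ## notion); short chance matches against a conserved core are
      ## dropped here rather than masquerading as review-band evidence
      slen <- ot$plen[sub_rows]
      qlen <- nchar(q)
      span <- ifelse(qlen >= slen,
                     stats[, "qend"] - stats[, "qstart"] + 1,
                     stats[, "send"] - stats[, "sstart"] + 1)
      cov <- span / pmax(qlen, slen)
      keep <- which(ev <= config@blastp_evalue & stats[, "aln_len"] > 0 &
                      cov >= config@cluster_coverage)
      if (!length(keep)) next
      res[[length(res) + 1L]] <- data.frame(
        orf_id = ot$orf_id[sub_rows[keep]],
        query_id = queries$seed_id[qi], role = queries$role[qi],
        score = stats[keep, "score"],
        identity = stats[keep, "n_id"] / stats[keep, "aln_len"],
        similarity = stats[keep, "n_pos"] / stats[keep, "aln_len"],
        len_ratio = ot$plen[sub_rows[keep]] / nchar(q),
        evalue = ev[keep], stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.emptySeqHits())
  do.call(rbind, res)
}

.emptySeqHits <- function() {
  data.frame(orf_id = character(), query_id = character(),
             role = character(), score = numeric(), identity = numeric(),
             similarity = numeric(), len_ratio = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

## Domain-profile scan of all ORFs, per-strain databases.
.profileHits <- function(ot, profiles, config,
                         evalue_max = config@rps_evalue) {
  if (nrow(ot) == 0L || length(profiles) == 0L) return(.emptyDomHits())
  res <- list()
  for (strain in unique(ot$strain_id)) {
    rows <- which(ot$strain_id == strain)
    subj <- stats::setNames(ot$protein[rows], ot$orf_id[rows])
    db_res <- sum(ot$plen[rows])
    for (p in profiles) {
      h <- searchPssm(p, subj, config@gap_open, config@gap_extend,
                      evalue_max = evalue_max, db_residues = db_res)
      if (nrow(h) == 0L) next
      h$role <- p@role
      res[[length(res) + 1L]] <- h
    }
  }
  if (!length(res)) return(.emptyDomHits())
  out <- do.call(rbind, res)
  names(out)[names(out) == "subject_id"] <- "orf_id"
  out
}

.emptyDomHits <- function() {
  out <- .emptyProfileHits()
  names(out)[names(out) == "subject_id"] <- "orf_id"
  out$role <- character(0)
  out
}

#' Apply the TA inclusion criteria to candidate loci
#'
#' Decides each candidate pair. A candidate is
#' `accepted_high_similarity` when both components align to their
#' queries at similarity `>= sim_accept` with a match-to-query length
#' ratio inside `[len_ratio_min, len_ratio_max]`. Otherwise it is
#' `accepted_by_criteria` when (a) at least one component carries
#' supporting evidence -- a sequence hit with similarity above the review
#' floor `sim_review` and an in-range length ratio, or a domain-profile
#' hit -- and (b) the toxin has a complete toxin-domain hit or a length
#' within `toxin_len_range`, and (c) the antitoxin has a complete
#' antitoxin-domain hit or a length within `antitoxin_len_range`.
#' Anything else is `rejected` with a reason.
#'
#' @param candidates `data.frame` with columns `tox_len`, `at_len` and
#'   either per-component evidence (`tox_similarity`, `tox_ratio`,
#'   `at_similarity`, `at_ratio`; `NA` = no hit) or a single `similarity`
#'   / `len_ratio` pair applied to both components; optional logical
#'   columns `tox_domain_complete`, `at_domain_complete` (default FALSE).
#' @param config a [PipelineConfig-class].
#' @return The input with `decision` and `rejection_reason` columns.
#' @export
applyInclusionCriteria <- function(candidates, config = pipelineConfig()) {
  df <- candidates
  if (!"tox_similarity" %in% names(df) && "similarity" %in% names(df)) {
    df$tox_similarity <- df$similarity
    df$at_similarity <- df$similarity
  }
  if (!"tox_ratio" %in% names(df) && "len_ratio" %in% names(df)) {
    df$tox_ratio <- df$len_ratio
    df$at_ratio <- df$len_ratio
  }
  for (col in c("tox_similarity", "at_similarity", "tox_ratio",
                "at_ratio"))
    if (!col %in% names(df)) df[[col]] <- NA_real_
  for (col in c("tox_domain_complete", "at_domain_complete"))
    if (!col %in% names(df)) df[[col]] <- FALSE
  ratio_ok <- function(r) !is.na(r) & r >= config@len_ratio_min &
    r <= config@len_ratio_max
  sim_ok <- function(s, r, thr) !is.na(s) & s >= thr & ratio_ok(r)
  high <- sim_ok(df$tox_similarity, df$tox_ratio, config@sim_accept) &
    sim_ok(df$at_similarity, df$at_ratio, config@sim_accept)
  evid <- (!is.na(df$tox_similarity) & df$tox_similarity >
             config@sim_review & ratio_ok(df$tox_ratio)) |
    (!is.na(df$at_similarity) & df$at_similarity > config@sim_review &
       ratio_ok(df$at_ratio)) |
    df$tox_domain_complete | df$at_domain_complete
  tox_ok <- df$tox_domain_complete |
    (df$tox_len >= config@toxin_len_range[1] &
       df$tox_len <= config@toxin_len_range[2])
  at_ok <- df$at_domain_complete |
    (df$at_len >= config@antitoxin_len_range[1] &
       df$at_len <= config@antitoxin_len_range[2])
  decision <- ifelse(high, "accepted_high_similarity",
                     ifelse(evid & tox_ok & at_ok, "accepted_by_criteria",
                            "rejected"))
  reason <- rep(NA_character_, nrow(df))
  rej <- decision == "rejected"
  reason[rej & !evid] <- "below review floor"
  reason[rej & evid & !tox_ok] <- "toxin length/domain"
  reason[rej & evid & tox_ok & !at_ok] <- "antitoxin length/domain"
  df$decision <- decision
  df$rejection_reason <- reason
  df
}

## Build candidate pairs from arrangement-satisfying adjacency plus
## sequence/domain hit evidence, assign roles, and decide each pair.
## Returns the decided candidate table (one row per adjacent pair with
## any evidence).
.buildCandidates <- function(ot, pairs, seq_hits, dom_hits, config) {
  if (nrow(pairs) == 0L) return(.emptyCandidates())
  best_by <- function(hits, role) {
    h <- hits[hits$role == role, , drop = FALSE]
    if (nrow(h) == 0L)
      return(list(sim = function(id) NA_real_,
                  ratio = function(id) NA_real_,
                  query = function(id) NA_character_))
    ## prefer hits whose ratio qualifies, then the most similar
    r_ok <- h$len_ratio >= config@len_ratio_min &
      h$len_ratio <= config@len_ratio_max
    o <- order(-r_ok, -h$similarity)
    h <- h[o, , drop = FALSE]
    first <- !duplicated(h$orf_id)
    h <- h[first, , drop = FALSE]
    sim <- stats::setNames(h$similarity, h$orf_id)
    rat <- stats::setNames(h$len_ratio, h$orf_id)
    qq <- stats::setNames(h$query_id, h$orf_id)
    list(sim = function(id) unname(sim[id]),
         ratio = function(id) unname(rat[id]),
         query = function(id) unname(qq[id]))
  }
  tox_best <- best_by(seq_hits, "toxin")
  at_best <- best_by(seq_hits, "antitoxin")
  dom_complete <- function(role) {
    h <- dom_hits[dom_hits$role == role &
                    dom_hits$profile_coverage >= config@domain_coverage_min,
                  , drop = FALSE]
    unique(h$orf_id)
  }
  dom_any <- unique(dom_hits$orf_id)
  tox_dom <- dom_complete("toxin")
  at_dom <- dom_complete("antitoxin")
  hit_ids <- unique(c(seq_hits$orf_id, dom_any))

  u_id <- ot$orf_id[pairs$u]
  d_id <- ot$orf_id[pairs$d]
  involved <- u_id %in% hit_ids | d_id %in% hit_ids
  pairs <- pairs[involved, , drop = FALSE]
  u_id <- u_id[involved]; d_id <- d_id[involved]
  if (nrow(pairs) == 0L) return(.emptyCandidates())

  has_tox_ev <- function(id) !is.na(tox_best$sim(id)) | id %in% tox_dom
  has_at_ev <- function(id) !is.na(at_best$sim(id)) | id %in% at_dom
  ## canonical order puts the antitoxin upstream; roles flip only when
  ## toxin evidence sits exclusively on the upstream gene
  flip <- has_tox_ev(u_id) & !has_tox_ev(d_id) & !has_at_ev(u_id)
  at_orf <- ifelse(flip, d_id, u_id)
  tox_orf <- ifelse(flip, u_id, d_id)
  lens <- stats::setNames(ot$plen, ot$orf_id)
  cand <- data.frame(
    at_orf_id = at_orf, tox_orf_id = tox_orf,
    gap_nt = pairs$gap_nt,
    antitoxin_upstream = !flip,
    at_len = unname(lens[at_orf]), tox_len = unname(lens[tox_orf]),
    at_similarity = at_best$sim(at_orf),
    at_ratio = at_best$ratio(at_orf),
    tox_similarity = tox_best$sim(tox_orf),
    tox_ratio = tox_best$ratio(tox_orf),
    at_domain_complete = at_orf %in% at_dom,
    tox_domain_complete = tox_orf %in% tox_dom,
    seed_query_id = ifelse(!is.na(tox_best$query(tox_orf)),
                           tox_best$query(tox_orf),
                           at_best$query(at_orf)),
    stringsAsFactors = FALSE)
  cand <- applyInclusionCriteria(cand, config)
  cand$decision[cand$decision != "rejected" &
                  !cand$antitoxin_upstream] <- "rejected"
  cand$rejection_reason[cand$decision == "rejected" &
                          !cand$antitoxin_upstream] <-
    "toxin upstream of antitoxin"
  cand
}

.emptyCandidates <- function() {
  data.frame(at_orf_id = character(), tox_orf_id = character(),
             gap_nt = integer(), antitoxin_upstream = logical(),
             at_len = integer(), tox_len = integer(),
             at_similarity = numeric(), at_ratio = numeric(),
             tox_similarity = numeric(), tox_ratio = numeric(),
             at_domain_complete = logical(), tox_domain_complete = logical(),
             seed_query_id = character(), decision = character(),
             rejection_reason = character(), stringsAsFactors = FALSE)
}

## Turn accepted candidates into the canonical locus table. A gene can
## belong to at most one operon: candidates are ranked (high-similarity
## decision first, then number of evidenced components, then smallest
## absolute gap, then similarity) and resolved greedily so no ORF is
## used twice; the survivors are deduplicated by (strain, contig, toxin
## coordinates).
.candidatesToLoci <- function(cand, ot, strategy) {
  acc <- cand[startsWith(cand$decision, "accepted"), , drop = FALSE]
  if (nrow(acc) == 0L) return(.emptyLoci())
  rank0 <- ifelse(acc$decision == "accepted_high_similarity", 0L, 1L)
  n_ev <- (!is.na(acc$tox_similarity) | acc$tox_domain_complete) +
    (!is.na(acc$at_similarity) | acc$at_domain_complete)
  sim0 <- pmax(acc$at_similarity, acc$tox_similarity, na.rm = TRUE)
  sim0[is.na(sim0)] <- 0
  acc <- acc[order(rank0, -n_ev, abs(acc$gap_nt), -sim0), , drop = FALSE]
  used <- character(0)
  keep <- logical(nrow(acc))
  for (i in seq_len(nrow(acc))) {
    if (acc$at_orf_id[i] %in% used || acc$tox_orf_id[i] %in% used) next
    keep[i] <- TRUE
    used <- c(used, acc$at_orf_id[i], acc$tox_orf_id[i])
  }
  acc <- acc[keep, , drop = FALSE]
  info <- ot[match(acc$tox_orf_id, ot$orf_id), ]
  at_info <- ot[match(acc$at_orf_id, ot$orf_id), ]
  loci <- data.frame(
    locus_id = paste(info$strain_id, info$contig_id, info$start,
                     info$end, sep = "|"),
    strain_id = info$strain_id, contig_id = info$contig_id,
    strand = info$strand,
    at_orf_id = acc$at_orf_id, tox_orf_id = acc$tox_orf_id,
    at_start = at_info$start, at_end = at_info$end,
    tox_start = info$start, tox_end = info$end,
    gap_nt = acc$gap_nt,
    at_len = acc$at_len, tox_len = acc$tox_len,
    at_protein = at_info$protein, tox_protein = info$protein,
    at_similarity = acc$at_similarity, tox_similarity = acc$tox_similarity,
    similarity = pmax(acc$at_similarity, acc$tox_similarity, na.rm = TRUE),
    at_domain_complete = acc$at_domain_complete,
    tox_domain_complete = acc$tox_domain_complete,
    seed_query_id = acc$seed_query_id,
    decision = acc$decision, strategy = strategy,
    stringsAsFactors = FALSE)
  rank <- ifelse(loci$decision == "accepted_high_similarity", 0L, 1L)
  o <- order(loci$locus_id, rank, abs(loci$gap_nt), -loci$similarity)
  loci <- loci[o, , drop = FALSE]
  loci <- loci[!duplicated(loci$locus_id), , drop = FALSE]
  loci[order(loci$locus_id), , drop = FALSE]
}

.emptyLoci <- function() {
  data.frame(locus_id = character(), strain_id = character(),
             contig_id = character(), strand = character(),
             at_orf_id = character(), tox_orf_id = character(),
             at_start = integer(), at_end = integer(),
             tox_start = integer(), tox_end = integer(),
             gap_nt = integer(), at_len = integer(), tox_len = integer(),
             at_protein = character(), tox_protein = character(),
             at_similarity = numeric(), tox_similarity = numeric(),
             similarity = numeric(), at_domain_complete = logical(),
             tox_domain_complete = logical(), seed_query_id = character(),
             decision = character(), strategy = character(),
             stringsAsFactors = FALSE)
}

#' Conservative iterative cascade search
#'
#' Round 0 queries the seed toxin/antitoxin proteins against every
#' strain's translated ORF set; hits passing the E-value pre-filter form
#' candidate loci with their arrangement-satisfying neighbours, decided
#' by [applyInclusionCriteria()]. Every accepted locus contributes its
#' toxin and antitoxin proteins as new queries for the next round, and
#' the procedure iterates until convergence -- a round that adds no new
#' locus. The result is the union over rounds, deduplicated by (strain,
#' contig, toxin coordinates).
#'
#' @param orfs ORF `GRanges` from [findOrfs()] covering all strains.
#' @param seeds a [seedSet()].
#' @param config a [PipelineConfig-class].
#' @param profiles optional named list of [PSSMProfile-class] used only to
#'   flag complete domains during the inclusion decision.
#' @return The accepted locus table; the full decided candidate table and
#'   the number of rounds are attached as attributes `candidates` and
#'   `rounds`.
#' @export
cascadeSearch <- function(orfs, seeds, config = pipelineConfig(),
                          profiles = list()) {
  ot <- .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  dom_hits <- .profileHits(ot, profiles, config)
  queries <- seeds
  seen_q <- unique(seeds$protein)
  all_hits <- .emptySeqHits()
  loci <- .emptyLoci()
  rounds <- 0L
  rw <- c(config@len_ratio_min, config@len_ratio_max)
  repeat {
    rounds <- rounds + 1L
    hits <- .searchHits(ot, queries, config, ratio_window = rw)
    all_hits <- rbind(all_hits, hits)
    cand <- .buildCandidates(ot, pairs, all_hits, dom_hits, config)
    new_loci <- .candidatesToLoci(cand, ot, "cascade")
    added <- setdiff(new_loci$locus_id, loci$locus_id)
    loci <- new_loci
    if (length(added) == 0L) break
    add <- loci[loci$locus_id %in% added, , drop = FALSE]
    new_prot <- data.frame(
      seed_id = c(paste0(add$locus_id, "|tox"),
                  paste0(add$locus_id, "|at")),
      role = rep(c("toxin", "antitoxin"), each = nrow(add)),
      protein = c(add$tox_protein, add$at_protein),
      stringsAsFactors = FALSE)
    new_prot <- new_prot[!new_prot$protein %in% seen_q, , drop = FALSE]
    seen_q <- c(seen_q, unique(new_prot$protein))
    if (nrow(new_prot) == 0L) break
    queries <- new_prot
  }
  attr(loci, "candidates") <- .buildCandidates(ot, pairs, all_hits,
                                               dom_hits, config)
  attr(loci, "rounds") <- rounds
  loci
}

#' Extensive single-pass search with clustering and co-localisation
#'
#' Collects every hit at the E-value pre-filter (no similarity floor at
#' the hit stage), augments the result list with arrangement-satisfying
#' neighbour ORFs, clusters the union with [clusterProteins()], and
#' reports every toxin-like/antitoxin-like cluster pair whose members
#' co-localise in at least one strain together with its co-localisation
#' coefficient. Accepted loci are re-filtered by
#' [applyInclusionCriteria()].
#'
#' @inheritParams cascadeSearch
#' @return A list with elements `loci` (accepted locus table),
#'   `cluster_pairs` (`data.frame`: cluster ids, `n_colocalised`,
#'   `coloc_coefficient`), `clusters` (from [clusterProteins()]) and
#'   `candidates`.
#' @export
extensiveSearch <- function(orfs, seeds, config = pipelineConfig(),
                            profiles = list()) {
  ot <- .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  dom_hits <- .profileHits(ot, profiles, config)
  hits <- .searchHits(ot, seeds, config)
  cand <- .buildCandidates(ot, pairs, hits, dom_hits, config)
  loci <- .candidatesToLoci(cand, ot, "extensive")
  ## cluster the union of hit ORFs and their arrangement neighbours
  member_ids <- unique(c(hits$orf_id,
                         ot$orf_id[pairs$u][ot$orf_id[pairs$d] %in%
                                              hits$orf_id],
                         ot$orf_id[pairs$d][ot$orf_id[pairs$u] %in%
                                              hits$orf_id]))
  cluster_pairs <- .emptyClusterPairs()
  clusters <- NULL
  if (length(member_ids) >= 1L) {
    prot <- stats::setNames(ot$protein[match(member_ids, ot$orf_id)],
                            member_ids)
    clusters <- clusterProteins(prot, config@cluster_coverage,
                                config@cluster_identity,
                                config@gap_open, config@gap_extend)
    cluster_pairs <- .clusterPairTable(clusters, ot, pairs, config)
  }
  list(loci = loci, cluster_pairs = cluster_pairs, clusters = clusters,
       candidates = cand)
}

.emptyClusterPairs <- function() {
  data.frame(antitoxin_cluster = character(), toxin_cluster = character(),
             n_colocalised = integer(), coloc_coefficient = numeric(),
             stringsAsFactors = FALSE)
}

## Every ordered cluster pair with at least one strain in which an
## upstream member of the first cluster sits in TA arrangement with a
## downstream member of the second.
.clusterPairTable <- function(clusters, ot, pairs, config) {
  memb <- stats::setNames(
    rep(clusters$cluster_id, lengths(clusters$members)),
    unlist(clusters$members))
  u_id <- ot$orf_id[pairs$u]; d_id <- ot$orf_id[pairs$d]
  keep <- u_id %in% names(memb) & d_id %in% names(memb)
  if (!any(keep)) return(.emptyClusterPairs())
  u_cl <- unname(memb[u_id[keep]])
  d_cl <- unname(memb[d_id[keep]])
  strain <- ot$strain_id[pairs$u][keep]
  key <- paste(u_cl, d_cl, sep = "\r")
  out <- lapply(split(seq_along(key), key), function(rows) {
    a <- u_cl[rows[1]]; b <- d_cl[rows[1]]
    ns <- length(unique(strain[rows]))
    data.frame(antitoxin_cluster = a, toxin_cluster = b,
               n_colocalised = ns,
               coloc_coefficient = colocCoefficient(
                 clusters$members[[which(clusters$cluster_id == a)]],
                 clusters$members[[which(clusters$cluster_id == b)]],
                 ot, config),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$antitoxin_cluster, out$toxin_cluster), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Co-localisation coefficient of two ORF clusters
#'
#' The number of strains containing an arrangement-satisfying pair with
#' one member from each cluster, divided by the number of strains
#' containing a member of either cluster. It equals 1 when the clusters
#' always travel together as an operon pair and degrades toward 0 when
#' members occur solo.
#'
#' @param members_a,members_b character vectors of member ORF ids.
#' @param orfs ORF `GRanges` from [findOrfs()], or the internal ORF table.
#' @param config a [PipelineConfig-class].
#' @return A value in \[0, 1\].
#' @export
colocCoefficient <- function(members_a, members_b, orfs,
                             config = pipelineConfig()) {
  ot <- if (is.data.frame(orfs)) orfs else .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  u_id <- ot$orf_id[pairs$u]; d_id <- ot$orf_id[pairs$d]
  hit <- (u_id %in% members_a & d_id %in% members_b) |
    (u_id %in% members_b & d_id %in% members_a)
  strains_pair <- unique(ot$strain_id[pairs$u][hit])
  strains_any <- unique(ot$strain_id[ot$orf_id %in% c(members_a,
                                                      members_b)])
  if (length(strains_any) == 0L) return(0)
  length(strains_pair) / length(strains_any)
}

#' PSI-style iterative PSSM search
#'
#' Per seed: an initial pairwise pass collects hits above the inclusion
#' threshold, which are aligned to the seed and condensed into a PSSM
#' ([buildPssm()]); the profile is searched against all ORFs and refined
#' from the new inclusion set until the set is stable or `psi_max_iter`
#' rounds have run. Final profile hits at the E-value pre-filter (their
#' similarity being the fraction of positively scoring profile columns)
#' feed the same candidate construction and inclusion criteria as the
#' extensive search. Seeds with no hits above the inclusion threshold
#' fall back to their plain pairwise hit list.
#'
#' @inheritParams cascadeSearch
#' @return The accepted locus table with attributes `candidates` and
#'   `iterations` (per-seed refinement rounds).
#' @export
psiSearch <- function(orfs, seeds, config = pipelineConfig(),
                      profiles = list()) {
  ot <- .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  dom_hits <- .profileHits(ot, profiles, config)
  all_hits <- .emptySeqHits()
  iters <- integer(0)
  for (qi in seq_len(nrow(seeds))) {
    seed <- seeds$protein[qi]
    sid <- seeds$seed_id[qi]
    role <- seeds$role[qi]
    plain <- .searchHits(ot, seeds[qi, , drop = FALSE], config)
    incl <- plain$orf_id[plain$evalue <= config@psi_inclusion_evalue]
    if (length(incl) == 0L) {
      all_hits <- rbind(all_hits, plain)
      iters <- c(iters, 1L)
      next
    }
    it <- 0L
    prof <- NULL
    repeat {
      it <- it + 1L
      aln <- lapply(incl, function(id) {
        alignPair(seed, ot$protein[match(id, ot$orf_id)],
                  query_id = sid, subject_id = id,
                  gap_open = config@gap_open,
                  gap_extend = config@gap_extend)
      })
      prof <- buildPssm(seed, aln, profile_id = sid, role = role)
      ph <- .profileHits(ot, list(prof), config,
                         evalue_max = config@psi_inclusion_evalue)
      new_incl <- sort(unique(ph$orf_id))
      if (identical(new_incl, sort(incl)) || it >= config@psi_max_iter ||
          length(new_incl) == 0L) {
        if (length(new_incl)) incl <- new_incl
        break
      }
      incl <- new_incl
    }
    iters <- c(iters, it)
    final <- .profileHits(ot, list(prof), config,
                          evalue_max = config@blastp_evalue)
    if (nrow(final)) {
      all_hits <- rbind(all_hits, data.frame(
        orf_id = final$orf_id, query_id = sid, role = role,
        score = final$score, identity = final$identity,
        similarity = final$similarity, len_ratio = final$len_ratio,
        evalue = final$evalue, stringsAsFactors = FALSE))
    }
  }
  cand <- .buildCandidates(ot, pairs, all_hits, dom_hits, config)
  loci <- .candidatesToLoci(cand, ot, "psi")
  attr(loci, "candidates") <- cand
  attr(loci, "iterations") <- iters
  loci
}

#' RPS-style domain-profile search
#'
#' Scores every translated ORF against every bundled domain profile and
#' keeps hits at `rps_evalue` (default 0.001). Candidate loci are then
#' built exactly as in the cascade: a profile-hit ORF plus an
#' arrangement-satisfying neighbour, decided by the inclusion criteria
#' (profile hits supply both the role assignment and the
#' complete-domain evidence). A toxin whose domain is undetectable can
#' still be recovered through a detectable-domain antitoxin next door.
#'
#' @inheritParams cascadeSearch
#' @param profiles named list of [PSSMProfile-class] domain profiles with
#'   roles.
#' @return The accepted locus table with attributes `candidates` and
#'   `domain_hits` (the raw profile scan).
#' @export
rpsSearch <- function(orfs, profiles, config = pipelineConfig()) {
  if (length(profiles) == 0L)
    stop("configuration error: empty domain profile set")
  ot <- .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  dom_hits <- .profileHits(ot, profiles, config)
  cand <- .buildCandidates(ot, pairs, .emptySeqHits(), dom_hits, config)
  loci <- .candidatesToLoci(cand, ot, "rps")
  attr(loci, "candidates") <- cand
  attr(loci, "domain_hits") <- dom_hits
  loci
}

#' DELTA-style profile-mediated search
#'
#' Each seed first queries the domain-profile database; profiles matched
#' at `rps_evalue` are then searched against all ORFs, and the resulting
#' profile hits (similarity = fraction of positively scoring profile
#' columns) go through the extensive-search post-processing. A seed
#' matching no profile contributes nothing (with a warning); an empty
#' profile database is a configuration error.
#'
#' @inheritParams rpsSearch
#' @param seeds a [seedSet()].
#' @return The accepted locus table with attributes `candidates` and
#'   `matched_profiles`.
#' @export
deltaSearch <- function(orfs, seeds, profiles,
                        config = pipelineConfig()) {
  if (length(profiles) == 0L)
    stop("configuration error: empty domain profile set")
  ot <- .orfTable(orfs)
  pairs <- .adjacentPairs(ot, config)
  matched <- character(0)
  for (qi in seq_len(nrow(seeds))) {
    subj <- stats::setNames(seeds$protein[qi], seeds$seed_id[qi])
    for (p in profiles) {
      h <- searchPssm(p, subj, config@gap_open, config@gap_extend,
                      evalue_max = config@rps_evalue,
                      db_residues = nchar(subj))
      if (nrow(h)) matched <- c(matched, p@profile_id)
    }
  }
  matched <- unique(matched)
  if (length(matched) == 0L) {
    warning("no seed matched any domain profile; empty result")
    loci <- .emptyLoci()
    attr(loci, "candidates") <- .emptyCandidates()
    attr(loci, "matched_profiles") <- character(0)
    return(loci)
  }
  prof_use <- Filter(function(p) p@profile_id %in% matched, profiles)
  hits <- .profileHits(ot, prof_use, config,
                       evalue_max = config@blastp_evalue)
  seq_like <- if (nrow(hits)) data.frame(
    orf_id = hits$orf_id, query_id = hits$profile_id, role = hits$role,
    score = hits$score, identity = hits$identity,
    similarity = hits$similarity, len_ratio = hits$len_ratio,
    evalue = hits$evalue, stringsAsFactors = FALSE) else .emptySeqHits()
  dom_hits <- hits[hits$evalue <= config@rps_evalue, , drop = FALSE]
  cand <- .buildCandidates(ot, pairs, seq_like, dom_hits, config)
  loci <- .candidatesToLoci(cand, ot, "delta")
  attr(loci, "candidates") <- cand
  attr(loci, "matched_profiles") <- matched
  loci
}

#' Concordance report across search strategies
#'
#' @param results named list of locus tables (one per strategy).
#' @return A list with per-strategy `totals`, per-strategy `uniques`
#'   (loci found by that strategy alone), the `intersection` and `union`
#'   locus-id sets.
#' @export
strategyConcordance <- function(results) {
  keys <- lapply(results, function(x) unique(x$locus_id))
  all_keys <- sort(unique(unlist(keys)))
  totals <- vapply(keys, length, 0L)
  uniques <- vapply(names(keys), function(nm) {
    others <- unique(unlist(keys[setdiff(names(keys), nm)]))
    sum(!keys[[nm]] %in% others)
  }, 0L)
  inter <- if (length(keys)) Reduce(intersect, keys) else character(0)
  list(totals = totals, uniques = uniques,
       intersection = sort(inter), union = all_keys)
}
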