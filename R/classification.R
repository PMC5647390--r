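# Homologue grouping by toxin similarity and Table-style occurrence
# summaries.

#' Group accepted loci into homologue families
#'
#' Single-linkage components over pairwise toxin similarity: two loci are
#' linked when their toxin proteins align at similarity at or above
#' `threshold` (default 0.80, the toxin-similarity grouping threshold).
#' Similarity here is coverage-aware: positive-scoring aligned columns
#' divided by the length of the longer toxin. For genuine homologues the
#' local alignment spans the proteins and this coincides with the
#' per-column positives fraction; for unrelated toxins it collapses the
#' short high-scoring local matches that would otherwise chain distinct
#' families together. Groups are named in descending strain-count order
#' (`pemIK-like-01`, ...) unless a seed-name map assigns published names.
#'
#' @param loci an accepted locus table (see [cascadeSearch()]).
#' @param threshold toxin similarity threshold in \[0, 1\].
#' @param config a [PipelineConfig-class] (gap penalties).
#' @param name_map optional named character vector mapping a member
#'   `locus_id` or `seed_query_id` to a group name.
#' @param prefix group-name prefix for unnamed groups.
#' @return A `data.frame` with one row per group: `group_id`, `n_loci`,
#'   `n_strains`, `min_within_similarity`, list-column `member_loci`;
#'   attribute `assignments` maps every locus to its group and attribute
#'   `between_similarity` holds the max between-group similarity matrix.
#' @export
groupHomologues <- function(loci, threshold = 0.80,
                            config = pipelineConfig(), name_map = NULL,
                            prefix = "pemIK-like") {
  if (nrow(loci) == 0L)
    stop("no loci to group")
  n <- nrow(loci)
  sim <- .toxinSimMatrix(loci$tox_protein, config)
  g <- igraph::graph_from_adjacency_matrix(sim >= threshold,
                                           mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  ids <- loci$locus_id
  groups <- split(seq_len(n), comp)
  ## stable order: descending strain count, ties by smallest member id
  n_strains <- vapply(groups, function(m)
    length(unique(loci$strain_id[m])), 0L)
  first_id <- vapply(groups, function(m) min(ids[m]), "")
  ord <- order(-n_strains, first_id)
  groups <- groups[ord]
  gnames <- sprintf("%s-%02d", prefix, seq_along(groups))
  if (!is.null(name_map)) {
    for (k in seq_along(groups)) {
      m <- groups[[k]]
      hit <- c(intersect(ids[m], names(name_map)),
               intersect(unique(loci$seed_query_id[m]), names(name_map)))
      if (length(hit)) gnames[k] <- unname(name_map[hit[1]])
    }
  }
  min_within <- vapply(seq_along(groups), function(k) {
    m <- groups[[k]]
    if (length(m) == 1L) 1 else min(sim[m, m])
  }, 0)
  between <- matrix(NA_real_, length(groups), length(groups),
                    dimnames = list(gnames, gnames))
  for (a in seq_along(groups))
    for (b in seq_along(groups))
      if (a != b)
        between[a, b] <- max(sim[groups[[a]], groups[[b]]])
  assignments <- stats::setNames(
    rep(gnames, lengths(groups)), ids[unlist(groups)])
  out <- data.frame(
    group_id = gnames,
    n_loci = lengths(groups),
    n_strains = n_strains[ord],
    min_within_similarity = min_within,
    member_loci = I(lapply(groups, function(m) sort(ids[m]))),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "assignments") <- assignments
  attr(out, "between_similarity") <- between
  out
}

## Round half up to `digits` decimals (printed-table convention; R's
## round() rounds half to even).
.roundHalfUp <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarise homologue occurrence across species and strains
#'
#' Per homologue group: the number and percentage of roster species and
#' strains carrying at least one member locus, and the replicon location
#' call. Percentages are `100 * n / total` rounded half-up to 2 decimals.
#'
#' @param groups output of [groupHomologues()] (its `assignments`
#'   attribute is used), or a `data.frame` with columns `locus_id`,
#'   `group_id`.
#' @param loci the locus table the groups were built from.
#' @param strain_roster metadata `data.frame` from [readMetadata()]
#'   listing every analysed strain.
#' @param contig_locations optional named character vector mapping
#'   contig ids to `"chromosome"`/`"plasmid"` for the location call.
#' @return A `data.frame` with columns `homologue`, `n_species`,
#'   `pct_species`, `n_strains`, `pct_strains`, `location`.
#' @export
summarizeOccurrence <- function(groups, loci, strain_roster,
                                contig_locations = NULL) {
  assignments <- if (is.data.frame(groups) &&
                     !is.null(attr(groups, "assignments")))
    attr(groups, "assignments")
  else stats::setNames(groups$group_id, groups$locus_id)
  unknown <- setdiff(unique(loci$strain_id), strain_roster$strain_id)
  if (length(unknown))
    stop("locus with strain absent from roster: ",
         paste(unknown, collapse = ", "))
  total_strains <- nrow(strain_roster)
  total_species <- length(unique(strain_roster$species))
  species_of <- stats::setNames(strain_roster$species,
                                strain_roster$strain_id)
  out <- lapply(unique(unname(assignments)), function(g) {
    m <- loci[loci$locus_id %in% names(assignments)[assignments == g], ,
              drop = FALSE]
    ns <- length(unique(m$strain_id))
    nsp <- length(unique(species_of[unique(m$strain_id)]))
    loc <- "undetermined"
    if (!is.null(contig_locations)) {
      calls <- unique(vapply(m$contig_id, function(cid)
        callLocation(cid, contig_locations), ""))
      calls <- setdiff(calls, "undetermined")
      loc <- if (length(calls) == 0L) "undetermined"
      else if (length(calls) == 1L) calls
      else "chromosome, plasmid"
    }
    data.frame(homologue = g, n_species = nsp,
               pct_species = .roundHalfUp(100 * nsp / total_species),
               n_strains = ns,
               pct_strains = .roundHalfUp(100 * ns / total_strains),
               location = loc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(-out$n_strains, out$homologue), , drop = FALSE]
}

#' Replicon location call for a contig
#'
#' Pure annotation propagation: the call comes from a user-supplied (or
#' simulator truth) replicon label for the contig; unlabelled contigs are
#' `undetermined`. No inference from sequence context is attempted.
#'
#' @param contig_id contig identifier.
#' @param contig_locations named character vector of labels
#'   (`"chromosome"` or `"plasmid"`).
#' @return `"chromosome"`, `"plasmid"` or `"undetermined"`.
#' @export
callLocation <- function(contig_id, contig_locations = NULL) {
  if (is.null(contig_locations) ||
      !contig_id %in% names(contig_locations))
    return("undetermined")
  lab <- unname(contig_locations[contig_id])
  if (!lab %in% c("chromosome", "plasmid")) "undetermined" else lab
}

#' Write the occurrence summary as TSV
#'
#' @param summary output of [summarizeOccurrence()].
#' @param path output file.
#' @export
writeOccurrenceTsv <- function(summary, path) {
  utils::write.table(
    data.frame(summary$homologue, summary$n_species,
               sprintf("%.2f", summary$pct_species), summary$n_strains,
               sprintf("%.2f", summary$pct_strains), summary$location),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("homologue", "n_species", "pct_species", "n_strains",
                  "pct_strains", "location"))
  invisible(path)
}

#' Pairwise toxin similarity matrix
#'
#' Exported for external tree builders: the full locus-by-locus toxin
#' similarity matrix used by [groupHomologues()] (positive-scoring
#' aligned columns over the longer toxin's length).
#'
#' @inheritParams groupHomologues
#' @return A symmetric numeric matrix with locus ids as dimnames.
#' @export
toxinSimilarityMatrix <- function(loci, config = pipelineConfig()) {
  sim <- .toxinSimMatrix(loci$tox_protein, config)
  dimnames(sim) <- list(loci$locus_id, loci$locus_id)
  sim
}

## Coverage-aware pairwise similarity: positives over the longer length.
.toxinSimMatrix <- function(proteins, config) {
  n <- length(proteins)
  enc <- lapply(proteins, aa_encode)
  lens <- nchar(proteins)
  sim <- matrix(1, n, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      stats <- .C_sw_batch(enc[[i]], enc[(i + 1L):n], BLOSUM62_20,
                           config@gap_open, config@gap_extend)
      s <- stats[, "n_pos"] / pmax(lens[i], lens[(i + 1L):n])
      sim[i, (i + 1L):n] <- s
      sim[(i + 1L):n, i] <- s
    }
  }
  sim
}
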