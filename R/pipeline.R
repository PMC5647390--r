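# End-to-end orchestration: ORFs -> search strategies -> criteria ->
# homologue grouping -> occurrence summaries -> optional host stats.

#' Run the TA-discovery pipeline end to end
#'
#' Executes [findOrfs()] over every contig, runs the requested search
#' strategies, groups the accepted loci into homologue families, builds
#' the occurrence summary against the strain roster, and (when host
#' metadata is informative) the host-association report for the largest
#' group. Search scoping is per strain throughout, so co-localisation
#' semantics match a per-strain database search. All randomness derives
#' from `config@rng_seed`.
#'
#' @param contigs `DNAStringSet` across all strains (see
#'   [readAssembly()], [makeContigSet()] or [generateScenario()]).
#' @param seeds a [seedSet()] of query proteins.
#' @param profiles named list of [PSSMProfile-class] domain profiles
#'   (required by the rps and delta strategies).
#' @param metadata strain roster from [readMetadata()]; default derives
#'   a minimal roster from the contig annotations.
#' @param config a [PipelineConfig-class].
#' @param strategies subset of
#'   `c("cascade", "extensive", "psi", "rps", "delta")`.
#' @param host_stats whether to attach a host-association report.
#' @return A list of class `ta_run_report`: `config` snapshot, `counts`
#'   per stage, per-strategy locus tables (`loci`), `concordance`,
#'   `groups`, `occurrence`, optional `host`, and `orfs`.
#' @export
runPipeline <- function(contigs, seeds, profiles = list(),
                        metadata = NULL, config = pipelineConfig(),
                        strategies = c("cascade", "extensive", "psi",
                                       "rps", "delta"),
                        host_stats = FALSE) {
  if (length(contigs) == 0L)
    stop("validation error [input]: no contigs supplied")
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (any(strategies %in% c("rps", "delta")) && length(profiles) == 0L)
    stop("configuration error [profiles]: rps/delta need domain profiles")
  mc <- S4Vectors::mcols(contigs)
  if (is.null(metadata))
    metadata <- unique(data.frame(strain_id = mc$strain_id,
                                  species = mc$species,
                                  host = NA_character_,
                                  geo_location = NA_character_,
                                  collection_date = NA_character_,
                                  stringsAsFactors = FALSE))
  message("stage=orf_calling contigs=", length(contigs))
  orfs <- findOrfs(contigs, config)
  message("stage=orf_calling orfs=", length(orfs))

  loci <- list()
  candidates <- list()
  for (s in strategies) {
    res <- switch(s,
      cascade = cascadeSearch(orfs, seeds, config, profiles),
      extensive = {
        ex <- extensiveSearch(orfs, seeds, config, profiles)
        attr(ex$loci, "candidates") <- ex$candidates
        attr(ex$loci, "cluster_pairs") <- ex$cluster_pairs
        ex$loci
      },
      psi = psiSearch(orfs, seeds, config, profiles),
      rps = rpsSearch(orfs, profiles, config),
      delta = deltaSearch(orfs, seeds, profiles, config))
    loci[[s]] <- res
    candidates[[s]] <- attr(res, "candidates")
    message("stage=search strategy=", s, " candidates=",
            NROW(candidates[[s]]), " accepted=", nrow(res))
  }
  concordance <- strategyConcordance(loci)
  union_loci <- do.call(rbind, lapply(loci, function(x)
    x[, setdiff(names(x), "strategy"), drop = FALSE]))
  union_loci <- union_loci[!duplicated(union_loci$locus_id), ,
                           drop = FALSE]
  union_loci <- union_loci[order(union_loci$locus_id), , drop = FALSE]
  supporting <- lapply(union_loci$locus_id, function(id)
    names(loci)[vapply(loci, function(x) id %in% x$locus_id, NA)])
  union_loci$supporting_strategies <-
    vapply(supporting, paste, "", collapse = ",")

  groups <- NULL
  occurrence <- NULL
  if (nrow(union_loci) > 0L) {
    groups <- groupHomologues(union_loci, config@group_similarity,
                              config)
    message("stage=grouping groups=", nrow(groups))
    occurrence <- summarizeOccurrence(groups, union_loci, metadata)
  }

  host <- NULL
  if (host_stats && !is.null(groups) && any(!is.na(metadata$host))) {
    top <- groups$group_id[1]
    carriers <- unique(union_loci$strain_id[
      union_loci$locus_id %in% groups$member_loci[[1]]])
    host <- tryCatch(hostAssociationReport(carriers, metadata),
                     error = function(e) list(error = conditionMessage(e)))
  }

  counts <- list(
    contigs = length(contigs), orfs = length(orfs),
    candidates = vapply(candidates, NROW, 0L),
    accepted = vapply(loci, nrow, 0L),
    union_loci = nrow(union_loci),
    groups = if (is.null(groups)) 0L else nrow(groups))
  structure(list(
    config = config, counts = counts, loci = loci,
    union_loci = union_loci, concordance = concordance,
    groups = groups, occurrence = occurrence, host = host,
    orfs = orfs), class = "ta_run_report")
}

#' @export
print.ta_run_report <- function(x, ...) {
  cat("TA discovery run\n")
  cat("  contigs:", x$counts$contigs, " ORFs:", x$counts$orfs, "\n")
  for (s in names(x$loci))
    cat(sprintf("  %-10s accepted loci: %d\n", s, nrow(x$loci[[s]])))
  cat("  union loci:", x$counts$union_loci,
      " homologue groups:", x$counts$groups, "\n")
  invisible(x)
}

#' Serialise a run report to JSON
#'
#' Writes the machine-readable part of a [runPipeline()] report
#' (config snapshot, per-stage counts, concordance, occurrence table)
#' with stable ordering, so identical inputs give byte-identical files.
#'
#' @param report a `ta_run_report`.
#' @param path output JSON path.
#' @export
writeRunReport <- function(report, path) {
  cfg <- report$config
  cfg_list <- stats::setNames(
    lapply(slotNames(cfg), function(s) slot(cfg, s)), slotNames(cfg))
  out <- list(
    tool = paste0("taMiner ",
                  as.character(utils::packageVersion("taMiner"))),
    config = cfg_list,
    counts = report$counts,
    concordance = list(totals = as.list(report$concordance$totals),
                       uniques = as.list(report$concordance$uniques),
                       n_intersection =
                         length(report$concordance$intersection),
                       n_union = length(report$concordance$union)),
    occurrence = report$occurrence)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
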