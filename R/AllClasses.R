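#' @import methods
NULL

#' Pipeline configuration
#'
#' Holds every numeric threshold used by the TA-discovery pipeline: ORF
#' calling parameters, alignment E-value cutoffs, the similarity acceptance
#' and review thresholds, the operon arrangement gap bound, toxin/antitoxin
#' length ranges, clustering and homologue-grouping thresholds, and the
#' random seed. Construct with [pipelineConfig()].
#'
#' @slot min_orf_len_nt minimal ORF length in nucleotides, start through
#'   stop codon inclusive (default 100).
#' @slot start_codons accepted start codons (default the canonical ATG plus
#'   the alternative starts ATA, ATC, ATT, CTG, GTG, TTG).
#' @slot translation_table NCBI genetic code id (default 11, bacterial).
#' @slot blastp_evalue E-value cutoff for pairwise protein searches
#'   (default 0.1).
#' @slot rps_evalue E-value cutoff for domain-profile scans (default 0.001).
#' @slot psi_inclusion_evalue PSSM inclusion threshold for iterative
#'   profile refinement (default 0.002).
#' @slot psi_max_iter maximum PSSM refinement rounds (default 5).
#' @slot sim_accept similarity at or above which a hit is accepted outright
#'   (default 0.80, corresponding to about 0.60 identity).
#' @slot sim_review similarity floor below which hits are discarded
#'   (default 0.50); hits between the floor and `sim_accept` must satisfy
#'   the domain/length criteria.
#' @slot len_ratio_min,len_ratio_max admissible match-to-query protein
#'   length ratio (defaults 0.55 and 1.65).
#' @slot max_gap_nt exclusive upper bound on the intergenic gap of a TA
#'   arrangement (default 100: genes overlapping or < 100 bp apart).
#' @slot toxin_len_range,antitoxin_len_range admissible protein lengths in
#'   amino acids (defaults 80--150 and 50--100).
#' @slot cluster_coverage,cluster_identity blastclust-style clustering
#'   thresholds (defaults 0.55 length coverage of the longer sequence and
#'   0.60 identity).
#' @slot group_similarity toxin similarity threshold for homologue grouping
#'   (default 0.80).
#' @slot domain_coverage_min profile coverage at or above which a domain
#'   hit counts as a complete domain (default 0.90).
#' @slot gap_open,gap_extend affine gap penalties (defaults 11 and 1).
#' @slot require_same_strand whether the arrangement test demands
#'   co-orientation (default TRUE).
#' @slot rng_seed integer seed for all stochastic components.
#'
#' @export
setClass("PipelineConfig", representation(
  min_orf_len_nt = "integer",
  start_codons = "character",
  translation_table = "integer",
  blastp_evalue = "numeric",
  rps_evalue = "numeric",
  psi_inclusion_evalue = "numeric",
  psi_max_iter = "integer",
  sim_accept = "numeric",
  sim_review = "numeric",
  len_ratio_min = "numeric",
  len_ratio_max = "numeric",
  max_gap_nt = "integer",
  toxin_len_range = "integer",
  antitoxin_len_range = "integer",
  cluster_coverage = "numeric",
  cluster_identity = "numeric",
  group_similarity = "numeric",
  domain_coverage_min = "numeric",
  gap_open = "numeric",
  gap_extend = "numeric",
  require_same_strand = "logical",
  rng_seed = "integer"
))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (object@sim_review < 0 || object@sim_review >= object@sim_accept ||
      object@sim_accept > 1)
    msg <- c(msg, "must have 0 <= sim_review < sim_accept <= 1")
  if (!(object@len_ratio_min < 1 && 1 < object@len_ratio_max))
    msg <- c(msg, "must have len_ratio_min < 1 < len_ratio_max")
  for (nm in c("toxin_len_range", "antitoxin_len_range")) {
    r <- slot(object, nm)
    if (length(r) != 2L || r[1] > r[2])
      msg <- c(msg, paste0(nm, " must be c(min, max) with min <= max"))
  }
  if (object@min_orf_len_nt < 3L)
    msg <- c(msg, "min_orf_len_nt must be >= 3")
  if (!all(nchar(object@start_codons) == 3L))
    msg <- c(msg, "start codons must be codon triplets")
  if (length(msg)) msg else TRUE
})

#' Create a pipeline configuration
#'
#' @param ... named overrides for any [PipelineConfig-class] slot.
#' @return A validated `PipelineConfig` object.
#' @examples
#' cfg <- pipelineConfig(sim_accept = 0.85)
#' cfg
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    min_orf_len_nt = 100L,
    start_codons = c("ATA", "ATC", "ATG", "ATT", "CTG", "GTG", "TTG"),
    translation_table = 11L,
    blastp_evalue = 0.1,
    rps_evalue = 0.001,
    psi_inclusion_evalue = 0.002,
    psi_max_iter = 5L,
    sim_accept = 0.80,
    sim_review = 0.50,
    len_ratio_min = 0.55,
    len_ratio_max = 1.65,
    max_gap_nt = 100L,
    toxin_len_range = c(80L, 150L),
    antitoxin_len_range = c(50L, 100L),
    cluster_coverage = 0.55,
    cluster_identity = 0.60,
    group_similarity = 0.80,
    domain_coverage_min = 0.90,
    gap_open = 11,
    gap_extend = 1,
    require_same_strand = TRUE,
    rng_seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  vals <- modifyList(defaults, over)
  int_slots <- c("min_orf_len_nt", "translation_table", "psi_max_iter",
                 "max_gap_nt", "toxin_len_range", "antitoxin_len_range",
                 "rng_seed")
  for (nm in int_slots) vals[[nm]] <- as.integer(vals[[nm]])
  vals$start_codons <- unique(toupper(vals$start_codons))
  do.call(new, c(list("PipelineConfig"), vals))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  ORF: min", object@min_orf_len_nt, "nt, starts",
      paste(object@start_codons, collapse = "/"),
      ", table", object@translation_table, "\n")
  cat("  search: blastp E<=", object@blastp_evalue,
      ", rps E<=", object@rps_evalue, "\n", sep = "")
  cat("  similarity: accept >=", object@sim_accept,
      ", review floor", object@sim_review,
      ", length ratio [", object@len_ratio_min, ",",
      object@len_ratio_max, "]\n")
  cat("  arrangement: same strand, gap <", object@max_gap_nt, "nt\n")
  cat("  lengths: toxin", paste(object@toxin_len_range, collapse = "-"),
      "aa, antitoxin", paste(object@antitoxin_len_range, collapse = "-"),
      "aa\n")
  cat("  clustering: coverage", object@cluster_coverage, ", identity",
      object@cluster_identity, "; grouping similarity",
      object@group_similarity, "\n")
  invisible(object)
})

#' Position-specific score matrix
#'
#' A PSSM built from an alignment of homologues anchored on a seed
#' sequence. `weights` holds one row per seed position with one half-bit
#' log-odds score per standard residue (columns in engine residue order).
#'
#' @slot profile_id character identifier.
#' @slot weights numeric matrix, length x 20, all finite.
#' @slot source_alignment_size number of sequences the profile was built
#'   from (seed included).
#' @slot role optional annotation, e.g. "toxin" or "antitoxin", used by the
#'   domain-profile search strategies.
#' @export
setClass("PSSMProfile", representation(
  profile_id = "character",
  weights = "matrix",
  source_alignment_size = "integer",
  role = "character"
))

setValidity("PSSMProfile", function(object) {
  w <- object@weights
  if (!is.numeric(w) || ncol(w) != 20L || nrow(w) < 1L)
    return("weights must be a length x 20 numeric matrix with length >= 1")
  if (!all(is.finite(w)))
    return("all profile scores must be finite")
  if (length(object@profile_id) != 1L || !nzchar(object@profile_id))
    return("profile_id must be a non-empty string")
  TRUE
})

#' @describeIn PSSMProfile-class number of profile positions
#' @param x,object a `PSSMProfile`
#' @export
setMethod("length", "PSSMProfile", function(x) nrow(x@weights))

#' Accessors for PSSMProfile
#'
#' @param x a [PSSMProfile-class]
#' @return `profileId` the identifier; `profileWeights` the length x 20
#'   score matrix; `profileRole` the role annotation.
#' @export
profileId <- function(x) x@profile_id

#' @rdname profileId
#' @export
profileWeights <- function(x) x@weights

#' @rdname profileId
#' @export
profileRole <- function(x) x@role

setMethod("show", "PSSMProfile", function(object) {
  cat("PSSMProfile", object@profile_id, "(", nrow(object@weights),
      "positions, built from", object@source_alignment_size,
      "sequences", if (length(object@role) && nzchar(object@role))
        paste0(", role ", object@role) else "", ")\n")
  invisible(object)
})
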