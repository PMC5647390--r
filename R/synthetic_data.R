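# Synthetic genome generator: multi-strain corpora with staphylococcal-like
# GC content, planted bicistronic TA operons at controlled divergence,
# decoy loci of five classes, domain-profile fixtures, host metadata with a
# configurable carrier-host association, and an exact truth set.

## Reverse genetic code (table 11), stops excluded.
CODONS_FOR <- local({
  cf <- split(names(GENETIC_CODE_11), GENETIC_CODE_11)
  cf[["*"]] <- NULL
  cf
})

#' Random protein with background residue composition
#'
#' Residues are drawn i.i.d. from the Robinson-Robinson background
#' frequencies; the first residue is always M so the sequence back-
#' translates to a startable ORF.
#'
#' @param len protein length in amino acids.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return A protein string.
#' @export
randomProtein <- function(len, seed = NULL) {
  gen <- function() {
    body <- sample(AA20, len - 1L, replace = TRUE, prob = AA_BACKGROUND)
    paste(c("M", body), collapse = "")
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

#' Mutate a protein to an exact target divergence
#'
#' Substitutes exactly `round(divergence * nchar(seq))` positions,
#' sampled without replacement; replacement residues are drawn
#' BLOSUM62-biased (probability proportional to `exp(score / 2)` against
#' the original residue, the original excluded), so realised identity to
#' the input is `1 - divergence` by construction while similarity decays
#' more slowly. Position 1 (the initiator M) is never substituted.
#'
#' @param seq protein string.
#' @param divergence target divergence in `[0, 1)`.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return The mutated protein (same length).
#' @export
mutateProtein <- function(seq, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence < 1)
  gen <- function() {
    n <- nchar(seq)
    k <- round(divergence * n)
    if (k == 0L) return(seq)
    res <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample(2:n, k)
    for (p in pos) {
      orig <- match(res[p], AA20)
      w <- exp(BLOSUM62_20[orig, ] / 2)
      w[orig] <- 0
      res[p] <- sample(AA20, 1L, prob = w)
    }
    paste(res, collapse = "")
  }
  if (is.null(seed)) gen() else .withSeed(seed, gen())
}

## Back-translate a protein into an ORF nucleotide sequence (uniform
## synonymous codon choice, ATG initiator, stop appended).
.backTranslate <- function(protein, stop_codon = "TAA") {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(seq_along(res), function(i) {
    if (i == 1L) return("ATG")
    opts <- CODONS_FOR[[res[i]]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(c(codons, stop_codon), collapse = "")
}

## Stop codons in all three forward frames; placed immediately upstream
## of every planted ORF so the longest-variant rule cannot extend it.
.GUARD <- "TAAATAAATAA"

## Residues whose codon set includes an A-initial codon: required at
## toxin position 2 for the -4 nt stop/start fusion.
.A_INITIAL <- c("I", "M", "T", "N", "K", "S", "R")

## Keep a derived toxin -4-fusion-compatible by restoring the pinned
## ancestor residue at position 2 when mutation has replaced it.
.pinTox2 <- function(tox, ancestor) {
  if (!substr(tox, 2L, 2L) %in% .A_INITIAL)
    substr(tox, 2L, 2L) <- substr(ancestor, 2L, 2L)
  tox
}

## TRUE when no qualifying start codon sits between the toxin start and
## the last in-frame stop upstream of it within the cassette -- i.e. the
## longest-variant rule will report the toxin ORF exactly as planted.
.cleanToxinFrame <- function(cassette, tox_start) {
  p <- tox_start - 3L
  while (p >= 1L) {
    codon <- substr(cassette, p, p + 2L)
    if (codon %in% STOP_CODONS) return(TRUE)
    if (codon %in% c("ATA", "ATC", "ATG", "ATT", "CTG", "GTG", "TTG"))
      return(FALSE)
    p <- p - 3L
  }
  TRUE
}

## Assemble the nucleotide cassette for an antitoxin-toxin pair with the
## requested gap (negative = overlap; supported overlaps are the
## canonical -1 and -4 nt stop/start fusions). Synonymous codon choices
## are redrawn until the toxin's upstream frame is clean (so both ORFs
## are recovered verbatim). Returns the cassette and the 1-based ORF
## spans within it.
.operonCassette <- function(at_protein, tox_protein, gap_nt) {
  for (try_ in seq_len(200L)) {
    cs <- .operonCassetteOnce(at_protein, tox_protein, gap_nt)
    if (.cleanToxinFrame(cs$cassette, cs$tox_span[1])) return(cs)
  }
  stop("could not realise a clean operon cassette (gap ", gap_nt, " nt)")
}

.operonCassetteOnce <- function(at_protein, tox_protein, gap_nt) {
  g <- nchar(.GUARD)
  if (gap_nt >= 0L) {
    at_nt <- .backTranslate(at_protein)
    tox_nt <- .backTranslate(tox_protein)
    gap_seq <- if (gap_nt == 0L) "" else
      paste(sample(c("C", "G", "A", "T"), gap_nt, replace = TRUE),
            collapse = "")
    if (gap_nt >= 3L) # toxin-frame stop directly abutting the toxin start
      substr(gap_seq, gap_nt - 2L, gap_nt) <- "TAA"
    cassette <- paste0(.GUARD, at_nt, gap_seq, tox_nt)
    at_span <- c(g + 1L, g + nchar(at_nt))
    tox_start <- g + nchar(at_nt) + gap_nt + 1L
    tox_span <- c(tox_start, tox_start + nchar(tox_nt) - 1L)
  } else if (gap_nt == -1L) {
    ## antitoxin stop TAA shares its final A with the toxin ATG: ...TA|ATG
    at_nt <- .backTranslate(at_protein, stop_codon = "TAA")
    tox_nt <- .backTranslate(tox_protein)
    cassette <- paste0(.GUARD, substr(at_nt, 1L, nchar(at_nt) - 1L),
                       tox_nt)
    at_span <- c(g + 1L, g + nchar(at_nt))
    tox_span <- c(g + nchar(at_nt), g + nchar(at_nt) + nchar(tox_nt) - 1L)
  } else if (gap_nt == -4L) {
    ## 4-nt stop/start fusion: the toxin start codon begins one nt
    ## before the antitoxin stop. With stop TGA the start codon is
    ## zTG (z = last nt of the antitoxin's final sense codon; ATG, CTG,
    ## GTG and TTG are all accepted starts) and the toxin's second
    ## codon must begin with the stop's trailing A; with stop TAG the
    ## start is ATA and the second codon must begin with G.
    t2 <- substr(tox_protein, 2L, 2L)
    c2A <- CODONS_FOR[[t2]][substr(CODONS_FOR[[t2]], 1L, 1L) == "A"]
    c2G <- CODONS_FOR[[t2]][substr(CODONS_FOR[[t2]], 1L, 1L) == "G"]
    ra <- substr(at_protein, nchar(at_protein), nchar(at_protein))
    raA <- CODONS_FOR[[ra]][substr(CODONS_FOR[[ra]], 3L, 3L) == "A"]
    use_A <- length(c2A) > 0L &&
      (length(c2G) == 0L || length(raA) == 0L || stats::runif(1) < 0.5)
    if (use_A) {
      at_nt <- .backTranslate(at_protein, stop_codon = "TGA")
      c2 <- c2A[sample.int(length(c2A), 1L)]
    } else if (length(c2G) && length(raA)) {
      at_nt <- .backTranslate(at_protein, stop_codon = "TAG")
      n_at0 <- nchar(at_nt)
      substr(at_nt, n_at0 - 5L, n_at0 - 3L) <-
        raA[sample.int(length(raA), 1L)]
      c2 <- c2G[sample.int(length(c2G), 1L)]
    } else {
      stop("cannot build a -4 nt overlap for toxin residue 2 '", t2,
           "' with antitoxin terminal residue '", ra, "'")
    }
    tail_res <- strsplit(substr(tox_protein, 3L, nchar(tox_protein)),
                         "", fixed = TRUE)[[1]]
    tail_codons <- vapply(tail_res, function(r) {
      opts <- CODONS_FOR[[r]]
      opts[sample.int(length(opts), 1L)]
    }, "")
    n_at <- nchar(at_nt)
    tox_rest <- paste0(substr(c2, 2L, 3L),
                       paste(tail_codons, collapse = ""), "TAA")
    cassette <- paste0(.GUARD, at_nt, tox_rest)
    at_span <- c(g + 1L, g + n_at)
    tox_len_nt <- 3L * (nchar(tox_protein) + 1L)
    tox_span <- c(g + n_at - 3L, g + n_at - 4L + tox_len_nt)
  } else {
    stop("unsupported overlap ", gap_nt,
         " nt; supported overlaps are -1 and -4")
  }
  list(cassette = cassette, at_span = at_span, tox_span = tox_span)
}

## Cassette for a single guarded ORF (orphan/decoy components).
.orfCassette <- function(protein) {
  nt <- .backTranslate(protein)
  list(cassette = paste0(.GUARD, nt),
       span = c(nchar(.GUARD) + 1L, nchar(.GUARD) + nchar(nt)))
}

#' Plant a TA operon into a contig
#'
#' Overwrites a window of the contig with a guarded operon cassette:
#' stop codons in all three frames directly upstream of the antitoxin
#' start, the back-translated antitoxin ORF, the requested gap (with an
#' in-frame stop abutting the toxin start) or a canonical -1/-4 nt
#' stop-start overlap, and the back-translated toxin ORF. Both ORFs are
#' recoverable verbatim by [findOrfs()].
#'
#' @param contig_seq contig DNA string.
#' @param at_protein,tox_protein the proteins to plant (initial M).
#' @param position 1-based insertion offset of the cassette.
#' @param strand `"+"` or `"-"`.
#' @param gap_nt intergenic gap in nt (negative = overlap; -1 and -4
#'   supported).
#' @param seed optional seed for the synonymous codon choices.
#' @return A list: `contig_seq` (modified), and 1-based forward-strand
#'   `at_start`, `at_end`, `tox_start`, `tox_end`.
#' @export
plantOperon <- function(contig_seq, at_protein, tox_protein, position,
                        strand = "+", gap_nt = 0L, seed = NULL) {
  build <- function() {
    cs <- .operonCassette(at_protein, tox_protein, gap_nt)
    .spliceCassette(contig_seq, cs$cassette, position, strand,
                    list(at = cs$at_span, tox = cs$tox_span))
  }
  out <- if (is.null(seed)) build() else .withSeed(seed, build())
  list(contig_seq = out$contig_seq,
       at_start = out$spans$at[1], at_end = out$spans$at[2],
       tox_start = out$spans$tox[1], tox_end = out$spans$tox[2])
}

## Overwrite contig[position, position+len-1] with the cassette (reverse
## complemented for the minus strand) and map the within-cassette spans
## to forward-strand contig coordinates.
.spliceCassette <- function(contig_seq, cassette, position, strand,
                            spans) {
  len <- nchar(cassette)
  L <- nchar(contig_seq)
  if (position < 1L || position + len - 1L > L)
    stop("contig too short for cassette at position ", position)
  ins <- if (strand == "-")
    as.character(reverseComplement(DNAStringSet(cassette)[[1]]))
  else cassette
  substr(contig_seq, position, position + len - 1L) <- ins
  p0 <- position - 1L
  map <- function(sp) {
    if (strand == "+") c(p0 + sp[1], p0 + sp[2])
    else c(p0 + len - sp[2] + 1L, p0 + len - sp[1] + 1L)
  }
  list(contig_seq = contig_seq, spans = lapply(spans, map))
}

#' Describe a planted TA family
#'
#' A family is defined by ancestor toxin/antitoxin proteins (the search
#' seeds), a family *centre* derived from the ancestor at
#' `center_divergence` (possibly through `lineage_steps` successive
#' mutation rounds, producing stepping-stone intermediates), and members
#' drawn around the centre at `member_jitter`. With a small jitter the
#' within-family pairwise similarity stays high while the divergence
#' from the seed is controlled by the centre.
#'
#' @param family_id family label.
#' @param ancestor_toxin,ancestor_antitoxin ancestor proteins; defaults
#'   are generated from the background composition at 110 and 70 aa.
#' @param center_divergence per-step divergence of the family centre
#'   from the ancestor.
#' @param lineage_steps number of successive mutation rounds between the
#'   ancestor and the centre (default 1).
#' @param member_jitter per-member divergence from the centre.
#' @param gap_nt operon arrangement gap (negative = overlap).
#' @param carrier_fraction fraction of strains carrying the family.
#' @param replicon_label `"chromosome"` or `"plasmid"`.
#' @return A `planted_family` list.
#' @export
plantedFamily <- function(family_id, ancestor_toxin = NULL,
                          ancestor_antitoxin = NULL,
                          center_divergence = 0.1, lineage_steps = 1L,
                          member_jitter = 0.02, gap_nt = 0L,
                          carrier_fraction = 0.5,
                          replicon_label = "chromosome") {
  structure(list(
    family_id = family_id, ancestor_toxin = ancestor_toxin,
    ancestor_antitoxin = ancestor_antitoxin,
    center_divergence = center_divergence,
    lineage_steps = as.integer(lineage_steps),
    member_jitter = member_jitter, gap_nt = as.integer(gap_nt),
    carrier_fraction = carrier_fraction,
    replicon_label = replicon_label), class = "planted_family")
}

#' Define a simulation scenario
#'
#' @param n_strains,n_species corpus size (species assigned round-robin).
#' @param contigs_per_strain,contig_len_nt contig layout per strain.
#' @param gc_content background GC fraction (default 0.33,
#'   staphylococcal-like).
#' @param families list of [plantedFamily()] descriptions.
#' @param decoy_spec named integer vector of decoy counts by class:
#'   `orphan_toxin`, `wide_gap`, `opposite_strand`, `oversized_toxin`,
#'   `undersized_antitoxin`.
#' @param host_model list with `categories` (named host probabilities),
#'   and optionally `focal_family`, `focal_host`, `strength` in \[0, 1\]
#'   (probability that a focal-family carrier is drawn from the focal
#'   host instead of the base distribution).
#' @param rng_seed integer seed governing the whole corpus.
#' @return A `ta_scenario` list.
#' @export
simulationScenario <- function(n_strains = 20L, n_species = 4L,
                               contigs_per_strain = 1L,
                               contig_len_nt = 12000L,
                               gc_content = 0.33, families = list(),
                               decoy_spec = c(orphan_toxin = 0L,
                                              wide_gap = 0L,
                                              opposite_strand = 0L,
                                              oversized_toxin = 0L,
                                              undersized_antitoxin = 0L),
                               host_model = NULL, rng_seed = 42L) {
  if (is.null(host_model))
    host_model <- list(categories = c(
      "Homo sapiens" = 0.4, "Bos taurus" = 0.2, "Gallus gallus" = 0.2,
      "Meleagris gallopavo" = 0.1, "Mus musculus" = 0.1))
  stopifnot(abs(sum(host_model$categories) - 1) < 1e-8)
  structure(list(
    n_strains = as.integer(n_strains), n_species = as.integer(n_species),
    contigs_per_strain = as.integer(contigs_per_strain),
    contig_len_nt = as.integer(contig_len_nt), gc_content = gc_content,
    families = families, decoy_spec = decoy_spec,
    host_model = host_model, rng_seed = as.integer(rng_seed)),
    class = "ta_scenario")
}

#' The default study scenario
#'
#' Twenty strains over four species, one 12 kb contig each, GC 0.33;
#' five planted families whose centres sit at 5/10/15/20/25% divergence
#' from their seed ancestors with 2% member jitter (so within-family
#' similarity stays >= 0.95 while seed divergence spans the regime where
#' all strategies should agree); carrier fractions 1.0 down to 0.3;
#' arrangements covering the canonical overlaps (-4, -1) and gaps (0,
#' 12, 45 nt); two decoys of each of the five classes; and a
#' poultry-biased host association for the rarest family.
#'
#' @param rng_seed corpus seed.
#' @param divergences family-centre divergences from the seeds.
#' @return A `ta_scenario`.
#' @export
defaultScenario <- function(rng_seed = 42L,
                            divergences = c(0.05, 0.10, 0.15, 0.20,
                                            0.25)) {
  fams <- lapply(seq_along(divergences), function(k) {
    plantedFamily(
      family_id = sprintf("fam%02d", k),
      center_divergence = divergences[k],
      member_jitter = 0.02,
      gap_nt = c(-4L, -1L, 0L, 12L, 45L)[(k - 1L) %% 5L + 1L],
      carrier_fraction = c(1.0, 0.6, 0.5, 0.4, 0.3)[(k - 1L) %% 5L + 1L],
      replicon_label = c("chromosome", "plasmid")[(k - 1L) %% 2L + 1L])
  })
  sc <- simulationScenario(
    n_strains = 20L, n_species = 4L, contig_len_nt = 12000L,
    families = fams,
    decoy_spec = c(orphan_toxin = 2L, wide_gap = 2L,
                   opposite_strand = 2L, oversized_toxin = 2L,
                   undersized_antitoxin = 2L),
    rng_seed = rng_seed)
  sc$host_model$focal_family <- sprintf("fam%02d", length(divergences))
  sc$host_model$focal_host <- "Meleagris gallopavo"
  sc$host_model$strength <- 0.9
  sc
}

#' Generate a synthetic corpus with ground truth
#'
#' Deterministic under `rng_seed`: background sequence i.i.d. at the
#' requested GC, planted family operons at controlled divergence, decoy
#' loci of the five classes, domain-profile fixtures built from each
#' family's ancestor alignments, and host metadata drawn from the host
#' model. Every planted ORF is verified to be recovered exactly by
#' [findOrfs()] (strains are re-drawn, deterministically, in the rare
#' case a random background ORF would distort a planted locus or rescue
#' a decoy).
#'
#' @param scenario a `ta_scenario` from [simulationScenario()].
#' @param config a [PipelineConfig-class] (ORF calling parameters used
#'   during verification).
#' @return A list: `contigs` (`DNAStringSet` across strains), `metadata`
#'   (strain roster), `seeds` (ancestor [seedSet()]), `profiles` (named
#'   list of [PSSMProfile-class]), `truth` (planted locus table),
#'   `decoys` (decoy registry), `contig_locations` (replicon labels).
#' @export
generateScenario <- function(scenario, config = pipelineConfig()) {
  stopifnot(inherits(scenario, "ta_scenario"))
  .withSeed(scenario$rng_seed, .generateScenarioImpl(scenario, config))
}

.generateScenarioImpl <- function(scenario, config) {
  ns <- scenario$n_strains
  strains <- sprintf("S%02d", seq_len(ns))
  species <- sprintf("Staphylococcus sp%02d",
                     rep_len(seq_len(scenario$n_species), ns))
  ## materialise family ancestors and centres
  fams <- lapply(scenario$families, function(f) {
    user_anc <- !is.null(f$ancestor_toxin) ||
      !is.null(f$ancestor_antitoxin)
    for (draw in seq_len(30L)) {
      if (is.null(f$ancestor_toxin) || draw > 1L)
        f$ancestor_toxin <- randomProtein(110L)
      if (is.null(f$ancestor_antitoxin) || draw > 1L)
        f$ancestor_antitoxin <- randomProtein(70L)
      if (f$gap_nt == -4L) {
        ## the 4-nt stop/start fusion requires an A-initial codon for
        ## the toxin's second residue; pin it in the ancestor
        t2 <- substr(f$ancestor_toxin, 2L, 2L)
        if (!t2 %in% .A_INITIAL)
          substr(f$ancestor_toxin, 2L, 2L) <- sample(.A_INITIAL, 1L)
      }
      ct <- f$ancestor_toxin
      ca <- f$ancestor_antitoxin
      f$intermediates_tox <- character(0)
      f$intermediates_at <- character(0)
      for (s in seq_len(f$lineage_steps)) {
        ct <- mutateProtein(ct, f$center_divergence)
        if (f$gap_nt == -4L) ct <- .pinTox2(ct, f$ancestor_toxin)
        ca <- mutateProtein(ca, f$center_divergence)
        if (s < f$lineage_steps) {
          f$intermediates_tox <- c(f$intermediates_tox, ct)
          f$intermediates_at <- c(f$intermediates_at, ca)
        }
      }
      f$center_toxin <- ct
      f$center_antitoxin <- ca
      ## overlap cassettes constrain both reading frames: certain
      ## residue patterns near the antitoxin C-terminus make a family
      ## unplantable for any synonymous choice, so verify on the
      ## centre pair and re-draw the ancestors when stuck
      ok <- f$gap_nt >= 0L ||
        !is.null(tryCatch(.operonCassette(f$center_antitoxin,
                                          f$center_toxin, f$gap_nt),
                          error = function(e) NULL))
      if (ok) break
      if (user_anc)
        stop("family ", f$family_id, ": the supplied ancestors cannot ",
             "realise a ", f$gap_nt, " nt overlap cassette")
      if (draw == 30L)
        stop("family ", f$family_id, ": no realisable ancestor pair ",
             "found for a ", f$gap_nt, " nt overlap")
    }
    ## exact carrier quota
    n_car <- round(f$carrier_fraction * ns)
    f$carriers <- strains[sample.int(ns, n_car)]
    f
  })
  names(fams) <- vapply(fams, `[[`, "", "family_id")

  ## domain-profile fixtures from the family alignments: near mutants
  ## of the ancestor plus, for lineage families, the planted
  ## intermediates and the family centre, so the profile spans the
  ## family's realised diversity the way a curated domain model would
  profiles <- list()
  for (f in fams) {
    for (role in c("toxin", "antitoxin")) {
      anc <- if (role == "toxin") f$ancestor_toxin else
        f$ancestor_antitoxin
      members <- c(replicate(6L, mutateProtein(anc, 0.08)),
                   if (role == "toxin")
                     c(f$intermediates_tox, f$center_toxin)
                   else c(f$intermediates_at, f$center_antitoxin))
      aln <- lapply(members, function(m) alignPair(anc, m))
      pid <- paste0(f$family_id, "_", substr(role, 1, 3), "_dom")
      profiles[[pid]] <- buildPssm(anc, aln, profile_id = pid,
                                   role = role)
    }
  }

  ## decoy assignment: round-robin over strains
  decoy_plan <- list()
  dn <- scenario$decoy_spec
  dn <- dn[dn > 0L]
  si <- 0L
  for (cls in names(dn)) for (r in seq_len(dn[[cls]])) {
    si <- si + 1L
    decoy_plan[[length(decoy_plan) + 1L]] <-
      list(class = cls, strain = strains[(si - 1L) %% ns + 1L])
  }
  donor <- fams[[1L]] # decoy proteins derive from the first family

  contigs_seq <- character(0)
  contig_meta <- list()
  truth <- list()
  decoys <- list()
  contig_locations <- character(0)

  for (k in seq_len(ns)) {
    strain <- strains[k]
    plan_fams <- Filter(function(f) strain %in% f$carriers, fams)
    plan_decs <- Filter(function(d) d$strain == strain, decoy_plan)
    ## lineage stepping stones are planted in the first two carriers
    extra <- list()
    for (f in plan_fams) {
      if (length(f$intermediates_tox) &&
          match(strain, f$carriers) <= length(f$intermediates_tox)) {
        step <- match(strain, f$carriers)
        extra[[length(extra) + 1L]] <-
          list(family = f, tox = f$intermediates_tox[step],
               at = f$intermediates_at[step], stepping_stone = TRUE)
      }
    }
    built <- NULL
    for (attempt in seq_len(25L)) {
      built <- .buildStrain(strain, species[k], plan_fams, plan_decs,
                            extra, donor, scenario, config, profiles)
      if (!is.null(built)) break
    }
    if (is.null(built))
      stop("could not build a clean strain for ", strain,
           " after 25 attempts; contig too short or too crowded")
    contigs_seq <- c(contigs_seq, built$seqs)
    contig_meta <- c(contig_meta, built$meta)
    truth <- c(truth, built$truth)
    decoys <- c(decoys, built$decoys)
    contig_locations <- c(contig_locations, built$locations)
  }

  meta_df <- do.call(rbind, lapply(contig_meta, as.data.frame))
  contigs <- DNAStringSet(contigs_seq)
  names(contigs) <- meta_df$contig_id
  S4Vectors::mcols(contigs) <- S4Vectors::DataFrame(
    strain_id = meta_df$strain_id, species = meta_df$species,
    topology = "linear")

  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  decoy_df <- if (length(decoys)) do.call(rbind, decoys) else
    data.frame(class = character(), strain_id = character(),
               contig_id = character(), strand = character(),
               tox_start = integer(), tox_end = integer(),
               stringsAsFactors = FALSE)

  ## host metadata with the configured carrier-host association
  hm <- scenario$host_model
  hosts <- names(hm$categories)
  host_of <- sample(hosts, ns, replace = TRUE, prob = hm$categories)
  names(host_of) <- strains
  if (!is.null(hm$focal_family) && hm$focal_family %in% names(fams)) {
    for (s in fams[[hm$focal_family]]$carriers)
      if (stats::runif(1) < hm$strength) host_of[s] <- hm$focal_host
  }
  metadata <- data.frame(
    strain_id = strains, species = species, host = unname(host_of),
    geo_location = "simulated", collection_date = "2016-01-01",
    stringsAsFactors = FALSE)

  seeds <- seedSet(
    toxins = stats::setNames(
      vapply(fams, `[[`, "", "ancestor_toxin"),
      paste0(names(fams), "_toxK")),
    antitoxins = stats::setNames(
      vapply(fams, `[[`, "", "ancestor_antitoxin"),
      paste0(names(fams), "_antI")))

  list(contigs = contigs, metadata = metadata, seeds = seeds,
       profiles = profiles, truth = truth_df, decoys = decoy_df,
       contig_locations = contig_locations, families = fams)
}

## Build one strain: background contigs, planted cassettes, decoys.
## Returns NULL when verification fails (caller re-draws).
.buildStrain <- function(strain, species, plan_fams, plan_decs, extra,
                         donor, scenario, config, profiles) {
  L <- scenario$contig_len_nt
  gc <- scenario$gc_content
  n_ctg <- scenario$contigs_per_strain
  seqs <- vapply(seq_len(n_ctg), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = ""), "")
  cids <- paste0(strain, "_c", seq_len(n_ctg))

  ## slot layout: cassettes spaced >= 400 nt apart on contig 1 (plasmid
  ## families go to the last contig when there are several)
  n_items <- length(plan_fams) + length(plan_decs) + length(extra)
  if (n_items == 0L) {
    return(list(
      seqs = seqs,
      meta = lapply(seq_len(n_ctg), function(i)
        list(contig_id = cids[i], strain_id = strain,
             species = species)),
      truth = list(), decoys = list(),
      locations = stats::setNames(rep("chromosome", n_ctg), cids)))
  }
  slot_w <- floor((L - 200L) / max(n_items, 1L))
  if (slot_w < 1500L)
    stop("contig_len_nt too small for ", n_items, " planted items")
  positions <- 100L + slot_w * (seq_len(n_items) - 1L) +
    sample.int(200L, n_items, replace = TRUE)
  strands <- rep_len(c("+", "-"), n_items)

  truth <- list()
  decoys <- list()
  item <- 0L
  ctg_of <- function(f) if (n_ctg > 1L &&
                            identical(f$replicon_label, "plasmid"))
    n_ctg else 1L
  locations <- stats::setNames(rep("chromosome", n_ctg), cids)
  if (n_ctg > 1L) locations[n_ctg] <- "plasmid"

  for (f in plan_fams) {
    item <- item + 1L
    tox <- mutateProtein(f$center_toxin, f$member_jitter)
    if (f$gap_nt == -4L) tox <- .pinTox2(tox, f$ancestor_toxin)
    at <- mutateProtein(f$center_antitoxin, f$member_jitter)
    ci <- ctg_of(f)
    pl <- tryCatch(plantOperon(seqs[ci], at, tox, positions[item],
                               strands[item], f$gap_nt),
                   error = function(e) NULL)
    if (is.null(pl)) return(NULL) # un-plantable member: re-draw strain
    seqs[ci] <- pl$contig_seq
    truth[[length(truth) + 1L]] <- data.frame(
      family_id = f$family_id, strain_id = strain, contig_id = cids[ci],
      strand = strands[item], at_start = pl$at_start,
      at_end = pl$at_end, tox_start = pl$tox_start,
      tox_end = pl$tox_end, gap_nt = f$gap_nt, at_protein = at,
      tox_protein = tox, replicon = f$replicon_label,
      stepping_stone = FALSE, stringsAsFactors = FALSE)
  }
  for (e in extra) {
    item <- item + 1L
    pl <- tryCatch(plantOperon(seqs[1L], e$at, e$tox, positions[item],
                               strands[item], e$family$gap_nt),
                   error = function(e_) NULL)
    if (is.null(pl)) return(NULL)
    seqs[1L] <- pl$contig_seq
    truth[[length(truth) + 1L]] <- data.frame(
      family_id = e$family$family_id, strain_id = strain,
      contig_id = cids[1L], strand = strands[item],
      at_start = pl$at_start, at_end = pl$at_end,
      tox_start = pl$tox_start, tox_end = pl$tox_end,
      gap_nt = e$family$gap_nt, at_protein = e$at, tox_protein = e$tox,
      replicon = "chromosome", stepping_stone = TRUE,
      stringsAsFactors = FALSE)
  }
  for (d in plan_decs) {
    item <- item + 1L
    dec <- tryCatch(.plantDecoy(seqs[1L], d$class, donor,
                                positions[item], strands[item]),
                    error = function(e) NULL)
    if (is.null(dec)) return(NULL)
    seqs[1L] <- dec$contig_seq
    decoys[[length(decoys) + 1L]] <- data.frame(
      class = d$class, strain_id = strain, contig_id = cids[1L],
      strand = dec$tox_strand,
      tox_start = dec$tox_start, tox_end = dec$tox_end,
      at_strand = if (is.null(dec$at_strand)) NA_character_ else
        dec$at_strand,
      at_start = if (is.null(dec$at_start)) NA_integer_ else
        dec$at_start,
      at_end = if (is.null(dec$at_end)) NA_integer_ else dec$at_end,
      stringsAsFactors = FALSE)
  }

  ## verification: every planted ORF recovered exactly; no background
  ## ORF can stand in as a plausible partner for a decoy toxin
  ctg <- makeContigSet(seqs, cids, strain, species)
  orfs <- findOrfs(ctg, config)
  ot <- .orfTable(orfs)
  key <- function(c_, s_, a, b) paste(c_, s_, a, b)
  have <- key(ot$contig_id, ot$strand, ot$start, ot$end)
  for (t in truth) {
    if (!key(t$contig_id, t$strand, t$at_start, t$at_end) %in% have)
      return(NULL)
    if (!key(t$contig_id, t$strand, t$tox_start, t$tox_end) %in% have)
      return(NULL)
  }
  pairs <- .adjacentPairs(ot, config)
  u_key <- have[pairs$u]
  d_key <- have[pairs$d]
  at_rng <- config@antitoxin_len_range
  tox_rng <- config@toxin_len_range
  for (d in decoys) {
    ## a background ORF in the antitoxin length range upstream of a
    ## decoy toxin could rescue it (except the oversized class, which
    ## is rejected on the toxin arm alone); re-draw the strain
    if (d$class != "oversized_toxin") {
      dk <- key(d$contig_id, d$strand, d$tox_start, d$tox_end)
      ups <- pairs$u[d_key == dk]
      if (any(ot$plen[ups] >= at_rng[1] & ot$plen[ups] <= at_rng[2]))
        return(NULL)
    }
    ## symmetrically, a background ORF in the toxin length range
    ## downstream of an evidence-carrying decoy antitoxin could pair
    ## with it into a spurious locus
    if (!is.na(d$at_start) && d$class != "undersized_antitoxin") {
      ak <- key(d$contig_id, d$at_strand, d$at_start, d$at_end)
      downs <- pairs$d[u_key == ak]
      down_key <- have[downs]
      planted_tox <- key(d$contig_id, d$strand, d$tox_start, d$tox_end)
      extra_down <- downs[down_key != planted_tox]
      if (any(ot$plen[extra_down] >= tox_rng[1] &
              ot$plen[extra_down] <= tox_rng[2]))
        return(NULL)
    }
  }
  list(seqs = seqs,
       meta = lapply(seq_len(n_ctg), function(i)
         list(contig_id = cids[i], strain_id = strain,
              species = species)),
       truth = truth, decoys = decoys, locations = locations)
}

## Plant one decoy of the requested class; returns modified contig and
## the decoy toxin span (forward coordinates).
.plantDecoy <- function(contig_seq, class, donor, position, strand) {
  tox <- mutateProtein(donor$center_toxin, 0.05)
  at <- mutateProtein(donor$center_antitoxin, 0.05)
  if (class == "orphan_toxin") {
    cs <- .orfCassette(tox)
    sp <- .spliceCassette(contig_seq, cs$cassette, position, strand,
                          list(tox = cs$span))
    return(list(contig_seq = sp$contig_seq, tox_strand = strand,
                tox_start = sp$spans$tox[1], tox_end = sp$spans$tox[2]))
  }
  if (class == "wide_gap") {
    cs <- .operonCassette(at, tox, 150L)
    sp <- .spliceCassette(contig_seq, cs$cassette, position, strand,
                          list(at = cs$at_span, tox = cs$tox_span))
    return(list(contig_seq = sp$contig_seq, tox_strand = strand,
                tox_start = sp$spans$tox[1], tox_end = sp$spans$tox[2],
                at_strand = strand, at_start = sp$spans$at[1],
                at_end = sp$spans$at[2]))
  }
  if (class == "opposite_strand") {
    ## antitoxin on one strand, toxin close by on the other
    cs_at <- .orfCassette(at)
    sp1 <- .spliceCassette(contig_seq, cs_at$cassette, position, strand,
                           list(at = cs_at$span))
    cs_tox <- .orfCassette(tox)
    other <- if (strand == "+") "-" else "+"
    pos2 <- position + nchar(cs_at$cassette) + 40L
    sp2 <- .spliceCassette(sp1$contig_seq, cs_tox$cassette, pos2, other,
                           list(tox = cs_tox$span))
    return(list(contig_seq = sp2$contig_seq, tox_strand = other,
                tox_start = sp2$spans$tox[1],
                tox_end = sp2$spans$tox[2], at_strand = strand,
                at_start = sp1$spans$at[1], at_end = sp1$spans$at[2]))
  }
  if (class == "oversized_toxin") {
    ## domain-free 195-aa "toxin" downstream of a genuine family
    ## antitoxin: the antitoxin hit creates the candidate, which must
    ## then fail on the toxin arm (no domain, length out of range)
    big <- randomProtein(195L)
    cs <- .operonCassette(at, big, 10L)
    sp <- .spliceCassette(contig_seq, cs$cassette, position, strand,
                          list(at = cs$at_span, tox = cs$tox_span))
    return(list(contig_seq = sp$contig_seq, tox_strand = strand,
                tox_start = sp$spans$tox[1], tox_end = sp$spans$tox[2],
                at_strand = strand, at_start = sp$spans$at[1],
                at_end = sp$spans$at[2]))
  }
  if (class == "undersized_antitoxin") {
    ## moderately diverged toxin whose only neighbour is a 40-aa random
    ## partner: the antitoxin arm of the criteria cannot be satisfied
    tox2 <- mutateProtein(donor$center_toxin, 0.30)
    small <- randomProtein(40L)
    cs <- .operonCassette(small, tox2, 8L)
    sp <- .spliceCassette(contig_seq, cs$cassette, position, strand,
                          list(at = cs$at_span, tox = cs$tox_span))
    return(list(contig_seq = sp$contig_seq, tox_strand = strand,
                tox_start = sp$spans$tox[1], tox_end = sp$spans$tox[2]))
  }
  stop("unknown decoy class: ", class)
}

#' Build a profile-dead toxin
#'
#' Constructs a toxin whose domain signal is undetectable by a direct
#' profile scan: the most conserved profile positions are substituted
#' with that position's worst-scoring residue, increasing the
#' substituted fraction until the direct profile E-value exceeds
#' `rps_evalue`. Such a toxin mirrors a distant homologue whose domain
#' escapes direct profile detection; the locus remains discoverable
#' only through its intact-domain antitoxin neighbour.
#'
#' @param ancestor_toxin the ancestor toxin protein.
#' @param profile the family toxin [PSSMProfile-class].
#' @param config a [PipelineConfig-class].
#' @return The modified toxin protein.
#' @export
profileDeadToxin <- function(ancestor_toxin, profile,
                             config = pipelineConfig()) {
  w <- profile@weights
  res <- strsplit(ancestor_toxin, "", fixed = TRUE)[[1]]
  ord <- order(-apply(w, 1L, max)) # most conserved first
  ord <- ord[ord != 1L]
  for (frac in seq(0.40, 0.80, by = 0.05)) {
    k <- round(frac * length(res))
    mod <- res
    for (p in ord[seq_len(min(k, length(ord)))])
      mod[p] <- AA20[which.min(w[p, ])]
    seq_ <- paste(mod, collapse = "")
    direct <- searchPssm(profile, stats::setNames(seq_, "x"),
                         config@gap_open, config@gap_extend,
                         db_residues = nchar(seq_))
    if (nrow(direct) == 0L || direct$evalue[1] > config@rps_evalue)
      return(seq_)
  }
  stop("could not construct a profile-dead toxin")
}

#' Corpus with a domain-escape rescue strain
#'
#' Generates a single-family corpus and appends one extra strain whose
#' planted toxin is a [profileDeadToxin()]: its domain escapes a direct
#' profile scan while the adjacent antitoxin keeps a detectable domain.
#' This exercises the neighbour-rescue path -- a locus invisible to the
#' direct toxin scan of the domain-profile strategy but recovered by the
#' sequence-based strategies (and by the profile strategy through its
#' antitoxin).
#'
#' @param rng_seed corpus seed.
#' @param n_strains carrier strains before the rescue strain is added.
#' @param config a [PipelineConfig-class].
#' @return As [generateScenario()], plus `rescue`: the special strain's
#'   locus coordinates and proteins.
#' @export
rescueCorpus <- function(rng_seed = 42L, n_strains = 6L,
                         config = pipelineConfig()) {
  sc <- simulationScenario(
    n_strains = n_strains, n_species = 2L, contig_len_nt = 8000L,
    families = list(plantedFamily("fam01", center_divergence = 0.05,
                                  gap_nt = 6L, carrier_fraction = 1.0)),
    rng_seed = rng_seed)
  corpus <- generateScenario(sc, config)
  fam <- corpus$families$fam01
  dead <- profileDeadToxin(fam$ancestor_toxin,
                           corpus$profiles$fam01_tox_dom, config)
  res <- .withSeed(rng_seed + 99991L, {
    strain <- "SR1"
    cid <- "SR1_c1"
    at <- mutateProtein(fam$center_antitoxin, 0.02)
    done <- NULL
    for (attempt in seq_len(50L)) {
      seq_ <- paste(sample(c("A", "C", "G", "T"), 8000L, replace = TRUE,
                           prob = c(0.335, 0.165, 0.165, 0.335)),
                    collapse = "")
      pl <- plantOperon(seq_, at, dead, 3000L, "+", 8L)
      ctg <- makeContigSet(pl$contig_seq, cid, strain, "Staph sp01")
      ot <- .orfTable(findOrfs(ctg, config))
      ok_at <- any(ot$strand == "+" & ot$start == pl$at_start &
                     ot$end == pl$at_end)
      ok_tox <- any(ot$strand == "+" & ot$start == pl$tox_start &
                      ot$end == pl$tox_end)
      if (ok_at && ok_tox) {
        done <- list(ctg = ctg, pl = pl, at = at)
        break
      }
    }
    done
  })
  if (is.null(res)) stop("could not build the rescue strain")
  corpus$contigs <- c(corpus$contigs, res$ctg)
  corpus$metadata <- rbind(corpus$metadata, data.frame(
    strain_id = "SR1", species = "Staph sp01", host = NA_character_,
    geo_location = "simulated", collection_date = "2016-01-01",
    stringsAsFactors = FALSE))
  corpus$truth <- rbind(corpus$truth, data.frame(
    family_id = "fam01", strain_id = "SR1", contig_id = "SR1_c1",
    strand = "+", at_start = res$pl$at_start, at_end = res$pl$at_end,
    tox_start = res$pl$tox_start, tox_end = res$pl$tox_end,
    gap_nt = 8L, at_protein = res$at, tox_protein = dead,
    replicon = "chromosome", stepping_stone = FALSE,
    stringsAsFactors = FALSE))
  corpus$rescue <- list(strain_id = "SR1", contig_id = "SR1_c1",
                        tox_start = res$pl$tox_start,
                        tox_end = res$pl$tox_end,
                        at_start = res$pl$at_start,
                        at_end = res$pl$at_end,
                        tox_protein = dead, at_protein = res$at)
  corpus
}

#' Write a generated corpus to disk
#'
#' One FASTA per strain, the metadata TSV, the profile fixture file and
#' the truth set as JSON.
#'
#' @param corpus output of [generateScenario()].
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mc <- S4Vectors::mcols(corpus$contigs)
  for (strain in unique(mc$strain_id)) {
    sel <- corpus$contigs[mc$strain_id == strain]
    Biostrings::writeXStringSet(sel, file.path(dir,
                                               paste0(strain, ".fasta")))
  }
  writeMetadata(corpus$metadata, file.path(dir, "metadata.tsv"))
  writePssmSet(corpus$profiles, file.path(dir, "profiles.pssm"))
  jsonlite::write_json(
    list(truth = corpus$truth, decoys = corpus$decoys,
         contig_locations = as.list(corpus$contig_locations)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
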