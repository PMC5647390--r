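make_orf_gr <- function(contig, strand, start, end, strain = "s1",
                        protein = strrep("MK", 30)) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    orf_id = paste(strain, contig, strand, start, end, sep = "|"),
    strain_id = strain, protein = protein,
    start_codon = "ATG", nt_len = end - start + 1L)
  gr
}

test_that("the TA arrangement predicate enforces the 100 bp bound", {
  cfg <- pipelineConfig()
  up <- make_orf_gr("c1", "+", 101, 313)
  ## gap of 99 nt: downstream starts at 313 + 100
  expect_true(isTaArrangement(up, make_orf_gr("c1", "+", 413, 745), cfg))
  ## gap of exactly 100 nt is excluded
  expect_false(isTaArrangement(up, make_orf_gr("c1", "+", 414, 746), cfg))
  ## 4-nt overlap passes
  expect_true(isTaArrangement(up, make_orf_gr("c1", "+", 310, 642), cfg))
  ## opposite strands fail under the default co-orientation rule
  expect_false(isTaArrangement(up, make_orf_gr("c1", "-", 413, 745), cfg))
  ## ... but are admitted when co-orientation is relaxed
  cfg2 <- pipelineConfig(require_same_strand = FALSE)
  expect_true(isTaArrangement(up, make_orf_gr("c1", "-", 413, 745), cfg2))
  ## different contigs never pair
  expect_false(isTaArrangement(up, make_orf_gr("c2", "+", 413, 745), cfg))
  ## minus-strand pair: upstream gene has the larger coordinates
  upm <- make_orf_gr("c1", "-", 500, 712)
  dnm <- make_orf_gr("c1", "-", 150, 482)
  expect_true(isTaArrangement(upm, dnm, cfg))
  expect_false(isTaArrangement(dnm, upm, cfg))
})

test_that("inclusion criteria implement the similarity/length decision", {
  cfg <- pipelineConfig()
  dec <- function(...) {
    df <- applyInclusionCriteria(data.frame(...), cfg)
    list(d = df$decision, r = df$rejection_reason)
  }
  ## high similarity with in-range ratio
  x <- dec(similarity = 0.85, len_ratio = 1.0, tox_len = 110L,
           at_len = 70L)
  expect_equal(x$d, "accepted_high_similarity")
  ## review band rescued by the length criteria
  x <- dec(similarity = 0.65, len_ratio = 1.0, tox_len = 120L,
           at_len = 70L)
  expect_equal(x$d, "accepted_by_criteria")
  ## review band, oversized toxin without a domain hit
  x <- dec(similarity = 0.65, len_ratio = 1.0, tox_len = 160L,
           at_len = 70L)
  expect_equal(x$d, "rejected")
  expect_equal(x$r, "toxin length/domain")
  ## below the review floor
  x <- dec(similarity = 0.45, len_ratio = 1.0, tox_len = 110L,
           at_len = 70L)
  expect_equal(x$d, "rejected")
  expect_equal(x$r, "below review floor")
  ## a complete domain substitutes for an out-of-range length
  x <- dec(similarity = 0.65, len_ratio = 1.0, tox_len = 160L,
           at_len = 70L, tox_domain_complete = TRUE)
  expect_equal(x$d, "accepted_by_criteria")
  ## high similarity with out-of-range ratio falls through and fails
  x <- dec(similarity = 0.9, len_ratio = 1.8, tox_len = 200L,
           at_len = 70L)
  expect_equal(x$d, "rejected")
})

test_that("co-localisation coefficient counts carrier strains", {
  ## 6 strains carry cluster members; members co-localise in 3
  cfg <- pipelineConfig()
  ot <- list()
  for (i in 1:6) {
    s <- sprintf("s%d", i)
    ot[[length(ot) + 1]] <- data.frame(
      orf_id = paste0(s, "_A"), strain_id = s, contig_id = paste0(s, "_c"),
      strand = "+", start = 101L, end = 313L,
      protein = strrep("MK", 35), plen = 70L)
    ## in strains 1-3 the partner sits 10 nt downstream; in 4-6 it is
    ## 500 nt away (no arrangement)
    off <- if (i <= 3) 324L else 814L
    ot[[length(ot) + 1]] <- data.frame(
      orf_id = paste0(s, "_B"), strain_id = s, contig_id = paste0(s, "_c"),
      strand = "+", start = off, end = off + 332L,
      protein = strrep("MW", 55), plen = 110L)
  }
  ot <- do.call(rbind, ot)
  coef <- colocCoefficient(paste0("s", 1:6, "_A"),
                           paste0("s", 1:6, "_B"), ot, cfg)
  expect_equal(coef, 0.5)
  ## never co-localised
  expect_equal(colocCoefficient(paste0("s", 4:6, "_A"),
                                paste0("s", 4:6, "_B"),
                                ot[ot$strain_id %in% paste0("s", 4:6), ],
                                cfg), 0)
  ## co-localised in every carrier strain
  expect_equal(colocCoefficient(paste0("s", 1:3, "_A"),
                                paste0("s", 1:3, "_B"),
                                ot[ot$strain_id %in% paste0("s", 1:3), ],
                                cfg), 1)
})

test_that("strategy concordance reports totals, uniques and overlaps", {
  mk <- function(ids) data.frame(locus_id = ids,
                                 stringsAsFactors = FALSE)
  same <- strategyConcordance(list(a = mk(c("x", "y")),
                                   b = mk(c("x", "y")),
                                   c = mk(c("x", "y")),
                                   d = mk(c("x", "y"))))
  expect_true(all(same$uniques == 0))
  expect_identical(same$intersection, same$union)

  two <- strategyConcordance(list(a = mk(c("a", "b")),
                                  b = mk(c("a", "c"))))
  expect_equal(unname(two$totals), c(2L, 2L))
  expect_equal(unname(two$uniques), c(1L, 1L))
  expect_identical(two$intersection, "a")
  expect_setequal(two$union, c("a", "b", "c"))
})

test_that("cascade converges immediately on genomes with no plantings", {
  cfg <- pipelineConfig()
  set.seed(300)
  ctg <- makeContigSet(vapply(1:3, function(i) random_dna(4000), ""),
                       paste0("c", 1:3), "s1")
  orfs <- findOrfs(ctg, cfg)
  seeds <- seedSet(toxins = c(t1 = random_protein_chr(110)),
                   antitoxins = c(a1 = random_protein_chr(70)))
  loci <- cascadeSearch(orfs, seeds, cfg)
  expect_equal(nrow(loci), 0L)
  expect_equal(attr(loci, "rounds"), 1L)
})

test_that("rps and delta validate their profile inputs", {
  cfg <- pipelineConfig()
  set.seed(301)
  ctg <- makeContigSet(random_dna(2000), "c1", "s1")
  orfs <- findOrfs(ctg, cfg)
  seeds <- seedSet(toxins = c(t1 = random_protein_chr(110)),
                   antitoxins = c(a1 = random_protein_chr(70)))
  expect_error(rpsSearch(orfs, list(), cfg), "configuration error")
  expect_error(deltaSearch(orfs, seeds, list(), cfg),
               "configuration error")
  ## a seed matching no profile warns and returns an empty result
  other <- random_protein_chr(50)
  hits <- lapply(1:3, function(i) alignPair(other,
                                            mutateProtein(other, 0.1)))
  prof <- buildPssm(other, hits, "unrelated", role = "toxin")
  expect_warning(res <- deltaSearch(orfs, seeds,
                                    list(unrelated = prof), cfg),
                 "no seed matched")
  expect_equal(nrow(res), 0L)
})
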