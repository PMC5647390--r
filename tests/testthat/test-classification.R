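mk_loci <- function(tox_proteins, strains = NULL) {
  n <- length(tox_proteins)
  if (is.null(strains)) strains <- sprintf("s%02d", seq_len(n))
  data.frame(
    locus_id = sprintf("L%02d", seq_len(n)), strain_id = strains,
    contig_id = paste0(strains, "_c"), strand = "+",
    at_start = 101L, at_end = 313L, tox_start = 310L, tox_end = 642L,
    tox_protein = tox_proteins, at_protein = strrep("MK", 35),
    seed_query_id = "seed", stringsAsFactors = FALSE)
}

test_that("homologue grouping is single linkage at 80% similarity", {
  a <- random_protein_chr(110)
  g <- groupHomologues(mk_loci(c(a, a)))
  expect_equal(nrow(g), 1L)
  expect_equal(g$min_within_similarity, 1)

  set.seed(101)
  b <- mutateProtein(a, 0.6) # far below the grouping threshold
  stopifnot(alignPair(a, b)$similarity < 0.78)
  g2 <- groupHomologues(mk_loci(c(a, b)))
  expect_equal(nrow(g2), 2L)
  bet <- attr(g2, "between_similarity")
  expect_true(all(bet[!is.na(bet)] < 0.80))

  ## every locus lands in exactly one group
  asg <- attr(g2, "assignments")
  expect_setequal(names(asg), c("L01", "L02"))
})

test_that("group naming follows strain counts and the seed-name map", {
  a <- random_protein_chr(110)
  set.seed(103)
  b <- mutateProtein(a, 0.6)
  loci <- mk_loci(c(a, a, a, b), strains = c("s1", "s2", "s3", "s4"))
  g <- groupHomologues(loci)
  expect_equal(g$n_strains, c(3L, 1L))
  expect_equal(g$group_id, c("pemIK-like-01", "pemIK-like-02"))
  g2 <- groupHomologues(loci, name_map = c(L01 = "mazEF-Sa",
                                           L04 = "pemIK-Sa1"))
  expect_equal(g2$group_id, c("mazEF-Sa", "pemIK-Sa1"))
})

test_that("occurrence percentages follow printed-table rounding", {
  roster <- data.frame(
    strain_id = sprintf("g%04d", 1:6132),
    species = rep(sprintf("sp%02d", 1:36), length.out = 6132),
    stringsAsFactors = FALSE)
  a <- random_protein_chr(110)
  carriers <- roster$strain_id[1:6121]
  loci <- mk_loci(rep(a, length(carriers)), strains = carriers)
  g <- groupHomologues(loci[1:2, ])  # grouping only needs the shape
  asg <- stats::setNames(rep("mazEF-like", nrow(loci)), loci$locus_id)
  fake_groups <- data.frame(locus_id = loci$locus_id,
                            group_id = "mazEF-like",
                            stringsAsFactors = FALSE)
  occ <- summarizeOccurrence(fake_groups, loci, roster)
  expect_equal(occ$n_strains, 6121L)
  expect_equal(occ$pct_strains, 99.82)
  expect_equal(occ$n_species, 36L)
  expect_equal(occ$pct_species, 100.00)

  occ2 <- summarizeOccurrence(
    data.frame(locus_id = loci$locus_id[1:65], group_id = "pemIK-like"),
    loci[1:65, ], roster)
  expect_equal(occ2$pct_strains, 1.06)

  ## 0 carriers -> the group simply has no loci; half-up rounding check
  expect_equal(taMiner:::.roundHalfUp(0.125 * 100, 2), 12.5)
  expect_equal(taMiner:::.roundHalfUp(99.815, 2), 99.82)
  expect_equal(taMiner:::.roundHalfUp(1.0599 * 100 / 100, 2), 1.06)

  ## a locus with an unknown strain is a validation error
  bad <- loci[1, ]
  bad$strain_id <- "nope"
  expect_error(summarizeOccurrence(
    data.frame(locus_id = bad$locus_id, group_id = "x"), bad, roster),
    "absent from roster")
})

test_that("location calls propagate contig labels only", {
  labs <- c(c1 = "plasmid", c2 = "chromosome")
  expect_equal(callLocation("c1", labs), "plasmid")
  expect_equal(callLocation("c2", labs), "chromosome")
  expect_equal(callLocation("c3", labs), "undetermined")
  expect_equal(callLocation("c1", NULL), "undetermined")

  a <- random_protein_chr(110)
  loci <- mk_loci(c(a, a), strains = c("s1", "s2"))
  loci$contig_id <- c("c1", "c2")
  roster <- data.frame(strain_id = c("s1", "s2"), species = "sp",
                       stringsAsFactors = FALSE)
  occ <- summarizeOccurrence(
    data.frame(locus_id = loci$locus_id, group_id = "g"),
    loci, roster, contig_locations = labs)
  expect_equal(occ$location, "chromosome, plasmid")
})

test_that("occurrence TSV recomputes exactly from counts", {
  roster <- data.frame(strain_id = sprintf("s%03d", 1:200),
                       species = rep(c("spA", "spB"), 100),
                       stringsAsFactors = FALSE)
  a <- random_protein_chr(110)
  loci <- mk_loci(rep(a, 37), strains = roster$strain_id[1:37])
  occ <- summarizeOccurrence(
    data.frame(locus_id = loci$locus_id, group_id = "g"), loci, roster)
  path <- tempfile(fileext = ".tsv")
  writeOccurrenceTsv(occ, path)
  back <- utils::read.delim(path)
  expect_equal(back$pct_strains, 100 * back$n_strains / 200,
               tolerance = 5e-3)
  expect_equal(back$pct_strains, 18.50)
})
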