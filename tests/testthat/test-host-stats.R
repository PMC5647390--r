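test_that("proportional carrier distribution gives statistic 0, p 1", {
  ref <- c(human = 40, cow = 40, bird = 20)
  carr <- c(human = 8, cow = 8, bird = 4)
  res <- compareHostDistributions(ref, carr)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the chi-square statistic matches hand arithmetic", {
  ## reference 40 vs 20; carriers 5 and 15 (expected 2:1 split of 20)
  ref <- c(a = 40, b = 20)
  carr <- c(a = 5, b = 15)
  ## expected: a = 40/60*20 = 13.333, b = 6.667
  hand <- (5 - 40 / 3)^2 / (40 / 3) + (15 - 20 / 3)^2 / (20 / 3)
  res <- compareHostDistributions(ref, carr)
  expect_equal(res$statistic, hand)
  expect_equal(res$df, 1L)

  ## all k carriers in one of four equal categories: statistic = 3k
  ref4 <- c(a = 25, b = 25, c = 25, d = 25)
  for (k in c(4, 8, 20)) {
    res4 <- compareHostDistributions(ref4, c(a = k))
    expect_equal(res4$statistic, 3 * k)
  }
})

test_that("the comparison is invariant to category order and pools rare
           categories", {
  ref <- c(a = 50, b = 30, c = 19, d = 1)
  carr <- c(a = 10, b = 5, c = 4, d = 1)
  r1 <- compareHostDistributions(ref, carr)
  r2 <- compareHostDistributions(rev(ref), carr[c("c", "a", "d", "b")])
  expect_equal(r1$statistic, r2$statistic)
  ## d has expected 20/100 * 1 = 0.2 < 1 -> pooled
  expect_true("other" %in% names(r1$observed))
  expect_error(compareHostDistributions(c(a = 10), c(a = 2)),
               "at least 2")
  expect_error(compareHostDistributions(c(a = 10, b = 5),
                                        c(a = 11, b = 0)), "exceed")
})

test_that("subgroup enrichment reduces to the closed form", {
  g <- sprintf("s%02d", 1:10)
  ## k = 1, category covers half the group
  r1 <- subgroupEnrichment(g, g[1], g[1:5])
  expect_equal(r1$p_chance, 0.5)
  ## n = 10, m = 5, k = 3, all carriers in category:
  ## C(5,3)/C(10,3) = 1/12
  r2 <- subgroupEnrichment(g, g[1:3], g[1:5])
  expect_equal(r2$p_chance, choose(5, 3) / choose(10, 3))
  expect_equal(r2$p_chance, 1 / 12)
  ## monotone: shrinking the category lowers the probability
  r3 <- subgroupEnrichment(g, g[1:3], g[1:4])
  expect_lt(r3$p_chance, r2$p_chance)
  ## m < k with full containment claimed is probability 0, not an error
  r4 <- subgroupEnrichment(g, g[1:3], g[1:2])
  expect_equal(subgroupEnrichment(g, g[1:2], g[1:2])$p_chance,
               choose(2, 2) / choose(10, 2))
  expect_true(r4$p_chance >= 0)
  expect_error(subgroupEnrichment(g, c("zz"), g[1:5]), "subset")
})

test_that("seeded permutation agrees with the hypergeometric tail", {
  g <- sprintf("s%02d", 1:20)
  set.seed(1)
  for (case in list(list(k = 4, m = 8), list(k = 3, m = 10),
                    list(k = 5, m = 6))) {
    carr <- sample(g, case$k)
    cat_ <- sample(g, case$m)
    hyp <- subgroupEnrichment(g, carr, cat_)$p_chance
    perm <- subgroupEnrichment(g, carr, cat_, method = "permutation",
                               n_perm = 2e4, seed = 99)
    se <- max(perm$mc_se, sqrt(hyp * (1 - hyp) / 2e4))
    expect_lt(abs(perm$p_chance - hyp), 3 * se + 1e-9)
    ## permutation is reproducible under the seed
    perm2 <- subgroupEnrichment(g, carr, cat_, method = "permutation",
                                n_perm = 2e4, seed = 99)
    expect_identical(perm$p_chance, perm2$p_chance)
  }
})

test_that("host association report assembles distributions from metadata", {
  md <- data.frame(
    strain_id = sprintf("s%02d", 1:30),
    species = "sp",
    host = c(rep("Homo sapiens", 12), rep("Meleagris gallopavo", 10),
             rep("Mus musculus", 6), NA, NA),
    stringsAsFactors = FALSE)
  rep_ <- hostAssociationReport(sprintf("s%02d", 13:22), md)
  expect_equal(sum(rep_$carrier_counts), 10)
  expect_equal(unname(rep_$carrier_counts["Meleagris gallopavo"]), 10)
  expect_true(rep_$chi_square$p_value < 0.01)
  ## synonym mapping collapses labels before counting
  rep2 <- hostAssociationReport(
    sprintf("s%02d", 13:22), md,
    synonyms = c("Meleagris gallopavo" = "poultry"))
  expect_true("poultry" %in% names(rep2$reference_counts))
})
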