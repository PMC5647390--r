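test_that("self-alignment and single-substitution examples behave", {
  a <- alignPair(strrep("MKWVLE", 17), strrep("MKWVLE", 17))
  expect_equal(a$identity, 1)
  expect_equal(a$similarity, 1)
  expect_equal(a$len_ratio, 1)

  ## one A->G substitution in a 10-mer: identity 0.9 over 10 columns
  b <- alignPair("HEAGAWGHEE", "HEAGGWGHEE")
  expect_equal(b$aln_len, 10L)
  expect_equal(b$identity, 0.9)

  expect_error(alignPair("MKX", "MK"), "non-standard")
  expect_error(alignPair("", "MK"), "non-empty")
})

test_that("pairwise scores and column counts match the brute-force DP", {
  set.seed(17)
  for (i in 1:40) {
    q <- random_protein_chr(sample(10:60, 1))
    s <- if (i %% 3 == 0) random_protein_chr(sample(10:60, 1)) else
      mutateProtein(q, runif(1, 0, 0.5))
    got <- alignPair(q, s)
    want <- oracle_sw(q, s)
    expect_equal(got$score, want$score)
    expect_equal(got$aln_len, want$aln_len)
    expect_equal(got$identity * got$aln_len, want$n_id)
    expect_equal(got$similarity * got$aln_len, want$n_pos)
  }
})

test_that("alignment score is symmetric and len_ratio inverts", {
  set.seed(23)
  for (i in 1:10) {
    a <- random_protein_chr(40)
    b <- random_protein_chr(55)
    x <- alignPair(a, b)
    y <- alignPair(b, a)
    expect_equal(x$score, y$score)
    expect_equal(x$len_ratio, 1 / y$len_ratio)
  }
})

test_that("E-value estimate is monotone and linear in database size", {
  e1 <- estimateEvalue(50, 100, 1e5)
  expect_lt(estimateEvalue(100, 100, 1e5), e1)
  expect_equal(estimateEvalue(50, 100, 2e5), 2 * e1)
  ## closed form at S = 0: E = K * m * n (gapped BLOSUM62 constants)
  expect_equal(estimateEvalue(0, 100, 1e5), 0.041 * 100 * 1e5)
  ## strictly decreasing over a score grid
  ev <- estimateEvalue(seq(0, 200, by = 10), 100, 1e5)
  expect_true(all(diff(ev) < 0))
})

test_that("PSSM construction reflects observed conservation", {
  seed <- random_protein_chr(40)
  set.seed(31)
  hits <- lapply(1:5, function(i) alignPair(seed, mutateProtein(seed, 0.1)))
  p <- buildPssm(seed, hits, "test")
  expect_s4_class(p, "PSSMProfile")
  expect_equal(length(p), 40L)
  ## the seed residue scores strictly positive at every position
  seed_res <- strsplit(seed, "")[[1]]
  idx <- match(seed_res, colnames(profileWeights(p)))
  expect_true(all(profileWeights(p)[cbind(seq_len(40), idx)] > 0))

  ## a column with 100% K outranks every other residue there
  seedK <- paste0("M", strrep("K", 29))
  hitsK <- lapply(1:6, function(i) {
    mut <- mutateProtein(seedK, 0.2, seed = i)
    substr(mut, 15, 15) <- "K"
    alignPair(seedK, mut)
  })
  pK <- buildPssm(seedK, hitsK, "k")
  w15 <- profileWeights(pK)[15, ]
  expect_equal(names(which.max(w15)), "K")

  expect_error(buildPssm(seed, list()), "alignPair")
})

test_that("a profile scores its own seed above shuffled seeds", {
  seed <- random_protein_chr(50)
  set.seed(47)
  hits <- lapply(1:5, function(i) alignPair(seed, mutateProtein(seed, 0.15)))
  p <- buildPssm(seed, hits, "perm")
  own <- searchPssm(p, c(seed = seed))$score
  shuffled <- vapply(1:100, function(i) {
    sh <- paste(sample(strsplit(seed, "")[[1]]), collapse = "")
    searchPssm(p, c(s = sh))$score
  }, 0)
  expect_true(all(own >= shuffled))
})

test_that("profile search is local and reports profile coverage", {
  seed <- random_protein_chr(45)
  set.seed(53)
  hits <- lapply(1:4, function(i) alignPair(seed, mutateProtein(seed, 0.1)))
  p <- buildPssm(seed, hits, "cov")
  self <- searchPssm(p, c(self = seed))
  expect_equal(self$profile_coverage, 1)
  ## unrelated N-terminal extension: local alignment keeps score/coverage
  ext <- paste0(random_protein_chr(21), substring(seed, 1))
  hit <- searchPssm(p, c(ext = ext))
  expect_equal(hit$score, self$score)
  expect_equal(hit$profile_coverage, 1)
})

test_that("profile scores match a brute-force profile DP", {
  seed <- random_protein_chr(30)
  set.seed(61)
  hits <- lapply(1:3, function(i) alignPair(seed, mutateProtein(seed, 0.2)))
  p <- buildPssm(seed, hits, "oracle")
  for (i in 1:15) {
    s <- if (i %% 2) mutateProtein(seed, runif(1, 0, 0.6)) else
      random_protein_chr(sample(15:45, 1))
    got <- searchPssm(p, c(x = s))$score
    want <- oracle_profile_score(profileWeights(p), s)
    expect_equal(got, want)
  }
})

test_that("clustering follows blastclust-style identity and coverage", {
  a <- random_protein_chr(60)
  cl <- clusterProteins(c(p1 = a, p2 = a))
  expect_equal(nrow(cl), 1L)
  expect_setequal(cl$members[[1]], c("p1", "p2"))

  set.seed(71)
  b <- mutateProtein(a, 0.7) # far below the identity threshold
  cl2 <- clusterProteins(c(p1 = a, p2 = b))
  expect_equal(nrow(cl2), 2L)

  ## single-linkage chain: A~B, B~C above thresholds, A and C distant
  for (s in 73:100) {
    set.seed(s)
    A <- random_protein_chr(80)
    B <- mutateProtein(A, 0.3)
    C <- mutateProtein(B, 0.3)
    if (alignPair(A, B)$identity >= 0.60 &&
        alignPair(B, C)$identity >= 0.60 &&
        alignPair(A, C)$identity < 0.60) break
  }
  expect_lt(alignPair(A, C)$identity, 0.60)
  cl3 <- clusterProteins(c(A = A, B = B, C = C))
  expect_equal(nrow(cl3), 1L)
  expect_setequal(cl3$members[[1]], c("A", "B", "C"))

  ## order invariance
  cl4 <- clusterProteins(c(C = C, A = A, B = B))
  expect_identical(cl3$cluster_id, cl4$cluster_id)
  expect_identical(cl3$members, cl4$members)
})

test_that("PSSM fixture files round-trip", {
  seed <- random_protein_chr(25)
  set.seed(83)
  hits <- lapply(1:3, function(i) alignPair(seed, mutateProtein(seed, 0.1)))
  p <- buildPssm(seed, hits, "io_test", role = "toxin")
  path <- tempfile(fileext = ".pssm")
  writePssmSet(list(io_test = p), path)
  back <- readPssmSet(path)
  expect_named(back, "io_test")
  expect_equal(profileRole(back$io_test), "toxin")
  expect_equal(profileWeights(back$io_test), profileWeights(p),
               tolerance = 1e-6)
})
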