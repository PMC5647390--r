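test_that("mutateProtein hits the target divergence exactly", {
  p <- randomProtein(100, seed = 1)
  expect_identical(mutateProtein(p, 0, seed = 2), p)
  m <- mutateProtein(p, 0.10, seed = 3)
  diffs <- sum(strsplit(p, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diffs, 10L)
  expect_equal(nchar(m), nchar(p))
  ## determinism under the seed
  expect_identical(mutateProtein(p, 0.25, seed = 5),
                   mutateProtein(p, 0.25, seed = 5))
  expect_false(identical(mutateProtein(p, 0.25, seed = 5),
                         mutateProtein(p, 0.25, seed = 6)))
  ## realised identity equals 1 - divergence by construction
  m2 <- mutateProtein(p, 0.3, seed = 7)
  expect_equal(mean(strsplit(p, "")[[1]] == strsplit(m2, "")[[1]]), 0.7)
})

test_that("planted operons are recovered verbatim by findOrfs", {
  cfg <- pipelineConfig()
  set.seed(11)
  for (case in list(list(gap = 0L, strand = "+"),
                    list(gap = 45L, strand = "-"),
                    list(gap = -1L, strand = "+"),
                    list(gap = -4L, strand = "-"))) {
    at <- randomProtein(70)
    tox <- randomProtein(110)
    substr(tox, 2, 2) <- "K" # keep the -4 fusion constructible
    ctg_seq <- random_dna(3000)
    pl <- plantOperon(ctg_seq, at, tox, 600, case$strand, case$gap)
    o <- findOrfs(makeContigSet(pl$contig_seq, "c1", "s1"), cfg)
    df <- data.frame(start = BiocGenerics::start(o),
                     end = BiocGenerics::end(o),
                     strand = as.character(BiocGenerics::strand(o)),
                     protein = S4Vectors::mcols(o)$protein)
    at_row <- df[df$start == pl$at_start & df$end == pl$at_end &
                   df$strand == case$strand, ]
    tox_row <- df[df$start == pl$tox_start & df$end == pl$tox_end &
                    df$strand == case$strand, ]
    expect_equal(nrow(at_row), 1L, info = paste("gap", case$gap))
    expect_equal(nrow(tox_row), 1L, info = paste("gap", case$gap))
    expect_identical(at_row$protein, at)
    expect_identical(tox_row$protein, tox)
    ## the realised gap matches the requested arrangement
    gap_got <- if (case$strand == "+") pl$tox_start - pl$at_end - 1L else
      pl$at_start - pl$tox_end - 1L
    expect_equal(gap_got, as.integer(case$gap))
  }
  expect_error(plantOperon(random_dna(100), randomProtein(70),
                           randomProtein(110), 50, "+", 0L),
               "too short")
})

test_that("arrangement truth matches the planted gap classes", {
  cfg <- pipelineConfig()
  set.seed(13)
  at <- randomProtein(70)
  tox <- randomProtein(110)
  mk <- function(gap) {
    pl <- plantOperon(random_dna(3000), at, tox, 500, "+", gap)
    o <- findOrfs(makeContigSet(pl$contig_seq, "c1", "s1"), cfg)
    a <- o[BiocGenerics::start(o) == pl$at_start &
             as.character(BiocGenerics::strand(o)) == "+"]
    t <- o[BiocGenerics::start(o) == pl$tox_start &
             as.character(BiocGenerics::strand(o)) == "+"]
    isTaArrangement(a, t, cfg)
  }
  expect_true(mk(-4L))
  expect_true(mk(99L))
  expect_false(mk(150L))
})

test_that("scenario generation is deterministic and respects quotas", {
  run <- ta_small_run()
  corpus2 <- generateScenario(run$scenario, run$cfg)
  expect_identical(as.character(run$corpus$contigs),
                   as.character(corpus2$contigs))
  expect_identical(run$corpus$truth, corpus2$truth)
  expect_identical(run$corpus$metadata, corpus2$metadata)

  ## carrier quotas are exact
  tr <- run$corpus$truth[!run$corpus$truth$stepping_stone, ]
  carriers <- tapply(tr$strain_id, tr$family_id,
                     function(x) length(unique(x)))
  expect_equal(as.vector(carriers[c("famA", "famB")]), c(6L, 3L))

  ## decoy registry covers the requested classes
  expect_equal(sort(run$corpus$decoys$class),
               sort(c("orphan_toxin", "wide_gap", "opposite_strand",
                      "oversized_toxin", "undersized_antitoxin")))

  ## profile fixtures: one toxin + one antitoxin profile per family
  expect_setequal(names(run$corpus$profiles),
                  c("famA_tox_dom", "famA_ant_dom", "famB_tox_dom",
                    "famB_ant_dom"))

  ## every planted ORF is present verbatim in the ORF calls
  ot <- as.data.frame(run$orfs)
  have <- paste(ot$seqnames, ot$strand, ot$start, ot$end)
  expect_true(all(paste(tr$contig_id, tr$strand, tr$at_start,
                        tr$at_end) %in% have))
  expect_true(all(paste(tr$contig_id, tr$strand, tr$tox_start,
                        tr$tox_end) %in% have))
})

test_that("family separation supports exact homologue regrouping", {
  run <- ta_small_run()
  tr <- run$corpus$truth[!run$corpus$truth$stepping_stone, ]
  ## within-family toxin similarity high, between-family low
  grp_sim <- function(x, y) {
    a <- alignPair(x, y)
    a$similarity * a$aln_len / max(nchar(x), nchar(y))
  }
  fams <- split(tr$tox_protein, tr$family_id)
  for (f in fams) {
    if (length(f) < 2) next
    sims <- combn(f, 2, function(x) grp_sim(x[1], x[2]))
    expect_true(all(sims >= 0.90))
  }
  expect_lt(grp_sim(fams$famA[1], fams$famB[1]), 0.78)
})

test_that("the corpus writer emits per-strain FASTA and fixtures", {
  run <- ta_small_run()
  dir <- file.path(tempdir(), "ta_corpus_test")
  writeCorpus(run$corpus, dir)
  fas <- list.files(dir, pattern = "\\.fasta$")
  expect_length(fas, 6L)
  back <- readAssembly(file.path(dir, "S01.fasta"), "S01")
  expect_identical(
    as.character(back[[1]]),
    as.character(run$corpus$contigs[
      S4Vectors::mcols(run$corpus$contigs)$strain_id == "S01"][[1]]))
  profs <- readPssmSet(file.path(dir, "profiles.pssm"))
  expect_setequal(names(profs), names(run$corpus$profiles))
  md <- readMetadata(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), 6L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(truth$truth, nrow(run$corpus$truth))
  unlink(dir, recursive = TRUE)
})
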