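test_that("ORF length accounting is start-through-stop inclusive", {
  cfg <- pipelineConfig()
  ## 102 nt: start + 32 sense codons + stop -> one ORF, 33-aa protein
  ctg <- makeContigSet(paste0("ATG", strrep("GCT", 32), "TAA"),
                       "c1", "s1")
  o <- findOrfs(ctg, cfg)
  expect_length(o, 1L)
  expect_equal(S4Vectors::mcols(o)$nt_len, 102L)
  expect_equal(nchar(S4Vectors::mcols(o)$protein), 33L)
  expect_equal(S4Vectors::mcols(o)$protein, paste0("M", strrep("A", 32)))

  ## 99 nt total: below the 100 bp floor -> nothing
  ctg99 <- makeContigSet(paste0("ATG", strrep("GCT", 31), "TAA"),
                         "c1", "s1")
  expect_length(findOrfs(ctg99, cfg), 0L)
})

test_that("only the longest variant per stop is reported", {
  cfg <- pipelineConfig()
  ## GTG ... ATG ... TAA sharing one in-frame stop: single ORF from GTG
  seq <- paste0("GTG", strrep("GCT", 10), "ATG", strrep("GCT", 25),
                "TAA")
  o <- findOrfs(makeContigSet(seq, "c1", "s1"), cfg)
  plus <- o[as.character(BiocGenerics::strand(o)) == "+"]
  expect_length(plus, 1L)
  expect_equal(BiocGenerics::start(plus), 1L)
  expect_equal(S4Vectors::mcols(plus)$start_codon, "GTG")
})

test_that("ORFs containing N are skipped", {
  cfg <- pipelineConfig()
  seq <- paste0("ATG", strrep("GCT", 15), "NAT", strrep("GCT", 16),
                "TAA")
  expect_length(findOrfs(makeContigSet(seq, "c1", "s1"), cfg), 0L)
})

test_that("find_orfs matches a brute-force six-frame oracle", {
  cfg <- pipelineConfig()
  set.seed(421)
  for (rep in 1:8) {
    seq <- random_dna(sample(300:1200, 1))
    got <- findOrfs(makeContigSet(seq, "c1", "s1"), cfg)
    got_df <- data.frame(start = BiocGenerics::start(got),
                         end = BiocGenerics::end(got),
                         strand = as.character(BiocGenerics::strand(got)))
    got_df <- got_df[order(got_df$strand, got_df$start, got_df$end), ]
    want <- oracle_orfs(seq)
    expect_equal(nrow(got_df), nrow(want))
    if (nrow(want))
      expect_equal(unname(as.matrix(got_df)), unname(as.matrix(want)))
  }
})

test_that("strand symmetry: reverse-complemented input mirrors calls", {
  cfg <- pipelineConfig()
  set.seed(99)
  seq <- random_dna(800)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  a <- findOrfs(makeContigSet(seq, "c1", "s1"), cfg)
  b <- findOrfs(makeContigSet(rc, "c1", "s1"), cfg)
  L <- nchar(seq)
  mirrored <- data.frame(
    start = L - BiocGenerics::end(b) + 1L,
    end = L - BiocGenerics::start(b) + 1L,
    strand = ifelse(as.character(BiocGenerics::strand(b)) == "+",
                    "-", "+"))
  mirrored <- mirrored[order(mirrored$strand, mirrored$start), ]
  orig <- data.frame(start = BiocGenerics::start(a),
                     end = BiocGenerics::end(a),
                     strand = as.character(BiocGenerics::strand(a)))
  orig <- orig[order(orig$strand, orig$start), ]
  expect_equal(unname(as.matrix(orig)), unname(as.matrix(mirrored)))
})

test_that("no two ORFs share (strand, frame, stop)", {
  cfg <- pipelineConfig()
  set.seed(5)
  seq <- random_dna(2000)
  o <- findOrfs(makeContigSet(seq, "c1", "s1"), cfg)
  key <- paste(BiocGenerics::strand(o),
               ifelse(as.character(BiocGenerics::strand(o)) == "+",
                      BiocGenerics::end(o) %% 3,
                      BiocGenerics::start(o) %% 3),
               ifelse(as.character(BiocGenerics::strand(o)) == "+",
                      BiocGenerics::end(o), BiocGenerics::start(o)))
  expect_false(anyDuplicated(key) > 0)
})

test_that("translation follows table 11 with Met initiators", {
  expect_identical(translateOrf("ATGAAATAA"), "MK")
  expect_identical(translateOrf("TTGAAATAA"), "MK")  # TTG initiator -> M
  expect_identical(translateOrf("ATGCTGTAA"), "ML")  # internal CTG = Leu
  expect_identical(translateOrf("ATACATTAA"), "MH")  # ATA initiator -> M
  expect_error(translateOrf("ATGAAA"), "stop")
  expect_error(translateOrf("ATGTAAAAATAA"), "internal stop")
  expect_error(translateOrf("ATGAAATA"), "divisible")
})
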