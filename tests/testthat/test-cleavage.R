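## Cleavage/ligation model: exact slicing, length conservation, rotation
## canonicalisation, and closure with the genome generator.

test_that("a 102-nt precursor cut after 26 and 73 yields 26/47/29 fragments", {
  withr::with_seed(555, {
    seq <- paste(sample(c("A", "C", "G", "U"), 102, TRUE), collapse = "")
  })
  res <- cleaveSubstrate(precursorSubstrate(seq, cuts = c(26L, 73L)))
  expect_equal(unname(nchar(fragments(res))), c(26L, 47L, 29L))
  expect_equal(sum(nchar(fragments(res))), 102L)
  expect_equal(ligatedExons(res),
               paste0(substr(seq, 1, 26), substr(seq, 74, 102)))
  expect_equal(circularIntron(res), canonicalRotation(substr(seq, 27, 73)))
})

test_that("extreme cuts conserve length exactly", {
  seq <- strrep("ACGU", 10)
  res <- cleaveSubstrate(precursorSubstrate(seq, cuts = c(1L, 39L)))
  expect_equal(unname(nchar(fragments(res))), c(1L, 38L, 1L))
  expect_equal(sum(nchar(fragments(res))), 40L)
})

test_that("invalid cut positions are rejected", {
  expect_error(precursorSubstrate("ACGUACGU", cuts = c(5L, 5L)), "cut")
  expect_error(precursorSubstrate("ACGUACGU", cuts = c(6L, 3L)), "cut")
  expect_error(precursorSubstrate("ACGUACGU", cuts = c(0L, 4L)), "cut")
  expect_error(precursorSubstrate("ACGUACGU", cuts = c(4L, 8L)), "cut")
})

test_that("cleavage equals the string-slicing oracle on random instances", {
  withr::with_seed(909, {
    for (case in seq_len(200)) {
      n <- sample(10:300, 1)
      seq <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
      c1 <- sample.int(n - 2L, 1)
      c2 <- c1 + sample.int(n - 1L - c1, 1)
      res <- cleaveSubstrate(precursorSubstrate(seq, cuts = c(c1, c2)))
      want <- oracleSlice(seq, c(c1, c2))
      expect_identical(unname(fragments(res)),
                       c(want$f5, want$mid, want$f3))
      expect_equal(sum(nchar(fragments(res))), n)
      lig <- ligateFragments(res)
      expect_identical(lig$ligated_exons, paste0(want$f5, want$f3))
      expect_identical(lig$circular_intron, canonicalRotation(want$mid))
    }
  })
})

test_that("toy ligation and rotation equivalence behave as defined", {
  res <- cleaveSubstrate(precursorSubstrate("AAAGGGCCC", cuts = c(3L, 6L)))
  lig <- ligateFragments(res)
  expect_equal(lig$ligated_exons, "AAACCC")
  expect_equal(lig$circular_intron, canonicalRotation("GGG"))
  expect_equal(canonicalRotation("GAU"), canonicalRotation("AUG"))
  ## idempotent and rotation-invariant
  withr::with_seed(303, {
    for (case in seq_len(50)) {
      s <- paste(sample(c("A", "C", "G", "U"), sample(2:40, 1), TRUE),
                 collapse = "")
      canon <- canonicalRotation(s)
      expect_equal(canonicalRotation(canon), canon)
      k <- sample.int(nchar(s), 1)
      rot <- paste0(substr(s, k, nchar(s)), substr(s, 1, k - 1))
      expect_equal(canonicalRotation(rot), canon)
    }
  })
})

test_that("precursors built from planted introns cleave back to the designed pieces", {
  sim <- buildGenome(list(locusSpec("t1", "tRNA", intronLen = 103L)),
                     backgroundLen = 1200L, seed = 47L)
  tr <- truthJunctions(sim)
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  pre <- precursorFromIntron(sim, c(s, e), flank = 25L)
  expect_equal(nchar(pre@sequence), 103L + 50L)
  res <- cleaveSubstrate(pre)
  expect_equal(unname(nchar(fragments(res))), c(25L, 103L, 25L))
  ## the circularised middle fragment is the planted intron
  intronRna <- chartr("T", "U",
    as.character(genomeSeq(sim)[s:e]))
  expect_equal(circularIntron(res), canonicalRotation(intronRna))
  ## alternative cut rules shift both cuts by the same offset
  pre1 <- precursorFromIntron(sim, c(s, e), cutRule = "after1")
  pre3 <- precursorFromIntron(sim, c(s, e), cutRule = "after3")
  expect_equal(pre1@cuts, pre@cuts + 1L)
  expect_equal(pre3@cuts, pre@cuts - 1L)
})

test_that("a circularised intron re-enters the pipeline at the planted junction", {
  sim <- buildGenome(list(locusSpec("t1", "tRNA", intronLen = 103L)),
                     backgroundLen = 1200L, seed = 53L)
  tr <- truthJunctions(sim)
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  res <- cleaveSubstrate(precursorFromIntron(sim, c(s, e)))
  ## back-junction reads taken directly from the cleavage product's circle
  circ <- chartr("U", "T", fragments(res)[["fragmentMid"]])
  doubled <- paste0(circ, circ)
  reads <- vapply(c(25L, 40L, 55L), function(o)
    substr(doubled, 103L - o + 1L, 103L - o + 75L), character(1))
  names(reads) <- sprintf("bj%d", seq_along(reads))
  obs <- callJunctions(mapSplitReads(reads, sim), length(genomeSeq(sim)))
  expect_equal(unique(obs$topology), "circular")
  expect_equal(unique(obs$left), tr$left_site)
  expect_equal(unique(obs$right), tr$right_site)
  expect_equal(unique(obs$right - obs$left), 103L)
})
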