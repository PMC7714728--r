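## Unit and property tests for the mapper, caller, filter and merge steps.

.mkSeg <- function(read_id, starts, ends, strand = "+", replicate = 1L) {
  n <- length(starts)
  data.frame(segment = seq_len(n), ref_start = starts, ref_end = ends,
             read_start = NA_integer_, read_end = NA_integer_,
             mismatches = NA_integer_, read_id = read_id,
             replicate = replicate, strand = strand, n_segments = n)
}

test_that("the mapper distinguishes contiguous, split and unmappable reads", {
  sim <- buildGenome(list(locusSpec("t1", "tRNA", intronLen = 103L)),
                     backgroundLen = 1500L, seed = 17L)
  g <- as.character(genomeSeq(sim))
  ## contiguous read
  aln <- mapSplitReads(c(r1 = substr(g, 101, 175)), sim)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$ref_start, 101L)
  expect_equal(aln$ref_end, 175L)
  expect_equal(aln$n_segments, 1L)
  ## back-junction read: downstream genome segment first in read order
  tr <- truthJunctions(sim)
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  bj <- paste0(substr(g, e - 29, e), substr(g, s, s + 44))
  aln <- mapSplitReads(c(bj1 = bj), sim)
  expect_equal(aln$n_segments, c(2L, 2L))
  expect_equal(aln$ref_start, c(e - 29L, s))
  expect_equal(aln$ref_end, c(e, s + 44L))
  expect_gt(aln$ref_start[1], aln$ref_start[2])
  ## random read absent from the genome
  set.seed(99)
  junk <- paste(sample(c("A", "C", "G", "T"), 75, TRUE), collapse = "")
  aln <- mapSplitReads(stats::setNames(junk, "junk"), sim)
  expect_equal(nrow(aln), 0L)
  expect_equal(attr(aln, "unmapped"), "junk")
  expect_error(mapSplitReads(c(r = "ACGT"), Biostrings::DNAString("")),
               "empty genome")
  expect_error(mapSplitReads(c(r = "ACGT"), sim, minSeed = 5), ">= 12")
})

test_that("junction geometry: genomic order gives linear, reversed gives circular", {
  ## canonical spliced read
  obs <- callJunctions(.mkSeg("r1", c(100L, 200L), c(150L, 250L)), 1000L)
  expect_equal(obs$topology, "linear")
  expect_equal(obs$left, 151L)
  expect_equal(obs$right, 200L)
  ## back-junction geometry
  obs <- callJunctions(.mkSeg("r2", c(200L, 100L), c(250L, 150L)), 1000L)
  expect_equal(obs$topology, "circular")
  expect_equal(obs$left, 100L)
  expect_equal(obs$right, 251L)
  ## unsplit alignments yield no junctions
  obs <- callJunctions(.mkSeg("r3", 100L, 175L), 1000L)
  expect_equal(nrow(obs), 0L)
  ## adjacent segments (no gap) yield no junction
  obs <- callJunctions(.mkSeg("r4", c(100L, 151L), c(150L, 200L)), 1000L)
  expect_equal(nrow(obs), 0L)
  ## >2 segments: skipped with a warning, counted
  aln3 <- .mkSeg("r5", c(1L, 50L, 100L), c(40L, 90L, 140L))
  expect_warning(obs <- callJunctions(aln3, 1000L), "skipped")
  expect_equal(attr(obs, "skipped_multisegment"), 1L)
})

test_that("minus-strand junctions mirror plus-strand geometry", {
  ## spliced read of a minus-strand transcript: exon5 at [300,350],
  ## exon3 at [100,150], intron [151,299]
  obs <- callJunctions(.mkSeg("m1", c(300L, 100L), c(350L, 150L), "-"), 400L)
  expect_equal(obs$topology, "linear")
  expect_equal(obs$left, 151L)
  expect_equal(obs$right, 300L)
  ## back-junction of the circularised minus-strand intron [151,299]
  obs <- callJunctions(.mkSeg("m2", c(151L, 255L), c(180L, 299L), "-"), 400L)
  expect_equal(obs$topology, "circular")
  expect_equal(obs$left, 151L)
  expect_equal(obs$right, 300L)
})

test_that("replicate-coverage filter enforces its boundary exactly", {
  mkObs <- function(counts, left = 50L, right = 100L) {
    do.call(rbind, lapply(seq_along(counts), function(r) {
      if (counts[r] == 0L) return(NULL)
      data.frame(read_id = sprintf("x%d_%d", r, seq_len(counts[r])),
                 replicate = r, strand = "+", topology = "circular",
                 left = left, right = right)
    }))
  }
  expect_equal(nrow(filterJunctions(mkObs(c(3L, 2L, 5L)))), 1L)
  expect_equal(nrow(filterJunctions(mkObs(c(2L, 2L, 2L)))), 1L)   # boundary
  expect_equal(nrow(filterJunctions(mkObs(c(3L, 1L, 5L)))), 0L)
  expect_equal(nrow(filterJunctions(mkObs(c(3L, 0L, 5L)))), 0L)
  ## laxer total-coverage reading
  expect_equal(nrow(filterJunctions(mkObs(c(3L, 1L, 5L)), mode = "total")), 1L)
  expect_equal(nrow(filterJunctions(mkObs(c(3L, 0L, 5L)), mode = "total")), 0L)
  obs <- mkObs(c(2L, 2L, 2L)); obs$replicate[1] <- 4L
  expect_error(filterJunctions(obs), "beyond")
})

test_that("filter agrees with the brute-force oracle on random instances", {
  withr::with_seed(404, {
    for (case in seq_len(60)) {
      obs <- randomObservations(sample(5:80, 1), span = 40L)
      minCov <- sample(1:3, 1)
      got <- filterJunctions(obs, minCov, 3L)
      want <- oracleFilter(obs, minCov, 3L)
      expect_equal(got[c("left", "right", "strand", "topology")],
                   want[c("left", "right", "strand", "topology")])
      if (nrow(got))
        expect_equal(as.matrix(got[paste0("cov_rep", 1:3)]),
                     as.matrix(want[paste0("cov_rep", 1:3)]),
                     ignore_attr = TRUE)
    }
  })
})

test_that("merge boundary sits exactly at the configured distance", {
  jn <- data.frame(strand = "+", topology = "circular",
                   left = c(100L, 110L), right = c(300L, 300L),
                   cov_rep1 = c(5L, 2L), cov_rep2 = c(5L, 2L),
                   cov_rep3 = c(5L, 2L))
  expect_equal(nrow(mergeJunctions(jn, maxDist = 10L)), 1L)
  jn$left[2] <- 111L
  expect_equal(nrow(mergeJunctions(jn, maxDist = 10L)), 2L)
  ## both coordinates must be near: Chebyshev, not just one endpoint
  jn$left[2] <- 110L; jn$right[2] <- 312L
  expect_equal(nrow(mergeJunctions(jn, maxDist = 10L)), 2L)
  ## singleton cluster is its own representative
  one <- mergeJunctions(jn[1, ], maxDist = 10L)
  expect_equal(one$left, 100L)
  expect_equal(one$n_members, 1L)
  expect_equal(one$intron_length, 200L)
})

test_that("merging matches the O(n^2) single-linkage oracle with jittered junctions", {
  withr::with_seed(808, {
    truth <- data.frame(left = c(100L, 500L, 900L), right = c(200L, 650L, 980L))
    jitters <- lapply(seq_len(50), function(i) {
      k <- sample(1:3, 1)
      data.frame(strand = "+", topology = "circular",
                 left = truth$left[k] + sample(-5:5, 1),
                 right = truth$right[k] + sample(-5:5, 1),
                 cov_rep1 = sample(1:5, 1), cov_rep2 = sample(1:5, 1),
                 cov_rep3 = sample(1:5, 1))
    })
    jn <- unique(do.call(rbind, jitters))
    cl <- mergeJunctions(jn, maxDist = 10L)
    expect_equal(nrow(cl), 3L)
    comp <- oracleMergeGroups(jn, 10L)
    expect_equal(length(unique(comp)), 3L)
    ## representative = highest-coverage member; coverage conserved
    for (k in unique(comp)) {
      mem <- jn[comp == k, ]
      tot <- mem$cov_rep1 + mem$cov_rep2 + mem$cov_rep3
      best <- mem[order(-tot, mem$left, mem$right)[1], ]
      row <- cl[cl$left == best$left & cl$right == best$right, ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$cov_rep1 + row$cov_rep2 + row$cov_rep3, sum(tot))
    }
    expect_equal(sum(cl$n_members), nrow(jn))  # no member in two clusters
  })
})

test_that("filtering and merging are monotone in their thresholds", {
  withr::with_seed(505, {
    for (case in seq_len(20)) {
      obs <- randomObservations(60, span = 60L)
      n1 <- nrow(filterJunctions(obs, 1L))
      n2 <- nrow(filterJunctions(obs, 2L))
      n3 <- nrow(filterJunctions(obs, 3L))
      expect_true(n1 >= n2 && n2 >= n3)
      kept <- filterJunctions(obs, 1L)
      if (nrow(kept) >= 2) {
        c5 <- nrow(mergeJunctions(kept, 5L))
        c10 <- nrow(mergeJunctions(kept, 10L))
        c20 <- nrow(mergeJunctions(kept, 20L))
        expect_true(c5 >= c10 && c10 >= c20)
      }
    }
  })
})

test_that("intron conversion follows length = right - left", {
  expect_equal(intronFromCluster(data.frame(left = 1165777L,
                                            right = 1165880L))$length, 103L)
  expect_equal(intronFromCluster(data.frame(left = 1195172L,
                                            right = 1195218L))$length, 46L)
  adj <- intronFromCluster(data.frame(left = 10L, right = 11L))
  expect_equal(adj$length, 1L)
  expect_equal(adj$start, 10L)
  expect_equal(adj$end, 10L)
  expect_error(intronFromCluster(data.frame(left = 10L, right = 10L)),
               "non-positive")
})
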