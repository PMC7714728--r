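## Detector tests: context extraction, layout grammar, splice-in-bulge,
## oracle equivalence and the cluster-screening report.

test_that("context extraction glues flanks with the splice boundary at flank+1", {
  sim <- buildGenome(list(locusSpec("u1", "mRNA_5UTR", intronLen = 46L)),
                     backgroundLen = 1000L, seed = 23L)
  tr <- truthJunctions(sim)
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  ctx <- extractContext(sim, c(s, e), flank = 25L)
  ## 46 nt intron: intronic halves truncate at the midpoint (23 nt each)
  expect_equal(nchar(upstreamArm(ctx)), 48L)
  expect_equal(nchar(downstreamArm(ctx)), 48L)
  expect_equal(unname(spliceSites(ctx)), c(26L, 24L))
  ## arms are genome subsequences in RNA alphabet
  g <- chartr("T", "U", as.character(genomeSeq(sim)))
  expect_equal(upstreamArm(ctx), substr(g, s - 25L, s + 22L))
  expect_equal(downstreamArm(ctx), substr(g, e - 22L, e + 25L))
})

test_that("minus-strand extraction equals the mirrored plus-strand context", {
  sim <- buildGenome(list(locusSpec("t1", "tRNA", intronLen = 103L)),
                     backgroundLen = 1200L, seed = 29L)
  tr <- truthJunctions(sim)
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  g <- as.character(genomeSeq(sim))
  glen <- nchar(g)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))
  ctxMinus <- extractContext(g, c(s, e), flank = 20L, strand = "-")
  ctxMirror <- extractContext(rc, c(glen - e + 1L, glen - s + 1L), flank = 20L)
  expect_equal(upstreamArm(ctxMinus), upstreamArm(ctxMirror))
  expect_equal(downstreamArm(ctxMinus), downstreamArm(ctxMirror))
  expect_error(extractContext(g, c(5L, 100L), flank = 25L), "edge")
  expect_error(extractContext(g, c(500L, 100L)), "interval")
})

test_that("the canonical construct is matched with exact motif geometry", {
  ctx <- makeCanonicalContext()
  m <- matchBhb(ctx)
  expect_gt(nrow(m), 0)
  best <- m[1, ]
  expect_equal(best$up_helix_start, 13L)
  expect_equal(best$down_helix_start, 13L)
  expect_equal(best$helix_len, 4L)
  expect_equal(best$bulge_len, 3L)
  expect_gte(best$h_len, 4L)
  expect_gte(best$hprime_len, 4L)
  expect_true(best$splice_up_in_bulge && best$splice_down_in_bulge)
  expect_lt(best$energy, 0)
})

test_that("poly-A arms cannot host a motif", {
  ctx <- new("GluedContext", up = strrep("A", 30), down = strrep("A", 30),
             spliceUp = 15L, spliceDown = 15L, flank = 14L,
             intronLength = 50L, origin = list(), id = "polyA")
  expect_equal(nrow(matchBhb(ctx)), 0L)
})

test_that("enumeration equals the brute-force oracle on short random arms", {
  withr::with_seed(1234, {
    for (case in seq_len(150)) {
      m <- sample(8:20, 1); n <- sample(8:20, 1)
      up <- paste(sample(c("A", "C", "G", "U"), m, TRUE), collapse = "")
      dn <- paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
      hl <- sample(2:3, 1); bl <- sample(1:3, 1)
      hL <- sample(0:2, 1); hpL <- sample(0:2, 1)
      strict <- sample(c(TRUE, FALSE), 1)
      wob <- sample(c(TRUE, FALSE), 1)
      ctx <- new("GluedContext", up = up, down = dn,
                 spliceUp = 1L, spliceDown = 1L, flank = 1L,
                 intronLength = 10L, origin = list(), id = "prop")
      got <- matchBhb(ctx, motifSpec(hl, bl, hL, hpL, wob), strict)
      want <- oracleMatchBhb(up, dn, hl, bl, hL, hpL, wob, strict)
      expect_equal(nrow(got), nrow(want))
      if (nrow(got)) {
        gotPQ <- got[order(got$up_helix_start, got$down_helix_start),
                     c("up_helix_start", "down_helix_start")]
        wantPQ <- want[order(want$p, want$q), ]
        expect_equal(gotPQ$up_helix_start, wantPQ$p)
        expect_equal(gotPQ$down_helix_start, wantPQ$q)
      }
    }
  })
})

test_that("strict matching never returns placements absent from the relaxed scan", {
  withr::with_seed(77, {
    for (case in seq_len(60)) {
      up <- paste(sample(c("A", "C", "G", "U"), 25, TRUE), collapse = "")
      dn <- paste(sample(c("A", "C", "G", "U"), 25, TRUE), collapse = "")
      ctx <- new("GluedContext", up = up, down = dn, spliceUp = 1L,
                 spliceDown = 1L, flank = 1L, intronLength = 10L,
                 origin = list(), id = "strictprop")
      motif <- motifSpec(3L, 2L, 1L, 1L)
      strict <- matchBhb(ctx, motif, strict = TRUE)
      relaxed <- matchBhb(ctx, motif, strict = FALSE)
      keyS <- paste(strict$up_helix_start, strict$down_helix_start)
      keyR <- paste(relaxed$up_helix_start, relaxed$down_helix_start)
      expect_true(all(keyS %in% keyR))
    }
  })
})

test_that("splice-in-bulge flags equal positional membership across a scan", {
  ctx0 <- makeCanonicalContext()
  m0 <- matchBhb(ctx0)[1, ]
  for (pos in 1:25) {
    ctx <- new("GluedContext", up = ctx0@up, down = ctx0@down,
               spliceUp = as.integer(pos), spliceDown = 11L,
               flank = 10L, intronLength = 40L, origin = list(),
               id = ctx0@id)
    m <- matchBhb(ctx)
    hit <- m[m$up_helix_start == 13L & m$down_helix_start == 13L, ][1, ]
    want <- pos >= 10L && pos <= 12L     # the designed bulge interval
    expect_equal(hit$splice_up_in_bulge, want)
    expect_equal(unname(checkSpliceInBulge(hit, ctx)["up"]), want)
  }
  ## a site inside the central helix is never in-bulge
  ctxH <- new("GluedContext", up = ctx0@up, down = ctx0@down,
              spliceUp = 14L, spliceDown = 11L, flank = 10L,
              intronLength = 40L, origin = list(), id = ctx0@id)
  mH <- matchBhb(ctxH)
  hitH <- mH[mH$up_helix_start == 13L & mH$down_helix_start == 13L, ][1, ]
  expect_false(hitH$splice_up_in_bulge)
  ## provenance mismatch is an error
  other <- new("GluedContext", up = ctx0@up, down = ctx0@down,
               spliceUp = 11L, spliceDown = 11L, flank = 10L,
               intronLength = 40L, origin = list(), id = "other-context")
  expect_error(checkSpliceInBulge(m0, other), "not derived")
})

test_that("layout strings re-parse to the reported motif intervals", {
  withr::with_seed(2468, {
    checked <- 0L
    for (case in seq_len(200)) {
      up <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
      dn <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
      ctx <- new("GluedContext", up = up, down = dn, spliceUp = 1L,
                 spliceDown = 1L, flank = 1L, intronLength = 10L,
                 origin = list(), id = "layoutprop")
      motif <- motifSpec(3L, 2L, 1L, 1L)
      m <- matchBhb(ctx, motif)
      for (i in seq_len(min(nrow(m), 3L))) {
        parsed <- parseLayout(m$layout[i], motif)
        expect_equal(parsed$up_helix_start, m$up_helix_start[i])
        expect_equal(parsed$down_helix_start, m$down_helix_start[i])
        expect_equal(parsed$bulge_up,
                     c(m$bulge_up_start[i], m$bulge_up_end[i]))
        expect_equal(parsed$bulge_down,
                     c(m$bulge_down_start[i], m$bulge_down_end[i]))
        expect_equal(parsed$h_len, m$h_len[i])
        expect_equal(parsed$hprime_len, m$hprime_len[i])
        checked <- checked + 1L
      }
    }
    expect_gt(checked, 50L)    # the property was actually exercised
  })
})

test_that("cluster screening separates planted substrates from decoys", {
  loci <- c(demoLoci()[c(1, 2, 6)],
            list(locusSpec("d1", "tRNA", intronLen = 90L, decoy = TRUE),
                 locusSpec("d2", "rRNA", intronLen = 120L, decoy = TRUE)))
  sim <- buildGenome(loci, backgroundLen = 2500L, seed = 41L)
  tr <- truthJunctions(sim)
  clusters <- data.frame(left = tr$left_site, right = tr$right_site,
                         topology = "circular", strand = "+",
                         intron_length = tr$right_site - tr$left_site,
                         n_members = 1L, cov_rep1 = 3L, cov_rep2 = 3L,
                         cov_rep3 = 3L)
  rep <- detectSubstrates(sim, clusters)
  expect_equal(nrow(rep), 5L)
  cand <- rep$verdict == "SE-substrate-candidate"
  expect_equal(sort(rep$left[cand]), sort(tr$left_site[!tr$decoy]))
  expect_true(all(rep$verdict[match(tr$left_site[tr$decoy], rep$left)] ==
                  "no-motif"))
  expect_true(all(rep$energy[cand] < 0))
  ## empty cluster list: empty report
  expect_equal(nrow(detectSubstrates(sim, clusters[0, ])), 0L)
})

test_that("pairing the bulges away destroys the motif verdict", {
  ctx0 <- makeCanonicalContext()
  expect_gt(nrow(matchBhb(ctx0)), 0)
  ## mutate the upstream bulge so the central helix extends across it:
  ## bulge position 12 (adjacent to the helix) must pair dn[17] = U
  up <- ctx0@up
  substr(up, 10, 12) <- "GGA"   # up[12] = A pairs dn[17] = U
  ctxMut <- new("GluedContext", up = up, down = ctx0@down,
                spliceUp = 11L, spliceDown = 11L, flank = 10L,
                intronLength = 40L, origin = list(), id = "mutated")
  m <- matchBhb(ctxMut)
  expect_false(any(m$up_helix_start == 13L & m$down_helix_start == 13L))
})
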