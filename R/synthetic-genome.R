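## Synthetic genome construction with planted hBHBh'-flanked introns.
##
## The designed duplex around a planted intron, written along the two glued
## arms (defaults: h = h' = 4 bp, central helix 4 bp, bulges 3 nt):
##
##   upstream arm   5'- [h][bulge_up][helix][h'top] -3'
##   downstream arm 5'- [h'][bulge_down][helix_bot][h_bot] -3'
##
## with h_bot/helix_bot/h' the reverse complements of h/helix/h'top, so the
## three helices pair inter-arm while the two bulges stay unpaired.  The
## splice sites sit at bulge position 2: the intron begins at the second
## bulge_up nucleotide and ends one base before the second bulge_down
## nucleotide, i.e. cuts fall between bulge nucleotides 2 and 3 counted
## from the central-helix-proximal side.

## motif window bookkeeping for a LocusSpec (lengths of the designed
## segments on each side of the two splice sites)
.motifGeometry <- function(motif) {
  hL <- motif@hLen; bl <- motif@bulgeLen
  hl <- motif@helixLen; hpL <- motif@hprimeLen
  list(hL = hL, bl = bl, hl = hl, hpL = hpL,
       exon5Tail = hL + bl - 2L,        # designed exonic nt before the intron
       intronHead = 2L + hl + hpL,      # designed nt at the intron 5' end
       intronTail = hpL + bl - 2L,      # designed nt at the intron 3' end
       exon3Head = 2L + hl + hL)        # designed exonic nt after the intron
}

## draw the two bulges under the design constraints; errors after too many
## rejections (only possible for degenerate geometries)
.drawBulges <- function(bl, hbot1, hptop1, wobble) {
  for (i in seq_len(200L)) {
    bu <- .randBases(bl)
    bd <- .randBases(bl)
    buR <- chartr("T", "U", bu); bdR <- chartr("T", "U", bd)
    ok <- !canPair(buR[bl], chartr("T", "U", hbot1), wobble) &&
          !canPair(bdR[bl], chartr("T", "U", hptop1), wobble)
    if (bl >= 3L)       # keep the ligation junction unambiguous for mapping
      ok <- ok && bu[bl - 2L] != bd[bl - 2L] && bd[bl - 1L] != bu[bl - 1L]
    if (ok) return(list(up = bu, down = bd))
  }
  stop("motif construction infeasible: could not draw bulges under constraints")
}

## designed sequence pieces for one motif locus
.designMotif <- function(motif) {
  g <- .motifGeometry(motif)
  comp <- function(x) .DNA_COMP[x]
  h <- .randBases(g$hL)
  helix <- .randBases(g$hl)
  hptop <- .randBases(g$hpL)
  hbot <- rev(comp(h))
  helixBot <- rev(comp(helix))
  hp <- rev(comp(hptop))
  bulges <- .drawBulges(g$bl,
                        hbot1 = if (g$hL > 0L) hbot[1L] else "N",
                        hptop1 = if (g$hpL > 0L) hptop[1L] else "N",
                        wobble = motif@allowWobble)
  up <- c(h, bulges$up, helix, hptop)           # upstream-arm window
  down <- c(hp, bulges$down, helixBot, hbot)    # downstream-arm window
  list(geom = g, up = up, down = down)
}

#' Build a synthetic genome with planted BHB-flanked introns
#'
#' Plants each locus (5' exon, intron, 3' exon) into i.i.d. uniform ACGT
#' background so that the windows around the two splice sites form the
#' designed hBHBh' duplex: complementary helix arms, intentionally
#' unpairable bulges, splice sites inside the bulges.  Decoy loci are
#' planted as circularised intervals with no motif.  Loci are placed left
#' to right separated by random spacers of at least `spacerMin`
#' nucleotides.
#'
#' @param loci A list of [LocusSpec-class] objects (may be empty).
#' @param backgroundLen Total genome length; must accommodate all loci plus
#'   spacers.
#' @param seed Integer seed; the genome is a deterministic function of it.
#' @param spacerMin Minimum gap between planted loci and to the genome ends.
#' @return A [SimulatedGenome-class] whose truth `GRanges` holds one intron
#'   interval per locus with `left_site`/`right_site` junction columns
#'   (`right_site - left_site` equals the intron length), `topology`,
#'   `kind`, `decoy`, and the locus bounds `locus_start`/`locus_end`.
#' @export
buildGenome <- function(loci = list(), backgroundLen = 4000L, seed = 1L,
                        spacerMin = 30L) {
  if (is(loci, "LocusSpec")) loci <- list(loci)
  for (lc in loci) stopifnot(is(lc, "LocusSpec"))
  ids <- vapply(loci, function(x) x@locusId, character(1))
  if (anyDuplicated(ids)) stop("locus ids must be unique")
  backgroundLen <- as.integer(backgroundLen)
  withr::with_seed(as.integer(seed), {
    locusSeqs <- lapply(loci, .buildLocusSeq)
    locusLens <- vapply(locusSeqs, function(x) length(x$seq), integer(1))
    n <- length(loci)
    slack <- backgroundLen - sum(locusLens)
    if (slack < (n + 1L) * spacerMin)
      stop("backgroundLen too small: loci would overlap or touch ",
           "(need total locus length plus spacers)")
    extra <- slack - (n + 1L) * spacerMin
    gaps <- spacerMin +
      as.integer(stats::rmultinom(1L, extra, rep(1, n + 1L)))
    chars <- .randBases(backgroundLen)
    pos <- 0L
    truthRows <- list()
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      lstart <- pos + 1L
      chars[lstart:(pos + locusLens[i])] <- locusSeqs[[i]]$seq
      s <- lstart + loci[[i]]@exon5Len
      e <- s + loci[[i]]@intronLen - 1L
      if (loci[[i]]@decoy) {
        ## keep the ligation junction unambiguous for exact recovery
        if (chars[e] == chars[s - 1L])
          chars[e] <- sample(setdiff(c("A", "C", "G", "T"), chars[s - 1L]), 1L)
        if (chars[e + 1L] == chars[s])
          chars[e + 1L] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
      }
      truthRows[[i]] <- data.frame(
        locus_id = loci[[i]]@locusId, kind = loci[[i]]@kind,
        decoy = loci[[i]]@decoy, intron_start = s, intron_end = e,
        left_site = s, right_site = e + 1L,
        locus_start = lstart, locus_end = pos + locusLens[i],
        stringsAsFactors = FALSE)
      pos <- pos + locusLens[i]
    }
    genome <- Biostrings::DNAString(paste(chars, collapse = ""))
    truth <- if (n) {
      tr <- do.call(rbind, truthRows)
      gr <- GenomicRanges::GRanges("synthetic",
              IRanges::IRanges(tr$intron_start, tr$intron_end), strand = "+")
      mcols(gr) <- tr[c("locus_id", "kind", "decoy", "left_site",
                        "right_site", "locus_start", "locus_end")]
      gr$topology <- "circular"
      gr
    } else GenomicRanges::GRanges()
    new("SimulatedGenome", genome = genome, truth = truth, loci = loci,
        seed = as.integer(seed))
  })
}

## full locus sequence (exon5 + intron + exon3) with the motif overwritten
.buildLocusSeq <- function(locus) {
  e5 <- locus@exon5Len; L <- locus@intronLen; e3 <- locus@exon3Len
  seq <- .randBases(e5 + L + e3)
  if (!locus@decoy) {
    d <- .designMotif(locus@motif)
    g <- d$geom
    if (L < g$intronHead + g$intronTail + 1L)
      stop(sprintf("motif construction infeasible for locus '%s': intron of %d nt cannot hold the designed boundaries",
                   locus@locusId, L))
    if (e5 < max(g$exon5Tail, 1L) || e3 < max(g$exon3Head, 1L))
      stop(sprintf("motif construction infeasible for locus '%s': exons too short for the motif windows",
                   locus@locusId))
    upAt <- e5 - g$exon5Tail + 1L          # window spans splice site 1
    seq[upAt:(upAt + length(d$up) - 1L)] <- d$up
    dnAt <- e5 + L - g$intronTail + 1L     # window spans splice site 2
    seq[dnAt:(dnAt + length(d$down) - 1L)] <- d$down
  }
  list(seq = seq)
}

#' Demonstration locus set
#'
#' A compact substrate spectrum for demonstrations and pipeline runs: three
#' tRNA-like introns (103, 75 and 31 nt), two rRNA-processing-stem-like
#' introns (1658 and 2980 nt), one mRNA 5'-UTR intron (46 nt), plus
#' optional motif-free decoy circles.  Intron lengths span the range
#' reported for halophilic splicing-endonuclease substrates.
#'
#' @param decoys Number of decoy loci to append (default 0).
#' @param motif The [MotifSpec-class] used for all designed loci.
#' @return A list of [LocusSpec-class] objects.
#' @export
demoLoci <- function(decoys = 0L, motif = motifSpec()) {
  base <- list(
    locusSpec("trna_trp", "tRNA", intronLen = 103L, motif = motif),
    locusSpec("trna_met", "tRNA", intronLen = 75L, motif = motif),
    locusSpec("trna_gln", "tRNA", intronLen = 31L, motif = motif),
    locusSpec("rrna_16s", "rRNA", intronLen = 1658L, motif = motif),
    locusSpec("rrna_23s", "rRNA", intronLen = 2980L, motif = motif),
    locusSpec("utr_m24", "mRNA_5UTR", intronLen = 46L, motif = motif))
  if (decoys > 0L) {
    base <- c(base, lapply(seq_len(decoys), function(i)
      locusSpec(sprintf("decoy_%02d", i), "mRNA_5UTR", intronLen = 90L,
                motif = motif, decoy = TRUE)))
  }
  base
}
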