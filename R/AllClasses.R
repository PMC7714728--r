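#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Geometry of the hBHBh' motif
#'
#' Parameters of the bulge-helix-bulge structure recognised by the archaeal
#' splicing endonuclease: a central helix of `helixLen` base pairs flanked by
#' two unpaired bulges of `bulgeLen` nucleotides on opposite strands, each
#' bounded distally by an outer helix (`hLen` / `hprimeLen` base pairs).  The
#' halophile enzyme is strict: it requires the outer helices (the "h" and
#' "h'" of hBHBh') and the canonical 4-bp/3-nt geometry, which are the
#' defaults here.
#'
#' @slot helixLen Central helix length in base pairs (default 4).
#' @slot bulgeLen Bulge length in nucleotides (default 3).
#' @slot hLen,hprimeLen Minimum outer helix lengths in base pairs (default 4).
#' @slot allowWobble Whether G:U wobble pairs count as paired (default TRUE).
#' @exportClass MotifSpec
setClass("MotifSpec",
  representation(helixLen = "integer", bulgeLen = "integer",
                 hLen = "integer", hprimeLen = "integer",
                 allowWobble = "logical"))

setValidity("MotifSpec", function(object) {
  msg <- character(0)
  if (object@helixLen < 1L) msg <- c(msg, "helixLen must be >= 1")
  if (object@bulgeLen < 1L) msg <- c(msg, "bulgeLen must be >= 1")
  if (object@hLen < 0L || object@hprimeLen < 0L)
    msg <- c(msg, "outer helix lengths must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param helixLen,bulgeLen,hLen,hprimeLen,allowWobble See slot descriptions.
#' @return `motifSpec()` returns a `MotifSpec` object.
#' @rdname MotifSpec-class
#' @export
motifSpec <- function(helixLen = 4L, bulgeLen = 3L, hLen = 4L,
                      hprimeLen = 4L, allowWobble = TRUE) {
  new("MotifSpec", helixLen = as.integer(helixLen),
      bulgeLen = as.integer(bulgeLen), hLen = as.integer(hLen),
      hprimeLen = as.integer(hprimeLen), allowWobble = allowWobble)
}

setMethod("show", "MotifSpec", function(object) {
  cat(sprintf("hBHBh' motif: h=%d bp | bulge=%d nt | helix=%d bp | bulge=%d nt | h'=%d bp; wobble %s\n",
              object@hLen, object@bulgeLen, object@helixLen, object@bulgeLen,
              object@hprimeLen,
              if (object@allowWobble) "allowed" else "disallowed"))
})

#' Specification of one planted locus
#'
#' Describes a locus to plant into a synthetic genome: a 5' exon, an intron
#' whose boundaries carry a designed hBHBh' motif, and a 3' exon.  `kind`
#' mirrors the substrate classes in which BHB introns occur (tRNA, rRNA
#' processing stems, mRNA 5' UTR).  A `decoy` locus plants a circularised
#' interval with ordinary random sequence and *no* motif; such loci emulate
#' circular RNAs that are not splicing-endonuclease products and serve as
#' negative controls for the detector.
#'
#' @slot locusId Unique identifier.
#' @slot kind One of `"tRNA"`, `"rRNA"`, `"mRNA_5UTR"`.
#' @slot exon5Len,intronLen,exon3Len Segment lengths in nucleotides.
#' @slot motif A [MotifSpec-class] describing the designed motif.
#' @slot decoy Logical; plant without a motif.
#' @exportClass LocusSpec
setClass("LocusSpec",
  representation(locusId = "character", kind = "character",
                 exon5Len = "integer", intronLen = "integer",
                 exon3Len = "integer", motif = "MotifSpec",
                 decoy = "logical"))

setValidity("LocusSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("tRNA", "rRNA", "mRNA_5UTR"))
    msg <- c(msg, "kind must be tRNA, rRNA or mRNA_5UTR")
  if (object@intronLen < 16L)
    msg <- c(msg, "intronLen must be >= 16 (two bulge halves plus insert)")
  if (object@exon5Len < 1L || object@exon3Len < 1L)
    msg <- c(msg, "exon lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' @param locusId,kind,exon5Len,intronLen,exon3Len,motif,decoy See slots.
#' @return `locusSpec()` returns a `LocusSpec` object.
#' @rdname LocusSpec-class
#' @export
locusSpec <- function(locusId, kind = c("tRNA", "rRNA", "mRNA_5UTR"),
                      intronLen, exon5Len = 60L, exon3Len = 60L,
                      motif = motifSpec(), decoy = FALSE) {
  kind <- match.arg(kind)
  new("LocusSpec", locusId = as.character(locusId), kind = kind,
      exon5Len = as.integer(exon5Len), intronLen = as.integer(intronLen),
      exon3Len = as.integer(exon3Len), motif = motif, decoy = decoy)
}

setMethod("show", "LocusSpec", function(object) {
  cat(sprintf("locus %s [%s%s]: exon5=%d, intron=%d, exon3=%d nt\n",
              object@locusId, object@kind,
              if (object@decoy) ", decoy" else "",
              object@exon5Len, object@intronLen, object@exon3Len))
})

#' A synthetic genome with planted introns and its ground truth
#'
#' Returned by [buildGenome()].  Couples the genome sequence with a
#' `GRanges` of planted intron intervals (the truth set): each range is the
#' intron `[left, right - 1]`, and its metadata columns record the expected
#' junction (`left_site`, `right_site`, with length `right - left`),
#' topology, locus identity and whether the locus is a motif-free decoy.
#'
#' @slot genome A `DNAString` holding the single replicon.
#' @slot truth A `GRanges` of planted introns with junction metadata.
#' @slot loci The list of [LocusSpec-class] objects that were planted.
#' @slot seed Integer seed the genome was built from.
#' @exportClass SimulatedGenome
setClass("SimulatedGenome",
  representation(genome = "DNAString", truth = "GRanges",
                 loci = "list", seed = "integer"))

setValidity("SimulatedGenome", function(object) {
  if (length(object@truth) &&
      any(BiocGenerics::end(object@truth) > length(object@genome)))
    return("truth intervals exceed genome bounds")
  TRUE
})

setMethod("show", "SimulatedGenome", function(object) {
  cat(sprintf("SimulatedGenome: %d nt, %d planted loci (%d decoys), seed %d\n",
              length(object@genome), length(object@truth),
              sum(object@truth$decoy), object@seed))
})

#' @param x A `SimulatedGenome`.
#' @return `genomeSeq()` returns the genome as a `DNAString`;
#'   `truthJunctions()` the truth `GRanges`.
#' @rdname SimulatedGenome-class
#' @export
genomeSeq <- function(x) x@genome

#' @rdname SimulatedGenome-class
#' @export
truthJunctions <- function(x) x@truth

#' Read-simulation settings
#'
#' Conditions under which circRNA-seq style read sets are simulated from a
#' [SimulatedGenome-class]: single-end reads of `readLen` nucleotides in
#' `nReplicates` replicates; every circular junction receives
#' `perJunctionDepth[r]` back-junction reads in replicate `r` (scaled by
#' `circularEnrichment`, the RNase-R style enrichment knob); contiguous
#' genomic background reads at `linearBackgroundDepth` mean coverage;
#' i.i.d. substitution errors at `errorRate` per base.
#'
#' @slot nReplicates,readLen,perJunctionDepth,linearBackgroundDepth Numeric
#'   settings as described above.
#' @slot errorRate Per-base substitution probability in `[0, 0.1]`.
#' @slot circularEnrichment Sampling-weight multiplier (>= 1) on circular
#'   templates.
#' @slot minAnchor Minimum length of each genomic segment of a back-junction
#'   read (guarantees split-mappability).
#' @slot seed Integer seed; all randomness flows from it.
#' @slot baseQuality Constant Phred+33 quality character written to FASTQ.
#' @exportClass ReadSimConfig
setClass("ReadSimConfig",
  representation(nReplicates = "integer", readLen = "integer",
                 perJunctionDepth = "integer",
                 linearBackgroundDepth = "numeric", errorRate = "numeric",
                 circularEnrichment = "numeric", minAnchor = "integer",
                 seed = "integer", baseQuality = "character"))

setValidity("ReadSimConfig", function(object) {
  msg <- character(0)
  if (object@readLen < 20L) msg <- c(msg, "readLen must be >= 20")
  if (object@errorRate < 0 || object@errorRate > 0.1)
    msg <- c(msg, "errorRate must be in [0, 0.1]")
  if (any(object@perJunctionDepth < 0L) || object@linearBackgroundDepth < 0)
    msg <- c(msg, "depths must be >= 0")
  if (length(object@perJunctionDepth) != object@nReplicates)
    msg <- c(msg, "perJunctionDepth must have one entry per replicate")
  if (object@circularEnrichment < 1)
    msg <- c(msg, "circularEnrichment must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @param nReplicates,readLen,perJunctionDepth,linearBackgroundDepth,errorRate,circularEnrichment,minAnchor,seed,baseQuality
#'   See slot descriptions.
#' @return `readSimConfig()` returns a `ReadSimConfig` object.
#' @rdname ReadSimConfig-class
#' @export
readSimConfig <- function(nReplicates = 3L, readLen = 75L,
                          perJunctionDepth = rep(6L, nReplicates),
                          linearBackgroundDepth = 2,
                          errorRate = 0, circularEnrichment = 1,
                          minAnchor = 20L, seed = 1L, baseQuality = "I") {
  new("ReadSimConfig", nReplicates = as.integer(nReplicates),
      readLen = as.integer(readLen),
      perJunctionDepth = as.integer(perJunctionDepth),
      linearBackgroundDepth = linearBackgroundDepth,
      errorRate = errorRate, circularEnrichment = circularEnrichment,
      minAnchor = as.integer(minAnchor), seed = as.integer(seed),
      baseQuality = baseQuality)
}

#' Glued exon-flank context around a candidate intron
#'
#' The BHB motif is an inter-strand structure formed by the regions flanking
#' the two splice sites; the intron interior contributes nothing and is
#' treated as an insert.  `GluedContext` therefore holds two arms in RNA
#' alphabet: the upstream arm (exonic flank before the intron followed by
#' the first intronic nucleotides) and the downstream arm (last intronic
#' nucleotides followed by the exonic flank after the intron).  Splice-site
#' positions record, within each arm, the nucleotide immediately 3' of the
#' scissile cut: the first intronic base upstream and the first exonic base
#' downstream.
#'
#' @slot up,down Arm sequences (character, RNA alphabet).
#' @slot spliceUp,spliceDown Splice-site positions within the arms.
#' @slot flank Exonic flank length used for extraction.
#' @slot intronLength Length of the candidate intron.
#' @slot origin List with the genomic `start`, `end` and `strand`.
#' @slot id Content hash linking matches back to this context.
#' @exportClass GluedContext
setClass("GluedContext",
  representation(up = "character", down = "character",
                 spliceUp = "integer", spliceDown = "integer",
                 flank = "integer", intronLength = "integer",
                 origin = "list", id = "character"))

setValidity("GluedContext", function(object) {
  msg <- character(0)
  if (!nzchar(object@up) || !nzchar(object@down))
    msg <- c(msg, "arms must be non-empty")
  if (object@spliceUp < 1L || object@spliceUp > nchar(object@up) ||
      object@spliceDown < 1L || object@spliceDown > nchar(object@down))
    msg <- c(msg, "splice sites must lie inside the arms")
  if (grepl("[^ACGU]", object@up) || grepl("[^ACGU]", object@down))
    msg <- c(msg, "arms must be over the RNA alphabet ACGU")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GluedContext", function(object) {
  cat(sprintf("GluedContext (intron %d nt, flank %d):\n  up   (%2d nt, splice@%d): %s\n  down (%2d nt, splice@%d): %s\n",
              object@intronLength, object@flank,
              nchar(object@up), object@spliceUp, object@up,
              nchar(object@down), object@spliceDown, object@down))
})

#' @param x A `GluedContext`.
#' @return `upstreamArm()`/`downstreamArm()` return the arm sequences;
#'   `spliceSites()` the two within-arm splice positions.
#' @rdname GluedContext-class
#' @export
upstreamArm <- function(x) x@up

#' @rdname GluedContext-class
#' @export
downstreamArm <- function(x) x@down

#' @rdname GluedContext-class
#' @export
spliceSites <- function(x) c(up = x@spliceUp, down = x@spliceDown)

#' A precursor RNA with defined endonuclease cut positions
#'
#' The substrate of the cleavage model: an RNA and the two scissile
#' positions inside its BHB bulges.  A cut "after position k" severs the
#' backbone between nucleotides k and k+1.  The 2',3'-cyclic phosphate and
#' 5'-OH ends produced by the endonuclease are carried as labels only.
#'
#' @slot sequence RNA sequence (character).
#' @slot cuts Integer pair of cut positions, `1 <= cuts[1] < cuts[2] < length`.
#' @slot label Free-text substrate label.
#' @exportClass PrecursorSubstrate
setClass("PrecursorSubstrate",
  representation(sequence = "character", cuts = "integer", label = "character"))

setValidity("PrecursorSubstrate", function(object) {
  n <- nchar(object@sequence)
  if (length(object@cuts) != 2L)
    return("exactly two cut positions are required")
  if (object@cuts[1] < 1L || object@cuts[2] <= object@cuts[1] ||
      object@cuts[2] >= n)
    return("cuts must satisfy 1 <= cut1 < cut2 < length(sequence)")
  TRUE
})

#' @param sequence,cuts,label See slot descriptions.
#' @return `precursorSubstrate()` returns a `PrecursorSubstrate`.
#' @rdname PrecursorSubstrate-class
#' @export
precursorSubstrate <- function(sequence, cuts, label = "substrate") {
  new("PrecursorSubstrate",
      sequence = paste(.rnaChars(sequence), collapse = ""),
      cuts = as.integer(cuts), label = as.character(label))
}

setMethod("show", "PrecursorSubstrate", function(object) {
  cat(sprintf("PrecursorSubstrate '%s': %d nt, cuts after %d and %d\n",
              object@label, nchar(object@sequence),
              object@cuts[1], object@cuts[2]))
})

#' Products of splicing-endonuclease cleavage and ligation
#'
#' Cleavage at the two BHB bulges yields three fragments in 5'->3' order;
#' ligation joins the outer fragments (ligated exons) and circularises the
#' middle fragment (the species circRNA-seq observes).  The circular intron
#' is stored as its canonical (lexicographically minimal) rotation.
#'
#' @slot fragment5,fragmentMid,fragment3 The three fragments.
#' @slot ligatedExons `fragment5` joined to `fragment3`.
#' @slot circularIntron Canonical rotation of `fragmentMid`.
#' @slot cutPositions The cut positions used.
#' @exportClass CleavageResult
setClass("CleavageResult",
  representation(fragment5 = "character", fragmentMid = "character",
                 fragment3 = "character", ligatedExons = "character",
                 circularIntron = "character", cutPositions = "integer"))

setValidity("CleavageResult", function(object) {
  msg <- character(0)
  if (!nzchar(object@fragmentMid))
    msg <- c(msg, "middle fragment must be non-empty")
  if (object@ligatedExons !=
      paste0(object@fragment5, object@fragment3))
    msg <- c(msg, "ligatedExons must equal fragment5 + fragment3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CleavageResult", function(object) {
  cat(sprintf("CleavageResult: fragments %d + %d + %d nt (cuts after %d, %d); ligated exons %d nt; circular intron %d nt\n",
              nchar(object@fragment5), nchar(object@fragmentMid),
              nchar(object@fragment3), object@cutPositions[1],
              object@cutPositions[2], nchar(object@ligatedExons),
              nchar(object@circularIntron)))
})

#' @param x A `CleavageResult`.
#' @return `fragments()` returns the named character vector of the three
#'   fragments; `ligatedExons()` and `circularIntron()` the ligation
#'   products.
#' @rdname CleavageResult-class
#' @export
fragments <- function(x) c(fragment5 = x@fragment5, fragmentMid = x@fragmentMid,
                           fragment3 = x@fragment3)

#' @rdname CleavageResult-class
#' @export
ligatedExons <- function(x) x@ligatedExons

#' @rdname CleavageResult-class
#' @export
circularIntron <- function(x) x@circularIntron
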