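## Splicing-endonuclease cleavage and ligation model.
##
## Cleavage at the two bulge-internal scissile positions yields three
## fragments; ligation joins the outer fragments (exon ligation) and
## closes the middle one into a circle.  Chemical ends (2',3'-cyclic
## phosphate / 5'-OH) are metadata, not modeled chemistry.

#' Cleave a precursor at its two scissile positions
#'
#' Cuts the backbone after `cuts[1]` and after `cuts[2]`, returning the
#' three fragments in 5'->3' order together with the ligation products.
#' Fragment lengths always sum to the precursor length.
#'
#' @param precursor A [PrecursorSubstrate-class].
#' @return A [CleavageResult-class].
#' @examples
#' pre <- precursorSubstrate(strrep("ACGU", 26), cuts = c(26, 73))  # 104 nt
#' nchar(fragments(cleaveSubstrate(pre)))                           # 26 47 31
#' @export
cleaveSubstrate <- function(precursor) {
  stopifnot(is(precursor, "PrecursorSubstrate"))
  s <- precursor@sequence
  c1 <- precursor@cuts[1]; c2 <- precursor@cuts[2]
  f5 <- substr(s, 1L, c1)
  mid <- substr(s, c1 + 1L, c2)
  f3 <- substr(s, c2 + 1L, nchar(s))
  new("CleavageResult", fragment5 = f5, fragmentMid = mid, fragment3 = f3,
      ligatedExons = paste0(f5, f3),
      circularIntron = canonicalRotation(mid),
      cutPositions = precursor@cuts)
}

#' Ligation products of a cleavage
#'
#' The exon-bearing outer fragments are joined; the middle fragment is
#' circularised, represented by its canonical rotation.
#'
#' @param result A [CleavageResult-class].
#' @return A list with `ligated_exons` and `circular_intron`.
#' @export
ligateFragments <- function(result) {
  stopifnot(is(result, "CleavageResult"))
  if (!nzchar(result@fragmentMid))
    stop("cannot circularise an empty middle fragment")
  list(ligated_exons = result@ligatedExons,
       circular_intron = result@circularIntron)
}

#' Build a precursor substrate from a genomic intron
#'
#' Extracts the region `flank` nucleotides either side of the intron and
#' places the two cuts inside the bulges according to `cutRule`: `"afterK"`
#' severs between bulge nucleotides K and K+1, counted from the
#' central-helix-proximal side.  The default (`"after2"`) reproduces the
#' splice sites the genome generator designs; the scissile position within
#' the bulge is not determined by the motif itself, so the alternatives are
#' offered as explicit conventions.
#'
#' @param genome Genome sequence (or [SimulatedGenome-class]).
#' @param intron Integer pair `c(start, end)`, 1-based inclusive.
#' @param flank Exonic length retained either side (default 25 nt).
#' @param cutRule One of `"after1"`, `"after2"`, `"after3"`.
#' @param label Substrate label.
#' @return A [PrecursorSubstrate-class].
#' @export
precursorFromIntron <- function(genome, intron, flank = 25L,
                                cutRule = c("after2", "after1", "after3"),
                                label = "substrate") {
  cutRule <- match.arg(cutRule)
  K <- as.integer(sub("after", "", cutRule))
  if (is(genome, "SimulatedGenome")) genome <- genomeSeq(genome)
  gseq <- toupper(as.character(genome))
  s <- as.integer(intron[1]); e <- as.integer(intron[2])
  if (s - flank < 1L || e + flank > nchar(gseq))
    stop("insufficient flank at the genome edge")
  seq <- chartr("T", "U", substr(gseq, s - flank, e + flank))
  L <- e - s + 1L
  cuts <- c(flank + 2L - K, flank + L + 2L - K)
  precursorSubstrate(seq, cuts, label)
}
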