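## Internal sequence utilities shared across modules.

.RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")
.DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A")

## split a sequence string into a character vector of bases (RNA alphabet)
.rnaChars <- function(x) {
  x <- chartr("Tt", "Uu", toupper(as.character(x)))
  strsplit(x, "", fixed = TRUE)[[1]]
}

.dnaString <- function(x) Biostrings::DNAString(chartr("U", "T", toupper(as.character(x))))

.revcompChr <- function(x) {
  as.character(Biostrings::reverseComplement(.dnaString(x)))
}

## Watson-Crick (+ optional GU wobble) pairing predicate on RNA letters.
## Vectorised over equal-length inputs.
canPair <- function(a, b, wobble = TRUE) {
  duo <- paste0(a, b)
  wc <- duo %in% c("AU", "UA", "GC", "CG")
  if (wobble) wc | duo %in% c("GU", "UG") else wc
}

#' Canonical rotation of a circular sequence
#'
#' Circular RNAs have no distinguished 5' end, so two sequences describe the
#' same circle iff one is a rotation of the other.  This returns the
#' lexicographically minimal rotation, a canonical representative usable for
#' comparison and serialization.
#'
#' @param x A character scalar (or `XString`) holding the sequence.
#' @return A character scalar, the minimal rotation of `x`.
#' @examples
#' canonicalRotation("GAU") == canonicalRotation("AUG")
#' @export
canonicalRotation <- function(x) {
  x <- as.character(x)
  n <- nchar(x)
  if (n <= 1L) return(x)
  doubled <- paste0(x, x)
  rots <- substring(doubled, seq_len(n), seq_len(n) + n - 1L)
  sort(rots, method = "radix")[1L]  # radix = C-locale order, locale-independent
}

## deterministic uniform base draw
.randBases <- function(n, alphabet = c("A", "C", "G", "T")) {
  sample(alphabet, n, replace = TRUE)
}

## stable content hash used for provenance links between objects
.hashOf <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(vapply(list(...), paste, character(1), collapse = ","),
                   collapse = "|"), f)
  unname(tools::md5sum(f))
}
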