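## A small exact/near-exact split-read mapper for desk-scale genomes.
## It reports each read as unsplit, split into two genomic segments (with
## segment order in read coordinates), or unmapped.  It is deliberately
## simple -- seed both read ends, extend along the two diagonals, choose the
## split point minimising mismatches -- which is all the synthetic fixtures
## need; real data would arrive as SAM split alignments instead.

.seedHits <- function(seed, genome, maxMM) {
  h <- Biostrings::start(Biostrings::matchPattern(seed, genome,
                                                  max.mismatch = 0))
  if (!length(h) && maxMM > 0)
    h <- Biostrings::start(Biostrings::matchPattern(seed, genome,
                                                    max.mismatch = 1))
  h
}

## mismatch vector of read laid on the genome with read position 1 at gpos
.diagMismatch <- function(readChars, gchars, gpos) {
  len <- length(readChars)
  idx <- gpos + seq_len(len) - 1L
  ok <- idx >= 1L & idx <= length(gchars)
  mm <- rep(Inf, len)
  mm[ok] <- as.numeric(readChars[ok] != gchars[idx[ok]])
  mm
}

.mapOneStrand <- function(readStr, genome, gchars, minSeed, maxMM) {
  len <- nchar(readStr)
  rd <- Biostrings::DNAString(readStr)
  ## unsplit?
  full <- Biostrings::matchPattern(rd, genome, max.mismatch = maxMM)
  if (length(full)) {
    nmm <- Biostrings::neditStartingAt(rd, genome,
                                       starting.at = Biostrings::start(full))
    best <- which.min(nmm)
    return(list(type = "unsplit",
                seg = data.frame(segment = 1L,
                                 ref_start = Biostrings::start(full)[best],
                                 ref_end = Biostrings::end(full)[best],
                                 read_start = 1L, read_end = len,
                                 mismatches = as.integer(nmm[best]))))
  }
  if (len < 2L * minSeed) return(NULL)
  readChars <- strsplit(readStr, "")[[1]]
  pre <- .seedHits(Biostrings::DNAString(substr(readStr, 1L, minSeed)),
                   genome, maxMM)
  suf <- .seedHits(Biostrings::DNAString(substr(readStr, len - minSeed + 1L, len)),
                   genome, maxMM)
  if (!length(pre) || !length(suf)) return(NULL)
  pre <- utils::head(pre, 10L)
  suf <- utils::head(suf, 10L)
  best <- NULL
  for (gp in pre) {
    mm1 <- cumsum(.diagMismatch(readChars, gchars, gp))
    for (gs in suf) {
      g2pos <- gs - (len - minSeed)   # genome pos aligned with read pos 1
      if (g2pos == gp) next           # same diagonal: contiguous, not split
      mm2 <- .diagMismatch(readChars, gchars, g2pos)
      mm2tail <- c(rev(cumsum(rev(mm2))), 0)     # mm2tail[i] = sum mm2[i..len]
      i <- seq.int(minSeed, len - minSeed)
      cost <- mm1[i] + mm2tail[i + 1L]
      j <- which(cost == min(cost))[1L]
      ci <- i[j]; cc <- cost[j]
      if (is.finite(cc) && cc <= maxMM &&
          (is.null(best) || cc < best$cost)) {
        best <- list(cost = cc, split = ci, gp = gp, g2 = g2pos)
      }
    }
  }
  if (is.null(best)) return(NULL)
  i <- best$split
  list(type = "split",
       seg = data.frame(segment = 1:2,
                        ref_start = c(best$gp, best$g2 + i),
                        ref_end = c(best$gp + i - 1L, best$g2 + len - 1L),
                        read_start = c(1L, i + 1L),
                        read_end = c(i, len),
                        mismatches = NA_integer_))
}

#' Map reads against a genome, reporting split alignments
#'
#' Aligns each read to the genome, first as one contiguous match (up to
#' `maxMismatch` substitutions), otherwise as two near-exact genomic
#' segments found by seeding both read ends and choosing the split point
#' with the fewest total mismatches (ties resolved to the smallest split).
#' Both strands are tried (`+` first); minus-strand hits report genome
#' coordinates of the reverse-complemented read with segment order in read
#' coordinates.  Deterministic for fixed input.
#'
#' @param reads A `DNAStringSet`, named character vector, or the list
#'   returned for one replicate by [simulateReads()].
#' @param genome Genome sequence (or [SimulatedGenome-class]).
#' @param minSeed Seed/segment length in nt (>= 12; default 18).
#' @param maxMismatch Total substitution budget per read (default 3).
#' @param replicate Replicate id recorded in the output.
#' @return A data.frame with one row per aligned segment: `read_id`,
#'   `replicate`, `strand`, `n_segments`, `segment` (read order),
#'   `ref_start`, `ref_end`, `read_start`, `read_end`.  Unmapped read ids
#'   are in `attr(, "unmapped")`.
#' @export
mapSplitReads <- function(reads, genome, minSeed = 18L, maxMismatch = 3L,
                          replicate = 1L) {
  if (is(genome, "SimulatedGenome")) genome <- genomeSeq(genome)
  if (is.character(genome)) genome <- Biostrings::DNAString(genome)
  if (length(genome) == 0L) stop("empty genome")
  minSeed <- as.integer(minSeed)
  if (minSeed < 12L) stop("minSeed must be >= 12")
  if (is(reads, "XStringSet")) {
    nm <- names(reads)
    reads <- as.character(reads)
    names(reads) <- nm
  }
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  gchars <- strsplit(as.character(genome), "")[[1]]
  res <- vector("list", length(reads))
  unmapped <- character(0)
  for (i in seq_along(reads)) {
    rid <- names(reads)[i]
    hit <- .mapOneStrand(reads[[i]], genome, gchars, minSeed, maxMismatch)
    strand <- "+"
    if (is.null(hit)) {
      hit <- .mapOneStrand(.revcompChr(reads[[i]]), genome, gchars,
                           minSeed, maxMismatch)
      strand <- "-"
    }
    if (is.null(hit)) {
      unmapped <- c(unmapped, rid)
      next
    }
    seg <- hit$seg
    if (strand == "-") {
      ## segments were found for the reverse complement; restore read order
      ## and read coordinates of the original read
      len <- nchar(reads[[i]])
      seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
      newStart <- len - seg$read_end + 1L
      newEnd <- len - seg$read_start + 1L
      seg$read_start <- newStart
      seg$read_end <- newEnd
      seg$segment <- seq_len(nrow(seg))
    }
    seg$read_id <- rid
    seg$replicate <- as.integer(replicate)
    seg$strand <- strand
    seg$n_segments <- nrow(seg)
    res[[i]] <- seg
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(segment = integer(0), ref_start = integer(0),
                      ref_end = integer(0), read_start = integer(0),
                      read_end = integer(0), mismatches = integer(0),
                      read_id = character(0), replicate = integer(0),
                      strand = character(0), n_segments = integer(0))
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  out
}
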