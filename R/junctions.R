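## Junction calling, replicate-coverage filtering, proximity merging and
## intron conversion.
##
## Coordinate convention used throughout: a junction is the pair
## (left, right) with `left` the first intronic base and `right` the first
## base after the intron (both 1-based); the intron interval is
## [left, right - 1] and its length is right - left.

#' Call splice-site pairs from split alignments
#'
#' A two-segment alignment whose segments are genomically ordered (the 5'
#' segment upstream) is read evidence of ligated exons and yields a
#' `linear` junction spanning the skipped interval; segments in reversed
#' genomic order are a back-junction across the ligation point of a
#' circularised intron and yield a `circular` junction over the
#' circularised interval.  Minus-strand alignments are handled by mirroring
#' the coordinates, applying the plus-strand logic and mirroring back, so
#' both strands behave symmetrically.  Reads with more than two segments
#' are skipped with a warning (count in `attr(, "skipped_multisegment")`).
#'
#' @param alignments Segment table from [mapSplitReads()] or
#'   [readSplitAlignmentsSam()].
#' @param genomeLength Genome length (needed to mirror minus-strand
#'   coordinates).
#' @return A data.frame of junction observations: `read_id`, `replicate`,
#'   `strand`, `topology` (`linear`/`circular`), `left`, `right`.
#' @export
callJunctions <- function(alignments, genomeLength) {
  emp <- data.frame(read_id = character(0), replicate = integer(0),
                    strand = character(0), topology = character(0),
                    left = integer(0), right = integer(0))
  if (!nrow(alignments)) {
    attr(emp, "skipped_multisegment") <- 0L
    return(emp)
  }
  skipped <- 0L
  obs <- list()
  for (rid in unique(alignments$read_id)) {
    seg <- alignments[alignments$read_id == rid, , drop = FALSE]
    if (seg$n_segments[1] > 2L) {
      skipped <- skipped + 1L
      next
    }
    if (nrow(seg) != 2L) next                  # unsplit: no junction
    seg <- seg[order(seg$segment), , drop = FALSE]
    strand <- seg$strand[1]
    a <- seg[1, ]; b <- seg[2, ]
    if (strand == "-") {
      ## mirror: pos' = glen - pos + 1 turns a minus-strand alignment into
      ## an equivalent plus-strand one (segment read order is preserved)
      a2 <- a; b2 <- b
      a2$ref_start <- genomeLength - a$ref_end + 1L
      a2$ref_end <- genomeLength - a$ref_start + 1L
      b2$ref_start <- genomeLength - b$ref_end + 1L
      b2$ref_end <- genomeLength - b$ref_start + 1L
      j <- .plusJunction(a2, b2)
      if (is.null(j)) next
      ## junction (l', r') over mirrored intron [l', r'-1] maps back to the
      ## genomic intron [glen - r' + 2, glen - l' + 1]
      obs[[length(obs) + 1L]] <- data.frame(
        read_id = rid, replicate = a$replicate, strand = strand,
        topology = j$topology,
        left = genomeLength - j$right + 2L,
        right = genomeLength - j$left + 2L)
    } else {
      j <- .plusJunction(a, b)
      if (is.null(j)) next
      obs[[length(obs) + 1L]] <- data.frame(
        read_id = rid, replicate = a$replicate, strand = strand,
        topology = j$topology, left = j$left, right = j$right)
    }
  }
  if (skipped)
    warning(sprintf("%d read(s) with >2 segments skipped", skipped))
  out <- if (length(obs)) do.call(rbind, obs) else emp
  rownames(out) <- NULL
  attr(out, "skipped_multisegment") <- skipped
  out
}

## plus-strand junction geometry for segments a (first in read) and b
.plusJunction <- function(a, b) {
  if (b$ref_start > a$ref_end + 1L) {
    ## genomically ordered with a gap: spliced (linear) junction
    list(topology = "linear", left = a$ref_end + 1L, right = b$ref_start)
  } else if (a$ref_start >= b$ref_start && a$ref_end >= b$ref_end) {
    ## reversed genomic order: back-junction over the circularised interval
    list(topology = "circular", left = b$ref_start, right = a$ref_end + 1L)
  } else {
    NULL                                       # adjacent/overlapping: no call
  }
}

#' Filter junctions by per-replicate coverage
#'
#' Keeps a junction only if it is sufficiently covered in every replicate.
#' The strict default requires at least `minCoverage` observations in each
#' of the `nReplicates` replicates; `mode = "total"` implements the laxer
#' reading (total coverage >= `minCoverage` and present in all replicates).
#'
#' @param observations Observation table from [callJunctions()].
#' @param minCoverage Coverage threshold (default 2).
#' @param nReplicates Number of replicates that must support a junction
#'   (default 3).
#' @param mode `"per_replicate"` (strict, default) or `"total"`.
#' @return A data.frame of kept junctions sorted by coordinates, with
#'   per-replicate coverage columns `cov_rep1..N`.
#' @export
filterJunctions <- function(observations, minCoverage = 2L,
                            nReplicates = 3L,
                            mode = c("per_replicate", "total")) {
  mode <- match.arg(mode)
  nReplicates <- as.integer(nReplicates)
  if (nrow(observations) &&
      max(observations$replicate) > nReplicates)
    stop("observations carry replicate ids beyond nReplicates")
  key <- c("strand", "topology", "left", "right")
  emp <- data.frame(strand = character(0), topology = character(0),
                    left = integer(0), right = integer(0))
  for (r in seq_len(nReplicates)) emp[[paste0("cov_rep", r)]] <- integer(0)
  if (!nrow(observations)) return(emp)
  grp <- interaction(observations[key], drop = TRUE, sep = "\r")
  tab <- table(grp, factor(observations$replicate, levels = seq_len(nReplicates)))
  meta <- observations[match(levels(grp), as.character(grp)), key,
                       drop = FALSE]                # one row per group, in
  cov <- matrix(as.integer(tab), nrow = nrow(tab))  # the same (level) order
  keep <- if (mode == "per_replicate") {
    apply(cov >= minCoverage, 1L, all)
  } else {
    rowSums(cov) >= minCoverage & apply(cov >= 1L, 1L, all)
  }
  out <- meta[keep, , drop = FALSE]
  covk <- cov[keep, , drop = FALSE]
  colnames(covk) <- paste0("cov_rep", seq_len(nReplicates))
  out <- cbind(out, as.data.frame(covk))
  out <- out[order(out$left, out$right), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge nearby junctions into clusters
#'
#' Single-linkage clustering of junctions sharing topology and strand: two
#' junctions link when both the left and the right coordinates differ by at
#' most `maxDist` nucleotides.  Each cluster is represented by its member
#' with the highest total coverage (ties: smaller left, then smaller
#' right); cluster coverage is the per-replicate sum over members.
#'
#' @param junctions Filtered junction table from [filterJunctions()].
#' @param maxDist Chebyshev merge distance in nt (default 10).
#' @return A data.frame with one row per cluster: representative `left`,
#'   `right`, `topology`, `strand`, `intron_length` (right - left),
#'   `n_members`, summed `cov_rep*` columns and a `members` string
#'   (`left:right` pairs, `;`-separated).
#' @export
mergeJunctions <- function(junctions, maxDist = 10L) {
  covCols <- grep("^cov_rep", names(junctions), value = TRUE)
  emp <- data.frame(left = integer(0), right = integer(0),
                    topology = character(0), strand = character(0),
                    intron_length = integer(0), n_members = integer(0))
  for (cc in covCols) emp[[cc]] <- integer(0)
  emp$members <- character(0)
  if (!nrow(junctions)) return(emp)
  out <- list()
  for (gkey in unique(paste(junctions$topology, junctions$strand))) {
    sub <- junctions[paste(junctions$topology, junctions$strand) == gkey, ,
                     drop = FALSE]
    n <- nrow(sub)
    parent <- seq_len(n)
    find <- function(x) {
      while (parent[x] != x) x <- parent[x]
      x
    }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (abs(sub$left[i] - sub$left[j]) <= maxDist &&
            abs(sub$right[i] - sub$right[j]) <= maxDist) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    comp <- vapply(seq_len(n), find, integer(1))
    for (cid in unique(comp)) {
      mem <- sub[comp == cid, , drop = FALSE]
      tot <- rowSums(as.matrix(mem[covCols]))
      best <- order(-tot, mem$left, mem$right)[1L]
      rec <- data.frame(left = mem$left[best], right = mem$right[best],
                        topology = mem$topology[best],
                        strand = mem$strand[best],
                        intron_length = mem$right[best] - mem$left[best],
                        n_members = nrow(mem), stringsAsFactors = FALSE)
      for (cc in covCols) rec[[cc]] <- sum(mem[[cc]])
      rec$members <- paste(sprintf("%d:%d", mem$left, mem$right),
                           collapse = ";")
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$left, res$right), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Intron records from junction clusters
#'
#' Converts representative junction coordinates into intron intervals:
#' the intron is `[left, right - 1]` (1-based inclusive) with length
#' `right - left`.
#'
#' @param clusters Cluster table from [mergeJunctions()], or any data.frame
#'   with `left` and `right` columns.
#' @return A data.frame with `start`, `end`, `length` and (when present)
#'   `topology` columns.
#' @examples
#' intronFromCluster(data.frame(left = 1165777, right = 1165880))$length  # 103
#' @export
intronFromCluster <- function(clusters) {
  len <- clusters$right - clusters$left
  if (any(len <= 0))
    stop("non-positive intron length: right must exceed left")
  out <- data.frame(start = clusters$left, end = clusters$right - 1L,
                    length = len)
  if (!is.null(clusters$topology)) out$topology <- clusters$topology
  out
}
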