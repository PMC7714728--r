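## Ingestion of split alignments from SAM/BAM: supplementary-alignment
## pairs (SA-tag style chimeric reads, the form back-junctions take) and
## N-CIGAR spliced alignments (linear junctions).

#' Read split alignments from a SAM or BAM file
#'
#' Converts aligner output into the segment table consumed by
#' [callJunctions()].  Two alignment records of the same read (primary +
#' supplementary) become a two-segment split alignment ordered by read
#' coordinate; a single record whose CIGAR contains `N` becomes a
#' two-segment spliced alignment; plain records are unsplit.  Reads whose
#' records sit on both strands are skipped (counted in
#' `attr(, "skipped_mixed_strand")`).
#'
#' @param path SAM or BAM file; SAM is converted on the fly.
#' @param replicate Replicate id recorded in the output.
#' @return The same segment table layout as [mapSplitReads()] returns.
#' @export
readSplitAlignmentsSam <- function(path, replicate = 1L) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "strand", "pos", "cigar", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE))
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(rec$qname)
  segs <- list()
  skippedStrand <- 0L
  if (n) {
    perRead <- split(seq_len(n), rec$qname)
    for (rid in names(perRead)) {
      idx <- perRead[[rid]]
      if (length(unique(as.character(rec$strand[idx]))) > 1L) {
        skippedStrand <- skippedStrand + 1L
        next
      }
      parts <- list()
      for (i in idx) {
        parts <- c(parts, .cigarSegments(rec$cigar[i], rec$pos[i],
                                         as.character(rec$strand[i])))
      }
      df <- do.call(rbind, parts)
      ## read coordinates of minus-strand records refer to the original
      ## read; order segments along the read
      df <- df[order(df$read_start), , drop = FALSE]
      df$segment <- seq_len(nrow(df))
      df$read_id <- rid
      df$replicate <- as.integer(replicate)
      df$strand <- as.character(rec$strand[idx[1]])
      df$n_segments <- nrow(df)
      df$mismatches <- NA_integer_
      segs[[length(segs) + 1L]] <- df
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(segment = integer(0), ref_start = integer(0),
               ref_end = integer(0), read_start = integer(0),
               read_end = integer(0), read_id = character(0),
               replicate = integer(0), strand = character(0),
               n_segments = integer(0), mismatches = integer(0))
  rownames(out) <- NULL
  attr(out, "skipped_mixed_strand") <- skippedStrand
  out[c("segment", "ref_start", "ref_end", "read_start", "read_end",
        "mismatches", "read_id", "replicate", "strand", "n_segments")]
}

## walk a CIGAR, splitting the aligned region at N gaps; returns one
## data.frame row per block with reference and original-read coordinates
.cigarSegments <- function(cigar, pos, strand) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  len <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  qlen <- sum(len[op %in% c("M", "I", "S", "=", "X")]) +
    sum(len[op == "H"])
  qpos <- sum(len[op == "H" & seq_along(op) == 1L])  # leading hard clip
  rpos <- pos
  blocks <- list()
  curQ <- NA_integer_; curR <- NA_integer_
  endQ <- NA_integer_; endR <- NA_integer_
  flush <- function() {
    if (!is.na(curQ))
      blocks[[length(blocks) + 1L]] <<- c(curQ, endQ, curR, endR)
    curQ <<- NA_integer_
  }
  for (i in seq_along(op)) {
    o <- op[i]; l <- len[i]
    if (o %in% c("M", "=", "X")) {
      if (is.na(curQ)) { curQ <- qpos + 1L; curR <- rpos }
      qpos <- qpos + l; rpos <- rpos + l
      endQ <- qpos; endR <- rpos - 1L
    } else if (o == "I") {
      qpos <- qpos + l; endQ <- qpos
    } else if (o == "D") {
      rpos <- rpos + l; endR <- rpos - 1L
    } else if (o == "N") {
      flush()
      rpos <- rpos + l
    } else if (o == "S") {
      qpos <- qpos + l
    }
  }
  flush()
  lapply(blocks, function(b) {
    qs <- b[1]; qe <- b[2]
    if (strand == "-") {       # map back onto the original read
      qs2 <- qlen - b[2] + 1L
      qe <- qlen - b[1] + 1L
      qs <- qs2
    }
    data.frame(ref_start = b[3], ref_end = b[4],
               read_start = qs, read_end = qe)
  })
}
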