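## File-format plumbing: FASTA/FASTQ/GFF3/BED/TSV writers and readers.

#' Write the genome as FASTA
#'
#' Single record named `synthetic`, wrapped at 60 columns.
#'
#' @param sim A [SimulatedGenome-class] (or a `DNAString`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeGenomeFasta <- function(sim, path) {
  g <- if (is(sim, "SimulatedGenome")) genomeSeq(sim) else sim
  set <- Biostrings::DNAStringSet(as.character(g))
  names(set) <- "synthetic"
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Write simulated reads as per-replicate FASTQ files
#'
#' Phred+33 with the constant base quality from the config.
#'
#' @param rs The list returned by [simulateReads()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix; files are `<prefix>_rep<i>.fastq`.
#' @return Character vector of the written paths, invisibly.
#' @export
writeReadSet <- function(rs, dir, prefix = "reads") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- rs$config@baseQuality
  paths <- character(0)
  for (r in seq_along(rs$reads)) {
    path <- file.path(dir, sprintf("%s_rep%d.fastq", prefix, r))
    reads <- rs$reads[[r]]
    lines <- as.vector(rbind(paste0("@", names(reads)),
                             unname(reads),
                             "+",
                             strrep(q, nchar(reads))))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a FASTQ file of reads
#'
#' @param path FASTQ path.
#' @return A named character vector of read sequences.
#' @export
readFastqReads <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write the truth set as GFF3
#'
#' One `exon`/`intron`/`exon` triple per locus plus a `splice_junction`
#' feature over the intron interval carrying the topology attribute.
#' Coordinates are 1-based inclusive.
#'
#' @param sim A [SimulatedGenome-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTruthGff3 <- function(sim, path) {
  tr <- truthJunctions(sim)
  if (!length(tr)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  s <- BiocGenerics::start(tr); e <- BiocGenerics::end(tr)
  feats <- list(
    GenomicRanges::GRanges("synthetic",
      IRanges::IRanges(tr$locus_start, s - 1L), "+",
      type = "exon", ID = paste0(tr$locus_id, ".exon5"),
      locus = tr$locus_id, topology = NA_character_),
    GenomicRanges::GRanges("synthetic", IRanges::IRanges(s, e), "+",
      type = "intron", ID = paste0(tr$locus_id, ".intron"),
      locus = tr$locus_id, topology = NA_character_),
    GenomicRanges::GRanges("synthetic",
      IRanges::IRanges(e + 1L, tr$locus_end), "+",
      type = "exon", ID = paste0(tr$locus_id, ".exon3"),
      locus = tr$locus_id, topology = NA_character_),
    GenomicRanges::GRanges("synthetic", IRanges::IRanges(s, e), "+",
      type = "splice_junction", ID = paste0(tr$locus_id, ".junction"),
      locus = tr$locus_id, topology = tr$topology))
  gr <- sort(do.call(c, feats))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write the truth set as TSV
#'
#' @param sim A [SimulatedGenome-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeTruthTsv <- function(sim, path) {
  tr <- truthJunctions(sim)
  df <- as.data.frame(tr)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write junction clusters as BED6
#'
#' Representative intron intervals in the 0-based half-open BED transform,
#' `name` = topology, `score` = total coverage.
#'
#' @param clusters Cluster table from [mergeJunctions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeJunctionsBed <- function(clusters, path) {
  covCols <- grep("^cov_rep", names(clusters), value = TRUE)
  if (!nrow(clusters)) {
    file.create(path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges("synthetic",
          IRanges::IRanges(clusters$left, clusters$right - 1L),
          strand = clusters$strand)
  gr$name <- clusters$topology
  score <- rowSums(as.matrix(clusters[covCols]))
  gr$score <- as.numeric(score)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write the substrate report with motif sub-features as GFF3
#'
#' For every substrate candidate the motif layout is emitted as genomic
#' sub-features: `helix_h`, `bulge`, `central_helix`, `bulge`,
#' `helix_hprime`.
#'
#' @param report Report from [detectSubstrates()].
#' @param genome Genome sequence (or [SimulatedGenome-class]); needed to
#'   re-derive arm-to-genome coordinates.
#' @param path Output path.
#' @param motif The [MotifSpec-class] used in detection.
#' @param flank The flank used in detection.
#' @return The path, invisibly.
#' @export
writeSubstratesGff3 <- function(report, genome, path, motif = motifSpec(),
                                flank = 25L) {
  cand <- report[report$verdict == "SE-substrate-candidate", , drop = FALSE]
  if (!nrow(cand)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    cl <- cand[i, ]
    ctx <- extractContext(genome, c(cl$left, cl$right - 1L), flank,
                          cl$strand)
    p <- cl$up_helix_start; q <- cl$down_helix_start
    bl <- motif@bulgeLen; hl <- motif@helixLen
    segs <- rbind(
      data.frame(type = "helix_h", arm = "up",
                 from = p - bl - cl$h_len, to = p - bl - 1L),
      data.frame(type = "bulge", arm = "up", from = p - bl, to = p - 1L),
      data.frame(type = "central_helix", arm = "up",
                 from = p, to = p + hl - 1L),
      data.frame(type = "central_helix", arm = "down",
                 from = q, to = q + hl - 1L),
      data.frame(type = "bulge", arm = "down", from = q - bl, to = q - 1L),
      data.frame(type = "helix_hprime", arm = "down",
                 from = q - bl - cl$hprime_len, to = q - bl - 1L))
    segs <- segs[segs$to >= segs$from, , drop = FALSE]
    g1 <- .armToGenome(ctx, segs$arm, segs$from)
    g2 <- .armToGenome(ctx, segs$arm, segs$to)
    rows[[i]] <- data.frame(
      start = pmin(g1, g2), end = pmax(g1, g2), type = segs$type,
      parent = sprintf("substrate_%d_%d", cl$left, cl$right),
      strand = cl$strand, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges("synthetic",
          IRanges::IRanges(df$start, df$end), strand = df$strand,
          type = df$type, Parent = df$parent)
  rtracklayer::export(sort(gr), path, format = "gff3")
  invisible(path)
}

## genomic coordinate of an arm position (plus-strand contexts)
.armToGenome <- function(ctx, arm, pos) {
  s <- ctx@origin$start; e <- ctx@origin$end
  f <- ctx@flank
  idn <- ctx@spliceDown - 1L
  ifelse(arm == "up", s - f - 1L + pos, e - idn + pos)
}
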