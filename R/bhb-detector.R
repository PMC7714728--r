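## hBHBh' motif detection on glued splice-site contexts.
##
## The motif is searched with an explicit layout grammar: a placement is a
## pair (p, q) of central-helix start positions on the two arms, and it
## matches when the central helix pairs, each bulge is a genuine bulge (the
## helix cannot be extended across it), and -- in strict mode -- each bulge
## is bounded distally by an outer helix of the required length.  This is a
## deterministic, enumeration-based expression of the structural constraint
## usually encoded in a structure-only covariance model.

#' Extract the glued context around a candidate intron
#'
#' Cuts the regions around the two splice sites out of the genome and glues
#' them into the two arms on which the BHB motif is searched: the upstream
#' arm is the `flank` exonic nucleotides before the intron followed by the
#' first intronic nucleotides, the downstream arm the last intronic
#' nucleotides followed by the `flank` exonic nucleotides after it.  For
#' introns shorter than `2 * flank` the intronic halves are truncated at the
#' intron midpoint so the arms never overlap.  DNA is transliterated to
#' RNA; minus-strand introns are extracted from the reverse complement.
#'
#' @param genome A `DNAString`/character genome sequence, or a
#'   [SimulatedGenome-class].
#' @param intron Integer pair `c(start, end)`: the intron interval, 1-based
#'   inclusive.
#' @param flank Exonic flank length per side (default 25 nt).
#' @param strand `"+"` or `"-"`.
#' @return A [GluedContext-class].
#' @export
extractContext <- function(genome, intron, flank = 25L, strand = "+") {
  if (is(genome, "SimulatedGenome")) genome <- genomeSeq(genome)
  gseq <- toupper(as.character(genome))
  glen <- nchar(gseq)
  flank <- as.integer(flank)
  s <- as.integer(intron[1]); e <- as.integer(intron[2])
  if (s < 1L || e > glen || e < s)
    stop("intron interval outside the genome")
  if (strand == "-") {
    ctx <- extractContext(.revcompChr(gseq),
                          c(glen - e + 1L, glen - s + 1L), flank, "+")
    ctx@origin <- list(start = s, end = e, strand = "-")
    return(ctx)
  }
  L <- e - s + 1L
  if (s - flank < 1L || e + flank > glen)
    stop("insufficient exonic flank at the genome edge")
  iup <- min(flank, as.integer(ceiling(L / 2)))
  idn <- min(flank, L - iup)
  up <- substr(gseq, s - flank, s - 1L + iup)
  dn <- substr(gseq, e - idn + 1L, e + flank)
  up <- chartr("T", "U", up)
  dn <- chartr("T", "U", dn)
  new("GluedContext", up = up, down = dn,
      spliceUp = flank + 1L, spliceDown = idn + 1L,
      flank = flank, intronLength = L,
      origin = list(start = s, end = e, strand = "+"),
      id = .hashOf(up, dn, flank))
}

## all placement candidates (p, q) for a context/motif; the grammar itself.
## Returns a logical for one placement.
.placementOk <- function(up, dn, p, q, hl, bl, hL, hpL, wobble, strict) {
  m <- length(up); n <- length(dn)
  ## bulges and central helix in bounds
  if (p - bl < 1L || q - bl < 1L) return(FALSE)
  if (p + hl - 1L > m || q + hl - 1L > n) return(FALSE)
  ## central helix pairs: up[p+k] ~ dn[q+hl-1-k]
  k <- 0:(hl - 1L)
  if (!all(canPair(up[p + k], dn[q + hl - 1L - k], wobble))) return(FALSE)
  ## genuine bulges: the central helix must not extend across either bulge
  if (p - 1L >= 1L && q + hl <= n &&
      canPair(up[p - 1L], dn[q + hl], wobble)) return(FALSE)
  if (q - 1L >= 1L && p + hl <= m &&
      canPair(dn[q - 1L], up[p + hl], wobble)) return(FALSE)
  if (strict) {
    if (hL > 0L) {
      k <- 0:(hL - 1L)
      if (p - bl - hL < 1L || q + hl - 1L + hL > n) return(FALSE)
      if (!all(canPair(up[p - bl - 1L - k], dn[q + hl + k], wobble)))
        return(FALSE)
    }
    if (hpL > 0L) {
      k <- 0:(hpL - 1L)
      if (p + hl - 1L + hpL > m || q - bl - hpL < 1L) return(FALSE)
      if (!all(canPair(up[p + hl + k], dn[q - bl - 1L - k], wobble)))
        return(FALSE)
    }
  }
  TRUE
}

## maximal run of outer-helix pairs distal to each bulge
.outerRun <- function(up, dn, p, q, hl, bl, wobble, side) {
  m <- length(up); n <- length(dn)
  run <- 0L
  repeat {
    k <- run
    ok <- if (side == "h") {
      p - bl - 1L - k >= 1L && q + hl + k <= n &&
        canPair(up[p - bl - 1L - k], dn[q + hl + k], wobble)
    } else {
      p + hl + k <= m && q - bl - 1L - k >= 1L &&
        canPair(up[p + hl + k], dn[q - bl - 1L - k], wobble)
    }
    if (!ok) break
    run <- run + 1L
  }
  run
}

#' Enumerate hBHBh' layouts on a glued context
#'
#' Scans all placements of the motif grammar on the two arms: `helixLen`
#' consecutive inter-arm base pairs (the central helix) flanked by a
#' `bulgeLen`-nt unpaired bulge immediately 5' of the helix on the upstream
#' arm and, on the opposite side of the helix, a bulge immediately 5' of the
#' downstream arm's helix half; each bulge must be a genuine bulge (the
#' central helix cannot be extended across it) and, with `strict = TRUE`,
#' is bounded distally by an outer helix of at least `hLen` / `hprimeLen`
#' pairs.  Matches are returned sorted by energy (ascending), then leftmost
#' central helix, then longest outer helices.
#'
#' @param context A [GluedContext-class].
#' @param motif A [MotifSpec-class].
#' @param strict Require the outer helices (the full hBHBh' demanded by the
#'   halophilic enzyme).  With `FALSE` only the core BHB is required.
#' @return A data.frame with one row per match: central-helix start
#'   positions `up_helix_start` (p) and `down_helix_start` (q), geometry
#'   columns (`helix_len`, `bulge_len`, achieved outer-helix lengths
#'   `h_len`, `hprime_len`), bulge intervals, `splice_up_in_bulge` /
#'   `splice_down_in_bulge` flags, the internal stacking `energy`
#'   (kcal/mol), the annotated `layout` string and the `context_id`.
#'   Zero rows when the motif is absent.
#' @export
matchBhb <- function(context, motif = motifSpec(), strict = TRUE) {
  up <- .rnaChars(context@up)
  dn <- .rnaChars(context@down)
  hl <- motif@helixLen; bl <- motif@bulgeLen
  hL <- motif@hLen; hpL <- motif@hprimeLen
  wob <- motif@allowWobble
  m <- length(up); n <- length(dn)
  pq <- expand.grid(p = seq_len(m), q = seq_len(n))
  keep <- mapply(function(p, q)
    .placementOk(up, dn, p, q, hl, bl, hL, hpL, wob, strict),
    pq$p, pq$q)
  pq <- pq[keep, , drop = FALSE]
  if (!nrow(pq)) return(.emptyMatches(context))
  rows <- lapply(seq_len(nrow(pq)), function(i) {
    p <- pq$p[i]; q <- pq$q[i]
    hA <- .outerRun(up, dn, p, q, hl, bl, wob, "h")
    hpA <- .outerRun(up, dn, p, q, hl, bl, wob, "hprime")
    data.frame(
      up_helix_start = p, down_helix_start = q,
      helix_len = hl, bulge_len = bl, h_len = hA, hprime_len = hpA,
      bulge_up_start = p - bl, bulge_up_end = p - 1L,
      bulge_down_start = q - bl, bulge_down_end = q - 1L,
      splice_up_in_bulge =
        context@spliceUp >= p - bl && context@spliceUp <= p - 1L,
      splice_down_in_bulge =
        context@spliceDown >= q - bl && context@spliceDown <= q - 1L,
      energy = NA_real_, layout = NA_character_,
      context_id = context@id, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$energy <- vapply(seq_len(nrow(res)), function(i)
    .matchStackEnergy(res[i, ], context), numeric(1))
  res$layout <- vapply(seq_len(nrow(res)), function(i)
    layoutString(res[i, ], context), character(1))
  ord <- order(res$energy, res$up_helix_start,
               -(res$h_len + res$hprime_len))
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.emptyMatches <- function(context) {
  data.frame(up_helix_start = integer(0), down_helix_start = integer(0),
             helix_len = integer(0), bulge_len = integer(0),
             h_len = integer(0), hprime_len = integer(0),
             bulge_up_start = integer(0), bulge_up_end = integer(0),
             bulge_down_start = integer(0), bulge_down_end = integer(0),
             splice_up_in_bulge = logical(0),
             splice_down_in_bulge = logical(0),
             energy = numeric(0), layout = character(0),
             context_id = character(0), stringsAsFactors = FALSE)
}

#' Dot-bracket layout with bulge annotation
#'
#' Renders one match as `up&down` with `(`/`)` for paired positions, `b`
#' for the bulge nucleotides and `.` elsewhere.
#'
#' @param match A single-row match from [matchBhb()].
#' @param context The originating [GluedContext-class].
#' @return A character scalar.
#' @export
layoutString <- function(match, context) {
  m <- nchar(context@up); n <- nchar(context@down)
  upc <- rep(".", m); dnc <- rep(".", n)
  p <- match$up_helix_start; q <- match$down_helix_start
  hl <- match$helix_len; bl <- match$bulge_len
  upc[p:(p + hl - 1L)] <- "("
  dnc[q:(q + hl - 1L)] <- ")"
  upc[(p - bl):(p - 1L)] <- "b"
  dnc[(q - bl):(q - 1L)] <- "b"
  if (match$h_len >= 1L) {
    k <- seq_len(match$h_len) - 1L
    upc[p - bl - 1L - k] <- "("
    dnc[q + hl + k] <- ")"
  }
  if (match$hprime_len >= 1L) {
    k <- seq_len(match$hprime_len) - 1L
    upc[p + hl + k] <- "("
    dnc[q - bl - 1L - k] <- ")"
  }
  paste0(paste(upc, collapse = ""), "&", paste(dnc, collapse = ""))
}

#' Parse a layout string back into motif intervals
#'
#' Inverse of [layoutString()] given the motif geometry: recovers the
#' bulge intervals and helix positions on both arms.
#'
#' @param layout A layout string (`up&down`).
#' @param motif The [MotifSpec-class] the layout was produced under.
#' @return A list with `up_helix_start`, `down_helix_start`, bulge
#'   intervals and achieved outer-helix lengths.
#' @export
parseLayout <- function(layout, motif = motifSpec()) {
  parts <- strsplit(layout, "&", fixed = TRUE)[[1]]
  upc <- strsplit(parts[1], "")[[1]]
  dnc <- strsplit(parts[2], "")[[1]]
  hl <- motif@helixLen; bl <- motif@bulgeLen
  bUp <- which(upc == "b"); bDn <- which(dnc == "b")
  p <- max(bUp) + 1L
  q <- max(bDn) + 1L
  afterUp <- upc[seq(p, length(upc))]
  runUp <- match(FALSE, afterUp == "(", nomatch = length(afterUp) + 1L) - 1L
  beforeDnIdx <- seq_len(min(bDn) - 1L)
  runDnPre <- 0L
  for (i in rev(beforeDnIdx)) {
    if (dnc[i] == ")") runDnPre <- runDnPre + 1L else break
  }
  list(up_helix_start = p, down_helix_start = q,
       bulge_up = range(bUp), bulge_down = range(bDn),
       hprime_len = min(runDnPre, runUp - hl),
       h_len = {
         preUpIdx <- seq_len(min(bUp) - 1L)
         r <- 0L
         for (i in rev(preUpIdx)) if (upc[i] == "(") r <- r + 1L else break
         r
       })
}

#' Are the splice sites inside the bulges?
#'
#' The endonuclease cleaves within the bulges, so a match is only
#' substrate-consistent when both recorded splice-site positions fall
#' inside their respective bulge interval.
#'
#' @param match A single-row match from [matchBhb()].
#' @param context The [GluedContext-class] the match was derived from
#'   (provenance is checked).
#' @return A named logical pair `c(up = , down = )`.
#' @export
checkSpliceInBulge <- function(match, context) {
  if (nrow(match) != 1L) stop("check one match at a time")
  if (!identical(match$context_id, context@id))
    stop("match was not derived from this context")
  c(up = context@spliceUp >= match$bulge_up_start &&
        context@spliceUp <= match$bulge_up_end,
    down = context@spliceDown >= match$bulge_down_start &&
           context@spliceDown <= match$bulge_down_end)
}

#' Screen junction clusters for hBHBh'-flanked introns
#'
#' For each merged junction cluster: extract the glued context of its
#' representative intron, enumerate motif layouts, keep those with both
#' splice sites inside the bulges (substrate-consistent), and report the
#' best one (lowest stacking energy).  Clusters without a
#' substrate-consistent motif are reported with verdict `"no-motif"`.
#'
#' @param genome Genome sequence (or [SimulatedGenome-class]).
#' @param clusters Cluster table from [mergeJunctions()].
#' @param motif A [MotifSpec-class].
#' @param flank Exonic flank for context extraction.
#' @param strict Require outer helices (see [matchBhb()]).
#' @return A data.frame with one row per cluster: junction coordinates,
#'   intron length, topology, total coverage, `verdict`
#'   (`"SE-substrate-candidate"` or `"no-motif"`), stacking `energy` and
#'   `layout` of the best substrate-consistent match (NA when none).
#' @export
detectSubstrates <- function(genome, clusters, motif = motifSpec(),
                             flank = 25L, strict = TRUE) {
  if (is(genome, "SimulatedGenome")) genome <- genomeSeq(genome)
  covCols <- grep("^cov_rep", names(clusters), value = TRUE)
  out <- lapply(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    rec <- data.frame(left = cl$left, right = cl$right,
                      strand = cl$strand, topology = cl$topology,
                      intron_length = cl$right - cl$left,
                      coverage = sum(unlist(cl[covCols])),
                      verdict = "no-motif", energy = NA_real_,
                      layout = NA_character_,
                      up_helix_start = NA_integer_,
                      down_helix_start = NA_integer_,
                      h_len = NA_integer_, hprime_len = NA_integer_,
                      stringsAsFactors = FALSE)
    ctx <- tryCatch(
      extractContext(genome, c(cl$left, cl$right - 1L), flank, cl$strand),
      error = function(e) NULL)
    if (is.null(ctx)) return(rec)
    mt <- matchBhb(ctx, motif, strict)
    mt <- mt[mt$splice_up_in_bulge & mt$splice_down_in_bulge, , drop = FALSE]
    if (nrow(mt)) {
      best <- mt[1, ]
      rec$verdict <- "SE-substrate-candidate"
      rec$energy <- best$energy
      rec$layout <- best$layout
      rec$up_helix_start <- best$up_helix_start
      rec$down_helix_start <- best$down_helix_start
      rec$h_len <- best$h_len
      rec$hprime_len <- best$hprime_len
    }
    rec
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame()
  res
}
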