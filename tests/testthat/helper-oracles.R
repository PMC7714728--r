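## Independent brute-force oracles used to cross-check the package
## implementations.  These are deliberately written as plain nested loops,
## separate from the package code paths.

oraclePair <- function(a, b, wobble = TRUE) {
  duo <- paste0(a, b)
  duo %in% c("AU", "UA", "GC", "CG") || (wobble && duo %in% c("GU", "UG"))
}

## exhaustive enumeration of the hBHBh' layout grammar
oracleMatchBhb <- function(up, dn, hl = 4L, bl = 3L, hL = 4L, hpL = 4L,
                           wobble = TRUE, strict = TRUE) {
  u <- strsplit(up, "")[[1]]
  d <- strsplit(dn, "")[[1]]
  m <- length(u); n <- length(d)
  hits <- list()
  for (p in seq_len(m)) for (q in seq_len(n)) {
    if (p - bl < 1 || q - bl < 1) next
    if (p + hl - 1 > m || q + hl - 1 > n) next
    ok <- TRUE
    for (k in 0:(hl - 1)) {
      if (!oraclePair(u[p + k], d[q + hl - 1 - k], wobble)) { ok <- FALSE; break }
    }
    if (!ok) next
    ## a genuine bulge: the central helix cannot be grown across it
    if (q + hl <= n && oraclePair(u[p - 1], d[q + hl], wobble)) next
    if (p + hl <= m && oraclePair(d[q - 1], u[p + hl], wobble)) next
    if (strict) {
      if (hL > 0) {
        if (p - bl - hL < 1 || q + hl - 1 + hL > n) next
        for (k in 0:(hL - 1)) {
          if (!oraclePair(u[p - bl - 1 - k], d[q + hl + k], wobble)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
      }
      if (hpL > 0) {
        if (p + hl - 1 + hpL > m || q - bl - hpL < 1) next
        for (k in 0:(hpL - 1)) {
          if (!oraclePair(u[p + hl + k], d[q - bl - 1 - k], wobble)) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
      }
    }
    hits[[length(hits) + 1L]] <- c(p = p, q = q)
  }
  if (!length(hits)) return(data.frame(p = integer(0), q = integer(0)))
  as.data.frame(do.call(rbind, hits))
}

## naive re-implementation of the replicate-coverage filter
oracleFilter <- function(obs, minCov = 2L, nRep = 3L, mode = "per_replicate") {
  keys <- unique(obs[c("strand", "topology", "left", "right")])
  kept <- list()
  for (i in seq_len(nrow(keys))) {
    counts <- integer(nRep)
    for (r in seq_len(nRep)) {
      counts[r] <- sum(obs$strand == keys$strand[i] &
                       obs$topology == keys$topology[i] &
                       obs$left == keys$left[i] &
                       obs$right == keys$right[i] &
                       obs$replicate == r)
    }
    ok <- if (mode == "per_replicate") all(counts >= minCov)
          else sum(counts) >= minCov && all(counts >= 1L)
    if (ok) kept[[length(kept) + 1L]] <- cbind(keys[i, ],
      stats::setNames(as.data.frame(t(counts)), paste0("cov_rep", seq_len(nRep))))
  }
  if (!length(kept))
    return(data.frame(strand = character(0), topology = character(0),
                      left = integer(0), right = integer(0)))
  out <- do.call(rbind, kept)
  out <- out[order(out$left, out$right), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## O(n^2) single-linkage clustering by repeated transitive closure
oracleMergeGroups <- function(junc, maxDist = 10L) {
  n <- nrow(junc)
  if (!n) return(integer(0))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- junc$topology[i] == junc$topology[j] &&
      junc$strand[i] == junc$strand[j] &&
      abs(junc$left[i] - junc$left[j]) <= maxDist &&
      abs(junc$right[i] - junc$right[j]) <= maxDist
  }
  reach <- adj | diag(n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  comp
}

## string slicing oracle for the cleavage model
oracleSlice <- function(seq, cuts) {
  ch <- strsplit(seq, "")[[1]]
  list(f5 = paste(ch[seq_len(cuts[1])], collapse = ""),
       mid = paste(ch[seq.int(cuts[1] + 1L, cuts[2])], collapse = ""),
       f3 = paste(ch[seq.int(cuts[2] + 1L, length(ch))], collapse = ""))
}

## a hand-built canonical hBHBh' glued context, independent of the genome
## generator: h=GGCA, bulge=AAC, helix=GCGA, h'=CUGC on the upstream arm,
## complements on the downstream arm, A-padding outside.  Central helix
## starts at position 13 on both arms; splice sites at bulge position 2.
makeCanonicalContext <- function() {
  up <- paste0("AAAAA", "GGCA", "AAC", "GCGA", "CUGC", "AAAAA")
  dn <- paste0("AAAAA", "GCAG", "AUA", "UCGC", "UGCC", "AAAAA")
  new("GluedContext", up = up, down = dn,
      spliceUp = 11L, spliceDown = 11L, flank = 10L, intronLength = 40L,
      origin = list(start = NA, end = NA, strand = "+"),
      id = "canonical-test-context")
}

## random junction observation tables for property tests
randomObservations <- function(n, nRep = 3L, span = 300L) {
  left <- sample.int(span, n, replace = TRUE)
  data.frame(read_id = sprintf("r%04d", seq_len(n)),
             replicate = sample.int(nRep, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE),
             topology = sample(c("linear", "circular"), n, replace = TRUE),
             left = left,
             right = left + sample.int(150L, n, replace = TRUE))
}
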