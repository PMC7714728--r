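## Nearest-neighbor stacking energetics (internal engine) and the optional
## external cofolding oracle.

## Turner 2004 helix stacking free energies at 37 C, kcal/mol.
## Entry [p1, p2] is the stack 5'-a b-3' / 3'-a' b'-5' with p1 = pair (a,a')
## and p2 = pair (b',b), i.e. the second pair is keyed in reversed
## orientation (the convention of the published parameter tables).
.STACK_PAIRS <- c("CG", "GC", "GU", "UG", "AU", "UA")
.STACK37 <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30),
  nrow = 6, byrow = TRUE,
  dimnames = list(.STACK_PAIRS, .STACK_PAIRS))

## Every formed stack is counted as at least marginally stabilizing so the
## score is strictly monotone in the number of stacked pairs; the full
## Turner model's destabilizing tandem-wobble stacks are a documented
## limitation of this score (use the external engine for exact MFEs).
.STACK_CAP <- -0.1

## Stack term for consecutive pairs (u1.d1) then (u2.d2), u1 5' of u2 on the
## upper strand.  NA (treated as 0) when either duo is not a recognised pair.
.stackTerm <- function(u1, u2, d1, d2, cap = TRUE) {
  p1 <- paste0(u1, d1)
  p2 <- paste0(d2, u2)
  ok <- p1 %in% .STACK_PAIRS & p2 %in% .STACK_PAIRS
  out <- rep(0, length(ok))
  v <- .STACK37[cbind(match(p1[ok], .STACK_PAIRS), match(p2[ok], .STACK_PAIRS))]
  out[ok] <- if (cap) pmin(v, .STACK_CAP) else v
  out
}

## Stacking sum over one helix given aligned pair vectors: upper strand
## bases in 5'->3' order, lower strand bases as their partners.
.helixStackSum <- function(upper, lower) {
  n <- length(upper)
  if (n < 2L) return(0)
  sum(.stackTerm(upper[-n], upper[-1L], lower[-n], lower[-1L]))
}

#' Stacking stability score of a perfect duplex
#'
#' Sums nearest-neighbor stacking free energies (37 C, Watson-Crick and G:U
#' wobble) over the consecutive base pairs of two fully complementary
#' strands.  This is the same additive score the internal energy engine
#' applies to the helices of a BHB match: a relative stability measure in
#' kcal/mol where more negative means more stable, with no duplex
#' initiation or loop terms.
#'
#' @param strand1 RNA sequence, 5'->3'.
#' @param strand2 RNA sequence of the complementary strand, 5'->3'
#'   (`strand2[n]` pairs `strand1[1]`).
#' @param wobble Allow G:U pairs.
#' @return The stacking sum in kcal/mol (0 for a single pair).
#' @examples
#' duplexStackingEnergy("GCGC", "GCGC") < duplexStackingEnergy("AUAU", "AUAU")
#' @export
duplexStackingEnergy <- function(strand1, strand2, wobble = TRUE) {
  s1 <- .rnaChars(strand1)
  s2 <- rev(.rnaChars(strand2))
  if (length(s1) != length(s2))
    stop("strands must have equal length for a perfect duplex")
  if (!all(canPair(s1, s2, wobble)))
    stop("strands are not fully complementary under the active pairing alphabet")
  .helixStackSum(s1, s2)
}

#' Minimum free energy of cofolding two strands (external engine)
#'
#' Delegates to the `RNAcofold` program (ViennaRNA suite, Turner 2004
#' parameters) and returns the minimum free energy of the dimer.  This is
#' the exact thermodynamic oracle the internal stacking score approximates
#' in rank; it requires `RNAcofold` on the `PATH`.
#'
#' @param strand1,strand2 RNA sequences, 5'->3'.
#' @return MFE in kcal/mol.
#' @export
cofoldMfe <- function(strand1, strand2) {
  if (!nzchar(Sys.which("RNAcofold")))
    stop("external engine unavailable: RNAcofold not found on PATH")
  inp <- paste0(chartr("T", "U", toupper(strand1)), "&",
                chartr("T", "U", toupper(strand2)))
  out <- system2("RNAcofold", args = "--noPS", input = inp, stdout = TRUE)
  m <- regmatches(out, regexpr("\\(\\s*-?[0-9.]+\\s*\\)\\s*$", out))
  m <- m[lengths(regmatches(m, gregexpr("[0-9]", m))) > 0]
  if (!length(m)) stop("could not parse RNAcofold output")
  as.numeric(gsub("[()\\s]", "", m[[length(m)]], perl = TRUE))
}

#' Score the stability of a BHB match
#'
#' @param match A single-row match as returned by [matchBhb()].
#' @param context The [GluedContext-class] the match was derived from.
#' @param engine `"internal"`: additive nearest-neighbor stacking score over
#'   the consecutive pairs of the central and (achieved) outer helices, no
#'   loop terms -- a relative score where more negative is more stable.
#'   `"external"`: cofold the two arms with `RNAcofold` and return its MFE.
#' @return A number in kcal/mol, with the engine recorded in
#'   `attr(, "engine")`.
#' @export
scoreEnergy <- function(match, context, engine = c("internal", "external")) {
  engine <- match.arg(engine)
  if (nrow(match) != 1L) stop("score one match at a time")
  if (!identical(match$context_id, context@id))
    stop("match was not derived from this context")
  val <- if (engine == "internal") {
    .matchStackEnergy(match, context)
  } else {
    cofoldMfe(context@up, context@down)
  }
  structure(val, engine = engine)
}

## internal score of a match row: stacking over central helix + achieved
## outer helices (each helix scored separately; bulges contribute nothing)
.matchStackEnergy <- function(match, context) {
  up <- .rnaChars(context@up)
  dn <- .rnaChars(context@down)
  hl <- match$helix_len
  p <- match$up_helix_start
  q <- match$down_helix_start
  bl <- match$bulge_len
  e <- .helixStackSum(up[p:(p + hl - 1L)], dn[(q + hl - 1L):q])
  if (match$h_len >= 1L) {
    k <- seq_len(match$h_len) - 1L
    e <- e + .helixStackSum(rev(up[p - bl - 1L - k]), rev(dn[q + hl + k]))
  }
  if (match$hprime_len >= 1L) {
    k <- seq_len(match$hprime_len) - 1L
    e <- e + .helixStackSum(up[p + hl + k], dn[q - bl - 1L - k])
  }
  e
}
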