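---
title: "Finding splicing-endonuclease substrates from circularized introns"
author: "bhbscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding splicing-endonuclease substrates from circularized introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhbscan)
```

## The biological model

Archaeal splicing endonucleases (SE) excise introns from pre-tRNAs and
cut the processing stems that flank the 16S and 23S rRNAs within their
multicistronic precursor. Recognition is structural, not sequence-based:
the enzyme docks onto a **bulge-helix-bulge (BHB)** element — a central
helix of four base pairs flanked by two three-nucleotide bulges on
opposite strands — and cleaves once inside each bulge. Halophilic
enzymes are strict: they additionally require outer helices distal to
both bulges (**hBHBh′**) and reject other BHB variants. After cleavage a
ligase joins the two exon-bearing fragments and seals the excised intron
into a circle.

That circle is the observable this package is built around. When
circular RNAs are enriched (RNase R digests linear RNA) and sequenced,
the excised intron produces reads that cross its ligation point. Mapped
to the genome, such a read splits into two segments in *reversed*
genomic order — the intron's 3′ end first, then its 5′ end — which is
unmistakable evidence of a circle. A substrate of the enzyme is
therefore a genomic interval that (i) is supported by reproducible
back-junction reads and (ii) carries an hBHBh′ motif across its
boundaries with the splice sites inside the bulges.

## Coordinate and splice-site conventions

Throughout the package a junction is an ordered pair *(left, right)*:
*left* is the first intronic base and *right* the first base after the
intron, both 1-based. The intron interval is `[left, right − 1]` and its
length is `right − left`. This single convention reproduces published
intron lengths from their printed splice-site coordinates
(e.g. `1,165,777/1,165,880 → 103 nt`); public coordinate tables are not
always internally consistent at the ±1 level, so the convention is
documented here rather than asserted as universal.

Within a glued context (below), a splice site is recorded as the
nucleotide immediately 3′ of the scissile phosphate: the first intronic
base on the upstream arm, the first exonic base on the downstream arm.
Under the default cut rule both sit at bulge position 2.

## The layout grammar replacing a covariance model

Structure-only searches for BHB elements are commonly run with
covariance models trained on hand-set consensus structures. Because the
motif has essentially no sequence signal, such a model reduces to a
structural constraint — which can be expressed directly. `matchBhb()`
therefore enumerates every placement `(p, q)` of a central helix on the
two arms of a `GluedContext` and accepts it iff

* the `helixLen` (default 4) inter-arm pairs all form under the active
  pairing alphabet (Watson–Crick, plus G:U when `allowWobble = TRUE`);
* a `bulgeLen`-nt (default 3) bulge lies immediately 5′ of the helix on
  each arm, on opposite sides of the helix in duplex geometry;
* each bulge is *genuine*: the central helix cannot be extended across
  it by pairing the bulge base adjacent to the helix with the opposing
  strand's continuation — without this test a fully paired stem would
  "match" with arbitrary bulges annotated onto it;
* in strict mode, outer helices of at least `hLen`/`hprimeLen` pairs
  (default 4) bound each bulge distally — the hBHBh′ requirement of the
  halophilic enzyme. `strict = FALSE` drops only this clause, for
  enzymes with broader substrate spectra.

The enumeration is deterministic, dependency-free and — on short arms —
exhaustively cross-checked in the test suite against an independent
brute-force implementation of the same grammar. Matches are ordered by
stacking energy, then leftmost placement, then outer-helix length.

The arms themselves are built by `extractContext()`: `flank` exonic
nucleotides (default 25) before the intron plus the first intronic
nucleotides on one arm; the last intronic nucleotides plus the exonic
flank on the other. The intron interior is irrelevant to the motif and
is treated as an insert between the arms. For introns shorter than
`2 × flank` the intronic halves truncate at the intron midpoint so the
arms never overlap. The default flank of 25 nt comfortably covers outer
helix + bulge + central helix (11 nt) with margin for helix slippage,
while keeping the search space so small that full enumeration is
instantaneous.

## The stacking stability score

The internal energy engine assigns each match the sum of
nearest-neighbor stacking free energies (37 °C, Watson–Crick and wobble
pairs) over consecutive base pairs within each helix. There are no
initiation, loop or terminal terms: the value is a *relative stability
score* — more negative means more stable — not a minimum free energy.
Two deliberate choices:

* **Monotonicity cap.** Each formed stack contributes at most
  −0.1 kcal/mol. In the full parameter set a few tandem-wobble stacks
  are destabilising (up to +1.3 kcal/mol); capping them makes the score
  strictly decreasing in the number of stacked pairs, so longer helices
  never score worse — the property the ranking use-case needs. Exact
  thermodynamics, including those destabilising stacks, are available
  through the external engine (`scoreEnergy(..., engine = "external")`),
  which shells out to `RNAcofold`.
* **No acceptance threshold.** Reported substrate energies are carried
  in the output for the caller to filter; the package imposes no energy
  cutoff because the enzyme's requirement is structural and published
  substrate energies span a wide range.

The test suite pins the score's rank behaviour to 20 designed duplexes
whose cofold MFEs were computed once with `RNAcofold` (ViennaRNA 2.7.2,
Turner 2004 parameters) and frozen as a plain-text fixture; Spearman
agreement is ≥ 0.9 (measured ≈ 0.998).

## What the generator emulates — and what it does not

`buildGenome()` plants loci of the three substrate classes into i.i.d.
uniform ACGT background (the simplest null that rarely forms long
helices by chance). For each designed locus the 15-nt windows around the
two splice sites are overwritten with a sampled hBHBh′ duplex:
complementary helix arms, bulges drawn so they can neither extend the
helices nor create ligation-junction ambiguity (the bases flanking the
future circle's seam are forced to differ, so back-junction breakpoints
are unique). Decoy loci plant a circularised interval with *no* motif —
circles that are not SE products — giving the detector a negative
control inside every simulated experiment.

`simulateReads()` emulates the enrichment chemistry at the level that
matters for junction calling: per circular intron and replicate, an
exact number of back-junction reads (default 6 per replicate, three
replicates, 75-nt single-end reads) sampled uniformly over the
placements that cross the ligation point exactly once with ≥ 20 nt on
each side; uniform genomic background reads at 2× coverage for the
linear carry-over; i.i.d. substitution errors; a `circularEnrichment`
multiplier standing in for RNase-R kinetics. Circles shorter than half
the read length cannot host a single-crossing read at all — the
desk-scale analogue of the known bias of circRNA-seq against short
circles, and the reason the 31-nt tRNA-like intron in the demonstration
set is simulated at zero junction depth.

Not emulated: fragmentation-length distributions, adapter artifacts,
coverage biases along the circle, paired-end reads, rolling-circle
multi-pass cDNAs, or expression differences between loci. Passing tests
therefore show that the *logic* of the pipeline — geometry, filtering,
merging, motif detection — is correct under controlled conditions; they
do not certify mapper performance on real, biased libraries.

## Filtering, merging, and their ambiguities

The replicate filter keeps a junction iff its coverage is at least
`minCoverage` (default 2) in *every* one of `nReplicates` (default 3)
replicates. The underlying published rule ("coverage of at least two,
present in all replicates") admits a laxer total-coverage reading, which
is available as `mode = "total"`; the strict per-replicate reading is
the default because it is the more conservative and reproducible of the
two.

Merging is single-linkage with a Chebyshev criterion: two junctions link
iff both their left and their right coordinates differ by ≤ `maxDist`
(default 10 nt) and topologies match. The cluster representative is the
member with the highest total coverage, ties resolved to the smaller
left then right coordinate; cluster coverage is the per-replicate sum
over members. Single-linkage is the faithful reading of "sites merged if
their distance was at most 10 nt" and is cross-checked against an
O(n²) transitive-closure oracle in the tests.

## The cleavage model

`cleaveSubstrate()` cuts a precursor after its two scissile positions
and returns the three fragments (lengths conserved exactly), the
ligated exons, and the circular intron represented by its
lexicographically minimal rotation — circles have no distinguished 5′
end, so a canonical rotation makes equality testing and serialisation
well defined. The nucleotide-level scissile position within a 3-nt
bulge is not fixed by the motif; `precursorFromIntron()` defaults to
cutting between bulge nucleotides 2 and 3 (counted from the
central-helix-proximal side), which reproduces the generator's designed
splice sites, and offers `after1`/`after3` as explicit alternative
conventions. Fragment accountings such as 26 + 47 + 29 = 102 or
334 + 214 + 20 = 568 follow from the cut positions alone. Chemical ends
(2′,3′-cyclic phosphate, 5′-OH) are labels, not modeled chemistry; the
2′-phosphotransferase step present in some eukaryotes is out of scope.

## Numerical and degenerate-input choices

* All randomness flows through one seeded generator per entry point
  (`buildGenome`, `simulateReads`, pipeline configs); identical seeds
  give byte-identical FASTQ and report files.
* The split mapper seeds both read ends (18 nt, one mismatch fallback),
  aligns the two diagonals, and chooses the split point minimising total
  mismatches (ties: smallest split). Reads with more than two segments
  are skipped and counted, never fatal.
* Junction observations with adjacent or overlapping segments (no
  intervening intron) are silently dropped; `intronFromCluster()` errors
  on non-positive lengths.
* Problem sizes in tests and the acceptance script are desk-scale by
  design: genomes of 1–14 kb, hundreds to ~1,200 reads, introns of
  31–2,980 nt — large enough to exercise every rule, small enough to run
  interactively.

## Known limitations

* The internal score is a ranking device; absolute folding energies of
  real substrates require the external cofold engine and full-length
  context.
* The generator plants loci on the plus strand only; strand symmetry of
  extraction and calling is covered by constructed-input tests.
* The naive mapper is for synthetic fixtures; real libraries should
  arrive as SAM/BAM split alignments (`readSplitAlignmentsSam()`).
* Multi-chromosome genomes and chimeras between replicons are not
  supported; `pseudoknots` and non-canonical crenarchaeal BHB variants
  are outside the grammar (a relaxed mode drops only the outer-helix
  requirement).
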