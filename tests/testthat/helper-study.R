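## Shared study-scale fixture: a genome with seven hBHBh'-flanked introns
## spanning the substrate length spectrum plus three motif-free decoy
## circles, and one full discovery pass over simulated reads.

studyLoci <- function() {
  list(
    locusSpec("utr_46", "mRNA_5UTR", intronLen = 46L),
    locusSpec("trna_75", "tRNA", intronLen = 75L),
    locusSpec("trna_103", "tRNA", intronLen = 103L),
    locusSpec("rrna16_a", "rRNA", intronLen = 1658L),
    locusSpec("rrna16_b", "rRNA", intronLen = 1658L),
    locusSpec("rrna23_a", "rRNA", intronLen = 2979L),
    locusSpec("rrna23_b", "rRNA", intronLen = 2980L),
    locusSpec("decoy_1", "mRNA_5UTR", intronLen = 90L, decoy = TRUE),
    locusSpec("decoy_2", "tRNA", intronLen = 120L, decoy = TRUE),
    locusSpec("decoy_3", "rRNA", intronLen = 150L, decoy = TRUE))
}

runSubstrateStudy <- function(seed, errorRate = 0) {
  sim <- buildGenome(studyLoci(), backgroundLen = 14000L, seed = seed)
  cfg <- readSimConfig(errorRate = errorRate, seed = seed + 1L)
  rs <- simulateReads(sim, cfg)
  aln <- do.call(rbind, lapply(seq_len(cfg@nReplicates), function(r)
    mapSplitReads(rs$reads[[r]], sim, replicate = r)))
  obs <- callJunctions(aln, length(genomeSeq(sim)))
  kept <- filterJunctions(obs, minCoverage = 2L, nReplicates = 3L)
  clusters <- mergeJunctions(kept, maxDist = 10L)
  report <- detectSubstrates(sim, clusters)
  list(sim = sim, report = report)
}

studyRecall <- function(study) {
  tr <- truthJunctions(study$sim)
  planted <- data.frame(left = tr$left_site, right = tr$right_site,
                        decoy = tr$decoy)
  cand <- study$report[study$report$verdict == "SE-substrate-candidate", ]
  hits <- sum(planted$left[!planted$decoy] %in% cand$left &
              planted$right[!planted$decoy] %in% cand$right)
  falsePos <- sum(!(cand$left %in% planted$left[!planted$decoy] &
                    cand$right %in% planted$right[!planted$decoy]))
  list(n_true = sum(!planted$decoy), hits = hits, false_pos = falsePos)
}
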