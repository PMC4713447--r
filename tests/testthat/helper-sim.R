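# Shared fixture: one moderate synthetic study reused across test files,
# built once per test run.
testSimConfig <- function(...) {
  MztSimConfig(nGenes = 120L, nMirnas = 12L, librarySizes = rep(1e6, 7),
               smallRnaReads = 1e4, seed = 42L, ...)
}

.simCache <- new.env(parent = emptyenv())

testSim <- function() {
  if (is.null(.simCache$sim))
    .simCache$sim <- simulateMztStudy(testSimConfig())
  .simCache$sim
}

testExperiment <- function() {
  if (is.null(.simCache$exp)) {
    sim <- testSim()
    .simCache$exp <- buildExpressionMatrix(simCounts(sim),
                                           simGenes(sim)$tx_length)
  }
  .simCache$exp
}

testArmData <- function() {
  if (is.null(.simCache$arm)) {
    sim <- testSim()
    aln <- mapReadsToHairpins(simSmallRna(sim), simHairpins(sim))
    ac <- armCounts(aln, simHairpins(sim), simArmCoords(sim))
    m <- armCountMatrix(ac, samples = colnames(simCounts(sim)))
    armLen <- stats::setNames(
      simArmCoords(sim)$end - simArmCoords(sim)$start + 1L,
      paste(simArmCoords(sim)$hairpin, simArmCoords(sim)$arm, sep = "-"))
    .simCache$arm <- list(
      alignments = aln, counts = ac, matrix = m,
      experiment = buildExpressionMatrix(m, armLen[rownames(m)],
                                         featureType = "miRNA_arm"))
  }
  .simCache$arm
}

# naive exact-substring search used as the mapping oracle
naiveMap <- function(readSeq, hairpins) {
  hits <- list()
  for (h in names(hairpins)) {
    hseq <- as.character(hairpins[[h]])
    w <- nchar(readSeq)
    for (s in seq_len(nchar(hseq) - w + 1)) {
      if (substr(hseq, s, s + w - 1) == readSeq)
        hits[[length(hits) + 1]] <- list(hairpin = h, start = s,
                                         end = s + w - 1)
    }
  }
  hits
}

randomDnaString <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
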