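test_that("generation is deterministic under a fixed seed", {
  cfg <- MztSimConfig(nGenes = 50, nMirnas = 5, seed = 1)
  a1 <- generateAnnotation(cfg, seed = cfg@seed)
  a2 <- generateAnnotation(cfg, seed = cfg@seed)
  expect_identical(as.character(a1$genome), as.character(a2$genome))
  expect_identical(a1$genes, a2$genes)
  expect_identical(as.character(a1$hairpins), as.character(a2$hairpins))
  expect_identical(a1$armCoords, a2$armCoords)

  s1 <- simulateMztStudy(cfg)
  s2 <- simulateMztStudy(cfg)
  expect_identical(simCounts(s1), simCounts(s2))
  expect_identical(as.character(simSmallRna(s1)),
                   as.character(simSmallRna(s2)))
  expect_identical(simTruth(s1)$targets, simTruth(s2)$targets)
})

test_that("the empty study degenerates cleanly", {
  cfg <- MztSimConfig(nGenes = 0, nMirnas = 0, seed = 1)
  ann <- generateAnnotation(cfg, seed = 1)
  expect_equal(nrow(ann$genes), 0)
  expect_equal(length(ann$hairpins), 0)
  expect_equal(length(ann$genome), 1)  # valid FASTA contig remains
  expect_true(nzchar(names(ann$genome)))
})

test_that("hairpins carry disjoint 5p/3p arms of mature length", {
  sim <- testSim()
  ac <- simArmCoords(sim)
  hpLen <- Biostrings::width(simHairpins(sim))
  names(hpLen) <- names(simHairpins(sim))
  for (h in unique(ac$hairpin)) {
    a <- ac[ac$hairpin == h, ]
    expect_true(hpLen[h] >= 70 && hpLen[h] <= 110)
    len <- a$end - a$start + 1
    expect_true(all(len >= 19 & len <= 24))
    expect_lt(a$end[a$arm == "5p"], a$start[a$arm == "3p"])
    expect_true(all(a$start >= 1 & a$end <= hpLen[h]))
  }
})

test_that("library counts are conserved exactly", {
  sim <- testSim()
  expect_equal(unname(colSums(simCounts(sim))),
               unname(simConfig(sim)@librarySizes))
})

test_that("planted class II genes rise strictly from oocyte to 18-24 h", {
  truth <- simTruth(testSim())
  ii <- truth$geneClass$gene_id[truth$geneClass$diploid == "II"]
  ab <- truth$abundance[ii, , drop = FALSE]
  expect_true(all(ab[, "oocyte"] < ab[, "diploid_18_24h"]))
  expect_true(all(ab[, "oocyte"] < ab[, "haploid_18_24h"]))
  sz <- truth$geneClass$shape[match(ii, truth$geneClass$gene_id)] == "sz"
  expect_true(all(ab[sz, "oocyte"] == 0))
})

test_that("class III mean counts follow the V-shape", {
  sim <- testSim()
  truth <- simTruth(sim)
  iii <- truth$geneClass$gene_id[truth$geneClass$diploid == "III"]
  cnt <- simCounts(sim)[iii, ploidySamples("diploid"), drop = FALSE]
  m <- colMeans(cnt)
  expect_gt(m[1], m[2]); expect_gt(m[4], m[3])
})

test_that("degenerate truth is rejected", {
  sim <- testSim()
  truth <- simTruth(sim)
  truth$abundance[] <- 0
  cfg <- simConfig(sim)
  ann <- list(hairpins = simHairpins(sim), armCoords = simArmCoords(sim))
  expect_error(generateCounts(ann, truth, cfg), "degenerate truth")
})

test_that("motif planting at rate 1 marks every class II promoter", {
  cfg <- MztSimConfig(nGenes = 40, nMirnas = 2, motifPlantRate = 1,
                      sitePlantRate = 0, seed = 9)
  sim <- simulateMztStudy(cfg)
  truth <- simTruth(sim)
  ii <- truth$geneClass$gene_id[truth$geneClass$diploid == "II"]
  expect_setequal(truth$motifCarriers, ii)
  prom <- extractPromoters(
    simGenes(sim)[simGenes(sim)$gene_id %in% ii, ], simGenome(sim))
  hasCore <- grepl("AGGTA", as.character(prom)) |
    grepl("TACCT", as.character(prom))
  expect_true(all(hasCore))
  expect_equal(nrow(truth$targets), 0)   # site rate 0 plants nothing
})

test_that("planted sites reverse-complement the miRNA 5' 16-mer", {
  sim <- testSim()
  truth <- simTruth(sim)
  sp <- truth$sitePositions
  expect_gt(nrow(sp), 0)
  utrs <- extractUtrProxies(simGenes(sim), simGenome(sim))
  armSeq <- matureArmSequences(simHairpins(sim), simArmCoords(sim))
  idx <- sample(nrow(sp), min(25, nrow(sp)))
  for (i in idx) {
    site <- substr(as.character(utrs[[sp$gene[i]]]),
                   sp$utr_start[i], sp$utr_end[i])
    mir16 <- substr(armSeq[[sp$arm[i]]], 1, 16)
    expect_identical(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(site))), mir16)
  }
})

test_that("small-RNA reads are 19-24 nt substrings of their hairpins", {
  sim <- testSim()
  reads <- simSmallRna(sim)
  w <- Biostrings::width(reads)
  expect_true(all(w >= 19 & w <= 24))
  hp <- paste(as.character(simHairpins(sim)), collapse = " ")
  idx <- sample(length(reads), 50)
  expect_true(all(vapply(as.character(reads[idx]), grepl, logical(1),
                         x = hp, fixed = TRUE)))
})

test_that("the planted abundance pool is stage-stationary", {
  truth <- simTruth(testSim())
  tot <- colSums(truth$abundance)
  expect_lt(max(tot) / min(tot), 1.10)
  totArm <- colSums(truth$armAbundance)
  expect_lt(max(totArm) / min(totArm), 1.15)
})

test_that("invalid configurations are rejected", {
  expect_error(MztSimConfig(classFractions = c(I = 0.5, II = 0.5,
                                               III = 0.2,
                                               unclassified = -0.2)))
  expect_error(MztSimConfig(foldChange = 0.5), "foldChange")
  expect_error(MztSimConfig(librarySizes = rep(1e6, 6)), "librarySizes")
  expect_error(MztSimConfig(plantedMotif = "CCCCCCC"), "plantedMotif")
})

test_that("a written simulation reads back consistently", {
  sim <- testSim()
  dir <- withr::local_tempdir()
  writeSimulation(sim, dir)
  back <- readSimulation(dir)
  expect_identical(back$genes, simGenes(sim))
  expect_identical(back$counts[rownames(simCounts(sim)), ],
                   simCounts(sim))
  expect_identical(back$armCoords, simArmCoords(sim))
  expect_identical(as.character(back$genome), as.character(simGenome(sim)))
  expect_error(readSimulation(file.path(dir, "nope")),
               "missing input file")
})
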