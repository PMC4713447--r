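test_that("profile correlation matches the direct formula", {
  expect_equal(profileCorrelation(c(10, 8, 6, 4), c(1, 2, 3, 4)), -1)
  x <- c(3, 1, 4, 1.5)
  expect_equal(profileCorrelation(x, x), 1)
  set.seed(41)
  for (i in 1:20) {
    a <- runif(4); b <- runif(4)
    direct <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(profileCorrelation(a, b), direct, tolerance = 1e-12)
  }
  expect_error(profileCorrelation(rep(1, 4), 1:4), "constant")
})

test_that("duplex energy sums stacks and penalizes interruptions", {
  params <- loadEnergyParams()
  # single pair: nothing to stack
  expect_equal(duplexEnergy("AGGGG", "CCCCU",
                            data.frame(i = 1, j = 5), params), 0)
  # two adjacent GC/CG pairs: exactly one stack term
  expect_equal(duplexEnergy("GC", "GC", data.frame(i = 1:2, j = 2:1),
                            params),
               unname(params$stack[["GC.CG"]]))
  # invalid pair rejected
  expect_error(duplexEnergy("AA", "AA", data.frame(i = 1:2, j = 2:1),
                            params), "invalid base pair")
  expect_error(duplexEnergy("GC", "GC", data.frame(i = 1:2, j = 1:2),
                            params), "non-crossing")
})

test_that("a perfect 8-mer duplex on the toy table sits above -15", {
  toy <- toyParams()
  mir <- "ACGUACGU"
  tg <- rcDna(mir)                     # full complement, DNA
  dG <- duplexEnergy(mir, tg, data.frame(i = 1:8, j = 8:1), toy)
  expect_equal(dG, 7 * -2)             # -14: would fail a -15 threshold
})

test_that("duplex energy equals the exhaustive-decomposition oracle", {
  set.seed(43)
  params <- loadEnergyParams()
  for (rep in 1:25) {
    m <- sample(8:12, 1)
    mir <- paste(sample(c("A", "C", "G", "U"), m, TRUE), collapse = "")
    tg <- rcDna(mir)
    # random sub-pairing of the antiparallel complement (always valid WC)
    keep <- sort(sample(m, sample(2:m, 1)))
    pairs <- data.frame(i = keep, j = m - keep + 1)
    expect_equal(duplexEnergy(mir, tg, pairs, params),
                 oracleEnergy(mir, tg, pairs, params))
  }
})

test_that("duplex energy is additive over independent helices", {
  toy <- toyParams()
  mir <- "GCGCAAAGCGC"
  tg <- rcDna(mir)
  helix1 <- data.frame(i = 1:4, j = 11:8)
  helix2 <- data.frame(i = 8:11, j = 4:1)
  joint <- rbind(helix1, helix2)
  e1 <- duplexEnergy(mir, tg, helix1, toy)
  e2 <- duplexEnergy(mir, tg, helix2, toy)
  eJ <- duplexEnergy(mir, tg, joint, toy)
  expect_equal(eJ, e1 + e2 + toy$loopInit)   # one internal loop joins them
})

test_that("a full-complement site is found with the exact stack-sum energy", {
  set.seed(44)
  params <- loadEnergyParams()
  mir <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
  site <- rcDna(mir)
  utr <- paste0(randomDnaString(400), site, randomDnaString(400))
  sites <- findSites(mir, utr, params)
  expect_gt(nrow(sites), 0)
  best <- which.min(sites$dG)
  expect_equal(sites$start[best], 401)
  expect_equal(sites$end[best], 421)
  fullPairs <- data.frame(i = 1:21, j = 21:1)
  expect_equal(sites$dG[best],
               duplexEnergy(mir, site, fullPairs, params))
  # the returned pairing map reproduces the reported energy
  pm <- attr(sites, "pairs")[[best]]
  pm$j <- pm$j - 400
  expect_equal(duplexEnergy(mir, site, pm, params), sites$dG[best])
})

test_that("UTRs without a seed complement yield no sites", {
  params <- loadEnergyParams()
  mir <- paste0("GG", strrep("A", 19))         # seed GAAAAA-ish
  utr <- strrep("C", 500)                      # cannot pair the seed
  expect_equal(nrow(findSites(mir, utr, params)), 0)
})

test_that("site energies are reproducible from their pairing maps", {
  set.seed(45)
  params <- loadEnergyParams()
  found <- 0
  for (rep in 1:30) {
    mir <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    utr <- randomDnaString(800)
    sites <- findSites(mir, utr, params, minEnergy = -5)
    if (nrow(sites) == 0) next
    pm <- attr(sites, "pairs")
    for (k in seq_len(nrow(sites))) {
      found <- found + 1
      expect_equal(duplexEnergy(mir, utr, pm[[k]], params), sites$dG[k])
    }
  }
  expect_gt(found, 10)
})

test_that("network edges require both anticorrelation and binding energy", {
  sim <- testSim()
  exp <- testExperiment()
  armD <- testArmData()
  armSeqs <- matureArmSequences(simHairpins(sim), simArmCoords(sim))
  utrs <- extractUtrProxies(simGenes(sim), simGenome(sim))
  cache <- new.env(parent = emptyenv())
  base <- buildTargetNetwork(stageProfiles(armD$experiment, "diploid"),
                             stageProfiles(exp, "diploid"),
                             armSeqs, utrs, siteCache = cache)
  expect_true(all(base$edges$R < -0.8))
  expect_true(all(base$edges$dG < -15))

  # tightening either threshold can only shrink the edge set
  keyB <- paste(base$edges$arm, base$edges$gene)
  tightR <- buildTargetNetwork(stageProfiles(armD$experiment, "diploid"),
                               stageProfiles(exp, "diploid"),
                               armSeqs, utrs, rThreshold = -0.9,
                               siteCache = cache)
  tightE <- buildTargetNetwork(stageProfiles(armD$experiment, "diploid"),
                               stageProfiles(exp, "diploid"),
                               armSeqs, utrs, energyThreshold = -25,
                               siteCache = cache)
  expect_true(all(paste(tightR$edges$arm, tightR$edges$gene) %in% keyB))
  expect_true(all(paste(tightE$edges$arm, tightE$edges$gene) %in% keyB))
  expect_lte(nrow(tightR$edges), nrow(base$edges))
  expect_lte(nrow(tightE$edges), nrow(base$edges))
})

test_that("planted target pairs are recovered with high fidelity", {
  sim <- testSim()
  exp <- testExperiment()
  armD <- testArmData()
  armSeqs <- matureArmSequences(simHairpins(sim), simArmCoords(sim))
  utrs <- extractUtrProxies(simGenes(sim), simGenome(sim))
  net <- buildTargetNetwork(stageProfiles(armD$experiment, "diploid"),
                            stageProfiles(exp, "diploid"),
                            armSeqs, utrs)
  planted <- paste(simTruth(sim)$targets$arm, simTruth(sim)$targets$gene)
  called <- paste(net$edges$arm, net$edges$gene)
  expect_gte(mean(planted %in% called), 0.8)   # recall
  expect_gte(mean(called %in% planted), 0.8)   # precision
})

test_that("network export writes SIF and attribute tables", {
  edges <- data.frame(arm = c("mir_01-5p", "mir_02-3p"),
                      gene = c("gene_001", "gene_002"),
                      R = c(-0.9, -0.95), dG = c(-20, -18),
                      siteStart = c(10L, 50L), siteEnd = c(30L, 70L))
  labels <- data.frame(feature = c("mir_01-5p", "gene_001"),
                       label = c("II", "I"))
  base <- file.path(withr::local_tempdir(), "net")
  files <- exportNetwork(edges, base, labels)
  expect_true(all(file.exists(files)))
  sif <- readLines(paste0(base, ".sif"))
  expect_equal(sif, c("mir_01-5p targets gene_001",
                      "mir_02-3p targets gene_002"))
})
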