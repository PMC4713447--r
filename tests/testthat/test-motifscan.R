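test_that("promoter and UTR windows obey the coordinate arithmetic", {
  g <- Biostrings::DNAStringSet(c(chr1 = randomDnaString(8000)))
  genes <- data.frame(gene_id = c("p", "m"), contig = "chr1",
                      strand = c("+", "-"),
                      start_codon = c(2001L, 4000L),
                      stop_codon = c(3000L, 3001L),
                      tx_length = 1000L)
  prom <- extractPromoters(genes, g, 1000)
  expect_equal(as.character(prom[["p"]]),
               as.character(Biostrings::subseq(g[[1]], 1001, 2000)))
  # minus strand: reverse complement of the downstream-coordinate window
  expect_equal(as.character(prom[["m"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(g[[1]], 4001, 5000))))
  utr <- extractUtrProxies(genes, g, 1000)
  expect_equal(as.character(utr[["p"]]),
               as.character(Biostrings::subseq(g[[1]], 3001, 4000)))
  expect_equal(as.character(utr[["m"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::subseq(g[[1]], 2001, 3000))))
  expect_true(all(Biostrings::width(utr) <= 1000))
  # off-contig windows truncate with a warning
  short <- data.frame(gene_id = "s", contig = "chr1", strand = "+",
                      start_codon = 500L, stop_codon = 900L,
                      tx_length = 400L)
  expect_warning(p2 <- extractPromoters(short, g, 1000), "truncated")
  expect_equal(Biostrings::width(p2), 499)
})

test_that("k-mer coverage matches a brute-force per-promoter search", {
  set.seed(21)
  proms <- Biostrings::DNAStringSet(
    vapply(1:10, function(i) randomDnaString(100), character(1)))
  names(proms) <- paste0("g", 1:10)
  cov <- kmerCoverage(proms, k = 5, minCoverage = 0)
  seqs <- as.character(proms)
  rc <- function(s) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  pick <- cov[sample(nrow(cov), 50), ]
  for (i in seq_len(nrow(pick))) {
    km <- pick$kmer[i]
    naive <- mean(grepl(km, seqs, fixed = TRUE) |
                    grepl(rc(km), seqs, fixed = TRUE))
    expect_equal(pick$coverage[i], naive)
  }
})

test_that("the coverage threshold is strict", {
  mk <- function(nWith) {
    base <- strrep("C", 100)
    out <- rep(base, 10)
    out[seq_len(nWith)] <- paste0(substr(base, 1, 50), "AGGTA",
                                  substr(base, 56, 100))
    s <- Biostrings::DNAStringSet(out)
    names(s) <- paste0("g", 1:10)
    s
  }
  cov9 <- kmerCoverage(mk(9), k = 5, minCoverage = 0.8)
  expect_true("AGGTA" %in% cov9$kmer)
  expect_equal(cov9$coverage[cov9$kmer == "AGGTA"], 0.9)
  cov8 <- kmerCoverage(mk(8), k = 5, minCoverage = 0.8)
  expect_false("AGGTA" %in% cov8$kmer)   # 0.8 is not > 0.8
})

test_that("coverage counts reverse-complement occurrences", {
  s <- Biostrings::DNAStringSet(c(g1 = paste0(strrep("C", 40), "TACCT",
                                              strrep("C", 40))))
  cov <- kmerCoverage(s, k = 5, minCoverage = 0)
  expect_equal(cov$coverage[cov$kmer == "AGGTA"], 1)
})

test_that("k-mer coverage never exceeds that of its substrings", {
  set.seed(22)
  proms <- Biostrings::DNAStringSet(
    vapply(1:15, function(i) randomDnaString(200), character(1)))
  names(proms) <- paste0("g", 1:15)
  cov5 <- kmerCoverage(proms, k = 5, minCoverage = 0)
  cov6 <- kmerCoverage(proms, k = 6, minCoverage = 0)
  c5 <- stats::setNames(cov5$coverage, cov5$kmer)
  idx <- sample(nrow(cov6), 100)
  for (i in idx) {
    km <- cov6$kmer[i]
    expect_lte(cov6$coverage[i], c5[[substr(km, 1, 5)]])
    expect_lte(cov6$coverage[i], c5[[substr(km, 2, 6)]])
  }
})

test_that("the TAGteam filter keeps AGGTA/TACCT cores only", {
  cand <- data.frame(kmer = c("CAGGTAG", "CAGGCAG", "GTACCTG", "AAAAAAA"),
                     k = 7, coverage = 0.9)
  kept <- filterTagteam(cand)
  expect_setequal(kept$kmer, c("CAGGTAG", "GTACCTG"))
})

test_that("PWM construction aligns instances and normalizes columns", {
  proms <- Biostrings::DNAStringSet(c(g1 = "TTAGGTACC", g2 = "TTAGGTTCC"))
  inst <- motifInstances("AGGTA", proms)
  expect_equal(nrow(inst), 1)
  pwm1 <- buildPwm(inst, proms, width = 5, flank = 0, pseudocount = 0)
  expect_true(all(pwm1 %in% c(0, 1)))          # single instance: unit columns
  expect_equal(unname(colSums(pwm1)), rep(1, 5))

  # two instances differing at one position (second via reverse strand)
  proms2 <- Biostrings::DNAStringSet(c(g1 = "TTAGGTACC", g2 = "TTAGGTCCC"))
  i2 <- rbind(data.frame(gene = "g1", position = 3, strand = "+"),
              data.frame(gene = "g2", position = 3, strand = "+"))
  pwm2 <- buildPwm(i2, proms2, width = 6, flank = 0, pseudocount = 0)
  expect_equal(unname(pwm2["A", 5]), 0.5)  # AGGTAC vs AGGTCC differ at 5
  expect_equal(unname(pwm2["C", 5]), 0.5)
  pwm3 <- buildPwm(i2, proms2, width = 6)  # default flank adds 2 columns
  expect_equal(unname(colSums(pwm3)), rep(1, 8), tolerance = 1e-9)
})

test_that("PWM comparison finds identity, reverse complements and offsets", {
  refs <- tagteamReferencePwms()
  p <- refs$CAGGTAG
  self <- comparePwm(p, p)
  expect_equal(self$offset, 0)
  expect_equal(self$orientation, "forward")
  expect_equal(self$similarity, 1)

  revd <- comparePwm(reverseComplementPwm(p), p)
  expect_equal(revd$orientation, "reverse")
  expect_equal(revd$similarity, 1)
  expect_true(abs(self$similarity) <= 1)
  expect_error(comparePwm(p[, 1:2], p), "overlap")
})

test_that("PWM comparison equals a brute-force scan of all placements", {
  set.seed(31)
  rand_pwm <- function(w) {
    m <- matrix(runif(4 * w), 4, dimnames = list(c("A", "C", "G", "T")))
    sweep(m, 2, colSums(m), "/")
  }
  cand <- rand_pwm(5); ref <- rand_pwm(8)
  got <- comparePwm(cand, ref)
  best <- -Inf
  for (orient in 1:2) {
    cc <- if (orient == 1) cand else reverseComplementPwm(cand)
    for (off in -4:7) {
      cols <- intersect(seq_len(5) + off, seq_len(8))
      if (length(cols) < 3) next
      sims <- vapply(cols, function(j)
        cor(cc[, j - off], ref[, j]), numeric(1))
      best <- max(best, mean(sims))
    }
  }
  expect_equal(got$similarity, best)
})

test_that("an AGGTA candidate aligns to the TACCT orientation reference", {
  refs <- tagteamReferencePwms()
  got <- comparePwm(refs$CAGGTAG, reverseComplementPwm(refs$CAGGTAG))
  expect_equal(got$orientation, "reverse")
  expect_equal(got$similarity, 1)
})

test_that("planted motifs are discovered in class II promoters", {
  sim <- testSim()
  truth <- simTruth(sim)
  genes <- simGenes(sim)
  classII <- truth$geneClass$gene_id[truth$geneClass$diploid == "II"]
  prom <- extractPromoters(genes[genes$gene_id %in% classII, ],
                           simGenome(sim))
  # planted carriers contain the planted 7-mer at the recorded offset
  mp <- truth$motifPositions
  for (i in sample(nrow(mp), min(10, nrow(mp)))) {
    p <- as.character(prom[[mp$gene_id[i]]])
    expect_equal(substr(p, mp$promoter_pos[i], mp$promoter_pos[i] + 6),
                 truth$motif)
  }
  cands <- filterTagteam(kmerCoverage(prom))
  expect_true(truth$motif %in% cands$kmer)
  # the planted candidate's PWM aligns forward onto its consensus reference
  inst <- motifInstances(truth$motif, prom)
  pwm <- buildPwm(inst, prom, width = 7, flank = 0)
  cmpRef <- comparePwm(pwm, tagteamReferencePwms()$CAGGTAG)
  expect_equal(cmpRef$orientation, "forward")
  expect_equal(cmpRef$offset, 0)
  expect_gt(cmpRef$similarity, 0.9)
})

test_that("scanPromoters is order invariant and handles empty input", {
  sim <- testSim()
  prom <- extractPromoters(simGenes(sim)[1:10, ], simGenome(sim))
  a <- scanPromoters("AGGTA", prom)
  b <- scanPromoters("AGGTA", prom[sample(10)])
  expect_equal(a$count, b$count)
  empty <- scanPromoters("AGGTA", Biostrings::DNAStringSet())
  expect_equal(empty$count, 0)
})
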