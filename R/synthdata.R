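## Synthetic MZT study generator.
##
## Emulates the study design: one shared mature-oocyte library plus three
## embryo stages (0-2 h, 0-6 h, 18-24 h) per ploidy, with planted class
## I/II/III expression profiles, miRNA hairpins emitting 19-24 nt arm reads,
## AGGTA-containing motifs in class II promoters, and fully complementary
## miRNA binding sites in the 3'UTR proxies of anticorrelated genes.

.GENE_SPACER <- 100L

## sample() that never falls into the scalar-x shortcut
.resample <- function(x, k, replace = FALSE)
  x[sample.int(length(x), k, replace = replace)]

## Stage multipliers per shape group, mostly linear in stage index so that
## planted regulator/target profiles are (anti-)collinear across the four
## stages. f is the fold change between the extreme stages. "sz" is the
## strictly zygotic shape (zero in the oocyte); "invV" is the
## cleavage-peak mirror of the class III V-shape, carried by part of the
## unclassified pool so that the total abundance pool can be balanced
## across stages.
.SHAPE_CLASS <- c(fall = "I", rise = "II", sz = "II", V = "III",
                  invV = "unclassified", flat = "unclassified")

.stageProfile <- function(shape, f) {
  switch(shape,
    fall = seq(f, 1, length.out = 4),
    rise = seq(1, f, length.out = 4),
    sz = c(0, seq(f / 3, f, length.out = 3)),
    V = c(f, 1, 1, f),
    invV = c(1, f, f, 1),
    flat = rep(1, 4),
    stop("unknown shape: ", shape))
}

## Distribute class labels over shape groups: class II splits between
## rising and strictly zygotic; the unclassified pool splits between the
## inverted-V mirror (as many as there are V-shaped features, so that the
## two cancel) and flat.
.assignShapes <- function(classes) {
  shape <- character(length(classes))
  shape[classes == "I"] <- "fall"
  shape[classes == "III"] <- "V"
  ii <- which(classes == "II")
  if (length(ii) > 0) {
    shape[ii] <- "rise"
    nSz <- floor(length(ii) / 2)
    if (nSz > 0) shape[.resample(ii, nSz)] <- "sz"
  }
  uu <- which(classes == "unclassified")
  if (length(uu) > 0) {
    shape[uu] <- "flat"
    nInv <- min(sum(classes == "III"), length(uu))
    if (nInv > 0) shape[.resample(uu, nInv)] <- "invV"
  }
  shape
}

## Per-shape-group base weights making the summed abundance pool as
## stage-stationary as possible (ridge-regularized least squares, weights
## near 1). A stationary pool keeps sampled proportions faithful to the
## planted per-gene profiles, as the random-sampling model assumes.
.balanceWeights <- function(base, shape, f) {
  groups <- setdiff(unique(shape), character(0))
  if (length(groups) <= 1) return(setNames(rep(1, length(groups)), groups))
  mass <- vapply(groups, function(g)
    sum(base[shape == g]) * .stageProfile(g, f), numeric(4))
  A <- diff(mass)                      # 3 x nGroups stage differences
  resid <- A %*% rep(1, length(groups))
  delta <- crossprod(A, solve(tcrossprod(A) + 1e-8 * diag(3), -resid))
  w <- pmax(as.numeric(1 + delta), 0.05)
  setNames(w, groups)
}

.randomDna <- function(n) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Largest-remainder apportionment of n items over named fractions.
.apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate the synthetic annotation: genome, gene table and hairpins
#'
#' Lays out `nGenes` genes on a single contig, each with a full promoter
#' window upstream of the start codon and a full 3'UTR-proxy window
#' downstream of the stop codon (flanks are never truncated), and `nMirnas`
#' hairpin precursors of 70-110 nt with disjoint 5p and 3p mature arms of
#' 19-24 nt.
#'
#' @param config an [MztSimConfig-class].
#' @param seed optional seed; when `NULL` the current RNG state is used
#'   (as when called from [simulateMztStudy()], which seeds once).
#' @return list with `genome` (`DNAStringSet`), `genes` (data.frame:
#'   gene_id, contig, strand, start_codon, stop_codon, tx_length; 1-based
#'   inclusive coordinates), `hairpins` (`DNAStringSet`) and `armCoords`
#'   (data.frame: hairpin, arm, start, end).
#' @export
generateAnnotation <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config@nGenes
  pl <- config@promoterLen
  ul <- config@utrLen

  txLen <- if (n > 0) sample(300:1500, n, replace = TRUE) else integer()
  strand <- rep("+", n)
  if (n > 0 && config@minusStrandFrac > 0) {
    nMinus <- round(config@minusStrandFrac * n)
    if (nMinus > 0) strand[.resample(seq_len(n), nMinus)] <- "-"
  }
  blockLen <- pl + txLen + ul + .GENE_SPACER
  blockStart <- cumsum(c(1L, head(blockLen, -1L)))
  startCodon <- stopCodon <- integer(n)
  for (i in seq_len(n)) {
    if (strand[i] == "+") {
      startCodon[i] <- blockStart[i] + pl
      stopCodon[i] <- startCodon[i] + txLen[i] - 1L
    } else {
      startCodon[i] <- blockStart[i] + pl + txLen[i] - 1L
      stopCodon[i] <- blockStart[i] + pl
    }
  }
  genomeLen <- if (n > 0) sum(blockLen) + .GENE_SPACER else 2000L
  genome <- Biostrings::DNAStringSet(.randomDna(genomeLen))
  names(genome) <- "chr1"

  genes <- data.frame(
    gene_id = if (n > 0) sprintf("gene_%03d", seq_len(n)) else character(),
    contig = rep("chr1", n),
    strand = strand,
    start_codon = startCodon,
    stop_codon = stopCodon,
    tx_length = txLen,
    stringsAsFactors = FALSE)

  m <- config@nMirnas
  hpLen <- if (m > 0) sample(70:110, m, replace = TRUE) else integer()
  hairpins <- Biostrings::DNAStringSet(vapply(hpLen, .randomDna, character(1)))
  names(hairpins) <- if (m > 0) sprintf("mir_%02d", seq_len(m)) else character()
  armCoords <- do.call(rbind, lapply(seq_len(m), function(i) {
    s5 <- sample(2:5, 1); l5 <- sample(19:24, 1)
    e3 <- hpLen[i] - sample(1:4, 1); l3 <- sample(19:24, 1)
    data.frame(hairpin = names(hairpins)[i],
               arm = c("5p", "3p"),
               start = c(s5, e3 - l3 + 1L),
               end = c(s5 + l5 - 1L, e3),
               stringsAsFactors = FALSE)
  }))
  if (is.null(armCoords))
    armCoords <- data.frame(hairpin = character(), arm = character(),
                            start = integer(), end = integer())
  list(genome = genome, genes = genes, hairpins = hairpins,
       armCoords = armCoords)
}

#' Assign planted ground truth to a synthetic annotation
#'
#' Draws the planted class of every gene and miRNA arm, true abundances at
#' the four stages per ploidy (shared oocyte), the class II promoters that
#' will carry the planted motif, and the planted (regulator arm, target
#' gene) pairs. Regulator arms are the class II (zygotically rising) and
#' class I (maternally declining) arms; their planted targets are drawn
#' from the gene class with the opposite profile, so that every planted
#' pair is strongly anticorrelated across stages.
#'
#' @param annotation output of [generateAnnotation()].
#' @param config an [MztSimConfig-class].
#' @return list of ground-truth components; see [simulateMztStudy()].
#' @export
assignGroundTruth <- function(annotation, config) {
  genes <- annotation$genes
  n <- nrow(genes)
  f <- config@foldChange

  nPerClass <- .apportion(n, config@classFractions)
  classes <- rep(names(config@classFractions), nPerClass)
  if (n > 0) classes <- .resample(classes, length(classes))
  shape <- .assignShapes(classes)

  base <- rlnorm(n, meanlog = 0, sdlog = 0.5)
  jitter <- function(k) rlnorm(k, 0, config@abundanceJitter)
  abundance <- matrix(0, n, 7, dimnames = list(genes$gene_id, .MZT_SAMPLES))
  if (n > 0) {
    w <- .balanceWeights(base, shape, f)
    base <- base * w[shape]
    stageMat <- t(vapply(shape, .stageProfile, numeric(4), f = f))
    abundance[, "oocyte"] <- base * stageMat[, 1] * jitter(n)
    for (pl in c("diploid", "haploid")) {
      for (s in 2:4) {
        col <- paste(pl, .MZT_STAGES[s], sep = "_")
        abundance[, col] <- base * stageMat[, s] * jitter(n)
      }
    }
    ## truth consistency: class II oocyte abundance strictly below 18-24 h
    riseII <- which(shape == "rise")
    if (length(riseII) > 0) {
      minLate <- pmin(abundance[riseII, "diploid_18_24h"],
                      abundance[riseII, "haploid_18_24h"])
      abundance[riseII, "oocyte"] <- pmin(abundance[riseII, "oocyte"],
                                          0.99 * minLate)
    }
  }

  ## miRNA arms: a planted class (and shape) per arm, hairpin base
  ## abundance split between the arms
  ac <- annotation$armCoords
  nArm <- nrow(ac)
  armId <- paste(ac$hairpin, ac$arm, sep = "-")
  armClass <- rep(names(config@classFractions),
                  .apportion(nArm, c(I = 0.20, II = 0.15, III = 0.20,
                                     unclassified = 0.45)))
  if (nArm > 0) armClass <- .resample(armClass, length(armClass))
  armShape <- .assignShapes(armClass)
  hpBase <- setNames(rlnorm(length(annotation$hairpins), 0, 0.5),
                     names(annotation$hairpins))
  share <- runif(nArm, 0.25, 0.75)
  armAbundance <- matrix(0, nArm, 7, dimnames = list(armId, .MZT_SAMPLES))
  if (nArm > 0) {
    armBase <- hpBase[ac$hairpin] * share
    wA <- .balanceWeights(armBase, armShape, f)
    armBase <- armBase * wA[armShape]
    armStage <- t(vapply(armShape, .stageProfile, numeric(4), f = f))
    armAbundance[, "oocyte"] <- armBase * armStage[, 1] * jitter(nArm)
    for (pl in c("diploid", "haploid")) {
      for (s in 2:4) {
        col <- paste(pl, .MZT_STAGES[s], sep = "_")
        armAbundance[, col] <- armBase * armStage[, s] * jitter(nArm)
      }
    }
  }

  ## planted motif carriers among class II genes
  ii <- which(classes == "II")
  carriers <- character()
  if (length(ii) > 0 && config@motifPlantRate > 0) {
    nCarry <- round(config@motifPlantRate * length(ii))
    if (nCarry > 0)
      carriers <- genes$gene_id[sort(.resample(ii, nCarry))]
  }

  ## planted target pairs: every regulator arm targets a random fraction
  ## of the gene pool whose planted profile is anticorrelated with its own
  targets <- data.frame(arm = character(), gene = character(),
                        stringsAsFactors = FALSE)
  antiPool <- list(rise = c("fall"), fall = c("rise", "sz"),
                   V = c("invV"), invV = c("V"))
  for (sh in names(antiPool)) {
    regArms <- armId[armShape == sh]
    pool <- genes$gene_id[shape %in% antiPool[[sh]]]
    nPick <- round(config@sitePlantRate * length(pool))
    if (length(regArms) == 0 || nPick == 0) next
    for (a in regArms) {
      tg <- sort(.resample(seq_along(pool), nPick))
      targets <- rbind(targets,
                       data.frame(arm = a, gene = pool[tg],
                                  stringsAsFactors = FALSE))
    }
  }

  list(geneClass = data.frame(gene_id = genes$gene_id,
                              diploid = classes, haploid = classes,
                              shape = shape, stringsAsFactors = FALSE),
       abundance = abundance,
       armClass = data.frame(arm = armId, hairpin = ac$hairpin,
                             which_arm = ac$arm, class = armClass,
                             shape = armShape, share = share,
                             stringsAsFactors = FALSE),
       armAbundance = armAbundance,
       motif = config@plantedMotif,
       motifCarriers = carriers,
       motifPositions = data.frame(gene_id = character(),
                                   promoter_pos = integer()),
       targets = targets,
       sitePositions = data.frame(arm = character(), gene = character(),
                                  utr_start = integer(), utr_end = integer()))
}

## Coding-strand window coordinates on the genome (1-based inclusive).
.promoterWindow <- function(gene, len) {
  if (gene$strand == "+")
    c(gene$start_codon - len, gene$start_codon - 1L)
  else
    c(gene$start_codon + 1L, gene$start_codon + len)
}

.utrWindow <- function(gene, len) {
  if (gene$strand == "+")
    c(gene$stop_codon + 1L, gene$stop_codon + len)
  else
    c(gene$stop_codon - len, gene$stop_codon - 1L)
}

## Genomic coordinates and strand-adjusted sequence for writing `repl`
## (given on the coding strand, 5'->3') at coding-strand offset `offset`
## (1-based) of the window.
.windowReplacement <- function(gene, window, offset, repl) {
  w <- nchar(repl)
  if (gene$strand == "+") {
    gStart <- window[1] + offset - 1L
    seqRepl <- repl
  } else {
    gEnd <- window[2] - offset + 1L
    gStart <- gEnd - w + 1L
    seqRepl <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(repl)))
  }
  list(start = gStart, end = gStart + w - 1L, seq = seqRepl)
}

#' Plant the regulatory signal into promoters and UTR proxies
#'
#' Writes the configured AGGTA-containing motif into the promoters of the
#' chosen class II carrier genes, and for every planted (arm, gene) target
#' pair writes a site fully complementary to miRNA positions 1-16 into the
#' gene's 3'UTR proxy. Site placements within one UTR never overlap; a
#' colliding position is redrawn, never truncated. All positions are
#' recorded in the returned truth.
#'
#' @param annotation output of [generateAnnotation()].
#' @param truth output of [assignGroundTruth()].
#' @param config an [MztSimConfig-class].
#' @return list with updated `annotation` and `truth`.
#' @export
plantRegulatorySignal <- function(annotation, truth, config) {
  genes <- annotation$genes
  rownames(genes) <- genes$gene_id
  repl <- list()

  motif <- truth$motif
  mw <- nchar(motif)
  mpos <- integer(length(truth$motifCarriers))
  for (i in seq_along(truth$motifCarriers)) {
    g <- genes[truth$motifCarriers[i], ]
    win <- .promoterWindow(g, config@promoterLen)
    off <- sample(config@promoterLen - mw + 1L, 1)
    repl[[length(repl) + 1]] <- .windowReplacement(g, win, off, motif)
    mpos[i] <- off
  }
  truth$motifPositions <- data.frame(gene_id = truth$motifCarriers,
                                     promoter_pos = mpos,
                                     stringsAsFactors = FALSE)

  tg <- truth$targets
  if (nrow(tg) > 0) {
    armSeq <- matureArmSequences(annotation$hairpins, annotation$armCoords)
    siteStart <- siteEnd <- integer(nrow(tg))
    occupied <- split(integer(0), character(0))
    siteLen <- 16L
    for (i in seq_len(nrow(tg))) {
      mir <- substr(armSeq[[tg$arm[i]]], 1, siteLen)
      site <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(mir)))
      g <- genes[tg$gene[i], ]
      win <- .utrWindow(g, config@utrLen)
      occ <- occupied[[tg$gene[i]]]
      for (try in 1:200) {
        off <- sample(config@utrLen - siteLen + 1L, 1)
        if (!any(abs(off - occ) < siteLen)) break
      }
      occupied[[tg$gene[i]]] <- c(occ, off)
      repl[[length(repl) + 1]] <- .windowReplacement(g, win, off, site)
      siteStart[i] <- off
      siteEnd[i] <- off + siteLen - 1L
    }
    truth$sitePositions <- data.frame(arm = tg$arm, gene = tg$gene,
                                      utr_start = siteStart,
                                      utr_end = siteEnd,
                                      stringsAsFactors = FALSE)
  }
  if (length(repl) > 0) {
    annotation$genome[[1]] <- Biostrings::replaceAt(
      annotation$genome[[1]],
      IRanges::IRanges(vapply(repl, `[[`, integer(1), "start"),
                       vapply(repl, `[[`, integer(1), "end")),
      vapply(repl, `[[`, character(1), "seq"))
  }
  list(annotation = annotation, truth = truth)
}

#' Mature arm sequences from hairpins and arm coordinates
#'
#' @param hairpins `DNAStringSet` of precursors.
#' @param armCoords data.frame with hairpin, arm, start, end (1-based).
#' @return Named character vector of arm sequences (DNA alphabet), names
#'   `<hairpin>-<arm>`.
#' @export
matureArmSequences <- function(hairpins, armCoords) {
  out <- vapply(seq_len(nrow(armCoords)), function(i) {
    as.character(Biostrings::subseq(hairpins[[armCoords$hairpin[i]]],
                                    armCoords$start[i], armCoords$end[i]))
  }, character(1))
  setNames(out, paste(armCoords$hairpin, armCoords$arm, sep = "-"))
}

#' Draw read counts and small-RNA reads from the planted truth
#'
#' mRNA counts for each library are one multinomial draw of the configured
#' library size over the true stage abundances (marginally binomial per
#' gene, exactly the random-sampling null of the MARS statistic). Small-RNA
#' reads are exact substrings of the mature arms, 19-24 nt, with per-arm
#' counts multinomial in the planted arm abundances.
#'
#' @param annotation output of [plantRegulatorySignal()] (`$annotation`).
#' @param truth the planted ground truth.
#' @param config an [MztSimConfig-class].
#' @return list with `counts` (gene x 7 matrix), `smallRna`
#'   (`DNAStringSet`, names `read_<n>|<sample>`) and `armReadCounts`
#'   (arm x 7 matrix of emitted read counts).
#' @export
generateCounts <- function(annotation, truth, config) {
  n <- nrow(truth$abundance)
  counts <- matrix(0L, n, 7,
                   dimnames = list(rownames(truth$abundance), .MZT_SAMPLES))
  for (s in .MZT_SAMPLES) {
    ab <- truth$abundance[, s]
    if (n > 0) {
      if (sum(ab) <= 0) stop("degenerate truth: abundance sums to 0 in ", s)
      counts[, s] <- rmultinom(1, size = config@librarySizes[
        match(s, .MZT_SAMPLES)], prob = ab)[, 1]
    }
  }

  armSeq <- matureArmSequences(annotation$hairpins, annotation$armCoords)
  nArm <- length(armSeq)
  armReadCounts <- matrix(0L, nArm, 7,
                          dimnames = list(names(armSeq), .MZT_SAMPLES))
  seqs <- character(0)
  ids <- character(0)
  for (s in .MZT_SAMPLES) {
    if (nArm == 0) next
    ab <- truth$armAbundance[, s]
    if (sum(ab) <= 0) stop("degenerate truth: arm abundance sums to 0 in ", s)
    armReadCounts[, s] <- rmultinom(1, size = config@smallRnaReads,
                                    prob = ab)[, 1]
    for (a in seq_len(nArm)) {
      k <- armReadCounts[a, s]
      if (k == 0) next
      armLen <- nchar(armSeq[a])
      len <- .resample(19:min(24, armLen), k, replace = TRUE)
      start <- vapply(len, function(l) sample(armLen - l + 1L, 1), integer(1))
      seqs <- c(seqs, substring(armSeq[a], start, start + len - 1L))
      ids <- c(ids, paste0("read_", length(ids) + seq_len(k), "|", s))
    }
  }
  smallRna <- Biostrings::DNAStringSet(seqs)
  names(smallRna) <- ids
  list(counts = counts, smallRna = smallRna, armReadCounts = armReadCounts)
}

#' Simulate a complete miniature MZT study
#'
#' Runs annotation generation, ground-truth assignment, regulatory-signal
#' planting and count/read sampling under a single seed, returning an
#' [MztSimulation-class] with every artifact and the planted truth.
#' Identical configurations (including seed) reproduce byte-identical
#' results.
#'
#' @param config an [MztSimConfig-class].
#' @return An [MztSimulation-class].
#' @examples
#' sim <- simulateMztStudy(MztSimConfig(nGenes = 40, nMirnas = 4, seed = 3))
#' sim
#' @export
simulateMztStudy <- function(config) {
  validObject(config)
  set.seed(config@seed)
  ann <- generateAnnotation(config)
  truth <- assignGroundTruth(ann, config)
  planted <- plantRegulatorySignal(ann, truth, config)
  drawn <- generateCounts(planted$annotation, planted$truth, config)
  truth <- planted$truth
  truth$armReadCounts <- drawn$armReadCounts
  new("MztSimulation",
      config = config,
      genome = planted$annotation$genome,
      genes = planted$annotation$genes,
      hairpins = planted$annotation$hairpins,
      armCoords = planted$annotation$armCoords,
      counts = drawn$counts,
      smallRna = drawn$smallRna,
      truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes genome.fa, hairpins.fa (arm coordinates as key=value pairs in the
#' headers), genes.tsv, one counts_<sample>.tsv per library, smallrna.fa
#' and truth.json. All coordinates are 1-based inclusive.
#'
#' @param sim an [MztSimulation-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(sim@genome, p)
  paths <- c(paths, p)

  hp <- sim@hairpins
  if (length(hp) > 0) {
    ac <- sim@armCoords
    hdr <- vapply(names(hp), function(h) {
      a <- ac[ac$hairpin == h, ]
      paste0(h, " ", paste0(a$arm, "=", a$start, "-", a$end, collapse = " "))
    }, character(1))
    names(hp) <- hdr
  }
  p <- file.path(dir, "hairpins.fa")
  Biostrings::writeXStringSet(hp, p)
  paths <- c(paths, p)

  p <- file.path(dir, "genes.tsv")
  write.table(sim@genes, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  for (s in colnames(sim@counts)) {
    p <- file.path(dir, paste0("counts_", s, ".tsv"))
    write.table(data.frame(gene_id = rownames(sim@counts),
                           count = sim@counts[, s]),
                p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }

  p <- file.path(dir, "smallrna.fa")
  Biostrings::writeXStringSet(sim@smallRna, p)
  paths <- c(paths, p)

  p <- file.path(dir, "truth.json")
  jsonlite::write_json(sim@truth, p, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  paths <- c(paths, p)
  invisible(paths)
}
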