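## End-to-end orchestration: simulate -> quantify -> small RNA -> MARS ->
## classify -> motif -> targets, with a deterministic manifest.

#' Pipeline configuration
#'
#' Bundles the simulation configuration with every analysis threshold at
#' its study default: mapped-read cutoff 5, alpha 0.05, promoter coverage
#' 0.8, Pearson R -0.8 and duplex dG -15 kcal/mol. Stage toggles switch
#' individual pipeline stages off.
#'
#' @param simConfig an [MztSimConfig-class].
#' @param cutoff mapped-read cutoff for expression.
#' @param alpha significance level for MARS.
#' @param coverageThreshold promoter coverage threshold (strict >).
#' @param motifCore motif core for the TAGteam filter.
#' @param rThreshold Pearson threshold (strict <).
#' @param energyThreshold duplex dG threshold, kcal/mol (strict <).
#' @param stages named logical vector of stage toggles.
#' @return A `mztPipelineConfig` list.
#' @export
mztPipelineConfig <- function(simConfig = MztSimConfig(),
                              cutoff = 5, alpha = 0.05,
                              coverageThreshold = 0.8,
                              motifCore = "AGGTA",
                              rThreshold = -0.8, energyThreshold = -15,
                              stages = c(simulate = TRUE, expression = TRUE,
                                         smallrna = TRUE, deg = TRUE,
                                         classify = TRUE, motif = TRUE,
                                         targets = TRUE)) {
  structure(list(simConfig = simConfig, cutoff = cutoff, alpha = alpha,
                 coverageThreshold = coverageThreshold,
                 motifCore = motifCore, rThreshold = rThreshold,
                 energyThreshold = energyThreshold, stages = stages),
            class = "mztPipelineConfig")
}

#' Bundled demo configuration
#'
#' A reduced study (80 genes, 8 hairpins, 2e5-read libraries) that runs
#' the full pipeline in well under five minutes on one CPU, used by the
#' examples and the end-to-end determinism checks.
#'
#' @param seed RNG seed.
#' @return An [mztPipelineConfig()] list.
#' @export
demoPipelineConfig <- function(seed = 7L) {
  mztPipelineConfig(MztSimConfig(nGenes = 80L, nMirnas = 8L,
                                 librarySizes = rep(2e5, 7),
                                 smallRnaReads = 5000, seed = seed))
}

.writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full MZT analysis pipeline
#'
#' Executes the enabled stages in order on a simulated (or supplied)
#' study, writing every product plus a `manifest.json` recording the
#' seed, per-stage row counts and the MD5 hash of every output file.
#' Rerunning with the same configuration reproduces byte-identical
#' outputs and an identical manifest.
#'
#' @param config an [mztPipelineConfig()] list.
#' @param outdir output directory.
#' @param sim optional pre-built [MztSimulation-class]; required when the
#'   simulate stage is toggled off.
#' @return Invisibly, a list with the main in-memory products (sim,
#'   experiment, comparisons, classes, motif candidates, networks,
#'   manifest).
#' @export
runPipeline <- function(config, outdir, sim = NULL) {
  stopifnot(inherits(config, "mztPipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  st <- config$stages
  files <- character()
  rowCounts <- list()
  res <- list()

  if (isTRUE(st[["simulate"]])) {
    sim <- simulateMztStudy(config$simConfig)
    files <- c(files, writeSimulation(sim, file.path(outdir, "sim")))
  }
  if (is.null(sim)) stop("no simulation available: enable the simulate ",
                         "stage or pass `sim`")
  res$sim <- sim
  rowCounts$genes <- nrow(sim@genes)

  exp <- armExp <- combined <- NULL
  if (isTRUE(st[["expression"]])) {
    exp <- buildExpressionMatrix(sim@counts, sim@genes$tx_length,
                                 libSizes = colSums(sim@counts),
                                 featureType = "mRNA",
                                 cutoff = config$cutoff)
    em <- data.frame(feature = rownames(exp),
                     SummarizedExperiment::assay(exp, "counts"),
                     rpkm = SummarizedExperiment::assay(exp, "rpkm"),
                     check.names = FALSE)
    files <- c(files, .writeTsv(em, file.path(outdir,
                                              "expression_matrix.tsv")))
    sets <- lapply(setNames(nm = colnames(exp)),
                   function(s) expressedSet(exp, s))
    ov <- do.call(rbind, lapply(c("diploid", "haploid"), function(pl) {
      o <- stageOverlap(sets[ploidySamples(pl)])
      data.frame(ploidy = pl, region = o$region, count = o$count)
    }))
    files <- c(files, .writeTsv(ov, file.path(outdir, "overlaps.tsv")))
    rowCounts$expression <- nrow(em)
    res$experiment <- exp
  }

  if (isTRUE(st[["smallrna"]])) {
    aln <- mapReadsToHairpins(sim@smallRna, sim@hairpins)
    ac <- armCounts(aln, sim@hairpins, sim@armCoords)
    files <- c(files, .writeTsv(ac, file.path(outdir, "arm_counts.tsv")))
    armMat <- armCountMatrix(ac, samples = .MZT_SAMPLES)
    armLen <- setNames(sim@armCoords$end - sim@armCoords$start + 1L,
                       paste(sim@armCoords$hairpin, sim@armCoords$arm,
                             sep = "-"))
    armExp <- buildExpressionMatrix(armMat, armLen[rownames(armMat)],
                                    libSizes = pmax(colSums(armMat), 1),
                                    featureType = "miRNA_arm",
                                    cutoff = config$cutoff)
    rowCounts$armAlignments <- nrow(aln)
    res$armExperiment <- armExp
  }

  if (!is.null(exp) && !is.null(armExp)) {
    combined <- buildExpressionMatrix(
      rbind(SummarizedExperiment::assay(exp, "counts"),
            SummarizedExperiment::assay(armExp, "counts")),
      c(SummarizedExperiment::rowData(exp)$length,
        SummarizedExperiment::rowData(armExp)$length),
      libSizes = SummarizedExperiment::colData(exp)$libSize,
      featureType = c(as.character(
        SummarizedExperiment::rowData(exp)$featureType),
        as.character(SummarizedExperiment::rowData(armExp)$featureType)),
      cutoff = config$cutoff)
  } else {
    combined <- exp
  }

  comparisons <- NULL
  if (isTRUE(st[["deg"]]) && !is.null(combined)) {
    comparisons <- lapply(setNames(nm = c("diploid", "haploid")),
                          function(pl)
                            canonicalComparisons(combined, pl,
                                                 alpha = config$alpha))
    for (pl in names(comparisons))
      for (nm in names(comparisons[[pl]]))
        files <- c(files, .writeTsv(
          comparisons[[pl]][[nm]],
          file.path(outdir, paste0("deg_", pl, "_", nm, ".tsv"))))
    res$comparisons <- comparisons
  }

  classes <- NULL
  if (isTRUE(st[["classify"]]) && !is.null(combined)) {
    classes <- classifyAll(combined, alpha = config$alpha)
    for (pl in c("diploid", "haploid")) {
      sub <- classes$labels[classes$labels$ploidy == pl, ]
      files <- c(files, .writeTsv(sub, file.path(
        outdir, paste0("mzt_classes_", pl, ".tsv"))))
    }
    files <- c(files, .writeTsv(classes$summary,
                                file.path(outdir, "class_summary.tsv")))
    rowCounts$classes <- nrow(classes$labels)
    res$classes <- classes
  }

  if (isTRUE(st[["motif"]]) && !is.null(classes)) {
    motifTabs <- list()
    for (pl in c("diploid", "haploid")) {
      lab <- classes$labels[classes$labels$ploidy == pl, ]
      classII <- lab$feature[lab$label == "II" &
                               lab$featureType == "mRNA"]
      if (length(classII) == 0) next
      prom <- extractPromoters(sim@genes[sim@genes$gene_id %in% classII, ],
                               sim@genome, config$simConfig@promoterLen)
      cands <- filterTagteam(
        kmerCoverage(prom, minCoverage = config$coverageThreshold),
        core = config$motifCore)
      if (nrow(cands) > 0) {
        cands$ploidy <- pl
        motifTabs[[pl]] <- cands
      }
    }
    motifTab <- if (length(motifTabs)) do.call(rbind, motifTabs) else
      data.frame(kmer = character(), k = integer(), coverage = numeric(),
                 ploidy = character())
    files <- c(files, .writeTsv(motifTab,
                                file.path(outdir, "motif_candidates.tsv")))
    rowCounts$motifCandidates <- nrow(motifTab)
    res$motifCandidates <- motifTab
  }

  if (isTRUE(st[["targets"]]) && !is.null(combined) && !is.null(armExp)) {
    armSeqs <- matureArmSequences(sim@hairpins, sim@armCoords)
    utrs <- extractUtrProxies(sim@genes, sim@genome,
                              config$simConfig@utrLen)
    params <- loadEnergyParams()
    cache <- new.env(parent = emptyenv())
    networks <- list()
    for (pl in c("diploid", "haploid")) {
      armProf <- stageProfiles(armExp, pl)
      geneProf <- stageProfiles(exp, pl)
      net <- buildTargetNetwork(armProf, geneProf, armSeqs, utrs, params,
                                rThreshold = config$rThreshold,
                                energyThreshold = config$energyThreshold,
                                siteCache = cache)
      networks[[pl]] <- net
      files <- c(files, exportNetwork(
        net$edges, file.path(outdir, paste0("edges_", pl)),
        labels = if (!is.null(classes))
          classes$labels[classes$labels$ploidy == pl, ]))
      rowCounts[[paste0("edges_", pl)]] <- nrow(net$edges)
    }
    res$networks <- networks
  }

  manifest <- list(
    package = "beeMZT",
    version = as.character(utils::packageVersion("beeMZT")),
    seed = config$simConfig@seed,
    thresholds = list(cutoff = config$cutoff, alpha = config$alpha,
                      coverage = config$coverageThreshold,
                      r = config$rThreshold,
                      energy = config$energyThreshold),
    stages = as.list(config$stages),
    rowCounts = rowCounts,
    files = {
      rel <- sort(unique(sub(paste0("^", outdir, "/?"), "", files)))
      lapply(setNames(nm = rel), function(f)
        unname(tools::md5sum(file.path(outdir, f))))
    })
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}

#' Read a written simulation back from disk
#'
#' Restores the annotation, counts, small-RNA reads and ground truth
#' written by [writeSimulation()]. Fails fast naming the first missing
#' file.
#'
#' @param dir directory written by [writeSimulation()].
#' @return list with genome, genes, hairpins, armCoords, counts, smallRna
#'   and truth (classes/targets tables; abundance matrices are not
#'   round-tripped).
#' @export
readSimulation <- function(dir) {
  need <- c("genome.fa", "hairpins.fa", "genes.tsv", "smallrna.fa",
            "truth.json", paste0("counts_", .MZT_SAMPLES, ".tsv"))
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing input file: ", file.path(dir, f))
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  hp <- Biostrings::readDNAStringSet(file.path(dir, "hairpins.fa"))
  armCoords <- data.frame(hairpin = character(), arm = character(),
                          start = integer(), end = integer())
  if (length(hp) > 0) {
    parts <- strsplit(names(hp), " +")
    names(hp) <- vapply(parts, `[`, character(1), 1)
    armCoords <- do.call(rbind, lapply(parts, function(p) {
      kv <- p[-1]
      arm <- sub("=.*", "", kv)
      rng <- strsplit(sub(".*=", "", kv), "-")
      data.frame(hairpin = p[1], arm = arm,
                 start = as.integer(vapply(rng, `[`, character(1), 1)),
                 end = as.integer(vapply(rng, `[`, character(1), 2)),
                 stringsAsFactors = FALSE)
    }))
  }
  genes <- read.delim(file.path(dir, "genes.tsv"),
                      stringsAsFactors = FALSE)
  counts <- NULL
  for (s in .MZT_SAMPLES) {
    tab <- read.delim(file.path(dir, paste0("counts_", s, ".tsv")),
                      stringsAsFactors = FALSE)
    if (is.null(counts))
      counts <- matrix(0L, nrow(tab), 7,
                       dimnames = list(tab$gene_id, .MZT_SAMPLES))
    counts[tab$gene_id, s] <- tab$count
  }
  if (is.null(counts))
    counts <- matrix(0L, 0, 7, dimnames = list(NULL, .MZT_SAMPLES))
  smallRna <- Biostrings::readDNAStringSet(file.path(dir, "smallrna.fa"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(genome = genome, genes = genes, hairpins = hp,
       armCoords = armCoords, counts = counts, smallRna = smallRna,
       truth = truth)
}
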