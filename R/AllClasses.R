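#' @import methods
#' @importFrom stats cor pnorm rmultinom runif rlnorm setNames
#' @importFrom utils read.delim write.table head
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Canonical sample layout: one shared mature-oocyte library plus three
## embryo stages per ploidy. Order is fixed throughout the package.
.MZT_SAMPLES <- c("oocyte",
                  "diploid_0_2h", "diploid_0_6h", "diploid_18_24h",
                  "haploid_0_2h", "haploid_0_6h", "haploid_18_24h")

.MZT_STAGES <- c("oocyte", "0_2h", "0_6h", "18_24h")

#' Sample names for a ploidy
#'
#' Returns the four sample identifiers (shared oocyte plus the three embryo
#' stages) for one ploidy, in developmental order.
#'
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return Character vector of length 4.
#' @export
ploidySamples <- function(ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  c("oocyte", paste(ploidy, c("0_2h", "0_6h", "18_24h"), sep = "_"))
}

#' Configuration for the synthetic MZT study generator
#'
#' Holds every tunable of the simulated study: problem sizes, the planted
#' class composition, the stage effect size, sequencing depths, regulatory
#' signal planting rates and the RNG seed. Validity enforces that class
#' fractions sum to one, all lengths are positive and the fold change is
#' at least one.
#'
#' @slot nGenes number of protein-coding genes.
#' @slot nMirnas number of miRNA hairpins (each contributes a 5p and 3p arm).
#' @slot classFractions named proportions over c(I, II, III, unclassified).
#' @slot foldChange multiplicative stage effect (unitless, >= 1); the ratio
#'   between the highest and lowest true abundance of a profiled gene.
#' @slot librarySizes 7 positive integers, total mapped reads per mRNA
#'   library, in the canonical sample order.
#' @slot smallRnaReads reads per small-RNA library.
#' @slot promoterLen promoter window, bp upstream of the start codon.
#' @slot utrLen 3'UTR-proxy window, bp downstream of the stop codon.
#' @slot motifPlantRate proportion of class II promoters carrying the
#'   planted motif.
#' @slot plantedMotif the AGGTA-containing 7-mer written into promoters.
#' @slot sitePlantRate proportion of anticorrelated genes per regulator
#'   miRNA arm that receive a planted binding site.
#' @slot abundanceJitter lognormal sd of per-gene, per-stage jitter applied
#'   to true abundances.
#' @slot minusStrandFrac fraction of genes placed on the minus strand.
#' @slot seed RNG seed.
#' @export
setClass("MztSimConfig", representation(
  nGenes = "integer",
  nMirnas = "integer",
  classFractions = "numeric",
  foldChange = "numeric",
  librarySizes = "numeric",
  smallRnaReads = "numeric",
  promoterLen = "integer",
  utrLen = "integer",
  motifPlantRate = "numeric",
  plantedMotif = "character",
  sitePlantRate = "numeric",
  abundanceJitter = "numeric",
  minusStrandFrac = "numeric",
  seed = "integer"
))

setValidity("MztSimConfig", function(object) {
  msg <- character()
  f <- object@classFractions
  if (!identical(sort(names(f)), sort(c("I", "II", "III", "unclassified"))))
    msg <- c(msg, "classFractions must be named I, II, III, unclassified")
  if (abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "classFractions must sum to 1")
  if (any(f < 0)) msg <- c(msg, "classFractions must be non-negative")
  if (object@foldChange < 1) msg <- c(msg, "foldChange must be >= 1")
  if (length(object@librarySizes) != 7 || any(object@librarySizes <= 0))
    msg <- c(msg, "librarySizes must be 7 positive values")
  if (object@promoterLen <= 0L || object@utrLen <= 0L)
    msg <- c(msg, "promoterLen and utrLen must be positive")
  if (object@nGenes < 0L || object@nMirnas < 0L)
    msg <- c(msg, "nGenes and nMirnas must be non-negative")
  if (object@motifPlantRate < 0 || object@motifPlantRate > 1 ||
      object@sitePlantRate < 0 || object@sitePlantRate > 1)
    msg <- c(msg, "plant rates must lie in [0, 1]")
  if (!grepl("AGGTA|TACCT", object@plantedMotif))
    msg <- c(msg, "plantedMotif must contain AGGTA or TACCT")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic-study configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 500 genes, 30 hairpins, an 8-fold stage effect and 1e6-read mRNA
#' libraries.
#'
#' @param nGenes,nMirnas problem sizes.
#' @param classFractions named proportions over I, II, III, unclassified.
#' @param foldChange stage effect (>= 1).
#' @param librarySizes 7 mRNA library depths (canonical sample order).
#' @param smallRnaReads small-RNA reads per library.
#' @param promoterLen,utrLen window sizes in bp.
#' @param motifPlantRate proportion of class II promoters with the motif.
#' @param plantedMotif AGGTA-containing 7-mer to plant.
#' @param sitePlantRate proportion of planted targets per regulator arm.
#' @param abundanceJitter lognormal sd of abundance jitter.
#' @param minusStrandFrac fraction of genes on the minus strand.
#' @param seed RNG seed.
#' @return An [MztSimConfig-class] object.
#' @examples
#' cfg <- MztSimConfig(nGenes = 50, nMirnas = 5, seed = 7)
#' @export
MztSimConfig <- function(nGenes = 500L, nMirnas = 30L,
                         classFractions = c(I = 0.25, II = 0.30, III = 0.15,
                                            unclassified = 0.30),
                         foldChange = 8,
                         librarySizes = rep(1e6, 7),
                         smallRnaReads = 2e4,
                         promoterLen = 1000L, utrLen = 1000L,
                         motifPlantRate = 0.9,
                         plantedMotif = "CAGGTAG",
                         sitePlantRate = 0.6,
                         abundanceJitter = 0.05,
                         minusStrandFrac = 0,
                         seed = 1L) {
  new("MztSimConfig",
      nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
      classFractions = classFractions, foldChange = foldChange,
      librarySizes = as.numeric(librarySizes),
      smallRnaReads = as.numeric(smallRnaReads),
      promoterLen = as.integer(promoterLen), utrLen = as.integer(utrLen),
      motifPlantRate = motifPlantRate, plantedMotif = plantedMotif,
      sitePlantRate = sitePlantRate, abundanceJitter = abundanceJitter,
      minusStrandFrac = minusStrandFrac, seed = as.integer(seed))
}

setMethod("show", "MztSimConfig", function(object) {
  cat("MztSimConfig:", object@nGenes, "genes,", object@nMirnas,
      "hairpins, fold change", object@foldChange,
      ", seed", object@seed, "\n")
  cat("  class fractions:",
      paste(names(object@classFractions), object@classFractions,
            sep = "=", collapse = " "), "\n")
})

#' A complete simulated MZT study
#'
#' Container for all artifacts of one synthetic study: genome and hairpin
#' sequences, the gene table, mRNA count matrix, small-RNA reads and the
#' planted ground truth. Produced by [simulateMztStudy()].
#'
#' @slot config the generating [MztSimConfig-class].
#' @slot genome `DNAStringSet` with one or more contigs.
#' @slot genes `data.frame` with gene_id, contig, strand, start_codon,
#'   stop_codon (1-based, inclusive) and tx_length.
#' @slot hairpins `DNAStringSet` of precursor sequences; arm coordinates in
#'   `armCoords`.
#' @slot armCoords `data.frame` with hairpin, arm, start, end (1-based).
#' @slot counts gene x 7-sample matrix of mRNA read counts.
#' @slot smallRna `DNAStringSet` of small-RNA reads; names encode
#'   `read id|sample`.
#' @slot truth list of planted ground truth (classes, abundances, motif
#'   carriers, target pairs).
#' @export
setClass("MztSimulation", representation(
  config = "MztSimConfig",
  genome = "DNAStringSet",
  genes = "data.frame",
  hairpins = "DNAStringSet",
  armCoords = "data.frame",
  counts = "matrix",
  smallRna = "DNAStringSet",
  truth = "list"
))

setMethod("show", "MztSimulation", function(object) {
  cat("MztSimulation:", nrow(object@genes), "genes,",
      length(object@hairpins), "hairpins,",
      length(object@smallRna), "small-RNA reads\n")
  cat("  contigs:", length(object@genome),
      " total", sum(Biostrings::width(object@genome)), "bp\n")
  cat("  planted target pairs:", nrow(object@truth$targets), "\n")
})

#' Accessors for MztSimulation components
#'
#' @param x an [MztSimulation-class].
#' @return The corresponding component.
#' @name simAccessors
NULL

#' @rdname simAccessors
#' @export
simGenome <- function(x) x@genome
#' @rdname simAccessors
#' @export
simGenes <- function(x) x@genes
#' @rdname simAccessors
#' @export
simHairpins <- function(x) x@hairpins
#' @rdname simAccessors
#' @export
simArmCoords <- function(x) x@armCoords
#' @rdname simAccessors
#' @export
simCounts <- function(x) x@counts
#' @rdname simAccessors
#' @export
simSmallRna <- function(x) x@smallRna
#' @rdname simAccessors
#' @export
simTruth <- function(x) x@truth
#' @rdname simAccessors
#' @export
simConfig <- function(x) x@config

#' Expression container for the MZT study
#'
#' A thin `SummarizedExperiment` subclass holding raw counts, RPKM values and
#' the below-cutoff flag for every feature (mRNA or miRNA arm) across the
#' seven samples. Column data carry the per-library mapped-read totals; row
#' data carry feature lengths and types.
#'
#' @export
setClass("MztExperiment", contains = "SummarizedExperiment")

setValidity("MztExperiment", function(object) {
  msg <- character()
  a <- SummarizedExperiment::assayNames(object)
  if (!all(c("counts", "rpkm", "belowCutoff") %in% a))
    msg <- c(msg, "assays counts, rpkm and belowCutoff are required")
  if (!"libSize" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain libSize")
  if (!"length" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain length")
  if (length(msg)) msg else TRUE
})
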