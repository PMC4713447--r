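## Expression quantification: RPKM with the 5-mapped-read cutoff,
## expressed-feature sets and stage-overlap partitions.

#' RPKM with a mapped-read cutoff
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `count * 1e9 / (libraryTotal * length)`. Features whose raw count falls
#' below `cutoff` mapped reads are reported as 0 and flagged; the flag is
#' returned as the `belowCutoff` attribute so that downstream rules can
#' still test "absent in oocyte" rather than dropping the feature.
#'
#' @param count raw read count(s), >= 0.
#' @param libraryTotal total mapped reads in the library (> 0).
#' @param length feature length in bp (> 0).
#' @param cutoff minimum mapped reads for a non-zero RPKM (default 5).
#' @return Numeric vector of RPKM values with attribute `belowCutoff`
#'   (logical vector).
#' @examples
#' rpkm(100, 1e7, 1000)   # 10
#' rpkm(4, 1e6, 500)      # 0, flagged
#' @export
rpkm <- function(count, libraryTotal, length, cutoff = 5) {
  if (any(libraryTotal <= 0)) stop("libraryTotal must be positive")
  if (any(length <= 0)) stop("length must be positive")
  if (any(count < 0)) stop("count must be non-negative")
  below <- count < cutoff
  val <- ifelse(below, 0, count * 1e9 / (libraryTotal * length))
  attr(val, "belowCutoff") <- below
  val
}

#' Build the expression container
#'
#' Assembles raw counts, RPKM values and below-cutoff flags for all
#' features into an [MztExperiment-class]. Counts are assumed to come from
#' uniquely mapped reads (the small-RNA mapper enforces this; mRNA count
#' tables must satisfy it upstream).
#'
#' @param counts feature x sample matrix of raw counts.
#' @param lengths feature lengths in bp (recycled against rows).
#' @param libSizes per-sample totals of mapped reads; defaults to the
#'   column sums of `counts`.
#' @param featureType `"mRNA"` or `"miRNA_arm"` per feature.
#' @param cutoff mapped-read cutoff (default 5).
#' @return An [MztExperiment-class].
#' @export
buildExpressionMatrix <- function(counts, lengths,
                                  libSizes = colSums(counts),
                                  featureType = "mRNA", cutoff = 5) {
  counts <- as.matrix(counts)
  lengths <- rep(unname(lengths), length.out = nrow(counts))
  libSizes <- rep(unname(libSizes), length.out = ncol(counts))
  rp <- counts
  below <- counts < cutoff
  for (j in seq_len(ncol(counts))) {
    v <- rpkm(counts[, j], libSizes[j], lengths, cutoff)
    attributes(v) <- NULL
    rp[, j] <- v
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, rpkm = rp, belowCutoff = below),
    rowData = S4Vectors::DataFrame(
      length = lengths,
      featureType = rep(featureType, length.out = nrow(counts))),
    colData = S4Vectors::DataFrame(libSize = libSizes,
                                   row.names = colnames(counts)))
  S4Vectors::metadata(se)$cutoff <- cutoff
  new("MztExperiment", se)
}

#' Features expressed in one sample
#'
#' A feature counts as expressed when its raw count reaches the mapped-read
#' cutoff (default 5) in that sample.
#'
#' @param x an [MztExperiment-class].
#' @param sample sample name.
#' @param cutoff mapped-read cutoff; defaults to the one stored in `x`.
#' @return Character vector of feature IDs.
#' @export
expressedSet <- function(x, sample, cutoff = S4Vectors::metadata(x)$cutoff) {
  if (!sample %in% colnames(x))
    stop("unknown sample: ", sample)
  cnt <- SummarizedExperiment::assay(x, "counts")[, sample]
  rownames(x)[cnt >= cutoff]
}

#' Partition features by expressed-set membership
#'
#' Assigns every feature in the union of the given expressed sets to
#' exactly one membership region (the Venn-diagram cells): region counts
#' always sum to the size of the union.
#'
#' @param sets named list of >= 2 character vectors.
#' @return data.frame with `region` (membership pattern, set names joined
#'   by `&`), `count` and `features` (list column).
#' @export
stageOverlap <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- paste0("set", seq_along(sets))
  all <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) all %in% s, logical(length(all)))
  if (length(all) == 1) member <- matrix(member, nrow = 1,
                                         dimnames = list(NULL, names(sets)))
  region <- apply(member, 1, function(r)
    paste(names(sets)[r], collapse = "&"))
  spl <- split(all, region)
  data.frame(region = names(spl),
             count = lengths(spl),
             features = I(unname(spl)),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-ploidy stage RPKM profiles
#'
#' Extracts the ordered 4-point RPKM profile (oocyte, 0-2 h, 0-6 h,
#' 18-24 h) of every feature for one ploidy; the oocyte library is shared
#' between ploidies.
#'
#' @param x an [MztExperiment-class].
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return Feature x 4 matrix of RPKM values, columns in stage order.
#' @export
stageProfiles <- function(x, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  s <- ploidySamples(ploidy)
  m <- SummarizedExperiment::assay(x, "rpkm")[, s, drop = FALSE]
  colnames(m) <- .MZT_STAGES
  m
}
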