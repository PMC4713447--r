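## Exact mapping of 19-24 nt small-RNA reads to miRNA hairpin precursors,
## unique-mapping filter, and 5p/3p arm assignment.

#' Map small-RNA reads exactly onto hairpin precursors
#'
#' Reads are first length-filtered to 19-24 nt, then matched as exact,
#' sense-strand substrings of the hairpins. A read sequence matching more
#' than one location (across or within hairpins) is discarded entirely:
#' only uniquely mapped reads are retained.
#'
#' @param reads `DNAStringSet` of reads; a name of the form
#'   `"<id>|<sample>"` attaches a sample label (otherwise all reads belong
#'   to `"sample1"`).
#' @param hairpins non-empty `DNAStringSet` of precursor sequences.
#' @return data.frame with read_id, sample, sequence, hairpin, start, end,
#'   length (positions 1-based inclusive on the hairpin).
#' @export
mapReadsToHairpins <- function(reads, hairpins) {
  if (length(hairpins) == 0) stop("empty hairpin set")
  if (is.null(names(hairpins)))
    names(hairpins) <- paste0("hairpin_", seq_along(hairpins))
  w <- Biostrings::width(reads)
  reads <- reads[w >= 19 & w <= 24]
  empty <- data.frame(read_id = character(), sample = character(),
                      sequence = character(), hairpin = character(),
                      start = integer(), end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (length(reads) == 0) return(empty)
  if (is.null(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))

  seqs <- as.character(reads)
  uniq <- unique(seqs)
  ## one hit table per distinct sequence
  hit <- data.frame(sequence = character(), hairpin = character(),
                    start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  for (wd in sort(unique(nchar(uniq)))) {
    grp <- uniq[nchar(uniq) == wd]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(grp))
    for (h in names(hairpins)) {
      m <- Biostrings::matchPDict(pd, hairpins[[h]])
      nm <- lengths(m)
      idx <- which(nm > 0)
      for (i in idx) {
        st <- BiocGenerics::start(m[[i]])
        hit <- rbind(hit, data.frame(sequence = grp[i], hairpin = h,
                                     start = st, end = st + wd - 1L,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  nHits <- table(hit$sequence)
  uniqueSeqs <- names(nHits)[nHits == 1]
  hit <- hit[hit$sequence %in% uniqueSeqs, , drop = FALSE]
  if (nrow(hit) == 0) return(empty)

  keep <- seqs %in% hit$sequence
  idx <- match(seqs[keep], hit$sequence)
  nm <- names(reads)[keep]
  hasSample <- grepl("|", nm, fixed = TRUE)
  sample <- ifelse(hasSample, sub("^.*\\|", "", nm), "sample1")
  readId <- ifelse(hasSample, sub("\\|.*$", "", nm), nm)
  data.frame(read_id = readId, sample = sample,
             sequence = seqs[keep],
             hairpin = hit$hairpin[idx],
             start = hit$start[idx], end = hit$end[idx],
             length = nchar(seqs[keep]),
             stringsAsFactors = FALSE)
}

#' Assign a mapped read to the 5p or 3p arm
#'
#' By default the read midpoint is compared with the hairpin midpoint:
#' reads lying in the 5' half are `"5p"`, in the 3' half `"3p"`, and reads
#' whose midpoint coincides with the hairpin midpoint are `"ambiguous"`
#' (excluded from arm counts). When annotated arm intervals are supplied,
#' an overlap of at least half the read length with an annotated arm takes
#' precedence; the midpoint rule is the fallback.
#'
#' @param start,end 1-based inclusive read positions on the hairpin.
#' @param hairpinLength hairpin length(s) in nt.
#' @param arm5,arm3 optional 2-column matrices (start, end) of annotated
#'   arm intervals, one row per alignment.
#' @return Character vector over `c("5p", "3p", "ambiguous")`.
#' @export
assignArm <- function(start, end, hairpinLength, arm5 = NULL, arm3 = NULL) {
  n <- max(length(start), length(end), length(hairpinLength))
  start <- rep(as.numeric(start), length.out = n)
  end <- rep(as.numeric(end), length.out = n)
  hairpinLength <- rep(as.numeric(hairpinLength), length.out = n)
  if (any(start < 1 | end > hairpinLength | start > end))
    stop("alignment outside hairpin bounds")
  readMid <- (start + end) / 2
  hpMid <- (1 + hairpinLength) / 2
  out <- ifelse(readMid < hpMid, "5p",
                ifelse(readMid > hpMid, "3p", "ambiguous"))
  if (!is.null(arm5) && !is.null(arm3)) {
    ov <- function(a) pmax(0, pmin(end, a[, 2]) - pmax(start, a[, 1]) + 1)
    o5 <- ov(arm5); o3 <- ov(arm3)
    len <- end - start + 1
    annot <- o5 >= len / 2 | o3 >= len / 2
    call <- ifelse(o5 > o3, "5p", ifelse(o3 > o5, "3p", "ambiguous"))
    out[annot] <- call[annot]
  }
  out
}

#' Tally arm-level read counts per sample
#'
#' Adds the arm call to an alignment table and counts retained reads per
#' (hairpin, arm, sample). Ambiguous reads are reported but carry their own
#' arm level, so 5p + 3p + ambiguous totals equal the retained alignments.
#'
#' @param alignments output of [mapReadsToHairpins()].
#' @param hairpins the `DNAStringSet` the reads were mapped to.
#' @param armCoords optional annotated arm coordinates (data.frame with
#'   hairpin, arm, start, end) enabling the annotation-overlap rule.
#' @return data.frame with hairpin, arm, sample, count.
#' @export
armCounts <- function(alignments, hairpins, armCoords = NULL) {
  if (nrow(alignments) == 0)
    return(data.frame(hairpin = character(), arm = character(),
                      sample = character(), count = integer(),
                      stringsAsFactors = FALSE))
  hpLen <- setNames(Biostrings::width(hairpins), names(hairpins))
  arm5 <- arm3 <- NULL
  if (!is.null(armCoords)) {
    a5 <- armCoords[armCoords$arm == "5p", ]
    a3 <- armCoords[armCoords$arm == "3p", ]
    i5 <- match(alignments$hairpin, a5$hairpin)
    i3 <- match(alignments$hairpin, a3$hairpin)
    arm5 <- cbind(a5$start[i5], a5$end[i5])
    arm3 <- cbind(a3$start[i3], a3$end[i3])
    arm5[is.na(arm5)] <- -1e9
    arm3[is.na(arm3)] <- -1e9
  }
  alignments$arm <- assignArm(alignments$start, alignments$end,
                              hpLen[alignments$hairpin], arm5, arm3)
  agg <- stats::aggregate(list(count = rep(1L, nrow(alignments))),
                          by = alignments[, c("hairpin", "arm", "sample")],
                          FUN = sum)
  agg[order(agg$hairpin, agg$arm, agg$sample), , drop = FALSE]
}

#' Arm count matrix for the expression container
#'
#' Reshapes the long arm-count table into an arm x sample matrix (rows
#' named `<hairpin>-<arm>`, ambiguous calls dropped), ready for
#' [buildExpressionMatrix()] with mature arm lengths as feature lengths.
#'
#' @param counts output of [armCounts()].
#' @param samples column order; defaults to the samples present.
#' @return Integer matrix.
#' @export
armCountMatrix <- function(counts, samples = sort(unique(counts$sample))) {
  counts <- counts[counts$arm %in% c("5p", "3p"), , drop = FALSE]
  id <- paste(counts$hairpin, counts$arm, sep = "-")
  rows <- sort(unique(id))
  m <- matrix(0L, length(rows), length(samples),
              dimnames = list(rows, samples))
  for (i in seq_len(nrow(counts)))
    m[id[i], counts$sample[i]] <- m[id[i], counts$sample[i]] + counts$count[i]
  m
}
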