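## TAGteam candidate discovery: promoter extraction, exhaustive k-mer
## coverage scoring, the AGGTA/TACCT filter, PWM construction and
## comparison against bundled reference TAGteam PWMs.

.BASES <- c("A", "C", "G", "T")

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

#' Extract promoter windows
#'
#' Returns the coding-strand sequence of the `len` bp immediately upstream
#' of each start codon: for plus-strand genes bases
#' `[start_codon - len, start_codon - 1]`, for minus-strand genes the
#' reverse complement of `[start_codon + 1, start_codon + len]` (1-based
#' inclusive). Windows running off the contig are truncated with a
#' warning.
#'
#' @param genes gene table (gene_id, contig, strand, start_codon, ...).
#' @param genome `DNAStringSet` of contigs.
#' @param len window size in bp (default 1000).
#' @return Named `DNAStringSet` of promoter sequences.
#' @export
extractPromoters <- function(genes, genome, len = 1000L) {
  .extractWindows(genes, genome, len, anchor = "start_codon",
                  side = "upstream")
}

#' Extract 3'UTR-proxy windows
#'
#' Returns the coding-strand sequence of the `len` bp immediately
#' downstream of each stop codon (the study's stand-in for unannotated
#' 3'UTRs); minus-strand genes are reverse-complemented. Windows running
#' off the contig are truncated with a warning.
#'
#' @inheritParams extractPromoters
#' @return Named `DNAStringSet` of UTR-proxy sequences.
#' @export
extractUtrProxies <- function(genes, genome, len = 1000L) {
  .extractWindows(genes, genome, len, anchor = "stop_codon",
                  side = "downstream")
}

.extractWindows <- function(genes, genome, len, anchor, side) {
  out <- character(nrow(genes))
  truncated <- FALSE
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    pos <- g[[anchor]]
    upstream <- (side == "upstream") == (g$strand == "+")
    win <- if (upstream) c(pos - len, pos - 1L) else c(pos + 1L, pos + len)
    contigLen <- Biostrings::width(genome[g$contig])
    clipped <- c(max(1L, win[1]), min(contigLen, win[2]))
    if (!identical(clipped, win)) truncated <- TRUE
    s <- Biostrings::subseq(genome[[g$contig]], clipped[1], clipped[2])
    if (g$strand == "-") s <- Biostrings::reverseComplement(s)
    out[i] <- as.character(s)
  }
  if (truncated) warning("window(s) truncated at contig bounds")
  res <- Biostrings::DNAStringSet(out)
  names(res) <- genes$gene_id
  res
}

#' Exhaustive k-mer coverage scoring
#'
#' Scores every k-mer (default k = 5..8) occurring in a promoter set by
#' its coverage: the fraction of promoters containing at least one
#' occurrence of the k-mer or of its reverse complement. Candidates with
#' coverage strictly greater than `minCoverage` are retained. Windows
#' containing N never match.
#'
#' @param promoters `DNAStringSet` of promoter sequences.
#' @param k integer vector of k-mer sizes (default 5:8).
#' @param minCoverage retention threshold (strict inequality, default 0.8).
#' @return data.frame with kmer, k, coverage, sorted by coverage then
#'   k-mer.
#' @export
kmerCoverage <- function(promoters, k = 5:8, minCoverage = 0.8) {
  if (length(promoters) == 0) stop("empty promoter set")
  out <- list()
  for (kk in k) {
    freq <- Biostrings::oligonucleotideFrequency(promoters, width = kk)
    present <- freq > 0
    rc <- .revcomp(colnames(freq))
    either <- present | present[, rc, drop = FALSE]
    cov <- colMeans(either)
    keep <- cov > minCoverage & cov > 0
    if (any(keep))
      out[[length(out) + 1]] <- data.frame(kmer = colnames(freq)[keep],
                                           k = kk, coverage = cov[keep],
                                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(kmer = character(), k = integer(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(-res$coverage, res$kmer), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep AGGTA-containing candidates
#'
#' Retains candidates whose consensus contains the TAGteam core AGGTA or
#' its reverse complement TACCT as a substring.
#'
#' @param candidates output of [kmerCoverage()].
#' @param core core motif (default `"AGGTA"`).
#' @return The filtered candidate table.
#' @export
filterTagteam <- function(candidates, core = "AGGTA") {
  rc <- .revcomp(core)
  keep <- grepl(core, candidates$kmer, fixed = TRUE) |
    grepl(rc, candidates$kmer, fixed = TRUE)
  candidates[keep, , drop = FALSE]
}

#' Locate instances of a k-mer in a promoter set
#'
#' Finds every occurrence of the k-mer on either strand of each promoter.
#'
#' @param kmer consensus string.
#' @param promoters named `DNAStringSet`.
#' @return data.frame with gene, position (1-based start on the promoter),
#'   strand.
#' @export
motifInstances <- function(kmer, promoters) {
  rc <- .revcomp(kmer)
  rows <- list()
  for (g in names(promoters)) {
    for (str in c("+", "-")) {
      pat <- if (str == "+") kmer else rc
      m <- Biostrings::matchPattern(pat, promoters[[g]])
      st <- BiocGenerics::start(m)
      if (length(st) > 0)
        rows[[length(rows) + 1]] <- data.frame(gene = g, position = st,
                                               strand = str,
                                               stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Build a position weight matrix from motif instances
#'
#' Aligns all instances (minus-strand occurrences are reverse-complemented
#' onto the consensus orientation), optionally extends each by `flank`
#' context bases, adds a pseudocount per base and normalizes columns to
#' sum to one. Instances whose flanks would run off the promoter are
#' dropped from the alignment.
#'
#' @param instances output of [motifInstances()].
#' @param promoters the promoter set the instances came from.
#' @param width k-mer width.
#' @param flank context bases on each side (default 1).
#' @param pseudocount added to every cell before normalization
#'   (default 0.25).
#' @return 4 x (width + 2 flank) column-stochastic matrix, rows A, C, G, T.
#' @export
buildPwm <- function(instances, promoters, width, flank = 1L,
                     pseudocount = 0.25) {
  if (nrow(instances) == 0) stop("need at least one instance")
  seqs <- character()
  for (i in seq_len(nrow(instances))) {
    p <- promoters[[instances$gene[i]]]
    st <- instances$position[i] - flank
    en <- instances$position[i] + width - 1L + flank
    if (st < 1 || en > length(p)) next
    s <- Biostrings::subseq(p, st, en)
    if (instances$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs <- c(seqs, as.character(s))
  }
  if (length(seqs) == 0) stop("no instance with full flanks")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  cm <- cm[.BASES, , drop = FALSE]
  cm <- cm + pseudocount
  sweep(cm, 2, colSums(cm), "/")
}

#' Reverse complement of a PWM
#'
#' @param pwm 4 x w matrix with rows A, C, G, T.
#' @return The reverse-complemented PWM.
#' @export
reverseComplementPwm <- function(pwm) {
  out <- pwm[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm))), drop = FALSE]
  rownames(out) <- .BASES
  out
}

#' Align two PWMs by sliding column correlation
#'
#' Slides the candidate over the reference in both orientations, requiring
#' at least `minOverlap` overlapping columns, and scores each placement by
#' the mean Pearson correlation between the overlapping 4-vectors. Returns
#' the best placement.
#'
#' @param candidate,reference 4 x w column-stochastic matrices (rows
#'   A, C, G, T).
#' @param minOverlap minimum number of overlapping columns (default 3).
#' @return list with `offset` (candidate column 1 minus reference column
#'   1), `orientation` (`"forward"` or `"reverse"`) and `similarity`.
#' @export
comparePwm <- function(candidate, reference, minOverlap = 3L) {
  wc <- ncol(candidate); wr <- ncol(reference)
  if (min(wc, wr) < minOverlap)
    stop("PWMs too short for the required overlap")
  colCor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  best <- list(offset = NA_integer_, orientation = NA_character_,
               similarity = -Inf)
  for (orient in c("forward", "reverse")) {
    cand <- if (orient == "forward") candidate
            else reverseComplementPwm(candidate)
    for (off in seq(-(wc - minOverlap), wr - minOverlap)) {
      ci <- seq_len(wc)
      ri <- ci + off
      keep <- ri >= 1 & ri <= wr
      if (sum(keep) < minOverlap) next
      sim <- mean(vapply(which(keep), function(j)
        colCor(cand[, j], reference[, ri[j]]), numeric(1)))
      if (sim > best$similarity)
        best <- list(offset = off, orientation = orient, similarity = sim)
    }
  }
  best
}

#' Bundled reference TAGteam PWMs
#'
#' Loads the reference TAGteam position weight matrices shipped with the
#' package. These are synthetic consensus-derived matrices built from the
#' published Drosophila TAGteam consensus sequences (CAGGTAG, CAGGCAG,
#' TAGGTAG) with 0.91 weight on the consensus base; see the file header
#' for provenance.
#'
#' @return Named list of 4 x 7 column-stochastic matrices.
#' @export
tagteamReferencePwms <- function() {
  path <- system.file("extdata", "tagteam_reference_pwms.tsv",
                      package = "beeMZT")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list()
  for (m in unique(tab$motif)) {
    sub <- tab[tab$motif == m, ]
    mat <- as.matrix(sub[match(.BASES, sub$base),
                         grep("^pos", colnames(sub)), drop = FALSE])
    rownames(mat) <- .BASES
    colnames(mat) <- NULL
    out[[m]] <- sweep(mat, 2, colSums(mat), "/")
  }
  out
}

#' Count promoters carrying a motif
#'
#' Reports, per gene, whether the motif occurs on either strand of its
#' promoter (with positions), and the per-set count of genes with at
#' least one occurrence.
#'
#' @param motif consensus string.
#' @param promoters named `DNAStringSet`.
#' @return list with `perGene` (gene, hasMotif, nSites) and `count`.
#' @export
scanPromoters <- function(motif, promoters) {
  inst <- motifInstances(motif, promoters)
  genes <- names(promoters)
  n <- table(factor(inst$gene, levels = genes))
  perGene <- data.frame(gene = genes, hasMotif = as.integer(n) > 0,
                        nSites = as.integer(n), stringsAsFactors = FALSE)
  list(perGene = perGene, count = sum(perGene$hasMotif),
       instances = inst)
}
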