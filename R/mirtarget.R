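## miRNA-target network inference: stage-profile anticorrelation, seed-
## anchored duplex search with a nearest-neighbor stacking energy model,
## the -15 kcal/mol minimum-free-energy threshold, and network export.

.RNA_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

.toRna <- function(x) chartr("Tt", "Uu", toupper(x))

.pairOk <- function(a, b) paste0(a, b) %in% .RNA_PAIRS

#' Load the duplex energy parameters
#'
#' Reads the nearest-neighbor stack table and loop/bulge penalties. The
#' bundled default file carries the standard Watson-Crick helix stack
#' free energies (dG37, kcal/mol) with a uniform simplified value for
#' stacks involving G:U pairs, and linear bulge/internal-loop costs; see
#' the file header. The file is editable: any 36-entry stack table over
#' pairs AU, UA, GC, CG, GU, UG can be substituted.
#'
#' @param path optional path to an alternative parameter file.
#' @return list with `stack` (named vector, keys `"<pair1>.<pair2>"` for a
#'   helix step read 5'->3' along the miRNA), `bulgeInit`, `bulgePerNt`,
#'   `loopInit`, `loopPerNt`.
#' @export
loadEnergyParams <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "energy_params.tsv", package = "beeMZT")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- tab[tab$type == "stack", ]
  stack <- setNames(st$value, st$key)
  sc <- tab[tab$type == "scalar", ]
  scalars <- setNames(sc$value, sc$key)
  list(stack = stack,
       bulgeInit = scalars[["bulge_init"]],
       bulgePerNt = scalars[["bulge_per_nt"]],
       loopInit = scalars[["loop_init"]],
       loopPerNt = scalars[["loop_per_nt"]])
}

## Penalty for an unpaired gap between consecutive helix pairs: g1 unpaired
## miRNA bases and g2 unpaired target bases (g1 + g2 >= 1).
.gapPenalty <- function(g1, g2, params) {
  if (g1 == 0 || g2 == 0) {
    b <- g1 + g2
    params$bulgeInit + params$bulgePerNt * (b - 1)
  } else {
    params$loopInit + params$loopPerNt * (g1 + g2 - 2)
  }
}

#' Free energy of an explicit duplex pairing
#'
#' Sums nearest-neighbor stack energies over adjacent base pairs, plus
#' bulge/internal-loop penalties for interruptions. No duplex-initiation
#' term is applied. A single isolated pair has energy 0 (nothing to stack
#' with).
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param target target site sequence 5'->3' (RNA or DNA alphabet).
#' @param pairs data.frame with columns `i` (miRNA position) and `j`
#'   (target position); pairing is antiparallel, so `j` must strictly
#'   decrease as `i` increases (non-crossing, each position once).
#' @param params energy parameters from [loadEnergyParams()].
#' @return dG in kcal/mol.
#' @export
duplexEnergy <- function(mirna, target, pairs, params = loadEnergyParams()) {
  mir <- strsplit(.toRna(mirna), "")[[1]]
  tg <- strsplit(.toRna(target), "")[[1]]
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  if (anyDuplicated(pairs$i) || anyDuplicated(pairs$j))
    stop("each position may pair only once")
  if (nrow(pairs) > 1 && any(diff(pairs$j) >= 0))
    stop("pairing must be non-crossing and antiparallel")
  pstr <- paste0(mir[pairs$i], tg[pairs$j])
  if (!all(pstr %in% .RNA_PAIRS))
    stop("invalid base pair: ",
         paste(unique(pstr[!pstr %in% .RNA_PAIRS]), collapse = ", "))
  if (nrow(pairs) < 2) return(0)
  dG <- 0
  for (r in 2:nrow(pairs)) {
    di <- pairs$i[r] - pairs$i[r - 1] - 1L
    dj <- pairs$j[r - 1] - pairs$j[r] - 1L
    if (di == 0 && dj == 0) {
      dG <- dG + params$stack[[paste0(pstr[r - 1], ".", pstr[r])]]
    } else {
      dG <- dG + .gapPenalty(di, dj, params)
    }
  }
  dG
}

## Seed patterns: DNA substrings of the target that pair with miRNA
## positions 2-7 contiguously, Watson-Crick with at most one G:U wobble.
## The returned patterns read 5'->3' on the target (reverse of the seed).
.seedPatterns <- function(mirSeed) {
  wc <- c(A = "T", C = "G", G = "C", U = "A")
  gu <- c(G = "T", U = "G")
  bases <- strsplit(mirSeed, "")[[1]]
  exact <- rev(wc[bases])
  pats <- paste(exact, collapse = "")
  for (p in seq_along(bases)) {
    b <- bases[p]
    if (b %in% names(gu)) {
      v <- exact
      v[length(bases) - p + 1] <- gu[[b]]
      pats <- c(pats, paste(v, collapse = ""))
    }
  }
  unique(pats)
}

## Duplex DP between the miRNA (5'->3') and a reversed target window
## (so index k runs 3'->5' on the target and pairing is position-aligned).
## Returns the minimum energy and the traceback pairing, or NULL if no
## pair is possible.
.duplexDp <- function(mir, revWin, params, maxGap = 8L) {
  m <- length(mir); w <- length(revWin)
  pairStr <- outer(mir, revWin, paste0)
  ok <- matrix(pairStr %in% .RNA_PAIRS, m, w)
  best <- matrix(Inf, m, w)
  parI <- matrix(0L, m, w); parK <- matrix(0L, m, w)
  gapPen <- outer(0:(maxGap - 1), 0:(maxGap - 1),
                  Vectorize(function(g1, g2)
                    if (g1 + g2 == 0) NA_real_
                    else .gapPenalty(g1, g2, params)))
  for (i in seq_len(m)) {
    okRow <- ok[i, ]
    if (!any(okRow)) next
    cand <- rep(0, w)          # start a new helix: energy 0
    pi <- rep(0L, w); pk <- rep(0L, w)
    if (i > 1) {
      ## stack transition from (i-1, k-1)
      prev <- c(Inf, best[i - 1, -w])
      prevOk <- c(FALSE, ok[i - 1, -w])
      key <- paste0(c("", pairStr[i - 1, -w]), ".", pairStr[i, ])
      sE <- unname(params$stack[key])
      sE[is.na(sE)] <- Inf
      stackCand <- ifelse(prevOk, prev + sE, Inf)
      upd <- stackCand < cand
      cand[upd] <- stackCand[upd]
      pi[upd] <- i - 1L
      pk[upd] <- (seq_len(w) - 1L)[upd]
      ## gap transitions
      for (di in 1:min(maxGap, i - 1)) {
        for (dk in 1:maxGap) {
          if (di == 1 && dk == 1) next
          pen <- gapPen[di, dk]
          if (dk >= w) next
          shifted <- c(rep(Inf, dk), best[i - di, seq_len(w - dk)])
          gc <- shifted + pen
          upd <- gc < cand
          if (any(upd)) {
            cand[upd] <- gc[upd]
            pi[upd] <- i - di
            pk[upd] <- (seq_len(w) - dk)[upd]
          }
        }
      }
    }
    cand[!okRow] <- Inf
    pi[!okRow] <- 0L; pk[!okRow] <- 0L
    best[i, ] <- cand
    parI[i, ] <- pi; parK[i, ] <- pk
  }
  if (!any(is.finite(best))) return(NULL)
  idx <- arrayInd(which.min(best), dim(best))
  i <- idx[1]; k <- idx[2]
  pairsI <- integer(); pairsK <- integer()
  while (i > 0) {
    pairsI <- c(i, pairsI); pairsK <- c(k, pairsK)
    i2 <- parI[i, k]; k2 <- parK[i, k]
    i <- i2; k <- k2
  }
  list(dG = min(best), i = pairsI, k = pairsK)
}

#' Find miRNA binding sites in a 3'UTR proxy
#'
#' Scans for anchors where miRNA seed positions 2-7 pair contiguously with
#' the UTR (Watson-Crick with at most one G:U), then extends each anchor
#' by a dynamic-programming duplex alignment of the full miRNA against a
#' UTR window of length `length(mirna) + 15`, allowing bulges and internal
#' loops under the nearest-neighbor energy model. Sites with dG below
#' `minEnergy` are returned. T and U are interchangeable on input.
#'
#' @param mirna mature miRNA sequence, 19-24 nt, 5'->3'.
#' @param utr UTR-proxy sequence (DNA), 5'->3'.
#' @param params energy parameters ([loadEnergyParams()]).
#' @param minEnergy retention threshold in kcal/mol (strict `<`,
#'   default -15).
#' @return data.frame with start, end (1-based site interval on the UTR),
#'   dG, seedGu (0 or 1 wobbles in the anchor match); the pairing map of
#'   each site is attached as the `pairs` attribute (list of data.frames
#'   with i = miRNA position, j = UTR position).
#' @export
findSites <- function(mirna, utr, params = loadEnergyParams(),
                      minEnergy = -15) {
  mirR <- .toRna(mirna)
  m <- nchar(mirR)
  if (m < 19 || m > 24) stop("miRNA must be 19-24 nt")
  utrDna <- chartr("Uu", "Tt", toupper(utr))
  len <- nchar(utrDna)
  mirV <- strsplit(mirR, "")[[1]]
  seed <- substr(mirR, 2, 7)
  pats <- .seedPatterns(seed)
  exactPat <- pats[1]

  anchors <- integer(); wob <- integer()
  for (p in pats) {
    hits <- gregexpr(p, utrDna, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    if (length(hits) > 0) {
      anchors <- c(anchors, hits)
      wob <- c(wob, rep(if (p == exactPat) 0L else 1L, length(hits)))
    }
  }
  if (length(anchors) == 0)
    return(structure(data.frame(start = integer(), end = integer(),
                                dG = numeric(), seedGu = integer()),
                     pairs = list()))
  o <- order(anchors, wob)
  anchors <- anchors[o]; wob <- wob[o]
  dup <- duplicated(anchors)
  anchors <- anchors[!dup]; wob <- wob[!dup]

  out <- data.frame(start = integer(), end = integer(), dG = numeric(),
                    seedGu = integer())
  pairsList <- list()
  winLen <- m + 15L
  for (a in seq_along(anchors)) {
    q <- anchors[a]
    ## seed occupies UTR [q, q+5] pairing miRNA 7..2; miRNA position 1
    ## pairs just 3' of it, the 3' end of the miRNA extends 5' on the UTR
    wEnd <- min(len, q + 5L + 3L)
    wStart <- max(1L, wEnd - winLen + 1L)
    win <- strsplit(.toRna(substr(utrDna, wStart, wEnd)), "")[[1]]
    revWin <- rev(win)
    dp <- .duplexDp(mirV, revWin, params)
    if (is.null(dp) || dp$dG >= minEnergy) next
    utrPos <- wEnd - dp$k + 1L
    out <- rbind(out, data.frame(start = min(utrPos), end = max(utrPos),
                                 dG = dp$dG, seedGu = wob[a]))
    pairsList[[nrow(out)]] <- data.frame(i = dp$i, j = utrPos)
  }
  ## collapse duplicate sites found from adjacent anchors
  if (nrow(out) > 1) {
    key <- paste(out$start, out$end, signif(out$dG, 10))
    keep <- !duplicated(key)
    pairsList <- pairsList[keep]
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  structure(out, pairs = pairsList)
}

#' Pearson correlation between two stage profiles
#'
#' Standard Pearson correlation over the four ordered stage points.
#' Profiles with zero variance are rejected: on four points a constant
#' profile carries no direction and cannot support an edge.
#'
#' @param x,y numeric vectors of equal length (RPKM profiles).
#' @return Correlation coefficient.
#' @export
profileCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("profiles must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant profile: correlation undefined")
  stats::cor(x, y)
}

#' Infer the miRNA-target network for one ploidy
#'
#' Applies the two-stage rule: candidate (arm, gene) pairs are those with
#' Pearson R strictly below `rThreshold` across the four stage RPKM
#' points, and a pair becomes an edge when the UTR proxy carries at least
#' one duplex site with dG strictly below `energyThreshold`. Features with
#' constant (typically all-zero) profiles are excluded and logged in the
#' `excluded` component.
#'
#' @param armProfiles arm x 4 matrix of RPKM stage profiles.
#' @param geneProfiles gene x 4 matrix of RPKM stage profiles.
#' @param armSeqs named character vector of mature arm sequences
#'   (DNA or RNA).
#' @param utrs named `DNAStringSet` of UTR proxies.
#' @param params energy parameters.
#' @param rThreshold correlation threshold (default -0.8, strict).
#' @param energyThreshold dG threshold in kcal/mol (default -15, strict).
#' @param siteCache optional environment reusing duplex scans across
#'   calls (site discovery is sequence-only, so both ploidies share it).
#' @return list with `edges` (arm, gene, R, dG, siteStart, siteEnd),
#'   `candidates` (count of pairs passing the correlation filter) and
#'   `excluded` (features dropped for zero variance).
#' @export
buildTargetNetwork <- function(armProfiles, geneProfiles, armSeqs, utrs,
                               params = loadEnergyParams(),
                               rThreshold = -0.8, energyThreshold = -15,
                               siteCache = new.env(parent = emptyenv())) {
  armVar <- apply(armProfiles, 1, stats::sd)
  geneVar <- apply(geneProfiles, 1, stats::sd)
  excluded <- c(rownames(armProfiles)[armVar == 0],
                rownames(geneProfiles)[geneVar == 0])
  armProfiles <- armProfiles[armVar > 0, , drop = FALSE]
  geneProfiles <- geneProfiles[geneVar > 0, , drop = FALSE]

  edges <- data.frame(arm = character(), gene = character(), R = numeric(),
                      dG = numeric(), siteStart = integer(),
                      siteEnd = integer(), stringsAsFactors = FALSE)
  if (nrow(armProfiles) == 0 || nrow(geneProfiles) == 0)
    return(list(edges = edges, candidates = 0L, excluded = excluded))

  R <- stats::cor(t(armProfiles), t(geneProfiles))
  cand <- which(R < rThreshold, arr.ind = TRUE)
  rows <- vector("list", nrow(cand))
  for (r in seq_len(nrow(cand))) {
    arm <- rownames(armProfiles)[cand[r, 1]]
    gene <- rownames(geneProfiles)[cand[r, 2]]
    if (!arm %in% names(armSeqs) || !gene %in% names(utrs)) next
    key <- paste0(arm, "\r", gene)
    if (is.null(siteCache[[key]])) {
      sites <- findSites(armSeqs[[arm]], as.character(utrs[[gene]]),
                         params, minEnergy = energyThreshold)
      siteCache[[key]] <- if (nrow(sites) == 0) NA else
        sites[which.min(sites$dG), , drop = FALSE]
    }
    bestSite <- siteCache[[key]]
    if (identical(bestSite, NA)) next
    rows[[r]] <- data.frame(arm = arm, gene = gene,
                            R = R[cand[r, 1], cand[r, 2]],
                            dG = bestSite$dG,
                            siteStart = bestSite$start,
                            siteEnd = bestSite$end,
                            stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) > 0) edges <- do.call(rbind, rows)
  list(edges = edges, candidates = nrow(cand), excluded = excluded)
}

#' Export a network as SIF and edge-attribute tables
#'
#' Writes a Cytoscape-compatible SIF file (`arm targets gene`), a TSV edge
#' list with correlation, energy and site coordinates, and optionally a
#' node-attribute table with MZT class labels for network coloring.
#'
#' @param edges edge table from [buildTargetNetwork()].
#' @param file base path; `.sif` and `.tsv` are appended.
#' @param labels optional classification table (feature, label) used for
#'   node attributes.
#' @return Invisibly, the files written.
#' @export
exportNetwork <- function(edges, file, labels = NULL) {
  sif <- paste0(file, ".sif")
  writeLines(if (nrow(edges) > 0)
    paste(edges$arm, "targets", edges$gene) else character(), sif)
  tsv <- paste0(file, ".tsv")
  write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(sif, tsv)
  if (!is.null(labels)) {
    nodes <- unique(c(edges$arm, edges$gene))
    na <- data.frame(node = nodes,
                     label = labels$label[match(nodes, labels$feature)],
                     stringsAsFactors = FALSE)
    nat <- paste0(file, "_nodes.tsv")
    write.table(na, nat, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, nat)
  }
  invisible(written)
}
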