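## Class I / II / III maternal-zygotic classifier over the four canonical
## stage-pair comparisons of one ploidy.
##
## Class I: maternal transcripts declining through development (or detected
## only in the oocyte). Class II: strictly zygotic (absent in the oocyte,
## detected in every embryo stage) or rising as embryogenesis progresses.
## Class III: maternal transcripts degraded during cleavage and resupplied
## zygotically by 18-24 h (V-shaped profile).

.CMP_STATES <- c("up1_sig", "up2_sig", "ns")

#' Build per-feature significance patterns
#'
#' Encodes, for every feature, the direction-and-significance state of each
#' of the four canonical comparisons (`up1_sig`: first sample higher,
#' significant; `up2_sig`: second higher; `ns`: neither) together with
#' detection flags (raw count at or above the cutoff) in the oocyte and in
#' each embryo stage. Zero-substituted comparisons keep their significance
#' call but are marked in the `anyFlagged` column for audit.
#'
#' @param comparisons output of [canonicalComparisons()].
#' @param x the [MztExperiment-class] the comparisons came from.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return data.frame with feature, s1..s4, detectedOocyte, detectedE2,
#'   detectedE6, detectedE24, anyFlagged.
#' @export
buildPattern <- function(comparisons, x, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  need <- names(.stagePairs(ploidy))
  if (!all(need %in% names(comparisons)))
    stop("missing comparison(s): ",
         paste(setdiff(need, names(comparisons)), collapse = ", "))
  state <- function(cmp)
    ifelse(cmp$significant & cmp$Z > 0, "up1_sig",
           ifelse(cmp$significant & cmp$Z < 0, "up2_sig", "ns"))
  cnt <- SummarizedExperiment::assay(x, "counts")
  cutoff <- S4Vectors::metadata(x)$cutoff
  s <- ploidySamples(ploidy)
  feat <- comparisons[[need[1]]]$feature
  data.frame(feature = feat,
             s1 = state(comparisons[[need[1]]]),
             s2 = state(comparisons[[need[2]]]),
             s3 = state(comparisons[[need[3]]]),
             s4 = state(comparisons[[need[4]]]),
             detectedOocyte = cnt[feat, s[1]] >= cutoff,
             detectedE2 = cnt[feat, s[2]] >= cutoff,
             detectedE6 = cnt[feat, s[3]] >= cutoff,
             detectedE24 = cnt[feat, s[4]] >= cutoff,
             anyFlagged = comparisons[[need[1]]]$flagged |
               comparisons[[need[2]]]$flagged |
               comparisons[[need[3]]]$flagged |
               comparisons[[need[4]]]$flagged,
             stringsAsFactors = FALSE)
}

#' Classify significance patterns into MZT classes
#'
#' Applies the class predicates to a pattern table. The three class
#' predicates are mutually exclusive by construction (class I requires a
#' significant fall into 18-24 h, class III a significant rise after a
#' maternal fall, class II a rise versus the oocyte or strict absence from
#' it); an internal assertion verifies that no pattern satisfies two
#' predicates, so evaluation order cannot matter. Patterns with
#' significant calls in opposite early directions fail every predicate and
#' are `unclassified`.
#'
#' @param pattern output of [buildPattern()] (columns s1, s3, s4 and the
#'   detection flags are used; s2 is carried for audit only).
#' @return data.frame with feature, label (one of I, II, III,
#'   unclassified, not_expressed) and rule (audit string).
#' @export
classifyMzt <- function(pattern) {
  s1 <- pattern$s1; s3 <- pattern$s3; s4 <- pattern$s4
  ooc <- pattern$detectedOocyte
  e2 <- pattern$detectedE2; e6 <- pattern$detectedE6
  e24 <- pattern$detectedE24
  allNs <- s1 == "ns" & pattern$s2 == "ns" & s3 == "ns" & s4 == "ns"
  detAllEmb <- e2 & e6 & e24
  detNoEmb <- !e2 & !e6 & !e24

  fallEarly <- (s1 == "up1_sig" | s3 == "up1_sig") &
    s1 != "up2_sig" & s3 != "up2_sig"
  riseEarly <- (s1 == "up2_sig" | s3 == "up2_sig") &
    s1 != "up1_sig" & s3 != "up1_sig"

  notExpr <- !ooc & detNoEmb & allNs
  isI_fall <- fallEarly & s4 == "up1_sig"
  isI_ooc <- ooc & detNoEmb & !riseEarly & s4 != "up2_sig"
  isIII <- s1 == "up1_sig" & s3 == "up1_sig" & s4 == "up2_sig"
  isII_rise <- riseEarly & s4 == "up2_sig"
  isII_sz <- !ooc & detAllEmb & !fallEarly

  isI <- isI_fall | isI_ooc
  isII <- isII_rise | isII_sz
  hits <- cbind(notExpr, isI, isII, isIII)
  stopifnot(all(rowSums(hits) <= 1))

  label <- rep("unclassified", nrow(pattern))
  rule <- rep("fall_through", nrow(pattern))
  label[notExpr] <- "not_expressed"; rule[notExpr] <- "below_cutoff_everywhere"
  label[isI] <- "I"
  rule[isI_fall] <- "maternal_fall"
  rule[isI_ooc] <- "oocyte_only"
  label[isII] <- "II"
  rule[isII_rise] <- "zygotic_rise"
  rule[isII_sz & !isII_rise] <- "strictly_zygotic"
  label[isIII] <- "III"; rule[isIII] <- "maternal_fall_then_rise"
  data.frame(feature = pattern$feature, label = label, rule = rule,
             stringsAsFactors = FALSE)
}

#' Classify every feature for one or both ploidies
#'
#' Runs the four canonical comparisons, builds the significance patterns
#' and applies the class predicates, returning one label per (feature,
#' ploidy) plus a class-count summary per feature type.
#'
#' @param x an [MztExperiment-class].
#' @param ploidy ploidies to classify (default both).
#' @param alpha significance level for the comparisons.
#' @return list with `labels` (feature, ploidy, featureType, label, rule)
#'   and `summary` (ploidy x featureType x label counts, long format).
#' @export
classifyAll <- function(x, ploidy = c("diploid", "haploid"), alpha = 0.05) {
  res <- do.call(rbind, lapply(ploidy, function(pl) {
    cmp <- canonicalComparisons(x, pl, alpha = alpha)
    pat <- buildPattern(cmp, x, pl)
    lab <- classifyMzt(pat)
    ft <- as.character(SummarizedExperiment::rowData(x)$featureType)
    cbind(data.frame(ploidy = rep(pl, nrow(lab)),
                     stringsAsFactors = FALSE),
          lab, featureType = ft[match(lab$feature, rownames(x))])
  }))
  if (nrow(res) == 0) {
    summ <- data.frame(ploidy = character(), featureType = character(),
                       label = character(), count = integer())
  } else {
    summ <- stats::aggregate(list(count = rep(1L, nrow(res))),
                             by = res[, c("ploidy", "featureType",
                                          "label")],
                             FUN = sum)
  }
  list(labels = res, summary = summ)
}

#' Enumerate all abstract significance patterns
#'
#' Generates all 3^4 x 2^2 combinations of comparison states and presence
#' flags (embryo-stage detection tied: a feature is detected in all three
#' embryo stages or in none). Used by the classifier property tests.
#'
#' @return A pattern data.frame acceptable to [classifyMzt()].
#' @export
enumeratePatterns <- function() {
  g <- expand.grid(s1 = .CMP_STATES, s2 = .CMP_STATES, s3 = .CMP_STATES,
                   s4 = .CMP_STATES, detectedOocyte = c(TRUE, FALSE),
                   allEmbryo = c(TRUE, FALSE),
                   stringsAsFactors = FALSE)
  data.frame(feature = sprintf("pattern_%03d", seq_len(nrow(g))),
             s1 = g$s1, s2 = g$s2, s3 = g$s3, s4 = g$s4,
             detectedOocyte = g$detectedOocyte,
             detectedE2 = g$allEmbryo, detectedE6 = g$allEmbryo,
             detectedE24 = g$allEmbryo,
             anyFlagged = FALSE, stringsAsFactors = FALSE)
}
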