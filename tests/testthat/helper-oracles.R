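# toy energy model: every WC stack -2, every G:U stack -1, bulges/loops +3
toyParams <- function() {
  pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
  keys <- as.vector(outer(pairs, pairs, paste, sep = "."))
  hasGu <- function(k) grepl("GU|UG", k)
  stack <- stats::setNames(ifelse(hasGu(keys), -1, -2), keys)
  list(stack = stack, bulgeInit = 3, bulgePerNt = 0, loopInit = 3,
       loopPerNt = 0)
}

# independent duplex-energy oracle: walk the sorted pairing directly
oracleEnergy <- function(mirna, target, pairs, params) {
  mir <- strsplit(chartr("T", "U", mirna), "")[[1]]
  tg <- strsplit(chartr("T", "U", target), "")[[1]]
  pairs <- pairs[order(pairs$i), ]
  if (nrow(pairs) < 2) return(0)
  total <- 0
  for (r in 2:nrow(pairs)) {
    di <- pairs$i[r] - pairs$i[r - 1] - 1
    dj <- pairs$j[r - 1] - pairs$j[r] - 1
    if (di == 0 && dj == 0) {
      k <- paste0(mir[pairs$i[r - 1]], tg[pairs$j[r - 1]], ".",
                  mir[pairs$i[r]], tg[pairs$j[r]])
      total <- total + params$stack[[k]]
    } else if (di == 0 || dj == 0) {
      total <- total + params$bulgeInit + params$bulgePerNt * (di + dj - 1)
    } else {
      total <- total + params$loopInit + params$loopPerNt * (di + dj - 2)
    }
  }
  total
}

rcDna <- function(x) as.character(Biostrings::reverseComplement(
  Biostrings::DNAString(chartr("U", "T", x))))
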