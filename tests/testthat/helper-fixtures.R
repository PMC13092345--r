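# shared fixture builders for the statistics and simulator tests

# random polarized haplotype matrix with at least one segregating site
randomHapMatrix <- function(nHap, nSites, pDerived = 0.3) {
  m <- matrix(rbinom(nHap * nSites, 1L, pDerived), nHap, nSites)
  seg <- colSums(m) > 0 & colSums(m) < nHap
  if (!any(seg)) {
    m[1, 1] <- 1L
    m[-1, 1] <- 0L
    seg[1] <- TRUE
  }
  m[, seg, drop = FALSE]
}

# brute-force mean pairwise Hamming distance (independent pi oracle)
bruteForcePi <- function(m) {
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(m[i, ] != m[j, ])
  tot / choose(n, 2)
}

# brute-force haplotype spectrum by exhaustive tallying
bruteForceHapFreqs <- function(m) {
  keys <- apply(m, 1, paste, collapse = "")
  sort(as.vector(table(keys)) / nrow(m), decreasing = TRUE)
}

# minimal long-format statistic table for feature-assembly tests:
# every (replicate, class, timepoint, cyclePoint, window) combination
# filled with deterministic values
tinyStatLong <- function(nRep = 2, nWin = 30, classes = c("neutral",
                         "fluctuating", "het_advantage")) {
  cps <- c("mid_summer", "end_summer", "mid_winter", "end_winter")
  grid <- expand.grid(replicate = seq_len(nRep), class = classes,
                      timepoint = c("early", "long"), cyclePoint = cps,
                      window = seq_len(nWin), stringsAsFactors = FALSE)
  stats <- flucsel::featureStatistics()
  for (k in seq_along(stats))
    grid[[stats[k]]] <- as.numeric(seq_len(nrow(grid))) / 100 + k
  grid
}
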