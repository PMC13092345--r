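test_that("diversity statistics match hand-derived fixture values", {
  # one site with derived count 2 of 4: 4 differing pairs / 6 pairs = 2/3
  m1 <- matrix(c(1, 1, 0, 0), ncol = 1)
  expect_equal(diversityStats(m1)$pi, 2 / 3, tolerance = 1e-12)
  # S = 3 singletons in 4 haplotypes: theta_w = 3 / (1 + 1/2 + 1/3)
  m2 <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  d2 <- diversityStats(m2)
  expect_equal(d2$S, 3L)
  expect_equal(d2$thetaW, 3 / (1 + 1 / 2 + 1 / 3), tolerance = 1e-12)
  # monomorphic window
  m3 <- matrix(0L, 4, 2)
  d3 <- diversityStats(m3)
  expect_equal(d3$S, 0L)
  expect_equal(d3$pi, 0)
  expect_equal(d3$thetaW, 0)
  expect_true(is.nan(d3$tajimasD))
  expect_error(diversityStats(matrix(1, 1, 3)), "2 haplotypes")
})

test_that("pi equals brute-force mean pairwise differences on random fixtures", {
  set.seed(5)
  for (i in 1:25) {
    m <- randomHapMatrix(sample(3:10, 1), sample(2:20, 1), runif(1, 0.1, 0.7))
    expect_equal(diversityStats(m)$pi, bruteForcePi(m), tolerance = 1e-10)
  }
})

test_that("pi agrees with an independent reference implementation", {
  skip_if_not_installed("ape")
  set.seed(6)
  m <- randomHapMatrix(10, 15)
  chars <- matrix(c("a", "t")[m + 1], nrow(m), ncol(m))
  rownames(chars) <- paste0("h", seq_len(nrow(m)))
  dna <- ape::as.DNAbin(chars)
  ref <- mean(ape::dist.dna(dna, model = "N"))
  expect_equal(diversityStats(m)$pi, ref, tolerance = 1e-10)
})

test_that("Tajima's D matches an independently coded normalisation", {
  # independent route: brute-force pi, textbook variance constants
  refTajima <- function(m) {
    n <- nrow(m); S <- sum(colSums(m) > 0 & colSums(m) < n)
    a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
    b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    (bruteForcePi(m) - S / a1) /
      sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  }
  set.seed(11)
  for (i in 1:10) {
    m <- randomHapMatrix(sample(4:12, 1), sample(3:25, 1))
    expect_equal(diversityStats(m)$tajimasD, refTajima(m), tolerance = 1e-10)
  }
})

test_that("unfolded SFS counts derived-allele classes and conserves S", {
  m <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0))
  expect_equal(unfoldedSFS(m), c(2L, 0L, 0L))
  set.seed(13)
  for (i in 1:10) {
    m <- randomHapMatrix(sample(4:10, 1), sample(2:30, 1))
    expect_equal(sum(unfoldedSFS(m)), diversityStats(m)$S)
  }
})

test_that("SFS moments use the documented conventions", {
  mo <- sfsMoments(c(0.1, 0.5, 0.9))
  expect_equal(mo$variance, 0.16, tolerance = 1e-12)  # sum sq dev / (n-1)
  expect_equal(mo$skew, 0)                            # symmetric set
  # population-moment g1/g2 on an asymmetric set, checked by hand formulas
  p <- c(0.1, 0.2, 0.7)
  m2 <- mean((p - mean(p))^2)
  expect_equal(sfsMoments(p)$skew, mean((p - mean(p))^3) / m2^1.5,
               tolerance = 1e-12)
  expect_equal(sfsMoments(p)$kurtosis, mean((p - mean(p))^4) / m2^2 - 3,
               tolerance = 1e-12)
  deg <- sfsMoments(c(0.4, 0.4, 0.4))
  expect_equal(deg$variance, 0)
  expect_true(is.nan(deg$skew) && is.nan(deg$kurtosis))
  expect_true(is.nan(sfsMoments(0.5)$variance))
})

test_that("NCD is the root-mean-square deviation from the target frequency", {
  expect_equal(ncd(c(0.5, 0.5, 0.5), 0.5), 0)
  expect_equal(ncd(c(0.5, 0.4, 0.1), 0.5), sqrt((0 + 0.01 + 0.16) / 3),
               tolerance = 1e-12)
  expect_equal(ncd(0, 0.5), 0.5)  # maximal deviation for a single SNP
  expect_equal(ncd(c(0.5, 0.4, 0.1), 0.5, root = FALSE), 0.17 / 3,
               tolerance = 1e-12)
  expect_true(is.nan(ncd(numeric(0), 0.5)))
  # invariance to folding direction
  set.seed(17)
  p <- runif(20)
  for (tf in c(0.5, 0.4, 0.3))
    expect_equal(ncd(foldMinor(p), tf), ncd(foldMinor(1 - p), tf))
})

test_that("NCD standardization follows the S-binned neutral reference", {
  # hand-built neutral tables spanning two S-bins (width 25)
  neut <- list(
    data.frame(S = c(10, 40), ncd_tf50 = c(0.30, 0.20)),
    data.frame(S = c(12, 30), ncd_tf50 = c(0.40, 0.10)))
  ref <- neutralNCDReference(neut, tfs = 0.5)
  expect_equal(ref$mean[ref$bin == 0], 0.35)
  expect_equal(ref$mean[ref$bin == 1], 0.15)
  expect_equal(ref$sd[ref$bin == 0], sd(c(0.3, 0.4)))
  # bin 0 window: (0.42 - 0.35) / sd; bin 1 window: (0.15 - 0.15) / sd = 0
  z <- standardizeNCD(c(0.42, 0.15), c(5, 28), ref, 0.5)
  expect_equal(z, c((0.42 - 0.35) / sd(c(0.3, 0.4)), 0), tolerance = 1e-12)
  # mean + 2 sd standardizes to 2 (linearity)
  z2 <- standardizeNCD(0.35 + 2 * sd(c(0.3, 0.4)), 10, ref, 0.5)
  expect_equal(z2, 2, tolerance = 1e-12)
  # empty bin falls back to the nearest populated bin with a warning
  expect_warning(z3 <- standardizeNCD(0.2, 260, ref, 0.5), "empty")
  expect_equal(z3, (0.2 - 0.15) / sd(c(0.2, 0.1)), tolerance = 1e-12)
})

test_that("Garud H statistics match hand-computed values and orderings", {
  h <- makeFixtureHaplotypes(list(c(1, 1), c(1, 0), c(0, 0)), c(5, 3, 2))
  gh <- garudH(haplotypes(h))
  expect_equal(gh$H1, 0.38, tolerance = 1e-12)
  expect_equal(gh$H2, 0.13, tolerance = 1e-12)
  expect_equal(gh$H12, 0.68, tolerance = 1e-12)
  expect_equal(gh$H123, 1.0, tolerance = 1e-12)
  expect_equal(gh$H2_H1, 0.13 / 0.38, tolerance = 1e-12)
  # all identical haplotypes
  mono <- garudH(matrix(0L, 6, 3))
  expect_equal(mono$H1, 1)
  expect_equal(mono$H2, 0)
  expect_equal(mono$H12, 1)
  expect_equal(mono$H2_H1, 0)
  # all distinct haplotypes: H1 = 1/n
  dis <- garudH(diag(6))
  expect_equal(dis$H1, 1 / 6, tolerance = 1e-12)
  expect_error(garudH(matrix(0L, 0, 2)), "empty")
  # ordering invariants on random fixtures
  set.seed(19)
  for (i in 1:20) {
    g <- garudH(randomHapMatrix(sample(4:12, 1), sample(1:8, 1)))
    expect_lte(g$H2, g$H1)
    expect_lte(g$H1, g$H12 + 1e-12)
    expect_lte(g$H12, g$H123 + 1e-12)
    expect_lte(g$H123, 1 + 1e-12)
  }
})

test_that("top haplotype frequencies are padded, ordered and exhaustive", {
  h <- makeFixtureHaplotypes(list(c(1, 1), c(1, 0), c(0, 0)), c(5, 3, 2))
  expect_equal(topHaplotypeFrequencies(haplotypes(h)),
               c(0.5, 0.3, 0.2, 0, 0))
  expect_equal(topHaplotypeFrequencies(matrix(1L, 7, 2)), c(1, 0, 0, 0, 0))
  set.seed(23)
  m <- randomHapMatrix(10, 6)
  expect_equal(topHaplotypeFrequencies(m, 10)[seq_along(bruteForceHapFreqs(m))],
               bruteForceHapFreqs(m))
})

test_that("neutral quantile envelopes interpolate order statistics", {
  v <- matrix(1:50, 50, 2)
  q <- neutralQuantiles(v)
  expect_equal(q$q50, c(25.5, 25.5))
  expect_equal(q$q05, rep(quantile(1:50, 0.05, names = FALSE), 2))
  const <- neutralQuantiles(matrix(3, 5, 1))
  expect_equal(const$q05, const$q50)
  expect_equal(const$q50, const$q95)
  set.seed(29)
  r <- neutralQuantiles(matrix(rnorm(200), 20, 10))
  expect_true(all(r$q05 <= r$q50 & r$q50 <= r$q95))
  expect_error(neutralQuantiles(matrix(1, 1, 3)), "2 replicate")
})

test_that("window partition covers the sequence exactly once", {
  wb <- windowBreaks(95000, 10000)
  expect_equal(wb$start[1], 0)
  expect_equal(wb$end[nrow(wb)], 95000)
  expect_true(all(wb$start[-1] == wb$end[-nrow(wb)]))
  set.seed(31)
  pos <- runif(500, 0, 95000)
  idx <- findInterval(pos, wb$start)
  expect_true(all(idx >= 1 & idx <= nrow(wb)))
  for (w in seq_len(nrow(wb)))
    expect_true(all(pos[idx == w] >= wb$start[w] & pos[idx == w] < wb$end[w]))
})

test_that("window tables carry every statistic and flag empty windows as NaN", {
  set.seed(37)
  m <- randomHapMatrix(20, 40)
  hap <- new("HapMatrix", mat = m,
             positions = sort(runif(ncol(m), 0, 15000)),
             seqLength = 30000, siteClass = rep(0L, ncol(m)),
             metadata = list())
  tab <- windowStats(hap, windowSize = 10000)
  expect_equal(nrow(tab), 3)
  expect_true(all(c("S", "pi", "theta_w", "tajimas_d", "sfs_var",
                    "ncd_tf50", "ncd_tf40", "ncd_tf30", "H1", "H12",
                    "H2_H1", "hapfreq1") %in% colnames(tab)))
  expect_true(is.nan(tab$pi[3]))     # no sites landed beyond 15 kb
  expect_true(is.nan(tab$H1[3]))
  expect_equal(sum(tab$S), ncol(m))
  # per-window S and pi agree with direct computation on the sub-matrix
  idx <- findInterval(positions(hap), c(0, 10000, 20000))
  expect_equal(tab$pi[1], diversityStats(m[, idx == 1, drop = FALSE])$pi)
})
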