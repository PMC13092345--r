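#' Classical diversity statistics for a window
#'
#' For a 0/1 haplotype sub-matrix (n haplotypes x sites): the number of
#' segregating sites S, nucleotide diversity pi (mean pairwise
#' differences, i.e. `sum_sites 2 p (1-p) n/(n-1)`, reported per window;
#' divide by window length for the per-bp variant), Watterson's theta
#' `S / a_n` with `a_n = sum_{i<n} 1/i`, and Tajima's D with the standard
#' e1/e2 normalisation (`NaN` when `S = 0`).
#'
#' @param m 0/1 matrix, haplotypes in rows.
#' @return list with `S`, `pi`, `thetaW`, `tajimasD`.
#' @examples
#' m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 0))
#' diversityStats(m)
#' @export
diversityStats <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 2) stop("need at least 2 haplotypes")
  if (ncol(m) == 0)
    return(list(S = 0L, pi = 0, thetaW = 0, tajimasD = NaN))
  k <- colSums(m)
  seg <- k > 0 & k < n
  S <- sum(seg)
  if (S == 0) return(list(S = 0L, pi = 0, thetaW = 0, tajimasD = NaN))
  p <- k[seg] / n
  pi <- sum(2 * p * (1 - p)) * n / (n - 1)
  a1 <- sum(1 / seq_len(n - 1))
  thetaW <- S / a1
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  vD <- e1 * S + e2 * S * (S - 1)
  D <- if (vD > 0) (pi - thetaW) / sqrt(vD) else NaN
  list(S = as.integer(S), pi = pi, thetaW = thetaW, tajimasD = D)
}

#' Unfolded site frequency spectrum
#'
#' Counts of sites at each derived-allele count `k = 1 .. n-1` for a
#' polarized 0/1 haplotype matrix (ancestral state known from the
#' simulator). The spectrum sums to S.
#'
#' @param m 0/1 matrix, haplotypes in rows, derived allele coded 1.
#' @return integer vector of length `n - 1`.
#' @export
unfoldedSFS <- function(m) {
  n <- nrow(m)
  if (is.null(n) || n < 2) stop("need at least 2 haplotypes")
  k <- colSums(m)
  k <- k[k > 0 & k < n]
  tabulate(k, nbins = n - 1)
}

#' Moments of the window allele-frequency distribution
#'
#' Sample variance (n-1 denominator), population-moment skewness
#' `g1 = m3 / m2^(3/2)` and excess kurtosis `g2 = m4 / m2^2 - 3` of the
#' derived-allele frequencies in a window. Fewer than 2 (variance) or 3
#' (skew/kurtosis) frequencies, or zero spread, yield `NaN`.
#'
#' @param p numeric vector of allele frequencies.
#' @return list with `variance`, `skew`, `kurtosis`.
#' @examples
#' sfsMoments(c(0.1, 0.5, 0.9))
#' @export
sfsMoments <- function(p) {
  nv <- length(p)
  v <- if (nv >= 2) stats::var(p) else NaN
  if (nv >= 3) {
    m <- mean(p)
    m2 <- mean((p - m)^2)
    if (m2 > 0) {
      sk <- mean((p - m)^3) / m2^1.5
      ku <- mean((p - m)^4) / m2^2 - 3
    } else {
      sk <- NaN; ku <- NaN
    }
  } else {
    sk <- NaN; ku <- NaN
  }
  list(variance = v, skew = sk, kurtosis = ku)
}

#' Fold frequencies to the minor allele
#' @param p derived-allele frequencies.
#' @return `pmin(p, 1 - p)`.
#' @export
foldMinor <- function(p) pmin(p, 1 - p)

#' Noncentral deviation statistic (NCD)
#'
#' Root-mean-square deviation of the window's minor-allele frequencies
#' from a target frequency: `sqrt(sum_i (p_i - TF)^2 / n)`. Low values
#' indicate an excess of alleles near the target frequency, the signature
#' of balancing selection; this is the outgroup-free variant (NCD1) which
#' requires only the within-population minor-allele frequencies.
#'
#' @param p minor-allele frequencies (fold with [foldMinor()] first when
#'   starting from derived frequencies).
#' @param tf target frequency, conventionally 0.5, 0.4 or 0.3.
#' @param root include the square root (the original definition); set
#'   `FALSE` for the mean-squared-deviation variant.
#' @return NCD value; `NaN` for an empty window.
#' @examples
#' ncd(c(0.5, 0.4, 0.1), tf = 0.5)
#' @export
ncd <- function(p, tf = 0.5, root = TRUE) {
  if (!length(p)) return(NaN)
  v <- sum((p - tf)^2) / length(p)
  if (root) sqrt(v) else v
}

#' Garud's haplotype homozygosity statistics
#'
#' With ordered haplotype frequencies `p(1) >= p(2) >= ...` over the exact
#' site patterns in the window: `H1 = sum p(i)^2`, `H2 = H1 - p(1)^2`,
#' `H12 = (p(1)+p(2))^2 + sum_{i>=3} p(i)^2`,
#' `H123 = (p(1)+p(2)+p(3))^2 + sum_{i>=4} p(i)^2` and `H2/H1`. High H12
#' with low H2/H1 indicates a hard sweep; high H2/H1 marks soft sweeps.
#'
#' @param m 0/1 matrix, haplotypes in rows (a window sub-matrix).
#' @return list with `H1`, `H2`, `H12`, `H123`, `H2_H1`.
#' @examples
#' m <- matrix(c(rep(0, 5), rep(1, 5)), ncol = 1)
#' garudH(m)
#' @export
garudH <- function(m) {
  if (is.null(nrow(m)) || nrow(m) == 0) stop("empty haplotype matrix")
  p <- sort(.hapFreqs(m), decreasing = TRUE)
  H1 <- sum(p^2)
  H2 <- H1 - p[1]^2
  p2 <- if (length(p) >= 2) p[2] else 0
  p3 <- if (length(p) >= 3) p[3] else 0
  H12 <- (p[1] + p2)^2 + if (length(p) >= 3) sum(p[-(1:2)]^2) else 0
  H123 <- (p[1] + p2 + p3)^2 + if (length(p) >= 4) sum(p[-(1:3)]^2) else 0
  list(H1 = H1, H2 = H2, H12 = H12, H123 = H123, H2_H1 = H2 / H1)
}

.hapFreqs <- function(m) {
  if (ncol(m) == 0) return(1)
  key <- apply(m, 1L, paste, collapse = "")
  as.vector(table(key)) / nrow(m)
}

#' Frequencies of the most common haplotypes
#'
#' Descending frequencies of the `k` most common exact haplotype patterns
#' in the window, zero-padded when fewer distinct haplotypes exist.
#'
#' @param m 0/1 matrix, haplotypes in rows.
#' @param k how many to report.
#' @return numeric vector of length `k`.
#' @export
topHaplotypeFrequencies <- function(m, k = 5) {
  if (k < 1) stop("k must be >= 1")
  p <- sort(.hapFreqs(m), decreasing = TRUE)
  out <- numeric(k)
  out[seq_len(min(k, length(p)))] <- p[seq_len(min(k, length(p)))]
  out
}

#' Window partition of a sequence
#'
#' 0-based half-open windows `[ (i-1) w, i w )` covering `[0, L)`; the
#' final window absorbs any remainder shorter than `w`.
#'
#' @param L sequence length.
#' @param windowSize window width in bp.
#' @return data.frame with `window`, `start`, `end`.
#' @export
windowBreaks <- function(L, windowSize) {
  nW <- max(1L, floor(L / windowSize))
  start <- (seq_len(nW) - 1) * windowSize
  end <- start + windowSize
  end[nW] <- L
  data.frame(window = seq_len(nW), start = start, end = end)
}

#' Windowed summary-statistic table
#'
#' Computes every implemented statistic in successive windows of a
#' [HapMatrix-class]: S, pi, Watterson's theta, Tajima's D, the variance,
#' skew and kurtosis of the unfolded SFS, basic NCD at target frequencies
#' 0.5/0.4/0.3, Garud's H1, H2, H12, H123 and H2/H1, and the top five
#' haplotype frequencies. Standardized NCD columns are added by
#' [standardizeNCD()] against a neutral reference. Empty windows yield
#' `NaN` statistics (never zero) so that absence is distinguishable from
#' signal.
#'
#' @param hap a [HapMatrix-class].
#' @param windowSize window width in bp (default 10 kb).
#' @param tfs NCD target frequencies.
#' @return data.frame, one row per window.
#' @export
windowStats <- function(hap, windowSize = 1e4, tfs = c(0.5, 0.4, 0.3)) {
  stopifnot(is(hap, "HapMatrix"))
  wb <- windowBreaks(hap@seqLength, windowSize)
  m <- hap@mat
  pos <- hap@positions
  idx <- findInterval(pos, wb$start)
  rows <- lapply(seq_len(nrow(wb)), function(w) {
    sub <- m[, idx == w, drop = FALSE]
    if (ncol(sub) == 0) {
      # empty window: NaN, never zero, so absence is distinguishable
      return(c(window = w, start = wb$start[w], end = wb$end[w],
               S = 0, pi = NaN, theta_w = NaN, tajimas_d = NaN,
               sfs_var = NaN, sfs_skew = NaN, sfs_kurt = NaN,
               setNames(rep(NaN, length(tfs)),
                        sprintf("ncd_tf%02d", round(tfs * 100))),
               H1 = NaN, H2 = NaN, H12 = NaN, H123 = NaN, H2_H1 = NaN,
               setNames(rep(NaN, 5), paste0("hapfreq", 1:5))))
    }
    d <- diversityStats(sub)
    p <- colMeans(sub)
    mo <- sfsMoments(p)
    pm <- foldMinor(p)
    nc <- vapply(tfs, function(tf) ncd(pm, tf), numeric(1))
    gh <- garudH(sub)
    tp <- topHaplotypeFrequencies(sub, 5)
    c(window = w, start = wb$start[w], end = wb$end[w],
      S = d$S, pi = d$pi,
      theta_w = d$thetaW, tajimas_d = d$tajimasD,
      sfs_var = mo$variance, sfs_skew = mo$skew, sfs_kurt = mo$kurtosis,
      setNames(nc, sprintf("ncd_tf%02d", round(tfs * 100))),
      H1 = gh$H1, H2 = gh$H2, H12 = gh$H12, H123 = gh$H123,
      H2_H1 = gh$H2_H1,
      setNames(tp, paste0("hapfreq", 1:5)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$window <- as.integer(out$window)
  out$S <- as.integer(out$S)
  out
}

#' Neutral NCD reference by segregating-site bin
#'
#' Pools the per-window NCD values of neutral replicates into bins of the
#' number of segregating sites (width 25, `bin = floor(S / 25)`) and
#' records the neutral mean and standard deviation per bin and target
#' frequency - the inputs of the NCD standardization.
#'
#' @param tables list of [windowStats()] data.frames from neutral
#'   replicates (matching window size).
#' @param tfs target frequencies present in the tables.
#' @param binWidth S-bin width.
#' @return data.frame with `tf`, `bin`, `mean`, `sd`, `n`.
#' @export
neutralNCDReference <- function(tables, tfs = c(0.5, 0.4, 0.3),
                                binWidth = 25) {
  all <- do.call(rbind, tables)
  bin <- floor(all$S / binWidth)
  out <- do.call(rbind, lapply(tfs, function(tf) {
    col <- sprintf("ncd_tf%02d", round(tf * 100))
    v <- all[[col]]
    ok <- is.finite(v)
    agg <- tapply(v[ok], bin[ok], function(x)
      c(mean = mean(x), sd = stats::sd(x), n = length(x)))
    data.frame(tf = tf, bin = as.integer(names(agg)),
               mean = vapply(agg, `[[`, numeric(1), "mean"),
               sd = vapply(agg, `[[`, numeric(1), "sd"),
               n = vapply(agg, `[[`, numeric(1), "n"))
  }))
  rownames(out) <- NULL
  attr(out, "binWidth") <- binWidth
  out
}

#' Standardize NCD against the neutral reference
#'
#' `(NCD - mean_neutral[bin(S)]) / sd_neutral[bin(S)]` with
#' `bin(S) = floor(S / 25)`. A bin unobserved under neutrality falls back
#' to the nearest populated bin (with a warning); a zero neutral standard
#' deviation yields `NaN`.
#'
#' @param ncdValues NCD values (vectorised).
#' @param S segregating sites of the corresponding windows.
#' @param reference a [neutralNCDReference()] table.
#' @param tf target frequency to standardize against.
#' @return standardized values.
#' @export
standardizeNCD <- function(ncdValues, S, reference, tf = 0.5) {
  ref <- reference[abs(reference$tf - tf) < 1e-9, , drop = FALSE]
  if (!nrow(ref)) stop("no reference rows for this target frequency")
  bw <- attr(reference, "binWidth")
  if (is.null(bw)) bw <- 25
  bin <- floor(S / bw)
  miss <- !(bin %in% ref$bin)
  if (any(miss)) {
    warning(sum(miss), " window(s) fall in empty neutral S-bins; ",
            "using nearest populated bin")
    bin[miss] <- vapply(bin[miss], function(b)
      ref$bin[which.min(abs(ref$bin - b))], numeric(1))
  }
  i <- match(bin, ref$bin)
  out <- (ncdValues - ref$mean[i]) / ref$sd[i]
  out[!is.na(i) & ref$sd[i] == 0] <- NaN
  out
}

#' Add standardized NCD columns to a window table
#'
#' @param tab a [windowStats()] data.frame.
#' @param reference a [neutralNCDReference()] table.
#' @param tfs target frequencies.
#' @return `tab` with `ncd_std_tf*` columns appended.
#' @export
addStandardizedNCD <- function(tab, reference, tfs = c(0.5, 0.4, 0.3)) {
  for (tf in tfs) {
    col <- sprintf("ncd_tf%02d", round(tf * 100))
    tab[[sprintf("ncd_std_tf%02d", round(tf * 100))]] <-
      standardizeNCD(tab[[col]], tab$S, reference, tf)
  }
  tab
}

#' Neutral quantile envelope
#'
#' Per-window 5%, 50% and 95% empirical quantiles (linear interpolation
#' between order statistics) of a statistic across neutral replicates.
#'
#' @param values replicates x windows numeric matrix.
#' @return data.frame with `window`, `q05`, `q50`, `q95`.
#' @export
neutralQuantiles <- function(values) {
  if (nrow(values) < 2) stop("need at least 2 replicate values per window")
  q <- apply(values, 2L, stats::quantile, probs = c(0.05, 0.5, 0.95),
             na.rm = TRUE, names = FALSE, type = 7)
  data.frame(window = seq_len(ncol(values)),
             q05 = q[1, ], q50 = q[2, ], q95 = q[3, ])
}
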