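#' Cohen's d and distribution overlap
#'
#' Standardized mean difference
#' `d = (mean_a - mean_b) / s_pooled`,
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2))`,
#' with the normal overlapping-coefficient interpretation of the overlap
#' between the two distributions, `OVL = 2 Phi(-|d| / 2)`. When both
#' groups are constant, `d` is 0 (equal means, overlap 1) or signed
#' infinite (unequal means, overlap 0).
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return list with `d` and `overlap`.
#' @examples
#' cohensD(c(0.5, 1.5), c(-0.5, 0.5))  # d = 1, overlap ~0.617
#' @export
cohensD <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per group")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  dm <- mean(a) - mean(b)
  if (sp2 <= 0) {
    d <- if (dm == 0) 0 else sign(dm) * Inf
    return(list(d = d, overlap = as.numeric(dm == 0)))
  }
  d <- dm / sqrt(sp2)
  list(d = d, overlap = 2 * stats::pnorm(-abs(d) / 2))
}

#' Pairwise mode comparisons at the focal window
#'
#' For one statistic observed across replicates of several selection
#' modes: every pairwise two-sample t-test (Welch by default), with the
#' Hochberg step-up adjustment applied across the family of all mode
#' pairs, plus Cohen's d and the normal-overlap coefficient per pair.
#'
#' @param values numeric vector of replicate values (e.g. a statistic at
#'   the central window).
#' @param modes factor/character of the same length giving each
#'   replicate's selection mode.
#' @param varEqual use the pooled-variance Student t-test instead of
#'   Welch.
#' @return data.frame with one row per mode pair: `groupA`, `groupB`,
#'   `t`, `p`, `pAdj` (Hochberg), `cohensD`, `overlap`.
#' @export
compareModes <- function(values, modes, varEqual = FALSE) {
  modes <- as.factor(modes)
  lev <- levels(modes)
  if (length(lev) < 2) stop("need at least two modes")
  prs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    a <- values[modes == prs[1, j]]
    b <- values[modes == prs[2, j]]
    if (length(a) < 2 || length(b) < 2) stop("need >= 2 replicates per mode")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      eq <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                 p.value = as.numeric(eq))
    } else {
      tt <- stats::t.test(a, b, var.equal = varEqual)
    }
    cd <- cohensD(a, b)
    data.frame(groupA = prs[1, j], groupB = prs[2, j],
               t = unname(tt$statistic), p = tt$p.value,
               cohensD = cd$d, overlap = cd$overlap)
  })
  out <- do.call(rbind, rows)
  out$pAdj <- stats::p.adjust(out$p, method = "hochberg")
  out[, c("groupA", "groupB", "t", "p", "pAdj", "cohensD", "overlap")]
}
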