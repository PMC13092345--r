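#' Statistics used as discriminant features
#'
#' The 18 per-window statistics entering the discriminant analysis:
#' segregating sites, pi, Watterson's theta, Tajima's D, the three SFS
#' moments, basic and standardized NCD at the three target frequencies,
#' and the five Garud H statistics.
#' @export
featureStatistics <- function() {
  c("S", "pi", "theta_w", "tajimas_d", "sfs_var", "sfs_skew", "sfs_kurt",
    "ncd_tf50", "ncd_tf40", "ncd_tf30",
    "ncd_std_tf50", "ncd_std_tf40", "ncd_std_tf30",
    "H1", "H2", "H12", "H123", "H2_H1")
}

#' Cycle-point label of a sampled generation
#'
#' Maps a generation's offset within the seasonal cycle (0 .. 2g-1) to
#' `"mid_summer"`, `"end_summer"`, `"mid_winter"` or `"end_winter"`
#' under the convention that the middle of a season is generation
#' `ceiling(g/2) - 1` within it and the end is its last generation.
#'
#' @param offset generation offset within the cycle.
#' @param g season length.
#' @return character label (`NA` for offsets that are neither).
#' @export
cyclePointLabel <- function(offset, g = 10) {
  mid <- ceiling(g / 2) - 1
  lab <- rep(NA_character_, length(offset))
  lab[offset == mid] <- "mid_summer"
  lab[offset == g - 1] <- "end_summer"
  lab[offset == g + mid] <- "mid_winter"
  lab[offset == 2 * g - 1] <- "end_winter"
  lab
}

#' Assemble per-replicate feature vectors under a sampling scheme
#'
#' Builds the replicate x feature matrix for the discriminant analysis
#' from a long table of windowed statistics. The four schemes correspond
#' to different seasonal sampling designs:
#' \describe{
#'   \item{1}{central window only, sampled at the end of summer;}
#'   \item{2}{central, immediately adjacent and a distal window (250 kb
#'     away at full scale; clamped to the available sequence), end of
#'     summer;}
#'   \item{3}{central window at the end of both seasons;}
#'   \item{4}{central window at the middle and end of summer.}
#' }
#' Class labels combine mode and timepoint: `Neutral`, `FS_early`,
#' `FS_long`, `HA_early`, `HA_long`. Neutral replicates contribute one
#' row each, built from their long-term samples at the matching
#' generation offsets. Feature columns containing missing values are
#' dropped with a warning.
#'
#' @param statLong data.frame with columns `replicate`, `class`
#'   (`"neutral"`, `"fluctuating"`, `"het_advantage"`), `timepoint`
#'   (`"early"`/`"long"`), `cyclePoint`, `window`, and the statistic
#'   columns of [featureStatistics()].
#' @param scheme sampling scheme 1-4.
#' @param centralWindow index of the window containing the selected site.
#' @param distalWindow index of the distal window for scheme 2; defaults
#'   to `centralWindow + 25` (250 kb at 10 kb windows) clamped to the
#'   largest window present.
#' @return list with `X` (matrix), `labels` (factor), `replicate`
#'   (original replicate ids).
#' @export
assembleFeatures <- function(statLong, scheme, centralWindow,
                             distalWindow = NULL) {
  stopifnot(scheme %in% 1:4)
  stats <- intersect(featureStatistics(), colnames(statLong))
  maxW <- max(statLong$window)
  if (is.null(distalWindow)) distalWindow <- min(centralWindow + 25L, maxW)
  wins <- switch(scheme,
                 `1` = centralWindow,
                 `2` = unique(c(centralWindow,
                                min(centralWindow + 1L, maxW), distalWindow)),
                 `3` = centralWindow,
                 `4` = centralWindow)
  cps <- switch(scheme,
                `1` = "end_summer",
                `2` = "end_summer",
                `3` = c("end_summer", "end_winter"),
                `4` = c("mid_summer", "end_summer"))
  classLabel <- function(class, timepoint) {
    switch(class,
           neutral = "Neutral",
           fluctuating = paste0("FS_", timepoint),
           het_advantage = paste0("HA_", timepoint),
           stop("unknown class: ", class))
  }
  # one row per (replicate, class, timepoint); neutral uses long only
  keys <- unique(statLong[, c("replicate", "class", "timepoint")])
  keys <- keys[!(keys$class == "neutral" & keys$timepoint == "early"), ,
               drop = FALSE]
  featNames <- as.vector(outer(
    as.vector(outer(stats, paste0("w", wins - centralWindow), paste, sep = "_")),
    cps, paste, sep = "_"))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    v <- numeric(0)
    for (cp in cps) {
      sub <- statLong[statLong$replicate == k$replicate &
                      statLong$class == k$class &
                      statLong$timepoint == k$timepoint &
                      statLong$cyclePoint == cp &
                      statLong$window %in% wins, , drop = FALSE]
      sub <- sub[order(match(sub$window, wins)), , drop = FALSE]
      if (nrow(sub) != length(wins))
        stop("missing window statistics for replicate ", k$replicate,
             " (", k$class, ", ", k$timepoint, ", ", cp, ")")
      v <- c(v, as.vector(t(as.matrix(sub[, stats]))))
    }
    rows[[i]] <- v
  }
  X <- do.call(rbind, rows)
  colnames(X) <- featNames
  labels <- factor(mapply(classLabel, keys$class, keys$timepoint))
  bad <- apply(X, 2, function(col) any(!is.finite(col)))
  if (any(bad)) {
    warning("dropping ", sum(bad), " feature(s) with missing values: ",
            paste(utils::head(colnames(X)[bad], 5), collapse = ", "),
            if (sum(bad) > 5) ", ...")
    X <- X[, !bad, drop = FALSE]
  }
  list(X = X, labels = labels, replicate = keys$replicate)
}

#' Stratified train/test split
#'
#' Splits replicates into training and held-out sets with the same
#' fraction per class (the 150/200 design corresponds to
#' `trainFraction = 0.75`).
#'
#' @param labels class labels.
#' @param trainFraction fraction of each class used for training.
#' @return logical vector, `TRUE` for training rows.
#' @export
splitTrainTest <- function(labels, trainFraction = 0.75) {
  labels <- as.factor(labels)
  train <- logical(length(labels))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    nTr <- round(length(idx) * trainFraction)
    train[sample(idx, nTr)] <- TRUE
  }
  train
}
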