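#' Deterministic haplotype fixture
#'
#' Builds a [HapMatrix-class] with an exactly specified haplotype
#' frequency spectrum, for unit-testing statistics against hand-computed
#' values: `patterns` lists distinct 0/1 site patterns and `counts` their
#' multiplicities.
#'
#' @param patterns list of equal-length 0/1 vectors.
#' @param counts integer multiplicities, one per pattern.
#' @param L sequence length; default places sites evenly on `[0, L)`.
#' @param positions optional site coordinates.
#' @return A [HapMatrix-class].
#' @examples
#' h <- makeFixtureHaplotypes(list(c(1, 0), c(0, 1), c(0, 0)), c(5, 3, 2))
#' garudH(haplotypes(h))$H1  # 0.38
#' @export
makeFixtureHaplotypes <- function(patterns, counts, L = 1e4,
                                  positions = NULL) {
  if (length(patterns) != length(counts))
    stop("one count per pattern required")
  len <- unique(vapply(patterns, length, integer(1)))
  if (length(len) != 1) stop("patterns must have equal length")
  if (any(counts < 1)) stop("counts must be positive")
  m <- do.call(rbind, rep(patterns, counts))
  storage.mode(m) <- "integer"
  if (is.null(positions))
    positions <- (seq_len(len) - 0.5) / len * L
  new("HapMatrix", mat = m, positions = as.numeric(positions),
      seqLength = as.numeric(L), siteClass = rep(0L, len),
      metadata = list(fixture = TRUE))
}

#' Synthetic Gaussian feature table
#'
#' Class-conditional multivariate Gaussian samples with shared
#' covariance - exactly the generative model linear discriminant analysis
#' assumes - for Bayes-accuracy oracles and feature-recovery tests of the
#' discriminant pipeline without running simulations.
#'
#' @param classMeans classes x features matrix (rownames = class labels).
#' @param covariance shared positive-definite covariance.
#' @param nPerClass replicates per class.
#' @param seed optional seed.
#' @return list with `X` (matrix with the column names of `classMeans`)
#'   and `labels` (factor).
#' @export
makeSyntheticFeatureTable <- function(classMeans, covariance, nPerClass,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  classMeans <- as.matrix(classMeans)
  p <- ncol(classMeans)
  R <- tryCatch(chol(covariance),
                error = function(e) stop("covariance must be positive definite"))
  Xs <- lapply(seq_len(nrow(classMeans)), function(k) {
    Z <- matrix(stats::rnorm(nPerClass * p), nPerClass, p)
    sweep(Z %*% R, 2, classMeans[k, ], "+")
  })
  X <- do.call(rbind, Xs)
  colnames(X) <- colnames(classMeans)
  labels <- factor(rep(rownames(classMeans), each = nPerClass),
                   levels = rownames(classMeans))
  list(X = X, labels = labels)
}

#' Write a trajectory as TSV
#'
#' Columns: generation, season, frequency, restart_count.
#'
#' @param trajectory a [SeasonalTrajectory-class].
#' @param file output path.
#' @export
writeTrajectory <- function(trajectory, file) {
  n <- length(trajectory@freq) - 1L
  df <- data.frame(generation = 0:n,
                   season = seasonOf(0:n, trajectory@seasonLength),
                   frequency = trajectory@freq,
                   restart_count = trajectory@restartCount)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export a haplotype matrix as phased VCF
#'
#' Minimal VCF 4.2 with one diploid sample per pair of haplotype rows,
#' phased GT fields, the ancestral allele in `INFO/AA` and the exact
#' (continuous) simulator coordinate in `INFO/XP`. Integer POS values are
#' de-duplicated by bumping, so round-trips should rely on `XP`.
#'
#' @param hap a [HapMatrix-class].
#' @param file output path.
#' @export
writeHapVCF <- function(hap, file) {
  m <- hap@mat
  nInd <- nrow(m) %/% 2L
  pos <- floor(hap@positions) + 1
  while (anyDuplicated(pos)) pos[duplicated(pos)] <- pos[duplicated(pos)] + 1
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=sim,length=%d>", as.integer(ceiling(hap@seqLength)) + ncol(m)),
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=XP,Number=1,Type=Float,Description=\"Exact position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", seq_len(nInd))), collapse = "\t")), con)
  for (j in seq_len(ncol(m))) {
    gt <- paste(m[seq(1, 2 * nInd, 2), j], m[seq(2, 2 * nInd, 2), j],
                sep = "|")
    writeLines(paste(c("sim", pos[j], sprintf("site%d", j), "A", "T", ".",
                       "PASS",
                       sprintf("AA=A;XP=%.6f", hap@positions[j]), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' Read a phased VCF into a haplotype matrix
#'
#' Reads a phased diploid VCF (e.g. written by [writeHapVCF()], or any
#' phased biallelic VCF) into a [HapMatrix-class]; the derived allele is
#' the ALT allele unless `INFO/AA` equals ALT. Requires the `vcfR`
#' package.
#'
#' @param file VCF path.
#' @param seqLength sequence length; taken from the contig header when
#'   absent.
#' @return A [HapMatrix-class].
#' @export
readHapVCF <- function(file, seqLength = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readHapVCF requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  sp <- strsplit(as.vector(gt), "[|/]")
  a1 <- vapply(sp, function(x) as.integer(x[1]), integer(1))
  a2 <- vapply(sp, function(x) as.integer(x[2]), integer(1))
  nSite <- nrow(gt); nInd <- ncol(gt)
  m <- matrix(0L, 2L * nInd, nSite)
  A1 <- matrix(a1, nSite, nInd)
  A2 <- matrix(a2, nSite, nInd)
  m[seq(1, 2 * nInd, 2), ] <- t(A1)
  m[seq(2, 2 * nInd, 2), ] <- t(A2)
  info <- vcfR::getINFO(v)
  xp <- suppressWarnings(as.numeric(sub(".*XP=([0-9.eE+-]+).*", "\\1", info)))
  pos <- ifelse(is.na(xp), as.numeric(vcfR::getPOS(v)) - 1, xp)
  aa <- sub(".*AA=([A-Za-z]).*", "\\1", info)
  alt <- vcfR::getALT(v)
  flip <- !is.na(aa) & aa == alt
  if (any(flip)) m[, flip] <- 1L - m[, flip]
  o <- order(pos)
  if (is.null(seqLength)) {
    meta <- v@meta
    ln <- grep("##contig", meta, value = TRUE)
    seqLength <- if (length(ln))
      as.numeric(sub(".*length=([0-9]+).*", "\\1", ln[1]))
    else max(pos) + 1
  }
  new("HapMatrix", mat = m[, o, drop = FALSE], positions = pos[o],
      seqLength = as.numeric(seqLength),
      siteClass = rep(0L, length(pos)), metadata = list(source = file))
}

.replicateSeed <- function(baseSeed, scenario, replicate) {
  as.integer((as.numeric(baseSeed) + scenario * 1e6 + replicate) %%
               2147483647)
}

#' Run a scenario suite
#'
#' Runs a list of scenarios (each a [SimConfig-class] plus a label and a
#' replicate count), computing windowed statistics for every emitted
#' sample, and writes per-replicate trajectory and statistic TSVs plus a
#' manifest with content hashes under one directory per scenario.
#' Replicate seeds are derived deterministically from the global seed and
#' the (scenario, replicate) index, so suites are reproducible and
#' resumable: replicates whose outputs already exist with matching hashes
#' are skipped on re-runs. Partial outputs without a manifest are refused
#' unless `force = TRUE`.
#'
#' @param scenarios list of `list(label=, config=, nReplicates=)`.
#' @param outDir output directory.
#' @param baseSeed global seed.
#' @param windowSize window size for [windowStats()].
#' @param force overwrite unmanifested partial outputs.
#' @return (invisibly) the manifest data.frame.
#' @export
runSuite <- function(scenarios, outDir, baseSeed = 1, windowSize = 1e4,
                     force = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifestPath <- file.path(outDir, "manifest.tsv")
  manifest <- if (file.exists(manifestPath))
    utils::read.table(manifestPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  else data.frame(file = character(), md5 = character(),
                  stringsAsFactors = FALSE)
  rows <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    dir <- file.path(outDir, sc$label)
    if (dir.exists(dir) && length(list.files(dir)) &&
        !file.exists(manifestPath) && !force)
      stop("partial outputs in ", dir, " without a manifest; use force=TRUE")
    dir.create(dir, showWarnings = FALSE)
    for (i in seq_len(sc$nReplicates)) {
      trajFile <- file.path(dir, sprintf("trajectory_%03d.tsv", i))
      statFile <- file.path(dir, sprintf("stats_%03d.tsv", i))
      done <- all(file.exists(c(trajFile, statFile))) &&
        all(c(trajFile, statFile) %in% manifest$file) &&
        identical(unname(tools::md5sum(trajFile)),
                  manifest$md5[match(trajFile, manifest$file)]) &&
        identical(unname(tools::md5sum(statFile)),
                  manifest$md5[match(statFile, manifest$file)])
      if (done) next
      cfg <- sc$config
      cfg@seed <- .replicateSeed(baseSeed, si, i)
      rep <- runReplicate(cfg)
      writeTrajectory(rep$trajectory, trajFile)
      st <- do.call(rbind, lapply(rep$samples, function(s) {
        tab <- windowStats(s, windowSize)
        cbind(replicate = i, timepoint = s@metadata$timepoint,
              generation = s@metadata$generation,
              cycleOffset = s@metadata$cycleOffset, tab)
      }))
      if (is.null(st))
        st <- data.frame(replicate = i, note = "no samples scheduled")
      utils::write.table(st, statFile, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      rows[[length(rows) + 1L]] <-
        data.frame(file = c(trajFile, statFile),
                   md5 = unname(tools::md5sum(c(trajFile, statFile))),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    manifest <- rbind(manifest[!manifest$file %in%
                                 do.call(rbind, rows)$file, , drop = FALSE],
                      do.call(rbind, rows))
    utils::write.table(manifest, manifestPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(manifest)
}
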