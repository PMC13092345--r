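#' Simulation configuration
#'
#' Holds every demographic, genetic, seasonal and selection parameter of a
#' forward Wright-Fisher replicate, plus the sampling schedule and seed.
#' Construct with [simConfig()] or one of the presets ([paperScaleConfig()],
#' [deskScaleConfig()], [miniScaleConfig()]).
#'
#' @slot N diploid population size (individuals).
#' @slot L sequence length in bp.
#' @slot mu neutral mutation rate per bp per generation.
#' @slot r recombination rate per bp per generation.
#' @slot g season length in generations (unscaled; default 10).
#' @slot nGenerations forward generations of selection after burn-in.
#' @slot mode one of `"neutral"`, `"fluctuating"`, `"het_advantage"`,
#'   `"hard_sweep"`, `"soft_sweep"`.
#' @slot sSummer,sWinter seasonal selection coefficients; for
#'   non-seasonal modes only `sSummer` is used.
#' @slot hSummer,hWinter seasonal dominance coefficients.
#' @slot selectedPosition coordinate of the selected locus in `[0, L)`.
#' @slot softSweepRate expected beneficial mutations per generation,
#'   population-wide, at the selected site (soft sweeps only).
#' @slot burnIn neutral forward burn-in length in generations.
#' @slot dfeEnabled,dfeMean,dfeShape,deleteriousFraction,deleteriousH
#'   optional background-selection parameters: gamma DFE with mean
#'   `dfeMean` (magnitude of the mean deleterious effect), shape
#'   `dfeShape`, deleterious mutations arising at
#'   `deleteriousFraction * mu * L` per gamete with dominance
#'   `deleteriousH`.
#' @slot samplingSchedule list controlling haplotype sampling; see
#'   [simConfig()].
#' @slot restartOnLoss restart the forward phase (from the stored burn-in
#'   population) whenever the selected locus becomes monomorphic before
#'   `nGenerations`.
#' @slot maxRestarts restart cap before giving up with an error.
#' @slot seed integer seed (`NA` to leave the RNG stream untouched).
#'
#' @export
setClass("SimConfig", representation(
  N = "integer", L = "numeric", mu = "numeric", r = "numeric",
  g = "integer", nGenerations = "integer", mode = "character",
  sSummer = "numeric", sWinter = "numeric",
  hSummer = "numeric", hWinter = "numeric",
  selectedPosition = "numeric", softSweepRate = "numeric",
  burnIn = "integer", dfeEnabled = "logical", dfeMean = "numeric",
  dfeShape = "numeric", deleteriousFraction = "numeric",
  deleteriousH = "numeric", samplingSchedule = "list",
  restartOnLoss = "logical", maxRestarts = "integer", seed = "integer"))

.validSimConfig <- function(object) {
  msg <- character()
  if (object@N < 2L) msg <- c(msg, "N must be >= 2")
  if (object@L <= 0) msg <- c(msg, "L must be > 0")
  if (object@mu < 0 || object@r < 0) msg <- c(msg, "mu and r must be >= 0")
  if (object@g < 1L) msg <- c(msg, "season length g must be >= 1")
  if (!object@mode %in% c("neutral", "fluctuating", "het_advantage",
                          "hard_sweep", "soft_sweep"))
    msg <- c(msg, "unknown selection mode")
  if (any(c(object@sSummer, object@sWinter) < 0))
    msg <- c(msg, "selection coefficients must be >= 0")
  if (any(c(object@hSummer, object@hWinter) < 0 |
          c(object@hSummer, object@hWinter) > 1))
    msg <- c(msg, "dominance coefficients must lie in [0, 1]")
  if (object@selectedPosition < 0 || object@selectedPosition >= object@L)
    msg <- c(msg, "selectedPosition must lie in [0, L)")
  if (object@burnIn < 0L) msg <- c(msg, "burnIn must be >= 0")
  if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' Haplotype matrix with site positions
#'
#' Sampled haplotypes (rows, 2 per individual) by biallelic sites
#' (columns, 0 = ancestral, 1 = derived). Site polarity is known because
#' the simulator provides the ancestral state; monomorphic columns are
#' excluded. The substrate for all summary statistics.
#'
#' @slot mat integer 0/1 matrix, haplotypes x sites.
#' @slot positions strictly increasing site coordinates in `[0, L)`.
#' @slot seqLength sequence length L in bp.
#' @slot siteClass integer per site: 0 neutral, 1 selected, 2 deleterious.
#' @slot metadata free-form list (generation, timepoint, season, ...).
#'
#' @export
setClass("HapMatrix", representation(
  mat = "matrix", positions = "numeric", seqLength = "numeric",
  siteClass = "integer", metadata = "list"))

.validHapMatrix <- function(object) {
  msg <- character()
  m <- object@mat
  if (length(m) && !all(m %in% c(0L, 1L)))
    msg <- c(msg, "haplotype entries must be 0/1")
  if (ncol(m) != length(object@positions))
    msg <- c(msg, "positions length must equal number of sites")
  if (length(object@positions) > 1 && any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly increasing")
  if (length(object@positions) &&
      (min(object@positions) < 0 || max(object@positions) >= object@seqLength))
    msg <- c(msg, "positions must lie in [0, L)")
  if (length(object@siteClass) && length(object@siteClass) != ncol(m))
    msg <- c(msg, "siteClass length must equal number of sites")
  if (length(msg)) msg else TRUE
}
setValidity("HapMatrix", .validHapMatrix)

#' Per-generation trajectory of the selected allele
#'
#' Frequency of the summer-favored (or selected) allele class, pooled
#' across mutational origins, for every generation of the final
#' (surviving) attempt of a replicate, together with restart bookkeeping.
#'
#' @slot freq numeric vector, generations 0..nGenerations.
#' @slot seasonLength season length g.
#' @slot mode selection mode the trajectory was generated under.
#' @slot restartCount restarts taken before the surviving attempt.
#' @slot terminalState `"polymorphic"`, `"fixed"` or `"lost"`.
#' @slot nOrigins distinct beneficial origins per generation (sequence
#'   engine only; empty otherwise).
#' @slot traitFixed per generation, whether every individual carries the
#'   beneficial class on both haplotypes (sequence engine only).
#' @slot tEq first generation at which the deterministic equilibrium
#'   frequency was reached (-1 if never / not tracked).
#'
#' @export
setClass("SeasonalTrajectory", representation(
  freq = "numeric", seasonLength = "integer", mode = "character",
  restartCount = "integer", terminalState = "character",
  nOrigins = "integer", traitFixed = "logical", tEq = "integer"))

.validTrajectory <- function(object) {
  msg <- character()
  if (any(object@freq < 0 | object@freq > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (object@restartCount < 0L) msg <- c(msg, "restartCount must be >= 0")
  if (!object@terminalState %in% c("polymorphic", "fixed", "lost"))
    msg <- c(msg, "unknown terminal state")
  if (length(msg)) msg else TRUE
}
setValidity("SeasonalTrajectory", .validTrajectory)

#' Fitted stepwise-Wilks linear discriminant model
#'
#' Result of [fitLDA()] on the features admitted by [greedyWilks()]:
#' class means, pooled within-class covariance and class priors, with the
#' forward-selection trace (Wilks' lambda and partial-F p-value per step).
#'
#' @slot features ordered selected feature names.
#' @slot trace data.frame with one row per admitted feature: step,
#'   feature, lambda, Fvalue, pvalue.
#' @slot classMeans classes x features matrix.
#' @slot pooledCov pooled within-class covariance of the features.
#' @slot priors class prior probabilities.
#' @slot classes class labels.
#'
#' @export
setClass("WilksLDA", representation(
  features = "character", trace = "data.frame", classMeans = "matrix",
  pooledCov = "matrix", priors = "numeric", classes = "character"))

.validWilksLDA <- function(object) {
  msg <- character()
  if (nrow(object@classMeans) != length(object@classes))
    msg <- c(msg, "one row of class means per class required")
  if (ncol(object@classMeans) != length(object@features))
    msg <- c(msg, "one column of class means per feature required")
  if (abs(sum(object@priors) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (nrow(object@trace) > 1 && any(diff(object@trace$lambda) >= 0))
    msg <- c(msg, "Wilks lambda must be strictly decreasing along the path")
  if (length(msg)) msg else TRUE
}
setValidity("WilksLDA", .validWilksLDA)
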