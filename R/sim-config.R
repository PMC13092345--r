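#' Build a simulation configuration
#'
#' Assembles and validates a [SimConfig-class]. Defaults follow the scaled
#' Drosophila-like parameterisation used throughout the package: 10-generation
#' seasons, symmetric seasonal coefficients, selected locus at the sequence
#' midpoint, and a neutral forward burn-in of `10 * N` generations (the
#' point at which neutral diversity is expected to have equilibrated).
#'
#' @param mode selection mode: `"neutral"`, `"fluctuating"`,
#'   `"het_advantage"`, `"hard_sweep"` or `"soft_sweep"`.
#' @param N diploid population size.
#' @param L sequence length (bp).
#' @param mu neutral mutation rate per bp per generation.
#' @param r recombination rate per bp per generation.
#' @param g season length in generations (left unscaled).
#' @param nGenerations forward generations of selection.
#' @param s,h convenience scalars applied to both seasons (symmetric
#'   parameterisation); override per season with `sSummer`/`sWinter`,
#'   `hSummer`/`hWinter`.
#' @param sSummer,sWinter,hSummer,hWinter seasonal coefficients.
#' @param selectedPosition coordinate of the selected locus; default `L/2`.
#' @param softSweepRate population-wide beneficial mutation rate at the
#'   selected site per generation; the default gives a population-scaled
#'   beneficial mutation rate `4 * N * softSweepRate = 2`, which makes
#'   multiple-origin soft sweeps the typical outcome.
#' @param burnIn neutral burn-in generations; default `10 * N`.
#' @param dfeEnabled enable background selection.
#' @param dfeMean,dfeShape gamma distribution of deleterious effects
#'   (mean given as magnitude; default mean 0.000133, shape 0.35).
#' @param deleteriousFraction deleterious mutations per gamete relative to
#'   `mu * L` (0 disables).
#' @param deleteriousH dominance of deleterious mutations.
#' @param sampleGenerations explicit generations at which to sample.
#' @param sampleSize individuals per sample.
#' @param equilibriumSampling sample one full seasonal cycle after the
#'   selected allele first reaches `pEq` (early timepoint) and the final
#'   complete cycle (long-term timepoint).
#' @param earlyAt fixed cycle start for the early timepoint (used for
#'   neutral runs which have no equilibrium of their own); `-1` detects
#'   the equilibrium from the trajectory.
#' @param cycleOffsets generations within the sampled cycle at which to
#'   take samples; defaults to mid-summer, end-of-summer, mid-winter and
#'   end-of-winter for `g = 10`.
#' @param pEq equilibrium frequency for detection (0.5 in all symmetric
#'   cases).
#' @param restartOnLoss restart when the selected locus goes monomorphic.
#' @param maxRestarts restart cap.
#' @param seed integer seed or `NA`.
#'
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig("fluctuating", N = 500, L = 1e4, s = 0.5, h = 0.6,
#'                  nGenerations = 200, burnIn = 0)
#' cfg
#' @export
simConfig <- function(mode = "neutral", N = 1000, L = 1e5, mu = 1e-7,
                      r = 1e-6, g = 10, nGenerations = 1000,
                      s = 0, h = 0.5,
                      sSummer = s, sWinter = s, hSummer = h, hWinter = h,
                      selectedPosition = L / 2,
                      softSweepRate = 2 / (4 * N),
                      burnIn = 10 * N,
                      dfeEnabled = FALSE, dfeMean = 0.000133,
                      dfeShape = 0.35, deleteriousFraction = 0,
                      deleteriousH = 0.5,
                      sampleGenerations = integer(), sampleSize = 100,
                      equilibriumSampling = FALSE, earlyAt = -1,
                      cycleOffsets = c(ceiling(g / 2) - 1, g - 1,
                                       g + ceiling(g / 2) - 1, 2 * g - 1),
                      pEq = 0.5,
                      restartOnLoss = TRUE, maxRestarts = 1000,
                      seed = NA_integer_) {
  schedule <- list(
    generations = as.integer(sampleGenerations),
    n = as.integer(sampleSize),
    equilibrium = isTRUE(equilibriumSampling),
    earlyAt = as.integer(earlyAt),
    cycleOffsets = as.integer(cycleOffsets),
    pEq = as.numeric(pEq))
  new("SimConfig", N = as.integer(N), L = as.numeric(L),
      mu = as.numeric(mu), r = as.numeric(r), g = as.integer(g),
      nGenerations = as.integer(nGenerations), mode = mode,
      sSummer = as.numeric(sSummer), sWinter = as.numeric(sWinter),
      hSummer = as.numeric(hSummer), hWinter = as.numeric(hWinter),
      selectedPosition = as.numeric(selectedPosition),
      softSweepRate = as.numeric(softSweepRate),
      burnIn = as.integer(burnIn), dfeEnabled = isTRUE(dfeEnabled),
      dfeMean = as.numeric(dfeMean), dfeShape = as.numeric(dfeShape),
      deleteriousFraction = as.numeric(deleteriousFraction),
      deleteriousH = as.numeric(deleteriousH),
      samplingSchedule = schedule,
      restartOnLoss = isTRUE(restartOnLoss),
      maxRestarts = as.integer(maxRestarts), seed = as.integer(seed))
}

#' Scale presets
#'
#' `paperScaleConfig()` is the full study parameterisation: a 5 Mb sequence,
#' N = 10,000 diploids (a 100-fold down-scaling of a natural population of
#' one million), mutation rate 1e-7, recombination rate 1e-6 and 100,000
#' selection generations. `deskScaleConfig()` shrinks this to N = 1,000 and
#' 500 kb over 20,000 generations with the selection coefficient rescaled so
#' that `N * s` matches the paper-scale product. `miniScaleConfig()` is a
#' further reduction (N = 200, 90 kb, 2,000 generations, mutation rate 1e-6)
#' sized for interactive end-to-end runs and the test suite; its selection
#' coefficients are left on the per-generation scale so that deterministic
#' trajectory features (equilibria, cycle amplitudes) match the full-scale
#' model.
#'
#' @param mode selection mode.
#' @param s,h selection and dominance coefficients (applied symmetrically).
#' @param ... further arguments passed to [simConfig()].
#' @return A [SimConfig-class].
#' @export
paperScaleConfig <- function(mode = "fluctuating", s = 0.5, h = 0.6, ...) {
  simConfig(mode = mode, N = 10000, L = 5e6, mu = 1e-7, r = 1e-6,
            nGenerations = 100000, s = s, h = h, sampleSize = 100, ...)
}

#' @rdname paperScaleConfig
#' @export
deskScaleConfig <- function(mode = "fluctuating", s = 0.5, h = 0.6, ...) {
  simConfig(mode = mode, N = 1000, L = 5e5, mu = 1e-7, r = 1e-6,
            nGenerations = 20000, s = min(s * 10, 1), h = h,
            sampleSize = 100, ...)
}

#' @rdname paperScaleConfig
#' @export
miniScaleConfig <- function(mode = "fluctuating", s = 0.5, h = 0.6, ...) {
  simConfig(mode = mode, N = 200, L = 9e4, mu = 1e-6, r = 1e-6,
            nGenerations = 2000, s = s, h = h, sampleSize = 50, ...)
}

#' Rescale population parameters
#'
#' Standard diffusion-scale rescaling by a factor `Q`: the population size is
#' divided by `Q` while mutation, recombination and selection are multiplied
#' by `Q`, keeping `N*mu`, `N*r` and `N*s` constant. Season length is never
#' scaled (seasons shorter than one generation cannot be represented).
#'
#' @param N,r,mu,s natural-population parameters.
#' @param Q scaling factor, `>= 1`.
#' @return list with elements `N`, `r`, `mu`, `s`.
#' @examples
#' scaleParameters(N = 1e6, r = 1e-8, mu = 1e-9, s = 0.01, Q = 100)
#' @export
scaleParameters <- function(N, r, mu, s, Q) {
  if (any(c(N, r, mu, Q) <= 0) || s < 0)
    stop("parameters must be positive (s may be zero)")
  if (Q < 1) stop("Q must be >= 1")
  list(N = N / Q, r = r * Q, mu = mu * Q, s = s * Q)
}
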