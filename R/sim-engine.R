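.modeCode <- c(neutral = 0L, fluctuating = 1L, het_advantage = 2L,
               hard_sweep = 3L, soft_sweep = 4L)

#' Season of a generation
#'
#' Generations are grouped into alternating seasons of `g` generations;
#' generation 0 is the first summer generation (the selected mutation is
#' introduced at the beginning of the summer season).
#'
#' @param t generation index (vectorised), `>= 0`.
#' @param g season length in generations, `>= 1`.
#' @return character vector, `"summer"` or `"winter"`.
#' @examples
#' seasonOf(c(0, 10, 25), g = 10)
#' @export
seasonOf <- function(t, g = 10) {
  if (any(t < 0)) stop("generation index must be >= 0")
  if (g < 1) stop("season length must be >= 1")
  ifelse((t %/% g) %% 2 == 0, "summer", "winter")
}

#' Genotype fitness at the selected locus
#'
#' The seasonal fitness model: in summer the summer allele S is favored
#' ((WW, SW, SS) fitnesses 1, 1 + h_s*s_s, 1 + s_s) and in winter the
#' winter allele W ((1 + s_w, 1 + h_w*s_w, 1)). Heterozygote advantage is
#' season-independent with heterozygote fitness 1 and both homozygotes
#' 1 - s. Sweep modes use (1, 1 + h*s, 1 + s) in every season; neutral is
#' always 1.
#'
#' @param mode selection mode.
#' @param genotype `"WW"`, `"SW"` or `"SS"` (W = winter/ancestral allele,
#'   S = summer/derived allele).
#' @param season `"summer"` or `"winter"`.
#' @param sSummer,sWinter,hSummer,hWinter seasonal coefficients; sweep and
#'   heterozygote-advantage modes read `sSummer`/`hSummer`.
#' @return fitness multiplier.
#' @examples
#' genotypeFitness("fluctuating", "SS", "summer", sSummer = 0.5)   # 1.5
#' genotypeFitness("het_advantage", "SW", "winter", sSummer = 0.1) # 1
#' @export
genotypeFitness <- function(mode, genotype, season = "summer",
                            sSummer = 0, sWinter = sSummer,
                            hSummer = 0.5, hWinter = hSummer) {
  if (!genotype %in% c("WW", "SW", "SS")) stop("unknown genotype")
  if (!season %in% c("summer", "winter")) stop("unknown season")
  w <- switch(mode,
    neutral = c(WW = 1, SW = 1, SS = 1),
    fluctuating = if (season == "summer")
      c(WW = 1, SW = 1 + hSummer * sSummer, SS = 1 + sSummer)
    else
      c(WW = 1 + sWinter, SW = 1 + hWinter * sWinter, SS = 1),
    het_advantage = c(WW = 1 - sSummer, SW = 1, SS = 1 - sSummer),
    hard_sweep = ,
    soft_sweep = c(WW = 1, SW = 1 + hSummer * sSummer, SS = 1 + sSummer),
    stop("unknown selection mode"))
  unname(w[genotype])
}

#' One-generation deterministic allele-frequency update
#'
#' The infinite-population (N -> infinity) recursion for the selected
#' allele under random mating:
#' `p' = (p^2 w_SS + p(1-p) w_SW) / (p^2 w_SS + 2p(1-p) w_SW + (1-p)^2 w_WW)`.
#' Serves as the expectation oracle for the stochastic engines.
#'
#' @param p frequency of the summer/derived allele, in `[0, 1]`.
#' @inheritParams genotypeFitness
#' @return updated frequency.
#' @examples
#' deterministicUpdate(0.5, "fluctuating", "summer", sSummer = 1,
#'                     hSummer = 0.6)  # 0.9 / 1.55
#' @export
deterministicUpdate <- function(p, mode, season = "summer",
                                sSummer = 0, sWinter = sSummer,
                                hSummer = 0.5, hWinter = hSummer) {
  if (any(p < 0 | p > 1)) stop("frequency must lie in [0, 1]")
  wSS <- genotypeFitness(mode, "SS", season, sSummer, sWinter, hSummer, hWinter)
  wSW <- genotypeFitness(mode, "SW", season, sSummer, sWinter, hSummer, hWinter)
  wWW <- genotypeFitness(mode, "WW", season, sSummer, sWinter, hSummer, hWinter)
  num <- p^2 * wSS + p * (1 - p) * wSW
  den <- p^2 * wSS + 2 * p * (1 - p) * wSW + (1 - p)^2 * wWW
  out <- ifelse(p %in% c(0, 1), p, num / den)
  out
}

#' Deterministic seasonal limit cycle
#'
#' Iterates the deterministic recursion over whole seasonal cycles from
#' `p = 0.5` until the cycle map converges, then returns one full cycle of
#' frequencies together with its amplitude (max - min) and mean.
#'
#' @inheritParams genotypeFitness
#' @param g season length.
#' @param tol convergence tolerance on the cycle-start frequency.
#' @param maxCycles iteration cap.
#' @return list with `freq` (length `2 g`, generations within the cycle),
#'   `amplitude` and `meanFreq`.
#' @examples
#' limitCycle(sSummer = 1, hSummer = 0.6)$amplitude  # ~0.68
#' @export
limitCycle <- function(sSummer, sWinter = sSummer, hSummer = 0.5,
                       hWinter = hSummer, g = 10, tol = 1e-12,
                       maxCycles = 1e5) {
  p <- 0.5
  cycle <- function(p) {
    for (t in seq_len(g))
      p <- deterministicUpdate(p, "fluctuating", "summer",
                               sSummer, sWinter, hSummer, hWinter)
    for (t in seq_len(g))
      p <- deterministicUpdate(p, "fluctuating", "winter",
                               sSummer, sWinter, hSummer, hWinter)
    p
  }
  for (i in seq_len(maxCycles)) {
    p2 <- cycle(p)
    if (abs(p2 - p) < tol) break
    p <- p2
  }
  freq <- numeric(2 * g)
  q <- p
  for (t in seq_len(g)) {
    q <- deterministicUpdate(q, "fluctuating", "summer",
                             sSummer, sWinter, hSummer, hWinter)
    freq[t] <- q
  }
  for (t in seq_len(g)) {
    q <- deterministicUpdate(q, "fluctuating", "winter",
                             sSummer, sWinter, hSummer, hWinter)
    freq[g + t] <- q
  }
  list(freq = freq, amplitude = max(freq) - min(freq), meanFreq = mean(freq))
}

#' Simulate a single-locus allele-frequency trajectory
#'
#' Fast diploid Wright-Fisher path at the selected locus only: each
#' generation applies the deterministic selection update and then samples
#' 2N gametes binomially. The allele is introduced as a single de novo
#' copy (frequency `1/(2N)`) at the beginning of the summer season;
#' replicates in which the locus goes monomorphic before `nGenerations`
#' are restarted (fluctuating / heterozygote advantage; hard sweeps
#' restart on loss only).
#'
#' @param N diploid population size.
#' @param mode selection mode (`"soft_sweep"` requires the sequence
#'   engine, [runReplicate()]).
#' @inheritParams genotypeFitness
#' @param g season length.
#' @param nGenerations generations to simulate.
#' @param p0 initial frequency.
#' @param restartOnLoss restart when the locus goes monomorphic.
#' @param maxRestarts restart cap.
#' @param stopAtFixation for hard sweeps, stop once fixed.
#' @return A [SeasonalTrajectory-class].
#' @examples
#' set.seed(1)
#' tr <- simulateTrajectory(1000, "fluctuating", sSummer = 0.5,
#'                          hSummer = 0.6, nGenerations = 400)
#' terminalState(tr)
#' @export
simulateTrajectory <- function(N, mode, sSummer = 0, sWinter = sSummer,
                               hSummer = 0.5, hWinter = hSummer, g = 10,
                               nGenerations = 1000, p0 = 1 / (2 * N),
                               restartOnLoss = TRUE, maxRestarts = 1000,
                               stopAtFixation = FALSE) {
  if (!mode %in% names(.modeCode) || mode == "soft_sweep")
    stop("mode must be neutral, fluctuating, het_advantage or hard_sweep")
  res <- cpp_single_locus_wf(as.integer(N), as.integer(nGenerations),
                             .modeCode[[mode]], sSummer, sWinter, hSummer,
                             hWinter, as.integer(g), p0,
                             isTRUE(restartOnLoss), as.integer(maxRestarts),
                             isTRUE(stopAtFixation))
  new("SeasonalTrajectory", freq = res$freq, seasonLength = as.integer(g),
      mode = mode, restartCount = as.integer(res$restarts),
      terminalState = res$terminal, nOrigins = integer(),
      traitFixed = logical(), tEq = -1L)
}

.cppConfig <- function(config, nGenerations = config@nGenerations,
                       introduce = TRUE, returnPopulation = FALSE,
                       initPop = NULL) {
  sch <- config@samplingSchedule
  list(N = config@N, L = config@L, mu = config@mu, r = config@r,
       g = config@g, n_generations = as.integer(nGenerations),
       mode = .modeCode[[config@mode]],
       s_s = config@sSummer, s_w = config@sWinter,
       h_s = config@hSummer, h_w = config@hWinter,
       selected_position = config@selectedPosition,
       soft_sweep_rate = config@softSweepRate,
       burn_in = config@burnIn, dfe_enabled = config@dfeEnabled,
       dfe_mean = config@dfeMean, dfe_shape = config@dfeShape,
       deleterious_fraction = config@deleteriousFraction,
       deleterious_h = config@deleteriousH,
       restart_on_loss = config@restartOnLoss,
       max_restarts = config@maxRestarts,
       stop_at_fixation = config@mode %in% c("hard_sweep", "soft_sweep"),
       return_population = isTRUE(returnPopulation),
       sample_gens = sch$generations, sample_n = sch$n,
       eq_sampling = sch$equilibrium, p_eq = sch$pEq,
       early_at = sch$earlyAt, cycle_offsets = sch$cycleOffsets,
       introduce = isTRUE(introduce), init_pop = initPop)
}

.wrapPopulation <- function(p, config) {
  structure(list(haplotypes = p$haplotypes, beneficial = p$beneficial,
                 mut_position = p$mut_position, mut_class = p$mut_class,
                 mut_s = p$mut_s, mut_h = p$mut_h,
                 N = config@N, L = config@L),
            class = "wfPopulation")
}

#' Run the neutral burn-in
#'
#' Evolves a population neutrally for `burnIn` generations (default
#' `10 * N`, after which neutral diversity is expected to be at its
#' equilibrium `4 N mu` per bp) and returns the resulting population. No
#' selected mutation is present.
#'
#' @param config a [SimConfig-class].
#' @return A `wfPopulation`: list of 2N haplotypes (integer mutation ids),
#'   the per-haplotype beneficial-origin vector (all zero) and the
#'   mutation table.
#' @export
runBurnIn <- function(config) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  cfg <- .cppConfig(config, nGenerations = 0L, introduce = FALSE,
                    returnPopulation = TRUE)
  cfg$eq_sampling <- FALSE
  cfg$sample_gens <- integer()
  res <- cpp_sequence_wf(cfg)
  .wrapPopulation(res$population, config)
}

#' Introduce the selected mutation
#'
#' Places a single summer-beneficial mutation on one uniformly chosen
#' haplotype (fluctuating, heterozygote advantage, hard sweep); for soft
#' sweeps no copy is added (origins arrive by recurrent mutation during
#' the run) and for neutral runs nothing happens. Calling twice on the
#' same population is a state error.
#'
#' @param pop a `wfPopulation` from [runBurnIn()].
#' @param config the [SimConfig-class] (supplies the mode).
#' @return The population with the beneficial-origin vector updated.
#' @export
introduceSelected <- function(pop, config) {
  if (!inherits(pop, "wfPopulation")) stop("pop must be a wfPopulation")
  if (any(pop$beneficial > 0))
    stop("selected mutation already introduced")
  if (config@mode %in% c("fluctuating", "het_advantage", "hard_sweep")) {
    j <- sample.int(2L * pop$N, 1L)
    pop$beneficial[j] <- 1L
  }
  pop
}

#' Advance a population by whole generations
#'
#' Runs the individual-based engine for `generations` generations from an
#' existing population, without burn-in and without introducing a selected
#' mutation. Season labels continue from `startGeneration`.
#'
#' @param pop a `wfPopulation`.
#' @param config a [SimConfig-class] supplying rates and selection.
#' @param generations generations to advance.
#' @return list with the advanced `population` and the frequency
#'   trajectory of the beneficial class.
#' @export
advancePopulation <- function(pop, config, generations = 1L) {
  if (!inherits(pop, "wfPopulation")) stop("pop must be a wfPopulation")
  cfg <- .cppConfig(config, nGenerations = generations, introduce = FALSE,
                    returnPopulation = TRUE, initPop = unclass(pop))
  cfg$burn_in <- 0L
  cfg$eq_sampling <- FALSE
  cfg$sample_gens <- integer()
  cfg$restart_on_loss <- FALSE
  cfg$stop_at_fixation <- FALSE
  res <- cpp_sequence_wf(cfg)
  list(population = .wrapPopulation(res$population, config),
       freq = res$freq)
}

#' Run one full simulation replicate
#'
#' Burn-in, introduction of the selected mutation at the start of summer,
#' and `nGenerations` of seasonal forward simulation with restart-on-loss,
#' emitting haplotype samples according to the sampling schedule. With
#' `equilibriumSampling`, samples are taken across one full seasonal cycle
#' immediately after the selected allele first reaches its equilibrium
#' frequency (early timepoint) and across the final complete cycle
#' (long-term timepoint). Sweep modes stop at fixation of the beneficial
#' trait and sample there.
#'
#' @param config a [SimConfig-class].
#' @param initialPopulation optional `wfPopulation` to start from (skips
#'   the burn-in), e.g. an externally generated equilibrium population.
#' @param returnPopulation also return the final population.
#' @return list with elements `trajectory` ([SeasonalTrajectory-class]),
#'   `samples` (list of [HapMatrix-class]), `restartCount`, `tEq`,
#'   `fixationGeneration` and optionally `population`.
#' @examples
#' cfg <- simConfig("neutral", N = 50, L = 1e4, mu = 1e-5, r = 1e-6,
#'                  nGenerations = 10, burnIn = 500,
#'                  sampleGenerations = 10, sampleSize = 10, seed = 7)
#' rep <- runReplicate(cfg)
#' rep$samples[[1]]
#' @export
runReplicate <- function(config, initialPopulation = NULL,
                         returnPopulation = FALSE) {
  validObject(config)
  if (!is.na(config@seed)) set.seed(config@seed)
  initPop <- if (!is.null(initialPopulation)) unclass(initialPopulation)
  cfg <- .cppConfig(config, introduce = TRUE,
                    returnPopulation = returnPopulation, initPop = initPop)
  if (!is.null(initPop)) cfg$burn_in <- 0L
  res <- cpp_sequence_wf(cfg)
  traj <- new("SeasonalTrajectory", freq = res$freq,
              seasonLength = config@g, mode = config@mode,
              restartCount = as.integer(res$restarts),
              terminalState = res$terminal,
              nOrigins = as.integer(res$n_origins),
              traitFixed = as.logical(res$trait_fixed),
              tEq = as.integer(res$t_eq))
  samples <- lapply(res$samples, function(s) {
    gen <- s$generation
    new("HapMatrix", mat = s$matrix, positions = as.numeric(s$positions),
        seqLength = config@L, siteClass = as.integer(s$site_class),
        metadata = list(generation = gen, timepoint = s$label,
                        season = seasonOf(gen, config@g),
                        cycleOffset = gen %% (2L * config@g),
                        mode = config@mode))
  })
  out <- list(trajectory = traj, samples = samples,
              restartCount = as.integer(res$restarts),
              tEq = as.integer(res$t_eq),
              fixationGeneration = as.integer(res$fixation_generation))
  if (returnPopulation)
    out$population <- .wrapPopulation(res$population, config)
  out
}

#' Detect fixation of the beneficial trait
#'
#' Hard sweep: the first generation at which the derived allele reaches
#' frequency 1. Soft sweep: the first generation at which every individual
#' carries beneficial alleles on both haplotypes while at least two
#' distinct mutational origins segregate population-wide; a sweep that
#' fixes from a single origin is a hardened sweep and returns `NA` with
#' attribute `hardened = TRUE`.
#'
#' @param trajectory a [SeasonalTrajectory-class] from a sweep replicate.
#' @param mode `"hard_sweep"` or `"soft_sweep"`.
#' @return generation of fixation, or `NA` if never reached.
#' @export
detectFixation <- function(trajectory, mode = trajectory@mode) {
  if (!mode %in% c("hard_sweep", "soft_sweep"))
    stop("fixation detection applies to sweep modes only")
  if (mode == "hard_sweep") {
    hit <- which(trajectory@freq >= 1)
    return(if (length(hit)) hit[1L] - 1L else NA_integer_)
  }
  if (!length(trajectory@traitFixed))
    stop("soft-sweep detection requires per-origin records from runReplicate")
  hit <- which(trajectory@traitFixed & trajectory@nOrigins >= 2L)
  if (length(hit)) return(hit[1L] - 1L)
  hardened <- any(trajectory@traitFixed & trajectory@nOrigins == 1L)
  structure(NA_integer_, hardened = hardened)
}

#' Mean within-cycle amplitude of fluctuation
#'
#' Per seasonal cycle (2g generations), the amplitude is the range
#' (max - min) of the selected-allele frequency within the cycle; the mean
#' over the final `cycles` complete cycles is returned. At the
#' deterministic limit this equals the end-of-summer minus end-of-winter
#' frequency.
#'
#' @param trajectory a [SeasonalTrajectory-class] at long-term equilibrium.
#' @param cycles number of final complete cycles to average over.
#' @return mean amplitude (allele frequency units).
#' @export
amplitudeOfFluctuation <- function(trajectory, cycles = 10) {
  g <- trajectory@seasonLength
  cl <- 2L * g
  p <- trajectory@freq
  nGen <- length(p) - 1L
  nCycles <- nGen %/% cl
  if (nCycles < 1) stop("need at least one complete seasonal cycle")
  cycles <- min(cycles, nCycles)
  amps <- vapply(seq_len(cycles), function(i) {
    e <- nGen - (i - 1L) * cl
    s <- e - cl + 1L
    win <- p[(s:e) + 1L]
    max(win) - min(win)
  }, numeric(1))
  mean(amps)
}

#' First-hitting time of the equilibrium frequency
#'
#' The first generation at which the trajectory reaches `pEq`, the
#' deterministic equilibrium frequency (0.5 for symmetric heterozygote
#' advantage and symmetric fluctuating parameters). `NA` if the allele was
#' lost before reaching it.
#'
#' @param trajectory a [SeasonalTrajectory-class].
#' @param pEq equilibrium frequency.
#' @return generation index, or `NA`.
#' @export
timeToEquilibrium <- function(trajectory, pEq = 0.5) {
  hit <- which(trajectory@freq >= pEq)
  if (length(hit)) hit[1L] - 1L else NA_integer_
}
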