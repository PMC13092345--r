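# Reduced-scale simulation cohort shared by the end-to-end tests.
#
# Study conditions (chosen once; see the methods vignette): N = 200
# diploids, 90 kb sequence (nine 10 kb windows, selected site at the
# centre of window 5), mu = 1e-6, r = 1e-6, 10-generation seasons,
# 10N burn-in, 2,000 selection generations, 50 individuals sampled per
# timepoint, 50 replicates per mode (30 for the strong-selection arm).

.cohortEnv <- new.env(parent = emptyenv())

cohortConfig <- function(mode, s, h, seed) {
  simConfig(mode = mode, N = 200, L = 9e4, mu = 1e-6, r = 1e-6,
            s = s, h = h, nGenerations = 2000, burnIn = 2000,
            equilibriumSampling = TRUE, sampleSize = 50,
            earlyAt = if (mode == "neutral") 160L else -1L,
            seed = seed)
}

# long-format window statistics for one replicate's samples
replicateStatLong <- function(rep, replicateId, class) {
  do.call(rbind, lapply(rep$samples, function(s) {
    cp <- cyclePointLabel(s@metadata$cycleOffset, 10)
    tab <- windowStats(s, windowSize = 1e4)
    cbind(replicate = replicateId, class = class,
          timepoint = s@metadata$timepoint, cyclePoint = cp,
          generation = s@metadata$generation, tab)
  }))
}

# runs (or returns the cached) cohort: neutral / FS s=0.5 / HA s=0.1
# for the classifier, plus FS s=1 for the footprint checks
miniCohort <- function() {
  if (!is.null(.cohortEnv$statLong)) return(as.list(.cohortEnv))
  arms <- list(
    list(class = "neutral", mode = "neutral", s = 0, h = 0.5, n = 50),
    list(class = "fluctuating", mode = "fluctuating", s = 0.5, h = 0.6,
         n = 50),
    list(class = "het_advantage", mode = "het_advantage", s = 0.1, h = 0.5,
         n = 50),
    list(class = "fluctuating_strong", mode = "fluctuating", s = 1, h = 0.6,
         n = 30))
  rows <- list()
  restarts <- numeric()
  for (ai in seq_along(arms)) {
    arm <- arms[[ai]]
    for (i in seq_len(arm$n)) {
      cfg <- cohortConfig(arm$mode, arm$s, arm$h,
                          seed = 202609L + ai * 10000L + i)
      rep <- runReplicate(cfg)
      rows[[length(rows) + 1L]] <-
        replicateStatLong(rep, replicateId = i, class = arm$class)
      restarts <- c(restarts, rep$restartCount)
    }
  }
  statLong <- do.call(rbind, rows)
  # neutral NCD reference from the neutral arm's long-term summer samples
  neutralTabs <- split(
    statLong[statLong$class == "neutral" & statLong$timepoint == "long" &
               statLong$cyclePoint == "end_summer", ],
    statLong$replicate[statLong$class == "neutral" &
                         statLong$timepoint == "long" &
                         statLong$cyclePoint == "end_summer"])
  ref <- neutralNCDReference(neutralTabs)
  statLong <- suppressWarnings(addStandardizedNCD(statLong, ref))
  .cohortEnv$statLong <- statLong
  .cohortEnv$ncdReference <- ref
  .cohortEnv$restarts <- restarts
  as.list(.cohortEnv)
}
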