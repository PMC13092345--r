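test_that("seasons alternate in blocks of g generations starting with summer", {
  expect_equal(seasonOf(0, 10), "summer")
  expect_equal(seasonOf(10, 10), "winter")
  expect_equal(seasonOf(25, 10), "summer")  # floor(25/10) = 2, even
  expect_equal(seasonOf(0:39, 10),
               rep(c("summer", "winter"), each = 10, times = 2))
  expect_error(seasonOf(-1, 10), "must be")
  expect_error(seasonOf(5, 0), "must be")
})

test_that("genotype fitness follows the seasonal model", {
  expect_equal(genotypeFitness("fluctuating", "SS", "summer", sSummer = 0.5),
               1.5)
  expect_equal(genotypeFitness("fluctuating", "SW", "winter",
                               sWinter = 0.5, hWinter = 0.6), 1.3)
  expect_equal(genotypeFitness("fluctuating", "WW", "winter", sWinter = 0.5),
               1.5)
  expect_equal(genotypeFitness("fluctuating", "WW", "summer", sSummer = 1), 1)
  # heterozygote advantage: heterozygote fitness 1 in every season
  expect_equal(genotypeFitness("het_advantage", "SW", "summer",
                               sSummer = 0.1), 1)
  expect_equal(genotypeFitness("het_advantage", "SW", "winter",
                               sSummer = 0.1), 1)
  expect_equal(genotypeFitness("het_advantage", "SS", "summer",
                               sSummer = 0.1), 0.9)
  expect_equal(genotypeFitness("neutral", "SS", "winter"), 1)
  expect_equal(genotypeFitness("hard_sweep", "SW", "winter",
                               sSummer = 0.2, hSummer = 0.5), 1.1)
  expect_error(genotypeFitness("fluctuating", "XX", "summer"), "genotype")
  expect_error(genotypeFitness("banana", "SS", "summer"), "mode")
})

test_that("deterministic update matches the one-locus recursion", {
  expect_equal(deterministicUpdate(0.5, "neutral"), 0.5)
  expect_equal(deterministicUpdate(0, "fluctuating", sSummer = 1), 0)
  expect_equal(deterministicUpdate(1, "fluctuating", sSummer = 1), 1)
  expect_equal(deterministicUpdate(0.5, "fluctuating", "summer",
                                   sSummer = 1, hSummer = 0.6),
               0.9 / 1.55, tolerance = 1e-12)
  # symmetric overdominance has a fixed point at 0.5
  expect_equal(deterministicUpdate(0.5, "het_advantage", sSummer = 0.1), 0.5)
  expect_error(deterministicUpdate(1.2, "neutral"), "\\[0, 1\\]")
})

test_that("parameter scaling preserves population-scaled compound parameters", {
  sc <- scaleParameters(N = 1e6, r = 1e-8, mu = 1e-9, s = 0.01, Q = 100)
  expect_equal(sc$N, 10000)
  expect_equal(sc$r, 1e-6)
  expect_equal(sc$mu, 1e-7)
  expect_equal(sc$s, 1)
  expect_equal(sc$N * sc$mu, 1e6 * 1e-9)
  expect_error(scaleParameters(-1, 1e-8, 1e-9, 0.1, 10), "positive")
  expect_error(scaleParameters(1e6, 1e-8, 1e-9, 0.1, 0.5), "Q")
})

test_that("deterministic limit-cycle amplitude increases with selection", {
  amps <- vapply(c(0.1, 0.5, 1), function(s)
    limitCycle(sSummer = s, hSummer = 0.6)$amplitude, numeric(1))
  expect_true(all(diff(amps) > 0))
  # frozen values from iterating the recursion to convergence
  expect_equal(amps, c(0.1182390, 0.4592714, 0.6769624), tolerance = 1e-6)
  # symmetric parameters oscillate around 0.5
  lc <- limitCycle(sSummer = 0.5, hSummer = 0.6)
  expect_equal(mean(range(lc$freq)), 0.5, tolerance = 0.02)
})

test_that("single-locus trajectories are deterministic given a seed", {
  run <- function() simulateTrajectory(500, "fluctuating", sSummer = 0.5,
                                       hSummer = 0.6, nGenerations = 300)
  set.seed(99); a <- run()
  set.seed(99); b <- run()
  expect_identical(frequencies(a), frequencies(b))
  expect_identical(restartCount(a), restartCount(b))
})

test_that("one-generation change under selection matches the deterministic oracle", {
  set.seed(7)
  N <- 1e5
  reps <- 50
  pNext <- replicate(reps, {
    tr <- simulateTrajectory(N, "fluctuating", sSummer = 1, hSummer = 0.6,
                             nGenerations = 1, p0 = 0.5,
                             restartOnLoss = FALSE)
    frequencies(tr)[2]
  })
  expected <- 0.9 / 1.55
  se <- sqrt(expected * (1 - expected) / (2 * N)) / sqrt(reps)
  expect_lt(abs(mean(pNext) - expected), 4 * se)
})

test_that("neutral reproduction conserves allele frequency in expectation", {
  set.seed(8)
  N <- 2000
  reps <- 400
  pNext <- replicate(reps, {
    tr <- simulateTrajectory(N, "neutral", nGenerations = 1, p0 = 0.3,
                             restartOnLoss = FALSE)
    frequencies(tr)[2]
  })
  se <- sqrt(0.3 * 0.7 / (2 * N)) / sqrt(reps)
  expect_lt(abs(mean(pNext) - 0.3), 4 * se)
})

test_that("monomorphic selected loci trigger restarts and survival", {
  set.seed(10)
  tr <- simulateTrajectory(200, "fluctuating", sSummer = 0.5, hSummer = 0.6,
                           nGenerations = 500)
  expect_gte(restartCount(tr), 0)
  expect_equal(terminalState(tr), "polymorphic")
  p <- frequencies(tr)
  expect_true(all(p > 0 & p < 1))
  # without restarts a de novo copy is usually lost
  set.seed(10)
  losses <- replicate(20, terminalState(
    simulateTrajectory(200, "fluctuating", sSummer = 0.1, hSummer = 0.6,
                       nGenerations = 100, restartOnLoss = FALSE)))
  expect_true(any(losses == "lost"))
})

test_that("hard sweeps absorb at fixation and are detected there", {
  set.seed(12)
  tr <- simulateTrajectory(300, "hard_sweep", sSummer = 1, hSummer = 0.5,
                           nGenerations = 2000, stopAtFixation = TRUE)
  expect_equal(terminalState(tr), "fixed")
  gFix <- detectFixation(tr, "hard_sweep")
  p <- frequencies(tr)
  expect_equal(p[gFix + 1], 1)
  expect_true(all(p[(gFix + 1):length(p)] == 1))  # absorbed forever
  expect_true(all(p[seq_len(gFix)] < 1))
  expect_error(detectFixation(tr, "fluctuating"), "sweep")
})

test_that("amplitude and time-to-equilibrium behave on degenerate trajectories", {
  flat <- new("SeasonalTrajectory", freq = rep(0.5, 61),
              seasonLength = 10L, mode = "fluctuating", restartCount = 0L,
              terminalState = "polymorphic", nOrigins = integer(),
              traitFixed = logical(), tEq = -1L)
  expect_equal(amplitudeOfFluctuation(flat), 0)
  expect_equal(timeToEquilibrium(flat), 0)  # starts at equilibrium
  short <- new("SeasonalTrajectory", freq = rep(0.5, 10),
               seasonLength = 10L, mode = "fluctuating", restartCount = 0L,
               terminalState = "polymorphic", nOrigins = integer(),
               traitFixed = logical(), tEq = -1L)
  expect_error(amplitudeOfFluctuation(short), "cycle")
  lost <- new("SeasonalTrajectory", freq = c(0.1, 0.05, 0),
              seasonLength = 1L, mode = "het_advantage", restartCount = 0L,
              terminalState = "lost", nOrigins = integer(),
              traitFixed = logical(), tEq = -1L)
  expect_true(is.na(timeToEquilibrium(lost)))
})

test_that("symmetric fluctuating selection oscillates around one half", {
  set.seed(21)
  means <- replicate(12, {
    tr <- simulateTrajectory(2000, "fluctuating", sSummer = 0.5,
                             hSummer = 0.6, nGenerations = 2000)
    mean(frequencies(tr)[1001:2001])
  })
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.5), 3 * se + 0.01)
})
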