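test_that("release populations are founded with the stated composition", {
  pop <- buildReleasePopulation(releaseSpec(25, 50, 50))
  expect_identical(populationSize(pop), 125L)
  expect_identical(unname(genotypeCounts(pop)["D/T", "male"]), 25L)
  expect_identical(unname(genotypeCounts(pop)["T/T", "female"]), 50L)
  expect_equal(alleleFrequencies(pop)$frequencies[["D"]], 0.10)

  big <- buildReleasePopulation(releaseSpec(50, 75, 75))
  expect_identical(populationSize(big), 200L)
  expect_equal(alleleFrequencies(big)$frequencies[["D"]], 0.125)

  ctrl <- buildReleasePopulation(releaseSpec(25, 50, 50, "N"))
  expect_identical(unname(genotypeCounts(ctrl)["D/N", "male"]), 25L)
  expect_equal(alleleFrequencies(ctrl)$gfp_negative, 1)
})

test_that("initial drive-allele frequency follows the release arithmetic", {
  expect_equal(initialAlleleFrequency(releaseSpec(50, 75, 75)), 0.125)
  expect_equal(initialAlleleFrequency(releaseSpec(25, 50, 50)), 0.10)
  expect_equal(initialAlleleFrequency(releaseSpec(0, 50, 50)), 0)
  expect_equal(initialAlleleFrequency(releaseSpec(25, 50, 50, "N")), 0.10)
  expect_error(initialAlleleFrequency(releaseSpec(0, 0, 0)), "empty")
})

test_that("one stochastic generation respects brood size, cap and genotype logic", {
  set.seed(5)
  # all-wild-type population: offspring all T/T, size min(cap, 40 * females)
  pop <- buildReleasePopulation(releaseSpec(0, 10, 10))
  off <- stepGeneration(pop, paramsTALEN(), eggsPerFemale = 40, cap = 1000)
  expect_identical(populationSize(off), 400L)
  expect_identical(sum(genotypeCounts(off)["T/T", ]), 400L)
  expect_identical(generation(off), 1L)
  # capping retains exactly cap offspring
  capped <- stepGeneration(pop, paramsTALEN(), eggsPerFemale = 40, cap = 123)
  expect_identical(populationSize(capped), 123L)
  # perfect drive: a single D/T father sires only D/T offspring
  m <- sseDrive:::.emptyCounts()
  m["D/T", "male"] <- 1L; m["T/T", "female"] <- 1L
  tiny <- sseDrive:::newPopulation(m)
  off <- stepGeneration(tiny, DriveParams(1, 1, 1), 40, cap = 400)
  expect_identical(populationSize(off), 40L)
  expect_identical(sum(genotypeCounts(off)["D/T", ]), 40L)
})

test_that("losing either sex terminates the run with an extinct flag", {
  m <- sseDrive:::.emptyCounts()
  m["T/T", "male"] <- 5L
  malesOnly <- sseDrive:::newPopulation(m)
  off <- stepGeneration(malesOnly, paramsTALEN(), 40, cap = 100)
  expect_true(isExtinct(off))
  expect_identical(populationSize(off), 0L)
  # a full run pads the trajectory with terminal records
  trajs <- runSimulation(releaseSpec(0, 5, 0), paramsTALEN(), cap = 100,
                         generations = 4, iterations = 1, seed = 9)
  rec <- trajectoryRecords(trajs[[1]])
  expect_identical(nrow(rec), 5L)
  expect_true(all(rec$extinct[-1]))
  expect_true(all(is.na(rec$gfp_negative[-1])))
})

test_that("identical seeds reproduce bit-identical trajectories", {
  run <- function() runSimulation(releaseSpec(25, 50, 50), paramsZFN(),
                                  cap = 100, generations = 4,
                                  iterations = 3, seed = 77)
  a <- run(); b <- run()
  expect_identical(lapply(a, trajectoryRecords), lapply(b, trajectoryRecords))
  # and a different seed gives a different realization
  c_ <- runSimulation(releaseSpec(25, 50, 50), paramsZFN(), cap = 100,
                      generations = 4, iterations = 3, seed = 78)
  expect_false(identical(trajectoryRecords(a[[1]]),
                         trajectoryRecords(c_[[1]])))
})

test_that("population size never exceeds the cap along a run", {
  trajs <- runSimulation(releaseSpec(50, 75, 75), paramsZFN(), cap = 400,
                         generations = 6, iterations = 3, seed = 4)
  for (t in trajs) {
    rec <- trajectoryRecords(t)
    expect_true(all(rec$n[-1] <= 400))
    live <- !rec$extinct
    sums <- with(rec[live, ], freq_T + freq_D + freq_DN + freq_N)
    expect_equal(sums, rep(1, sum(live)), tolerance = 1e-9)
  }
})

test_that("single-generation offspring match the deterministic recursion (oracle)", {
  release <- releaseSpec(50, 75, 75)
  oracle <- recursionStep(releaseState(release), paramsZFN())
  expected <- alleleFrequencies(oracle)$frequencies[["D"]]
  pop <- buildReleasePopulation(release)
  set.seed(101)
  reps <- 500
  freqs <- vapply(seq_len(reps), function(i) {
    off <- stepGeneration(pop, paramsZFN(), 40, cap = 400)
    alleleFrequencies(off)$frequencies[["D"]]
  }, numeric(1))
  se <- sd(freqs) / sqrt(reps)
  expect_lt(abs(mean(freqs) - expected), 3 * se)
})

test_that("without cleavage the drive-allele frequency is a martingale", {
  # sex-balanced release (50 males, 50 females) so the count-based release
  # frequency and the sex-averaged mating expectation coincide at 0.125
  neutral <- DriveParams(0, 0.5, 0.5)
  release <- releaseSpec(25, 25, 50)
  trajs <- runSimulation(release, neutral, cap = 100, generations = 5,
                         iterations = 200, seed = 55)
  finals <- vapply(trajs, function(t) {
    rec <- trajectoryRecords(t)
    rec$freq_D[nrow(rec)]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - initialAlleleFrequency(release)), 3 * se)
})

test_that("the refractory control shows no systematic drive-allele trend", {
  # 25 D/N males + 50 N/N males + 50 N/N females: generation 0 carries D at
  # 10% of alleles; random mating weighs the two sexes equally, so from
  # generation 1 on the expected D frequency is (0 + 25/150) / 2 = 1/12 and
  # stays there (martingale: the drive has no cleavable substrate)
  release <- releaseSpec(25, 50, 50, "N")
  trajs <- runSimulation(release, paramsTALEN(), cap = 100,
                         generations = 10, iterations = 200, seed = 13)
  mat <- vapply(trajs, function(t) trajectoryRecords(t)$freq_D, numeric(11))
  expect_equal(mean(mat[1, ]), 0.10)
  for (g in 2:11) {
    se <- sd(mat[g, ]) / sqrt(ncol(mat))
    expect_lt(abs(mean(mat[g, ]) - 1 / 12), 3 * se)
  }
})

test_that("trajectory summaries aggregate the GFP-negative fraction correctly", {
  trajs <- runSimulation(releaseSpec(25, 50, 50), paramsTALEN(), cap = 100,
                         generations = 3, iterations = 4, seed = 2)
  s <- summarizeTrajectories(trajs)
  expect_identical(nrow(s), 4L)
  mat <- vapply(trajs, gfpNegative, numeric(4))
  expect_equal(s$mean, rowMeans(mat))
  expect_equal(s$min, apply(mat, 1, min))
  expect_equal(s$max, apply(mat, 1, max))
  # a single trajectory summarizes to itself
  s1 <- summarizeTrajectories(trajs[1])
  expect_equal(s1$mean, gfpNegative(trajs[[1]]))
  expect_equal(s1$median, s1$mean)
  expect_error(summarizeTrajectories(list()), "no trajectories")
})
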