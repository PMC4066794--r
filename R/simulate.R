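#' One generation of the stochastic simulator
#'
#' Implements one discrete, non-overlapping generation of random mating:
#' each female is assigned a single father drawn uniformly at random from
#' the males (with replacement across females, so one male may sire several
#' broods); each female lays `eggsPerFemale` eggs; each egg draws one gamete
#' from each parent's [gameteDistribution()] and a sex with probability 1/2;
#' all genotypes have equal survival and fertility. If the offspring pool
#' exceeds `cap`, a uniform random subset of exactly `cap` offspring founds
#' the next generation.
#'
#' If either sex is absent the run is terminated: an empty population
#' flagged extinct is returned.
#'
#' Uses R's global RNG stream; seed with [set.seed()] (or use
#' [runSimulation()] which manages per-iteration seeds).
#'
#' @param pop A [`Population-class`] object.
#' @param params A [`DriveParams-class`] object.
#' @param eggsPerFemale Eggs laid per female (default 40).
#' @param cap Population size ceiling applied to the offspring pool.
#' @return The next-generation [`Population-class`].
#' @examples
#' set.seed(1)
#' pop <- buildReleasePopulation(releaseSpec(25, 50, 50))
#' stepGeneration(pop, paramsTALEN(), cap = 100)
#' @export
stepGeneration <- function(pop, params, eggsPerFemale = 40L, cap) {
  methods::validObject(params)
  if (eggsPerFemale < 1L) stop("eggsPerFemale must be >= 1")
  if (cap < 2L) stop("cap must be >= 2")
  males <- rep(genotypePairs(), pop@counts[, "male"])
  females <- rep(genotypePairs(), pop@counts[, "female"])
  if (length(males) == 0L || length(females) == 0L)
    return(newPopulation(.emptyCounts(), generation = pop@generation + 1L,
                         extinct = TRUE))
  fathers <- males[sample.int(length(males), length(females),
                              replace = TRUE)]
  motherEgg <- rep(females, each = eggsPerFemale)
  fatherEgg <- rep(fathers, each = eggsPerFemale)
  mAllele <- .drawGametes(motherEgg, "female", params)
  fAllele <- .drawGametes(fatherEgg, "male", params)
  sex <- sample.int(2L, length(motherEgg), replace = TRUE)
  if (length(motherEgg) > cap) {
    keep <- sample.int(length(motherEgg), cap)
    mAllele <- mAllele[keep]; fAllele <- fAllele[keep]; sex <- sex[keep]
  }
  geno <- .pairKey(mAllele, fAllele)
  m <- .emptyCounts()
  tabM <- table(factor(geno[sex == 1L], levels = genotypePairs()))
  tabF <- table(factor(geno[sex == 2L], levels = genotypePairs()))
  m[, "male"] <- as.integer(tabM)
  m[, "female"] <- as.integer(tabF)
  newPopulation(m, generation = pop@generation + 1L)
}

# Draw one gamete allele per egg, vectorized over eggs grouped by parent
# genotype (RNG calls are grouped, but output order follows input order).
.drawGametes <- function(genotypes, sex, params) {
  out <- character(length(genotypes))
  for (g in unique(genotypes)) {
    idx <- which(genotypes == g)
    probs <- gameteDistribution(g, sex, params)
    out[idx] <- .ALLELES[sample.int(4L, length(idx), replace = TRUE,
                                    prob = probs)]
  }
  out
}

# Vectorized canonical pair labels from two allele vectors.
.pairKey <- function(a, b) {
  ia <- match(a, .ALLELES); ib <- match(b, .ALLELES)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  paste(.ALLELES[lo], .ALLELES[hi], sep = "/")
}

# Order-independent per-iteration substream seeds below 2^31.
.iterationSeed <- function(seed, iteration) {
  as.integer((as.double(seed) %% 2147483647 * 2654435761 + iteration) %%
               2147483647)
}

.popRecord <- function(pop) {
  if (sum(pop@counts) == 0L) {
    return(data.frame(generation = pop@generation, n = 0,
                      freq_T = NA_real_, freq_D = NA_real_,
                      freq_DN = NA_real_, freq_N = NA_real_,
                      gfp_negative = NA_real_, extinct = TRUE))
  }
  af <- alleleFrequencies(pop)
  data.frame(generation = pop@generation, n = sum(pop@counts),
             freq_T = af$frequencies[["T"]], freq_D = af$frequencies[["D"]],
             freq_DN = af$frequencies[["DN"]], freq_N = af$frequencies[["N"]],
             gfp_negative = af$gfp_negative, extinct = pop@extinct)
}

#' Run replicate stochastic release simulations
#'
#' Founds the release population, then advances it `generations` times with
#' [stepGeneration()], recording allele-class frequencies each generation;
#' repeats for `iterations` independent replicates. Each replicate uses its
#' own RNG substream derived from the master `seed` and the iteration index,
#' so identical inputs reproduce identical output and replicates are
#' order-independent. If a replicate loses one sex, its trajectory is padded
#' to full length with the terminal (extinct) record.
#'
#' @param release A [`ReleaseSpec-class`] object.
#' @param params A [`DriveParams-class`] object.
#' @param eggsPerFemale Eggs per female (default 40).
#' @param cap Population size ceiling.
#' @param generations Number of generations to simulate.
#' @param iterations Number of independent replicates (default 1).
#' @param seed Master RNG seed.
#' @return List of [`Trajectory-class`] objects, one per iteration.
#' @examples
#' trajs <- runSimulation(releaseSpec(25, 50, 50), paramsTALEN(),
#'                        cap = 100, generations = 5, iterations = 3,
#'                        seed = 42)
#' summarizeTrajectories(trajs)
#' @export
runSimulation <- function(release, params, eggsPerFemale = 40L, cap,
                          generations, iterations = 1L, seed) {
  if (iterations < 1L) stop("iterations must be >= 1")
  if (generations < 0L) stop("generations must be >= 0")
  lapply(seq_len(iterations), function(it) {
    itSeed <- .iterationSeed(seed, it)
    set.seed(itSeed)
    pop <- buildReleasePopulation(release)
    recs <- vector("list", generations + 1L)
    recs[[1L]] <- .popRecord(pop)
    if (generations > 0L) {
      for (g in seq_len(generations)) {
        if (!pop@extinct && sum(pop@counts) > 0L)
          pop <- stepGeneration(pop, params, eggsPerFemale, cap)
        else
          pop <- newPopulation(.emptyCounts(),
                               generation = pop@generation + 1L,
                               extinct = TRUE)
        recs[[g + 1L]] <- .popRecord(pop)
      }
    }
    newTrajectory(do.call(rbind, recs), iteration = it, seed = itSeed)
  })
}
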