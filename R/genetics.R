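#' Gamete distribution of a parent genotype
#'
#' Returns the probability with which a parent of the given genotype and sex
#' transmits each of the four allele classes. Homing is male-limited and
#' occurs only in drive/target (`D/T`) trans-heterozygous males, where
#' cleavage of the target chromosome followed by repair produces four gamete
#' classes:
#' \deqn{P(D) = 1/2 + (1/2)\,c\,h\,\phi,\quad
#'       P(D^N) = (1/2)\,c\,h\,(1-\phi),\quad
#'       P(N) = (1/2)\,c\,(1-h),\quad
#'       P(T) = (1/2)\,(1-c).}
#' Every other genotype (all females included) transmits its two alleles in
#' Mendelian 1/2 : 1/2 proportions.
#'
#' @param genotype Genotype label such as `"D/T"` (allele order irrelevant).
#' @param sex `"male"` or `"female"`.
#' @param params A [`DriveParams-class`] object.
#' @return Named numeric vector of length 4 over the allele classes, summing
#'   to 1.
#' @examples
#' gameteDistribution("D/T", "male", paramsTALEN())
#' gameteDistribution("D/T", "female", paramsTALEN())  # Mendelian
#' @export
gameteDistribution <- function(genotype, sex = c("male", "female"), params) {
  sex <- match.arg(sex)
  methods::validObject(params)
  pair <- .parsePair(genotype)
  out <- .alleleVector()
  if (sex == "male" && setequal(pair, c("D", "T"))) {
    c_ <- params@c; h <- params@h; phi <- params@phi
    out["D"] <- 0.5 + 0.5 * c_ * h * phi
    out["DN"] <- 0.5 * c_ * h * (1 - phi)
    out["N"] <- 0.5 * c_ * (1 - h)
    out["T"] <- 0.5 * (1 - c_)
  } else {
    out[pair[1]] <- out[pair[1]] + 0.5
    out[pair[2]] <- out[pair[2]] + 0.5
  }
  out
}

#' Offspring genotype distribution of a cross
#'
#' Crosses a female and a male gamete distribution and collapses the outer
#' product over allele order, giving the probability of each of the 10
#' unordered diploid genotypes among offspring.
#'
#' @param mother,father Genotype labels such as `"T/T"`; the mother is
#'   female and the father male.
#' @param params A [`DriveParams-class`] object.
#' @return Named numeric vector of length 10 over genotype pairs, summing
#'   to 1.
#' @examples
#' offspringDistribution("T/T", "D/T", paramsTALEN())
#' @export
offspringDistribution <- function(mother, father, params) {
  gm <- gameteDistribution(mother, "female", params)
  gf <- gameteDistribution(father, "male", params)
  .collapseGametes(gm, gf)
}

# Outer product of two gamete distributions collapsed to unordered pairs.
.collapseGametes <- function(gm, gf) {
  out <- .pairVector()
  for (i in seq_along(.ALLELES)) {
    for (j in seq_along(.ALLELES)) {
      pr <- gm[[i]] * gf[[j]]
      if (pr == 0) next
      key <- .canonicalPair(c(.ALLELES[i], .ALLELES[j]))
      out[key] <- out[key] + pr
    }
  }
  out
}

#' Sex-structured genotype-frequency state
#'
#' Carrier for the deterministic infinite-population recursion: genotype
#' frequencies within males and within females, plus a generation counter.
#' Each frequency vector is over the 10 unordered genotype pairs and sums
#' to 1.
#'
#' @slot maleFreqs,femaleFreqs Named numeric vectors over [genotypePairs()].
#' @slot generation Non-negative integer generation index.
#' @name SexStructuredState-class
#' @aliases SexStructuredState-class
#' @exportClass SexStructuredState
setClass("SexStructuredState",
         representation(maleFreqs = "numeric", femaleFreqs = "numeric",
                        generation = "integer"))

setValidity("SexStructuredState", function(object) {
  for (nm in c("maleFreqs", "femaleFreqs")) {
    f <- methods::slot(object, nm)
    if (!identical(names(f), genotypePairs()))
      return(paste(nm, "must be named over genotypePairs()"))
    if (any(f < 0)) return(paste(nm, "has negative frequencies"))
    if (abs(sum(f) - 1) > 1e-9) return(paste(nm, "does not sum to 1"))
  }
  if (length(object@generation) != 1L || object@generation < 0L)
    return("generation must be a single non-negative integer")
  TRUE
})

#' Construct a sex-structured state
#'
#' @param maleFreqs,femaleFreqs Named numeric vectors of genotype
#'   frequencies; names must be a subset of [genotypePairs()] (in any allele
#'   order); missing genotypes get frequency 0.
#' @param generation Generation index (default 0).
#' @return A [`SexStructuredState-class`] object.
#' @examples
#' sexStructuredState(maleFreqs = c("D/T" = 1), femaleFreqs = c("T/T" = 1))
#' @export
sexStructuredState <- function(maleFreqs, femaleFreqs, generation = 0L) {
  fill <- function(x) {
    out <- .pairVector()
    if (length(x)) {
      keys <- vapply(names(x),
                     function(g) .canonicalPair(strsplit(g, "/")[[1]]), "")
      for (i in seq_along(x)) out[keys[i]] <- out[keys[i]] + x[[i]]
    }
    out
  }
  methods::new("SexStructuredState", maleFreqs = fill(maleFreqs),
               femaleFreqs = fill(femaleFreqs),
               generation = as.integer(generation))
}

setMethod("show", "SexStructuredState", function(object) {
  cat("SexStructuredState, generation", object@generation, "\n")
  nz <- object@maleFreqs > 0 | object@femaleFreqs > 0
  print(round(rbind(male = object@maleFreqs[nz],
                    female = object@femaleFreqs[nz]), 4))
})

#' One generation of the deterministic expectation recursion
#'
#' Advances a sex-structured genotype-frequency state by one generation of
#' random mating: each female mates a single male drawn at random, so the
#' expected offspring distribution is the frequency-weighted sum of
#' [offspringDistribution()] over all mother x father combinations.
#' Offspring sex is independent of genotype, so the next generation has
#' identical male and female frequencies.
#'
#' This recursion is the infinite-population expectation of the stochastic
#' simulator ([stepGeneration()]) and serves as its oracle in validation.
#'
#' @param state A [`SexStructuredState-class`] object.
#' @param params A [`DriveParams-class`] object.
#' @return The next-generation [`SexStructuredState-class`].
#' @examples
#' s0 <- sexStructuredState(c("D/T" = 1), c("T/T" = 1))
#' recursionStep(s0, paramsZFN())
#' @export
recursionStep <- function(state, params) {
  methods::validObject(state)
  nxt <- .pairVector()
  pairs <- genotypePairs()
  gamF <- lapply(pairs, gameteDistribution, sex = "female", params = params)
  gamM <- lapply(pairs, gameteDistribution, sex = "male", params = params)
  for (i in seq_along(pairs)) {
    fw <- state@femaleFreqs[[i]]
    if (fw == 0) next
    for (j in seq_along(pairs)) {
      mw <- state@maleFreqs[[j]]
      if (mw == 0) next
      nxt <- nxt + fw * mw * .collapseGametes(gamF[[i]], gamM[[j]])
    }
  }
  nxt <- nxt / sum(nxt)
  methods::new("SexStructuredState", maleFreqs = nxt, femaleFreqs = nxt,
               generation = state@generation + 1L)
}

#' Run the deterministic recursion over multiple generations
#'
#' @param initial A [`SexStructuredState-class`] starting state
#'   (generation 0).
#' @param params A [`DriveParams-class`] object.
#' @param generations Number of generations to advance (>= 0).
#' @return A [`Trajectory-class`] with `generations + 1` records of
#'   allele-class frequencies (generation 0 included).
#' @examples
#' s0 <- sexStructuredState(c("D/T" = 0.2, "T/T" = 0.8), c("T/T" = 1))
#' runRecursion(s0, paramsZFN(), generations = 5)
#' @export
runRecursion <- function(initial, params, generations) {
  if (length(generations) != 1L || is.na(generations) || generations < 0)
    stop("generations must be a single non-negative integer")
  generations <- as.integer(generations)
  state <- initial
  recs <- vector("list", generations + 1L)
  recs[[1L]] <- .stateRecord(state)
  if (generations > 0L) {
    for (g in seq_len(generations)) {
      state <- recursionStep(state, params)
      recs[[g + 1L]] <- .stateRecord(state)
    }
  }
  newTrajectory(do.call(rbind, recs), iteration = NA_integer_,
                seed = NA_integer_)
}

.stateRecord <- function(state) {
  af <- alleleFrequencies(state)
  data.frame(generation = state@generation, n = NA_real_,
             freq_T = af$frequencies[["T"]], freq_D = af$frequencies[["D"]],
             freq_DN = af$frequencies[["DN"]], freq_N = af$frequencies[["N"]],
             gfp_negative = af$gfp_negative, extinct = FALSE)
}

#' Allele-class frequencies of a state or population
#'
#' Computes the frequency of each of the four allele classes and the
#' aggregate GFP-negative allele fraction `freq(D) + freq(DN) + freq(N)`
#' (equivalently `1 - freq(T)`), the population-level readout of drive
#' spread.
#'
#' For a [`SexStructuredState-class`] the two sexes are weighted equally;
#' for a [`Population-class`] frequencies are counted over all alleles
#' actually present.
#'
#' @param x A `SexStructuredState` or `Population` object.
#' @return A list with elements `frequencies` (named numeric over the allele
#'   classes, summing to 1) and `gfp_negative`.
#' @examples
#' pop <- buildReleasePopulation(releaseSpec(25, 50, 50))
#' alleleFrequencies(pop)
#' @export
setGeneric("alleleFrequencies", function(x) standardGeneric("alleleFrequencies"))

#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "SexStructuredState", function(x) {
  perSex <- function(freqs) {
    v <- .alleleVector()
    pairs <- .genotypePairList
    for (k in seq_along(pairs)) {
      v[pairs[[k]][1]] <- v[pairs[[k]][1]] + 0.5 * freqs[[k]]
      v[pairs[[k]][2]] <- v[pairs[[k]][2]] + 0.5 * freqs[[k]]
    }
    v
  }
  v <- (perSex(x@maleFreqs) + perSex(x@femaleFreqs)) / 2
  list(frequencies = v, gfp_negative = unname(v["D"] + v["DN"] + v["N"]))
})
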