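#' A finite, sexed population of drive-locus genotypes
#'
#' Integer counts of individuals for each of the 10 genotype pairs in each
#' sex, with a generation counter and an extinction flag (set when a
#' generation ends with no males or no females, which terminates a
#' stochastic run).
#'
#' @slot counts 10 x 2 integer matrix; rows [genotypePairs()], columns
#'   `male`, `female`.
#' @slot generation non-negative integer.
#' @slot extinct logical flag.
#' @name Population-class
#' @aliases Population-class
#' @exportClass Population
setClass("Population",
         representation(counts = "matrix", generation = "integer",
                        extinct = "logical"))

setValidity("Population", function(object) {
  m <- object@counts
  if (!identical(rownames(m), genotypePairs()) ||
      !identical(colnames(m), c("male", "female")))
    return("counts must be a genotypePairs() x (male, female) matrix")
  if (any(m < 0) || any(m != round(m)))
    return("counts must be non-negative integers")
  if (length(object@generation) != 1L || object@generation < 0L)
    return("generation must be a single non-negative integer")
  TRUE
})

.emptyCounts <- function() {
  matrix(0L, nrow = 10L, ncol = 2L,
         dimnames = list(genotypePairs(), c("male", "female")))
}

newPopulation <- function(counts, generation = 0L, extinct = FALSE) {
  storage.mode(counts) <- "integer"
  methods::new("Population", counts = counts,
               generation = as.integer(generation), extinct = extinct)
}

#' @describeIn Population-class Total number of individuals.
#' @param x A `Population` object.
#' @export
populationSize <- function(x) sum(x@counts)

#' @describeIn Population-class Genotype count matrix accessor.
#' @export
genotypeCounts <- function(x) x@counts

#' @describeIn Population-class Generation counter accessor.
#' @export
generation <- function(x) x@generation

#' @describeIn Population-class TRUE if the run hit a sex extinction.
#' @export
isExtinct <- function(x) x@extinct

setMethod("show", "Population", function(object) {
  cat("Population of", sum(object@counts), "flies, generation",
      object@generation, if (object@extinct) "(extinct)", "\n")
  nz <- rowSums(object@counts) > 0
  if (any(nz)) print(object@counts[nz, , drop = FALSE])
})

#' @rdname alleleFrequencies
#' @export
setMethod("alleleFrequencies", "Population", function(x) {
  if (sum(x@counts) == 0L)
    stop("empty population: allele frequencies are undefined")
  v <- .alleleVector()
  pairs <- .genotypePairList
  tot <- rowSums(x@counts)
  for (k in seq_along(pairs)) {
    v[pairs[[k]][1]] <- v[pairs[[k]][1]] + tot[[k]]
    v[pairs[[k]][2]] <- v[pairs[[k]][2]] + tot[[k]]
  }
  v <- v / sum(v)
  list(frequencies = v, gfp_negative = unname(v["D"] + v["DN"] + v["N"]))
})

#' Release-experiment configuration
#'
#' Describes the founding of a population-cage experiment: drive-bearing
#' trans-heterozygous males (`D/target`) released into a homozygous target
#' population. `targetAllele = "T"` gives the standard cleavable target
#' population; `targetAllele = "N"` founds the refractory (non-cleavable)
#' control population, in which the drive has no substrate and should stay
#' at its release frequency.
#'
#' @slot nTransHetMales,nTargetMales,nTargetFemales non-negative integers.
#' @slot targetAllele `"T"` or `"N"`.
#' @name ReleaseSpec-class
#' @aliases ReleaseSpec-class
#' @exportClass ReleaseSpec
setClass("ReleaseSpec",
         representation(nTransHetMales = "integer", nTargetMales = "integer",
                        nTargetFemales = "integer", targetAllele = "character"))

setValidity("ReleaseSpec", function(object) {
  ns <- c(object@nTransHetMales, object@nTargetMales, object@nTargetFemales)
  if (any(is.na(ns)) || any(ns < 0L))
    return("all release counts must be non-negative integers")
  if (!object@targetAllele %in% c("T", "N"))
    return("targetAllele must be \"T\" or \"N\"")
  TRUE
})

#' @param nTransHetMales Number of released drive/target trans-heterozygous
#'   males.
#' @param nTargetMales,nTargetFemales Homozygous target residents.
#' @param targetAllele `"T"` (cleavable) or `"N"` (refractory control).
#' @return A [`ReleaseSpec-class`] object.
#' @rdname ReleaseSpec-class
#' @examples
#' releaseSpec(50, 75, 75)            # drive release at 12.5% alleles
#' releaseSpec(25, 50, 50, "N")       # refractory control
#' @export
releaseSpec <- function(nTransHetMales, nTargetMales, nTargetFemales,
                        targetAllele = "T") {
  methods::new("ReleaseSpec", nTransHetMales = as.integer(nTransHetMales),
               nTargetMales = as.integer(nTargetMales),
               nTargetFemales = as.integer(nTargetFemales),
               targetAllele = targetAllele)
}

setMethod("show", "ReleaseSpec", function(object) {
  cat("ReleaseSpec:", object@nTransHetMales, "D/", object@targetAllele,
      " males + ", object@nTargetMales, "/", object@nTargetFemales,
      " target males/females (target allele ", object@targetAllele, ")\n",
      sep = "")
})

#' Found the generation-0 population of a release experiment
#'
#' @param release A [`ReleaseSpec-class`] object.
#' @return A [`Population-class`] at generation 0.
#' @examples
#' buildReleasePopulation(releaseSpec(25, 50, 50))
#' @export
buildReleasePopulation <- function(release) {
  methods::validObject(release)
  m <- .emptyCounts()
  het <- .canonicalPair(c("D", release@targetAllele))
  hom <- .canonicalPair(rep(release@targetAllele, 2L))
  m[het, "male"] <- release@nTransHetMales
  m[hom, "male"] <- m[hom, "male"] + release@nTargetMales
  m[hom, "female"] <- release@nTargetFemales
  newPopulation(m, generation = 0L)
}

#' Initial drive-allele frequency of a release
#'
#' Each released trans-heterozygous male carries one donor (`D`) allele, so
#' the initial drive-allele frequency is
#' `nTransHetMales / (2 * total individuals)`. For a cleavable target
#' population this equals the initial GFP-negative allele fraction; for the
#' refractory control (all alleles GFP-negative by construction) it is the
#' reported nuclease-allele frequency.
#'
#' @param release A [`ReleaseSpec-class`] object.
#' @return A single number in \eqn{[0, 1]}.
#' @examples
#' initialAlleleFrequency(releaseSpec(50, 75, 75))  # 0.125
#' initialAlleleFrequency(releaseSpec(25, 50, 50))  # 0.10
#' @export
initialAlleleFrequency <- function(release) {
  methods::validObject(release)
  total <- release@nTransHetMales + release@nTargetMales +
    release@nTargetFemales
  if (total == 0L) stop("empty release population")
  release@nTransHetMales / (2 * total)
}
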