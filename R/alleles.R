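#' Allele classes of the four-allele drive model
#'
#' The model tracks four heritable states of the drive locus:
#' \describe{
#'   \item{\code{D}}{drive-capable donor allele: the nuclease cassette,
#'     whether originally released or copied into a target chromosome by
#'     homing. Resistant to cleavage; the only allele able to home.}
#'   \item{\code{DN}}{non-functional homed donor: a cassette damaged during
#'     copying. Resistant to cleavage, transmitted Mendelianly, cannot home.}
#'   \item{\code{N}}{out-of-frame end-joining (NHEJ) product: the target site
#'     is destroyed, so the allele is a cleavage-resistant resistance allele.}
#'   \item{\code{T}}{intact, cleavable target site, marked GFP-positive.}
#' }
#' `T` is the only GFP-positive and only cleavable class; `D` is the only
#' drive-capable class.
#'
#' @return `alleleClasses()` returns the four allele labels in canonical
#'   order; `alleleInfo()` returns a data frame with one row per class and
#'   logical columns `gfp_positive`, `cleavable` and `drive_capable`.
#' @examples
#' alleleClasses()
#' alleleInfo()
#' @export
alleleClasses <- function() .ALLELES

#' @rdname alleleClasses
#' @export
alleleInfo <- function() {
  data.frame(
    label = .ALLELES,
    gfp_positive = .ALLELES == "T",
    cleavable = .ALLELES == "T",
    drive_capable = .ALLELES == "D",
    row.names = .ALLELES
  )
}

.ALLELES <- c("D", "DN", "N", "T")

# All 10 unordered diploid allele pairs, canonical order D < DN < N < T.
.genotypePairList <- local({
  combos <- c(utils::combn(c("D", "DN", "N", "T"), 2, simplify = FALSE),
              lapply(c("D", "DN", "N", "T"), function(a) c(a, a)))
  names(combos) <- vapply(combos, paste, "", collapse = "/")
  combos[order(match(vapply(combos, `[`, "", 1), c("D", "DN", "N", "T")),
               match(vapply(combos, `[`, "", 2), c("D", "DN", "N", "T")))]
})

#' Enumerate the diploid genotypes of the drive locus
#'
#' The four allele classes form 10 unordered diploid pairs; with two sexes
#' this yields 20 possible genotypes. Pairs are written with the alleles in
#' canonical order (`D < DN < N < T`), e.g. `"D/T"`.
#'
#' @return Character vector of the 10 canonical pair labels.
#' @examples
#' genotypePairs()
#' @export
genotypePairs <- function() names(.genotypePairList)

# Split a "X/Y" label into its two alleles (validated).
.parsePair <- function(genotype) {
  stopifnot(is.character(genotype), length(genotype) == 1L)
  key <- .canonicalPair(strsplit(genotype, "/", fixed = TRUE)[[1]])
  .genotypePairList[[key]]
}

# Canonical label for a pair of alleles given in any order.
.canonicalPair <- function(alleles) {
  if (length(alleles) != 2L || !all(alleles %in% .ALLELES))
    stop("genotype must be two allele classes among ",
         paste(.ALLELES, collapse = ", "), call. = FALSE)
  paste(alleles[order(match(alleles, .ALLELES))], collapse = "/")
}

# Zero-filled named numeric over the four allele classes.
.alleleVector <- function() stats::setNames(numeric(4L), .ALLELES)

# Zero-filled named numeric over the ten genotype pairs.
.pairVector <- function() stats::setNames(numeric(10L), names(.genotypePairList))
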