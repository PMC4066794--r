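#' Simulate the progeny of a homing-assay cross
#'
#' Draws the fates of `n` target chromosomes from a male drive/target
#' trans-heterozygote cross as a single multinomial sample with the class
#' probabilities implied by the drive parameters: unmodified `1 - c`,
#' functionally homed `c h phi`, non-functionally homed `c h (1 - phi)`,
#' misrepair `c (1 - h)`. Each chromosome is drawn independently; the mass
#' matings of the real assay provide no brood structure to emulate.
#'
#' Optionally also returns the per-progeny phenotype table the classifiers
#' consume (all rows are white-eyed target-chromosome progeny; functional
#' and non-functional homed chromosomes are phenotypically identical).
#'
#' @param params A [`DriveParams-class`] object.
#' @param n Number of target chromosomes scored (>= 1).
#' @param map A [markerMap()] used to set marker columns of the phenotype
#'   table.
#' @param seed Optional RNG seed.
#' @return List with `counts` (an [`AssayCounts-class`]), `classCounts`
#'   (named integer vector of the four outcome classes) and `phenotypes`
#'   (data.frame, one row per progeny).
#' @examples
#' sim <- simulateAssayProgeny(paramsTALEN(), n = 1422, seed = 7)
#' estimateRates(sim$counts)
#' @export
simulateAssayProgeny <- function(params, n, map = markerMap(), seed = NULL) {
  methods::validObject(params)
  if (n < 1L) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  c_ <- params@c; h <- params@h; phi <- params@phi
  probs <- c(unmodified = 1 - c_, homed_functional = c_ * h * phi,
             homed_nonfunctional = c_ * h * (1 - phi),
             misrepair = c_ * (1 - h))
  cls <- stats::setNames(as.integer(stats::rmultinom(1L, n, probs)),
                         names(probs))
  nLoss <- n - cls[["unmodified"]]
  nHomed <- cls[["homed_functional"]] + cls[["homed_nonfunctional"]]
  counts <- assayCounts(n, nLoss, nHomed)
  lab <- rep(names(probs), cls)
  phenotypes <- data.frame(
    white_plus = FALSE,
    curled = !map$cu_on_donor,
    gfp = lab == "unmodified",
    rfp_or_pcr = lab %in% c("homed_functional", "homed_nonfunctional")
  )
  phenotypes <- phenotypes[sample.int(nrow(phenotypes)), , drop = FALSE]
  rownames(phenotypes) <- NULL
  list(counts = counts, classCounts = cls, phenotypes = phenotypes)
}

#' Simulate F2 segregation crosses
#'
#' Emulates the functional-homing readout: each of `nCrosses` homed F1
#' flies is functional with probability `functionalProb`. A functional
#' cross cleaves target chromosomes in the next generation, depressing the
#' GFP-positive fraction of its progeny to `gfpPosFraction`; a
#' non-functional cross segregates 1:1. Progeny counts are binomial draws
#' of size `progenyPerCross`.
#'
#' The default `gfpPosFraction` of 0.138 matches the GFP-positive fraction
#' observed in active ZFN-construct crosses, so the simulated test power
#' matches the experimentally observed regime.
#'
#' @param nCrosses Number of F2 crosses (>= 1).
#' @param progenyPerCross Progeny scored per cross (>= 1).
#' @param functionalProb Probability a cross carries a functional drive.
#' @param gfpPosFraction Expected GFP-positive fraction of a functional
#'   cross's progeny (default 0.138).
#' @param seed Optional RNG seed.
#' @return data.frame with columns `cross_id`, `functional` (the latent
#'   truth), `gfp_pos`, `gfp_neg`.
#' @examples
#' crosses <- simulateF2Crosses(20, 200, functionalProb = 0.75, seed = 3)
#' functionalHomingFraction(crosses)
#' @export
simulateF2Crosses <- function(nCrosses, progenyPerCross, functionalProb,
                              gfpPosFraction = 0.138, seed = NULL) {
  if (nCrosses < 1L || progenyPerCross < 1L)
    stop("nCrosses and progenyPerCross must be >= 1")
  if (functionalProb < 0 || functionalProb > 1 ||
      gfpPosFraction < 0 || gfpPosFraction > 1)
    stop("functionalProb and gfpPosFraction must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  functional <- stats::rbinom(nCrosses, 1L, functionalProb) == 1L
  p <- ifelse(functional, gfpPosFraction, 0.5)
  gfpPos <- stats::rbinom(nCrosses, progenyPerCross, p)
  data.frame(cross_id = seq_len(nCrosses), functional = functional,
             gfp_pos = gfpPos, gfp_neg = progenyPerCross - gfpPos)
}
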