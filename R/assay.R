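#' Marker map of a homing-assay cross
#'
#' The homing assay crosses drive/target trans-heterozygous flies to the
#' genetic background and reads the fate of each target chromosome off
#' dominant and recessive markers: the dominant `mini-white` eye marker
#' distinguishes donor (w+) from target (w-) chromosomes; the recessive
#' `curled` (cu) wing marker sits on the donor chromosome in the TALEN line
#' and on the target chromosome in the ZFN lines; homing is read as gain of
#' RFP expression (TALEN line) or a positive diagnostic PCR (ZFN lines).
#'
#' @param cuOnDonor TRUE when `curled` marks the donor chromosome (TALEN
#'   line), FALSE when it marks the target chromosome (ZFN lines).
#' @param homingReadout `"rfp"` or `"pcr"`.
#' @return A list of class `"markerMap"`.
#' @examples
#' markerMap()                         # TALEN-line convention
#' markerMap(FALSE, "pcr")             # ZFN-line convention
#' @export
markerMap <- function(cuOnDonor = TRUE, homingReadout = c("rfp", "pcr")) {
  homingReadout <- match.arg(homingReadout)
  structure(list(cu_on_donor = isTRUE(cuOnDonor),
                 homing_readout = homingReadout),
            class = "markerMap")
}

.CHROM_CLASSES <- c("donor_inherited", "unmodified_target", "homed",
                    "misrepair", "co_conversion")

#' Classify progeny phenotypes into chromosome fates
#'
#' Maps each scored fly to the fate of the drive-locus chromosome it
#' inherited from the trans-heterozygous parent:
#' \itemize{
#'   \item `donor_inherited`: w+ with the homing readout and the `curled`
#'     pattern of the donor chromosome -- the donor chromosome transmitted
#'     vertically, not a product of nuclease activity;
#'   \item `co_conversion`: w+ with the homing readout but without the
#'     donor `curled` pattern -- conversion tract reached the `mini-white`
#'     marker (not observed experimentally, but detectable);
#'   \item `unmodified_target`: w- and GFP-positive -- uncut, or repaired
#'     invisibly (in-frame end-joining / sister-chromatid repair);
#'   \item `homed`: w-, GFP lost, homing readout positive -- cassette copied
#'     into the target chromosome;
#'   \item `misrepair`: w-, GFP lost, homing readout negative --
#'     out-of-frame end-joining resistance allele.
#' }
#' A w- fly scored both GFP-positive and homing-readout-positive is
#' inconsistent with the marker model and raises an error.
#'
#' All phenotype arguments are vectorized and recycled to common length.
#'
#' @param whitePlus Logical, eye pigmentation (dominant `mini-white`).
#' @param curled Logical, `curled` wing phenotype.
#' @param gfp Logical, GFP expression.
#' @param rfpOrPcr Logical, RFP expression (TALEN line) or diagnostic PCR
#'   positivity (ZFN lines).
#' @param map A [markerMap()].
#' @return Character vector of chromosome classes.
#' @examples
#' classifyPhenotype(FALSE, FALSE, gfp = FALSE, rfpOrPcr = TRUE, markerMap())
#' @export
classifyPhenotype <- function(whitePlus, curled, gfp, rfpOrPcr,
                              map = markerMap()) {
  n <- max(length(whitePlus), length(curled), length(gfp), length(rfpOrPcr))
  whitePlus <- rep_len(as.logical(whitePlus), n)
  curled <- rep_len(as.logical(curled), n)
  gfp <- rep_len(as.logical(gfp), n)
  rfpOrPcr <- rep_len(as.logical(rfpOrPcr), n)
  bad <- !whitePlus & gfp & rfpOrPcr
  if (any(bad))
    stop(sum(bad), " w- fly/flies scored both GFP-positive and homing-",
         "readout-positive: inconsistent with the marker model")
  donorCu <- if (map$cu_on_donor) curled else !curled
  out <- character(n)
  out[whitePlus & rfpOrPcr & donorCu] <- "donor_inherited"
  out[whitePlus & rfpOrPcr & !donorCu] <- "co_conversion"
  out[whitePlus & !rfpOrPcr] <- "donor_inherited"
  out[!whitePlus & gfp] <- "unmodified_target"
  out[!whitePlus & !gfp & rfpOrPcr] <- "homed"
  out[!whitePlus & !gfp & !rfpOrPcr] <- "misrepair"
  out
}

#' Homing-assay progeny counts
#'
#' Counts over the white-eyed (target-chromosome) progeny of a homing-assay
#' cross: total target chromosomes scored, number with GFP loss, number
#' scored as homed, and the denominator actually assayed for homing
#' (`nHomingAssayed`), which can be smaller than `nGfpLoss` when homing is
#' scored by PCR on a subset (as for the ZFN lines).
#'
#' @slot nTargetTotal,nGfpLoss,nHomed,nHomingAssayed integers satisfying
#'   `0 <= nHomed <= nHomingAssayed <= nGfpLoss <= nTargetTotal`.
#' @name AssayCounts-class
#' @aliases AssayCounts-class
#' @exportClass AssayCounts
setClass("AssayCounts",
         representation(nTargetTotal = "integer", nGfpLoss = "integer",
                        nHomed = "integer", nHomingAssayed = "integer"))

setValidity("AssayCounts", function(object) {
  v <- c(object@nHomed, object@nHomingAssayed, object@nGfpLoss,
         object@nTargetTotal)
  if (any(is.na(v)) || any(v < 0L))
    return("counts must be non-negative integers")
  if (is.unsorted(v))
    return("need nHomed <= nHomingAssayed <= nGfpLoss <= nTargetTotal")
  TRUE
})

#' @param nTargetTotal Total white-eyed (target-chromosome) progeny.
#' @param nGfpLoss Of those, number with GFP loss.
#' @param nHomed Of the homing-assayed, number scored homed.
#' @param nHomingAssayed Denominator scored for homing (defaults to
#'   `nGfpLoss`).
#' @return An [`AssayCounts-class`] object.
#' @rdname AssayCounts-class
#' @examples
#' assayCounts(1422, 998, 697)            # RFP readout on all GFP-loss flies
#' assayCounts(425, 366, 117, 296)        # PCR readout on a subset
#' @export
assayCounts <- function(nTargetTotal, nGfpLoss, nHomed,
                        nHomingAssayed = nGfpLoss) {
  methods::new("AssayCounts", nTargetTotal = as.integer(nTargetTotal),
               nGfpLoss = as.integer(nGfpLoss), nHomed = as.integer(nHomed),
               nHomingAssayed = as.integer(nHomingAssayed))
}

setMethod("show", "AssayCounts", function(object) {
  cat("AssayCounts: ", object@nGfpLoss, "/", object@nTargetTotal,
      " GFP loss; ", object@nHomed, "/", object@nHomingAssayed,
      " homed\n", sep = "")
})

#' Tabulate a classified progeny list into assay counts
#'
#' Applies [classifyPhenotype()] to a per-progeny phenotype table and counts
#' the white-eyed (target-chromosome) classes. `nHomingAssayed` defaults to
#' the number of GFP-loss flies; supply it explicitly when homing was scored
#' on a subset only (PCR assays).
#'
#' @param progeny data.frame with logical columns `white_plus`, `curled`,
#'   `gfp`, `rfp_or_pcr` (one row per fly).
#' @param map A [markerMap()].
#' @param nHomingAssayed Optional explicit homing denominator.
#' @return An [`AssayCounts-class`] object.
#' @examples
#' flies <- data.frame(white_plus = FALSE, curled = FALSE,
#'                     gfp = c(TRUE, FALSE), rfp_or_pcr = c(FALSE, TRUE))
#' tabulateCross(flies)
#' @export
tabulateCross <- function(progeny, map = markerMap(), nHomingAssayed = NULL) {
  if (nrow(progeny) == 0L)
    return(assayCounts(0L, 0L, 0L, 0L))
  cls <- classifyPhenotype(progeny$white_plus, progeny$curled, progeny$gfp,
                           progeny$rfp_or_pcr, map)
  nTarget <- sum(cls %in% c("unmodified_target", "homed", "misrepair"))
  nLoss <- sum(cls %in% c("homed", "misrepair"))
  nHomed <- sum(cls == "homed")
  assayCounts(nTarget, nLoss, nHomed,
              if (is.null(nHomingAssayed)) nLoss else nHomingAssayed)
}

#' Drive-rate estimates with confidence intervals
#'
#' Point estimates and 95\% Wilson score intervals for the cleavage rate
#' `c = nGfpLoss / nTargetTotal`, the homing fraction
#' `h = nHomed / nHomingAssayed`, the total homed fraction `c * h`, and the
#' end-joining (resistance) fraction `c * (1 - h)`. Estimates whose
#' denominator is zero are reported as NA and listed in the `undefined`
#' slot rather than silently set to zero.
#'
#' @slot estimates named numeric: `cleavage_rate`, `homing_fraction`,
#'   `total_homed`, `nhej_fraction`.
#' @slot ci 4 x 2 matrix of 95\% interval bounds.
#' @slot counts the [`AssayCounts-class`] the estimates derive from.
#' @slot undefined character vector of estimate names with zero denominator.
#' @name RateEstimates-class
#' @aliases RateEstimates-class
#' @exportClass RateEstimates
setClass("RateEstimates",
         representation(estimates = "numeric", ci = "matrix",
                        counts = "AssayCounts", undefined = "character"))

.RATE_NAMES <- c("cleavage_rate", "homing_fraction", "total_homed",
                 "nhej_fraction")

#' Wilson score interval for a binomial proportion
#'
#' @param x Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`, always inside \eqn{[0, 1]} and
#'   containing `x / n`.
#' @examples
#' wilsonInterval(998, 1422)
#' @export
wilsonInterval <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Estimate cleavage, homing and resistance rates from assay counts
#'
#' @param counts An [`AssayCounts-class`] object.
#' @param conf Confidence level for the Wilson intervals (default 0.95).
#' @return A [`RateEstimates-class`] object.
#' @examples
#' estimateRates(assayCounts(1422, 998, 697))   # c 70.2%, h 69.8%, 49% homed
#' estimateRates(assayCounts(425, 366, 117, 296))
#' @export
estimateRates <- function(counts, conf = 0.95) {
  methods::validObject(counts)
  est <- stats::setNames(rep(NA_real_, 4L), .RATE_NAMES)
  ci <- matrix(NA_real_, 4L, 2L,
               dimnames = list(.RATE_NAMES, c("lower", "upper")))
  undefined <- character()
  nT <- counts@nTargetTotal
  if (nT > 0L) {
    est["cleavage_rate"] <- counts@nGfpLoss / nT
    ci["cleavage_rate", ] <- wilsonInterval(counts@nGfpLoss, nT, conf)
  } else undefined <- c(undefined, "cleavage_rate")
  if (counts@nHomingAssayed > 0L) {
    est["homing_fraction"] <- counts@nHomed / counts@nHomingAssayed
    ci["homing_fraction", ] <- wilsonInterval(counts@nHomed,
                                              counts@nHomingAssayed, conf)
  } else undefined <- c(undefined, "homing_fraction")
  if (!anyNA(est[1:2])) {
    est["total_homed"] <- est[["cleavage_rate"]] * est[["homing_fraction"]]
    est["nhej_fraction"] <- est[["cleavage_rate"]] *
      (1 - est[["homing_fraction"]])
    # No exact interval exists for the product of the two nested
    # proportions; approximate with Wilson on the implied count out of all
    # target chromosomes.
    ci["total_homed", ] <- wilsonInterval(round(est[["total_homed"]] * nT),
                                          nT, conf)
    ci["nhej_fraction", ] <- wilsonInterval(round(est[["nhej_fraction"]] * nT),
                                            nT, conf)
  } else undefined <- union(undefined, c("total_homed", "nhej_fraction"))
  methods::new("RateEstimates", estimates = est, ci = ci, counts = counts,
               undefined = undefined)
}

#' @describeIn RateEstimates-class Named vector of point estimates.
#' @param x A `RateEstimates` object.
#' @export
rateEstimates <- function(x) x@estimates

#' @describeIn RateEstimates-class Interval bounds matrix.
#' @export
rateConfint <- function(x) x@ci

setMethod("show", "RateEstimates", function(object) {
  cat("RateEstimates (95% Wilson CI):\n")
  for (nm in .RATE_NAMES) {
    e <- object@estimates[[nm]]
    if (is.na(e)) {
      cat(sprintf("  %-16s undefined (zero denominator)\n", nm))
    } else {
      cat(sprintf("  %-16s %5.1f%%  [%.1f, %.1f]\n", nm, 100 * e,
                  100 * object@ci[nm, 1], 100 * object@ci[nm, 2]))
    }
  }
})

#' Chi-square test of 1:1 segregation
#'
#' Tests two progeny counts against the 1:1 Mendelian expectation with a
#' one-degree-of-freedom chi-square goodness-of-fit test (no continuity
#' correction): statistic \eqn{(n_A - n_B)^2 / (n_A + n_B)}, p-value from
#' the upper chi-square tail.
#'
#' @param nA,nB The two observed counts (e.g. GFP-positive and
#'   GFP-negative progeny).
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `significant`.
#' @examples
#' chiSquare1to1(222, 209)    # consistent with 1:1
#' chiSquare1to1(30, 70)      # significant deviation
#' @export
chiSquare1to1 <- function(nA, nB, alpha = 0.05) {
  if (length(nA) != 1L || length(nB) != 1L || nA < 0 || nB < 0)
    stop("nA and nB must be single non-negative counts")
  if (nA + nB == 0) stop("no progeny to test")
  ht <- suppressWarnings(stats::chisq.test(c(nA, nB), p = c(0.5, 0.5),
                                           correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       significant = unname(ht$p.value) < alpha)
}

#' Fraction of F2 crosses showing functional drive
#'
#' The functional-homing fraction is read out in the next generation:
#' individual homed F1 flies are crossed to fresh target flies, and a cross
#' counts as carrying a functional drive when its progeny shows a
#' statistically significant deficit of GFP-positive flies
#' ([chiSquare1to1()] against 1:1 at level `alpha`). By default only
#' GFP-deficit deviations count, since the biological readout is loss of
#' GFP; set `directional = FALSE` to count any significant deviation.
#'
#' @param crosses data.frame with integer columns `gfp_pos` and `gfp_neg`,
#'   one row per F2 cross.
#' @param alpha Significance level (default 0.05).
#' @param directional Count only GFP-deficit deviations (default TRUE).
#' @return List with `n_significant`, `n_total`, `fraction`.
#' @examples
#' functionalHomingFraction(data.frame(gfp_pos = c(11, 50),
#'                                     gfp_neg = c(89, 50)))
#' @export
functionalHomingFraction <- function(crosses, alpha = 0.05,
                                     directional = TRUE) {
  if (is.null(crosses) || nrow(crosses) == 0L)
    stop("no F2 crosses supplied")
  sig <- vapply(seq_len(nrow(crosses)), function(i) {
    res <- chiSquare1to1(crosses$gfp_pos[i], crosses$gfp_neg[i], alpha)
    res$significant &&
      (!directional || crosses$gfp_pos[i] < crosses$gfp_neg[i])
  }, logical(1))
  list(n_significant = sum(sig), n_total = nrow(crosses),
       fraction = mean(sig))
}
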