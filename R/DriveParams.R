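#' Drive parameters measured by the homing assay
#'
#' `DriveParams` holds the three rates that determine gamete output of a
#' drive-bearing (D/T) male:
#' \describe{
#'   \item{`c`}{cleavage rate: the fraction of target chromosomes scored as
#'     modified (loss of the GFP marker) among progeny of a drive parent.
#'     Because in-frame end-joining and sister-chromatid repair restore GFP,
#'     this phenotypic rate understates true cutting; the model uses the
#'     observed rate.}
#'   \item{`h`}{homing fraction: of the cleaved chromosomes, the fraction
#'     resolved by homologous recombination (cassette copied in) rather than
#'     end-joining. The remaining `1 - h` become resistance alleles `N`.}
#'   \item{`phi`}{functional-homing fraction: of the homed cassettes, the
#'     fraction still able to drive in the next generation. The remainder
#'     become non-functional donors `DN`.}
#' }
#' All three are probabilities in \eqn{[0, 1]}.
#'
#' @slot c numeric(1), cleavage rate.
#' @slot h numeric(1), homing fraction of cleaved chromosomes.
#' @slot phi numeric(1), functional fraction of homed cassettes.
#'
#' @examples
#' DriveParams(c = 0.702, h = 0.698, phi = 0.40)
#' @name DriveParams-class
#' @aliases DriveParams-class
#' @exportClass DriveParams
setClass("DriveParams",
         representation(c = "numeric", h = "numeric", phi = "numeric"))

setValidity("DriveParams", function(object) {
  vals <- c(c = object@c, h = object@h, phi = object@phi)
  if (length(object@c) != 1L || length(object@h) != 1L ||
      length(object@phi) != 1L)
    return("c, h and phi must each be a single number")
  if (anyNA(vals)) return("c, h and phi must not be NA")
  bad <- names(vals)[vals < 0 | vals > 1]
  if (length(bad))
    return(paste0("parameter(s) out of [0, 1]: ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Construct drive parameters
#'
#' @param c Cleavage rate in \eqn{[0, 1]}.
#' @param h Homing fraction of cleaved chromosomes in \eqn{[0, 1]}.
#' @param phi Functional fraction of homed cassettes in \eqn{[0, 1]}.
#' @return A [`DriveParams-class`] object.
#' @examples
#' p <- DriveParams(c = 0.861, h = 0.395, phi = 0.75)
#' cleavageRate(p)
#' @export
DriveParams <- function(c, h, phi) {
  methods::new("DriveParams", c = as.numeric(c), h = as.numeric(h),
               phi = as.numeric(phi))
}

#' @describeIn DriveParams Cleavage rate accessor.
#' @param x A `DriveParams` object.
#' @export
cleavageRate <- function(x) x@c

#' @describeIn DriveParams Homing fraction accessor.
#' @export
homingFraction <- function(x) x@h

#' @describeIn DriveParams Functional-homing fraction accessor.
#' @export
functionalFraction <- function(x) x@phi

setMethod("show", "DriveParams", function(object) {
  cat("DriveParams: c =", format(object@c),
      " h =", format(object@h),
      " phi =", format(object@phi), "\n")
  cat("  implied misrepair fraction of cleaved (1 - h):",
      format(1 - object@h), "\n")
})

#' Measured parameter sets for the TALEN and ZFN drive constructs
#'
#' Convenience constructors returning the homing-assay estimates for the two
#' drive lines used throughout the examples: the TALEN-based construct
#' (TALELAT: c = 0.702, h = 0.698, phi = 0.40) and the ZFN-based construct
#' (ZFN-AAVS1: c = 0.861, h = 0.395, phi = 0.75).
#'
#' @return A [`DriveParams-class`] object.
#' @examples
#' paramsTALEN()
#' paramsZFN()
#' @export
paramsTALEN <- function() DriveParams(c = 0.702, h = 0.698, phi = 0.40)

#' @rdname paramsTALEN
#' @export
paramsZFN <- function() DriveParams(c = 0.861, h = 0.395, phi = 0.75)
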