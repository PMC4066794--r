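#' Per-generation trajectory of allele-class frequencies
#'
#' One record per generation (generation 0, the release state, included)
#' holding the population size `n` (NA for the deterministic recursion),
#' the four allele-class frequencies, the aggregate GFP-negative allele
#' fraction, and an extinction flag. Stochastic trajectories also carry the
#' iteration index and the seed that produced them.
#'
#' @slot records data.frame with columns `generation`, `n`, `freq_T`,
#'   `freq_D`, `freq_DN`, `freq_N`, `gfp_negative`, `extinct`.
#' @slot iteration integer iteration index (NA for deterministic runs).
#' @slot seed integer RNG seed used (NA for deterministic runs).
#' @name Trajectory-class
#' @aliases Trajectory-class
#' @exportClass Trajectory
setClass("Trajectory",
         representation(records = "data.frame", iteration = "integer",
                        seed = "integer"))

.TRAJ_COLS <- c("generation", "n", "freq_T", "freq_D", "freq_DN", "freq_N",
                "gfp_negative", "extinct")

setValidity("Trajectory", function(object) {
  r <- object@records
  if (!all(.TRAJ_COLS %in% names(r)))
    return(paste("records must have columns",
                 paste(.TRAJ_COLS, collapse = ", ")))
  if (nrow(r) < 1L) return("trajectory must contain at least generation 0")
  if (!identical(r$generation, seq_len(nrow(r)) - 1))
    return("generations must run 0, 1, ... without gaps")
  live <- !r$extinct
  s <- r$freq_T[live] + r$freq_D[live] + r$freq_DN[live] + r$freq_N[live]
  if (any(abs(s - 1) > 1e-9))
    return("allele frequencies of non-extinct records must sum to 1")
  TRUE
})

newTrajectory <- function(records, iteration, seed) {
  rownames(records) <- NULL
  records$generation <- as.numeric(records$generation)
  methods::new("Trajectory", records = records,
               iteration = as.integer(iteration), seed = as.integer(seed))
}

#' @describeIn Trajectory-class Extract the per-generation record table.
#' @param x A `Trajectory` object.
#' @export
trajectoryRecords <- function(x) x@records

#' @describeIn Trajectory-class GFP-negative allele fraction per generation.
#' @export
gfpNegative <- function(x) x@records$gfp_negative

setMethod("show", "Trajectory", function(object) {
  r <- object@records
  cat("Trajectory: ", nrow(r), " generations (0..", nrow(r) - 1L, ")",
      if (!is.na(object@iteration))
        paste0(" [iteration ", object@iteration, ", seed ", object@seed, "]"),
      "\n", sep = "")
  cat("  GFP-negative allele fraction: ",
      format(round(r$gfp_negative[1], 4)), " -> ",
      format(round(r$gfp_negative[nrow(r)], 4)), "\n", sep = "")
})

#' @export
as.data.frame.Trajectory <- function(x, ...) {
  df <- x@records
  df$iteration <- x@iteration
  df
}

#' Summarize GFP-negative fractions across stochastic trajectories
#'
#' Builds a per-generation summary (mean, median, min, max and chosen
#' quantiles) of the GFP-negative allele fraction over a set of replicate
#' trajectories, the quantity plotted when comparing simulations with
#' population-cage experiments. Extinct generations (undefined frequencies)
#' are excluded from the statistics; `n_iterations` counts the replicates
#' contributing at each generation.
#'
#' @param trajectories List of [`Trajectory-class`] objects of equal length.
#' @param probs Quantile probabilities to report (default 0.25 and 0.75).
#' @return data.frame with one row per generation.
#' @examples
#' trajs <- runSimulation(releaseSpec(25, 50, 50), paramsTALEN(),
#'                        cap = 100, generations = 3, iterations = 5,
#'                        seed = 1)
#' summarizeTrajectories(trajs)
#' @export
summarizeTrajectories <- function(trajectories, probs = c(0.25, 0.75)) {
  if (length(trajectories) == 0L)
    stop("no trajectories to summarize")
  lens <- vapply(trajectories, function(t) nrow(t@records), 1L)
  if (length(unique(lens)) != 1L)
    stop("trajectories must have equal length")
  mat <- vapply(trajectories, gfpNegative, numeric(lens[1]))
  mat <- matrix(mat, nrow = lens[1])
  qs <- t(apply(mat, 1L, stats::quantile, probs = probs, na.rm = TRUE,
                names = FALSE))
  colnames(qs) <- paste0("q", formatC(100 * probs, format = "fg"))
  out <- data.frame(
    generation = seq_len(lens[1]) - 1,
    n_iterations = rowSums(!is.na(mat)),
    mean = rowMeans(mat, na.rm = TRUE),
    median = apply(mat, 1L, stats::median, na.rm = TRUE),
    min = apply(mat, 1L, min, na.rm = TRUE),
    max = apply(mat, 1L, max, na.rm = TRUE)
  )
  cbind(out, qs)
}
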