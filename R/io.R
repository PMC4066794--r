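#' Load and validate a pipeline configuration file
#'
#' Reads a YAML or JSON configuration with optional blocks `drive_params`
#' (`c`, `h`, `phi`), `sim` (`release`, `eggs_per_female`, `cap`,
#' `generations`, `iterations`, `seed`), `assay` (`input`, `marker_map`),
#' `f2` (`input`, `alpha`) and `output_dir`. Unknown keys are rejected by
#' name; probabilities are validated to \eqn{[0, 1]}; defaults
#' (`eggs_per_female = 40`, `alpha = 0.05`, `target_allele = "T"`) are
#' filled in.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated, defaults-filled named list.
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("drive_params:", "  c: 0.861", "  h: 0.395",
#'              "  phi: 0.75"), cfg)
#' loadConfig(cfg)$drive_params
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg) || !is.list(cfg))
    stop("config file is empty or not a mapping: ", path)
  .checkKeys(cfg, c("drive_params", "sim", "assay", "f2", "output_dir"), "")
  if (!is.null(cfg$drive_params)) {
    .checkKeys(cfg$drive_params, c("c", "h", "phi"), "drive_params")
    for (k in c("c", "h", "phi")) {
      v <- cfg$drive_params[[k]]
      if (is.null(v) || !is.numeric(v) || v < 0 || v > 1)
        stop("drive_params.", k, " must be a probability in [0, 1]")
    }
  }
  if (!is.null(cfg$sim)) {
    .checkKeys(cfg$sim, c("release", "eggs_per_female", "cap", "generations",
                          "iterations", "seed"), "sim")
    if (!is.null(cfg$sim$release)) {
      .checkKeys(cfg$sim$release,
                 c("n_trans_het_males", "n_target_males", "n_target_females",
                   "target_allele"), "sim.release")
      if (is.null(cfg$sim$release$target_allele))
        cfg$sim$release$target_allele <- "T"
      if (!cfg$sim$release$target_allele %in% c("T", "N"))
        stop("sim.release.target_allele must be \"T\" or \"N\"")
    }
    if (is.null(cfg$sim$eggs_per_female)) cfg$sim$eggs_per_female <- 40L
    if (cfg$sim$eggs_per_female < 1) stop("sim.eggs_per_female must be >= 1")
  }
  if (!is.null(cfg$assay))
    .checkKeys(cfg$assay, c("input", "marker_map"), "assay")
  if (!is.null(cfg$f2)) {
    .checkKeys(cfg$f2, c("input", "alpha"), "f2")
    if (is.null(cfg$f2$alpha)) cfg$f2$alpha <- 0.05
    if (cfg$f2$alpha <= 0 || cfg$f2$alpha >= 1)
      stop("f2.alpha must be in (0, 1)")
  }
  cfg
}

.checkKeys <- function(block, allowed, where) {
  unknown <- setdiff(names(block), allowed)
  if (length(unknown))
    stop("unknown config key(s)",
         if (nzchar(where)) paste0(" in ", where), ": ",
         paste(unknown, collapse = ", "))
}

# Canonical TSV dialect: tab-separated, LF endings, '.' decimals, no quotes.
.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Write stochastic trajectories to TSV
#'
#' One row per (iteration, generation) with columns `generation`,
#' `iteration`, `n`, `freq_T`, `freq_D`, `freq_DN`, `freq_N`,
#' `gfp_negative`.
#'
#' @param trajectories List of [`Trajectory-class`] objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeTrajectories <- function(trajectories, path) {
  rows <- do.call(rbind, lapply(trajectories, as.data.frame))
  cols <- c("generation", "iteration", "n", "freq_T", "freq_D", "freq_DN",
            "freq_N", "gfp_negative")
  .writeTSV(rows[, cols], path)
}

#' Write a per-generation trajectory summary to TSV
#'
#' @param summary data.frame from [summarizeTrajectories()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeSummary <- function(summary, path) .writeTSV(summary, path)

#' Write rate estimates to TSV
#'
#' Emits one row per rate with the raw fraction, the percentage rounded to
#' one decimal (round-half-even), the interval bounds and the underlying
#' counts, so downstream consumers never need to re-derive rounding.
#'
#' @param rates A [`RateEstimates-class`] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeRates <- function(rates, path) {
  est <- rates@estimates
  df <- data.frame(
    rate = names(est),
    fraction = unname(est),
    percent = round(100 * unname(est), 1),
    ci_lower = unname(rates@ci[, 1]),
    ci_upper = unname(rates@ci[, 2]),
    n_target_total = rates@counts@nTargetTotal,
    n_gfp_loss = rates@counts@nGfpLoss,
    n_homed = rates@counts@nHomed,
    n_homing_assayed = rates@counts@nHomingAssayed
  )
  .writeTSV(df, path)
}

#' Read a per-progeny phenotype table
#'
#' Accepts comma- or tab-separated files with logical (or 0/1) columns
#' `white_plus`, `curled`, `gfp`, `rfp_or_pcr`. Lines starting with `#`
#' are ignored.
#'
#' @param path Input file path.
#' @return data.frame of logicals ready for [tabulateCross()].
#' @export
readProgenyTable <- function(path) {
  df <- .readTable(path)
  need <- c("white_plus", "curled", "gfp", "rfp_or_pcr")
  if (!all(need %in% names(df)))
    stop("progeny table must have columns ", paste(need, collapse = ", "))
  df[need] <- lapply(df[need], function(x) as.logical(x) | x == 1)
  df
}

#' Read a pre-aggregated assay counts table
#'
#' Expects columns `n_target_total`, `n_gfp_loss`, `n_homed` and optionally
#' `n_homing_assayed`; one row per line/cross.
#'
#' @param path Input file path.
#' @return List of [`AssayCounts-class`] objects, one per row.
#' @export
readCountsTable <- function(path) {
  df <- .readTable(path)
  need <- c("n_target_total", "n_gfp_loss", "n_homed")
  if (!all(need %in% names(df)))
    stop("counts table must have columns ", paste(need, collapse = ", "))
  if (is.null(df$n_homing_assayed)) df$n_homing_assayed <- df$n_gfp_loss
  lapply(seq_len(nrow(df)), function(i)
    assayCounts(df$n_target_total[i], df$n_gfp_loss[i], df$n_homed[i],
                df$n_homing_assayed[i]))
}

#' Read an F2 cross table
#'
#' Expects columns `gfp_pos` and `gfp_neg` (plus optional `cross_id`).
#'
#' @param path Input file path.
#' @return data.frame ready for [functionalHomingFraction()].
#' @export
readF2Table <- function(path) {
  df <- .readTable(path)
  if (!all(c("gfp_pos", "gfp_neg") %in% names(df)))
    stop("F2 table must have columns gfp_pos, gfp_neg")
  df
}

.readTable <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the seed,
#' the parameters and configuration used, and the package version.
#'
#' @param path Output file path.
#' @param seed Master seed of the run (may be NA for deterministic runs).
#' @param params A [`DriveParams-class`] object or NULL.
#' @param config Arbitrary named list of further settings.
#' @return The path, invisibly.
#' @export
writeManifest <- function(path, seed = NA, params = NULL, config = list()) {
  manifest <- list(
    package = "sseDrive",
    version = as.character(utils::packageVersion("sseDrive")),
    seed = seed,
    drive_params = if (!is.null(params))
      list(c = params@c, h = params@h, phi = params@phi),
    config = config
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
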