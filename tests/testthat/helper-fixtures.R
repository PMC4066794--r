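# Reference homing-assay counts from the characterized drive constructs: one row per cross,
# (n_target_total, n_gfp_loss, n_homed, n_homing_assayed).
referenceCounts <- list(
  talelat_male = assayCounts(1422, 998, 697),
  talelat_female = assayCounts(1487, 21, 17),
  zfn_male = assayCounts(425, 366, 117, 296),
  zfn_long_male = assayCounts(565, 483, 173, 435),
  zfn_female = assayCounts(517, 110, 0, 0),
  zfn_long_female = assayCounts(997, 119, 0, 0)
)

# Random valid drive parameters for property tests.
randomParams <- function() {
  DriveParams(c = runif(1), h = runif(1), phi = runif(1))
}

# All 20 genotype/sex combinations.
allGenotypes <- expand.grid(pair = genotypePairs(),
                            sex = c("male", "female"),
                            stringsAsFactors = FALSE)

# Sex-structured state matching a release population's per-sex frequencies.
releaseState <- function(release) {
  cts <- genotypeCounts(buildReleasePopulation(release))
  sexStructuredState(maleFreqs = cts[, "male"] / sum(cts[, "male"]),
                     femaleFreqs = cts[, "female"] / sum(cts[, "female"]))
}

# Run the bundled CLI in a child R process with the current library paths.
runCli <- function(args) {
  script <- system.file("scripts", "ssedrive.R", package = "sseDrive")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(
    rscript, c(script, args), stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  ))
  list(status = attr(out, "status") %||% 0L, output = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
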