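test_that("phenotypes map to chromosome classes under both marker conventions", {
  talen <- markerMap(cuOnDonor = TRUE, homingReadout = "rfp")
  # target-chromosome (w-) classes
  expect_identical(classifyPhenotype(FALSE, FALSE, TRUE, FALSE, talen),
                   "unmodified_target")
  expect_identical(classifyPhenotype(FALSE, FALSE, FALSE, TRUE, talen),
                   "homed")
  expect_identical(classifyPhenotype(FALSE, FALSE, FALSE, FALSE, talen),
                   "misrepair")
  # donor chromosome carries cu in the TALEN line
  expect_identical(classifyPhenotype(TRUE, TRUE, FALSE, TRUE, talen),
                   "donor_inherited")
  expect_identical(classifyPhenotype(TRUE, FALSE, FALSE, TRUE, talen),
                   "co_conversion")
  # ZFN convention: cu marks the target chromosome instead
  zfn <- markerMap(cuOnDonor = FALSE, homingReadout = "pcr")
  expect_identical(classifyPhenotype(TRUE, FALSE, FALSE, TRUE, zfn),
                   "donor_inherited")
  expect_identical(classifyPhenotype(TRUE, TRUE, FALSE, TRUE, zfn),
                   "co_conversion")
  # w- fly scored GFP+ and readout+ contradicts the marker model
  expect_error(classifyPhenotype(FALSE, FALSE, TRUE, TRUE, talen),
               "inconsistent")
})

test_that("classification is total and tabulation conserves progeny", {
  grid <- expand.grid(white_plus = c(TRUE, FALSE), curled = c(TRUE, FALSE),
                      gfp = c(TRUE, FALSE), rfp_or_pcr = c(TRUE, FALSE))
  grid <- grid[!(!grid$white_plus & grid$gfp & grid$rfp_or_pcr), ]
  for (map in list(markerMap(TRUE, "rfp"), markerMap(FALSE, "pcr"))) {
    cls <- classifyPhenotype(grid$white_plus, grid$curled, grid$gfp,
                             grid$rfp_or_pcr, map)
    expect_true(all(nzchar(cls)))
    expect_true(all(cls %in% c("donor_inherited", "unmodified_target",
                               "homed", "misrepair", "co_conversion")))
    expect_length(cls, nrow(grid))
  }
})

test_that("tabulated counts reflect the white-minus progeny classes", {
  expect_identical(tabulateCross(data.frame(white_plus = logical(),
                                            curled = logical(),
                                            gfp = logical(),
                                            rfp_or_pcr = logical()))@nTargetTotal,
                   0L)
  flies <- data.frame(
    white_plus = rep(c(FALSE, FALSE, FALSE, TRUE), c(10, 5, 5, 7)),
    curled = rep(c(FALSE, FALSE, FALSE, TRUE), c(10, 5, 5, 7)),
    gfp = rep(c(TRUE, FALSE, FALSE, FALSE), c(10, 5, 5, 7)),
    rfp_or_pcr = rep(c(FALSE, TRUE, FALSE, TRUE), c(10, 5, 5, 7))
  )
  ac <- tabulateCross(flies)  # donor-inherited rows excluded from counts
  expect_identical(c(ac@nTargetTotal, ac@nGfpLoss, ac@nHomed,
                     ac@nHomingAssayed), c(20L, 10L, 5L, 10L))
  # an explicitly supplied PCR-assayed denominator is respected
  ac2 <- tabulateCross(flies, nHomingAssayed = 8L)
  expect_identical(ac2@nHomingAssayed, 8L)
})

test_that("rate estimates reproduce the measured construct rates and satisfy identities", {
  est <- estimateRates(referenceCounts$talelat_male)
  e <- rateEstimates(est)
  expect_equal(round(100 * e[["cleavage_rate"]], 1), 70.2)
  expect_equal(round(100 * e[["homing_fraction"]], 1), 69.8)
  expect_equal(round(100 * e[["total_homed"]]), 49)
  est2 <- rateEstimates(estimateRates(referenceCounts$zfn_male))
  expect_equal(round(100 * est2[["cleavage_rate"]], 1), 86.1)
  expect_equal(round(100 * est2[["homing_fraction"]], 1), 39.5)
  expect_equal(round(100 * est2[["total_homed"]]), 34)
  # identities hold exactly
  expect_equal(e[["total_homed"]],
               e[["cleavage_rate"]] * e[["homing_fraction"]],
               tolerance = 1e-12)
  expect_equal(e[["nhej_fraction"]],
               e[["cleavage_rate"]] * (1 - e[["homing_fraction"]]),
               tolerance = 1e-12)
  # zero denominators are flagged, not silently zero
  none <- estimateRates(assayCounts(100, 0, 0, 0))
  expect_equal(rateEstimates(none)[["cleavage_rate"]], 0)
  expect_true(is.na(rateEstimates(none)[["homing_fraction"]]))
  expect_true("homing_fraction" %in% none@undefined)
  expect_error(assayCounts(10, 20, 5, 20), "nGfpLoss")
})

test_that("Wilson intervals are proper and contain the point estimate", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(1:2000, 1)
    x <- sample(0:n, 1)
    ci <- wilsonInterval(x, n)
    expect_true(ci["lower"] >= 0 && ci["upper"] <= 1)
    expect_true(ci["lower"] <= x / n && x / n <= ci["upper"])
  }
  est <- estimateRates(referenceCounts$zfn_male)
  ci <- rateConfint(est)
  e <- rateEstimates(est)
  for (nm in rownames(ci))
    expect_true(ci[nm, 1] <= e[[nm]] && e[[nm]] <= ci[nm, 2])
})

test_that("the 1:1 chi-square test matches closed-form arithmetic", {
  even <- chiSquare1to1(100, 100)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  expect_false(even$significant)
  # control cross counts: (222 - 209)^2 / 431
  ctrl <- chiSquare1to1(222, 209)
  expect_equal(ctrl$statistic, 169 / 431, tolerance = 1e-12)
  expect_equal(ctrl$p_value, pchisq(169 / 431, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(ctrl$significant)
  # (30, 70): 2 * 20^2 / 50 = 16 by hand
  skew <- chiSquare1to1(30, 70)
  expect_equal(skew$statistic, 16)
  expect_lt(skew$p_value, 0.001)
  expect_true(skew$significant)
  # symmetry and monotonicity in the imbalance
  expect_equal(chiSquare1to1(30, 70)$statistic,
               chiSquare1to1(70, 30)$statistic)
  ps <- sapply(seq(0, 40, by = 10),
               function(d) chiSquare1to1(100 + d, 100 - d)$p_value)
  expect_true(all(diff(ps) < 0))
  expect_error(chiSquare1to1(0, 0), "no progeny")
})

test_that("functional-homing counts only significant GFP deficits", {
  crosses <- data.frame(
    gfp_pos = c(rep(11, 15), rep(50, 5)),
    gfp_neg = c(rep(89, 15), rep(50, 5))
  )
  res <- functionalHomingFraction(crosses)
  expect_identical(res$n_significant, 15L)
  expect_equal(res$fraction, 0.75)
  # balanced crosses never count
  balanced <- data.frame(gfp_pos = rep(50, 4), gfp_neg = rep(50, 4))
  expect_equal(functionalHomingFraction(balanced)$fraction, 0)
  # a strong deficit counts; an equally strong excess does not (directional)
  expect_equal(functionalHomingFraction(
    data.frame(gfp_pos = 10, gfp_neg = 90))$fraction, 1)
  excess <- data.frame(gfp_pos = 90, gfp_neg = 10)
  expect_equal(functionalHomingFraction(excess)$fraction, 0)
  expect_equal(functionalHomingFraction(excess,
                                        directional = FALSE)$fraction, 1)
  expect_error(functionalHomingFraction(data.frame(gfp_pos = integer(),
                                                   gfp_neg = integer())),
               "no F2 crosses")
})
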