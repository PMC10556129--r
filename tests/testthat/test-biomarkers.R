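test_that("the aquatic flag needs both C18 and C20 APAAs, or DHAs alone", {
  onlyC18 <- makeSherds(1, abMatrix(1, APAA_C18 = 1))
  expect_false(computeBiomarkers(onlyC18)$aquatic_flag)
  both <- makeSherds(1, abMatrix(1, APAA_C18 = 1, APAA_C20 = 0.5))
  expect_true(computeBiomarkers(both)$aquatic_flag)
  dha <- makeSherds(1, abMatrix(1, DHA = 0.7))
  expect_true(computeBiomarkers(dha)$aquatic_flag)
  # disjunctive rule is configurable
  cfgOr <- pipelineConfig(aquaticApaaConjunctive = FALSE)
  expect_true(computeBiomarkers(onlyC18, cfgOr)$aquatic_flag)
})

test_that("ratios follow their definitions and absent denominators yield absent values", {
  se <- makeSherds(1, abMatrix(1, `C16:0` = 10.7, `C18:0` = 1.0))
  expect_equal(computeBiomarkers(se)$ps_ratio, 10.7)
  sym <- makeSherds(1, abMatrix(1, phytanic_SRR = 1, phytanic_RRR = 1))
  expect_equal(computeBiomarkers(sym)$pct_srr, 50)
  zero <- makeSherds(1, abMatrix(1, `C16:0` = 10, `C18:0` = 0))
  expect_true(is.na(computeBiomarkers(zero)$ps_ratio))   # no infinities
  onlySRR <- makeSherds(1, abMatrix(1, phytanic_SRR = 1))
  expect_true(is.na(computeBiomarkers(onlySRR)$pct_srr))
  allAbsent <- computeBiomarkers(makeSherds(1))
  expect_true(is.na(allAbsent$ps_ratio))
  expect_false(allAbsent$aquatic_flag)
  expect_identical(allAbsent$aquatic_subtype, "indeterminate")
})

test_that("%SRR complementarity: pct_srr(a,b) + pct_srr(b,a) = 100", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 0.01, 5); b <- runif(1, 0.01, 5)
    p1 <- computeBiomarkers(makeSherds(1, abMatrix(1, phytanic_SRR = a,
                                                   phytanic_RRR = b)))$pct_srr
    p2 <- computeBiomarkers(makeSherds(1, abMatrix(1, phytanic_SRR = b,
                                                   phytanic_RRR = a)))$pct_srr
    expect_equal(p1 + p2, 100)
  }
})

test_that("aquatic subtype windows are closed intervals and missing ratios stay indeterminate", {
  mk <- function(srr, tmtd) {
    ab <- abMatrix(1, APAA_C18 = 1, APAA_C20 = 1,
                   phytanic_SRR = srr, phytanic_RRR = 100 - srr,
                   TMTD = tmtd)
    computeBiomarkers(makeSherds(1, ab))$aquatic_subtype
  }
  expect_identical(mk(30, 50), "shellfish_like")      # tmtd/phy = 0.5
  expect_identical(mk(80, 200), "fish_or_mammal_like")
  expect_identical(mk(20, 34), "shellfish_like")      # lower boundaries in
  expect_identical(mk(47, 163), "shellfish_like")     # upper boundaries in
  expect_identical(mk(30, 200), "fish_or_mammal_like") # one ratio outside
  noRatios <- makeSherds(1, abMatrix(1, APAA_C18 = 1, APAA_C20 = 1))
  expect_identical(computeBiomarkers(noRatios)$aquatic_subtype,
                   "indeterminate")
})

test_that("maize alkanol, palm and hopane flags follow their abundance rules", {
  cfg <- pipelineConfig(alkanolTraceThreshold = 1, palmC12Threshold = 5)
  full <- makeSherds(1, abMatrix(1, alkanol_C32 = 3, alkanol_C28 = 1,
                                 alkanol_C30 = 0.5))
  expect_true(computeBiomarkers(full, cfg)$maize_alkanol_flag)
  trace <- makeSherds(1, abMatrix(1, alkanol_C32 = 0.5, alkanol_C28 = 1,
                                  alkanol_C30 = 0.5))
  expect_false(computeBiomarkers(trace, cfg)$maize_alkanol_flag)
  alone <- makeSherds(1, abMatrix(1, alkanol_C32 = 3, alkanol_C28 = 1))
  expect_false(computeBiomarkers(alone, cfg)$maize_alkanol_flag)
  palm <- makeSherds(1, abMatrix(1, `C12:0` = 20))
  expect_true(computeBiomarkers(palm, cfg)$palm_flag)
  hop <- makeSherds(1, abMatrix(1, hopane_C31 = 0.2))
  expect_true(computeBiomarkers(hop, cfg)$hopane_flag)
})

test_that("site summaries count sherds above the yield threshold and average offsets", {
  ab <- abMatrix(10, APAA_C18 = c(1, rep(NA, 9)), APAA_C20 = c(1, rep(NA, 9)))
  se <- makeSherds(10, ab, yield = 10, d16 = -25, d18 = -27)
  pan <- computeBiomarkers(se)
  s <- summarizeSites(se, pan)
  expect_equal(s$n, 10)
  expect_equal(s$aquatic_pct, 10)
  expect_equal(s$mean_delta, -2.0)

  # a sherd at 4.9 ug/g falls below the default threshold of 5
  se2 <- makeSherds(3, yield = c(4.9, 10, 10), d16 = -25, d18 = -26)
  s2 <- summarizeSites(se2, computeBiomarkers(se2))
  expect_equal(s2$n, 2)

  # a site with nothing above threshold keeps its row, with blanks
  se3 <- makeSherds(2, yield = 1)
  s3 <- summarizeSites(se3, computeBiomarkers(se3))
  expect_equal(s3$n, 0)
  expect_true(is.na(s3$aquatic_pct) && is.na(s3$mean_delta))
})

test_that("raising the yield threshold never increases a site's n, and order does not matter", {
  set.seed(7)
  sim <- simulateSherds(simulationScenario(nSherds = 60L, seed = 3L))
  se <- sim$sherds
  pan <- computeBiomarkers(se)
  ns <- vapply(c(1, 5, 20, 50), function(th)
    summarizeSites(se, pan, pipelineConfig(lipidYieldThreshold = th))$n[1],
    0)
  expect_true(all(diff(ns) <= 0))

  perm <- sample(ncol(se))
  sPerm <- summarizeSites(se[, perm], computeBiomarkers(se[, perm]))
  expect_equal(sPerm, summarizeSites(se, pan))
})
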