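test_that("forward mixing reduces correctly in its closed-form cases", {
  src <- maizeRuminantSet()
  # pure source returns that source's mean exactly
  expect_equal(forwardMix(c(1, 0), src, "C16:0"), -14.5)
  expect_equal(forwardMix(c(0, 1), src, "C18:0"), -31.0)
  # equal concentrations reduce to the plain fraction-weighted mean
  eq <- SourceSet(c("a", "b"),
                  deltaMean = rbind(c(-20, -20, -20), c(-30, -30, -30)),
                  deltaSd = matrix(1, 2, 3), conc = matrix(10, 2, 3))
  expect_equal(forwardMix(c(0.3, 0.7), eq, "C16:0"), 0.3 * -20 + 0.7 * -30)
  # hand-arithmetic oracle for the concentration-weighted mean
  expect_equal(forwardMix(c(0.5, 0.5), src, "C16:0"), -449.5 / 18.5)
  expect_equal(forwardMix(c(0.5, 0.5), src, "C18:0"), -326 / 11)
  d <- deltaOffset(forwardMix(c(0.5, 0.5), src, "C18:0"),
                   forwardMix(c(0.5, 0.5), src, "C16:0"))
  expect_equal(d, -5.34, tolerance = 5e-3)
})

test_that("forward mixing is invariant to rescaling all concentrations", {
  src <- maizeRuminantSet()
  scaled <- SourceSet(sourceNames(src), src@deltaMean, src@deltaSd,
                      src@conc * 0.37, src@faPerDryWeight)
  set.seed(6)
  for (i in 1:10) {
    f <- rgamma(2, 1); f <- f / sum(f)
    for (p in c("C16:0", "C18:0", "C18:1"))
      expect_equal(forwardMix(f, src, p), forwardMix(f, scaled, p))
  }
})

test_that("mixing curves hit pure-source endpoints and an all-zero proxy errors", {
  src <- maizeRuminantSet()
  cur <- mixingCurve(src, "maize", "ruminant", nSteps = 10)
  expect_equal(nrow(cur), 11)
  expect_equal(cur$d13c_16_0[1], -29.0)     # f_A = 0 is pure ruminant
  expect_equal(cur$d13c_16_0[11], -14.5)
  expect_equal(cur$delta_18_0_16_0[1], -2.0)
  expect_equal(cur$delta_18_0_16_0[11], -1.5)
  expect_error(mixingCurve(src, "maize", "ruminant", nSteps = 0), "nSteps")
  # identical sources give a constant trajectory
  same <- SourceSet(c("a", "b"),
                    deltaMean = rbind(c(-20, -22, -21), c(-20, -22, -21)),
                    deltaSd = matrix(1, 2, 3),
                    conc = rbind(c(10, 5, 8), c(10, 5, 8)))
  curSame <- mixingCurve(same, "a", "b", nSteps = 5)
  expect_equal(diff(range(curSame$delta_18_0_16_0)), 0)
  zeroConc <- SourceSet(c("a", "b"),
                        deltaMean = matrix(-20, 2, 3),
                        deltaSd = matrix(1, 2, 3),
                        conc = rbind(c(0, 10, 10), c(0, 10, 10)))
  expect_error(forwardMix(c(0.5, 0.5), zeroConc, "C16:0"),
               "undefined proxy")
})

test_that("maize mixed into ruminant fat drives the offset strictly down until maize dominates the C18:0 pool", {
  cur <- mixingCurve(maizeRuminantSet(), "maize", "ruminant", nSteps = 100)
  d <- cur$delta_18_0_16_0
  turn <- which.min(d)
  # the offset falls monotonically over the whole mixing range until the
  # maize fraction is large enough that its tiny C18:0 pool takes over
  expect_true(all(diff(d[1:turn]) < 0))
  expect_gt(cur$f_A[turn], 0.8)
  # and even near-pure maize stays well below both pure endpoints
  expect_lt(max(d[-c(1, length(d))]), max(d[1], d[length(d)]))
})

test_that("the marginal likelihood has its closed-form single-source limit", {
  src <- defaultSourceSet()["marine"]
  obs <- data.frame(proxy = "C16:0", value = -23.1, sd = 0.3)
  cfg <- pipelineConfig(sigmaModel = 0.5)
  want <- dnorm(-23.1, -24.0, sqrt(1.5^2 + 0.3^2 + 0.5^2), log = TRUE)
  expect_equal(marginalLogLik(1, src, obs, cfg), want)
})

test_that("a source carrying none of any observed proxy does not affect the likelihood", {
  base <- defaultSourceSet()[c("maize", "marine")]
  ghost <- SourceSet(c("maize", "marine", "ghost"),
                     deltaMean = rbind(base@deltaMean, c(-20, -20, -20)),
                     deltaSd = rbind(base@deltaSd, c(1, 1, 1)),
                     conc = rbind(base@conc, c(0, 0, 0)))
  obs <- data.frame(proxy = c("C16:0", "C18:0"),
                    value = c(-20, -25), sd = 0.3)
  set.seed(8)
  for (i in 1:5) {
    f2 <- rgamma(2, 1); f2 <- f2 / sum(f2)
    g <- runif(1, 0, 0.9)
    expect_equal(
      marginalLogLik(c(f2 * (1 - g), g), ghost, obs),
      marginalLogLik(f2, base, obs))
  }
})

test_that("with vanishing source variance and model error the likelihood collapses onto the forward prediction", {
  src <- maizeRuminantSet()
  tiny <- SourceSet(sourceNames(src), src@deltaMean,
                    matrix(1e-9, 2, 3), src@conc)
  cfg <- pipelineConfig(sigmaModel = 1e-12)
  f <- c(0.3, 0.7)
  obs <- data.frame(proxy = "C18:0", value = -28, sd = 0.4)
  want <- dnorm(-28, forwardMix(f, tiny, "C18:0"), 0.4, log = TRUE)
  expect_equal(marginalLogLik(f, tiny, obs, cfg), want, tolerance = 1e-6)
})

test_that("the analytic marginalization agrees with Monte-Carlo integration over source signatures", {
  src <- threeSourceSet()
  f <- c(0.5, 0.2, 0.3)
  # observe close to the forward prediction so densities are well scaled
  obs <- data.frame(proxy = c("C16:0", "C18:0", "C18:1"),
                    value = vapply(c("C16:0", "C18:0", "C18:1"),
                                   function(p) forwardMix(f, src, p) + 0.4,
                                   0),
                    sd = 0.3)
  cfg <- pipelineConfig(sigmaModel = 0.5)
  set.seed(9)
  ll <- marginalLogLik(f, src, obs, cfg)
  nmc <- 1e6
  S <- 3
  dens <- matrix(1, nmc, 1)
  totVar <- obs$sd^2 + cfg@sigmaModel^2
  for (j in seq_len(3)) {
    p <- c("C16:0", "C18:0", "C18:1")[j]
    cj <- src@conc[, p]
    w <- f * cj / sum(f * cj)
    # draw signatures, mix, and average the Gaussian observation density
    sig <- matrix(rnorm(nmc * S, mean = rep(src@deltaMean[, p], each = nmc),
                        sd = rep(src@deltaSd[, p], each = nmc)), nmc, S)
    mu <- as.vector(sig %*% w)
    dens <- dens * dnorm(obs$value[j], mu, sqrt(totVar[j]))
  }
  mcMean <- mean(dens)
  mcSe <- sd(dens) / sqrt(nmc)
  expect_lt(abs(exp(ll) - mcMean), 3 * mcSe)
})

test_that("the grid posterior normalizes, concentrates at pure-source observations and respects symmetry", {
  src <- threeSourceSet()
  cfg <- pipelineConfig(gridStep = 0.05, sigmaModel = 0.5)
  obs <- data.frame(proxy = c("C16:0", "C18:0"), value = c(-20, -26),
                    sd = 0.3)
  gp <- gridPosterior(src, obs, cfg)
  expect_equal(sum(gp$mass), 1, tolerance = 1e-12)
  expect_equal(sum(gp$means), 1, tolerance = 1e-9)

  # observation placed exactly at the marine signature with tiny variances
  tight <- SourceSet(sourceNames(src), src@deltaMean,
                     matrix(0.05, 3, 3), src@conc)
  atMarine <- data.frame(proxy = c("C16:0", "C18:0", "C18:1"),
                         value = src@deltaMean["marine", ], sd = 0.05)
  gpV <- gridPosterior(tight, atMarine,
                       pipelineConfig(gridStep = 0.05, sigmaModel = 0.05))
  mass <- sum(gpV$mass[gpV$grid[, "marine"] >= 0.9])
  expect_gt(mass, 0.95)

  # two interchangeable sources give a posterior symmetric under the swap
  twin <- SourceSet(c("a", "b", "c"),
                    deltaMean = rbind(c(-20, -25, -22), c(-20, -25, -22),
                                      c(-30, -31, -30)),
                    deltaSd = matrix(1, 3, 3),
                    conc = rbind(c(10, 10, 10), c(10, 10, 10),
                                 c(20, 20, 20)))
  gpT <- gridPosterior(twin, obs, cfg)
  swapped <- gpT$grid[, c("b", "a", "c")]
  colnames(swapped) <- c("a", "b", "c")
  key <- function(m) apply(round(m * 1e6), 1, paste, collapse = "_")
  m2 <- gpT$mass[match(key(gpT$grid), key(swapped))]
  expect_equal(gpT$mass, m2, tolerance = 1e-9)
  src5 <- SourceSet(letters[1:5], deltaMean = matrix(-25, 5, 3),
                    deltaSd = matrix(1, 5, 3), conc = matrix(10, 5, 3))
  expect_error(gridPosterior(src5, obs, cfg), "more than 4")
})

test_that("weight-basis conversion follows its closed form and favours lipid-poor sources", {
  src2 <- SourceSet(c("a", "b"), deltaMean = matrix(-25, 2, 3),
                    deltaSd = matrix(1, 2, 3), conc = matrix(10, 2, 3),
                    faPerDryWeight = c(1, 4))
  expect_equal(unname(faToWeightFractions(c(0.5, 0.5), src2)), c(0.8, 0.2))
  eqPhi <- SourceSet(c("a", "b"), deltaMean = matrix(-25, 2, 3),
                     deltaSd = matrix(1, 2, 3), conc = matrix(10, 2, 3),
                     faPerDryWeight = c(2, 2))
  expect_equal(unname(faToWeightFractions(c(0.3, 0.7), eqPhi)), c(0.3, 0.7))
  # maize has the lowest FA content per dry weight in the default set
  src <- defaultSourceSet()
  set.seed(10)
  for (i in 1:10) {
    f <- rgamma(4, 1); f <- f / sum(f)
    names(f) <- sourceNames(src)
    w <- faToWeightFractions(f, src)
    expect_gt(w[["maize"]], f[["maize"]])
  }
  noPhi <- SourceSet(c("a", "b"), deltaMean = matrix(-25, 2, 3),
                     deltaSd = matrix(1, 2, 3), conc = matrix(10, 2, 3))
  expect_error(faToWeightFractions(c(0.5, 0.5), noPhi), "missing")
})
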