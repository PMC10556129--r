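test_that("the sampler is deterministic given seed and configuration", {
  src <- threeSourceSet()
  obs <- data.frame(proxy = c("C16:0", "C18:0"), value = c(-19, -27),
                    sd = 0.3)
  cfg <- fastConfig(seed = 4L)
  a <- runMixing(src, obs, cfg)
  b <- runMixing(src, obs, cfg)
  expect_identical(posteriorSamples(a), posteriorSamples(b))
  c <- runMixing(src, obs, fastConfig(seed = 5L))
  expect_false(identical(posteriorSamples(a), posteriorSamples(c)))
})

test_that("MCMC marginal means agree with the grid-posterior oracle", {
  src <- threeSourceSet()
  obs <- data.frame(proxy = c("C16:0", "C18:0", "C18:1"),
                    value = c(-18, -27, -18.5), sd = 0.3)
  cfg <- pipelineConfig(mcmcIter = 5000L, mcmcBurnin = 1000L,
                        gridStep = 0.02, seed = 11L)
  gp <- gridPosterior(src, obs, cfg)
  fit <- runMixing(src, obs, cfg)
  expect_true(fit@converged)
  expect_true(all(abs(colMeans(posteriorSamples(fit)) - gp$means) < 0.02))
})

test_that("a source with no fatty acids collapses onto its prior marginal", {
  base <- threeSourceSet()
  ghost <- SourceSet(c(sourceNames(base), "ghost"),
                     deltaMean = rbind(base@deltaMean, c(-20, -20, -20)),
                     deltaSd = rbind(base@deltaSd, c(1, 1, 1)),
                     conc = rbind(base@conc, c(0, 0, 0)))
  obs <- data.frame(proxy = c("C16:0", "C18:0"), value = c(-19, -27),
                    sd = 0.3)
  fit <- runMixing(ghost, obs,
                   pipelineConfig(mcmcIter = 8000L, mcmcBurnin = 2000L,
                                  seed = 12L))
  g <- posteriorSamples(fit)[, "ghost"]
  S <- 4
  priorMean <- 1 / S                       # Beta(1, S-1)
  priorSd <- sqrt((S - 1) / (S^2 * (S + 1)))
  expect_lt(abs(mean(g) - priorMean), 0.03)   # within autocorrelated MC error
  expect_lt(abs(sd(g) - priorSd), 0.03)
})

test_that("full signature covariance changes the likelihood in the predicted direction and stays MC-consistent", {
  nm <- c("maize", "marine")
  base <- defaultSourceSet()[nm]
  C <- matrix(0.9, 3, 3); diag(C) <- 1    # strongly correlated signatures
  withCov <- SourceSet(nm, base@deltaMean, base@deltaSd, base@conc,
                       signatureCov = list(C, NULL))
  obs <- data.frame(proxy = c("C16:0", "C18:0"), value = c(-16, -18),
                    sd = 0.3)
  f <- c(0.8, 0.2)
  cfg <- pipelineConfig(sigmaModel = 0.3)
  llDiag <- marginalLogLik(f, base, obs, cfg)
  llCov <- marginalLogLik(f, withCov, obs, cfg)
  expect_false(isTRUE(all.equal(llDiag, llCov)))
  # Monte-Carlo check of the joint-covariance path
  set.seed(13)
  nmc <- 2e5
  L <- chol(C[1:2, 1:2] * tcrossprod(base@deltaSd[1, 1:2]))
  cj <- base@conc[, c("C16:0", "C18:0")]
  dens <- numeric(nmc)
  eps1 <- matrix(rnorm(2 * nmc), nmc, 2) %*% L
  sig2 <- cbind(rnorm(nmc, base@deltaMean[2, 1], base@deltaSd[2, 1]),
                rnorm(nmc, base@deltaMean[2, 2], base@deltaSd[2, 2]))
  v <- obs$sd^2 + cfg@sigmaModel^2
  dens <- rep(1, nmc)
  for (j in 1:2) {
    w <- f * cj[, j] / sum(f * cj[, j])
    mu <- w[1] * (base@deltaMean[1, j] + eps1[, j]) + w[2] * sig2[, j]
    dens <- dens * dnorm(obs$value[j], mu, sqrt(v[j]))
  }
  mcSe <- sd(dens) / sqrt(nmc)
  expect_lt(abs(exp(llCov) - mean(dens)), 3 * mcSe)
})

test_that("an uninformative configuration is flagged as non-identifiable", {
  same <- SourceSet(c("a", "b", "c"),
                    deltaMean = matrix(-25, 3, 3),
                    deltaSd = matrix(1, 3, 3),
                    conc = matrix(10, 3, 3))
  obs <- data.frame(proxy = "C16:0", value = -25, sd = 0.3)
  fit <- runMixing(same, obs, fastConfig(seed = 14L))
  expect_true(fit@nonIdentifiable)
  expect_equal(colMeans(posteriorSamples(fit)),
               c(a = 1/3, b = 1/3, c = 1/3), tolerance = 0.05)
})

test_that("posterior draws stay on the simplex and diagnostics are reported per source", {
  src <- threeSourceSet()
  obs <- data.frame(proxy = c("C16:0", "C18:0"), value = c(-22, -28),
                    sd = 0.3)
  fit <- runMixing(src, obs, fastConfig(seed = 15L))
  s <- posteriorSamples(fit)
  expect_true(all(abs(rowSums(s) - 1) < 1e-9))
  expect_true(all(s >= 0))
  expect_identical(names(fit@rhat), sourceNames(src))
  expect_length(fit@ess, 3)
  expect_length(fit@acceptRate, 4)
})
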