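## Concentration-dependent mixing of fatty-acid d13C signatures:
## forward model, analytically marginalized likelihood, brute-force grid
## posterior, random-walk Metropolis on ALR-transformed fractions, and
## FA-basis -> dry-weight-basis conversion.

.checkSimplex <- function(f, S, tol = 1e-9) {
  if (length(f) != S) stop("composition length must match sources")
  if (any(f < -tol) || abs(sum(f) - 1) > tol)
    stop("composition must lie on the unit simplex", call. = FALSE)
  pmax(f, 0)
}

.orderObserved <- function(observed) {
  # observed: named list/data.frame with elements value, sd per proxy, or a
  # data.frame with columns proxy, value, sd
  if (is.data.frame(observed)) {
    stopifnot(all(c("proxy", "value", "sd") %in% colnames(observed)))
    obs <- observed
  } else {
    obs <- data.frame(proxy = names(observed),
                      value = vapply(observed, `[[`, 0, "value"),
                      sd = vapply(observed, `[[`, 0, "sd"))
  }
  bad <- setdiff(obs$proxy, .PROXIES)
  if (length(bad)) stop("unknown proxy: ", paste(bad, collapse = ", "))
  if (nrow(obs) < 1) stop("at least one observed proxy is required")
  if (any(obs$sd <= 0)) stop("observation sd must be positive")
  obs[match(intersect(.PROXIES, obs$proxy), obs$proxy), , drop = FALSE]
}

#' Forward concentration-dependent mixing
#'
#' Expected delta-13C of fatty-acid proxy \code{proxy} in a mixture where
#' source i contributes fraction \code{f[i]} of total fatty acids: the
#' concentration-weighted mean
#' \deqn{\delta_j(f) = \sum_i f_i c_{ij} \delta_{ij} / \sum_i f_i c_{ij},}
#' with \eqn{c_{ij}} the proxy's concentration (\% of total fatty acids) in
#' source i. Sources rich in a proxy dominate that proxy's isotope value,
#' which is what makes maize (C16:0-rich, C18:0-poor) pull
#' \eqn{\Delta^{13}C_{18:0-16:0}} strongly negative in mixtures with animal
#' fats. Invariant to rescaling all concentrations by a common factor.
#'
#' @param f Numeric composition over sources (fractions of total fatty
#'   acids, summing to 1), in the order of \code{sourceNames(sources)} or
#'   named.
#' @param sources A \linkS4class{SourceSet}.
#' @param proxy One of \code{"C16:0"}, \code{"C18:0"}, \code{"C18:1"}.
#' @return Expected delta-13C (per mille VPDB).
#' @export
forwardMix <- function(f, sources, proxy) {
  proxy <- match.arg(proxy, .PROXIES)
  S <- length(sources@sourceNames)
  if (!is.null(names(f))) f <- f[sources@sourceNames]
  f <- .checkSimplex(f, S)
  cj <- sources@conc[, proxy]
  denom <- sum(f * cj)
  if (denom <= 0)
    stop("undefined proxy: mixture contains no ", proxy, call. = FALSE)
  sum(f * cj * sources@deltaMean[, proxy]) / denom
}

#' Two-source mixing trajectory
#'
#' Evaluates the forward model along f_A = 0 ... 1 between two sources and
#' reports both saturated-proxy values and their offset. Endpoints equal the
#' pure-source values exactly.
#'
#' @param sources A \linkS4class{SourceSet}.
#' @param sourceA,sourceB Names of the two sources to mix.
#' @param nSteps Number of intervals (>= 1); the curve has nSteps + 1 points.
#' @return data.frame with columns \code{f_A}, \code{d13c_16_0},
#'   \code{d13c_18_0}, \code{delta_18_0_16_0}.
#' @export
#' @examples
#' src <- defaultSourceSet()
#' curve <- mixingCurve(src, "maize", "ruminant", nSteps = 10)
#' head(curve)
mixingCurve <- function(sources, sourceA, sourceB, nSteps = 100) {
  if (nSteps < 1) stop("nSteps must be >= 1")
  sub <- sources[c(sourceA, sourceB)]
  fA <- seq(0, 1, length.out = nSteps + 1)
  d16 <- vapply(fA, function(a) forwardMix(c(a, 1 - a), sub, "C16:0"), 0)
  d18 <- vapply(fA, function(a) forwardMix(c(a, 1 - a), sub, "C18:0"), 0)
  data.frame(f_A = fA, d13c_16_0 = d16, d13c_18_0 = d18,
             delta_18_0_16_0 = deltaOffset(d18, d16))
}

# Likelihood factory: returns function(f) -> log-likelihood of the observed
# proxies. Source-signature uncertainty is marginalized analytically: given
# f, the mixture mean is linear in the signatures, so each observed proxy is
# Gaussian with mean sum_i w_ij delta_ij and variance
# sum_i w_ij^2 var_ij + sd_obs_j^2 + sigma_model^2, where
# w_ij = f_i c_ij / sum_k f_k c_kj. Sources with a full signature covariance
# induce cross-proxy covariance sum_i w_ij w_il C_i[j,l] and the proxies are
# scored jointly.
.makeLogLik <- function(sources, observed, cfg) {
  obs <- .orderObserved(observed)
  pj <- obs$proxy
  y <- obs$value
  obsVar <- obs$sd^2 + cfg@sigmaModel^2
  conc <- sources@conc[, pj, drop = FALSE]
  dmean <- sources@deltaMean[, pj, drop = FALSE]
  S <- length(sources@sourceNames)
  P <- length(pj)
  hasCov <- any(!vapply(sources@signatureCov, is.null, logical(1)))
  covs <- lapply(seq_len(S), function(i) {
    C <- sources@signatureCov[[i]]
    if (is.null(C)) C <- diag(sources@deltaSd[i, ]^2)
    dimnames(C) <- list(.PROXIES, .PROXIES)
    C[pj, pj, drop = FALSE]
  })
  dvar <- sources@deltaSd[, pj, drop = FALSE]^2
  function(f) {
    f <- .checkSimplex(f, S)
    denom <- colSums(f * conc)
    if (any(denom <= 0)) return(-Inf)
    W <- (f * conc) / rep(denom, each = S)   # S x P weights
    mu <- colSums(W * dmean)
    if (!hasCov) {
      v <- colSums(W^2 * dvar) + obsVar
      return(sum(dnorm(y, mu, sqrt(v), log = TRUE)))
    }
    Sig <- matrix(0, P, P)
    for (i in seq_len(S))
      Sig <- Sig + tcrossprod(W[i, ]) * covs[[i]]
    Sig <- Sig + diag(obsVar, P)
    L <- chol(Sig)
    z <- backsolve(L, y - mu, transpose = TRUE)
    -0.5 * sum(z^2) - sum(log(diag(L))) - 0.5 * P * log(2 * pi)
  }
}

#' Marginal log-likelihood of observed proxies given a composition
#'
#' Log-density of the observed delta-13C proxies under the
#' concentration-dependent mixing model, with source-signature uncertainty
#' marginalized analytically (exact, since the mixture mean is linear in the
#' signatures given the composition). Each observed proxy contributes a
#' Gaussian term with concentration-weighted mean and variance
#' \eqn{\sum_i w_{ij}^2 \sigma_{ij}^2 + sd_{obs,j}^2 + \sigma_{model}^2};
#' sources carrying a full signature covariance make the proxies jointly
#' Gaussian with the induced cross-proxy covariance.
#'
#' @param f Composition on the simplex (order of
#'   \code{sourceNames(sources)}).
#' @param sources A \linkS4class{SourceSet}.
#' @param observed Either a data.frame with columns \code{proxy},
#'   \code{value}, \code{sd}, or a named list of \code{list(value=, sd=)}
#'   per proxy; at least one proxy.
#' @param cfg A \code{\link{pipelineConfig}} (supplies
#'   \code{sigmaModel}).
#' @return Log-likelihood (scalar; \code{-Inf} where a mixture carries none
#'   of an observed proxy).
#' @export
marginalLogLik <- function(f, sources, observed, cfg = pipelineConfig()) {
  if (!is.null(names(f))) f <- f[sources@sourceNames]
  .makeLogLik(sources, observed, cfg)(as.numeric(f))
}

# all compositions of m into S non-negative parts (rows sum to m)
.simplexLattice <- function(S, m) {
  if (S == 1) return(matrix(m, 1, 1))
  do.call(rbind, lapply(0:m, function(k)
    cbind(k, .simplexLattice(S - 1, m - k))))
}

#' Brute-force posterior on a simplex lattice
#'
#' Exact-marginalization oracle for the Bayesian mixing model: enumerates
#' every composition on a regular simplex lattice with step
#' \code{cfg@gridStep}, weights each node by the flat Dirichlet(1) prior
#' times the marginal likelihood, and normalizes. Intended as an independent
#' check of the MCMC sampler; refuses more than 4 sources (combinatorial
#' blow-up).
#'
#' @param sources A \linkS4class{SourceSet} with at most 4 sources.
#' @param observed As in \code{\link{marginalLogLik}}.
#' @param cfg A \code{\link{pipelineConfig}}; \code{gridStep} must divide 1.
#' @return List with \code{grid} (nodes x sources matrix), \code{mass}
#'   (posterior masses summing to 1) and \code{means} (lattice-marginal
#'   posterior mean per source).
#' @export
gridPosterior <- function(sources, observed, cfg = pipelineConfig()) {
  S <- length(sources@sourceNames)
  if (S > 4)
    stop("grid posterior refuses more than 4 sources", call. = FALSE)
  m <- round(1 / cfg@gridStep)
  if (abs(m * cfg@gridStep - 1) > 1e-9) stop("gridStep must divide 1")
  F <- .simplexLattice(S, m) / m
  colnames(F) <- sources@sourceNames
  obs <- .orderObserved(observed)
  hasCov <- any(!vapply(sources@signatureCov, is.null, logical(1)))
  if (!hasCov) {
    ll <- rep(0, nrow(F))
    alive <- rep(TRUE, nrow(F))
    for (r in seq_len(nrow(obs))) {
      p <- obs$proxy[r]
      cj <- sources@conc[, p]
      denom <- as.vector(F %*% cj)
      alive <- alive & denom > 0
      mu <- as.vector(F %*% (cj * sources@deltaMean[, p])) / denom
      v <- as.vector((F * F) %*% (cj^2 * sources@deltaSd[, p]^2)) / denom^2 +
        obs$sd[r]^2 + cfg@sigmaModel^2
      ll <- ll + dnorm(obs$value[r], mu, sqrt(v), log = TRUE)
    }
    ll[!alive] <- -Inf
  } else {
    lik <- .makeLogLik(sources, observed, cfg)
    ll <- apply(F, 1, lik)
  }
  w <- exp(ll - max(ll[is.finite(ll)]))
  mass <- w / sum(w)
  list(grid = F, mass = mass,
       means = setNames(as.vector(crossprod(F, mass)),
                        sources@sourceNames))
}

## ALR transform between the open simplex and R^(S-1)
.alr <- function(f) log(f[-length(f)]) - log(f[length(f)])
.alrInv <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# split-Rhat over a draws x chains matrix
.splitRhat <- function(x) {
  n <- nrow(x)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  means <- colMeans(xs)
  vars <- apply(xs, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# effective sample size via Geyer's initial positive sequence, summed over
# chains
.essChain <- function(x) {
  n <- length(x)
  if (var(x) == 0) return(n)
  a <- acf(x, lag.max = min(200L, n - 1L), plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(a)) {
    pair <- a[k] + a[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Sample the mixing-model posterior by MCMC
#'
#' Random-walk Metropolis on additive-log-ratio-transformed source fractions
#' with the log-Jacobian included, under a flat Dirichlet(1) prior and the
#' analytically marginalized likelihood of \code{\link{marginalLogLik}}.
#' Runs \code{cfg@mcmcChains} chains from dispersed Dirichlet(1) starts; the
#' proposal scale is tuned during burn-in towards a 20--40\% acceptance
#' rate and frozen afterwards; all post-burn-in draws are retained
#' (no thinning). The run is flagged non-converged when any split-Rhat
#' exceeds 1.05, and non-identifiable when the posterior is essentially as
#' wide as the prior. Fully reproducible from \code{cfg@seed}.
#'
#' @param sources A \linkS4class{SourceSet} with at least 2 sources.
#' @param observed As in \code{\link{marginalLogLik}}; at least one proxy.
#' @param cfg A \code{\link{pipelineConfig}}.
#' @return A \linkS4class{MixPosterior}.
#' @export
#' @examples
#' src <- defaultSourceSet()[c("maize", "marine", "ruminant")]
#' obs <- data.frame(proxy = c("C16:0", "C18:0"),
#'                   value = c(-18, -27), sd = c(0.3, 0.3))
#' fit <- runMixing(src, obs, pipelineConfig(mcmcIter = 500L, seed = 2))
#' posteriorSummary(fit)
runMixing <- function(sources, observed, cfg = pipelineConfig()) {
  S <- length(sources@sourceNames)
  if (S < 2) stop("need at least 2 sources")
  lik <- .makeLogLik(sources, observed, cfg)
  logPost <- function(z) {
    f <- .alrInv(z)
    if (any(f <= 0)) return(-Inf)
    lik(f) + sum(log(f))    # flat Dirichlet(1) prior + ALR Jacobian
  }
  nKeep <- cfg@mcmcIter
  nBurn <- cfg@mcmcBurnin
  chains <- cfg@mcmcChains
  draws <- array(NA_real_, c(nKeep, S, chains))
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(cfg@seed + 1000003L * (ch - 1L))
    f0 <- rgamma(S, 1)
    f0 <- f0 / sum(f0)
    z <- .alr(f0)
    lp <- logPost(z)
    scale <- cfg@mcmcProposalScale
    accBlock <- 0L
    nAcc <- 0L
    total <- nBurn + nKeep
    for (it in seq_len(total)) {
      zProp <- z + scale * rnorm(S - 1)
      lpProp <- logPost(zProp)
      if (log(runif(1)) < lpProp - lp) {
        z <- zProp
        lp <- lpProp
        accBlock <- accBlock + 1L
        if (it > nBurn) nAcc <- nAcc + 1L
      }
      if (it <= nBurn && it %% 50L == 0L) {
        rate <- accBlock / 50
        if (rate < 0.2) scale <- max(scale * 0.8, 1e-3)
        else if (rate > 0.4) scale <- min(scale * 1.25, 10)
        accBlock <- 0L
      }
      if (it > nBurn) draws[it - nBurn, , ch] <- .alrInv(z)
    }
    accept[ch] <- nAcc / nKeep
  }
  rhat <- vapply(seq_len(S), function(j) .splitRhat(draws[, j, ]), 0)
  ess <- vapply(seq_len(S), function(j)
    sum(vapply(seq_len(chains), function(ch) .essChain(draws[, j, ch]), 0)),
    0)
  samples <- do.call(rbind, lapply(seq_len(chains),
                                   function(ch) draws[, , ch]))
  colnames(samples) <- sources@sourceNames
  priorSd <- sqrt((S - 1) / (S^2 * (S + 1)))   # Beta(1, S-1) marginal sd
  postSd <- apply(samples, 2, sd)
  new("MixPosterior", samples = samples,
      chainId = rep(seq_len(chains), each = nKeep),
      sourceNames = sources@sourceNames,
      rhat = setNames(rhat, sources@sourceNames),
      ess = setNames(ess, sources@sourceNames),
      acceptRate = accept,
      converged = all(rhat <= 1.05),
      nonIdentifiable = mean(postSd) > 0.95 * priorSd,
      seed = cfg@seed,
      config = .configAsList(cfg))
}

#' Convert fatty-acid fractions to dry-weight fractions
#'
#' A source contributing fraction f_i of total fatty acids contributes
#' \deqn{w_i = (f_i/\phi_i) / \sum_k (f_k/\phi_k)} of dry tissue weight,
#' where \eqn{\phi_i} is the source's total fatty-acid content per unit dry
#' tissue. Lipid-poor sources (e.g. maize kernels) therefore represent an
#' even greater share by weight than by fatty acids.
#'
#' @param f Composition over sources on the fatty-acid basis (named or in
#'   source order).
#' @param sources A \linkS4class{SourceSet} with \code{fa_per_dry_weight}
#'   set for every source.
#' @return Named composition on the dry-weight basis.
#' @export
#' @examples
#' src <- SourceSet(c("a", "b"),
#'                  deltaMean = matrix(-25, 2, 3), deltaSd = matrix(1, 2, 3),
#'                  conc = matrix(10, 2, 3), faPerDryWeight = c(1, 4))
#' faToWeightFractions(c(0.5, 0.5), src)  # 0.8, 0.2
faToWeightFractions <- function(f, sources) {
  S <- length(sources@sourceNames)
  if (!is.null(names(f))) f <- f[sources@sourceNames]
  f <- .checkSimplex(as.numeric(f), S)
  phi <- sources@faPerDryWeight
  if (anyNA(phi))
    stop("fa_per_dry_weight missing for: ",
         paste(sources@sourceNames[is.na(phi)], collapse = ", "),
         call. = FALSE)
  w <- (f / phi) / sum(f / phi)
  setNames(w, sources@sourceNames)
}
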