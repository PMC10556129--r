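#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame
#' @importFrom stats acf cor dnorm mahalanobis pchisq pnorm pt qchisq quantile
#'   rbinom rgamma rlnorm rnorm runif sd var setNames
#' @importFrom utils combn packageVersion read.csv write.csv
NULL

## canonical vocabulary ------------------------------------------------------

.PROXIES <- c("C16:0", "C18:0", "C18:1")
.PROXY_COLS <- c("C16:0" = "d13c_16_0", "C18:0" = "d13c_18_0",
                 "C18:1" = "d13c_18_1")
.TRADITIONS <- c("Taquara-Itararé", "Guarani")
.DECORATIONS <- c("plain", "decorated", "unknown")
.D13C_WINDOW <- c(-45, 0)

#' Recognised lipid compound identifiers
#'
#' The fixed vocabulary of compounds a sherd table may report: the major
#' saturated/unsaturated fatty acids, the aquatic degradation markers
#' (APAAs, dihydroxy acids), the isoprenoid acids (TMTD, pristanic and the
#' two phytanic acid diastereomers), even-carbon long-chain n-alkanols
#' C24--C36, bacteriohopanes C30--C33, levoglucosan and the non-specific
#' plant sterols/terpenes. Unknown identifiers are rejected at parse time.
#'
#' @return Character vector of compound identifiers.
#' @export
#' @examples
#' compoundKeys()
compoundKeys <- function() {
  c("C12:0", "C16:0", "C18:0", "C18:1",
    "TMTD", "pristanic", "phytanic_SRR", "phytanic_RRR",
    "APAA_C16", "APAA_C18", "APAA_C20", "DHA",
    paste0("alkanol_C", seq(24, 36, by = 2)),
    paste0("hopane_C", 30:33),
    "levoglucosan", "sterol", "terpene")
}

## PipelineConfig -------------------------------------------------------------

#' @rdname pipelineConfig
#' @export
setClass("PipelineConfig", representation(
  lipidYieldThreshold = "numeric",
  ellipseLevel = "numeric",
  shellfishSrrWindow = "numeric",
  shellfishTmtdWindow = "numeric",
  alkanolTraceThreshold = "numeric",
  palmC12Threshold = "numeric",
  defaultDeltaSd = "numeric",
  deltaShift = "numeric",
  aquaticApaaConjunctive = "logical",
  sigmaModel = "numeric",
  gridStep = "numeric",
  mcmcChains = "integer",
  mcmcIter = "integer",
  mcmcBurnin = "integer",
  mcmcProposalScale = "numeric",
  seed = "integer"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  pos <- c(lipidYieldThreshold = object@lipidYieldThreshold,
           alkanolTraceThreshold = object@alkanolTraceThreshold,
           palmC12Threshold = object@palmC12Threshold,
           defaultDeltaSd = object@defaultDeltaSd,
           sigmaModel0 = object@sigmaModel + 1e-12, # sigmaModel may be 0
           gridStep = object@gridStep,
           mcmcProposalScale = object@mcmcProposalScale)
  if (any(!is.finite(pos)) || any(pos <= 0))
    msg <- c(msg, "thresholds and scales must be positive finite numbers")
  if (object@ellipseLevel <= 0 || object@ellipseLevel >= 1)
    msg <- c(msg, "ellipseLevel must lie in (0, 1)")
  for (w in c("shellfishSrrWindow", "shellfishTmtdWindow")) {
    win <- slot(object, w)
    if (length(win) != 2L || diff(win) < 0)
      msg <- c(msg, paste(w, "must be an ordered [low, high] pair"))
  }
  m <- round(1 / object@gridStep)
  if (abs(m * object@gridStep - 1) > 1e-9)
    msg <- c(msg, "gridStep must divide 1")
  if (object@mcmcChains < 1L || object@mcmcIter < 1L || object@mcmcBurnin < 0L)
    msg <- c(msg, "mcmc settings must be positive counts")
  if (length(msg)) msg else TRUE
})

#' Pipeline configuration
#'
#' Bundles every tunable threshold of the screening and mixing pipeline:
#' the lipid-yield inclusion threshold (micrograms of lipid per gram of
#' ceramic), the confidence-ellipse probability level, the shellfish-like
#' windows on the phytanic-acid \%SRR and TMTD/phytanic ratios, abundance
#' thresholds for the maize alkanol and palm-oil (C12:0) flags, the default
#' analytical uncertainty assigned to delta-13C values that come without one,
#' an additive correction applied to reference-fat values (e.g. for the
#' modern fossil-fuel carbon shift; default 0), the mixing-model residual
#' term, the simplex grid step of the brute-force posterior, and the MCMC
#' settings.
#'
#' @param lipidYieldThreshold Minimum lipid yield (ug g-1) for a sherd to
#'   enter site summaries. Default 5.
#' @param ellipseLevel Coverage probability of reference ellipses. Default 0.68.
#' @param shellfishSrrWindow Closed \%SRR interval typifying shellfish.
#'   Default c(20, 47).
#' @param shellfishTmtdWindow Closed TMTD/phytanic interval typifying
#'   shellfish. Default c(0.34, 1.63).
#' @param alkanolTraceThreshold Abundance above which n-dotriacontanol counts
#'   as more than trace. Default 1.
#' @param palmC12Threshold Abundance of lauric acid flagging palm oil.
#'   Default 5.
#' @param defaultDeltaSd Analytical sd (per mille) used when a delta-13C value
#'   has none. Default 0.3.
#' @param deltaShift Additive per-mille correction applied to reference
#'   points before ellipse fitting. Default 0.
#' @param aquaticApaaConjunctive If TRUE (default) the aquatic flag requires
#'   both C18 and C20 APAAs; if FALSE either suffices.
#' @param sigmaModel Residual model error (per mille) absorbing unmodelled
#'   cooking/alteration fractionation. Default 0.5.
#' @param gridStep Simplex lattice step of the grid posterior; must divide 1.
#'   Default 0.02.
#' @param mcmcChains,mcmcIter,mcmcBurnin,mcmcProposalScale Metropolis sampler
#'   settings: number of chains (>= 4 recommended for split-Rhat), retained
#'   iterations per chain, burn-in iterations (discarded, used for proposal
#'   adaptation), and the initial random-walk scale.
#' @param seed Integer seed recorded in every output.
#' @return A \code{PipelineConfig} object.
#' @export
#' @examples
#' cfg <- pipelineConfig(seed = 7)
#' cfg
pipelineConfig <- function(lipidYieldThreshold = 5,
                           ellipseLevel = 0.68,
                           shellfishSrrWindow = c(20, 47),
                           shellfishTmtdWindow = c(0.34, 1.63),
                           alkanolTraceThreshold = 1,
                           palmC12Threshold = 5,
                           defaultDeltaSd = 0.3,
                           deltaShift = 0,
                           aquaticApaaConjunctive = TRUE,
                           sigmaModel = 0.5,
                           gridStep = 0.02,
                           mcmcChains = 4L,
                           mcmcIter = 3000L,
                           mcmcBurnin = 1000L,
                           mcmcProposalScale = 0.5,
                           seed = 1L) {
  new("PipelineConfig",
      lipidYieldThreshold = lipidYieldThreshold,
      ellipseLevel = ellipseLevel,
      shellfishSrrWindow = as.numeric(shellfishSrrWindow),
      shellfishTmtdWindow = as.numeric(shellfishTmtdWindow),
      alkanolTraceThreshold = alkanolTraceThreshold,
      palmC12Threshold = palmC12Threshold,
      defaultDeltaSd = defaultDeltaSd,
      deltaShift = deltaShift,
      aquaticApaaConjunctive = aquaticApaaConjunctive,
      sigmaModel = sigmaModel,
      gridStep = gridStep,
      mcmcChains = as.integer(mcmcChains),
      mcmcIter = as.integer(mcmcIter),
      mcmcBurnin = as.integer(mcmcBurnin),
      mcmcProposalScale = mcmcProposalScale,
      seed = as.integer(seed))
}

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig\n")
  cat("  lipid yield threshold:", object@lipidYieldThreshold, "ug/g\n")
  cat("  ellipse level:", object@ellipseLevel, "\n")
  cat("  shellfish %SRR window: [",
      paste(object@shellfishSrrWindow, collapse = ", "), "]\n", sep = "")
  cat("  shellfish TMTD/phytanic window: [",
      paste(object@shellfishTmtdWindow, collapse = ", "), "]\n", sep = "")
  cat("  sigma_model:", object@sigmaModel, "permil;  grid step:",
      object@gridStep, "\n")
  cat("  MCMC:", object@mcmcChains, "chains x", object@mcmcIter,
      "iter (+", object@mcmcBurnin, "burn-in), seed", object@seed, "\n")
})

## SherdExperiment ------------------------------------------------------------

#' Container for a sherd lipid dataset
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one pottery sherd per
#' column: the \code{"abundance"} assay stores compound relative abundances
#' (rows are \code{\link{compoundKeys}}; \code{NA} means the compound was not
#' observed, which is distinct from an abundance of zero), while
#' \code{colData} carries the per-sherd metadata (site, ceramic tradition,
#' decoration, lipid yield) and the delta-13C proxy values with their
#' analytical uncertainties.
#'
#' @export
setClass("SherdExperiment", contains = "SummarizedExperiment")

.SHERD_META_COLS <- c("sample_id", "site", "tradition", "decoration",
                      "lipid_yield")
.D13C_COLS <- as.vector(rbind(.PROXY_COLS, paste0(.PROXY_COLS, "_sd")))

setValidity("SherdExperiment", function(object) {
  msg <- character()
  if (!"abundance" %in% assayNames(object))
    return("assay 'abundance' is required")
  ab <- assay(object, "abundance")
  bad <- setdiff(rownames(ab), compoundKeys())
  if (length(bad))
    msg <- c(msg, paste("unknown compound identifiers:",
                        paste(bad, collapse = ", ")))
  if (any(ab[!is.na(ab)] < 0))
    msg <- c(msg, "compound abundances must be non-negative")
  cd <- colData(object)
  miss <- setdiff(c(.SHERD_META_COLS, .D13C_COLS), colnames(cd))
  if (length(miss))
    return(paste("missing colData columns:", paste(miss, collapse = ", ")))
  if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id values must be unique")
  if (any(!cd$tradition %in% .TRADITIONS))
    msg <- c(msg, "unknown tradition label")
  if (any(!cd$decoration %in% .DECORATIONS))
    msg <- c(msg, "unknown decoration label")
  ly <- cd$lipid_yield
  if (any(is.na(ly)) || any(ly < 0))
    msg <- c(msg, "lipid_yield must be present and >= 0")
  for (p in .PROXIES) {
    v <- cd[[.PROXY_COLS[[p]]]]
    s <- cd[[paste0(.PROXY_COLS[[p]], "_sd")]]
    ok <- !is.na(v)
    if (any(v[ok] < .D13C_WINDOW[1] | v[ok] > .D13C_WINDOW[2]))
      msg <- c(msg, paste0("delta13C ", p, " outside sanity window [",
                           .D13C_WINDOW[1], ", ", .D13C_WINDOW[2], "] permil"))
    if (any(ok & (is.na(s) | s <= 0)))
      msg <- c(msg, paste0("delta13C ", p, " present without positive sd"))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SherdExperiment
#'
#' @param abundance Numeric matrix, compounds x sherds; rownames must be a
#'   subset of \code{\link{compoundKeys}}. \code{NA} marks unobserved
#'   compounds. Rows for unobserved compounds may be omitted entirely.
#' @param colData A data.frame or DataFrame with one row per sherd and columns
#'   \code{sample_id}, \code{site}, \code{tradition}, \code{decoration},
#'   \code{lipid_yield}, \code{d13c_16_0}, \code{d13c_16_0_sd},
#'   \code{d13c_18_0}, \code{d13c_18_0_sd}, \code{d13c_18_1},
#'   \code{d13c_18_1_sd}.
#' @return A \linkS4class{SherdExperiment}.
#' @export
SherdExperiment <- function(abundance, colData) {
  colData <- as(colData, "DataFrame")
  full <- matrix(NA_real_, nrow = length(compoundKeys()), ncol = nrow(colData),
                 dimnames = list(compoundKeys(), colData$sample_id))
  if (!is.null(abundance) && nrow(abundance))
    full[rownames(abundance), ] <- as.matrix(abundance)
  colnames(full) <- colData$sample_id
  rownames(colData) <- colData$sample_id
  se <- SummarizedExperiment(assays = list(abundance = full),
                             colData = colData)
  new("SherdExperiment", se)
}

setMethod("show", "SherdExperiment", function(object) {
  cat("SherdExperiment with", ncol(object), "sherds,",
      sum(!apply(is.na(assay(object, "abundance")), 1, all)),
      "compounds observed\n")
  tab <- table(colData(object)$tradition)
  cat("  traditions:", paste(names(tab), tab, sep = ": ", collapse = "; "),
      "\n")
  cat("  sites:", length(unique(colData(object)$site)), "\n")
  nprox <- rowSums(!is.na(d13cValues(object)))
  cat("  d13C proxies per sherd: ",
      paste(names(table(nprox)), table(nprox), sep = "x", collapse = ", "),
      "\n", sep = "")
})

#' Accessors for SherdExperiment metadata
#'
#' \code{lipidYield}, \code{tradition} and \code{decoration} return the
#' per-sherd metadata vectors; \code{d13cValues} and \code{d13cSds} return
#' sherd x proxy matrices of delta-13C values (per mille VPDB) and their
#' analytical uncertainties, with \code{NA} where a proxy was not measured.
#'
#' @param object A \linkS4class{SherdExperiment}.
#' @return Named vector or matrix, see details.
#' @export
lipidYield <- function(object) {
  setNames(colData(object)$lipid_yield, colData(object)$sample_id)
}

#' @rdname lipidYield
#' @export
tradition <- function(object) {
  setNames(colData(object)$tradition, colData(object)$sample_id)
}

#' @rdname lipidYield
#' @export
decoration <- function(object) {
  setNames(colData(object)$decoration, colData(object)$sample_id)
}

#' @rdname lipidYield
#' @export
d13cValues <- function(object) {
  cd <- colData(object)
  m <- matrix(NA_real_, nrow(cd), length(.PROXIES),
              dimnames = list(cd$sample_id, .PROXIES))
  for (p in .PROXIES) m[, p] <- cd[[.PROXY_COLS[[p]]]]
  m
}

#' @rdname lipidYield
#' @export
d13cSds <- function(object) {
  cd <- colData(object)
  m <- matrix(NA_real_, nrow(cd), length(.PROXIES),
              dimnames = list(cd$sample_id, .PROXIES))
  for (p in .PROXIES) m[, p] <- cd[[paste0(.PROXY_COLS[[p]], "_sd")]]
  m
}

## SourceSet ------------------------------------------------------------------

#' Reference fatty-acid signatures of candidate food sources
#'
#' Holds, for each candidate source (by default maize, marine, C3 plant and
#' wild ruminant), the mean and uncertainty of its delta-13C signature for
#' each of the three fatty-acid proxies, the concentration of each proxy as a
#' percentage of total fatty acids, the total fatty-acid content per unit dry
#' tissue (used to convert fatty-acid contributions to weight contributions),
#' and an optional full 3x3 covariance of the three signatures that
#' overrides the diagonal sds.
#'
#' @export
setClass("SourceSet", representation(
  sourceNames = "character",
  deltaMean = "matrix",
  deltaSd = "matrix",
  conc = "matrix",
  faPerDryWeight = "numeric",
  signatureCov = "list"))

setValidity("SourceSet", function(object) {
  msg <- character()
  S <- length(object@sourceNames)
  if (anyDuplicated(object@sourceNames))
    msg <- c(msg, "source names must be unique")
  for (sl in c("deltaMean", "deltaSd", "conc")) {
    m <- slot(object, sl)
    if (!identical(dim(m), c(S, 3L)) ||
        !identical(colnames(m), .PROXIES))
      msg <- c(msg, paste(sl, "must be an S x 3 matrix with proxy columns"))
  }
  if (length(msg)) return(msg)
  if (any(object@deltaSd <= 0))
    msg <- c(msg, "delta_sd must be > 0")
  if (any(object@conc < 0))
    msg <- c(msg, "concentrations must be >= 0")
  if (any(rowSums(object@conc) > 100 + 1e-9))
    msg <- c(msg, "per-source proxy concentrations must sum to <= 100 %")
  phi <- object@faPerDryWeight
  if (length(phi) != S || any(!is.na(phi) & phi <= 0))
    msg <- c(msg, "fa_per_dry_weight must be > 0 where given")
  if (length(object@signatureCov) != S) {
    msg <- c(msg, "signatureCov must have one entry per source")
  } else {
    for (C in object@signatureCov) {
      if (is.null(C)) next
      if (!is.matrix(C) || !identical(dim(C), c(3L, 3L)) ||
          max(abs(C - t(C))) > 1e-8 || min(eigen(C, TRUE)$values) < -1e-8)
        msg <- c(msg, "signatureCov entries must be symmetric PSD 3x3")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SourceSet
#'
#' @param sourceNames Character vector of unique source names.
#' @param deltaMean,deltaSd,conc Numeric S x 3 matrices (columns
#'   \code{"C16:0"}, \code{"C18:0"}, \code{"C18:1"}): signature means (per
#'   mille VPDB), signature sds (> 0, per mille) and proxy concentrations as
#'   \% of total fatty acids (row sums at most 100; the remainder is other
#'   fatty acids).
#' @param faPerDryWeight Total fatty acid mass fraction per unit dry tissue
#'   for each source (> 0); \code{NA} allowed if weight conversion is not
#'   needed.
#' @param signatureCov Optional list (one entry per source) of 3x3 signature
#'   covariance matrices; \code{NULL} entries fall back to the diagonal sds.
#' @return A \linkS4class{SourceSet}.
#' @export
SourceSet <- function(sourceNames, deltaMean, deltaSd, conc,
                      faPerDryWeight = rep(NA_real_, length(sourceNames)),
                      signatureCov = vector("list", length(sourceNames))) {
  fix <- function(m) {
    m <- as.matrix(m)
    dimnames(m) <- list(sourceNames, .PROXIES)
    storage.mode(m) <- "double"
    m
  }
  new("SourceSet", sourceNames = sourceNames, deltaMean = fix(deltaMean),
      deltaSd = fix(deltaSd), conc = fix(conc),
      faPerDryWeight = setNames(as.numeric(faPerDryWeight), sourceNames),
      signatureCov = signatureCov)
}

#' @rdname SourceSet-class
#' @param object A \code{SourceSet}.
#' @export
sourceNames <- function(object) object@sourceNames

setMethod("show", "SourceSet", function(object) {
  cat("SourceSet with", length(object@sourceNames), "sources:",
      paste(object@sourceNames, collapse = ", "), "\n")
  for (i in seq_along(object@sourceNames)) {
    cat(sprintf("  %-10s d13C = (%s) permil, conc = (%s) %%FA\n",
                object@sourceNames[i],
                paste(sprintf("%.1f", object@deltaMean[i, ]), collapse = ", "),
                paste(sprintf("%.0f", object@conc[i, ]), collapse = ", ")))
  }
})

#' Subset a SourceSet by source name
#'
#' @param x A \linkS4class{SourceSet}.
#' @param i Character or integer index of sources to keep.
#' @param j,drop,... Ignored.
#' @return A \linkS4class{SourceSet} with the selected sources.
#' @export
setMethod("[", "SourceSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sourceNames)
  if (anyNA(i)) stop("unknown source name")
  SourceSet(x@sourceNames[i], x@deltaMean[i, , drop = FALSE],
            x@deltaSd[i, , drop = FALSE], x@conc[i, , drop = FALSE],
            x@faPerDryWeight[i], x@signatureCov[i])
})

## EllipseModel ---------------------------------------------------------------

#' Bivariate confidence ellipse of a reference fat class
#'
#' A Gaussian coverage ellipse in (delta-13C 16:0, delta-13C 18:0) space:
#' centre = sample mean, shape = unbiased sample covariance, and squared
#' Mahalanobis radius equal to the chi-squared (2 df) quantile at the chosen
#' coverage level, so that the ellipse contains the stated fraction of the
#' fitted population.
#'
#' @export
setClass("EllipseModel", representation(
  className = "character",
  center = "numeric",
  covariance = "matrix",
  level = "numeric",
  radius2 = "numeric"))

setValidity("EllipseModel", function(object) {
  msg <- character()
  if (length(object@center) != 2L)
    msg <- c(msg, "center must be a 2-vector")
  C <- object@covariance
  if (!identical(dim(C), c(2L, 2L)) || abs(C[1, 2] - C[2, 1]) > 1e-8)
    msg <- c(msg, "covariance must be symmetric 2x2")
  else if (min(eigen(C, TRUE)$values) <= 0)
    msg <- c(msg, "covariance must be positive definite")
  if (object@radius2 <= 0) msg <- c(msg, "radius2 must be > 0")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "level must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EllipseModel", function(object) {
  cat(sprintf(
    "EllipseModel '%s': center (%.2f, %.2f) permil, level %.2f, radius2 %.3f\n",
    object@className, object@center[1], object@center[2], object@level,
    object@radius2))
})

## MixPosterior ---------------------------------------------------------------

#' Posterior of source contributions for one sherd
#'
#' Retained MCMC draws of the source fractions (as proportions of total fatty
#' acids), together with convergence diagnostics: split-Rhat and effective
#' sample size per source, per-chain acceptance rates, a convergence flag
#' (all split-Rhat at most 1.05) and a non-identifiability note set when the
#' posterior is essentially as wide as the prior.
#'
#' @export
setClass("MixPosterior", representation(
  samples = "matrix",        # draws x sources, each row on the simplex
  chainId = "integer",
  sourceNames = "character",
  rhat = "numeric",
  ess = "numeric",
  acceptRate = "numeric",
  converged = "logical",
  nonIdentifiable = "logical",
  seed = "integer",
  config = "list"))

setValidity("MixPosterior", function(object) {
  msg <- character()
  if (ncol(object@samples) != length(object@sourceNames))
    msg <- c(msg, "samples columns must match sourceNames")
  if (nrow(object@samples)) {
    rs <- rowSums(object@samples)
    if (max(abs(rs - 1)) > 1e-6 || min(object@samples) < -1e-12)
      msg <- c(msg, "each retained draw must lie on the simplex")
  }
  if (length(object@rhat) != length(object@sourceNames))
    msg <- c(msg, "rhat must be reported for every source")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MixPosterior", function(object) {
  cat("MixPosterior:", nrow(object@samples), "draws over",
      length(object@sourceNames), "sources",
      sprintf("(seed %d)\n", object@seed))
  print(posteriorSummary(object), digits = 3)
  cat(if (object@converged) "  converged" else "  NOT converged",
      sprintf("(max split-Rhat %.3f, min ESS %.0f, accept %.2f)\n",
              max(object@rhat), min(object@ess), mean(object@acceptRate)))
  if (object@nonIdentifiable)
    cat("  note: posterior ~ prior width; data barely constrain fractions\n")
})

#' @rdname MixPosterior-class
#' @param object A \code{MixPosterior}.
#' @return \code{posteriorSamples}: the draws x sources matrix.
#' @export
posteriorSamples <- function(object) object@samples

#' @rdname MixPosterior-class
#' @return \code{posteriorSummary}: a data.frame with per-source posterior
#'   mean, sd, 2.5/50/97.5 percentiles, split-Rhat and ESS.
#' @export
posteriorSummary <- function(object) {
  s <- object@samples
  q <- t(apply(s, 2, quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  data.frame(source = object@sourceNames,
             mean = colMeans(s), sd = apply(s, 2, sd),
             q2.5 = q[, 1], q50 = q[, 2], q97.5 = q[, 3],
             rhat = object@rhat, ess = object@ess,
             row.names = NULL)
}

## TestResult -----------------------------------------------------------------

#' Result of a group-contrast statistic
#'
#' @export
setClass("TestResult", representation(
  statistic = "numeric",
  statisticName = "character",
  n = "integer",
  df = "numeric",
  pValue = "numeric",
  method = "character"))

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) &&
      (object@pValue < 0 || object@pValue > 1))
    "p-value must lie in [0, 1]" else TRUE
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s = %.4g", object@statisticName, object@statistic))
  if (!is.na(object@df)) cat(sprintf(", df = %g", object@df))
  cat(sprintf(", p = %.4g  (n = %s; %s)\n", object@pValue,
              paste(object@n, collapse = ", "), object@method))
})
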