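## Delta offsets and 68% reference-fat confidence ellipses in
## (d13C 16:0, d13C 18:0) space.

#' Offset between stearic and palmitic acid delta-13C values
#'
#' The classification axis Delta13C_18:0-16:0 = d13C_18:0 - d13C_16:0.
#' Vectorized; \code{NA} in either argument propagates.
#'
#' @param d18 delta-13C of C18:0 (per mille VPDB).
#' @param d16 delta-13C of C16:0 (per mille VPDB).
#' @return \code{d18 - d16}.
#' @export
#' @examples
#' deltaOffset(-29.5, -25.0)  # -4.5
deltaOffset <- function(d18, d16) d18 - d16

#' Fit a Gaussian coverage ellipse to reference points
#'
#' Centre = sample mean, shape = unbiased sample covariance, squared radius =
#' chi-squared (2 df) quantile at \code{level}, i.e. the density contour
#' containing the stated fraction of the fitted bivariate normal population.
#' This is a population-coverage ellipse for classifying individual samples,
#' not a standard-error-of-the-mean ellipse.
#'
#' @param points Numeric matrix or data.frame with 2 columns (d13C 16:0,
#'   d13C 18:0), at least 3 non-collinear rows.
#' @param level Coverage probability; default 0.68.
#' @param className Label carried by the ellipse.
#' @return An \linkS4class{EllipseModel}.
#' @export
fitConfidenceEllipse <- function(points, level = 0.68,
                                 className = "reference") {
  m <- as.matrix(points)
  if (nrow(m) < 3)
    stop("degenerate input: need at least 3 reference points", call. = FALSE)
  ctr <- colMeans(m)
  C <- var(m)
  if (!is.finite(determinant(C)$modulus) || det(C) <= 1e-12)
    stop("degenerate input: reference points are (near-)collinear",
         call. = FALSE)
  new("EllipseModel", className = className, center = unname(ctr),
      covariance = unname(C), level = level,
      radius2 = qchisq(level, df = 2))
}

#' Test whether a point lies in an ellipse
#'
#' Boundary inclusive: TRUE iff the squared Mahalanobis distance of \code{p}
#' from the ellipse centre is at most the ellipse's squared radius.
#'
#' @param e An \linkS4class{EllipseModel}.
#' @param p Numeric 2-vector, or a 2-column matrix of points.
#' @return Logical (one value per point).
#' @export
ellipseContains <- function(e, p) {
  m <- if (is.null(dim(p))) matrix(p, ncol = 2) else as.matrix(p)
  mahalanobis(m, e@center, e@covariance) <= e@radius2 + 1e-12
}

#' Fit one ellipse per reference class
#'
#' @param refPoints Output of \code{\link{readReferencePoints}}.
#' @param level Coverage probability.
#' @param deltaShift Additive per-mille correction applied to both
#'   coordinates of every reference point before fitting (default 0).
#' @return Named list of \linkS4class{EllipseModel} objects.
#' @export
fitReferenceEllipses <- function(refPoints, level = 0.68, deltaShift = 0) {
  classes <- unique(refPoints$class)
  setNames(lapply(classes, function(cl) {
    pts <- refPoints[refPoints$class == cl, c("d13c_16_0", "d13c_18_0")]
    fitConfidenceEllipse(pts + deltaShift, level = level, className = cl)
  }), classes)
}

#' Classify sherds against reference-fat ellipses
#'
#' For every sherd with both the 16:0 and 18:0 proxies, returns the names of
#' every reference ellipse containing its point. Membership is multi-label:
#' overlap between reference classes is real and reported, not resolved to a
#' nearest class. Sherds missing either proxy get \code{NULL} (absent
#' classification).
#'
#' @param se A \linkS4class{SherdExperiment}, or a numeric 2-vector
#'   (d13C 16:0, d13C 18:0) for a single query point.
#' @param ellipses Named list of \linkS4class{EllipseModel} objects.
#' @return For a 2-vector: character vector of class names (possibly empty).
#'   For a \code{SherdExperiment}: named list of such vectors, \code{NULL}
#'   where a proxy is missing.
#' @export
classifyAgainstReferences <- function(se, ellipses) {
  classify1 <- function(pt) {
    hit <- vapply(ellipses, ellipseContains, logical(1), p = pt)
    names(ellipses)[hit]
  }
  if (is.numeric(se)) return(classify1(se))
  dl <- d13cValues(se)
  out <- setNames(vector("list", nrow(dl)), rownames(dl))
  for (i in seq_len(nrow(dl))) {
    pt <- c(dl[i, "C16:0"], dl[i, "C18:0"])
    if (!anyNA(pt)) out[[i]] <- classify1(pt)
  }
  out
}
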