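## Group-contrast statistics implemented from first principles so that the
## comparisons behind residue-study tables are reproducible and auditable:
## tie-corrected Mann-Whitney U with exact enumeration where feasible,
## Pearson product-moment correlation with the t transform, and the
## two-sample t statistic (Welch or pooled).

# exact two-sided p by enumerating all assignments of the pooled midranks to
# group 1 (handles ties); feasible for small samples only
.uExactEnum <- function(ranks, n1, uObs) {
  idx <- combn(length(ranks), n1)
  uAll <- colSums(matrix(ranks[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  n2 <- length(ranks) - n1
  uMin <- pmin(uAll, n1 * n2 - uAll)
  mean(uMin <= min(uObs, n1 * n2 - uObs) + 1e-9)
}

# exact distribution of the rank-sum statistic without ties via the standard
# counting recursion; returns two-sided p for U = uObs
.uExactDP <- function(n1, n2, uObs) {
  # count[u+1] = number of n1-subsets of ranks 1..n1+n2 with U = u
  maxU <- n1 * n2
  counts <- vapply(0:maxU, function(u) .uCount(n1, n2, u), 0)
  tot <- sum(counts)
  u <- round(uObs)                       # U is integer when there are no ties
  pLe <- sum(counts[seq_len(u + 1)]) / tot
  pGe <- sum(counts[(u + 1):(maxU + 1)]) / tot
  min(1, 2 * min(pLe, pGe))
}

.uCountCache <- new.env(parent = emptyenv())
.uCount <- function(n1, n2, u) {
  if (u < 0 || u > n1 * n2) return(0)
  if (n1 == 0 || n2 == 0) return(as.numeric(u == 0))
  key <- paste(n1, n2, u)
  hit <- .uCountCache[[key]]
  if (!is.null(hit)) return(hit)
  val <- .uCount(n1 - 1, n2, u - n2) + .uCount(n1, n2 - 1, u)
  .uCountCache[[key]] <- val
  val
}

#' Mann-Whitney U test
#'
#' U computed from midranks (tie-corrected). The reported statistic is
#' min(U_x, U_y) by default (\code{report = "x"} gives the x-group U).
#' The two-sided p-value is exact -- by enumeration over all label
#' assignments when that is feasible (handles ties), or by the rank-sum
#' counting recursion when there are no ties and n1*n2 <= 400 -- and
#' otherwise uses the normal approximation with tie-corrected variance and
#' a continuity correction.
#'
#' @param x,y Non-empty numeric samples.
#' @param report Which U to report: \code{"min"} (default) or \code{"x"}.
#' @return A \linkS4class{TestResult}.
#' @export
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))   # U = 0
mannWhitneyU <- function(x, y, report = c("min", "x")) {
  report <- match.arg(report)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))           # midranks
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- if (report == "min") min(ux, uy) else ux
  ties <- table(r)
  hasTies <- any(ties > 1)
  if (choose(N, n1) <= 1e5) {
    p <- .uExactEnum(r, n1, ux)
    method <- "exact (enumeration)"
  } else if (!hasTies && n1 * n2 <= 400) {
    p <- .uExactDP(n1, n2, ux)
    method <- "exact (rank-sum recursion)"
  } else {
    mu <- n1 * n2 / 2
    tieTerm <- sum(ties^3 - ties) / (N * (N - 1))
    v <- n1 * n2 / 12 * ((N + 1) - tieTerm)
    z <- (ux - mu - sign(ux - mu) * 0.5) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  new("TestResult", statistic = u, statisticName = "U",
      n = c(n1, n2), df = NA_real_, pValue = min(1, p), method = method)
}

#' Pearson product-moment correlation
#'
#' Pairs with any absent value are dropped and the effective n reported;
#' df = n - 2 and the two-sided p-value comes from the t transform
#' t = r sqrt(df / (1 - r^2)).
#'
#' @param x,y Paired numeric samples (same length).
#' @return A \linkS4class{TestResult} with statistic \code{r}.
#' @export
pearsonR <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(t), df)
  }
  new("TestResult", statistic = r, statisticName = "r",
      n = n, df = as.numeric(df), pValue = p, method = "t transform")
}

#' Two-sample t test statistic
#'
#' Welch's unequal-variance form by default, with a pooled-variance option.
#' A zero standard error with unequal means reports an overflow-safe large
#' statistic with p = 0; zero within-group variance in both groups with
#' equal means is an error (the statistic is undefined).
#'
#' @param x,y Numeric samples with at least 2 values each.
#' @param equalVariance Use the pooled-variance form. Default FALSE (Welch).
#' @return A \linkS4class{TestResult} with statistic \code{t}.
#' @export
twoSampleT <- function(x, y, equalVariance = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("need at least 2 values per group")
  v1 <- var(x); v2 <- var(y)
  d <- mean(x) - mean(y)
  if (v1 == 0 && v2 == 0) {
    if (d == 0) stop("undefined statistic: zero variance in both groups",
                     call. = FALSE)
    return(new("TestResult", statistic = sign(d) * 1e15,
               statisticName = "t", n = c(n1, n2), df = NA_real_,
               pValue = 0, method = "degenerate: zero within-group variance"))
  }
  if (equalVariance) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "pooled variance"
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "Welch"
  }
  t <- d / se
  new("TestResult", statistic = t, statisticName = "t",
      n = c(n1, n2), df = df, pValue = 2 * pt(-abs(t), df), method = method)
}
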