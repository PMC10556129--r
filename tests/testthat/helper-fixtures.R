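# Fixtures built in code: a minimal sherd CSV writer and small source sets.

sherdCsvHeader <- paste(
  "sample_id,site,tradition,decoration,lipid_yield_ug_g",
  "d13c_16_0,d13c_16_0_sd,d13c_18_0,d13c_18_0_sd,d13c_18_1,d13c_18_1_sd",
  "C16:0,C18:0,APAA_C18,APAA_C20,DHA,phytanic_SRR,phytanic_RRR,TMTD",
  sep = ",")

writeSherdCsv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c(sherdCsvHeader, rows), path, useBytes = TRUE)
  path
}

# spec'd two-source fixture: maize C16:0-rich and 13C-enriched, ruminant the
# C3 animal-fat endpoint
maizeRuminantSet <- function() {
  SourceSet(c("maize", "ruminant"),
            deltaMean = rbind(c(-14.5, -16.0, -13.5),
                              c(-29.0, -31.0, -29.5)),
            deltaSd = matrix(1, 2, 3),
            conc = rbind(c(12, 2, 30), c(25, 20, 30)),
            faPerDryWeight = c(0.045, 0.60))
}

threeSourceSet <- function() defaultSourceSet()[c("maize", "marine",
                                                  "ruminant")]

fastConfig <- function(seed = 1L, ...) {
  pipelineConfig(mcmcIter = 1500L, mcmcBurnin = 500L, seed = seed, ...)
}

# build a SherdExperiment in code; `abundance` is a compounds x n matrix (or
# NULL), d13c vectors recycle to n
makeSherds <- function(n, abundance = NULL, yield = 10, site = "S",
                       tradition = "Guarani", d16 = NA_real_,
                       d18 = NA_real_, d181 = NA_real_) {
  r <- function(x) rep_len(x, n)
  sdFor <- function(v) ifelse(is.na(v), NA_real_, 0.3)
  cd <- data.frame(sample_id = paste0("S", seq_len(n)), site = r(site),
                   tradition = r(tradition), decoration = "unknown",
                   lipid_yield = r(yield),
                   d13c_16_0 = r(d16), d13c_16_0_sd = sdFor(r(d16)),
                   d13c_18_0 = r(d18), d13c_18_0_sd = sdFor(r(d18)),
                   d13c_18_1 = r(d181), d13c_18_1_sd = sdFor(r(d181)),
                   stringsAsFactors = FALSE)
  SherdExperiment(abundance, cd)
}

# independent permutation oracle for the rank-sum statistic: enumerate every
# assignment of the pooled values to group 1, recompute U from midranks, and
# take the tail fraction of the min-U statistic
permutationOracle <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  r <- rank(pool)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  uObs <- uOf(seq_len(n1))
  uMinObs <- min(uObs, n1 * (N - n1) - uObs)
  all <- combn(N, n1)
  uAll <- apply(all, 2, uOf)
  uMinAll <- pmin(uAll, n1 * (N - n1) - uAll)
  list(u = uObs, p = mean(uMinAll <= uMinObs + 1e-9))
}

abMatrix <- function(n, ...) {
  vals <- list(...)
  m <- matrix(NA_real_, length(vals), n,
              dimnames = list(names(vals), NULL))
  for (k in names(vals)) m[k, ] <- rep_len(vals[[k]], n)
  m
}
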