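## Biomarker screening: aquatic (APAA/DHA), shellfish-like isoprenoid
## windows, maize alkanol, palm (lauric acid), hopanes, levoglucosan;
## plus per-site summary rows.

.AQUATIC_SUBTYPES <- c("fish_or_mammal_like", "shellfish_like",
                       "indeterminate")

#' Derive the biomarker panel of every sherd
#'
#' Computes, per sherd: the palmitic/stearic abundance ratio (P/S), the
#' phytanic-acid diastereomer percentage \%SRR = 100 SRR/(SRR+RRR), the
#' TMTD/phytanic ratio, the aquatic-product flag (C18 and C20 APAAs jointly,
#' or dihydroxy acids; the conjunctive APAA rule is configurable), its
#' shellfish/fish subtype (see \code{\link{classifyAquaticSubtype}}), the
#' maize alkanol flag (above-trace n-dotriacontanol plus at least two other
#' even-carbon C28--C36 alkanols), the palm-oil flag (high lauric acid), the
#' bacteriohopane flag and levoglucosan presence. Ratios with an absent or
#' zero denominator are reported absent, never infinite; an all-absent sherd
#' yields an all-absent/false panel.
#'
#' @param se A \linkS4class{SherdExperiment}.
#' @param cfg A \code{\link{pipelineConfig}} supplying thresholds/windows.
#' @return A \code{DataFrame} with one row per sherd, in column order of
#'   \code{se}.
#' @export
#' @examples
#' sim <- simulateSherds(presetScenarios()$guarani_like)
#' head(as.data.frame(computeBiomarkers(sim$sherds)))
computeBiomarkers <- function(se, cfg = pipelineConfig()) {
  ab <- assay(se, "abundance")
  val <- function(k) ab[k, ]
  pres <- function(k) !is.na(ab[k, ]) & ab[k, ] > 0
  n <- ncol(se)

  ps <- ifelse(pres("C18:0") & !is.na(val("C16:0")),
               val("C16:0") / val("C18:0"), NA_real_)
  bothPhy <- !is.na(val("phytanic_SRR")) & !is.na(val("phytanic_RRR"))
  phyTot <- val("phytanic_SRR") + val("phytanic_RRR")
  srr <- ifelse(bothPhy & phyTot > 0,
                100 * val("phytanic_SRR") / phyTot, NA_real_)
  tmtd <- ifelse(!is.na(val("TMTD")) & bothPhy & phyTot > 0,
                 val("TMTD") / phyTot, NA_real_)
  apaa <- if (cfg@aquaticApaaConjunctive) pres("APAA_C18") & pres("APAA_C20")
          else pres("APAA_C18") | pres("APAA_C20")
  aquatic <- apaa | pres("DHA")
  countPresent <- function(keys)
    Reduce(`+`, lapply(keys, function(k) as.integer(pres(k))))
  alk <- paste0("alkanol_C", seq(28, 36, by = 2))
  others <- countPresent(setdiff(alk, "alkanol_C32"))
  maizeAlk <- !is.na(val("alkanol_C32")) &
    val("alkanol_C32") > cfg@alkanolTraceThreshold & others >= 2
  palm <- !is.na(val("C12:0")) & val("C12:0") > cfg@palmC12Threshold
  hop <- countPresent(paste0("hopane_C", 30:33)) > 0
  panel <- DataFrame(sample_id = colnames(se),
                     ps_ratio = unname(ps),
                     pct_srr = unname(srr),
                     tmtd_phytanic = unname(tmtd),
                     aquatic_flag = unname(aquatic),
                     maize_alkanol_flag = unname(maizeAlk),
                     palm_flag = unname(palm),
                     hopane_flag = unname(hop),
                     levoglucosan_present = unname(pres("levoglucosan")),
                     row.names = colnames(se))
  panel$aquatic_subtype <- classifyAquaticSubtype(panel, cfg)
  panel[, c("sample_id", "ps_ratio", "pct_srr", "tmtd_phytanic",
            "aquatic_flag", "aquatic_subtype", "maize_alkanol_flag",
            "palm_flag", "hopane_flag", "levoglucosan_present")]
}

#' Classify aquatic sherds as shellfish-like or fish/mammal-like
#'
#' A sherd is \code{shellfish_like} when it carries aquatic biomarkers and
#' both its \%SRR and TMTD/phytanic ratios fall inside the configured closed
#' shellfish windows; \code{fish_or_mammal_like} when it is aquatic and at
#' least one of the two ratios is present and falls outside its window; and
#' \code{indeterminate} otherwise (including every non-aquatic sherd).
#'
#' @param panel Output of \code{\link{computeBiomarkers}} (the
#'   \code{aquatic_subtype} column is ignored if present).
#' @param cfg A \code{\link{pipelineConfig}} supplying the windows.
#' @return Character vector of subtypes.
#' @export
classifyAquaticSubtype <- function(panel, cfg = pipelineConfig()) {
  inWin <- function(x, w) !is.na(x) & x >= w[1] & x <= w[2]
  outWin <- function(x, w) !is.na(x) & (x < w[1] | x > w[2])
  srrIn <- inWin(panel$pct_srr, cfg@shellfishSrrWindow)
  tmtdIn <- inWin(panel$tmtd_phytanic, cfg@shellfishTmtdWindow)
  anyOut <- outWin(panel$pct_srr, cfg@shellfishSrrWindow) |
    outWin(panel$tmtd_phytanic, cfg@shellfishTmtdWindow)
  ifelse(panel$aquatic_flag & srrIn & tmtdIn, "shellfish_like",
         ifelse(panel$aquatic_flag & anyOut, "fish_or_mammal_like",
                "indeterminate"))
}

#' Summarize sherds per site and tradition
#'
#' Reproduces the layout of a site summary table: per (site, tradition), the
#' number of sherds whose lipid yield exceeds the configured threshold, the
#' percentage of those carrying aquatic biomarkers (rounded to integer) and
#' the mean 18:0--16:0 delta-13C offset over sherds with both proxies
#' (1 decimal). Site/tradition combinations with no sherd above the
#' threshold emit a row with n = 0 and blank statistics.
#'
#' @param se A \linkS4class{SherdExperiment}.
#' @param panels Output of \code{\link{computeBiomarkers}} for \code{se}.
#' @param cfg A \code{\link{pipelineConfig}}.
#' @return A data.frame with columns \code{site}, \code{tradition},
#'   \code{n}, \code{aquatic_pct}, \code{mean_delta}.
#' @export
summarizeSites <- function(se, panels, cfg = pipelineConfig()) {
  cd <- as.data.frame(colData(se))
  dl <- d13cValues(se)
  delta <- deltaOffset(dl[, "C18:0"], dl[, "C16:0"])
  keep <- cd$lipid_yield > cfg@lipidYieldThreshold
  groups <- unique(cd[, c("site", "tradition")])
  groups <- groups[order(groups$tradition, groups$site), ]
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- cd$site == groups$site[g] & cd$tradition == groups$tradition[g]
    use <- sel & keep
    n <- sum(use)
    if (n == 0)
      return(data.frame(site = groups$site[g],
                        tradition = groups$tradition[g], n = 0L,
                        aquatic_pct = NA_real_, mean_delta = NA_real_))
    aq <- round(100 * sum(panels$aquatic_flag[use]) / n)
    d <- delta[use]
    md <- if (any(!is.na(d))) round(mean(d, na.rm = TRUE), 1) else NA_real_
    data.frame(site = groups$site[g], tradition = groups$tradition[g],
               n = n, aquatic_pct = aq, mean_delta = md)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
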