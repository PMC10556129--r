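## Tabular readers/writers for the sherd, source and reference-point CSV
## dialects, plus the YAML pipeline configuration and the per-run report.

# Published tables use typographic minus and per-mille glyphs; normalize to
# ASCII before numeric parsing.
.normalizeAscii <- function(x) {
  x <- gsub("−|–", "-", x)
  x <- gsub("‰", "", x)
  trimws(x)
}

# strict numeric parser naming row and column on failure; "" -> NA
.parseNum <- function(x, column, rows = seq_along(x)) {
  x <- .normalizeAscii(x)
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & nzchar(x)
  suppressWarnings(out[has] <- as.numeric(x[has]))
  bad <- has & is.na(out)
  if (any(bad))
    stop(sprintf("malformed numeric value '%s' in column '%s', row %d",
                 x[bad][1], column, rows[bad][1]), call. = FALSE)
  out
}

.readCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, check.names = FALSE, colClasses = "character",
           fileEncoding = "UTF-8", na.strings = c("NA", ""))
}

.SHERD_FIXED_COLS <- c("sample_id", "site", "tradition", "decoration",
                       "lipid_yield_ug_g", .D13C_COLS)

#' Read a sherd table
#'
#' Parses the one-row-per-sherd CSV dialect: fixed metadata and delta-13C
#' columns followed by one abundance column per recognised compound
#' identifier (see \code{\link{compoundKeys}}). Empty cells stay absent
#' (\code{NA}) rather than being coerced to zero; typographic minus signs and
#' per-mille glyphs are normalized before parsing; delta-13C values present
#' without an analytical sd receive \code{defaultDeltaSd} from the
#' configuration.
#'
#' @param path Path to a \code{sherds.csv}-dialect file.
#' @param cfg A \code{\link{pipelineConfig}}; supplies the default
#'   analytical sd.
#' @return A \linkS4class{SherdExperiment} with rows in file order.
#' @export
readSherdTable <- function(path, cfg = pipelineConfig()) {
  df <- .readCsv(path)
  miss <- setdiff(c("sample_id", "site", "tradition", "lipid_yield_ug_g"),
                  colnames(df))
  if (length(miss))
    stop("sherd table lacks required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(df), c(.SHERD_FIXED_COLS, compoundKeys()))
  if (length(extra))
    stop("unknown columns in sherd table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  id <- df$sample_id
  if (anyDuplicated(id))
    stop("duplicate sample_id: ", id[duplicated(id)][1], call. = FALSE)
  trad <- .normalizeAscii(df$tradition)
  trad[trad == "Taquara-Itarare"] <- "Taquara-Itararé"
  bad <- !trad %in% .TRADITIONS
  if (any(bad))
    stop(sprintf("unknown tradition label '%s' in row %d",
                 trad[bad][1], which(bad)[1]), call. = FALSE)
  deco <- if ("decoration" %in% colnames(df)) df$decoration
          else rep(NA_character_, n)
  deco[is.na(deco)] <- "unknown"
  bad <- !deco %in% .DECORATIONS
  if (any(bad))
    stop(sprintf("unknown decoration label '%s' in row %d",
                 deco[bad][1], which(bad)[1]), call. = FALSE)
  yield <- .parseNum(df$lipid_yield_ug_g, "lipid_yield_ug_g")
  if (any(is.na(yield) | yield < 0))
    stop(sprintf("lipid_yield_ug_g missing or negative in row %d",
                 which(is.na(yield) | yield < 0)[1]), call. = FALSE)
  cd <- data.frame(sample_id = id, site = df$site, tradition = trad,
                   decoration = deco, lipid_yield = yield,
                   stringsAsFactors = FALSE)
  for (p in .PROXIES) {
    vc <- .PROXY_COLS[[p]]
    sc <- paste0(vc, "_sd")
    v <- if (vc %in% colnames(df)) .parseNum(df[[vc]], vc) else rep(NA_real_, n)
    s <- if (sc %in% colnames(df)) .parseNum(df[[sc]], sc) else rep(NA_real_, n)
    s[!is.na(v) & is.na(s)] <- cfg@defaultDeltaSd
    cd[[vc]] <- v
    cd[[sc]] <- s
  }
  ckeys <- intersect(compoundKeys(), colnames(df))
  ab <- if (length(ckeys)) {
    m <- vapply(ckeys, function(k) .parseNum(df[[k]], k), numeric(n))
    t(matrix(m, nrow = n, dimnames = list(id, ckeys)))
  } else NULL
  SherdExperiment(ab, cd)
}

#' Write a sherd table
#'
#' Inverse of \code{\link{readSherdTable}}: emits the same CSV dialect with
#' numeric values rounded to 6 decimals, so that a write/read round trip
#' reproduces every field to that precision. Compounds never observed in any
#' sherd are omitted as columns.
#'
#' @param se A \linkS4class{SherdExperiment}.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeSherdTable <- function(se, path) {
  cd <- as.data.frame(colData(se))
  out <- data.frame(sample_id = cd$sample_id, site = cd$site,
                    tradition = cd$tradition, decoration = cd$decoration,
                    lipid_yield_ug_g = round(cd$lipid_yield, 6),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in .D13C_COLS) out[[cl]] <- round(cd[[cl]], 6)
  ab <- assay(se, "abundance")
  keep <- rownames(ab)[rowSums(!is.na(ab)) > 0]
  for (k in keep) out[[k]] <- round(ab[k, ], 6)
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a reference-fat source table
#'
#' Parses the long-format \code{sources.csv} dialect (columns \code{source},
#' \code{fatty_acid}, \code{delta_mean}, \code{delta_sd}, \code{conc_pct_fa},
#' \code{fa_per_dry_weight}); every source must carry all three fatty-acid
#' proxies, sds must be positive, and per-source concentrations must sum to
#' at most 100 \% (the remainder being other fatty acids).
#'
#' @param path Path to the CSV file.
#' @return A \linkS4class{SourceSet} keyed by unique source name.
#' @export
readSourceTable <- function(path) {
  df <- .readCsv(path)
  need <- c("source", "fatty_acid", "delta_mean", "delta_sd", "conc_pct_fa")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("source table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df[c("source", "fatty_acid")]))
    stop("duplicate source/fatty_acid row in source table", call. = FALSE)
  srcs <- unique(df$source)
  dm <- ds <- cc <- matrix(NA_real_, length(srcs), 3,
                           dimnames = list(srcs, .PROXIES))
  phi <- setNames(rep(NA_real_, length(srcs)), srcs)
  dmv <- .parseNum(df$delta_mean, "delta_mean")
  dsv <- .parseNum(df$delta_sd, "delta_sd")
  ccv <- .parseNum(df$conc_pct_fa, "conc_pct_fa")
  phiv <- if ("fa_per_dry_weight" %in% colnames(df))
    .parseNum(df$fa_per_dry_weight, "fa_per_dry_weight")
  else rep(NA_real_, nrow(df))
  for (r in seq_len(nrow(df))) {
    fa <- df$fatty_acid[r]
    if (!fa %in% .PROXIES)
      stop(sprintf("unknown fatty_acid '%s' in row %d", fa, r), call. = FALSE)
    s <- df$source[r]
    dm[s, fa] <- dmv[r]; ds[s, fa] <- dsv[r]; cc[s, fa] <- ccv[r]
    if (!is.na(phiv[r])) phi[s] <- phiv[r]
  }
  if (anyNA(dm))
    stop("each source needs all three fatty acids; missing for: ",
         paste(rownames(dm)[apply(is.na(dm), 1, any)], collapse = ", "),
         call. = FALSE)
  if (any(dsv <= 0, na.rm = TRUE))
    stop("delta_sd must be positive", call. = FALSE)
  SourceSet(srcs, dm, ds, cc, phi)
}

#' Read reference-fat scatter points
#'
#' Points of authentic reference fats in (delta-13C 16:0, delta-13C 18:0)
#' space used to fit the per-class confidence ellipses; columns \code{class},
#' \code{d13c_16_0}, \code{d13c_18_0}.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with those three columns.
#' @export
readReferencePoints <- function(path) {
  df <- .readCsv(path)
  miss <- setdiff(c("class", "d13c_16_0", "d13c_18_0"), colnames(df))
  if (length(miss))
    stop("reference point table lacks columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(class = df$class,
             d13c_16_0 = .parseNum(df$d13c_16_0, "d13c_16_0"),
             d13c_18_0 = .parseNum(df$d13c_18_0, "d13c_18_0"),
             stringsAsFactors = FALSE)
}

#' Read a YAML pipeline configuration
#'
#' Keys mirror the arguments of \code{\link{pipelineConfig}}; absent keys keep
#' their defaults, unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A \linkS4class{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(pipelineConfig, vals)
}

.configAsList <- function(cfg) {
  sn <- slotNames(cfg)
  setNames(lapply(sn, function(s) slot(cfg, s)), sn)
}

#' Write the per-sherd analysis report
#'
#' Emits one CSV row per sherd combining metadata, the biomarker panel, the
#' delta-13C proxies and their 18:0--16:0 offset, the reference-ellipse
#' classes, and (where a posterior was computed) the per-source posterior
#' means and 95\% credible bounds; alongside it a machine-readable JSON
#' metadata document recording configuration, seed and software version.
#' Rerunning with identical inputs and seed reproduces the numeric CSV
#' content byte for byte.
#'
#' @param se A \linkS4class{SherdExperiment}.
#' @param panels Output of \code{\link{computeBiomarkers}} for \code{se} (or
#'   \code{NULL}).
#' @param posteriors Named list (by sample_id) of
#'   \linkS4class{MixPosterior} objects; sherds without an entry get blank
#'   posterior columns.
#' @param path Output CSV path; the metadata document is written next to it.
#' @param cfg The \code{\link{pipelineConfig}} used for the run.
#' @param ellipseClasses Optional named list (by sample_id) of character
#'   vectors of reference-ellipse memberships.
#' @param metadataPath Path for the JSON run-metadata document.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(se, panels = NULL, posteriors = list(), path,
                        cfg = pipelineConfig(), ellipseClasses = NULL,
                        metadataPath = paste0(path, ".meta.json")) {
  cd <- as.data.frame(colData(se))
  ids <- cd$sample_id
  dl <- d13cValues(se)
  out <- data.frame(sample_id = ids, site = cd$site,
                    tradition = cd$tradition, decoration = cd$decoration,
                    lipid_yield_ug_g = round(cd$lipid_yield, 6),
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(panels)) {
    p <- as.data.frame(panels)
    stopifnot(identical(p$sample_id, ids))
    for (cl in setdiff(colnames(p), "sample_id"))
      out[[cl]] <- if (is.numeric(p[[cl]])) round(p[[cl]], 6) else p[[cl]]
  }
  out$d13c_16_0 <- round(dl[, "C16:0"], 6)
  out$d13c_18_0 <- round(dl[, "C18:0"], 6)
  out$d13c_18_1 <- round(dl[, "C18:1"], 6)
  out$delta_18_0_16_0 <- round(deltaOffset(dl[, "C18:0"], dl[, "C16:0"]), 6)
  if (!is.null(ellipseClasses))
    out$ellipse_classes <- vapply(ids, function(i) {
      cls <- ellipseClasses[[i]]
      if (is.null(cls)) NA_character_ else paste(cls, collapse = ";")
    }, character(1))
  srcs <- if (length(posteriors)) posteriors[[1]]@sourceNames else character()
  for (s in srcs) {
    for (stat in c("mean", "sd", "q2.5", "q97.5")) {
      col <- paste0("post_", gsub("\\.", "", stat), "_", s)
      out[[col]] <- vapply(ids, function(i) {
        mp <- posteriors[[i]]
        if (is.null(mp)) return(NA_real_)
        ps <- posteriorSummary(mp)
        round(ps[ps$source == s, stat], 6)
      }, numeric(1))
    }
  }
  write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  meta <- list(package = "csiaMix",
               version = as.character(packageVersion("csiaMix")),
               seed = cfg@seed,
               config = .configAsList(cfg),
               n_sherds = length(ids),
               n_posteriors = length(posteriors))
  jsonlite::write_json(meta, metadataPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
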