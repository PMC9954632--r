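## Orchestration: run every exposure x outcome analysis of a plan,
## assemble the forest table and a structured diagnostics report.
##
## Each cell runs the full suite: harmonization (with optional proxy
## substitution), fixed- and random-effects IVW, MR-Egger, weighted
## median, leave-one-out, MR-PRESSO and a post-outlier-removal IVW.
## Cells fail independently: an error in one analysis is recorded in its
## cell and the remaining cells still run.  Every cell is flagged with a
## headline model -- random-effects when the Cochran-Q p-value is below
## 0.05, fixed-effects otherwise -- and Egger results are annotated
## unreliable when I2GX < 0.90.

.defaultSettings <- function() {
  list(effects_model = "random", n_boot = 1000, presso_nsim = 1000,
       presso_alpha = 0.05, alpha = 0.05, r2_proxy = 0.8,
       palindrome_window = c(0.42, 0.58))
}

#' Build an analysis plan
#'
#' @param exposures named list of exposure [MRPanel-class] objects
#'   (e.g. PC1, PC2, PC3).
#' @param outcomes named list of outcome [MRPanel-class] objects
#'   (e.g. overall and sub-type GWASs).
#' @param ld optional LD r-squared matrix for proxy substitution.
#' @param settings estimator/PRESSO settings; missing entries take the
#'   defaults (`effects_model = "random"`, `n_boot = 1000`,
#'   `presso_nsim = 1000`, `presso_alpha = 0.05`, `alpha = 0.05`,
#'   `r2_proxy = 0.8`, `palindrome_window = c(0.42, 0.58)`).
#' @param seed integer master seed; every cell derives its own stream
#'   from it, so a plan rerun is deterministic.
#' @return list of class `"analysisPlan"`.
#' @export
analysisPlan <- function(exposures, outcomes, ld = NULL, settings = list(),
                         seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L)
  if (is.null(names(exposures)))
    names(exposures) <- vapply(exposures, exposureName, character(1))
  if (is.null(names(outcomes)))
    names(outcomes) <- vapply(outcomes, exposureName, character(1))
  s <- utils::modifyList(.defaultSettings(), settings)
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 settings = s, seed = as.integer(seed)),
            class = "analysisPlan")
}

#' Load an analysis plan from a YAML config
#'
#' The config mirrors [analysisPlan()]: `exposures` and `outcomes` are
#' lists of `{name, path}` entries (TSV summary statistics, see
#' [readSummaryStats()]), `ld` an optional LD-matrix path, `settings` a
#' mapping, `seed` an integer.
#'
#' @param path YAML file path.
#' @return an `"analysisPlan"`.
#' @export
loadPlan <- function(path) {
  cfg <- yaml::read_yaml(path)
  readSide <- function(entries) {
    panels <- lapply(entries, function(e)
      readSummaryStats(e$path, exposureName = e$name))
    names(panels) <- vapply(entries, `[[`, character(1), "name")
    panels
  }
  analysisPlan(readSide(cfg$exposures), readSide(cfg$outcomes),
               ld = if (!is.null(cfg$ld)) readLDMatrix(cfg$ld),
               settings = if (is.null(cfg$settings)) list() else cfg$settings,
               seed = cfg$seed)
}

.runCell <- function(exposure, outcome, ld, s, cellSeed) {
  harm <- harmonizePanels(exposure, outcome, ld = ld,
                          r2_proxy = s$r2_proxy,
                          palindrome_window = s$palindrome_window)
  d <- harm@data
  J <- nrow(d)
  actions <- table(factor(d$action, levels = c("direct", "sign_flipped",
                                               "strand_flipped",
                                               "proxy_substituted")))
  ledger <- list(kept = J, dropped = nrow(harm@dropped),
                 proxied = unname(actions["proxy_substituted"]),
                 actions = as.list(actions),
                 drop_reasons = harm@dropped)
  if (J < 2L)
    return(list(harmonization = ledger,
                error = "fewer than 2 instruments after harmonization"))

  ivw_fixed  <- mrIVW(d, model = "fixed")
  ivw_random <- mrIVW(d, model = "random")
  fits <- list(ivw_fixed = ivw_fixed$estimate,
               ivw_random = ivw_random$estimate)
  egger <- tryCatch(mrEgger(d, model = s$effects_model),
                    error = function(e) conditionMessage(e))
  wm <- tryCatch(weightedMedian(d, n_boot = s$n_boot, seed = cellSeed),
                 error = function(e) conditionMessage(e))
  loo <- tryCatch(leaveOneOut(d, model = s$effects_model),
                  error = function(e) conditionMessage(e))
  presso <- tryCatch(mrPresso(d, n_sim = s$presso_nsim, seed = cellSeed,
                              alpha = s$presso_alpha),
                     error = function(e) conditionMessage(e))
  if (is(egger, "list")) fits$egger_slope <- egger$estimate
  if (is(wm, "MREstimate")) fits$weighted_median <- wm

  post <- NULL
  if (is(presso, "PressoResult") && length(presso@outliers) &&
      J - length(presso@outliers) >= 2L) {
    kept <- d[!(d$rsid %in% presso@outliers), , drop = FALSE]
    post <- mrIVW(kept, model = "random")$estimate
    post@method <- "ivw_random_no_outliers"
    fits$ivw_random_no_outliers <- post
  }

  qp <- ivw_random$diagnostics@qPvalue
  headline <- if (is.finite(qp) && qp < 0.05) "ivw_random" else "ivw_fixed"
  ## reporting diagnostics: IVW Cochran's Q plus the Egger intercept/I2GX
  diagnostics <- ivw_random$diagnostics
  if (is(egger, "list")) {
    dg <- egger$diagnostics
    diagnostics@eggerIntercept        <- dg@eggerIntercept
    diagnostics@eggerInterceptSE      <- dg@eggerInterceptSE
    diagnostics@eggerInterceptCILower <- dg@eggerInterceptCILower
    diagnostics@eggerInterceptCIUpper <- dg@eggerInterceptCIUpper
    diagnostics@eggerInterceptP       <- dg@eggerInterceptP
    diagnostics@i2GX                  <- dg@i2GX
    diagnostics@nomeReliable          <- dg@nomeReliable
  }
  list(harmonization = ledger, harmonized = harm, fits = fits,
       diagnostics = diagnostics,
       ivw_q = list(q = ivw_random$diagnostics@qStatistic,
                    df = ivw_random$diagnostics@qDf, p = qp),
       egger_error = if (is.character(egger)) egger,
       egger_unreliable = if (is(egger, "list"))
         !isTRUE(egger$diagnostics@nomeReliable) else NA,
       weighted_median_error = if (is.character(wm)) wm,
       leave_one_out = if (is.list(loo)) loo else NULL,
       leave_one_out_error = if (is.character(loo)) loo,
       presso = if (is(presso, "PressoResult")) presso else NULL,
       presso_error = if (is.character(presso)) presso,
       headline = headline)
}

#' Run an analysis plan
#'
#' Executes every exposure x outcome cell of the plan, tolerating
#' per-cell failures, and assembles the report: harmonization ledger,
#' the estimate set (IVW fixed and random, Egger slope, weighted median,
#' post-outlier-removal IVW), pleiotropy diagnostics, MR-PRESSO,
#' leave-one-out, plot-ready tables and the headline-model flag per
#' cell, plus the forest table ordered exposures-major.  Deterministic
#' for a fixed plan seed.
#'
#' @param plan an [analysisPlan()].
#' @return list of class `"mrReport"` with elements `cells` (named
#'   `exposure|outcome`), `forest` (`data.frame`), `settings`, `seed`.
#' @export
runPlan <- function(plan) {
  stopifnot(inherits(plan, "analysisPlan"))
  s <- plan$settings
  cells <- list()
  forest <- list()
  for (i in seq_along(plan$exposures)) {
    for (j in seq_along(plan$outcomes)) {
      en <- names(plan$exposures)[i]
      on <- names(plan$outcomes)[j]
      key <- paste(en, on, sep = "|")
      cellSeed <- plan$seed + 1000L * i + j
      cell <- tryCatch(
        .runCell(plan$exposures[[i]], plan$outcomes[[j]], plan$ld, s,
                 cellSeed),
        error = function(e) list(error = conditionMessage(e)))
      cell$exposure <- en
      cell$outcome <- on
      cell$seed <- cellSeed
      if (!is.null(cell$fits)) {
        ft <- resultsTable(en, on, cell$fits, cell$diagnostics)
        ft$headline <- ft$method == cell$headline
        ft$egger_unreliable <- ifelse(ft$method == "egger_slope",
                                      cell$egger_unreliable, NA)
        forest[[key]] <- ft
        cell$plot_data <- funnelScatterData(cell$harmonized, cell$fits,
                                            cell$diagnostics)
      }
      cells[[key]] <- cell
    }
  }
  forest <- if (length(forest)) do.call(rbind, forest) else NULL
  if (!is.null(forest)) rownames(forest) <- NULL
  structure(list(cells = cells, forest = forest, settings = s,
                 seed = plan$seed,
                 significance = "two-sided p < 0.05, no multiple-testing correction across cells"),
            class = "mrReport")
}

.estimateAsList <- function(f) {
  if (is.null(f)) return(NULL)
  list(method = f@method, theta = f@theta, se = f@se, ci_low = f@ciLower,
       ci_high = f@ciUpper, p = f@pvalue, or = f@oddsRatio,
       or_ci_low = f@orCILower, or_ci_high = f@orCIUpper,
       n_variants = f@nVariants)
}

.diagAsList <- function(dg) {
  if (is.null(dg)) return(NULL)
  list(q = dg@qStatistic, q_df = dg@qDf, q_p = dg@qPvalue,
       egger_intercept = dg@eggerIntercept,
       egger_intercept_se = dg@eggerInterceptSE,
       egger_intercept_ci = c(dg@eggerInterceptCILower,
                              dg@eggerInterceptCIUpper),
       egger_intercept_p = dg@eggerInterceptP,
       i2_gx = dg@i2GX, nome_reliable = dg@nomeReliable)
}

.pressoAsList <- function(p) {
  if (is.null(p)) return(NULL)
  list(rss_observed = p@rssObserved, p_global = p@pGlobal,
       outliers = as.list(p@outliers),
       per_variant_p = as.list(p@perVariantP),
       theta_all = .estimateAsList(p@thetaAll),
       theta_no_outliers = .estimateAsList(p@thetaNoOutliers),
       distortion_coefficient = p@distortionCoefficient,
       p_distortion = p@pDistortion, n_sim = p@nSim, seed = p@seed)
}

#' Serialize a report to JSON and TSV
#'
#' Writes `<stem>.json` (structured diagnostics report; byte-identical
#' across reruns with the same plan seed) and `<stem>.tsv` (the forest
#' table).
#'
#' @param report an `"mrReport"` from [runPlan()].
#' @param stem output path without extension.
#' @return character vector of the two paths, invisibly.
#' @export
writeReport <- function(report, stem) {
  cellsOut <- lapply(report$cells, function(cell) {
    list(exposure = cell$exposure, outcome = cell$outcome,
         seed = cell$seed, error = cell$error,
         harmonization = if (!is.null(cell$harmonization))
           list(kept = cell$harmonization$kept,
                dropped = cell$harmonization$dropped,
                actions = cell$harmonization$actions,
                drop_reasons = cell$harmonization$drop_reasons),
         estimates = if (!is.null(cell$fits))
           lapply(cell$fits, .estimateAsList),
         diagnostics = .diagAsList(cell$diagnostics),
         egger_unreliable = cell$egger_unreliable,
         leave_one_out = if (!is.null(cell$leave_one_out))
           list(results = cell$leave_one_out$results,
                most_influential = cell$leave_one_out$mostInfluential),
         presso = .pressoAsList(cell$presso),
         headline = cell$headline)
  })
  out <- list(package = "shapeMR",
              seed = report$seed, settings = report$settings,
              significance = report$significance, cells = cellsOut)
  json <- paste0(stem, ".json")
  jsonlite::write_json(out, json, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  tsv <- paste0(stem, ".tsv")
  if (!is.null(report$forest)) writeResultsTable(report$forest, tsv)
  invisible(c(json, tsv))
}

#' STROBE-MR style reporting checklist
#'
#' Summarizes, one markdown line per reporting domain, what the report
#' covers: instrument counts per analysis (matching the harmonization
#' ledger), how each MR assumption is addressed, and the inventory of
#' sensitivity analyses; domains whose analysis did not run are marked
#' "not run".
#'
#' @param report an `"mrReport"`.
#' @return character vector of markdown lines.
#' @export
strobeChecklist <- function(report) {
  lines <- c("# Reporting checklist",
             paste0("- Design: two-sample summary-data MR; ",
                    length(report$cells), " exposure-outcome analyses."),
             paste0("- Significance convention: ", report$significance, "."))
  for (key in names(report$cells)) {
    cell <- report$cells[[key]]
    if (!is.null(cell$error) && is.null(cell$harmonization)) {
      lines <- c(lines, paste0("- [", key, "] analysis not run: ",
                               cell$error))
      next
    }
    h <- cell$harmonization
    lines <- c(lines, paste0(
      "- [", key, "] instruments: ", h$kept, " kept, ", h$dropped,
      " dropped, ", ifelse(is.na(h$proxied), 0, h$proxied), " proxied."))
    lines <- c(lines, paste0(
      "  - Sensitivity analyses: heterogeneity (Cochran's Q) ",
      if (!is.null(cell$ivw_q)) sprintf("p=%.3g", cell$ivw_q$p) else "not run",
      "; MR-Egger ",
      if (!is.null(cell$fits$egger_slope))
        paste0("run", if (isTRUE(cell$egger_unreliable))
          " (unreliable, I2GX<0.90)" else "")
      else "not run",
      "; weighted median ",
      if (!is.null(cell$fits$weighted_median)) "run" else "not run",
      "; MR-PRESSO ",
      if (!is.null(cell$presso))
        paste0("run (", length(cell$presso@outliers), " outlier(s))")
      else "not run",
      "; leave-one-out ",
      if (!is.null(cell$leave_one_out)) "run" else "not run", "."))
  }
  lines
}
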