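## Reading and writing GWAS summary statistics and results tables.
## Files are tab-separated with a header row; gzip-compressed files are
## read transparently.  Column headers differ across consortia, so the
## reader resolves them through a dialect (column-synonym) mapping.

#' Default column-name dialect for summary-statistic files
#'
#' GWAS consortia do not share column headers (GIANT-style files say
#' `b`/`SE`/`Freq`, BCAC-style files say `beta`/`stderr`/`eaf`), so the
#' reader maps each canonical field to a list of case-insensitive
#' synonyms.  Extend or override entries to load a new dialect without
#' editing the file itself.
#'
#' @return named list mapping canonical field names to synonym vectors.
#' @examples
#' d <- defaultDialect()
#' d$beta <- c(d$beta, "log_odds")
#' @export
defaultDialect <- function() {
  list(
    rsid          = c("rsid", "snp", "markername", "variant_id", "rs_id", "id"),
    chrom         = c("chrom", "chr", "chromosome"),
    pos           = c("pos", "bp", "position", "base_pair_location"),
    effect_allele = c("effect_allele", "ea", "a1", "allele1", "alt",
                      "tested_allele"),
    other_allele  = c("other_allele", "oa", "a2", "allele2", "ref", "nea",
                      "reference_allele"),
    eaf           = c("eaf", "freq", "effect_allele_frequency", "af", "maf",
                      "freq1"),
    beta          = c("beta", "b", "effect", "log_or"),
    se            = c("se", "stderr", "standard_error", "sebeta"),
    pval          = c("pval", "p", "p_value", "pvalue", "p.value"),
    n             = c("n", "samplesize", "sample_size", "neff")
  )
}

.resolveColumns <- function(header, dialect) {
  lower <- tolower(header)
  out <- vapply(names(dialect), function(field) {
    hit <- which(lower %in% tolower(dialect[[field]]))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  out
}

#' Read a summary-statistics file into a validated panel
#'
#' Reads a tab-separated file (gzip accepted), resolves columns through
#' the dialect, uppercases alleles, and validates every row.  Rows that
#' violate an invariant (non-positive or non-numeric `se`, non-numeric
#' `beta`, identical alleles, empty rsid, `eaf` outside `[0,1]`, `pval`
#' outside `(0,1]`) are rejected with a per-row reason recorded in the
#' panel's rejection log; kept rows plus rejected rows always account for
#' every data row of the file.  A duplicated rsid among the kept rows is
#' an error (it indicates a malformed panel, not a bad row).
#'
#' @param path path to a TSV (optionally `.gz`) file with a header row.
#' @param dialect column-synonym mapping, see [defaultDialect()].
#' @param exposureName trait label for the panel.
#' @param genomeBuild genome build label.
#' @return an [MRPanel-class]; the rejection log is available via
#'   [dropLog()].
#' @export
readSummaryStats <- function(path, dialect = defaultDialect(),
                             exposureName = "exposure",
                             genomeBuild = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  idx <- .resolveColumns(names(raw), dialect)
  mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
  miss <- mandatory[is.na(idx[mandatory])]
  if (length(miss))
    stop("configuration error: mandatory column(s) not resolvable via ",
         "dialect: ", paste(miss, collapse = ", "))

  n <- nrow(raw)
  get <- function(field, default) {
    if (is.na(idx[[field]])) rep(default, n) else raw[[idx[[field]]]]
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  d <- data.frame(
    rsid          = trimws(get("rsid", NA_character_)),
    chrom         = get("chrom", NA_character_),
    pos           = num(get("pos", NA_character_)),
    effect_allele = toupper(trimws(get("effect_allele", NA_character_))),
    other_allele  = toupper(trimws(get("other_allele", NA_character_))),
    eaf           = num(get("eaf", NA_character_)),
    beta          = num(get("beta", NA_character_)),
    se            = num(get("se", NA_character_)),
    pval          = num(get("pval", NA_character_)),
    n             = num(get("n", NA_character_)),
    stringsAsFactors = FALSE
  )

  reason <- rep(NA_character_, n)
  flag <- function(cond, why) {
    hit <- cond & is.na(reason)
    reason[hit] <<- why
  }
  flag(is.na(d$rsid) | !nzchar(d$rsid), "empty rsid")
  flag(is.na(d$beta), "non-numeric beta")
  flag(is.na(d$se), "non-numeric se")
  flag(!is.na(d$se) & d$se <= 0, "non-positive se")
  flag(is.na(d$effect_allele) | is.na(d$other_allele) |
         !nzchar(d$effect_allele) | !nzchar(d$other_allele), "missing allele")
  flag(d$effect_allele == d$other_allele, "identical alleles")
  flag(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf outside [0,1]")
  flag(!is.na(d$pval) & (d$pval <= 0 | d$pval > 1), "pval outside (0,1]")

  bad <- !is.na(reason)
  rejected <- data.frame(row = which(bad), rsid = d$rsid[bad],
                         reason = reason[bad], stringsAsFactors = FALSE)
  kept <- d[!bad, , drop = FALSE]
  if (anyDuplicated(kept$rsid))
    stop("validation error: duplicate rsid: ",
         paste(unique(kept$rsid[duplicated(kept$rsid)]), collapse = ", "))
  MRPanel(kept, exposureName = exposureName, genomeBuild = genomeBuild,
          rejected = rejected)
}

#' Write a panel back to a tab-separated file
#'
#' Inverse of [readSummaryStats()]: `readSummaryStats(writeSummaryStats(p))`
#' reproduces `p` field-for-field (numeric fields at full double
#' precision).
#'
#' @param panel an [MRPanel-class].
#' @param path output path; a `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
writeSummaryStats <- function(panel, path) {
  stopifnot(is(panel, "MRPanel"))
  d <- panel@data
  num <- c("pos", "eaf", "beta", "se", "pval", "n")
  for (col in num) d[[col]] <- format(d[[col]], digits = 17, trim = TRUE)
  d[d == "NA"] <- NA
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Write an analysis results table
#'
#' One row per exposure x outcome x method, with the odds ratio per 1 SD,
#' its 95% CI, p-value, instrument count, Cochran-Q p-value and Egger
#' intercept p-value.  Numeric fields are written with enough digits to
#' round-trip at 6 significant digits.
#'
#' @param results `data.frame` as assembled by [resultsTable()] or
#'   [runPlan()], or a list of such frames (rbound).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeResultsTable <- function(results, path) {
  if (is.list(results) && !is.data.frame(results))
    results <- do.call(rbind, results)
  if (is.null(results) || !is.data.frame(results) || nrow(results) == 0L)
    stop("results must be non-empty")
  d <- results
  for (col in names(d))
    if (is.numeric(d[[col]]))
      d[[col]] <- format(signif(d[[col]], 10), digits = 10, trim = TRUE)
  ok <- tryCatch({
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Flatten one analysis cell into results-table rows
#'
#' @param exposure,outcome labels for the analysis cell.
#' @param fits named list of [MREstimate-class] objects.
#' @param diagnostics optional [PleiotropyDiagnostics-class] whose Q and
#'   Egger-intercept p-values are attached to every row.
#' @return `data.frame` with one row per estimate.
#' @export
resultsTable <- function(exposure, outcome, fits, diagnostics = NULL) {
  stopifnot(length(fits) >= 1L)
  qp <- if (is.null(diagnostics)) NA_real_ else diagnostics@qPvalue
  ip <- if (is.null(diagnostics)) NA_real_ else diagnostics@eggerInterceptP
  do.call(rbind, lapply(fits, function(f) {
    data.frame(exposure = exposure, outcome = outcome, method = f@method,
               n_variants = f@nVariants, or = f@oddsRatio,
               or_ci_low = f@orCILower, or_ci_high = f@orCIUpper,
               p = f@pvalue, q_pvalue = qp, egger_intercept_p = ip,
               stringsAsFactors = FALSE)
  }))
}

#' Read an LD matrix from a TSV file
#'
#' Accepts either long format (columns `rsid_a`, `rsid_b`, `r2`; missing
#' pairs default to 0, the diagonal to 1) or a square matrix with rsid
#' header and first column.
#'
#' @param path TSV path (gzip accepted).
#' @return symmetric numeric matrix of squared correlations with unit
#'   diagonal and rsid dimnames.
#' @export
readLDMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (all(c("rsid_a", "rsid_b", "r2") %in% tolower(first))) {
    long <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(long) <- tolower(names(long))
    ids <- sort(unique(c(long$rsid_a, long$rsid_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(long))) {
      m[long$rsid_a[i], long$rsid_b[i]] <- long$r2[i]
      m[long$rsid_b[i], long$rsid_a[i]] <- long$r2[i]
    }
    diag(m) <- 1
  } else {
    sq <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(sq)
    dimnames(m) <- list(rownames(sq), colnames(sq))
  }
  validateLDMatrix(m)
  m
}

#' Validate an LD r-squared matrix
#'
#' Checks symmetry, unit diagonal, values in `[0,1]` and rsid dimnames.
#'
#' @param m numeric matrix.
#' @return `TRUE`, invisibly; stops on violation.
#' @export
validateLDMatrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("LD matrix must be numeric")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    stop("LD matrix needs identical rsid row/col names")
  if (any(abs(m - t(m)) > 1e-8)) stop("LD matrix not symmetric")
  if (any(abs(diag(m) - 1) > 1e-8)) stop("LD matrix diagonal must be 1")
  if (any(m < -1e-12 | m > 1 + 1e-12)) stop("LD r2 values outside [0,1]")
  invisible(TRUE)
}

#' Write a JSON run-metadata sidecar
#'
#' Records inputs, settings, seed and package version next to a results
#' file so a run can be reproduced.
#'
#' @param path output JSON path.
#' @param inputs,settings lists describing the run.
#' @param seed integer seed used.
#' @return `path`, invisibly.
#' @export
writeRunMetadata <- function(path, inputs = list(), settings = list(),
                             seed = NA_integer_) {
  meta <- list(package = "shapeMR",
               version = as.character(utils::packageVersion("shapeMR")),
               seed = seed, inputs = inputs, settings = settings)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
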