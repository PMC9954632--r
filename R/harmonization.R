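## Allele harmonization, LD pruning and proxy lookup.
##
## Exposure and outcome GWAS may code the same variant on different
## alleles or strands.  Harmonization re-expresses every outcome
## association on the exposure's effect allele: a swapped coding flips
## the sign of the outcome beta and complements its frequency; a strand
## difference complements the allele labels.  Palindromic variants (A/T,
## C/G) cannot be resolved from labels alone and are aligned by effect
## allele frequency or dropped when the frequency is uninformative.

.BASES <- c(A = "T", C = "G", G = "C", T = "A")

.complementAllele <- function(a) {
  ifelse(nchar(a) == 1L & a %in% names(.BASES), unname(.BASES[a]),
         NA_character_)
}

.isPalindromic <- function(ea, oa) {
  !is.na(.complementAllele(ea)) & !is.na(.complementAllele(oa)) &
    .complementAllele(ea) == oa
}

.dropDecision <- function(rsid, reason) {
  list(kept = FALSE, rsid = rsid, reason = reason)
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome association onto the exposure's effect allele.
#' Swapped allele coding flips the outcome beta's sign and complements
#' its frequency; alleles matching only under strand complement are
#' complemented first.  Palindromic variants are dropped as
#' `"ambiguous palindrome"` when either frequency is missing or falls
#' inside `palindrome_window`; otherwise they are aligned so that both
#' studies agree on which allele is the minor one.  Incompatible allele
#' sets yield a typed drop decision; no errors are raised.
#'
#' @param exposure,outcome single-variant records (one-row `data.frame`
#'   or list) with fields `rsid`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, and optional `eaf`; both must refer to the same rsid.
#' @param palindrome_window numeric length-2, the effect-allele-frequency
#'   interval around 0.5 inside which a palindromic variant is considered
#'   ambiguous (default `c(0.42, 0.58)`); `c(0, 1)` drops all palindromes.
#' @return a list: either `kept = TRUE` with a one-row harmonized record
#'   (`rsid`, alleles, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, `action`, `proxy_rsid`)
#'   or `kept = FALSE` with a `reason`.
#' @examples
#' e <- list(rsid = "rs1", effect_allele = "A", other_allele = "G",
#'           beta = 0.10, se = 0.01, eaf = 0.3)
#' o <- list(rsid = "rs1", effect_allele = "G", other_allele = "A",
#'           beta = 0.05, se = 0.02, eaf = 0.7)
#' harmonizePair(e, o)$row$beta_outcome  # -0.05, sign flipped
#' @export
harmonizePair <- function(exposure, outcome,
                          palindrome_window = c(0.42, 0.58)) {
  exposure <- as.list(exposure); outcome <- as.list(outcome)
  if (!identical(as.character(exposure$rsid), as.character(outcome$rsid)))
    stop("exposure and outcome records must share the same rsid")
  rsid <- as.character(exposure$rsid)
  eEA <- toupper(exposure$effect_allele); eOA <- toupper(exposure$other_allele)
  oEA <- toupper(outcome$effect_allele);  oOA <- toupper(outcome$other_allele)
  eafE <- if (is.null(exposure$eaf)) NA_real_ else as.numeric(exposure$eaf)
  eafO <- if (is.null(outcome$eaf))  NA_real_ else as.numeric(outcome$eaf)
  betaO <- as.numeric(outcome$beta)

  finish <- function(betaO, eafO, action) {
    list(kept = TRUE, row = data.frame(
      rsid = rsid, effect_allele = eEA, other_allele = eOA,
      beta_exposure = as.numeric(exposure$beta),
      se_exposure = as.numeric(exposure$se),
      beta_outcome = betaO, se_outcome = as.numeric(outcome$se),
      eaf_exposure = eafE, eaf_outcome = eafO,
      action = action, proxy_rsid = NA_character_,
      stringsAsFactors = FALSE))
  }

  if (.isPalindromic(eEA, eOA)) {
    if (!setequal(c(oEA, oOA), c(eEA, eOA)))
      return(.dropDecision(rsid, "incompatible alleles"))
    ## naive label alignment first, then frequency arbitration
    flip <- oEA == eOA
    if (flip) { betaO <- -betaO; eafO <- 1 - eafO }
    ambiguous <- function(f) is.na(f) ||
      (f >= palindrome_window[1] && f <= palindrome_window[2])
    if (ambiguous(eafE) || ambiguous(eafO))
      return(.dropDecision(rsid, "ambiguous palindrome"))
    if ((eafE < 0.5) != (eafO < 0.5)) {
      betaO <- -betaO; eafO <- 1 - eafO; flip <- !flip
    }
    return(finish(betaO, eafO, if (flip) "sign_flipped" else "direct"))
  }

  cEA <- .complementAllele(oEA); cOA <- .complementAllele(oOA)
  if (oEA == eEA && oOA == eOA) {
    finish(betaO, eafO, "direct")
  } else if (oEA == eOA && oOA == eEA) {
    finish(-betaO, 1 - eafO, "sign_flipped")
  } else if (!is.na(cEA) && !is.na(cOA) && cEA == eEA && cOA == eOA) {
    finish(betaO, eafO, "strand_flipped")
  } else if (!is.na(cEA) && !is.na(cOA) && cEA == eOA && cOA == eEA) {
    finish(-betaO, 1 - eafO, "sign_flipped")
  } else {
    .dropDecision(rsid, "incompatible alleles")
  }
}

#' Harmonize an exposure panel against an outcome panel
#'
#' Applies [harmonizePair()] to every exposure instrument.  Instruments
#' absent from the outcome panel are recovered through a proxy in high LD
#' (`r2 >= r2_proxy`) when an LD matrix is supplied; the proxy's outcome
#' beta and standard error are adopted unchanged while the exposure
#' association stays that of the original instrument.  Instruments with
#' no outcome data and no proxy are dropped and logged.
#'
#' @param exposure,outcome [MRPanel-class] objects.
#' @param ld optional LD r-squared matrix (see [readLDMatrix()]).
#' @param r2_proxy minimum r-squared for proxy substitution (default 0.8).
#' @param palindrome_window see [harmonizePair()].
#' @return an [MRHarmonized-class]; `dropLog()` lists every excluded
#'   variant with its reason.
#' @export
harmonizePanels <- function(exposure, outcome, ld = NULL, r2_proxy = 0.8,
                            palindrome_window = c(0.42, 0.58)) {
  stopifnot(is(exposure, "MRPanel"), is(outcome, "MRPanel"))
  ed <- exposure@data
  od <- outcome@data
  rows <- vector("list", nrow(ed))
  drops <- list()
  for (i in seq_len(nrow(ed))) {
    e <- ed[i, ]
    j <- match(e$rsid, od$rsid)
    if (is.na(j)) {
      prox <- if (is.null(ld) || !(e$rsid %in% rownames(ld))) NULL
              else findProxy(e$rsid, ld, outcome, r2_min = r2_proxy)
      if (is.null(prox)) {
        drops[[length(drops) + 1L]] <-
          data.frame(rsid = e$rsid, reason = "no outcome data",
                     stringsAsFactors = FALSE)
      } else {
        rows[[i]] <- data.frame(
          rsid = e$rsid, effect_allele = e$effect_allele,
          other_allele = e$other_allele,
          beta_exposure = e$beta, se_exposure = e$se,
          beta_outcome = prox$beta, se_outcome = prox$se,
          eaf_exposure = e$eaf, eaf_outcome = prox$eaf,
          action = "proxy_substituted", proxy_rsid = prox$rsid,
          stringsAsFactors = FALSE)
      }
    } else {
      o <- od[j, ]
      res <- harmonizePair(e, o, palindrome_window = palindrome_window)
      if (res$kept) rows[[i]] <- res$row
      else drops[[length(drops) + 1L]] <-
        data.frame(rsid = res$rsid, reason = res$reason,
                   stringsAsFactors = FALSE)
    }
  }
  kept <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(kept))
    kept <- data.frame(rsid = character(), effect_allele = character(),
                       other_allele = character(), beta_exposure = numeric(),
                       se_exposure = numeric(), beta_outcome = numeric(),
                       se_outcome = numeric(), eaf_exposure = numeric(),
                       eaf_outcome = numeric(), action = character(),
                       proxy_rsid = character(), stringsAsFactors = FALSE)
  dropped <- if (length(drops)) do.call(rbind, drops)
             else data.frame(rsid = character(), reason = character(),
                             stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  new("MRHarmonized", exposureName = exposure@exposureName,
      outcomeName = outcome@exposureName, data = kept, dropped = dropped)
}

#' Greedy LD pruning of an instrument panel
#'
#' Variants are visited in ascending exposure p-value order (ties broken
#' by rsid); each is kept iff its r-squared with every already-kept
#' variant is at most `r2_max`.  This reproduces standard clumping
#' behaviour and is deterministic and invariant to input row order.
#'
#' @param panel an [MRPanel-class].
#' @param ld LD r-squared matrix covering every panel rsid.
#' @param r2_max pruning threshold in (0,1), default 0.01.
#' @return the pruned [MRPanel-class], rows in kept (p-value) order, with
#'   attribute `"removed"` holding the excluded rsids.
#' @export
ldPrune <- function(panel, ld, r2_max = 0.01) {
  stopifnot(is(panel, "MRPanel"), r2_max > 0, r2_max < 1)
  validateLDMatrix(ld)
  d <- panel@data
  missing <- setdiff(d$rsid, rownames(ld))
  if (length(missing))
    stop("rsid absent from LD matrix: ", paste(missing, collapse = ", "))
  ord <- order(d$pval, d$rsid, na.last = TRUE)
  d <- d[ord, , drop = FALSE]
  kept <- character()
  for (r in d$rsid) {
    if (!length(kept) || all(ld[r, kept] <= r2_max)) kept <- c(kept, r)
  }
  out <- d[match(kept, d$rsid), , drop = FALSE]
  rownames(out) <- NULL
  pruned <- MRPanel(out, exposureName = panel@exposureName,
                    genomeBuild = panel@genomeBuild)
  attr(pruned, "removed") <- setdiff(d$rsid, kept)
  pruned
}

#' Find a proxy variant in the outcome panel
#'
#' Returns the outcome-panel variant with maximal r-squared to `rsid`
#' among candidates with `r2 >= r2_min`; ties are broken by smaller
#' outcome p-value, then lexicographic rsid.
#'
#' @param rsid the missing instrument's identifier (must be in `ld`).
#' @param ld LD r-squared matrix.
#' @param outcomePanel [MRPanel-class] of outcome associations.
#' @param r2_min minimum r-squared in (0,1], default 0.8.
#' @return a one-row `data.frame` (the proxy's outcome record), or
#'   `NULL` when no candidate reaches `r2_min`.
#' @export
findProxy <- function(rsid, ld, outcomePanel, r2_min = 0.8) {
  stopifnot(r2_min > 0, r2_min <= 1)
  validateLDMatrix(ld)
  if (!(rsid %in% rownames(ld)))
    stop("rsid absent from LD matrix: ", rsid)
  od <- outcomePanel@data
  cand <- od[od$rsid %in% rownames(ld) & od$rsid != rsid, , drop = FALSE]
  if (!nrow(cand)) return(NULL)
  r2 <- ld[rsid, cand$rsid]
  cand <- cand[r2 >= r2_min, , drop = FALSE]
  r2 <- r2[r2 >= r2_min]
  if (!nrow(cand)) return(NULL)
  ord <- order(-r2, cand$pval, cand$rsid, na.last = TRUE)
  cand[ord[1], , drop = FALSE]
}
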