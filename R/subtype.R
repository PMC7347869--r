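#' Pentaplex microsatellite-instability classification
#'
#' Applies the Bethesda rule to the five-locus pentaplex panel (BAT-26,
#' BAT-25, D5S346, D17S250, D2S123). A sample is MSI-H when at least two of
#' the five markers display additional alleles relative to the matched
#' normal, MSI-L when exactly one does, and MSS when none does. For the
#' binary classification used throughout the subtype trees, only MSI-H is
#' "MSI"; MSI-L and MSS samples are "MSS".
#'
#' @param markerCalls named character vector over the five loci with values
#'   \code{identical}, \code{additional_alleles} or \code{missing}.
#' @return list with \code{status} (\code{MSI_H}, \code{MSI_L} or
#'   \code{MSS}), \code{binary} (\code{MSI} or \code{MSS}) and
#'   \code{nUnstable}, the count of loci with additional alleles.
#' @examples
#' calls <- c("BAT-26" = "additional_alleles", "BAT-25" = "additional_alleles",
#'            "D5S346" = "identical", "D17S250" = "identical",
#'            "D2S123" = "identical")
#' classifyMsiPentaplex(calls)$binary  # "MSI"
#' @export
classifyMsiPentaplex <- function(markerCalls) {
  stopifnot(is.character(markerCalls))
  if (length(markerCalls) != 5L || !setequal(names(markerCalls), PENTAPLEX_LOCI))
    stop("markerCalls must cover exactly the 5 pentaplex loci")
  if (!all(markerCalls %in% MARKER_STATES))
    stop("marker calls must be identical|additional_alleles|missing")
  informative <- markerCalls != "missing"
  if (!any(informative))
    stop("all 5 markers missing: MSI status unclassifiable")
  n <- sum(markerCalls == "additional_alleles")
  status <- if (n >= 2) "MSI_H" else if (n == 1) "MSI_L" else "MSS"
  list(status = status,
       binary = if (status == "MSI_H") "MSI" else "MSS",
       nUnstable = n)
}

#' MSI surrogate call from MLH1 status
#'
#' Xenografts lack a matched normal for the pentaplex assay, so MSI status
#' is inferred from mismatch-repair deficiency evidence: a sample is MSI if
#' MLH1 chromatin staining is not homogeneous (loss of expression) or if
#' MLH1 carries a mutation; otherwise MSS.
#'
#' @param ihcHomogeneous logical; \code{TRUE} when MLH1 staining is
#'   homogeneous. \code{NA} if IHC was not performed.
#' @param mlh1Mutated logical; \code{NA} if mutation status unknown.
#' @return \code{"MSI"} or \code{"MSS"}.
#' @export
msiFromMlh1 <- function(ihcHomogeneous = NA, mlh1Mutated = NA) {
  if (is.na(ihcHomogeneous) && is.na(mlh1Mutated))
    stop("no MLH1 evidence provided: MSI status unclassifiable")
  lost <- !is.na(ihcHomogeneous) && !ihcHomogeneous
  mut <- !is.na(mlh1Mutated) && mlh1Mutated
  if (lost || mut) "MSI" else "MSS"
}

#' EBV infection load from the EBNA1 qPCR assay
#'
#' The viral burden is computed from the EBNA1 cycle threshold, normalized
#' to the 40-cycle maximum: load = 2^(40 - Ct) / 1000 arbitrary units.
#' Samples with load above 1000 units carry an infection burden and are
#' classified as the EBV subtype.
#'
#' @param ctEbna1 EBNA1 Ct in cycles, in (0, 40]; assays with no
#'   amplification are recorded at the maximum Ct of 40.
#' @param threshold positivity threshold in arbitrary units (default 1000).
#' @return list with \code{load} (arbitrary units) and logical
#'   \code{positive}.
#' @examples
#' ebvLoad(19)$load      # 2^21/1000 = 2097.152, positive
#' ebvLoad(40)$positive  # FALSE
#' @export
ebvLoad <- function(ctEbna1, threshold = 1000) {
  if (!is.finite(ctEbna1) || ctEbna1 <= 0 || ctEbna1 > 40)
    stop("ctEbna1 must lie in (0, 40]")
  load <- 2^(40 - ctEbna1) / 1000
  list(load = load, positive = load > threshold)
}

#' Relative expression from paired cycle thresholds
#'
#' Expression of a gene of interest relative to the 18S ribosomal reference:
#' 2^(Ct_18s - Ct_gene), in arbitrary units. A missing gene Ct yields the
#' not-detected sentinel 0, which is excluded from cohort medians.
#'
#' @param ctGene gene Ct in cycles, or \code{NA} when not detected.
#' @param ct18s 18S reference Ct in cycles.
#' @return expression in arbitrary units (> 0), or 0 when not detected.
#' @export
relativeExpression <- function(ctGene, ct18s) {
  if (!is.finite(ct18s) || ct18s <= 0 || ct18s > 40)
    stop("ct18s must lie in (0, 40]")
  if (is.na(ctGene)) return(0)
  if (ctGene <= 0 || ctGene > 40) stop("ctGene must lie in (0, 40]")
  2^(ct18s - ctGene)
}

#' Build the cohort ScoreContext
#'
#' Computes the per-gene cohort medians that the TP53-activation and
#' proliferation scores normalize by. Not-detected sentinels (0) are
#' excluded; medians are taken over all supplied samples (tumors and PDX
#' pooled by default — restrict the input to change the population).
#'
#' @param exprs data.frame or matrix of expressions (arbitrary units) with
#'   columns CDKN1A, MDM2, TOP2A, MKI67, one row per sample.
#' @return a \linkS4class{ScoreContext}.
#' @export
scoreContext <- function(exprs) {
  exprs <- as.data.frame(exprs)
  need <- c("CDKN1A", "MDM2", "TOP2A", "MKI67")
  stopifnot(all(need %in% names(exprs)))
  if (nrow(exprs) < 2) stop("medians require >= 2 samples")
  med <- vapply(need, function(g) {
    x <- exprs[[g]]
    x <- x[is.finite(x) & x > 0]
    if (!length(x)) stop("no detected expression for ", g)
    median(x)
  }, numeric(1))
  new("ScoreContext", medians = med, n = nrow(exprs))
}

#' TP53 pathway activation score
#'
#' Sum of the median-normalized expressions of the two TP53 target genes:
#' CDKN1A_exp / median(CDKN1A_exp) + MDM2_exp / median(MDM2_exp).
#' Samples scoring strictly above 2.5 arbitrary units are TP53-activated.
#'
#' @param cdkn1aExp,mdm2Exp sample expressions in arbitrary units.
#' @param ctx a \linkS4class{ScoreContext}.
#' @param threshold activation cutoff (default 2.5, strict).
#' @return list with \code{score} and logical \code{activated}.
#' @export
tp53ActivationScore <- function(cdkn1aExp, mdm2Exp, ctx, threshold = 2.5) {
  stopifnot(is(ctx, "ScoreContext"))
  m <- ctx@medians
  score <- cdkn1aExp / m[["CDKN1A"]] + mdm2Exp / m[["MDM2"]]
  list(score = score, activated = score > threshold)
}

#' Proliferation score and subclass
#'
#' Sum of the median-normalized TOP2A and MKI67 expressions. Subclasses:
#' low below 1 arbitrary unit, intermediate in [1, 4], high above 4
#' (descriptive annotation; it does not enter the subtype assignment).
#'
#' @param top2aExp,mki67Exp sample expressions in arbitrary units.
#' @param ctx a \linkS4class{ScoreContext}.
#' @return list with \code{score} and \code{class} in
#'   \code{low}/\code{intermediate}/\code{high}.
#' @export
proliferationScore <- function(top2aExp, mki67Exp, ctx) {
  stopifnot(is(ctx, "ScoreContext"))
  m <- ctx@medians
  score <- top2aExp / m[["TOP2A"]] + mki67Exp / m[["MKI67"]]
  cls <- if (score < 1) "low" else if (score > 4) "high" else "intermediate"
  list(score = score, class = cls)
}

resolveMsi <- function(panel) {
  if (length(panel@msiMarkers) > 0)
    return(classifyMsiPentaplex(panel@msiMarkers)$binary)
  if (!is.na(panel@mlh1Homogeneous) || !is.na(panel@mlh1Mutated))
    return(msiFromMlh1(panel@mlh1Homogeneous, panel@mlh1Mutated))
  NA_character_
}

panelExpression <- function(panel, gene) {
  if (is.na(panel@ct18s)) return(NA_real_)
  ct <- panel@ct
  if (!gene %in% names(ct)) return(NA_real_)
  if (is.na(ct[[gene]])) return(NA_real_)
  relativeExpression(ct[[gene]], panel@ct18s)
}

#' ACRG-style subtype assignment
#'
#' Deterministic decision tree over one sample's panel: (1) MSI samples are
#' ACRG MSI; (2) MSS samples with CDH1 expression strictly below 40
#' arbitrary units are MSS/EMT; (3) remaining MSS samples are split by the
#' TP53 activation score into MSS/TP53+ (score > 2.5) and MSS/TP53-.
#' MSS samples lacking the RNA measurements required for steps 2-3 are
#' UNCLASSIFIED.
#'
#' @param panel a \linkS4class{SamplePanel}.
#' @param ctx a \linkS4class{ScoreContext} with cohort medians.
#' @param cdh1Cutoff EMT cutoff on CDH1 expression (default 40, strict <).
#' @return one of \code{MSI}, \code{MSS_EMT}, \code{MSS_TP53_POS},
#'   \code{MSS_TP53_NEG}, \code{UNCLASSIFIED}.
#' @export
classifyACRG <- function(panel, ctx, cdh1Cutoff = 40) {
  stopifnot(is(panel, "SamplePanel"))
  msi <- resolveMsi(panel)
  if (is.na(msi)) stop("MSI status unresolvable for ", panel@sampleId)
  if (msi == "MSI") return("MSI")
  cdh1 <- panelExpression(panel, "CDH1")
  if (is.na(cdh1)) return("UNCLASSIFIED")
  if (cdh1 < cdh1Cutoff) return("MSS_EMT")
  cdkn1a <- panelExpression(panel, "CDKN1A")
  mdm2 <- panelExpression(panel, "MDM2")
  if (is.na(cdkn1a) || is.na(mdm2)) return("UNCLASSIFIED")
  tp53 <- tp53ActivationScore(cdkn1a, mdm2, ctx)
  if (tp53$activated) "MSS_TP53_POS" else "MSS_TP53_NEG"
}

#' TCGA-style subtype assignment
#'
#' Deterministic tree with MSI taking precedence: MSI samples are MSI;
#' otherwise EBV if the viral load exceeds 1000 arbitrary units; otherwise
#' GS or CIN by the autosomal SCNA count (<= 15 is genomically stable,
#' > 15 chromosome-instable); MSS samples without a copy-number assay stay
#' MSS_UNRESOLVED.
#'
#' @param msi binary MSI status, \code{"MSI"} or \code{"MSS"}.
#' @param ebvLoadValue EBV load in arbitrary units.
#' @param scnaCount autosomal SCNA count, or \code{NA} when unavailable.
#' @param ebvThreshold EBV positivity cutoff (default 1000 units).
#' @param gsMax largest SCNA count still called GS (default 15).
#' @return one of \code{MSI}, \code{EBV}, \code{GS}, \code{CIN},
#'   \code{MSS_UNRESOLVED}.
#' @export
classifyTCGA <- function(msi, ebvLoadValue, scnaCount = NA,
                         ebvThreshold = 1000, gsMax = 15) {
  stopifnot(msi %in% c("MSI", "MSS"), is.finite(ebvLoadValue))
  if (msi == "MSI") return("MSI")
  if (ebvLoadValue > ebvThreshold) return("EBV")
  if (is.na(scnaCount)) return("MSS_UNRESOLVED")
  if (scnaCount <= gsMax) "GS" else "CIN"
}

#' Full subtype call for one sample
#'
#' Runs both decision trees and the descriptive scores on a sample panel,
#' returning every intermediate quantity.
#'
#' @param panel a \linkS4class{SamplePanel}.
#' @param ctx a \linkS4class{ScoreContext}.
#' @return one-row data.frame: sample_id, msi, ebv_load, tp53_score,
#'   proliferation_score, proliferation_class, acrg, tcga.
#' @export
subtypeSample <- function(panel, ctx) {
  msi <- resolveMsi(panel)
  ebv <- if (is.na(panel@ctEbna1)) list(load = 0, positive = FALSE)
         else ebvLoad(panel@ctEbna1)
  cdkn1a <- panelExpression(panel, "CDKN1A")
  mdm2 <- panelExpression(panel, "MDM2")
  tp53 <- if (!is.na(cdkn1a) && !is.na(mdm2))
    tp53ActivationScore(cdkn1a, mdm2, ctx) else list(score = NA_real_)
  top2a <- panelExpression(panel, "TOP2A")
  mki67 <- panelExpression(panel, "MKI67")
  prol <- if (!is.na(top2a) && !is.na(mki67))
    proliferationScore(top2a, mki67, ctx)
    else list(score = NA_real_, class = NA_character_)
  data.frame(
    sample_id = panel@sampleId,
    msi = msi,
    ebv_load = ebv$load,
    tp53_score = tp53$score,
    proliferation_score = prol$score,
    proliferation_class = prol$class,
    acrg = classifyACRG(panel, ctx),
    tcga = classifyTCGA(msi, ebv$load, panel@scna),
    stringsAsFactors = FALSE)
}

#' Subtype a list of sample panels
#'
#' Builds the score context from the panels' own expressions (pooled
#' cohort medians) unless one is supplied, then calls
#' \code{\link{subtypeSample}} on each panel.
#'
#' @param panels list of \linkS4class{SamplePanel} objects.
#' @param ctx optional \linkS4class{ScoreContext}; computed from the
#'   cohort when \code{NULL}.
#' @return data.frame of per-sample subtype calls and scores.
#' @export
subtypeCohort <- function(panels, ctx = NULL) {
  stopifnot(length(panels) >= 1)
  if (is.null(ctx)) {
    exprs <- do.call(rbind, lapply(panels, function(p) {
      data.frame(CDKN1A = panelExpression(p, "CDKN1A"),
                 MDM2 = panelExpression(p, "MDM2"),
                 TOP2A = panelExpression(p, "TOP2A"),
                 MKI67 = panelExpression(p, "MKI67"))
    }))
    ctx <- scoreContext(exprs)
  }
  out <- do.call(rbind, lapply(panels, subtypeSample, ctx = ctx))
  rownames(out) <- NULL
  out
}
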