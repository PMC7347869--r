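#' @import methods
#' @importFrom stats median setNames
NULL

PENTAPLEX_LOCI <- c("BAT-26", "BAT-25", "D5S346", "D17S250", "D2S123")
MARKER_STATES <- c("identical", "additional_alleles", "missing")
CT_GENES <- c("CDKN1A", "MDM2", "CDH1", "TOP2A", "MKI67", "MLH1")
ACRG_LEVELS <- c("MSI", "MSS_EMT", "MSS_TP53_POS", "MSS_TP53_NEG", "UNCLASSIFIED")
TCGA_LEVELS <- c("MSI", "EBV", "GS", "CIN", "MSS_UNRESOLVED")
IMPACT_LEVELS <- c("high", "moderate", "low", "modifier")
VARIANT_CLASSES <- c("SNV", "insertion", "deletion")
STAGE_LABELS <- c("P0", "P1", "P2", "P3", "PDX")

#' SamplePanel: one sample's subtyping inputs
#'
#' Bundles everything the deterministic subtype trees consume for a single
#' sample: qPCR cycle thresholds (Ct) for the reference 18S assay, the
#' EBNA1 viral-load assay and the signature genes, the five pentaplex
#' microsatellite marker calls, the MLH1 immunohistochemistry / mutation
#' surrogate used for xenografts, and (optionally) a somatic copy-number
#' alteration count for GS/CIN resolution.
#'
#' @slot sampleId single character identifier.
#' @slot role one of \code{"tumor"}, \code{"normal"}, \code{"PDX"},
#'   \code{"passage"}.
#' @slot ct named numeric vector of cycle thresholds in cycles; names from
#'   \code{CDKN1A, MDM2, CDH1, TOP2A, MKI67, MLH1}; \code{NA} = not measured.
#' @slot ct18s numeric, reference 18S Ct (cycles); required for any
#'   expression computation.
#' @slot ctEbna1 numeric, EBNA1 Ct in cycles; no amplification is recorded
#'   as 40, the maximum cycle number.
#' @slot msiMarkers named character vector over the five pentaplex loci with
#'   values \code{identical}, \code{additional_alleles} or \code{missing}.
#' @slot mlh1Homogeneous logical; \code{TRUE} if MLH1 staining is
#'   homogeneous (\code{NA} if no IHC available).
#' @slot mlh1Mutated logical; \code{NA} if unknown.
#' @slot scna numeric; autosomal SCNA count, \code{NA} when no copy-number
#'   assay is available.
#' @export
setClass("SamplePanel", representation(
  sampleId = "character",
  role = "character",
  ct = "numeric",
  ct18s = "numeric",
  ctEbna1 = "numeric",
  msiMarkers = "character",
  mlh1Homogeneous = "logical",
  mlh1Mutated = "logical",
  scna = "numeric"
))

setValidity("SamplePanel", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be length 1")
  if (!object@role %in% c("tumor", "normal", "PDX", "passage"))
    msg <- c(msg, "role must be tumor|normal|PDX|passage")
  ct <- object@ct
  if (!all(names(ct) %in% CT_GENES))
    msg <- c(msg, "ct names must be among the signature genes")
  bad <- ct[!is.na(ct)]
  if (any(bad <= 0 | bad > 40))
    msg <- c(msg, "present Ct values must lie in (0, 40]")
  if (!is.na(object@ct18s) && (object@ct18s <= 0 || object@ct18s > 40))
    msg <- c(msg, "ct18s must lie in (0, 40]")
  if (!is.na(object@ctEbna1) && (object@ctEbna1 <= 0 || object@ctEbna1 > 40))
    msg <- c(msg, "ctEbna1 must lie in (0, 40]")
  mk <- object@msiMarkers
  if (length(mk) > 0) {
    if (!setequal(names(mk), PENTAPLEX_LOCI))
      msg <- c(msg, "msiMarkers must cover exactly the 5 pentaplex loci")
    if (!all(mk %in% MARKER_STATES))
      msg <- c(msg, "marker calls must be identical|additional_alleles|missing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SamplePanel
#'
#' @param sampleId sample identifier.
#' @param role sample role (\code{tumor}, \code{normal}, \code{PDX},
#'   \code{passage}).
#' @param ct named numeric vector of gene Ct values (cycles).
#' @param ct18s 18S reference Ct (cycles).
#' @param ctEbna1 EBNA1 Ct (cycles); defaults to 40 (no amplification).
#' @param msiMarkers named character vector of pentaplex marker calls, or
#'   zero-length if the assay was not run.
#' @param mlh1Homogeneous,mlh1Mutated MLH1 surrogate evidence (logical,
#'   \code{NA} if absent).
#' @param scna autosomal SCNA count or \code{NA}.
#' @return a \linkS4class{SamplePanel}.
#' @examples
#' SamplePanel("T01", ct = c(CDKN1A = 10, MDM2 = 11), ct18s = 12)
#' @export
SamplePanel <- function(sampleId, role = "tumor", ct = numeric(),
                        ct18s = NA_real_, ctEbna1 = 40,
                        msiMarkers = character(),
                        mlh1Homogeneous = NA, mlh1Mutated = NA,
                        scna = NA_real_) {
  new("SamplePanel", sampleId = as.character(sampleId), role = role,
      ct = ct, ct18s = as.numeric(ct18s), ctEbna1 = as.numeric(ctEbna1),
      msiMarkers = msiMarkers,
      mlh1Homogeneous = as.logical(mlh1Homogeneous),
      mlh1Mutated = as.logical(mlh1Mutated), scna = as.numeric(scna))
}

setMethod("show", "SamplePanel", function(object) {
  cat("SamplePanel", object@sampleId, sprintf("(%s)\n", object@role))
  cat("  Ct:", if (length(object@ct))
    paste(names(object@ct), round(object@ct, 2), sep = "=", collapse = " ")
    else "none", "\n")
  cat("  18S Ct:", object@ct18s, " EBNA1 Ct:", object@ctEbna1, "\n")
  if (length(object@msiMarkers))
    cat("  pentaplex:", sum(object@msiMarkers == "additional_alleles"),
        "of 5 loci unstable\n")
})

#' ScoreContext: cohort medians for score normalization
#'
#' The TP53-activation and proliferation scores normalize each sample's
#' expression by the cohort median of that gene. A ScoreContext freezes
#' those medians so samples can be scored consistently.
#'
#' @slot medians named numeric vector of cohort median expressions
#'   (arbitrary units) for CDKN1A, MDM2, TOP2A, MKI67.
#' @slot n number of samples the medians were computed over.
#' @export
setClass("ScoreContext",
         representation(medians = "numeric", n = "integer"))

setValidity("ScoreContext", function(object) {
  need <- c("CDKN1A", "MDM2", "TOP2A", "MKI67")
  if (!all(need %in% names(object@medians)))
    return("medians must name CDKN1A, MDM2, TOP2A, MKI67")
  if (any(!is.finite(object@medians[need]) | object@medians[need] <= 0))
    return("medians must be finite and > 0")
  if (object@n < 2L) return("medians must be computed over >= 2 samples")
  TRUE
})

setMethod("show", "ScoreContext", function(object) {
  cat("ScoreContext over", object@n, "samples\n  medians:",
      paste(names(object@medians), signif(object@medians, 4),
            sep = "=", collapse = " "), "\n")
})

#' VariantSet: a table of normalized variant records
#'
#' A thin S4 container around a per-variant data.frame with a fixed core
#' schema. Records are keyed by (chrom, pos, ref, alt) after parsimony
#' trimming; per-record fields carry read support, allele fraction, caller
#' provenance, predicted protein impact and population annotations.
#'
#' @slot variants data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}, \code{variant_class} (SNV/insertion/deletion),
#'   \code{depth}, \code{alt_support}, \code{allele_fraction},
#'   \code{callers}, \code{impact}, \code{zygosity}, plus optional
#'   population-annotation columns (\code{hapmap_ac}, \code{cgi69_ac},
#'   \code{evs1000_ac}, \code{dbsnp_max_maf}), \code{context} (SNV
#'   trinucleotide context) and \code{gene}.
#' @export
setClass("VariantSet", representation(variants = "data.frame"))

setValidity("VariantSet", function(object) {
  v <- object@variants
  core <- c("chrom", "pos", "ref", "alt", "variant_class", "depth",
            "alt_support", "allele_fraction")
  miss <- setdiff(core, names(v))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(v) == 0) return(TRUE)
  msg <- character()
  if (any(v$alt_support > v$depth))
    msg <- c(msg, "alt_support must be <= depth")
  if (any(v$allele_fraction < 0 | v$allele_fraction > 1))
    msg <- c(msg, "allele_fraction must lie in [0, 1]")
  ok_depth <- v$depth > 0
  dev <- abs(v$allele_fraction[ok_depth] -
               v$alt_support[ok_depth] / v$depth[ok_depth])
  if (any(dev > 1 / v$depth[ok_depth] + 1e-9))
    msg <- c(msg, "allele_fraction inconsistent with counts beyond 1/depth")
  is_snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  if (any(is_snv != (v$variant_class == "SNV")))
    msg <- c(msg, "variant_class SNV must coincide with len(ref)=len(alt)=1")
  if (!all(v$variant_class %in% VARIANT_CLASSES))
    msg <- c(msg, "variant_class must be SNV|insertion|deletion")
  if (length(msg)) msg else TRUE
})

#' Construct a VariantSet from a data.frame
#'
#' Fills derivable columns: \code{variant_class} from allele lengths,
#' \code{allele_fraction} from \code{alt_support/depth}, and default
#' \code{callers}/\code{impact}/\code{zygosity} when absent.
#'
#' @param df data.frame with at least chrom, pos, ref, alt, depth,
#'   alt_support.
#' @return a \linkS4class{VariantSet}.
#' @examples
#' VariantSet(data.frame(chrom = "1", pos = 100, ref = "A", alt = "T",
#'                       depth = 50, alt_support = 25))
#' @export
VariantSet <- function(df = data.frame()) {
  if (nrow(df) == 0) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), variant_class = character(),
                     depth = numeric(), alt_support = numeric(),
                     allele_fraction = numeric(), callers = character(),
                     impact = character(), zygosity = character(),
                     stringsAsFactors = FALSE)
    return(new("VariantSet", variants = df))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- as.character(df$ref)
  df$alt <- as.character(df$alt)
  if (is.null(df$variant_class)) {
    df$variant_class <- ifelse(
      nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV",
      ifelse(nchar(df$alt) > nchar(df$ref), "insertion", "deletion"))
  }
  if (is.null(df$allele_fraction))
    df$allele_fraction <- ifelse(df$depth > 0, df$alt_support / df$depth, 0)
  if (is.null(df$callers)) df$callers <- NA_character_
  if (is.null(df$impact)) df$impact <- NA_character_
  if (is.null(df$zygosity))
    df$zygosity <- ifelse(df$allele_fraction >= 0.8, "hom", "het")
  rownames(df) <- NULL
  new("VariantSet", variants = df)
}

setMethod("show", "VariantSet", function(object) {
  v <- object@variants
  cat("VariantSet with", nrow(v), "records\n")
  if (nrow(v)) {
    tab <- table(v$variant_class)
    cat(" ", paste(names(tab), tab, sep = ":", collapse = "  "), "\n")
  }
})

#' CopyNumberProfile: per-gene integer copy-number calls
#'
#' Holds absolute integer copy-number calls (PICNIC-style) per gene together
#' with chromosome placement and gene span lengths, the inputs for SCNA
#' event calling, genomic-stability classification and ploidy estimation.
#'
#' @slot genes data.frame with columns \code{gene}, \code{chrom},
#'   \code{length} (bp), \code{copy_number} (non-negative integer) and the
#'   derived \code{autosome} flag.
#' @export
setClass("CopyNumberProfile", representation(genes = "data.frame"))

setValidity("CopyNumberProfile", function(object) {
  g <- object@genes
  need <- c("gene", "chrom", "length", "copy_number", "autosome")
  miss <- setdiff(need, names(g))
  if (length(miss))
    return(paste("missing columns:", paste(miss, collapse = ", ")))
  if (nrow(g) == 0) return(TRUE)
  msg <- character()
  if (any(g$copy_number < 0) || any(g$copy_number != round(g$copy_number)))
    msg <- c(msg, "copy numbers must be non-negative integers")
  if (any(g$length <= 0)) msg <- c(msg, "gene lengths must be positive")
  auto <- !sub("^chr", "", g$chrom) %in% c("X", "Y")
  if (any(auto != g$autosome))
    msg <- c(msg, "autosome flag inconsistent with chromosome")
  if (length(msg)) msg else TRUE
})

#' Construct a CopyNumberProfile
#'
#' @param df data.frame with columns gene, chrom, copy_number and either
#'   \code{length} or \code{start}/\code{end} gene coordinates.
#' @return a \linkS4class{CopyNumberProfile}.
#' @export
CopyNumberProfile <- function(df) {
  df$gene <- as.character(df$gene)
  df$chrom <- as.character(df$chrom)
  if (is.null(df$length)) {
    stopifnot(!is.null(df$start), !is.null(df$end))
    df$length <- df$end - df$start + 1
  }
  df$copy_number <- as.numeric(df$copy_number)
  df$autosome <- !sub("^chr", "", df$chrom) %in% c("X", "Y")
  keep <- intersect(c("gene", "chrom", "start", "end", "length",
                      "copy_number", "autosome"), names(df))
  rownames(df) <- NULL
  new("CopyNumberProfile", genes = df[, keep])
}

setMethod("show", "CopyNumberProfile", function(object) {
  g <- object@genes
  cat("CopyNumberProfile:", nrow(g), "genes,",
      sum(g$autosome), "autosomal\n")
  if (nrow(g))
    cat("  CN range:", min(g$copy_number), "-", max(g$copy_number), "\n")
})

#' PassageSeries: matched variant calls across serial passages
#'
#' Per-variant allele fractions and read depths across the ordered stages
#' of PDX establishment: the patient tumor (P0), passages P1-P3 and the
#' established PDX. Variant keys index the rows of both matrices.
#'
#' @slot modelId model identifier.
#' @slot stages ordered character vector of stage labels.
#' @slot af numeric matrix (variants x stages) of allele fractions in [0,1];
#'   an absent call at a covered site is 0.
#' @slot depth numeric matrix (variants x stages) of read depths.
#' @export
setClass("PassageSeries", representation(
  modelId = "character", stages = "character",
  af = "matrix", depth = "matrix"))

setValidity("PassageSeries", function(object) {
  msg <- character()
  if (length(object@stages) < 2) msg <- c(msg, "need >= 2 stages")
  if (!identical(colnames(object@af), object@stages) ||
      !identical(colnames(object@depth), object@stages))
    msg <- c(msg, "matrix columns must equal stages in order")
  if (!identical(dim(object@af), dim(object@depth)))
    msg <- c(msg, "af and depth must have identical shape")
  if (length(object@af) && (any(object@af < 0) || any(object@af > 1)))
    msg <- c(msg, "allele fractions must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Construct a PassageSeries
#'
#' @param modelId model identifier.
#' @param af,depth numeric matrices (variants x stages) with identical
#'   dimnames; rownames are variant keys, colnames the ordered stages.
#' @return a \linkS4class{PassageSeries}.
#' @export
PassageSeries <- function(modelId, af, depth) {
  new("PassageSeries", modelId = as.character(modelId),
      stages = colnames(af), af = af, depth = depth)
}

setMethod("show", "PassageSeries", function(object) {
  cat("PassageSeries", object@modelId, ":", nrow(object@af), "variants x",
      paste(object@stages, collapse = " > "), "\n")
})

#' CohortTable: per-patient clinical annotation and engraftment outcome
#'
#' One row per patient with the clinical fields used for engraftment-rate
#' stratification (gender, Lauren class, pT/pN/pM stage, ERBB2 IHC score,
#' MSI and EBV status, molecular subtype calls) and the engraftment flag.
#'
#' @slot patients data.frame; must contain \code{id} and logical
#'   \code{engrafted}.
#' @export
setClass("CohortTable", representation(patients = "data.frame"))

setValidity("CohortTable", function(object) {
  p <- object@patients
  if (!all(c("id", "engrafted") %in% names(p)))
    return("patients must have columns id and engrafted")
  if (nrow(p) && !is.logical(p$engrafted))
    return("engrafted must be logical")
  if (anyDuplicated(p$id)) return("patient ids must be unique")
  TRUE
})

#' Construct a CohortTable
#'
#' @param df per-patient data.frame with \code{id} and logical
#'   \code{engrafted} plus any categorical stratifiers.
#' @return a \linkS4class{CohortTable}.
#' @export
CohortTable <- function(df) {
  df$id <- as.character(df$id)
  df$engrafted <- as.logical(df$engrafted)
  rownames(df) <- NULL
  new("CohortTable", patients = df)
}

setMethod("show", "CohortTable", function(object) {
  p <- object@patients
  cat("CohortTable:", nrow(p), "patients,", sum(p$engrafted),
      "engrafted\n")
})
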