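#' Mouse-read deconvolution by comparative alignment score
#'
#' Xenograft sequencing libraries contain reads from infiltrating mouse
#' stroma. Given per-read alignment scores against the human and mouse
#' references, reads that map strictly better to mouse are discarded; ties
#' and mouse-unmapped reads are kept as human.
#'
#' @param scorePairs data.frame with columns \code{read_id},
#'   \code{human_score}, \code{mouse_score} (same scoring scheme; \code{NA}
#'   = unmapped on that genome).
#' @return list with \code{kept} (character read ids),
#'   \code{discarded} (read ids) and \code{contamination}, the discarded
#'   fraction of all input reads.
#' @examples
#' sp <- data.frame(read_id = c("r1", "r2", "r3"),
#'                  human_score = c(60, 55, 60),
#'                  mouse_score = c(55, 60, 60))
#' deconvolveReads(sp)$contamination  # 1/3
#' @export
deconvolveReads <- function(scorePairs) {
  stopifnot(is.data.frame(scorePairs),
            all(c("read_id", "human_score", "mouse_score") %in%
                  names(scorePairs)))
  if (nrow(scorePairs) == 0) stop("empty read-score input")
  hs <- scorePairs$human_score
  ms <- scorePairs$mouse_score
  if (any(is.na(hs) & is.na(ms)))
    warning("reads unmapped on both genomes are kept")
  # discard only reads mapping strictly better to mouse
  discard <- !is.na(ms) & (is.na(hs) | ms > hs)
  list(kept = as.character(scorePairs$read_id[!discard]),
       discarded = as.character(scorePairs$read_id[discard]),
       contamination = mean(discard))
}

trimAllelePair <- function(pos, ref, alt) {
  # parsimony trimming: shared suffix first, then shared prefix (keeping
  # at least one base each), advancing pos over the trimmed prefix
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Normalize a raw caller table to the canonical key convention
#'
#' Splits multi-allelic records (comma-separated ALT) and parsimony-trims
#' ref/alt allele pairs so records from callers emitting different indel
#' dialects intersect on identical (chrom, pos, ref, alt) keys.
#'
#' @param df caller output data.frame (chrom, pos, ref, alt, depth,
#'   alt_support, ...).
#' @return a \linkS4class{VariantSet} with normalized keys.
#' @export
normalizeVariants <- function(df) {
  if (nrow(df) == 0) return(VariantSet())
  df$alt <- as.character(df$alt)
  multi <- grepl(",", df$alt)
  if (any(multi)) {
    parts <- lapply(seq_len(nrow(df)), function(i) {
      alts <- strsplit(df$alt[i], ",", fixed = TRUE)[[1]]
      out <- df[rep(i, length(alts)), , drop = FALSE]
      out$alt <- alts
      out
    })
    df <- do.call(rbind, parts)
  }
  trimmed <- Map(trimAllelePair, df$pos, as.character(df$ref), df$alt)
  df$pos <- vapply(trimmed, `[[`, numeric(1), "pos")
  df$ref <- vapply(trimmed, `[[`, character(1), "ref")
  df$alt <- vapply(trimmed, `[[`, character(1), "alt")
  df$variant_class <- NULL
  VariantSet(df)
}

#' Three-caller consensus intersection
#'
#' Retains only variants reported by all three callers (intersection on the
#' normalized (chrom, pos, ref, alt) key). Per-record fields (depth, allele
#' fraction, annotations) are taken from the designated primary caller.
#'
#' @param callsA,callsB,callsC \linkS4class{VariantSet}s (or raw
#'   data.frames, normalized on entry) from the three callers.
#' @param primary which caller's per-field values to report
#'   (\code{"A"}, \code{"B"} or \code{"C"}; default \code{"A"}).
#' @return a \linkS4class{VariantSet} with \code{callers = "A,B,C"}.
#' @export
consensusVariants <- function(callsA, callsB, callsC, primary = "A") {
  as_vs <- function(x) if (is(x, "VariantSet")) x else normalizeVariants(x)
  sets <- list(A = as_vs(callsA), B = as_vs(callsB), C = as_vs(callsC))
  stopifnot(primary %in% names(sets))
  keys <- lapply(sets, variantKeys)
  shared <- intersect(intersect(keys$A, keys$B), keys$C)
  pv <- variants(sets[[primary]])
  keep <- pv[match(shared, keys[[primary]]), , drop = FALSE]
  if (nrow(keep)) keep$callers <- "A,B,C"
  rownames(keep) <- NULL
  if (nrow(keep) == 0) VariantSet() else new("VariantSet", variants = keep)
}

#' Read-support and allele-fraction filter
#'
#' Keeps variants with at least \code{minSupport} variant-supporting reads
#' and an allele fraction of at least \code{minAf} (both inclusive).
#'
#' @param vs a \linkS4class{VariantSet}.
#' @param minSupport minimum supporting reads (default 3).
#' @param minAf minimum allele fraction (default 0.05).
#' @return filtered \linkS4class{VariantSet}.
#' @export
supportFilter <- function(vs, minSupport = 3, minAf = 0.05) {
  v <- variants(vs)
  keep <- v$alt_support >= minSupport & v$allele_fraction >= minAf
  new("VariantSet", variants = v[keep, , drop = FALSE])
}

#' Known-polymorphism filter
#'
#' Drops a variant if (1) it has at least three allele counts in HapMap or
#' the CGI 69 genomes or EVS+1000 genomes, or (2) it shows more than 5%
#' minor-allele frequency in at least one dbSNP population. Records without
#' annotations are kept.
#'
#' @param vs a \linkS4class{VariantSet}; annotation columns
#'   \code{hapmap_ac}, \code{cgi69_ac}, \code{evs1000_ac} (allele counts)
#'   and \code{dbsnp_max_maf} (max per-population MAF) are honored when
#'   present.
#' @param minAc allele-count threshold for rule (1) (default 3, inclusive).
#' @param maxMaf MAF threshold for rule (2) (default 0.05, strict >).
#' @return filtered \linkS4class{VariantSet}.
#' @export
polymorphismFilter <- function(vs, minAc = 3, maxMaf = 0.05) {
  v <- variants(vs)
  if (nrow(v) == 0) return(vs)
  col0 <- function(nm) {
    x <- if (nm %in% names(v)) v[[nm]] else rep(NA_real_, nrow(v))
    ifelse(is.na(x), 0, x)
  }
  known_ac <- col0("hapmap_ac") >= minAc | col0("cgi69_ac") >= minAc |
    col0("evs1000_ac") >= minAc
  common <- col0("dbsnp_max_maf") > maxMaf
  new("VariantSet", variants = v[!(known_ac | common), , drop = FALSE])
}

#' Protein-impact filter
#'
#' Keeps only variants annotated with a high or moderate predicted protein
#' impact. Records lacking an impact annotation are dropped with a warning
#' (conservative reading of "high or moderate only").
#'
#' @param vs a \linkS4class{VariantSet} with an \code{impact} column.
#' @return filtered \linkS4class{VariantSet}.
#' @export
impactFilter <- function(vs) {
  v <- variants(vs)
  if (nrow(v) == 0) return(vs)
  missing_impact <- is.na(v$impact)
  if (any(missing_impact))
    warning(sum(missing_impact), " records without impact annotation dropped")
  keep <- !missing_impact & v$impact %in% c("high", "moderate")
  new("VariantSet", variants = v[keep, , drop = FALSE])
}

#' Germline subtraction
#'
#' Removes from the tumor set every variant also observed in the matched
#' (or pooled) normal set, by normalized key.
#'
#' @param tumorVs,normalVs \linkS4class{VariantSet}s sharing the key
#'   convention.
#' @return somatic \linkS4class{VariantSet} (tumor minus normal).
#' @export
germlineSubtract <- function(tumorVs, normalVs) {
  tk <- variantKeys(tumorVs)
  nk <- variantKeys(normalVs)
  v <- variants(tumorVs)
  new("VariantSet", variants = v[!(tk %in% nk), , drop = FALSE])
}

#' Run the full somatic filter chain
#'
#' Convenience wrapper: three-caller consensus, then support/AF filter,
#' polymorphism filter, impact filter and germline subtraction. The three
#' record-wise filters are pure predicates, so their order does not affect
#' the result.
#'
#' @param callsA,callsB,callsC caller tables.
#' @param normalVs matched-normal \linkS4class{VariantSet} (possibly empty).
#' @param minSupport,minAf support-filter thresholds.
#' @return somatic \linkS4class{VariantSet}.
#' @export
somaticPipeline <- function(callsA, callsB, callsC,
                            normalVs = VariantSet(),
                            minSupport = 3, minAf = 0.05) {
  vs <- consensusVariants(callsA, callsB, callsC)
  vs <- supportFilter(vs, minSupport, minAf)
  vs <- polymorphismFilter(vs)
  vs <- impactFilter(vs)
  germlineSubtract(vs, normalVs)
}

#' Mutation prevalence per megabase
#'
#' Somatic mutation count divided by the exome target size. The
#' hypermutation flag defaults to prevalence strictly above 21.1
#' mutations/Mb, the upper end of the microsatellite-stable range.
#'
#' @param vs somatic \linkS4class{VariantSet} (or an integer count).
#' @param targetSizeMb capture target size in megabases (e.g. 38, 50, 51).
#' @param hypermutatedAbove prevalence cutoff for the flag (default 21.1).
#' @return list with \code{perMb}, \code{count} and logical
#'   \code{hypermutated}.
#' @export
mutationPrevalence <- function(vs, targetSizeMb, hypermutatedAbove = 21.1) {
  if (!is.finite(targetSizeMb) || targetSizeMb <= 0)
    stop("targetSizeMb must be > 0")
  n <- if (is(vs, "VariantSet")) nVariants(vs) else as.numeric(vs)
  perMb <- n / targetSizeMb
  list(perMb = perMb, count = n, hypermutated = perMb > hypermutatedAbove)
}
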