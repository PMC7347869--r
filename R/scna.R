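#' Per-gene copy-number event calls
#'
#' Labels each gene from its absolute integer copy number: amplified when
#' the call is >= 8, homozygous deletion when it equals 0, neutral
#' otherwise.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param ampMin smallest copy number called amplified (default 8,
#'   inclusive).
#' @return data.frame: the gene table plus an \code{event} column in
#'   \code{amplified}/\code{homozygous_deletion}/\code{neutral}.
#' @export
callEvents <- function(profile, ampMin = 8) {
  g <- cnGenes(profile)
  g$event <- ifelse(g$copy_number >= ampMin, "amplified",
                    ifelse(g$copy_number == 0, "homozygous_deletion",
                           "neutral"))
  g
}

#' Autosomal SCNA count
#'
#' Somatic copy-number alteration count: amplifications plus homozygous
#' deletions over autosomal genes only.
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param ampMin amplification cutoff passed to \code{\link{callEvents}}.
#' @return list with \code{amplifications}, \code{homozygousDeletions} and
#'   \code{scnaTotal} (their sum).
#' @export
scnaCount <- function(profile, ampMin = 8) {
  ev <- callEvents(profile, ampMin)
  ev <- ev[ev$autosome, , drop = FALSE]
  amp <- sum(ev$event == "amplified")
  del <- sum(ev$event == "homozygous_deletion")
  list(amplifications = amp, homozygousDeletions = del,
       scnaTotal = amp + del)
}

#' Genomic-stability classification from the SCNA count
#'
#' Models with at most 15 autosomal SCNA are genomically stable (GS);
#' more than 15 is chromosome-instable (CIN).
#'
#' @param scnaTotal non-negative integer SCNA count.
#' @param gsMax largest count still called GS (default 15).
#' @return \code{"GS"} or \code{"CIN"}.
#' @export
classifyStability <- function(scnaTotal, gsMax = 15) {
  stopifnot(is.finite(scnaTotal), scnaTotal >= 0)
  if (scnaTotal <= gsMax) "GS" else "CIN"
}

#' Ploidy estimate from a copy-number profile
#'
#' Mean integer copy number over autosomal genes, weighted by gene span
#' length by default (an unweighted mean is available).
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param weighted weight genes by span length (default \code{TRUE}).
#' @return numeric ploidy (unitless).
#' @export
ploidy <- function(profile, weighted = TRUE) {
  g <- cnGenes(profile)
  g <- g[g$autosome, , drop = FALSE]
  if (nrow(g) == 0 || sum(g$length) == 0)
    stop("no autosomal gene spans to average over")
  if (weighted) sum(g$copy_number * g$length) / sum(g$length)
  else mean(g$copy_number)
}

#' Full SCNA summary of one profile
#'
#' @param profile a \linkS4class{CopyNumberProfile}.
#' @param ampMin,gsMax thresholds for event calling and stability.
#' @return list: amplifications, homozygousDeletions, scnaTotal,
#'   stabilityClass, ploidy.
#' @export
scnaSummary <- function(profile, ampMin = 8, gsMax = 15) {
  cnt <- scnaCount(profile, ampMin)
  c(cnt, list(stabilityClass = classifyStability(cnt$scnaTotal, gsMax),
              ploidy = ploidy(profile)))
}
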