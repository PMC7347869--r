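#' Assemble a PassageSeries from per-stage variant sets
#'
#' Harmonizes variant keys across the ordered stages (patient tumor P0,
#' passages P1-P3, established PDX). A variant absent at a stage but
#' covered there is assigned allele fraction 0 at that stage's site depth;
#' sites with unknown coverage get the supplied default depth.
#'
#' @param modelId model identifier.
#' @param stageSets named list of \linkS4class{VariantSet}s in stage order.
#' @param defaultDepth depth assumed at stages where a variant was not
#'   reported and no site coverage is known (default 0, which excludes the
#'   variant under the coverage rule unless \code{siteDepths} says
#'   otherwise).
#' @param siteDepths optional matrix (variant keys x stages) of site
#'   coverages overriding per-record depths for absent calls.
#' @return a \linkS4class{PassageSeries}.
#' @export
buildPassageSeries <- function(modelId, stageSets, defaultDepth = 0,
                               siteDepths = NULL) {
  if (length(stageSets) < 2) stop("need at least 2 stages")
  stopifnot(!is.null(names(stageSets)))
  keys <- unique(unlist(lapply(stageSets, variantKeys)))
  nst <- length(stageSets)
  af <- matrix(0, length(keys), nst,
               dimnames = list(keys, names(stageSets)))
  dp <- matrix(as.numeric(defaultDepth), length(keys), nst,
               dimnames = list(keys, names(stageSets)))
  for (s in names(stageSets)) {
    vk <- variantKeys(stageSets[[s]])
    v <- variants(stageSets[[s]])
    idx <- match(vk, keys)
    af[idx, s] <- v$allele_fraction
    dp[idx, s] <- v$depth
  }
  if (!is.null(siteDepths)) {
    common <- intersect(rownames(siteDepths), keys)
    for (s in intersect(colnames(siteDepths), names(stageSets))) {
      absent <- dp[common, s] == defaultDepth & af[common, s] == 0
      dp[common, s][absent] <- siteDepths[common, s][absent]
    }
  }
  PassageSeries(modelId, af, dp)
}

#' Extract coverage-qualified AF trajectories
#'
#' A variant enters trajectory analysis only if its read depth is at least
#' \code{minDepth} at every stage of the model; the number of excluded
#' variants is reported.
#'
#' @param series a \linkS4class{PassageSeries}.
#' @param minDepth minimum per-stage coverage (default 10 reads).
#' @return list with \code{af} (qualified AF matrix, variants x stages)
#'   and \code{nExcluded}.
#' @export
buildTrajectories <- function(series, minDepth = 10) {
  if (length(stages(series)) < 2) stop("need at least 2 stages")
  dp <- depthMatrix(series)
  ok <- apply(dp >= minDepth, 1, all)
  if (nrow(dp) == 0) ok <- logical(0)
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(n_excl, " variants excluded by the >=", minDepth,
            "x coverage rule")
  list(af = afMatrix(series)[ok, , drop = FALSE], nExcluded = n_excl)
}

#' Classify one allele-fraction trajectory
#'
#' Three clonal behaviours are distinguished across passages:
#' \itemize{
#'   \item \code{selected_at_P1}: the allele fraction rises by at least
#'     \code{deltaRise} between the patient tumor and P1 and stays within
#'     \code{deltaStable} afterwards — a clone selected at engraftment.
#'   \item \code{transient}: the presence indicator (AF >= \code{detectAf})
#'     flips at least twice, or the variant disappears after having been
#'     detected — low-fraction clones appearing and disappearing.
#'   \item \code{stable}: total AF variation across stages within
#'     \code{deltaStable}.
#' }
#' Precedence is selected_at_P1 > transient > stable; trajectories matching
#' none of the rules (slow drift) fall back to stable so the map is total.
#'
#' @param af numeric AF vector over the ordered stages (length >= 3, first
#'   element = patient tumor P0).
#' @param detectAf detection floor on AF (default 0.05, the calling floor).
#' @param deltaStable maximum AF range called stable (default 0.15).
#' @param deltaRise minimum P0-to-P1 AF gain for selection (default 0.25).
#' @return one of \code{"stable"}, \code{"selected_at_P1"},
#'   \code{"transient"}.
#' @examples
#' classifyTrajectory(c(0.02, 0.48, 0.50, 0.51, 0.49))  # selected_at_P1
#' classifyTrajectory(c(0, 0.08, 0, 0.07, 0))           # transient
#' @export
classifyTrajectory <- function(af, detectAf = 0.05, deltaStable = 0.15,
                               deltaRise = 0.25) {
  stopifnot(length(af) >= 3, all(af >= 0), all(af <= 1))
  post <- af[-1]
  if ((af[2] - af[1]) >= deltaRise &&
      (max(post) - min(post)) <= deltaStable)
    return("selected_at_P1")
  present <- af >= detectAf
  flips <- sum(abs(diff(present)))
  disappeared <- any(present) &&
    !present[length(present)] && which(present)[1] < length(af)
  if (flips >= 2 || disappeared) return("transient")
  "stable"
}

#' Classify every qualified trajectory of a series
#'
#' @param series a \linkS4class{PassageSeries}.
#' @param minDepth coverage rule (default 10).
#' @param ... thresholds passed to \code{\link{classifyTrajectory}}.
#' @return data.frame: variant key, one AF column per stage, class.
#' @export
classifySeries <- function(series, minDepth = 10, ...) {
  tr <- buildTrajectories(series, minDepth)
  af <- tr$af
  if (nrow(af) == 0)
    return(data.frame(key = character(), class = character()))
  cls <- apply(af, 1, classifyTrajectory, ...)
  out <- data.frame(key = rownames(af), af,
                    class = cls, row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out
}

BAND_SETS <- list(
  loh = c(0, 1),
  two_allele_normal = c(0, 0.5, 1),
  copy_gain_3 = c(0, 1 / 3, 2 / 3, 1),
  copy_gain_4 = c(0, 0.25, 0.5, 0.75, 1)
)

bandFitMad <- function(afs, bands) {
  mean(vapply(afs, function(a) min(abs(a - bands)), numeric(1)))
}

#' Detect allelic-fraction banding in a chromosome window
#'
#' At germline heterozygous sites of a two-allele region, allele fractions
#' cluster near 0, 0.5 and 1; loss of heterozygosity removes the 0.5 band,
#' and copy-number gains add intermediate bands (0, 1/3, 2/3, 1 for three
#' copies; 0, 0.25, 0.5, 0.75, 1 for four). The observed AFs are fitted to
#' each candidate band set by mean absolute deviation to the nearest band;
#' the minimizing set wins, with ties broken toward the set with fewer
#' bands.
#'
#' @param afs numeric vector of allele fractions at heterozygous sites in
#'   one window.
#' @param minSites minimum sites required (default 5).
#' @return list with \code{label} (\code{two_allele_normal}, \code{loh},
#'   \code{copy_gain} or \code{undetermined}), \code{bandSet} (name of the
#'   winning set) and \code{mad} per candidate set.
#' @export
detectAfBanding <- function(afs, minSites = 5) {
  stopifnot(all(afs >= 0), all(afs <= 1))
  mads <- vapply(BAND_SETS, bandFitMad, numeric(1), afs = afs)
  if (length(afs) < minSites)
    return(list(label = "undetermined", bandSet = NA_character_,
                mad = mads))
  sizes <- lengths(BAND_SETS)
  # ties toward fewer bands: order candidates by (mad, band count)
  ord <- order(mads, sizes)
  best <- names(BAND_SETS)[ord[1]]
  label <- switch(best,
                  loh = "loh",
                  two_allele_normal = "two_allele_normal",
                  "copy_gain")
  list(label = label, bandSet = best, mad = mads)
}

#' Hierarchical clustering of passage stages
#'
#' Clusters the stages of a series on their somatic-variant
#' presence/absence profiles (AF >= \code{detectAf}) with Jaccard distance
#' and average linkage. Leaf order is made deterministic by ordering ties
#' on the stage label.
#'
#' @param series a \linkS4class{PassageSeries}.
#' @param minDepth coverage rule applied before clustering (default 10).
#' @param detectAf presence threshold (default 0.05).
#' @return list with \code{hclust} (a stats::hclust object) and
#'   \code{newick} (the dendrogram as a newick string).
#' @importFrom stats hclust dist as.dist
#' @importFrom ape as.phylo write.tree
#' @export
clusterStages <- function(series, minDepth = 10, detectAf = 0.05) {
  tr <- suppressMessages(buildTrajectories(series, minDepth))
  pres <- tr$af >= detectAf
  if (nrow(pres) == 0 || ncol(pres) < 2)
    stop("need >= 2 stages with shared qualified variants")
  m <- t(pres) * 1
  d <- dist(m, method = "binary")  # Jaccard distance on presence profiles
  d[!is.finite(d)] <- 0
  hc <- hclust(d, method = "average")
  list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)))
}

#' Mutant allele fraction from droplet counts
#'
#' Point estimate of the mutant allele fraction from gated droplet digital
#' PCR counts. When channel occupancy exceeds 10%, droplet counts are
#' converted to expected template molecules per droplet via the Poisson
#' occupancy correction lambda = -ln(1 - k/N) before forming the ratio.
#' A mutation is called detected when the estimate exceeds the
#' negative-control estimate (or a fixed floor of 5e-4 when no control is
#' supplied) by more than three Poisson standard errors of the background
#' rate over the observed template count.
#'
#' @param mutantPositive,wildtypePositive gated droplet counts.
#' @param totalDroplets total droplets read.
#' @param negativeControl negative-control fraction estimate, or \code{NA}
#'   to use the fixed floor.
#' @param floorFraction detection floor without a control (default 5e-4).
#' @return list with \code{fraction}, logical \code{detected}, \code{se}
#'   (Poisson standard error of the fraction) and the per-channel
#'   \code{lambdaMutant}/\code{lambdaWildtype}. Zero template in both
#'   channels returns the \code{NA} sentinel.
#' @examples
#' ddpcrFraction(10, 9990, 1e6)$fraction  # ~0.001
#' @export
ddpcrFraction <- function(mutantPositive, wildtypePositive, totalDroplets,
                          negativeControl = NA, floorFraction = 5e-4) {
  stopifnot(totalDroplets > 0,
            mutantPositive >= 0, wildtypePositive >= 0,
            mutantPositive + wildtypePositive <= totalDroplets * 2)
  if (mutantPositive + wildtypePositive == 0)
    return(list(fraction = NA_real_, detected = NA, se = NA_real_,
                lambdaMutant = 0, lambdaWildtype = 0))
  occ_to_lambda <- function(k) {
    occ <- k / totalDroplets
    if (occ > 0.10) -log(1 - occ) * totalDroplets else k
  }
  lam_m <- occ_to_lambda(mutantPositive)
  lam_w <- occ_to_lambda(wildtypePositive)
  templates <- lam_m + lam_w
  frac <- lam_m / templates
  # Poisson error of the mutant channel, for reporting the estimate
  se <- sqrt(max(lam_m, 1)) / templates
  limit <- if (is.na(negativeControl)) floorFraction else negativeControl
  # background fluctuation: Poisson error of a count at the control rate
  # over the same number of templates
  seBg <- sqrt(max(limit * templates, 1)) / templates
  list(fraction = frac, detected = frac > limit + 3 * seBg, se = se,
       lambdaMutant = lam_m / totalDroplets,
       lambdaWildtype = lam_w / totalDroplets)
}
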