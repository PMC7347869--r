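#' @importFrom stats rnorm runif rbinom rpois rlnorm rmultinom
NULL

# deterministic per-substream seed so one stage's parameters do not perturb
# another stage's draws
substreamSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Default subtype mixture and engraftment probabilities
#'
#' Cohort-level defaults: the subtype mixture observed among classifiable
#' gastric tumors (27% MSI, 13% MSS/EMT, 32% MSS/TP53-, 21% MSS/TP53+,
#' 10% EBV, renormalized to sum 1) and per-subtype engraftment
#' probabilities (MSI 0.56, MSS 0.16).
#'
#' @return list with \code{proportions} (named, sums to 1) and
#'   \code{engraftment} (named probabilities).
#' @export
cohortDefaults <- function() {
  p <- c(MSI = 0.27, MSS_EMT = 0.13, MSS_TP53_NEG = 0.32,
         MSS_TP53_POS = 0.21, EBV = 0.10)
  list(proportions = p / sum(p),
       engraftment = c(MSI = 0.56, MSS = 0.16))
}

#' Simulate a patient cohort with subtype structure
#'
#' Draws a true molecular label per patient from the subtype mixture, then
#' generates qPCR panels (Ct values) such that the subtype classifier
#' recovers the label exactly in the noise-free limit: TP53+ samples get
#' TP53-target expressions well above the cohort medians, TP53- well below,
#' EMT samples get CDH1 expression below 40 units, EBV samples an EBNA1 Ct
#' giving a load above 1000 units, and MSI samples unstable pentaplex
#' markers plus MLH1 loss. Engraftment is Bernoulli with the subtype's
#' probability. EBV-positive samples carry the MSS/TP53+ transcriptional
#' profile (their ACRG truth label).
#'
#' @param nPatients cohort size.
#' @param seed integer seed (mandatory).
#' @param proportions named subtype mixture (default
#'   \code{cohortDefaults()$proportions}).
#' @param engraftment named MSI/MSS engraftment probabilities.
#' @param ctSigma Ct measurement noise, standard deviation in cycles
#'   (default 0.1).
#' @return list with \code{cohort} (a \linkS4class{CohortTable} carrying
#'   the truth columns \code{true_label}, \code{acrg_true},
#'   \code{tcga_true}, \code{msi_status}, \code{ebv_status},
#'   \code{lauren}) and \code{panels} (list of
#'   \linkS4class{SamplePanel}s).
#' @export
simulateCohort <- function(nPatients, seed,
                           proportions = cohortDefaults()$proportions,
                           engraftment = cohortDefaults()$engraftment,
                           ctSigma = 0.1) {
  stopifnot(!missing(seed))
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("subtype proportions must sum to 1")
  if (nPatients == 0)
    return(list(cohort = CohortTable(data.frame(id = character(),
                                                engrafted = logical())),
                panels = list()))
  set.seed(substreamSeed(seed, "cohort"))
  labels <- sample(names(proportions), nPatients, replace = TRUE,
                   prob = proportions)
  ct18s <- 12
  base <- c(CDKN1A = 100, MDM2 = 80, CDH1 = 200, TOP2A = 60, MKI67 = 70,
            MLH1 = 50)
  panels <- vector("list", nPatients)
  rows <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    lab <- labels[i]
    msi <- lab == "MSI"
    ebv <- lab == "EBV"
    tp53mult <- switch(lab,
                       MSS_TP53_POS = runif(2, 1.8, 3.2),
                       EBV = runif(2, 1.8, 3.2),
                       MSS_TP53_NEG = runif(2, 0.2, 0.8),
                       runif(2, 0.9, 1.1))
    expr <- c(CDKN1A = base[["CDKN1A"]] * tp53mult[1],
              MDM2 = base[["MDM2"]] * tp53mult[2],
              CDH1 = if (lab == "MSS_EMT") runif(1, 5, 20)
                     else runif(1, 100, 400),
              TOP2A = base[["TOP2A"]] * runif(1, 0.5, 2),
              MKI67 = base[["MKI67"]] * runif(1, 0.5, 2),
              MLH1 = if (msi) runif(1, 0.5, 5) else base[["MLH1"]])
    ct <- pmin(pmax(ct18s - log2(expr) + rnorm(length(expr), 0, ctSigma),
                    0.1), 40)
    names(ct) <- names(expr)
    nUnstable <- if (msi) sample(2:5, 1)
                 else sample(c(0L, 1L), 1, prob = c(0.9, 0.1))
    markers <- setNames(rep("identical", 5), PENTAPLEX_LOCI)
    if (nUnstable > 0)
      markers[sample(PENTAPLEX_LOCI, nUnstable)] <- "additional_alleles"
    ctEbna1 <- if (ebv) runif(1, 14, 19) else 40
    # copy-number context: MSS non-EBV samples split 5:1 CIN vs GS,
    # mirroring the 10 CIN / 2 GS split among profiled MSS models
    tcga_true <- if (msi) "MSI" else if (ebv) "EBV"
                 else sample(c("CIN", "GS"), 1, prob = c(10, 2))
    scna <- switch(tcga_true,
                   MSI = sample(0:10, 1),
                   EBV = NA_real_,
                   GS = sample(0:15, 1),
                   CIN = sample(42:258, 1))
    lauren <- if (msi)
      sample(c("intestinal", "diffuse", "mixed"), 1,
             prob = c(0.75, 0.20, 0.05))
    else sample(c("intestinal", "diffuse", "mixed"), 1,
                prob = c(0.45, 0.50, 0.05))
    eprob <- engraftment[[if (msi) "MSI" else "MSS"]]
    panels[[i]] <- SamplePanel(
      sampleId = sprintf("SIM_%04d", i), role = "tumor", ct = ct,
      ct18s = ct18s, ctEbna1 = ctEbna1, msiMarkers = markers,
      mlh1Homogeneous = !msi, mlh1Mutated = msi, scna = scna)
    rows[[i]] <- data.frame(
      id = sprintf("SIM_%04d", i),
      true_label = lab,
      acrg_true = if (ebv) "MSS_TP53_POS" else lab,
      tcga_true = tcga_true,
      msi_status = if (msi) "MSI" else "MSS",
      ebv_status = if (ebv) "Positive" else "Negative",
      lauren = lauren,
      engrafted = runif(1) < eprob,
      stringsAsFactors = FALSE)
  }
  list(cohort = CohortTable(do.call(rbind, rows)), panels = panels)
}

#' Default genome-simulation configuration
#'
#' Exome-scale defaults: a 51 Mb capture target, subtype-specific somatic
#' mutation-rate ranges (MSI uniform 21.9-57.5/Mb, MSS 2.2-21.1/Mb),
#' subtype indel fractions (0.30 vs 0.19), mouse-read contamination drawn
#' uniformly in 1.6-21%, mean on-target depth 131x, and caller error rates
#' (caller-specific false positives at 2%, no shared false negatives, so
#' the three-way consensus recovers the simulated truth).
#'
#' @return named list of generator parameters.
#' @export
genomeSimDefaults <- function() {
  list(targetSizeMb = 51,
       rateRange = list(MSI = c(21.9, 57.5), MSS = c(2.2, 21.1)),
       indelFraction = c(MSI = 0.30, MSS = 0.19),
       contaminationRange = c(0.016, 0.21),
       meanDepth = 131,
       fpRate = 0.02, fnRate = 0)
}

randomContext <- function(ref) {
  paste0(sample(BASES, 1), ref, sample(BASES, 1))
}

#' Simulate a somatic truth variant set for one model
#'
#' Draws the model's mutation rate uniformly from its subtype range,
#' places that many variants on the autosomes, assigns SNV/indel class by
#' the subtype indel fraction, allele fractions uniform in [0.2, 0.6],
#' depths Poisson around the configured mean, and high/moderate impact
#' annotations (the generated truth passes every documented filter).
#'
#' @param subtype \code{"MSI"} or \code{"MSS"}.
#' @param seed integer seed.
#' @param cfg configuration list (\code{\link{genomeSimDefaults}}).
#' @return list with \code{truth} (\linkS4class{VariantSet}),
#'   \code{ratePerMb} (the drawn rate) and \code{realizedCount}.
#' @export
simulateTruthVariants <- function(subtype, seed, cfg = genomeSimDefaults()) {
  stopifnot(subtype %in% c("MSI", "MSS"))
  set.seed(substreamSeed(seed, paste0("truth_", subtype)))
  rr <- cfg$rateRange[[subtype]]
  rate <- runif(1, rr[1], rr[2])
  n <- max(1L, round(rate * cfg$targetSizeMb))
  indel <- runif(n) < cfg$indelFraction[[subtype]]
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  # indels: pad one allele
  ins <- indel & runif(n) < 0.5
  del <- indel & !ins
  pad <- function(b, k) paste0(b, paste(sample(BASES, k, replace = TRUE),
                                        collapse = ""))
  alt[ins] <- vapply(which(ins), function(i)
    pad(ref[i], sample(1:3, 1)), character(1))
  ref[del] <- vapply(which(del), function(i)
    pad(ref[i], sample(1:3, 1)), character(1))
  alt[del] <- substr(ref[del], 1, 1)
  depth <- pmax(20L, rpois(n, cfg$meanDepth))
  af <- runif(n, 0.2, 0.6)
  alt_support <- round(af * depth)
  df <- data.frame(
    chrom = as.character(sample(1:22, n, replace = TRUE)),
    pos = sample(1e7, n),
    ref = ref, alt = alt,
    depth = depth, alt_support = alt_support,
    allele_fraction = alt_support / depth,
    impact = sample(c("high", "moderate"), n, replace = TRUE,
                    prob = c(0.3, 0.7)),
    stringsAsFactors = FALSE)
  df$context <- ifelse(nchar(df$ref) == 1 & nchar(df$alt) == 1,
                       vapply(df$ref, randomContext, character(1)),
                       NA_character_)
  df <- df[!duplicated(paste(df$chrom, df$pos)), , drop = FALSE]
  list(truth = VariantSet(df), ratePerMb = rate,
       realizedCount = nrow(df))
}

#' Simulate three caller outputs from a truth set
#'
#' Each caller reports the truth minus seeded caller-specific false
#' negatives plus seeded caller-specific false positives (false positives
#' are never shared between callers, so they cannot survive the three-way
#' consensus). Optionally appends shared germline variants that also appear
#' in the matched-normal output.
#'
#' @param truth a \linkS4class{VariantSet}.
#' @param seed integer seed.
#' @param fpRate expected caller-specific false positives as a fraction of
#'   the truth size (default 0.02).
#' @param fnRate per-caller false-negative probability (default 0).
#' @param nGermline number of shared germline variants to add (default 0).
#' @return list with caller data.frames \code{A}, \code{B}, \code{C} and
#'   \code{normal} (a \linkS4class{VariantSet} of the germline records).
#' @export
simulateCallerOutputs <- function(truth, seed, fpRate = 0.02, fnRate = 0,
                                  nGermline = 0) {
  set.seed(substreamSeed(seed, "callers"))
  tv <- variants(truth)
  makeFp <- function(tag, k) {
    ref <- sample(BASES, k, replace = TRUE)
    data.frame(
      chrom = as.character(sample(1:22, k, replace = TRUE)),
      pos = sample((2e7 + 1):(3e7), k),  # disjoint from truth positions
      ref = ref,
      alt = vapply(ref, function(r) sample(setdiff(BASES, r), 1),
                   character(1)),
      depth = pmax(20L, rpois(k, 131)),
      alt_support = rep_len(10L, k),
      allele_fraction = rep_len(NA_real_, k),
      impact = rep_len("moderate", k),
      context = rep_len(NA_character_, k),
      stringsAsFactors = FALSE)
  }
  germ <- if (nGermline > 0) {
    g <- makeFp("g", nGermline)
    g$pos <- sample((3e7 + 1):(4e7), nGermline)
    g$allele_fraction <- NULL
    g
  } else tv[0, setdiff(names(tv), "allele_fraction"), drop = FALSE]
  caller <- function(tag) {
    keep <- runif(nrow(tv)) >= fnRate
    out <- tv[keep, , drop = FALSE]
    k <- rpois(1, fpRate * nrow(tv))
    fp <- makeFp(tag, k)
    fp$allele_fraction <- fp$alt_support / fp$depth
    common <- intersect(names(out), names(fp))
    out <- rbind(out[, common, drop = FALSE], fp[, common, drop = FALSE])
    if (nrow(germ)) {
      g2 <- germ
      g2$allele_fraction <- g2$alt_support / g2$depth
      out <- rbind(out, g2[, common, drop = FALSE])
    }
    rownames(out) <- NULL
    out
  }
  normal <- if (nrow(germ)) {
    g2 <- germ
    g2$allele_fraction <- g2$alt_support / g2$depth
    VariantSet(g2)
  } else VariantSet()
  list(A = caller("A"), B = caller("B"), C = caller("C"), normal = normal)
}

#' Simulate per-read human/mouse alignment score pairs
#'
#' Each read is contaminating mouse stroma with the given probability; such
#' reads score strictly higher on the mouse genome, all others strictly
#' higher on human.
#'
#' @param nReads number of read pairs.
#' @param contamination mouse fraction in [0, 1].
#' @param seed integer seed.
#' @return list with \code{scores} (data.frame read_id, human_score,
#'   mouse_score) and \code{realizedContamination}.
#' @export
simulateReadScores <- function(nReads, contamination, seed) {
  stopifnot(contamination >= 0, contamination <= 1, nReads > 0)
  set.seed(substreamSeed(seed, "reads"))
  mouse <- runif(nReads) < contamination
  human_score <- round(runif(nReads, 40, 60))
  mouse_score <- ifelse(mouse, human_score + sample(1:10, nReads, TRUE),
                        human_score - sample(1:10, nReads, TRUE))
  list(scores = data.frame(read_id = sprintf("r%06d", seq_len(nReads)),
                           human_score = human_score,
                           mouse_score = mouse_score,
                           stringsAsFactors = FALSE),
       realizedContamination = mean(mouse))
}

#' Simulate a per-gene copy-number profile for one subtype
#'
#' MSI profiles are near-diploid (target ploidy 2.29) with few events; GS
#' profiles draw at most 15 autosomal events; CIN profiles draw 42-258
#' events around target ploidy 3.09. The non-event baseline copy number is
#' solved so the length-weighted autosomal mean hits the subtype's target
#' ploidy in expectation.
#'
#' @param subtype one of \code{"MSI"}, \code{"GS"}, \code{"CIN"}.
#' @param seed integer seed.
#' @param nGenes autosomal gene count (default 4000; ~100 chrX genes are
#'   appended to exercise the autosome restriction).
#' @return list with \code{profile} (\linkS4class{CopyNumberProfile}),
#'   \code{trueScna} (the seeded autosomal event count) and
#'   \code{targetPloidy}.
#' @export
simulateCopyNumber <- function(subtype, seed, nGenes = 4000) {
  stopifnot(subtype %in% c("MSI", "GS", "CIN"))
  set.seed(substreamSeed(seed, paste0("cn_", subtype)))
  target <- if (subtype == "MSI") 2.29 else 3.09
  k <- switch(subtype,
              MSI = sample(0:10, 1),
              GS = sample(0:15, 1),
              CIN = sample(42:258, 1))
  nAmp <- floor(k / 2)
  nDel <- k - nAmp
  ampCN <- if (nAmp) sample(8:12, nAmp, replace = TRUE) else integer()
  eventCN <- c(ampCN, rep(0L, nDel))
  nBase <- nGenes - k
  mBase <- (nGenes * target - sum(eventCN)) / nBase
  lo <- floor(mBase)
  cnBase <- lo + rbinom(nBase, 1, mBase - lo)
  cn <- c(cnBase, eventCN)
  ord <- sample(nGenes)
  cn <- cn[ord]
  nX <- 100
  df <- data.frame(
    gene = sprintf("G%05d", seq_len(nGenes + nX)),
    chrom = c(as.character(sample(1:22, nGenes, replace = TRUE)),
              rep("X", nX)),
    length = round(rlnorm(nGenes + nX, log(3e4), 0.8)),
    copy_number = c(cn, rep(2L, nX)),
    stringsAsFactors = FALSE)
  list(profile = CopyNumberProfile(df), trueScna = k,
       targetPloidy = target)
}

#' Default clone specification: the KRAS G12D/G13D swap
#'
#' Two tumor clones sharing a truncal variant backbone: the major clone
#' (99.9% of tumor cells at P0) privately carries KRAS G12D and PIK3CA
#' E542K; a rare minor clone (0.1% at P0) privately carries KRAS G13D and
#' PIK3CA H1047R and fully replaces the major clone from passage 1 onward.
#'
#' @param nTruncal number of shared truncal variants (default 20).
#' @param minorP0 minor-clone cell fraction at P0 (default 0.001).
#' @return clone specification list for \code{\link{simulatePassages}}.
#' @export
cloneSpecKrasSwap <- function(nTruncal = 20, minorP0 = 0.001) {
  stagesN <- STAGE_LABELS
  truncal <- sprintf("1:%d:C>T", seq(1e6, by = 1e4, length.out = nTruncal))
  list(
    stages = stagesN,
    fractions = rbind(
      major = c(1 - minorP0, 0, 0, 0, 0),
      minor = c(minorP0, 1, 1, 1, 1)),
    clones = list(
      major = c(truncal, "12:25398284:C>T_KRAS_G12D",
                "3:178936091:G>A_PIK3CA_E542K"),
      minor = c(truncal, "12:25398281:C>T_KRAS_G13D",
                "3:178952085:A>G_PIK3CA_H1047R")),
    ploidy = 2, dosage = 1)
}

#' Simulate a passage series from a clone specification
#'
#' Per-variant true allele fraction at each stage is the dosage-weighted
#' sum of carrying-clone fractions over the ploidy, scaled by the stage's
#' tumor purity; observed support is binomial at a Poisson-distributed
#' depth.
#'
#' @param spec clone specification (see \code{\link{cloneSpecKrasSwap}}):
#'   \code{stages}, \code{fractions} (clones x stages, columns summing to
#'   1), \code{clones} (variant keys per clone), \code{ploidy},
#'   \code{dosage}.
#' @param seed integer seed.
#' @param depth mean sequencing depth (default 150).
#' @param purity per-stage tumor purity in (0, 1], recycled (default 1).
#' @param modelId identifier for the simulated model.
#' @return list with \code{series} (\linkS4class{PassageSeries}),
#'   \code{trueAf} (matrix of noise-free allele fractions) and
#'   \code{modelId}.
#' @export
simulatePassages <- function(spec, seed, depth = 150, purity = 1,
                             modelId = "SIM_MODEL") {
  fr <- spec$fractions
  if (any(abs(colSums(fr) - 1) > 1e-9))
    stop("clone fractions must sum to 1 at every stage")
  set.seed(substreamSeed(seed, "passages"))
  stagesN <- spec$stages
  purity <- rep(purity, length.out = length(stagesN))
  keys <- unique(unlist(spec$clones))
  trueAf <- matrix(0, length(keys), length(stagesN),
                   dimnames = list(keys, stagesN))
  for (cl in rownames(fr)) {
    carried <- keys %in% spec$clones[[cl]]
    trueAf[carried, ] <- trueAf[carried, , drop = FALSE] +
      matrix(fr[cl, ], sum(carried), length(stagesN), byrow = TRUE)
  }
  trueAf <- sweep(trueAf * spec$dosage / spec$ploidy, 2, purity, `*`)
  dp <- matrix(pmax(10L, rpois(length(trueAf), depth)),
               nrow(trueAf), ncol(trueAf), dimnames = dimnames(trueAf))
  alt <- matrix(rbinom(length(trueAf), as.vector(dp), as.vector(trueAf)),
                nrow(trueAf), ncol(trueAf), dimnames = dimnames(trueAf))
  af <- alt / dp
  list(series = PassageSeries(modelId, af, dp), trueAf = trueAf,
       modelId = modelId)
}

#' Simulate gated droplet counts for a ddPCR assay
#'
#' Droplets load template molecules under Poisson occupancy at the given
#' mean loading; a fraction \code{trueMaf} of molecules is mutant. Gates
#' are exclusive: any droplet containing a mutant molecule counts as
#' mutant-positive; wildtype-positive droplets contain wildtype template
#' only.
#'
#' @param trueMaf mutant allele fraction in [0, 1].
#' @param nDroplets droplet count (> 0).
#' @param seed integer seed.
#' @param lambda mean template molecules per droplet (default 0.5).
#' @return list with \code{mutantPositive}, \code{wildtypePositive},
#'   \code{totalDroplets}.
#' @export
simulateDroplets <- function(trueMaf, nDroplets, seed, lambda = 0.5) {
  stopifnot(trueMaf >= 0, trueMaf <= 1)
  if (nDroplets <= 0) stop("nDroplets must be > 0")
  set.seed(substreamSeed(seed, "droplets"))
  pAnyMut <- 1 - exp(-lambda * trueMaf)
  pWtOnly <- exp(-lambda * trueMaf) * (1 - exp(-lambda * (1 - trueMaf)))
  pEmpty <- 1 - pAnyMut - pWtOnly
  counts <- rmultinom(1, nDroplets, c(pAnyMut, pWtOnly, pEmpty))
  list(mutantPositive = counts[1], wildtypePositive = counts[2],
       totalDroplets = nDroplets)
}
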