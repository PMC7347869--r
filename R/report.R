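roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Engraftment summary stratified by a clinical field
#'
#' For each level of the stratifier: number of patients, share of the
#' cohort, number engrafted, and the engraftment success rate in percent
#' (rounded half away from zero to integers, matching how such tables are
#' conventionally printed). Unknown levels are reported but flagged; empty
#' levels are omitted with a warning.
#'
#' @param cohort a \linkS4class{CohortTable}.
#' @param by name of a categorical column of the cohort table.
#' @return data.frame: level, n, pct, n_engrafted, success_rate,
#'   is_unknown.
#' @export
engraftmentSummary <- function(cohort, by) {
  p <- patients(cohort)
  if (nrow(p) == 0) stop("empty cohort")
  if (!by %in% names(p)) stop("no such field: ", by)
  x <- as.character(p[[by]])
  levels_seen <- unique(x)
  empty <- setdiff(levels(factor(p[[by]])), levels_seen)
  if (length(empty))
    warning("levels with 0 patients omitted: ", paste(empty, collapse = ", "))
  out <- do.call(rbind, lapply(levels_seen, function(lv) {
    sel <- x == lv
    n <- sum(sel)
    e <- sum(p$engrafted[sel])
    data.frame(level = lv, n = n,
               pct = as.numeric(roundHalfAway(100 * n / nrow(p))),
               n_engrafted = e,
               success_rate = as.numeric(roundHalfAway(100 * e / n)),
               is_unknown = tolower(lv) == "unknown",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Subtype concordance between tumors and derived PDX
#'
#' Percent of engrafted models whose PDX subtype call matches the parental
#' tumor call (rounded to integer), with the full cross-tabulation.
#' Unpaired models (NA on either side) are excluded with a warning.
#'
#' @param tumorCalls,pdxCalls character vectors of subtype labels, aligned
#'   by model.
#' @return list with \code{matchPercent}, \code{nMatched}, \code{n} and
#'   \code{table}.
#' @export
concordance <- function(tumorCalls, pdxCalls) {
  stopifnot(length(tumorCalls) == length(pdxCalls))
  ok <- !is.na(tumorCalls) & !is.na(pdxCalls)
  if (any(!ok)) warning(sum(!ok), " unpaired models excluded")
  t2 <- tumorCalls[ok]
  p2 <- pdxCalls[ok]
  if (!length(t2)) stop("no paired models")
  m <- sum(t2 == p2)
  list(matchPercent = as.numeric(roundHalfAway(100 * m / length(t2))),
       nMatched = m, n = length(t2),
       table = table(tumor = t2, pdx = p2))
}

#' Association test between two categorical fields
#'
#' 2x2 tables are tested with Fisher's exact test (two-sided); larger
#' tables with the chi-square test. Either a contingency table or a cohort
#' plus two field names may be supplied.
#'
#' @param x a \linkS4class{CohortTable}, or a matrix/table.
#' @param fieldA,fieldB column names when \code{x} is a cohort; ignored
#'   otherwise. \code{"engrafted"} is allowed as a field.
#' @return list with \code{method}, \code{p.value}, \code{statistic}
#'   (chi-square only) and \code{table}.
#' @importFrom stats fisher.test chisq.test
#' @export
associationTests <- function(x, fieldA = NULL, fieldB = NULL) {
  tab <- if (is(x, "CohortTable")) {
    p <- patients(x)
    stopifnot(fieldA %in% names(p), fieldB %in% names(p))
    table(p[[fieldA]], p[[fieldB]])
  } else as.table(as.matrix(x))
  if (any(dim(tab) < 2)) stop("degenerate table: need >= 2 levels per margin")
  if (all(dim(tab) == 2)) {
    ft <- fisher.test(tab)
    list(method = "fisher", p.value = ft$p.value, statistic = NA_real_,
         table = tab)
  } else {
    ct <- suppressWarnings(chisq.test(tab))
    list(method = "chi-square", p.value = ct$p.value,
         statistic = unname(ct$statistic), table = tab)
  }
}

#' Targetable-alteration landscape over a gene panel
#'
#' Builds the gene x sample alteration matrix over a user-supplied panel
#' of potentially targetable genes: a gene is altered in a sample if it
#' carries any retained somatic mutation, an amplification or a homozygous
#' deletion. A gene counts at most once per sample; mutation takes display
#' precedence over copy-number state.
#'
#' @param variantSets named list of somatic \linkS4class{VariantSet}s
#'   (records need a \code{gene} column), one per sample.
#' @param cnProfiles named list of \linkS4class{CopyNumberProfile}s (may
#'   be missing samples).
#' @param genePanel data.frame with columns \code{gene} and optionally
#'   \code{therapy_class}.
#' @return list with \code{matrix} (gene x sample, levels none/mutation/
#'   amplification/deletion), \code{frequency} (per-gene altered %, over
#'   all samples) and \code{alterationsPerSample}.
#' @export
alterationLandscape <- function(variantSets, cnProfiles = list(),
                                genePanel) {
  if (is.null(genePanel) || nrow(genePanel) == 0) stop("empty gene panel")
  genes <- unique(as.character(genePanel$gene))
  samples <- names(variantSets)
  stopifnot(!is.null(samples))
  m <- matrix("none", length(genes), length(samples),
              dimnames = list(genes, samples))
  for (s in samples) {
    prof <- cnProfiles[[s]]
    if (!is.null(prof)) {
      ev <- callEvents(prof)
      amp <- unique(ev$gene[ev$event == "amplified"])
      del <- unique(ev$gene[ev$event == "homozygous_deletion"])
      m[intersect(genes, del), s] <- "deletion"
      m[intersect(genes, amp), s] <- "amplification"
    }
    v <- variants(variantSets[[s]])
    if (nrow(v) && "gene" %in% names(v))
      m[intersect(genes, unique(v$gene)), s] <- "mutation"
  }
  altered <- m != "none"
  list(matrix = m,
       frequency = 100 * rowMeans(altered),
       alterationsPerSample = colSums(altered))
}

#' Spearman correlation between two per-gene frequency vectors
#'
#' @param freqsA,freqsB per-gene alteration frequencies (%), same gene
#'   order, length >= 3.
#' @return Spearman rho, or \code{NA} when either vector is constant.
#' @export
frequencyCorrelation <- function(freqsA, freqsB) {
  stopifnot(length(freqsA) == length(freqsB), length(freqsA) >= 3)
  if (length(unique(freqsA)) == 1 || length(unique(freqsB)) == 1) {
    warning("constant frequency vector: correlation undefined")
    return(NA_real_)
  }
  cor(freqsA, freqsB, method = "spearman")
}

# per-stratifier (total, engrafted) counts of the packaged gastric cohort
TABLE1_COUNTS <- list(
  gender = list(Female = c(36, 10), Male = c(64, 17)),
  lauren = list(intestinal = c(53, 21), diffuse = c(42, 6), mixed = c(5, 0)),
  pT = list(T1 = c(6, 0), T2 = c(49, 18), T3 = c(32, 8), T4 = c(10, 1),
            Unknown = c(3, 0)),
  pN = list(N0 = c(25, 8), N1 = c(30, 9), N2 = c(18, 3), N3 = c(26, 7),
            Unknown = c(1, 0)),
  pM = list(pM0 = c(89, 25), pM1 = c(10, 2), Unknown = c(1, 0)),
  msi_status = list(MSI = c(27, 15), MSS = c(73, 12)),
  erbb2 = list(`0` = c(37, 9), `1` = c(34, 8), `2` = c(8, 2), `3` = c(7, 5),
               Unknown = c(14, 3)),
  ebv_status = list(Positive = c(10, 0), Negative = c(89, 27),
                    Unknown = c(1, 0)))

#' The packaged 100-patient gastric cohort fixture
#'
#' A per-patient cohort table whose stratified engraftment margins match
#' the published characteristics of the 100-tumor Asian gastric cancer
#' cohort (27 engrafted models; MSI 27 patients / 15 engrafted, etc.).
#' Only each stratifier x engraftment margin is constrained — the joint
#' distribution across fields is a deterministic fill, since only the
#' marginals are published.
#'
#' @return a \linkS4class{CohortTable} with 100 patients and columns
#'   gender, lauren, pT, pN, pM, msi_status, erbb2, ebv_status, engrafted.
#' @export
table1Cohort <- function() {
  n <- 100
  nEng <- 27
  df <- data.frame(id = sprintf("GXA_%03d", seq_len(n)),
                   engrafted = c(rep(TRUE, nEng), rep(FALSE, n - nEng)),
                   stringsAsFactors = FALSE)
  for (field in names(TABLE1_COUNTS)) {
    counts <- TABLE1_COUNTS[[field]]
    eng <- unlist(lapply(names(counts), function(lv)
      rep(lv, counts[[lv]][2])))
    non <- unlist(lapply(names(counts), function(lv)
      rep(lv, counts[[lv]][1] - counts[[lv]][2])))
    stopifnot(length(eng) == nEng, length(non) == n - nEng)
    df[[field]] <- c(eng, non)
  }
  CohortTable(df)
}
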