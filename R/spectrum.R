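SIX_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Names of the 96 trinucleotide substitution channels
#'
#' Standard pyrimidine-strand channel labels "5'[ref>alt]3'", ordered by
#' substitution class (C>A, C>G, C>T, T>A, T>C, T>G) then alphabetically by
#' flanking bases.
#'
#' @return character vector of length 96.
#' @export
channelNames96 <- function() {
  unlist(lapply(SIX_CLASSES, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(BASES, BASES, function(p5, p3)
      paste0(p5, "[", cl, "]", p3))))
  }))
}

revComp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s)
           paste(rev(s), collapse = ""), character(1)))
}

#' Collapse an SNV to its pyrimidine-strand channel
#'
#' Substitutions with a purine reference (A or G) are reverse-complemented
#' (ref, alt and trinucleotide context) so every SNV is expressed with a C
#' or T reference base.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context trinucleotide context centered on the reference base
#'   (e.g. \code{"TAG"}), or \code{NA} when unavailable.
#' @return list with \code{class} (one of the six pyrimidine classes) and
#'   \code{channel} (96-channel label, or \code{NA} without context).
#' @examples
#' pyrimidineChannel("A", "G", "TAG")  # T>C in context CTA
#' @export
pyrimidineChannel <- function(ref, alt, context = NA) {
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
  if (ref %in% c("A", "G")) {
    ref2 <- revComp(ref)
    alt2 <- revComp(alt)
    context <- if (is.na(context)) NA else revComp(context)
  } else {
    ref2 <- ref
    alt2 <- alt
  }
  cl <- paste0(ref2, ">", alt2)
  if (!cl %in% SIX_CLASSES) stop("not a substitution: ", ref, ">", alt)
  channel <- NA_character_
  if (!is.na(context)) {
    if (nchar(context) != 3L || substr(context, 2, 2) != ref2)
      stop("context must be a trinucleotide centered on the reference base")
    channel <- paste0(substr(context, 1, 1), "[", cl, "]",
                      substr(context, 3, 3))
  }
  list(class = cl, channel = channel)
}

#' Mutation spectrum of a somatic variant set
#'
#' Tabulates SNVs into the six pyrimidine substitution classes and, where a
#' trinucleotide context is available, into the 96 substitution channels;
#' indels are counted separately. SNVs without context contribute to the
#' six-class counts only (their number is reported in
#' \code{nWithoutContext}).
#'
#' @param vs a \linkS4class{VariantSet}; SNV contexts are read from the
#'   \code{context} column when present.
#' @return list with \code{counts96} (named integer vector, length 96),
#'   \code{sixClass} (named length-6), \code{indelCount},
#'   \code{snvCount}, \code{indelProportion} =
#'   indels / (indels + SNVs), and \code{nWithoutContext}.
#' @export
mutationSpectrum <- function(vs) {
  v <- variants(vs)
  counts96 <- setNames(integer(96), channelNames96())
  six <- setNames(integer(6), SIX_CLASSES)
  snv <- v[v$variant_class == "SNV", , drop = FALSE]
  indelCount <- sum(v$variant_class %in% c("insertion", "deletion"))
  noCtx <- 0L
  if (nrow(snv)) {
    ctx <- if ("context" %in% names(snv)) snv$context
           else rep(NA_character_, nrow(snv))
    for (i in seq_len(nrow(snv))) {
      ch <- pyrimidineChannel(snv$ref[i], snv$alt[i], ctx[i])
      six[ch$class] <- six[ch$class] + 1L
      if (is.na(ch$channel)) noCtx <- noCtx + 1L
      else counts96[ch$channel] <- counts96[ch$channel] + 1L
    }
  }
  total <- nrow(snv) + indelCount
  list(counts96 = counts96, sixClass = six, indelCount = indelCount,
       snvCount = nrow(snv),
       indelProportion = if (total > 0) indelCount / total else 0,
       nWithoutContext = noCtx)
}

#' Transition / transversion / indel proportions
#'
#' @param spectrum result of \code{\link{mutationSpectrum}}.
#' @return named numeric vector of proportions (transitions, transversions,
#'   indels) summing to 1 over all counted events.
#' @export
tsTvIndel <- function(spectrum) {
  ts <- sum(spectrum$sixClass[c("C>T", "T>C")])
  tv <- sum(spectrum$sixClass[c("C>A", "C>G", "T>A", "T>G")])
  ind <- spectrum$indelCount
  tot <- ts + tv + ind
  if (tot == 0) return(c(transitions = 0, transversions = 0, indels = 0))
  c(transitions = ts, transversions = tv, indels = ind) / tot
}

#' Match sample spectra against a signature matrix
#'
#' Decomposes each sample's normalized 96-channel spectrum into nonnegative
#' exposures over the supplied signature matrix (nonnegative least squares,
#' exposures renormalized to sum 1), and reports the Spearman correlation
#' of the spectrum against every signature column. The mean cohort spectrum
#' is matched the same way.
#'
#' @param spectra list of \code{\link{mutationSpectrum}} results (or a
#'   numeric matrix with 96 rows, one column per sample).
#' @param signatureMatrix numeric matrix, 96 rows x S signature columns,
#'   each column a probability vector over the channels.
#' @return list with \code{exposures} (samples x signatures),
#'   \code{spearman} (samples x signatures), \code{meanSpectrum},
#'   \code{meanSpearman} (per signature, for the mean cohort spectrum) and
#'   \code{bestSignature} per sample. All-zero spectra yield \code{NA}
#'   sentinels.
#' @importFrom pracma lsqnonneg
#' @importFrom stats cor
#' @export
signatureMatch <- function(spectra, signatureMatrix) {
  M <- as.matrix(signatureMatrix)
  stopifnot(nrow(M) == 96)
  if (is.null(colnames(M)))
    colnames(M) <- paste0("S", seq_len(ncol(M)))
  if (is.list(spectra) && !is.null(spectra[[1]]$counts96))
    X <- vapply(spectra, function(s) as.numeric(s$counts96), numeric(96))
  else X <- as.matrix(spectra)
  stopifnot(nrow(X) == 96)
  nS <- ncol(M)
  n <- ncol(X)
  exposures <- matrix(NA_real_, n, nS, dimnames = list(colnames(X),
                                                       colnames(M)))
  rho <- exposures
  for (j in seq_len(n)) {
    x <- X[, j]
    if (sum(x) == 0) next
    p <- x / sum(x)
    w <- pracma::lsqnonneg(M, p)$x
    exposures[j, ] <- if (sum(w) > 0) w / sum(w) else NA_real_
    rho[j, ] <- apply(M, 2, function(s) cor(p, s, method = "spearman"))
  }
  meanSpec <- rowMeans(X)
  meanRho <- if (sum(meanSpec) > 0)
    apply(M, 2, function(s)
      cor(meanSpec / sum(meanSpec), s, method = "spearman"))
    else setNames(rep(NA_real_, nS), colnames(M))
  best <- apply(rho, 1, function(r)
    if (all(is.na(r))) NA_character_ else colnames(M)[which.max(r)])
  list(exposures = exposures, spearman = rho, meanSpectrum = meanSpec,
       meanSpearman = meanRho, bestSignature = best)
}

#' Synthetic orthogonal mutational signatures
#'
#' Builds S signatures with disjoint (orthogonal) channel support, each a
#' uniform probability vector over its own block of the 96 channels. Used
#' for exposure-recovery testing without any external signature download.
#'
#' @param nSignatures number of signatures (must divide 96 evenly or the
#'   last block absorbs the remainder; default 4).
#' @return 96 x nSignatures matrix with columns summing to 1.
#' @export
syntheticSignatures <- function(nSignatures = 4) {
  stopifnot(nSignatures >= 1, nSignatures <= 96)
  block <- floor(96 / nSignatures)
  M <- matrix(0, 96, nSignatures,
              dimnames = list(channelNames96(),
                              paste0("S", seq_len(nSignatures))))
  for (j in seq_len(nSignatures)) {
    from <- (j - 1) * block + 1
    to <- if (j == nSignatures) 96 else j * block
    M[from:to, j] <- 1 / (to - from + 1)
  }
  M
}
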