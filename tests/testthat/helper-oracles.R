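# Independent brute-force oracles and small random-input generators used
# across the suite. These deliberately use naive loops, closed forms or
# exhaustive enumeration, never the package's own code paths.

# random caller-style variant table whose keys come from a shared pool so
# that three-way intersections are non-trivial
randomVariantTable <- function(n, poolSize = 2 * n) {
  pool <- data.frame(
    chrom = as.character(sample(1:5, poolSize, replace = TRUE)),
    pos = sample(1e5, poolSize),
    ref = sample(c("A", "C", "G", "T"), poolSize, replace = TRUE),
    stringsAsFactors = FALSE)
  pool$alt <- vapply(pool$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  pool <- pool[!duplicated(paste(pool$chrom, pool$pos)), ]
  idx <- sample(nrow(pool), min(n, nrow(pool)))
  df <- pool[idx, ]
  df$depth <- sample(10:200, nrow(df), replace = TRUE)
  df$alt_support <- vapply(df$depth, function(d) sample(0:d, 1), integer(1))
  df$impact <- sample(c("high", "moderate", "low", "modifier", NA),
                      nrow(df), replace = TRUE)
  df$hapmap_ac <- sample(c(NA, 0:5), nrow(df), replace = TRUE)
  df$cgi69_ac <- sample(c(NA, 0:5), nrow(df), replace = TRUE)
  df$evs1000_ac <- sample(c(NA, 0:5), nrow(df), replace = TRUE)
  df$dbsnp_max_maf <- sample(c(NA, 0, 0.01, 0.05, 0.06, 0.2),
                             nrow(df), replace = TRUE)
  rownames(df) <- NULL
  df
}

vkey <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = "|")

# triple set intersection, naive loop version
bruteConsensusKeys <- function(a, b, c) {
  out <- character()
  kb <- vkey(b)
  kc <- vkey(c)
  for (k in vkey(a)) if (k %in% kb && k %in% kc) out <- c(out, k)
  unique(out)
}

# record-wise re-statement of the three somatic filters
bruteFilterKeep <- function(df, minSupport = 3, minAf = 0.05) {
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    af <- df$alt_support[i] / df$depth[i]
    if (df$alt_support[i] < minSupport || af < minAf) next
    ac <- c(df$hapmap_ac[i], df$cgi69_ac[i], df$evs1000_ac[i])
    if (any(!is.na(ac) & ac >= 3)) next
    maf <- df$dbsnp_max_maf[i]
    if (!is.na(maf) && maf > 0.05) next
    if (is.na(df$impact[i]) || !df$impact[i] %in% c("high", "moderate"))
      next
    keep[i] <- TRUE
  }
  keep
}

# exhaustive hypergeometric two-sided Fisher p for a 2x2 table
bruteFisherP <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(x) dhyper(x, r1, r2, c1), numeric(1))
  pobs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# explicit-loop band-set fit: minimize mean absolute deviation to the
# nearest band; ties broken toward fewer bands
bruteBandingLabel <- function(afs) {
  sets <- list(loh = c(0, 1),
               two_allele_normal = c(0, 0.5, 1),
               copy_gain_3 = c(0, 1 / 3, 2 / 3, 1),
               copy_gain_4 = c(0, 0.25, 0.5, 0.75, 1))
  best <- NULL; bestMad <- Inf; bestSize <- Inf
  for (nm in names(sets)) {
    tot <- 0
    for (a in afs) {
      dmin <- Inf
      for (b in sets[[nm]]) if (abs(a - b) < dmin) dmin <- abs(a - b)
      tot <- tot + dmin
    }
    mad <- tot / length(afs)
    sz <- length(sets[[nm]])
    if (mad < bestMad - 1e-12 ||
        (abs(mad - bestMad) <= 1e-12 && sz < bestSize)) {
      best <- nm; bestMad <- mad; bestSize <- sz
    }
  }
  if (best == "loh") "loh"
  else if (best == "two_allele_normal") "two_allele_normal"
  else "copy_gain"
}

# closed-form NNLS for signatures with disjoint (orthogonal) support:
# w_j = <M_j, p> / <M_j, M_j>, clamped at zero
orthogonalNnls <- function(M, p) {
  w <- vapply(seq_len(ncol(M)), function(j)
    max(0, sum(M[, j] * p) / sum(M[, j]^2)), numeric(1))
  if (sum(w) > 0) w / sum(w) else w
}

# naive SCNA event enumeration on a per-gene data.frame
bruteScna <- function(df) {
  amp <- 0; del <- 0
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] %in% c("X", "Y")) next
    if (df$copy_number[i] >= 8) amp <- amp + 1
    else if (df$copy_number[i] == 0) del <- del + 1
  }
  c(amp = amp, del = del)
}
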