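test_that("mouse-read deconvolution keeps ties and discards mouse-better", {
  sp <- data.frame(read_id = c("r1", "r2", "r3"),
                   human_score = c(60, 55, 60),
                   mouse_score = c(55, 60, 60))
  out <- deconvolveReads(sp)
  expect_equal(out$kept, c("r1", "r3"))
  expect_equal(out$discarded, "r2")
  expect_equal(out$contamination, 1 / 3)
  expect_error(deconvolveReads(sp[0, ]), "empty")
  # partition: kept and discarded tile the input
  expect_setequal(c(out$kept, out$discarded), sp$read_id)
})

test_that("kept fraction is monotone non-increasing in mouse scores", {
  set.seed(7)
  sp <- data.frame(read_id = sprintf("r%d", 1:500),
                   human_score = sample(30:70, 500, TRUE),
                   mouse_score = sample(30:70, 500, TRUE))
  kept <- vapply(0:10, function(bump) {
    sp2 <- sp
    sp2$mouse_score <- sp2$mouse_score + bump
    length(deconvolveReads(sp2)$kept)
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("key normalization splits multi-allelics and parsimony-trims", {
  raw <- data.frame(chrom = "1", pos = 100, ref = "C", alt = "T,G",
                    depth = 50, alt_support = 10)
  vs <- normalizeVariants(raw)
  expect_equal(nVariants(vs), 2)
  expect_setequal(variants(vs)$alt, c("T", "G"))
  # shared prefix: CT>CA at 100 becomes T>A at 101
  vs2 <- normalizeVariants(data.frame(chrom = "1", pos = 100, ref = "CT",
                                      alt = "CA", depth = 50,
                                      alt_support = 10))
  expect_equal(variants(vs2)$pos, 101)
  expect_equal(variants(vs2)$ref, "T")
  expect_equal(variants(vs2)$alt, "A")
  # shared suffix: ATGTG>ATG is a deletion left-trimmed to pos 100
  vs3 <- normalizeVariants(data.frame(chrom = "1", pos = 100, ref = "ATGTG",
                                      alt = "ATG", depth = 50,
                                      alt_support = 10))
  v3 <- variants(vs3)
  expect_equal(nchar(v3$ref) - nchar(v3$alt), 2)
  expect_equal(v3$variant_class, "deletion")
})

test_that("three-caller consensus equals brute-force triple intersection", {
  vA <- data.frame(chrom = "1", pos = c(1, 2, 3), ref = "A",
                   alt = "T", depth = 50, alt_support = 10)
  vB <- vA[c(1, 2), ]
  vC <- vA[c(1, 3), ]
  cons <- consensusVariants(vA, vB, vC)
  expect_equal(nVariants(cons), 1)  # only pos 1 in all three
  expect_equal(variants(cons)$callers, "A,B,C")
  expect_equal(nVariants(consensusVariants(vA[0, ], vB, vC)), 0)
  for (s in 1:5) {
    set.seed(s)
    a <- randomVariantTable(80)
    b <- randomVariantTable(80)
    c3 <- randomVariantTable(80)
    got <- consensusVariants(a, b, c3)
    keys_got <- paste(variants(got)$chrom, variants(got)$pos,
                      variants(got)$ref, variants(got)$alt, sep = "|")
    expect_setequal(keys_got, bruteConsensusKeys(a, b, c3))
  }
})

test_that("support filter uses inclusive >=3 reads and >=5% AF", {
  df <- data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "T",
                   depth = c(60, 4, 250), alt_support = c(3, 2, 10))
  vs <- VariantSet(df)
  kept <- supportFilter(vs)
  expect_equal(variants(kept)$pos, 1L)  # 3 reads, AF 0.05: kept inclusive
  # 2 reads at AF 0.5 dropped; 10 reads at AF 0.04 dropped
  expect_false(2L %in% variants(kept)$pos)
  expect_false(3L %in% variants(kept)$pos)
})

test_that("polymorphism filter drops known and common variants", {
  df <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "T",
                   depth = 100, alt_support = 30,
                   hapmap_ac = c(3, NA, NA, NA),
                   dbsnp_max_maf = c(NA, 0.06, 0.05, NA))
  vs <- VariantSet(df)
  kept <- variants(polymorphismFilter(vs))$pos
  expect_false(1L %in% kept)   # >= 3 allele counts
  expect_false(2L %in% kept)   # MAF > 5%
  expect_true(3L %in% kept)    # MAF exactly 5% is not "more than 5%"
  expect_true(4L %in% kept)    # no annotations
})

test_that("impact filter keeps high/moderate, drops missing with warning", {
  df <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "T",
                   depth = 100, alt_support = 30,
                   impact = c("high", "moderate", "modifier", NA))
  vs <- VariantSet(df)
  expect_warning(kept <- impactFilter(vs), "without impact")
  expect_setequal(variants(kept)$pos, c(1L, 2L))
})

test_that("germline subtraction removes shared keys only", {
  tum <- VariantSet(data.frame(chrom = "1", pos = 1:3, ref = "A", alt = "T",
                               depth = 100, alt_support = 30))
  nor <- VariantSet(data.frame(chrom = "1", pos = 2, ref = "A", alt = "T",
                               depth = 100, alt_support = 50))
  expect_setequal(variants(germlineSubtract(tum, nor))$pos, c(1L, 3L))
  expect_equal(nVariants(germlineSubtract(tum, VariantSet())), 3)
})

test_that("the three record-wise filters commute (any order, same set)", {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  filters <- list(supportFilter, polymorphismFilter,
                  function(v) suppressWarnings(impactFilter(v)))
  for (s in 1:8) {
    set.seed(100 + s)
    df <- randomVariantTable(sample(50:200, 1))
    vs <- VariantSet(df)
    ref_keys <- NULL
    for (p in perms) {
      out <- vs
      for (f in filters[p]) out <- f(out)
      k <- variantKeys(out)
      if (is.null(ref_keys)) ref_keys <- k else expect_setequal(k, ref_keys)
    }
    # and the chain agrees with the brute-force record-wise predicate
    expect_setequal(ref_keys, variantKeys(vs)[bruteFilterKeep(df)])
  }
})

test_that("mutation prevalence divides count by target size", {
  expect_equal(mutationPrevalence(100, 50)$perMb, 2.0)
  expect_equal(mutationPrevalence(0, 50)$perMb, 0.0)
  p <- mutationPrevalence(1672, 51)
  expect_equal(p$perMb, 1672 / 51, tolerance = 1e-12)
  expect_gt(p$perMb, 21.9)   # lands in the hypermutated MSI range
  expect_lt(p$perMb, 57.5)
  expect_true(p$hypermutated)
  expect_false(mutationPrevalence(100, 50)$hypermutated)
  expect_error(mutationPrevalence(10, 0), "> 0")
})
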