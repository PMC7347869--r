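test_that("engraftment summary totals and edge cases behave", {
  co <- table1Cohort()
  es <- engraftmentSummary(co, "msi_status")
  expect_equal(sum(es$n), 100)
  expect_equal(sum(es$n_engrafted), 27)
  expect_equal(es$success_rate[es$level == "MSI"], 56)
  all_in <- CohortTable(data.frame(id = c("a", "b"), engrafted = TRUE,
                                   grp = "g"))
  expect_equal(engraftmentSummary(all_in, "grp")$success_rate, 100)
  expect_error(engraftmentSummary(CohortTable(
    data.frame(id = character(), engrafted = logical())), "grp"), "empty")
})

test_that("success rates round half away from zero", {
  co <- CohortTable(data.frame(id = sprintf("p%d", 1:8),
                               engrafted = c(rep(TRUE, 1), rep(FALSE, 7)),
                               grp = "g"))
  # 1/8 = 12.5% -> 13
  expect_equal(engraftmentSummary(co, "grp")$success_rate, 13)
})

test_that("subtype concordance counts matches and excludes unpaired", {
  expect_equal(concordance(c("MSI", "CIN"), c("MSI", "CIN"))$matchPercent,
               100)
  t27 <- c(rep("MSI", 15), rep("CIN", 12))
  p27 <- t27
  p27[1:3] <- "CIN"  # 24 of 27 match
  expect_equal(concordance(t27, p27)$matchPercent, 89)
  expect_equal(concordance(c("A", "B"), c("B", "A"))$matchPercent, 0)
  expect_warning(out <- concordance(c("A", NA, "B"), c("A", "B", "B")),
                 "unpaired")
  expect_equal(out$n, 2)
})

test_that("Fisher p on 2x2 tables equals exhaustive hypergeometric", {
  tabs <- list(matrix(c(15, 12, 12, 61), 2),   # MSI/MSS x engrafted
               matrix(c(5, 5, 5, 5), 2),
               matrix(c(1, 9, 11, 3), 2),
               matrix(c(0, 10, 10, 0), 2))
  for (tb in tabs) {
    got <- associationTests(tb)
    expect_equal(got$method, "fisher")
    expect_equal(got$p.value, bruteFisherP(tb), tolerance = 1e-9)
  }
  # the MSI x engraftment comparison lands at the published order p ~ 2e-4
  expect_lt(associationTests(tabs[[1]])$p.value, 5e-4)
  expect_gt(associationTests(tabs[[1]])$p.value, 1e-4)
})

test_that("larger tables fall through to chi-square; degenerate error", {
  tb <- matrix(c(10, 20, 30, 12, 18, 29), nrow = 2, byrow = TRUE)
  got <- associationTests(tb)
  expect_equal(got$method, "chi-square")
  expect_gt(got$p.value, 0.5)  # near-identical rows: independence
  expect_error(associationTests(matrix(1:3, 1)), "degenerate")
})

test_that("alteration landscape: one state per gene, mutation precedence", {
  panel <- data.frame(gene = c("TP53", "ERBB2", "KRAS"))
  vs <- VariantSet(data.frame(chrom = "17", pos = 1:2, ref = "C", alt = "T",
                              depth = 100, alt_support = 40,
                              gene = c("TP53", "TP53")))
  cn <- CopyNumberProfile(data.frame(
    gene = c("TP53", "ERBB2"), chrom = "17", length = 2000,
    copy_number = c(9, 10)))
  ls <- alterationLandscape(list(s1 = vs), list(s1 = cn), panel)
  expect_equal(ls$matrix["TP53", "s1"], "mutation")   # precedence
  expect_equal(ls$matrix["ERBB2", "s1"], "amplification")
  expect_equal(ls$matrix["KRAS", "s1"], "none")
  expect_equal(unname(ls$alterationsPerSample["s1"]), 2)
  # duplicate mutation records count once
  expect_equal(unname(ls$frequency["TP53"]), 100)
  # empty inputs: all none
  ls0 <- alterationLandscape(list(s1 = VariantSet()), list(), panel)
  expect_true(all(ls0$matrix == "none"))
  expect_error(alterationLandscape(list(s1 = vs), list(), panel[0, , drop = FALSE]),
               "empty")
})

test_that("landscape frequencies ignore sample order", {
  panel <- data.frame(gene = c("TP53", "KRAS"))
  v1 <- VariantSet(data.frame(chrom = "1", pos = 1, ref = "C", alt = "T",
                              depth = 100, alt_support = 40, gene = "TP53"))
  v2 <- VariantSet(data.frame(chrom = "1", pos = 2, ref = "C", alt = "T",
                              depth = 100, alt_support = 40, gene = "KRAS"))
  f1 <- alterationLandscape(list(a = v1, b = v2), list(), panel)$frequency
  f2 <- alterationLandscape(list(b = v2, a = v1), list(), panel)$frequency
  expect_equal(f1, f2)
})

test_that("frequency correlation: identity, reversal, and the null", {
  expect_equal(frequencyCorrelation(1:10, 1:10), 1.0)
  expect_equal(frequencyCorrelation(1:10, 10:1), -1.0)
  expect_warning(out <- frequencyCorrelation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(out))
  set.seed(61)
  rhos <- vapply(1:500, function(i) {
    frequencyCorrelation(runif(48), runif(48))
  }, numeric(1))
  expect_equal(mean(rhos), 0, tolerance = 0.05)
})
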