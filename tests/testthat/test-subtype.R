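mk_markers <- function(nAdd, nMissing = 0) {
  states <- c(rep("additional_alleles", nAdd), rep("missing", nMissing))
  states <- c(states, rep("identical", 5 - length(states)))
  setNames(states, c("BAT-26", "BAT-25", "D5S346", "D17S250", "D2S123"))
}

test_that("pentaplex Bethesda rule classifies by unstable marker count", {
  expect_equal(classifyMsiPentaplex(mk_markers(2))$status, "MSI_H")
  expect_equal(classifyMsiPentaplex(mk_markers(2))$binary, "MSI")
  expect_equal(classifyMsiPentaplex(mk_markers(5))$binary, "MSI")
  expect_equal(classifyMsiPentaplex(mk_markers(1))$status, "MSI_L")
  expect_equal(classifyMsiPentaplex(mk_markers(1))$binary, "MSS")
  expect_equal(classifyMsiPentaplex(mk_markers(0))$status, "MSS")
  # missing markers don't count as unstable
  expect_equal(classifyMsiPentaplex(mk_markers(1, nMissing = 3))$binary,
               "MSS")
  expect_error(classifyMsiPentaplex(mk_markers(0, nMissing = 5)),
               "unclassifiable")
  expect_error(classifyMsiPentaplex(mk_markers(2)[1:4]), "5 pentaplex")
})

test_that("MLH1 surrogate calls MSI on staining loss or mutation", {
  expect_equal(msiFromMlh1(ihcHomogeneous = FALSE), "MSI")
  expect_equal(msiFromMlh1(TRUE, FALSE), "MSS")
  expect_equal(msiFromMlh1(TRUE, TRUE), "MSI")
  expect_equal(msiFromMlh1(NA, TRUE), "MSI")
  expect_error(msiFromMlh1(NA, NA), "unclassifiable")
})

test_that("EBV load follows 2^(40-Ct)/1000 with a strict 1000-unit cutoff", {
  expect_equal(ebvLoad(40)$load, 0.001)
  expect_false(ebvLoad(40)$positive)
  expect_equal(ebvLoad(19)$load, 2097.152)
  expect_true(ebvLoad(19)$positive)
  # boundary: just under the threshold
  just_below <- ebvLoad(20.1)
  expect_equal(just_below$load, 2^19.9 / 1000, tolerance = 1e-12)
  expect_lt(just_below$load, 1000)
  expect_false(just_below$positive)
  expect_error(ebvLoad(41), "40")
  expect_error(ebvLoad(0), "40")
})

test_that("relative expression is 2^(Ct18s - CtGene), monotone in both Cts", {
  expect_equal(relativeExpression(15, 15), 1.0)
  expect_equal(relativeExpression(22, 12), 2^-10)
  # CDH1 boundary: Ct 6.68 at 18S Ct 12 sits just under the 40-unit cutoff
  expect_equal(relativeExpression(6.68, 12), 2^5.32, tolerance = 1e-12)
  expect_lt(relativeExpression(6.68, 12), 40)
  expect_equal(relativeExpression(NA, 12), 0)  # not-detected sentinel
  cts <- seq(5, 35, by = 0.5)
  vals <- vapply(cts, relativeExpression, numeric(1), ct18s = 12)
  expect_true(all(diff(vals) < 0))
  vals18 <- vapply(cts, function(x) relativeExpression(20, x), numeric(1))
  expect_true(all(diff(vals18) > 0))
})

ctx_at <- function(cdkn1a = 10, mdm2 = 20, top2a = 5, mki67 = 8) {
  scoreContext(data.frame(CDKN1A = rep(cdkn1a, 3), MDM2 = rep(mdm2, 3),
                          TOP2A = rep(top2a, 3), MKI67 = rep(mki67, 3)))
}

test_that("TP53 activation score normalizes by cohort medians, strict > 2.5", {
  ctx <- ctx_at()
  expect_equal(tp53ActivationScore(10, 20, ctx)$score, 2.0)
  expect_false(tp53ActivationScore(10, 20, ctx)$activated)
  expect_equal(tp53ActivationScore(20, 20, ctx)$score, 3.0)
  expect_true(tp53ActivationScore(20, 20, ctx)$activated)
  at_cut <- tp53ActivationScore(15, 20, ctx)  # 1.5 + 1.0 = 2.5 exactly
  expect_equal(at_cut$score, 2.5)
  expect_false(at_cut$activated)
})

test_that("proliferation subclasses use <1 low, [1,4] intermediate, >4 high", {
  ctx <- ctx_at()
  expect_equal(proliferationScore(5, 8, ctx)$class, "intermediate")
  expect_equal(proliferationScore(5 / 4, 8 / 4, ctx)$score, 0.5)
  expect_equal(proliferationScore(5 / 4, 8 / 4, ctx)$class, "low")
  expect_equal(proliferationScore(5 * 2.5, 8 * 2.5, ctx)$class, "high")
  # closed interval: both endpoints are intermediate
  expect_equal(proliferationScore(5 / 2, 8 / 2, ctx)$class, "intermediate")
  expect_equal(proliferationScore(5 * 2, 8 * 2, ctx)$class, "intermediate")
})

test_that("median normalization makes scores invariant to common rescaling", {
  set.seed(42)
  exprs <- data.frame(CDKN1A = runif(10, 1, 100), MDM2 = runif(10, 1, 100),
                      TOP2A = runif(10, 1, 100), MKI67 = runif(10, 1, 100))
  for (k in c(0.01, 1, 250)) {
    ctx1 <- scoreContext(exprs)
    ctx2 <- scoreContext(exprs * k)
    s1 <- tp53ActivationScore(exprs$CDKN1A[1], exprs$MDM2[1], ctx1)$score
    s2 <- tp53ActivationScore(exprs$CDKN1A[1] * k, exprs$MDM2[1] * k,
                              ctx2)$score
    expect_equal(s1, s2, tolerance = 1e-12)
    p1 <- proliferationScore(exprs$TOP2A[2], exprs$MKI67[2], ctx1)$score
    p2 <- proliferationScore(exprs$TOP2A[2] * k, exprs$MKI67[2] * k,
                             ctx2)$score
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

# Ct values encoding a target expression at 18S Ct 12
ct_for <- function(expr) 12 - log2(expr)

panel_mss <- function(cdh1 = 200, cdkn1a = 10, mdm2 = 20, ...) {
  SamplePanel("S1", ct = c(CDH1 = ct_for(cdh1), CDKN1A = ct_for(cdkn1a),
                           MDM2 = ct_for(mdm2)),
              ct18s = 12, msiMarkers = mk_markers(0), ...)
}

test_that("ACRG tree: MSI first, then CDH1-low EMT, then TP53 split", {
  ctx <- ctx_at(cdkn1a = 10, mdm2 = 20)
  msi_panel <- SamplePanel("S0", ct = c(CDH1 = ct_for(10)), ct18s = 12,
                           msiMarkers = mk_markers(3))
  expect_equal(classifyACRG(msi_panel, ctx), "MSI")
  expect_equal(classifyACRG(panel_mss(cdh1 = 10), ctx), "MSS_EMT")
  # CDH1 = 100, CDKN1A at 2.1x median -> score 3.1
  expect_equal(classifyACRG(panel_mss(cdh1 = 100, cdkn1a = 21), ctx),
               "MSS_TP53_POS")
  expect_equal(classifyACRG(panel_mss(cdh1 = 100, cdkn1a = 5, mdm2 = 10),
                            ctx), "MSS_TP53_NEG")
  # missing RNA -> unclassified
  no_rna <- SamplePanel("S2", ct = numeric(), ct18s = NA,
                        msiMarkers = mk_markers(0))
  expect_equal(classifyACRG(no_rna, ctx), "UNCLASSIFIED")
})

test_that("TCGA tree: MSI precedence, EBV by load, GS/CIN by SCNA", {
  expect_equal(classifyTCGA("MSI", 5000), "MSI")
  expect_equal(classifyTCGA("MSS", 5000), "EBV")
  expect_equal(classifyTCGA("MSS", 0.2, scnaCount = 13), "GS")
  expect_equal(classifyTCGA("MSS", 0.2, scnaCount = 15), "GS")
  expect_equal(classifyTCGA("MSS", 0.2, scnaCount = 16), "CIN")
  expect_equal(classifyTCGA("MSS", 0.2), "MSS_UNRESOLVED")
})

test_that("decision trees are total: every panel maps to exactly one label", {
  sim <- simulateCohort(40, seed = 101, ctSigma = 0.3)
  calls <- subtypeCohort(sim$panels)
  expect_equal(nrow(calls), 40)
  expect_true(all(calls$acrg %in% c("MSI", "MSS_EMT", "MSS_TP53_POS",
                                    "MSS_TP53_NEG", "UNCLASSIFIED")))
  expect_true(all(calls$tcga %in% c("MSI", "EBV", "GS", "CIN",
                                    "MSS_UNRESOLVED")))
  # MSI labels agree between the two trees
  expect_equal(calls$acrg == "MSI", calls$tcga == "MSI")
})
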