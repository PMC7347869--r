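mk_series <- function(af, depth) {
  stages <- c("P0", "P1", "P2", "P3", "PDX")[seq_len(ncol(af))]
  colnames(af) <- stages
  colnames(depth) <- stages
  rownames(af) <- rownames(depth) <- sprintf("1:%d:A>T", seq_len(nrow(af)))
  PassageSeries("M1", af, depth)
}

test_that("trajectories require >=10x coverage at every stage", {
  af <- rbind(c(0.5, 0.5, 0.5, 0.5, 0.5),
              c(0.4, 0.4, 0.4, 0.4, 0.4))
  dp <- rbind(rep(150, 5), c(150, 150, 9, 150, 150))
  s <- mk_series(af, dp)
  expect_message(tr <- buildTrajectories(s), "excluded")
  expect_equal(nrow(tr$af), 1)
  expect_equal(tr$nExcluded, 1)
  # absent at P0 but covered: enters with AF 0
  vsP0 <- VariantSet(data.frame(chrom = "1", pos = 1, ref = "A", alt = "T",
                                depth = 100, alt_support = 50))
  vsP1 <- VariantSet(data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "T",
                                depth = 100, alt_support = c(50, 40)))
  sd_mat <- matrix(100, 2, 2,
                   dimnames = list(c("1:1:A>T", "1:2:A>T"), c("P0", "P1")))
  ser <- buildPassageSeries("M2", list(P0 = vsP0, P1 = vsP1),
                            siteDepths = sd_mat)
  tr2 <- buildTrajectories(ser)
  expect_equal(nrow(tr2$af), 2)
  expect_equal(unname(tr2$af["1:2:A>T", "P0"]), 0)
  expect_error(buildPassageSeries("M3", list(P0 = vsP0)), "2 stages")
})

test_that("trajectory classes follow the three clonal behaviours", {
  expect_equal(classifyTrajectory(c(0.5, 0.5, 0.5, 0.5, 0.5)), "stable")
  expect_equal(classifyTrajectory(c(0.02, 0.48, 0.50, 0.51, 0.49)),
               "selected_at_P1")
  expect_equal(classifyTrajectory(c(0, 0.08, 0, 0.07, 0)), "transient")
  # disappearance after detection is transient
  expect_equal(classifyTrajectory(c(0.5, 0, 0, 0, 0)), "transient")
  expect_error(classifyTrajectory(c(0.5, 0.5)), "3")
})

test_that("noisy constant trajectories stay stable in >=99% of replicates", {
  set.seed(55)
  delta_stable <- 0.15
  n_stable <- 0
  for (i in 1:1000) {
    af <- pmin(pmax(0.5 + rnorm(5, 0, delta_stable / 4), 0), 1)
    if (classifyTrajectory(af) == "stable") n_stable <- n_stable + 1
  }
  expect_gte(n_stable, 990)
})

test_that("stromal dilution at P0 pushes trajectories toward selection", {
  base <- c(0.45, 0.5, 0.5, 0.5, 0.5)
  classes <- vapply(c(1, 0.8, 0.6, 0.4), function(purity) {
    af <- base
    af[1] <- af[1] * purity
    classifyTrajectory(af)
  }, character(1))
  # once the P0 AF is diluted enough, the class flips to selected_at_P1
  expect_equal(classes[1], "stable")
  expect_equal(classes[4], "selected_at_P1")
  sel <- classes == "selected_at_P1"
  expect_false(any(diff(sel) < 0))  # monotone in the dilution
})

test_that("AF banding picks the MAD-minimizing band set", {
  expect_equal(detectAfBanding(c(0.01, 0.49, 0.52, 0.99, 0.5))$label,
               "two_allele_normal")
  expect_equal(detectAfBanding(c(0.02, 0.01, 0.97, 0.99, 0.98))$label,
               "loh")
  expect_equal(detectAfBanding(c(0.01, 0.32, 0.34, 0.66, 0.67, 0.99))$label,
               "copy_gain")
  expect_equal(detectAfBanding(c(0.24, 0.26, 0.74, 0.76, 0.5))$label,
               "copy_gain")
  expect_equal(detectAfBanding(c(0.5, 0.5))$label, "undetermined")
})

test_that("banding equals the brute-force MAD minimizer on random windows", {
  set.seed(77)
  for (i in 1:300) {
    n <- sample(5:30, 1)
    afs <- runif(n)
    expect_equal(detectAfBanding(afs)$label, bruteBandingLabel(afs))
  }
})

test_that("stage clustering puts the divergent stage as outgroup", {
  # P0 divergent, P1..PDX identical
  set.seed(9)
  af <- matrix(0, 40, 5)
  af[1:20, 1] <- 0.5                      # P0-private variants
  af[21:40, 2:5] <- 0.5                   # selected variants, shared P1..PDX
  dp <- matrix(150, 40, 5)
  s <- mk_series(af, dp)
  cl <- clusterStages(s)
  hc <- cl$hclust
  # P0 merges last: its merge height is the maximum
  heights_with_p0 <- hc$height[apply(hc$merge, 1, function(m)
    any(m < 0 & hc$labels[abs(m[m < 0])] == "P0"))]
  expect_equal(max(hc$height), max(heights_with_p0))
  expect_match(cl$newick, "P0")
  # two stages: a single merge
  s2 <- mk_series(af[, 1:2], dp[, 1:2])
  expect_equal(length(clusterStages(s2)$hclust$height), 1)
  # identical profiles: all merge heights zero
  af3 <- matrix(0.5, 10, 3)
  s3 <- mk_series(af3, matrix(150, 10, 3))
  expect_true(all(clusterStages(s3)$hclust$height == 0))
})

test_that("ddPCR fraction: exact low-occupancy ratio and symmetry", {
  expect_equal(ddpcrFraction(10, 9990, 1e6)$fraction, 0.001)
  expect_equal(ddpcrFraction(500, 500, 1e5)$fraction, 0.5)
  z <- ddpcrFraction(0, 5000, 1e5)
  expect_equal(z$fraction, 0)
  expect_false(z$detected)
  expect_true(is.na(ddpcrFraction(0, 0, 1e5)$fraction))
})

test_that("Poisson occupancy correction kicks in above 10% occupancy", {
  N <- 1e5
  k_mut <- 200
  k_wt <- 40000  # 40% occupancy: uncorrected ratio is biased
  got <- ddpcrFraction(k_mut, k_wt, N)
  lam_wt <- -log(1 - k_wt / N) * N
  expect_equal(got$fraction, k_mut / (k_mut + lam_wt), tolerance = 1e-12)
  expect_lt(got$fraction, k_mut / (k_mut + k_wt))  # correction lowers it
})

test_that("simulated droplets at 0.1% MAF are recovered within 3 SE", {
  d <- simulateDroplets(0.001, 1e5, seed = 21)
  est <- ddpcrFraction(d$mutantPositive, d$wildtypePositive,
                       d$totalDroplets)
  expect_lt(abs(est$fraction - 0.001), 3 * est$se)
  # boundary truths
  d0 <- simulateDroplets(0, 1e4, seed = 22)
  expect_equal(d0$mutantPositive, 0)
  d1 <- simulateDroplets(1, 1e4, seed = 23)
  expect_equal(d1$wildtypePositive, 0)
})
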