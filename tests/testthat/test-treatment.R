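test_that("per-patient consensus averages replicate cores", {
  man <- data.frame(
    core_id = c("c1", "c2", "c3"), patient = c("A", "A", "B"),
    timepoint = c("pre", "pre", "on"), stringsAsFactors = FALSE
  )
  v <- matrix(c(1, 3, 7), 1, 3, dimnames = list("g", c("c1", "c2", "c3")))
  cons <- consensusPerPatient(QuantMatrix(v, "protein"), man)
  cv <- quantValues(cons)
  expect_equal(cv["g", "A_pre"], 2) # duplicate cores 1 and 3
  expect_equal(cv["g", "B_on"], 7) # single core passes through
  # random manifest equals brute-force groupby mean
  set.seed(14)
  man2 <- data.frame(
    core_id = sprintf("c%02d", 1:12),
    patient = sample(c("A", "B", "C"), 12, TRUE),
    timepoint = sample(c("pre", "on"), 12, TRUE), stringsAsFactors = FALSE
  )
  v2 <- matrix(rnorm(60), 5, 12,
    dimnames = list(sprintf("g%d", 1:5), man2$core_id))
  got <- quantValues(consensusPerPatient(QuantMatrix(v2, "protein"), man2))
  key <- paste(man2$patient, man2$timepoint, sep = "_")
  for (k in unique(key)) {
    expect_equal(got[, k], rowMeans(v2[, key == k, drop = FALSE]), info = k)
  }
  expect_error(
    consensusPerPatient(QuantMatrix(v, "protein"), man[1:2, ]), "not in manifest"
  )
})

test_that("exact signed-rank p-values match full enumeration", {
  # n = 5, all differences negative: W = 0, p = 2/32
  r <- pairedSignedRank(c(-1, -2, -3, -4, -5))
  expect_true(r$exact)
  expect_equal(r$p, 0.0625)
  # n = 7, one positive with smallest |difference|: W = 1, p = 4/128
  d7 <- c(0.5, -1, -2, -3, -4, -5, -6)
  r7 <- pairedSignedRank(d7)
  expect_equal(r7$W, 1)
  expect_equal(r7$p, 0.03125)
  # sign-flip symmetry
  expect_equal(pairedSignedRank(-d7)$p, r7$p)
  # zero differences are dropped with a message
  expect_message(rz <- pairedSignedRank(c(0, -1, -2, -3, -4)), "zero difference")
  expect_equal(rz$n, 4)
  expect_error(suppressMessages(pairedSignedRank(c(0, 1, -1))), "at least 3")
  # enumeration agrees with the independent base-R oracle for all n <= 8
  set.seed(20)
  for (n in 3:8) {
    for (rep in 1:5) {
      d <- round(rnorm(n), 4)
      while (any(d == 0) || anyDuplicated(abs(d))) d <- round(rnorm(n), 4)
      expect_equal(
        pairedSignedRank(d)$p,
        wilcox.test(d, exact = TRUE)$p.value,
        info = sprintf("n=%d rep=%d", n, rep)
      )
    }
  }
  # ties fall back to the normal approximation with a message
  expect_message(rt <- pairedSignedRank(c(1, -1, 2, -3)), "approximation")
  expect_false(rt$exact)
})

test_that("exact rank-sum p-values match full enumeration", {
  # complete separation 7 vs 3: p = 2 / choose(10, 3)
  a <- 1:7
  b <- 11:13
  r <- rankSum(a, b)
  expect_true(r$exact)
  expect_equal(r$p, 2 / choose(10, 3))
  expect_equal(signif(r$p, 2), 0.017)
  # complete separation 5 vs 15: p = 2 / choose(20, 5)
  r2 <- rankSum(101:115, 1:5)
  expect_equal(r2$p, 2 / choose(20, 5))
  expect_equal(signif(r2$p, 2), 0.00013)
  # group-swap symmetry
  expect_equal(rankSum(b, a)$p, r$p)
  # agreement with the independent base-R oracle for all nA <= 5, nB <= 7
  set.seed(33)
  for (nA in 1:5) {
    for (nB in nA:7) {
      x <- round(rnorm(nA), 4)
      y <- round(rnorm(nB), 4)
      while (anyDuplicated(c(x, y))) {
        x <- round(rnorm(nA), 4); y <- round(rnorm(nB), 4)
      }
      if (nA + nB < 4) next
      expect_equal(
        rankSum(x, y)$p,
        wilcox.test(x, y, exact = TRUE)$p.value,
        info = sprintf("nA=%d nB=%d", nA, nB)
      )
    }
  }
  expect_message(rt <- rankSum(c(1, 2, 3), c(2, 4, 5)), "approximation")
  expect_false(rt$exact)
  expect_error(rankSum(numeric(), 1:3), "non-empty")
})

test_that("moderated t absorbs plex batch offsets and flags confounding", {
  set.seed(40)
  n <- 12
  v <- matrix(rnorm(200 * n), 200, n,
    dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:n)))
  group <- rep(c("pre_pCR", "on_pCR"), each = 6)
  plex <- rep(c("p1", "p2"), times = 6)
  res <- moderatedT(QuantMatrix(v, "protein"), group, plex, "on_pCR - pre_pCR")
  # adding a constant offset to one plex changes nothing
  v2 <- v
  v2[, plex == "p2"] <- v2[, plex == "p2"] + 5
  res2 <- moderatedT(QuantMatrix(v2, "protein"), group, plex, "on_pCR - pre_pCR")
  expect_equal(res$t, res2$t, tolerance = 1e-9)
  expect_equal(res$p, res2$p, tolerance = 1e-9)
  expect_gt(attr(res, "d0"), 0)
  expect_true(all(res$adjP >= res$p))
  # plex perfectly confounded with group
  expect_error(
    moderatedT(QuantMatrix(v, "protein"), group, rep(c("p1", "p2"), each = 6),
      "on_pCR - pre_pCR"),
    "rank deficient"
  )
})

test_that("spiked features dominate the moderated-t ranking", {
  set.seed(41)
  hits <- 0
  for (rep in 1:20) {
    v <- matrix(rnorm(500 * 9, 0, 0.5), 500, 9,
      dimnames = list(sprintf("g%03d", 1:500), sprintf("s%d", 1:9)))
    spiked <- sprintf("g%03d", 1:10)
    group <- c(rep("a", 7), rep("b", 2))
    v[spiked, group == "b"] <- v[spiked, group == "b"] + 2
    res <- moderatedT(QuantMatrix(v, "protein"), group, NULL, "b - a")
    cut <- quantile(res$p, 0.05)
    hits <- hits + all(res$p[res$feature %in% spiked] <= cut)
  }
  expect_gte(hits / 20, 0.95)
})

test_that("BH adjustment reproduces the hand-computed step-up values", {
  expect_equal(bhAdjust(0.07), 0.07) # single p unchanged
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bhAdjust(rep(0.2, 4)), rep(0.2, 4))
  # order invariance
  p <- c(0.4, 0.01, 0.9, 0.03, 0.2)
  ord <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p)[ord], bhAdjust(p[ord]))
  expect_true(all(bhAdjust(p) <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("mRNA-protein correlation endpoints behave", {
  set.seed(50)
  v <- matrix(rnorm(100 * 8), 100, 8,
    dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:8)))
  rna <- QuantMatrix(v, "rna")
  protSame <- QuantMatrix(v, "protein")
  mc <- mrnaProteinCorr(rna, protSame)
  expect_equal(unname(mc$perGene), rep(1, 100))
  expect_equal(mc$median, 1)
  expect_equal(mrnaProteinCorr(rna, QuantMatrix(-v, "protein"))$median, -1)
  other <- QuantMatrix(
    matrix(rnorm(4), 2, 2, dimnames = list(c("x1", "x2"), c("a", "b"))), "protein"
  )
  expect_error(mrnaProteinCorr(rna, other), "shared")
})

test_that("replicate cores cluster together on the most-variable genes", {
  set.seed(60)
  base <- matrix(rnorm(300 * 5, 0, 2), 300, 5)
  v <- cbind(base, base + rnorm(300 * 5, 0, 0.1)) # 5 replicate pairs
  colnames(v) <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  rownames(v) <- sprintf("g%03d", 1:300)
  man <- data.frame(
    core_id = colnames(v), patient = rep(sprintf("P%d", 1:5), 2),
    timepoint = "pre", stringsAsFactors = FALSE
  )
  res <- variableGeneCluster(QuantMatrix(v, "protein"), man, k = 100)
  expect_true(all(res$replicates$adjacent))
  expect_equal(nrow(res$replicates), 5L)
  # k larger than the matrix uses all features, with a message
  expect_message(
    resAll <- variableGeneCluster(QuantMatrix(v, "protein"), man, k = 1000),
    "using all"
  )
  # deterministic for fixed input
  resB <- variableGeneCluster(QuantMatrix(v, "protein"), man, k = 100)
  expect_identical(res$replicates, resB$replicates)
})

test_that("on-treatment suppression is recovered from the generated cohort", {
  b <- smallBundle()
  man <- bundleManifest(b)
  prot <- centerScale(bundleProtein(b))
  cons <- consensusPerPatient(prot, man)
  cv <- quantValues(cons)
  tr <- bundleTruth(b)
  pcrOn <- tr$patients$patient[tr$patients$group == "pCR" & tr$patients$hasOnTreatment]
  d <- cv["ERBB2", paste0(pcrOn, "_on")] - cv["ERBB2", paste0(pcrOn, "_pre")]
  expect_equal(length(d), 7L)
  r <- pairedSignedRank(d)
  expect_lt(r$p, 0.05) # pCR ERBB2 suppression is significant
  # pCR vs non-pCR fold-change comparison via exact rank sum
  nonOn <- tr$patients$patient[tr$patients$group == "non-pCR" & tr$patients$hasOnTreatment]
  dn <- cv["ERBB2", paste0(nonOn, "_on")] - cv["ERBB2", paste0(nonOn, "_pre")]
  expect_equal(length(dn), 3L)
  rs <- rankSum(d, dn)
  expect_true(rs$exact)
  expect_lt(mean(d), 0) # suppression signal present in the pCR group
  # the deeper-suppression contrast is clean at phosphosite level, where the
  # mTOR-target spike acts only in pCR patients
  phos <- consensusPerPatient(centerScale(bundlePhosphosite(b)), man)
  pv <- quantValues(phos)
  mtor <- bundleTruth(b)$mtorSites
  dp <- colMeans(pv[mtor, paste0(pcrOn, "_on")] - pv[mtor, paste0(pcrOn, "_pre")])
  dpn <- colMeans(pv[mtor, paste0(nonOn, "_on")] - pv[mtor, paste0(nonOn, "_pre")])
  expect_lt(median(dp), median(dpn))
})
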