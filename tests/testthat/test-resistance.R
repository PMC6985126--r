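test_that("ERBB2 status rules fire as stated", {
  prof <- function(cn, z, zf = 0) {
    list(patient = "X", cnErbb2 = cn, zErbb2 = z, zFlankMean = zf)
  }
  expect_equal(erbb2Class(classifyErbb2Status(prof(0.0, -3, -2.5))), "false_pos")
  expect_equal(erbb2Class(classifyErbb2Status(prof(1.2, -2.5, -2))), "pseudo_pos")
  expect_equal(erbb2Class(classifyErbb2Status(prof(1.2, 1, 0.5))), "true_pos")
  # flanking-gene low protein alone also makes a pseudo positive
  expect_equal(erbb2Class(classifyErbb2Status(prof(1.2, -1, -2.5))), "pseudo_pos")
  # no gain, protein not low: complement rule -> true_pos
  expect_equal(erbb2Class(classifyErbb2Status(prof(0.1, 0.5))), "true_pos")
  # exactly one class for every input on a grid; evidence always recorded
  for (cn in c(-0.5, 0, 0.29, 0.3, 1, 2.5)) {
    for (z in c(-4, -2.01, -2, 0, 2)) {
      call <- classifyErbb2Status(prof(cn, z))
      expect_true(erbb2Class(call) %in% c("true_pos", "pseudo_pos", "false_pos"))
      expect_gte(length(erbb2Evidence(call)), 2L)
    }
  }
  expect_error(classifyErbb2Status(prof(NA, 1)), "non-missing")
})

test_that("amplicon classes are recovered 100% on the generated cohort", {
  b <- smallBundle()
  man <- bundleManifest(b)
  prot <- centerScale(bundleProtein(b))
  ref <- buildReference(prot, coresOf(man, "pCR", "pre"), filter = "variance")
  cn <- geneCopyNumber(bundleSegments(b), bundleGenes(b))
  profs <- ampliconProfiles(prot, cn, ref, man)
  calls <- vapply(seq_len(nrow(profs)), function(i) {
    erbb2Class(classifyErbb2Status(profs[i, ]))
  }, character(1))
  names(calls) <- profs$patient
  truth <- bundleTruth(b)$ampliconClassMap
  expect_equal(calls, truth[names(calls)])
  # spiking a true positive onto a non-pCR patient is recovered end to end
  b2 <- spikeAmpliconClass(b, "P13", "true_pos")
  prot2 <- centerScale(bundleProtein(b2))
  ref2 <- buildReference(prot2, coresOf(man, "pCR", "pre"), filter = "variance")
  cn2 <- geneCopyNumber(bundleSegments(b2), bundleGenes(b2))
  prof2 <- ampliconProfiles(prot2, cn2, ref2, bundleManifest(b2), patients = "P13")
  expect_equal(erbb2Class(classifyErbb2Status(prof2)), "true_pos")
})

test_that("amplicon group test compares genes and their arithmetic mean", {
  set.seed(70)
  genes <- c("STARD3", "ERBB2", "GRB7")
  v <- matrix(rnorm(3 * 12, 0, 0.3), 3, 12,
    dimnames = list(genes, sprintf("s%02d", 1:12)))
  gA <- sprintf("s%02d", 1:3)
  gB <- sprintf("s%02d", 4:12)
  # identical values in both groups degenerate to p = 1
  same <- matrix(1, 3, 12, dimnames = dimnames(v))
  resSame <- ampliconGroupTest(QuantMatrix(same, "protein"), gA, gB)
  expect_equal(resSame$p, rep(1, 4))
  # single-gene set: the mean test equals that gene's test
  res1 <- ampliconGroupTest(QuantMatrix(v, "protein"), gA, gB, genes = "ERBB2")
  expect_equal(res1$p[res1$gene == "mean"], res1$p[res1$gene == "ERBB2"])
  # spiked -1.5 shift in group A is detected in >= 90% of replicates
  hits <- 0
  nRep <- 30
  for (i in seq_len(nRep)) {
    vi <- matrix(rnorm(3 * 12, 0, 0.3), 3, 12, dimnames = dimnames(v))
    vi[, gA] <- vi[, gA] - 1.5
    res <- ampliconGroupTest(QuantMatrix(vi, "protein"), gA, gB)
    hits <- hits + (res$p[res$gene == "mean"] < 0.05)
  }
  expect_gte(hits / nRep, 0.9)
  expect_error(ampliconGroupTest(QuantMatrix(v, "protein"), gA[1], gB), "at least 2")
})

test_that("mucin panel flags patients with >= 2 elevated panel genes", {
  z <- rbind(
    MUC4 = c(3, 0, -1),
    MUC6 = c(4, 2.5, 0),
    MUC5AC = c(0, 0, 1)
  )
  colnames(z) <- c("q1", "q2", "q3")
  out <- new("OutlierResult", z = z, eligible = c(MUC4 = TRUE, MUC6 = TRUE, MUC5AC = TRUE))
  res <- mucinPanel(out, c("MUC4", "MUC6", "MUC5AC"))
  expect_true(res$flagged[res$sample == "q1"])
  expect_equal(res$genes[res$sample == "q1"], "MUC4;MUC6")
  expect_false(res$flagged[res$sample == "q2"]) # one gene is not enough
  expect_false(res$flagged[res$sample == "q3"])
  expect_error(mucinPanel(out, character()), "non-empty")
  expect_error(mucinPanel(out, c("MUC4", "NOPE")), "absent")
})

test_that("the generated mucin outlier patient is flagged with its genes", {
  b <- smallBundle()
  man <- bundleManifest(b)
  prot <- centerScale(bundleProtein(b))
  ref <- buildReference(prot, coresOf(man, "pCR", "pre"), filter = "variance")
  out <- zscoreOutliers(prot, ref, coresOf(man, "non-pCR", "pre"))
  tr <- bundleTruth(b)
  res <- mucinPanel(out, tr$mucinGenes)
  mpCore <- man$core_id[man$patient == tr$mucinPatient & man$timepoint == "pre"][1]
  expect_true(res$flagged[res$sample == mpCore])
  expect_gte(res$nElevated[res$sample == mpCore], 2)
  others <- res$sample != mpCore
  expect_false(any(res$flagged[others]))
})

test_that("literature tally implements the query and the >100-gene exclusion", {
  cit <- data.frame(
    pub_id = c("p1", "p2", "p3", "p4", "p5"),
    text_blob = c(
      "Trastuzumab Resistance in breast cancer",
      "recurrence in lung cancer", # no breast cancer
      "RECURRENT disease in Breast Cancer", # case-insensitive
      "biomarkers in breast cancer", # no resist/recur
      "chemoresistance in BREAST CANCER" # high-throughput, excluded below
    ),
    gene_symbols = c(
      "ERBB2;MUC4", "ERBB2", "ERBB2", "MUC4",
      paste(sprintf("G%03d", 1:101), collapse = ";")
    ),
    stringsAsFactors = FALSE
  )
  tally <- literatureTally(cit, c("ERBB2", "MUC4", "G001"))
  expect_equal(unname(tally["ERBB2"]), 2L)
  expect_equal(unname(tally["MUC4"]), 1L)
  expect_equal(unname(tally["G001"]), 0L) # >100 associations excluded
  # exactly 100 associations is retained
  cit100 <- data.frame(
    pub_id = "q", text_blob = "resist breast cancer",
    gene_symbols = paste(sprintf("G%03d", 1:100), collapse = ";"),
    stringsAsFactors = FALSE
  )
  expect_equal(unname(literatureTally(cit100, "G001")["G001"]), 1L)
  # additive over disjoint lists; order invariant
  t1 <- literatureTally(cit[1:2, ], c("ERBB2", "MUC4"))
  t2 <- literatureTally(cit[3:5, ], c("ERBB2", "MUC4"))
  expect_equal(t1 + t2, tally[c("ERBB2", "MUC4")])
  expect_equal(literatureTally(cit[5:1, ], c("ERBB2", "MUC4")), tally[c("ERBB2", "MUC4")])
  expect_equal(unname(literatureTally(cit[0, ], "ERBB2")["ERBB2"]), 0L)
})
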