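makePsm <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    psm_id = sprintf("p%03d", seq_len(n)),
    feature_id = sample(sprintf("F%02d", 1:8), n, TRUE),
    plex = 1L,
    label_state = sample(c("full", "partial", "none"), n, TRUE, c(0.8, 0.1, 0.1)),
    precursor_purity = round(runif(n), 2),
    delta_fr_score = round(rnorm(n), 2),
    ch01 = 2^rnorm(n, 10), ch02 = 2^rnorm(n, 10), ch03 = 2^rnorm(n, 10),
    stringsAsFactors = FALSE
  )
}

test_that("PSM filtering applies the three exclusion rules with exact boundaries", {
  base <- data.frame(
    label_state = "full", precursor_purity = 0.9, delta_fr_score = 1
  )
  atPurity <- function(p) transform(base, precursor_purity = p)
  expect_equal(nrow(filterPsms(atPurity(0.49))), 0L) # < 50% excluded
  expect_equal(nrow(filterPsms(atPurity(0.50))), 1L) # boundary retained
  expect_equal(nrow(filterPsms(transform(base, delta_fr_score = -0.01))), 0L)
  expect_equal(nrow(filterPsms(transform(base, delta_fr_score = 0))), 1L)
  expect_equal(nrow(filterPsms(transform(base, label_state = "none"))), 0L)
  expect_equal(nrow(filterPsms(transform(base, label_state = "partial"))), 1L)

  # compliant table passes unchanged; idempotent; subset of input
  psm <- makePsm(200)
  once <- filterPsms(psm)
  expect_identical(filterPsms(once), once)
  expect_true(all(once$psm_id %in% psm$psm_id))
  compliant <- psm[psm$label_state != "none" & psm$precursor_purity >= 0.5 &
    psm$delta_fr_score >= 0, ]
  expect_identical(once, compliant)
  # independent per-rule recount
  nViol <- sum(psm$label_state == "none" | psm$precursor_purity < 0.5 |
    psm$delta_fr_score < 0)
  expect_equal(nrow(once), nrow(psm) - nViol)
  expect_equal(nrow(filterPsms(psm[0, ])), 0L)
})

test_that("reference normalization is log2 ratio with missing-safe edges", {
  expect_equal(referenceNormalize(5, 5), 0)
  expect_equal(referenceNormalize(10, 5), 1)
  expect_true(is.na(referenceNormalize(0, 5))) # zero never becomes -Inf
  expect_warning(out <- referenceNormalize(5, 0), "common-reference")
  expect_true(is.na(out))
  expect_true(is.na(suppressWarnings(referenceNormalize(5, NA))))
})

test_that("PSM rollup takes the median linear ratio then log2", {
  man <- data.frame(
    core_id = c("S1", "S2", "CR_1"), patient = c("A", "B", "CR"),
    timepoint = c("pre", "pre", NA), group = c("pCR", "pCR", NA),
    plex = 1L, channel = c("ch01", "ch02", "ch03"), stringsAsFactors = FALSE
  )
  one <- data.frame(
    psm_id = "p1", feature_id = "F1", plex = 1L,
    ch01 = 200, ch02 = 50, ch03 = 100, stringsAsFactors = FALSE
  )
  qm <- rollupPsms(one, man)
  expect_equal(quantValues(qm)["F1", "S1"], 1) # 2x CR
  expect_equal(quantValues(qm)["F1", "S2"], -1)

  three <- data.frame(
    psm_id = c("p1", "p2", "p3"), feature_id = "F1", plex = 1L,
    ch01 = c(100, 200, 400), ch02 = 100, ch03 = 100, stringsAsFactors = FALSE
  )
  expect_equal(quantValues(rollupPsms(three, man))["F1", "S1"], 1) # median(1,2,4)=2

  # random table vs brute-force groupby-median oracle; PSM-order invariance
  psm <- makePsm(120, seed = 5)
  qm <- rollupPsms(psm, man)
  for (f in unique(psm$feature_id)) {
    sub <- psm[psm$feature_id == f, ]
    expect_equal(
      quantValues(qm)[f, "S1"], log2(median(sub$ch01 / sub$ch03)),
      info = f
    )
  }
  shuf <- psm[sample(nrow(psm)), ]
  expect_equal(quantValues(rollupPsms(shuf, man)), quantValues(qm))
})

test_that("median/MAD sample scaling has its stated postconditions", {
  set.seed(3)
  v <- matrix(rnorm(600), 100, 6,
    dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  shifts <- c(-2, 0, 1, 3, -1, 5)
  scales <- c(0.5, 1, 2, 4, 1.5, 3)
  v <- sweep(sweep(v, 2, scales, "*"), 2, shifts, "+")
  v[sample(length(v), 40)] <- NA
  qm <- QuantMatrix(v, "protein")
  out <- centerScale(qm)
  ov <- quantValues(out)
  expect_equal(unname(apply(ov, 2, median, na.rm = TRUE)), rep(0, 6))
  expect_equal(unname(apply(ov, 2, mad, na.rm = TRUE)), rep(1, 6), tolerance = 1e-9)
  # recovered shifts/scales equal directly computed column medians/MADs
  expect_equal(
    unname((v[, 3] - median(v[, 3], na.rm = TRUE)) / mad(v[, 3], na.rm = TRUE)),
    unname(ov[, 3])
  )
  # idempotent, missing mask preserved, rank order preserved per column
  expect_equal(quantValues(centerScale(out)), ov)
  expect_identical(is.na(ov), is.na(v))
  expect_equal(order(ov[!is.na(ov[, 1]), 1]), order(v[!is.na(v[, 1]), 1]))

  const <- QuantMatrix(
    matrix(c(1, 1, 1, 2, 3, 4), 3, 2, dimnames = list(letters[1:3], c("flat", "ok"))),
    "protein"
  )
  expect_error(centerScale(const), "flat")
})

test_that("upper-quartile RNA normalization removes zeros and matches its oracle", {
  set.seed(8)
  counts <- matrix(rpois(300, 60), 50, 6,
    dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:6)))
  counts[3, ] <- 0 # all-zero gene
  counts[10, 2] <- 0 # sporadic zero
  qm <- upperQuartileNormalize(counts)
  expect_equal(quantLevel(qm), "rna")
  v <- quantValues(qm)
  expect_false("g03" %in% rownames(v))
  expect_true(is.na(v["g10", "s2"]))
  # brute-force per-column 75th-percentile division
  nz <- counts[rowSums(counts) > 0, ]
  nz[nz == 0] <- NA
  uq <- quantile(nz[, 4], 0.75, na.rm = TRUE)
  expect_equal(v[, "s4"], log2(nz[, 4] / uq * 1000))
  # constant column: all values identical after normalization
  cc <- matrix(c(7, 7, 7), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(unname(quantValues(upperQuartileNormalize(cc))[, 1]), rep(log2(1000), 3))
  allz <- matrix(0, 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  expect_error(upperQuartileNormalize(allz))
  expect_error(upperQuartileNormalize(-cc), "non-negative")
})

test_that("tumor-content gate averages slides with an inclusive 50% boundary", {
  g <- gateTumorContent(c(60, 60, 40, 40))
  expect_equal(g$avgTC, 50)
  expect_true(g$pass) # strictly "<50%" fails, so exactly 50 passes
  expect_false(gateTumorContent(c(0, 0, 0))$pass)
  expect_error(gateTumorContent(numeric()), "no slide")
  expect_error(gateTumorContent(c(50, 120)), "0, 100")
  # 19 enrolled, exactly 5 below the gate -> 14 analyzable
  set.seed(21)
  tcs <- c(
    replicate(14, runif(4, 55, 90), simplify = FALSE),
    replicate(5, runif(4, 10, 45), simplify = FALSE)
  )
  passes <- vapply(tcs, function(x) gateTumorContent(x)$pass, logical(1))
  expect_equal(sum(passes), 14L)
})

test_that("labeling QC gates use strict 'over' thresholds and name channels", {
  man <- data.frame(
    core_id = c("S1", "S2", "CR_1"), patient = c("A", "B", "CR"),
    timepoint = c("pre", "pre", NA), group = c("pCR", "pCR", NA),
    plex = 1L, channel = c("ch01", "ch02", "ch03"), stringsAsFactors = FALSE
  )
  mkPsm <- function(nPartial, nNone, total = 1000, ch01Scale = 1) {
    data.frame(
      psm_id = seq_len(total), feature_id = "F1", plex = 1L,
      label_state = c(
        rep("none", nNone), rep("partial", nPartial),
        rep("full", total - nNone - nPartial)
      ),
      precursor_purity = 0.9, delta_fr_score = 1,
      ch01 = 100 * ch01Scale, ch02 = 100, ch03 = 100, stringsAsFactors = FALSE
    )
  }
  ok <- checkLabelingQc(mkPsm(nPartial = 45, nNone = 5), man) # 99.5 / 95.0
  expect_true(ok@pass)
  # partial exactly 99.0 fails: "over 99%" is strict
  boundary <- checkLabelingQc(mkPsm(nPartial = 40, nNone = 10), man)
  expect_false(boundary@pass)
  expect_match(boundary@failedChannels, "partial", all = FALSE)
  # one channel at -20% deviation fails, channel named
  mix <- checkLabelingQc(mkPsm(45, 5, ch01Scale = 0.8), man)
  expect_false(mix@pass)
  expect_match(mix@failedChannels, "ch01", all = FALSE)
  expect_error(checkLabelingQc(mkPsm(1, 1)[0, ], man), "empty")
})

test_that("a clean generated bundle passes all QC gates end to end", {
  b <- smallBundle()
  man <- bundleManifest(b)
  qc <- checkLabelingQc(bundlePsm(b), man)
  expect_true(qc@pass)
  slides <- bundleSlides(b)
  passes <- vapply(split(slides$tumorContent, slides$core_id),
    function(x) gateTumorContent(x)$pass, logical(1))
  expect_true(all(passes))
})
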