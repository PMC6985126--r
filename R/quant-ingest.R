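#' Filter PSMs on TMT label state, precursor purity and delta forward-reverse score
#'
#' Retains exactly the peptide-spectrum matches with a TMT label (partial or
#' full), precursor ion purity of at least 50%, and a non-negative delta
#' forward-reverse score. The purity boundary is inclusive: the exclusion rule
#' is strictly "purity < 50%". Idempotent; the output is a subset of the
#' input.
#'
#' @param psms data.frame with columns `label_state` (`"none"`, `"partial"`,
#'   `"full"`), `precursor_purity` (in \[0, 1\]) and `delta_fr_score`.
#' @return the retained rows of `psms`.
#' @export
filterPsms <- function(psms) {
  need <- c("label_state", "precursor_purity", "delta_fr_score")
  miss <- setdiff(need, names(psms))
  if (length(miss)) stop(sprintf("psm table lacks column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(psms) == 0L) return(psms)
  keep <- psms$label_state != "none" &
    psms$precursor_purity >= 0.5 &
    psms$delta_fr_score >= 0
  psms[keep, , drop = FALSE]
}

#' Common-reference ratio on log2 scale
#'
#' `log2(intensity / crIntensity)`. Zero or missing intensities never produce
#' infinities: a non-positive or missing numerator or reference yields `NA`
#' (with a warning when the reference itself is unusable).
#'
#' @param intensity reporter-ion intensity (vectorized).
#' @param crIntensity common-reference channel intensity (recycled).
#' @return log2 ratio, `NA` where undefined.
#' @export
referenceNormalize <- function(intensity, crIntensity) {
  n <- max(length(intensity), length(crIntensity))
  intensity <- rep_len(as.numeric(intensity), n)
  crIntensity <- rep_len(as.numeric(crIntensity), n)
  badCr <- is.na(crIntensity) | crIntensity <= 0
  if (any(badCr)) {
    warning(sprintf("%d value(s) with missing or non-positive common-reference intensity set to NA", sum(badCr)))
  }
  out <- rep(NA_real_, n)
  ok <- !badCr & !is.na(intensity) & intensity > 0
  out[ok] <- log2(intensity[ok] / crIntensity[ok])
  out
}

#' Roll up filtered PSMs to protein or phosphosite ratios
#'
#' Per feature and channel, the value is the median over PSMs of the
#' linear-scale ratio of the channel intensity to the common-reference
#' intensity of the same PSM, reported on log2 scale (medians are taken on
#' linear ratios, then log2-transformed). Features with no PSM in a plex are
#' missing for that plex's samples. Permutation-invariant in PSM order.
#'
#' @param psms filtered PSM table (see [filterPsms()]) with `feature_id`,
#'   `plex` and one intensity column per channel (`ch01`, ...).
#' @param manifest sample manifest mapping (`plex`, `channel`) to `core_id`;
#'   rows with `patient == "CR"` mark the common-reference channel of each
#'   plex.
#' @param level `"protein"` or `"phosphosite"`.
#' @return a [QuantMatrix-class] of log2 common-reference ratios.
#' @export
rollupPsms <- function(psms, manifest, level = c("protein", "phosphosite")) {
  level <- match.arg(level)
  features <- sort(unique(psms$feature_id))
  smp <- manifest[manifest$patient != "CR", , drop = FALSE]
  out <- matrix(NA_real_, length(features), nrow(smp),
    dimnames = list(features, smp$core_id))
  for (k in sort(unique(smp$plex))) {
    crCh <- manifest$channel[manifest$patient == "CR" & manifest$plex == k]
    if (length(crCh) != 1L) {
      stop(sprintf("plex %s must have exactly one common-reference channel", k))
    }
    pk <- psms[psms$plex == k, , drop = FALSE]
    if (nrow(pk) == 0L) next
    mk <- smp[smp$plex == k, , drop = FALSE]
    cr <- pk[[crCh]]
    for (j in seq_len(nrow(mk))) {
      ratio <- pk[[mk$channel[j]]] / cr
      med <- vapply(split(ratio, pk$feature_id), stats::median, numeric(1), na.rm = TRUE)
      med[!is.finite(med) | med <= 0] <- NA_real_
      out[names(med), mk$core_id[j]] <- log2(med)
    }
  }
  QuantMatrix(out, level)
}

#' Median-center and MAD-scale each sample
#'
#' Per column: subtract the median and divide by the median absolute
#' deviation scaled by the consistency constant 1.4826 (so the scaled MAD
#' estimates the SD under normality), over non-missing values. Idempotent and
#' rank-preserving per column; the missing mask is preserved.
#'
#' @param m a [QuantMatrix-class].
#' @return the normalized [QuantMatrix-class].
#' @export
centerScale <- function(m) {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  nOk <- colSums(!is.na(v))
  if (any(nOk < 2L)) {
    stop(sprintf(
      "column(s) with fewer than 2 non-missing values: %s",
      paste(colnames(v)[nOk < 2L], collapse = ", ")
    ))
  }
  med <- .colMedians(v)
  madv <- vapply(seq_len(ncol(v)), function(j) {
    stats::mad(v[, j], constant = 1.4826, na.rm = TRUE)
  }, numeric(1))
  if (any(madv == 0)) {
    stop(sprintf(
      "zero MAD in sample(s): %s", paste(colnames(v)[madv == 0], collapse = ", ")
    ))
  }
  out <- sweep(sweep(v, 2L, med, "-"), 2L, madv, "/")
  qm <- m
  SummarizedExperiment::assay(qm, "ratio") <- out
  qm
}

#' Upper-quartile normalize an RNA count matrix
#'
#' Zeros are treated as missing; genes with zero counts in every sample are
#' removed. Each column is divided by the 75th percentile of its non-zero
#' values and rescaled by a fixed constant (default 1000), then
#' log2-transformed (no pseudocount is needed because zeros are already
#' missing).
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @param scaleConstant fixed rescaling constant applied after upper-quartile
#'   division.
#' @param log2Transform return log2 values (default) or linear.
#' @return a [QuantMatrix-class] with level `"rna"`.
#' @export
upperQuartileNormalize <- function(counts, scaleConstant = 1000, log2Transform = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  counts[counts == 0] <- NA_real_
  allZero <- rowSums(!is.na(counts)) == 0L
  counts <- counts[!allZero, , drop = FALSE]
  uq <- apply(counts, 2L, stats::quantile, probs = 0.75, na.rm = TRUE)
  if (any(is.na(uq))) {
    stop(sprintf(
      "sample(s) with no non-zero counts: %s",
      paste(colnames(counts)[is.na(uq)], collapse = ", ")
    ))
  }
  norm <- sweep(counts, 2L, uq, "/") * scaleConstant
  if (log2Transform) norm <- log2(norm)
  QuantMatrix(norm, "rna")
}

#' Average tumor content gate
#'
#' `avgTC` is the arithmetic mean of the per-slide tumor-content percentages
#' of one core; the core passes iff `avgTC >= 50` (the exclusion rule is
#' strictly "< 50%", so exactly 50 passes).
#'
#' @param slideTcs numeric vector of per-slide tumor-content percentages.
#' @return list with `avgTC` and logical `pass`.
#' @export
gateTumorContent <- function(slideTcs) {
  if (length(slideTcs) == 0L) stop("no slide tumor-content values supplied")
  if (any(is.na(slideTcs)) || any(slideTcs < 0) || any(slideTcs > 100)) {
    stop("slide tumor-content values must lie in [0, 100]")
  }
  avgTC <- mean(slideTcs)
  list(avgTC = avgTC, pass = avgTC >= 50)
}

#' TMT labeling-efficiency and mixing-ratio QC
#'
#' Partial-label efficiency is the percentage of PSMs with at least a partial
#' TMT label; full-label efficiency the percentage fully labeled; the mixing
#' deviation of a channel is `|median(channel / CR) - 1| * 100` over PSMs of
#' its plex. The plex set passes iff partial > 99, full > 94 and every
#' channel deviation is within 15% (boundaries strict for the label gates, as
#' "over 99%" / "over 94%" demand).
#'
#' @param psms PSM table (unfiltered; efficiency is a property of the whole
#'   experiment).
#' @param manifest sample manifest as in [rollupPsms()].
#' @param mixingTolerancePct mixing-ratio tolerance, percent (default 15).
#' @return a [QcReport-class].
#' @export
checkLabelingQc <- function(psms, manifest, mixingTolerancePct = 15) {
  if (nrow(psms) == 0L) stop("psm table is empty")
  partial <- 100 * mean(psms$label_state != "none")
  full <- 100 * mean(psms$label_state == "full")
  smp <- manifest[manifest$patient != "CR", , drop = FALSE]
  devs <- numeric(0)
  for (k in sort(unique(smp$plex))) {
    crCh <- manifest$channel[manifest$patient == "CR" & manifest$plex == k]
    pk <- psms[psms$plex == k, , drop = FALSE]
    mk <- smp[smp$plex == k, , drop = FALSE]
    for (j in seq_len(nrow(mk))) {
      md <- stats::median(pk[[mk$channel[j]]] / pk[[crCh]], na.rm = TRUE)
      devs[sprintf("plex%d.%s", k, mk$channel[j])] <- abs(md - 1) * 100
    }
  }
  failed <- character(0)
  if (!(partial > 99)) failed <- c(failed, sprintf("partial label %.2f%% (need > 99)", partial))
  if (!(full > 94)) failed <- c(failed, sprintf("full label %.2f%% (need > 94)", full))
  over <- devs > mixingTolerancePct
  if (any(over)) {
    failed <- c(failed, sprintf(
      "mixing deviation > %g%% in %s", mixingTolerancePct,
      paste(names(devs)[over], collapse = ", ")
    ))
  }
  new("QcReport",
    partialLabelPct = partial, fullLabelPct = full,
    mixingDeviationPct = devs, failedChannels = failed,
    pass = length(failed) == 0L
  )
}
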