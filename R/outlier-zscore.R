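#' Build a per-feature reference distribution from pCR baseline samples
#'
#' For each feature, computes mean, sample SD, variance and a Shapiro-Wilk
#' normality p-value over the pre-treatment pCR reference samples. A feature
#' is eligible for outlier Z-scoring when its reference variance is at least
#' `varMin` (default 1.5) and the Shapiro-Wilk test does not reject normality
#' at level `alpha`; removal on either ground is the conservative reading
#' that keeps only features satisfying both model assumptions
#' (`filter = "both"`); `"variance"` / `"normality"` apply a single gate.
#'
#' @param m a [QuantMatrix-class].
#' @param refSamples column names of the reference (pCR baseline) samples;
#'   at least 3 (Shapiro-Wilk minimum).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @param varMin variance eligibility threshold (default 1.5).
#' @param filter which gates to apply.
#' @return a [ReferenceDistribution-class].
#' @export
buildReference <- function(m, refSamples, alpha = 0.05, varMin = 1.5,
                           filter = c("both", "variance", "normality")) {
  stopifnot(is(m, "QuantMatrix"))
  filter <- match.arg(filter)
  v <- quantValues(m)
  miss <- setdiff(refSamples, colnames(v))
  if (length(miss)) stop(sprintf("unknown reference sample(s): %s", paste(miss, collapse = ", ")))
  if (length(refSamples) < 3L) {
    stop("at least 3 reference samples are required (Shapiro-Wilk minimum)")
  }
  ref <- v[, refSamples, drop = FALSE]
  mu <- rowMeans(ref, na.rm = TRUE)
  vr <- .rowVars(ref)
  sw <- apply(ref, 1L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 3L || length(unique(x)) == 1L) return(NA_real_)
    stats::shapiro.test(x)$p.value
  })
  passVar <- !is.na(vr) & vr >= varMin
  passNorm <- !is.na(sw) & sw >= alpha
  eligible <- switch(filter,
    both = passVar & passNorm,
    variance = passVar,
    normality = passNorm
  )
  st <- data.frame(
    mean = mu, sd = sqrt(vr), variance = vr, shapiro_p = sw,
    eligible = eligible, row.names = rownames(v)
  )
  new("ReferenceDistribution",
    stats = st, samples = as.character(refSamples),
    alpha = if (filter == "variance") 0 else alpha,
    varMin = if (filter == "normality") -Inf else varMin
  )
}

#' Z-scores of query samples against a reference distribution
#'
#' `Z = (x - mean) / sd` per feature for eligible features; ineligible
#' features are missing. Query samples must be disjoint from the reference
#' set (leakage guard); the guard can be disabled to verify the
#' self-normalization property (reference samples scored against their own
#' reference have per-feature mean Z ~ 0 and SD ~ 1).
#'
#' @param m a [QuantMatrix-class] containing the query samples.
#' @param ref a [ReferenceDistribution-class] built from disjoint samples.
#' @param querySamples column names of the (non-pCR baseline) query samples.
#' @param allowOverlap disable the leakage guard (tests only).
#' @return an [OutlierResult-class].
#' @export
zscoreOutliers <- function(m, ref, querySamples, allowOverlap = FALSE) {
  stopifnot(is(m, "QuantMatrix"), is(ref, "ReferenceDistribution"))
  v <- quantValues(m)
  miss <- setdiff(querySamples, colnames(v))
  if (length(miss)) stop(sprintf("unknown query sample(s): %s", paste(miss, collapse = ", ")))
  leak <- intersect(querySamples, ref@samples)
  if (length(leak) && !allowOverlap) {
    stop(sprintf(
      "query sample(s) present in the reference set: %s", paste(leak, collapse = ", ")
    ))
  }
  st <- ref@stats
  shared <- intersect(rownames(v), rownames(st))
  q <- v[shared, querySamples, drop = FALSE]
  z <- (q - st[shared, "mean"]) / st[shared, "sd"]
  elig <- st[shared, "eligible"]
  z[!elig, ] <- NA_real_
  new("OutlierResult", z = z, eligible = structure(elig, names = shared))
}

#' Roll phosphosite values up to phosphoprotein level
#'
#' Per protein and sample, the mean over that protein's sites' non-missing
#' values.
#'
#' @param m a [QuantMatrix-class] at phosphosite level; the protein mapping
#'   is taken from `rowData(m)$protein` unless `proteins` is given.
#' @param proteins optional character vector mapping each site (row) to its
#'   protein.
#' @return a [QuantMatrix-class] with level `"phosphoprotein"`.
#' @export
rollupPhosphoprotein <- function(m, proteins = NULL) {
  stopifnot(is(m, "QuantMatrix"))
  if (is.null(proteins)) proteins <- rowData(m)$protein
  if (is.null(proteins) || length(proteins) != nrow(m)) {
    stop("a protein mapping of length nrow(m) is required")
  }
  unmapped <- rownames(m)[is.na(proteins) | proteins == ""]
  if (length(unmapped)) {
    stop(sprintf("site(s) without protein mapping: %s", paste(unmapped, collapse = ", ")))
  }
  v <- quantValues(m)
  groups <- split(seq_len(nrow(v)), proteins)
  out <- t(vapply(groups, function(idx) {
    colMeans(v[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(v))))
  out[is.nan(out)] <- NA_real_
  colnames(out) <- colnames(v)
  QuantMatrix(out, "phosphoprotein")
}
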