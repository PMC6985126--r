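#' Per-patient consensus over replicate cores
#'
#' Averages replicate cores per patient and timepoint (mean over non-missing
#' values), yielding one column per `patient_timepoint`.
#'
#' @param m a [QuantMatrix-class] with core columns.
#' @param manifest manifest data.frame mapping `core_id` to `patient` and
#'   `timepoint`.
#' @return a [QuantMatrix-class] with columns `<patient>_<timepoint>`.
#' @export
consensusPerPatient <- function(m, manifest) {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  idx <- match(colnames(v), manifest$core_id)
  if (any(is.na(idx))) {
    stop(sprintf(
      "core(s) not in manifest: %s", paste(colnames(v)[is.na(idx)], collapse = ", ")
    ))
  }
  key <- paste(manifest$patient[idx], manifest$timepoint[idx], sep = "_")
  groups <- split(seq_len(ncol(v)), key)
  out <- matrix(NA_real_, nrow(v), length(groups),
    dimnames = list(rownames(v), names(groups)))
  for (g in seq_along(groups)) {
    out[, g] <- rowMeans(v[, groups[[g]], drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  qm <- QuantMatrix(out, quantLevel(m))
  qm
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided p-value for the signed-rank statistic of paired differences.
#' Zero differences are dropped before ranking (classical convention; a
#' message reports the count). For n <= `exactMax` untied absolute
#' differences the p-value is exact, from the full null distribution of the
#' positive-rank sum over all 2^n sign patterns (computed by convolution);
#' ties in |difference| fall back to the mid-rank normal approximation with
#' tie correction.
#'
#' @param differences numeric vector of paired differences (on - pre).
#' @param exactMax largest n for which the exact null is enumerated.
#' @return list with `p` (two-sided), `W` (positive-rank sum), `n` (pairs
#'   used) and `exact` flag.
#' @export
pairedSignedRank <- function(differences, exactMax = 25L) {
  d <- differences[!is.na(differences)]
  nZero <- sum(d == 0)
  if (nZero) {
    message(sprintf("dropping %d zero difference(s)", nZero))
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < 3L) stop("at least 3 non-zero paired differences are required")
  tied <- anyDuplicated(abs(d)) > 0L
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (!tied && n <= exactMax) {
    # null distribution of W by convolution over ranks 1..n
    counts <- rep(0, n * (n + 1) / 2 + 1)
    counts[1] <- 1
    for (k in seq_len(n)) {
      shifted <- c(rep(0, k), counts)[seq_along(counts)]
      counts <- counts + shifted
    }
    total <- 2^n
    lower <- sum(counts[seq_len(W + 1)]) / total
    upper <- sum(counts[(W + 1):length(counts)]) / total
    p <- min(1, 2 * min(lower, upper))
    return(list(p = p, W = W, n = n, exact = TRUE))
  }
  message("ties in |differences| or large n: using normal approximation")
  mu <- n * (n + 1) / 4
  tieTab <- table(r)
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tieTab^3 - tieTab) / 48)
  z <- (W - mu - sign(W - mu) * 0.5) / sig
  list(p = min(1, 2 * stats::pnorm(-abs(z))), W = W, n = n, exact = FALSE)
}

#' Exact Wilcoxon rank-sum test
#'
#' Two-sided p-value for the rank-sum statistic of two independent groups.
#' Without cross-group ties and when `choose(nA+nB, min(nA, nB))` does not
#' exceed `maxEnumeration`, the p-value is exact, by enumeration of all rank
#' assignments of the smaller group; otherwise the mid-rank normal
#' approximation with tie correction is used (with a message). Symmetric in
#' the two groups.
#'
#' @param groupA,groupB numeric vectors, both non-empty.
#' @param maxEnumeration largest number of rank assignments enumerated.
#' @return list with `p` (two-sided), `W` (rank sum of the smaller group),
#'   and `exact` flag.
#' @export
rankSum <- function(groupA, groupB, maxEnumeration = 2e5) {
  a <- groupA[!is.na(groupA)]
  b <- groupB[!is.na(groupB)]
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  swapped <- length(b) < length(a)
  if (swapped) {
    tmp <- a; a <- b; b <- tmp
  }
  nA <- length(a); nB <- length(b); N <- nA + nB
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(nA)])
  tied <- anyDuplicated(pooled) > 0L
  if (!tied && choose(N, nA) <= maxEnumeration) {
    combos <- utils::combn(N, nA)
    sums <- colSums(combos)
    lower <- mean(sums <= W)
    upper <- mean(sums >= W)
    p <- min(1, 2 * min(lower, upper))
    return(list(p = p, W = W, exact = TRUE))
  }
  message("ties across groups or large design: using normal approximation")
  mu <- nA * (N + 1) / 2
  tieTab <- table(r)
  sig <- sqrt(nA * nB / 12 * ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1))))
  z <- (W - mu - sign(W - mu) * 0.5) / sig
  list(p = min(1, 2 * stats::pnorm(-abs(z))), W = W, exact = FALSE)
}

#' Moderated-t differential analysis with group and plex coefficients
#'
#' Fits each feature to a linear model with a coefficient for each
#' group-by-timepoint cell and each TMT plex (batch), then computes
#' empirical-Bayes moderated t-statistics for the requested contrasts:
#' residual variances are shrunk toward a prior variance s0^2 with prior
#' degrees of freedom d0 estimated by moment matching on the distribution of
#' log residual variances, and the moderated t uses d0 + residual df. The
#' fitting and shrinkage are delegated to limma (lmFit / contrasts.fit /
#' eBayes).
#'
#' @param m a [QuantMatrix-class] (features x samples).
#' @param group factor-like vector per sample (e.g.
#'   `"pre_pCR"`, `"on_pCR"`, `"pre_nonpCR"`, `"on_nonpCR"`).
#' @param plex optional factor-like vector per sample of plex labels; a
#'   single level is dropped.
#' @param contrasts character vector of contrast expressions in terms of the
#'   group levels, e.g. `"on_pCR - pre_pCR"`.
#' @return data.frame per feature x contrast: `feature`, `contrast`,
#'   `logFC`, `t`, `p`, `adjP`, `s2Post`, with the prior df `d0` and prior
#'   variance `s02` as attributes.
#' @export
moderatedT <- function(m, group, plex = NULL, contrasts) {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  group <- factor(group)
  if (length(group) != ncol(v)) stop("'group' must have one entry per sample")
  if (!is.null(plex)) {
    plex <- factor(plex)
    if (nlevels(plex) < 2L) plex <- NULL
  }
  if (is.null(plex)) {
    design <- stats::model.matrix(~ 0 + group)
    colnames(design) <- levels(group)
  } else {
    design <- stats::model.matrix(~ 0 + group + plex)
    colnames(design) <- c(levels(group), paste0("plex", levels(plex)[-1L]))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop(sprintf("design is rank deficient; confounded coefficient(s): %s",
      paste(drop, collapse = ", ")))
  }
  fit <- limma::lmFit(v, design)
  cm <- limma::makeContrasts(contrasts = contrasts, levels = design)
  fit2 <- limma::eBayes(limma::contrasts.fit(fit, cm))
  rows <- list()
  for (cn in colnames(cm)) {
    p <- fit2$p.value[, cn]
    rows[[cn]] <- data.frame(
      feature = rownames(v), contrast = cn,
      logFC = fit2$coefficients[, cn], t = fit2$t[, cn],
      p = p, adjP = bhAdjust(p), s2Post = fit2$s2.post,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "d0") <- unname(fit2$df.prior[1])
  attr(out, "s02") <- unname(fit2$s2.prior[1])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment, monotone and capped at 1; invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene mRNA-protein Spearman correlation
#'
#' For genes shared between the two matrices, computes the Spearman
#' correlation across shared samples (complete pairs; at least `minShared`
#' pairs required per gene) and the cohort median across genes.
#'
#' @param rna a [QuantMatrix-class] (level `"rna"`).
#' @param protein a [QuantMatrix-class] (level `"protein"`).
#' @param minShared minimum complete pairs per gene (default 3).
#' @return list with `perGene` (named vector, NA where too few pairs) and
#'   `median`.
#' @export
mrnaProteinCorr <- function(rna, protein, minShared = 3L) {
  vr <- quantValues(rna)
  vp <- quantValues(protein)
  genes <- intersect(rownames(vr), rownames(vp))
  samples <- intersect(colnames(vr), colnames(vp))
  if (length(genes) == 0L) stop("no shared genes between RNA and protein matrices")
  if (length(samples) < minShared) stop("fewer shared samples than 'minShared'")
  vr <- vr[genes, samples, drop = FALSE]
  vp <- vp[genes, samples, drop = FALSE]
  rho <- vapply(seq_along(genes), function(i) {
    ok <- !is.na(vr[i, ]) & !is.na(vp[i, ])
    if (sum(ok) < minShared) return(NA_real_)
    stats::cor(vr[i, ok], vp[i, ok], method = "spearman")
  }, numeric(1))
  names(rho) <- genes
  list(perGene = rho, median = stats::median(rho, na.rm = TRUE))
}

#' Cluster samples on the most-variable features and report replicate adjacency
#'
#' Selects the `k` most-variable features, clusters samples by average
#' linkage on correlation distance (1 - Pearson correlation over pairwise
#' complete values), and reports for each replicate pair (cores sharing
#' patient and timepoint) whether the two cores join each other (in
#' cophenetic distance) before either joins any non-replicate sample.
#'
#' @param m a [QuantMatrix-class].
#' @param manifest manifest with `core_id`, `patient`, `timepoint`.
#' @param k number of most-variable features (default 500; capped at the
#'   feature count with a message).
#' @return list with `hclust`, and `replicates` (data.frame `patient`,
#'   `timepoint`, `core1`, `core2`, `adjacent`).
#' @export
variableGeneCluster <- function(m, manifest, k = 500L) {
  stopifnot(is(m, "QuantMatrix"))
  v <- quantValues(m)
  if (ncol(v) < 2L) stop("at least 2 samples are required")
  if (k > nrow(v)) {
    message(sprintf("k = %d exceeds feature count %d: using all features", k, nrow(v)))
    k <- nrow(v)
  }
  vars <- .rowVars(v)
  top <- order(vars, decreasing = TRUE)[seq_len(k)]
  cc <- stats::cor(v[top, , drop = FALSE], use = "pairwise.complete.obs")
  hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
  coph <- as.matrix(stats::cophenetic(hc))
  idx <- match(colnames(v), manifest$core_id)
  key <- paste(manifest$patient[idx], manifest$timepoint[idx], sep = "_")
  reps <- list()
  for (g in unique(key[duplicated(key)])) {
    cols <- which(key == g)
    pair <- utils::combn(cols, 2L)
    for (j in seq_len(ncol(pair))) {
      c1 <- pair[1, j]; c2 <- pair[2, j]
      others <- setdiff(seq_len(ncol(v)), cols)
      adjacent <- coph[c1, c2] < min(coph[c1, others], coph[c2, others])
      reps[[length(reps) + 1L]] <- data.frame(
        patient = manifest$patient[idx[c1]],
        timepoint = manifest$timepoint[idx[c1]],
        core1 = colnames(v)[c1], core2 = colnames(v)[c2],
        adjacent = adjacent, stringsAsFactors = FALSE
      )
    }
  }
  list(
    hclust = hc,
    replicates = if (length(reps)) do.call(rbind, reps) else
      data.frame(patient = character(), timepoint = character(),
        core1 = character(), core2 = character(), adjacent = logical())
  )
}
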