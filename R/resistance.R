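#' Multi-omic amplicon profiles for ERBB2 status classification
#'
#' Assembles, per patient, the gene-level copy-number log2 for ERBB2 and the
#' flanking amplicon genes (STARD3, PGAP3, GRB7) together with protein
#' Z-scores against the pCR reference. Z-scores here are computed directly
#' from the reference mean/SD for every amplicon gene, regardless of the
#' genome-wide eligibility flag: eligibility gates unbiased outlier
#' discovery, not targeted interrogation of a locus of known interest.
#' Multiple cores per patient are averaged before Z-scoring.
#'
#' @param protein a [QuantMatrix-class] of protein log2 ratios (cores).
#' @param cn a [QuantMatrix-class] of gene-level copy number (level
#'   `"cna-gene"`, per patient).
#' @param ref a [ReferenceDistribution-class] built from pCR baseline cores.
#' @param manifest manifest mapping cores to patients/timepoints.
#' @param patients patients to profile (default: all non-reference patients
#'   with a pre-treatment core).
#' @return data.frame per patient: `patient`, `cnErbb2`, `zErbb2`,
#'   `zFlankMean`.
#' @export
ampliconProfiles <- function(protein, cn, ref, manifest, patients = NULL) {
  stopifnot(is(protein, "QuantMatrix"), is(cn, "QuantMatrix"),
    is(ref, "ReferenceDistribution"))
  vp <- quantValues(protein)
  vc <- quantValues(cn)
  st <- referenceStats(ref)
  flank <- c("STARD3", "PGAP3", "GRB7")
  pre <- manifest[manifest$timepoint %in% "pre" & manifest$patient != "CR", , drop = FALSE]
  if (is.null(patients)) patients <- unique(pre$patient)
  rows <- lapply(patients, function(p) {
    cores <- intersect(pre$core_id[pre$patient == p], colnames(vp))
    if (length(cores) == 0L) stop(sprintf("no pre-treatment core for patient %s", p))
    cons <- rowMeans(vp[, cores, drop = FALSE], na.rm = TRUE)
    z <- (cons - st$mean) / st$sd
    names(z) <- rownames(st)
    if (!("ERBB2" %in% names(z)) || is.na(z[["ERBB2"]]) ||
      !("ERBB2" %in% rownames(vc)) || is.na(vc["ERBB2", p])) {
      stop(sprintf("missing ERBB2 copy-number or protein value for patient %s", p))
    }
    data.frame(
      patient = p, cnErbb2 = vc["ERBB2", p], zErbb2 = unname(z[["ERBB2"]]),
      zFlankMean = mean(z[intersect(flank, names(z))], na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Classify ERBB2 amplicon status from a multi-omic profile
#'
#' Decision rules: `false_pos` iff copy-number log2 below `cnGainMin` and
#' protein Z below `zLow` (no amplification, low protein despite the
#' clinical positive call); `pseudo_pos` iff copy-number gain is present but
#' ERBB2 protein Z (or the mean flanking-gene protein Z) is below `zLow`
#' (gain without focal overexpression); otherwise `true_pos`. Every
#' comparison is recorded as evidence.
#'
#' @param profile one-row data.frame (or list) with `patient`, `cnErbb2`,
#'   `zErbb2`, `zFlankMean` as from [ampliconProfiles()].
#' @param cnGainMin copy-number log2 gain threshold (default 0.3).
#' @param zLow low-protein Z threshold (default -2).
#' @return an [Erbb2Call-class].
#' @export
classifyErbb2Status <- function(profile, cnGainMin = 0.3, zLow = -2) {
  need <- c("patient", "cnErbb2", "zErbb2")
  if (!all(need %in% names(profile)) ||
    is.na(profile[["cnErbb2"]]) || is.na(profile[["zErbb2"]])) {
    stop("profile must carry non-missing ERBB2 copy-number and protein Z values")
  }
  cn <- profile[["cnErbb2"]]
  z <- profile[["zErbb2"]]
  zf <- if ("zFlankMean" %in% names(profile)) profile[["zFlankMean"]] else NA_real_
  evidence <- c(
    sprintf("ERBB2 CN log2 = %.3f vs gain threshold %.3f (%s)", cn, cnGainMin,
      if (cn >= cnGainMin) "gain" else "no gain"),
    sprintf("ERBB2 protein Z = %.3f vs low threshold %.3f (%s)", z, zLow,
      if (z < zLow) "low" else "not low")
  )
  if (!is.na(zf)) {
    evidence <- c(evidence, sprintf(
      "flanking-gene mean protein Z = %.3f vs low threshold %.3f (%s)",
      zf, zLow, if (zf < zLow) "low" else "not low"
    ))
  }
  cls <- if (cn < cnGainMin && z < zLow) {
    "false_pos"
  } else if (cn >= cnGainMin && (z < zLow || (!is.na(zf) && zf < zLow))) {
    "pseudo_pos"
  } else {
    "true_pos"
  }
  new("Erbb2Call",
    patient = as.character(profile[["patient"]]), status = cls,
    evidence = evidence)
}

#' Two-sample t-tests on amplicon genes and their arithmetic mean
#'
#' Per sample, the arithmetic mean of the amplicon genes' protein log
#' ratios; Welch two-sample t-tests compare the two groups on this mean and
#' on each gene separately. With identical values in both groups the test
#' degenerates to t = 0, p = 1.
#'
#' @param protein a [QuantMatrix-class] of protein log2 ratios.
#' @param groupA,groupB column names of the two groups (each >= 2 samples).
#' @param genes amplicon core genes (default STARD3, ERBB2, GRB7).
#' @return data.frame: `gene` (first row `"mean"`), `t`, `df`, `p`.
#' @export
ampliconGroupTest <- function(protein, groupA, groupB,
                              genes = c("STARD3", "ERBB2", "GRB7")) {
  stopifnot(is(protein, "QuantMatrix"))
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("each group needs at least 2 samples")
  }
  v <- quantValues(protein)
  missG <- setdiff(genes, rownames(v))
  if (length(missG)) stop(sprintf("gene(s) absent from matrix: %s", paste(missG, collapse = ", ")))
  welch <- function(a, b) {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(unique(c(a, b))) == 1L) {
      return(list(statistic = 0, parameter = length(a) + length(b) - 2, p.value = 1))
    }
    tt <- stats::t.test(a, b)
    list(statistic = unname(tt$statistic), parameter = unname(tt$parameter),
      p.value = tt$p.value)
  }
  meanA <- colMeans(v[genes, groupA, drop = FALSE], na.rm = TRUE)
  meanB <- colMeans(v[genes, groupB, drop = FALSE], na.rm = TRUE)
  rows <- list()
  tt <- welch(meanA, meanB)
  rows[[1]] <- data.frame(gene = "mean", t = tt$statistic, df = tt$parameter,
    p = tt$p.value, stringsAsFactors = FALSE)
  for (g in genes) {
    tt <- welch(v[g, groupA], v[g, groupB])
    rows[[length(rows) + 1L]] <- data.frame(gene = g, t = tt$statistic,
      df = tt$parameter, p = tt$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mucin-panel outlier flags per patient
#'
#' Per query sample, lists the panel genes with Z at or above `zHigh`; the
#' sample is flagged when at least `minGenes` panel genes are elevated
#' (default 2, so a single elevated gene never flags).
#'
#' @param outliers an [OutlierResult-class].
#' @param panel mucin panel gene symbols (non-empty, present in the Z
#'   matrix).
#' @param zHigh elevation threshold (default 2).
#' @param minGenes minimum number of elevated panel genes to flag.
#' @return data.frame: `sample`, `nElevated`, `genes`
#'   (semicolon-separated), `flagged`.
#' @export
mucinPanel <- function(outliers, panel, zHigh = 2, minGenes = 2L) {
  stopifnot(is(outliers, "OutlierResult"))
  if (length(panel) == 0L) stop("'panel' must be non-empty")
  z <- outlierZ(outliers)
  missG <- setdiff(panel, rownames(z))
  if (length(missG)) {
    stop(sprintf("panel gene(s) absent from Z matrix: %s", paste(missG, collapse = ", ")))
  }
  rows <- lapply(colnames(z), function(s) {
    zi <- z[panel, s]
    hit <- panel[!is.na(zi) & zi >= zHigh]
    data.frame(
      sample = s, nElevated = length(hit),
      genes = paste(hit, collapse = ";"),
      flagged = length(hit) >= minGenes, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Tally literature associations with resistance/recurrence in breast cancer
#'
#' A publication qualifies iff its text contains (substring "resist" OR
#' substring "recur") AND substring "breast cancer", case-insensitively, and
#' it is associated with at most 100 distinct genes (records with over 100
#' gene associations are excluded as high-throughput noise; exactly 100 is
#' retained). Each qualifying publication increments the count of every
#' associated queried gene. Additive over disjoint citation lists and
#' invariant to publication order.
#'
#' @param citations data.frame with `pub_id`, `text_blob`, `gene_symbols`
#'   (semicolon-separated), e.g. from [generateCitationFixture()].
#' @param genes gene symbols to tally.
#' @return named integer vector of per-gene qualifying publication counts.
#' @export
literatureTally <- function(citations, genes) {
  counts <- structure(integer(length(genes)), names = genes)
  if (nrow(citations) == 0L) return(counts)
  text <- tolower(citations$text_blob)
  qualifies <- (grepl("resist", text, fixed = TRUE) |
    grepl("recur", text, fixed = TRUE)) &
    grepl("breast cancer", text, fixed = TRUE)
  geneLists <- strsplit(citations$gene_symbols, ";", fixed = TRUE)
  for (i in which(qualifies)) {
    assoc <- unique(geneLists[[i]])
    if (length(assoc) > 100L) next
    hit <- intersect(assoc, genes)
    counts[hit] <- counts[hit] + 1L
  }
  counts
}
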