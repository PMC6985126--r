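#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps pintersect
#' @importFrom IRanges IRanges
NULL

.QUANT_LEVELS <- c("protein", "phosphosite", "phosphoprotein", "rna", "cna-gene")

#' QuantMatrix: a features-by-samples quantification matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' single assay `"ratio"` of log2 common-reference ratios (or normalized RNA,
#' or gene-level copy number) plus a feature-level tag. Missing values are
#' `NA` throughout; the class never stores infinities.
#'
#' @slot level one of `"protein"`, `"phosphosite"`, `"phosphoprotein"`,
#'   `"rna"`, `"cna-gene"`.
#' @export
setClass("QuantMatrix",
  contains = "SummarizedExperiment",
  representation(level = "character")
)

setValidity("QuantMatrix", function(object) {
  msg <- NULL
  if (length(object@level) != 1L || !(object@level %in% .QUANT_LEVELS)) {
    msg <- c(msg, sprintf(
      "'level' must be one of: %s", paste(.QUANT_LEVELS, collapse = ", ")
    ))
  }
  if (!"ratio" %in% names(assays(object))) {
    msg <- c(msg, "assay 'ratio' is required")
  } else {
    m <- assay(object, "ratio")
    if (!is.numeric(m)) msg <- c(msg, "assay 'ratio' must be numeric")
    if (any(is.infinite(m))) msg <- c(msg, "assay 'ratio' must not contain infinities")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a QuantMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns. Row and
#'   column names are required (feature and sample identifiers).
#' @param level feature level tag; see [QuantMatrix-class].
#' @param rowData optional `DataFrame`/`data.frame` of feature annotation
#'   (e.g. `protein`, `flank`, `localized` for phosphosites).
#' @param colData optional sample annotation.
#' @return a [QuantMatrix-class] object.
#' @export
QuantMatrix <- function(values, level, rowData = NULL, colData = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have feature rownames and sample colnames")
  }
  args <- list(assays = list(ratio = values))
  if (!is.null(rowData)) args$rowData <- rowData
  if (!is.null(colData)) args$colData <- colData
  se <- do.call(SummarizedExperiment, args)
  new("QuantMatrix", se, level = level)
}

#' @describeIn QuantMatrix the feature-level tag of a QuantMatrix.
#' @param x a `QuantMatrix`.
#' @export
quantLevel <- function(x) {
  stopifnot(is(x, "QuantMatrix"))
  x@level
}

#' @describeIn QuantMatrix the quantification values as a plain matrix.
#' @export
quantValues <- function(x) {
  stopifnot(is(x, "QuantMatrix"))
  assay(x, "ratio")
}

setMethod("show", "QuantMatrix", function(object) {
  cat(sprintf(
    "QuantMatrix [%s]: %d features x %d samples (%.1f%% missing)\n",
    object@level, nrow(object), ncol(object),
    100 * mean(is.na(assay(object, "ratio")))
  ))
  callNextMethod()
})

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Holds the stated study design as generator parameters: cohort size and pCR
#' fraction, feature counts, TMT plex geometry, replicate plan, per-patient
#' ERBB2-amplicon truth classes, effect sizes, the target per-gene
#' mRNA-protein correlation, noise level and the master seed.
#'
#' @export
setClass("CohortConfig", representation(
  nPatients = "integer",
  pcrFraction = "numeric",
  nGenes = "integer",
  nPhosphosites = "integer",
  plexSize = "integer",
  replicatePlan = "data.frame",
  ampliconClassMap = "character",
  effectSizes = "list",
  mrnaProteinRho = "numeric",
  noiseSd = "numeric",
  psmViolationRates = "list",
  nPsmGenes = "integer",
  seed = "integer"
))

setValidity("CohortConfig", function(object) {
  msg <- NULL
  if (object@nPatients < 2L) msg <- c(msg, "invalid 'nPatients': must be >= 2")
  if (object@pcrFraction < 0 || object@pcrFraction > 1) {
    msg <- c(msg, "invalid 'pcrFraction': must lie in [0, 1]")
  }
  if (object@nGenes < 50L) msg <- c(msg, "invalid 'nGenes': must be >= 50")
  if (object@nPhosphosites < 10L) msg <- c(msg, "invalid 'nPhosphosites': must be >= 10")
  if (!(object@plexSize %in% c(10L, 11L))) {
    msg <- c(msg, "invalid 'plexSize': TMT plexes have 10 or 11 channels")
  }
  if (object@noiseSd <= 0) msg <- c(msg, "invalid 'noiseSd': must be > 0")
  if (object@mrnaProteinRho <= 0 || object@mrnaProteinRho >= 1) {
    msg <- c(msg, "invalid 'mrnaProteinRho': must lie in (0, 1)")
  }
  patients <- .patientIds(object@nPatients)
  if (!all(names(object@ampliconClassMap) %in% patients)) {
    msg <- c(msg, "invalid 'ampliconClassMap': unknown patient id")
  }
  if (!all(object@ampliconClassMap %in% c("true_pos", "pseudo_pos", "false_pos"))) {
    msg <- c(msg, "invalid 'ampliconClassMap': classes must be true_pos/pseudo_pos/false_pos")
  }
  needEff <- c(
    "cnGainMean", "cnGainSd", "cnGainMin", "proteinDoseCoef", "rnaDoseCoef",
    "erbb2LowShift", "onTreatErbb2", "onTreatMtor", "nonPcrOnTreatFactor",
    "mucinShift"
  )
  missEff <- setdiff(needEff, names(object@effectSizes))
  if (length(missEff)) {
    msg <- c(msg, sprintf("invalid 'effectSizes': missing %s", paste(missEff, collapse = ", ")))
  }
  if (!all(c("patient", "timepoint", "nCores") %in% names(object@replicatePlan))) {
    msg <- c(msg, "invalid 'replicatePlan': needs columns patient, timepoint, nCores")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(
    "CohortConfig: %d patients (pCR fraction %.2f), %d genes, %d phosphosites, TMT%d, seed %d\n",
    object@nPatients, object@pcrFraction, object@nGenes,
    object@nPhosphosites, object@plexSize, object@seed
  ))
})

#' CohortBundle: one complete synthetic study
#'
#' Everything one run of the generator produces: sample manifest, PSM table,
#' protein / phosphosite / RNA matrices, copy-number segments and integer
#' calls, tumor-content slide records, a citation fixture and the ground-truth
#' labels for every spiked effect.
#'
#' @export
setClass("CohortBundle", representation(
  config = "CohortConfig",
  manifest = "data.frame",
  psm = "data.frame",
  protein = "QuantMatrix",
  phosphosite = "QuantMatrix",
  rnaCounts = "matrix",
  segments = "GRanges",
  genes = "GRanges",
  integerCalls = "matrix",
  slides = "data.frame",
  citations = "data.frame",
  truth = "list"
))

setMethod("show", "CohortBundle", function(object) {
  man <- object@manifest
  smp <- man[man$patient != "CR", , drop = FALSE]
  cat(sprintf(
    "CohortBundle: %d patients, %d cores, %d plexes (seed %d)\n",
    length(unique(smp$patient)), nrow(smp),
    length(unique(smp$plex)), object@config@seed
  ))
  cat(sprintf(
    "  protein %d x %d; phosphosite %d x %d; rna %d x %d; segments %d\n",
    nrow(object@protein), ncol(object@protein),
    nrow(object@phosphosite), ncol(object@phosphosite),
    nrow(object@rnaCounts), ncol(object@rnaCounts), length(object@segments)
  ))
})

#' Accessors for CohortBundle components
#'
#' @param x a [CohortBundle-class].
#' @name bundle-accessors
NULL

#' @rdname bundle-accessors
#' @export
bundleManifest <- function(x) x@manifest
#' @rdname bundle-accessors
#' @export
bundleProtein <- function(x) x@protein
#' @rdname bundle-accessors
#' @export
bundlePhosphosite <- function(x) x@phosphosite
#' @rdname bundle-accessors
#' @export
bundleRnaCounts <- function(x) x@rnaCounts
#' @rdname bundle-accessors
#' @export
bundleSegments <- function(x) x@segments
#' @rdname bundle-accessors
#' @export
bundleGenes <- function(x) x@genes
#' @rdname bundle-accessors
#' @export
bundlePsm <- function(x) x@psm
#' @rdname bundle-accessors
#' @export
bundleTruth <- function(x) x@truth
#' @rdname bundle-accessors
#' @export
bundleSlides <- function(x) x@slides
#' @rdname bundle-accessors
#' @export
bundleCitations <- function(x) x@citations
#' @rdname bundle-accessors
#' @export
bundleIntegerCalls <- function(x) x@integerCalls

#' ReferenceDistribution: per-feature reference statistics
#'
#' Mean, SD, variance, Shapiro-Wilk p and an eligibility flag per feature,
#' derived from the pre-treatment pCR baseline samples. A feature is eligible
#' when its reference variance is at least `varMin` and the Shapiro-Wilk test
#' does not reject normality at level `alpha`.
#'
#' @export
setClass("ReferenceDistribution", representation(
  stats = "data.frame",
  samples = "character",
  alpha = "numeric",
  varMin = "numeric"
))

setValidity("ReferenceDistribution", function(object) {
  msg <- NULL
  need <- c("mean", "sd", "variance", "shapiro_p", "eligible")
  if (!all(need %in% names(object@stats))) {
    msg <- c(msg, sprintf("stats needs columns %s", paste(need, collapse = ", ")))
  } else {
    if (any(object@stats$sd < 0, na.rm = TRUE)) msg <- c(msg, "sd must be >= 0")
    el <- object@stats$eligible
    ok <- !el | (object@stats$variance >= object@varMin &
      (is.na(object@stats$shapiro_p) | object@stats$shapiro_p >= object@alpha))
    if (!all(ok)) msg <- c(msg, "eligible features must satisfy variance and normality gates")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "ReferenceDistribution", function(object) {
  cat(sprintf(
    "ReferenceDistribution: %d features from %d reference samples; %d eligible (var >= %.2g, Shapiro alpha %.2g)\n",
    nrow(object@stats), length(object@samples),
    sum(object@stats$eligible), object@varMin, object@alpha
  ))
})

#' @describeIn ReferenceDistribution per-feature statistics as a data.frame.
#' @param x a `ReferenceDistribution`.
#' @export
referenceStats <- function(x) x@stats

#' OutlierResult: Z-scores of query samples against a reference
#'
#' @slot z feature x query-sample matrix of Z-scores; `NA` where the feature
#'   failed the reference eligibility gates.
#' @slot eligible per-feature eligibility used for masking.
#' @export
setClass("OutlierResult", representation(
  z = "matrix",
  eligible = "logical"
))

setMethod("show", "OutlierResult", function(object) {
  cat(sprintf(
    "OutlierResult: %d features x %d query samples; %d eligible features\n",
    nrow(object@z), ncol(object@z), sum(object@eligible)
  ))
})

#' @describeIn OutlierResult the Z-score matrix.
#' @param x an `OutlierResult`.
#' @export
outlierZ <- function(x) x@z
#' @describeIn OutlierResult the per-feature eligibility mask.
#' @export
outlierEligible <- function(x) x@eligible

#' QcReport: TMT labeling-efficiency and mixing QC
#'
#' @export
setClass("QcReport", representation(
  partialLabelPct = "numeric",
  fullLabelPct = "numeric",
  mixingDeviationPct = "numeric",
  failedChannels = "character",
  pass = "logical"
))

setMethod("show", "QcReport", function(object) {
  cat(sprintf(
    "QcReport: partial label %.2f%% (>99 required), full label %.2f%% (>94 required)\n",
    object@partialLabelPct, object@fullLabelPct
  ))
  cat(sprintf(
    "  worst mixing deviation %.1f%% (<=15 required); %s\n",
    max(object@mixingDeviationPct),
    if (object@pass) "PASS" else paste("FAIL:", paste(object@failedChannels, collapse = ", "))
  ))
})

#' Erbb2Call: multi-omic ERBB2 amplicon status of one patient
#'
#' @slot patient patient identifier.
#' @slot status one of `true_pos`, `pseudo_pos`, `false_pos`.
#' @slot evidence one string per rule comparison.
#' @export
setClass("Erbb2Call", representation(
  patient = "character",
  status = "character",
  evidence = "character"
))

setValidity("Erbb2Call", function(object) {
  msg <- NULL
  if (length(object@status) != 1L ||
    !(object@status %in% c("true_pos", "pseudo_pos", "false_pos"))) {
    msg <- c(msg, "status must be exactly one of true_pos/pseudo_pos/false_pos")
  }
  if (length(object@evidence) == 0L) msg <- c(msg, "evidence must be non-empty")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "Erbb2Call", function(object) {
  cat(sprintf("Erbb2Call: %s -> %s\n", object@patient, object@status))
  for (e in object@evidence) cat("  ", e, "\n")
})

#' @describeIn Erbb2Call the assigned class label.
#' @param x an `Erbb2Call`.
#' @export
erbb2Class <- function(x) x@status
#' @describeIn Erbb2Call the evidence trail (one string per rule comparison).
#' @export
erbb2Evidence <- function(x) x@evidence
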