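#' Build a synthetic cohort configuration
#'
#' The defaults state the emulated study design: 14 patients of whom 9 reach
#' pathological complete response (pCR), pre-treatment cores for all patients,
#' on-treatment cores for 10 (7 pCR, 3 non-pCR), duplicate cores in four
#' patients and triplicate pre-treatment cores in one (35 cores total), TMT
#' 11-plexes with one pooled common-reference channel, and a target median
#' per-gene mRNA-protein Spearman correlation of 0.38.
#'
#' @param nPatients number of patients (>= 2).
#' @param pcrFraction fraction of patients with pCR; the default gives 9/14.
#' @param nGenes number of genes (includes the 19 designated amplicon /
#'   pathway / mucin genes).
#' @param nPhosphosites number of phosphosites.
#' @param plexSize TMT channels per plex (10 or 11); one channel is the
#'   common reference.
#' @param replicatePlan data.frame with columns `patient`, `timepoint`
#'   (`"pre"`/`"on"`), `nCores`; `NULL` uses the default 35-core plan.
#' @param ampliconClassMap named character vector patient -> one of
#'   `"true_pos"`, `"pseudo_pos"`, `"false_pos"`; `NULL` uses the default
#'   (all true positive except one false positive and two pseudo positives
#'   among the non-pCR patients).
#' @param effectSizes named list of spike magnitudes; partial lists are
#'   merged over the defaults. `cnGainMean`/`cnGainSd`/`cnGainMin`
#'   parameterize the (left-truncated normal) focal ERBB2-amplicon copy-number
#'   log2 gain; `proteinDoseCoef` and `rnaDoseCoef` convert copy number into
#'   expression; `erbb2LowShift` is the low-protein shift of pseudo/false
#'   positives; `onTreatErbb2`/`onTreatMtor` are the pCR on-treatment log2
#'   fold changes of ERBB2 protein+sites and mTOR-target phosphosites;
#'   `nonPcrOnTreatFactor` attenuates them in non-pCR patients; `mucinShift`
#'   is the mucin-panel protein outlier spike.
#' @param mrnaProteinRho target per-gene Spearman correlation between RNA and
#'   protein.
#' @param noiseSd per-core measurement noise SD (log2).
#' @param psmViolationRates named list: `none`, `partial` (TMT label states),
#'   `lowPurity`, `negDeltaFr`.
#' @param nPsmGenes number of genes represented in the PSM-level table.
#' @param seed master seed; the bundle is fully determined by the config.
#' @return a [CohortConfig-class].
#' @export
cohortConfig <- function(nPatients = 14L, pcrFraction = 9 / 14,
                         nGenes = 2500L, nPhosphosites = 1200L,
                         plexSize = 11L, replicatePlan = NULL,
                         ampliconClassMap = NULL, effectSizes = list(),
                         mrnaProteinRho = 0.38, noiseSd = 0.45,
                         psmViolationRates = list(), nPsmGenes = 150L,
                         seed = 1L) {
  nPatients <- as.integer(nPatients)
  defaults <- list(
    cnGainMean = 1.5, cnGainSd = 1.0, cnGainMin = 0.6,
    proteinDoseCoef = 2.0, rnaDoseCoef = 1.0,
    erbb2LowShift = -3.0,
    onTreatErbb2 = -1.2, onTreatMtor = -1.0, nonPcrOnTreatFactor = 0.15,
    mucinShift = 8.0
  )
  bad <- setdiff(names(effectSizes), names(defaults))
  if (length(bad)) {
    stop(sprintf("invalid 'effectSizes': unknown effect(s) %s", paste(bad, collapse = ", ")))
  }
  defaults[names(effectSizes)] <- effectSizes
  vr <- list(none = 0.002, partial = 0.025, lowPurity = 0.01, negDeltaFr = 0.01)
  badv <- setdiff(names(psmViolationRates), names(vr))
  if (length(badv)) {
    stop(sprintf("invalid 'psmViolationRates': unknown rate(s) %s", paste(badv, collapse = ", ")))
  }
  vr[names(psmViolationRates)] <- psmViolationRates
  lapply(names(vr), function(nm) .checkFraction(vr[[nm]], paste0("psmViolationRates$", nm)))
  .checkFraction(pcrFraction, "pcrFraction")

  patients <- .patientIds(nPatients)
  nPcr <- as.integer(round(pcrFraction * nPatients))
  pcr <- patients[seq_len(nPcr)]
  nonPcr <- setdiff(patients, pcr)
  if (is.null(replicatePlan)) {
    replicatePlan <- .defaultReplicatePlan(pcr, nonPcr)
  }
  if (is.null(ampliconClassMap)) {
    ampliconClassMap <- structure(rep("true_pos", nPatients), names = patients)
    if (length(nonPcr) >= 2L) ampliconClassMap[nonPcr[2L]] <- "false_pos"
    if (length(nonPcr) >= 4L) {
      ampliconClassMap[nonPcr[seq(length(nonPcr) - 1L, length(nonPcr))]] <- "pseudo_pos"
    }
  }
  new("CohortConfig",
    nPatients = nPatients, pcrFraction = pcrFraction,
    nGenes = as.integer(nGenes), nPhosphosites = as.integer(nPhosphosites),
    plexSize = as.integer(plexSize),
    replicatePlan = replicatePlan,
    ampliconClassMap = ampliconClassMap,
    effectSizes = defaults,
    mrnaProteinRho = mrnaProteinRho, noiseSd = noiseSd,
    psmViolationRates = vr, nPsmGenes = as.integer(nPsmGenes),
    seed = as.integer(seed)
  )
}

# default 35-core plan: duplicates for the first four pCR patients (pre+on),
# triplicate pre + duplicate on for the fifth, single pre+on for the next two,
# pre only for remaining pCR; single pre+on for the first three non-pCR,
# pre only for the rest
.defaultReplicatePlan <- function(pcr, nonPcr) {
  rows <- list()
  addRow <- function(p, tp, n) rows[[length(rows) + 1L]] <<- data.frame(
    patient = p, timepoint = tp, nCores = n, stringsAsFactors = FALSE
  )
  for (i in seq_along(pcr)) {
    p <- pcr[i]
    if (i <= 4L) {
      addRow(p, "pre", 2L); addRow(p, "on", 2L)
    } else if (i == 5L) {
      addRow(p, "pre", 3L); addRow(p, "on", 2L)
    } else if (i <= 7L) {
      addRow(p, "pre", 1L); addRow(p, "on", 1L)
    } else {
      addRow(p, "pre", 1L)
    }
  }
  for (i in seq_along(nonPcr)) {
    p <- nonPcr[i]
    addRow(p, "pre", 1L)
    if (i <= 3L) addRow(p, "on", 1L)
  }
  do.call(rbind, rows)
}

#' Tumor volume from caliper measurements
#'
#' `V = 4/3 * pi * (Length/2)^2 * (Width/2)`, in mm^3 for measurements in mm.
#' Quadratic in length, linear in width.
#'
#' @param length tumor length, mm (> 0).
#' @param width tumor width, mm (> 0). Recycled against `length`.
#' @return volume in mm^3.
#' @examples
#' tumorVolume(2, 2) # 4*pi/3
#' @export
tumorVolume <- function(length, width) {
  if (!is.numeric(length) || !is.numeric(width) ||
    any(is.na(length)) || any(is.na(width)) ||
    any(length <= 0) || any(width <= 0)) {
    stop("tumor dimensions must be positive numbers")
  }
  (4 / 3) * pi * (length / 2)^2 * (width / 2)
}

#' Generate an offline citation fixture with known ground truth
#'
#' Builds publication records (`pub_id`, `text_blob`, `gene_symbols`) with
#' controlled presence of the phrases "resist", "recur" and "breast cancer"
#' (in mixed case) and controlled gene-association counts, including
#' high-throughput-style records with more than 100 associated genes. The
#' per-gene count of qualifying publications is bookkept at generation time
#' and attached as `attr(x, "truth")` so downstream tallies can be verified
#' without re-deriving truth from the data.
#'
#' @param nPubs number of publications (>= 0).
#' @param geneUniverse character vector of gene symbols to associate.
#' @param seed integer seed.
#' @param qualifyProb probability a record carries a qualifying phrase
#'   combination.
#' @param bigProb probability a record is a >100-gene high-throughput record.
#' @return data.frame with one row per publication; `gene_symbols` is a
#'   semicolon-separated list.
#' @export
generateCitationFixture <- function(nPubs, geneUniverse, seed = 1L,
                                    qualifyProb = 0.4, bigProb = 0.1) {
  if (nPubs < 0) stop("'nPubs' must be >= 0")
  if (nPubs > 0 && length(geneUniverse) == 0L) {
    stop("'geneUniverse' must be non-empty when nPubs > 0")
  }
  truth <- structure(numeric(length(geneUniverse)), names = geneUniverse)
  if (nPubs == 0L) {
    out <- data.frame(
      pub_id = character(), text_blob = character(),
      gene_symbols = character(), stringsAsFactors = FALSE
    )
    attr(out, "truth") <- truth
    return(out)
  }
  set.seed(seed)
  resistWords <- c("resist", "Resistance", "RESISTANT", "chemoresistance")
  recurWords <- c("recur", "Recurrence", "recurrent disease")
  bcWords <- c("breast cancer", "Breast Cancer", "BREAST CANCER")
  filler <- c(
    "A study of tumor biology.", "Signaling dynamics in epithelial cells.",
    "Genomic landscape of solid tumors.", "Kinase activity profiling report."
  )
  pubs <- vector("list", nPubs)
  for (i in seq_len(nPubs)) {
    qualifies <- stats::runif(1) < qualifyProb
    big <- length(geneUniverse) > 100L && stats::runif(1) < bigProb
    nGenes <- if (big) {
      sample(101:min(140L, length(geneUniverse)), 1L)
    } else {
      sample(1:min(5L, length(geneUniverse)), 1L)
    }
    genes <- sample(geneUniverse, nGenes)
    if (qualifies) {
      key <- paste(
        sample(c(resistWords, recurWords), 1L), "in", sample(bcWords, 1L)
      )
    } else {
      # near-miss distractors: phrase without disease, or disease without phrase
      key <- sample(c(
        paste(sample(c(resistWords, recurWords), 1L), "in lung cancer"),
        paste("biomarkers in", sample(bcWords, 1L))
      ), 1L)
    }
    text <- paste(sample(filler, 1L), key)
    if (qualifies && !big) truth[genes] <- truth[genes] + 1
    pubs[[i]] <- data.frame(
      pub_id = sprintf("PUB%05d", i), text_blob = text,
      gene_symbols = paste(genes, collapse = ";"), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, pubs)
  attr(out, "truth") <- truth
  out
}

#' Generate a complete synthetic study bundle
#'
#' Produces a sample manifest (cores, timepoints, TMT plex/channel layout with
#' one pooled common-reference channel per plex), a PSM-level table, protein /
#' phosphosite log2 common-reference ratio matrices, RNA counts, per-patient
#' copy-number segment tables and integer calls, tumor-content slide records,
#' a citation fixture and ground-truth labels for every spiked effect. The
#' bundle is fully determined by `config` (including its seed).
#'
#' The generative model: per feature, sample value = patient effect +
#' copy-number dosage / spike effects + treatment effect + per-plex batch
#' residual + Gaussian noise. RNA counts are Poisson draws around a latent
#' log2 level sharing the patient effect with protein, with RNA noise solved
#' per gene so the per-gene mRNA-protein correlation matches
#' `mrnaProteinRho`. Spiked outliers replace the affected patient's random
#' effect for the spiked feature.
#'
#' @param config a [CohortConfig-class] from [cohortConfig()].
#' @return a [CohortBundle-class].
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)
  eff <- config@effectSizes
  patients <- .patientIds(config@nPatients)
  nPcr <- as.integer(round(config@pcrFraction * config@nPatients))
  group <- structure(
    ifelse(seq_along(patients) <= nPcr, "pCR", "non-pCR"),
    names = patients
  )

  ## ---- manifest: cores, timepoints, plex / channel layout -----------------
  plan <- config@replicatePlan
  cores <- do.call(rbind, lapply(seq_len(nrow(plan)), function(i) {
    data.frame(
      patient = plan$patient[i], timepoint = plan$timepoint[i],
      coreIdx = seq_len(plan$nCores[i]), stringsAsFactors = FALSE
    )
  }))
  cores$core_id <- sprintf("%s_%s%d", cores$patient, cores$timepoint, cores$coreIdx)
  nCores <- nrow(cores)
  nSampleCh <- config@plexSize - 1L
  nPlex <- ceiling(nCores / nSampleCh)
  perm <- sample.int(nCores)
  plex <- integer(nCores)
  channel <- character(nCores)
  for (k in seq_len(nPlex)) {
    idx <- perm[((k - 1L) * nSampleCh + 1L):min(k * nSampleCh, nCores)]
    plex[idx] <- k
    channel[idx] <- sprintf("ch%02d", seq_along(idx))
  }
  manifest <- data.frame(
    core_id = cores$core_id, patient = cores$patient,
    timepoint = cores$timepoint, group = unname(group[cores$patient]),
    plex = plex, channel = channel, stringsAsFactors = FALSE
  )
  crRows <- data.frame(
    core_id = sprintf("CR_plex%d", seq_len(nPlex)), patient = "CR",
    timepoint = NA_character_, group = NA_character_,
    plex = seq_len(nPlex), channel = sprintf("ch%02d", config@plexSize),
    stringsAsFactors = FALSE
  )
  manifest <- rbind(manifest, crRows)

  ## ---- gene universe ------------------------------------------------------
  nGenes <- config@nGenes
  des <- .DESIGNATED_GENES
  nGeneric <- nGenes - nrow(des)
  genChrom <- sample(names(.CHROM_LENGTHS)[1:22], nGeneric, replace = TRUE,
    prob = .CHROM_LENGTHS[1:22])
  genStart <- floor(stats::runif(nGeneric, 1, .CHROM_LENGTHS[genChrom] - 1e5))
  geneTab <- rbind(des, data.frame(
    symbol = sprintf("G%04d", seq_len(nGeneric)), chrom = genChrom,
    start = genStart, end = genStart + 5e4, stringsAsFactors = FALSE
  ))
  genes <- GRanges(geneTab$chrom, IRanges(geneTab$start, geneTab$end),
    symbol = geneTab$symbol)
  names(genes) <- geneTab$symbol
  symbols <- geneTab$symbol

  ## ---- per-gene biological scales -----------------------------------------
  patientSd <- stats::rlnorm(nGenes, meanlog = log(1.1), sdlog = 0.35)
  names(patientSd) <- symbols
  patientSd[.AMPLICON_GENES] <- 0.3   # dosage-driven, little residual biology
  patientSd[.MUCIN_PANEL] <- 2.5      # mucins are highly variable across tumors

  ## ---- amplicon copy-number truth -----------------------------------------
  classMap <- structure(rep("true_pos", config@nPatients), names = patients)
  classMap[names(config@ampliconClassMap)] <- config@ampliconClassMap
  cnGain <- structure(numeric(config@nPatients), names = patients)
  gainPatients <- patients[classMap %in% c("true_pos", "pseudo_pos")]
  cnGain[gainPatients] <- pmax(
    stats::rnorm(length(gainPatients), eff$cnGainMean, eff$cnGainSd),
    eff$cnGainMin
  )
  cnGain[classMap == "false_pos"] <- stats::rnorm(sum(classMap == "false_pos"), 0, 0.05)

  mucinTruePos <- patients[group == "non-pCR" & classMap == "true_pos"]
  mucinPatient <- if (length(mucinTruePos)) mucinTruePos[length(mucinTruePos)] else NA_character_
  mucinGenes <- c("MUC1", "MUC4", "MUC6", "MUC5AC")

  ## ---- patient effects (shared by RNA and protein) ------------------------
  patientEff <- matrix(
    stats::rnorm(nGenes * config@nPatients), nGenes, config@nPatients,
    dimnames = list(symbols, patients)
  ) * patientSd
  if (!is.na(mucinPatient) && eff$mucinShift != 0) {
    # the spike IS the patient's biology: replace, don't add
    patientEff[mucinGenes, mucinPatient] <- eff$mucinShift
  }

  ## amplicon expression effects, per patient (protein scale)
  protAmp <- matrix(0, nGenes, config@nPatients, dimnames = list(symbols, patients))
  rnaAmp <- protAmp
  for (p in patients) {
    cls <- classMap[p]
    if (cls == "true_pos") {
      protAmp[.AMPLICON_GENES, p] <- eff$proteinDoseCoef * cnGain[p]
      rnaAmp[.AMPLICON_GENES, p] <- eff$rnaDoseCoef * cnGain[p]
    } else if (cls == "pseudo_pos") {
      protAmp[.AMPLICON_GENES, p] <- eff$erbb2LowShift
      rnaAmp[.AMPLICON_GENES, p] <- eff$rnaDoseCoef * cnGain[p]
      protAmp[c("ERBB3", "ERBB4"), p] <- eff$erbb2LowShift / 2
    } else { # false_pos: no amplification, low expression
      protAmp[.AMPLICON_GENES, p] <- eff$erbb2LowShift
      rnaAmp[.AMPLICON_GENES, p] <- eff$erbb2LowShift / 2
      protAmp[c("ERBB3", "ERBB4"), p] <- eff$erbb2LowShift / 2
    }
  }

  ## ---- treatment response -------------------------------------------------
  respMult <- structure(stats::rnorm(config@nPatients, 1, 0.25), names = patients)
  treatFactor <- ifelse(group == "pCR", 1, eff$nonPcrOnTreatFactor)

  ## ---- protein matrix (log2 common-reference ratio scale) -----------------
  coreIdx <- seq_len(nCores)
  corePatient <- manifest$patient[coreIdx]
  coreTp <- manifest$timepoint[coreIdx]
  corePlex <- manifest$plex[coreIdx]
  plexResid <- array(stats::rnorm(nGenes * nPlex, 0, 0.15), c(nGenes, nPlex),
    dimnames = list(symbols, NULL))
  prot <- patientEff[, corePatient, drop = FALSE] +
    protAmp[, corePatient, drop = FALSE] +
    plexResid[, corePlex, drop = FALSE] +
    matrix(stats::rnorm(nGenes * nCores, 0, config@noiseSd), nGenes, nCores)
  onIdx <- which(coreTp == "on")
  for (j in onIdx) {
    p <- corePatient[j]
    prot["ERBB2", j] <- prot["ERBB2", j] +
      eff$onTreatErbb2 * treatFactor[p] * respMult[p]
  }
  colnames(prot) <- manifest$core_id[coreIdx]

  ## ---- RNA counts ---------------------------------------------------------
  rnaPatients <- patients[seq_len(max(2L, config@nPatients - 3L))]
  rnaCoreIdx <- which(corePatient %in% rnaPatients)
  rPearson <- 2 * sin(pi * config@mrnaProteinRho / 6) # Spearman -> Pearson
  sigP2 <- config@noiseSd^2 + 0.15^2
  s2 <- patientSd^2
  sigR2 <- pmax(s2^2 / (rPearson^2 * (s2 + sigP2)) - s2, 0.05^2)
  rnaBase <- stats::rnorm(nGenes, 6.5, 1.5)
  zeroGenes <- sample(setdiff(symbols, .DESIGNATED_GENES$symbol), 5L)
  rnaLatent <- patientEff[, corePatient[rnaCoreIdx], drop = FALSE] +
    rnaAmp[, corePatient[rnaCoreIdx], drop = FALSE] +
    matrix(stats::rnorm(nGenes * length(rnaCoreIdx)), nGenes, length(rnaCoreIdx)) *
      sqrt(sigR2)
  depth <- stats::rnorm(length(rnaCoreIdx), 0, 0.2)
  mu <- 2^(rnaBase + sweep(rnaLatent, 2L, depth, "+"))
  mu <- pmin(mu, 5e6)
  rnaCounts <- matrix(
    stats::rpois(length(mu), mu), nGenes, length(rnaCoreIdx),
    dimnames = list(symbols, manifest$core_id[rnaCoreIdx])
  )
  rnaCounts[zeroGenes, ] <- 0L

  ## ---- phosphosites -------------------------------------------------------
  nSites <- config@nPhosphosites
  desSites <- rbind(
    data.frame(protein = "ERBB2", residue = c("Y1248", "Y1221", "T1240", "S1151")),
    do.call(rbind, lapply(.MTOR_TARGET_GENES, function(g) {
      data.frame(protein = g, residue = paste0(c("S", "T", "S"), sample(100:900, 3L)))
    }))
  )
  hostPool <- symbols[seq_len(floor(nGenes * 0.6))]
  nGenSites <- nSites - nrow(desSites)
  genHosts <- sample(hostPool, nGenSites, replace = TRUE)
  genRes <- paste0(sample(c("S", "T", "Y"), nGenSites, TRUE),
    sample(30:1500, nGenSites, TRUE))
  siteTab <- rbind(desSites, data.frame(protein = genHosts, residue = genRes))
  siteTab$site_id <- make.unique(paste0(siteTab$protein, "_p", siteTab$residue))
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
    "Q", "R", "S", "T", "V", "W", "Y")
  flanks <- vapply(substr(siteTab$residue, 1, 1), function(ctr) {
    paste0(paste(sample(aa, 7L, TRUE), collapse = ""), ctr,
      paste(sample(aa, 7L, TRUE), collapse = ""))
  }, character(1))
  # flanking windows must be unique keys; regenerate clashes deterministically
  while (anyDuplicated(flanks)) {
    d <- which(duplicated(flanks))
    flanks[d] <- vapply(substr(siteTab$residue[d], 1, 1), function(ctr) {
      paste0(paste(sample(aa, 7L, TRUE), collapse = ""), ctr,
        paste(sample(aa, 7L, TRUE), collapse = ""))
    }, character(1))
  }
  siteTab$flank <- unname(flanks)
  localized <- stats::runif(nSites) > 0.05
  localized[seq_len(nrow(desSites))] <- TRUE

  siteOffset <- stats::rnorm(nSites, 0, 0.3)
  phospho <- prot[siteTab$protein, , drop = FALSE] + siteOffset +
    matrix(stats::rnorm(nSites * nCores, 0, 0.3), nSites, nCores)
  mtorSites <- which(siteTab$protein %in% .MTOR_TARGET_GENES)
  erbb2Sites <- which(siteTab$protein == "ERBB2")
  for (j in onIdx) {
    p <- corePatient[j]
    phospho[mtorSites, j] <- phospho[mtorSites, j] +
      eff$onTreatMtor * treatFactor[p] * respMult[p]
    phospho[erbb2Sites, j] <- phospho[erbb2Sites, j] +
      0.3 * eff$onTreatErbb2 * treatFactor[p] * respMult[p]
  }
  rownames(phospho) <- siteTab$site_id
  colnames(phospho) <- manifest$core_id[coreIdx]

  ## ---- segments and integer calls -----------------------------------------
  segList <- list()
  for (p in patients) {
    for (chr in names(.CHROM_LENGTHS)) {
      len <- .CHROM_LENGTHS[[chr]]
      if (chr == "17") {
        bounds <- c(1, 39.4e6, 40.4e6, len)
        vals <- c(stats::rnorm(1, 0, 0.12), cnGain[p], stats::rnorm(1, 0, 0.12))
      } else {
        nseg <- sample(1:3, 1L)
        cuts <- sort(floor(stats::runif(nseg - 1L, 0.1 * len, 0.9 * len)))
        bounds <- c(1, cuts, len)
        vals <- stats::rnorm(nseg, 0, 0.12)
      }
      segList[[length(segList) + 1L]] <- data.frame(
        sample = p, chrom = chr,
        start = floor(bounds[-length(bounds)]) + c(0L, rep(1L, length(vals) - 1L)),
        end = floor(bounds[-1L]), log2ratio = vals, stringsAsFactors = FALSE
      )
    }
  }
  segTab <- do.call(rbind, segList)
  segments <- GRanges(segTab$chrom, IRanges(segTab$start, segTab$end),
    sample = segTab$sample, log2ratio = segTab$log2ratio)

  calls <- matrix(0L, nGenes, config@nPatients, dimnames = list(symbols, patients))
  rand <- matrix(stats::runif(nGenes * config@nPatients), nGenes, config@nPatients)
  calls[rand < 0.02] <- sample(c(-1L, 1L), sum(rand < 0.02), TRUE)
  calls[.AMPLICON_GENES, ] <- 0L
  calls[.AMPLICON_GENES, gainPatients] <- 2L

  ## ---- tumor-content slides -----------------------------------------------
  slides <- do.call(rbind, lapply(manifest$core_id[coreIdx], function(cid) {
    data.frame(
      core_id = cid, slide = paste0("TC", 1:4),
      tumorContent = pmin(pmax(round(stats::rnorm(4, 70, 8)), 0), 100),
      stringsAsFactors = FALSE
    )
  }))

  ## ---- PSM-level table ----------------------------------------------------
  psm <- .generatePsmTable(prot, manifest, config)

  ## ---- citation fixture ---------------------------------------------------
  citations <- generateCitationFixture(
    nPubs = 80L, geneUniverse = symbols, seed = config@seed + 1L
  )

  truth <- list(
    patients = data.frame(
      patient = patients, group = unname(group),
      ampliconClass = unname(classMap), cnGain = unname(cnGain),
      hasOnTreatment = patients %in% manifest$patient[manifest$timepoint %in% "on"],
      hasRna = patients %in% rnaPatients, stringsAsFactors = FALSE
    ),
    ampliconClassMap = classMap,
    cnGain = cnGain,
    ampliconGenes = .AMPLICON_GENES,
    mucinPatient = mucinPatient,
    mucinGenes = mucinGenes,
    mucinShift = eff$mucinShift,
    mucinFeatureSd = sqrt(patientSd[mucinGenes]^2 + config@noiseSd^2 + 0.15^2),
    mtorTargetGenes = .MTOR_TARGET_GENES,
    erbb2Sites = siteTab$site_id[erbb2Sites],
    mtorSites = siteTab$site_id[mtorSites],
    onTreatEffects = c(erbb2 = eff$onTreatErbb2, mtor = eff$onTreatMtor),
    zeroCountGenes = zeroGenes,
    respMult = respMult,
    citationCounts = attr(citations, "truth")
  )

  new("CohortBundle",
    config = config, manifest = manifest, psm = psm,
    protein = QuantMatrix(prot, "protein",
      colData = DataFrame(manifest[coreIdx, -1L], row.names = manifest$core_id[coreIdx])),
    phosphosite = QuantMatrix(phospho, "phosphosite",
      rowData = DataFrame(
        protein = siteTab$protein, flank = siteTab$flank,
        localized = localized, row.names = siteTab$site_id
      ),
      colData = DataFrame(manifest[coreIdx, -1L], row.names = manifest$core_id[coreIdx])),
    rnaCounts = rnaCounts, segments = segments, genes = genes,
    integerCalls = calls, slides = slides, citations = citations,
    truth = truth
  )
}

# PSM channel intensities are consistent with the rolled protein matrix: each
# member channel carries 2^(ratio value) around a per-PSM base intensity, and
# the common-reference channel is the geometric mean of the member channels
# (pooled CR). After assembly, sample channels are rescaled within each plex
# so the median ratio to CR is ~1, emulating the physical step of mixing all
# channels to equal amounts once the mixing-ratio check has been run.
.generatePsmTable <- function(prot, manifest, config) {
  vr <- config@psmViolationRates
  symbols <- rownames(prot)
  psmGenes <- unique(c(
    .DESIGNATED_GENES$symbol,
    symbols[seq_len(min(config@nPsmGenes, length(symbols)))]
  ))
  psmGenes <- psmGenes[seq_len(min(config@nPsmGenes, length(psmGenes)))]
  nPlex <- max(manifest$plex)
  chNames <- sprintf("ch%02d", seq_len(config@plexSize))
  crCh <- chNames[config@plexSize]
  rows <- list()
  for (k in seq_len(nPlex)) {
    mk <- manifest[manifest$plex == k & manifest$patient != "CR", , drop = FALSE]
    for (g in psmGenes) {
      nPsm <- 1L + stats::rpois(1L, 1.2)
      for (i in seq_len(nPsm)) {
        base <- 2^stats::rnorm(1, 7, 1)
        intens <- structure(rep(NA_real_, config@plexSize), names = chNames)
        vals <- prot[g, mk$core_id] + stats::rnorm(nrow(mk), 0, 0.25)
        intens[mk$channel] <- base * 2^vals
        intens[crCh] <- 2^mean(log2(intens[mk$channel]))
        u <- stats::runif(1)
        labelState <- if (u < vr$none) "none" else if (u < vr$none + vr$partial) "partial" else "full"
        purity <- if (stats::runif(1) < vr$lowPurity) {
          stats::runif(1, 0.1, 0.499)
        } else {
          stats::runif(1, 0.55, 1)
        }
        deltaFr <- if (stats::runif(1) < vr$negDeltaFr) {
          -stats::runif(1, 0.1, 2)
        } else {
          stats::runif(1, 0.1, 5)
        }
        rows[[length(rows) + 1L]] <- c(
          list(
            psm_id = sprintf("psm_%d_%s_%d", k, g, i), feature_id = g,
            plex = k, label_state = labelState, precursor_purity = purity,
            delta_fr_score = deltaFr
          ),
          as.list(intens)
        )
      }
    }
  }
  psm <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  # mix channels to equal amounts (median ratio to CR ~ 1, small residual)
  for (k in seq_len(nPlex)) {
    mk <- manifest[manifest$plex == k & manifest$patient != "CR", , drop = FALSE]
    pk <- psm$plex == k
    for (ch in mk$channel) {
      md <- stats::median(psm[[ch]][pk] / psm[[crCh]][pk], na.rm = TRUE)
      psm[[ch]][pk] <- psm[[ch]][pk] / md * 2^stats::rnorm(1, 0, 0.03)
    }
  }
  psm
}

#' Re-spike the ERBB2 amplicon class of one patient
#'
#' Returns a new bundle regenerated from the same configuration and seed with
#' the requested patient's amplicon class replaced. Regeneration keeps the
#' determinism contract: two bundles from identical configs are identical.
#'
#' @param bundle a [CohortBundle-class].
#' @param patient patient identifier present in the bundle.
#' @param class `"true_pos"`, `"pseudo_pos"` or `"false_pos"`.
#' @return a new [CohortBundle-class].
#' @export
spikeAmpliconClass <- function(bundle, patient, class) {
  stopifnot(is(bundle, "CohortBundle"))
  if (!(class %in% c("true_pos", "pseudo_pos", "false_pos"))) {
    stop(sprintf("unknown amplicon class '%s'", class))
  }
  cfg <- bundle@config
  if (!(patient %in% .patientIds(cfg@nPatients))) {
    stop(sprintf("unknown patient '%s'", patient))
  }
  map <- cfg@ampliconClassMap
  map[patient] <- class
  cfg@ampliconClassMap <- map
  generateCohort(cfg)
}
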