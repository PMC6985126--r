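# shared fixtures, built once per test run

# small cohort for fast end-to-end checks (full study geometry, fewer genes)
smallConfig <- function(seed = 42L, ...) {
  cohortConfig(
    nGenes = 400L, nPhosphosites = 120L, nPsmGenes = 60L, seed = seed, ...
  )
}

.smallBundle <- NULL
smallBundle <- function() {
  if (is.null(.smallBundle)) .smallBundle <<- generateCohort(smallConfig())
  .smallBundle
}

# cores of given group/timepoint
coresOf <- function(manifest, group, timepoint) {
  manifest$core_id[manifest$group %in% group & manifest$timepoint %in% timepoint]
}

# brute-force ssGSEA running-sum oracle, written independently of the
# package implementation (explicit loop over the ranking)
bruteEs <- function(scores, members, w) {
  ord <- names(sort(scores, decreasing = TRUE))
  members <- intersect(members, ord)
  norm <- sum(abs(scores[members])^w)
  run <- 0
  total <- 0
  for (id in ord) {
    if (id %in% members) {
      run <- run + (if (norm > 0) abs(scores[id])^w / norm else 1 / length(members))
    } else {
      run <- run - 1 / (length(ord) - length(members))
    }
    total <- total + run
  }
  as.numeric(total / length(ord))
}
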