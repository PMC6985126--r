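.patientIds <- function(n) sprintf("P%02d", seq_len(n))

# approximate autosome + X lengths (bp), used to lay out synthetic gene models
# and copy-number segments
.CHROM_LENGTHS <- c(
  "1" = 248956422, "2" = 242193529, "3" = 198295559, "4" = 190214555,
  "5" = 181538259, "6" = 170805979, "7" = 159345973, "8" = 145138636,
  "9" = 138394717, "10" = 133797422, "11" = 135086622, "12" = 133275309,
  "13" = 114364328, "14" = 107043718, "15" = 101991189, "16" = 90338345,
  "17" = 83257441, "18" = 80373285, "19" = 58617616, "20" = 64444167,
  "21" = 46709983, "22" = 50818468, "X" = 156040895
)

# real ERBB2-amplicon neighborhood plus designated partner / pathway / mucin
# genes; coordinates are approximate hg38 gene spans
.DESIGNATED_GENES <- data.frame(
  symbol = c(
    "ERBB2", "STARD3", "PGAP3", "GRB7", "TOP2A",
    "EGFR", "ERBB3", "ERBB4", "AR",
    "MTOR", "RPS6", "RPS6KB1", "EIF4EBP1", "AKT1S1",
    "MUC1", "MUC4", "MUC6", "MUC5AC", "MUC16"
  ),
  chrom = c(
    "17", "17", "17", "17", "17",
    "7", "12", "2", "X",
    "1", "9", "17", "8", "19",
    "1", "3", "11", "11", "19"
  ),
  start = c(
    39687914, 39636222, 39671100, 39737939, 40388502,
    55019017, 56080025, 211375717, 67544021,
    11106531, 19376254, 59893046, 38030502, 49869038,
    155185824, 195746765, 1012823, 1157953, 8848844
  ),
  stringsAsFactors = FALSE
)
.DESIGNATED_GENES$end <- .DESIGNATED_GENES$start + c(
  40738, 27000, 17000, 9700, 29000,
  192611, 23000, 1163000, 186000,
  155000, 4000, 58000, 30000, 9000,
  4500, 65000, 24000, 38000, 132000
)

.AMPLICON_GENES <- c("ERBB2", "STARD3", "PGAP3", "GRB7")
.MTOR_TARGET_GENES <- c("MTOR", "RPS6", "RPS6KB1", "EIF4EBP1", "AKT1S1")
.MUCIN_PANEL <- c("MUC1", "MUC4", "MUC6", "MUC5AC", "MUC16")

.checkFraction <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", what))
  }
  invisible(x)
}

# column medians / MADs ignoring NA, without matrixStats
.colMedians <- function(m) apply(m, 2L, stats::median, na.rm = TRUE)
.rowVars <- function(m) apply(m, 1L, stats::var, na.rm = TRUE)
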