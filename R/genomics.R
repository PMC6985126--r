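#' Convert a SEG-style table to GRanges
#'
#' Input coordinates are 1-based inclusive (SEG convention); the GRanges
#' representation is likewise 1-based inclusive, so conversions are
#' bit-exact.
#'
#' @param seg data.frame with columns `sample`, `chrom`, `start`, `end`,
#'   `log2ratio`.
#' @return a `GRanges` with metadata columns `sample` and `log2ratio`.
#' @export
segmentsAsGRanges <- function(seg) {
  need <- c("sample", "chrom", "start", "end", "log2ratio")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop(sprintf("segment table lacks column(s): %s", paste(miss, collapse = ", ")))
  bad <- which(!(seg$start < seg$end))
  if (length(bad)) {
    stop(sprintf("malformed segment interval(s) at row(s): %s", paste(bad, collapse = ", ")))
  }
  chrom <- sub("^chr", "", as.character(seg$chrom))
  okChrom <- chrom %in% c(as.character(1:22), "X", "Y")
  if (!all(okChrom)) {
    stop(sprintf("unknown chromosome(s) at row(s): %s", paste(which(!okChrom), collapse = ", ")))
  }
  GRanges(chrom, IRanges(seg$start, seg$end),
    sample = as.character(seg$sample), log2ratio = seg$log2ratio)
}

#' Gene-level copy number from segments
#'
#' Per gene and sample: the overlap-length-weighted mean of the log2 ratios
#' of all segments intersecting the gene span. Genes with no overlapping
#' segment in a sample are missing. With a single whole-chromosome segment,
#' every gene on the chromosome receives that segment's ratio.
#'
#' @param segments `GRanges` of segments (metadata `sample`, `log2ratio`),
#'   e.g. from [segmentsAsGRanges()] or [bundleSegments()].
#' @param genes `GRanges` of gene models with metadata column `symbol`.
#' @return a [QuantMatrix-class] with level `"cna-gene"` (genes x samples).
#' @export
geneCopyNumber <- function(segments, genes) {
  stopifnot(is(segments, "GRanges"), is(genes, "GRanges"))
  if (is.null(segments$sample) || is.null(segments$log2ratio)) {
    stop("'segments' needs metadata columns 'sample' and 'log2ratio'")
  }
  if (is.null(genes$symbol)) stop("'genes' needs metadata column 'symbol'")
  samples <- sort(unique(segments$sample))
  out <- matrix(NA_real_, length(genes), length(samples),
    dimnames = list(genes$symbol, samples))
  for (s in samples) {
    seg <- segments[segments$sample == s]
    hits <- findOverlaps(genes, seg)
    if (length(hits) == 0L) next
    ov <- width(pintersect(genes[S4Vectors::queryHits(hits)], seg[S4Vectors::subjectHits(hits)]))
    r <- seg$log2ratio[S4Vectors::subjectHits(hits)]
    q <- S4Vectors::queryHits(hits)
    wsum <- tapply(ov, q, sum)
    rsum <- tapply(ov * r, q, sum)
    out[as.integer(names(wsum)), s] <- rsum / wsum
  }
  QuantMatrix(out, "cna-gene")
}

#' Chromosome instability scores and genome-wide index
#'
#' Per chromosome, the instability score is the segment-length-weighted sum
#' of absolute segment log2 ratios. With `normalize = TRUE` (default) the
#' weights are the segments' fractions of the chromosome's total segmented
#' length, making scores comparable across samples and invariant to
#' splitting a segment into adjacent halves; with `normalize = FALSE` the raw
#' sum of `|log2 ratio| * length` is returned. The genome-wide index sums the
#' scores of the 22 autosomes only.
#'
#' @param segments `GRanges` of one sample's segments with metadata
#'   `log2ratio` (a `sample` column, if present, must be a single sample).
#' @param normalize use per-chromosome length-fraction weights.
#' @return list with `perChromosome` (data.frame `chrom`, `score`) and
#'   `genomeIndex`.
#' @export
chromosomeInstability <- function(segments, normalize = TRUE) {
  stopifnot(is(segments, "GRanges"))
  if (length(segments) == 0L) stop("at least one segment is required")
  if (!is.null(segments$sample) && length(unique(segments$sample)) > 1L) {
    stop("'segments' must contain a single sample; split by sample first")
  }
  chrom <- sub("^chr", "", as.character(seqnames(segments)))
  len <- as.numeric(width(segments))
  absr <- abs(segments$log2ratio)
  scores <- vapply(split(seq_along(segments), chrom), function(idx) {
    w <- if (normalize) len[idx] / sum(len[idx]) else len[idx]
    sum(absr[idx] * w)
  }, numeric(1))
  per <- data.frame(chrom = names(scores), score = unname(scores),
    stringsAsFactors = FALSE)
  autosomes <- per$chrom %in% as.character(1:22)
  list(perChromosome = per, genomeIndex = sum(per$score[autosomes]))
}

#' Stringent copy-number aberration calls
#'
#' A gene is aberrant in a sample iff its integer call is at or beyond the
#' stringent threshold: `>= threshold` (amplified) or `<= -threshold`
#' (deleted). Calls of +/-1 are not aberrant at the default threshold 2.
#'
#' @param integerCalls gene x sample matrix of integer calls (e.g. GISTIC2
#'   -2..2 values).
#' @param threshold positive integer threshold (default 2).
#' @return logical matrix of the same shape.
#' @export
callAberrantGenes <- function(integerCalls, threshold = 2L) {
  m <- as.matrix(integerCalls)
  if (any(is.na(m)) || any(m != round(m))) {
    stop("'integerCalls' must be an integer matrix without missing values")
  }
  threshold <- as.integer(threshold)
  m >= threshold | m <= -threshold
}

#' Extract protein-affecting mutations
#'
#' Retains SNVs annotated as non-synonymous, stopgain, stoploss or splicing,
#' and INDELs annotated as exonic. Returns both a unique-mutation-by-patient
#' table and a mutated-gene-by-patient incidence table.
#'
#' @param variants data.frame with columns `patient`, `gene`, `type`
#'   (`"SNV"` / `"INDEL"`), `annotation`, and a mutation identifier column
#'   `mutation_id`.
#' @return list with `mutations` (retained rows) and `genes`
#'   (gene x patient logical incidence matrix).
#' @export
filterCodingMutations <- function(variants) {
  need <- c("patient", "gene", "type", "annotation", "mutation_id")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop(sprintf("variant table lacks column(s): %s", paste(miss, collapse = ", ")))
  snvKeep <- c("non-synonymous SNV", "nonsynonymous SNV", "stopgain", "stoploss", "splicing")
  keep <- (variants$type == "SNV" & variants$annotation %in% snvKeep) |
    (variants$type == "INDEL" & grepl("exonic", variants$annotation, ignore.case = TRUE))
  mut <- variants[keep, , drop = FALSE]
  if (nrow(mut) == 0L) {
    genes <- matrix(FALSE, 0, 0)
  } else {
    genes <- table(mut$gene, mut$patient) > 0
    genes <- matrix(genes, nrow(genes), ncol(genes),
      dimnames = dimnames(genes))
  }
  list(mutations = mut, genes = genes)
}
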