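#' Read a GCT v1.2 expression matrix
#'
#' @param path GCT file path.
#' @param level feature level tag for the returned matrix.
#' @return a [QuantMatrix-class]; the Description column is kept as
#'   `rowData(x)$description`.
#' @export
readGct <- function(path, level = "protein") {
  header <- readLines(path, n = 2L)
  if (!identical(header[1], "#1.2")) stop("not a GCT v1.2 file (missing '#1.2' header)")
  dims <- as.integer(strsplit(header[2], "\t", fixed = TRUE)[[1]])
  tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
    stringsAsFactors = FALSE)
  if (nrow(tab) != dims[1] || ncol(tab) - 2L != dims[2]) {
    stop("GCT dimensions do not match the header line")
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  rownames(m) <- tab[[1]]
  QuantMatrix(m, level, rowData = DataFrame(description = tab[[2]]))
}

#' Write a GCT v1.2 expression matrix
#'
#' @param m a [QuantMatrix-class] (or plain matrix with dimnames).
#' @param path output path.
#' @export
writeGct <- function(m, path) {
  v <- if (is(m, "QuantMatrix")) quantValues(m) else as.matrix(m)
  desc <- if (is(m, "QuantMatrix") && "description" %in% names(rowData(m))) {
    rowData(m)$description
  } else {
    rownames(v)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(v), ncol(v), sep = "\t")), con)
  tab <- data.frame(Name = rownames(v), Description = desc, v,
    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a SEG-style segment table
#'
#' Expects tab-separated columns `sample`, `chrom`, `start`, `end`,
#' `log2ratio` (1-based inclusive coordinates).
#'
#' @param path SEG file path.
#' @return a `GRanges` as from [segmentsAsGRanges()].
#' @export
readSeg <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  segmentsAsGRanges(tab)
}

#' Write a SEG-style segment table
#'
#' @param segments `GRanges` with metadata `sample`, `log2ratio`.
#' @param path output path.
#' @export
writeSeg <- function(segments, path) {
  tab <- data.frame(
    sample = segments$sample,
    chrom = as.character(seqnames(segments)),
    start = start(segments), end = end(segments),
    log2ratio = segments$log2ratio, stringsAsFactors = FALSE
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort bundle to a directory of plain-text files
#'
#' Writes the manifest, slides, PSM and citation tables as TSV, the protein
#' and phosphosite matrices and RNA counts as GCT v1.2, segments as SEG, the
#' integer-call matrix as TSV, and the truth labels as JSON.
#'
#' @param bundle a [CohortBundle-class].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writeCohortBundle <- function(bundle, dir) {
  stopifnot(is(bundle, "CohortBundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
    quote = FALSE, row.names = FALSE)
  w(bundle@manifest, "manifest.tsv")
  w(bundle@slides, "slides.tsv")
  w(bundle@psm, "psm.tsv")
  w(bundle@citations, "citations.tsv")
  writeGct(bundle@protein, file.path(dir, "protein.gct"))
  writeGct(bundle@phosphosite, file.path(dir, "phosphosite.gct"))
  writeGct(bundle@rnaCounts, file.path(dir, "rna_counts.gct"))
  writeSeg(bundle@segments, file.path(dir, "segments.seg"))
  utils::write.table(
    data.frame(symbol = rownames(bundle@integerCalls), bundle@integerCalls,
      check.names = FALSE),
    file.path(dir, "integer_calls.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  truth <- bundle@truth
  truth$citationCounts <- as.list(truth$citationCounts)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
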