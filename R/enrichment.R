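#' Signed log10 p-value ranking transform
#'
#' `sign * (-log10(p))`, with p floored at `floor` so p = 0 maps to a finite
#' extreme rather than infinity.
#'
#' @param p p-values in \[0, 1\] (vectorized).
#' @param sign direction of each effect, +1 or -1 (recycled).
#' @param floor smallest p used (default 1e-15).
#' @return signed log10 p scores.
#' @export
signedLogP <- function(p, sign, floor = 1e-15) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  n <- max(length(p), length(sign))
  p <- rep_len(p, n)
  sign <- rep_len(sign, n)
  if (!all(sign %in% c(-1, 1))) stop("'sign' must be +1 or -1")
  sign * (-log10(pmax(p, floor)))
}

#' Collapse feature-level scores to gene-centric scores
#'
#' Per gene symbol, keeps the score of maximal absolute value (the "most
#' significant p-value per gene symbol" when scores are signed log10 p).
#' Ties in absolute value with opposite signs are broken deterministically by
#' lexicographic feature identifier and flagged.
#'
#' @param scores named numeric vector of feature scores.
#' @param genes character vector mapping each feature to one gene symbol.
#' @return named numeric vector of gene scores; tied genes are listed in
#'   `attr(x, "ties")`.
#' @export
collapseGeneCentric <- function(scores, genes) {
  stopifnot(length(scores) == length(genes))
  feat <- names(scores)
  if (is.null(feat)) feat <- as.character(seq_along(scores))
  ord <- order(genes, -abs(scores), feat)
  scores <- scores[ord]; genes <- genes[ord]; feat <- feat[ord]
  first <- !duplicated(genes)
  out <- structure(scores[first], names = genes[first])
  ties <- character(0)
  idx <- which(first)
  nxt <- idx + 1L
  hasNext <- nxt <= length(scores) & genes[pmin(nxt, length(genes))] == genes[idx]
  tied <- hasNext & abs(scores[pmin(nxt, length(scores))]) == abs(scores[idx]) &
    scores[pmin(nxt, length(scores))] != scores[idx]
  ties <- genes[idx][tied]
  attr(out, "ties") <- ties
  out
}

#' Single-sample weighted running-sum enrichment score
#'
#' Identifiers are ranked by descending score; walking down the ranking, the
#' running sum gains `|score|^weight` (normalized over the set's members) at
#' each in-set identifier and loses `1 / (N - set size)` at each out-of-set
#' identifier. The ES is the area variant: the sum of the running-sum values
#' divided by N. Positive when the set concentrates at the top of the
#' ranking, negative at the bottom; at `weight = 0` it is invariant to any
#' strictly monotone transform of the scores.
#'
#' @param scores named numeric vector (identifier -> signed score), finite,
#'   unique names.
#' @param members character vector of set member identifiers; members absent
#'   from `scores` are dropped.
#' @param weight score weight exponent (default 0.75).
#' @return the enrichment score, with the realized overlap size as
#'   `attr(x, "size")`.
#' @export
ssgseaES <- function(scores, members, weight = 0.75) {
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    stop("'scores' must have unique identifier names")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  members <- intersect(unique(members), names(scores))
  N <- length(scores)
  m <- length(members)
  if (m == 0L || m == N) stop("set overlap must be non-empty and proper")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  inset <- names(s) %in% members
  w <- abs(s)^weight
  win <- sum(w[inset])
  steps <- ifelse(inset,
    if (win > 0) w / win else 1 / m, # all-zero in-set scores: equal weights
    -1 / (N - m)
  )
  es <- sum(cumsum(steps)) / N
  attr(es, "size") <- m
  es
}

#' Normalize enrichment scores and attach permutation p-values and FDR
#'
#' For each set, a null ES distribution is built by drawing random member
#' sets of the same size from the score identifiers (`nPerm` identifier
#' permutations, fixed seed). NES is the ES divided by the mean |null ES| of
#' matching sign; the nominal p is the same-sign null tail probability (with
#' the +1 continuity correction); FDR is Benjamini-Hochberg across sets,
#' with a reporting flag at FDR < 0.25.
#'
#' @param scores named score vector as in [ssgseaES()].
#' @param sets named list of member identifier vectors.
#' @param weight score weight exponent.
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param minSize minimum realized overlap; smaller sets are skipped with a
#'   message.
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `FDR`,
#'   `significant` (FDR < 0.25), `leadingEdge` (semicolon-joined members at
#'   or above the extreme running-sum deviation side).
#' @export
enrichScores <- function(scores, sets, weight = 0.75, nPerm = 1000L,
                         seed = 1L, minSize = 5L) {
  if (nPerm < 100L) stop("'nPerm' must be >= 100")
  ids <- names(scores)
  keep <- vapply(sets, function(mm) length(intersect(mm, ids)), integer(1)) >= minSize
  if (any(!keep)) {
    message(sprintf(
      "skipping %d set(s) with overlap < %d: %s",
      sum(!keep), minSize, paste(names(sets)[!keep], collapse = ", ")
    ))
  }
  sets <- sets[keep]
  if (length(sets) == 0L) {
    return(data.frame(
      set = character(), size = integer(), ES = numeric(), NES = numeric(),
      p = numeric(), FDR = numeric(), significant = logical(),
      leadingEdge = character(), stringsAsFactors = FALSE
    ))
  }
  es <- vapply(sets, function(mm) as.numeric(ssgseaES(scores, mm, weight)), numeric(1))
  sizes <- vapply(sets, function(mm) length(intersect(mm, ids)), integer(1))
  set.seed(seed)
  uniqSizes <- sort(unique(sizes))
  nullBySize <- lapply(uniqSizes, function(k) {
    vapply(seq_len(nPerm), function(i) {
      as.numeric(ssgseaES(scores, sample(ids, k), weight))
    }, numeric(1))
  })
  names(nullBySize) <- as.character(uniqSizes)
  nes <- p <- numeric(length(es))
  for (i in seq_along(es)) {
    null <- nullBySize[[as.character(sizes[i])]]
    same <- null[sign(null) == sign(es[i])]
    if (length(same) == 0L) same <- abs(null) # degenerate: one-sided null
    nes[i] <- es[i] / mean(abs(same))
    p[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  fdr <- bhAdjust(p)
  le <- vapply(seq_along(sets), function(i) {
    paste(.leadingEdge(scores, intersect(sets[[i]], ids), weight), collapse = ";")
  }, character(1))
  data.frame(
    set = names(sets), size = sizes, ES = es, NES = nes, p = p, FDR = fdr,
    significant = fdr < 0.25, leadingEdge = le,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# members at or before the extreme of the running sum (positive ES) or at or
# after it (negative ES)
.leadingEdge <- function(scores, members, weight) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  inset <- names(s) %in% members
  w <- abs(s)^weight
  win <- sum(w[inset])
  steps <- ifelse(inset, if (win > 0) w / win else 1 / sum(inset),
    -1 / (length(s) - sum(inset)))
  rs <- cumsum(steps)
  if (sum(rs) >= 0) {
    k <- which.max(rs)
    names(s)[seq_len(k)][inset[seq_len(k)]]
  } else {
    k <- which.min(rs)
    idx <- k:length(s)
    names(s)[idx][inset[idx]]
  }
}

#' PTM-signature enrichment over flanking-window site scores
#'
#' Site scores are keyed by the +/-7-amino-acid flanking window (15-mer,
#' center = modified residue); only fully localized sites should be supplied.
#' Signature members carry `;u` / `;d` direction suffixes; down-tagged
#' members contribute with inverted sign (their site scores are negated
#' before ranking), after which the machinery is identical to
#' [ssgseaES()] + [enrichScores()].
#'
#' @param siteScores named numeric vector keyed by 15-mer flanking windows.
#' @param signatures named list of member strings `"<window>;u"` /
#'   `"<window>;d"` (a bare window counts as up).
#' @param ... passed to [enrichScores()] (`weight`, `nPerm`, `seed`,
#'   `minSize`).
#' @return data.frame as from [enrichScores()].
#' @export
ptmSea <- function(siteScores, signatures, ...) {
  keys <- names(siteScores)
  bad <- keys[nchar(keys) != 15L]
  if (length(bad)) {
    stop(sprintf(
      "malformed flanking window key(s) (length != 15): %s",
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  parsed <- lapply(signatures, function(mm) {
    dir <- ifelse(grepl(";d$", mm), "d", "u")
    win <- sub(";[ud]$", "", mm)
    badw <- win[nchar(win) != 15L]
    if (length(badw)) {
      stop(sprintf(
        "malformed flanking window key(s) in signature (length != 15): %s",
        paste(utils::head(badw, 5L), collapse = ", ")
      ))
    }
    list(window = win, dir = dir)
  })
  dots <- list(...)
  weight <- if (is.null(dots$weight)) 0.75 else dots$weight
  nPerm <- if (is.null(dots$nPerm)) 1000L else dots$nPerm
  seed <- if (is.null(dots$seed)) 1L else dots$seed
  minSize <- if (is.null(dots$minSize)) 5L else dots$minSize
  if (nPerm < 100L) stop("'nPerm' must be >= 100")
  rows <- list()
  set.seed(seed)
  for (nm in names(parsed)) {
    sig <- parsed[[nm]]
    sc <- siteScores
    down <- intersect(sig$window[sig$dir == "d"], names(sc))
    sc[down] <- -sc[down]
    members <- intersect(sig$window, names(sc))
    if (length(members) < minSize) {
      message(sprintf("skipping signature '%s' with overlap < %d", nm, minSize))
      next
    }
    es <- as.numeric(ssgseaES(sc, members, weight))
    null <- vapply(seq_len(nPerm), function(i) {
      as.numeric(ssgseaES(sc, sample(names(sc), length(members)), weight))
    }, numeric(1))
    same <- null[sign(null) == sign(es)]
    if (length(same) == 0L) same <- abs(null)
    rows[[nm]] <- data.frame(
      set = nm, size = length(members), ES = es, NES = es / mean(abs(same)),
      p = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)),
      leadingEdge = paste(.leadingEdge(sc, members, weight), collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0L) {
    return(data.frame(
      set = character(), size = integer(), ES = numeric(), NES = numeric(),
      p = numeric(), FDR = numeric(), significant = logical(),
      leadingEdge = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out$FDR <- bhAdjust(out$p)
  out$significant <- out$FDR < 0.25
  rownames(out) <- NULL
  out[, c("set", "size", "ES", "NES", "p", "FDR", "significant", "leadingEdge")]
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>member...`.
#' @return named list of member character vectors; descriptions in
#'   `attr(x, "description")`.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop(sprintf("malformed GMT line(s): %s", paste(bad, collapse = ", ")))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  attr(sets, "description") <- vapply(parts, `[`, character(1), 2L)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of member vectors.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to the set names).
#' @export
writeGmt <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}
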