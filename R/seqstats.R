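## Signal-peptide region extraction, 3-mer motif occurrence, composition
## and logo-matrix export.

#' Extract signal-peptide and partial transit-peptide regions
#'
#' The signal-peptide region runs from the first residue to the predicted
#' cleavage position; the putative partial transit-peptide region is the
#' `tpLen` (~25) residues immediately following it, truncated at the end
#' of the sequence.
#'
#' @param seq amino-acid sequence.
#' @param call a positive [SignalPeptideCall-class].
#' @param tpLen transit-peptide region length (default 25).
#' @return List with `id`, `spRegion`, `tpRegion`.
#' @export
extractRegions <- function(seq, call, tpLen = 25) {
  if (!call@hasSp)
    stop(sprintf("'%s' has no predicted signal peptide", call@id))
  cp <- as.integer(call@cleavagePos)
  if (cp > nchar(seq))
    stop(sprintf("cleavage position %d beyond sequence '%s'", cp, call@id))
  list(id = call@id,
       spRegion = substring(seq, 1, cp),
       tpRegion = substring(seq, cp + 1, min(cp + tpLen, nchar(seq))))
}

#' Occurrence of three-letter motifs across signal-peptide regions
#'
#' For each motif, the percentage of regions containing the motif at least
#' once (multiple occurrences within one region count once). With
#' `motifs = "all"`, every 3-mer present in at least one region is
#' enumerated.
#'
#' @param regions character vector of region strings.
#' @param motifs character vector of 3-letter motifs, or `"all"`.
#' @return data.frame with columns `motif` and `percentage` (descending).
#' @examples
#' motifOccurrence(c("MLACLACGHG", "MKKVLTT"), c("ACL", "GHG"))
#' @export
motifOccurrence <- function(regions, motifs = "all") {
  if (!length(regions)) stop("no regions supplied")
  if (identical(motifs, "all")) {
    motifs <- unique(unlist(lapply(regions, function(r) {
      n <- nchar(r)
      if (n < 3) return(character(0))
      substring(r, 1:(n - 2), 3:n)
    })))
    if (!length(motifs))
      return(data.frame(motif = character(0), percentage = numeric(0)))
  }
  if (any(nchar(motifs) != 3))
    stop("motifs must be exactly 3 letters long")
  pct <- vapply(motifs, function(m)
    100 * mean(vapply(regions, function(r)
      grepl(m, r, fixed = TRUE), logical(1))), numeric(1))
  out <- data.frame(motif = motifs, percentage = unname(pct),
                    stringsAsFactors = FALSE)
  out[order(-out$percentage, out$motif), , drop = FALSE]
}

#' Amino-acid composition and position frequency matrix of aligned regions
#'
#' Input regions must be aligned to equal length; gap characters (`-`) are
#' excluded from all denominators. The position x letter frequency matrix
#' is directly usable for sequence-logo rendering.
#'
#' @param regions character vector (or `AAStringSet`) of equal-length
#'   aligned strings.
#' @return List with `composition` (named frequencies summing to 1),
#'   `logoMatrix` (positions x letters, each covered row summing to 1) and
#'   `coverage` (non-gap count per position; zero flags an all-gap
#'   column).
#' @export
compositionAndLogo <- function(regions) {
  if (is(regions, "AAStringSet") || is(regions, "BStringSet"))
    regions <- as.character(regions)
  if (!length(regions)) stop("no regions supplied")
  L <- unique(nchar(regions))
  if (length(L) != 1)
    stop("aligned regions must all have the same length")
  mat <- do.call(rbind, strsplit(regions, ""))
  letters <- sort(setdiff(unique(as.vector(mat)), "-"))
  comp <- vapply(letters, function(a) sum(mat == a), numeric(1))
  comp <- comp / sum(comp)
  logo <- t(vapply(seq_len(L), function(p) {
    col <- mat[, p]
    col <- col[col != "-"]
    if (!length(col)) return(stats::setNames(rep(0, length(letters)),
                                             letters))
    vapply(letters, function(a) mean(col == a), numeric(1))
  }, numeric(length(letters))))
  rownames(logo) <- as.character(seq_len(L))
  coverage <- vapply(seq_len(L), function(p) sum(mat[, p] != "-"),
                     integer(1))
  list(composition = comp, logoMatrix = logo, coverage = coverage)
}
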