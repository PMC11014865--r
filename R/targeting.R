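## Bipartite plastid-targeting prediction: SignalP table parsing, variant
## pooling, the cleavage-site PSSM, window scoring/classification, and the
## alternative PrediSI+ChloroP ("SPTP-") route.

#' Construct a signal-peptide call
#'
#' @param id sequence id.
#' @param hasSp logical(1).
#' @param cleavagePos 1-based index of the last signal-peptide residue.
#' @param spProbability predictor probability.
#' @param sourceVariant `"original"` or `"first_met_trimmed"`.
#' @return A [SignalPeptideCall-class].
#' @export
signalPeptideCall <- function(id, hasSp, cleavagePos = NA_real_,
                              spProbability = NA_real_,
                              sourceVariant = "original") {
  new("SignalPeptideCall", id = id, hasSp = hasSp,
      cleavagePos = as.numeric(cleavagePos),
      spProbability = as.numeric(spProbability),
      sourceVariant = sourceVariant)
}

#' @export
setMethod("show", "SignalPeptideCall", function(object) {
  cat(sprintf("SignalPeptideCall %s: %s%s [%s]\n", object@id,
              if (object@hasSp) "SP" else "no SP",
              if (object@hasSp) sprintf(", cleavage after %d",
                                        as.integer(object@cleavagePos))
              else "",
              object@sourceVariant))
})

#' Parse a SignalP 5.0 short-format prediction table
#'
#' Header lines start with `#`; each data row holds the sequence id, the
#' prediction class (`SP(Sec/SPI)` or `OTHER`), the two class
#' probabilities, and for positive calls a `CS pos: a-b` field from which
#' the cleavage position `a` (last signal-peptide residue) is taken.
#'
#' @param table file path or document text.
#' @param sourceVariant variant tag stored on the calls.
#' @return A list of [SignalPeptideCall-class], one per row.
#' @export
parseSignalp5 <- function(table, sourceVariant = "original") {
  lines <- readDocument(table)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec(
      "^(\\S+)\\s+(\\S+)\\s+([0-9.eE+-]+)\\s+([0-9.eE+-]+)\\s*(.*)$", ln))[[1]]
    if (!length(m))
      stop(sprintf("malformed SignalP 5.0 row: '%s'", ln))
    id <- m[2]; pred <- m[3]
    spProb <- as.numeric(m[4])
    rest <- m[6]
    if (grepl("^SP", pred)) {
      cs <- regmatches(rest, regexec("CS pos:\\s*([0-9]+)-([0-9]+)", rest))[[1]]
      if (length(cs) < 3)
        stop(sprintf("SP row for '%s' lacks a parsable CS position", id))
      signalPeptideCall(id, TRUE, as.numeric(cs[2]), spProb, sourceVariant)
    } else {
      signalPeptideCall(id, FALSE, NA_real_, spProb, sourceVariant)
    }
  })
}

#' Write signal-peptide calls as a SignalP 3.0--4.1-style legacy table
#'
#' Tab-separated short format: name, Cmax, pos (first residue of the
#' mature protein, i.e. cleavagePos + 1), Ymax, pos, Smax, pos, Smean, D,
#' and the Y/N decision. Probabilities fall back to the D column; the
#' numeric columns other than `pos` and `D` are placeholders for dialect
#' compatibility.
#'
#' @param calls list of [SignalPeptideCall-class].
#' @param path output file, or `NULL` to return the text.
#' @return Invisibly, the document text.
#' @export
writeLegacySignalp <- function(calls, path = NULL) {
  rows <- vapply(calls, function(cl) {
    d <- if (is.na(cl@spProbability)) as.numeric(cl@hasSp)
         else cl@spProbability
    pos <- if (cl@hasSp) cl@cleavagePos + 1 else 1
    sprintf("%s\t%.3f\t%d\t%.3f\t%d\t%.3f\t%d\t%.3f\t%.3f\t%s",
            cl@id, d, as.integer(pos), d, as.integer(pos), d,
            as.integer(max(pos - 1, 1)), d, d,
            if (cl@hasSp) "Y" else "N")
  }, "")
  txt <- c("# plastosort legacy signal-peptide table (SignalP 3.0-4.1 dialect)",
           "# name\tCmax\tpos\tYmax\tpos\tSmax\tpos\tSmean\tD\t?",
           rows)
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Parse a legacy (SignalP 3.0--4.1 dialect) table back into calls
#'
#' @param table file path or document text as written by
#'   [writeLegacySignalp()].
#' @param sourceVariant variant tag stored on the calls.
#' @return A list of [SignalPeptideCall-class].
#' @export
readLegacySignalp <- function(table, sourceVariant = "original") {
  lines <- readDocument(table)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 10)
      stop(sprintf("malformed legacy row: '%s'", ln))
    hasSp <- f[10] == "Y"
    signalPeptideCall(f[1], hasSp,
                      if (hasSp) as.numeric(f[3]) - 1 else NA_real_,
                      as.numeric(f[9]), sourceVariant)
  })
}

#' Trim a protein sequence to its first methionine
#'
#' Accommodates translated UTRs or spliced leaders ahead of the true start.
#'
#' @param seq amino-acid sequence (character scalar).
#' @return The subsequence starting at the first `M`, or `NA_character_`
#'   when the sequence contains no methionine (the variant is skipped).
#' @examples
#' firstMetTrim("ARMLKV")  # "MLKV"
#' @export
firstMetTrim <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nzchar(seq))
  i <- regexpr("M", seq, fixed = TRUE)
  if (i == -1) return(NA_character_)
  substring(seq, i)
}

#' Pool original and first-methionine-trimmed signal-peptide calls
#'
#' A positive prediction takes priority over a negative one; a positive
#' call on the trimmed variant is shifted back into original coordinates
#' by `trimOffset`. When both variants are positive the original-variant
#' call is kept.
#'
#' @param original [SignalPeptideCall-class] on the untrimmed sequence.
#' @param trimmed [SignalPeptideCall-class] on the trimmed variant, or
#'   `NULL` when the variant was skipped.
#' @param trimOffset number of residues removed before the first
#'   methionine.
#' @return The pooled [SignalPeptideCall-class] in original coordinates.
#' @export
poolVariantCalls <- function(original, trimmed, trimOffset = 0) {
  if (is.null(trimmed)) return(original)
  stopifnot(original@id == trimmed@id)
  if (original@hasSp) return(original)
  if (trimmed@hasSp) {
    return(signalPeptideCall(trimmed@id, TRUE,
                             trimmed@cleavagePos + trimOffset,
                             trimmed@spProbability,
                             "first_met_trimmed"))
  }
  original
}

#' Uniform amino-acid background frequencies
#' @return Named numeric(20), each 0.05.
#' @export
uniformBackground <- function() {
  stats::setNames(rep(1 / 20, 20), AA20)
}

#' Build a log-odds cleavage-site scoring matrix from training windows
#'
#' Windows are equal-length gap-free amino-acid strings aligned on the
#' cleavage site. Scores are
#' `log2((count(p, a) + pseudocount * background[a]) / (N + pseudocount) /
#' background[a])`, so training frequencies equal to the background give
#' score 0 everywhere.
#'
#' @param trainingWindows character vector of equal-length windows.
#' @param background named numeric(20) of background frequencies.
#' @param pseudocount non-negative pseudocount mass (default 1).
#' @param start relative coordinate of the first window column (default
#'   -5; coordinate 0 is the first residue after the cleavage site).
#' @return A [PSSM-class].
#' @export
buildPssm <- function(trainingWindows, background = uniformBackground(),
                      pseudocount = 1, start = -5L) {
  if (!length(trainingWindows)) stop("need at least one training window")
  L <- unique(nchar(trainingWindows))
  if (length(L) != 1) stop("training windows differ in length")
  mat <- do.call(rbind, strsplit(trainingWindows, ""))
  bad <- setdiff(unique(as.vector(mat)), AA20)
  if (length(bad))
    stop(sprintf("unknown residue(s) in training windows: %s",
                 paste(bad, collapse = ", ")))
  if (!all(AA20 %in% names(background)))
    stop("background must cover all 20 amino acids")
  background <- background[AA20]
  N <- length(trainingWindows)
  scores <- t(vapply(seq_len(L), function(p) {
    cnt <- vapply(AA20, function(a) sum(mat[, p] == a), numeric(1))
    log2((cnt + pseudocount * background) / (N + pseudocount) / background)
  }, numeric(20)))
  colnames(scores) <- AA20
  positions <- as.integer(start) + 0:(L - 1L)
  rownames(scores) <- as.character(positions)
  new("PSSM", positions = positions, scores = scores,
      background = background, pseudocount = as.numeric(pseudocount))
}

#' @describeIn PSSM-class the score matrix (positions x amino acids)
#' @param object a `PSSM`
#' @export
setGeneric("pssmScores", function(object) standardGeneric("pssmScores"))
#' @rdname PSSM-class
#' @export
setMethod("pssmScores", "PSSM", function(object) object@scores)

#' @describeIn PSSM-class window coordinates relative to the cleavage site
#' @export
setGeneric("pssmPositions", function(object) standardGeneric("pssmPositions"))
#' @rdname PSSM-class
#' @export
setMethod("pssmPositions", "PSSM", function(object) object@positions)

#' @export
setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM: window %d..%d (%d positions), pseudocount %g\n",
              min(object@positions), max(object@positions),
              length(object@positions), object@pseudocount))
})

#' Positional residue frequencies implied by a PSSM
#'
#' Inverts the log-odds: `freq(p, a)` proportional to
#' `background[a] * 2^score(p, a)`, renormalized per position.
#'
#' @param pssm a [PSSM-class].
#' @return Numeric matrix, positions x amino acids, rows summing to 1.
#' @export
pssmFrequencies <- function(pssm) {
  f <- sweep(2^pssm@scores, 2, pssm@background[AA20], `*`)
  f / rowSums(f)
}

#' Write a PSSM as TSV
#'
#' Rows are window positions (first column `pos`, the relative
#' coordinate), columns the 20 amino acids; background and pseudocount are
#' kept in `#` header lines so the matrix round-trips through
#' [readPssm()].
#'
#' @param pssm a [PSSM-class].
#' @param path output file, or `NULL` to return the text.
#' @return Invisibly, the document text.
#' @export
writePssm <- function(pssm, path = NULL) {
  hdr <- c(sprintf("# background\t%s",
                   paste(sprintf("%s=%.10g", AA20,
                                 pssm@background[AA20]), collapse = "\t")),
           sprintf("# pseudocount\t%.10g", pssm@pseudocount),
           paste(c("pos", AA20), collapse = "\t"))
  rows <- vapply(seq_along(pssm@positions), function(i)
    paste(c(pssm@positions[i],
            sprintf("%.10g", pssm@scores[i, ])), collapse = "\t"), "")
  txt <- c(hdr, rows)
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}

#' Read a PSSM from TSV
#'
#' @param table file path or document text as written by [writePssm()].
#'   Any matrix with a `pos` column and 20 amino-acid columns loads;
#'   background defaults to uniform when no `# background` header is
#'   present (window geometry is matrix metadata, so published matrices of
#'   any width can be loaded).
#' @return A [PSSM-class].
#' @export
readPssm <- function(table) {
  lines <- readDocument(table)
  lines <- lines[nzchar(trimws(lines))]
  bg <- uniformBackground()
  pc <- 0
  bgLine <- grep("^#\\s*background", lines, value = TRUE)
  if (length(bgLine)) {
    kv <- regmatches(bgLine[1],
                     gregexpr("([A-Z])=([0-9.eE+-]+)", bgLine[1]))[[1]]
    vals <- as.numeric(sub("^[A-Z]=", "", kv))
    names(vals) <- sub("=.*$", "", kv)
    bg[names(vals)] <- vals
  }
  pcLine <- grep("^#\\s*pseudocount", lines, value = TRUE)
  if (length(pcLine))
    pc <- as.numeric(sub("^#\\s*pseudocount\\s*", "", pcLine[1]))
  lines <- lines[!grepl("^\\s*#", lines)]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "pos" || !all(AA20 %in% hdr))
    stop("PSSM table must have a 'pos' column and all 20 amino acids")
  body <- do.call(rbind, strsplit(lines[-1], "\t", fixed = TRUE))
  positions <- as.integer(body[, 1])
  scores <- matrix(as.numeric(body[, -1, drop = FALSE]),
                   nrow = nrow(body),
                   dimnames = list(as.character(positions), hdr[-1]))
  scores <- scores[, AA20, drop = FALSE]
  new("PSSM", positions = positions, scores = scores, background = bg,
      pseudocount = pc)
}

## Window score with the matrix anchored `offset` residues downstream of
## the predicted cleavage site; positions outside the sequence contribute
## the background expectation, 0.
windowScoreAt <- function(seq, cleavagePos, pssm, offset = 0) {
  n <- nchar(seq)
  idx <- cleavagePos + offset + 1 + pssm@positions
  inside <- which(idx >= 1 & idx <= n)
  if (!length(inside))
    stop("scoring window lies entirely outside the sequence")
  total <- 0
  for (i in inside) {
    a <- substring(seq, idx[i], idx[i])
    if (a %in% AA20) total <- total + pssm@scores[i, a]
  }
  unname(total)
}

#' Classify a bipartite presequence by cleavage-site window scoring
#'
#' Implements the modified ASAFind decision structure: given a pooled
#' signal-peptide call, the scoring matrix is aligned to the predicted
#' cleavage site and the window is scored at each offset in `offsets`.
#' The call is `plastid_high` when the at-site (offset 0) score reaches
#' `tHigh` and is the maximum over the offset scan, `plastid_low` when it
#' reaches `tLow` but not the high rule, `not_plastid` otherwise, and
#' `no_sp` without a signal peptide. Window positions outside the sequence
#' contribute the background-expected score 0, so C-terminally short
#' proteins remain classifiable.
#'
#' Default thresholds scale with the matrix: with `S*` the sum of
#' per-position maximum scores, `tHigh = 0.4 * S*` and `tLow = 0.2 * S*`.
#'
#' @param seq amino-acid sequence (original coordinates).
#' @param sp the pooled [SignalPeptideCall-class].
#' @param matrix a [PSSM-class].
#' @param offsets integer offsets for the scan (default `-2:2`).
#' @param tHigh,tLow score thresholds; `NULL` uses the matrix-scaled
#'   defaults.
#' @return A [PresequenceCall-class] with route `"asafind"`.
#' @export
asafindClassify <- function(seq, sp, matrix, offsets = -2:2,
                            tHigh = NULL, tLow = NULL) {
  sMax <- sum(apply(matrix@scores, 1, max))
  if (is.null(tHigh)) tHigh <- 0.4 * sMax
  if (is.null(tLow)) tLow <- 0.2 * sMax
  if (tLow > tHigh) stop("tLow must not exceed tHigh")
  if (!sp@hasSp) {
    return(new("PresequenceCall", id = sp@id, sp = sp,
               atSiteScore = NA_real_, bestOffsetScore = NA_real_,
               bestOffset = NA_real_, klass = "no_sp", route = "asafind",
               outputId = sp@id))
  }
  offsets <- sort(unique(c(0L, as.integer(offsets))))
  scores <- vapply(offsets, function(d)
    windowScoreAt(seq, sp@cleavagePos, matrix, d), numeric(1))
  atSite <- scores[offsets == 0L]
  bestI <- which.max(scores)
  klass <- if (atSite >= tHigh && atSite >= max(scores)) "plastid_high"
           else if (atSite >= tLow) "plastid_low"
           else "not_plastid"
  new("PresequenceCall", id = sp@id, sp = sp, atSiteScore = atSite,
      bestOffsetScore = scores[bestI], bestOffset = offsets[bestI],
      klass = klass, route = "asafind", outputId = sp@id)
}

#' @export
setMethod("show", "PresequenceCall", function(object) {
  cat(sprintf("PresequenceCall %s: %s", object@outputId, object@klass))
  if (!is.na(object@atSiteScore))
    cat(sprintf(" (at-site %.2f, best %.2f at offset %+d)",
                object@atSiteScore, object@bestOffsetScore,
                as.integer(object@bestOffset)))
  cat(sprintf(" [%s]\n", object@route))
})

#' Screen many sequences through the presequence classifier
#'
#' Runs [asafindClassify()] per sequence after pooling original and
#' first-methionine-trimmed signal-peptide calls when both are supplied.
#'
#' @param seqs named character vector or `AAStringSet`.
#' @param calls list of [SignalPeptideCall-class] for the original
#'   sequences (ids must match).
#' @param matrix a [PSSM-class].
#' @param trimmedCalls optional list of calls on the first-methionine
#'   variants, pooled into the originals.
#' @param ... passed to [asafindClassify()].
#' @return data.frame with one row per sequence: `id`, `hasSp`,
#'   `cleavagePos`, `atSiteScore`, `bestOffsetScore`, `bestOffset`,
#'   `klass`.
#' @export
asafindScreen <- function(seqs, calls, matrix, trimmedCalls = NULL, ...) {
  if (is(seqs, "AAStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  byId <- stats::setNames(calls, vapply(calls, function(x) x@id, ""))
  trimById <- if (is.null(trimmedCalls)) list()
    else stats::setNames(trimmedCalls,
                         vapply(trimmedCalls, function(x) x@id, ""))
  rows <- lapply(names(seqs), function(id) {
    cl <- byId[[id]]
    if (is.null(cl))
      stop(sprintf("no signal-peptide call for sequence '%s'", id))
    tr <- trimById[[id]]
    if (!is.null(tr)) {
      off <- regexpr("M", seqs[[id]], fixed = TRUE) - 1L
      cl <- if (off >= 0) poolVariantCalls(cl, tr, off) else cl
    }
    pc <- asafindClassify(seqs[[id]], cl, matrix, ...)
    data.frame(id = id, hasSp = cl@hasSp,
               cleavagePos = cl@cleavagePos,
               atSiteScore = pc@atSiteScore,
               bestOffsetScore = pc@bestOffsetScore,
               bestOffset = pc@bestOffset, klass = pc@klass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Parse a PrediSI-style tabular prediction
#'
#' Tab-separated rows: id, score, cleavage position, Y/N decision.
#'
#' @param table file path or document text.
#' @return data.frame with `id`, `score`, `pos`, `positive`.
#' @export
parsePredisi <- function(table) {
  lines <- readDocument(table)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(id = f[, 1], score = as.numeric(f[, 2]),
             pos = as.integer(f[, 3]), positive = f[, 4] == "Y",
             stringsAsFactors = FALSE)
}

#' Parse a ChloroP-style tabular prediction
#'
#' Tab-separated rows: id, length, score, cTP decision (Y/N or Y/_),
#' CS-score, predicted transit-peptide length.
#'
#' @param table file path or document text.
#' @return data.frame with `id`, `score`, `positive`, `tpLen`.
#' @export
parseChlorop <- function(table) {
  lines <- readDocument(table)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(id = f[, 1], score = as.numeric(f[, 3]),
             positive = f[, 4] == "Y", tpLen = as.integer(f[, 6]),
             stringsAsFactors = FALSE)
}

#' Sequence ids positive by both PrediSI and ChloroP
#'
#' @param predisi data.frame from [parsePredisi()].
#' @param chlorop data.frame from [parseChlorop()].
#' @return Character vector of ids positive in both tables.
#' @export
altPositiveIds <- function(predisi, chlorop) {
  intersect(predisi$id[predisi$positive], chlorop$id[chlorop$positive])
}

#' Merge the primary and alternative prediction routes
#'
#' The final predicted plastid-proteome id list: all sequences called
#' `plastid_high` or `plastid_low` by the primary route, plus -- prefixed
#' with `"SPTP-"` -- the sequences negative by the primary route but
#' positive by both PrediSI and ChloroP.
#'
#' @param primaryCalls list of [PresequenceCall-class] (or the data.frame
#'   from [asafindScreen()]).
#' @param altPositiveIds character vector of alternative-route-positive
#'   ids.
#' @return Sorted character vector of final ids, `"SPTP-"`-prefixed where
#'   applicable, without duplicates.
#' @export
mergeRoutes <- function(primaryCalls, altPositiveIds = character(0)) {
  if (is.data.frame(primaryCalls)) {
    ids <- primaryCalls$id
    klass <- primaryCalls$klass
  } else {
    ids <- vapply(primaryCalls, function(x) x@id, "")
    klass <- vapply(primaryCalls, function(x) x@klass, "")
  }
  positive <- ids[klass %in% c("plastid_high", "plastid_low")]
  altOnly <- setdiff(altPositiveIds, positive)
  sort(unique(c(positive, paste0("SPTP-", altOnly))))
}
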