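## Hit-table filtering, decontamination, homolog-set categorization and the
## alignment acceptance filters that gate which proteins receive trees.

#' Read a 12-column tabular homology hit file
#'
#' BLAST outfmt-6 dialect (as emitted by LAST's tab converter): qseqid,
#' sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart, send,
#' evalue, bitscore. Lines starting with `#` are skipped.
#'
#' @param path file path.
#' @return data.frame with columns `query`, `subject`, `evalue`, `score`
#'   (bitscore) plus the remaining standard columns.
#' @export
readHitTable <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "score")
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = cols)
  df$evalue <- as.numeric(df$evalue)
  df$score <- as.numeric(df$score)
  if (any(df$evalue < 0)) stop("negative e-value in hit table")
  df
}

## order hits best-first: lowest e-value, then highest score, then subject id
orderHits <- function(hits) {
  hits[order(hits$evalue, -hits$score, hits$subject, method = "radix"), ,
       drop = FALSE]
}

#' Filter homology hits for one query
#'
#' Drops hits above the e-value threshold (the threshold itself is kept,
#' i.e. `evalue <= eMax` is retained), removes the query's self-hit, then
#' keeps the single best hit per in-house dataset and the best `perFucoxK`
#' hits per fucoxanthin-dinoflagellate library (members of `fucoxGroup`),
#' the latter to accommodate recent paralogs. Best = lowest e-value, ties
#' by higher score then subject id.
#'
#' @param hits data.frame as from [readHitTable()] (one query).
#' @param scheme a [TaxonScheme-class] resolving subject ids to datasets.
#' @param eMax e-value threshold (default `1e-10`, inclusive).
#' @param perFucoxK hits retained per fucoxanthin library (default 5).
#' @param fucoxGroup group id marking fucoxanthin-dinoflagellate libraries.
#' @param query the query id (self-hits to it are excluded); defaults to
#'   the table's single query id.
#' @return The retained subset of `hits`, best-first within dataset.
#' @export
filterHits <- function(hits, scheme, eMax = 1e-10, perFucoxK = 5,
                       fucoxGroup = "fucoxanthin", query = NULL) {
  if (!nrow(hits)) return(hits)
  if (length(unique(hits$query)) > 1)
    stop("filterHits expects hits of a single query")
  if (is.null(query)) query <- hits$query[1]
  hits <- hits[hits$evalue <= eMax & hits$subject != query, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  info <- lapply(hits$subject, resolveLeaf, scheme = scheme)
  hits$dataset <- vapply(info, `[[`, "", "dataset")
  fucox <- vapply(info, function(r) fucoxGroup %in% r$groups, logical(1))
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$dataset),
                        function(idx) {
    k <- if (fucox[idx[1]]) perFucoxK else 1L
    ord <- idx[order(hits$evalue[idx], -hits$score[idx],
                     hits$subject[idx], method = "radix")]
    utils::head(ord, k)
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Categorize a query's retained homolog set
#'
#' No hits at all: `lineage-specific`. Homologs only within dinoflagellates
#' (kareniacean or otherwise): `dinoflagellate-specific`. Anything else:
#' `phylogeny-candidate` (the query proceeds to alignment and tree
#' building).
#'
#' @param query the query id.
#' @param hits the retained hits (after [filterHits()]).
#' @param scheme a [TaxonScheme-class].
#' @param dinoGroup the group spanning all dinoflagellates.
#' @return One of `"lineage-specific"`, `"dinoflagellate-specific"`,
#'   `"phylogeny-candidate"`.
#' @export
categorizeHomologSet <- function(query, hits, scheme,
                                 dinoGroup = "dinoflagellates") {
  if (is.null(hits) || !nrow(hits)) return("lineage-specific")
  dino <- vapply(hits$subject, function(s)
    dinoGroup %in% resolveLeaf(scheme, s)$groups, logical(1))
  if (all(dino)) "dinoflagellate-specific" else "phylogeny-candidate"
}

#' Decontamination rule on the overall best hit
#'
#' A sequence is dropped when its best homology hit is to a eubacterial,
#' archaeal or metazoan sequence at e-value `<= eMax`.
#'
#' @param bestHit one-row data.frame (the query's overall best hit) or
#'   `NULL`/zero rows when the query had no hit.
#' @param scheme a [TaxonScheme-class].
#' @param eMax e-value threshold (default `1e-10`, inclusive).
#' @param contaminantGroups group ids treated as contamination sources.
#' @return `TRUE` to keep the sequence, `FALSE` to drop it.
#' @export
decontaminate <- function(bestHit, scheme, eMax = 1e-10,
                          contaminantGroups = c("eubacteria", "archaea",
                                                "metazoa")) {
  if (is.null(bestHit) || !nrow(bestHit)) return(TRUE)
  if (nrow(bestHit) > 1) bestHit <- orderHits(bestHit)[1, , drop = FALSE]
  groups <- resolveLeaf(scheme, bestHit$subject)$groups
  !(any(contaminantGroups %in% groups) && bestHit$evalue <= eMax)
}

## normalize alignment input to a named character vector of rows
alignmentRows <- function(aln) {
  if (is(aln, "AAStringSet") || is(aln, "BStringSet"))
    aln <- stats::setNames(as.character(aln), names(aln))
  if (!is.character(aln)) stop("alignment must be AAStringSet or character")
  if (length(aln) && length(unique(nchar(aln))) != 1)
    stop("alignment rows differ in length")
  if (length(aln) && is.null(names(aln)))
    names(aln) <- paste0("seq", seq_along(aln))
  aln
}

#' Gap-based row removal and acceptance filter for trimmed alignments
#'
#' Rows with a gap fraction strictly greater than `maxGapFrac` (gaps over
#' total alignment columns) are removed first; the alignment is then
#' accepted iff it has at least `minColumns` columns and at least `minTaxa`
#' remaining rows. Retained residues are never altered.
#'
#' @param aln an `AAStringSet` or named character vector of equal-length
#'   aligned rows (`-` gaps).
#' @param maxGapFrac maximum tolerated gap fraction (default 0.75).
#' @param minColumns minimum alignment length (default 100).
#' @param minTaxa minimum number of retained rows (default 10).
#' @return List with `alignment` (the retained rows, as
#'   `Biostrings::AAStringSet`), `accepted` flag, and `report`
#'   (data.frame of all rows with `gapFrac` and `removed`).
#' @export
filterAlignment <- function(aln, maxGapFrac = 0.75, minColumns = 100,
                            minTaxa = 10) {
  rows <- alignmentRows(aln)
  if (!length(rows)) {
    return(list(alignment = Biostrings::AAStringSet(), accepted = FALSE,
                report = data.frame(id = character(0), gapFrac = numeric(0),
                                    removed = logical(0))))
  }
  ncol <- nchar(rows[1])
  gapFrac <- vapply(rows, function(r)
    lengths(regmatches(r, gregexpr("-", r, fixed = TRUE))) / ncol,
    numeric(1))
  removed <- gapFrac > maxGapFrac
  kept <- rows[!removed]
  accepted <- ncol >= minColumns && length(kept) >= minTaxa
  list(alignment = Biostrings::AAStringSet(kept),
       accepted = accepted,
       report = data.frame(id = names(rows), gapFrac = unname(gapFrac),
                           removed = unname(removed),
                           stringsAsFactors = FALSE))
}
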