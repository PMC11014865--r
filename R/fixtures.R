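## Deterministic synthetic-data generators with planted ground truth.
## Every generator is reproducible under its seed and emits the exact
## external formats the consuming modules read.

## evaluate expr under a temporary RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a planted-origin synthetic gene tree
#'
#' @slot category name of the planted category.
#' @slot support planted support on the qualifying edge, in `[0, 100]`.
#' @slot cladeSize number of category-member leaves in the planted clade
#'   (>= 2).
#' @slot nBackgroundLeaves number of non-competing background leaves
#'   (>= 2).
#' @slot kareniaceanInclusion also nest a (neutral) kareniacean leaf
#'   inside the qualifying clade, next to the seed.
#' @slot rngSeed integer seed; equal seeds give byte-identical output.
#' @exportClass PlantedTreeSpec
setClass("PlantedTreeSpec",
  slots = c(category = "character", support = "numeric",
            cladeSize = "numeric", nBackgroundLeaves = "numeric",
            kareniaceanInclusion = "logical", rngSeed = "numeric"))

setValidity("PlantedTreeSpec", function(object) {
  if (object@cladeSize < 2) return("cladeSize must be >= 2")
  if (object@nBackgroundLeaves < 2)
    return("nBackgroundLeaves must be >= 2")
  if (is.na(object@support) || object@support < 0 || object@support > 100)
    return("support must lie in [0, 100]")
  TRUE
})

#' @rdname PlantedTreeSpec-class
#' @param category,support,cladeSize,nBackgroundLeaves,kareniaceanInclusion,rngSeed
#'   see the class slots.
#' @export
plantedTreeSpec <- function(category, support, cladeSize = 2,
                            nBackgroundLeaves = 6,
                            kareniaceanInclusion = FALSE, rngSeed = 1) {
  new("PlantedTreeSpec", category = category, support = support,
      cladeSize = cladeSize, nBackgroundLeaves = nBackgroundLeaves,
      kareniaceanInclusion = kareniaceanInclusion, rngSeed = rngSeed)
}

## random binary join of leaf/newick tokens, internal nodes labelled with
## random supports
randomJoin <- function(tokens) {
  while (length(tokens) > 1) {
    i <- sample.int(length(tokens), 2)
    joined <- sprintf("(%s,%s)%d", tokens[i[1]], tokens[i[2]],
                      sample.int(101, 1) - 1L)
    tokens <- c(tokens[-i], joined)
  }
  tokens
}

#' Simulate a gene tree with a planted evolutionary-origin signal
#'
#' Builds a random binary tree in which the seed (kareniacean) leaf is
#' sister to a pure clade of `cladeSize` members of the planted category,
#' with the planted support on the subtending edge. Background leaves are
#' drawn from groups that share no category-relevant ancestry with the
#' planted group and alternate between two such groups, so no competing
#' category criterion can qualify on any seed-containing side; planted
#' recovery is exact by construction. For a category with a witness
#' subgroup, the first clade member is drawn from the witness.
#'
#' @param spec a [PlantedTreeSpec-class].
#' @param scheme a [TaxonScheme-class].
#' @param categories category definitions the tree must discriminate
#'   (default [defaultCategories()]); used to find the planted category
#'   and to rule out competing background groups.
#' @return List with `tree` (a [PhyloTree-class]) and `truth` (list:
#'   `category`, `support`, `seed`, `cladeLeaves`, `newick`).
#' @export
simulateOriginTree <- function(spec, scheme,
                               categories = defaultCategories()) {
  validObject(spec)
  catNames <- vapply(categories, function(c) c@name, "")
  if (!(spec@category %in% catNames))
    stop(sprintf("unknown category '%s'", spec@category))
  cat <- categories[[match(spec@category, catNames)]]
  X <- cat@memberGroup

  neutralDs <- if (!is.na(seedLineage(scheme)))
    schemeDatasets(scheme, seedLineage(scheme)) else character(0)
  xAncAll <- groupAncestors(scheme, X)
  ## a clade member must not belong to another category's member group
  ## (unless that group is an ancestor of the planted group, where the
  ## witness rule keeps the categories apart), or an exact-score tie with
  ## that category would defeat planted recovery
  unambiguous <- function(d) {
    cl <- datasetGroupClosure(scheme, d)
    !any(vapply(categories, function(c2)
      c2@name != cat@name && c2@memberGroup %in% cl &&
        !(c2@memberGroup %in% xAncAll), logical(1)))
  }
  memberDs <- Filter(unambiguous,
                     setdiff(schemeDatasets(scheme, X), neutralDs))
  if (!length(memberDs))
    stop(sprintf("no non-neutral datasets in group '%s'", X))
  witnessDs <- if (!is.na(cat@witnessGroup))
    Filter(unambiguous,
           setdiff(schemeDatasets(scheme, cat@witnessGroup), neutralDs))
  else character(0)
  if (!is.na(cat@witnessGroup) && !length(witnessDs))
    stop(sprintf("no datasets in witness group '%s'", cat@witnessGroup))

  ## background datasets must share no ancestor lineage with the planted
  ## group (rules out wider categories absorbing supersets of the clade)
  xAnc <- groupAncestors(scheme, X)
  bgDs <- Filter(function(d) {
    cl <- datasetGroupClosure(scheme, d)
    !length(intersect(cl, xAnc)) && !(d %in% neutralDs)
  }, schemeDatasets(scheme))
  if (length(bgDs) < 2)
    stop(sprintf("scheme offers too few background datasets for '%s'", X))
  bgGroupOf <- vapply(bgDs, function(d) scheme@datasetGroups[[d]][1], "")

  withSeed(spec@rngSeed, {
    serial <- 0L
    mkLeaf <- function(ds) {
      serial <<- serial + 1L
      sprintf("%s_%04d", ds, serial)
    }
    nW <- if (length(witnessDs)) 1L else 0L
    cladeDs <- c(if (nW) sample(witnessDs, 1),
                 sample(memberDs, spec@cladeSize - nW, replace = TRUE))
    cladeLeaves <- vapply(cladeDs, mkLeaf, "")

    seedDs <- if (length(neutralDs)) neutralDs[1] else memberDs[1]
    seedLeaf <- mkLeaf(seedDs)
    seedPart <- if (spec@kareniaceanInclusion && length(neutralDs))
      sprintf("(%s,%s)%d", seedLeaf, mkLeaf(neutralDs[min(2, length(neutralDs))]),
              sample.int(101, 1) - 1L)
    else seedLeaf

    cladePart <- randomJoin(cladeLeaves)
    planted <- sprintf("(%s,%s)%s", seedPart, cladePart,
                       formatSupportLabel(spec@support))

    ## alternate background leaves between two unrelated groups
    twoGroups <- unique(bgGroupOf)
    if (length(twoGroups) >= 2) {
      gA <- bgDs[bgGroupOf == twoGroups[1]]
      gB <- bgDs[bgGroupOf == twoGroups[2]]
      pick <- function(i) if (i %% 2 == 1) sample(gA, 1) else sample(gB, 1)
    } else pick <- function(i) sample(bgDs, 1)
    bgLeaves <- vapply(seq_len(spec@nBackgroundLeaves),
                       function(i) mkLeaf(pick(i)), "")
    half <- ceiling(length(bgLeaves) / 2)
    bg1 <- randomJoin(bgLeaves[seq_len(half)])
    bg2 <- randomJoin(bgLeaves[-seq_len(half)])
    nwk <- sprintf("(%s,%s,%s);", planted, bg1, bg2)
    tree <- parseNewickTrees(nwk,
                             sprintf("planted_%s_%d", spec@category,
                                     spec@rngSeed))[[1]]
    list(tree = tree,
         truth = list(category = spec@category, support = spec@support,
                      seed = seedLeaf, cladeLeaves = sort(cladeLeaves),
                      newick = nwk))
  })
}

#' Simulate an alignment with prescribed per-row gap fractions
#'
#' Row `i` receives exactly `round(gapFracs[i] * nCols)` gaps at random
#' positions; residues are uniform over the 20-letter alphabet.
#'
#' @param nRows,nCols alignment dimensions.
#' @param gapFracs numeric vector of length `nRows`, each in `[0, 1]`.
#' @param rngSeed integer seed.
#' @return A `Biostrings::AAStringSet` of aligned rows.
#' @export
simulateAlignment <- function(nRows, nCols, gapFracs, rngSeed = 1) {
  if (length(gapFracs) != nRows)
    stop("gapFracs must have one entry per row")
  if (any(gapFracs < 0 | gapFracs > 1))
    stop("gap fractions must lie in [0, 1]")
  withSeed(rngSeed, {
    rows <- vapply(seq_len(nRows), function(i) {
      chars <- sample(AA20, nCols, replace = TRUE)
      ng <- round(gapFracs[i] * nCols)
      if (ng > 0) chars[sample.int(nCols, ng)] <- "-"
      paste(chars, collapse = "")
    }, "")
    names(rows) <- sprintf("seq_%03d", seq_len(nRows))
    Biostrings::AAStringSet(rows)
  })
}

#' Simulate presequences with known cleavage sites from a PSSM
#'
#' Each sequence is a random signal peptide of sampled length (starting
#' with methionine), its C-terminal residues and the transit-peptide start
#' drawn from the matrix's positional residue distributions anchored on
#' the cleavage site, followed by a random tail. A matching SignalP 5.0
#' short-format document with the true cleavage sites is emitted.
#'
#' @param matrix a [PSSM-class].
#' @param n number of sequences.
#' @param spLenRange integer range of signal-peptide lengths; the minimum
#'   must exceed the number of negative window positions.
#' @param rngSeed integer seed.
#' @param tailLen residues appended after the window.
#' @return List with `sequences` (`AAStringSet`), `truth` (data.frame
#'   `id`, `cleavagePos`) and `signalp` (character vector of SignalP 5.0
#'   short-format lines).
#' @export
simulatePresequences <- function(matrix, n, spLenRange = c(15, 30),
                                 rngSeed = 1, tailLen = 40) {
  stopifnot(n >= 1)
  nNeg <- sum(matrix@positions < 0)
  if (spLenRange[1] <= nNeg)
    stop(sprintf("minimum signal-peptide length must exceed %d", nNeg))
  freqs <- pssmFrequencies(matrix)
  withSeed(rngSeed, {
    ids <- sprintf("prot_%04d", seq_len(n))
    cleavage <- integer(n)
    seqs <- vapply(seq_len(n), function(i) {
      lens <- spLenRange[1]:spLenRange[2]
      L <- lens[sample.int(length(lens), 1)]
      cleavage[i] <<- L
      prefix <- c("M", sample(AA20, L - nNeg - 1, replace = TRUE))
      win <- vapply(seq_len(nrow(freqs)), function(p)
        sample(AA20, 1, prob = freqs[p, ]), "")
      tail <- sample(AA20, tailLen, replace = TRUE)
      paste(c(prefix, win, tail), collapse = "")
    }, "")
    names(seqs) <- ids
    signalp <- c("# SignalP-5.0   Organism: Eukarya",
                 "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
                 sprintf("%s\tSP(Sec/SPI)\t0.9900\t0.0100\tCS pos: %d-%d. Pr: 0.9500",
                         ids, cleavage, cleavage + 1L))
    list(sequences = Biostrings::AAStringSet(seqs),
         truth = data.frame(id = ids, cleavagePos = cleavage,
                            stringsAsFactors = FALSE),
         signalp = signalp)
  })
}

#' Simulate a homology hit table with known retention truth
#'
#' Emits hits for one query across chosen datasets with prescribed
#' e-values, in the 12-column tabular dialect read by [readHitTable()].
#'
#' @param query query id.
#' @param subjectDatasets character vector: the dataset of each hit.
#' @param evalues numeric vector of e-values (same length).
#' @param rngSeed integer seed (controls bitscores and subject serials).
#' @return data.frame in [readHitTable()] column layout.
#' @export
simulateHitTable <- function(query, subjectDatasets, evalues, rngSeed = 1) {
  stopifnot(length(subjectDatasets) == length(evalues))
  withSeed(rngSeed, {
    n <- length(evalues)
    data.frame(query = query,
               subject = sprintf("%s_%04d", subjectDatasets, seq_len(n)),
               pident = round(stats::runif(n, 30, 90), 1),
               length = sample(80:400, n, replace = TRUE),
               mismatch = sample(0:50, n, replace = TRUE),
               gapopen = sample(0:5, n, replace = TRUE),
               qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
               evalue = evalues,
               score = round(stats::runif(n, 50, 300), 1),
               stringsAsFactors = FALSE)
  })
}
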