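## Reading, writing and bipartition structure of support-valued gene trees.
##
## Newick statements are parsed by ape::read.tree after a light rewrite that
## turns branch-annotation support comments ("[&support=95]") into internal
## node labels, the dialect ape understands. The Nexus TREES block (with an
## optional TRANSLATE table) is handled by a small reader here so that
## support labels survive translation exactly.

#' Parse gene trees from Newick or Nexus input
#'
#' Accepts a file path or the document text itself. Each tree statement
#' yields one [PhyloTree-class]. Supports may be given as internal node
#' labels (`"(A,B)95:0.1"`) or as branch annotations (`"(A,B)[&support=95]"`);
#' values on a 0--1 scale (all labelled supports <= 1) are interpreted as
#' proportions and multiplied by 100. Internal edges without a support label
#' are imputed as 0 and flagged. Rooted inputs are stored as read but all
#' downstream operations treat them as unrooted.
#'
#' @param pathOrText path to a tree file, or a character scalar/vector
#'   holding the document text.
#' @param format `"newick"`, `"nexus"`, or `"auto"` (detects Nexus from a
#'   leading `#NEXUS`).
#' @return A list of [PhyloTree-class] objects.
#' @examples
#' trees <- parseTreeFile("((A:1,B:1)95:1,(C:1,D:1)80:1);")
#' nLeaves(trees[[1]])
#' @export
parseTreeFile <- function(pathOrText, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  txt <- readDocument(pathOrText)
  if (!any(nzchar(trimws(txt))))
    stop("empty tree document")
  full <- paste(txt, collapse = "\n")
  if (format == "auto")
    format <- if (grepl("^\\s*#NEXUS", full, ignore.case = TRUE))
      "nexus" else "newick"
  if (format == "nexus") parseNexusTrees(full) else parseNewickTrees(full)
}

readDocument <- function(pathOrText) {
  if (length(pathOrText) == 1 && file.exists(pathOrText) &&
      !dir.exists(pathOrText))
    return(readLines(pathOrText, warn = FALSE))
  looksLikePath <- length(pathOrText) == 1 &&
    !grepl("[(;\n\t ]", pathOrText) &&
    grepl("[/\\\\]|\\.[A-Za-z0-9_]{1,10}$", pathOrText)
  if (looksLikePath)
    stop(sprintf("file not found: '%s'", pathOrText))
  unlist(strsplit(pathOrText, "\n", fixed = TRUE))
}

## rewrite "[&...support=x...]" comments into node labels, drop the rest
rewriteSupportComments <- function(txt) {
  txt <- gsub("\\)\\s*\\[&[^\\]]*?support=([0-9.eE+-]+)[^\\]]*\\]",
              ")\\1", txt, perl = TRUE)
  txt <- gsub("\\)(:[0-9.eE+-]+)\\s*\\[&[^\\]]*?support=([0-9.eE+-]+)[^\\]]*\\]",
              ")\\2\\1", txt, perl = TRUE)
  gsub("\\[[^\\]]*\\]", "", txt, perl = TRUE)
}

parseNewickTrees <- function(txt, ids = NULL) {
  txt <- rewriteSupportComments(txt)
  stmts <- strsplit(txt, ";", fixed = TRUE)[[1]]
  stmts <- trimws(stmts)
  stmts <- stmts[nzchar(stmts)]
  if (!length(stmts)) stop("no tree statements found")
  if (is.null(ids)) ids <- paste0("tree_", seq_along(stmts))
  mapply(function(s, id) {
    opens <- lengths(regmatches(s, gregexpr("(", s, fixed = TRUE)))
    closes <- lengths(regmatches(s, gregexpr(")", s, fixed = TRUE)))
    if (opens != closes)
      stop(sprintf("unbalanced parentheses in tree '%s' (%d '(' vs %d ')')",
                   id, opens, closes))
    ph <- tryCatch(ape::read.tree(text = paste0(s, ";")),
                   error = function(e)
                     stop(sprintf("cannot parse tree '%s': %s",
                                  id, conditionMessage(e)), call. = FALSE))
    if (is.null(ph))
      stop(sprintf("cannot parse tree '%s'", id))
    newPhyloTree(ph, id)
  }, stmts, ids, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

parseNexusTrees <- function(txt) {
  txt2 <- rewriteSupportComments(txt)
  m <- regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", txt2, perl = TRUE)
  if (m == -1) stop("no TREES block found in Nexus document")
  block <- regmatches(txt2, m)
  block <- sub("(?is)^begin\\s+trees\\s*;", "", block, perl = TRUE)
  block <- sub("(?is)\\bend\\s*;$", "", block, perl = TRUE)
  stmts <- trimws(strsplit(block, ";", fixed = TRUE)[[1]])
  stmts <- stmts[nzchar(stmts)]
  translate <- NULL
  treeStmts <- character(0)
  treeIds <- character(0)
  for (s in stmts) {
    if (grepl("^translate\\b", s, ignore.case = TRUE)) {
      body <- sub("(?i)^translate\\s*", "", s, perl = TRUE)
      entries <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
      entries <- entries[nzchar(entries)]
      toks <- do.call(rbind, lapply(entries, function(e) {
        p <- strsplit(e, "\\s+")[[1]]
        if (length(p) < 2)
          stop(sprintf("malformed TRANSLATE entry: '%s'", e))
        c(p[1], paste(p[-1], collapse = " "))
      }))
      translate <- stats::setNames(toks[, 2], toks[, 1])
    } else if (grepl("^tree\\b", s, ignore.case = TRUE)) {
      id <- sub("(?i)^tree\\s+([^=\\s]+)\\s*=.*$", "\\1", s, perl = TRUE)
      nwk <- sub("(?i)^tree\\s+[^=]*=\\s*", "", s, perl = TRUE)
      treeStmts <- c(treeStmts, nwk)
      treeIds <- c(treeIds, id)
    }
  }
  if (!length(treeStmts)) stop("TREES block contains no tree statements")
  trees <- parseNewickTrees(paste0(treeStmts, ";", collapse = "\n"), treeIds)
  if (!is.null(translate)) {
    trees <- lapply(trees, function(tr) {
      lab <- tr@phylo$tip.label
      hit <- lab %in% names(translate)
      lab[hit] <- unname(translate[lab[hit]])
      tr@phylo$tip.label <- lab
      validObject(tr)
      tr
    })
  }
  trees
}

## Build a PhyloTree from an ape phylo whose node.label carries supports.
newPhyloTree <- function(ph, id = "tree_1") {
  nnode <- ph$Nnode
  ntip <- length(ph$tip.label)
  lab <- ph$node.label
  if (is.null(lab)) lab <- rep("", nnode)
  length(lab) <- nnode
  lab[is.na(lab)] <- ""
  num <- suppressWarnings(as.numeric(lab))
  odd <- nzchar(lab) & is.na(num)
  if (any(odd))
    warning(sprintf("tree '%s': non-numeric internal label(s) %s treated as missing support",
                    id, paste(sQuote(unique(lab[odd])), collapse = ", ")))
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])
  vals <- num[!is.na(num)]
  if (length(vals) && max(vals) <= 1) num <- num * 100
  if (any(!is.na(num) & (num < 0 | num > 100)))
    stop(sprintf("tree '%s': support value(s) outside [0, 100] after normalization",
                 id))
  imputed <- is.na(num)
  imputed[root - ntip] <- FALSE  # the root carries no unrooted edge
  num[is.na(num)] <- 0
  new("PhyloTree", treeId = id, phylo = ph,
      supports = num, imputed = imputed)
}

#' Coerce an ape phylo (supports in node labels) to a PhyloTree
#'
#' @param ph an `ape::phylo` whose `node.label` holds bootstrap supports.
#' @param treeId identifier for the resulting tree.
#' @return A [PhyloTree-class].
#' @export
asPhyloTree <- function(ph, treeId = "tree_1") newPhyloTree(ph, treeId)

#' @describeIn PhyloTree-class tree identifier
#' @param object,tree a `PhyloTree`
#' @export
setGeneric("treeId", function(object) standardGeneric("treeId"))
#' @rdname PhyloTree-class
#' @export
setMethod("treeId", "PhyloTree", function(object) object@treeId)

#' @describeIn PhyloTree-class leaf labels
#' @export
setGeneric("treeLeaves", function(object) standardGeneric("treeLeaves"))
#' @rdname PhyloTree-class
#' @export
setMethod("treeLeaves", "PhyloTree", function(object) object@phylo$tip.label)

#' @describeIn PhyloTree-class number of leaves
#' @export
setGeneric("nLeaves", function(object) standardGeneric("nLeaves"))
#' @rdname PhyloTree-class
#' @export
setMethod("nLeaves", "PhyloTree",
          function(object) length(object@phylo$tip.label))

#' @describeIn PhyloTree-class supports of the internal edges (named by the
#'   internal node each edge subtends; the root entry is not an edge)
#' @export
setGeneric("edgeSupports", function(object) standardGeneric("edgeSupports"))
#' @rdname PhyloTree-class
#' @export
setMethod("edgeSupports", "PhyloTree", function(object) {
  ph <- object@phylo
  ntip <- length(ph$tip.label)
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])
  s <- object@supports
  names(s) <- as.character(ntip + seq_len(ph$Nnode))
  s[names(s) != as.character(root)]
})

#' @export
setMethod("show", "PhyloTree", function(object) {
  s <- edgeSupports(object)
  cat(sprintf("PhyloTree '%s': %d leaves, %d internal nodes\n",
              object@treeId, nLeaves(object), object@phylo$Nnode))
  if (length(s))
    cat(sprintf("  supports: %g-%g (%d imputed)\n", min(s), max(s),
                sum(object@imputed)))
})

#' @export
setMethod("show", "Bipartition", function(object) {
  cat(sprintf("Bipartition%s {%s} | {%s}  support=%s\n",
              if (object@trivial) " (trivial)" else "",
              paste(object@sideA, collapse = ","),
              paste(object@sideB, collapse = ","),
              format(object@support)))
})

## tip index sets below every node, postorder accumulation
descendantTips <- function(ph) {
  ntip <- length(ph$tip.label)
  nn <- ntip + ph$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  ed <- ape::reorder.phylo(ph, "postorder")$edge
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1]; ch <- ed[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Enumerate the bipartitions of a tree
#'
#' One [Bipartition-class] per internal edge of the unrooted topology; the
#' two root-adjacent edges of a rooted binary input collapse to a single
#' bipartition whose `support` is the larger of the two labels (a warning is
#' emitted when two explicit labels disagree) and whose `sideSupports`
#' retain the per-side clade labels. Output order is deterministic
#' (lexicographic by the canonical smaller side).
#'
#' @param tree a [PhyloTree-class] with at least 3 leaves.
#' @param includeTrivial also return the leaf-edge (trivial) bipartitions.
#' @return A list of [Bipartition-class] objects.
#' @examples
#' tr <- parseTreeFile("((A,B)95,(C,D)80);")[[1]]
#' enumerateBipartitions(tr)
#' @export
enumerateBipartitions <- function(tree, includeTrivial = FALSE) {
  stopifnot(is(tree, "PhyloTree"))
  ph <- tree@phylo
  ntip <- length(ph$tip.label)
  if (ntip < 3)
    stop(sprintf("tree '%s' has fewer than 3 leaves", tree@treeId))
  tips <- ph$tip.label
  sets <- descendantTips(ph)
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])
  rootChildren <- ph$edge[ph$edge[, 1] == root, 2]
  labelOf <- function(node) {
    if (node <= ntip) return(NA_real_)
    tree@supports[node - ntip]
  }
  labelPresent <- function(node) node > ntip && !tree@imputed[node - ntip]

  bips <- list()
  addBip <- function(inTips, supA, supB, collapsedSup) {
    sideIn <- sort(tips[inTips])
    sideOut <- sort(tips[-inTips])
    trivial <- min(length(sideIn), length(sideOut)) == 1
    ## canonical orientation: smaller side first, ties lexicographic
    keyIn <- paste(sideIn, collapse = "\r")
    keyOut <- paste(sideOut, collapse = "\r")
    flip <- length(sideOut) < length(sideIn) ||
      (length(sideOut) == length(sideIn) && keyOut < keyIn)
    if (flip) {
      b <- new("Bipartition", sideA = sideOut, sideB = sideIn,
               support = collapsedSup, sideSupports = c(supB, supA),
               trivial = trivial)
    } else {
      b <- new("Bipartition", sideA = sideIn, sideB = sideOut,
               support = collapsedSup, sideSupports = c(supA, supB),
               trivial = trivial)
    }
    bips[[length(bips) + 1L]] <<- b
  }

  collapseRoot <- length(rootChildren) == 2
  for (k in seq_len(nrow(ph$edge))) {
    parent <- ph$edge[k, 1]; child <- ph$edge[k, 2]
    if (collapseRoot && parent == root && child == rootChildren[2])
      next  # second root edge: same bipartition as the first
    if (collapseRoot && parent == root) {
      c1 <- rootChildren[1]; c2 <- rootChildren[2]
      p1 <- labelPresent(c1); p2 <- labelPresent(c2)
      l1 <- labelOf(c1); l2 <- labelOf(c2)
      if (p1 && p2) {
        if (l1 != l2)
          warning(sprintf(
            "tree '%s': root-adjacent edges carry different supports (%g, %g); keeping the maximum",
            tree@treeId, l1, l2))
        sup <- max(l1, l2); sA <- l1; sB <- l2
      } else if (p1) { sup <- l1; sA <- l1; sB <- l1
      } else if (p2) { sup <- l2; sA <- l2; sB <- l2
      } else {
        both <- c(l1, l2)
        sup <- if (all(is.na(both))) NA_real_ else max(both, na.rm = TRUE)
        sA <- sup; sB <- sup
      }
      trivialHere <- min(length(sets[[c1]]), length(sets[[c2]])) == 1
      if (trivialHere) { sup <- NA_real_; sA <- NA_real_; sB <- NA_real_ }
      addBip(sets[[c1]], sA, sB, sup)
    } else {
      ## an ordinary edge: only the child side is a printed clade, so only
      ## that side carries an evaluable support label
      inTips <- sets[[child]]
      trivialHere <- min(length(inTips), ntip - length(inTips)) == 1
      l <- if (trivialHere) NA_real_ else labelOf(child)
      addBip(inTips, l, NA_real_, l)
    }
  }
  if (!includeTrivial)
    bips <- Filter(function(b) !b@trivial, bips)
  keys <- vapply(bips, function(b) paste(b@sideA, collapse = "\r"), "")
  bips[order(keys, method = "radix")]
}

#' Side of a bipartition containing a given leaf
#'
#' @param bipartition a [Bipartition-class].
#' @param leaf a leaf label present in the tree.
#' @return The character vector of leaf labels on the side holding `leaf`.
#' @export
sideContaining <- function(bipartition, leaf) {
  stopifnot(is(bipartition, "Bipartition"))
  if (leaf %in% bipartition@sideA) return(bipartition@sideA)
  if (leaf %in% bipartition@sideB) return(bipartition@sideB)
  stop(sprintf("leaf '%s' is not in this bipartition's tree", leaf))
}

## support to use when treating `side` as the evaluated clade
supportForSide <- function(bipartition, side) {
  if (setequal(side, bipartition@sideA)) return(bipartition@sideSupports[1])
  if (setequal(side, bipartition@sideB)) return(bipartition@sideSupports[2])
  stop("side does not belong to this bipartition")
}

formatSupportLabel <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  out <- ifelse(grepl("\\.", out), sub("\\.?0+$", "", out), out)
  ifelse(is.na(x), "", out)
}

#' Write trees to Newick or Nexus
#'
#' Supports are written as internal node labels on the 0--100 scale, so a
#' write/parse round trip preserves leaf sets, topology and supports.
#'
#' @param trees a [PhyloTree-class] or list thereof.
#' @param path output file, or `NULL` to return the document text.
#' @param format `"newick"` (one tree per line) or `"nexus"` (TREES block).
#' @return Invisibly, the document text.
#' @export
writeTreeFile <- function(trees, path = NULL,
                          format = c("newick", "nexus")) {
  format <- match.arg(format)
  if (is(trees, "PhyloTree")) trees <- list(trees)
  lines <- vapply(trees, function(tr) {
    ph <- tr@phylo
    lab <- tr@supports
    lab[tr@imputed] <- 0
    ph$node.label <- formatSupportLabel(lab)
    root <- setdiff(ph$edge[, 1], ph$edge[, 2])
    ph$node.label[root - length(ph$tip.label)] <- ""
    ape::write.tree(ph)
  }, "")
  txt <- if (format == "newick") lines else {
    c("#NEXUS", "begin trees;",
      sprintf("  tree %s = [&U] %s",
              vapply(trees, treeId, ""), lines),
      "end;")
  }
  if (!is.null(path)) writeLines(txt, path)
  invisible(paste(txt, collapse = "\n"))
}
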