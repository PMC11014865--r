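#' @import methods
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Single-gene tree with support-valued internal edges
#'
#' A leaf-labelled tree parsed from Newick or Nexus. The topology is stored
#' as read (possibly rooted) but is treated as unrooted by all downstream
#' operations, which work on bipartitions. Supports are normalized to the
#' 0--100 bootstrap scale at parse time; internal edges that carried no
#' support label are imputed as 0 and flagged.
#'
#' @slot treeId character(1) identifier (file-derived or Nexus tree name).
#' @slot phylo the underlying \code{ape::phylo} object.
#' @slot supports numeric vector of supports, one per internal node
#'   (indexed \code{Ntip+1 .. Ntip+Nnode}), each in \code{[0, 100]}.
#' @slot imputed logical vector parallel to \code{supports}; \code{TRUE}
#'   where no support label was present in the input.
#' @exportClass PhyloTree
setClass("PhyloTree",
  slots = c(treeId = "character", phylo = "ANY",
            supports = "numeric", imputed = "logical"))

setValidity("PhyloTree", function(object) {
  ph <- object@phylo
  if (!inherits(ph, "phylo")) return("@phylo must be an ape 'phylo' object")
  if (anyDuplicated(ph$tip.label)) {
    return(sprintf("duplicate leaf labels: %s",
                   paste(unique(ph$tip.label[duplicated(ph$tip.label)]),
                         collapse = ", ")))
  }
  if (length(object@supports) != ph$Nnode)
    return("@supports must have one entry per internal node")
  if (length(object@imputed) != ph$Nnode)
    return("@imputed must have one entry per internal node")
  s <- object@supports[!is.na(object@supports)]
  if (any(s < 0 | s > 100))
    return("supports must lie in [0, 100] after normalization")
  TRUE
})

#' Bipartition of a tree's leaf set
#'
#' The split induced by removing one edge of the unrooted topology. The two
#' root-adjacent edges of a rooted binary input describe the same
#' bipartition; they are collapsed and \code{support} keeps the maximum of
#' their labels, while \code{sideSupports} retains the label attached to the
#' clade subtending each side (used by seed-side scoring).
#'
#' @slot sideA,sideB disjoint leaf-label sets whose union is all leaves;
#'   \code{sideA} is the canonical (smaller, then lexicographically first)
#'   side.
#' @slot support numeric(1) in \code{[0, 100]}, or \code{NA} for a trivial
#'   (leaf-edge) bipartition.
#' @slot sideSupports numeric(2): support label to use when evaluating
#'   side A resp. side B as a clade; `NA` when that side is not a printed
#'   clade of the input tree (an ordinary edge's label belongs to the
#'   subtree it subtends, so only the child side is scoreable).
#' @slot trivial logical(1); \code{TRUE} when one side is a single leaf.
#' @exportClass Bipartition
setClass("Bipartition",
  slots = c(sideA = "character", sideB = "character", support = "numeric",
            sideSupports = "numeric", trivial = "logical"))

setValidity("Bipartition", function(object) {
  if (!length(object@sideA) || !length(object@sideB))
    return("both sides must be non-empty")
  if (length(intersect(object@sideA, object@sideB)))
    return("sides must be disjoint")
  small <- min(length(object@sideA), length(object@sideB))
  if (object@trivial && small != 1)
    return("trivial bipartition must have a single-leaf side")
  if (!object@trivial && small < 2)
    return("non-trivial bipartition needs >= 2 leaves on each side")
  if (length(object@sideSupports) != 2)
    return("sideSupports must have length 2")
  TRUE
})

#' Mapping from leaf identifiers to datasets and nested taxonomic groups
#'
#' @slot leafRules ordered data.frame with columns \code{pattern} (regular
#'   expression) and \code{dataset}; the first matching rule wins.
#' @slot datasetGroups named list: dataset id -> character vector of the
#'   groups it belongs to directly (ancestors are implied by nesting).
#' @slot groupParents named character: group id -> parent group id
#'   (\code{NA} for a top-level group). Must be acyclic.
#' @slot seedLineage group id treated as neutral in clade-purity checks
#'   (default \code{"Kareniaceae"}).
#' @slot seedLineageNeutral logical(1); when \code{FALSE} seed-lineage
#'   leaves count as ordinary leaves in purity checks.
#' @exportClass TaxonScheme
setClass("TaxonScheme",
  slots = c(leafRules = "data.frame", datasetGroups = "list",
            groupParents = "character", seedLineage = "character",
            seedLineageNeutral = "logical"))

setValidity("TaxonScheme", function(object) {
  gp <- object@groupParents
  if (is.null(names(gp)) || anyDuplicated(names(gp)))
    return("groupParents must be uniquely named by group id")
  known <- names(gp)
  bad <- gp[!is.na(gp) & !(gp %in% known)]
  if (length(bad))
    return(sprintf("undeclared parent group(s): %s",
                   paste(unique(bad), collapse = ", ")))
  ## cycle detection by repeated parent-following
  for (g in known) {
    seen <- character(0)
    cur <- g
    while (!is.na(gp[[cur]])) {
      if (cur %in% seen) return(sprintf("cyclic group nesting at '%s'", g))
      seen <- c(seen, cur)
      cur <- gp[[cur]]
    }
  }
  if (anyDuplicated(names(object@datasetGroups)))
    return("duplicate dataset ids")
  for (d in names(object@datasetGroups)) {
    dg <- object@datasetGroups[[d]]
    if (!length(dg))
      return(sprintf("dataset '%s' maps to no group", d))
    if (!all(dg %in% known))
      return(sprintf("dataset '%s' references undeclared group(s): %s", d,
                     paste(setdiff(dg, known), collapse = ", ")))
  }
  lr <- object@leafRules
  if (!all(c("pattern", "dataset") %in% names(lr)))
    return("leafRules needs columns 'pattern' and 'dataset'")
  if (nrow(lr) && !all(lr$dataset %in% names(object@datasetGroups)))
    return("leafRules reference undeclared dataset(s)")
  if (length(object@seedLineage) != 1)
    return("seedLineage must be a single group id")
  if (!is.na(object@seedLineage) && !(object@seedLineage %in% known))
    return(sprintf("seed lineage group '%s' is not declared",
                   object@seedLineage))
  TRUE
})

#' Definition of an evolutionary-origin category
#'
#' A category qualifies on a tree when the seed is sister to or nested
#' within a clade made exclusively of members of \code{memberGroup}
#' (seed-lineage leaves being neutral), with at least \code{minMembers}
#' member taxa and, when \code{witnessGroup} is set, at least one member of
#' that subgroup.
#'
#' @slot name category name, e.g. \code{"plastid-late"}.
#' @slot memberGroup group id whose members make up qualifying clades.
#' @slot witnessGroup subgroup of \code{memberGroup} of which one member
#'   must be present, or \code{NA}.
#' @slot minMembers minimum number of member taxa (>= 2).
#' @exportClass CategoryDef
setClass("CategoryDef",
  slots = c(name = "character", memberGroup = "character",
            witnessGroup = "character", minMembers = "numeric"))

setValidity("CategoryDef", function(object) {
  if (length(object@name) != 1 || !nzchar(object@name))
    return("name must be a non-empty string")
  if (object@minMembers < 2)
    return("minMembers must be >= 2")
  TRUE
})

#' Taxon-set criterion evaluated on the seed side of a bipartition
#'
#' Bounds are evaluated on the seed-containing side after removing the seed
#' itself and (when the scheme says so) seed-lineage leaves. Proportions use
#' the same reduced side as denominator.
#'
#' @slot constraints named list (by group id); each element is a list with
#'   optional entries \code{minCount}, \code{maxCount}, \code{minProp},
#'   \code{maxProp}.
#' @slot allowedGroups optional character vector: when non-empty, every
#'   counted leaf on the evaluated side must belong to at least one of these
#'   groups (clade-purity constraint).
#' @exportClass SortCriterion
setClass("SortCriterion",
  slots = c(constraints = "list", allowedGroups = "character"))

setValidity("SortCriterion", function(object) {
  for (g in names(object@constraints)) {
    cc <- object@constraints[[g]]
    bad <- setdiff(names(cc), c("minCount", "maxCount", "minProp", "maxProp"))
    if (length(bad))
      return(sprintf("unknown bound(s) for group '%s': %s", g,
                     paste(bad, collapse = ", ")))
    mn <- cc$minCount; mx <- cc$maxCount
    if (!is.null(mn) && !is.null(mx) && mn > mx)
      return(sprintf("minCount > maxCount for group '%s'", g))
    for (p in c("minProp", "maxProp")) {
      if (!is.null(cc[[p]]) && (cc[[p]] < 0 || cc[[p]] > 1))
        return(sprintf("%s for group '%s' must lie in [0, 1]", p, g))
    }
    if (!is.null(cc$minProp) && !is.null(cc$maxProp) &&
        cc$minProp > cc$maxProp)
      return(sprintf("minProp > maxProp for group '%s'", g))
  }
  TRUE
})

#' Per-tree evolutionary-origin call
#'
#' @slot seedId the seed (query) leaf.
#' @slot treeId tree identifier.
#' @slot category winning category name, or \code{"unresolved"}.
#' @slot score support of the qualifying edge in \code{[0, 100]}, or
#'   \code{NA} when unresolved.
#' @slot qualifyingSide leaf set of the qualifying seed side (empty when
#'   unresolved).
#' @slot passedThreshold \code{TRUE} iff \code{score >= 75}.
#' @exportClass OriginCall
setClass("OriginCall",
  slots = c(seedId = "character", treeId = "character",
            category = "character", score = "numeric",
            qualifyingSide = "character", passedThreshold = "logical"))

setValidity("OriginCall", function(object) {
  special <- c("unresolved", "dinoflagellate-specific", "lineage-specific")
  if (!(object@category %in% special)) {
    if (is.na(object@score)) return("a categorized call must carry a score")
    if (!length(object@qualifyingSide))
      return("a categorized call must carry its qualifying side")
  }
  expect <- !is.na(object@score) && object@score >= 75
  if (!identical(object@passedThreshold, expect))
    return("passedThreshold must equal (score >= 75)")
  TRUE
})

#' Internal kareniacean topology call for one tree
#'
#' @slot treeId tree identifier.
#' @slot topology one of \code{"KL|T"}, \code{"KT|L"}, \code{"LT|K"},
#'   \code{"ambiguous"}.
#' @slot score support of the best edge supporting the topology
#'   (\code{NA} when ambiguous).
#' @slot kareniaceaeMonophyletic \code{TRUE} iff some bipartition side
#'   equals exactly the set of kareniacean leaves.
#' @slot familyAffiliation haptophyte subgroup id, or \code{NA}.
#' @exportClass TopologyCall
setClass("TopologyCall",
  slots = c(treeId = "character", topology = "character", score = "numeric",
            kareniaceaeMonophyletic = "logical",
            familyAffiliation = "character"))

setValidity("TopologyCall", function(object) {
  if (!(object@topology %in% c("KL|T", "KT|L", "LT|K", "ambiguous")))
    return("invalid topology label")
  if (object@topology != "ambiguous" && is.na(object@score))
    return("a resolved topology must carry a score")
  TRUE
})

#' Position-specific scoring matrix anchored on a cleavage site
#'
#' Log2-odds scores over a contiguous window of positions relative to the
#' signal-peptide cleavage site. Relative coordinate 0 is the first residue
#' after the cleavage site (the start of the transit-peptide region);
#' negative coordinates index the C-terminal residues of the signal peptide.
#'
#' @slot positions integer vector of contiguous relative coordinates,
#'   e.g. \code{-5:21}.
#' @slot scores numeric matrix, \code{length(positions)} rows (named by
#'   coordinate) x 20 amino-acid columns.
#' @slot background named numeric(20) of background frequencies summing to 1.
#' @slot pseudocount numeric(1) used at build time.
#' @exportClass PSSM
setClass("PSSM",
  slots = c(positions = "integer", scores = "matrix",
            background = "numeric", pseudocount = "numeric"))

setValidity("PSSM", function(object) {
  p <- object@positions
  if (!length(p) || any(diff(p) != 1L))
    return("positions must be contiguous integers")
  if (nrow(object@scores) != length(p))
    return("scores must have one row per window position")
  if (!identical(colnames(object@scores), AA20))
    return("scores columns must be the 20 amino acids in standard order")
  bg <- object@background
  if (!identical(sort(names(bg)), sort(AA20)))
    return("background must cover the 20-letter alphabet")
  if (abs(sum(bg) - 1) > 1e-9)
    return("background frequencies must sum to 1")
  TRUE
})

#' Pooled signal-peptide prediction for one protein
#'
#' @slot id sequence id.
#' @slot hasSp logical(1).
#' @slot cleavagePos 1-based index of the last signal-peptide residue
#'   (\code{NA} when no signal peptide).
#' @slot spProbability predictor probability in \code{[0, 1]} or \code{NA}.
#' @slot sourceVariant \code{"original"} or \code{"first_met_trimmed"}.
#' @exportClass SignalPeptideCall
setClass("SignalPeptideCall",
  slots = c(id = "character", hasSp = "logical", cleavagePos = "numeric",
            spProbability = "numeric", sourceVariant = "character"))

setValidity("SignalPeptideCall", function(object) {
  if (object@hasSp && (is.na(object@cleavagePos) || object@cleavagePos < 1))
    return("a positive call must carry cleavagePos >= 1")
  if (!(object@sourceVariant %in% c("original", "first_met_trimmed")))
    return("sourceVariant must be 'original' or 'first_met_trimmed'")
  TRUE
})

#' Bipartite presequence classification for one protein
#'
#' @slot id sequence id.
#' @slot sp the pooled [SignalPeptideCall-class].
#' @slot atSiteScore window score at the predicted cleavage site
#'   (\code{NA} without a signal peptide).
#' @slot bestOffsetScore,bestOffset best window score over the offset scan
#'   and the offset achieving it.
#' @slot klass one of \code{"plastid_high"}, \code{"plastid_low"},
#'   \code{"not_plastid"}, \code{"no_sp"}.
#' @slot route \code{"asafind"} or \code{"sptp_alternative"}.
#' @slot outputId id, prefixed with \code{"SPTP-"} iff the call came through
#'   the alternative route.
#' @exportClass PresequenceCall
setClass("PresequenceCall",
  slots = c(id = "character", sp = "SignalPeptideCall",
            atSiteScore = "numeric", bestOffsetScore = "numeric",
            bestOffset = "numeric", klass = "character", route = "character",
            outputId = "character"))

setValidity("PresequenceCall", function(object) {
  if (!(object@klass %in%
        c("plastid_high", "plastid_low", "not_plastid", "no_sp")))
    return("invalid klass")
  if ((object@klass == "no_sp") != !object@sp@hasSp)
    return("klass 'no_sp' must coincide with a negative signal-peptide call")
  if (!(object@route %in% c("asafind", "sptp_alternative")))
    return("invalid route")
  pref <- startsWith(object@outputId, "SPTP-")
  if (pref != (object@route == "sptp_alternative"))
    return("outputId carries 'SPTP-' prefix iff route is sptp_alternative")
  TRUE
})
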