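## TreeSorter core: seed-side criterion evaluation over bipartitions,
## origin classification, internal-topology and family-affiliation tallies.

#' Construct a taxon-set sorting criterion
#'
#' @param constraints named list (by group id) of per-group bounds, each a
#'   list with any of `minCount`, `maxCount`, `minProp`, `maxProp`.
#'   Proportions are over the evaluated side excluding the seed and
#'   seed-lineage (neutral) leaves.
#' @param allowedGroups optional character vector; when given, every
#'   counted leaf on the evaluated side must belong to at least one of
#'   these groups (clade purity).
#' @return A [SortCriterion-class].
#' @examples
#' sortCriterion(list(haptophytes = list(minCount = 2)),
#'               allowedGroups = "haptophytes")
#' @export
sortCriterion <- function(constraints = list(), allowedGroups = character(0)) {
  new("SortCriterion", constraints = constraints,
      allowedGroups = as.character(allowedGroups))
}

#' Construct a category definition
#'
#' @param name category name.
#' @param memberGroup group id whose members form qualifying clades.
#' @param witnessGroup optional subgroup of which at least one member must
#'   be present on the qualifying side.
#' @param minMembers minimum number of member taxa (default 2).
#' @return A [CategoryDef-class].
#' @export
categoryDef <- function(name, memberGroup, witnessGroup = NA_character_,
                        minMembers = 2) {
  new("CategoryDef", name = name, memberGroup = memberGroup,
      witnessGroup = witnessGroup, minMembers = minMembers)
}

#' Load category definitions from a YAML/JSON document
#'
#' Each entry declares `name`, `member_group` and optionally
#' `required_witness_group` and `min_members`.
#'
#' @param config file path or list of entries.
#' @return List of [CategoryDef-class].
#' @export
loadCategories <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = FALSE)
    else yaml::read_yaml(config)
  }
  lapply(config, function(e) {
    categoryDef(name = e$name, memberGroup = e$member_group,
                witnessGroup = if (is.null(e$required_witness_group))
                  NA_character_ else e$required_witness_group,
                minMembers = if (is.null(e$min_members)) 2
                             else e$min_members)
  })
}

#' The packaged default origin categories
#'
#' plastid-late (haptophytes), plastid-early (dinoflagellates), alveolate
#' (with a ciliate witness), and green/brown/prokaryote LGT.
#'
#' @return List of [CategoryDef-class].
#' @export
defaultCategories <- function() {
  loadCategories(system.file("extdata", "default_categories.yaml",
                             package = "plastosort", mustWork = TRUE))
}

#' @export
setMethod("show", "CategoryDef", function(object) {
  cat(sprintf("CategoryDef '%s': members of '%s' (>= %d)%s\n", object@name,
              object@memberGroup, object@minMembers,
              if (is.na(object@witnessGroup)) ""
              else sprintf(", witness '%s'", object@witnessGroup)))
})

## Evaluate one seed side against a criterion.
## `res` is the resolveLeaves() table for the whole tree.
sideSatisfies <- function(side, seed, criterion, res) {
  others <- setdiff(side, seed)
  info <- res[others]
  neutral <- vapply(info, `[[`, logical(1), "neutral")
  counted <- info[!neutral]
  n <- length(counted)
  if (length(criterion@allowedGroups)) {
    ok <- vapply(counted, function(r)
      any(criterion@allowedGroups %in% r$groups), logical(1))
    if (!all(ok)) return(FALSE)
  }
  for (g in names(criterion@constraints)) {
    cc <- criterion@constraints[[g]]
    cnt <- sum(vapply(counted, function(r) g %in% r$groups, logical(1)))
    if (!is.null(cc$minCount) && cnt < cc$minCount) return(FALSE)
    if (!is.null(cc$maxCount) && cnt > cc$maxCount) return(FALSE)
    if (!is.null(cc$minProp) || !is.null(cc$maxProp)) {
      if (n == 0) return(FALSE)
      p <- cnt / n
      if (!is.null(cc$minProp) && p < cc$minProp) return(FALSE)
      if (!is.null(cc$maxProp) && p > cc$maxProp) return(FALSE)
    }
  }
  TRUE
}

#' Highest-supported bipartition whose seed side meets a criterion
#'
#' Scans every non-trivial bipartition of the tree; a bipartition
#' qualifies when its seed-containing side is a subtree (printed clade) of
#' the input tree, scored by the support label subtending it, and
#' satisfies all bounds of `criterion`. The maximum support among
#' qualifying edges is returned; ties on support are broken toward the
#' smaller side, then lexicographically.
#'
#' @param tree a [PhyloTree-class].
#' @param seed the seed leaf label.
#' @param criterion a [SortCriterion-class].
#' @param scheme a [TaxonScheme-class] resolving every leaf.
#' @return `NULL` when no bipartition qualifies, else a list with
#'   `support` and `side` (the qualifying seed side).
#' @export
bestSupportedEdge <- function(tree, seed, criterion, scheme) {
  if (!(seed %in% treeLeaves(tree)))
    stop(sprintf("seed '%s' is not a leaf of tree '%s'", seed, treeId(tree)))
  res <- resolveLeaves(scheme, treeLeaves(tree))
  bips <- enumerateBipartitions(tree, includeTrivial = FALSE)
  bestSupportedEdgeImpl(bips, seed, criterion, res)
}

bestSupportedEdgeImpl <- function(bips, seed, criterion, res) {
  best <- NULL
  for (b in bips) {
    side <- sideContaining(b, seed)
    sup <- supportForSide(b, side)
    if (is.na(sup)) next
    if (!sideSatisfies(side, seed, criterion, res)) next
    if (is.null(best) || sup > best$support ||
        (sup == best$support &&
         (length(side) < length(best$side) ||
          (length(side) == length(best$side) &&
           paste(sort(side), collapse = "\r") <
             paste(sort(best$side), collapse = "\r"))))) {
      best <- list(support = sup, side = sort(side))
    }
  }
  best
}

## criterion implementing "sister to or nested within a clade comprising
## exclusively members of the category, of at least minMembers taxa"
categoryCriterion <- function(cat) {
  cons <- list()
  cons[[cat@memberGroup]] <- list(minCount = cat@minMembers)
  if (!is.na(cat@witnessGroup))
    cons[[cat@witnessGroup]] <- list(minCount = 1)
  sortCriterion(cons, allowedGroups = cat@memberGroup)
}

#' Classify the evolutionary origin of a seed protein from its gene tree
#'
#' Each category qualifies when the seed is sister to or nested within a
#' clade made exclusively of members of the category's group (seed-lineage
#' leaves are neutral), of at least `minMembers` member taxa, with the
#' witness subgroup represented when required. The category achieving the
#' highest qualifying support wins; on an exact support tie, a nested pair
#' (one member group an ancestor of the other, one qualifying side
#' containing the other) resolves to the wider category, any other tie is
#' unresolved. Trees where no category qualifies are unresolved with no
#' score. `passedThreshold` annotates calls at the bootstrap-75
#' interpretation threshold without suppressing lower-scoring calls.
#'
#' @param tree a [PhyloTree-class].
#' @param seed the seed leaf label.
#' @param categories list of [CategoryDef-class]
#'   (default [defaultCategories()]).
#' @param scheme a [TaxonScheme-class].
#' @return An [OriginCall-class].
#' @examples
#' sc <- defaultScheme()
#' tr <- parseTreeFile(paste0(
#'   "((Karenia_mikimotoi_1,(Emiliania_huxleyi_1,Prymnesium_parvum_1)90)70,",
#'   "(Symbiodinium_microadriaticum_1,Heterocapsa_triquetra_1)99);"))[[1]]
#' classifyOrigin(tr, "Karenia_mikimotoi_1", defaultCategories(), sc)
#' @export
classifyOrigin <- function(tree, seed, categories = defaultCategories(),
                           scheme) {
  if (!(seed %in% treeLeaves(tree)))
    stop(sprintf("seed '%s' is not a leaf of tree '%s'", seed, treeId(tree)))
  res <- resolveLeaves(scheme, treeLeaves(tree))
  bips <- enumerateBipartitions(tree, includeTrivial = FALSE)
  quals <- list()
  for (cat in categories) {
    hit <- bestSupportedEdgeImpl(bips, seed, categoryCriterion(cat), res)
    if (!is.null(hit))
      quals[[cat@name]] <- list(cat = cat, support = hit$support,
                                side = hit$side)
  }
  unresolvedCall <- function()
    new("OriginCall", seedId = seed, treeId = treeId(tree),
        category = "unresolved", score = NA_real_,
        qualifyingSide = character(0), passedThreshold = FALSE)
  if (!length(quals)) return(unresolvedCall())
  sups <- vapply(quals, `[[`, numeric(1), "support")
  best <- max(sups)
  tied <- quals[sups == best]
  winner <- NULL
  if (length(tied) == 1) {
    winner <- tied[[1]]
  } else {
    ## nested-category rule: the wider category absorbs narrower ties whose
    ## qualifying sides it contains; otherwise the tie is unresolved
    cands <- Filter(function(w) {
      all(vapply(tied, function(o) {
        w$cat@memberGroup %in% groupAncestors(scheme, o$cat@memberGroup) &&
          all(o$side %in% w$side)
      }, logical(1)))
    }, tied)
    if (length(cands) == 1) winner <- cands[[1]]
  }
  if (is.null(winner)) return(unresolvedCall())
  new("OriginCall", seedId = seed, treeId = treeId(tree),
      category = winner$cat@name, score = winner$support,
      qualifyingSide = winner$side,
      passedThreshold = winner$support >= 75)
}

#' @export
setMethod("show", "OriginCall", function(object) {
  cat(sprintf("OriginCall %s [%s]: %s", object@seedId, object@treeId,
              object@category))
  if (!is.na(object@score))
    cat(sprintf(" (support %g%s, clade of %d)", object@score,
                if (object@passedThreshold) ", >= 75" else "",
                length(object@qualifyingSide)))
  cat("\n")
})

#' Tally the internal kareniacean topology supported by a tree
#'
#' A topology `XY|Z` is supported when some bipartition has a side
#' containing every leaf of genera X and Y present in the tree, no leaf of
#' genus Z, and no non-kareniacean leaf. The topology with the
#' highest-supported such edge wins; an exact tie between distinct
#' topologies (or a tree missing one of the three genera) is ambiguous.
#' `kareniaceaeMonophyletic` is `TRUE` iff some bipartition side equals
#' exactly the set of all kareniacean leaves.
#'
#' @param tree a [PhyloTree-class].
#' @param scheme a [TaxonScheme-class].
#' @param genera named character of the three genus groups; names `K`, `L`,
#'   `T` give the topology letters.
#' @param karGroup the group spanning all kareniacean leaves.
#' @return A [TopologyCall-class].
#' @export
tallyInternalTopology <- function(tree, scheme,
                                  genera = c(K = "Karenia",
                                             L = "Karlodinium",
                                             T = "Takayama"),
                                  karGroup = "Kareniaceae") {
  res <- resolveLeaves(scheme, treeLeaves(tree))
  inGroup <- function(g)
    names(Filter(function(r) g %in% r$groups, res))
  kar <- inGroup(karGroup)
  gl <- lapply(genera, inGroup)

  bips <- if (nLeaves(tree) >= 3)
    enumerateBipartitions(tree, includeTrivial = FALSE) else list()
  mono <- length(kar) >= 1 && any(vapply(bips, function(b)
    setequal(b@sideA, kar) || setequal(b@sideB, kar), logical(1)))

  amb <- function() new("TopologyCall", treeId = treeId(tree),
                        topology = "ambiguous", score = NA_real_,
                        kareniaceaeMonophyletic = mono,
                        familyAffiliation = NA_character_)
  if (any(lengths(gl) == 0)) return(amb())

  pairs <- list("KL|T" = c("K", "L"), "KT|L" = c("K", "T"),
                "LT|K" = c("L", "T"))
  scores <- vapply(names(pairs), function(tp) {
    xy <- unlist(gl[pairs[[tp]]], use.names = FALSE)
    z <- gl[[setdiff(c("K", "L", "T"), pairs[[tp]])]]
    best <- NA_real_
    for (b in bips) {
      for (side in list(b@sideA, b@sideB)) {
        if (!all(xy %in% side)) next
        if (any(z %in% side)) next
        if (!all(side %in% kar)) next
        sup <- supportForSide(b, side)
        if (!is.na(sup) && (is.na(best) || sup > best)) best <- sup
      }
    }
    best
  }, numeric(1))

  if (all(is.na(scores))) return(amb())
  top <- max(scores, na.rm = TRUE)
  winners <- names(scores)[!is.na(scores) & scores == top]
  if (length(winners) != 1) return(amb())
  new("TopologyCall", treeId = treeId(tree), topology = winners,
      score = top, kareniaceaeMonophyletic = mono,
      familyAffiliation = NA_character_)
}

#' @export
setMethod("show", "TopologyCall", function(object) {
  cat(sprintf("TopologyCall %s: %s%s, Kareniaceae %smonophyletic\n",
              object@treeId, object@topology,
              if (is.na(object@score)) ""
              else sprintf(" (support %g)", object@score),
              if (object@kareniaceaeMonophyletic) "" else "not "))
})

#' Haptophyte-family affiliation of a seed protein
#'
#' Runs the origin classifier with one category per haptophyte subgroup;
#' qualifying clades must be pure for a single family (seed-lineage leaves
#' neutral) with at least `minMembers` members.
#'
#' @param tree a [PhyloTree-class].
#' @param seed the seed leaf label.
#' @param scheme a [TaxonScheme-class].
#' @param families the candidate subgroup ids.
#' @param minMembers minimum family members in the clade.
#' @return A list with `family` (id or `NA`) and `support`.
#' @export
familyAffiliation <- function(tree, seed, scheme,
                              families = c("Chrysochromulinaceae",
                                           "Isochrysidales", "Prymnesiales",
                                           "Phaeocystales", "Coccolithales",
                                           "Pavlovales"),
                              minMembers = 2) {
  cats <- lapply(families, function(f)
    categoryDef(name = f, memberGroup = f, minMembers = minMembers))
  call <- classifyOrigin(tree, seed, cats, scheme)
  if (call@category %in% families)
    list(family = call@category, support = call@score)
  else
    list(family = NA_character_, support = NA_real_)
}

#' Batch-sort a set of trees
#'
#' @param trees list of [PhyloTree-class] (or a tree file path).
#' @param seeds named character vector (treeId -> seed leaf), or a single
#'   regular expression matched against each tree's leaves (first match is
#'   the seed).
#' @param categories list of [CategoryDef-class].
#' @param scheme a [TaxonScheme-class].
#' @return data.frame with one row per tree: `treeId`, `seedId`,
#'   `category`, `score`, `passedThreshold`, `sideSize`.
#' @export
sortTrees <- function(trees, seeds, categories = defaultCategories(),
                      scheme) {
  if (is.character(trees)) trees <- parseTreeFile(trees)
  if (is(trees, "PhyloTree")) trees <- list(trees)
  rows <- lapply(trees, function(tr) {
    seed <- if (!is.null(names(seeds))) {
      s <- seeds[[treeId(tr)]]
      if (is.null(s) || is.na(s))
        stop(sprintf("no seed given for tree '%s'", treeId(tr)))
      s
    } else {
      hit <- grep(seeds, treeLeaves(tr), value = TRUE)
      if (!length(hit))
        stop(sprintf("seed pattern matches no leaf of tree '%s'",
                     treeId(tr)))
      hit[1]
    }
    oc <- classifyOrigin(tr, seed, categories, scheme)
    data.frame(treeId = oc@treeId, seedId = oc@seedId,
               category = oc@category, score = oc@score,
               passedThreshold = oc@passedThreshold,
               sideSize = length(oc@qualifyingSide),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize origin or topology calls
#'
#' For origin calls, reports per-category counts and the proportion of
#' classified trees per category (the special rows `unresolved`,
#' `dinoflagellate-specific` and `lineage-specific` are excluded from the
#' proportion denominator and get `NA` proportions). For topology calls,
#' reports counts per topology including `ambiguous`.
#'
#' @param calls list of [OriginCall-class] or [TopologyCall-class], or a
#'   data.frame with a `category` column (as from [sortTrees()]).
#' @return data.frame with columns `category` (or `topology`), `n`,
#'   `proportion`.
#' @export
summarizeCalls <- function(calls) {
  if (is.data.frame(calls)) {
    cats <- calls$category
  } else if (!length(calls)) {
    return(data.frame(category = character(0), n = integer(0),
                      proportion = numeric(0)))
  } else if (is(calls[[1]], "TopologyCall")) {
    tp <- vapply(calls, function(x) x@topology, "")
    lev <- c("KL|T", "KT|L", "LT|K", "ambiguous")
    n <- vapply(lev, function(l) sum(tp == l), integer(1))
    resolved <- sum(n[lev != "ambiguous"])
    return(data.frame(topology = lev, n = as.integer(n),
                      proportion = if (resolved > 0)
                        ifelse(lev == "ambiguous", NA_real_, n / resolved)
                      else rep(NA_real_, length(lev)),
                      row.names = NULL, stringsAsFactors = FALSE))
  } else {
    cats <- vapply(calls, function(x) x@category, "")
  }
  special <- c("unresolved", "dinoflagellate-specific", "lineage-specific")
  lev <- c(setdiff(unique(cats), special), intersect(special, unique(cats)))
  n <- vapply(lev, function(l) sum(cats == l), integer(1))
  classified <- sum(n[!(lev %in% special)])
  prop <- ifelse(lev %in% special, NA_real_,
                 if (classified > 0) n / classified else NA_real_)
  data.frame(category = lev, n = as.integer(n), proportion = prop,
             row.names = NULL, stringsAsFactors = FALSE)
}
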