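## Leaf -> dataset -> nested-group resolution used by all sorting criteria.

#' Load a taxon scheme from configuration
#'
#' The configuration (YAML or JSON file, or an equivalent named list)
#' declares the nested group hierarchy, the datasets with their direct
#' groups, and optional leaf rules:
#'
#' ```yaml
#' seed_lineage: Kareniaceae
#' groups:
#'   alveolates: ~            # top-level
#'   dinoflagellates: alveolates
#' datasets:
#'   Karenia_mikimotoi: [Karenia]
#' leaf_rules:                # optional; defaults to "^<dataset>_"
#'   - {pattern: "^Kmik", dataset: Karenia_mikimotoi}
#' ```
#'
#' When `leaf_rules` is omitted, one rule per dataset is generated matching
#' the `<dataset>_<anything>` leaf-naming convention (arbitrary suffixes,
#' e.g. paralog serials, are tolerated).
#'
#' @param config path to a YAML/JSON file, or a named list with entries
#'   `groups`, `datasets`, and optionally `leaf_rules`, `seed_lineage`,
#'   `seed_lineage_neutral`.
#' @return A validated [TaxonScheme-class].
#' @export
loadScheme <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop(sprintf("no such file: '%s'", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  if (is.null(config$groups)) stop("config must declare 'groups'")
  if (is.null(config$datasets)) stop("config must declare 'datasets'")

  gp <- vapply(config$groups, function(p)
    if (is.null(p) || !length(p) || is.na(p[1])) NA_character_
    else as.character(p[1]), "")
  names(gp) <- names(config$groups)

  dg <- lapply(config$datasets, function(g) as.character(unlist(g)))

  if (is.null(config$leaf_rules)) {
    rules <- data.frame(pattern = paste0("^", names(dg), "_"),
                        dataset = names(dg), stringsAsFactors = FALSE)
  } else {
    lr <- config$leaf_rules
    if (is.data.frame(lr)) {
      rules <- data.frame(pattern = as.character(lr$pattern),
                          dataset = as.character(lr$dataset),
                          stringsAsFactors = FALSE)
    } else {
      rules <- do.call(rbind, lapply(lr, function(r)
        data.frame(pattern = as.character(r$pattern),
                   dataset = as.character(r$dataset),
                   stringsAsFactors = FALSE)))
    }
  }

  new("TaxonScheme",
      leafRules = rules,
      datasetGroups = dg,
      groupParents = gp,
      seedLineage = if (is.null(config$seed_lineage)) "Kareniaceae"
                    else as.character(config$seed_lineage),
      seedLineageNeutral = if (is.null(config$seed_lineage_neutral)) TRUE
                           else isTRUE(config$seed_lineage_neutral))
}

#' The packaged default taxon scheme
#'
#' Mirrors the grouping used for fucoxanthin-dinoflagellate plastid
#' proteomes: Kareniaceae (genera Karenia, Karlodinium, Takayama) nested in
#' dinoflagellates nested in alveolates (with ciliates as the non-
#' dinoflagellate alveolate witness group), haptophytes with six subgroups,
#' plus green, ochrophyte (brown), prokaryote and metazoan outgroups. The
#' seed lineage is Kareniaceae.
#'
#' @return A [TaxonScheme-class].
#' @export
defaultScheme <- function() {
  loadScheme(system.file("extdata", "default_scheme.yaml",
                         package = "plastosort", mustWork = TRUE))
}

#' @describeIn TaxonScheme-class seed-lineage group id
#' @param object a `TaxonScheme`
#' @export
setGeneric("seedLineage", function(object) standardGeneric("seedLineage"))
#' @rdname TaxonScheme-class
#' @export
setMethod("seedLineage", "TaxonScheme", function(object) object@seedLineage)

#' @describeIn TaxonScheme-class declared dataset ids, optionally restricted
#'   to members of a group
#' @param group optional group id
#' @export
setGeneric("schemeDatasets",
           function(object, group = NULL) standardGeneric("schemeDatasets"))
#' @rdname TaxonScheme-class
#' @export
setMethod("schemeDatasets", "TaxonScheme", function(object, group = NULL) {
  ds <- names(object@datasetGroups)
  if (is.null(group)) return(ds)
  ds[vapply(ds, function(d) group %in% datasetGroupClosure(object, d),
            logical(1))]
})

#' @describeIn TaxonScheme-class declared group ids
#' @export
setGeneric("schemeGroups", function(object) standardGeneric("schemeGroups"))
#' @rdname TaxonScheme-class
#' @export
setMethod("schemeGroups", "TaxonScheme",
          function(object) names(object@groupParents))

#' @export
setMethod("show", "TaxonScheme", function(object) {
  cat(sprintf("TaxonScheme: %d datasets, %d groups, %d leaf rules\n",
              length(object@datasetGroups), length(object@groupParents),
              nrow(object@leafRules)))
  cat(sprintf("  seed lineage: %s (%s in purity checks)\n",
              object@seedLineage,
              if (object@seedLineageNeutral) "neutral" else "counted"))
})

#' Ancestors of a group (including itself)
#'
#' @param scheme a [TaxonScheme-class].
#' @param group a group id.
#' @return Character vector: the group and its chain of parents.
#' @export
groupAncestors <- function(scheme, group) {
  gp <- scheme@groupParents
  if (!(group %in% names(gp)))
    stop(sprintf("unknown group '%s'", group))
  out <- group
  while (!is.na(gp[[group]])) {
    group <- gp[[group]]
    out <- c(out, group)
  }
  out
}

## transitive group set of a dataset
datasetGroupClosure <- function(scheme, dataset) {
  direct <- scheme@datasetGroups[[dataset]]
  if (is.null(direct)) stop(sprintf("unknown dataset '%s'", dataset))
  unique(unlist(lapply(direct, groupAncestors, scheme = scheme)))
}

#' Resolve a leaf label to its dataset and transitive group set
#'
#' Rules are tried in declaration order; the first matching pattern wins.
#' Group membership is closed under nesting: a leaf in a dataset assigned to
#' `dinoflagellates` also resolves to every ancestor group.
#'
#' @param scheme a [TaxonScheme-class].
#' @param leaf a leaf label.
#' @return A list with elements `dataset` and `groups`.
#' @examples
#' sc <- defaultScheme()
#' resolveLeaf(sc, "Karenia_mikimotoi_0001")$groups
#' @export
resolveLeaf <- function(scheme, leaf) {
  for (i in seq_len(nrow(scheme@leafRules))) {
    if (grepl(scheme@leafRules$pattern[i], leaf)) {
      d <- scheme@leafRules$dataset[i]
      return(list(dataset = d, groups = datasetGroupClosure(scheme, d)))
    }
  }
  stop(sprintf("no leaf rule matches '%s'", leaf))
}

## Resolve all leaves of a tree at once; returns a list keyed by leaf with
## dataset, groups, and neutrality under the scheme's seed lineage.
resolveLeaves <- function(scheme, leaves) {
  res <- lapply(leaves, function(l) {
    r <- resolveLeaf(scheme, l)
    r$neutral <- scheme@seedLineageNeutral &&
      !is.na(scheme@seedLineage) && scheme@seedLineage %in% r$groups
    r
  })
  names(res) <- leaves
  res
}

#' Report leaves of a tree file that a scheme cannot resolve
#'
#' @param scheme a [TaxonScheme-class].
#' @param trees a list of [PhyloTree-class] (or a tree file path).
#' @return data.frame with columns `treeId` and `leaf` (zero rows when all
#'   leaves resolve).
#' @export
unresolvableLeaves <- function(scheme, trees) {
  if (is.character(trees)) trees <- parseTreeFile(trees)
  if (is(trees, "PhyloTree")) trees <- list(trees)
  out <- lapply(trees, function(tr) {
    bad <- Filter(function(l)
      inherits(tryCatch(resolveLeaf(scheme, l), error = function(e) e),
               "error"), treeLeaves(tr))
    if (length(bad)) data.frame(treeId = treeId(tr), leaf = unlist(bad),
                                stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(treeId = character(0), leaf = character(0))
  out
}
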