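# Independent brute-force oracles. These re-derive the sorting semantics
# from first principles (direct recursion over the ape edge matrix, plain
# loops over candidate clades and categories) and share no code with the
# package's bipartition enumeration or criterion machinery.

# every (tips, support) candidate clade of a tree: one per non-root
# internal node; for a rooted binary input the two root children describe
# the same unrooted edge, so a single printed label applies to both sides
oracleSeedClades <- function(tree, seed) {
  ph <- tree@phylo
  ntip <- length(ph$tip.label)
  root <- setdiff(ph$edge[, 1], ph$edge[, 2])
  kids <- function(v) ph$edge[ph$edge[, 1] == v, 2]
  tipsBelow <- function(v) {
    if (v <= ntip) return(ph$tip.label[v])
    unlist(lapply(kids(v), tipsBelow))
  }
  sup <- function(v) tree@supports[v - ntip]
  present <- function(v) v > ntip && !tree@imputed[v - ntip]
  rc <- kids(root)
  cands <- list()
  for (v in setdiff((ntip + 1):(ntip + ph$Nnode), root)) {
    tips <- tipsBelow(v)
    if (length(tips) < 2 || length(tips) > ntip - 2) next
    s <- sup(v)
    if (length(rc) == 2 && v %in% rc) {
      other <- setdiff(rc, v)
      if (!present(v) && present(other)) s <- sup(other)
    }
    cands[[length(cands) + 1]] <- list(tips = tips, support = s)
  }
  Filter(function(cl) seed %in% cl$tips, cands)
}

oracleSideOk <- function(tips, seed, cat, scheme) {
  others <- setdiff(tips, seed)
  n <- 0
  witness <- 0
  for (l in others) {
    g <- resolveLeaf(scheme, l)$groups
    if (scheme@seedLineageNeutral && seedLineage(scheme) %in% g) next
    if (!(cat@memberGroup %in% g)) return(FALSE)
    n <- n + 1
    if (!is.na(cat@witnessGroup) && cat@witnessGroup %in% g)
      witness <- witness + 1
  }
  n >= cat@minMembers && (is.na(cat@witnessGroup) || witness >= 1)
}

# plain re-derivation of the category decision incl. tie rules
oracleClassify <- function(tree, seed, categories, scheme) {
  cands <- oracleSeedClades(tree, seed)
  best <- list()
  for (cat in categories) {
    sup <- NA_real_
    side <- NULL
    for (cl in cands) {
      if (!oracleSideOk(cl$tips, seed, cat, scheme)) next
      if (is.na(sup) || cl$support > sup) {
        sup <- cl$support
        side <- sort(cl$tips)
      } else if (cl$support == sup &&
                 (length(cl$tips) < length(side) ||
                  (length(cl$tips) == length(side) &&
                   paste(sort(cl$tips), collapse = "\r") <
                     paste(side, collapse = "\r")))) {
        side <- sort(cl$tips)
      }
    }
    if (!is.na(sup)) best[[cat@name]] <- list(cat = cat, support = sup,
                                              side = side)
  }
  if (!length(best))
    return(list(category = "unresolved", score = NA_real_))
  top <- max(vapply(best, `[[`, numeric(1), "support"))
  tied <- Filter(function(b) b$support == top, best)
  if (length(tied) == 1)
    return(list(category = tied[[1]]$cat@name, score = top))
  wide <- Filter(function(w)
    all(vapply(tied, function(o)
      w$cat@memberGroup %in% groupAncestors(scheme, o$cat@memberGroup) &&
        all(o$side %in% w$side), logical(1))), tied)
  if (length(wide) == 1)
    return(list(category = wide[[1]]$cat@name, score = top))
  list(category = "unresolved", score = NA_real_)
}

# random support-labelled tree over the test scheme's datasets, with the
# seed leaf guaranteed present; some supports left missing
randomSortTree <- function(nTips, id = "rnd") {
  pool <- c("kar", "h", "h", "d", "d", "cil", "g", "o", "p", "m")
  ph <- ape::rtree(nTips)
  pre <- sample(pool, nTips, replace = TRUE)
  ph$tip.label <- paste0(pre, seq_len(nTips))
  ph$tip.label[sample.int(nTips, 1)] <- "seed1"
  lab <- as.character(sample(0:100, ph$Nnode, replace = TRUE))
  lab[stats::runif(ph$Nnode) < 0.15] <- ""
  ph$node.label <- lab
  suppressWarnings(asPhyloTree(ph, id))
}

# brute-force at-least-one-per-region motif scan
oracleMotifPct <- function(regions, motif) {
  hit <- 0
  for (r in regions) {
    chars <- strsplit(r, "")[[1]]
    found <- FALSE
    if (length(chars) >= 3)
      for (i in 1:(length(chars) - 2))
        if (paste(chars[i:(i + 2)], collapse = "") == motif) found <- TRUE
    if (found) hit <- hit + 1
  }
  100 * hit / length(regions)
}

# per-residue window scoring oracle (no vectorized shortcuts)
oracleWindowScore <- function(seq, cleavagePos, pssm, offset = 0) {
  chars <- strsplit(seq, "")[[1]]
  total <- 0
  for (k in seq_along(pssm@positions)) {
    i <- cleavagePos + offset + 1 + pssm@positions[k]
    if (i >= 1 && i <= length(chars)) {
      a <- chars[i]
      if (a %in% colnames(pssm@scores))
        total <- total + pssm@scores[as.character(pssm@positions[k]), a]
    }
  }
  unname(total)
}
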