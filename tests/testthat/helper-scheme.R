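# Compact scheme and categories with one-letter-ish leaf prefixes, used by
# the hand-constructed trees throughout the suite:
#   seed*        -> seed kareniacean (neutral in purity checks)
#   kar*         -> another kareniacean (neutral)
#   h*           -> haptophytes          d*   -> peridinin dinoflagellates
#   cil*         -> ciliates             g*   -> green
#   o*           -> ochrophytes (brown)  p*   -> prokaryotes
#   m*           -> metazoa
testScheme <- function(seedLineageNeutral = TRUE) {
  loadScheme(list(
    seed_lineage = "Kareniaceae",
    seed_lineage_neutral = seedLineageNeutral,
    groups = list(alveolates = NULL, dinoflagellates = "alveolates",
                  ciliates = "alveolates", Kareniaceae = "dinoflagellates",
                  haptophytes = NULL,
                  Chrysochromulinaceae = "haptophytes",
                  Isochrysidales = "haptophytes",
                  green = NULL, ochrophytes = NULL, prokaryotes = NULL,
                  metazoa = NULL),
    datasets = list(seedsp = "Kareniaceae", karsp = "Kareniaceae",
                    hap = "haptophytes",
                    chry = "Chrysochromulinaceae", iso = "Isochrysidales",
                    dino = "dinoflagellates", cil = "ciliates",
                    grn = "green", och = "ochrophytes",
                    go = c("green", "ochrophytes"),
                    prok = "prokaryotes", met = "metazoa"),
    leaf_rules = list(
      list(pattern = "^seed", dataset = "seedsp"),
      list(pattern = "^kar", dataset = "karsp"),
      list(pattern = "^chry", dataset = "chry"),
      list(pattern = "^iso", dataset = "iso"),
      list(pattern = "^h", dataset = "hap"),
      list(pattern = "^d", dataset = "dino"),
      list(pattern = "^cil", dataset = "cil"),
      list(pattern = "^go", dataset = "go"),
      list(pattern = "^g", dataset = "grn"),
      list(pattern = "^o", dataset = "och"),
      list(pattern = "^p", dataset = "prok"),
      list(pattern = "^m", dataset = "met"))))
}

testCategories <- function() {
  list(categoryDef("plastid-late", "haptophytes"),
       categoryDef("plastid-early", "dinoflagellates"),
       categoryDef("alveolate", "alveolates", witnessGroup = "ciliates"),
       categoryDef("green-LGT", "green"),
       categoryDef("brown-LGT", "ochrophytes"),
       categoryDef("prokaryote-LGT", "prokaryotes"))
}

# parse a single hand-written newick, silencing the root-label warning that
# rooted binary test trees trigger by construction
tr1 <- function(newick, id = "t") {
  suppressWarnings(parseTreeFile(newick)[[1]])
}

classify1 <- function(newick, seed = "seed1", scheme = testScheme(),
                      categories = testCategories()) {
  suppressWarnings(
    classifyOrigin(tr1(newick), seed, categories, scheme))
}
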