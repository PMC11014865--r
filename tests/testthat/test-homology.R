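mkHits <- function(subjects, evalues, scores = NULL, query = "q1") {
  n <- length(subjects)
  if (n == 0)
    return(data.frame(query = character(0), subject = character(0),
                      evalue = numeric(0), score = numeric(0)))
  data.frame(query = query, subject = subjects,
             pident = 50, length = 100, mismatch = 10, gapopen = 1,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalues,
             score = if (is.null(scores)) seq(200, 100, length.out = n)
                     else scores,
             stringsAsFactors = FALSE)
}

test_that("the e-value threshold is inclusive and self-hits are dropped", {
  sc <- defaultScheme()
  hits <- mkHits(c("Emiliania_huxleyi_0001", "Emiliania_huxleyi_0002", "q1"),
                 c(1e-10, 1e-9, 0))
  kept <- filterHits(hits, sc, query = "q1")
  expect_identical(kept$subject, "Emiliania_huxleyi_0001")  # 1e-10 kept
  expect_false("Emiliania_huxleyi_0002" %in% kept$subject)  # 1e-9 dropped
  expect_false("q1" %in% kept$subject)                      # self-hit
})

test_that("one best hit per in-house dataset, five per fucoxanthin library", {
  sc <- defaultScheme()
  hits <- rbind(
    mkHits(paste0("Emiliania_huxleyi_", 1:2), c(1e-30, 1e-20)),
    mkHits(paste0("Karenia_brevis_", 1:7), 10^-(30:24)))
  kept <- filterHits(hits, sc, query = "q1")
  expect_identical(kept$subject[kept$dataset == "Emiliania_huxleyi"],
                   "Emiliania_huxleyi_1")
  expect_length(kept$subject[kept$dataset == "Karenia_brevis"], 5)
  expect_setequal(kept$subject[kept$dataset == "Karenia_brevis"],
                  paste0("Karenia_brevis_", 1:5))
})

test_that("best-hit ties break by score then subject id", {
  sc <- defaultScheme()
  hits <- mkHits(c("Homo_sapiens_b", "Homo_sapiens_a", "Homo_sapiens_c"),
                 rep(1e-20, 3), scores = c(150, 200, 200))
  kept <- filterHits(hits, sc, query = "q1")
  expect_identical(kept$subject, "Homo_sapiens_a")
})

test_that("retention is monotone in the e-value threshold", {
  sc <- defaultScheme()
  set.seed(5)
  hits <- mkHits(sprintf("Phaeodactylum_tricornutum_%02d", 1:20),
                 10^-runif(20, 5, 40))
  for (pair in list(c(1e-10, 1e-20), c(1e-15, 1e-30))) {
    wide <- filterHits(hits, sc, eMax = pair[1], query = "q1")
    narrow <- filterHits(hits, sc, eMax = pair[2], query = "q1")
    expect_true(all(narrow$subject %in% wide$subject))
  }
})

test_that("homolog sets are categorized by taxonomic breadth", {
  sc <- defaultScheme()
  expect_identical(categorizeHomologSet("q1", NULL, sc), "lineage-specific")
  expect_identical(
    categorizeHomologSet("q1", mkHits(character(0), numeric(0)), sc),
    "lineage-specific")
  dino <- mkHits(c("Symbiodinium_microadriaticum_1", "Karenia_brevis_2"),
                 c(1e-30, 1e-25))
  expect_identical(categorizeHomologSet("q1", dino, sc),
                   "dinoflagellate-specific")
  mixed <- rbind(dino, mkHits("Emiliania_huxleyi_1", 1e-12))
  expect_identical(categorizeHomologSet("q1", mixed, sc),
                   "phylogeny-candidate")
})

test_that("categorization is invariant under hit permutation", {
  sc <- defaultScheme()
  hits <- rbind(mkHits("Symbiodinium_microadriaticum_1", 1e-30),
                mkHits("Emiliania_huxleyi_1", 1e-12),
                mkHits("Karenia_brevis_9", 1e-40))
  set.seed(9)
  base <- categorizeHomologSet("q1", filterHits(hits, sc, query = "q1"), sc)
  for (i in 1:5) {
    perm <- hits[sample.int(nrow(hits)), , drop = FALSE]
    expect_identical(
      categorizeHomologSet("q1", filterHits(perm, sc, query = "q1"), sc),
      base)
  }
})

test_that("decontamination drops sequences with strong contaminant best hits", {
  sc <- defaultScheme()
  expect_false(decontaminate(mkHits("Homo_sapiens_1", 1e-30), sc))
  expect_false(decontaminate(mkHits("Escherichia_coli_1", 1e-10), sc))
  expect_true(decontaminate(mkHits("Homo_sapiens_1", 1e-5), sc))
  expect_true(decontaminate(mkHits("Emiliania_huxleyi_1", 1e-60), sc))
  expect_true(decontaminate(NULL, sc))
})

test_that("alignment rows are removed strictly above the gap threshold", {
  rows <- c(a = paste(rep("A", 100), collapse = ""),
            b = paste(c(rep("-", 76), rep("K", 24)), collapse = ""),
            c = paste(c(rep("-", 75), rep("K", 25)), collapse = ""))
  out <- filterAlignment(rows, minTaxa = 2)
  expect_setequal(names(out$alignment), c("a", "c"))
  expect_identical(out$report$removed, c(FALSE, TRUE, FALSE))
  expect_equal(out$report$gapFrac[2], 0.76)
})

test_that("alignment acceptance applies the column and taxon minima", {
  mk <- function(n, len) stats::setNames(
    rep(paste(rep("A", len), collapse = ""), n), paste0("s", seq_len(n)))
  expect_false(filterAlignment(mk(12, 99))$accepted)
  expect_true(filterAlignment(mk(12, 100))$accepted)
  expect_false(filterAlignment(mk(9, 100))$accepted)
  expect_true(filterAlignment(mk(10, 100))$accepted)

  # exactly at the 10-taxon boundary after gap removal
  rows <- c(mk(10, 100), bad = paste(rep("-", 100), collapse = ""))
  expect_true(filterAlignment(rows)$accepted)
  rows9 <- c(mk(9, 100), bad = paste(rep("-", 100), collapse = ""))
  expect_false(filterAlignment(rows9)$accepted)

  empty <- filterAlignment(character(0))
  expect_false(empty$accepted)
})

test_that("retained residues and acceptance are order-invariant", {
  aln <- simulateAlignment(12, 120, rep(c(0.1, 0.8), 6), rngSeed = 3)
  out1 <- filterAlignment(aln)
  out2 <- filterAlignment(rev(as.character(aln)))
  expect_identical(out1$accepted, out2$accepted)
  expect_setequal(names(out1$alignment), names(out2$alignment))
  orig <- as.character(aln)
  kept <- as.character(out1$alignment)
  expect_identical(unname(kept), unname(orig[names(kept)]))
})

test_that("hit tables round-trip through the 12-column reader", {
  hits <- simulateHitTable("q1", c("Emiliania_huxleyi", "Homo_sapiens"),
                           c(1e-20, 1e-12), rngSeed = 4)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(hits, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  back <- readHitTable(f)
  expect_identical(back$subject, hits$subject)
  expect_equal(back$evalue, hits$evalue)
  expect_equal(back$score, hits$score)
})
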