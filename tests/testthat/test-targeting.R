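# a sharp test matrix: N identical windows on a 27-residue consensus with
# no short-period repeats, so shifted windows score far below the at-site
# window
consensusString <- function() {
  paste(rep(plastosort:::AA20, length.out = 27), collapse = "")
}
sharpPssm <- function(n = 10, pseudocount = 1) {
  buildPssm(rep(consensusString(), n), pseudocount = pseudocount)
}

test_that("SignalP 5.0 short-format rows parse to calls", {
  doc <- c("# SignalP-5.0",
           "# ID\tPrediction\tSP(Sec/SPI)\tOTHER\tCS Position",
           "prot1\tSP(Sec/SPI)\t0.97\t0.03\tCS pos: 20-21. Pr: 0.88",
           "prot2\tOTHER\t0.01\t0.99")
  calls <- parseSignalp5(paste(doc, collapse = "\n"))
  expect_length(calls, 2)
  expect_true(calls[[1]]@hasSp)
  expect_equal(calls[[1]]@cleavagePos, 20)
  expect_equal(calls[[1]]@spProbability, 0.97)
  expect_false(calls[[2]]@hasSp)

  expect_error(parseSignalp5("prot3\tSP(Sec/SPI)\t0.9\t0.1"),
               "lacks a parsable CS")
})

test_that("legacy-table conversion round-trips id, call and cleavage site", {
  calls <- list(signalPeptideCall("a", TRUE, 20, 0.97),
                signalPeptideCall("b", FALSE),
                signalPeptideCall("c", TRUE, 33, 0.81))
  back <- readLegacySignalp(writeLegacySignalp(calls))
  expect_identical(vapply(back, function(x) x@id, ""), c("a", "b", "c"))
  expect_identical(vapply(back, function(x) x@hasSp, TRUE),
                   c(TRUE, FALSE, TRUE))
  expect_equal(vapply(back, function(x) x@cleavagePos, 1)[c(1, 3)],
               c(20, 33))
})

test_that("first-methionine trimming", {
  expect_identical(firstMetTrim("ARMLKV"), "MLKV")
  expect_identical(firstMetTrim("MKV"), "MKV")
  expect_true(is.na(firstMetTrim("ARLKV")))
})

test_that("variant pooling prioritizes positives and shifts coordinates", {
  orig <- signalPeptideCall("p", FALSE, spProbability = 0.1)
  trim <- signalPeptideCall("p", TRUE, 18, 0.9, "first_met_trimmed")
  pooled <- poolVariantCalls(orig, trim, trimOffset = 4)
  expect_true(pooled@hasSp)
  expect_equal(pooled@cleavagePos, 22)
  expect_identical(pooled@sourceVariant, "first_met_trimmed")

  origPos <- signalPeptideCall("p", TRUE, 20, 0.8)
  expect_identical(poolVariantCalls(origPos, trim, 4)@cleavagePos, 20)

  negTrim <- signalPeptideCall("p", FALSE)
  expect_false(poolVariantCalls(orig, negTrim, 4)@hasSp)
  expect_false(poolVariantCalls(orig, NULL, 0)@hasSp)
})

test_that("PSSM log-odds match the closed forms", {
  # training equal to background at every position: all scores zero
  flat <- buildPssm(plastosort:::AA20, pseudocount = 1, start = 0)
  expect_true(all(abs(pssmScores(flat)) < 1e-9))

  # pure column, zero pseudocount: log2(1 / 0.05)
  pure0 <- buildPssm(rep("R", 10), pseudocount = 0, start = 0)
  expect_equal(pssmScores(pure0)["0", "R"], log2(1 / 0.05),
               tolerance = 1e-9)
  expect_equal(pssmScores(pure0)["0", "R"], 4.3219, tolerance = 1e-4)

  # pure column, pseudocount 1
  pure1 <- buildPssm(rep("R", 10), pseudocount = 1, start = 0)
  expect_equal(pssmScores(pure1)["0", "R"], 4.1919, tolerance = 1e-4)

  expect_error(buildPssm(c("AR", "A")), "differ in length")
  expect_error(buildPssm("AB-"), "unknown residue")
})

test_that("PSSM TSV round trip preserves scores, window and background", {
  m <- sharpPssm()
  f <- tempfile(fileext = ".tsv")
  writePssm(m, f)
  m2 <- readPssm(f)
  expect_identical(pssmPositions(m2), pssmPositions(m))
  expect_equal(pssmScores(m2), pssmScores(m), tolerance = 1e-9)
  expect_equal(m2@background, m@background, tolerance = 1e-12)
})

test_that("implied positional frequencies invert the log-odds", {
  m <- sharpPssm()
  fr <- pssmFrequencies(m)
  expect_equal(unname(rowSums(fr)), rep(1, nrow(fr)), tolerance = 1e-9)
  cons <- strsplit(consensusString(), "")[[1]]
  expect_identical(colnames(fr)[apply(fr, 1, which.max)], cons)
})

test_that("window scores are per-position sums (brute-force agreement)", {
  m <- sharpPssm()
  set.seed(31)
  for (i in 1:50) {
    n <- sample(40:90, 1)
    seq <- paste(sample(plastosort:::AA20, n, replace = TRUE),
                 collapse = "")
    cp <- sample(10:30, 1)
    off <- sample(-2:2, 1)
    expect_equal(plastosort:::windowScoreAt(seq, cp, m, off),
                 oracleWindowScore(seq, cp, m, off), tolerance = 1e-9)
  }
})

test_that("scores are unchanged when a prefix shifts the cleavage site", {
  m <- sharpPssm()
  set.seed(32)
  for (i in 1:20) {
    seq <- paste(sample(plastosort:::AA20, 70, replace = TRUE),
                 collapse = "")
    cp <- sample(15:25, 1)
    k <- sample(1:12, 1)
    shifted <- paste0(paste(sample(plastosort:::AA20, k, replace = TRUE),
                            collapse = ""), seq)
    for (off in -2:2)
      expect_equal(plastosort:::windowScoreAt(shifted, cp + k, m, off),
                   plastosort:::windowScoreAt(seq, cp, m, off),
                   tolerance = 1e-9)
  }
})

test_that("presequence classification follows the decision structure", {
  m <- sharpPssm()
  cons <- consensusString()
  sp20 <- function(id) signalPeptideCall(id, TRUE, 20, 0.95)
  # at-site window matches the consensus: the maximum over offsets
  seqHigh <- paste0(paste(rep("G", 15), collapse = ""), cons,
                    paste(rep("S", 10), collapse = ""))
  pc <- asafindClassify(seqHigh, sp20("hi"), m)
  expect_identical(pc@klass, "plastid_high")
  expect_equal(pc@bestOffset, 0)
  expect_equal(pc@atSiteScore, sum(apply(pssmScores(m), 1, max)),
               tolerance = 1e-9)

  # no signal peptide gates everything
  pcNo <- asafindClassify(seqHigh, signalPeptideCall("no", FALSE), m)
  expect_identical(pcNo@klass, "no_sp")
  expect_true(is.na(pcNo@atSiteScore))

  # random (non-consensus) window scores far below the low threshold
  set.seed(33)
  seqBad <- paste(sample(plastosort:::AA20, 70, replace = TRUE),
                  collapse = "")
  pcBad <- asafindClassify(seqBad, sp20("lo"), m)
  expect_identical(pcBad@klass, "not_plastid")

  # a high at-site score that is not the offset maximum cannot be
  # plastid_high
  seqShift <- paste0(paste(rep("G", 16), collapse = ""), cons,
                     paste(rep("S", 10), collapse = ""))
  pcShift <- asafindClassify(seqShift, sp20("sh"), m,
                             tHigh = 1, tLow = 0.5)
  expect_equal(pcShift@bestOffset, 1)
  expect_false(pcShift@klass == "plastid_high")

  # a C-terminally truncated protein still classifies (positions beyond
  # the end score 0)
  seqShort <- substr(seqHigh, 1, 30)
  pcShort <- asafindClassify(seqShort, sp20("tr"), m, tHigh = 5, tLow = 2)
  expect_identical(pcShort@klass, "plastid_high")

  expect_error(asafindClassify("AAAA", signalPeptideCall("x", TRUE, 50), m),
               "outside the sequence")
})

test_that("route merging prefixes alternative-only positives with SPTP-", {
  calls <- data.frame(id = c("a", "b", "c", "d"),
                      klass = c("plastid_high", "plastid_low",
                                "not_plastid", "no_sp"),
                      stringsAsFactors = FALSE)
  out <- mergeRoutes(calls, altPositiveIds = c("a", "c", "d"))
  expect_setequal(out, c("a", "b", "SPTP-c", "SPTP-d"))
  expect_identical(anyDuplicated(out), 0L)
})

test_that("PrediSI and ChloroP tables combine by double agreement", {
  pre <- parsePredisi(paste(c("a\t0.9\t20\tY", "b\t0.8\t18\tY",
                              "c\t0.2\t0\tN"), collapse = "\n"))
  chl <- parseChlorop(paste(c("a\t300\t0.55\tY\t4.2\t35",
                              "b\t280\t0.41\tN\t1.0\t0",
                              "c\t250\t0.58\tY\t3.3\t30"),
                            collapse = "\n"))
  expect_identical(altPositiveIds(pre, chl), "a")
})

test_that("screening pools trimmed-variant calls into original coordinates", {
  m <- sharpPssm()
  cons <- consensusString()
  # 4 junk residues before the first methionine; the trimmed variant has
  # its cleavage site at 16, which is 20 in original coordinates
  seq <- paste0("ARLE", "M", paste(rep("G", 10), collapse = ""), cons,
                paste(rep("S", 5), collapse = ""))
  orig <- list(signalPeptideCall("p1", FALSE, spProbability = 0.2))
  trim <- list(signalPeptideCall("p1", TRUE, 16, 0.9,
                                 "first_met_trimmed"))
  out <- asafindScreen(c(p1 = seq), orig, m, trimmedCalls = trim)
  expect_true(out$hasSp)
  expect_equal(out$cleavagePos, 20)
  expect_identical(out$klass, "plastid_high")
})
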