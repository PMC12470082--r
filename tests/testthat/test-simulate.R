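count_cg <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sum(ch[-length(ch)] == "C" & ch[-1] == "G")
}

test_that("root sequences honour the requested CpG density exactly", {
  p0 <- erosionParams(rootLength = 400, cpgFraction = 0, seed = 2)
  expect_equal(count_cg(makeRootSequence(p0)), 0)
  p5 <- erosionParams(rootLength = 200, cpgFraction = 0.5, seed = 2)
  expect_equal(makeRootSequence(p5), strrep("CG", 100))
  p <- erosionParams(rootLength = 1000, cpgFraction = 0.1, seed = 42)
  root <- makeRootSequence(p)
  expect_identical(root, makeRootSequence(p))
  frac <- count_cg(root) / nchar(root)
  expect_lte(abs(frac - 0.1) / 0.1, 0.1)
  gc <- mean(strsplit(root, "")[[1]] %in% c("C", "G"))
  expect_gte(gc, 0.5)
})

test_that("zero-length branches leave every leaf equal to the root", {
  tree <- readNewickTree("((x:0,y:0):0,z:0);")
  p <- erosionParams(rootLength = 300, seed = 4)
  root <- makeRootSequence(p)
  sim <- evolveSequences(root, tree, p)
  expect_equal(nrow(sim@eventLog), 0L)
  expect_true(all(as.character(sim@sequences) == root))
})

test_that("event-log replay reproduces leaf sequences bitwise", {
  p <- erosionParams(rootLength = 1200, seed = 8)
  sim <- simulateStudyDataset(p)
  expect_gt(nrow(sim@eventLog), 0L)
  expect_identical(as.character(replayEvents(sim)),
                   as.character(sim@sequences))
})

test_that("simulation is deterministic under a fixed seed", {
  p <- erosionParams(rootLength = 600, seed = 101)
  s1 <- simulateStudyDataset(p)
  s2 <- simulateStudyDataset(p)
  expect_identical(as.character(s1@sequences), as.character(s2@sequences))
  expect_identical(s1@eventLog, s2@eventLog)
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeFasta(s1@sequences, f1)
  writeFasta(s2@sequences, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hypermutability erodes CpGs and skews the spectrum", {
  p <- erosionParams(rootLength = 4000, lambdaCpg = 25, seed = 6)
  sim <- simulateStudyDataset(p)
  root_cg <- count_cg(sim@rootSeq)
  leaf_cg <- vapply(as.character(sim@sequences), count_cg, numeric(1))
  # erosion dominates: CpG count can only grow via background CG creation
  created <- sum(with(sim@eventLog, channel == "background"))
  expect_true(all(leaf_cg <= root_cg + created))
  expect_lt(mean(leaf_cg), root_cg)
  # deamination products dominate the pipeline's substitution spectrum
  tb <- classifyPositions(tileDinucleotides(simMsa(sim)))
  sp <- substitutionSpectrum(tb)
  top2 <- names(sp)[1:2]
  expect_setequal(top2, c("TG", "CA"))
  other <- sp[!names(sp) %in% c("TG", "CA")]
  if (length(other) > 0) expect_gt(min(sp[c("TG", "CA")]), max(other))
})

test_that("sequences stay closely related under default settings", {
  p <- erosionParams(rootLength = 3000, seed = 12)
  sim <- simulateStudyDataset(p)
  pid <- percentIdentity(simMsa(sim))
  expect_gte(min(pid), 94)
})

test_that("pipeline annotation agrees with event-log ground truth", {
  p <- erosionParams(rootLength = 2000, seed = 9)
  sim <- simulateStudyDataset(p)
  truth <- simTruth(sim, studyPartition())
  tb <- classifyPositions(tileDinucleotides(simMsa(sim)))
  expect_equal(which(positionClass(tb) == "conserved_cpg"), truth$conserved)
  expect_equal(which(positionClass(tb) == "variable_cpg"), truth$variable)
  got <- cladeMarkers(tb, studyPartition(), "cpg")
  expect_equal(got, truth$markers)
  # variable positions are exactly those CpG positions touched by the log
  st <- variabilityStats(tb, simMsa(sim))
  expect_equal(st@nCpgPositions, length(truth$cpgPositions))
})
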