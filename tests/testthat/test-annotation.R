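msa_of <- function(rows) buildMsa(rows, mode = "preloaded")

classified <- function(rows) classifyPositions(tileDinucleotides(msa_of(rows)))

test_that("tiling pairs columns in frame and ignores a trailing odd column", {
  tb <- tileDinucleotides(msa_of(c(s1 = "ACGTACGT", s2 = "ACGTACGT")))
  expect_equal(unname(positionStates(tb)[1, ]), c("AC", "GT", "AC", "GT"))
  tb <- tileDinucleotides(msa_of(c(a = "CGCGCG", b = "CGCGCG", c = "CGCGCG")))
  expect_true(all(positionStates(tb) == "CG"))
  expect_equal(ncol(positionStates(tb)), 3L)
  tb <- tileDinucleotides(msa_of(c(a = "ACGTA", b = "ACGTA")))
  expect_equal(ncol(positionStates(tb)), 2L)
})

test_that("tiling matches an independent column-pair enumeration", {
  set.seed(3)
  rows <- rand_related_rows(12, 500)
  tb <- tileDinucleotides(msa_of(rows))
  want <- oracle_annotate(rows)
  expect_identical(positionStates(tb), want$states)
  expect_identical(tb@evaluable, want$evaluable)
})

test_that("classification follows the CpG conservation and gap rules", {
  expect_equal(positionClass(classified(c(a = "CG", b = "CG", c = "CG"))),
               "conserved_cpg")
  expect_equal(positionClass(classified(c(a = "CG", b = "CA", c = "CG"))),
               "variable_cpg")
  # a two-column gap excludes the whole position
  expect_equal(positionClass(classified(c(a = "CGA", b = "--A", c = "CGA")))[1],
               "excluded")
  # a single-column gap only drops that species
  tb <- classified(c(a = "CGG", b = "A-G", c = "CGG"))
  expect_equal(positionClass(tb)[1], "conserved_cpg")
  expect_equal(sum(tb@evaluable[, 1]), 2)
  # N drops the species but never excludes the position
  expect_equal(positionClass(classified(c(a = "CG", b = "NG", c = "TG"))),
               "variable_cpg")
  expect_equal(positionClass(classified(c(a = "AT", b = "AT", c = "AT"))),
               "noncpg_conserved")
  expect_equal(positionClass(classified(c(a = "AT", b = "AA", c = "AT"))),
               "noncpg_variable")
})

test_that("classes partition the positions on random inputs", {
  set.seed(101)
  for (rep in 1:20) {
    rows <- rand_related_rows(sample(3:10, 1), sample(10:200, 1))
    tb <- classifyPositions(tileDinucleotides(msa_of(rows)))
    expect_equal(sum(table(factor(positionClass(tb),
                                  levels = c("conserved_cpg", "variable_cpg",
                                             "noncpg_conserved",
                                             "noncpg_variable", "excluded")))),
                 ncol(positionStates(tb)))
    expect_false(anyNA(positionClass(tb)))
  }
})

test_that("variability statistics count classes and non-CpG variable columns", {
  rows <- c(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  msa <- msa_of(rows)
  st <- variabilityStats(classifyPositions(tileDinucleotides(msa)), msa)
  expect_equal(st@nVariableCpg, 0L)
  expect_equal(st@nNonCpgVariableNt, 0L)
  # two identical rows except one non-CpG column among 100
  r2 <- rows
  substr(r2["b"], 1, 1) <- "T"
  msa <- msa_of(r2)
  st <- variabilityStats(classifyPositions(tileDinucleotides(msa)), msa)
  expect_equal(st@nNonCpgVariableNt, 1L)
  expect_equal(unname(variabilityFractions(st)["noncpg_variable_of_nt"]),
               0.01)
})

test_that("spectrum counts unique (position, alternative state) pairs", {
  sp <- substitutionSpectrum(classified(c(a = "CG", b = "CA")))
  expect_equal(sp, c(CA = 1L))
  sp <- substitutionSpectrum(classified(c(a = "CG", b = "CA", c = "TG",
                                          d = "CA")))
  expect_equal(sort(names(sp)), c("CA", "TG"))
  expect_true(all(sp == 1L))
})

test_that("spectrum matches brute-force enumeration on random tables", {
  set.seed(11)
  for (rep in 1:30) {
    rows <- rand_related_rows(sample(3:12, 1), sample(20:120, 1))
    got <- substitutionSpectrum(classified(rows))
    want <- oracle_spectrum(rows)
    expect_equal(sort(got), sort(want))
    # total >= number of variable positions, <= variable * (nspecies - 1)
    nv <- sum(positionClass(classified(rows)) == "variable_cpg")
    expect_gte(sum(got), nv)
    expect_lte(sum(got), nv * (length(rows) - 1))
  }
})

test_that("clade markers require uniform within-clade CpG states", {
  part <- cladePartition(c("a", "b"), c("c", "d"))
  tb <- classified(c(a = "CG", b = "CG", c = "CA", d = "CA"))
  expect_equal(cladeMarkers(tb, part, "cpg"), 1L)
  tb <- classified(c(a = "CG", b = "CA", c = "CG", d = "CA"))
  expect_equal(length(cladeMarkers(tb, part, "cpg")), 0L)
  expect_error(cladeMarkers(tb, cladePartition("a", "zzz"), "cpg"),
               "absent from the table")
})

test_that("clade markers match brute force and are polarity-invariant", {
  set.seed(13)
  for (rep in 1:30) {
    ns <- sample(4:10, 1)
    rows <- rand_related_rows(ns, sample(20:120, 1))
    na <- sample(2:(ns - 2), 1)
    A <- names(rows)[1:na]
    B <- names(rows)[(na + 1):ns]
    tb <- classified(rows)
    got <- cladeMarkers(tb, cladePartition(A, B), "cpg")
    expect_equal(got, oracle_markers_cpg(rows, A, B))
    expect_equal(got, cladeMarkers(tb, cladePartition(B, A), "cpg"))
    expect_true(all(positionClass(tb)[got] == "variable_cpg"))
    gs <- cladeMarkers(tb, cladePartition(A, B), "snv")
    expect_equal(gs, oracle_markers_snv(rows, A, B))
  }
})

test_that("results are invariant to alignment row order", {
  set.seed(17)
  rows <- rand_related_rows(8, 100)
  shuf <- rows[sample(length(rows))]
  t1 <- classified(rows)
  t2 <- classified(shuf)
  expect_equal(positionClass(t1), positionClass(t2))
  expect_equal(sort(substitutionSpectrum(t1)), sort(substitutionSpectrum(t2)))
  part <- cladePartition(names(rows)[1:4], names(rows)[5:8])
  expect_equal(cladeMarkers(t1, part, "cpg"), cladeMarkers(t2, part, "cpg"))
})

test_that("context counting assigns the left-neighbour dinucleotide", {
  msa <- msa_of(c(ref = "ACGA", oth = "ACAA"))
  cc <- contextCounts(msa, "ref", "oth")
  expect_equal(cc$g_changes, c(CG = 1L))
  expect_equal(length(cc$non_g_changes), 0L)
  cc <- contextCounts(msa_of(c(ref = "TGGA", oth = "TGCA")), "ref", "oth")
  expect_equal(cc$g_changes, c(GG = 1L))
  cc <- contextCounts(msa_of(c(ref = "ACGT", oth = "ACGT")), "ref", "oth")
  expect_equal(sum(cc$g_changes) + sum(cc$non_g_changes), 0L)
  # altered adenine in CpA context feeds the parallel tally
  cc <- contextCounts(msa_of(c(ref = "TCAT", oth = "TCGT")), "ref", "oth")
  expect_equal(cc$cpa_adenine, 1L)
  expect_error(contextCounts(msa, "ref", "nope"), "unknown id")
})
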