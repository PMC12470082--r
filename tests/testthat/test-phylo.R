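test_that("percent identity excludes gapped columns from both terms", {
  pid <- percentIdentity(buildMsa(c(a = "ACGT", b = "ACGT"), "preloaded"))
  expect_equal(pid["a", "b"], 100)
  pid <- percentIdentity(buildMsa(c(a = "ACGT", b = "ACGA"), "preloaded"))
  expect_equal(pid["a", "b"], 75)
  pid <- percentIdentity(buildMsa(c(a = "AC-T", b = "ACGT"), "preloaded"))
  expect_equal(pid["a", "b"], 100)
  expect_error(percentIdentity(buildMsa(c(a = "A--", b = "-CG"), "preloaded")),
               "no co-ungapped columns")
})

test_that("p-distance matches brute force in both indel modes", {
  d <- pDistance(buildMsa(c(a = "ACGT", b = "ACGT"), "preloaded"))
  expect_true(all(d == 0))
  set.seed(9)
  for (rep in 1:25) {
    rows <- rand_related_rows(sample(3:8, 1), sample(20:150, 1))
    msa <- buildMsa(rows, "preloaded")
    for (mode in c("exclude", "mismatch")) {
      got <- pDistance(msa, indels = mode)
      expect_equal(got, oracle_pdist(rows, mode), tolerance = 1e-12)
    }
    expect_equal(percentIdentity(msa), oracle_pid(rows), tolerance = 1e-12)
  }
})

test_that("percent identity and gap-excluded p-distance are complementary", {
  set.seed(31)
  rows <- rand_gapfree_rows(6, 200)
  msa <- buildMsa(rows, "preloaded")
  expect_equal(percentIdentity(msa) / 100 + pDistance(msa, "exclude"),
               matrix(1, 6, 6, dimnames = list(names(rows), names(rows))),
               tolerance = 1e-12)
})

test_that("recoded-matrix distances count character mismatches", {
  m <- matrix(c("A", "A", "T", "A", "T", "A"), nrow = 2, byrow = TRUE,
              dimnames = list(c("x", "y"), NULL))
  rc <- methods::new("RecodedMatrix", ids = c("x", "y"), chars = m,
                     positionIndex = 1:3)
  expect_equal(pDistance(rc)["x", "y"], 2 / 3)
  # missing symbols shrink the comparable denominator
  m[2, 2] <- "-"
  rc <- methods::new("RecodedMatrix", ids = c("x", "y"), chars = m,
                     positionIndex = 1:3)
  expect_equal(pDistance(rc)["x", "y"], 1 / 2)
})

test_that("UPGMA merges closest clusters at half their distance", {
  d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgmaTree(d)
  expect_equal(max(nodeHeights(tr)), 1)
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgmaTree(d)
  expect_equal(writeNewick(tr), "((A:1,B:1):1,C:2);")
  dn <- d
  dn[1, 2] <- dn[2, 1] <- NA
  expect_error(upgmaTree(dn), "finite")
  dn <- d
  dn[1, 2] <- dn[2, 1] <- -1
  expect_error(upgmaTree(dn), "non-negative")
})

test_that("UPGMA ties break deterministically by label", {
  # all distances equal: merge order must follow lexicographic labels
  lab <- c("d", "b", "c", "a")
  d <- matrix(2, 4, 4, dimnames = list(lab, lab))
  diag(d) <- 0
  expect_equal(writeNewick(upgmaTree(d)), writeNewick(upgmaTree(d[4:1, 4:1])))
  expect_match(writeNewick(upgmaTree(d)), "\\(a:1,b:1\\)")
})

test_that("UPGMA agrees with average-linkage hclust heights", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    d <- as.matrix(dist(matrix(runif(n * 3), n)))
    dimnames(d) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- upgmaTree(d)
    hc <- hclust(as.dist(d), method = "average")
    expect_equal(sort(unique(round(nodeHeights(tr)[-(1:n)], 10))),
                 sort(unique(round(hc$height / 2, 10))))
  }
})

test_that("UPGMA reconstructs random ultrametric trees exactly", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample(5:15, 1)
    truth <- sampleUltrametricTree(n)
    d <- ape::cophenetic.phylo(truth@phy)
    rec <- upgmaTree(d)
    expect_equal(rfDistance(rec, truth), 0)
    drec <- ape::cophenetic.phylo(rec@phy)
    expect_equal(drec[rownames(d), colnames(d)], d, tolerance = 1e-9)
    h <- ape::node.depth.edgelength(rec@phy)
    expect_lt(diff(range(h[seq_len(n)])), 1e-9)
  }
})

test_that("calibration scales heights linearly and is idempotent", {
  truth <- sampleUltrametricTree(8, seed = 3)
  # scale to a known anchor
  pair <- truth@phy$tip.label[1:2]
  cal <- calibrateTree(truth, pair, 1.7)
  node <- ape::getMRCA(cal@phy, pair)
  expect_equal(unname(nodeHeights(cal)[as.character(node)]), 1.7,
               tolerance = 1e-9)
  again <- calibrateTree(cal, pair, 1.7)
  expect_equal(nodeHeights(again), nodeHeights(cal), tolerance = 1e-12)
  expect_equal(again@timeScale, 1, tolerance = 1e-9)
  # calibrating on the root pins the root age
  tr <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  cal <- calibrateTree(tr, c("A", "C"), 10)
  expect_equal(max(nodeHeights(cal)), 10, tolerance = 1e-12)
  expect_error(calibrateTree(tr, c("A", "Z"), 1), "not in the tree")
})

test_that("Newick serialization round-trips topology and heights", {
  expect_equal(writeNewick(upgmaTree(matrix(c(0, 2, 2, 0), 2,
    dimnames = list(c("A", "B"), c("A", "B"))))), "(A:1,B:1);")
  set.seed(19)
  f <- withr::local_tempfile(fileext = ".nwk")
  for (rep in 1:20) {
    tr <- sampleUltrametricTree(sample(3:12, 1))
    writeNewick(tr, f)
    back <- readNewickTree(f)
    expect_equal(rfDistance(tr, back), 0)
    expect_equal(sort(nodeHeights(back)), sort(nodeHeights(tr)),
                 tolerance = 1e-9)
  }
  expect_error(readNewickTree("((A:1,B:1):1;"), "unbalanced")
  expect_error(readNewickTree("(A:1,B:1)):1;"), "offset 10")
})

test_that("Robinson-Foulds distance matches phangorn on random pairs", {
  t1 <- readNewickTree("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- readNewickTree("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(rfDistance(t1, t1), 0)
  expect_equal(rfDistance(t1, t2), 2)
  expect_error(rfDistance(t1, readNewickTree("((A:1,B:1):1,(C:1,E:1):1);")),
               "different leaf sets")
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(4:12, 1)
    a <- sampleUltrametricTree(n)
    b <- sampleUltrametricTree(n)
    want <- as.integer(phangorn::RF.dist(a@phy, b@phy))
    expect_equal(rfDistance(a, b), want)
  }
})
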