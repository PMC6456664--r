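test_that("the worked example splits on the balanced column C|T", {
  aln <- makeWorkedExampleAlignment()
  sp <- selectSplit(aln)
  expect_equal(sp$position, 1L)
  expect_equal(sp$up, "C")
  expect_equal(sp$down, "T")
  expect_equal(sp$profile$score, 2.0)
})

test_that("nucleotide ties at the split resolve in A<C<G<T order", {
  aln <- makeRandomAlignment(8, 6, list(`3` = c(C = 3, T = 3, A = 2)),
                             seed = 5)
  sp <- selectSplit(aln)
  expect_equal(sp$position, 3L)
  # C and T both deviate by 1 from mid=4; C wins by nucleotide order
  expect_equal(sp$up, "C")
  expect_setequal(sp$down, c("A", "T"))
})

test_that("identical rows raise an indistinguishable-species error", {
  aln <- BarcodeAlignment(c(x = "ACGT", y = "ACGT"))
  expect_error(selectSplit(aln), "indistinguishable.*x.*y")
  expect_error(buildTree(aln), "indistinguishable")
})

test_that("position ties resolve to the lowest position", {
  # columns 2 and 4 both balanced biallelic
  aln <- BarcodeAlignment(c(a = "ACAC", b = "ACAC", c = "ATAG", d = "ATAG"))
  expect_equal(selectSplit(aln)$position, 2L)
})

test_that("optimized split matches the brute-force oracle on random data", {
  set.seed(101)
  checked <- 0
  while (checked < 200) {
    m <- randomAcgtMatrix(sample(2:8, 1), sample(2:15, 1))
    oracle <- bruteForceSplit(m)
    if (!is.finite(oracle$score) || oracle$score <= 0) next  # no usable split
    got <- selectSplit(m)
    expect_equal(got$position, oracle$position)
    expect_equal(got$up, oracle$up)
    checked <- checked + 1
  }
})

test_that("tree on the worked example uses positions 1,2,3,4,7 with 3 and 4 twice", {
  tree <- buildTree(makeWorkedExampleAlignment())
  expect_equal(selectedPositions(tree), c(1L, 2L, 3L, 4L, 7L))
  used <- nodePositions(tree)
  expect_equal(sort(used), c(1L, 2L, 3L, 3L, 4L, 4L, 7L))
  expect_equal(treeDepth(tree), 3L)
})

test_that("two species differing at one column give a single-node tree", {
  aln <- BarcodeAlignment(c(a = "ACGT", b = "ACAT"))
  tree <- buildTree(aln)
  expect_equal(treeDepth(tree), 1L)
  expect_equal(selectedPositions(tree), 3L)
  st <- treeStats(tree)
  expect_equal(st$nodeCount, 1L)
  expect_equal(st$leafCount, 2L)
})

test_that("balanced code fixtures are recovered exactly for small k", {
  for (k in 1:4) {
    aln <- makeBalancedCodeAlignment(k, seed = k + 10)
    planted <- S4Vectors::metadata(aln)$planted
    tree <- buildTree(aln)
    expect_equal(treeDepth(tree), k)
    expect_equal(selectedPositions(tree), planted$columns)
    expect_equal(treeStats(tree)$balanceIndex, 0L)
  }
})

test_that("leaves partition the species set", {
  set.seed(33)
  for (i in 1:10) {
    aln <- makeBalancedCodeAlignment(sample(1:4, 1), seed = i)
    tree <- buildTree(aln)
    leaves <- dcstag:::leafSpecies(tree@root)
    expect_setequal(leaves, speciesIds(aln))
    expect_equal(length(leaves), nSpecies(aln))
  }
})

test_that("trees are deterministic and row-order invariant in selection", {
  aln <- makeBalancedCodeAlignment(3, seed = 9)
  t1 <- buildTree(aln); t2 <- buildTree(aln)
  expect_identical(treeToJSON(t1), treeToJSON(t2))
  set.seed(4)
  perm <- sample(nSpecies(aln))
  alnP <- BarcodeAlignment(stats::setNames(as.character(aln)[perm],
                                           speciesIds(aln)[perm]))
  tP <- buildTree(alnP, referenceId = speciesIds(aln)[1])
  expect_equal(selectedPositions(tP), selectedPositions(t1))
  expect_equal(treeDepth(tP), treeDepth(t1))
})

test_that("imbalanced strategies split where documented", {
  # column 2 is the first polymorphic site; column 4 has the most skewed
  # majority (5 of 6)
  aln <- BarcodeAlignment(c(a = "ACAA", b = "ACTA", c = "AGCA",
                            d = "AGCT", e = "AGGA", f = "AGTA"))
  fd <- selectSplit(aln, "first_diff")
  expect_equal(fd$position, 2L)
  expect_equal(fd$up, "C")  # alphabetically first observed allele
  md <- selectSplit(aln, "max_divergence")
  expect_equal(md$position, 4L)
  expect_equal(md$up, "A")  # the majority allele goes up
  # both still yield a valid full tree
  for (s in c("first_diff", "max_divergence")) {
    tree <- buildTree(aln, s)
    expect_equal(treeStats(tree)$leafCount, 6L)
  }
})

test_that("split of 3 species has balance index 1", {
  aln <- BarcodeAlignment(c(a = "AC", b = "AT", c = "CT"))
  expect_equal(treeStats(buildTree(aln))$balanceIndex, 1L)
})

test_that("non-ACGT characters at the split position route down with a warning", {
  aln <- BarcodeAlignment(c(a = "CAAA", b = "CAAC", c = "TAAA",
                            d = "TAAC", e = "NAAG"))
  expect_warning(tree <- buildTree(aln), "non-ACGT.*routed down")
  expect_setequal(dcstag:::leafSpecies(tree@root), speciesIds(aln))
})

test_that("total split work is bounded by N x depth (complexity structure)", {
  for (k in 2:5) {
    aln <- makeBalancedCodeAlignment(k, seed = k)
    tree <- buildTree(aln)
    st <- treeStats(tree)
    # every node re-scans its subgroup's M columns once, so total work is
    # (sum of internal-node sizes) x M <= N x D x M
    expect_lte(st$subgroupSizeSum, nSpecies(aln) * st$depth)
  }
})

test_that("tree serialisations are stable and carry node labels", {
  tree <- buildTree(makeWorkedExampleAlignment())
  js <- jsonlite::fromJSON(treeToJSON(tree), simplifyVector = FALSE)
  expect_equal(js$root$label, "CT(1)")
  expect_equal(js$root$size, 8L)
  txt <- treeToText(tree)
  expect_match(txt[1], "^CT\\(1\\)")
  expect_equal(sum(grepl("- S", txt)), 8L)
})
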