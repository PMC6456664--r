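writeFasta <- function(records) {
  f <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(records), function(n)
    c(paste0(">", n), records[[n]]))), f)
  f
}

test_that("reading a well-formed aligned FASTA preserves order and uppercases", {
  f <- writeFasta(list(sp1 = "acgt", sp2 = "ACGA"))
  aln <- readAlignment(f)
  expect_s4_class(aln, "BarcodeAlignment")
  expect_equal(nSpecies(aln), 2L)
  expect_equal(alignmentWidth(aln), 4L)
  expect_equal(speciesIds(aln), c("sp1", "sp2"))
  expect_equal(as.character(aln[["sp1"]]), "ACGT")
})

test_that("header id policy keeps or strips the description", {
  f <- writeFasta(list(`KT1.1 Ariomma bondi` = "ACGT", `KT2.1 Other sp` = "ACGA"))
  expect_equal(speciesIds(readAlignment(f, "full_header"))[1],
               "KT1.1 Ariomma bondi")
  expect_equal(speciesIds(readAlignment(f, "first_token")), c("KT1.1", "KT2.1"))
})

test_that("malformed inputs are rejected with the offending record named", {
  f <- writeFasta(list(a = "ACGT", b = "ACGTA"))
  expect_error(readAlignment(f), "not aligned.*b")
  f2 <- writeFasta(list(a = "ACGT", a = "ACGA"))
  expect_error(readAlignment(f2), "duplicate")
  f3 <- tempfile(); writeLines(character(), f3)
  expect_error(readAlignment(f3), "no records|FASTA")
  f4 <- writeFasta(list(only = "ACGT"))
  expect_error(readAlignment(f4), "at least 2")
  expect_error(readAlignment(tempfile()), "not found")
})

test_that("explicit trimming removes exactly the requested columns", {
  aln <- asAln(randomAcgtMatrix(4, 696))
  tr <- trimAlignment(aln, "explicit", dropHead = 35, dropTail = 24)
  expect_equal(alignmentWidth(tr), 637L)
  expect_equal(as.character(tr[[1]]),
               substr(as.character(aln[[1]]), 36, 672))
  expect_error(trimAlignment(aln, "explicit", 400, 300), "leaves no columns")
  expect_error(trimAlignment(aln, "explicit", -1, 0), "non-negative")
})

test_that("auto trimming removes terminal gap-column runs only", {
  aln <- BarcodeAlignment(c(a = "-ACG-", b = "TACGT"))
  tr <- trimAlignment(aln, "auto")
  expect_equal(alignmentWidth(tr), 3L)
  expect_equal(as.character(tr[["a"]]), "ACG")
  # interior gap columns are never removed
  aln2 <- BarcodeAlignment(c(a = "A-CG", b = "A-CG"))
  expect_equal(alignmentWidth(trimAlignment(aln2, "auto")), 4L)
  # gap-free alignment returned unchanged
  aln3 <- BarcodeAlignment(c(a = "ACGT", b = "ACGA"))
  expect_equal(as.character(trimAlignment(aln3, "auto")),
               as.character(aln3))
})

test_that("trimming with zero ranges is the identity (idempotence)", {
  aln <- asAln(randomAcgtMatrix(5, 30))
  tr <- trimAlignment(aln, "explicit", 3, 4)
  tr2 <- trimAlignment(tr, "explicit", 0, 0)
  expect_equal(as.character(tr2), as.character(tr))
  # composed trims accumulate in the bookkeeping
  expect_equal(S4Vectors::metadata(tr2)$trim$dropHead, 3L)
})

test_that("SNP columns are variable ACGT sites, ascending, permutation-invariant", {
  expect_equal(snpColumns(BarcodeAlignment(c(a = "AAC", b = "AAT", c = "AAC"))),
               3L)
  expect_equal(snpColumns(BarcodeAlignment(c(a = "AAA", b = "AAA"))),
               integer(0))
  # gaps and Ns never count as alleles
  expect_equal(snpColumns(BarcodeAlignment(c(a = "A-N", b = "AAN"))),
               integer(0))
  set.seed(42)
  for (i in 1:20) {
    m <- randomAcgtMatrix(sample(2:8, 1), sample(3:15, 1))
    aln <- asAln(m)
    sc <- snpColumns(aln)
    expect_true(all(sc >= 1 & sc <= ncol(m)))
    expect_false(is.unsorted(sc, strictly = TRUE))
    expect_lte(length(sc), ncol(m))
    perm <- sample(nrow(m))
    expect_equal(snpColumns(asAln(m[perm, , drop = FALSE])), sc)
  }
})

test_that("species metadata TSV is validated", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("family\tgenus\tspecies\tbp\taccession",
               "Ariommatidae\tAriomma\tbondi\t654\tKT883659.1"), f)
  md <- readSpeciesMetadata(f)
  expect_equal(nrow(md), 1L)
  expect_equal(md$accession, "KT883659.1")
  expect_equal(md$bp, 654L)
  # empty table with header is fine
  writeLines("family\tgenus\tspecies\tbp\taccession", f)
  expect_equal(nrow(readSpeciesMetadata(f)), 0L)
  # missing column and unversioned accession are errors
  writeLines(c("family\tgenus\tspecies\tbp", "x\ty\tz\t1"), f)
  expect_error(readSpeciesMetadata(f), "missing column")
  writeLines(c("family\tgenus\tspecies\tbp\taccession",
               "x\ty\tz\t1\tKT883659"), f)
  expect_error(readSpeciesMetadata(f), "accession")
})

test_that("alignments round-trip through FASTA", {
  aln <- asAln(randomAcgtMatrix(6, 120))
  f <- tempfile(fileext = ".fasta")
  writeAlignment(aln, f)
  back <- readAlignment(f)
  expect_equal(as.character(back), as.character(aln))
  # 80-column wrapping
  expect_true(all(nchar(readLines(f)) <= 80))
})
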