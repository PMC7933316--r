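test_that("mergePairs reconstructs the fragment from overlapping mates", {
  set.seed(101)
  # identity case: both mates cover the whole fragment
  frag <- randomSeq(40)
  expect_equal(mergePairs(frag, revcompStr(frag), min_overlap = 10), frag)

  # partial overlap: fwd = first 15, rev = revcomp of last 15, overlap 10
  frag20 <- randomSeq(20)
  fwd <- substr(frag20, 1, 15)
  rev <- revcompStr(substr(frag20, 6, 20))
  merged <- mergePairs(fwd, rev, min_overlap = 5)
  expect_equal(nchar(merged), 20)
  expect_equal(merged, frag20)

  # no sufficient overlap -> unmerged flag
  expect_true(is.na(mergePairs(randomSeq(30), randomSeq(30),
                               min_overlap = 20)))
  # malformed input
  expect_error(mergePairs("", "ACGT"), "empty")
})

test_that("mergePairs resolves overlap mismatches toward the higher-quality base", {
  set.seed(107)
  frag <- randomSeq(40)
  fwd <- substr(frag, 1, 30)
  # plant a disagreement inside the overlap (position 25 of the fragment)
  rev_frag <- frag
  planted <- setdiff(c("A", "C", "G", "T"), substr(frag, 25, 25))[1]
  substr(rev_frag, 25, 25) <- planted
  rev <- revcompStr(substr(rev_frag, 11, 40))
  hiq <- strrep("I", 30)
  loq <- strrep("#", 30)
  m_fwd_wins <- mergePairs(fwd, rev, fwd_qual = hiq, rev_qual = loq,
                           min_overlap = 10, max_mismatch_frac = 0.2)
  m_rev_wins <- mergePairs(fwd, rev, fwd_qual = loq, rev_qual = hiq,
                           min_overlap = 10, max_mismatch_frac = 0.2)
  expect_equal(substr(m_fwd_wins, 25, 25), substr(frag, 25, 25))
  expect_equal(substr(m_rev_wins, 25, 25), planted)
})

test_that("mergePairs is symmetric under swapping mates with reverse complement", {
  set.seed(102)
  for (i in 1:20) {
    frag <- randomSeq(sample(30:44, 1))  # keeps >= 5 nt of mate overlap
    fwd <- substr(frag, 1, 25)
    rev <- revcompStr(substr(frag, nchar(frag) - 24, nchar(frag)))
    a <- mergePairs(fwd, rev, min_overlap = 5)
    b <- mergePairs(rev, fwd, min_overlap = 5)
    expect_equal(revcompStr(b), a)
  }
})

test_that("demultiplex assigns exact barcode pairs and strips them", {
  sc <- tinyScheme()
  body <- "AAACAAACGGGGAAAGAAA"
  read1 <- paste0("ACGT", body, "TTGG")   # c1 barcodes
  read2 <- paste0("CGTA", body, "GGTT")   # c2 barcodes
  read3 <- paste0("TTTT", body, "TTTT")   # no barcode
  dm <- demultiplex(c(read1, read2, read3), sc)
  expect_equal(dm$condition, c("c1", "c2", NA))
  expect_equal(dm$body[1:2], c(body, body))
  expect_equal(unname(dm$qc["assigned"]), 2)
  expect_equal(unname(dm$qc["unassigned"]), 1)
})

test_that("demultiplex counts reads matching two conditions as ambiguous", {
  # 5' barcodes one substitution apart; under 1-mismatch matching a read
  # carrying either barcode matches both conditions (exhaustive check below)
  sc <- AmpliconScheme(
    prefixes = c(W = "AAACAAAC"), suffix = "AAAGAAA",
    barcodes = data.frame(condition = c("c1", "c2"),
                          bc5 = c("ACGT", "ACTT"),
                          bc3 = c("GGAA", "GGAT"),
                          stringsAsFactors = FALSE))
  body <- "AAACAAACGGGGAAAGAAA"
  read <- paste0("ACGT", body, "GGAA")
  # exhaustive match oracle at <=1 mismatch
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  n_matching <- sum(vapply(1:2, function(j) {
    hamming(substr(read, 1, 4), sc@barcodes$bc5[j]) <= 1 &&
      hamming(substr(read, nchar(read) - 3, nchar(read)),
              sc@barcodes$bc3[j]) <= 1
  }, logical(1)))
  expect_equal(n_matching, 2)
  dm0 <- demultiplex(read, sc, max_mismatch = 0)
  dm1 <- demultiplex(read, sc, max_mismatch = 1)
  expect_equal(dm0$condition, "c1")
  expect_true(is.na(dm1$condition))
  expect_equal(unname(dm1$qc["ambiguous"]), 1)
})

test_that("classifyPrefix identifies the prefix and extracts the core", {
  sc <- tinyScheme()
  core <- "GGCCGGCCGGCC"
  cl <- classifyPrefix(c(paste0("AAACAAAC", core, "AAAGAAA"),
                         paste0("AAGTCTAG", core, "AAAGAAA"),
                         core), sc)
  expect_equal(cl$prefix, c("W", "Z", NA))
  expect_equal(cl$core, c(core, core, ""))
})

test_that("a read is never assigned to two conditions or two prefixes", {
  sc <- tinyScheme(2)
  set.seed(103)
  reads <- vapply(1:200, function(i) {
    paste0(sample(c("ACGT", "CGTA", "AC"), 1),
           sample(c("AAACAAAC", "AAGTCTAG", ""), 1),
           randomSeq(20), "AAAGAAA",
           sample(c("TTGG", "GGTT", "GG"), 1))
  }, "")
  dm <- demultiplex(reads, sc, max_mismatch = 1)
  expect_true(all(is.na(dm$condition) | dm$condition %in% sc@barcodes$condition))
  cl <- classifyPrefix(dm$body[!is.na(dm$condition)], sc, max_mismatch = 1)
  expect_true(all(is.na(cl$prefix) | cl$prefix %in% names(sc@prefixes)))
})

test_that("tabulateReads counts per key, routes references, and is order-invariant", {
  sc <- tinyScheme()
  core <- "GGCCGGCCGGCC"
  ref <- sc@references$seq[1]
  cores <- c(rep(core, 4), ref, ref)
  prefixes <- c("Z", "Z", "Z", "W", "W", "W")
  conds <- rep("c1", 6)
  tab <- tabulateReads(cores, prefixes, conds, sc)
  ct <- seqCounts(tab)
  expect_equal(ct$count[ct$core == core & ct$prefix == "Z"], 3)
  expect_equal(ct$count[ct$core == core & ct$prefix == "W"], 1)
  expect_true(all(ct$is_reference[ct$core == ref]))
  expect_false(any(ct$is_reference[ct$core == core]))
  # order invariance
  set.seed(104)
  perm <- sample(6)
  tab2 <- tabulateReads(cores[perm], prefixes[perm], conds[perm], sc)
  expect_identical(seqCounts(tab), seqCounts(tab2))
  # empty stream -> empty table
  empty <- tabulateReads(character(), character(), character(), sc)
  expect_equal(nrow(seqCounts(empty)), 0)
})

test_that("misassignmentFilter flags low-abundance near-duplicates only", {
  sc <- tinyScheme()
  x <- "ACGTACGTACGTACGTACGAA"
  y1 <- sub("AA$", "AC", x)          # distance 1 from x
  y2 <- sub("GAA$", "TCC", x)        # distance >= 2 from x
  mk <- function(count_x, other, count_other) {
    makeTable(list(
      list(core = x, prefix = "Z", condition = "c1", replicate = "1",
           count = count_x),
      list(core = other, prefix = "Z", condition = "c1", replicate = "1",
           count = count_other)), sc)
  }
  expect_equal(flaggedCores(misassignmentFilter(mk(10, y1, 2000))), x)
  expect_length(flaggedCores(misassignmentFilter(mk(10, y1, 400))), 0)
  expect_length(flaggedCores(misassignmentFilter(mk(10, y2, 2000))), 0)
})

test_that("SequenceTable validity rejects malformed counts", {
  sc <- tinyScheme()
  expect_error(makeTable(list(
    list(core = "ACGT", prefix = "Z", condition = "c1", replicate = "1",
         count = -1)), sc), "non-negative")
  expect_error(AmpliconScheme(prefixes = c(W = "AAA", Z = "AAA"),
                              suffix = "A"), "distinct")
  expect_error(AmpliconScheme(
    prefixes = c(W = "AAA"), suffix = "A",
    barcodes = data.frame(condition = c("a", "b"), bc5 = c("AC", "ACG"),
                          bc3 = c("T", "G"))), "prefix-free")
})
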