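test_that("bonferroniThreshold divides the family alpha", {
  expect_equal(signif(bonferroniThreshold(0.1, 12025), 1), 8e-6)
  expect_equal(bonferroniThreshold(1, 1), 1)
  expect_equal(signif(bonferroniThreshold(1, 4328), 3), 2.31e-4)
  expect_error(bonferroniThreshold(0.1, 0))
})

test_that("referenceScale converts reads to concentration", {
  # 15 references at 18 pM each, 2700 total reference reads with prefix Z
  sc <- AmpliconScheme(
    prefixes = c(W = "AAACAAAC", Z = "AAGTCTAG"), suffix = "AAAGAAA",
    references = data.frame(seq = randomCores(15, 20, seed = 5),
                            prefix = "Z", conc_pM = 18,
                            stringsAsFactors = FALSE))
  rows <- lapply(seq_len(15), function(i)
    list(core = sc@references$seq[i], prefix = "Z", condition = "c1",
         replicate = "1", count = 180, is_reference = TRUE))
  tab <- makeTable(rows, sc)
  expect_equal(referenceScale(tab, "Z", "c1"), 270 / 2700)

  # single reference, concentration 1, one read
  sc1 <- AmpliconScheme(prefixes = c(Z = "AAGTCTAG"), suffix = "AAAGAAA",
                        references = data.frame(seq = "ACGTACGTAC",
                                                prefix = "Z", conc_pM = 1))
  tab1 <- makeTable(list(list(core = "ACGTACGTAC", prefix = "Z",
                              condition = "c1", replicate = "1", count = 1,
                              is_reference = TRUE)), sc1)
  expect_equal(referenceScale(tab1, "Z", "c1"), 1)
  expect_error(referenceScale(tab1, "Z", "c9"), "unusable")
})

test_that("cleavageFraction implements the reference-normalized ratio", {
  expect_equal(cleavageFraction(0, 100, 50, 200), 0)
  expect_equal(cleavageFraction(50, 100, 100, 200), 0.5)  # equal ratios
  expect_equal(cleavageFraction(300, 100, 100, 200), (300/100) / (100/200 + 300/100))
  expect_true(is.na(cleavageFraction(0, 100, 0, 200)))
  expect_error(cleavageFraction(1, 0, 1, 1), "positive")
  # invariant to common rescaling of all four counts; bounded in [0,1];
  # monotone in the cleaved-prefix count
  set.seed(21)
  for (i in 1:50) {
    cts <- rpois(4, 200) + 1
    c1 <- cleavageFraction(cts[1], cts[2], cts[3], cts[4])
    c2 <- cleavageFraction(3 * cts[1], 3 * cts[2], 3 * cts[3], 3 * cts[4])
    expect_equal(c1, c2)
    expect_true(c1 >= 0 && c1 <= 1)
    expect_true(cleavageFraction(cts[1] + 10, cts[2], cts[3], cts[4]) >= c1)
    expect_true(cleavageFraction(cts[1], cts[2], cts[3] + 10, cts[4]) <= c1)
  }
})

test_that("foldChangeTable normalizes the run median fold change to 1", {
  mk <- function(acc, c, nz, nw) {
    data.frame(accession = acc, core = paste0("s", acc), c = c,
               reads_cleaved = nz, reads_uncleaved = nw, flagged = FALSE,
               stringsAsFactors = FALSE)
  }
  # two sequences with raw ratios {1, 4}: k = 1/2.5, f = {0.4, 1.6}
  minus <- mk(1:2, c(0.5, 0.8), 100, 100)
  plus <- mk(1:2, c(0.5, 0.2), 100, 100)
  fc <- foldChangeTable(minus, plus)
  expect_equal(fc$normalization$k, 0.4)
  expect_equal(fc$results$f, c(0.4, 1.6))

  # single sequence: median forces f = 1
  fc1 <- foldChangeTable(mk(1, 0.3, 50, 50), mk(1, 0.9, 50, 50))
  expect_equal(fc1$results$f, 1)

  # all ratios equal -> all f = 1
  fc2 <- foldChangeTable(mk(1:5, rep(0.6, 5), 100, 100),
                         mk(1:5, rep(0.4, 5), 100, 100))
  expect_equal(fc2$results$f, rep(1, 5))

  # c_minus = 1 -> undefined fold change for that sequence
  fc3 <- foldChangeTable(mk(1:2, c(1, 0.5), 100, 100),
                         mk(1:2, c(0.5, 0.5), 100, 100))
  expect_true(is.na(fc3$results$f[1]))
  # median of qualifying f is exactly 1
  expect_equal(median(fc$results$f[fc$results$qualifying]), 1)
})

test_that("bootstrap CIs behave at symmetric, degenerate and simulated inputs", {
  set.seed(31)
  ci <- bootstrapCI(500, 500, 1e5, 1e5, B = 1000)$c
  expect_true(ci[1] < 0.5 && ci[2] > 0.5)
  expect_equal((0.5 - ci[1]) / (ci[2] - 0.5), 1, tolerance = 0.5)

  # all reads cleaved at huge depth: interval collapses at 1
  ci1 <- bootstrapCI(1e6, 0, 1e5, 1e5, B = 500)$c
  expect_equal(ci1[2], 1)
  expect_gt(ci1[1], 0.999)
  expect_error(bootstrapCI(0, 0, 10, 10), "zero total reads")
})

test_that("bootstrap 5-95% intervals achieve ~90% empirical coverage", {
  set.seed(11)
  c_true <- 0.7; nreads <- 200; B <- 1000; reps <- 500
  refZ <- 5e4; refW <- 5e4
  cover <- logical(reps)
  for (r in seq_len(reps)) {
    z <- rbinom(1, nreads, c_true)
    ci <- bootstrapCI(z, nreads - z, refZ, refW, B = B)$c
    cover[r] <- ci[1] <= c_true && c_true <= ci[2]
  }
  expect_gte(mean(cover), 0.87)
  expect_lte(mean(cover), 0.93)
})

test_that("switchingTest is an exact two-sided test with sane limits", {
  expect_equal(switchingTest(50, 50, 50, 50), 1)
  expect_lt(switchingTest(100, 0, 0, 100), 1e-20)
  # scaling counts at fixed proportions makes the test more significant
  p1 <- switchingTest(60, 40, 40, 60)
  p2 <- switchingTest(600, 400, 400, 600)
  p3 <- switchingTest(6000, 4000, 4000, 6000)
  expect_true(p1 > p2 && p2 > p3)
  # agreement with the exact conditional oracle at small counts
  expect_equal(switchingTest(20, 10, 10, 20),
               fisher.test(matrix(c(20, 10, 10, 20), 2))$p.value)
  # below min reads -> untested
  expect_true(is.na(switchingTest(10, 10, 50, 50, min_reads = 30)))
})

test_that("replicateTest flags only sequences whose replicas disagree", {
  sc <- tinyScheme()
  set.seed(41)
  cores <- randomCores(8, 30)
  mkrep <- function(zcounts, wcounts) {
    rows <- c(
      lapply(seq_along(cores), function(i)
        list(core = cores[i], prefix = "Z", condition = "c1",
             replicate = "1", count = zcounts[i])),
      lapply(seq_along(cores), function(i)
        list(core = cores[i], prefix = "W", condition = "c1",
             replicate = "1", count = wcounts[i])))
    makeTable(rows, sc)
  }
  z <- rep(90, 8); w <- rep(60, 8)
  t1 <- mkrep(z, w)
  # identical tables: all p = 1, no outliers
  rt <- replicateTest(t1, t1, "c1")
  expect_true(all(rt$tests$p == 1))
  expect_length(rt$outliers, 0)
  expect_equal(rt$threshold, 0.1 / rt$N)
  # one inverted sequence is flagged
  z2 <- z; w2 <- w
  z2[3] <- 10; w2[3] <- 140
  rt2 <- replicateTest(t1, mkrep(z2, w2), "c1")
  expect_equal(rt2$outliers, cores[3])
  # a (90,10) vs (10,90) disagreement is astronomically significant
  za <- z; wa <- w; zb <- z; wb <- w
  za[1] <- 90; wa[1] <- 10; zb[1] <- 10; wb[1] <- 90
  rt3 <- replicateTest(mkrep(za, wa), mkrep(zb, wb), "c1")
  expect_lt(rt3$tests$p[rt3$tests$core == cores[1]], 1e-15)
})

test_that("callHits applies fold, significance and misassignment rules", {
  res <- data.frame(f = c(2.5, 1.9, 2.5, 2.5),
                    p = c(1e-9, 1e-9, 1e-3, 1e-9),
                    flagged = c(FALSE, FALSE, FALSE, TRUE))
  out <- callHits(res, N = 1e4)
  expect_equal(out$is_hit, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("planted cleavage fractions and switchers are recovered end to end", {
  # 1000 sequences at ~1e4 reads/sequence/condition; 20 planted switchers
  # with a true uncleaved-fraction ratio of 3
  set.seed(51)
  N <- 1000
  n_switch <- 20
  cores <- randomCores(N, 50)
  c_minus <- runif(N, 0.3, 0.7)
  c_plus <- c_minus
  sw <- seq_len(n_switch)
  c_minus[sw] <- 0.85
  c_plus[sw] <- 0.55            # rho = 0.45 / 0.15 = 3
  tr <- truthSpec(cores, c_minus, c_plus)
  ref_share <- 270 / (2000 + 270)
  depth <- round(N * 1e4 / (1 - ref_share))
  tab <- generateCleaveSeqCounts(tr, depth = depth, seed = 52)
  sa <- switchAnalysis(tab, "c1", "c2")
  res <- sa$results
  ord <- match(cores, res$core)
  # planted c recovered within 3 binomial SD for >= 99% of sequences
  for (cond in c("minus", "plus")) {
    truth <- if (cond == "minus") c_minus else c_plus
    est <- if (cond == "minus") res$c_minus[ord] else res$c_plus[ord]
    reads <- if (cond == "minus") res$reads_minus[ord] else res$reads_plus[ord]
    sd3 <- 3 * sqrt(truth * (1 - truth) / reads)
    expect_gte(mean(abs(est - truth) <= sd3), 0.99)
  }
  # switchers called as hits with >= 95% sensitivity, few false alarms
  hits <- res$is_hit[ord]
  expect_gte(mean(hits[sw]), 0.95)
  expect_lte(sum(hits[-sw]), 2)
})
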