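## cleaveseq: cleavage fractions, fold changes, bootstrap CIs, replicate
## concordance and hit calling from a SequenceTable.

#' Per-test significance threshold under Bonferroni correction
#'
#' @param family_alpha Family-wise error rate in (0, 1].
#' @param N Number of hypotheses tested (>= 1).
#' @return \code{family_alpha / N}.
#' @examples
#' bonferroniThreshold(0.1, 12025)  # ~8e-6
#' @export
bonferroniThreshold <- function(family_alpha, N) {
  stopifnot(length(N) == 1, N >= 1,
            family_alpha > 0, family_alpha <= 1)
  family_alpha / N
}

#' Reads-to-concentration conversion factor from spike-in references
#'
#' Spike-in reference sequences enter the run at known concentrations, so
#' their observed read count fixes the conversion between reads and absolute
#' concentration for each prefix: the factor is the summed known concentration
#' of the reference species carrying that prefix divided by the total
#' reference reads observed with that prefix in the condition.
#'
#' @param table A [SequenceTable-class] whose scheme lists references.
#' @param prefix Prefix label (e.g. \code{"Z"}).
#' @param condition Condition id.
#' @return Scale in pM per read.
#' @export
referenceScale <- function(table, prefix, condition) {
  stopifnot(is(table, "SequenceTable"))
  refs <- table@scheme@references
  conc_total <- sum(refs$conc_pM[refs$prefix == prefix])
  ct <- table@counts
  reads <- sum(ct$count[ct$is_reference & ct$prefix == prefix &
                        ct$condition == condition])
  if (reads == 0)
    stop(sprintf("no reference reads with prefix %s in condition %s: run unusable",
                 prefix, condition))
  conc_total / reads
}

#' Cleavage fraction from prefix-resolved read counts
#'
#' The cleavage fraction of a sequence is the reference-normalized fraction of
#' its molecules observed with the cleaved prefix:
#' \deqn{c_s = \frac{r_{Z,s}/r_{Z,ref}}{r_{W,s}/r_{W,ref} + r_{Z,s}/r_{Z,ref}}}
#' where \eqn{r_{P,s}} are sample reads with prefix \eqn{P} and
#' \eqn{r_{P,ref}} the reference reads with that prefix. Normalizing each
#' prefix by its own reference reads cancels sequencing-depth differences
#' between the two prefix-specific amplifications.
#'
#' @param r_Z_s,r_W_s Sample reads with the cleaved (Z) / uncleaved (W) prefix.
#' @param r_Z_ref,r_W_ref Reference reads with each prefix (> 0).
#' @return Cleavage fraction in [0, 1]; \code{NA} when a sequence has zero
#'   reads in both prefixes.
#' @examples
#' cleavageFraction(300, 100, 100, 200)  # 6/7
#' @export
cleavageFraction <- function(r_Z_s, r_Z_ref, r_W_s, r_W_ref) {
  if (any(r_Z_ref <= 0) || any(r_W_ref <= 0))
    stop("reference read counts must be positive")
  z <- r_Z_s / r_Z_ref
  w <- r_W_s / r_W_ref
  out <- z / (w + z)
  out[r_Z_s + r_W_s == 0] <- NA_real_
  out
}

.prop_test_2x2 <- function(a, b, c, d) {
  # two-sided test of equal proportions on the 2x2 table (a,b) vs (c,d);
  # exact conditional test at small counts, normal approximation when any
  # cell exceeds 1e4 reads
  n <- length(a)
  p <- rep(NA_real_, n)
  big <- pmax(a, b, c, d) > 1e4
  for (i in which(!big)) {
    p[i] <- fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2))$p.value
  }
  if (any(big)) {
    i <- which(big)
    n1 <- a[i] + b[i]; n2 <- c[i] + d[i]
    pp <- (a[i] + c[i]) / (n1 + n2)
    se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    z <- (a[i] / n1 - c[i] / n2) / se
    pv <- 2 * stats::pnorm(-abs(z))
    pv[se == 0] <- 1
    p[i] <- pmin(pv, 1)
  }
  p
}

.prefix_counts <- function(table, condition, replicate = NULL,
                           cleaved = "Z", uncleaved = "W") {
  ct <- table@counts
  ct <- ct[ct$condition == condition, ]
  if (!is.null(replicate)) ct <- ct[ct$replicate %in% replicate, ]
  if (!nrow(ct)) stop(sprintf("no reads for condition %s", condition))
  refs <- ct[ct$is_reference, ]
  smp <- ct[!ct$is_reference, ]
  ref_Z <- sum(refs$count[refs$prefix == cleaved])
  ref_W <- sum(refs$count[refs$prefix == uncleaved])
  cores <- unique(smp$core)
  gather <- function(pfx) {
    x <- smp[smp$prefix == pfx, ]
    v <- tapply(x$count, x$core, sum)
    out <- rep(0L, length(cores))
    out[match(names(v), cores)] <- as.integer(v)
    out
  }
  data.frame(
    accession = smp$accession[match(cores, smp$core)],
    core = cores,
    cleaved = gather(cleaved),
    uncleaved = gather(uncleaved),
    flagged = cores %in% smp$core[smp$flagged],
    ref_cleaved = ref_Z,
    ref_uncleaved = ref_W,
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.boot_chat <- function(r_Z_s, r_W_s, r_Z_ref, r_W_ref, B, resample_refs = TRUE) {
  n_s <- r_Z_s + r_W_s
  zs <- rbinom(B, n_s, r_Z_s / n_s)
  if (resample_refs) {
    n_r <- r_Z_ref + r_W_ref
    zr <- rbinom(B, n_r, r_Z_ref / n_r)
    zr[zr == 0] <- 1L; zr[zr == n_r] <- n_r - 1L
    wr <- n_r - zr
  } else {
    zr <- r_Z_ref; wr <- r_W_ref
  }
  cleavageFraction(zs, zr, n_s - zs, wr)
}

#' Bootstrap confidence intervals for cleavage fraction and fold change
#'
#' Resamples the observed reads: the per-sequence prefix cells and the
#' reference cells are each redrawn from a multinomial with the observed
#' proportions and observed totals; the cleavage fraction (and, when counts
#' for a second condition are supplied, the fold change) is recomputed for
#' each of \code{B} bootstrap samples and the 5th/95th percentiles of the
#' estimates are returned.
#'
#' @param r_Z_s,r_W_s Sample reads with cleaved / uncleaved prefix.
#' @param r_Z_ref,r_W_ref Reference reads with each prefix.
#' @param plus Optional named list with the same four counts for the +ligand
#'   condition (\code{r_Z_s}, \code{r_W_s}, \code{r_Z_ref}, \code{r_W_ref});
#'   when present the interval for the fold change is also returned.
#' @param k Run-normalization factor applied to the fold change (default 1).
#' @param B Number of bootstrap samples (>= 100).
#' @param resample_refs Whether reference cells are resampled too.
#' @return A list with \code{c} = c(lo, hi) and, if \code{plus} was given,
#'   \code{c_plus} and \code{f} intervals.
#' @export
bootstrapCI <- function(r_Z_s, r_W_s, r_Z_ref, r_W_ref, plus = NULL,
                        k = 1, B = 1000, resample_refs = TRUE) {
  stopifnot(B >= 100)
  if (r_Z_s + r_W_s < 1) stop("zero total reads")
  ch <- .boot_chat(r_Z_s, r_W_s, r_Z_ref, r_W_ref, B, resample_refs)
  out <- list(c = unname(quantile(ch, c(0.05, 0.95), na.rm = TRUE)))
  if (!is.null(plus)) {
    if (plus$r_Z_s + plus$r_W_s < 1) stop("zero total reads (+ligand)")
    chp <- .boot_chat(plus$r_Z_s, plus$r_W_s, plus$r_Z_ref, plus$r_W_ref,
                      B, resample_refs)
    f <- k * (1 - chp) / (1 - ch)
    f[ch >= 1] <- NA_real_
    out$c_plus <- unname(quantile(chp, c(0.05, 0.95), na.rm = TRUE))
    out$f <- unname(quantile(f, c(0.05, 0.95), na.rm = TRUE))
  }
  out
}

#' Per-sequence cleavage measurements for one condition
#'
#' Computes the cleavage fraction of every (non-reference) core in a condition
#' together with a bootstrap confidence interval.
#'
#' @param table A [SequenceTable-class].
#' @param condition Condition id.
#' @param replicate Optional replicate subset; default pools replicates.
#' @param cleaved,uncleaved Prefix labels for the cleaved / uncleaved state.
#' @param B Bootstrap samples per sequence (0 skips the intervals).
#' @param resample_refs Whether reference counts are resampled in the bootstrap.
#' @return \code{data.frame} with columns \code{accession}, \code{core},
#'   \code{condition}, \code{c}, \code{ci_lo}, \code{ci_hi},
#'   \code{reads_cleaved}, \code{reads_uncleaved}, \code{flagged}.
#' @export
cleavageMeasurements <- function(table, condition, replicate = NULL,
                                 cleaved = "Z", uncleaved = "W",
                                 B = 1000, resample_refs = TRUE) {
  pc <- .prefix_counts(table, condition, replicate, cleaved, uncleaved)
  if (pc$ref_cleaved[1] == 0 || pc$ref_uncleaved[1] == 0)
    stop(sprintf("missing reference reads in condition %s", condition))
  cs <- cleavageFraction(pc$cleaved, pc$ref_cleaved,
                         pc$uncleaved, pc$ref_uncleaved)
  lo <- hi <- rep(NA_real_, nrow(pc))
  if (B > 0) {
    for (i in seq_len(nrow(pc))) {
      if (pc$cleaved[i] + pc$uncleaved[i] < 1) next
      ci <- .boot_chat(pc$cleaved[i], pc$uncleaved[i],
                       pc$ref_cleaved[i], pc$ref_uncleaved[i],
                       B, resample_refs)
      q <- quantile(ci, c(0.05, 0.95), na.rm = TRUE)
      lo[i] <- q[1]; hi[i] <- q[2]
    }
  }
  data.frame(accession = pc$accession, core = pc$core, condition = condition,
             c = cs, ci_lo = lo, ci_hi = hi,
             reads_cleaved = pc$cleaved, reads_uncleaved = pc$uncleaved,
             flagged = pc$flagged, stringsAsFactors = FALSE)
}

#' Run-normalized fold changes of cleavage fraction
#'
#' The fold change of a sequence between the -ligand and +ligand conditions is
#' \deqn{f_s = k \frac{1 - c_{s,+}}{1 - c_{s,-}}}
#' the normalized ratio of uncleaved fractions, which predicts the
#' gene-regulatory activity ratio of the sensor in vivo (only uncleaved
#' transcripts express). The run factor \eqn{k} absorbs condition-level
#' differences unrelated to the ligand and is set so that the median fold
#' change over all qualifying sequences in the run is exactly 1 (only a small
#' minority of sequences respond to any one ligand).
#'
#' @param minus,plus Measurement data.frames from [cleavageMeasurements()] for
#'   the -ligand and +ligand conditions.
#' @param min_reads Minimum reads (cleaved + uncleaved) required in both
#'   conditions for a sequence to enter the normalization and results.
#' @return A list with \code{normalization} (list: \code{k},
#'   \code{n_sequences_used}, \code{min_reads}) and \code{results}
#'   (\code{data.frame}: \code{accession}, \code{core}, \code{c_minus},
#'   \code{c_plus}, \code{rho}, \code{f}, \code{flagged}). Sequences with
#'   \eqn{c_- = 1} get \code{NA} fold changes.
#' @export
foldChangeTable <- function(minus, plus, min_reads = 30) {
  m <- merge(minus, plus, by = c("accession", "core"),
             suffixes = c("_minus", "_plus"))
  reads_m <- m$reads_cleaved_minus + m$reads_uncleaved_minus
  reads_p <- m$reads_cleaved_plus + m$reads_uncleaved_plus
  qual <- reads_m >= min_reads & reads_p >= min_reads &
    !is.na(m$c_minus) & !is.na(m$c_plus) & m$c_minus < 1
  if (!any(qual)) stop("no qualifying sequences for normalization")
  rho <- (1 - m$c_plus) / (1 - m$c_minus)
  rho[m$c_minus >= 1] <- NA_real_
  k <- 1 / median(rho[qual])
  res <- data.frame(
    accession = m$accession, core = m$core,
    c_minus = m$c_minus, c_plus = m$c_plus,
    rho = rho, f = k * rho,
    reads_minus = reads_m, reads_plus = reads_p,
    qualifying = qual,
    flagged = m$flagged_minus | m$flagged_plus,
    stringsAsFactors = FALSE
  )
  list(normalization = list(k = k, n_sequences_used = sum(qual),
                            min_reads = min_reads),
       results = res)
}

#' Test the non-switching null for one or more sequences
#'
#' Two-sided test of equal cleavage proportions between the -ligand and
#' +ligand conditions on the 2x2 (cleaved/uncleaved by condition) count table.
#' Sequences with fewer than \code{min_reads} in either condition are reported
#' untested (\code{NA}).
#'
#' @param cleaved_minus,uncleaved_minus,cleaved_plus,uncleaved_plus Count
#'   vectors, one element per sequence.
#' @param min_reads Minimum reads per condition (default 30).
#' @return Vector of two-sided p-values.
#' @export
switchingTest <- function(cleaved_minus, uncleaved_minus,
                          cleaved_plus, uncleaved_plus, min_reads = 30) {
  p <- .prop_test_2x2(cleaved_minus, uncleaved_minus,
                      cleaved_plus, uncleaved_plus)
  p[cleaved_minus + uncleaved_minus < min_reads |
    cleaved_plus + uncleaved_plus < min_reads] <- NA_real_
  p
}

#' Replicate concordance test
#'
#' Compares the cleaved/uncleaved counts of every shared sequence between two
#' replicate runs with a two-sided test of equal proportions, applying a
#' Bonferroni-corrected family threshold \code{family_alpha / N} to flag
#' outliers (sequences whose replicas genuinely disagree, e.g. due to read
#' misassignment).
#'
#' @param table_rep1,table_rep2 [SequenceTable-class] objects for the two
#'   replicates.
#' @param condition Condition id present in both.
#' @param min_reads Minimum reads per replicate for a sequence to be tested
#'   (default 100).
#' @param family_alpha Family-wise error rate (default 0.1).
#' @param cleaved,uncleaved Prefix labels.
#' @return A list with \code{tests} (\code{data.frame}: \code{accession},
#'   \code{core}, counts, \code{p}), \code{threshold} (the per-test alpha),
#'   \code{N} and \code{outliers} (cores with \code{p} below threshold).
#' @export
replicateTest <- function(table_rep1, table_rep2, condition,
                          min_reads = 100, family_alpha = 0.1,
                          cleaved = "Z", uncleaved = "W") {
  p1 <- .prefix_counts(table_rep1, condition, NULL, cleaved, uncleaved)
  p2 <- .prefix_counts(table_rep2, condition, NULL, cleaved, uncleaved)
  m <- merge(p1, p2, by = "core", suffixes = c("_1", "_2"))
  m <- m[m$cleaved_1 + m$uncleaved_1 >= min_reads &
         m$cleaved_2 + m$uncleaved_2 >= min_reads, ]
  if (!nrow(m)) stop("no shared sequences with sufficient reads")
  p <- .prop_test_2x2(m$cleaved_1, m$uncleaved_1, m$cleaved_2, m$uncleaved_2)
  N <- nrow(m)
  thr <- bonferroniThreshold(family_alpha, N)
  list(tests = data.frame(accession = m$accession_1, core = m$core,
                          cleaved_1 = m$cleaved_1, uncleaved_1 = m$uncleaved_1,
                          cleaved_2 = m$cleaved_2, uncleaved_2 = m$uncleaved_2,
                          p = p, stringsAsFactors = FALSE),
       threshold = thr, N = N,
       outliers = m$core[p < thr])
}

#' Flag potential sensors among switch results
#'
#' A sequence is called a hit when its fold change exceeds \code{min_fold},
#' its non-switching null is rejected at the \code{family_alpha / N} level,
#' and it is not flagged as a likely misassignment.
#'
#' @param results \code{data.frame} with columns \code{f}, \code{p} and
#'   optionally \code{flagged}.
#' @param N Number of sequences tested.
#' @param min_fold Fold-change threshold (default 2.0).
#' @param family_alpha Family-wise error rate (default 1).
#' @return Logical hit vector, appended to \code{results} as \code{is_hit}.
#' @export
callHits <- function(results, N, min_fold = 2.0, family_alpha = 1) {
  flagged <- if (!is.null(results$flagged)) results$flagged else FALSE
  thr <- bonferroniThreshold(family_alpha, N)
  results$is_hit <- !is.na(results$f) & !is.na(results$p) &
    results$f > min_fold & results$p < thr & !flagged
  results
}

#' Full switching analysis between two conditions
#'
#' Convenience wrapper running [cleavageMeasurements()] on both conditions,
#' [foldChangeTable()], [switchingTest()] and [callHits()], optionally with
#' bootstrap intervals on the fold change.
#'
#' @param table A [SequenceTable-class] containing both conditions.
#' @param minus,plus Condition ids for the -ligand and +ligand assays.
#' @param min_reads Minimum reads per condition (default 30).
#' @param min_fold Hit fold-change threshold (default 2.0).
#' @param family_alpha Family-wise error rate for hit calling (default 1).
#' @param B Bootstrap samples for the fold-change intervals (0 to skip).
#' @param cleaved,uncleaved Prefix labels.
#' @return A list with \code{normalization}, \code{results} (including
#'   \code{p}, \code{is_hit} and bootstrap \code{ci_lo}/\code{ci_hi} on
#'   \code{f}) and \code{N} (sequences tested).
#' @export
switchAnalysis <- function(table, minus, plus, min_reads = 30, min_fold = 2.0,
                           family_alpha = 1, B = 0,
                           cleaved = "Z", uncleaved = "W") {
  mm <- cleavageMeasurements(table, minus, cleaved = cleaved,
                             uncleaved = uncleaved, B = 0)
  mp <- cleavageMeasurements(table, plus, cleaved = cleaved,
                             uncleaved = uncleaved, B = 0)
  fc <- foldChangeTable(mm, mp, min_reads = min_reads)
  res <- fc$results
  ord_m <- match(res$accession, mm$accession)
  ord_p <- match(res$accession, mp$accession)
  res$p <- switchingTest(mm$reads_cleaved[ord_m], mm$reads_uncleaved[ord_m],
                         mp$reads_cleaved[ord_p], mp$reads_uncleaved[ord_p],
                         min_reads = min_reads)
  N <- sum(res$qualifying)
  res <- callHits(res, N = N, min_fold = min_fold,
                  family_alpha = family_alpha)
  res$ci_lo <- res$ci_hi <- NA_real_
  if (B > 0) {
    rc_m <- mm$reads_cleaved[ord_m]; ru_m <- mm$reads_uncleaved[ord_m]
    rc_p <- mp$reads_cleaved[ord_p]; ru_p <- mp$reads_uncleaved[ord_p]
    pcm <- .prefix_counts(table, minus, NULL, cleaved, uncleaved)
    pcp <- .prefix_counts(table, plus, NULL, cleaved, uncleaved)
    for (i in seq_len(nrow(res))) {
      if (is.na(res$f[i])) next
      ci <- bootstrapCI(rc_m[i], ru_m[i],
                        pcm$ref_cleaved[1], pcm$ref_uncleaved[1],
                        plus = list(r_Z_s = rc_p[i], r_W_s = ru_p[i],
                                    r_Z_ref = pcp$ref_cleaved[1],
                                    r_W_ref = pcp$ref_uncleaved[1]),
                        k = fc$normalization$k, B = B)
      res$ci_lo[i] <- ci$f[1]; res$ci_hi[i] <- ci$f[2]
    }
  }
  list(normalization = fc$normalization, results = res, N = N)
}
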