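## seqio: read, merge, demultiplex and tabulate amplicon reads.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rev_string <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' Read a pair of FASTQ files
#'
#' Reads paired FASTQ (optionally gzipped) files into a data.frame of read
#' pairs with per-base qualities kept as Phred+33 strings.
#'
#' @param r1,r2 Paths to the forward and reverse FASTQ files.
#' @return \code{data.frame} with columns \code{id}, \code{fwd}, \code{fwd_qual},
#'   \code{rev}, \code{rev_qual}.
#' @export
readFastqPairs <- function(r1, r2) {
  f <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  r <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(f) != length(r))
    stop("R1 and R2 contain different numbers of reads")
  data.frame(
    id = sub(" .*", "", names(f)),
    fwd = as.character(f),
    fwd_qual = as.character(S4Vectors::mcols(f)$qualities),
    rev = as.character(r),
    rev_qual = as.character(S4Vectors::mcols(r)$qualities),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

.merge_one <- function(fwd, revc, fq, rq, min_overlap, max_mismatch_frac) {
  n1 <- nchar(fwd); n2 <- nchar(revc)
  fv <- strsplit(fwd, "")[[1]]; rv <- strsplit(revc, "")[[1]]
  fqv <- if (!is.null(fq)) utf8ToInt(fq) else rep.int(30L, n1)
  rqv <- if (!is.null(rq)) utf8ToInt(rq) else rep.int(30L, n2)
  best <- NULL
  for (o in seq(min_overlap, min(n1, n2))) {
    a <- fv[(n1 - o + 1):n1]; b <- rv[1:o]
    mm <- a != b & a != "N" & b != "N"
    frac <- sum(mm) / o
    if (frac <= max_mismatch_frac &&
        (is.null(best) || frac < best$frac)) {
      best <- list(o = o, frac = frac, mm = mm)
    }
  }
  if (is.null(best)) return(NA_character_)
  o <- best$o
  a <- fv[(n1 - o + 1):n1]; b <- rv[1:o]
  cons <- a
  useb <- (a == "N" & b != "N") |
          (best$mm & rqv[1:o] > fqv[(n1 - o + 1):n1])
  cons[useb] <- b[useb]
  paste0(substr(fwd, 1, n1 - o), paste(cons, collapse = ""),
         substr(revc, o + 1, n2))
}

#' Merge paired-end reads by overlap
#'
#' Merges each forward/reverse read pair into a single amplicon sequence by
#' finding a consistent overlap between the forward read and the reverse
#' complement of the reverse read. An overlap is consistent when its mismatch
#' fraction is at most \code{max_mismatch_frac}; among consistent overlaps the
#' one with the lowest mismatch fraction wins, with ties resolved toward the
#' longer merged product. At mismatching overlap positions the base with the
#' higher quality score is kept (the forward base when qualities are absent or
#' tied); \code{N} defers to the non-\code{N} base.
#'
#' @param fwd,rev Character vectors of forward and reverse read sequences.
#' @param fwd_qual,rev_qual Optional Phred+33 quality strings, same lengths as
#'   the reads.
#' @param min_overlap Minimum overlap length considered (>= 5).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction in the overlap,
#'   in [0, 0.5).
#' @return Character vector of merged sequences; \code{NA} marks pairs with no
#'   consistent overlap.
#' @examples
#' frag <- "ACGTACGTACGTACGTACGT"
#' fwd <- substr(frag, 1, 15)
#' rev <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(substr(frag, 6, 20))))
#' mergePairs(fwd, rev, min_overlap = 5)  # == frag
#' @export
mergePairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                       min_overlap = 10, max_mismatch_frac = 0.1) {
  stopifnot(min_overlap >= 5,
            max_mismatch_frac >= 0, max_mismatch_frac < 0.5)
  if (any(!nzchar(fwd)) || any(!nzchar(rev)) || anyNA(fwd) || anyNA(rev))
    stop("malformed input: empty read")
  n <- length(fwd)
  revc <- .revcomp(rev)
  rq <- if (!is.null(rev_qual)) .rev_string(rev_qual) else NULL
  out <- rep(NA_character_, n)
  n1 <- nchar(fwd); n2 <- nchar(revc)
  # fast path: exact overlaps, scanned from the longest merged product down
  todo <- rep(TRUE, n)
  omax <- max(pmin(n1, n2))
  for (o in if (omax >= min_overlap) seq(min_overlap, omax) else integer()) {
    idx <- which(todo & o <= pmin(n1, n2))
    if (!length(idx)) next
    hit <- substring(fwd[idx], n1[idx] - o + 1, n1[idx]) ==
           substring(revc[idx], 1, o)
    ok <- idx[hit]
    if (length(ok)) {
      out[ok] <- paste0(substring(fwd[ok], 1, n1[ok] - o),
                        substring(revc[ok], 1, n2[ok]))
      todo[ok] <- FALSE
    }
  }
  # slow path: quality-aware scoring for pairs without an exact overlap
  for (i in which(todo)) {
    out[i] <- .merge_one(fwd[i], revc[i],
                         if (!is.null(fwd_qual)) fwd_qual[i] else NULL,
                         if (!is.null(rq)) rq[i] else NULL,
                         min_overlap, max_mismatch_frac)
  }
  out
}

.hamming_prefix <- function(x, pattern, from = 1L) {
  # mismatches of `pattern` against x starting at position `from`;
  # strings too short to hold the pattern get the maximal count
  len <- nchar(pattern)
  mm <- integer(length(x))
  for (k in seq_len(len)) {
    mm <- mm + (substring(x, from + k - 1L, from + k - 1L) !=
                substring(pattern, k, k))
  }
  mm[nchar(x) - from + 1L < len] <- len
  mm
}

#' Assign merged reads to conditions by barcode
#'
#' Matches the 5' and 3' barcodes of each scheme condition against the ends of
#' each merged read and strips them. A read matching zero or more than one
#' condition is left unassigned; ambiguous matches are tallied separately.
#'
#' @param merged Character vector of merged amplicon sequences.
#' @param scheme An [AmpliconScheme-class] with a non-empty barcode table.
#' @param max_mismatch Mismatches tolerated per barcode (0, the default, or 1).
#' @return A list with \code{condition} (character, \code{NA} when unassigned),
#'   \code{body} (read with barcodes stripped) and \code{qc} (counts of
#'   \code{assigned}, \code{unassigned}, \code{ambiguous}).
#' @export
demultiplex <- function(merged, scheme, max_mismatch = 0) {
  stopifnot(is(scheme, "AmpliconScheme"), max_mismatch %in% c(0, 1))
  bc <- scheme@barcodes
  if (nrow(bc) == 0) stop("scheme has no barcodes")
  n <- length(merged)
  match_mat <- matrix(FALSE, n, nrow(bc))
  for (j in seq_len(nrow(bc))) {
    l5 <- nchar(bc$bc5[j]); l3 <- nchar(bc$bc3[j])
    long_enough <- nchar(merged) >= l5 + l3
    m5 <- .hamming_prefix(merged, bc$bc5[j]) <= max_mismatch
    tail3 <- substring(merged, nchar(merged) - l3 + 1L, nchar(merged))
    m3 <- .hamming_prefix(tail3, bc$bc3[j]) <= max_mismatch
    match_mat[, j] <- long_enough & m5 & m3
  }
  nmatch <- rowSums(match_mat)
  cond <- rep(NA_character_, n)
  body <- rep(NA_character_, n)
  one <- which(nmatch == 1)
  if (length(one)) {
    j <- max.col(match_mat[one, , drop = FALSE])
    cond[one] <- bc$condition[j]
    body[one] <- substring(merged[one], nchar(bc$bc5[j]) + 1L,
                           nchar(merged[one]) - nchar(bc$bc3[j]))
  }
  list(condition = cond, body = body,
       qc = c(assigned = length(one),
              unassigned = sum(nmatch == 0),
              ambiguous = sum(nmatch > 1)))
}

#' Classify the cleavage-state prefix of a read body
#'
#' Identifies which scheme prefix begins each barcode-stripped read body and
#' checks that the suffix spacer ends it, each within \code{max_mismatch}
#' substitutions. The core is the body with prefix and suffix removed.
#'
#' @param body Character vector of barcode-stripped read bodies.
#' @param scheme An [AmpliconScheme-class].
#' @param max_mismatch Mismatches tolerated in the prefix and in the suffix
#'   (0 or 1).
#' @return \code{data.frame} with columns \code{prefix} (label, \code{NA} when
#'   unclassified) and \code{core} (empty string when unclassified).
#' @export
classifyPrefix <- function(body, scheme, max_mismatch = 0) {
  stopifnot(is(scheme, "AmpliconScheme"), max_mismatch %in% c(0, 1))
  p <- scheme@prefixes
  sfx <- scheme@suffix
  n <- length(body)
  lsfx <- nchar(sfx)
  tailseq <- substring(body, nchar(body) - lsfx + 1L, nchar(body))
  sfx_ok <- nchar(body) >= lsfx & .hamming_prefix(tailseq, sfx) <= max_mismatch
  match_mat <- matrix(FALSE, n, length(p))
  for (j in seq_along(p)) {
    lp <- nchar(p[j])
    match_mat[, j] <- nchar(body) >= lp + lsfx &
      .hamming_prefix(body, p[j]) <= max_mismatch
  }
  nmatch <- rowSums(match_mat)
  label <- rep(NA_character_, n)
  core <- rep("", n)
  one <- which(nmatch == 1 & sfx_ok)
  if (length(one)) {
    j <- max.col(match_mat[one, , drop = FALSE])
    label[one] <- names(p)[j]
    core[one] <- substring(body[one], nchar(p[j]) + 1L,
                           nchar(body[one]) - lsfx)
  }
  data.frame(prefix = label, core = core, stringsAsFactors = FALSE)
}

#' Tabulate classified reads into a SequenceTable
#'
#' Groups identical classified reads into a table of unique (core, prefix,
#' condition, replicate) combinations with read counts. Cores that exactly
#' match a scheme reference sequence are routed to reference rows. Distinct
#' cores receive stable accession integers assigned in lexicographic order of
#' the core sequence, so the result is invariant to the input read order.
#'
#' @param core,prefix,condition Character vectors, one element per classified
#'   read.
#' @param scheme An [AmpliconScheme-class].
#' @param replicate Replicate ids (recycled if length 1).
#' @return A [SequenceTable-class].
#' @export
tabulateReads <- function(core, prefix, condition, scheme, replicate = "1") {
  stopifnot(is(scheme, "AmpliconScheme"))
  n <- length(core)
  replicate <- rep_len(as.character(replicate), n)
  keep <- !is.na(prefix) & !is.na(condition) & nzchar(core)
  core <- core[keep]; prefix <- prefix[keep]
  condition <- condition[keep]; replicate <- replicate[keep]
  if (!length(core)) {
    return(SequenceTable(data.frame(
      accession = integer(), core = character(), prefix = character(),
      condition = character(), replicate = character(), count = integer(),
      is_reference = logical(), flagged = logical(),
      stringsAsFactors = FALSE), scheme))
  }
  key <- paste(core, prefix, condition, replicate, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  ct <- data.frame(
    core = vapply(parts, `[`, "", 1L),
    prefix = vapply(parts, `[`, "", 2L),
    condition = vapply(parts, `[`, "", 3L),
    replicate = vapply(parts, `[`, "", 4L),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  cores_sorted <- sort(unique(ct$core))
  ct$accession <- match(ct$core, cores_sorted)
  ct$is_reference <- ct$core %in% scheme@references$seq
  ct$flagged <- FALSE
  ct <- ct[order(ct$condition, ct$replicate, ct$prefix, ct$accession), ]
  rownames(ct) <- NULL
  SequenceTable(ct, scheme)
}

#' Flag likely misassigned low-abundance sequences
#'
#' PCR mutations during library preparation can assign a small number of reads
#' of an abundant sequence to a near-identical spurious sequence. Any core
#' whose total read count is at most 1/\code{abundance_ratio} times that of
#' another core within edit distance \code{max_distance} is flagged; flagged
#' cores stay in the table but are excluded from hit calling.
#'
#' @param table A [SequenceTable-class].
#' @param max_distance Maximum Levenshtein distance to an abundant neighbour
#'   (default 1). \code{N} never matches any base.
#' @param abundance_ratio Minimum abundance ratio of the neighbour over the
#'   flagged core (default 100).
#' @return The table with its \code{flagged} column updated.
#' @export
misassignmentFilter <- function(table, max_distance = 1, abundance_ratio = 100) {
  stopifnot(is(table, "SequenceTable"))
  ct <- table@counts
  if (!nrow(ct)) stop("empty table")
  smp <- ct[!ct$is_reference, ]
  tot <- tapply(smp$count, smp$core, sum)
  cores <- names(tot)
  tot <- as.numeric(tot)
  ord <- order(tot, decreasing = TRUE)
  cores <- cores[ord]; tot <- tot[ord]
  flagged <- character()
  for (i in seq_along(cores)) {
    big <- which(tot >= abundance_ratio * tot[i])
    big <- big[cores[big] != cores[i]]
    if (!length(big)) next
    d <- cpp_lv_distance(cores[i], cores[big], as.integer(max_distance))
    if (any(d <= max_distance)) flagged <- c(flagged, cores[i])
  }
  ct$flagged <- ct$core %in% flagged
  table@counts <- ct
  validObject(table)
  table
}

#' Flagged core sequences of a SequenceTable
#' @param table A [SequenceTable-class].
#' @return Character vector of flagged cores.
#' @export
flaggedCores <- function(table) {
  unique(table@counts$core[table@counts$flagged])
}

#' Run the full demultiplexing pipeline on paired FASTQ files
#'
#' Reads, merges, demultiplexes, classifies and tabulates a CleaveSeq-style
#' run, and reports QC tallies for every stage.
#'
#' @param r1,r2 Paths to paired FASTQ files.
#' @param scheme An [AmpliconScheme-class].
#' @param replicate Replicate id to record.
#' @param max_mismatch Mismatch tolerance for barcode and prefix matching.
#' @param min_overlap,max_mismatch_frac Passed to [mergePairs()].
#' @return A list with \code{table} (a [SequenceTable-class]) and \code{qc}
#'   (named numeric vector: \code{reads_in}, \code{merged},
#'   \code{demultiplexed}, \code{classified}, \code{ambiguous}).
#' @export
demuxRun <- function(r1, r2, scheme, replicate = "1", max_mismatch = 0,
                     min_overlap = 10, max_mismatch_frac = 0.1) {
  rp <- readFastqPairs(r1, r2)
  merged <- mergePairs(rp$fwd, rp$rev, rp$fwd_qual, rp$rev_qual,
                       min_overlap = min_overlap,
                       max_mismatch_frac = max_mismatch_frac)
  ok <- !is.na(merged)
  dm <- demultiplex(merged[ok], scheme, max_mismatch = max_mismatch)
  cl <- classifyPrefix(dm$body[!is.na(dm$condition)], scheme,
                       max_mismatch = max_mismatch)
  cond <- dm$condition[!is.na(dm$condition)]
  tab <- tabulateReads(cl$core, cl$prefix, cond, scheme,
                       replicate = replicate)
  list(table = tab,
       qc = c(reads_in = nrow(rp),
              merged = sum(ok),
              demultiplexed = unname(dm$qc["assigned"]),
              classified = sum(!is.na(cl$prefix)),
              ambiguous = unname(dm$qc["ambiguous"])))
}
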