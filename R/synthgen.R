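## synthgen: ground-truth generators for every input the pipeline consumes.
## Every generator is bit-reproducible under a fixed seed and ships its truth
## alongside, so expected pipeline outputs can be computed analytically.

# Fixture spike-in cores: 15 synthetic sequences spanning five lengths, three
# per length, assigned across the three prefixes at a fixed 18 pM each.
.REFERENCE_CORES <- c(
  "CAGTTTCTTACGTGAGGAATACGAAAGCCGATGGGTTATG",
  "GTGTCGCGTAGACTCGGTCGCTCCTCCCAAGACTATCTTC",
  "CCGAAACTATTTGGCATTTTTAGGTCTTAGAATACTACCC",
  "CTGGCCTAGCCCGTTTTTCCACTTATAGGCGCACCTTTTTCCTAG",
  "CTATAGCGGCAGCTCCTATTGACTTACAATATGCTGGTGTAATGC",
  "CCGCGGGACAGACACCCCATCCTTACAGAATCAAGCTGATGCCAC",
  "GATCGTTCAGGTCTCACTACCGTATTTGCCCCCTCTGTCTGACGGCTAAA",
  "TTTGCACTACTGTGTTAGCAAGTACTTGCTAGGGAATGCTCCCCCTCTTC",
  "AGCTCTTCGCATCTTTAAGGATAAGTCAGCCGGCCAGTTACTATACGGGG",
  "TTATTGACATACGCGCGTTGTTTACGCCGGAATAGCCCTAGCCATGGAGCTACCA",
  "TAGTTAACGAATGGCTACCGTCGTGGATGAACAACAGAGCGAACACTACACGAAT",
  "ACTCAAACCATGCGTATGCTATCGCCCAACGTGATACAACTTATTGATTCCTCGT",
  "CGCTCCGACATCGCGTACCTCCCACGGCCCCGGAAAGTTCTTTCTAGCGCCGTAGACATA",
  "AGGAGTCGATCAGGTCATATAGTTGATTTCTAGATCGTCTAGTTGGGGAAGCTTGTTCAG",
  "GATCGGCGCTATGACTACGAGGAATCTAGACACCTTAGCGAACAGGGTATAAAGACCACA"
)

.BC5_POOL <- c("T", "CAG", "CCTA", "GATCA", "GGAGTC", "ATCGGA", "ACTTGACG")
.BC3_POOL <- c("A", "GTC", "TGGA", "CATGC", "CCTTAG", "TGTCAGT", "GACCATTC")

#' A synthetic fixture AmpliconScheme
#'
#' A ready-to-use scheme with the structural properties of a real run: three
#' distinguishable A-rich prefixes (W for uncleaved, Z for regenerated/cleaved,
#' A for a second regeneration), an A-rich suffix spacer, prefix-free
#' variable-length barcodes for up to 7 conditions, and 15 synthetic spike-in
#' references (five lengths, spread over the three prefixes) at 18 pM each.
#' The sequences themselves are synthetic stand-ins; real runs supply their
#' own scheme via [AmpliconScheme()] or [readScheme()].
#'
#' @param n_conditions Number of barcoded conditions (1-7).
#' @param ref_conc_pM Spike-in concentration per reference (default 18).
#' @return An [AmpliconScheme-class].
#' @export
defaultScheme <- function(n_conditions = 2, ref_conc_pM = 18) {
  stopifnot(n_conditions >= 1, n_conditions <= length(.BC5_POOL))
  AmpliconScheme(
    prefixes = c(W = "AAACAAACAAAG", Z = "AAGTCAAATCCG", A = "AACCTAAAGCAG"),
    suffix = "AAAGAAACAAA",
    barcodes = data.frame(
      condition = paste0("c", seq_len(n_conditions)),
      bc5 = .BC5_POOL[seq_len(n_conditions)],
      bc3 = .BC3_POOL[seq_len(n_conditions)],
      stringsAsFactors = FALSE),
    references = data.frame(
      seq = .REFERENCE_CORES,
      prefix = rep(c("W", "Z", "A"), times = 5),
      conc_pM = ref_conc_pM,
      stringsAsFactors = FALSE)
  )
}

#' Random core sequences
#'
#' @param n Number of sequences.
#' @param length Length of each (recycled).
#' @param seed Optional RNG seed.
#' @return Character vector of DNA strings.
#' @export
randomCores <- function(n, length = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  length <- rep_len(length, n)
  vapply(length, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    "")
}

#' Ground truth for a synthetic CleaveSeq run
#'
#' Bundles the per-sequence truth that drives the generators: the core
#' sequences, their true cleavage probabilities without and with ligand, and
#' their relative template abundances.
#'
#' @param core Core sequences.
#' @param c_minus,c_plus True cleavage probabilities per sequence.
#' @param abundance Relative template abundances (normalized to sum to 1).
#' @param scheme An [AmpliconScheme-class] (needs at least 2 conditions for a
#'   -/+ ligand run).
#' @param library_conc_pM Total nominal template concentration of the library
#'   (sets the expected spike-in read share together with the scheme's
#'   reference concentrations; default 2000 pM, i.e. a 2 nM assay input).
#' @param error_rate Per-base substitution error rate in [0, 0.05].
#' @return A \code{"TruthSpec"} list.
#' @export
truthSpec <- function(core, c_minus, c_plus,
                      abundance = rep(1, length(core)),
                      scheme = defaultScheme(),
                      library_conc_pM = 2000, error_rate = 0) {
  stopifnot(length(c_minus) == length(core),
            length(c_plus) == length(core),
            all(c_minus >= 0 & c_minus <= 1),
            all(c_plus >= 0 & c_plus <= 1),
            all(abundance >= 0), sum(abundance) > 0,
            error_rate >= 0, error_rate <= 0.05,
            library_conc_pM > 0)
  structure(list(core = core, c_minus = c_minus, c_plus = c_plus,
                 abundance = abundance / sum(abundance),
                 scheme = scheme, library_conc_pM = library_conc_pM,
                 error_rate = error_rate),
            class = "TruthSpec")
}

#' Simulate the counts of a CleaveSeq run
#'
#' Forward model of the assay at the count level: per condition, sample reads
#' are allocated to sequences multinomially by abundance; each molecule
#' cleaves with its condition-appropriate probability and is read with the Z
#' prefix if cleaved, W otherwise. Spike-in reference reads are injected with
#' expected share \code{ref_conc_total / (library_conc + ref_conc_total)} of
#' the total, split multinomially across the reference species (each keeping
#' its designated prefix).
#'
#' @param truth A [truthSpec()] object.
#' @param depth Total reads per condition.
#' @param conditions Named character vector mapping the truth conditions
#'   \code{minus}/\code{plus} to scheme condition ids.
#' @param replicate Replicate id recorded in the table.
#' @param seed Optional RNG seed.
#' @return A [SequenceTable-class].
#' @export
generateCleaveSeqCounts <- function(truth, depth = 1e5,
                                    conditions = c(minus = "c1", plus = "c2"),
                                    replicate = "1", seed = NULL) {
  stopifnot(inherits(truth, "TruthSpec"))
  if (!is.null(seed)) set.seed(seed)
  scheme <- truth$scheme
  refs <- scheme@references
  ref_share <- sum(refs$conc_pM) / (truth$library_conc_pM + sum(refs$conc_pM))
  rows <- list()
  for (cond_key in names(conditions)) {
    cond <- conditions[[cond_key]]
    cvec <- if (cond_key == "minus") truth$c_minus else truth$c_plus
    n_ref <- rbinom(1, depth, ref_share)
    n_sample <- depth - n_ref
    per_seq <- as.vector(rmultinom(1, n_sample, truth$abundance))
    cleaved <- rbinom(length(per_seq), per_seq, cvec)
    uncleaved <- per_seq - cleaved
    per_ref <- as.vector(rmultinom(1, n_ref, refs$conc_pM / sum(refs$conc_pM)))
    rows[[cond_key]] <- data.frame(
      core = c(truth$core, truth$core, refs$seq),
      prefix = c(rep("Z", length(cleaved)), rep("W", length(uncleaved)),
                 refs$prefix),
      condition = cond,
      replicate = replicate,
      count = c(cleaved, uncleaved, per_ref),
      stringsAsFactors = FALSE)
  }
  ct <- do.call(rbind, rows)
  ct <- ct[ct$count > 0, ]
  # aggregate directly (equivalent to streaming the reads through
  # tabulateReads, without materializing one element per read)
  key <- paste(ct$core, ct$prefix, ct$condition, ct$replicate, sep = "\r")
  agg <- rowsum(ct$count, key)
  first <- !duplicated(key)
  ct <- ct[first, ]
  ct$count <- as.integer(agg[match(key[first], rownames(agg)), 1])
  cores_sorted <- sort(unique(ct$core))
  ct$accession <- match(ct$core, cores_sorted)
  ct$is_reference <- ct$core %in% refs$seq
  ct$flagged <- FALSE
  ct <- ct[order(ct$condition, ct$replicate, ct$prefix, ct$accession), ]
  rownames(ct) <- NULL
  SequenceTable(ct, scheme)
}

.add_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Render a synthetic CleaveSeq run as paired FASTQ files
#'
#' Draws per-condition reads as in [generateCleaveSeqCounts()], renders each
#' read as its full amplicon (5' barcode + prefix + core + suffix + 3'
#' barcode), applies uniform substitution errors, and splits each amplicon
#' into a forward read and a reverse-complemented reverse read with a
#' configured overlap, writing \code{R1.fastq}/\code{R2.fastq} (flat quality
#' \code{"I"}) and a \code{truth.tsv} into \code{dir}.
#'
#' @param truth A [truthSpec()] object.
#' @param dir Output directory (created if needed).
#' @param depth Total reads per condition.
#' @param conditions Named map as in [generateCleaveSeqCounts()].
#' @param read_length Length of each mate; must give at least 10 nt overlap
#'   on the longest amplicon.
#' @param replicate Replicate id written into the truth file.
#' @param seed Optional RNG seed.
#' @return Invisibly, a list with paths \code{r1}, \code{r2}, \code{truth}
#'   and the planted counts table.
#' @export
generateCleaveSeqRun <- function(truth, dir, depth = 1e4,
                                 conditions = c(minus = "c1", plus = "c2"),
                                 read_length = NULL, replicate = "1",
                                 seed = NULL) {
  stopifnot(inherits(truth, "TruthSpec"))
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scheme <- truth$scheme
  tab <- generateCleaveSeqCounts(truth, depth = depth,
                                 conditions = conditions,
                                 replicate = replicate)
  ct <- tab@counts
  bc <- scheme@barcodes
  bi <- match(ct$condition, bc$condition)
  amplicon <- paste0(bc$bc5[bi], scheme@prefixes[ct$prefix], ct$core,
                     scheme@suffix, bc$bc3[bi])
  reads_seq <- rep(amplicon, ct$count)
  if (is.null(read_length))
    read_length <- ceiling(max(nchar(amplicon)) * 0.6)
  if (any(2 * read_length - nchar(reads_seq) < 10))
    stop("read_length too short: amplicons need >= 10 nt overlap")
  if (min(nchar(reads_seq)) < read_length)
    stop("read_length exceeds the shortest amplicon")
  reads_seq <- .add_errors(reads_seq, truth$error_rate)
  ord <- sample.int(length(reads_seq))  # shuffle reads across conditions
  reads_seq <- reads_seq[ord]
  fwd <- substring(reads_seq, 1, read_length)
  rev_ <- .revcomp(substring(reads_seq, nchar(reads_seq) - read_length + 1,
                             nchar(reads_seq)))
  ids <- sprintf("read%06d", seq_along(fwd))
  write_fastq <- function(seqs, path) {
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), path)
  }
  r1 <- file.path(dir, "R1.fastq")
  r2 <- file.path(dir, "R2.fastq")
  write_fastq(fwd, r1)
  write_fastq(rev_, r2)
  truth_path <- file.path(dir, "truth.tsv")
  write.table(ct, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(r1 = r1, r2 = r2, truth = truth_path, counts = tab))
}

#' Synthetic flow-cytometry events with a planted expression ratio
#'
#' Log-normal mCherry with GFP = ratio x mCherry x log-normal noise, placed
#' well above the transformation gates.
#'
#' @param expression_ratio True mean GFP/mCherry ratio.
#' @param n Number of cells.
#' @param mcherry_meanlog,mcherry_sdlog Log-normal parameters of the mCherry
#'   channel (defaults put cells around 10^4).
#' @param noise_sdlog Log-sd of the per-cell ratio noise.
#' @param seed Optional RNG seed.
#' @return \code{data.frame} with columns \code{GFP}, \code{mCherry}.
#' @export
generateFlowEvents <- function(expression_ratio, n,
                               mcherry_meanlog = log(10^4),
                               mcherry_sdlog = 0.4,
                               noise_sdlog = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mch <- rlnorm(n, mcherry_meanlog, mcherry_sdlog)
  ratio <- expression_ratio * rlnorm(n, -noise_sdlog^2 / 2, noise_sdlog)
  data.frame(GFP = ratio * mch, mCherry = mch)
}

#' Synthetic gel lanes with planted cleavage fractions
#'
#' Inverse of the gel formula: band intensity above background is
#' proportional to molar amount times product length, so a planted fraction
#' \code{f} gives \code{I_cleaved = bg + T f L_c} and
#' \code{I_uncleaved = bg + T (1-f) L_u} (plus optional Gaussian noise).
#'
#' @param f Planted fractions cleaved, one lane each.
#' @param total_intensity Intensity scale T per lane (recycled).
#' @param length_cleaved,length_uncleaved Product lengths (nt).
#' @param bg Background intensity.
#' @param noise_sd Gaussian noise on the band intensities.
#' @param seed Optional RNG seed.
#' @return \code{data.frame} of lanes consumable by [gelFraction()].
#' @export
generateGelLanes <- function(f, total_intensity = 1000,
                             length_cleaved = 50, length_uncleaved = 100,
                             bg = 50, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(f)
  lanes <- data.frame(
    I_cleaved = bg + total_intensity * f * length_cleaved,
    I_uncleaved = bg + total_intensity * (1 - f) * length_uncleaved,
    I_bg = rep_len(bg, n),
    length_cleaved = rep_len(length_cleaved, n),
    length_uncleaved = rep_len(length_uncleaved, n)
  )
  if (noise_sd > 0) {
    lanes$I_cleaved <- lanes$I_cleaved + rnorm(n, 0, noise_sd)
    lanes$I_uncleaved <- lanes$I_uncleaved + rnorm(n, 0, noise_sd)
  }
  lanes
}

#' Synthetic multicycle sensorgram set with known kinetics
#'
#' Simulates one Langmuir sensorgram per analyte concentration (one cycle
#' each), suitable for [fitKinetics()] and [fitEquilibrium()].
#'
#' @param k_on,k_off,R_max True kinetic parameters.
#' @param concentrations Analyte concentrations (M).
#' @param t_assoc,t_dissoc,dt Timing (s).
#' @param noise_sd Gaussian noise (RU).
#' @param seed Optional RNG seed.
#' @return Long-format sensorgram \code{data.frame}.
#' @export
generateSensorgrams <- function(k_on, k_off, R_max, concentrations,
                                t_assoc = 180, t_dissoc = 180, dt = 1,
                                noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_along(concentrations), function(i) {
    simulateSensorgram(k_on, k_off, R_max, concentrations[i],
                       t_assoc = t_assoc, t_dissoc = t_dissoc, dt = dt,
                       noise_sd = noise_sd, cycle = i)
  })
  do.call(rbind, out)
}
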