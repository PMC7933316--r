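#' @useDynLib CleaveSeqR, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats median quantile rbinom rmultinom rpois rnorm rlnorm runif
#'   coef confint fisher.test prop.test lm nls approx setNames complete.cases
#'   na.omit cutree hclust as.dist
#' @importFrom utils adist head read.delim write.table
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.is_dna <- function(x) {
  !is.na(x) & grepl("^[ACGTN]*$", x)
}

#' Amplicon scheme for a CleaveSeq-style sequencing run
#'
#' Describes the fixed structure of the amplicons in a run: the alternative
#' 5' prefixes that encode cleavage state ("W" for molecules that did not
#' cleave, "Z" for cleaved molecules whose 5' end was regenerated, optionally
#' "A" for a further regeneration round), the common 3' suffix spacer, the
#' per-condition barcodes flanking the amplicon, and the spike-in reference
#' sequences of known concentration used to convert read counts to absolute
#' concentrations.
#'
#' @slot prefixes Named character vector of prefix sequences; names are the
#'   prefix labels (typically \code{"W"}, \code{"Z"}, \code{"A"}).
#' @slot suffix Single suffix (spacer) sequence shared by all amplicons.
#' @slot barcodes \code{data.frame} with columns \code{condition},
#'   \code{bc5}, \code{bc3}: the 5' and 3' barcode sequences identifying each
#'   assay condition. Barcodes on each side must be prefix-free within the
#'   scheme (no barcode may be a prefix of another), so that matching from the
#'   read end is unambiguous.
#' @slot references \code{data.frame} with columns \code{seq}, \code{prefix},
#'   \code{conc_pM}: spike-in sequences, the prefix each carries, and the known
#'   concentration (pM) at which each was added.
#'
#' @seealso [AmpliconScheme()], [defaultScheme()]
#' @export
setClass("AmpliconScheme",
  representation(
    prefixes   = "character",
    suffix     = "character",
    barcodes   = "data.frame",
    references = "data.frame"
  )
)

setValidity("AmpliconScheme", function(object) {
  msg <- character()
  p <- object@prefixes
  if (length(p) < 1 || is.null(names(p)) || any(names(p) == ""))
    msg <- c(msg, "'prefixes' must be a named character vector")
  if (anyDuplicated(p))
    msg <- c(msg, "prefix sequences must be pairwise distinct")
  if (anyDuplicated(names(p)))
    msg <- c(msg, "prefix labels must be unique")
  if (!all(.is_dna(p)) || !all(.is_dna(object@suffix)))
    msg <- c(msg, "prefixes and suffix must be DNA strings over {A,C,G,T,N}")
  if (length(object@suffix) != 1L)
    msg <- c(msg, "'suffix' must be a single string")
  bc <- object@barcodes
  if (nrow(bc) > 0) {
    if (!all(c("condition", "bc5", "bc3") %in% names(bc)))
      msg <- c(msg, "'barcodes' needs columns condition, bc5, bc3")
    else {
      if (anyDuplicated(bc$condition))
        msg <- c(msg, "barcode condition ids must be unique")
      for (side in c("bc5", "bc3")) {
        b <- bc[[side]]
        if (!all(.is_dna(b)) || any(nchar(b) < 1) || any(nchar(b) > 10))
          msg <- c(msg, sprintf("%s barcodes must be DNA of length 1-10", side))
        if (length(b) > 1) {
          for (i in seq_along(b)) for (j in seq_along(b)) {
            if (i != j && startsWith(b[j], b[i]))
              msg <- c(msg, sprintf("%s barcodes are not prefix-free", side))
          }
        }
      }
    }
  }
  rf <- object@references
  if (nrow(rf) > 0) {
    if (!all(c("seq", "prefix", "conc_pM") %in% names(rf)))
      msg <- c(msg, "'references' needs columns seq, prefix, conc_pM")
    else {
      if (!all(.is_dna(rf$seq)))
        msg <- c(msg, "reference sequences must be DNA")
      if (!all(rf$prefix %in% names(p)))
        msg <- c(msg, "reference prefixes must be scheme prefix labels")
      if (!all(rf$conc_pM > 0))
        msg <- c(msg, "reference concentrations must be > 0")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconScheme
#'
#' @param prefixes Named character vector of prefix sequences.
#' @param suffix Suffix (spacer) sequence.
#' @param barcodes \code{data.frame} with columns \code{condition},
#'   \code{bc5}, \code{bc3}.
#' @param references \code{data.frame} with columns \code{seq}, \code{prefix},
#'   \code{conc_pM}.
#' @return An [AmpliconScheme-class] object.
#' @examples
#' sc <- AmpliconScheme(
#'   prefixes = c(W = "AAACAAACAAA", Z = "AAGCTGTCACC"),
#'   suffix = "AAAGAAA",
#'   barcodes = data.frame(condition = "c1", bc5 = "ACGT", bc3 = "TGCA"),
#'   references = data.frame(seq = "ACGTACGTACGT", prefix = "W", conc_pM = 18)
#' )
#' @export
AmpliconScheme <- function(prefixes, suffix,
                           barcodes = data.frame(condition = character(),
                                                 bc5 = character(),
                                                 bc3 = character()),
                           references = data.frame(seq = character(),
                                                   prefix = character(),
                                                   conc_pM = numeric())) {
  barcodes[] <- lapply(barcodes, function(x) if (is.factor(x)) as.character(x) else x)
  references[] <- lapply(references, function(x) if (is.factor(x)) as.character(x) else x)
  if (nrow(references) && is.character(references$conc_pM))
    references$conc_pM <- as.numeric(references$conc_pM)
  new("AmpliconScheme", prefixes = prefixes, suffix = suffix,
      barcodes = as.data.frame(barcodes, stringsAsFactors = FALSE),
      references = as.data.frame(references, stringsAsFactors = FALSE))
}

#' Read an AmpliconScheme from a YAML or JSON config file
#'
#' The file must contain fields \code{prefixes} (map label -> sequence),
#' \code{suffix}, \code{barcodes} (list of maps with \code{condition},
#' \code{bc5}, \code{bc3}) and optionally \code{references} (list of maps with
#' \code{seq}, \code{prefix}, \code{conc_pM}).
#'
#' @param path Path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return An [AmpliconScheme-class].
#' @export
readScheme <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  bind_rows0 <- function(x, cols) {
    if (is.null(x) || length(x) == 0)
      return(setNames(as.data.frame(replicate(length(cols), character(0),
                                              simplify = FALSE)), cols))
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  AmpliconScheme(
    prefixes = unlist(cfg$prefixes),
    suffix = cfg$suffix,
    barcodes = bind_rows0(cfg$barcodes, c("condition", "bc5", "bc3")),
    references = bind_rows0(cfg$references, c("seq", "prefix", "conc_pM"))
  )
}

#' Table of read counts per (core sequence, prefix, condition, replicate)
#'
#' The central count container of the pipeline. One row per observed
#' combination of core sequence (prefix/suffix/barcodes removed), prefix label,
#' condition and replicate. Spike-in reference reads are kept in the same table
#' with \code{is_reference = TRUE} and are excluded from sample-level
#' quantification; cores flagged by [misassignmentFilter()] carry
#' \code{flagged = TRUE} and are excluded from hit calling.
#'
#' @slot counts \code{data.frame} with columns \code{accession} (stable integer
#'   id per distinct core), \code{core}, \code{prefix}, \code{condition},
#'   \code{replicate}, \code{count}, \code{is_reference}, \code{flagged}.
#' @slot scheme The [AmpliconScheme-class] the reads were classified against.
#' @export
setClass("SequenceTable",
  representation(counts = "data.frame", scheme = "AmpliconScheme")
)

.SEQTAB_COLS <- c("accession", "core", "prefix", "condition", "replicate",
                  "count", "is_reference", "flagged")

setValidity("SequenceTable", function(object) {
  msg <- character()
  ct <- object@counts
  if (!all(.SEQTAB_COLS %in% names(ct)))
    msg <- c(msg, paste("counts must have columns:",
                        paste(.SEQTAB_COLS, collapse = ", ")))
  else {
    if (nrow(ct)) {
      if (any(ct$count < 0) || any(ct$count != round(ct$count)))
        msg <- c(msg, "counts must be non-negative integers")
      key <- paste(ct$core, ct$prefix, ct$condition, ct$replicate)
      if (anyDuplicated(key))
        msg <- c(msg, "duplicate (core, prefix, condition, replicate) rows")
      acc <- tapply(ct$accession, ct$core, function(a) length(unique(a)))
      if (any(acc != 1))
        msg <- c(msg, "each core must map to exactly one accession")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SequenceTable-class Construct a SequenceTable from a counts
#'   data.frame (columns as described above; \code{accession} and \code{flagged}
#'   are filled in if missing).
#' @param counts counts \code{data.frame}.
#' @param scheme An [AmpliconScheme-class].
#' @export
SequenceTable <- function(counts, scheme) {
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  if (is.null(counts$flagged)) counts$flagged <- FALSE
  if (is.null(counts$is_reference)) counts$is_reference <- FALSE
  if (is.null(counts$replicate)) counts$replicate <- "1"
  counts$replicate <- as.character(counts$replicate)
  counts$condition <- as.character(counts$condition)
  if (is.null(counts$accession)) {
    cores <- unique(counts$core)
    counts$accession <- match(counts$core, cores)
  }
  counts$count <- as.integer(counts$count)
  counts <- counts[, .SEQTAB_COLS]
  rownames(counts) <- NULL
  new("SequenceTable", counts = counts, scheme = scheme)
}

#' @export
setGeneric("seqCounts", function(object, ...) standardGeneric("seqCounts"))

#' @describeIn SequenceTable-class Access the counts data.frame.
#' @param object,x A \code{SequenceTable}.
#' @param ... Unused.
#' @export
setMethod("seqCounts", "SequenceTable", function(object, ...) object@counts)

#' @export
setGeneric("scheme", function(object) standardGeneric("scheme"))

#' @describeIn SequenceTable-class Access the AmpliconScheme.
#' @export
setMethod("scheme", "SequenceTable", function(object) object@scheme)

#' @export
setGeneric("conditionNames", function(object) standardGeneric("conditionNames"))

#' @describeIn SequenceTable-class Conditions present in the table.
#' @export
setMethod("conditionNames", "SequenceTable",
          function(object) sort(unique(object@counts$condition)))

setMethod("show", "AmpliconScheme", function(object) {
  cat("AmpliconScheme\n")
  cat("  prefixes:  ", paste(sprintf("%s(%dnt)", names(object@prefixes),
                                     nchar(object@prefixes)), collapse = " "), "\n")
  cat("  suffix:    ", nchar(object@suffix), "nt\n")
  cat("  conditions:", nrow(object@barcodes), "\n")
  cat("  references:", nrow(object@references),
      if (nrow(object@references))
        sprintf("(%s pM)", paste(unique(object@references$conc_pM), collapse = ",")),
      "\n")
})

setMethod("show", "SequenceTable", function(object) {
  ct <- object@counts
  cat("SequenceTable with", nrow(ct), "rows\n")
  cat("  distinct cores:", length(unique(ct$core[!ct$is_reference])), "\n")
  cat("  conditions:    ", paste(sort(unique(ct$condition)), collapse = ", "), "\n")
  cat("  total reads:   ", sum(ct$count),
      sprintf("(%d reference)", sum(ct$count[ct$is_reference])), "\n")
  if (any(ct$flagged))
    cat("  flagged cores: ", length(unique(ct$core[ct$flagged])), "\n")
})

#' Write / read a SequenceTable as TSV
#'
#' @param x A [SequenceTable-class].
#' @param path Output (input) TSV path.
#' @param scheme Scheme to attach when reading.
#' @return \code{writeSequenceTable} returns \code{path} invisibly;
#'   \code{readSequenceTable} returns a [SequenceTable-class].
#' @export
writeSequenceTable <- function(x, path) {
  stopifnot(is(x, "SequenceTable"))
  write.table(x@counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSequenceTable
#' @export
readSequenceTable <- function(path, scheme) {
  ct <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(core = "character", prefix = "character",
                                  condition = "character",
                                  replicate = "character"))
  SequenceTable(ct, scheme)
}
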