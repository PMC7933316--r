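# Small fixtures shared across the suite; everything is built in code.

# a compact scheme with short cores for fast string-level tests
tinyScheme <- function(n_conditions = 2) {
  AmpliconScheme(
    prefixes = c(W = "AAACAAAC", Z = "AAGTCTAG"),
    suffix = "AAAGAAA",
    barcodes = data.frame(
      condition = paste0("c", seq_len(n_conditions)),
      bc5 = c("ACGT", "CGTA", "GTAC", "TACG")[seq_len(n_conditions)],
      bc3 = c("TTGG", "GGTT", "TGTG", "GTGT")[seq_len(n_conditions)],
      stringsAsFactors = FALSE),
    references = data.frame(
      seq = c("ACGTACGTACGTACGTACGT", "TGCATGCATGCATGCATGCA"),
      prefix = c("W", "Z"), conc_pM = 18, stringsAsFactors = FALSE)
  )
}

# SequenceTable built directly from a counts spec (list of rows)
makeTable <- function(rows, scheme = tinyScheme()) {
  ct <- do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
  SequenceTable(ct, scheme)
}

revcompStr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")
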