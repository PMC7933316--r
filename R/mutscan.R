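## mutscan: single-mutation effect maps from mutagenized-library runs, and
## clustering of hits into sequence families.

#' Minimal edit script between a parent and a variant sequence
#'
#' Levenshtein alignment decomposed into substitutions, insertions and
#' deletions. Positions are 1-based on the parent; an insertion is indexed by
#' the parent position it follows (0 = before the first base). When several
#' equal-cost scripts exist (e.g. a deletion anywhere in a homopolymer run)
#' the leftmost script is returned and the result is flagged ambiguous.
#' \code{N} never matches any base.
#'
#' @param parent,variant DNA strings.
#' @return \code{data.frame} with columns \code{op} (\code{"substitution"},
#'   \code{"insertion"}, \code{"deletion"}), \code{pos} and \code{base}, with
#'   attributes \code{distance} and \code{ambiguous}.
#' @examples
#' editScript("ACGT", "AGGT")  # substitution at position 2
#' @export
editScript <- function(parent, variant) {
  stopifnot(nzchar(parent))
  res <- cpp_edit_script(parent, variant)
  out <- data.frame(op = res$op, pos = res$pos, base = res$base,
                    stringsAsFactors = FALSE)
  attr(out, "distance") <- res$distance
  attr(out, "ambiguous") <- res$ambiguous
  out
}

#' Apply an edit script to a parent sequence
#'
#' Inverse of [editScript()]: replays the script on the parent and returns the
#' variant. Used to verify decomposition soundness.
#'
#' @param parent DNA string.
#' @param script \code{data.frame} as returned by [editScript()].
#' @return The edited sequence.
#' @export
applyEditScript <- function(parent, script) {
  chars <- strsplit(parent, "")[[1]]
  n <- length(chars)
  pieces <- character(n + 1)  # pieces[p + 1] holds output emitted after parent position p
  pieces[1] <- paste(script$base[script$op == "insertion" & script$pos == 0],
                     collapse = "")
  for (p in seq_len(n)) {
    sub <- script$base[script$op == "substitution" & script$pos == p]
    del <- any(script$op == "deletion" & script$pos == p)
    emit <- if (del) "" else if (length(sub)) sub[1] else chars[p]
    ins <- script$base[script$op == "insertion" & script$pos == p]
    pieces[p + 1] <- paste0(emit, paste(ins, collapse = ""))
  }
  paste(pieces, collapse = "")
}

#' Decompose observed variant sequences into mutation effects
#'
#' For every observed core within \code{max_distance} edits of the parent,
#' computes the edit script and the change in phenotype relative to the
#' parent's own measurement: \code{delta_c_minus} (change in cleavage
#' fraction without ligand) and the variant's fold change. Scripts with
#' equal-cost alternatives are resolved leftmost and flagged.
#'
#' @param parent Parent core sequence.
#' @param variants \code{data.frame} with columns \code{core},
#'   \code{c_minus}, and optionally \code{f} and \code{reads}. The parent's
#'   own row (if present) provides the baseline; otherwise supply
#'   \code{parent_c_minus} / \code{parent_f}.
#' @param max_distance Maximum edit distance considered (default 2).
#' @param parent_c_minus,parent_f Baseline measurements if the parent is not
#'   among the variants.
#' @return \code{data.frame} with one row per edit operation: \code{core},
#'   \code{n_ops} (script length for the variant), \code{op}, \code{pos},
#'   \code{base}, \code{delta_c_minus}, \code{fold_change}, \code{reads},
#'   \code{ambiguous}.
#' @export
assignVariants <- function(parent, variants, max_distance = 2,
                           parent_c_minus = NULL, parent_f = NULL) {
  stopifnot(nzchar(parent), is.data.frame(variants),
            all(c("core", "c_minus") %in% names(variants)))
  self <- variants[variants$core == parent, ]
  if (nrow(self)) {
    if (is.null(parent_c_minus)) parent_c_minus <- self$c_minus[1]
    if (is.null(parent_f) && !is.null(self$f)) parent_f <- self$f[1]
  }
  if (is.null(parent_c_minus))
    stop("parent measurement not found: supply parent_c_minus")
  others <- variants[variants$core != parent, ]
  if (!nrow(others)) {
    return(data.frame(core = character(), n_ops = integer(), op = character(),
                      pos = integer(), base = character(),
                      delta_c_minus = numeric(), fold_change = numeric(),
                      reads = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  d <- cpp_lv_distance(parent, others$core, as.integer(max_distance))
  others <- others[d <= max_distance, , drop = FALSE]
  if (!nrow(others)) {
    return(data.frame(core = character(), n_ops = integer(), op = character(),
                      pos = integer(), base = character(),
                      delta_c_minus = numeric(), fold_change = numeric(),
                      reads = numeric(), ambiguous = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(others)), function(i) {
    sc <- editScript(parent, others$core[i])
    data.frame(core = others$core[i], n_ops = nrow(sc),
               op = sc$op, pos = sc$pos, base = sc$base,
               delta_c_minus = others$c_minus[i] - parent_c_minus,
               fold_change = if (!is.null(others$f)) others$f[i] else NA_real_,
               reads = if (!is.null(others$reads)) others$reads[i] else NA_real_,
               ambiguous = attr(sc, "ambiguous"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Position-by-mutation effect matrices
#'
#' Arranges single-mutation effects into matrices: substitutions and the
#' deletion column over parent positions 1..L, insertions over the L+1 gap
#' slots (after positions 0..L). Only single-edit variants
#' (\code{n_ops == 1}) enter the matrices; duplicate cells are aggregated by
#' read-weighted mean and flagged.
#'
#' @param effects Output of [assignVariants()].
#' @param parent Parent core sequence (fixes the matrix dimensions).
#' @param value Which effect to tabulate: \code{"delta_c_minus"} (default) or
#'   \code{"fold_change"}.
#' @return A list with \code{substitution} (L x 4 matrix, columns A,C,G,T),
#'   \code{deletion} (length-L vector), \code{insertion} ((L+1) x 4 matrix,
#'   rows named by the gap position 0..L), \code{duplicates} (flag), and
#'   \code{top} (single-edit effects sorted by decreasing \code{value}).
#' @export
effectMatrix <- function(effects, parent, value = "delta_c_minus") {
  L <- nchar(parent)
  bases <- c("A", "C", "G", "T")
  single <- effects[effects$n_ops == 1, , drop = FALSE]
  sub <- matrix(NA_real_, L, 4, dimnames = list(seq_len(L), bases))
  del <- rep(NA_real_, L)
  ins <- matrix(NA_real_, L + 1, 4, dimnames = list(0:L, bases))
  dup <- FALSE
  if (nrow(single)) {
    key <- paste(single$op, single$pos, single$base)
    if (anyDuplicated(key)) {
      dup <- TRUE
      w <- single$reads
      w[!is.finite(w)] <- 1
      v_agg <- tapply(seq_len(nrow(single)), key, function(i) {
        sum(single[[value]][i] * w[i]) / sum(w[i])
      })
      first <- !duplicated(key)
      single <- single[first, , drop = FALSE]
      single[[value]] <- as.numeric(v_agg[key[first]])
    }
  }
  for (i in seq_len(nrow(single))) {
    v <- single[[value]][i]
    if (single$op[i] == "substitution")
      sub[single$pos[i], single$base[i]] <- v
    else if (single$op[i] == "deletion")
      del[single$pos[i]] <- v
    else
      ins[single$pos[i] + 1L, single$base[i]] <- v
  }
  top <- single[order(-single[[value]]), , drop = FALSE]
  rownames(top) <- NULL
  list(substitution = sub, deletion = del, insertion = ins,
       duplicates = dup, top = top)
}

#' Cluster hit sequences into families by sequence similarity
#'
#' Agglomerative hierarchical clustering on pairwise Levenshtein distances,
#' cut at \code{threshold}. Input order does not matter: sequences are sorted
#' before clustering and ties resolve lexicographically. Each family reports a
#' medoid (member with the smallest summed distance to the rest) and its
#' maximum intra-family distance.
#'
#' @param seqs Character vector of (distinct) hit sequences.
#' @param threshold Distance cut height; default 25% of the median sequence
#'   length.
#' @param linkage Agglomeration method (default \code{"average"}).
#' @return A list with \code{membership} (\code{data.frame}: \code{seq},
#'   \code{family}) and \code{families} (\code{data.frame}: \code{family},
#'   \code{n}, \code{medoid}, \code{max_distance}).
#' @export
clusterFamilies <- function(seqs, threshold = NULL, linkage = "average") {
  stopifnot(length(seqs) >= 1)
  seqs <- unique(seqs)
  if (is.null(threshold)) threshold <- 0.25 * median(nchar(seqs))
  ord <- order(seqs)
  s <- seqs[ord]
  if (length(s) == 1) {
    fam <- 1L
  } else {
    D <- adist(s)
    hc <- hclust(as.dist(D), method = linkage)
    fam <- cutree(hc, h = threshold)
    # renumber families by first occurrence for determinism
    fam <- as.integer(factor(fam, levels = unique(fam)))
  }
  membership <- data.frame(seq = s, family = fam, stringsAsFactors = FALSE)
  families <- do.call(rbind, lapply(split(membership$seq, membership$family),
    function(m) {
      if (length(m) == 1)
        return(data.frame(n = 1L, medoid = m, max_distance = 0,
                          stringsAsFactors = FALSE))
      D <- adist(m)
      data.frame(n = length(m), medoid = m[which.min(rowSums(D))],
                 max_distance = max(D), stringsAsFactors = FALSE)
    }))
  families$family <- as.integer(rownames(families))
  rownames(families) <- NULL
  list(membership = membership,
       families = families[, c("family", "n", "medoid", "max_distance")])
}
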