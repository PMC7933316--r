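## driver_sim: stochastic model of alternating-round ribozyme selection,
## enrichment-rate estimation and library-design combinatorics.

.AVOGADRO <- 6.022e23

#' Build a selection library
#'
#' A selection library is a set of switch phenotypes with relative abundances.
#' Each member is described by its true cleavage probability without ligand
#' (\code{c_minus}) and with ligand (\code{c_plus}); sequence identity is
#' abstract (an id) unless the caller supplies one.
#'
#' @param c_minus,c_plus Numeric vectors of true cleavage probabilities in
#'   [0, 1].
#' @param abundance Initial relative abundances (normalized to sum to 1).
#' @param id Member ids (default sequential).
#' @return \code{data.frame} with columns \code{id}, \code{c_minus},
#'   \code{c_plus}, \code{abundance}, carrying attribute \code{round = 0}.
#' @export
selectionLibrary <- function(c_minus, c_plus,
                             abundance = rep(1, length(c_minus)),
                             id = seq_along(c_minus)) {
  stopifnot(length(c_plus) == length(c_minus),
            length(abundance) == length(c_minus),
            all(c_minus >= 0 & c_minus <= 1),
            all(c_plus >= 0 & c_plus <= 1),
            all(abundance >= 0), sum(abundance) > 0)
  lib <- data.frame(id = id, c_minus = c_minus, c_plus = c_plus,
                    abundance = abundance / sum(abundance),
                    stringsAsFactors = FALSE)
  attr(lib, "round") <- 0L
  lib
}

#' Apply one selection round to a library
#'
#' On a cleaved-selection round (no ligand) each member survives with weight
#' equal to its cleavage probability \code{c_minus}; on an uncleaved-selection
#' round (ligand present) the weight is \code{1 - c_plus}. Abundances are
#' multiplied by the weights and renormalized (PCR amplification affects the
#' absolute yield, not the composition, and is absorbed by the
#' renormalization). In stochastic mode the surviving pool is additionally
#' resampled as \code{M} molecules drawn multinomially.
#'
#' @param lib Library from [selectionLibrary()].
#' @param round_type \code{"cleaved"} (negative round, -ligand) or
#'   \code{"uncleaved"} (positive round, +ligand).
#' @param M Number of molecules for stochastic mode; \code{NULL} (default)
#'   computes the deterministic expectation.
#' @return The updated library.
#' @export
simulateRound <- function(lib, round_type = c("cleaved", "uncleaved"),
                          M = NULL) {
  round_type <- match.arg(round_type)
  w <- if (round_type == "cleaved") lib$c_minus else 1 - lib$c_plus
  a <- lib$abundance * w
  if (sum(a) == 0) stop("library extinct: all survival weights are zero")
  a <- a / sum(a)
  if (!is.null(M)) {
    stopifnot(M >= 1)
    counts <- as.vector(rmultinom(1, size = M, prob = a))
    if (sum(counts) == 0) stop("library extinct after sampling")
    a <- counts / sum(counts)
  }
  lib$abundance <- a
  attr(lib, "round") <- attr(lib, "round") + 1L
  lib
}

#' Parse a round schedule string
#'
#' Round schedules are written as a repeating pattern of round types:
#' \code{"Z"} for a cleaved-selection round (-ligand) and \code{"U"} for an
#' uncleaved-selection round (+ligand). \code{"ZU"} alternates 1:1;
#' \code{"ZZU"} is the 1:2 positive:negative ratio used to bias selections
#' toward fast cleavers.
#'
#' @param pattern Schedule pattern string over \{Z, U\}.
#' @param rounds Total number of rounds.
#' @return Character vector of round types, length \code{rounds}.
#' @export
roundSchedule <- function(pattern, rounds) {
  stopifnot(nzchar(pattern), rounds >= 1)
  types <- strsplit(toupper(pattern), "")[[1]]
  if (!all(types %in% c("Z", "U")))
    stop("schedule pattern must use only Z (cleaved) and U (uncleaved)")
  rep(ifelse(types == "Z", "cleaved", "uncleaved"),
      length.out = rounds)
}

#' Simulate a multi-round selection
#'
#' Applies [simulateRound()] along a schedule, optionally with per-round
#' mutation: with probability \code{mutation_rate} per member per round, a
#' fraction of the member's abundance spawns a variant whose phenotype is
#' perturbed by \code{mutation_kernel} (a function mapping
#' \code{(c_minus, c_plus)} to new values). Abundance trajectories of all
#' members are recorded per round.
#'
#' @param lib Library from [selectionLibrary()].
#' @param schedule Round-type vector from [roundSchedule()] (or a pattern
#'   string, expanded to \code{rounds}).
#' @param rounds Number of rounds if \code{schedule} is a pattern string.
#' @param M Molecules per round for stochastic mode (\code{NULL} =
#'   expectation mode).
#' @param mutation_rate Per-member per-round probability of spawning a
#'   phenotype-perturbed variant (default 0).
#' @param mutation_kernel Function \code{(c_minus, c_plus) -> c(c_minus',
#'   c_plus')}; default adds N(0, 0.1) truncated to [0, 1].
#' @param seed Optional RNG seed for reproducibility.
#' @return A list with \code{library} (final state) and \code{trajectory}
#'   (\code{data.frame}: \code{round}, \code{id}, \code{abundance}).
#' @export
runSchedule <- function(lib, schedule, rounds = NULL, M = NULL,
                        mutation_rate = 0, mutation_kernel = NULL,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(schedule) == 1 && is.null(rounds))
    stop("give either an expanded schedule or a pattern plus 'rounds'")
  if (length(schedule) == 1) schedule <- roundSchedule(schedule, rounds)
  if (is.null(mutation_kernel)) {
    mutation_kernel <- function(c_minus, c_plus) {
      pmin(1, pmax(0, c(c_minus, c_plus) + rnorm(2, 0, 0.1)))
    }
  }
  traj <- list(data.frame(round = 0L, id = lib$id,
                          abundance = lib$abundance,
                          stringsAsFactors = FALSE))
  for (r in seq_along(schedule)) {
    if (mutation_rate > 0) {
      mut <- runif(nrow(lib)) < mutation_rate
      for (i in which(mut)) {
        newpheno <- mutation_kernel(lib$c_minus[i], lib$c_plus[i])
        moved <- lib$abundance[i] * 0.01  # small mass moves to the variant
        lib$abundance[i] <- lib$abundance[i] - moved
        lib <- rbind(lib, data.frame(
          id = paste0(lib$id[i], ".m", r),
          c_minus = newpheno[1], c_plus = newpheno[2],
          abundance = moved, stringsAsFactors = FALSE))
      }
      attr(lib, "round") <- r - 1L
    }
    lib <- simulateRound(lib, schedule[r], M = M)
    traj[[r + 1L]] <- data.frame(round = r, id = lib$id,
                                 abundance = lib$abundance,
                                 stringsAsFactors = FALSE)
  }
  list(library = lib, trajectory = do.call(rbind, traj))
}

#' Maximum per-round enrichment of a switch phenotype
#'
#' Relative to a background of ligand-insensitive sequences that cleave 50%
#' of the time in both conditions, the per-round enrichment of a phenotype
#' over one alternating (cleaved, uncleaved) cycle is the geometric mean of
#' its two round gains, \eqn{\sqrt{(c_-/0.5)\,((1-c_+)/0.5)}}. A perfect
#' switch (cleaves always without ligand, never with it) gains the maximum of
#' 2x per round; the 50% background itself is neutral at 1x.
#'
#' @param c_minus,c_plus True cleavage probabilities without / with ligand.
#' @param background Cleavage fraction of the ligand-insensitive background
#'   (default 0.5 in both conditions).
#' @return Enrichment factor per round; 0 when the phenotype cannot survive a
#'   full cycle (\code{c_minus = 0} or \code{c_plus = 1}).
#' @examples
#' maxEnrichment(1, 0)    # 2: the perfect switch
#' maxEnrichment(0.5, 0.5)  # 1: background itself
#' @export
maxEnrichment <- function(c_minus, c_plus, background = 0.5) {
  gain_cleaved <- c_minus / background
  gain_uncleaved <- (1 - c_plus) / (1 - background)
  sqrt(gain_cleaved * gain_uncleaved)
}

#' Expected molecule count of a constriction dilution
#'
#' @param conc_fM Library concentration in femtomolar.
#' @param volume_ul Volume transferred in microliters.
#' @return Expected number of molecules,
#'   \code{conc_fM * 1e-15 * N_A * volume_ul * 1e-6}.
#' @examples
#' expectedMolecules(8, 1)  # ~4818, i.e. ~5000 molecules/ul at 8 fM
#' @export
expectedMolecules <- function(conc_fM, volume_ul) {
  stopifnot(conc_fM > 0, volume_ul > 0)
  conc_fM * 1e-15 * .AVOGADRO * volume_ul * 1e-6
}

#' Constrict a library to a small random subset of molecules
#'
#' Dilution-based constriction bottlenecks a diverse library to a few
#' thousand molecules so that sequencing depth suffices to measure each
#' surviving sequence. The molecule count is Poisson around the expectation
#' set by concentration and volume, and molecules are drawn multinomially by
#' abundance.
#'
#' @param lib Library from [selectionLibrary()].
#' @param volume_ul Volume transferred (µl).
#' @param conc_fM Concentration of the dilution (fM).
#' @param seed Optional RNG seed.
#' @return A list with \code{library} (members with > 0 molecules, abundances
#'   renormalized), \code{molecules} (the sampled total) and
#'   \code{n_distinct}.
#' @export
constrict <- function(lib, volume_ul, conc_fM, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  expected <- expectedMolecules(conc_fM, volume_ul)
  if (expected < 1) stop("expected molecule count is zero")
  M <- rpois(1, expected)
  if (M == 0) stop("no molecules sampled")
  counts <- as.vector(rmultinom(1, M, lib$abundance))
  keep <- counts > 0
  out <- lib[keep, , drop = FALSE]
  out$molecules <- counts[keep]
  out$abundance <- counts[keep] / M
  rownames(out) <- NULL
  list(library = out, molecules = M, n_distinct = sum(keep))
}

#' Estimate enrichment rate and initial fraction from round trajectories
#'
#' Fits an exponential (log-linear) model to the observed library fraction of
#' a sequence across selection rounds: weighted least squares of
#' \eqn{\log f_n} on \eqn{n}, with delta-method weights from the binomial
#' standard deviation of each fraction estimate. The enrichment rate is
#' \eqn{\eta = e^{slope}} and the extrapolated round-0 fraction
#' \eqn{f_0 = e^{intercept}}, which projects the sequence's abundance back to
#' the starting library.
#'
#' @param round Round numbers.
#' @param fraction Observed library fractions at those rounds (zeros are
#'   dropped).
#' @param reads Total reads behind each fraction estimate (for the weights);
#'   default equal weights.
#' @return A list with \code{eta}, \code{f0}, \code{eta_ci} (95% confidence
#'   interval), \code{fit} (the \code{lm} object) and \code{points} (the data
#'   used, with binomial standard deviations).
#' @examples
#' est <- estimateEnrichment(c(10, 11, 12), c(1e-6, 2e-6, 4e-6))
#' est$eta   # 2
#' est$f0    # ~9.77e-10
#' @export
estimateEnrichment <- function(round, fraction, reads = NULL) {
  keep <- !is.na(fraction) & fraction > 0
  round <- round[keep]; fraction <- fraction[keep]
  if (!is.null(reads)) reads <- reads[keep]
  if (length(round) < 2) stop("need at least two rounds with nonzero fraction")
  sd_f <- if (is.null(reads)) rep(1, length(fraction))
          else sqrt(fraction * (1 - fraction) / reads)
  w <- if (is.null(reads)) rep(1, length(fraction))
       else (fraction / sd_f)^2   # delta method: var(log f) = var(f)/f^2
  fit <- lm(log(fraction) ~ round, weights = w)
  sl <- coef(fit)[["round"]]
  ci <- tryCatch(suppressWarnings(suppressMessages(confint(fit)))["round", ],
                 error = function(e) c(NA_real_, NA_real_))
  list(eta = exp(sl),
       f0 = exp(coef(fit)[["(Intercept)"]]),
       eta_ci = exp(unname(ci)),
       fit = fit,
       points = data.frame(round = round, fraction = fraction, sd = sd_f))
}

#' Size of a degenerate-library sequence space
#'
#' @param degenerate_positions Vector of degenerate position counts, one per
#'   library design.
#' @return A list with \code{size} (\eqn{\sum_d 4^d}) and \code{order} (the
#'   order of magnitude, \code{round(log10(size))}).
#' @examples
#' librarySpace(c(2, 2))$size  # 32
#' @export
librarySpace <- function(degenerate_positions) {
  stopifnot(all(degenerate_positions >= 0))
  size <- sum(4^degenerate_positions)
  list(size = size, order = round(log10(size)))
}

#' Number of library contexts containing a fixed subsequence
#'
#' With \code{d} degenerate positions, a fixed \code{k}-mer at a given
#' placement leaves \code{4^(d - k)} free positions, i.e. that many distinct
#' sequence contexts in which the same motif can occur.
#'
#' @param d Degenerate positions in the design.
#' @param k Length of the fixed subsequence (<= d).
#' @return A list with \code{count} (\eqn{4^{d-k}}) and \code{order}
#'   (\code{round(log10(count))}).
#' @examples
#' contexts(3, 1)$count  # 16
#' @export
contexts <- function(d, k) {
  if (k > d) stop("k must not exceed d")
  count <- 4^(d - k)
  list(count = count, order = round(log10(count)))
}

#' The degenerate-position counts of the standard library designs
#'
#' Twenty designs: one hammerhead loop replaced by 30 or 60 random
#' nucleotides, the other by four to eight, in both loop orientations, giving
#' 34-38 and 64-68 degenerate positions (each count occurring twice).
#'
#' @return Integer vector of length 20.
#' @export
designDegeneracies <- function() {
  rep(c(30 + 4:8, 60 + 4:8), times = 2)
}
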