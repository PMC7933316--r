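## reporters: gel densitometry and flow-cytometry quantification formulas.

#' Fraction cleaved from gel band intensities
#'
#' Band intensity is proportional to molar amount times product length, so
#' the cleavage fraction is the length-normalized, background-subtracted
#' intensity ratio
#' \deqn{f = \frac{(I_c - I_{bg})/L_c}{(I_c - I_{bg})/L_c +
#'   (I_u - I_{bg})/L_u}}
#' Background-subtracted intensities that come out negative (gel noise) are
#' clamped to zero with a warning; lanes where both bands are at or below
#' background yield \code{NA}.
#'
#' @param I_cleaved,I_uncleaved Band intensities (arbitrary units).
#' @param I_bg Background intensity.
#' @param length_cleaved,length_uncleaved Product lengths (nt).
#' @return Fraction cleaved in [0, 1], vectorized over lanes.
#' @examples
#' gelFraction(200, 150, 50, 50, 100)  # 0.75
#' @export
gelFraction <- function(I_cleaved, I_uncleaved, I_bg,
                        length_cleaved, length_uncleaved) {
  stopifnot(all(length_cleaved > 0), all(length_uncleaved > 0))
  ic <- I_cleaved - I_bg
  iu <- I_uncleaved - I_bg
  if (any(ic < 0 | iu < 0))
    warning("negative background-subtracted intensity clamped to zero")
  ic <- pmax(ic, 0)
  iu <- pmax(iu, 0)
  num <- ic / length_cleaved
  den <- num + iu / length_uncleaved
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Fold change of cleavage from gel-derived fractions
#'
#' The ratio of uncleaved fractions with and without ligand,
#' \eqn{(1 - f_{+})/(1 - f_{-})}: the gel counterpart of the sequencing-based
#' fold change, predictive of in vivo expression ratios.
#'
#' @param f_plus,f_minus Fractions cleaved with / without ligand.
#' @return Fold change; \code{NA} when \code{f_minus = 1}.
#' @examples
#' gelFoldChange(0.5, 0.75)  # 2
#' @export
gelFoldChange <- function(f_plus, f_minus) {
  out <- (1 - f_plus) / (1 - f_minus)
  out[f_minus >= 1] <- NA_real_
  out
}

#' Default flow-cytometry transformation gates
#'
#' Linear-scale thresholds on the raw channel units identifying transformed
#' cells: mCherry > 10^3.2 and GFP > 10^3.1.
#'
#' @return Named numeric vector with elements \code{mCherry} and \code{GFP}.
#' @export
defaultGates <- function() c(mCherry = 10^3.2, GFP = 10^3.1)

#' Control-normalized reporter expression from flow-cytometry events
#'
#' Events passing the transformation gates contribute the per-cell ratio
#' GFP/mCherry; the sample statistic is the arithmetic mean of these ratios,
#' \eqn{F = mean(GFP_i / mCherry_i)}, and the relative fluorescence unit
#' scales it against the inactive-ribozyme control:
#' \eqn{RFU = 100\, F_{sample} / F_{control}}, so the control itself reads
#' exactly 100 RFU.
#'
#' @param sample,control \code{data.frame}s of per-cell events with columns
#'   \code{GFP} and \code{mCherry} (viability/singlet gating is assumed
#'   already applied).
#' @param gates Named vector of channel thresholds (see [defaultGates()]).
#' @return A list with \code{F_sample}, \code{F_control}, \code{RFU} and the
#'   gated event counts.
#' @export
flowNormalize <- function(sample, control, gates = defaultGates()) {
  gate <- function(ev) {
    ev[ev$mCherry > gates[["mCherry"]] & ev$GFP > gates[["GFP"]], ,
       drop = FALSE]
  }
  gs <- gate(sample)
  gc <- gate(control)
  if (nrow(gs) == 0 || nrow(gc) == 0)
    stop("no events pass the gates in sample or control")
  Fs <- mean(gs$GFP / gs$mCherry)
  Fc <- mean(gc$GFP / gc$mCherry)
  list(F_sample = Fs, F_control = Fc, RFU = Fs / Fc * 100,
       n_sample = nrow(gs), n_control = nrow(gc))
}

#' Activation ratio of a switch
#'
#' Ratio of control-normalized reporter expression with and without ligand.
#'
#' @param RFU_plus,RFU_minus RFU values with / without ligand.
#' @return \code{RFU_plus / RFU_minus}.
#' @examples
#' activationRatio(340, 100)  # 3.4
#' @export
activationRatio <- function(RFU_plus, RFU_minus) {
  if (any(RFU_minus <= 0)) stop("RFU without ligand must be positive")
  RFU_plus / RFU_minus
}
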