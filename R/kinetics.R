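## kinetics: 1:1 Langmuir model for surface plasmon resonance sensorgrams --
## simulation, background-normalization chain, global kinetic fits and
## equilibrium binding fits.

.langmuir_pred <- function(time, conc, phase, k_on, k_off, R_max, R0 = 0,
                           t0 = time[1]) {
  # piecewise closed form for one contiguous segment; R(t0) = R0
  t <- time - t0
  if (phase == "association") {
    kobs <- k_on * conc + k_off
    Req <- R_max * conc / (conc + k_off / k_on)
    Req + (R0 - Req) * exp(-kobs * t)
  } else {
    R0 * exp(-k_off * t)
  }
}

.predict_sensorgram <- function(df, k_on, k_off, R_max) {
  # df sorted by (cycle, time); phase continuity carries the boundary RU
  # within a cycle, so single-cycle chained associations work the same way
  n <- nrow(df)
  out <- numeric(n)
  chg <- c(TRUE, df$cycle[-1] != df$cycle[-n] |
                 df$phase[-1] != df$phase[-n] |
                 df$concentration[-1] != df$concentration[-n])
  seg <- cumsum(chg)
  R0 <- 0
  last_cycle <- NULL
  prev_end <- NA_real_
  for (s in unique(seg)) {
    i <- which(seg == s)
    cyc <- df$cycle[i[1]]
    new_cycle <- !identical(cyc, last_cycle)
    if (new_cycle) R0 <- 0
    t0 <- if (new_cycle) df$time[i[1]] else prev_end
    v <- .langmuir_pred(df$time[i], df$concentration[i[1]], df$phase[i[1]],
                        k_on, k_off, R_max, R0 = R0, t0 = t0)
    out[i] <- v
    R0 <- v[length(v)]
    prev_end <- df$time[i[length(i)]]
    last_cycle <- cyc
  }
  out
}

#' Simulate a Langmuir 1:1 sensorgram
#'
#' Closed-form association
#' \eqn{RU(t) = R_{eq}(1 - e^{-(k_{on}C + k_{off})t})} with
#' \eqn{R_{eq} = R_{max} C / (C + K_D)}, followed by exponential dissociation
#' from the association endpoint, with optional Gaussian noise. The curve is
#' continuous at the phase boundary.
#'
#' @param k_on Association rate (1/M/s).
#' @param k_off Dissociation rate (1/s).
#' @param R_max Saturation response (RU).
#' @param conc Analyte concentration (M).
#' @param t_assoc,t_dissoc Phase durations (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise standard deviation (RU).
#' @param R0 Response carried in at the start of association (RU), used for
#'   chained single-cycle segments.
#' @param cycle,flow_cell Identifiers recorded in the output.
#' @param seed Optional RNG seed.
#' @return \code{data.frame} with columns \code{time}, \code{RU},
#'   \code{concentration}, \code{cycle}, \code{flow_cell}, \code{phase}.
#' @export
simulateSensorgram <- function(k_on, k_off, R_max, conc,
                               t_assoc = 180, t_dissoc = 180, dt = 1,
                               noise_sd = 0, R0 = 0, cycle = 1,
                               flow_cell = 2, seed = NULL) {
  stopifnot(k_on > 0, k_off > 0, R_max > 0, conc >= 0)
  if (!is.null(seed)) set.seed(seed)
  ta <- seq(0, t_assoc, by = dt)
  df_a <- data.frame(time = ta, concentration = conc, cycle = cycle,
                     flow_cell = flow_cell, phase = "association")
  ru_a <- .langmuir_pred(ta, conc, "association", k_on, k_off, R_max, R0 = R0)
  if (t_dissoc >= dt) {
    td <- seq(t_assoc + dt, t_assoc + t_dissoc, by = dt)
    ru_d <- ru_a[length(ru_a)] * exp(-k_off * (td - t_assoc))
    df <- rbind(df_a,
                data.frame(time = td, concentration = conc, cycle = cycle,
                           flow_cell = flow_cell, phase = "dissociation"))
    df$RU <- c(ru_a, ru_d)
  } else {
    df <- df_a
    df$RU <- ru_a
  }
  if (noise_sd > 0) df$RU <- df$RU + rnorm(nrow(df), 0, noise_sd)
  df[, c("time", "RU", "concentration", "cycle", "flow_cell", "phase")]
}

.align_ru <- function(ref, other) {
  if (length(other$time) == length(ref$time) &&
      all(other$time == ref$time)) return(other$RU)
  approx(other$time, other$RU, xout = ref$time, rule = 2)$y
}

#' Background-subtraction chain for SPR sensorgrams
#'
#' Normalizes a raw sample sensorgram through the standard referencing chain:
#' the active flow cell is referenced against the no-RNA flow cell, the blank
#' (buffer-only) cycle is subtracted, and finally the blank-subtracted
#' negative-control curve (a non-binding RNA run with the same ligand) is
#' subtracted, giving \eqn{RU_{norm} = ((fc2 - fc1) - blank) - negctrl}.
#' Curves on different time grids are linearly interpolated onto the grid of
#' \code{fc2}.
#'
#' @param fc2,fc1 Sample and reference flow-cell sensorgrams
#'   (\code{data.frame}s with \code{time}, \code{RU}, \code{phase}).
#' @param blank Blank-cycle sensorgram (already flow-cell referenced).
#' @param negative_control Blank-subtracted negative-control sensorgram.
#' @return \code{fc2} with its \code{RU} replaced by the normalized values.
#' @export
normalizeSensorgram <- function(fc2, fc1, blank, negative_control) {
  for (nm in c("fc2", "fc1", "blank", "negative_control")) {
    d <- get(nm)
    if (!all(c("time", "RU") %in% names(d)))
      stop(sprintf("'%s' must have columns time and RU", nm))
  }
  if (!is.null(fc2$phase) && !is.null(fc1$phase) &&
      nrow(fc2) == nrow(fc1) && !all(fc2$phase == fc1$phase))
    stop("phase structure of fc2 and fc1 does not match")
  out <- fc2
  out$RU <- (fc2$RU - .align_ru(fc2, fc1)) - .align_ru(fc2, blank) -
    .align_ru(fc2, negative_control)
  out
}

#' Globally fit Langmuir 1:1 kinetics across analyte concentrations
#'
#' Nonlinear least-squares fit of the closed-form Langmuir model to normalized
#' sensorgrams at several concentrations, sharing \code{k_on}, \code{k_off}
#' and \code{R_max} across all curves. Rates are fit on the log scale to
#' enforce positivity, with multiple starting points to avoid local optima.
#' In multicycle data every cycle starts from baseline; in single-cycle data
#' consecutive association segments of one cycle chain their boundary response
#' automatically. The kinetic dissociation constant is
#' \eqn{K_D = k_{off}/k_{on}}.
#'
#' @param data Long-format sensorgram \code{data.frame} (columns \code{time},
#'   \code{RU}, \code{concentration}, \code{cycle}, \code{phase}) covering at
#'   least 3 concentrations spanning at least 10-fold.
#' @param mode \code{"multicycle"} or \code{"single-cycle"} (documentation of
#'   the protocol; the segment structure is taken from the data).
#' @return A list with \code{k_on}, \code{k_off}, \code{R_max},
#'   \code{KD_kinetic}, \code{measurable} (FALSE when the optimizer failed to
#'   converge), \code{rss} and \code{fit} diagnostics.
#' @export
fitKinetics <- function(data, mode = c("multicycle", "single-cycle")) {
  mode <- match.arg(mode)
  concs <- sort(unique(data$concentration[data$concentration > 0]))
  if (length(concs) < 3) stop("need curves at >= 3 concentrations")
  if (max(concs) / min(concs) < 10)
    warning("concentrations span less than 10-fold; fit may be poorly determined")
  df <- data[order(data$cycle, data$time), ]
  resid_fn <- function(par) {
    pred <- .predict_sensorgram(df, exp(par[1]), exp(par[2]), exp(par[3]))
    df$RU - pred
  }
  rmax0 <- max(df$RU) * 1.2
  koff0 <- {
    dis <- df[df$phase == "dissociation", ]
    est <- 0.01
    if (nrow(dis) > 5) {
      d1 <- dis[dis$cycle == dis$cycle[1], ]
      pos <- d1$RU > max(d1$RU) * 0.05
      if (sum(pos) > 3) {
        sl <- coef(lm(log(d1$RU[pos]) ~ d1$time[pos]))[2]
        if (is.finite(sl) && sl < 0) est <- -sl
      }
    }
    est
  }
  starts <- expand.grid(lkon = log(10^c(3, 4.5, 6)),
                        lkoff = log(koff0 * c(0.3, 1, 3)),
                        lrmax = log(rmax0))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    return(list(k_on = NA_real_, k_off = NA_real_, R_max = NA_real_,
                KD_kinetic = NA_real_, measurable = FALSE, rss = NA_real_,
                fit = NULL))
  }
  p <- exp(best$fit$par)
  list(k_on = p[1], k_off = p[2], R_max = p[3],
       KD_kinetic = p[2] / p[1],
       measurable = best$fit$info %in% 1:4,
       rss = best$rss, fit = best$fit)
}

#' Equilibrium dissociation constant from plateau responses
#'
#' Extracts the mean response over the final \code{window} seconds of each
#' association phase (the saturation plateau) and fits the Langmuir binding
#' isotherm \eqn{RU(C) = R_{max} C / (C + K_D)} -- a fixed-slope sigmoid in
#' log concentration whose inflection is at \eqn{K_D}.
#'
#' @param data Sensorgram \code{data.frame} as in [fitKinetics()] with
#'   \code{>= 4} concentrations, or a \code{data.frame} with columns
#'   \code{concentration} and \code{RU} of pre-extracted plateaus.
#' @param window Plateau window length in seconds (default 5).
#' @return A list with \code{KD}, \code{R_max}, \code{plateaus}
#'   (\code{data.frame}) and \code{flag} (\code{"ok"}, \code{"lower_bound"}
#'   when the top concentration does not approach saturation, or
#'   \code{"unbounded"} for a flat response).
#' @export
fitEquilibrium <- function(data, window = 5) {
  if (!is.null(data$phase)) {
    assoc <- data[data$phase == "association" & data$concentration > 0, ]
    plat <- do.call(rbind, lapply(split(assoc, assoc$concentration), function(d) {
      tmax <- max(d$time)
      data.frame(concentration = d$concentration[1],
                 RU = mean(d$RU[d$time >= tmax - window]))
    }))
  } else {
    plat <- data.frame(concentration = data$concentration, RU = data$RU)
  }
  plat <- plat[order(plat$concentration), ]
  rownames(plat) <- NULL
  if (nrow(plat) < 4) stop("need plateaus at >= 4 concentrations")
  if (diff(range(plat$RU)) < 1e-9 * max(abs(plat$RU), 1)) {
    return(list(KD = NA_real_, R_max = NA_real_, plateaus = plat,
                flag = "unbounded"))
  }
  C <- plat$concentration; ru <- plat$RU
  start <- list(lrmax = log(max(ru) * 1.5),
                lkd = log(C[which.min(abs(ru - max(ru) / 2))]))
  fit <- minpack.lm::nlsLM(ru ~ exp(lrmax) * C / (C + exp(lkd)),
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  kd <- exp(coef(fit)[["lkd"]])
  rmax <- exp(coef(fit)[["lrmax"]])
  flag <- if (max(ru) < 0.8 * rmax) "lower_bound" else "ok"
  list(KD = kd, R_max = rmax, plateaus = plat, flag = flag)
}

#' Flag kinetic fits that the instrument cannot resolve
#'
#' A transition (association or dissociation) faster than the instrument's
#' response cannot be fit reliably: the fit is non-measurable when the time to
#' reach 95% of either transition, \eqn{\ln(20)/k}, is below
#' \code{min_seconds} (a boundary exactly at the threshold counts as
#' non-measurable). The association rate is evaluated at the highest analyte
#' concentration used.
#'
#' @param k_on,k_off Fitted rates.
#' @param conc Analyte concentrations used in the fit.
#' @param min_seconds Resolvability threshold in seconds (default 2).
#' @return \code{TRUE} when both transitions are measurable.
#' @examples
#' flagMeasurable(1e5, 10, 1e-7)    # FALSE: dissociation takes 0.3 s
#' flagMeasurable(1e5, 1e-3, 1e-7)  # TRUE: ~3000 s
#' @export
flagMeasurable <- function(k_on, k_off, conc, min_seconds = 2) {
  t95_assoc <- log(20) / (k_on * max(conc) + k_off)
  t95_dissoc <- log(20) / k_off
  t95_assoc > min_seconds && t95_dissoc > min_seconds
}
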