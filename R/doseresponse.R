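## doseresponse: EC50 fitting of fold-change vs ligand concentration, and
## selectivity matrices across ligand analogs.

#' Parse concentration strings with molar-unit suffixes
#'
#' @param x Numeric vector (returned as-is, assumed molar) or character vector
#'   with optional \code{nM}/\code{uM}/\code{mM}/\code{M} suffixes
#'   (\code{"µM"} is accepted for \code{uM}).
#' @return Numeric concentrations in molar.
#' @examples
#' parseConcentration(c("80nM", "5uM", "1e-3"))
#' @export
parseConcentration <- function(x) {
  if (is.numeric(x)) return(x)
  x <- trimws(x)
  mult <- rep(1, length(x))
  num <- x
  for (u in list(c("nM", 1e-9), c("uM", 1e-6), c("µM", 1e-6),
                 c("mM", 1e-3), c("M", 1))) {
    hit <- grepl(paste0(u[[1]], "$"), num) & mult == 1 & !grepl("e[-+]?\\d+$", num)
    mult[hit] <- as.numeric(u[[2]])
    num[hit] <- sub(paste0(u[[1]], "$"), "", num[hit])
  }
  as.numeric(num) * mult
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Fits \deqn{y = bottom + \frac{top - bottom}{1 + 10^{h\,(\log_{10}EC_{50} -
#' \log_{10}C)}}}{y = bottom + (top-bottom)/(1+10^(h(log10 EC50 - log10 C)))}
#' to response (typically fold change of cleavage fraction) versus ligand
#' concentration by weighted least squares in log10 concentration. A zero
#' concentration point, if present, anchors the starting bottom asymptote but
#' is excluded from the logistic fit. When the fitted EC50 falls outside the
#' measured concentration range the estimate is reported as a one-sided bound;
#' a flat response yields an unbounded flag.
#'
#' @param conc Ligand concentrations (molar, or strings for
#'   [parseConcentration()]); at least 4 points.
#' @param response Measured responses.
#' @param se Optional standard errors for weighting.
#' @return A list with \code{EC50}, \code{bottom}, \code{top}, \code{hill},
#'   \code{EC50_ci} (approximate 95% interval), \code{flag} (\code{"ok"},
#'   \code{"lower_bound"}, \code{"upper_bound"} or \code{"unbounded"}),
#'   \code{nonmonotone} warning flag and the underlying \code{fit}.
#' @export
fitEC50 <- function(conc, response, se = NULL) {
  conc <- parseConcentration(conc)
  if (length(conc) < 4) stop("need at least 4 concentration points")
  stopifnot(length(response) == length(conc))
  ord <- order(conc)
  conc <- conc[ord]; response <- response[ord]
  if (!is.null(se)) se <- se[ord]
  bottom0 <- if (any(conc == 0)) mean(response[conc == 0]) else min(response)
  pos <- conc > 0
  x <- log10(conc[pos]); y <- response[pos]
  w <- if (!is.null(se)) 1 / se[pos]^2 else rep(1, sum(pos))
  tol <- if (!is.null(se)) 2 * stats::median(se) else 0.05 * diff(range(y))
  nonmono <- any(diff(cummax(y)) == 0 & diff(y) < -tol)
  if (diff(range(y)) < max(tol, 1e-12)) {
    return(list(EC50 = NA_real_, bottom = mean(y), top = mean(y),
                hill = NA_real_, EC50_ci = c(NA_real_, NA_real_),
                flag = "unbounded", nonmonotone = nonmono, fit = NULL))
  }
  start <- list(bottom = bottom0, top = max(y), hill = 1,
                lec50 = x[which.min(abs(y - (bottom0 + max(y)) / 2))])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - x))),
      start = start, weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(EC50 = NA_real_, bottom = NA_real_, top = NA_real_,
                hill = NA_real_, EC50_ci = c(NA_real_, NA_real_),
                flag = "unbounded", nonmonotone = nonmono, fit = NULL))
  }
  cf <- coef(fit)
  ec50 <- 10^cf[["lec50"]]
  se_l <- tryCatch(summary(fit)$coefficients["lec50", "Std. Error"],
                   error = function(e) NA_real_)
  ci <- 10^(cf[["lec50"]] + c(-1.96, 1.96) * se_l)
  flag <- "ok"
  if (ec50 > max(conc)) flag <- "lower_bound"    # EC50 at least this large
  if (ec50 < min(conc[pos])) flag <- "upper_bound"
  list(EC50 = ec50, bottom = cf[["bottom"]], top = cf[["top"]],
       hill = cf[["hill"]], EC50_ci = ci, flag = flag,
       nonmonotone = nonmono, fit = fit)
}

#' Sensor-by-molecule selectivity matrix
#'
#' Arranges per-(sensor, molecule) fold changes of cleavage relative to the
#' common no-ligand condition into a matrix, with optional per-cell confidence
#' bounds. Rows and columns are sorted, so the result does not depend on the
#' input order; missing combinations are reported as \code{NA}, never imputed.
#'
#' @param results \code{data.frame} with columns \code{sensor},
#'   \code{molecule}, \code{f} and optionally \code{ci_lo}, \code{ci_hi},
#'   \code{concentration}.
#' @return A list with \code{fold} (sensors x molecules matrix), optional
#'   \code{ci_lo}/\code{ci_hi} matrices and \code{concentration} (named per
#'   molecule when supplied).
#' @export
selectivityMatrix <- function(results) {
  stopifnot(all(c("sensor", "molecule", "f") %in% names(results)))
  key <- paste(results$sensor, results$molecule)
  if (anyDuplicated(key)) stop("duplicate (sensor, molecule) entries")
  sensors <- sort(unique(results$sensor))
  molecules <- sort(unique(results$molecule))
  build <- function(col) {
    m <- matrix(NA_real_, length(sensors), length(molecules),
                dimnames = list(sensors, molecules))
    m[cbind(match(results$sensor, sensors),
            match(results$molecule, molecules))] <- results[[col]]
    m
  }
  out <- list(fold = build("f"))
  if (!is.null(results$ci_lo)) out$ci_lo <- build("ci_lo")
  if (!is.null(results$ci_hi)) out$ci_hi <- build("ci_hi")
  if (!is.null(results$concentration)) {
    cc <- tapply(results$concentration, results$molecule,
                 function(v) unique(v)[1])
    out$concentration <- cc[molecules]
  }
  out
}
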