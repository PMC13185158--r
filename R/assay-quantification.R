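## Calibration math for the colorimetric (Victoria Blue type) rhamnolipid
## assay and the droplet contact-angle geometry used to cross-validate it.

#' Fit a linear calibration (standard) curve
#'
#' Ordinary least squares of absorbance on concentration. `sigma` is the
#' residual standard deviation of the response (n - 2 denominator) unless a
#' blank-replicate SD is supplied; the limit of detection is
#' `LOD = 3.3 * sigma / slope`, and MAPE is the mean absolute percentage
#' error of back-predicting the standard concentrations from their
#' absorbances.
#'
#' @param concentration standard concentrations in ug/mL (>= 3 distinct
#'   values).
#' @param absorbance measured responses, same length.
#' @param blankSigma optional response SD from blank replicates, used in
#'   place of the regression residual SD for the LOD.
#' @return A [StandardCurve-class] object.
#' @examples
#' x <- c(10, 30, 60, 75, 85, 115, 140, 170)
#' crv <- fitStandardCurve(x, 0.0009 * x + 0.006)
#' curveSlope(crv)  # 0.0009
#' @export
fitStandardCurve <- function(concentration, absorbance, blankSigma = NULL) {
  if (length(concentration) != length(absorbance))
    stop("concentration and absorbance must have equal length")
  if (length(unique(concentration)) < 3L)
    stop("at least 3 distinct concentrations are required")
  if (stats::var(concentration) == 0) stop("zero concentration variance")
  fit <- lm(absorbance ~ concentration)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope <= 0) stop("calibration slope must be positive")
  n <- length(concentration)
  sigma <- if (!is.null(blankSigma)) blankSigma else
    sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  backPred <- (absorbance - intercept) / slope
  mapeVal <- mean(abs(backPred - concentration) / concentration) * 100
  new("StandardCurve", slope = slope, intercept = intercept, sigma = sigma,
      lod = 3.3 * sigma / slope, mape = mapeVal,
      range = range(concentration), n = as.integer(n))
}

#' Invert absorbance to concentration against a standard curve
#'
#' `concentration = (absorbance - intercept) / slope`; values below the
#' curve's LOD are censored (reported with `censored = TRUE`, printed as
#' `"<LOD"` in reports), values above the detection range are flagged
#' `extrapolated` but still returned.
#'
#' @param absorbance numeric vector of responses.
#' @param curve a [StandardCurve-class].
#' @return `data.frame` with columns `absorbance`, `concentration`,
#'   `censored`, `extrapolated`, `label`.
#' @export
quantify <- function(absorbance, curve) {
  stopifnot(is(curve, "StandardCurve"))
  conc <- (absorbance - curve@intercept) / curve@slope
  censored <- conc < curve@lod
  extrapolated <- conc > curve@range[2]
  data.frame(absorbance = absorbance, concentration = conc,
             censored = censored, extrapolated = extrapolated,
             label = ifelse(censored, "<LOD",
                            formatC(conc, format = "fg", digits = 6)),
             stringsAsFactors = FALSE)
}

#' Fold change at a stated precision
#'
#' Ratio of a sample concentration over a reference concentration, reported
#' at a requested number of decimals. Published fold changes are rounded
#' inconsistently often enough that the truncation mode is exposed
#' explicitly.
#'
#' @param sampleConc sample concentration (ug/mL).
#' @param referenceConc reference concentration (> 0).
#' @param decimals decimal places to report (default 2).
#' @param mode `"round"` (half-up via standard rounding) or `"truncate"`.
#' @return The fold change as a number at the requested precision.
#' @examples
#' foldChange(55.51, 20.1)                       # 2.76
#' foldChange(24.63, 20.1, mode = "truncate")    # 1.22
#' @export
foldChange <- function(sampleConc, referenceConc, decimals = 2L,
                       mode = c("round", "truncate")) {
  mode <- match.arg(mode)
  if (any(referenceConc <= 0)) stop("reference concentration must be positive")
  ratio <- sampleConc / referenceConc
  f <- 10^decimals
  if (mode == "round") round(ratio * f) / f else trunc(ratio * f) / f
}

#' Droplet contact angle from height and base radius
#'
#' `theta = 2 * arctan(H / R)` in degrees, for a spherical-cap droplet of
#' height `H` and base radius `R` in the same length unit.
#'
#' @param H droplet height (>= 0).
#' @param R base radius (> 0).
#' @return Contact angle in degrees, in `[0, 180)`.
#' @examples
#' contactAngle(1, 1)  # 90
#' @export
contactAngle <- function(H, R) {
  if (any(R <= 0)) stop("base radius must be positive")
  if (any(H < 0)) stop("droplet height must be non-negative")
  2 * atan(H / R) * 180 / pi
}
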