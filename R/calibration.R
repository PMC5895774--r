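# Quantitation support: internal-standard calibration curves (response
# ratio analyte/IS versus nominal concentration), detection and
# quantitation limits from calibration-curve noise, and precision/accuracy
# QC summaries.

#' Fit an internal-standard calibration curve
#'
#' Least-squares line of response ratio versus nominal concentration,
#' 1/x-weighted by default (MS responses are heteroscedastic, with
#' variance growing with concentration); duplicate nominal levels are
#' pooled.  The reported `residual_sd` is the standard deviation of the
#' raw (unweighted) residuals.
#'
#' @param nominal Nominal concentrations (ng/mL), all positive, >= 3
#'   points over >= 2 distinct levels.
#' @param response Response ratios (analyte area / internal-standard
#'   area).
#' @param weighting `"1/x"` (default) or `"none"`.
#' @param analyte Optional analyte name carried in the result.
#' @return Object of class `calibration_curve`: `slope`, `intercept`,
#'   `residual_sd`, `n`, `range` (of nominals), `weighting`, `analyte`,
#'   `fit` (the underlying `lm`).
#' @export
#' @examples
#' fit_calibration(c(1, 2, 5, 10, 20, 50, 100),
#'                 0.02 * c(1, 2, 5, 10, 20, 50, 100))
fit_calibration <- function(nominal, response, weighting = c("1/x", "none"),
                            analyte = NA_character_) {
  weighting <- match.arg(weighting)
  stopifnot(length(nominal) == length(response))
  if (length(nominal) < 3)
    stop("need at least 3 calibration points", call. = FALSE)
  if (any(nominal <= 0))
    stop("nominal concentrations must be positive", call. = FALSE)
  if (length(unique(nominal)) < 2)
    stop("zero-variance nominal levels: cannot fit a line", call. = FALSE)
  w <- if (weighting == "1/x") 1 / nominal else rep(1, length(nominal))
  fit <- stats::lm(response ~ nominal, weights = w)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_sd = stats::sd(stats::residuals(fit)),
                 n = length(nominal), range = range(nominal),
                 weighting = weighting, analyte = analyte, fit = fit),
            class = "calibration_curve")
}

#' Detection and quantitation limits from a calibration curve
#'
#' The 3.3-sigma / 10-sigma slope rule: `LOD = 3.3 * sd / slope`,
#' `LOQ = 10 * sd / slope`, with `sd` the curve's residual standard
#' deviation.  LOQ is therefore always `10 / 3.3` times LOD.
#'
#' @param curve A [fit_calibration()] result with positive slope.
#' @return Named numeric `c(lod, loq)` in ng/mL.
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope <= 0)
    stop("LOD/LOQ undefined for non-positive slope", call. = FALSE)
  c(lod = 3.3 * curve$residual_sd / curve$slope,
    loq = 10 * curve$residual_sd / curve$slope)
}

#' Precision and accuracy of replicate measurements
#'
#' Precision is the coefficient of variation `100 * sd / mean`; accuracy
#' error is `100 * |mean - nominal| / nominal`.
#'
#' @param replicates Numeric vector of >= 2 measured values.
#' @param nominal Positive nominal concentration.
#' @param analyte Optional analyte name carried in the result.
#' @return Object of class `qc_summary`: `precision_pct`,
#'   `accuracy_error_pct`, `mean`, `n`, `nominal`, `analyte`.
#' @export
#' @examples
#' qc_summary(c(9, 11), nominal = 10)
qc_summary <- function(replicates, nominal, analyte = NA_character_) {
  if (length(replicates) < 2)
    stop("need at least 2 replicates", call. = FALSE)
  if (nominal <= 0) stop("nominal must be positive", call. = FALSE)
  m <- mean(replicates)
  structure(list(precision_pct = 100 * stats::sd(replicates) / m,
                 accuracy_error_pct = 100 * abs(m - nominal) / nominal,
                 mean = m, n = length(replicates), nominal = nominal,
                 analyte = analyte),
            class = "qc_summary")
}

#' Reference assay-performance table
#'
#' The published per-analyte method-validation metadata shipped with the
#' package: internal-standard variation, intra-/inter-day precision and
#' accuracy percentages, LOD, LOQ and linearity range (ng/mL).  These are
#' reference values for report annotation, not recomputed quantities.
#'
#' @return Data frame, one row per panel analyte.
#' @export
builtin_assay_reference <- function() {
  utils::read.csv(.extdata("lod_loq_table3.csv"), check.names = FALSE,
                  stringsAsFactors = FALSE)
}

#' Read calibration points from delimited text
#'
#' Expects columns `analyte`, `nominal`, `response` (extra columns are
#' kept).
#'
#' @param path File to read.
#' @param sep Field separator.
#' @return Data frame of calibration points.
#' @export
read_calibration <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("analyte", "nominal", "response")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("calibration file missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}
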