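# Single-marker baselines: diagnostic cutoffs set at 95% confidence limits
# of the geometric mean of the cancer group's marker values, and the two
# threshold rules built from them (PSA high side = PCa, DHEAS low side =
# PCa).

#' Geometric mean with confidence interval
#'
#' `gm = exp(mean(log x))` with a Student-t interval on the log scale:
#' `exp(mean(log x) -/+ t * sd(log x) / sqrt(n))`.
#'
#' @param values Strictly positive numeric vector, length >= 2 (NAs are
#'   dropped).
#' @param level Confidence level (default 0.95).
#' @return Object of class `gm_ci`: fields `gm`, `lo`, `hi`, `n`, `level`.
#' @export
#' @examples
#' geometric_mean_ci(c(2, 4, 8))
geometric_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(values <= 0))
    stop("geometric mean requires strictly positive values", call. = FALSE)
  lx <- log(values)
  n <- length(lx)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(lx) / sqrt(n)
  structure(list(gm = exp(mean(lx)), lo = exp(mean(lx) - half),
                 hi = exp(mean(lx) + half), n = n, level = level),
            class = "gm_ci")
}

#' @export
print.gm_ci <- function(x, ...) {
  cat(sprintf("geometric mean %.4g  [%.4g, %.4g]  (%d values, %.0f%% CI)\n",
              x$gm, x$lo, x$hi, x$n, 100 * x$level))
  invisible(x)
}

#' PSA threshold rule
#'
#' `psa >= threshold` is called PCa, below is BPH/HC; missing PSA is
#' `"unclassified"`.  The reference threshold is the lower 95% CI limit of
#' the geometric mean of the cancer group's PSA.
#'
#' @param psa Numeric vector of total PSA (ng/mL), NAs allowed.
#' @param threshold Positive cutoff (ng/mL).
#' @return Character vector in `{"PCa", "BPH/HC", "unclassified"}`.
#' @export
psa_classify <- function(psa, threshold) {
  stopifnot(length(threshold) == 1, threshold > 0)
  ifelse(is.na(psa), "unclassified", ifelse(psa >= threshold, "PCa", "BPH/HC"))
}

#' DHEAS threshold rule
#'
#' `dheas < threshold` is called PCa (DHEAS runs low in the cancer group),
#' at or above is BPH/HC; the boundary value itself falls on the non-PCa
#' side.  The reference threshold is the upper 95% CI limit of the
#' geometric mean of the cancer group's DHEAS.
#'
#' @param dheas Numeric vector of DHEAS (ng/mL); missing values are an
#'   error (DHEAS is always measured in the panel).
#' @param threshold Positive cutoff (ng/mL).
#' @return Character vector in `{"PCa", "BPH/HC"}`.
#' @export
dheas_classify <- function(dheas, threshold) {
  stopifnot(length(threshold) == 1, threshold > 0)
  if (anyNA(dheas)) stop("missing DHEAS value(s)", call. = FALSE)
  ifelse(dheas < threshold, "PCa", "BPH/HC")
}
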