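# Canonical analyte order. Index i in all ratio formulas refers to this order;
# keeping it fixed makes every pairwise ratio index reproducible across runs.
.ANALYTES <- c(
  "aldosterone", "corticosterone", "cortisol", "11-deoxycortisol",
  "androstenedione", "testosterone", "DHEA", "DHEAS",
  "17-OH-progesterone", "progesterone"
)

.CLASSES <- c("BPH", "HC", "PCa")

#' Canonical steroid panel analytes
#'
#' The ten serum steroids of the panel, in the fixed canonical order used
#' throughout the package.  All ratio indices, vector layouts and fixture
#' columns follow this order.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' steroid_analytes()
steroid_analytes <- function() .ANALYTES

#' Construct and validate a steroid panel
#'
#' A panel is a named numeric vector of non-negative concentrations in
#' ng/mL, one entry per analyte of [steroid_analytes()].  The constructor
#' reorders entries into canonical order and rejects anything else.
#'
#' @param x Named numeric vector; names must be exactly the panel analytes.
#' @return Named numeric vector in canonical analyte order.
#' @export
#' @examples
#' p <- steroid_panel(setNames(c(0.1, 3, 100, 0.4, 1.2, 4.5, 3, 1200, 1, 0.15),
#'                             steroid_analytes()))
steroid_panel <- function(x) {
  if (!is.numeric(x) || is.null(names(x)))
    stop("a steroid panel must be a named numeric vector", call. = FALSE)
  if (!setequal(names(x), .ANALYTES))
    stop("panel analytes must be exactly: ", paste(.ANALYTES, collapse = ", "),
         call. = FALSE)
  wn <- attr(x, "weight_normalized")
  x <- x[.ANALYTES]
  attr(x, "weight_normalized") <- wn
  bad <- names(x)[!is.na(x) & x < 0]
  if (length(bad))
    stop("negative concentration for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  x
}

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "steroidratio")
  if (!nzchar(path)) stop("missing package data file: ", file, call. = FALSE)
  path
}
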