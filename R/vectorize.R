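# Two feature encodings are used for profile matching:
#  * the percent ("singular absolute") concentration vector, m/z-keyed
#    relative concentrations plus a virtual m/z 1000 entry carrying the
#    total concentration, and
#  * the combinatorial ratio vector, all n(n-1)/2 pairwise concentration
#    ratios in canonical order.
# Because cortisol and DHEAS circulate far above the other eight steroids,
# both encodings are normally built after a fixed weight normalization that
# divides cortisol by 10 and DHEAS by 100.

#' Weight-normalize a steroid panel
#'
#' Divides cortisol by 10 and DHEAS by 100, leaving the other analytes
#' untouched.  Without this, the two dominant analytes swamp every
#' similarity computation.  The operation is not idempotent (divisors
#' compound), so the result carries a `weight_normalized` attribute and
#' re-application raises an error unless `force = TRUE`.
#'
#' @param panel A [steroid_panel()].
#' @param divisors Named numeric divisors; default `c(cortisol = 10, DHEAS = 100)`.
#' @param force Allow re-normalizing an already normalized panel.
#' @return The normalized panel (input is not modified).
#' @export
weight_normalize <- function(panel, divisors = c(cortisol = 10, DHEAS = 100),
                             force = FALSE) {
  panel <- steroid_panel(panel)
  miss <- names(divisors)[!names(divisors) %in% names(panel) |
                            is.na(panel[names(divisors)])]
  if (length(miss))
    stop("cannot weight-normalize, analyte missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (isTRUE(attr(panel, "weight_normalized")) && !force)
    stop("panel is already weight-normalized (divisors would compound)",
         call. = FALSE)
  out <- panel
  out[names(divisors)] <- out[names(divisors)] / divisors
  attr(out, "weight_normalized") <- TRUE
  out
}

#' Percent concentration vector
#'
#' Encodes a panel as relative concentrations keyed by parent m/z:
#' `Cv = sum(Ci)` and `Cn_i = 100 * Ci / Cv`, plus a virtual entry at
#' m/z 1000 carrying `Cv` itself as normalizing factor.  Analytes sharing a
#' parent m/z (DHEA/DHEAS at 271.2) keep separate entries, ordered by the
#' canonical analyte index; the m/z key is an annotation, not a unique key.
#'
#' @param panel A [steroid_panel()]; at least one concentration must be
#'   positive and none missing.
#' @param transitions Transition table supplying parent m/z values.
#' @return Object of class `concentration_vector` with fields `analyte`,
#'   `mz`, `cn` (percent values summing to 100) and `cv` (total, ng/mL).
#' @export
percent_vector <- function(panel, transitions = builtin_transitions()) {
  panel <- steroid_panel(panel)
  if (anyNA(panel))
    stop("panel has missing concentrations: ",
         paste(names(panel)[is.na(panel)], collapse = ", "), call. = FALSE)
  cv <- sum(panel)
  if (cv <= 0) stop("all-zero panel: percent vector undefined", call. = FALSE)
  out <- list(analyte = names(panel),
              mz = parent_mz(names(panel), transitions),
              cn = as.numeric(panel) / cv * 100,
              cv = cv,
              virtual_mz = 1000)
  class(out) <- "concentration_vector"
  out
}

#' Combinatorial ratio vector
#'
#' Converts a panel into the full set of pairwise concentration ratios
#' `R(k, i) = C(k) / C(i)` enumerated in canonical order (`k = 1..n-1`,
#' `i = k+1..n`, numerator the earlier-indexed analyte), giving
#' `n(n-1)/2` entries.  Ratios are invariant to global scaling of the
#' panel, which is what makes them a compositional feature.
#'
#' @param panel A [steroid_panel()] with strictly positive concentrations
#'   (after the optional weight normalization).  Named numeric vectors over
#'   a different analyte set (>= 2 entries) are accepted as-is, in the
#'   given order, for non-standard panels.
#' @param apply_weight_normalization Apply [weight_normalize()] first
#'   (default TRUE, matching how profiles are matched downstream; only
#'   meaningful for the canonical panel).
#' @return Object of class `ratio_vector` with fields `num`, `den`
#'   (analyte names), `r` (ratio values) and `n` (analyte count).
#' @export
ratio_vector <- function(panel, apply_weight_normalization = TRUE) {
  canonical <- !is.null(names(panel)) && setequal(names(panel), .ANALYTES)
  if (canonical) {
    panel <- steroid_panel(panel)
    if (apply_weight_normalization &&
        !isTRUE(attr(panel, "weight_normalized")))
      panel <- weight_normalize(panel)
  } else {
    if (!is.numeric(panel) || is.null(names(panel)) || length(panel) < 2)
      stop("panel must be a named numeric vector with >= 2 analytes",
           call. = FALSE)
  }
  bad <- names(panel)[is.na(panel) | panel <= 0]
  if (length(bad))
    stop("ratio vector needs positive concentrations; offending analyte(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  n <- length(panel)
  k <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  i <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  out <- list(num = names(panel)[k], den = names(panel)[i],
              r = as.numeric(panel[k] / panel[i]), n = n)
  class(out) <- "ratio_vector"
  out
}

#' Number of pairwise ratios for n analytes
#'
#' Evaluates the combinatorial count `sum_{k=1}^{n-1} (n - k) = n(n-1)/2`,
#' the length of [ratio_vector()] output.
#'
#' @param n Analyte count, integer >= 1.
#' @return Integer ratio count.
#' @export
#' @examples
#' ratio_count(10)  # 45
ratio_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  if (n == 1L) return(0L)
  sum(n - seq_len(n - 1L))
}

#' Export a feature vector as delimited text
#'
#' Writes one row per entry (key, value) for inspection: ratio vectors as
#' `numerator/denominator` keys, percent vectors as m/z keys including the
#' virtual total entry.
#'
#' @param v A `ratio_vector` or `concentration_vector`.
#' @param path Output file.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
export_vector <- function(v, path, sep = ",") {
  df <- if (inherits(v, "ratio_vector")) {
    data.frame(key = paste0(v$num, "/", v$den), value = v$r)
  } else if (inherits(v, "concentration_vector")) {
    data.frame(key = c(v$mz, v$virtual_mz), value = c(v$cn, v$cv))
  } else stop("unsupported vector type", call. = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
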