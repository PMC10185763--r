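#' Frequency band specification
#'
#' A named frequency interval used for bandpass filtering and
#' phase/amplitude bookkeeping.
#'
#' @param name Band name (e.g. `"alpha"`).
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return An object of class `band_spec`: a list with `name`, `lo`, `hi`.
#' @examples
#' band_spec("alpha", 8, 12)
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  lo <- as.numeric(lo); hi <- as.numeric(hi)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("band edges must satisfy 0 < lo < hi (got [", lo, ", ", hi, "])")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band %s: %g-%g Hz>\n", x$name, x$lo, x$hi))
  invisible(x)
}

#' @export
format.band_spec <- function(x, ...) sprintf("%s (%g-%g Hz)", x$name, x$lo, x$hi)

#' Canonical low-frequency rhythm bands
#'
#' The four slow ECoG rhythms whose phase is used to probe high-gamma
#' amplitude: delta (1-3 Hz), theta (4-8 Hz), alpha (8-12 Hz) and beta
#' (12-20 Hz). The "canonical gamma" band (30-50 Hz) is excluded by
#' default because its selected amplitude bandwidth is too narrow relative
#' to twice its upper phase frequency to resolve coupling sidebands (see
#' [check_bandwidth_constraint()]).
#'
#' @param include_gamma Append canonical gamma (30-50 Hz)?
#' @return A list of [band_spec()] objects, in fixed order.
#' @examples
#' canonical_low_bands()
#' @export
canonical_low_bands <- function(include_gamma = FALSE) {
  bands <- list(
    band_spec("delta", 1, 3),
    band_spec("theta", 4, 8),
    band_spec("alpha", 8, 12),
    band_spec("beta", 12, 20)
  )
  if (isTRUE(include_gamma))
    bands <- c(bands, list(band_spec("canonical_gamma", 30, 50)))
  bands
}

#' High-gamma band
#'
#' The broadband 70-200 Hz range from which task-relevant sub-bands are
#' selected.
#' @return A [band_spec()].
#' @export
high_gamma_band <- function() band_spec("high_gamma", 70, 200)

#' Sideband-resolution advisory for a phase band
#'
#' Phase-amplitude coupling between a slow rhythm at frequency `f1` and a
#' fast carrier shows up as sidebands at `carrier +/- f1`; an amplitude
#' filter narrower than `2 * f1` cannot pass both sidebands and can return
#' a false negative. This check flags phase bands whose upper edge exceeds
#' half the amplitude bandwidth. It is advisory only: beta (12-20 Hz)
#' formally violates the rule at the default 20 Hz selection bandwidth but
#' is retained, while canonical gamma is dropped from the default band
#' list outright.
#'
#' @param low A [band_spec()] for the phase (slow) band.
#' @param amp_bandwidth Full bandwidth of the amplitude filter in Hz
#'   (default 20, i.e. a selected interval `[p - 10, p + 10]`).
#' @return A list with `band`, `ok`, `required` (the minimum amplitude
#'   bandwidth `2 * low$hi`) and `amp_bandwidth`.
#' @examples
#' check_bandwidth_constraint(band_spec("delta", 1, 3), 20)   # ok
#' check_bandwidth_constraint(band_spec("canonical_gamma", 30, 50), 20)
#' @export
check_bandwidth_constraint <- function(low, amp_bandwidth = 20) {
  stopifnot(inherits(low, "band_spec"), amp_bandwidth > 0)
  required <- 2 * low$hi
  list(band = low$name,
       ok = amp_bandwidth >= required,
       required = required,
       amp_bandwidth = amp_bandwidth)
}
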