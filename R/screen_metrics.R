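#' Robust Z scoring of senescence-marker panels
#'
#' High-content screening readout: each treatment measurement is scored
#' against the vehicle-control distribution of the same marker as
#' `z = (treatment - median(control)) / MAD(control)`, where the MAD is the
#' unscaled median absolute deviation `median(|x - median(x)|)` (no 1.4826
#' consistency factor). Calls are made against a symmetric cutoff with the
#' marker's senescence polarity deciding which tail means "senescent".
#'
#' @param control numeric vector of >= 3 control measurements.
#' @param treatment numeric vector of treatment measurements, same assay
#'   units.
#' @param marker marker name used in error messages and output.
#' @param polarity `"senescence-increases"` if the marker rises with
#'   senescence (e.g. p16, p21, SA-beta-Gal, IL-6, nuclear area), otherwise
#'   `"senescence-decreases"`.
#' @param cutoff absolute z cutoff for a call (default 0.5).
#' @return `robust_z()` returns a data.frame with one row per treatment value:
#'   `marker`, `value`, `z`, `call`, `control_median`, `mad`.
#' @examples
#' robust_z(c(10, 12, 14, 16, 18), 20)  # z = 3
#' @export
robust_z <- function(control, treatment, marker = "marker",
                     polarity = c("senescence-increases",
                                  "senescence-decreases"),
                     cutoff = 0.5) {
  polarity <- match.arg(polarity)
  if (length(control) < 3)
    stop("need >= 3 control values for marker ", marker, call. = FALSE)
  med <- stats::median(control)
  mad_ <- stats::median(abs(control - med))
  if (mad_ == 0)
    stop("degenerate control spread (MAD = 0) for marker ", marker,
         call. = FALSE)
  z <- (treatment - med) / mad_
  data.frame(marker = marker, value = treatment, z = z,
             call = vapply(z, classify_marker, character(1),
                           polarity = polarity, cutoff = cutoff),
             control_median = med, mad = mad_,
             stringsAsFactors = FALSE)
}

#' @rdname robust_z
#' @param z a robust Z score.
#' @return `classify_marker()` returns `"proliferative"`, `"senescent"` or
#'   `"no-change"`.
#' @export
classify_marker <- function(z, polarity = c("senescence-increases",
                                            "senescence-decreases"),
                            cutoff = 0.5) {
  polarity <- match.arg(polarity)
  zs <- if (polarity == "senescence-increases") z else -z
  if (zs >= cutoff) "senescent"
  else if (zs <= -cutoff) "proliferative"
  else "no-change"
}

#' Senescence polarity of the standard marker panel
#'
#' Direction in which each commonly used marker moves with senescence; used
#' to orient robust-Z calls.
#' @return named character vector of polarities.
#' @export
marker_polarity_panel <- function() {
  c("p16" = "senescence-increases",
    "p21" = "senescence-increases",
    "SA-b-Gal" = "senescence-increases",
    "IL-6" = "senescence-increases",
    "nuclear_area" = "senescence-increases",
    "cell_area" = "senescence-increases",
    "nucleolin" = "senescence-decreases",
    "cell_count" = "senescence-decreases")
}

#' Population-doubling arithmetic
#'
#' Per-passage population doublings from seeding and harvest cell counts,
#' `PD = ln(final / (seeded / 2)) / 0.6931 - 1`. The divisor is kept as the
#' literal constant 0.6931 to reproduce the printed arithmetic of standard
#' cell-culture worksheets; `exact_ln2 = TRUE` substitutes ln 2. The formula's
#' fixed point is `final = seeded / 2`, which gives exactly -1 doublings.
#'
#' @param seeded cells seeded (> 0).
#' @param final cells harvested (> 0).
#' @param exact_ln2 use `log(2)` instead of the truncated 0.6931.
#' @return population doublings (real, can be negative).
#' @examples
#' population_doubling(10000, 40000)  # ~2 doublings
#' @export
population_doubling <- function(seeded, final, exact_ln2 = FALSE) {
  if (any(seeded <= 0)) stop("seeded count must be > 0", call. = FALSE)
  if (any(final <= 0)) stop("final count must be > 0", call. = FALSE)
  log(final / (seeded / 2)) / (if (exact_ln2) log(2) else 0.6931) - 1
}

#' @rdname population_doubling
#' @param pd vector of per-passage population doublings, ordered by passage.
#' @return `cumulative_pd()` returns the running sum (cumulative population
#'   doublings).
#' @export
cumulative_pd <- function(pd) cumsum(pd)
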