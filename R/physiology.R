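# Physiological indicator formulas: electrolyte leakage, chlorophyll content,
# percent change, Na+/K+ ratio, time-course summaries.

#' Relative electrolyte leakage
#'
#' Membrane-integrity proxy computed from a conductivity pair: the initial
#' conductivity S1 of leaf discs soaked in ultrapure water and the final
#' conductivity S2 after boiling. Leakage = `(S1/S2) * 100` percent.
#'
#' Physically `0 <= S1 <= S2`, so leakage lies in `[0, 100]`; violations (noisy
#' instrument exports) produce a warning, not an error, and the raw value is
#' returned so batch processing does not abort.
#'
#' @param s1 Initial conductivity (any instrument unit).
#' @param s2 Post-boil conductivity (same unit, > 0).
#' @return Leakage in percent. Vectorised.
#' @examples
#' relative_electrolyte_leakage(30, 60) # 50
#' @export
relative_electrolyte_leakage <- function(s1, s2) {
  if (!is.numeric(s1) || !is.numeric(s2)) stop("conductivities must be numeric")
  if (any(!is.finite(s2)) || any(s2 <= 0)) stop("S2 must be finite and > 0")
  if (any(s1 < 0)) warning("S1 < 0: negative conductivity flagged")
  if (any(s1 > s2)) warning("S1 > S2: leakage above 100 % flagged")
  100 * s1 / s2
}

#' Chlorophyll content from ethanol-extract absorbances
#'
#' Applies the two-wavelength chlorophyll equations for 95 % ethanol extracts:
#' `Chl a = 13.95*A665 - 6.88*A649` and `Chl b = 24.96*A649 - 7.32*A665`
#' (mg/L in the extract), with `Chl a+b` their sum. Concentrations are scaled
#' to a per-gram-fresh-weight basis by `conc * volume / mass` using the
#' extraction volume and tissue mass (defaults: 25 mL and 0.2 g).
#'
#' The linear equations can yield small negative concentrations on noisy
#' absorbances; these are clipped to 0 with a warning. A470 is accepted and
#' carried through for completeness but no carotenoid equation is applied.
#'
#' @param a649,a665 Absorbances at 649 and 665 nm (>= 0).
#' @param a470 Optional absorbance at 470 nm (stored, unused).
#' @param volume_l Extract volume in litres (> 0), default 0.025.
#' @param mass_g Tissue fresh weight in grams (> 0), default 0.2.
#' @return A data.frame with `chl_a`, `chl_b`, `chl_total` (mg/L) and
#'   `chl_a_fw`, `chl_b_fw`, `chl_total_fw` (mg per g FW);
#'   `chl_total == chl_a + chl_b` exactly.
#' @examples
#' chlorophyll_content(a649 = 0.5, a665 = 1.0)
#' @export
chlorophyll_content <- function(a649, a665, a470 = NA_real_,
                                volume_l = 0.025, mass_g = 0.2) {
  if (!is.numeric(a649) || !is.numeric(a665))
    stop("absorbances must be numeric")
  if (any(a649 < 0, na.rm = TRUE) || any(a665 < 0, na.rm = TRUE))
    stop("absorbances must be >= 0")
  if (any(!is.finite(volume_l)) || any(volume_l <= 0)) stop("volume_l must be > 0")
  if (any(!is.finite(mass_g)) || any(mass_g <= 0)) stop("mass_g must be > 0")
  chl_a <- 13.95 * a665 - 6.88 * a649
  chl_b <- 24.96 * a649 - 7.32 * a665
  if (any(chl_a < 0) || any(chl_b < 0)) {
    warning("negative computed pigment concentration clipped to 0")
    chl_a <- pmax(chl_a, 0)
    chl_b <- pmax(chl_b, 0)
  }
  chl_total <- chl_a + chl_b
  scale <- volume_l / mass_g
  data.frame(a470 = a470, chl_a = chl_a, chl_b = chl_b, chl_total = chl_total,
             chl_a_fw = chl_a * scale, chl_b_fw = chl_b * scale,
             chl_total_fw = chl_total * scale)
}

#' Signed percent change from control to treatment
#'
#' `100 * (treated - control) / control`; positive for increases.
#'
#' @param control_mean Control mean (non-zero).
#' @param treated_mean Treated mean.
#' @return Percent change. Vectorised.
#' @examples
#' percent_change(20, 5) # -75
#' @export
percent_change <- function(control_mean, treated_mean) {
  if (!is.numeric(control_mean) || !is.numeric(treated_mean))
    stop("means must be numeric")
  if (any(control_mean == 0)) stop("control mean of 0: percent change undefined")
  100 * (treated_mean - control_mean) / control_mean
}

#' Sodium-to-potassium concentration ratio
#'
#' Na+/K+ in a tissue, a key ion-homeostasis indicator (low shoot values
#' indicate restricted Na+ translocation).
#'
#' @param na Na+ concentration (>= 0).
#' @param k K+ concentration (> 0), same units.
#' @return The ratio. Vectorised.
#' @examples
#' na_k_ratio(3, 12) # 0.25
#' @export
na_k_ratio <- function(na, k) {
  if (!is.numeric(na) || !is.numeric(k)) stop("concentrations must be numeric")
  if (any(!is.finite(k)) || any(k <= 0)) stop("K+ must be finite and > 0")
  if (any(na < 0)) stop("Na+ must be >= 0")
  na / k
}

#' Summarise a physiological time course
#'
#' Per (variety, indicator, day) cell: sample mean, sample SD (n-1
#' denominator, NA when only one replicate) and replicate count, the
#' "mean +/- SD" summary used for stress time courses.
#'
#' @param series Tidy data.frame with columns `variety`, `indicator`, `day`,
#'   `replicate`, `value`.
#' @param days Allowed sampling days; default `c(0, 1, 3, 6)`. Set to NULL to
#'   accept any day.
#' @return A data.frame `variety, indicator, day, mean, sd, n` sorted by
#'   variety, indicator, day.
#' @examples
#' ts <- data.frame(variety = "P47", indicator = "MDA", day = 0,
#'                  replicate = 1:3, value = c(2, 4, 6))
#' summarize_timecourse(ts) # mean 4, sd 2, n 3
#' @export
summarize_timecourse <- function(series, days = c(0, 1, 3, 6)) {
  need <- c("variety", "indicator", "day", "replicate", "value")
  if (!is.data.frame(series) || !all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  if (nrow(series) == 0) stop("empty time series")
  if (!is.null(days)) {
    bad <- setdiff(unique(series$day), days)
    if (length(bad))
      stop("day(s) outside the sampling design: ", paste(bad, collapse = ", "))
  }
  key <- list(variety = series$variety, indicator = series$indicator,
              day = series$day)
  mean_tab <- aggregate(series$value, key, FUN = mean)
  sd_tab <- aggregate(series$value, key, FUN = function(v)
    if (length(v) > 1) sd(v) else NA_real_)
  n_tab <- aggregate(series$value, key, FUN = length)
  out <- data.frame(mean_tab[c("variety", "indicator", "day")],
                    mean = mean_tab$x, sd = sd_tab$x, n = n_tab$x)
  out[order(out$variety, out$indicator, out$day), , drop = FALSE] |>
    `rownames<-`(NULL)
}
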