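# FTIR microspectroscopy: Mie-scatter QC, Savitzky-Golay second derivatives,
# band amplitudes, lipid-oxidation / lipid-protein ratios, and
# inclusion-vs-tissue comparison.

#' FTIR spectrum container
#'
#' @param wavenumber Ascending axis (cm^-1); full-range maps cover
#'   900-4000 cm^-1. Uniform spacing is required for derivative filtering.
#' @param absorbance Absorbance (AU), same length.
#' @return An `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumber, absorbance) {
  if (length(wavenumber) != length(absorbance)) {
    stop_input("wavenumber/absorbance length mismatch")
  }
  if (any(diff(wavenumber) <= 0)) stop_input("wavenumber must be ascending")
  structure(list(wavenumber = as.numeric(wavenumber),
                 absorbance = as.numeric(absorbance)),
            class = "ftir_spectrum")
}

#' Mie-scattering quality control
#'
#' Spectra dominated by Mie scattering show a strong broad sloping baseline.
#' A line is fitted over the 2000-3800 cm^-1 window (mostly band-free except
#' CH stretches); the spectrum is rejected when the absolute slope exceeds
#' the threshold.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param slope_threshold AU per cm^-1 (default 5e-5); `Inf` keeps all.
#' @param window Wavenumber window for the baseline fit.
#' @return List with `keep` (logical), `slope`, `reason`.
#' @export
qc_mie <- function(spectrum, slope_threshold = 5e-5, window = c(2000, 3800)) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  sel <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  if (sum(sel) < 3L) stop_input("QC window contains fewer than 3 points")
  fit <- stats::lm(spectrum$absorbance[sel] ~ spectrum$wavenumber[sel])
  slope <- unname(stats::coef(fit)[2])
  keep <- abs(slope) <= slope_threshold
  list(keep = keep, slope = slope,
       reason = if (keep) NA_character_ else
         sprintf("baseline slope %.2e exceeds threshold %.2e",
                 slope, slope_threshold))
}

# Savitzky-Golay convolution weights for the d-th derivative, window of
# `window` points, polynomial order `polyorder`, unit sample spacing.
sg_coefficients <- function(window, polyorder, deriv) {
  half <- (window - 1L) %/% 2L
  z <- (-half):half
  A <- outer(z, 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))  # rows = polynomial coefficients
  C[deriv + 1L, ] * factorial(deriv)
}

#' Savitzky-Golay second derivative of a spectrum
#'
#' 15-point window, polynomial order 2 by default. Requires a uniformly
#' spaced axis; the half-window at each edge is returned as `NA` rather than
#' extrapolated. Exact (to machine precision) for polynomials up to the
#' filter order.
#'
#' @param spectrum An [ftir_spectrum()].
#' @param window Odd window length <= number of points.
#' @param polyorder Polynomial order (>= 2 for a second derivative).
#' @return An `ftir_spectrum` whose `absorbance` holds d2A/dnu2 (AU cm^2),
#'   with NA in the invalid edge regions.
#' @export
second_derivative <- function(spectrum, window = 15L, polyorder = 2L) {
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  nu <- spectrum$wavenumber
  h <- diff(nu)
  if (max(h) - min(h) > 1e-6 * mean(h)) {
    stop_input("second_derivative requires a uniform wavenumber axis")
  }
  if (window %% 2L == 0L || window > length(nu)) {
    stop_input("window must be odd and <= spectrum length")
  }
  if (polyorder < 2L || polyorder >= window) {
    stop_input("polyorder must be >= 2 and < window")
  }
  w <- sg_coefficients(window, polyorder, 2L) / mean(h)^2
  half <- (window - 1L) %/% 2L
  n <- length(nu)
  d2 <- rep(NA_real_, n)
  conv <- stats::filter(spectrum$absorbance, rev(w), sides = 2)
  d2[(half + 1):(n - half)] <- conv[(half + 1):(n - half)]
  ftir_spectrum_deriv(nu, d2)
}

# derivative spectra may contain NA edges, so skip the finite check
ftir_spectrum_deriv <- function(wavenumber, values) {
  structure(list(wavenumber = wavenumber, absorbance = values),
            class = c("ftir_derivative", "ftir_spectrum"))
}

#' Band amplitude from a second-derivative spectrum
#'
#' Absorbance bands are concave down, so they appear as minima in the second
#' derivative; the amplitude is the absolute value of the local minimum
#' within `center +/- tol`.
#'
#' @param deriv Output of [second_derivative()].
#' @param center Band center (cm^-1). @param tol Search half-window (cm^-1).
#' @return List with `amplitude` (>= 0), `at` (cm^-1 of the minimum, NA if
#'   absent), `found` (logical; FALSE means amplitude 0, no local minimum).
#' @export
band_amplitude <- function(deriv, center, tol = 4) {
  stopifnot(inherits(deriv, "ftir_spectrum"))
  d <- deriv$absorbance
  n <- length(d)
  sel <- which(deriv$wavenumber >= center - tol &
               deriv$wavenumber <= center + tol & is.finite(d))
  # a band is a negative *local* minimum: deeper than both spectral
  # neighbours (not merely the flank of an adjacent band entering the
  # window); out-of-range/NA neighbours do not block
  is_min <- vapply(sel, function(j) {
    left <- if (j > 1 && is.finite(d[j - 1])) d[j - 1] else Inf
    right <- if (j < n && is.finite(d[j + 1])) d[j + 1] else Inf
    d[j] < 0 && d[j] <= left && d[j] <= right
  }, logical(1))
  cand <- sel[is_min]
  if (length(cand) == 0L) {
    return(list(amplitude = 0, at = NA_real_, found = FALSE))
  }
  j <- cand[which.min(d[cand])]
  list(amplitude = abs(d[j]), at = deriv$wavenumber[j], found = TRUE)
}

#' Second-derivative band ratio of one spectrum
#'
#' Default ratios follow common muscle-tissue usage: lipid/protein
#' 2925/1654 cm^-1 and lipid-oxidation (carbonyl/CH2) 1740/2925 cm^-1 (the
#' carbonyl default 1740 splits the two printed conventions 1739/1741; the
#' +/-4 cm^-1 search window covers both).
#'
#' @param spectrum An [ftir_spectrum()] (raw; the derivative is computed
#'   internally).
#' @param numerator,denominator Band centers (cm^-1).
#' @param tol Search half-window. @param window,polyorder SG parameters.
#' @return A `band_ratio`: list with `value` (NA + `undefined` flag when the
#'   denominator amplitude is 0), `numerator`, `denominator`, amplitudes.
#' @export
band_ratio <- function(spectrum, numerator = 2925, denominator = 1654,
                       tol = 4, window = 15L, polyorder = 2L) {
  d2 <- second_derivative(spectrum, window, polyorder)
  num <- band_amplitude(d2, numerator, tol)
  den <- band_amplitude(d2, denominator, tol)
  undef <- den$amplitude == 0
  structure(list(numerator_center = numerator,
                 denominator_center = denominator,
                 value = if (undef) NA_real_ else num$amplitude / den$amplitude,
                 undefined = undef,
                 numerator_amplitude = num$amplitude,
                 denominator_amplitude = den$amplitude), class = "band_ratio")
}

# per-pixel ratio values for a map
map_ratios <- function(map, numerator, denominator, tol = 4) {
  vapply(seq_len(nrow(map$spectra)), function(i) {
    sp <- ftir_spectrum(map$wavenumber, map$spectra[i, ])
    band_ratio(sp, numerator, denominator, tol = tol)$value
  }, numeric(1))
}

#' Compare a band ratio between inclusion and surrounding tissue
#'
#' Computes the per-pixel second-derivative band ratio and compares the two
#' regions with a two-sided unequal-variance (Welch) t-test. Significance is
#' flagged at p < 0.005.
#'
#' @param map An `ftir_map` (see [gen_ftir_map()]).
#' @param numerator,denominator Band centers (cm^-1).
#' @param min_n Minimum pixels per region (default 10).
#' @param regions Two region labels to compare.
#' @return List with `t`, `p`, `significant`, per-region `n`, `median`,
#'   `iqr`, and the per-pixel `values`.
#' @export
compare_regions <- function(map, numerator = 1740, denominator = 2925,
                            min_n = 10, regions = c("inclusion", "surround")) {
  stopifnot(inherits(map, "ftir_map"))
  vals <- map_ratios(map, numerator, denominator)
  g1 <- vals[map$region == regions[1] & is.finite(vals)]
  g2 <- vals[map$region == regions[2] & is.finite(vals)]
  if (length(g1) < min_n || length(g2) < min_n) {
    stop_input("insufficient pixels: %s n=%d, %s n=%d (min %d)",
               regions[1], length(g1), regions[2], length(g2), min_n)
  }
  if (stats::sd(g1) == 0 && stats::sd(g2) == 0 && mean(g1) == mean(g2)) {
    tt <- list(statistic = c(t = 0), p.value = 1)
  } else {
    tt <- stats::t.test(g1, g2, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < 0.005,
       n = c(length(g1), length(g2)),
       median = c(stats::median(g1), stats::median(g2)),
       iqr = c(stats::IQR(g1), stats::IQR(g2)),
       regions = regions, values = vals)
}
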