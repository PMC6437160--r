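# Midpoint-potential determination: spectroelectrochemical (OTTLE) Nernst
# analysis and square-wave voltammetry peak extraction, with
# reference-electrode conversion to SHE.

# Reference electrode potentials vs SHE at 25 C (standard table values).
REFERENCE_OFFSETS_V <- c("SHE" = 0, "SCE" = 0.2412, "Ag/AgCl/3M KCl" = 0.210)

#' Convert a potential between reference electrodes
#'
#' Additive shift using standard 25 C offsets vs SHE:
#' SCE +0.2412 V, Ag/AgCl/3M KCl +0.210 V.
#'
#' @param E Potential(s) in volts vs `from`.
#' @param from,to Reference names: `"SHE"`, `"SCE"`, `"Ag/AgCl/3M KCl"`.
#' @return Potential(s) vs `to`. Round trips are exact.
#' @export
convert_reference <- function(E, from, to = "SHE") {
  for (r in c(from, to)) {
    if (!r %in% names(REFERENCE_OFFSETS_V)) {
      stop_input("unknown reference electrode '%s' (known: %s)", r,
                 paste(names(REFERENCE_OFFSETS_V), collapse = ", "))
    }
  }
  E + REFERENCE_OFFSETS_V[[from]] - REFERENCE_OFFSETS_V[[to]]
}

#' Redox titration container
#'
#' @param potentials Applied potentials (V), >= 5 recommended.
#' @param wavelengths Spectral axis (nm).
#' @param absorbance Matrix wavelengths x potentials, finite.
#' @param reference Reference electrode of `potentials`.
#' @param temperature_C Cell temperature.
#' @return A `redox_titration`.
#' @export
redox_titration <- function(potentials, wavelengths, absorbance,
                            reference = "SHE", temperature_C = 25) {
  if (!is.matrix(absorbance) ||
      nrow(absorbance) != length(wavelengths) ||
      ncol(absorbance) != length(potentials)) {
    stop_input("absorbance must be a wavelengths x potentials matrix")
  }
  if (any(!is.finite(absorbance))) stop_input("absorbance must be finite")
  if (length(potentials) < 2L) stop_input("need >= 2 potentials")
  structure(list(potentials = potentials, wavelengths = wavelengths,
                 absorbance = absorbance, reference = reference,
                 temperature_C = temperature_C), class = "redox_titration")
}

#' Two-wavelength Nernst progress variables
#'
#' Uses one wavelength where the reduced species absorbs more
#' (`lambda_red`, deoxy Soret by default) and one where the oxidized
#' species absorbs more (`lambda_ox`, met Soret). With `A^max`/`A^min` the
#' extreme absorbances observed at each wavelength across the titration,
#' the progress signals are
#' `x_red(E) = (A_red(E) - A^min_red) + (A^max_ox - A_ox(E))` (both terms
#' proportional to the reduced fraction) and
#' `x_ox(E)  = (A^max_red - A_red(E)) + (A_ox(E) - A^min_ox)` (both
#' proportional to the oxidized fraction). Because the two signals share
#' the same proportionality constant, `log10(x_ox / x_red)` equals
#' `log10([ox]/[red])` exactly on noiseless data even when the analysis
#' bands overlap. Computed where both signals exceed a floor.
#'
#' @param titration A [redox_titration()].
#' @param lambda_red,lambda_ox Analysis wavelengths (nm), must be on grid.
#' @param floor_frac Points with either signal below `floor_frac` of its
#'   range are excluded (endpoint anchoring makes those logs unstable).
#' @return data.frame with `E`, `x_red`, `x_ox`, `log_ratio`, `usable`.
#' @export
nernst_variable <- function(titration, lambda_red = 434, lambda_ox = 409,
                            floor_frac = 0.05) {
  stopifnot(inherits(titration, "redox_titration"))
  ir <- match(lambda_red, titration$wavelengths)
  io <- match(lambda_ox, titration$wavelengths)
  if (is.na(ir) || is.na(io)) {
    stop_input("lambda_red/lambda_ox must lie on the spectral grid")
  }
  a_red <- titration$absorbance[ir, ]
  a_ox <- titration$absorbance[io, ]
  x_red <- (a_red - min(a_red)) + (max(a_ox) - a_ox)
  x_ox <- (max(a_red) - a_red) + (a_ox - min(a_ox))
  span <- diff(range(a_red)) + diff(range(a_ox))
  floor_x <- floor_frac * span
  usable <- x_red > floor_x & x_ox > floor_x
  if (sum(usable) < 2L) {
    stop_input("fewer than 2 usable points after flooring")
  }
  # endpoints where one signal vanishes map to +/-Inf, 0/0 to NA
  log_ratio <- suppressWarnings(log10(x_ox / x_red))
  log_ratio[x_ox == 0 & x_red == 0] <- NA_real_
  data.frame(E = titration$potentials, x_red = x_red, x_ox = x_ox,
             log_ratio = log_ratio, usable = usable)
}

#' Fit the Nernst line and extract E0' and the electron count
#'
#' Ordinary least squares of applied potential on log10(ox/red). The
#' midpoint potential is the potential at zero log-ratio (the intercept);
#' the electron count is `round(s / |slope|)` with `s = RT ln10 / F`
#' (59.16 mV/decade at 25 C).
#'
#' @param E Applied potentials (V). @param log_ratio log10(ox/red) values.
#' @param reference Reference electrode of `E`; the result is converted to
#'   SHE. @param temperature_C Temperature for the theoretical slope.
#' @return A `nernst_fit`: `E0` (V vs SHE), `slope` (V/decade),
#'   `n_electrons`, `r2`, `points_used`, `flag`.
#' @export
fit_nernst <- function(E, log_ratio, reference = "SHE", temperature_C = 25) {
  ok <- is.finite(E) & is.finite(log_ratio)
  E <- E[ok]; log_ratio <- log_ratio[ok]
  if (length(E) < 2L) stop_input("need >= 2 points")
  if (length(E) < 5L) {
    warning("Nernst plots should consist of at least five points",
            call. = FALSE)
  }
  fit <- stats::lm(E ~ log_ratio)
  cf <- stats::coef(fit)
  slope <- unname(cf[2])
  s_theory <- nernst_slope(temperature_C)
  flag <- if (slope <= 0) "slope sign inconsistent with reduction convention"
          else NA_character_
  n <- max(1L, as.integer(round(s_theory / abs(slope))))
  structure(list(E0 = convert_reference(unname(cf[1]), reference, "SHE"),
                 slope = slope, n_electrons = n,
                 r2 = suppressWarnings(summary(fit)$r.squared),
                 points_used = length(E),
                 reference = "SHE", flag = flag), class = "nernst_fit")
}

#' Full OTTLE analysis: titration to NernstFit
#'
#' Convenience wrapper chaining [nernst_variable()] and [fit_nernst()].
#'
#' @inheritParams nernst_variable
#' @return A `nernst_fit`.
#' @export
fit_ottle <- function(titration, lambda_red = 434, lambda_ox = 409,
                      floor_frac = 0.05) {
  nv <- nernst_variable(titration, lambda_red, lambda_ox, floor_frac)
  nv <- nv[nv$usable, ]
  fit_nernst(nv$E, nv$log_ratio, reference = titration$reference,
             temperature_C = titration$temperature_C)
}

#' Square-wave voltammetry peak potential
#'
#' Fits a linear baseline on flanking windows at both scan ends, subtracts
#' it, locates the maximum net current, and refines the peak position with a
#' parabola through the 5 points around the maximum. Plateau ties break
#' toward the lowest potential.
#'
#' @param vg A `voltammogram` (from [gen_swv()] or [read_voltammogram()]).
#' @param baseline_window Width (V) of each flanking window used for the
#'   baseline fit.
#' @param to Reference to report in (default SHE).
#' @return List with `E_peak` (V vs `to`), `E_peak_raw` (scan reference),
#'   `reference`, `flag` (`"truncated peak"` when the maximum sits at a scan
#'   edge).
#' @export
swv_peak <- function(vg, baseline_window = 0.06, to = "SHE") {
  stopifnot(inherits(vg, "voltammogram"))
  E <- vg$potential; i <- vg$net_current
  if (any(diff(E) < 0)) { o <- order(E); E <- E[o]; i <- i[o] }
  lo <- E <= min(E) + baseline_window
  hi <- E >= max(E) - baseline_window
  base_idx <- lo | hi
  bl <- stats::lm(i[base_idx] ~ E[base_idx])
  corr <- i - (stats::coef(bl)[1] + stats::coef(bl)[2] * E)
  peak_val <- max(corr)
  j <- which(corr == peak_val)[1]  # plateau tie -> lowest potential
  flag <- NA_character_
  # truncated: maximum sits against a scan edge, or the signal is still a
  # substantial fraction of the peak at either end of the scan
  edge_high <- peak_val > 0 &&
    max(corr[1], corr[length(E)]) > 0.5 * peak_val
  if (j <= 2 || j >= length(E) - 1 || edge_high) {
    flag <- "truncated peak"
    Ep <- E[j]
  } else {
    idx <- (j - 2):(j + 2)
    pf <- stats::lm(corr[idx] ~ poly(E[idx], 2, raw = TRUE))
    a <- stats::coef(pf)
    Ep <- if (a[3] < 0) -a[2] / (2 * a[3]) else E[j]
    if (Ep < E[j - 2] || Ep > E[j + 2]) Ep <- E[j]
  }
  list(E_peak = unname(convert_reference(Ep, vg$reference, to)),
       E_peak_raw = unname(Ep), reference = to, flag = flag)
}
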