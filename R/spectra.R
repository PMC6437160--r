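# Three-state myoglobin spectral model (deoxy / oxy / met).
#
# Band centers: the oxy form is anchored to the classic oxymyoglobin
# signature (Soret 418 nm, Q bands 545/580 nm). Deoxy (Soret 434, Q 556)
# and met (Soret 409, bands 505/635) use standard literature positions and
# are configurable. Amplitudes are relative molar absorptivities; absolute
# calibration is out of scope.

mb_band_defaults <- function() {
  list(
    deoxy = data.frame(center = c(434, 556),
                       amp    = c(110, 12),
                       width  = c(14, 14)),
    oxy   = data.frame(center = c(418, 545, 580),
                       amp    = c(120, 13, 12),
                       width  = c(12, 11, 11)),
    met   = data.frame(center = c(409, 505, 635),
                       amp    = c(150, 9, 3.5),
                       width  = c(14, 16, 16))
  )
}

gaussian_sum <- function(x, bands) {
  y <- numeric(length(x))
  for (i in seq_len(nrow(bands))) {
    y <- y + bands$amp[i] * exp(-0.5 * ((x - bands$center[i]) / bands$width[i])^2)
  }
  y
}

#' Reference spectrum of one myoglobin redox/ligation state
#'
#' Builds a sum-of-Gaussians molar-absorptivity curve for the deoxy, oxy or
#' met state. Units are relative (see the methods vignette).
#'
#' @param state One of `"deoxy"`, `"oxy"`, `"met"`.
#' @param wavelengths Strictly increasing wavelength grid (nm) covering at
#'   least 350-700 nm.
#' @param bands Optional band table (`data.frame` with `center`, `amp`,
#'   `width` in nm) overriding the built-in defaults for this state.
#' @return A `state_spectrum`: list with `state`, `wavelengths`, `epsilon`.
#' @export
basis_spectrum <- function(state, wavelengths = seq(350, 700, by = 1),
                           bands = NULL) {
  state <- match.arg(state, c("deoxy", "oxy", "met"))
  if (any(diff(wavelengths) <= 0)) {
    stop_input("wavelengths must be strictly increasing")
  }
  if (min(wavelengths) > 350 || max(wavelengths) < 700) {
    stop_input("wavelength grid must cover 350-700 nm")
  }
  if (is.null(bands)) bands <- mb_band_defaults()[[state]]
  structure(list(state = state, wavelengths = wavelengths,
                 epsilon = gaussian_sum(wavelengths, bands)),
            class = "state_spectrum")
}

#' Three-state spectral basis
#'
#' @param wavelengths Wavelength grid (nm), 350-700 nm coverage required.
#' @param bands Optional named list of band tables per state.
#' @return A `mb_basis`: list with `wavelengths` and an `epsilon` matrix with
#'   one column per state (deoxy, oxy, met).
#' @export
mb_basis <- function(wavelengths = seq(350, 700, by = 1), bands = NULL) {
  states <- c("deoxy", "oxy", "met")
  eps <- sapply(states, function(s) {
    basis_spectrum(s, wavelengths, bands = bands[[s]])$epsilon
  })
  colnames(eps) <- states
  structure(list(wavelengths = wavelengths, epsilon = eps),
            class = "mb_basis")
}

#' State fractions of a myoglobin sample
#'
#' @param f_deoxy,f_oxy,f_met Non-negative fractions; renormalized to sum 1.
#' @return A named numeric vector of class `state_fractions`.
#' @export
state_fractions <- function(f_deoxy = 0, f_oxy = 0, f_met = 0) {
  f <- c(deoxy = f_deoxy, oxy = f_oxy, met = f_met)
  if (any(!is.finite(f)) || any(f < 0)) {
    stop_input("fractions must be finite and non-negative")
  }
  s <- sum(f)
  if (s <= 0) stop_input("at least one fraction must be positive")
  structure(f / s, class = "state_fractions")
}

#' Compose a spectrum from state fractions (Beer-Lambert mixing)
#'
#' @param fractions A `state_fractions` or named vector over the basis states.
#' @param basis An `mb_basis`.
#' @param concentration Total heme concentration (relative units).
#' @param path Optical path length (relative units).
#' @return Numeric absorbance vector on `basis$wavelengths`.
#' @export
compose <- function(fractions, basis, concentration = 1, path = 1) {
  stopifnot(inherits(basis, "mb_basis"))
  f <- unclass(fractions)
  if (is.null(names(f)) || !all(colnames(basis$epsilon) %in% names(f))) {
    stop_input("fractions must be named over the basis states")
  }
  drop(basis$epsilon %*% f[colnames(basis$epsilon)]) * concentration * path
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b||, x >= 0.
nnls_solve <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol * max(1, max(abs(w))))) {
    iter <- iter + 1L
    if (iter > 30L * n) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- drop(qr.coef(qr(Ap), b))
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) {
        x <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Decompose an observed spectrum into state fractions
#'
#' Non-negative least squares against the basis, followed by renormalization
#' to sum 1 (so the result is invariant to overall concentration).
#'
#' @param spectrum Absorbance vector on the basis wavelength grid.
#' @param basis An `mb_basis`.
#' @return List with `fractions` (a `state_fractions`), `scale` (fitted total
#'   concentration x path) and `residual` (L2 norm of the fit residual).
#' @export
decompose <- function(spectrum, basis) {
  stopifnot(inherits(basis, "mb_basis"))
  if (length(spectrum) != length(basis$wavelengths)) {
    stop_input("spectrum length (%d) does not match basis grid (%d)",
               length(spectrum), length(basis$wavelengths))
  }
  if (length(spectrum) < 3L) stop_input("need >= 3 wavelengths")
  if (qr(basis$epsilon)$rank < ncol(basis$epsilon)) {
    stop_input("basis is singular (duplicate state spectra?)")
  }
  x <- nnls_solve(basis$epsilon, spectrum)
  resid <- sqrt(sum((spectrum - basis$epsilon %*% x)^2))
  s <- sum(x)
  if (s <= 0) {
    f <- structure(c(deoxy = NA_real_, oxy = NA_real_, met = NA_real_),
                   class = "state_fractions")
    return(list(fractions = f, scale = 0, residual = resid))
  }
  list(fractions = state_fractions(x[1], x[2], x[3]),
       scale = s, residual = resid)
}
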