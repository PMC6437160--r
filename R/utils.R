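#' @keywords internal
"_PACKAGE"

# Run expr with a local, restorable RNG state. All generators funnel their
# seed through here so no call disturbs the user's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input("'%s' must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    stop_input("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

#' Noise specification for synthetic generators
#'
#' Describes the iid Gaussian noise added by every synthetic-data generator.
#' The default sigma of 0.002 AU is typical stopped-flow absorbance noise.
#'
#' @param sigma_abs Standard deviation on the absorbance (or current /
#'   log-expression) scale, must be >= 0.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   output. `NULL` leaves the current RNG stream untouched.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(sigma_abs = 0.002, seed = NULL) {
  check_number(sigma_abs, "sigma_abs", lower = 0)
  if (!is.null(seed)) check_number(seed, "seed")
  structure(list(sigma_abs = sigma_abs, seed = seed), class = "noise_spec")
}

as_noise_spec <- function(noise) {
  if (is.null(noise)) return(noise_spec(0, NULL))
  if (inherits(noise, "noise_spec")) return(noise)
  if (is.numeric(noise) && length(noise) == 1L) return(noise_spec(noise, NULL))
  stop_input("'noise' must be a noise_spec, a single sigma, or NULL")
}

# Gaussian noise helper honouring a noise_spec.
add_noise <- function(x, noise) {
  noise <- as_noise_spec(noise)
  if (noise$sigma_abs == 0) return(x)
  with_seed(noise$seed, x + stats::rnorm(length(x), 0, noise$sigma_abs))
}
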