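#' Default compartmental diffusivities
#'
#' Fixed apparent diffusivities of the restricted, hindered and free water
#' compartments, in mm^2/s. Keeping D1 < D2 < D3 fixed linearizes the
#' three-compartment model so that only the volume fractions are estimated.
#'
#' @format Numeric vector of length 3: `c(D1 = 1e-3, D2 = 2e-3, D3 = 3e-3)`.
#' @export
rsi_diffusivities <- c(D1 = 1.0e-3, D2 = 2.0e-3, D3 = 3.0e-3)

#' Multi-b-value diffusion weighting schedule
#'
#' Constructs and validates an ordered schedule of diffusion weightings
#' (b-values, s/mm^2). The default is the 12-point schedule used for
#' lung multi-b-value DWI: 0, 25, 50, 100, 150, 200, 400, 600, 800, 1000,
#' 1500, 2000 s/mm^2.
#'
#' @param values Numeric vector of b-values in s/mm^2. Must start at 0, be
#'   strictly increasing, and contain at least 4 points (the fit needs more
#'   observations than free amplitudes).
#' @return An object of class `bvalue_schedule` (a validated numeric vector).
#' @examples
#' sched <- bvalue_schedule()
#' length(sched)
#' @export
bvalue_schedule <- function(values = c(0, 25, 50, 100, 150, 200,
                                       400, 600, 800, 1000, 1500, 2000)) {
  values <- as.numeric(values)
  if (length(values) < 4)
    abort_invalid("a b-value schedule needs at least 4 values")
  if (anyNA(values) || any(values < 0))
    abort_invalid("b-values must be non-negative and finite")
  if (values[1] != 0)
    abort_invalid("the first b-value must be 0 (unattenuated reference)")
  if (any(diff(values) <= 0))
    abort_invalid("b-values must be strictly increasing")
  structure(values, class = "bvalue_schedule")
}

#' Read a b-value file
#'
#' Reads whitespace-separated b-values (FSL-style single-line convention)
#' and validates them as a schedule.
#'
#' @param path Path to a text file of whitespace-separated b-values.
#' @return A [bvalue_schedule()].
#' @export
read_bvals <- function(path) {
  if (!file.exists(path)) abort_invalid(sprintf("b-value file not found: %s", path))
  bvalue_schedule(scan(path, what = numeric(), quiet = TRUE))
}

#' Three-compartment signal model parameters
#'
#' Volume fractions of the restricted (f1), hindered (f2) and free (f3)
#' water compartments together with their fixed diffusivities and the
#' unattenuated amplitude S0. Fractions must lie on the unit simplex;
#' inputs within `tol` of the simplex are renormalized.
#'
#' @param f1,f2,f3 Volume fractions, each in \[0, 1\], summing to 1.
#' @param D Diffusivities `c(D1, D2, D3)` in mm^2/s, strictly increasing.
#' @param S0 Unattenuated signal amplitude (> 0), arbitrary units.
#' @param tol Absolute tolerance for the simplex constraint.
#' @return An object of class `compartment_params`.
#' @examples
#' compartment_params(0.7, 0.1, 0.2)
#' @export
compartment_params <- function(f1, f2, f3, D = rsi_diffusivities, S0 = 1,
                               tol = 1e-9) {
  f <- c(f1, f2, f3)
  if (anyNA(f) || any(f < -tol))
    abort_invalid("volume fractions must be non-negative")
  if (abs(sum(f) - 1) > tol)
    abort_invalid(sprintf("volume fractions sum to %.12g, not 1", sum(f)))
  f <- pmax(f, 0)
  f <- f / sum(f)
  D <- as.numeric(D)
  if (length(D) != 3 || any(diff(D) <= 0))
    abort_invalid("diffusivities must satisfy D1 < D2 < D3")
  if (!is.numeric(S0) || length(S0) != 1 || S0 <= 0)
    abort_invalid("S0 must be a single positive number")
  structure(list(f = f, D = D, S0 = S0), class = "compartment_params")
}

#' Mono-exponential signal model parameters
#'
#' @param ADC Apparent diffusion coefficient, mm^2/s (> 0).
#' @param S0 Unattenuated signal amplitude (> 0).
#' @return An object of class `mono_exp_params`.
#' @export
mono_exp_params <- function(ADC, S0 = 1) {
  if (!is.numeric(ADC) || length(ADC) != 1 || ADC <= 0)
    abort_invalid("ADC must be a single positive number")
  if (!is.numeric(S0) || length(S0) != 1 || S0 <= 0)
    abort_invalid("S0 must be a single positive number")
  structure(list(ADC = ADC, S0 = S0), class = "mono_exp_params")
}

#' Mono-exponential diffusion signal
#'
#' Signal attenuation of the mono-exponential (ADC) model,
#' `S(b) = S0 * exp(-b * ADC)`.
#'
#' @param params A [mono_exp_params()] object.
#' @param b Non-negative b-values, s/mm^2 (vectorized).
#' @return Signal amplitudes, same length as `b`.
#' @export
mono_exp_signal <- function(params, b) {
  stopifnot(inherits(params, "mono_exp_params"))
  b <- as.numeric(b)
  if (anyNA(b) || any(b < 0)) abort_invalid("b-values must be non-negative")
  params$S0 * exp(-b * params$ADC)
}

#' Three-compartment (RSI) diffusion signal
#'
#' Forward tri-exponential model
#' `S(b) = S0 * (f1 exp(-b D1) + f2 exp(-b D2) + f3 exp(-b D3))`
#' with fixed diffusivities D1 < D2 < D3.
#'
#' @param params A [compartment_params()] object.
#' @param b Non-negative b-values, s/mm^2 (vectorized).
#' @return Signal amplitudes, same length as `b`.
#' @examples
#' p <- compartment_params(0.5, 0.3, 0.2)
#' tri_exp_signal(p, c(0, 1000))
#' @export
tri_exp_signal <- function(params, b) {
  stopifnot(inherits(params, "compartment_params"))
  b <- as.numeric(b)
  if (anyNA(b) || any(b < 0)) abort_invalid("b-values must be non-negative")
  basis <- exp(-outer(b, params$D))     # n_b x 3
  params$S0 * drop(basis %*% params$f)
}

#' Add Rician noise to magnitude signals
#'
#' Magnitude-MRI measurement noise: each noisy sample is
#' `sqrt((s + g1)^2 + g2^2)` with `g1, g2` independent zero-mean Gaussians
#' of standard deviation `sigma`. With `sigma = 0` the input is returned
#' unchanged. At high SNR this reduces to additive Gaussian noise; at zero
#' signal it is Rayleigh.
#'
#' @param signal Non-negative amplitude array (any shape; shape preserved).
#' @param sigma Gaussian channel noise standard deviation (>= 0), in the
#'   same units as `signal`.
#' @param seed Optional integer seed for reproducibility; if `NULL`, the
#'   current RNG state is used.
#' @return Noisy amplitudes with the same shape as `signal`.
#' @examples
#' s <- tri_exp_signal(compartment_params(0.7, 0.1, 0.2, S0 = 100),
#'                     bvalue_schedule())
#' add_rician_noise(s, sigma = 2, seed = 1)
#' @export
add_rician_noise <- function(signal, sigma, seed = NULL) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma < 0)
    abort_invalid("sigma must be a single non-negative number")
  if (anyNA(signal) || any(signal < 0))
    abort_invalid("signals must be non-negative")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) set.seed(seed)
  n <- length(signal)
  g1 <- stats::rnorm(n, 0, sigma)
  g2 <- stats::rnorm(n, 0, sigma)
  out <- sqrt((as.numeric(signal) + g1)^2 + g2^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}
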