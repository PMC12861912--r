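#' Fit the mono-exponential ADC model to one voxel
#'
#' Ordinary least squares of `log(amplitude)` against b over all points with
#' strictly positive amplitude; `ADC = -slope`, `S0 = exp(intercept)`. The
#' log-linear fit is exact on noiseless mono-exponential input. Unweighted
#' OLS over the full schedule is used; no b-value subset is dropped.
#'
#' @param amplitudes Signal amplitudes, one per scheduled b-value.
#' @param schedule A [bvalue_schedule()] (or numeric vector of b-values).
#' @return A [mono_exp_params()] object.
#' @section Errors: fewer than 2 positive amplitudes, or a non-positive
#'   fitted ADC, raise an unfittable-voxel condition; callers fitting maps
#'   catch it and drop the voxel from the output mask.
#' @examples
#' sched <- bvalue_schedule()
#' s <- mono_exp_signal(mono_exp_params(1.11e-3, S0 = 500), sched)
#' fit_adc(s, sched)$ADC
#' @export
fit_adc <- function(amplitudes, schedule) {
  b <- as.numeric(schedule)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(b))
    abort_invalid("amplitudes and schedule lengths differ")
  pos <- is.finite(amplitudes) & amplitudes > 0
  if (sum(pos) < 2)
    abort_unfittable("fewer than 2 positive amplitudes; ADC not identifiable")
  x <- b[pos]
  y <- log(amplitudes[pos])
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  adc <- -slope
  if (!is.finite(adc) || adc <= 0)
    abort_unfittable("fitted ADC is non-positive; voxel excluded")
  mono_exp_params(ADC = adc, S0 = exp(intercept))
}

# Lawson-Hanson active-set non-negative least squares. Handles the
# degenerate exact-fit cases this package produces constantly (signals
# lying exactly on one basis vector leave a zero residual).
nnls_solve <- function(A, b) {
  n <- ncol(A)
  tol <- 10 * .Machine$double.eps * norm(A, "F") * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))
  iter <- 0
  while (any(!passive) && any(w[!passive] > tol) && iter < 30 * n) {
    iter <- iter + 1
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      if (all(s[passive] > 0)) break
      viol <- passive & (s <= 0)
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Fit the three-compartment RSI model to one voxel
#'
#' Non-negative linear least squares of the amplitudes against the fixed
#' basis `exp(-b * Di)`. The unattenuated amplitude is recovered as the sum
#' of the non-negative basis weights, `S0 = c1 + c2 + c3`, and the volume
#' fractions as `fi = ci / S0`, so the simplex constraint holds exactly by
#' construction and the noisy b = 0 measurement is never divided by.
#'
#' @param amplitudes Signal amplitudes, one per scheduled b-value.
#' @param schedule A [bvalue_schedule()] (or numeric vector, length >= 4).
#' @param D Fixed diffusivities `c(D1, D2, D3)`, mm^2/s; not estimated.
#' @return A [compartment_params()] object.
#' @examples
#' sched <- bvalue_schedule()
#' s <- tri_exp_signal(compartment_params(0.5, 0.3, 0.2, S0 = 1000), sched)
#' fit_rsi(s, sched)$f
#' @export
fit_rsi <- function(amplitudes, schedule, D = rsi_diffusivities) {
  b <- as.numeric(schedule)
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != length(b))
    abort_invalid("amplitudes and schedule lengths differ")
  if (length(b) < 4)
    abort_invalid("at least 4 b-values are needed to fit 3 amplitudes")
  if (anyNA(amplitudes) || all(amplitudes == 0))
    abort_unfittable("all-zero or missing signal; RSI fit undefined")
  D <- as.numeric(D)
  basis <- exp(-outer(b, D))
  cc <- nnls_solve(basis, amplitudes)
  s0 <- sum(cc)
  if (s0 <= 0)
    abort_unfittable("non-negative least squares returned a zero solution")
  compartment_params(cc[1] / s0, cc[2] / s0, cc[3] / s0, D = D, S0 = s0)
}

#' Fit ADC and RSI parameter maps over an image stack
#'
#' Applies [fit_adc()] and [fit_rsi()] to every masked voxel of a 3D
#' (x, y, b) or 4D (x, y, z, b) signal stack whose last dimension indexes
#' the b-value schedule. Unfittable voxels (all-zero signal, fewer than two
#' positive amplitudes, non-positive fitted ADC) are removed from the
#' corresponding output mask; other voxels are unaffected. Deterministic
#' for fixed input.
#'
#' @param stack Numeric array; last dimension must match `length(schedule)`.
#' @param schedule A [bvalue_schedule()].
#' @param mask Logical array over the spatial dimensions (default: all
#'   voxels). Must be conformable with `stack`.
#' @param D Fixed diffusivities for the RSI fit.
#' @return A named list of `parameter_map` objects (`ADC`, `f1`, `f2`,
#'   `f3`), each with fields `name`, `values` (NA outside its mask) and
#'   `mask`.
#' @export
fit_parameter_maps <- function(stack, schedule, mask = NULL,
                               D = rsi_diffusivities) {
  dm <- dim(stack)
  if (is.null(dm) || length(dm) < 2)
    abort_invalid("stack must be an array with a trailing b dimension")
  nb <- dm[length(dm)]
  if (nb != length(schedule))
    abort_invalid(sprintf("stack has %d volumes but schedule has %d b-values",
                          nb, length(schedule)))
  sdim <- dm[-length(dm)]
  nvox <- prod(sdim)
  sig <- matrix(stack, nrow = nvox, ncol = nb)   # voxels x b
  if (is.null(mask)) mask <- array(TRUE, dim = sdim)
  if (!identical(as.integer(dim(mask)), as.integer(sdim)))
    abort_invalid("mask dimensions do not match the spatial stack dimensions")

  adc_vals <- rep(NA_real_, nvox)
  f_vals <- matrix(NA_real_, nvox, 3)
  adc_mask <- rsi_mask <- rep(FALSE, nvox)
  for (v in which(as.logical(mask))) {
    fit <- tryCatch(fit_adc(sig[v, ], schedule),
                    rsilung_unfittable_voxel = function(e) NULL)
    if (!is.null(fit)) {
      adc_vals[v] <- fit$ADC
      adc_mask[v] <- TRUE
    }
    fit <- tryCatch(fit_rsi(sig[v, ], schedule, D = D),
                    rsilung_unfittable_voxel = function(e) NULL)
    if (!is.null(fit)) {
      f_vals[v, ] <- fit$f
      rsi_mask[v] <- TRUE
    }
  }
  shape <- function(x) array(x, dim = sdim)
  mk <- function(name, values, msk) {
    structure(list(name = name, values = shape(values), mask = shape(msk)),
              class = "parameter_map")
  }
  list(ADC = mk("ADC", adc_vals, adc_mask),
       f1  = mk("f1", f_vals[, 1], rsi_mask),
       f2  = mk("f2", f_vals[, 2], rsi_mask),
       f3  = mk("f3", f_vals[, 3], rsi_mask))
}

#' Summarize parameter maps over a region of interest
#'
#' Arithmetic mean of each parameter map over the ROI voxels, restricted to
#' the voxels that survived fitting (each map's own mask).
#'
#' @param maps List of parameter maps from [fit_parameter_maps()].
#' @param roi_mask Logical array, same spatial shape as the maps.
#' @param roi_id Identifier carried into the output.
#' @return A one-row data frame with `roi_id`, one column per map (mean
#'   value) and `n_voxels` (minimum voxel count used across maps).
#' @export
summarize_roi <- function(maps, roi_mask, roi_id = "roi") {
  means <- list(roi_id = roi_id)
  n_used <- integer(0)
  for (m in maps) {
    sel <- as.logical(roi_mask) & as.logical(m$mask)
    if (!any(sel))
      abort("ROI does not intersect the fitted mask", class = "rsilung_empty_roi")
    means[[m$name]] <- mean(m$values[sel])
    n_used <- c(n_used, sum(sel))
  }
  means$n_voxels <- min(n_used)
  as.data.frame(means, stringsAsFactors = FALSE)
}
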