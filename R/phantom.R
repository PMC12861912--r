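#' Specify a synthetic lesion phantom
#'
#' Describes a 2D image with an elliptical "lesion" carrying known
#' three-compartment ground truth, surrounded by free-water background
#' (f = (0, 0, 1), same S0). The ground truth is either constant over the
#' lesion or a linear ramp between two simplex-valid parameter sets along
#' the x axis of the lesion extent.
#'
#' @param shape Image dimensions `c(nx, ny)`.
#' @param center Ellipse center `c(cx, cy)` in voxel coordinates.
#' @param axes Ellipse semi-axes `c(ax, ay)` in voxels.
#' @param truth A [compartment_params()] object (lesion ground truth, or
#'   the ramp start).
#' @param truth_end Optional [compartment_params()]; if given, fractions
#'   ramp linearly from `truth` to `truth_end` across the lesion x extent.
#' @param sigma Rician channel noise standard deviation (>= 0).
#' @param schedule A [bvalue_schedule()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32), center = shape / 2,
                         axes = c(6, 6), truth, truth_end = NULL,
                         sigma = 0, schedule = bvalue_schedule()) {
  stopifnot(inherits(truth, "compartment_params"))
  if (!is.null(truth_end)) stopifnot(inherits(truth_end, "compartment_params"))
  shape <- as.integer(shape); center <- as.numeric(center); axes <- as.numeric(axes)
  if (length(shape) != 2 || any(shape < 3))
    abort_invalid("phantom shape must be two dimensions of at least 3 voxels")
  if (any(axes <= 0)) abort_invalid("ellipse semi-axes must be positive")
  if (center[1] - axes[1] < 1 || center[1] + axes[1] > shape[1] ||
      center[2] - axes[2] < 1 || center[2] + axes[2] > shape[2])
    abort_invalid("lesion ellipse must lie fully inside the image")
  if (!is.numeric(sigma) || sigma < 0) abort_invalid("sigma must be >= 0")
  structure(list(shape = shape, center = center, axes = axes,
                 truth = truth, truth_end = truth_end, sigma = sigma,
                 schedule = schedule),
            class = "phantom_spec")
}

#' Generate a phantom signal stack with known ground truth
#'
#' Evaluates the three-compartment forward model voxelwise over the
#' schedule, fills the background with free-water signal and adds Rician
#' noise. Reproducible given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A list with `stack` (x, y, b array), `truth` (list of ground
#'   truth `parameter_map`s f1, f2, f3 over the lesion), `roi_mask`
#'   (logical lesion mask) and `schedule`.
#' @examples
#' p <- phantom_spec(truth = compartment_params(0.7, 0.1, 0.2, S0 = 100))
#' ph <- generate_phantom(p, seed = 1)
#' sum(ph$roi_mask)
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  nx <- spec$shape[1]; ny <- spec$shape[2]
  b <- as.numeric(spec$schedule); nb <- length(b)
  xs <- matrix(seq_len(nx), nx, ny)
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  roi <- ((xs - spec$center[1]) / spec$axes[1])^2 +
         ((ys - spec$center[2]) / spec$axes[2])^2 <= 1

  # per-voxel fractions: constant, or linear ramp in x across the lesion
  fmat <- matrix(rep(spec$truth$f, each = nx * ny), nx * ny, 3)
  if (!is.null(spec$truth_end)) {
    xr <- range(xs[roi])
    t <- if (diff(xr) > 0) (xs - xr[1]) / diff(xr) else xs * 0
    for (k in 1:3)
      fmat[, k] <- (1 - t) * spec$truth$f[k] + t * spec$truth_end$f[k]
  }
  fmat[!roi, ] <- rep(c(0, 0, 1), each = sum(!roi))  # free water background

  basis <- exp(-outer(b, spec$truth$D))              # nb x 3
  stack <- spec$truth$S0 * (fmat %*% t(basis))       # voxels x nb
  stack <- array(stack, dim = c(nx, ny, nb))
  if (spec$sigma > 0) stack <- add_rician_noise(stack, spec$sigma)

  mk <- function(name, k) {
    v <- array(NA_real_, dim = c(nx, ny)); v[roi] <- fmat[roi, k]
    structure(list(name = name, values = v, mask = roi), class = "parameter_map")
  }
  list(stack = stack,
       truth = list(f1 = mk("f1", 1), f2 = mk("f2", 2), f3 = mk("f3", 3)),
       roi_mask = roi,
       schedule = spec$schedule)
}
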