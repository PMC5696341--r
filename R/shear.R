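#' Construct a velocity field
#'
#' @param vx,vy component grids (matrices).
#' @param vz optional third component grid.
#' @param mask logical matrix of valid voxels (default: all valid).
#' @param b voxel width, cm.
#' @param h chamber height, cm.
#' @param units `"m/s"` (converted to CGS downstream) or `"cm/s"`.
#' @return a [VelocityField-class].
#' @export
velocityField <- function(vx, vy, vz = NULL, mask = NULL, b, h,
                          units = "m/s") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(vx), ncol(vx))
  if (is.null(vz)) vz <- matrix(numeric(0), 0, 0)
  new("VelocityField", vx = vx, vy = vy, vz = vz,
      mask = matrix(as.logical(mask), nrow(vx)), b = b, h = h, units = units)
}

#' Subtract a no-flow baseline field
#'
#' Componentwise difference; removes static phase offsets measured in the
#' absence of flow (gradient imperfections).
#'
#' @param field,noFlowField congruent [VelocityField-class] objects.
#' @return the corrected [VelocityField-class].
#' @export
subtractBaseline <- function(field, noFlowField) {
  if (!identical(dim(field@vx), dim(noFlowField@vx)))
    stop("fields have different grid shapes")
  vz <- if (length(field@vz) && length(noFlowField@vz))
    field@vz - noFlowField@vz else field@vz
  velocityField(field@vx - noFlowField@vx, field@vy - noFlowField@vy, vz,
                field@mask & noFlowField@mask, field@b, field@h, field@units)
}

#' Average a field with its 180-degree-rotated acquisition
#'
#' The chamber is physically rotated 180 degrees about the x axis and
#' re-imaged; directional velocity bias then enters the two acquisitions with
#' opposite sign and cancels in the mean. The rotated field is re-registered
#' by reversing its row order and negating the y (and z, if present)
#' component, then averaged with the unrotated field.
#'
#' @param field0 the unrotated acquisition.
#' @param field180 the rotated acquisition, congruent with `field0`.
#' @return the averaged [VelocityField-class].
#' @export
averageRotations <- function(field0, field180) {
  if (!identical(dim(field0@vx), dim(field180@vx)))
    stop("fields have different grid shapes")
  flip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  vx180 <- flip(field180@vx)
  vy180 <- -flip(field180@vy)
  vz180 <- if (length(field180@vz)) -flip(field180@vz) else field180@vz
  vz <- if (length(field0@vz) && length(vz180))
    (field0@vz + vz180) / 2 else field0@vz
  velocityField((field0@vx + vx180) / 2, (field0@vy + vy180) / 2, vz,
                field0@mask & flip(field180@mask),
                field0@b, field0@h, field0@units)
}

#' Per-voxel flow speed
#'
#' Euclidean norm of the available velocity components, converted to cm/s.
#'
#' @param field a [VelocityField-class].
#' @return numeric matrix of speeds, cm/s.
#' @export
speedMap <- function(field) {
  s2 <- field@vx^2 + field@vy^2
  if (length(field@vz)) s2 <- s2 + field@vz^2
  s <- sqrt(s2)
  if (field@units == "m/s") s <- s * 100
  s
}

#' Wall shear stress from a speed map
#'
#' Parallel-plate laminar formula `tau_w = 6 mu Q / (b h^2)` applied per
#' voxel with `Q = s * b * h` (the measured speed treated as the
#' cross-sectional mean), hence `tau = 6 mu s / h`. With
#' `profile = "parabolic"` the measured speed is instead treated as the
#' mid-plane peak of the parabolic profile (mean = peak / 1.5).
#'
#' @param speed speed grid, cm/s.
#' @param mu dynamic viscosity, dyn s cm^-2 (default 0.0078, culture medium
#'   at 37C).
#' @param b voxel width, cm (cancels algebraically under the mean-speed
#'   reading; kept for the formula's record).
#' @param h chamber height, cm.
#' @param mask logical matrix of valid voxels.
#' @param profile `"mean"` or `"parabolic"`.
#' @return a [ShearMap-class], dyn cm^-2.
#' @export
shearFromSpeed <- function(speed, mu = 0.0078, b, h, mask = NULL,
                           profile = c("mean", "parabolic")) {
  profile <- match.arg(profile)
  if (mu <= 0 || b <= 0 || h <= 0) stop("mu, b and h must be > 0")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(speed), ncol(speed))
  s <- if (profile == "parabolic") speed / 1.5 else speed
  new("ShearMap", tau = 6 * mu * s / h, mu = mu,
      mask = matrix(as.logical(mask), nrow(speed)))
}

#' Convenience: shear map of a velocity field
#'
#' @param field a [VelocityField-class].
#' @param mu dynamic viscosity, dyn s cm^-2.
#' @param profile see [shearFromSpeed()].
#' @return a [ShearMap-class].
#' @export
shearMap <- function(field, mu = 0.0078, profile = "mean") {
  shearFromSpeed(speedMap(field), mu = mu, b = field@b, h = field@h,
                 mask = field@mask, profile = profile)
}

#' Mean wall shear stress over a region of interest
#'
#' @param map a [ShearMap-class].
#' @param roiMask logical matrix, congruent with the map.
#' @return mean tau over the ROI's valid voxels, dyn cm^-2.
#' @export
roiMeanShear <- function(map, roiMask) {
  if (!identical(dim(roiMask), dim(map@tau))) stop("ROI mask shape mismatch")
  sel <- as.logical(roiMask) & map@mask
  if (!any(sel)) stop("empty ROI")
  mean(map@tau[sel])
}
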