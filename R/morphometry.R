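#' Per-cell shape metrics relative to the flow axis
#'
#' For each labeled cell: the extent of its pixel set projected on the flow
#' axis (length along flow), the extent on the perpendicular axis (width),
#' the elongation factor (length along flow divided by width; below 1 for
#' cells lying across the flow), and the orientation angle, the absolute
#' acute angle in degrees between the cell's major axis (from second central
#' moments) and the flow axis, folded into [0, 90]. Cells touching the image
#' border are excluded (their shape is clipped) with a message giving the
#' count.
#'
#' @param labels a [CellLabelMap-class].
#' @param flowAxis unit 2-vector (x, y) of the flow direction; default +x.
#' @return data.frame: `cell_id`, `length_along_flow`, `width`,
#'   `elongation_factor`, `orientation_deg`, `centroid_x`, `centroid_y`
#'   (lengths in microns when `pixelSize` is known, else pixels).
#' @export
cellShapeMetrics <- function(labels, flowAxis = c(1, 0)) {
  flowAxis <- flowAxis / sqrt(sum(flowAxis^2))
  perp <- c(-flowAxis[2], flowAxis[1])
  lab <- labelMatrix(labels)
  px <- if (is.na(labels@pixelSize)) 1 else labels@pixelSize
  k <- max(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  rows <- vector("list", k)
  dropped <- 0L
  for (l in seq_len(k)) {
    idx <- which(lab == l)
    i <- (idx - 1) %% nr + 1      # row index -> y
    j <- (idx - 1) %/% nr + 1     # col index -> x
    if (any(i == 1 | i == nr | j == 1 | j == nc)) {
      dropped <- dropped + 1L
      next
    }
    x <- j; y <- i
    pf <- x * flowAxis[1] + y * flowAxis[2]
    pp <- x * perp[1] + y * perp[2]
    len <- (max(pf) - min(pf) + 1) * px
    wid <- (max(pp) - min(pp) + 1) * px
    mx <- mean(x); my <- mean(y)
    mu20 <- mean((x - mx)^2); mu02 <- mean((y - my)^2)
    mu11 <- mean((x - mx) * (y - my))
    thetaMajor <- 0.5 * atan2(2 * mu11, mu20 - mu02)   # vs image +x
    thetaFlow <- atan2(flowAxis[2], flowAxis[1])
    ang <- (thetaMajor - thetaFlow) * 180 / pi
    ang <- abs(((ang + 90) %% 180) - 90)               # fold into [0, 90]
    rows[[l]] <- data.frame(cell_id = l, length_along_flow = len,
                            width = wid, elongation_factor = len / wid,
                            orientation_deg = ang,
                            centroid_x = mx * px, centroid_y = my * px)
  }
  if (dropped > 0)
    message(sprintf("%d border-touching cell(s) excluded", dropped))
  do.call(rbind, Filter(Negate(is.null), rows))
}

#' Junction coverage of a monolayer
#'
#' Thresholds the junction-marker image with [otsuThreshold()] and reports
#' the percentage of the reference region covered by above-threshold signal,
#' and its complement (the uncovered/gap percentage). The reference region is
#' the supplied mask: the expected junction skeleton when scoring rendered
#' monolayers, or the whole field when scoring confluent images.
#'
#' @param junctionImage numeric matrix, junction-marker intensity.
#' @param mask logical matrix, the reference region.
#' @return list with `pctCovered`, `pctUncovered`, `threshold`; the two
#'   percentages sum to 100 exactly.
#' @export
junctionCoverage <- function(junctionImage, mask) {
  if (!identical(dim(junctionImage), dim(mask)))
    stop("image and mask must be congruent")
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  if (!any(mask)) stop("empty mask")
  thr <- otsuThreshold(junctionImage)
  pos <- junctionImage > thr
  pct <- 100 * sum(pos & mask) / sum(mask)
  list(pctCovered = pct, pctUncovered = 100 - pct, threshold = thr)
}

#' Protein intensity profile along the cell body
#'
#' Sums the intensity across the direction perpendicular to the flow axis at
#' each station along it, then normalizes the position axis per side: the
#' distance from the nucleus center to each cell end maps to exactly +/-1
#' (downstream positive). The background, taken as the 5th percentile of the
#' raw profile, is subtracted and the profile floored at 0. Cells clipped by
#' the image border are rejected (their profile would be truncated).
#'
#' @param cellMask logical matrix, one cell's pixels.
#' @param intensityImage numeric matrix, congruent with the mask.
#' @param nucleusCentroid numeric (x, y) in pixel coordinates, inside the mask.
#' @param flowAxis unit 2-vector; currently the +x and -x conventions are
#'   supported for station binning.
#' @param cellId id recorded in the result.
#' @param timeMin acquisition time in minutes, for kinetic series.
#' @return a [PolarizationProfile-class].
#' @export
intensityProfile <- function(cellMask, intensityImage, nucleusCentroid,
                             flowAxis = c(1, 0), cellId = 1L,
                             timeMin = NA_real_) {
  if (!identical(dim(cellMask), dim(intensityImage)))
    stop("mask and image must be congruent")
  mask <- matrix(as.logical(cellMask), nrow = nrow(cellMask))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  i <- (idx - 1) %% nr + 1
  j <- (idx - 1) %/% nr + 1
  if (any(i == 1 | i == nr | j == 1 | j == nc))
    stop("cell touches the image border; partially visible cells are excluded")
  sgn <- if (flowAxis[1] >= 0) 1 else -1
  nx <- nucleusCentroid[1]
  if (!any(abs(j - nx) <= 1))
    stop("nucleus centroid must lie inside the cell mask")
  # station = image column; sum intensity over the cell's pixels per column
  cols <- sort(unique(j))
  prof <- vapply(cols, function(cc) {
    rowsIn <- i[j == cc]
    sum(intensityImage[cbind(rowsIn, rep(cc, length(rowsIn)))])
  }, numeric(1))
  bg <- stats::quantile(prof, 0.05, names = FALSE)
  prof <- pmax(prof - bg, 0)
  d <- (cols - nx) * sgn
  pos <- numeric(length(d))
  down <- d >= 0; up <- d < 0
  if (any(down) && max(d[down]) > 0) pos[down] <- d[down] / max(d[down])
  if (any(up) && min(d[up]) < 0) pos[up] <- -d[up] / min(d[up])
  o <- order(pos)
  new("PolarizationProfile", cellId = as.integer(cellId),
      position = pos[o], intensity = prof[o], timeMin = timeMin)
}

#' Downstream fraction of a polarization profile
#'
#' Trapezoidal area of the profile on the downstream side (position in
#' (0, 1]) divided by the total (upstream + downstream) area.
#'
#' @param profile a [PolarizationProfile-class], non-negative, not all zero.
#' @return the downstream fraction in [0, 1].
#' @export
polarizationIndex <- function(profile) {
  p <- profile@position
  y <- profile@intensity
  if (all(y == 0)) stop("all-zero profile")
  down <- p >= 0
  up <- p <= 0
  aDown <- if (sum(down) >= 2) pracma::trapz(p[down], y[down]) else 0
  aUp <- if (sum(up) >= 2) abs(pracma::trapz(p[up], y[up])) else 0
  aDown / (aDown + aUp)
}

#' Fit repolarization kinetics
#'
#' Least-squares fit of the relaxation
#' `d(t) = dInf - (dInf - d0) * exp(-t / tau)` to a downstream-fraction time
#' series, returning the characteristic time `tau` (same units as `times`)
#' and the asymptotes.
#'
#' @param times timepoints, minutes.
#' @param indices downstream fractions in [0, 1] at those timepoints.
#' @return list with `tau`, `d0`, `dInf`, `fitted`.
#' @export
fitRepolarization <- function(times, indices) {
  stopifnot(length(times) == length(indices), length(times) >= 4)
  if (diff(range(indices)) < 1e-12) stop("no relaxation: constant series")
  init <- c(dInf = indices[which.max(times)], d0 = indices[which.min(times)],
            tau = max(diff(range(times)) / 3, 1e-6))
  fit <- minpack.lm::nls.lm(
    par = init,
    lower = c(dInf = -Inf, d0 = -Inf, tau = 1e-9),
    fn = function(p, t, y)
      p[["dInf"]] - (p[["dInf"]] - p[["d0"]]) * exp(-t / p[["tau"]]) - y,
    t = times, y = indices,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  list(tau = p[["tau"]], d0 = p[["d0"]], dInf = p[["dInf"]],
       fitted = p[["dInf"]] - (p[["dInf"]] - p[["d0"]]) * exp(-times / p[["tau"]]))
}

#' Classify organelle polarity relative to the nucleus
#'
#' Signed projection of the organelle-minus-nucleus centroid displacement on
#' the flow axis: beyond `+deadband` is downstream, beyond `-deadband`
#' upstream, otherwise unpolarized (the deadband interval is closed, so a
#' displacement exactly at the deadband is unpolarized).
#'
#' @param nucleusCentroid,organelleCentroid numeric (x, y), same frame, um.
#' @param flowAxis unit 2-vector.
#' @param deadband tolerance, um (default 1).
#' @return `"downstream"`, `"upstream"` or `"unpolarized"`.
#' @export
classifyGolgiPolarity <- function(nucleusCentroid, organelleCentroid,
                                  flowAxis = c(1, 0), deadband = 1) {
  flowAxis <- flowAxis / sqrt(sum(flowAxis^2))
  disp <- organelleCentroid - nucleusCentroid
  s <- sum(disp * flowAxis)
  if (s > deadband) "downstream" else if (s < -deadband) "upstream" else "unpolarized"
}

#' Percentage of cells with nuclear signal above a threshold
#'
#' @param nuclearIntensities per-cell nuclear intensities in one ROI.
#' @param threshold intensity threshold; cells strictly above count positive.
#' @return percentage in [0, 100].
#' @export
nuclearPositiveFraction <- function(nuclearIntensities, threshold) {
  if (!length(nuclearIntensities)) stop("no cells")
  100 * sum(nuclearIntensities > threshold) / length(nuclearIntensities)
}

#' Logarithmic shear-response curve
#'
#' Least-squares fit of `pct = a * ln(shear) + c` across ROIs, describing a
#' response that rises steeply at low shear and saturates. When the two
#' highest-shear points differ by less than 2 percentage points their mean is
#' also reported as a plateau level.
#'
#' @param shear wall shear stresses, dyn cm^-2 (> 0, >= 3 distinct values).
#' @param pct response percentages.
#' @return list with `slope`, `intercept`, `r2`, `plateauLevel` (NA when no
#'   plateau is evident).
#' @export
shearResponseCurve <- function(shear, pct) {
  if (any(shear <= 0)) stop("shear must be positive")
  if (length(unique(shear)) < 3) stop("need >= 3 ROIs with distinct shear")
  fit <- stats::lm(pct ~ log(shear))
  o <- order(shear, decreasing = TRUE)
  top2 <- pct[o][1:2]
  plateau <- if (abs(diff(top2)) < 2) mean(top2) else NA_real_
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((pct - mean(pct))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else NA_real_
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2, plateauLevel = plateau)
}
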