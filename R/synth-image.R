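#' Paint per-cell traces into a synthetic movie
#'
#' Renders a fluorescence movie in which every pixel of label `l` follows
#' that label's trace, plus optional per-pixel Gaussian noise; background
#' pixels are zero. Used to exercise segmentation and trace extraction
#' against known painted values.
#'
#' @param labels a [CellLabelMap-class].
#' @param traces list of [CellTrace-class], one per label (matched by
#'   `cellId`).
#' @param noiseSd per-pixel Gaussian noise, a.u.
#' @param seed RNG seed.
#' @return a [FluorescenceMovie-class].
#' @export
synthMovie <- function(labels, traces, noiseSd = 0, seed = NULL) {
  lab <- labelMatrix(labels)
  k <- max(lab)
  ids <- vapply(traces, cellId, integer(1))
  missing <- setdiff(seq_len(k), ids)
  if (length(missing))
    stop(sprintf("no trace for label(s): %s", paste(missing, collapse = ", ")))
  tr1 <- traces[[1]]
  nT <- length(traceTime(tr1))
  dt <- .dt(tr1)
  vals <- matrix(0, max(k, 1), nT)
  for (tr in traces) vals[cellId(tr), ] <- traceValues(tr)
  d <- dim(lab)
  frames <- array(0, c(d[1], d[2], nT))
  fg <- which(lab > 0)
  labFg <- lab[fg]
  for (s in seq_len(nT)) {
    fr <- matrix(0, d[1], d[2])
    fr[fg] <- vals[labFg, s]
    frames[, , s] <- fr
  }
  if (noiseSd > 0)
    frames <- frames + .withSeed(seed,
      array(stats::rnorm(length(frames), 0, noiseSd), dim(frames)))
  new("FluorescenceMovie", frames = frames, dt = dt, phase = tracePhase(tr1))
}

# rasterize one ellipse into logical matrix coordinates
.ellipsePixels <- function(nr, nc, cx, cy, a, bAx, thetaDeg) {
  th <- thetaDeg * pi / 180
  xs <- seq_len(nc); ys <- seq_len(nr)
  X <- matrix(xs, nr, nc, byrow = TRUE) - cx
  Y <- matrix(ys, nr, nc) - cy
  u <- X * cos(th) + Y * sin(th)
  v <- -X * sin(th) + Y * cos(th)
  (u / a)^2 + (v / bAx)^2 <= 1
}

#' Synthesize an endothelial monolayer label image
#'
#' Places non-overlapping elliptical cells on a jittered grid with controlled
#' elongation (major/minor axis ratio) and orientation (degrees from the +x
#' flow axis), and renders a junction-marker image as the rasterized cell
#' borders with a fraction of border pixels knocked out (gaps).
#'
#' @param nCells number of cells to place.
#' @param elongationMean,elongationSd elongation distribution (>= 1).
#' @param orientationMean,orientationSd orientation distribution, degrees.
#' @param gapFraction fraction of border pixels removed, in [0, 1).
#' @param cellArea approximate cell area, px.
#' @param seed RNG seed.
#' @return list with `labels` ([CellLabelMap-class]), `shapes` (truth table:
#'   cell_id, a, b, orientation_deg, extent-based elongation truth),
#'   `junction` (intensity matrix), `borderMask` (complete skeleton, the
#'   coverage denominator).
#' @export
synthMonolayer <- function(nCells, elongationMean = 2, elongationSd = 0,
                           orientationMean = 0, orientationSd = 0,
                           gapFraction = 0, cellArea = 600, seed = 1L) {
  stopifnot(gapFraction >= 0, gapFraction < 1)
  .withSeed(seed, {
    elong <- pmax(stats::rnorm(nCells, elongationMean, elongationSd), 1)
    orient <- stats::rnorm(nCells, orientationMean, orientationSd)
    a <- sqrt(cellArea * elong / pi)   # semi-major
    bAx <- a / elong                   # semi-minor
    # grid spacing comfortably above the largest diameter
    pitch <- ceiling(2 * max(a) + 6)
    perRow <- ceiling(sqrt(nCells))
    nr <- pitch * ceiling(nCells / perRow) + pitch
    nc <- pitch * perRow + pitch
    lab <- matrix(0L, nr, nc)
    shapes <- vector("list", nCells)
    for (l in seq_len(nCells)) {
      gi <- (l - 1) %/% perRow
      gj <- (l - 1) %% perRow
      placed <- FALSE
      for (tries in 1:50) {
        cy <- pitch / 2 + gi * pitch + stats::runif(1, -2, 2) + pitch / 2
        cx <- pitch / 2 + gj * pitch + stats::runif(1, -2, 2) + pitch / 2
        px <- .ellipsePixels(nr, nc, cx, cy, a[l], bAx[l], orient[l])
        if (!any(lab[px] != 0L)) {
          lab[px] <- l
          placed <- TRUE
          break
        }
      }
      if (!placed) stop(sprintf("could not place cell %d without overlap", l))
      th <- orient[l] * pi / 180
      shapes[[l]] <- data.frame(
        cell_id = l, semi_major = a[l], semi_minor = bAx[l],
        orientation_deg = abs(orient[l]) %% 180,
        elongation_axes = elong[l],
        extent_x = 2 * sqrt((a[l] * cos(th))^2 + (bAx[l] * sin(th))^2),
        extent_y = 2 * sqrt((a[l] * sin(th))^2 + (bAx[l] * cos(th))^2))
    }
    # border: cell pixels 4-adjacent to a different value
    pad <- function(m) rbind(0L, cbind(0L, m, 0L), 0L)
    p <- pad(lab)
    core <- p[2:(nr + 1), 2:(nc + 1)]
    border <- core > 0 &
      (p[1:nr, 2:(nc + 1)] != core | p[3:(nr + 2), 2:(nc + 1)] != core |
       p[2:(nr + 1), 1:nc] != core | p[2:(nr + 1), 3:(nc + 2)] != core)
    junction <- matrix(0, nr, nc)
    bIdx <- which(border)
    drop <- if (gapFraction > 0)
      sample(bIdx, round(gapFraction * length(bIdx))) else integer(0)
    junction[setdiff(bIdx, drop)] <- 200
    junction <- junction + matrix(stats::runif(nr * nc, 0, 10), nr, nc)
    shapesDf <- do.call(rbind, shapes)
    shapesDf$elongation_extent <- shapesDf$extent_x / shapesDf$extent_y
    list(labels = new("CellLabelMap", labels = lab, pixelSize = NA_real_),
         shapes = shapesDf, junction = junction, borderMask = border)
  })
}

#' Synthesize a protein repolarization time series
#'
#' Downstream fractions relaxing as
#' `d(t) = dInf - (dInf - d0) * exp(-t / tau)` for `nCells` cells observed at
#' the given timepoints, plus Gaussian noise.
#'
#' @param tauMin characteristic time, minutes (default 30).
#' @param timepoints observation times, minutes (>= 3).
#' @param nCells cells per timepoint.
#' @param noiseSd SD of the per-cell index noise.
#' @param d0,dInf initial and asymptotic downstream fractions.
#' @param seed RNG seed.
#' @return list with `data` (long data.frame: cell_id, time_min,
#'   downstream_fraction), `meanSeries` (per-timepoint means) and `truth`
#'   (tau, d0, dInf).
#' @export
synthPolarSeries <- function(tauMin = 30, timepoints = c(0, 5, 10, 20, 30,
                                                         45, 60, 90, 120),
                             nCells = 100, noiseSd = 0.05, d0 = 0.25,
                             dInf = 0.75, seed = 1L) {
  stopifnot(tauMin > 0, length(timepoints) >= 3)
  .withSeed(seed, {
    mu <- dInf - (dInf - d0) * exp(-timepoints / tauMin)
    df <- do.call(rbind, lapply(seq_along(timepoints), function(k) {
      d <- mu[k] + stats::rnorm(nCells, 0, noiseSd)
      data.frame(cell_id = seq_len(nCells), time_min = timepoints[k],
                 downstream_fraction = pmin(pmax(d, 0), 1))
    }))
    means <- vapply(split(df$downstream_fraction, df$time_min), mean,
                    numeric(1))
    list(data = df,
         meanSeries = data.frame(time_min = sort(unique(df$time_min)),
                                 downstream_fraction = unname(means)),
         truth = list(tau = tauMin, d0 = d0, dInf = dInf))
  })
}

#' Synthesize a parallel-plate velocity field
#'
#' Uniform speed `s = Q / (b h)` across the interior of the grid (the
#' depth-averaged speed of laminar flow between parallel plates), zero on a
#' one-voxel boundary rim which is masked invalid, paired with the analytic
#' wall-shear truth `tau = 6 mu Q / (b h^2)`.
#'
#' @param Q volumetric flow rate, cm^3/s.
#' @param b voxel width, cm.
#' @param h chamber height, cm.
#' @param grid c(rows, cols) of the grid.
#' @param mu dynamic viscosity, dyn s cm^-2.
#' @return list with `field` ([VelocityField-class], cm/s),
#'   `analyticShear` ([ShearMap-class]) and `tauTruth` (scalar).
#' @export
synthVelocityField <- function(Q, b, h, grid = c(32, 32), mu = 0.0078) {
  if (Q <= 0 || b <= 0 || h <= 0 || mu <= 0)
    stop("Q, b, h and mu must be > 0")
  nr <- grid[1]; nc <- grid[2]
  s <- Q / (b * h)                      # cm/s
  vx <- matrix(0, nr, nc)
  vx[2:(nr - 1), 2:(nc - 1)] <- s
  vy <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  mask[2:(nr - 1), 2:(nc - 1)] <- TRUE
  field <- velocityField(vx, vy, mask = mask, b = b, h = h, units = "cm/s")
  tauGrid <- 6 * mu * abs(vx) / h       # same composition as shearFromSpeed
  list(field = field,
       analyticShear = new("ShearMap", tau = tauGrid, mu = mu, mask = mask),
       tauTruth = 6 * mu * Q / (b * h^2))
}
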