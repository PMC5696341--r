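#' Pixelwise temporal mean of a movie
#'
#' Averages all frames; the averaged image is what the threshold-based
#' segmentation operates on.
#'
#' @param movie a [FluorescenceMovie-class].
#' @return numeric matrix.
#' @export
temporalMean <- function(movie) {
  d <- dim(movie@frames)
  if (d[3] < 1) stop("empty movie")
  rowMeans(matrix(movie@frames, nrow = d[1] * d[2], ncol = d[3])) |>
    matrix(nrow = d[1], ncol = d[2])
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing the between-class variance, computed
#' on `nBins` equal bins spanning the image's min-max range. Candidate
#' thresholds are the interior bin edges; ties are broken toward the lowest
#' qualifying threshold. On 8-bit integer data with 256 bins this reproduces
#' the classic formulation exactly.
#'
#' @param image numeric matrix or vector.
#' @param nBins number of histogram bins.
#' @return the threshold, in image units (pixels strictly above it are
#'   foreground).
#' @export
otsuThreshold <- function(image, nBins = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop("degenerate histogram: image has fewer than 2 distinct values")
  # bin pixels; the top edge is inclusive
  bin <- pmin(floor((x - lo) / (hi - lo) * nBins) + 1, nBins)
  counts <- tabulate(bin, nBins)
  n <- length(x)
  p <- counts / n
  mids <- lo + (seq_len(nBins) - 0.5) * (hi - lo) / nBins
  w0 <- cumsum(p)[-nBins]              # class 0: bins 1..k
  mu0 <- cumsum(p * mids)[-nBins]
  muT <- sum(p * mids)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigmaB <- rep(-Inf, nBins - 1)
  sigmaB[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigmaB)               # which.max takes the first (lowest) tie
  lo + k * (hi - lo) / nBins           # edge between bin k and k+1
}

#' Label connected components of a binary mask
#'
#' 4-connected components, labeled 1..K in raster order (column-major, the
#' order of the first pixel encountered scanning down each column); components
#' smaller than `minArea` pixels are removed and remaining labels renumbered.
#'
#' @param mask logical or 0/1 matrix.
#' @param minArea minimum component area in pixels.
#' @param pixelSize microns per pixel (stored, optional).
#' @return a [CellLabelMap-class].
#' @export
labelCells <- function(mask, minArea = 0, pixelSize = NA_real_) {
  m <- matrix(as.logical(mask), nrow = nrow(mask))
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nextLab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!m[i, j] || lab[i, j] != 0L) next
    nextLab <- nextLab + 1L
    # iterative flood fill, 4-connectivity
    stack <- (j - 1L) * nr + i
    lab[i, j] <- nextLab
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- (cur - 1L) %% nr + 1L
      cj <- (cur - 1L) %/% nr + 1L
      for (d in 1:4) {
        ni <- ci + c(-1L, 1L, 0L, 0L)[d]
        nj <- cj + c(0L, 0L, -1L, 1L)[d]
        if (ni >= 1L && ni <= nr && nj >= 1L && nj <= nc &&
            m[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nextLab
          stack <- c(stack, (nj - 1L) * nr + ni)
        }
      }
    }
  }
  if (minArea > 0 && nextLab > 0) {
    areas <- tabulate(lab[lab > 0], nextLab)
    keep <- which(areas >= minArea)
    remap <- integer(nextLab)
    remap[keep] <- seq_along(keep)
    lab[lab > 0] <- remap[lab[lab > 0]]
  }
  new("CellLabelMap", labels = lab, pixelSize = pixelSize)
}

#' Extract per-cell traces from a movie
#'
#' For each frame and each label, the mean intensity over the label's pixels;
#' phase labels are copied from the movie.
#'
#' @param movie a [FluorescenceMovie-class].
#' @param labels a [CellLabelMap-class] congruent with the movie frames.
#' @return list of [CellTrace-class], one per label.
#' @export
extractTraces <- function(movie, labels) {
  lab <- labelMatrix(labels)
  d <- dim(movie@frames)
  if (!identical(dim(lab), d[1:2]))
    stop("label map and movie frames have different shapes")
  k <- max(lab)
  if (k < 1) stop("empty label set")
  t <- (seq_len(d[3]) - 1) * movie@dt
  flat <- matrix(movie@frames, nrow = d[1] * d[2], ncol = d[3])
  idxByLab <- split(which(lab > 0), lab[lab > 0])
  lapply(seq_len(k), function(l) {
    px <- idxByLab[[as.character(l)]]
    f <- if (length(px) == 1) flat[px, ] else colMeans(flat[px, , drop = FALSE])
    cellTrace(l, t, f, movie@phase)
  })
}
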