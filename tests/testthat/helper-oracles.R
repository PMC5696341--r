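# Independent oracles used across the suite. Each deliberately takes a
# different algorithmic route than the package implementation.

# Otsu: exhaustive search over the same candidate bin edges, but scoring each
# split directly from the pixel values (weighted between-class variance),
# not from histogram cumulants.
otsuOracle <- function(image, nBins = 256) {
  x <- as.numeric(image)
  lo <- min(x); hi <- max(x)
  edges <- lo + seq_len(nBins - 1) * (hi - lo) / nBins
  best <- -Inf; bestEdge <- NA
  for (e in edges) {
    g0 <- x[x <= e]; g1 <- x[x > e]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(x); w1 <- 1 - w0
    # bin-midpoint means, mirroring the histogram quantization
    m0 <- mean(binMid(g0, lo, hi, nBins))
    m1 <- mean(binMid(g1, lo, hi, nBins))
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best + 1e-12) { best <- v; bestEdge <- e }
  }
  bestEdge
}

binMid <- function(x, lo, hi, nBins) {
  b <- pmin(floor((x - lo) / (hi - lo) * nBins) + 1, nBins)
  lo + (b - 0.5) * (hi - lo) / nBins
}

# connected components via igraph on the 4-adjacency graph of foreground pixels
labelCountOracle <- function(mask) {
  idx <- which(mask)
  if (!length(idx)) return(0L)
  nr <- nrow(mask)
  i <- (idx - 1) %% nr + 1
  j <- (idx - 1) %/% nr + 1
  key <- paste(i, j)
  edges <- character(0)
  for (k in seq_along(idx)) {
    for (d in list(c(1, 0), c(0, 1))) {
      ni <- i[k] + d[1]; nj <- j[k] + d[2]
      if (ni <= nrow(mask) && nj <= ncol(mask) && mask[ni, nj])
        edges <- c(edges, key[k], paste(ni, nj))
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) matrix(edges, ncol = 2, byrow = TRUE) else
      matrix(character(0), ncol = 2),
    directed = FALSE, vertices = data.frame(name = key))
  igraph::components(g)$no
}

# spike detection by explicit window enumeration: every maximal window of
# consecutive above-threshold samples, kept iff long enough
spikeOracle <- function(x, thr, minDur, dt = 1) {
  n <- length(x)
  runs <- list()
  s <- NULL
  for (k in seq_len(n)) {
    if (x[k] > thr && is.null(s)) s <- k
    if ((x[k] <= thr || k == n) && !is.null(s)) {
      e <- if (x[k] <= thr) k - 1 else k
      runs[[length(runs) + 1]] <- c(s, e)
      s <- NULL
    }
  }
  keep <- Filter(function(r) (r[2] - r[1] + 1) * dt >= minDur, runs)
  if (!length(keep)) return(matrix(numeric(0), ncol = 2))
  do.call(rbind, keep)
}

# boxcar-with-half-edges spike shape used by the generator
spikeShape <- function(A, n) {
  s <- rep(A, n); s[1] <- A / 2; s[n] <- A / 2
  s
}

# quick synthetic calcium vector: baseline + one painted spike
paintSpike <- function(n, baseline, at, dur, A) {
  x <- rep(baseline, n)
  x[at:(at + dur - 1)] <- baseline + spikeShape(A, dur)
  x
}
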