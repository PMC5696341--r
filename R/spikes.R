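#' Spike detection configuration
#'
#' The detection rule: a spike is a maximal run of samples more than
#' `sdMultiplier` noise standard deviations above the baseline that lasts at
#' least `minDuration` seconds.
#'
#' @param sdMultiplier threshold in noise SDs above baseline (default 2).
#' @param minDuration minimum duration, s (default 3).
#' @param noiseEstimator label recorded for provenance; the estimator is the
#'   MAD-based robust SD over the lower 75% of samples.
#' @return list with class `"spikeConfig"`.
#' @export
spikeConfig <- function(sdMultiplier = 2, minDuration = 3,
                        noiseEstimator = "mad_lower75") {
  stopifnot(sdMultiplier > 0, minDuration > 0)
  structure(list(sdMultiplier = sdMultiplier, minDuration = minDuration,
                 noiseEstimator = noiseEstimator), class = "spikeConfig")
}

#' Estimate baseline and noise of a calcium trace
#'
#' Baseline is the trace median; the noise SD is a scaled median absolute
#' deviation about that baseline, computed over the samples at or below the
#' 75th percentile so the estimate is insensitive to the spikes about to be
#' detected. Because the upper tail is excluded, the classic MAD constant
#' 1.4826 would underestimate a Gaussian SD by about 27% (and so quietly
#' lower the detection threshold); the constant used here,
#' `1 / qnorm(0.6875) = 2.0459`, makes the estimator consistent for Gaussian
#' noise under exactly this truncation (the median of |x - median| over the
#' sub-75th-percentile samples of a standard normal is `qnorm(0.6875)`).
#'
#' @param ca a [CalciumTrace-class] or numeric vector (nM).
#' @return list with `baseline` (nM), `noiseSd` (nM) and `degenerate` flag
#'   (TRUE when all samples are identical, giving zero noise).
#' @export
estimateNoise <- function(ca) {
  x <- if (is(ca, "CalciumTrace")) traceValues(ca) else as.numeric(ca)
  if (length(x) < 30) stop("need at least 30 samples to estimate noise")
  baseline <- stats::median(x)
  sub <- x[x <= stats::quantile(x, 0.75)]
  noiseSd <- stats::median(abs(sub - baseline)) / stats::qnorm(0.6875)
  list(baseline = baseline, noiseSd = noiseSd, degenerate = noiseSd == 0)
}

#' Detect calcium spikes
#'
#' Maximal runs of consecutive samples with
#' `ca > baseline + sdMultiplier * noiseSd`; runs spanning less than
#' `minDuration` are discarded. The duration counts time above threshold:
#' a run of `n` samples at interval `dt` lasts `n * dt`. Runs are not merged
#' across sub-threshold gaps; a run touching the end of the trace is kept iff
#' it already satisfies the minimum duration.
#'
#' @param ca a [CalciumTrace-class] or numeric vector with uniform sampling.
#' @param cfg a [spikeConfig()].
#' @param baseline,noiseSd optionally precomputed; when NULL, taken from
#'   [estimateNoise()].
#' @param dt sampling interval, required when `ca` is a bare vector.
#' @return data.frame with one row per spike: `start_s`, `end_s`,
#'   `duration_s`, `amplitude_nM`, `auc_nM_s`, `auc_baseline_nM_s`.
#'   `amplitude_nM` is the highest concentration in the spike relative to the
#'   baseline. `auc_nM_s` is the trapezoidal area over the spike window of
#'   the trace minus its global minimum; `auc_baseline_nM_s` is the same area
#'   referenced to the baseline instead (see the methods vignette for why
#'   both are reported).
#' @export
detectSpikes <- function(ca, cfg = spikeConfig(), baseline = NULL,
                         noiseSd = NULL, dt = NULL) {
  if (is(ca, "CalciumTrace")) {
    x <- traceValues(ca)
    t <- traceTime(ca)
    dt <- .dt(ca)
  } else {
    x <- as.numeric(ca)
    if (is.null(dt)) stop("dt required for a bare numeric trace")
    t <- (seq_along(x) - 1) * dt
  }
  if (is.null(baseline) || is.null(noiseSd)) {
    est <- estimateNoise(x)
    if (is.null(baseline)) baseline <- est$baseline
    if (is.null(noiseSd)) noiseSd <- est$noiseSd
  }
  if (noiseSd <= 0) stop("degenerate threshold: noise SD is zero")
  thr <- baseline + cfg$sdMultiplier * noiseSd

  above <- x > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * dt >= cfg$minDuration)
  starts <- starts[keep]; ends <- ends[keep]

  globalMin <- min(x)
  rows <- lapply(seq_along(starts), function(k) {
    w <- starts[k]:ends[k]
    data.frame(start_s = t[starts[k]], end_s = t[ends[k]],
               duration_s = length(w) * dt,
               amplitude_nM = max(x[w]) - baseline,
               auc_nM_s = pracma::trapz(t[w], x[w] - globalMin),
               auc_baseline_nM_s = pracma::trapz(t[w], x[w] - baseline))
  })
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start_s = numeric(0), end_s = numeric(0),
               duration_s = numeric(0), amplitude_nM = numeric(0),
               auc_nM_s = numeric(0), auc_baseline_nM_s = numeric(0))
}

#' Summarize a cell's spikes
#'
#' @param spikes spike table from [detectSpikes()].
#' @param baseline,noiseSd the cell's baseline and noise (nM).
#' @param cellId integer id recorded in the row.
#' @return one-row data.frame: counts, arithmetic means of the spike metrics
#'   (NA when the cell has no spikes), `responder` flag, baseline and noise.
#' @export
summarizeCell <- function(spikes, baseline = NA_real_, noiseSd = NA_real_,
                          cellId = NA_integer_) {
  n <- nrow(spikes)
  data.frame(cell_id = as.integer(cellId), n_spikes = n, responder = n >= 1,
             mean_duration_s = if (n) mean(spikes$duration_s) else NA_real_,
             mean_amplitude_nM = if (n) mean(spikes$amplitude_nM) else NA_real_,
             mean_auc_nM_s = if (n) mean(spikes$auc_nM_s) else NA_real_,
             mean_auc_baseline_nM_s =
               if (n) mean(spikes$auc_baseline_nM_s) else NA_real_,
             baseline_nM = baseline, noise_sd_nM = noiseSd)
}
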