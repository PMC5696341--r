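#' Read and write traces as CSV
#'
#' Long format: `cell_id, t_s, F_au, phase`.
#'
#' @param traces list of [CellTrace-class].
#' @param path CSV path.
#' @return `writeTracesCSV` returns the path invisibly; `readTracesCSV`
#'   returns a list of [CellTrace-class].
#' @export
writeTracesCSV <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = cellId(tr), t_s = traceTime(tr),
               F_au = traceValues(tr), phase = tracePhase(tr))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTracesCSV
#' @export
readTracesCSV <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$cell_id), function(d)
    cellTrace(d$cell_id[1], d$t_s, d$F_au, d$phase))
}

#' Read and write multi-page TIFF movies
#'
#' Frames are written as 32-bit float TIFF pages; intensities are stored
#' as-is (no rescaling).
#'
#' @param movie a [FluorescenceMovie-class].
#' @param path TIFF path.
#' @param dt,phase frame interval and per-frame phases used on read (the
#'   TIFF itself does not carry them).
#' @return `writeMovieTIFF` returns the path invisibly; `readMovieTIFF` a
#'   [FluorescenceMovie-class].
#' @export
writeMovieTIFF <- function(movie, path) {
  pages <- lapply(seq_len(dim(movie@frames)[3]),
                  function(k) movie@frames[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeMovieTIFF
#' @export
readMovieTIFF <- function(path, dt = 1, phase = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  if (is.null(phase)) phase <- rep("flow", length(pages))
  new("FluorescenceMovie", frames = frames, dt = dt, phase = phase)
}

#' Write a label map as 16-bit TIFF
#'
#' @param labels a [CellLabelMap-class] (at most 65535 cells).
#' @param path TIFF path.
#' @return the path, invisibly.
#' @export
writeLabelMapTIFF <- function(labels, path) {
  m <- labelMatrix(labels)
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read and write velocity grids as CSV with a JSON sidecar
#'
#' Each component is a headerless CSV grid; the sidecar records the shape,
#' units and chamber geometry.
#'
#' @param field a [VelocityField-class].
#' @param prefix path prefix; writes `<prefix>_vx.csv`, `<prefix>_vy.csv`
#'   (and `_vz.csv`), plus `<prefix>.json`.
#' @return `writeVelocityGrid` returns the sidecar path invisibly;
#'   `readVelocityGrid` a [VelocityField-class].
#' @export
writeVelocityGrid <- function(field, prefix) {
  wr <- function(m, suff) utils::write.table(
    m, paste0(prefix, suff), sep = ",", row.names = FALSE, col.names = FALSE)
  wr(field@vx, "_vx.csv")
  wr(field@vy, "_vy.csv")
  hasVz <- length(field@vz) > 0
  if (hasVz) wr(field@vz, "_vz.csv")
  side <- paste0(prefix, ".json")
  jsonlite::write_json(list(rows = nrow(field@vx), cols = ncol(field@vx),
                            units = field@units, b_cm = field@b,
                            h_cm = field@h, has_vz = hasVz),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname writeVelocityGrid
#' @export
readVelocityGrid <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  rd <- function(suff) as.matrix(utils::read.table(paste0(prefix, suff),
                                                   sep = ","))
  vx <- unname(rd("_vx.csv"))
  vy <- unname(rd("_vy.csv"))
  vz <- if (isTRUE(meta$has_vz)) unname(rd("_vz.csv")) else NULL
  velocityField(vx, vy, vz, b = meta$b_cm, h = meta$h_cm, units = meta$units)
}
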