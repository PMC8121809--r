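#' Time-resolved difference-spectral dataset
#'
#' Container for a difference-absorbance matrix \eqn{\Delta E(\nu, t)}:
#' one row per spectral channel (wavenumber in cm\eqn{^{-1}} or wavelength
#' in nm), one column per delay time after the actinic flash at \eqn{t = 0}.
#' Channels are stored in ascending axis order regardless of input order;
#' times must be strictly increasing and strictly positive (exponential
#' kinetics are evaluated for \eqn{t > 0} only).
#'
#' @param axis numeric vector of channel positions, strictly monotonic.
#' @param times numeric vector of delay times in seconds, strictly
#'   increasing, all positive.
#' @param values numeric matrix of dimension `length(axis)` x
#'   `length(times)` holding dimensionless absorbance differences.
#' @param modality `"FTIR"` or `"UVVIS"`.
#' @param segment free-text segment label, e.g. `"step-scan"`,
#'   `"rapid-scan"`, `"merged"`.
#' @param axis_unit `"cm-1"` or `"nm"`.
#' @return An object of class `spectral_dataset`.
#' @examples
#' d <- spectral_dataset(c(1500, 1600), c(1e-6, 1e-3), matrix(0, 2, 2))
#' dim(d$values)
#' @export
spectral_dataset <- function(axis, times, values,
                             modality = c("FTIR", "UVVIS"),
                             segment = "merged",
                             axis_unit = c("cm-1", "nm")) {
  modality <- match.arg(modality)
  axis_unit <- match.arg(axis_unit)
  axis <- as.numeric(axis)
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (length(axis) < 1L) stop("dataset must contain at least one channel")
  if (length(times) < 1L) stop("dataset must contain at least one time point")
  if (anyNA(axis) || anyNA(times) || anyNA(values) || any(!is.finite(values)))
    stop("axis, times and values must be finite")
  d <- diff(axis)
  if (length(axis) > 1L && !(all(d > 0) || all(d < 0)))
    stop("channel axis must be strictly monotonic")
  if (any(times <= 0)) stop("all times must be strictly positive (flash at t = 0)")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (nrow(values) != length(axis) || ncol(values) != length(times))
    stop(sprintf("values must be %d x %d (channels x times), got %d x %d",
                 length(axis), length(times), nrow(values), ncol(values)))
  if (length(axis) > 1L && d[1] < 0) {        # canonicalise to ascending axis
    axis <- rev(axis)
    values <- values[rev(seq_along(axis)), , drop = FALSE]
  }
  dimnames(values) <- NULL
  structure(list(axis = axis, times = times, values = values,
                 modality = modality, segment = segment,
                 axis_unit = axis_unit),
            class = "spectral_dataset")
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat(sprintf("<spectral_dataset> %s (%s), %d channels x %d times\n",
              x$modality, x$segment, length(x$axis), length(x$times)))
  cat(sprintf("  axis : %g .. %g %s\n", min(x$axis), max(x$axis), x$axis_unit))
  cat(sprintf("  times: %.3g .. %.3g s\n", min(x$times), max(x$times)))
  cat(sprintf("  |dE| : max %.4g\n", max(abs(x$values))))
  invisible(x)
}

#' Single difference spectrum
#'
#' @param axis numeric channel positions, strictly monotonic.
#' @param values numeric vector, same length as `axis`.
#' @param label free-text label.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(axis, values, label = "") {
  axis <- as.numeric(axis); values <- as.numeric(values)
  if (length(axis) != length(values))
    stop("axis and values must have the same length")
  d <- diff(axis)
  if (length(axis) > 1L && !(all(d > 0) || all(d < 0)))
    stop("spectrum axis must be strictly monotonic")
  if (length(axis) > 1L && d[1] < 0) {
    axis <- rev(axis); values <- rev(values)
  }
  structure(list(axis = axis, values = values, label = label),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d channels, %g .. %g; extremum %.4g at %g\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$axis), min(x$axis), max(x$axis),
              x$values[which.max(abs(x$values))],
              x$axis[which.max(abs(x$values))]))
  invisible(x)
}

#' Single-channel kinetic trace
#'
#' @param center channel position of the band centre.
#' @param bandwidth averaging window width (same unit as the axis), >= 0.
#' @param times numeric vector of times in seconds.
#' @param values numeric vector of averaged difference absorbances.
#' @return An object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(center, bandwidth, times, values) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (bandwidth < 0) stop("bandwidth must be >= 0")
  structure(list(center = center, bandwidth = bandwidth,
                 times = as.numeric(times), values = as.numeric(values)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> %g +/- %g: %d points, peak %.4g at t = %.3g s\n",
              x$center, x$bandwidth / 2, length(x$times),
              x$values[which.max(abs(x$values))],
              x$times[which.max(abs(x$values))]))
  invisible(x)
}

# -- TSV matrix dialect -------------------------------------------------------
# '#' comment lines carry key=value metadata (modality, segment, axis_unit);
# first data row: empty corner cell then the times in seconds; every further
# row: channel position then one dE value per time. UTF-8, '.' decimal point,
# scientific notation accepted. Values are written with 17 significant digits
# so that a write/read cycle is lossless at double precision.

#' Write a dataset in the TSV matrix dialect
#'
#' @param dataset a [spectral_dataset()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# modality=%s", dataset$modality), con)
  writeLines(sprintf("# segment=%s", dataset$segment), con)
  writeLines(sprintf("# axis_unit=%s", dataset$axis_unit), con)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  writeLines(paste(c("", fmt(dataset$times)), collapse = "\t"), con)
  rows <- vapply(seq_along(dataset$axis), function(i) {
    paste(c(fmt(dataset$axis[i]), fmt(dataset$values[i, ])), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Read a dataset in the TSV matrix dialect
#'
#' @param path input file path.
#' @param format format tag; only `"tsv"` is supported.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, format = "tsv") {
  if (!identical(format, "tsv")) stop("unsupported format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(modality = "FTIR", segment = "merged", axis_unit = "cm-1")
  is_comment <- grepl("^\\s*#", lines)
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*=\\s*(\\S+)", ln))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2L) stop("format error: need a time header row and at least one channel row")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  times <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(times)) stop("format error: non-numeric entry in the time header row")
  nt <- length(times)
  axis <- numeric(length(body) - 1L)
  values <- matrix(NA_real_, length(body) - 1L, nt)
  for (i in seq_along(axis)) {
    cells <- suppressWarnings(as.numeric(strsplit(body[i + 1L], "\t", fixed = TRUE)[[1]]))
    if (length(cells) != nt + 1L)
      stop(sprintf("format error: row %d has %d values but the header has %d times",
                   i, length(cells) - 1L, nt))
    if (anyNA(cells))
      stop(sprintf("format error: non-numeric cell in row %d", i))
    axis[i] <- cells[1]
    values[i, ] <- cells[-1]
  }
  if (any(times <= 0)) stop("format error: non-positive time in header")
  d <- diff(axis)
  if (length(axis) > 1L && !(all(d > 0) || all(d < 0)))
    stop("format error: channel axis column is not strictly monotonic")
  spectral_dataset(axis, times, values,
                   modality = meta$modality, segment = meta$segment,
                   axis_unit = meta$axis_unit)
}

#' Merge an early and a late acquisition segment
#'
#' Combines a sub-microsecond (e.g. step-scan) and a slower (e.g.
#' rapid-scan) segment recorded on the same channel axis into one dataset
#' spanning the full photocycle. Under `overlap_policy = "scale_late"` the
#' late segment is first multiplied by the scalar minimising the squared
#' difference to the early segment over the overlapping time window
#' (\eqn{s = \sum xy / \sum y^2} over overlap cells); under `"none"` the
#' segments are concatenated unchanged. Duplicate time points are averaged
#' so the merged time axis is strictly increasing.
#'
#' @param early,late [spectral_dataset()] objects with identical axes.
#' @param overlap_policy `"scale_late"` or `"none"`.
#' @return A merged [spectral_dataset()] with segment label `"merged"`.
#'   The fitted scale factor is attached as attribute `"scale"`.
#' @export
merge_segments <- function(early, late, overlap_policy = c("scale_late", "none")) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(inherits(early, "spectral_dataset"), inherits(late, "spectral_dataset"))
  if (length(early$axis) != length(late$axis) ||
      any(abs(early$axis - late$axis) > 1e-9 * pmax(1, abs(early$axis))))
    stop("segments have disjoint channel axes; merging requires identical axes")
  if (!identical(early$modality, late$modality))
    stop("segments have different modalities")
  lo <- min(late$times); hi <- max(early$times)
  e_in <- early$times >= lo & early$times <= hi
  l_in <- late$times >= lo & late$times <= hi
  scale <- 1
  if (overlap_policy == "scale_late") {
    if (!any(e_in) || !any(l_in))
      stop("empty overlap window: policy 'scale_late' needs overlapping times")
    x <- early$values[, e_in, drop = FALSE]
    y <- late$values[, l_in, drop = FALSE]
    # align by matching each early overlap column to the nearest late column
    j <- vapply(early$times[e_in],
                function(t) which.min(abs(late$times[l_in] - t)), integer(1))
    y <- y[, j, drop = FALSE]
    syy <- sum(y * y)
    if (syy == 0) stop("late segment is zero over the overlap window")
    scale <- sum(x * y) / syy
  }
  lv <- late$values * scale
  all_t <- c(early$times, late$times)
  all_v <- cbind(early$values, lv)
  o <- order(all_t)
  all_t <- all_t[o]; all_v <- all_v[, o, drop = FALSE]
  keep_t <- unique(all_t)
  out <- matrix(0, nrow(all_v), length(keep_t))
  for (k in seq_along(keep_t)) {
    cols <- which(all_t == keep_t[k])
    out[, k] <- rowMeans(all_v[, cols, drop = FALSE])
  }
  m <- spectral_dataset(early$axis, keep_t, out, modality = early$modality,
                        segment = "merged", axis_unit = early$axis_unit)
  attr(m, "scale") <- scale
  m
}

#' Extract a marker-band kinetic trace
#'
#' Averages the difference absorbance over all channels inside
#' `[center - bandwidth/2, center + bandwidth/2]`, per time point.
#'
#' @param dataset a [spectral_dataset()].
#' @param center channel position of the band of interest.
#' @param bandwidth window width in axis units; `0` selects the single
#'   nearest grid point only if it lies exactly at `center`.
#' @return A [kinetic_trace()].
#' @export
extract_trace <- function(dataset, center, bandwidth = 0) {
  stopifnot(inherits(dataset, "spectral_dataset"), bandwidth >= 0)
  tol <- 1e-9 * max(1, abs(center))
  idx <- which(dataset$axis >= center - bandwidth / 2 - tol &
               dataset$axis <= center + bandwidth / 2 + tol)
  if (length(idx) == 0L)
    stop(sprintf("window [%g, %g] contains no channel",
                 center - bandwidth / 2, center + bandwidth / 2))
  v <- colMeans(dataset$values[idx, , drop = FALSE])
  kinetic_trace(center, bandwidth, dataset$times, v)
}

#' Time-window difference spectrum
#'
#' Per-channel mean of the difference absorbance over all time columns in
#' the closed window `[t_lo, t_hi]`.
#'
#' @param dataset a [spectral_dataset()].
#' @param t_lo,t_hi window bounds in seconds.
#' @return A [spectrum()].
#' @export
difference_spectrum_at <- function(dataset, t_lo, t_hi) {
  stopifnot(inherits(dataset, "spectral_dataset"), t_lo <= t_hi)
  idx <- which(dataset$times >= t_lo & dataset$times <= t_hi)
  if (length(idx) == 0L)
    stop(sprintf("time window [%g, %g] s contains no sample", t_lo, t_hi))
  spectrum(dataset$axis, rowMeans(dataset$values[, idx, drop = FALSE]),
           label = sprintf("mean over %g-%g s", t_lo, t_hi))
}
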