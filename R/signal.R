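# Extracted-ion chromatograms and peak detection/integration. This replaces
# the vendor integration step of a typical HRMS workflow with a transparent,
# parameter-documented equivalent: median baseline, MAD noise, moving-average
# smoothing for apex finding only, valley-or-1%-of-apex boundaries, and
# trapezoidal areas on the raw (unsmoothed) trace.

#' Read raw trace points
#'
#' Long-format TSV with columns `rt_min`, `mz`, `intensity`, or a centroided
#' mzML file when the `mzR` package is available (retention times are
#' converted from seconds to minutes).
#'
#' @param path File path (`.tsv`/`.txt` long format, or `.mzML`).
#' @return data.frame with columns `rt_min`, `mz`, `intensity`.
#' @export
read_trace_points <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("mzR", quietly = TRUE)) {
      stop("reading mzML requires the 'mzR' package")
    }
    handle <- mzR::openMSfile(path)
    on.exit(mzR::close(handle))
    hdr <- mzR::header(handle)
    ms1 <- which(hdr$msLevel == 1L)
    pk <- mzR::peaks(handle, ms1)
    if (is.matrix(pk)) pk <- list(pk)
    n <- vapply(pk, nrow, integer(1))
    return(data.frame(
      rt_min = rep(hdr$retentionTime[ms1] / 60, n),
      mz = unlist(lapply(pk, function(m) m[, 1])),
      intensity = unlist(lapply(pk, function(m) m[, 2]))
    ))
  }
  pts <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("rt_min", "mz", "intensity"), names(pts))
  if (length(missing_cols) > 0) {
    stop("trace file misses column(s): ", paste(missing_cols, collapse = ", "))
  }
  pts
}

#' Extract an ion chromatogram around a target m/z
#'
#' Sums, per scan (i.e. per distinct retention time in the run), the intensity
#' of all points within `+/- ppm_window` of `target_mz`. Scans with no points
#' in the window contribute zero, so the trace lives on the full acquisition
#' RT grid.
#'
#' @param run data.frame of centroided points (`rt_min`, `mz`, `intensity`) or
#'   a file path accepted by [read_trace_points()].
#' @param target_mz Target m/z (positive).
#' @param ppm_window Half-width of the extraction window in ppm (positive).
#' @return An object of class `ba_trace`: list with `rt` (minutes, strictly
#'   increasing), `intensity`, `target_mz`, `ppm_window`.
#' @export
extract_xic <- function(run, target_mz, ppm_window) {
  if (is.character(run)) {
    run <- read_trace_points(run)
  }
  if (nrow(run) == 0) {
    stop("empty run: no points to extract from")
  }
  if (!is.numeric(ppm_window) || ppm_window <= 0) {
    stop("ppm_window must be positive")
  }
  stopifnot(target_mz > 0)
  grid <- sort(unique(run$rt_min))
  tol <- target_mz * ppm_window * 1e-6
  sel <- abs(run$mz - target_mz) <= tol
  intensity <- numeric(length(grid))
  if (any(sel)) {
    sums <- tapply(run$intensity[sel], match(run$rt_min[sel], grid), sum)
    intensity[as.integer(names(sums))] <- as.numeric(sums)
  }
  structure(
    list(rt = grid, intensity = intensity,
         target_mz = target_mz, ppm_window = ppm_window),
    class = "ba_trace"
  )
}

#' @export
print.ba_trace <- function(x, ...) {
  cat(sprintf("<ba_trace> m/z %.4f +/- %g ppm, %d scans, RT %.2f-%.2f min\n",
              x$target_mz, x$ppm_window, length(x$rt),
              min(x$rt), max(x$rt)))
  invisible(x)
}

# centred moving average, edges padded by shrinking the window
moving_average <- function(x, window) {
  if (window <= 1 || length(x) < window) {
    return(x)
  }
  half <- window %/% 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Detect and integrate peaks in a trace
#'
#' Baseline is the trace median and noise is the median absolute deviation
#' scaled by 1.4826 (both robust and parameter free). Apexes are local maxima
#' of a 5-point moving average exceeding `baseline + min_snr * noise`; peak
#' boundaries extend from the apex to the nearest valley or to the point where
#' the raw trace falls below 1% of the apex, whichever comes first. Areas are
#' trapezoidal integrals of the raw trace, so smoothing never biases the area.
#'
#' @param trace A `ba_trace` from [extract_xic()] (or any list with numeric
#'   `rt` and `intensity` of equal length).
#' @param min_snr Minimum apex signal-to-noise over baseline (default 3).
#' @param min_points Minimum number of scans between the boundaries
#'   (default 5).
#' @param smooth_window Moving-average window in points used only for apex
#'   finding (default 5).
#' @return data.frame of peaks sorted by RT: `apex_rt`, `left_rt`, `right_rt`,
#'   `area`, `apex_intensity`, `snr`. Zero rows when nothing is detected.
#' @export
detect_peaks <- function(trace, min_snr = 3, min_points = 5,
                         smooth_window = 5) {
  rt <- trace$rt
  y <- trace$intensity
  stopifnot(length(rt) == length(y), !is.unsorted(rt, strictly = TRUE))
  empty <- data.frame(apex_rt = numeric(0), left_rt = numeric(0),
                      right_rt = numeric(0), area = numeric(0),
                      apex_intensity = numeric(0), snr = numeric(0))
  if (length(y) < min_points || all(y <= 0)) {
    return(empty)
  }
  baseline <- stats::median(y)
  noise <- stats::mad(y)   # 1.4826 * MAD by R's default constant
  if (noise == 0) noise <- stats::sd(y)  # degenerate (mostly-flat) traces
  threshold <- baseline + min_snr * noise
  ys <- moving_average(y, smooth_window)

  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] > ys[1:(n - 2)] &
                     ys[2:(n - 1)] >= ys[3:n], FALSE)
  cand <- which(is_max & ys > threshold & y > baseline)
  if (length(cand) == 0) {
    return(empty)
  }

  # outward walk from a smoothed maximum: the boundary is the nearest valley
  # (a rebound above the running minimum larger than the noise level) or the
  # point where the signal falls to 1% of the baseline-corrected apex height
  walk_boundary <- function(i, dir) {
    cutoff <- baseline + 0.01 * (ys[i] - baseline)
    j <- i
    min_j <- i
    min_v <- ys[i]
    while (j + dir >= 1L && j + dir <= n) {
      j <- j + dir
      if (ys[j] < min_v) {
        min_v <- ys[j]
        min_j <- j
      }
      if (ys[j] <= cutoff) {
        return(j)
      }
      if (ys[j] > min_v + noise) {
        return(min_j)
      }
    }
    min_j
  }
  peaks <- lapply(cand, function(i) {
    left <- walk_boundary(i, -1L)
    right <- walk_boundary(i, +1L)
    if (right - left < 2L) {
      return(c(apex = i, left = left, right = right))
    }
    # apex refined on the raw trace, interior to the boundaries
    interior <- (left + 1L):(right - 1L)
    apex <- interior[which.max(y[interior])]
    c(apex = apex, left = left, right = right)
  })
  peaks <- unique(do.call(rbind, peaks))
  keep <- (peaks[, "right"] - peaks[, "left"] + 1L) >= min_points &
    peaks[, "left"] < peaks[, "apex"] & peaks[, "apex"] < peaks[, "right"]
  peaks <- peaks[keep, , drop = FALSE]
  if (nrow(peaks) == 0) {
    return(empty)
  }
  # merge candidates resolving to overlapping supports: keep the tallest
  peaks <- peaks[order(peaks[, "apex"]), , drop = FALSE]
  kept <- list()
  for (k in seq_len(nrow(peaks))) {
    if (length(kept) > 0) {
      last <- kept[[length(kept)]]
      if (peaks[k, "left"] < last["right"]) {
        if (y[peaks[k, "apex"]] > y[last["apex"]]) {
          kept[[length(kept)]] <- peaks[k, ]
        }
        next
      }
    }
    kept[[length(kept) + 1L]] <- peaks[k, ]
  }
  peaks <- do.call(rbind, kept)
  out <- data.frame(
    apex_rt = rt[peaks[, "apex"]],
    left_rt = rt[peaks[, "left"]],
    right_rt = rt[peaks[, "right"]],
    area = vapply(seq_len(nrow(peaks)), function(k) {
      idx <- peaks[k, "left"]:peaks[k, "right"]
      pracma::trapz(rt[idx], y[idx])
    }, numeric(1)),
    apex_intensity = y[peaks[, "apex"]],
    snr = (y[peaks[, "apex"]] - baseline) / max(noise, .Machine$double.eps)
  )
  out <- out[!duplicated(out$apex_rt), , drop = FALSE]
  out <- out[order(out$apex_rt), , drop = FALSE]
  rownames(out) <- NULL
  out
}
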