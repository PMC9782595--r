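# Calcium signal layer: dF/F normalization and Schmitt-trigger binarization.

#' Estimate the per-ROI resting fluorescence baseline
#'
#' The baseline F0 of each ROI is a low running percentile of its raw trace:
#' neurons at rest sit at the bottom of the fluorescence distribution while
#' calcium transients only add mass above it. By default the 10th percentile
#' of the full recording is used; when `window` is given, the trace is split
#' into windows of that length, the percentile is taken per window, and the
#' per-ROI baseline is the median across windows (robust to slow drift).
#'
#' @param traces a `trace_set`.
#' @param window optional window length in seconds.
#' @param percentile percentile in (0, 1), default 0.1.
#' @return numeric vector of per-ROI baselines (strictly positive).
#' @export
estimate_baseline <- function(traces, window = NULL, percentile = 0.1) {
  assert_number(percentile, "percentile", 0, 1)
  if (percentile <= 0 || percentile >= 1) stopf("`percentile` must be in (0, 1)")
  v <- traces$values
  if (any(apply(v, 1, function(x) all(x == 0))))
    stopf("baseline undefined: at least one trace is identically zero")
  if (is.null(window)) {
    f0 <- apply(v, 1, quantile, probs = percentile, names = FALSE)
  } else {
    assert_number(window, "window", 0, strict_lower = TRUE)
    wf <- max(1L, round(window * traces$fps))
    idx <- split(seq_len(ncol(v)), ceiling(seq_len(ncol(v)) / wf))
    f0 <- apply(v, 1, function(x) {
      median(vapply(idx, function(i) quantile(x[i], percentile, names = FALSE),
                    numeric(1)))
    })
  }
  if (any(f0 <= 0)) stopf("baseline must be strictly positive for all ROIs")
  unname(f0)
}

#' Normalize fluorescence traces to percent dF/F
#'
#' Applies `dFF_i(t) = 100 * (F_i(t) - F0_i) / F0_i` per ROI.
#'
#' @param traces a `trace_set`.
#' @param baseline per-ROI baseline F0; estimated with [estimate_baseline()]
#'   when omitted.
#' @return a `dff_trace_set`: `values` (ROI x frame, percent), `fps`,
#'   `baseline`, `roi_meta`.
#' @export
dff_normalize <- function(traces, baseline = NULL) {
  baseline <- baseline %||% estimate_baseline(traces)
  if (length(baseline) != nrow(traces$values))
    stopf("baseline length must match ROI count")
  if (any(baseline <= 0)) stopf("baseline must be strictly positive")
  values <- 100 * sweep(sweep(traces$values, 1, baseline, "-"), 1, baseline, "/")
  structure(list(values = values, fps = traces$fps, baseline = baseline,
                 roi_meta = traces$roi_meta),
            class = "dff_trace_set")
}

#' @export
print.dff_trace_set <- function(x, ...) {
  cat(sprintf("<dff_trace_set: %d ROIs x %d frames @ %g fps>\n",
              nrow(x$values), ncol(x$values), x$fps))
  invisible(x)
}

# Robust per-trace noise scale: MAD of the first difference, rescaled by
# sqrt(2) so that on pure iid Gaussian noise it estimates the noise sd.
noise_sigma <- function(x) mad(diff(x)) / sqrt(2)

# Noise multiples for the default Schmitt thresholds. The on-threshold must
# sit several sigma above noise so baseline frames never fire, and the
# hysteresis gap (high - low) must be ~5 sigma wide: once a ROI switches off
# on the slow calcium decay, a re-onset requires noise to jump the whole
# gap, and a narrower gap produces spurious echo onsets on every burst tail
# at 50 fps x 10^3 ROIs.
SCHMITT_HIGH_SIGMA <- 6
SCHMITT_LOW_SIGMA <- 1

#' Binarize dF/F traces with a Schmitt trigger
#'
#' Two-threshold hysteresis: a ROI switches on when its dF/F reaches `high`
#' and switches off only when it falls below `low`; the initial state is
#' off. When thresholds are omitted they default to 6 and 1 times a
#' robust per-ROI noise scale (MAD of the trace derivative), which adapts to
#' the recording's noise level while keeping noise-triggered onsets rare at
#' 50 fps.
#'
#' @param dff a `dff_trace_set`.
#' @param high,low thresholds in %dF/F, `high > low`; `NULL` for the
#'   noise-scaled defaults.
#' @return an `event_raster`: `bits` (ROI x frame 0/1 matrix), `fps`,
#'   `roi_meta`.
#' @export
schmitt_binarize <- function(dff, high = NULL, low = NULL) {
  v <- dff$values
  n <- nrow(v)
  sig <- if (is.null(high) || is.null(low)) apply(v, 1, noise_sigma) else NULL
  hi <- if (is.null(high)) SCHMITT_HIGH_SIGMA * sig else rep_len(high, n)
  lo <- if (is.null(low)) SCHMITT_LOW_SIGMA * sig else rep_len(low, n)
  if (any(hi <= lo)) stopf("`high` must exceed `low`")
  bits <- matrix(0L, n, ncol(v))
  for (i in seq_len(n)) {
    s <- rep(NA_integer_, ncol(v))
    s[v[i, ] >= hi[i]] <- 1L
    s[v[i, ] < lo[i]] <- 0L
    idx <- which(!is.na(s))
    if (length(idx)) {
      pos <- findInterval(seq_along(s), idx)
      bits[i, ] <- c(0L, s[idx])[pos + 1L]
    }
  }
  new_event_raster(bits, dff$fps, dff$roi_meta)
}

new_event_raster <- function(bits, fps, roi_meta = NULL) {
  if (!all(bits %in% c(0L, 1L))) stopf("raster entries must be 0 or 1")
  assert_number(fps, "fps", 0, strict_lower = TRUE)
  structure(list(bits = bits, fps = fps, roi_meta = roi_meta),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("<event_raster: %d ROIs x %d frames @ %g fps, %d active frames>\n",
              nrow(x$bits), ncol(x$bits), x$fps, sum(x$bits)))
  invisible(x)
}

# Onset frames (1-based) per ROI: first frame of each 0->1 transition; a
# train that starts at 1 counts frame 1 as an onset. This onset convention
# feeds all burst statistics.
raster_onsets <- function(raster) {
  lapply(seq_len(nrow(raster$bits)), function(i) {
    b <- raster$bits[i, ]
    which(b == 1L & c(0L, b[-length(b)]) == 0L)
  })
}

#' Convenience wrapper: traces to event raster
#'
#' Chains [estimate_baseline()], [dff_normalize()] and [schmitt_binarize()].
#'
#' @param traces a `trace_set`.
#' @param percentile baseline percentile.
#' @param window optional baseline window (seconds).
#' @param high,low Schmitt thresholds (`NULL` = noise-scaled defaults).
#' @return an `event_raster`.
#' @export
binarize_traces <- function(traces, percentile = 0.1, window = NULL,
                            high = NULL, low = NULL) {
  schmitt_binarize(dff_normalize(traces,
                                 estimate_baseline(traces, window, percentile)),
                   high = high, low = low)
}

#' Lay out a square ROI grid over the field of view
#'
#' Tiles the square field with `grid` x `grid` ROIs and drops tiles whose
#' centres fall outside the mask (regions without tissue). With a circular
#' mask of diameter equal to the field side, a 40 x 40 grid retains about
#' 1300 tiles. Order is row-major; the origin is the field centre.
#'
#' @param field_side field of view side in mm (default 7.1).
#' @param grid tiles per side.
#' @param mask `NULL` (keep all) or `list(shape = "circle", radius = ,
#'   center = c(x, y))`.
#' @return data.frame with `roi`, `row`, `col`, `x`, `y` (tile centres, mm).
#' @export
grid_rois <- function(field_side = 7.1, grid = 40, mask = NULL) {
  if (grid < 1) stopf("`grid` must be at least 1")
  tile <- field_side / grid
  g <- expand.grid(col = seq_len(grid), row = seq_len(grid))
  g <- g[order(g$row, g$col), ]
  x <- -field_side / 2 + (g$col - 0.5) * tile
  y <- field_side / 2 - (g$row - 0.5) * tile
  keep <- rep(TRUE, nrow(g))
  if (!is.null(mask)) {
    if (!identical(mask$shape, "circle")) stopf("only circular masks are supported")
    ctr <- mask$center %||% c(0, 0)
    keep <- (x - ctr[1])^2 + (y - ctr[2])^2 <= mask$radius^2
  }
  out <- data.frame(roi = seq_len(sum(keep)), row = g$row[keep],
                    col = g$col[keep], x = x[keep], y = y[keep])
  rownames(out) <- NULL
  out
}
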