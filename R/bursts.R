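# Network burst detection and activity statistics.

#' Detect network bursts in an event raster
#'
#' Event onsets (first frame of each 0->1 transition, pooled over ROIs) are
#' chained: consecutive onsets closer than `window` seconds belong to the
#' same candidate event, which covers both the near-synchronous volleys of
#' homogeneous cultures and the cascading activations of aggregated ones.
#' Candidates recruiting at least `min_fraction` of the live ROIs are kept
#' as network bursts. Defaults: `min_fraction` 0.5 for homogeneous mode
#' (bursts practically engage the whole network) and 0.1 for aggregated
#' mode (cascades typically engage 10-20% of the islands).
#'
#' @param raster an `event_raster`.
#' @param window chaining window in seconds (default 0.2).
#' @param min_fraction minimum participation fraction of live ROIs; `NULL`
#'   picks the mode default.
#' @param mode `"homogeneous"` or `"aggregated"`.
#' @param live optional logical/integer vector marking live ROIs (removed
#'   ROIs are excluded from the participation denominator); defaults to the
#'   `removed` column of `roi_meta` when present, else all ROIs.
#' @return a `burst_sequence`: data.frame `bursts` (`onset`, `offset` in
#'   seconds, `n_participants`, `fraction`), list `participants` of ROI id
#'   vectors, `mode`, `n_live`.
#' @export
detect_network_bursts <- function(raster, window = 0.2, min_fraction = NULL,
                                  mode = c("homogeneous", "aggregated"),
                                  live = NULL) {
  mode <- match.arg(mode)
  assert_number(window, "window", 0, strict_lower = TRUE)
  min_fraction <- min_fraction %||% if (mode == "homogeneous") 0.5 else 0.1
  assert_number(min_fraction, "min_fraction", 0, 1)
  if (min_fraction <= 0) stopf("`min_fraction` must be in (0, 1]")
  if (nrow(raster$bits) == 0 || ncol(raster$bits) == 0) stopf("empty raster")
  live <- resolve_live(raster, live)
  onsets <- raster_onsets(raster)
  roi <- rep(seq_along(onsets), lengths(onsets))
  tm <- (unlist(onsets) - 1) / raster$fps
  keep <- roi %in% live
  roi <- roi[keep]; tm <- tm[keep]
  o <- order(tm)
  roi <- roi[o]; tm <- tm[o]
  bursts <- data.frame(onset = numeric(0), offset = numeric(0),
                       n_participants = integer(0), fraction = numeric(0))
  participants <- list()
  if (length(tm)) {
    grp <- cumsum(c(1, diff(tm) > window))
    for (g in unique(grp)) {
      sel <- grp == g
      ids <- unique(roi[sel])
      frac <- length(ids) / length(live)
      if (frac >= min_fraction) {
        bursts <- rbind(bursts, data.frame(
          onset = min(tm[sel]), offset = max(tm[sel]),
          n_participants = length(ids), fraction = frac))
        participants[[length(participants) + 1L]] <- ids
      }
    }
  }
  rownames(bursts) <- NULL
  structure(list(bursts = bursts, participants = participants, mode = mode,
                 n_live = length(live)),
            class = "burst_sequence")
}

resolve_live <- function(raster, live) {
  if (is.null(live)) {
    rm <- raster$roi_meta$removed
    if (!is.null(rm)) which(!rm) else seq_len(nrow(raster$bits))
  } else if (is.logical(live)) which(live) else as.integer(live)
}

#' @export
print.burst_sequence <- function(x, ...) {
  cat(sprintf("<burst_sequence: %d bursts (%s mode, %d live ROIs)>\n",
              nrow(x$bursts), x$mode, x$n_live))
  invisible(x)
}

#' Inter-burst intervals
#'
#' Onset-to-onset differences between consecutive network bursts, in
#' seconds. With fewer than two bursts the IBI is empty (with a warning).
#'
#' @param bursts a `burst_sequence`.
#' @return numeric vector of length `n_bursts - 1`.
#' @export
inter_burst_intervals <- function(bursts) {
  if (nrow(bursts$bursts) < 2) {
    warning("fewer than 2 bursts: no inter-burst intervals", call. = FALSE)
    return(numeric(0))
  }
  diff(bursts$bursts$onset)
}

#' Network activity A
#'
#' The collective firing frequency of the culture: the inverse of the mean
#' inter-burst interval, in bursts per second.
#'
#' @param bursts a `burst_sequence`.
#' @return A, in 1/s.
#' @export
network_activity <- function(bursts) {
  ibis <- suppressWarnings(inter_burst_intervals(bursts))
  if (length(ibis) == 0) stopf("network activity undefined with fewer than 2 bursts")
  1 / mean(ibis)
}

#' Activity ratio after vs before damage
#'
#' `Phi = A_after / A_before`: 1 means unchanged activity, below 1 a
#' depression, above 1 a boost.
#'
#' @param a_after,a_before network activities (or region burst counts).
#' @return Phi.
#' @export
activity_ratio <- function(a_after, a_before) {
  if (a_before <= 0) stopf("`a_before` must be positive")
  a_after / a_before
}

#' Per-region network burst counts
#'
#' Runs burst detection independently within each region's ROI subset (the
#' participation threshold applies to the region's own live ROI count) and
#' returns the number of bursts per region, the activity measure used for
#' synchronously bursting subpopulations.
#'
#' @param raster an `event_raster`.
#' @param regions a `region_partition` (see [partition_regions()]) or a
#'   character vector of per-ROI labels.
#' @param window,min_fraction as in [detect_network_bursts()] (default
#'   `min_fraction` 0.5: within a region, bursting is synchronous).
#' @return named integer vector of burst counts per region (wound ROIs,
#'   having no live members, are skipped).
#' @export
region_burst_counts <- function(raster, regions, window = 0.2,
                                min_fraction = 0.5) {
  labels <- if (inherits(regions, "region_partition")) regions$labels else regions
  if (length(labels) != nrow(raster$bits))
    stopf("every ROI must carry a region label")
  live <- resolve_live(raster, NULL)
  out <- integer(0)
  for (rg in setdiff(unique(labels), "wound")) {
    members <- intersect(which(labels == rg), live)
    if (length(members) == 0) stopf("region '%s' has no live ROIs", rg)
    sub <- new_event_raster(raster$bits[members, , drop = FALSE], raster$fps)
    bs <- detect_network_bursts(sub, window = window,
                                min_fraction = min_fraction,
                                mode = "homogeneous")
    out[rg] <- nrow(bs$bursts)
  }
  out
}
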