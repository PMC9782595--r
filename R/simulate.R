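# Spontaneous activity and calcium fluorescence synthesis.
#
# Dynamics are a stochastic cascade (branching) process rather than a
# biophysical neuron model: spontaneous initiations arrive as a Poisson
# process over live nodes; each spike attempts to recruit its structural
# out-neighbours with probability proportional to the coupling weight, with
# a jittered millisecond transmission delay; refractoriness terminates the
# cascade. Only burst-level statistics matter downstream, and this minimal
# model reproduces them: near-whole-network synchronous bursts in
# homogeneous cultures, modular cascades engaging 10-20% of the network in
# aggregated cultures.

default_excitability <- function(kind) {
  if (kind == "aggregated") {
    list(init_rate = 0.40, trans_scale = 0.20,
         delay_min = 0.005, delay_max = 0.025, refractory = 0.1)
  } else {
    list(init_rate = 0.15, trans_scale = 0.90,
         delay_min = 0.002, delay_max = 0.010, refractory = 0.1)
  }
}

#' Simulate spontaneous bursting activity on a culture model
#'
#' Runs the probabilistic cascade model on the structural couplings.
#' Spontaneous initiations occur at total rate `init_rate` (events per
#' second over the whole intact network, shared uniformly across nodes, so a
#' damaged network initiates proportionally less). A spiking node recruits
#' each out-neighbour with probability `min(1, weight * trans_scale)` after
#' a delay drawn uniformly from `[delay_min, delay_max]`; a node spikes at
#' most once per cascade and is refractory for `refractory` seconds across
#' cascades. Removed nodes neither initiate nor relay.
#'
#' @param model a `culture_model`.
#' @param duration recording length in seconds.
#' @param excitability optional list overriding any of `init_rate`,
#'   `trans_scale`, `delay_min`, `delay_max`, `refractory`; defaults depend
#'   on `model$kind`.
#' @param seed integer seed; output is a pure function of
#'   `(model, duration, excitability, seed)`.
#' @return a `spike_trains` object: `events` (data.frame `roi`, `time` in
#'   seconds, sorted by time), `duration`, `n_roi`, `seed`.
#' @export
simulate_activity <- function(model, duration, excitability = NULL, seed = 1) {
  assert_number(duration, "duration", 0, strict_lower = TRUE)
  exc <- utils::modifyList(default_excitability(model$kind), excitability %||% list())
  n <- nrow(model$nodes)
  live <- live_nodes(model)
  p <- pmin(model$weights * exc$trans_scale, 1)
  adj_t <- lapply(seq_len(n), function(i) which(p[i, ] > 0))
  adj_p <- lapply(seq_len(n), function(i) p[i, adj_t[[i]]])
  deg <- lengths(adj_t)

  with_seed(seed, {
    rate <- exc$init_rate * length(live) / n
    n_init <- if (rate > 0) rpois(1, rate * duration) else 0L
    if (n_init == 0) {
      return(new_spike_trains(data.frame(roi = integer(0), time = numeric(0)),
                              duration, n, seed))
    }
    init_t <- sort(runif(n_init, 0, duration))
    init_node <- sample(live, n_init, replace = TRUE)
    last_spike <- rep(-Inf, n)
    ev_roi <- vector("list", n_init)
    ev_t <- vector("list", n_init)
    for (ci in seq_len(n_init)) {
      t0 <- init_t[ci]
      v0 <- init_node[ci]
      if (t0 - last_spike[v0] < exc$refractory) next
      in_cascade <- rep(FALSE, n)
      in_cascade[v0] <- TRUE
      last_spike[v0] <- t0
      c_roi <- v0
      c_t <- t0
      fr_n <- v0
      fr_t <- t0
      while (length(fr_n) > 0) {
        has_out <- deg[fr_n] > 0
        fr_n <- fr_n[has_out]; fr_t <- fr_t[has_out]
        if (!length(fr_n)) break
        tg <- unlist(adj_t[fr_n], use.names = FALSE)
        pr <- unlist(adj_p[fr_n], use.names = FALSE)
        src_t <- rep(fr_t, deg[fr_n])
        hit <- runif(length(tg)) < pr
        if (!any(hit)) break
        tg <- tg[hit]
        t_new <- src_t[hit] + runif(sum(hit), exc$delay_min, exc$delay_max)
        ok <- !in_cascade[tg] & (t_new - last_spike[tg] >= exc$refractory) &
          t_new < duration
        tg <- tg[ok]; t_new <- t_new[ok]
        if (!length(tg)) break
        o <- order(t_new)
        tg <- tg[o]; t_new <- t_new[o]
        first <- !duplicated(tg)
        tg <- tg[first]; t_new <- t_new[first]
        in_cascade[tg] <- TRUE
        last_spike[tg] <- t_new
        c_roi <- c(c_roi, tg)
        c_t <- c(c_t, t_new)
        fr_n <- tg
        fr_t <- t_new
      }
      ev_roi[[ci]] <- c_roi
      ev_t[[ci]] <- c_t
    }
    events <- data.frame(roi = unlist(ev_roi), time = unlist(ev_t))
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
    new_spike_trains(events, duration, n, seed)
  })
}

new_spike_trains <- function(events, duration, n_roi, seed) {
  stopifnot(all(events$time >= 0), all(events$time < duration + 1e-12))
  structure(list(events = events, duration = duration, n_roi = n_roi,
                 seed = seed),
            class = "spike_trains")
}

#' @export
print.spike_trains <- function(x, ...) {
  cat(sprintf("<spike_trains: %d events, %d ROIs, %.1f s>\n",
              nrow(x$events), x$n_roi, x$duration))
  invisible(x)
}

#' Render calcium fluorescence traces from spike trains
#'
#' Each spike adds a causal difference-of-exponentials calcium transient
#' (fast rise, slow GCaMP6s-like decay, peak `amplitude` %dF/F) to its ROI's
#' trace; per-ROI transients sum and saturate at `cap`. Raw fluorescence is
#' `baseline * (1 + dFF/100)` plus Gaussian noise with standard deviation
#' `noise_sd * baseline`, sampled at `fps` frames per second (frame i holds
#' time `(i-1)/fps`).
#'
#' @param spikes a `spike_trains` object.
#' @param rise,decay kernel time constants in seconds (`decay > rise > 0`).
#' @param amplitude single-spike peak, in %dF/F.
#' @param cap saturation ceiling of the summed transient, %dF/F.
#' @param noise_sd additive noise sd as a fraction of baseline (>= 0).
#' @param baseline resting fluorescence, arbitrary units.
#' @param fps sampling rate in frames per second (50 in the standard
#'   recording configuration).
#' @param seed seed for the noise draw.
#' @param roi_meta optional data.frame of per-ROI metadata (e.g. the model's
#'   node table), carried through to downstream stages.
#' @return a `trace_set`: `values` (ROI x frame matrix of raw fluorescence),
#'   `fps`, `roi_meta`.
#' @export
render_fluorescence <- function(spikes, rise = 0.1, decay = 1.0,
                                amplitude = 20, cap = 300, noise_sd = 0.02,
                                baseline = 100, fps = 50, seed = 1,
                                roi_meta = NULL) {
  if (!(decay > rise && rise > 0)) stopf("need decay > rise > 0")
  assert_number(noise_sd, "noise_sd", 0)
  assert_number(fps, "fps", 0, strict_lower = TRUE)
  n <- spikes$n_roi
  t_frames <- round(spikes$duration * fps)
  # normalize kernel to unit peak, then scale to `amplitude`
  t_peak <- log(decay / rise) * rise * decay / (decay - rise)
  k_peak <- exp(-t_peak / decay) - exp(-t_peak / rise)
  support <- ceiling(6 * decay * fps)
  dff <- matrix(0, n, t_frames)
  if (nrow(spikes$events) > 0) {
    for (e in seq_len(nrow(spikes$events))) {
      s <- spikes$events$time[e]
      i <- spikes$events$roi[e]
      f0 <- floor(s * fps) + 1L
      fr <- f0:min(t_frames, f0 + support)
      if (fr[1] > t_frames) next
      tau <- (fr - 1) / fps - s
      tau[tau < 0] <- 0
      dff[i, fr] <- dff[i, fr] +
        (amplitude / k_peak) * (exp(-tau / decay) - exp(-tau / rise))
    }
  }
  dff[dff > cap] <- cap
  values <- baseline * (1 + dff / 100)
  if (noise_sd > 0) {
    with_seed(seed, {
      values <- values + matrix(rnorm(n * t_frames, sd = noise_sd * baseline),
                                n, t_frames)
    })
  }
  new_trace_set(values, fps, roi_meta)
}

new_trace_set <- function(values, fps, roi_meta = NULL) {
  if (!all(is.finite(values))) stopf("trace values must be finite")
  assert_number(fps, "fps", 0, strict_lower = TRUE)
  structure(list(values = values, fps = fps, roi_meta = roi_meta),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set: %d ROIs x %d frames @ %g fps>\n",
              nrow(x$values), ncol(x$values), x$fps))
  invisible(x)
}
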