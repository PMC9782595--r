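# Damage protocols: sequential targeted attack / random failure on
# aggregated cultures, and the diametral-cut + recovery timeline on
# homogeneous cultures with region-resolved activity and interactions.

network_ids <- function(network) {
  ids <- rownames(network$adjacency)
  if (is.null(ids)) as.character(seq_len(nrow(network$adjacency))) else ids
}

#' Select the next damage target
#'
#' `bc_attack` picks the node with the highest betweenness centrality,
#' `degree_attack` the highest total degree, `random` a uniformly random
#' live node (seeded). Ties break to the lowest node id.
#'
#' @param network an `effective_network` whose dimnames are node ids.
#' @param scheme `"bc_attack"`, `"degree_attack"` or `"random"`.
#' @param seed seed for the random scheme.
#' @return the selected node id (integer).
#' @export
select_target <- function(network, scheme = c("bc_attack", "degree_attack",
                                              "random"), seed = 1) {
  scheme <- match.arg(scheme)
  ids <- as.integer(network_ids(network))
  if (length(ids) == 0) stopf("no live nodes to target")
  score <- switch(scheme,
    bc_attack = betweenness_centrality(network),
    degree_attack = node_degrees(network)$k,
    random = NULL
  )
  if (is.null(score)) {
    return(with_seed(seed, ids[sample.int(length(ids), 1)]))
  }
  ids[order(-score, ids)[1]]
}

#' Global efficiency excluding deleted nodes
#'
#' Geff depends on network size, so pre- and post-damage values are
#' compared on identical node sets: the deleted node(s) are excluded from
#' the pre-damage network before evaluating the mean inverse distance.
#'
#' @param network an `effective_network` (dimnames = node ids).
#' @param deleted node ids to exclude.
#' @return Geff of the node-induced subgraph without `deleted`.
#' @export
geff_excluding_deleted <- function(network, deleted) {
  pos <- match(as.character(deleted), network_ids(network))
  pos <- pos[!is.na(pos)]
  global_efficiency(network$adjacency, exclude = pos)
}

#' Run a sequential damage protocol on an aggregated culture
#'
#' Reproduces the chained damage experiment: at each step the culture's
#' spontaneous activity is recorded (simulated, rendered to fluorescence,
#' binarized), the effective network inferred, pre-damage metrics computed;
#' a target is selected by `scheme` and removed; activity is recorded again
#' and post-damage metrics computed; finally homeostatic recovery (the
#' 24 h rest between sessions) is applied. Geff is evaluated with the
#' step's deleted node excluded on both sides, so the compared networks are
#' size-matched. A step whose recording shows fewer than 2 network bursts
#' is flagged (activity extinction) and the sequence continues.
#'
#' @param model an aggregated `culture_model`.
#' @param scheme damage scheme, see [select_target()].
#' @param steps number of chained damage actions (default 8).
#' @param recording_s simulated recording length per stage, seconds
#'   (default 1200, i.e. 20 min).
#' @param recovery_strength homeostatic scaling strength between steps.
#' @param seed master seed; the whole record is a pure function of
#'   `(model, scheme, config, seed)`.
#' @param excitability optional overrides for [simulate_activity()].
#' @param fps imaging rate, frames per second.
#' @param burst_window,burst_fraction burst-detection parameters
#'   (aggregated-mode defaults).
#' @return a `damage_record`: `steps` data.frame (step, scheme, target,
#'   phi, geff_pre, geff_post, q_pre, q_post, n_bursts_pre, n_bursts_post,
#'   flagged), plus the final damaged model.
#' @export
run_damage_sequence <- function(model, scheme = c("bc_attack", "degree_attack",
                                                  "random"),
                                steps = 8, recording_s = 1200,
                                recovery_strength = 0.5, seed = 1,
                                excitability = NULL, fps = 50,
                                burst_window = 0.2, burst_fraction = 0.1) {
  scheme <- match.arg(scheme)
  if (steps < 1) stopf("`steps` must be >= 1")
  rows <- vector("list", steps)
  for (s in seq_len(steps)) {
    pre <- record_stage(model, recording_s, excitability, fps,
                        derive_seed(seed, 10 * s + 1),
                        burst_window, burst_fraction, mode = "aggregated")
    target <- select_target(pre$network, scheme,
                            seed = derive_seed(seed, 10 * s + 3))
    model <- apply_node_removal(model, target)
    post <- record_stage(model, recording_s, excitability, fps,
                         derive_seed(seed, 10 * s + 2),
                         burst_window, burst_fraction, mode = "aggregated")
    flagged <- is.na(pre$activity) || is.na(post$activity)
    rows[[s]] <- data.frame(
      step = s, scheme = scheme, target = target,
      phi = if (flagged) NA_real_ else post$activity / pre$activity,
      geff_pre = geff_excluding_deleted(pre$network, target),
      geff_post = global_efficiency(post$network),
      q_pre = pre$q, q_post = post$q,
      n_bursts_pre = pre$n_bursts, n_bursts_post = post$n_bursts,
      flagged = flagged
    )
    model <- homeostatic_recovery(model, recovery_strength,
                                  seed = derive_seed(seed, 10 * s + 4))
  }
  structure(list(steps = do.call(rbind, rows), model = model, scheme = scheme,
                 seed = seed),
            class = "damage_record")
}

# One recording stage: simulate -> render -> binarize -> bursts + network.
record_stage <- function(model, recording_s, excitability, fps, seed,
                         burst_window, burst_fraction, mode) {
  spikes <- simulate_activity(model, recording_s, excitability, seed = seed)
  traces <- render_fluorescence(spikes, fps = fps,
                                seed = derive_seed(seed, 1),
                                roi_meta = model$nodes)
  raster <- binarize_traces(traces)
  bursts <- detect_network_bursts(raster, window = burst_window,
                                  min_fraction = burst_fraction, mode = mode)
  activity <- if (nrow(bursts$bursts) >= 2) network_activity(bursts) else NA_real_
  network <- infer_effective_network(raster)
  q <- if (sum(network$adjacency) > 0)
    modularity_q(network, louvain_communities(network, seed = seed))
  else NA_real_
  list(raster = raster, bursts = bursts, activity = activity,
       n_bursts = nrow(bursts$bursts), network = network, q = q)
}

#' @export
print.damage_record <- function(x, ...) {
  cat(sprintf("<damage_record: %s, %d steps>\n", x$scheme, nrow(x$steps)))
  print(x$steps, digits = 3)
  invisible(x)
}

#' Partition a homogeneous culture into regions A/B/C/S around a cut
#'
#' Disc ROIs on either side of the diametral cut band become the halves
#' `A` (positive side) and `B`; disc ROIs inside the band are `wound`; the
#' outermost disc ring (PDMS walls, out of the scalpel's reach) is the
#' contour `C`; ROIs on the glass outside the disc are the surroundings
#' `S`. With the default geometry the fractions are approximately
#' A = B = 0.30, S = 0.25-0.30, C = 0.05-0.08.
#'
#' @param model a homogeneous `culture_model`.
#' @param angle cut direction, radians.
#' @param width wound width, micrometres.
#' @return a `region_partition`: `labels` (per-ROI character vector, names
#'   = node ids) and `fractions`.
#' @export
partition_regions <- function(model, angle = 0, width = 500) {
  if (model$kind != "homogeneous") stopf("partition_regions requires a homogeneous culture")
  half <- width / 1000 / 2
  p <- -sin(angle) * model$nodes$x + cos(angle) * model$nodes$y
  labels <- character(nrow(model$nodes))
  labels[model$nodes$region == "surroundings"] <- "S"
  labels[model$nodes$region == "contour"] <- "C"
  disc <- model$nodes$region == "disc"
  labels[disc & abs(p) <= half] <- "wound"
  labels[disc & p > half] <- "A"
  labels[disc & p < -half] <- "B"
  names(labels) <- model$nodes$id
  fr <- table(labels) / length(labels)
  structure(list(labels = labels, fractions = c(fr)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition>\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Count effective connections between regions
#'
#' Folds the directed effective network into region-level interaction
#' counts: `counts[r, s]` is the number of connections between regions r
#' and s in either direction (the diagonal counts within-region
#' connections); the unfolded directed counts are kept alongside.
#'
#' @param network an `effective_network` (dimnames = ROI ids).
#' @param partition a `region_partition` labelling every ROI.
#' @param stage optional stage label (e.g. "before", "2h").
#' @return a `region_interaction`: `counts` (symmetric fold), `directed`,
#'   `stage`.
#' @export
region_interaction_matrix <- function(network, partition, stage = NULL) {
  ids <- network_ids(network)
  lab <- partition$labels[ids]
  if (any(is.na(lab))) stopf("unlabeled ROI in network")
  regions <- sort(unique(partition$labels))
  d <- matrix(0L, length(regions), length(regions),
              dimnames = list(regions, regions))
  edges <- which(network$adjacency == 1, arr.ind = TRUE)
  if (nrow(edges)) {
    tab <- table(factor(lab[edges[, 1]], regions),
                 factor(lab[edges[, 2]], regions))
    d <- d + unclass(tab)
  }
  counts <- d + t(d)
  diag(counts) <- diag(d)
  structure(list(counts = counts, directed = d, stage = stage),
            class = "region_interaction")
}

#' @export
print.region_interaction <- function(x, ...) {
  cat(sprintf("<region_interaction%s>\n",
              if (is.null(x$stage)) "" else paste0(": ", x$stage)))
  print(x$counts)
  invisible(x)
}

#' Diametral-cut experiment with staged recovery
#'
#' Simulates the homogeneous-culture damage protocol: a recording before
#' damage, the scalpel cut, a recording just after, and recordings at the
#' preset recovery times 2 h, 6 h, 24 h and 3 days. Between recovery stages
#' the homeostatic scaling/sprouting rule is applied with stage-increasing
#' cumulative strength. Each stage yields per-region burst counts (the
#' activity measure for synchronously bursting subpopulations) and the
#' region-level interaction matrix of the inferred effective network.
#' Wounded ROIs emit no events from the cut onwards.
#'
#' @param model a homogeneous `culture_model`.
#' @param angle,width cut geometry (radians; micrometres).
#' @param stages stage labels; must start with `"before"`, then `"after"`,
#'   then recovery times present in `recovery_schedule`.
#' @param recording_s simulated recording length per stage (seconds).
#' @param seed master seed.
#' @param excitability optional overrides for [simulate_activity()].
#' @param fps imaging rate.
#' @param recovery_schedule named vector of cumulative recovery strengths
#'   at each post-damage stage.
#' @param burst_window,burst_fraction region burst-detection parameters.
#' @return a `recovery_timeline`: `partition`, per-stage list with
#'   `counts` (region burst counts) and `interaction`
#'   (`region_interaction`), and a `counts` matrix (stage x region).
#' @export
recovery_timeline <- function(model, angle = 0, width = 500,
                              stages = c("before", "after", "2h", "6h",
                                         "24h", "3d"),
                              recording_s = 900, seed = 1,
                              excitability = NULL, fps = 50,
                              recovery_schedule = c("2h" = 0.2, "6h" = 0.35,
                                                    "24h" = 0.6, "3d" = 0.85),
                              burst_window = 0.2, burst_fraction = 0.5) {
  if (model$kind != "homogeneous") stopf("recovery_timeline requires a homogeneous culture")
  partition <- partition_regions(model, angle, width)
  out <- list()
  cum_prev <- 0
  for (si in seq_along(stages)) {
    st <- stages[si]
    if (st == "after") {
      model <- apply_cut(model, angle, width)
    } else if (st != "before") {
      if (!st %in% names(recovery_schedule))
        stopf("stage '%s' missing from recovery_schedule", st)
      cum <- recovery_schedule[[st]]
      inc <- (cum - cum_prev) / (1 - cum_prev)
      model <- homeostatic_recovery(model, inc, outgrowth = cum,
                                    seed = derive_seed(seed, 100 + si))
      cum_prev <- cum
    }
    spikes <- simulate_activity(model, recording_s, excitability,
                                seed = derive_seed(seed, 10 * si))
    traces <- render_fluorescence(spikes, fps = fps,
                                  seed = derive_seed(seed, 10 * si + 1),
                                  roi_meta = model$nodes)
    raster <- binarize_traces(traces)
    counts <- region_burst_counts(raster, partition, window = burst_window,
                                  min_fraction = burst_fraction)
    network <- infer_effective_network(raster)
    out[[st]] <- list(stage = st, counts = counts,
                      interaction = region_interaction_matrix(network,
                                                              partition, st))
  }
  regions <- sort(setdiff(unique(partition$labels), "wound"))
  cmat <- t(vapply(out, function(e) e$counts[regions], numeric(length(regions))))
  dimnames(cmat) <- list(stages, regions)
  structure(list(partition = partition, stages = out, counts = cmat,
                 model = model, seed = seed),
            class = "recovery_timeline")
}

#' @export
print.recovery_timeline <- function(x, ...) {
  cat("<recovery_timeline: per-region burst counts>\n")
  print(x$counts)
  invisible(x)
}
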