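# File formats, configuration and the end-to-end pipeline driver.
#
# All artifacts are plain text: wide CSV for traces (a leading comment line
# carries the sampling rate), sparse CSV for rasters, TSV edge lists or
# GraphML for networks, JSON + TSV for culture models, YAML for
# configuration. Every writer round-trips through its paired reader.

write_header_csv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE)
}

read_header <- function(path) {
  line <- readLines(path, n = 1)
  if (!startsWith(line, "#")) stopf("missing metadata header in %s", path)
  parts <- strsplit(trimws(sub("^#", "", line)), "\\s+")[[1]]
  kv <- strsplit(parts, "=")
  setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
}

#' Write / read fluorescence traces (wide CSV)
#'
#' One row per ROI (`roi` column then one column per frame); a `# fps=`
#' comment line carries the sampling rate.
#'
#' @param traces a `trace_set`.
#' @param path file path.
#' @return `read_traces` returns a `trace_set`.
#' @export
write_traces <- function(traces, path) {
  df <- data.frame(roi = seq_len(nrow(traces$values)), traces$values)
  colnames(df) <- c("roi", paste0("f", seq_len(ncol(traces$values))))
  write_header_csv(df, path, sprintf("# fps=%g", traces$fps))
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  meta <- read_header(path)
  if (is.na(meta["fps"])) stopf("missing fps metadata in %s", path)
  df <- read.csv(path, comment.char = "#")
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stopf("non-numeric cell in %s", path)
  new_trace_set(unname(vals), as.numeric(meta["fps"]))
}

#' Write / read an event raster (sparse CSV)
#'
#' One data row per active run frame: `roi`, `frame` (1-based). The header
#' comment carries `fps`, `n_rois` and `n_frames`. Duplicate rows are
#' collapsed with a warning on read.
#'
#' @param raster an `event_raster`.
#' @param path file path.
#' @return `read_raster` returns an `event_raster`.
#' @export
write_raster <- function(raster, path) {
  idx <- which(raster$bits == 1L, arr.ind = TRUE)
  df <- data.frame(roi = idx[, 1], frame = idx[, 2])
  df <- df[order(df$roi, df$frame), , drop = FALSE]
  write_header_csv(df, path,
                   sprintf("# fps=%g n_rois=%d n_frames=%d",
                           raster$fps, nrow(raster$bits), ncol(raster$bits)))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- read_header(path)
  df <- read.csv(path, comment.char = "#")
  if (anyDuplicated(df)) {
    warning("duplicate (roi, frame) rows collapsed", call. = FALSE)
    df <- unique(df)
  }
  bits <- matrix(0L, as.integer(meta["n_rois"]), as.integer(meta["n_frames"]))
  if (nrow(df)) bits[cbind(df$roi, df$frame)] <- 1L
  new_event_raster(bits, as.numeric(meta["fps"]))
}

#' Write / read an effective network
#'
#' `tsv_edgelist` writes one row per directed connection (`src`, `dst`,
#' `z`), with node ids and the z threshold in the header comment; `graphml`
#' writes an igraph GraphML file with the z edge attribute, openable in
#' standard graph viewers.
#'
#' @param network an `effective_network`.
#' @param path file path.
#' @param format `"tsv_edgelist"` or `"graphml"`.
#' @return `read_network` returns an `effective_network` (z-scores are only
#'   preserved on edges; absent connections read back with z = -Inf
#'   replaced by 0 and no adjacency).
#' @export
write_network <- function(network, path, format = c("tsv_edgelist", "graphml")) {
  format <- match.arg(format)
  ids <- network_ids(network)
  if (format == "tsv_edgelist") {
    e <- which(network$adjacency == 1L, arr.ind = TRUE)
    df <- data.frame(src = ids[e[, 1]], dst = ids[e[, 2]],
                     z = network$z[e])
    df <- df[order(df$src, df$dst), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# z_min=%g ids=%s", network$threshold,
                       paste(ids, collapse = ";")), con)
    write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    g <- as_digraph(network$adjacency)
    igraph::V(g)$name <- ids
    e <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$z <- network$z[e]
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("tsv_edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv_edgelist") {
    line <- readLines(path, n = 1)
    zmin <- as.numeric(sub(".*z_min=([^ ]+).*", "\\1", line))
    ids <- strsplit(sub(".*ids=", "", line), ";")[[1]]
    df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                     colClasses = c("character", "character", "numeric"))
    n <- length(ids)
    adjacency <- matrix(0L, n, n, dimnames = list(ids, ids))
    z <- matrix(0, n, n, dimnames = list(ids, ids))
    if (nrow(df)) {
      adjacency[cbind(df$src, df$dst)] <- 1L
      z[cbind(df$src, df$dst)] <- df$z
    }
    structure(list(adjacency = adjacency, z = z, threshold = zmin),
              class = "effective_network")
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    adjacency <- as.matrix(igraph::as_adjacency_matrix(g))
    ids <- igraph::V(g)$name
    dimnames(adjacency) <- list(ids, ids)
    z <- matrix(0, nrow(adjacency), ncol(adjacency), dimnames = dimnames(adjacency))
    e <- igraph::as_edgelist(g, names = FALSE)
    if (nrow(e)) z[e] <- igraph::E(g)$z
    structure(list(adjacency = adjacency, z = z, threshold = NA_real_),
              class = "effective_network")
  }
}

#' Write / read spike trains (CSV)
#'
#' Columns `roi`, `time_s`; the header comment carries `duration`, `n_roi`
#' and `seed`.
#'
#' @param spikes a `spike_trains`.
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(roi = spikes$events$roi, time_s = spikes$events$time)
  write_header_csv(df, path, sprintf("# duration=%g n_roi=%d seed=%d",
                                     spikes$duration, spikes$n_roi,
                                     spikes$seed))
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  meta <- read_header(path)
  df <- read.csv(path, comment.char = "#")
  new_spike_trains(data.frame(roi = df$roi, time = df$time_s),
                   as.numeric(meta["duration"]), as.integer(meta["n_roi"]),
                   as.integer(meta["seed"]))
}

#' Write / read a culture model (JSON + edge-list TSV)
#'
#' `<path>.json` holds nodes, geometry, kind and bookkeeping; the
#' `<path>_edges.tsv` edge list holds `src`, `dst`, `weight`.
#'
#' @param model a `culture_model`.
#' @param path base path (no extension).
#' @export
write_culture <- function(model, path) {
  meta <- list(kind = model$kind, geometry = model$geometry,
               seed = model$seed, nodes = model$nodes,
               baseline_in = model$baseline_in)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  e <- which(model$weights > 0, arr.ind = TRUE)
  df <- data.frame(src = e[, 1], dst = e[, 2], weight = model$weights[e])
  df <- df[order(df$src, df$dst), , drop = FALSE]
  write.table(df, paste0(path, "_edges.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_culture
#' @export
read_culture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nodes <- as.data.frame(meta$nodes)
  n <- nrow(nodes)
  w <- matrix(0, n, n)
  df <- read.table(paste0(path, "_edges.tsv"), sep = "\t", header = TRUE)
  if (nrow(df)) w[cbind(df$src, df$dst)] <- df$weight
  geometry <- meta$geometry
  model <- structure(list(nodes = nodes, weights = w, kind = meta$kind,
                          geometry = geometry,
                          baseline_in = meta$baseline_in, seed = meta$seed),
                     class = "culture_model")
  validate_culture_model(model)
  model
}

#' Default pipeline configuration
#'
#' Nested list with one section per stage (`culture`, `dynamics`,
#' `imaging`, `signal`, `bursts`, `connectivity`, `metrics`, `damage`) plus
#' the global `seed`. Every field has a default; `NULL` means "use the
#' stage's own default". Unknown keys are rejected on validation.
#'
#' @return the configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    culture = list(kind = "aggregated", n_aggregates = 100, modules = 8,
                   p_within = 0.7, p_between = 0.0022, grid = 40, h = 0.7,
                   surroundings_removed = FALSE),
    dynamics = list(duration = 1200, init_rate = NULL, trans_scale = NULL),
    imaging = list(fps = 50, noise_sd = 0.02, baseline = 100, rise = 0.1,
                   decay = 1.0, amplitude = 20),
    signal = list(percentile = 0.1, window = NULL, high = NULL, low = NULL),
    bursts = list(window = 0.2, min_fraction = NULL),
    connectivity = list(markov_order = 2, instant_feedback = TRUE, bin = 1,
                        z_min = 1, include_self = TRUE),
    metrics = list(louvain_seed = 1),
    damage = list(scheme = "bc_attack", steps = 8, recovery_strength = 0.5,
                  angle = 0, width = 500,
                  stages = c("before", "after", "2h", "6h", "24h", "3d"))
  )
}

validate_config <- function(config) {
  ref <- default_config()
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (sec in intersect(names(config), setdiff(names(ref), "seed"))) {
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad)) stopf("unknown config key(s) in [%s]: %s", sec,
                           paste(bad, collapse = ", "))
  }
  utils::modifyList(ref, config, keep.null = TRUE)
}

#' Read / write pipeline configuration (YAML)
#'
#' @param config a configuration list (see [default_config()]).
#' @param path file path.
#' @return `read_config` returns the validated, default-completed
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(validate_config(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline from a configuration
#'
#' For an aggregated culture: generate the model and run the sequential
#' damage protocol (simulate, render, binarize, detect bursts, infer
#' effective connectivity, metrics, target selection, removal, recovery at
#' each step). For a homogeneous culture: generate the gridded disc model
#' and run the diametral-cut recovery timeline. Artifacts (damage steps
#' CSV or per-stage region counts/interaction TSVs, plus a JSON summary)
#' are written under `out_dir`; one log line per stage reports its
#' parameters. The whole run is a pure function of the configuration.
#'
#' @param config configuration list; missing fields take defaults.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log lines.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("neuroresil_"),
                         quiet = FALSE) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  seed <- cfg$seed
  exc <- Filter(Negate(is.null),
                cfg$dynamics[c("init_rate", "trans_scale")])
  if (cfg$culture$kind == "aggregated") {
    log_line("culture", "aggregated n=%d modules=%d seed=%d",
             cfg$culture$n_aggregates, cfg$culture$modules, seed)
    model <- generate_aggregated_culture(cfg$culture$n_aggregates,
                                         cfg$culture$modules,
                                         cfg$culture$p_within,
                                         cfg$culture$p_between,
                                         seed = derive_seed(seed, 1))
    log_line("damage", "scheme=%s steps=%d recording=%gs",
             cfg$damage$scheme, cfg$damage$steps, cfg$dynamics$duration)
    rec <- run_damage_sequence(model, cfg$damage$scheme,
                               steps = cfg$damage$steps,
                               recording_s = cfg$dynamics$duration,
                               recovery_strength = cfg$damage$recovery_strength,
                               seed = derive_seed(seed, 2),
                               excitability = if (length(exc)) exc else NULL,
                               fps = cfg$imaging$fps,
                               burst_window = cfg$bursts$window,
                               burst_fraction = cfg$bursts$min_fraction %||% 0.1)
    write.csv(rec$steps, file.path(out_dir, "damage_steps.csv"),
              row.names = FALSE)
    summary <- list(kind = "aggregated", config = cfg, steps = rec$steps)
  } else {
    log_line("culture", "homogeneous grid=%d h=%g seed=%d",
             cfg$culture$grid, cfg$culture$h, seed)
    model <- generate_homogeneous_culture(cfg$culture$grid, cfg$culture$h,
                                          cfg$culture$surroundings_removed,
                                          seed = derive_seed(seed, 1))
    log_line("damage", "cut angle=%g width=%gum stages=%s",
             cfg$damage$angle, cfg$damage$width,
             paste(cfg$damage$stages, collapse = ","))
    tl <- recovery_timeline(model, cfg$damage$angle, cfg$damage$width,
                            stages = cfg$damage$stages,
                            recording_s = cfg$dynamics$duration,
                            seed = derive_seed(seed, 2),
                            excitability = if (length(exc)) exc else NULL,
                            fps = cfg$imaging$fps)
    write.table(tl$counts, file.path(out_dir, "region_burst_counts.tsv"),
                sep = "\t", quote = FALSE, col.names = NA)
    for (st in names(tl$stages)) {
      write.table(tl$stages[[st]]$interaction$counts,
                  file.path(out_dir, sprintf("interaction_%s.tsv", st)),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
    summary <- list(kind = "homogeneous", config = cfg,
                    region_fractions = as.list(tl$partition$fractions),
                    burst_counts = as.data.frame(tl$counts))
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  log_line("report", "summary written to %s", out_dir)
  invisible(summary)
}
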