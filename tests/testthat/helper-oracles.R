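# Independent literal implementations used as oracles. Each is a direct
# transcription of the defining formula, kept deliberately naive (loops,
# exhaustive enumeration) and separate from the package's computation path.

# All-pairs shortest hop counts by Floyd-Warshall.
floyd_warshall <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# Literal mean inverse distance over ordered pairs.
geff_literal <- function(a) {
  d <- floyd_warshall(a)
  n <- nrow(a)
  s <- 0
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && is.finite(d[i, j])) s <- s + 1 / d[i, j]
  s / (n * (n - 1))
}

# Literal undirected modularity double loop on a symmetrized adjacency.
modularity_literal <- function(a, memb) {
  und <- ((a + t(a)) > 0) * 1
  k <- rowSums(und)
  two_m <- sum(und)
  q <- 0
  for (i in seq_len(nrow(und)))
    for (j in seq_len(ncol(und)))
      if (memb[i] == memb[j])
        q <- q + und[i, j] - k[i] * k[j] / two_m
  q / two_m
}

# Exhaustive betweenness: enumerate every shortest path by depth-first
# search and count interior passages. Only usable for small n.
betweenness_exhaustive <- function(a) {
  n <- nrow(a)
  d <- floyd_warshall(a)
  bc <- numeric(n)
  paths_from <- function(j, k) {
    # all shortest j->k paths as lists of vertices
    res <- list()
    walk <- function(v, path) {
      if (v == k) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in which(a[v, ] == 1))
        if (d[v, k] == d[w, k] + 1) walk(w, c(path, w))
    }
    walk(j, j)
    res
  }
  for (j in seq_len(n))
    for (k in seq_len(n)) {
      if (j == k || !is.finite(d[j, k])) next
      ps <- paths_from(j, k)
      for (p in ps) {
        interior <- setdiff(p, c(j, k))
        bc[interior] <- bc[interior] + 1 / length(ps)
      }
    }
  bc
}

# Literal plug-in transfer entropy: loop over time, build the joint
# histogram of (target next bit, target past word, source word) with string
# keys, then sum the defining expression.
te_literal <- function(src, tgt, k = 2, instant_feedback = TRUE) {
  t_len <- length(src)
  counts <- new.env()
  bump <- function(key) {
    assign(key, (if (exists(key, counts)) get(key, counts) else 0) + 1, counts)
  }
  for (s in k:(t_len - 1)) {
    jn <- tgt[s + 1]
    jp <- paste(tgt[s:(s - k + 1)], collapse = "")
    ip <- if (instant_feedback) paste(src[(s + 1):(s - k + 2)], collapse = "")
    else paste(src[s:(s - k + 1)], collapse = "")
    bump(paste("abc", jn, jp, ip))
    bump(paste("bc", jp, ip))
    bump(paste("ab", jn, jp))
    bump(paste("b", jp))
  }
  n <- t_len - k
  te <- 0
  for (key in ls(counts)) {
    parts <- strsplit(key, " ")[[1]]
    if (parts[1] != "abc") next
    c_abc <- get(key, counts)
    c_bc <- get(paste("bc", parts[3], parts[4]), counts)
    c_ab <- get(paste("ab", parts[2], parts[3]), counts)
    c_b <- get(paste("b", parts[3]), counts)
    te <- te + (c_abc / n) * log2((c_abc * c_b) / (c_bc * c_ab))
  }
  te
}

# Raster directly from spike trains (one frame per event), bypassing the
# fluorescence layer; used where only burst timing matters.
spikes_to_raster <- function(spikes, fps = 50, roi_meta = NULL) {
  t_frames <- max(1L, round(spikes$duration * fps))
  bits <- matrix(0L, spikes$n_roi, t_frames)
  if (nrow(spikes$events)) {
    fr <- pmin(t_frames, floor(spikes$events$time * fps) + 1L)
    bits[cbind(spikes$events$roi, fr)] <- 1L
  }
  neuroresil:::new_event_raster(bits, fps, roi_meta)
}

# Raster with one-frame volleys of the given ROI sets at the given times.
volley_raster <- function(n_roi, n_frames, fps, volleys) {
  bits <- matrix(0L, n_roi, n_frames)
  for (v in volleys) {
    fr <- floor(v$time * fps) + 1L
    bits[v$rois, fr] <- 1L
  }
  neuroresil:::new_event_raster(bits, fps)
}

# Small deterministic random digraph.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(as.integer(runif(n * n) < p), n, n)
  diag(a) <- 0L
  a
}
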