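# Effective connectivity via generalized transfer entropy on binarized
# activity trains, with joint-distribution z-score significance.

word_codes <- function(x, k) {
  # code of the k-bit word ending at positions k..T (least significant bit =
  # most recent sample)
  t_len <- length(x)
  w <- x[k:t_len]
  if (k > 1) for (l in seq_len(k - 1)) w <- w + x[(k - l):(t_len - l)] * 2^l
  w
}

#' Transfer entropy between all ROI pairs
#'
#' Plug-in (joint histogram) estimator of the generalized transfer entropy
#' `TE(I -> J)` on binary activity trains, in bits: the reduction in
#' uncertainty of J's next sample given I's recent word, beyond what J's own
#' Markov past of order `markov_order` explains. With `instant_feedback`
#' (the calcium-imaging convention; default on) the source word is shifted
#' forward one bin so it includes the same bin as the predicted target
#' sample, capturing same-frame propagation, which dominates when cascade
#' delays are shorter than the frame period. No bias correction is applied;
#' significance is handled downstream by the joint-distribution z-score.
#' Removed ROIs (per `roi_meta$removed`) are excluded entirely.
#'
#' @param raster an `event_raster` (>= 2 live ROIs).
#' @param markov_order word length k in bins (default 2).
#' @param instant_feedback logical, default TRUE.
#' @param bin time-bin width in frames (default 1); wider bins OR the frames
#'   together.
#' @param onsets reduce each train to its activity onsets (the first frame
#'   of every 0 -> 1 transition) before estimation. This is the convention
#'   used by the network-inference pipeline: onset coincidences carry the
#'   propagation signal, whereas the multi-second decay envelopes of a slow
#'   calcium indicator overlap by chance between unrelated ROIs and leak
#'   into the estimate. Default FALSE: the estimator consumes the bits as
#'   given.
#' @param state_conditioning if TRUE, restrict the estimator to bins whose
#'   population activity is below `cond_quantile` of its distribution
#'   (conditioning out the global bursting state); off by default.
#' @param cond_quantile quantile used by `state_conditioning`.
#' @return a `te_matrix`: `te` (live ROI x live ROI, bits, zero diagonal,
#'   ROI ids as dimnames), `params`.
#' @export
transfer_entropy <- function(raster, markov_order = 2, instant_feedback = TRUE,
                             bin = 1, onsets = FALSE,
                             state_conditioning = FALSE,
                             cond_quantile = 0.5) {
  k <- as.integer(markov_order)
  if (k < 1) stopf("`markov_order` must be >= 1")
  live <- resolve_live(raster, NULL)
  if (length(live) < 2) stopf("need at least 2 live ROIs")
  bits <- raster$bits[live, , drop = FALSE]
  if (onsets) {
    bits <- bits * cbind(1L, bits[, -ncol(bits), drop = FALSE] == 0L)
    storage.mode(bits) <- "integer"
  }
  if (bin > 1) {
    nb <- floor(ncol(bits) / bin)
    idx <- rep(seq_len(nb), each = bin)
    bits <- t(apply(bits[, seq_len(nb * bin), drop = FALSE], 1,
                    function(x) as.integer(tapply(x, idx, max) > 0)))
  }
  n <- nrow(bits)
  t_len <- ncol(bits)
  m <- t_len - k
  if (m < 2^(2 * k) * 5)
    warning("train too short for reliable TE estimation at this Markov order",
            call. = FALSE)
  base <- 2^k
  # per-ROI pieces of the sample index (prediction of bin s+1, s = k..T-1)
  w <- vapply(seq_len(n), function(i) word_codes(bits[i, ], k),
              numeric(t_len - k + 1))
  jn <- t(bits[, (k + 1):t_len, drop = FALSE])            # m x n
  jp <- w[1:m, , drop = FALSE]                            # word ending at s
  ip <- if (instant_feedback) w[2:(m + 1), , drop = FALSE] else jp
  keep <- rep(TRUE, m)
  if (state_conditioning) {
    g <- colMeans(bits)[(k + 1):t_len]
    keep <- g <= quantile(g, cond_quantile, names = FALSE)
    if (sum(keep) < 2^(2 * k + 1))
      stopf("state conditioning leaves too few samples")
  }
  te <- matrix(0, n, n)
  tgt_code <- jn * (base * base) + jp * base  # m x n, target part of the code
  for (j in seq_len(n)) {
    cj <- tgt_code[keep, j]
    for (i in seq_len(n)) {
      if (i == j) next
      tab <- tabulate(cj + ip[keep, i] + 1L, nbins = 2L * base * base)
      te[i, j] <- te_from_counts(tab, base)
    }
  }
  te[te < 0] <- 0
  ids <- as.character(raster$roi_meta$id[live] %||% live)
  dimnames(te) <- list(ids, ids)
  structure(list(te = te, params = list(markov_order = k,
                                        instant_feedback = instant_feedback,
                                        bin = bin, onsets = onsets,
                                        state_conditioning = state_conditioning),
                 live = live),
            class = "te_matrix")
}

te_from_counts <- function(tab, base) {
  arr <- array(tab, c(base, base, 2))        # [ip, jp, jn]
  n_tot <- sum(arr)
  if (n_tot == 0) return(0)
  m_jp_ip <- arr[, , 1] + arr[, , 2]         # [ip, jp]
  m_jn_jp <- apply(arr, c(2, 3), sum)        # [jp, jn]
  m_jp <- colSums(m_jp_ip)                   # [jp]
  idx <- which(arr > 0, arr.ind = TRUE)
  c3 <- arr[idx]
  ratio <- c3 * m_jp[idx[, 2]] /
    (m_jn_jp[cbind(idx[, 2], idx[, 3])] * m_jp_ip[idx[, c(1, 2), drop = FALSE]])
  sum(c3 / n_tot * log2(ratio))
}

#' @export
print.te_matrix <- function(x, ...) {
  cat(sprintf("<te_matrix: %d ROIs, k = %d, instant feedback %s>\n",
              nrow(x$te), x$params$markov_order,
              if (x$params$instant_feedback) "on" else "off"))
  invisible(x)
}

#' Joint-distribution significance z-scores for TE values
#'
#' For each ordered pair (I, J), the null sample is the joint set of all TE
#' values of inputs X to J and outputs I to Y (any X, Y): the pair's column
#' and row of the TE matrix. The score is
#' `z = (TE(I->J) - mean(joint)) / sd(joint)`. The pair's own value belongs
#' to both the input and output sets and is counted once by default;
#' `include_self = FALSE` removes it from the null. A zero-variance null
#' gives z = 0.
#'
#' @param te a `te_matrix` or a square numeric matrix (zero diagonal).
#' @param include_self logical; see above.
#' @return matrix of z-scores, same dimnames, zero diagonal.
#' @export
significance_scores <- function(te, include_self = TRUE) {
  tm <- if (inherits(te, "te_matrix")) te$te else te
  n <- nrow(tm)
  if (!is.matrix(tm) || n != ncol(tm)) stopf("TE matrix must be square")
  if (n < 3) stopf("need at least 3 ROIs to build the joint null")
  cs <- colSums(tm); rs <- rowSums(tm)
  cs2 <- colSums(tm^2); rs2 <- rowSums(tm^2)
  sum_null <- outer(rs, cs, "+") - (if (include_self) tm else 2 * tm)
  ssq_null <- outer(rs2, cs2, "+") - (if (include_self) tm^2 else 2 * tm^2)
  m <- 2 * (n - 1) - (if (include_self) 1 else 2)
  mu <- sum_null / m
  v <- (ssq_null - sum_null^2 / m) / (m - 1)
  # guard against catastrophic cancellation: a variance that is zero up to
  # floating point (all null values equal) must yield z = 0 exactly
  v[v < 64 * .Machine$double.eps * ssq_null / m] <- 0
  s <- sqrt(v)
  z <- (tm - mu) / s
  z[!is.finite(z)] <- 0
  z[s == 0] <- 0
  diag(z) <- 0
  dimnames(z) <- dimnames(tm)
  z
}

#' Threshold z-scores into a directed effective network
#'
#' Accepts a connection I -> J when `z >= z_min` (default 1, the standard
#' working point: permissive enough to capture both global and local
#' communication while rejecting the bulk of the joint distribution).
#'
#' @param z z-score matrix (finite, zero diagonal).
#' @param z_min acceptance threshold.
#' @return an `effective_network`: `adjacency` (0/1, zero diagonal), `z`,
#'   `threshold`.
#' @export
threshold_connections <- function(z, z_min = 1) {
  if (!all(is.finite(z))) stopf("z-scores must be finite")
  adjacency <- (z >= z_min) * 1L
  diag(adjacency) <- 0L
  structure(list(adjacency = adjacency, z = z, threshold = z_min),
            class = "effective_network")
}

#' @export
print.effective_network <- function(x, ...) {
  cat(sprintf("<effective_network: %d nodes, %d directed connections (z >= %g)>\n",
              nrow(x$adjacency), sum(x$adjacency), x$threshold))
  invisible(x)
}

#' Infer the effective network from a raster in one call
#'
#' Chains [transfer_entropy()], [significance_scores()] and
#' [threshold_connections()].
#'
#' @inheritParams transfer_entropy
#' @inheritParams significance_scores
#' @inheritParams threshold_connections
#' @return an `effective_network` (ROI ids as dimnames).
#' @export
infer_effective_network <- function(raster, markov_order = 2,
                                    instant_feedback = TRUE, bin = 1,
                                    onsets = TRUE, z_min = 1,
                                    include_self = TRUE) {
  te <- transfer_entropy(raster, markov_order = markov_order,
                         instant_feedback = instant_feedback, bin = bin,
                         onsets = onsets)
  threshold_connections(significance_scores(te, include_self), z_min)
}
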