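# Synthetic culture models: structure, geometry, damage operators, recovery.
#
# A culture model holds ROI-level structural connectivity for one of the two
# in vitro preparations: "aggregated" cultures (~100 compact neuronal islands,
# each one node, with modular connectivity) and "homogeneous" cultures (a
# uniform monolayer gridded into square ROIs on a PDMS disc surrounded by a
# population on the glass). Damage never deletes rows/columns: removed nodes
# keep their index with zeroed couplings and a removal flag, so ROI identity
# is stable across a longitudinal damage sequence.

new_culture_model <- function(nodes, weights, kind, geometry, seed) {
  model <- structure(
    list(
      nodes = nodes,
      weights = weights,
      kind = kind,
      geometry = geometry,
      baseline_in = colSums(weights),
      seed = seed
    ),
    class = "culture_model"
  )
  validate_culture_model(model)
  model
}

validate_culture_model <- function(model) {
  w <- model$weights
  n <- nrow(model$nodes)
  if (!is.matrix(w) || nrow(w) != ncol(w) || nrow(w) != n)
    stopf("coupling matrix must be square and match the node table")
  if (any(w < 0)) stopf("coupling weights must be nonnegative")
  if (any(diag(w) != 0)) stopf("coupling matrix must have a zero diagonal")
  half <- model$geometry$field_side / 2
  if (any(abs(model$nodes$x) > half + 1e-9) || any(abs(model$nodes$y) > half + 1e-9))
    stopf("node positions must lie within the %.1f mm field", model$geometry$field_side)
  if (model$kind == "homogeneous" && !is.null(model$geometry$h) &&
      model$geometry$h >= 3) {
    disc <- model$nodes$region %in% c("disc", "contour")
    if (sum(w[disc, !disc]) + sum(w[!disc, disc]) != 0)
      stopf("disc and surroundings must be fully uncoupled for h >= 3 mm")
  }
  invisible(model)
}

#' @export
print.culture_model <- function(x, ...) {
  cat(sprintf("<culture_model: %s>\n", x$kind))
  cat(sprintf("  nodes: %d (%d removed)\n", nrow(x$nodes), sum(x$nodes$removed)))
  cat(sprintf("  couplings: %d nonzero, total weight %.2f\n",
              sum(x$weights > 0), sum(x$weights)))
  if (x$kind == "homogeneous")
    cat(sprintf("  geometry: disc radius %.2f mm, h = %.2f mm, field %.1f mm\n",
                x$geometry$disc_radius, x$geometry$h, x$geometry$field_side))
  invisible(x)
}

live_nodes <- function(model) which(!model$nodes$removed)

#' Generate an aggregated culture with planted modular structure
#'
#' Builds a structural model of an aggregated culture: compact neuronal
#' islands (one node each) scattered over a 6 mm diameter well, wired as a
#' directed stochastic block model in which islands of the same module couple
#' densely and strongly while modules are tied together by a handful of
#' weaker bridges. Within-module couplings are drawn from U(0.5, 1) and
#' between-module couplings from U(0.8, 1.6) (the thick axon bundles between
#' islands), so cascades engage a module partially and recruit neighbour
#' modules through their gateways.
#'
#' @param n_aggregates number of islands (default 100, the typical count in a
#'   6 mm well).
#' @param modules number of planted modules.
#' @param p_within,p_between directed edge probabilities inside/between
#'   modules; `p_within > p_between` plants modularity.
#' @param seed integer seed; the model is a pure function of its arguments.
#' @param field_side field of view side in mm.
#' @param disc_radius culture well radius in mm.
#' @return a `culture_model` with `kind = "aggregated"`; `nodes$module`
#'   carries the planted module labels.
#' @export
generate_aggregated_culture <- function(n_aggregates = 100, modules = 8,
                                        p_within = 0.7, p_between = 0.0022,
                                        seed = 1, field_side = 7.1,
                                        disc_radius = 3.0) {
  if (n_aggregates < 1 || modules < 1) stopf("counts must be positive")
  if (modules > n_aggregates) stopf("`modules` cannot exceed `n_aggregates`")
  assert_number(p_within, "p_within", 0, 1)
  assert_number(p_between, "p_between", 0, 1)
  n <- as.integer(n_aggregates)
  with_seed(seed, {
    r <- disc_radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    module <- sample(rep_len(seq_len(modules), n))
    same <- outer(module, module, "==")
    # inter-module coupling funnels through one connector island per module
    # (inter-island axon bundles follow few spatial paths, so each module
    # communicates through a gateway aggregate); the expected number of
    # cross edges matches plain Bernoulli(p_between) wiring but lands on
    # gateway pairs only
    conn <- vapply(seq_len(modules), function(mm) {
      members <- which(module == mm)
      members[sample.int(length(members), 1)]
    }, integer(1))
    is_conn <- seq_len(n) %in% conn
    p <- matrix(0, n, n)
    p[same] <- p_within
    cross_conn <- !same & outer(is_conn, is_conn, "&")
    p[cross_conn] <- min(1, p_between * sum(!same) / max(1, sum(cross_conn)))
    diag(p) <- 0
    a <- matrix(runif(n * n), n, n) < p
    w <- matrix(0, n, n)
    w[a & same] <- runif(sum(a & same), 0.5, 1.0)
    w[a & !same] <- runif(sum(a & !same), 0.8, 1.6)
    nodes <- data.frame(
      id = seq_len(n), x = r * cos(th), y = r * sin(th),
      region = "aggregate", module = module, removed = FALSE
    )
    new_culture_model(nodes, w, "aggregated",
                      list(field_side = field_side, disc_radius = disc_radius,
                           h = NULL, tile = NULL),
                      seed)
  })
}

# Disc-to-surroundings coupling attenuation versus PDMS disc height h (mm):
# full strength at h <= 0.7 (disc neurons reach the glass), linearly fading
# to exactly 0 at h >= 3 (full disconnection).
coupling_h_factor <- function(h) {
  assert_number(h, "h", 0, strict_lower = TRUE)
  max(0, min(1, (3 - h) / (3 - 0.7)))
}

#' Generate a homogeneous gridded culture on a PDMS disc
#'
#' Lays ROIs on a `grid` x `grid` square tiling of the field of view (tiles
#' outside the circular field mask are dropped), labels them by geometry
#' (`disc`, `contour` = outermost disc ring of one tile width on the PDMS
#' walls, `surroundings` = glass population outside the disc) and wires
#' short-range structural couplings between ROIs closer than
#' `connect_radius`. Couplings that cross the disc boundary are attenuated by
#' a factor that decreases linearly with the disc height `h`, reaching exactly
#' zero at `h >= 3` mm; contour (wall) ROIs couple weakly.
#'
#' @param grid ROIs per side (default 40).
#' @param h PDMS disc height in mm; controls disc-surroundings coupling.
#' @param surroundings_removed drop the glass population entirely (the
#'   manually-scraped preparation).
#' @param seed integer seed.
#' @param field_side,disc_radius field of view side and disc radius in mm.
#' @param connect_radius maximum coupling distance in mm; `NULL` (default)
#'   uses 1.7 grid tiles, i.e. the 8-neighbourhood (0.30 mm at the standard
#'   40 x 40 grid, the scale of local axodendritic wiring).
#' @param contour_scale attenuation of couplings incident to wall ROIs.
#' @return a `culture_model` with `kind = "homogeneous"`.
#' @export
generate_homogeneous_culture <- function(grid = 40, h = 0.7,
                                         surroundings_removed = FALSE,
                                         seed = 1, field_side = 7.1,
                                         disc_radius = 3.0,
                                         connect_radius = NULL,
                                         contour_scale = 0.4) {
  if (grid < 4) stopf("`grid` must be at least 4")
  assert_number(h, "h", 0, strict_lower = TRUE)
  tile <- field_side / grid
  connect_radius <- connect_radius %||% (1.7 * tile)
  rois <- grid_rois(field_side = field_side, grid = grid,
                    mask = list(shape = "circle", radius = field_side / 2))
  r <- sqrt(rois$x^2 + rois$y^2)
  region <- ifelse(r > disc_radius, "surroundings",
                   ifelse(r > disc_radius - tile, "contour", "disc"))
  if (surroundings_removed) {
    keep <- region != "surroundings"
    rois <- rois[keep, , drop = FALSE]
    region <- region[keep]
  }
  n <- nrow(rois)
  with_seed(seed, {
    dx <- outer(rois$x, rois$x, "-")
    dy <- outer(rois$y, rois$y, "-")
    near <- (dx * dx + dy * dy) <= connect_radius^2
    diag(near) <- FALSE
    w <- matrix(0, n, n)
    w[near] <- runif(sum(near), 0.6, 1.0)
    on_disc <- region %in% c("disc", "contour")
    cross <- outer(on_disc, !on_disc, "&") | outer(!on_disc, on_disc, "&")
    w[cross] <- w[cross] * coupling_h_factor(h)
    wall <- region == "contour"
    touches_wall <- outer(wall, wall, "|")
    w[touches_wall] <- w[touches_wall] * contour_scale
    nodes <- data.frame(
      id = seq_len(n), x = rois$x, y = rois$y,
      region = region, module = NA_integer_, removed = FALSE
    )
    new_culture_model(nodes, w, "homogeneous",
                      list(field_side = field_side, disc_radius = disc_radius,
                           h = h, tile = tile),
                      seed)
  })
}

#' Remove (disconnect) a single node, as by needle extraction
#'
#' Zeroes every coupling to and from the node and flags it removed. The node
#' keeps its index so ROI identity is preserved across a damage sequence.
#' Idempotent; positions never change.
#'
#' @param model a `culture_model`.
#' @param node node id.
#' @return the damaged model.
#' @export
apply_node_removal <- function(model, node) {
  if (!node %in% model$nodes$id) stopf("unknown node id: %s", node)
  model$weights[node, ] <- 0
  model$weights[, node] <- 0
  model$nodes$removed[model$nodes$id == node] <- TRUE
  model
}

#' Cut a homogeneous culture in half along a diameter
#'
#' Emulates the scalpel wound: a straight band of width `width` micrometres
#' through the disc centre at angle `angle`. Disc ROIs inside the band are
#' flagged removed; every structural coupling involving a disc ROI whose
#' segment crosses the band is zeroed. Wall (contour) and glass
#' (surroundings) ROIs are out of the scalpel's reach and keep their flags,
#' and couplings entirely on one side of the band are never touched.
#'
#' @param model a homogeneous `culture_model`.
#' @param angle cut direction in radians from the +x axis.
#' @param width wound width in micrometres (default 500).
#' @return the damaged model.
#' @export
apply_cut <- function(model, angle = 0, width = 500) {
  if (model$kind != "homogeneous") stopf("apply_cut requires a homogeneous culture")
  assert_number(width, "width", 0)
  half <- width / 1000 / 2  # band half-width in mm
  # signed perpendicular distance to the cut line
  p <- -sin(angle) * model$nodes$x + cos(angle) * model$nodes$y
  is_disc <- model$nodes$region == "disc"
  in_band <- abs(p) <= half
  wounded <- which(is_disc & in_band)
  n <- nrow(model$nodes)
  side <- ifelse(in_band, 0L, ifelse(p > 0, 1L, -1L))
  crosses <- outer(side, side, function(a, b) a * b <= 0 & !(a == 0 & b == 0)) |
    outer(in_band, in_band, "&")
  touches_disc <- outer(is_disc, is_disc, "|")
  sever <- crosses & touches_disc & model$weights > 0
  model$weights[sever] <- 0
  if (length(wounded)) {
    model$weights[wounded, ] <- 0
    model$weights[, wounded] <- 0
    model$nodes$removed[wounded] <- TRUE
  }
  model
}

#' Homeostatic recovery by synaptic scaling and local sprouting
#'
#' Models the between-session recovery of a damaged culture. First, nearby
#' surviving ROI pairs may sprout new short-range couplings (count
#' proportional to `strength`); then each surviving node's incoming couplings
#' are scaled multiplicatively so that a fraction `strength` of its lost
#' total input (relative to the undamaged model) is restored. At
#' `strength = 1` each node's total input returns exactly to its pre-damage
#' sum. Sprouting respects physical barriers: it never couples disc and
#' surroundings when the disc height forbids it, and its range is shorter
#' than the wound width, so it cannot bridge the cut directly.
#'
#' @param model a `culture_model`.
#' @param strength fraction of lost input restored, in `[0, 1]`.
#' @param seed integer seed for sprouting.
#' @param sprout_rate expected new edges per live node at `strength = 1`.
#' @param outgrowth cumulative neurite regrowth fraction in `[0, 1]`,
#'   defaulting to `strength`; it stretches the sprouting range by
#'   `1 + outgrowth`. Early in recovery sprouting stays local (shorter than
#'   the wound width, so the cut is not re-bridged); near-complete
#'   regrowth reaches across a 500 um wound, as axons do over days.
#' @param sprout_radius base sprouting distance in mm; `NULL` (default)
#'   uses 1.7 grid tiles for homogeneous cultures (local neurite
#'   outgrowth) and 1 mm for aggregated cultures (inter-aggregate axon
#'   bundles).
#' @return the (partially) recovered model.
#' @export
homeostatic_recovery <- function(model, strength, seed = 1,
                                 sprout_rate = 0.2, outgrowth = strength,
                                 sprout_radius = NULL) {
  assert_number(strength, "strength", 0, 1)
  assert_number(outgrowth, "outgrowth", 0, 1)
  sprout_radius <- (sprout_radius %||%
    if (model$kind == "homogeneous") 1.7 * model$geometry$tile else 1.0) *
    (1 + outgrowth)
  if (strength == 0) return(model)
  live <- live_nodes(model)
  with_seed(seed, {
    n_new <- round(strength * sprout_rate * length(live))
    if (n_new > 0 && length(live) > 1) {
      x <- model$nodes$x[live]; y <- model$nodes$y[live]
      d2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
      cand <- which(d2 <= sprout_radius^2 & d2 > 0 &
                      model$weights[live, live] == 0, arr.ind = TRUE)
      if (model$kind == "homogeneous") {
        hf <- coupling_h_factor(model$geometry$h)
        if (hf == 0) {
          on_disc <- model$nodes$region[live] %in% c("disc", "contour")
          cross <- on_disc[cand[, 1]] != on_disc[cand[, 2]]
          cand <- cand[!cross, , drop = FALSE]
        }
      }
      if (nrow(cand) > 0) {
        # regrowth concentrates where input was lost: candidate pairs are
        # sampled in proportion to their endpoints' remaining input deficit
        insum_live <- colSums(model$weights)[live]
        deficit <- pmax(0, model$baseline_in[live] - insum_live) /
          pmax(model$baseline_in[live], 1e-12)
        wgt <- deficit[cand[, 1]] * deficit[cand[, 2]] + 1e-4
        pick <- cand[sample.int(nrow(cand), min(n_new, nrow(cand)),
                                prob = wgt), , drop = FALSE]
        pos <- model$weights[model$weights > 0]
        w_new <- if (length(pos)) median(pos) else 0.5
        model$weights[cbind(live[pick[, 2]], live[pick[, 1]])] <- w_new
      }
    }
    NULL
  })
  insum <- colSums(model$weights)
  for (j in live) {
    deficit <- model$baseline_in[j] - insum[j]
    if (deficit > 0 && insum[j] > 0) {
      model$weights[, j] <- model$weights[, j] *
        (insum[j] + strength * deficit) / insum[j]
    }
  }
  model
}
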