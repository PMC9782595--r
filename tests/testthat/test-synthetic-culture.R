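test_that("aggregated culture generator honours counts and invariants", {
  m <- generate_aggregated_culture(n_aggregates = 100, modules = 5, seed = 42)
  expect_s3_class(m, "culture_model")
  expect_equal(nrow(m$nodes), 100)
  expect_equal(dim(m$weights), c(100, 100))
  expect_true(all(m$weights >= 0))
  expect_equal(diag(m$weights), rep(0, 100))
  expect_true(all(m$nodes$x^2 + m$nodes$y^2 <= 3^2 + 1e-9))

  # no edges possible at zero probabilities
  m0 <- generate_aggregated_culture(30, 3, p_within = 0, p_between = 0, seed = 1)
  expect_equal(sum(m0$weights), 0)

  expect_error(generate_aggregated_culture(0, 1), "positive")
  expect_error(generate_aggregated_culture(10, 3, p_within = 1.4), "p_within")
  expect_error(generate_aggregated_culture(5, 9), "modules")
})

test_that("planted partition beats a random one under the literal modularity", {
  m <- generate_aggregated_culture(30, 3, p_within = 0.8, p_between = 0.05,
                                   seed = 1)
  a <- (m$weights > 0) * 1
  q_planted <- modularity_literal(a, m$nodes$module)
  set.seed(2)
  q_random <- modularity_literal(a, sample(m$nodes$module))
  expect_gt(q_planted, q_random)
  expect_gt(q_planted, 0.3)
})

test_that("homogeneous culture geometry and h-controlled coupling", {
  m <- generate_homogeneous_culture(grid = 40, h = 0.7, seed = 1)
  expect_equal(nrow(m$nodes), nrow(grid_rois(7.1, 40,
    mask = list(shape = "circle", radius = 7.1 / 2))))
  expect_setequal(unique(m$nodes$region), c("disc", "contour", "surroundings"))

  disc_idx <- m$nodes$region %in% c("disc", "contour")
  cross_w <- sum(m$weights[disc_idx, !disc_idx]) +
    sum(m$weights[!disc_idx, disc_idx])
  expect_gt(cross_w, 0)  # h = 0.7: disc talks to the glass population

  m3 <- generate_homogeneous_culture(grid = 20, h = 3, seed = 1)
  d3 <- m3$nodes$region %in% c("disc", "contour")
  expect_identical(sum(m3$weights[d3, !d3]) + sum(m3$weights[!d3, d3]), 0)

  # intermediate height: strictly weaker than h = 0.7 at equal seed
  m2 <- generate_homogeneous_culture(grid = 20, h = 2, seed = 1)
  m07 <- generate_homogeneous_culture(grid = 20, h = 0.7, seed = 1)
  d <- m2$nodes$region %in% c("disc", "contour")
  expect_lt(sum(m2$weights[d, !d]), sum(m07$weights[d, !d]))
  expect_gt(sum(m2$weights[d, !d]), 0)

  ms <- generate_homogeneous_culture(grid = 20, h = 2,
                                     surroundings_removed = TRUE, seed = 1)
  expect_false("surroundings" %in% ms$nodes$region)

  expect_error(generate_homogeneous_culture(grid = 2), "grid")
  expect_error(generate_homogeneous_culture(h = 0), "h")
})

test_that("generators and simulator are pure functions of their seed", {
  m1 <- generate_aggregated_culture(seed = 9)
  m2 <- generate_aggregated_culture(seed = 9)
  expect_identical(m1, m2)
  expect_false(identical(m1$weights,
                         generate_aggregated_culture(seed = 10)$weights))

  s1 <- simulate_activity(m1, 60, seed = 4)
  s2 <- simulate_activity(m1, 60, seed = 4)
  expect_identical(s1$events, s2$events)
})

test_that("simulation respects silence, ordering and removal", {
  m <- generate_aggregated_culture(n_aggregates = 30, modules = 3, seed = 2)
  s0 <- simulate_activity(m, 30, excitability = list(init_rate = 0), seed = 1)
  expect_equal(nrow(s0$events), 0)

  s <- simulate_activity(m, 60, seed = 3)
  expect_true(all(diff(s$events$time) >= 0))
  expect_true(all(s$events$time >= 0 & s$events$time < 60))

  # a removed node never spikes
  md <- apply_node_removal(m, 5)
  sd <- simulate_activity(md, 60, seed = 3)
  expect_false(5 %in% sd$events$roi)
})

test_that("aggregated default calibration: cascades engage 10-20% of islands", {
  fr <- unlist(lapply(1:3, function(s) {
    m <- generate_aggregated_culture(seed = s)
    sp <- simulate_activity(m, 180, seed = s + 50)
    b <- detect_network_bursts(spikes_to_raster(sp), mode = "aggregated")
    b$bursts$fraction
  }))
  expect_gte(mean(fr), 0.10)
  expect_lte(mean(fr), 0.20)
})

test_that("homogeneous default calibration: bursts engage nearly everyone", {
  m <- generate_homogeneous_culture(seed = 4)
  sp <- simulate_activity(m, 90, seed = 14)
  b <- detect_network_bursts(spikes_to_raster(sp), mode = "homogeneous")
  expect_gt(nrow(b$bursts), 1)
  expect_gte(mean(b$bursts$fraction), 0.9)
})

test_that("fluorescence rendering: baseline, kernel and sampling", {
  empty <- neuroresil:::new_spike_trains(
    data.frame(roi = integer(0), time = numeric(0)), 2, 3, 1)
  tr0 <- render_fluorescence(empty, noise_sd = 0)
  expect_true(all(tr0$values == 100))
  expect_equal(dim(tr0$values), c(3, 100))  # 2 s at 50 fps = 100 frames

  tr <- render_fluorescence(empty, fps = 50)
  expect_equal(ncol(tr$values), 100)  # consecutive frames 20 ms apart

  expect_error(render_fluorescence(empty, noise_sd = -1), "noise_sd")
  expect_error(render_fluorescence(empty, rise = 2, decay = 1), "decay")
})

test_that("node removal zeroes exactly the node's couplings, idempotently", {
  w <- matrix(0, 7, 7)
  w[1, 2:6] <- 1  # out-degree 5
  w[2:6, 1] <- 1  # in-degree 5
  w[2, 3] <- 1    # node 7 stays isolated
  nodes <- data.frame(id = 1:7, x = 0, y = 0, region = "aggregate",
                      module = 1L, removed = FALSE)
  m <- neuroresil:::new_culture_model(nodes, w, "aggregated",
                                      list(field_side = 7.1, disc_radius = 3,
                                           h = NULL, tile = NULL), 1)
  before <- sum(m$weights > 0)
  m1 <- apply_node_removal(m, 1)
  expect_equal(before - sum(m1$weights > 0), 10)  # 5 in + 5 out zeroed
  expect_true(m1$nodes$removed[1])
  expect_identical(apply_node_removal(m1, 1)$weights, m1$weights)

  # removing an isolated node leaves the matrix unchanged
  m7 <- apply_node_removal(m, 7)
  expect_identical(m7$weights, m$weights)
  expect_error(apply_node_removal(m, 99), "unknown")
})

test_that("diametral cut severs crossing couplings and nothing else", {
  m <- generate_homogeneous_culture(grid = 20, h = 2, seed = 6)
  mc <- apply_cut(m, angle = 0, width = 500)

  # geometry conservation: positions never change
  expect_identical(mc$nodes[c("x", "y")], m$nodes[c("x", "y")])

  # wounded nodes are disc nodes inside the band
  wounded <- which(mc$nodes$removed)
  expect_true(all(m$nodes$region[wounded] == "disc"))
  expect_true(all(abs(m$nodes$y[wounded]) <= 0.25))

  # no coupling confined to one side of the band is touched
  side <- sign(m$nodes$y) * (abs(m$nodes$y) > 0.25)
  same_side <- outer(side, side, function(a, b) a == b & a != 0)
  expect_identical(mc$weights[same_side], m$weights[same_side])

  # couplings between disc nodes on opposite sides are zeroed
  disc <- m$nodes$region == "disc"
  opp <- outer(side, side, "*") < 0 & outer(disc, disc, "|")
  expect_equal(sum(mc$weights[opp]), 0)

  expect_error(apply_cut(generate_aggregated_culture(seed = 1)), "homogeneous")
})

test_that("a horizontal cut splits the isolated disc into equal halves", {
  m <- generate_homogeneous_culture(grid = 40, h = 2,
                                    surroundings_removed = TRUE, seed = 3)
  mc <- apply_cut(m, angle = 0, width = 500)
  keep <- !mc$nodes$removed & mc$nodes$region == "disc"
  sub <- (mc$weights[keep, keep] + t(mc$weights[keep, keep])) > 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(sub, "undirected"))
  big <- sort(comp$csize, decreasing = TRUE)[1:2]
  expect_equal(comp$no, 2)
  expect_lt(abs(big[1] - big[2]) / sum(big), 0.1)
})

test_that("homeostatic recovery restores lost input", {
  m <- generate_aggregated_culture(n_aggregates = 30, modules = 3, seed = 8)
  target <- 3
  donors <- which(m$weights[, target] > 0)
  expect_gt(length(donors), 1)
  pre_in <- sum(m$weights[, target])

  md <- apply_node_removal(m, donors[1])
  expect_lt(sum(md$weights[, target]), pre_in)

  # strength 0 changes nothing
  expect_identical(homeostatic_recovery(md, 0), md)

  # strength 1 restores the full pre-damage input sum
  mr <- homeostatic_recovery(md, 1, sprout_rate = 0)
  expect_equal(sum(mr$weights[, target]), pre_in, tolerance = 1e-12)

  expect_error(homeostatic_recovery(md, 1.5), "strength")
})

test_that("recovery sprouting never couples disc and glass when h forbids it", {
  m <- generate_homogeneous_culture(grid = 16, h = 3, seed = 2)
  mc <- apply_cut(m, 0, 500)
  mr <- homeostatic_recovery(mc, 1, seed = 7)
  d <- mr$nodes$region %in% c("disc", "contour")
  expect_identical(sum(mr$weights[d, !d]) + sum(mr$weights[!d, d]), 0)
})

test_that("recovery pushes the activity ratio back toward 1", {
  devs <- t(sapply(1:5, function(s) {
    m <- generate_aggregated_culture(seed = s)
    act <- function(mod, sd) {
      b <- detect_network_bursts(
        spikes_to_raster(simulate_activity(mod, 240, seed = sd)),
        mode = "aggregated")
      network_activity(b)
    }
    a_pre <- act(m, 100 + s)
    # heavy damage: remove the five strongest output hubs
    for (tgt in order(rowSums(m$weights), decreasing = TRUE)[1:5])
      m <- apply_node_removal(m, tgt)
    phi_post <- act(m, 200 + s) / a_pre
    mr <- homeostatic_recovery(m, 0.9, seed = s)
    phi_rec <- act(mr, 300 + s) / a_pre
    c(post = phi_post, rec = phi_rec)
  }))
  expect_lt(median(abs(devs[, "rec"] - 1)), median(abs(devs[, "post"] - 1)))
})
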