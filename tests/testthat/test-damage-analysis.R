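net_from <- function(a, z = NULL) {
  dimnames(a) <- list(seq_len(nrow(a)), seq_len(nrow(a)))
  structure(list(adjacency = a, z = z %||% (a * 2), threshold = 1),
            class = "effective_network")
}

test_that("target selection by centrality, degree and seeded randomness", {
  path <- matrix(0L, 3, 3); path[1, 2] <- path[2, 3] <- 1L
  expect_equal(select_target(net_from(path), "bc_attack"), 2)

  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star[2:5, 1] <- 1L
  expect_equal(select_target(net_from(star), "degree_attack"), 1)

  r1 <- select_target(net_from(star), "random", seed = 3)
  expect_identical(r1, select_target(net_from(star), "random", seed = 3))
  expect_true(r1 %in% 1:5)

  # ties break to the lowest id
  dy <- matrix(0L, 4, 4); dy[1, 2] <- dy[2, 1] <- dy[3, 4] <- dy[4, 3] <- 1L
  expect_equal(select_target(net_from(dy), "degree_attack"), 1)
})

test_that("size-matched global efficiency around a deletion", {
  # K4: excluding any node leaves K3, still complete
  k4 <- matrix(1L, 4, 4); diag(k4) <- 0L
  expect_equal(geff_excluding_deleted(net_from(k4), 2), 1)
  expect_equal(global_efficiency(k4[-2, -2]), 1)

  # 5-node bridge graph: two dyads joined through node 3, plus the direct
  # 2 <-> 4 effective shortcut that joint bursting sustains while the
  # bridge is alive
  a <- matrix(0L, 5, 5)
  a[1, 2] <- a[2, 1] <- a[4, 5] <- a[5, 4] <- 1L
  a[2, 3] <- a[3, 2] <- a[3, 4] <- a[4, 3] <- 1L
  a[2, 4] <- a[4, 2] <- 1L
  pre <- net_from(a)
  expect_equal(geff_excluding_deleted(pre, 3), geff_literal(a[-3, -3]))
  # with the bridge excluded the four outer nodes remain mutually reachable
  expect_gt(geff_excluding_deleted(pre, 3), 0.5)

  # post-damage the modules no longer co-burst: dyads only; strict
  # decrease on size-matched node sets
  post_adj <- a
  post_adj[3, ] <- 0L; post_adj[, 3] <- 0L
  post_adj[2, 4] <- post_adj[4, 2] <- 0L
  expect_lt(global_efficiency(post_adj[-3, -3]), geff_excluding_deleted(pre, 3))

  # excluding an isolated node equals dropping it from the matrix
  iso <- matrix(0L, 4, 4); iso[1, 2] <- iso[2, 1] <- 1L
  expect_equal(geff_excluding_deleted(net_from(iso), 4),
               global_efficiency(iso[-4, -4]))
})

test_that("damage sequences are reproducible and bookkeeping is sound", {
  m <- generate_aggregated_culture(n_aggregates = 40, modules = 4, seed = 3)
  r1 <- run_damage_sequence(m, "random", steps = 1, recording_s = 90, seed = 5)
  r2 <- run_damage_sequence(m, "random", steps = 1, recording_s = 90, seed = 5)
  expect_identical(r1$steps, r2$steps)
  expect_equal(nrow(r1$steps), 1)
  expect_true(r1$model$nodes$removed[r1$steps$target])
  expect_true(all(r1$steps$geff_pre >= 0 & r1$steps$geff_pre <= 1))
  expect_true(all(r1$steps$geff_post >= 0 & r1$steps$geff_post <= 1))

  r3 <- run_damage_sequence(m, "degree_attack", steps = 2, recording_s = 90,
                            seed = 6)
  expect_equal(r3$steps$step, 1:2)
  expect_equal(sum(r3$model$nodes$removed), 2)
})

test_that("bc attack on a two-module bridge culture removes the bridge first", {
  # two 10-node modules, all cross-module coupling through node 1 <-> node 11
  set.seed(4)
  n <- 20
  w <- matrix(0, n, n)
  for (blk in list(1:10, 11:20)) {
    for (i in blk) for (j in blk) if (i != j && runif(1) < 0.9)
      w[i, j] <- runif(1, 0.5, 1)
  }
  w[1, 11] <- w[11, 1] <- 1.5
  nodes <- data.frame(id = 1:n, x = rep(c(-1, 1), each = 10), y = 0,
                      region = "aggregate", module = rep(1:2, each = 10),
                      removed = FALSE)
  m <- neuroresil:::new_culture_model(nodes, w, "aggregated",
                                      list(field_side = 7.1, disc_radius = 3,
                                           h = NULL, tile = NULL), 1)
  rec <- run_damage_sequence(m, "bc_attack", steps = 1, recording_s = 300,
                             seed = 2, burst_fraction = 0.2)
  expect_true(rec$steps$target %in% c(1, 11))
})

test_that("region partition geometry around a horizontal cut", {
  m <- generate_homogeneous_culture(grid = 40, h = 0.7, seed = 2)
  p <- partition_regions(m, angle = 0, width = 500)
  labs <- p$labels

  # a ROI 1 mm above the cut on the disc is in half A
  i <- which.min((m$nodes$x - 0)^2 + (m$nodes$y - 1)^2)
  expect_equal(unname(labs[i]), "A")
  # mirrored below the cut: half B
  j <- which.min((m$nodes$x - 0)^2 + (m$nodes$y + 1)^2)
  expect_equal(unname(labs[j]), "B")
  # outside the disc radius: surroundings
  k <- which.min((m$nodes$x - 3.4)^2 + (m$nodes$y - 0.8)^2)
  expect_equal(unname(labs[k]), "S")

  # fractions near the experimental ones
  fr <- p$fractions
  expect_lt(abs(fr[["A"]] - 0.30), 0.10)
  expect_lt(abs(fr[["B"]] - 0.30), 0.10)
  expect_lt(abs(fr[["S"]] - 0.25), 0.10)
  expect_lt(abs(fr[["C"]] - 0.05), 0.10)
  expect_equal(sum(fr), 1)

  expect_error(partition_regions(generate_aggregated_culture(seed = 1)),
               "homogeneous")
})

test_that("region interaction counts fold directed connections", {
  # 6 ROIs labelled A,A,B,B,S,S with 3 A->B and 2 A->S connections
  a <- matrix(0L, 6, 6)
  a[1, 3] <- a[1, 4] <- a[2, 3] <- 1L  # A -> B x3
  a[1, 5] <- a[2, 6] <- 1L             # A -> S x2
  net <- net_from(a)
  part <- structure(list(labels = setNames(rep(c("A", "B", "S"), each = 2),
                                           1:6),
                         fractions = c(A = 1/3, B = 1/3, S = 1/3)),
                    class = "region_partition")
  ri <- region_interaction_matrix(net, part)
  expect_equal(ri$counts["A", "B"], 3)
  expect_equal(ri$counts["B", "A"], 3)
  expect_equal(ri$counts["A", "S"], 2)
  expect_equal(ri$counts["B", "S"], 0)

  empty <- net_from(matrix(0L, 6, 6))
  expect_true(all(region_interaction_matrix(empty, part)$counts == 0))
})

test_that("cut timeline: determinism, silent wound, staged recovery", {
  m <- generate_homogeneous_culture(grid = 16, h = 0.7, seed = 5)
  tl <- recovery_timeline(m, stages = c("before", "after", "2h"),
                          recording_s = 60, seed = 9,
                          excitability = list(init_rate = 0.5))
  tl2 <- recovery_timeline(m, stages = c("before", "after", "2h"),
                          recording_s = 60, seed = 9,
                          excitability = list(init_rate = 0.5))
  expect_identical(tl$counts, tl2$counts)
  expect_equal(rownames(tl$counts), c("before", "after", "2h"))

  # before damage the two halves interact
  expect_gt(tl$stages$before$interaction$counts["A", "B"], 0)

  # wounded ROIs never appear in post-cut events
  wound_ids <- as.integer(names(which(tl$partition$labels == "wound")))
  expect_gt(length(wound_ids), 0)
  expect_true(all(tl$model$nodes$removed[wound_ids]))

  expect_error(recovery_timeline(generate_aggregated_culture(seed = 1)),
               "homogeneous")
})
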