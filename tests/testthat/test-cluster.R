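test_that("dbscan recovers well-separated blobs and flags noise", {
  pts <- simulate_pc_cloud(
    data.frame(label = c("A", "B"), cx = c(0, 10), cy = 0, sd = 0.5, n = 40),
    noise_n = 0, seed = 71)
  one <- dbscan_points(pts[pts$declared_group == "A", ], eps = 1,
                       min_pts = 4)
  expect_equal(unname(unique(one)), 1L)

  noisy <- simulate_pc_cloud(
    data.frame(label = c("A", "B"), cx = c(0, 10), cy = 0, sd = 0.5, n = 40),
    noise_n = 6, noise_box = c(20, 40, 20, 40), seed = 72)
  lab <- dbscan_points(noisy, eps = 1, min_pts = 4)
  expect_equal(sort(unique(unname(lab))), 0:2)
  expect_true(all(lab[noisy$declared_group == "noise"] == 0))
  # each blob lands wholly in one cluster
  expect_equal(length(unique(lab[noisy$declared_group == "A"])), 1)
  expect_equal(length(unique(lab[noisy$declared_group == "B"])), 1)
})

test_that("dbscan equals the brute-force density-reachability oracle", {
  set.seed(73)
  for (i in 1:60) {
    n <- sample(5:50, 1)
    xy <- cbind(runif(n, 0, 4), runif(n, 0, 4))
    eps <- runif(1, 0.2, 1.2)
    min_pts <- sample(1:6, 1)
    got <- dbscan_points(xy, eps, min_pts)
    expect_equal(unname(got), dbscan_oracle(xy, eps, min_pts),
                 info = sprintf("instance %d (n=%d eps=%.2f minPts=%d)",
                                i, n, eps, min_pts))
  }
})

test_that("core-cluster selection follows the seed-group majority", {
  labels <- c(a1 = 1L, a2 = 1L, a3 = 2L, b1 = 2L, b2 = 0L, c1 = 1L)
  expect_setequal(select_core_cluster(labels, c("a1", "a2", "a3")),
                  c("a1", "a2", "c1"))
  expect_error(select_core_cluster(labels, "b2"), "noise")
  expect_message(tie <- select_core_cluster(labels, c("a1", "a3")), "tie")
  expect_setequal(tie, c("a1", "a2", "c1"))
})

test_that("IBD graph filtering uses strict (3, 30) cM bounds", {
  seg <- data.frame(
    id_a = c("x", "x", "x", "x", "x"),
    id_b = c("y", "y", "y", "z", "z"),
    length_cm = c(2, 5, 10, 30, 3),
    stringsAsFactors = FALSE
  )
  g <- build_ibd_graph(seg)
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 15)          # 5 + 10; 2, 3 and 30 excluded
  expect_setequal(g$nodes, c("x", "y", "z"))  # z kept as isolated node

  # conservation: total edge weight equals the sum of retained lengths
  sim <- simulate_ibd_segments(c(A = 25, B = 25), within_rate = 1,
                               between_rate = 0.2, seed = 74)
  g2 <- build_ibd_graph(sim$segments)
  retained <- sim$segments$length_cm[sim$segments$length_cm > 3 &
                                       sim$segments$length_cm < 30]
  expect_equal(sum(g2$edges$weight), sum(retained))
})

test_that("community detection separates disconnected cliques exactly", {
  clique <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(id_a = p[, 1], id_b = p[, 2], length_cm = 10,
               stringsAsFactors = FALSE)
  }
  seg <- rbind(clique(sprintf("a%d", 1:5)), clique(sprintf("b%d", 1:5)))
  g <- build_ibd_graph(seg)
  part <- detect_communities(g, seed = 75)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[sprintf("a%d", 1:5)])), 1)
  expect_equal(length(unique(part$membership[sprintf("b%d", 1:5)])), 1)

  # optimisation beats the singleton partition and the objective is the
  # modularity of the returned partition, recomputed independently
  singletons <- setNames(seq_along(g$nodes), g$nodes)
  expect_gt(part$modularity, graph_modularity(g, singletons))
  expect_equal(part$modularity, graph_modularity(g, part$membership))
})

test_that("no single node move can improve the returned partition", {
  sim <- simulate_ibd_segments(c(A = 30, B = 30, C = 30), within_rate = 1.5,
                               between_rate = 0.1, seed = 76)
  g <- build_ibd_graph(sim$segments)
  part <- detect_communities(g, seed = 77)
  q0 <- part$modularity
  memb <- part$membership
  comms <- unique(memb)
  set.seed(78)
  for (v in sample(names(memb), 25)) {
    for (c in comms) {
      if (c == memb[[v]]) next
      trial <- memb
      trial[v] <- c
      expect_lte(graph_modularity(g, trial), q0 + 1e-10)
    }
  }
})

test_that("planted communities are recovered and annotated", {
  sim <- simulate_ibd_segments(
    data.frame(label = c("NW Ireland", "Ulster", "Leinster", "Munster",
                         "Connacht"), n = 40),
    within_rate = 2.0, between_rate = 0.05, seed = 79)
  g <- build_ibd_graph(sim$segments)
  part <- detect_communities(g, seed = 80)
  expect_gt(ari(part$membership[names(sim$membership)], sim$membership),
            0.9)

  # annotate with a 30% labelled reference subset
  set.seed(81)
  refs <- sim$membership[sample(names(sim$membership), 60)]
  names_map <- annotate_communities(part, refs)
  expect_true(all(names_map %in% unique(sim$membership) |
                    names_map == "unlabelled"))
  # majority naming agrees with the dominant planted label per community
  for (cm in names(names_map)) {
    members <- names(part$membership)[part$membership == as.integer(cm)]
    dominant <- names(which.max(table(sim$membership[members])))
    if (names_map[[cm]] != "unlabelled") {
      expect_equal(names_map[[cm]], dominant)
    }
  }
})

test_that("detection is reproducible for a fixed seed and handles empties", {
  sim <- simulate_ibd_segments(c(A = 20, B = 20), within_rate = 1.5,
                               between_rate = 0.1, seed = 82)
  g <- build_ibd_graph(sim$segments)
  expect_identical(detect_communities(g, seed = 83),
                   detect_communities(g, seed = 83))

  empty <- build_ibd_graph(data.frame(id_a = character(0),
                                      id_b = character(0),
                                      length_cm = numeric(0)))
  part <- detect_communities(empty)
  expect_length(part$membership, 0)
})

test_that("modularity agrees with igraph on the same weighted graph", {
  sim <- simulate_ibd_segments(c(A = 25, B = 25), within_rate = 1.5,
                               between_rate = 0.1, seed = 84)
  g <- build_ibd_graph(sim$segments)
  part <- detect_communities(g, seed = 85)
  ig <- igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                      vertices = g$nodes)
  q_ig <- igraph::modularity(ig, part$membership[g$nodes],
                             weights = igraph::E(ig)$weight)
  expect_equal(part$modularity, q_ig, tolerance = 1e-10)

  # independent optimiser finds an equally good partition (cross-check,
  # not the implementation)
  cl <- igraph::cluster_leiden(ig, objective_function = "modularity",
                               weights = igraph::E(ig)$weight,
                               n_iterations = 5)
  q_leiden <- igraph::modularity(ig, igraph::membership(cl),
                                 weights = igraph::E(ig)$weight)
  expect_equal(part$modularity, q_leiden, tolerance = 0.02)
})
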