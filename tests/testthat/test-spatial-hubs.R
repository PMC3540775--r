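# Euclidean connection reach, hub ranking/frequency, and the seed-region
# connection profile with its pooled two-proportion z-test.

toy_table <- function(xyz) {
  data.frame(node_id = 0:(nrow(xyz) - 1L), name = paste0("n", seq_len(nrow(xyz))),
             hemisphere = "L", module_id = 1L, longrange_flag = FALSE,
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3])
}

test_that("neighbor mean distance averages distances to connected neighbors", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 5), c(50, 50, 50))
  adj <- matrix(0L, 4, 4)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[1, 3] <- adj[3, 1] <- 1L
  net <- as_net(adj)
  md <- neighbor_mean_distance(net, toy_table(xyz))
  expect_equal(md$mean_neighbor_distance[1], 5)   # mean of 5 and 5
  expect_equal(md$mean_neighbor_distance[2], 5)   # symmetry of an edge
  expect_false(md$defined_flag[4])                # isolated
  expect_true(is.na(md$mean_neighbor_distance[4]))
})

test_that("neighbor mean distance is invariant to rigid motion", {
  set.seed(41)
  xyz <- matrix(rnorm(15, sd = 20), 5, 3)
  adj <- matrix(rbinom(25, 1, 0.6), 5, 5)
  net <- as_net(adj)
  base <- neighbor_mean_distance(net, toy_table(xyz))$mean_neighbor_distance
  rot <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  moved <- xyz %*% rot + matrix(c(10, -5, 3), 5, 3, byrow = TRUE)
  expect_equal(neighbor_mean_distance(net, toy_table(moved))$mean_neighbor_distance,
               base)
})

test_that("top hubs sort by degree with node-id tie-breaking", {
  expect_equal(top_hubs(c(5, 3, 3, 1), hub_set_size = 2), c(0L, 1L))
  expect_equal(top_hubs(c(2, 2, 2, 2), hub_set_size = 3), c(0L, 1L, 2L))
  expect_equal(top_hubs(c(1, 9, 2), hub_set_size = 3), c(1L, 2L, 0L))
  expect_error(top_hubs(c(1, 2), hub_set_size = 3), "exceeds")
})

test_that("hub frequencies count top-set membership per group and sum to the set size", {
  set.seed(42)
  deg <- matrix(sample(0:40, 8 * 20, replace = TRUE), 8, 20)
  groups <- rep(c("control", "case"), each = 4L)
  hf <- hub_frequency(deg, groups, hub_set_size = 5)
  expect_true(all(hf$freq_control >= 0 & hf$freq_control <= 1))
  expect_equal(sum(hf$freq_control), 5)
  expect_equal(sum(hf$freq_case), 5)

  # A node always in the top set gets frequency 1; one never in it gets 0.
  deg2 <- deg; deg2[, 1] <- 100; deg2[, 2] <- -1
  hf2 <- hub_frequency(deg2, groups, hub_set_size = 5)
  expect_equal(hf2$freq_control[1], 1)
  expect_equal(hf2$freq_case[2], 0)
})

seed_fixture <- function(edges_per_subject, n_nodes = 6L, seed_node = 0L) {
  lapply(edges_per_subject, function(nbrs) {
    adj <- matrix(0L, n_nodes, n_nodes)
    for (nb in nbrs) {
      adj[seed_node + 1L, nb + 1L] <- 1L
      adj[nb + 1L, seed_node + 1L] <- 1L
    }
    as_net(adj)
  })
}

test_that("seed profile classifies specific, shared and absent connections", {
  # Controls (3): node 1 always, node 2 once. Cases (2): node 1 always, node 3 once.
  nets <- seed_fixture(list(c(1, 2), 1, 1, c(1, 3), 1))
  groups <- c("control", "control", "control", "case", "case")
  prof <- seed_profile(nets, groups, seed_node_id = 0L)
  expect_equal(prof$status[prof$node_id == 1], "shared")
  expect_equal(prof$status[prof$node_id == 2], "control_specific")
  expect_equal(prof$status[prof$node_id == 3], "case_specific")
  expect_false(4 %in% prof$node_id)  # never connected: not reported
  expect_false(0 %in% prof$node_id)  # the seed itself is not reported
  expect_error(seed_profile(nets, groups, seed_node_id = 99L), "out of range")

  # A stricter attribution threshold demotes single-subject connections.
  prof2 <- seed_profile(nets, groups, seed_node_id = 0L,
                        attribution_threshold = 0.5)
  expect_equal(prof2$status[prof2$node_id == 2], "unattributed")
})

test_that("pooled two-proportion z matches the hand formula", {
  # x1 = 8/16 vs x2 = 2/14: z = (0.5 - 1/7) / sqrt(1/3 * 2/3 * (1/16 + 1/14)).
  prof <- structure(
    data.frame(node_id = 1L, count_control = 8L, count_case = 2L,
               freq_control = 8 / 16, freq_case = 2 / 14, status = "shared",
               stringsAsFactors = FALSE),
    n_control = 16L, n_case = 14L, seed_node_id = 0L,
    class = c("seed_profile", "data.frame"))
  zt <- seed_frequency_z(prof)
  z_hand <- (0.5 - 2 / 14) / sqrt((10 / 30) * (20 / 30) * (1 / 16 + 1 / 14))
  expect_equal(zt$z, z_hand)
  expect_equal(round(zt$z, 2), 2.07)
  expect_true(zt$significant)

  # Swapping the two groups (counts and sizes) negates z.
  prof_sw <- prof
  prof_sw$count_control <- 2L; prof_sw$count_case <- 8L
  prof_sw$freq_control <- 2 / 14; prof_sw$freq_case <- 8 / 16
  attr(prof_sw, "n_control") <- 14L; attr(prof_sw, "n_case") <- 16L
  expect_equal(seed_frequency_z(prof_sw)$z, -zt$z)

  prof_eq <- prof
  prof_eq$count_control <- 8L; prof_eq$count_case <- 7L
  prof_eq$freq_control <- 0.5; prof_eq$freq_case <- 0.5
  attr(prof_eq, "n_control") <- 16L; attr(prof_eq, "n_case") <- 14L
  expect_equal(seed_frequency_z(prof_eq)$z, 0)

  # Pooled frequency 1: z undefined and flagged.
  prof_full <- prof
  prof_full$count_control <- 16L; prof_full$count_case <- 14L
  prof_full$freq_control <- 1; prof_full$freq_case <- 1
  zt_full <- seed_frequency_z(prof_full)
  expect_true(is.na(zt_full$z))
  expect_false(zt_full$z_defined)
})

test_that("raising case long-range coupling raises case ED at flagged nodes", {
  cfg <- generator_config(random_seed = 77L)
  co <- simulate_cohort(cfg)
  conn <- cohort_connectivity(co)
  ed <- do.call(rbind, lapply(conn$networks, function(net) {
    neighbor_mean_distance(net, co$node_table)$mean_neighbor_distance
  }))
  fl <- which(co$node_table$longrange_flag)
  ed_fl <- rowMeans(ed[, fl], na.rm = TRUE)
  mean_case <- mean(ed_fl[conn$groups == "case"])
  mean_control <- mean(ed_fl[conn$groups == "control"])
  expect_gt(mean_case, mean_control)
})
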