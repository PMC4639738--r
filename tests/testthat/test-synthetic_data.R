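flat_params <- function(sigma = 0.3, gamma = 0.2, kappa = 5,
                        individual_sd = 0) {
  behaviour_params(sociability = c(other = sigma),
                   grooming = c(other = gamma),
                   selectivity = c(other = kappa),
                   individual_sd = individual_sd)
}

test_that("roster generation is deterministic and validates sizes", {
  specs <- default_group_specs()
  expect_identical(make_roster(specs, seed = 3), make_roster(specs, seed = 3))
  bad <- list(G1 = tibble::tibble(deprivation_class = "ND", sex = "female",
                                  age_class = "mature", n = 1L))
  expect_error(make_roster(bad), "fewer than 2")
  expect_error(behaviour_params(sociability = c(other = 1.2),
                                grooming = c(other = 0.1),
                                selectivity = c(other = 1)),
               "out of range")
  expect_error(behaviour_params(sociability = c(other = 0.5),
                                grooming = c(other = 0.1),
                                selectivity = c(other = 0)),
               "out of range")
})

test_that("simulated scans are bit-identical given a seed", {
  ros <- tiny_roster(6)
  p <- flat_params(individual_sd = 0.5)
  s1 <- simulate_scans(ros, p, 40, seed = 11)
  s2 <- simulate_scans(ros, p, 40, seed = 11)
  expect_identical(s1[[1]]$events, s2[[1]]$events)
  expect_identical(attr(s1, "profiles"), attr(s2, "profiles"))
  s3 <- simulate_scans(ros, p, 40, seed = 12)
  expect_false(identical(s1[[1]]$events, s3[[1]]$events))
})

test_that("degenerate rates saturate or silence the behaviours", {
  ros <- tiny_roster(4)
  none <- simulate_scans(ros, flat_params(gamma = 0), 30, seed = 1)[[1]]
  expect_equal(sum(none$events$behaviour == "grooming"), 0)

  all_prox <- simulate_scans(ros, flat_params(sigma = 1), 30, seed = 1)[[1]]
  net <- build_proximity_network(all_prox, ros)
  w <- network_weights(net)
  expect_true(all(w[upper.tri(w)] == 100))
})

test_that("proximity weights match the dyadic product within binomial error", {
  ros <- tiny_roster(4)
  n_scans <- 5000
  rec <- simulate_scans(ros, flat_params(sigma = 0.5), n_scans, seed = 5)[[1]]
  w <- network_weights(build_proximity_network(rec, ros))
  off <- w[upper.tri(w)]
  tol <- 3 * 100 * sqrt(0.25 * 0.75 / n_scans)
  expect_true(all(abs(off - 25) < tol))
})

test_that("expected measures obey the closed forms", {
  ros <- tiny_roster(5)
  p <- flat_params(gamma = 0.3)
  profiles <- draw_profiles(ros, p, seed = 2)
  # force known preference structures
  mates <- setdiff(ros$id, ros$id[1])
  profiles$preferences[[ros$id[1]]] <-
    stats::setNames(rep(0.25, 4), mates)
  profiles$preferences[[ros$id[2]]] <-
    stats::setNames(c(1, 0, 0, 0), setdiff(ros$id, ros$id[2]))
  em <- expected_measures(ros, p, profiles)
  expect_equal(em$node$exp_grooming_y2[1], 0.25)     # uniform: 1/(N-1)
  expect_equal(em$node$exp_grooming_y2[2], 1)        # single partner

  ros6 <- tiny_roster(6)
  em6 <- expected_measures(ros6, p, draw_profiles(ros6, p, seed = 2))
  expect_equal(em6$node$exp_grooming_strength_centrality,
               rep(100 * 0.3 / 5, 6))
})

test_that("empirical networks converge to the expected measures", {
  ros <- tiny_roster(5)
  p <- flat_params(sigma = 0.4, gamma = 0.5, kappa = 2, individual_sd = 0.5)
  n_scans <- 20000
  sim <- simulate_scans(ros, p, n_scans, seed = 9)
  profiles <- attr(sim, "profiles")
  em <- expected_measures(ros, p, profiles)
  rec <- sim[[1]]

  wp <- network_weights(build_proximity_network(rec, ros))
  exp_w <- em$proximity_weights$G1
  p_dyad <- exp_w / 100
  tol <- 3 * 100 * sqrt(pmax(p_dyad * (1 - p_dyad), 1e-9) / n_scans)
  expect_true(all(abs(wp - exp_w)[upper.tri(wp)] <= tol[upper.tri(wp)]))

  gnet <- build_grooming_network(rec, ros)
  gsc <- vertex_strength_centrality(gnet)
  gam <- profiles$rates$gamma
  tol_g <- 3 * 100 * sqrt(gam * (1 - gam) / n_scans) / 4
  expect_true(all(abs(gsc - em$node$exp_grooming_strength_centrality) <=
                    tol_g))
  # realized grooming disparity approaches the preference-vector disparity
  y2 <- edge_weight_disparity(gnet)
  expect_true(all(abs(y2 - em$node$exp_grooming_y2) < 0.03))
})

test_that("stronger selectivity (smaller kappa) raises realized disparity", {
  ros <- tiny_roster(8)
  mean_dy2 <- function(kappa) {
    vals <- sapply(1:6, function(seed) {
      rec <- simulate_scans(ros, flat_params(gamma = 0.6, kappa = kappa),
                            400, seed = seed)[[1]]
      mean(deviation_from_disparity(build_grooming_network(rec, ros)),
           na.rm = TRUE)
    })
    mean(vals)
  }
  d <- c(mean_dy2(0.5), mean_dy2(3), mean_dy2(30))
  expect_true(d[1] > d[2])
  expect_true(d[2] > d[3])
})
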