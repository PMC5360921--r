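test_that("connectance counts realized links over possible links", {
  expect_equal(connectance(as_network(matrix(1, 2, 2))), 1)
  expect_equal(connectance(as_network(rbind(c(2, 0), c(0, 1)))), 0.5)
  expect_true(is.na(connectance(elevnet:::empty_network())))
})

test_that("generality and vulnerability are weighted effective partners", {
  # each ant uses a single plant: zero column entropy
  expect_equal(generality(as_network(rbind(c(3, 0), c(0, 2)))), 1)
  # uniform complete 3x2: effective partners equal partner counts
  u <- as_network(matrix(2, 3, 2))
  expect_equal(generality(u), 3)
  expect_equal(vulnerability(u), 2)
  # frozen from independent scalar evaluation of the entropy formula
  net <- as_network(rbind(c(2, 1), c(0, 3)))
  expect_equal(generality(net), 1.5031769004, tolerance = 1e-9)
  expect_equal(vulnerability(net), 1.4449407874, tolerance = 1e-9)
})

test_that("generality equals vulnerability on symmetric square matrices", {
  set.seed(31)
  for (i in 1:20) {
    a <- matrix(rpois(16, 2), 4, 4)
    a <- a + t(a) + diag(4L)  # symmetric, no empty margins
    net <- as_network(a)
    expect_equal(generality(net), vulnerability(net), tolerance = 1e-12)
  }
})

test_that("H2' hits its trivial extremes exactly", {
  expect_equal(h2_prime(as_network(diag(2) * 3L)), 1)
  expect_equal(h2_prime(as_network(matrix(1, 2, 2))), 0)
  # frozen via exhaustive enumeration of tables with marginals (3,3)/(2,4):
  # the observed table attains the constrained entropy minimum
  expect_equal(h2_prime(as_network(rbind(c(2, 1), c(0, 3)))), 1)
  # degenerate marginals: single row forces the matrix
  expect_true(is.na(h2_prime(as_network(matrix(c(2, 3), 1, 2)))))
})

test_that("metrics are invariant under permutation and count scaling", {
  set.seed(77)
  for (i in 1:25) {
    net <- random_network(sample(2:5, 1), sample(2:5, 1))
    a <- net$counts
    perm <- a[sample(nrow(a)), sample(ncol(a)), drop = FALSE]
    pnet <- elevnet:::new_bipartite_network(perm)
    expect_equal(connectance(pnet), connectance(net))
    expect_equal(generality(pnet), generality(net), tolerance = 1e-12)
    expect_equal(vulnerability(pnet), vulnerability(net), tolerance = 1e-12)
    h_obs <- h2_prime(net)
    expect_equal(h2_prime(pnet), h_obs, tolerance = 1e-9)
    # scaling the counts refines the integer feasible set, so the
    # constrained extrema (and hence H2') move slightly; invariance is
    # only asymptotic in m
    scaled <- elevnet:::new_bipartite_network(a * 3L)
    expect_lt(abs(h2_prime(scaled) - h_obs), 0.1)
  }
})

test_that("heuristic H2 extrema agree with enumeration on small marginals", {
  cases <- list(
    list(k = c(3, 3), d = c(2, 4)),
    list(k = c(5, 2, 1), d = c(4, 4)),
    list(k = c(4, 4, 4), d = c(6, 3, 3)),
    list(k = c(7, 1), d = c(2, 2, 4))
  )
  for (cs in cases) {
    heur <- h2_extrema(cs$k, cs$d)
    exact <- oracle_h2_extrema(cs$k, cs$d)
    expect_equal(heur$h2_min, exact$h2_min, tolerance = 1e-9)
    expect_equal(heur$h2_max, exact$h2_max, tolerance = 1e-9)
  }
})

test_that("metric_set composes the metrics and propagates NA", {
  set.seed(5)
  ms <- metric_set(as_network(rbind(c(2, 0), c(0, 1))))
  expect_equal(ms$plant_richness, 2L)
  expect_equal(ms$ant_richness, 2L)
  expect_equal(ms$connectance, 0.5)
  expect_equal(ms$generality, 1)
  expect_equal(ms$vulnerability, 1)
  empty <- metric_set(elevnet:::empty_network())
  expect_equal(empty$plant_richness, 0L)
  expect_true(all(is.na(empty[, c("connectance", "generality",
                                  "vulnerability", "h2_prime",
                                  "modularity_q")])))
})

test_that("herbivory index averages category midpoints by leaf counts", {
  expect_equal(herbivory_index(c(10, 0, 0, 0)), 0)
  expect_equal(herbivory_index(c(0, 2, 2, 0)), 10.75)
  expect_equal(herbivory_index(c(0, 0, 0, 5)), 66.5)
  expect_true(is.na(herbivory_index(c(0, 0, 0, 0))))
  expect_equal(herbivory_index(rbind(c(10, 0, 0, 0), c(0, 0, 0, 5))),
               c(0, 66.5))
})

test_that("occupancy counts uncertain occupants as occupied", {
  cen <- tiny_census(
    rep(700, 25),
    rep("P1", 25),
    c(rep("A1", 17), "uncertain", rep(NA, 7))
  )
  expect_equal(occupancy_rate(cen, "P1"), 0.72)
  expect_equal(occupancy_rate(tiny_census(700, rep("P2", 5), rep(NA, 5)), "P2"), 0)
  expect_equal(occupancy_rate(tiny_census(700, "P3", "A1"), "P3"), 1)
  expect_true(is.na(occupancy_rate(cen, "absent_species")))
})
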