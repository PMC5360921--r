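test_that("affinity concentration follows the specialization exponent", {
  cfg0 <- sim_config(specialization_gamma = 0, seed = 11)
  pools0 <- sample_species_pools(cfg0)
  expect_true(all(abs(pools0$affinity - 1 / cfg0$n_ant_species) < 1e-12))

  cfgL <- sim_config(specialization_gamma = 5000, seed = 11)
  poolsL <- sample_species_pools(cfgL)
  expect_true(all(apply(poolsL$affinity, 1, max) >= 0.999))

  expect_true(all(rowSums(pools0$affinity) - 1 < 1e-12))
  expect_error(sim_config(n_plant_species = 0), "counts")
  expect_error(sim_config(specialization_gamma = -1), "gamma")
  expect_error(sim_config(elevations = c(800, 700)), "increasing")
})

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(seed = 99)
  s1 <- simulate_census(cfg)
  s2 <- simulate_census(cfg)
  expect_identical(s1$pools, s2$pools)
  expect_identical(s1$census, s2$census)

  # census survives a CSV round trip
  path <- tempfile(fileext = ".csv")
  write_census(s1$census, path, seed = 99)
  back <- read_census(path)
  expect_equal(back$ant_species, s1$census$ant_species)
  expect_equal(back$herb_cat4, s1$census$herb_cat4)
})

test_that("every record carries zero or one ant species", {
  cen <- simulate_census(sim_config(seed = 4))$census
  occ <- as.logical(cen$occupied)
  expect_true(all(nzchar(cen$ant_species[occ])))
  expect_true(all(cen$ant_species[!occ] == ""))
  expect_true(all(cen$herb_cat1 >= 0))
  # one species only: the field is a single label, never a list
  expect_false(any(grepl("[,;]", cen$ant_species)))
})

test_that("zero occupancy forces an empty downstream network", {
  cfg <- sim_config(occupancy_curve = 0, seed = 2)
  cen <- simulate_census(cfg)$census
  expect_true(all(cen$occupied == 0))
  expect_equal(build_network(cen, 700)$m, 0L)
})

test_that("a halving decline rate quarters expected abundance 200 m up", {
  # turnover disabled so the range kernel is flat and the decline factor is
  # the only elevational signal; closed form: E[N(900)] / E[N(700)] = 0.25
  tot700 <- tot900 <- numeric(200)
  for (s in seq_len(200)) {
    cfg <- sim_config(abundance_decline_rate = 0.5, turnover = FALSE,
                      seed = s)
    cen <- generate_census(cfg)
    tot700[s] <- sum(cen$elevation_m == 700)
    tot900[s] <- sum(cen$elevation_m == 900)
  }
  expect_lt(abs(mean(tot900) / mean(tot700) - 0.25), 0.03)
})

test_that("strong specialization yields near-diagonal low-elevation networks", {
  h2 <- vapply(seq_len(50), function(s) {
    cfg <- sim_config(specialization_gamma = 50, turnover = FALSE, seed = s,
                      uncertain_fraction = 0)
    h2_prime(build_network(generate_census(cfg), 700))
  }, numeric(1))
  expect_gte(mean(h2, na.rm = TRUE), 0.9)
})

test_that("specialization and decline act monotonically on average", {
  n_seeds <- 50
  h2_lo <- h2_hi <- top_gentle <- top_steep <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    cen_lo <- generate_census(sim_config(specialization_gamma = 0, seed = s))
    cen_hi <- generate_census(sim_config(specialization_gamma = 5, seed = s))
    h2_lo[s] <- h2_prime(build_network(cen_lo, 700))
    h2_hi[s] <- h2_prime(build_network(cen_hi, 700))
    gentle <- generate_census(sim_config(abundance_decline_rate = 0.9, seed = s))
    steep <- generate_census(sim_config(abundance_decline_rate = 0.6, seed = s))
    high <- function(x) sum(x$elevation_m >= 1300 & x$occupied == 1)
    top_gentle[s] <- high(gentle)
    top_steep[s] <- high(steep)
  }
  expect_gt(mean(h2_hi, na.rm = TRUE), mean(h2_lo, na.rm = TRUE))
  expect_gt(mean(top_gentle), mean(top_steep))
})

test_that("herbivory damage shifts upward with elevation", {
  idx <- sapply(seq_len(30), function(s) {
    cen <- generate_census(sim_config(seed = s, turnover = FALSE))
    h <- herbivory_index(cen[, paste0("herb_cat", 1:4)])
    c(mean(h[cen$elevation_m == 700]), mean(h[cen$elevation_m == 1600]))
  })
  expect_gt(mean(idx[2, ]), mean(idx[1, ]))
})

test_that("a config survives a YAML round trip", {
  cfg <- sim_config(seed = 7, occupancy_curve = c(0.7, 0.6), turnover = FALSE)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$occupancy_curve, cfg$occupancy_curve)
  expect_identical(generate_census(cfg), generate_census(cfg2))
})
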