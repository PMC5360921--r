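test_that("pooling keeps identified occupied interactions only", {
  cen <- rbind(
    tiny_census(700, paste0("P", 1:5), paste0("A", c(1, 1, 2, 2, 3))),
    tiny_census(800, paste0("P", 6:8), c("A1", "A4", "uncertain")),
    tiny_census(900, "P9", "A1"),       # outside the pool
    tiny_census(700, "P1", NA)          # unoccupied
  )
  pool <- pool_community(cen, c(700, 800))
  expect_equal(nrow(pool), 7L)
  expect_false("uncertain" %in% pool$ant_species)
  expect_false("P9" %in% pool$plant_species)
  # pooling an elevation with no records changes nothing
  expect_equal(pool_community(cen, c(700, 800, 1200)), pool)
})

test_that("rarefaction is a without-replacement subsample of the pool", {
  cen <- tiny_census(700, rep(paste0("P", 1:3), each = 4),
                     rep(paste0("A", 1:2), 6))
  pool <- pool_community(cen, 700)
  set.seed(8)
  full <- rarefy(pool, nrow(pool))
  expect_identical(full$counts, build_network(cen, 700)$counts)

  set.seed(9)
  one <- rarefy(pool, 1)
  expect_equal(dim(one$counts), c(1L, 1L))
  expect_equal(connectance(one), 1)
  expect_true(is.na(h2_prime(one)))

  set.seed(10)
  r1 <- rarefy(pool, 5)
  set.seed(10)
  r2 <- rarefy(pool, 5)
  expect_identical(r1$counts, r2$counts)
  # no event appears more often than it exists in the pool
  tab_pool <- table(paste(pool$plant_species, pool$ant_species))
  for (i in 1:20) {
    r <- rarefy(pool, 7)
    for (pl in rownames(r$counts)) for (an in colnames(r$counts)) {
      expect_lte(r$counts[pl, an], tab_pool[[paste(pl, an)]])
    }
  }
  expect_error(rarefy(pool, nrow(pool) + 1), "cannot rarefy")
})

test_that("patefield draws preserve marginals exactly", {
  set.seed(21)
  for (i in 1:10) {
    net <- random_network(sample(2:5, 1), sample(2:5, 1))
    for (j in 1:20) {
      null <- patefield_null(net)
      expect_identical(rowSums(null$counts), rowSums(net$counts))
      expect_identical(colSums(null$counts), colSums(net$counts))
    }
  }
  # single-row matrices are forced by their marginals
  skinny <- as_network(matrix(c(2L, 5L, 1L), 1, 3))
  expect_identical(patefield_null(skinny)$counts, skinny$counts)
})

test_that("H2' significance behaves at both extremes", {
  set.seed(33)
  flat <- as_network(matrix(1L, 2, 2))
  res <- h2_significance(flat, n_null = 200)
  expect_gt(res$p_value, 0.9)   # observed sits at the null minimum

  diag4 <- as_network(diag(4L) * 10L)
  res2 <- h2_significance(diag4, n_null = 200)
  expect_lte(res2$p_value, 0.05)
  expect_gte(res2$p_value, 1 / 201)
  expect_length(res2$null, 200)
  expect_true(all(res2$null >= 0 & res2$null <= 1))

  # undefined H2' (single-row network) -> no result
  expect_null(h2_significance(as_network(matrix(c(2L, 3L), 1, 2))))
})

test_that("prediction bands collapse to the pooled value at full size", {
  cen <- tiny_census(700, rep(paste0("P", 1:4), times = c(6, 5, 4, 3)),
                     paste0("A", c(1, 1, 1, 2, 2, 2, 1, 1, 2, 3, 3, 3,
                                   1, 2, 3, 1, 2, 3)))
  pool <- pool_community(cen, 700)
  pooled_net <- build_network(cen, 700)
  bands <- prediction_bands(pool, c(`900` = nrow(pool)), n_replicates = 50,
                            metrics = c("connectance", "generality",
                                        "h2_prime"), seed = 5)
  obs <- c(connectance(pooled_net), generality(pooled_net),
           h2_prime(pooled_net))
  expect_equal(bands$lower, bands$upper, tolerance = 1e-12)
  expect_equal(sort(bands$lower), sort(obs), tolerance = 1e-9)

  # reproducible under seed, and undefined replicates are accounted for
  b1 <- prediction_bands(pool, c(`1300` = 3), n_replicates = 100, seed = 7,
                         metrics = c("connectance", "h2_prime"))
  b2 <- prediction_bands(pool, c(`1300` = 3), n_replicates = 100, seed = 7,
                         metrics = c("connectance", "h2_prime"))
  expect_identical(b1, b2)
  h2row <- b1[b1$metric == "h2_prime", ]
  expect_equal(h2row$n_undefined + 100 - h2row$n_undefined, h2row$n_replicates)
  expect_true(all(b1$lower <= b1$upper, na.rm = TRUE))
  expect_error(prediction_bands(pool, c(`900` = 1000), seed = 1),
               "exceeds pool size")
})

test_that("band width shrinks to zero as n approaches the pool size", {
  set.seed(50)
  cen <- simulate_census(sim_config(seed = 3))$census
  pool <- pool_community(cen, c(700, 800))
  widths <- vapply(c(0.3, 0.7, 1), function(f) {
    b <- prediction_bands(pool, c(`1000` = round(f * nrow(pool))),
                          n_replicates = 100, metrics = "generality",
                          seed = 2)
    b$upper - b$lower
  }, numeric(1))
  expect_true(widths[3] < widths[1])
  expect_equal(widths[3], 0, tolerance = 1e-12)
})
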