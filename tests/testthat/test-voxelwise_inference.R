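full_mask <- function(shape) {
  brain_mask(array(1L, shape), volume_grid(shape))
}

noise_maps <- function(n, shape) {
  lapply(seq_len(n), function(i) array(rnorm(prod(shape)), shape))
}

test_that("voxelwise statistics match the closed-form t from r", {
  shape <- c(6L, 6L, 6L)
  set.seed(41)
  n <- 15
  maps <- noise_maps(n, shape)
  y <- rnorm(n)
  # plant one perfect voxel and one constant voxel
  for (i in seq_len(n)) {
    maps[[i]][2, 2, 2] <- y[i]
    maps[[i]][3, 3, 3] <- 0
  }
  sm <- voxelwise_statistic(maps, y, full_mask(shape), min_coverage = 5)
  expect_equal(sm$t_values[2, 2, 2], 1e6)         # r = 1, capped sentinel
  expect_equal(sm$analysis_mask[3, 3, 3], 0L)     # all-zero voxel excluded
  # direct formula oracle on an ordinary voxel
  v <- vapply(maps, function(m) m[4, 5, 1], numeric(1))
  r <- cor(v, y)
  expect_equal(sm$t_values[4, 5, 1], r * sqrt((n - 2) / (1 - r^2)),
               tolerance = 1e-10)
  expect_equal(sm$r_values[4, 5, 1], r, tolerance = 1e-10)
})

test_that("tfce equals the brute-force threshold-loop oracle", {
  expect_true(all(tfce(array(0, c(5, 5, 5))) == 0))
  set.seed(42)
  for (conn in c(6L, 26L)) {
    t3 <- array(rnorm(12^3), c(12, 12, 12))
    dh <- max(t3) / 100
    got <- tfce(t3, tfce_params(dh = dh, connectivity = conn))
    want <- tfce_oracle(t3, dh = dh, connectivity = conn)
    expect_lt(max(abs(got - want)) / max(want), 1e-9)
  }
  # uniform cluster closed form: every member gets sum_k k^E h^H dh
  t3 <- array(0, c(8, 8, 8))
  t3[3:4, 3:4, 3] <- 1.7
  dh <- 0.25
  got <- tfce(t3, tfce_params(dh = dh))
  hs <- seq(dh, 1.7, by = dh)
  expect_equal(unique(got[got > 0]), sum(4^0.5 * hs^2 * dh),
               tolerance = 1e-12)
  # scaling the map strictly increases TFCE wherever t > 0
  got2 <- tfce(2 * t3, tfce_params(dh = dh))
  expect_true(all(got2[t3 > 0] > got[t3 > 0]))
  expect_error(tfce_params(E = -1), "E and H")
  expect_error(tfce_params(connectivity = 10), "connectivity")
})

test_that("permutation p-values respect the add-one floor", {
  shape <- c(6L, 6L, 6L)
  set.seed(43)
  n <- 12
  maps <- noise_maps(n, shape)
  y <- rnorm(n)
  res <- permutation_fwe(maps, y, full_mask(shape), n_perm = 10,
                         alpha = 0.01, seed = 1)
  inmask <- res$analysis_mask == 1L
  expect_gte(min(res$fwe_p[inmask]), 1 / 11)
  expect_equal(sum(res$significant), 0)  # 1/11 > 0.01: nothing can pass
  expect_error(permutation_fwe(maps, y, full_mask(shape), n_perm = 0),
               "n_perm")
})

test_that("a voxel carrying the outcome exactly is detected", {
  shape <- c(10L, 10L, 10L)
  set.seed(44)
  n <- 20
  maps <- noise_maps(n, shape)
  y <- rnorm(n)
  for (i in seq_len(n)) maps[[i]][5, 5, 5] <- y[i]
  res <- permutation_fwe(maps, y, full_mask(shape), n_perm = 200,
                         alpha = 0.05, seed = 2)
  expect_equal(res$significant[5, 5, 5], 1L)
  expect_lt(res$fwe_p[5, 5, 5], 0.05)
})

test_that("negating the maps swaps the two contrasts exactly", {
  shape <- c(8L, 8L, 8L)
  set.seed(45)
  n <- 14
  maps <- noise_maps(n, shape)
  y <- rnorm(n)
  neg <- lapply(maps, function(m) -m)
  pos <- permutation_fwe(maps, y, full_mask(shape), n_perm = 50,
                         alpha = 0.05, direction = "positive", seed = 7)
  swp <- permutation_fwe(neg, y, full_mask(shape), n_perm = 50,
                         alpha = 0.05, direction = "negative", seed = 7)
  expect_equal(pos$t_values, swp$t_values, tolerance = 1e-12)
  expect_equal(pos$tfce_observed, swp$tfce_observed, tolerance = 1e-12)
  expect_equal(pos$fwe_p, swp$fwe_p, tolerance = 1e-12)
})

test_that("network-outcome correlations report r, r2 and p per network", {
  cfg <- small_synth_config(seed = 46L)
  atl <- make_atlases(cfg)
  n <- 12
  y <- rnorm(n)
  # craft maps whose network-1 mean equals y exactly
  maps <- lapply(seq_len(n), function(i) {
    v <- array(0, cfg$grid_shape)
    v[atl$network$labels == 1L] <- y[i]
    disconnection_map(sprintf("s%02d", i), atl$brainmask$grid,
                      pmax(pmin(v, 1), -1), "functional")
  })
  y <- pmax(pmin(y, 1), -1)
  tab <- network_outcome_correlation(maps, atl$network, y)
  expect_equal(tab$r[tab$label == 1L], 1, tolerance = 1e-12)
  expect_equal(tab$r2[tab$label == 1L], 1, tolerance = 1e-12)
  # the other networks are constant zero: flagged degenerate with r = 0
  expect_true(all(tab$degenerate[tab$label != 1L]))
  expect_true(all(tab$r[tab$label != 1L] == 0))
  # p-value matches the closed form through cor.test
  set.seed(47)
  maps2 <- lapply(seq_len(n), function(i) {
    v <- array(rnorm(prod(cfg$grid_shape), 0, 0.2), cfg$grid_shape)
    disconnection_map(sprintf("s%02d", i), atl$brainmask$grid,
                      pmax(pmin(v, 1), -1), "functional")
  })
  tab2 <- network_outcome_correlation(maps2, atl$network, y)
  s1 <- vapply(maps2, function(m)
    mean(m$values[atl$network$labels == 2L]), numeric(1))
  ct <- cor.test(s1, y)
  expect_equal(tab2$r[tab2$label == 2L], unname(ct$estimate),
               tolerance = 1e-10)
  expect_equal(tab2$p[tab2$label == 2L], ct$p.value, tolerance = 1e-10)
})
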