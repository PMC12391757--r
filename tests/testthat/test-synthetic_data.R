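test_that("atlases partition the brain mask and are reproducible", {
  cfg <- synthetic_config(grid_shape = c(8L, 10L, 8L), n_networks = 2L,
                          n_vascular_territories = 2L, n_tracts = 2L,
                          n_subjects = 3L, n_timepoints = 20L, seed = 1L)
  atl <- make_atlases(cfg)
  bm <- atl$brainmask$data
  expect_equal(length(atl$vascular$names), 2L)
  expect_equal(length(atl$network$names), 2L)
  # per-voxel: exactly one vascular and one network label inside the mask
  expect_true(all((atl$vascular$labels > 0) == (bm == 1)))
  expect_true(all((atl$network$labels > 0) == (bm == 1)))
  # distributed systems: each network comprises >= 2 disjoint patches
  for (k in seq_len(cfg$n_networks)) {
    patches <- unique(atl$network$patches[atl$network$labels == k])
    expect_gte(length(patches), 2L)
  }
  # determinism: same config, same volumes
  atl2 <- make_atlases(cfg)
  expect_identical(atl$vascular$labels, atl2$vascular$labels)
  expect_identical(atl$network$labels, atl2$network$labels)
  expect_identical(atl$wm$labels, atl2$wm$labels)

  expect_error(make_atlases(synthetic_config(grid_shape = c(4L, 4L, 4L),
                                             n_networks = 40L,
                                             n_timepoints = 200L,
                                             seed = 1L)),
               "grid too small")
})

test_that("connectome correlations match the generative model", {
  # perfect coupling: all same-network pairs correlate at 1
  cfg1 <- small_synth_config(within_network_corr = 1, seed = 2L)
  atl <- make_atlases(cfg1)
  conn1 <- make_connectome(cfg1, atl$network)
  net <- atl$network$labels[conn1$voxel_index]
  i1 <- which(net == 1)[1:4]
  C <- cor(t(conn1$ts[i1, ]))
  expect_equal(max(abs(C - 1)), 0, tolerance = 1e-10)

  # Monte-Carlo against the generative correlation at c = 0.6
  cfg <- synthetic_config(grid_shape = c(14L, 16L, 14L), n_networks = 3L,
                          n_vascular_territories = 4L, n_tracts = 3L,
                          n_subjects = 3L, n_timepoints = 2000L,
                          within_network_corr = 0.6, seed = 3L)
  atl <- make_atlases(cfg)
  conn <- make_connectome(cfg, atl$network)
  net <- atl$network$labels[conn$voxel_index]
  set.seed(4)
  same <- cross <- numeric(300)
  for (r in 1:300) {
    k <- sample(3, 1)
    ij <- sample(which(net == k), 2)
    same[r] <- cor(conn$ts[ij[1], ], conn$ts[ij[2], ])
    ab <- c(sample(which(net == k), 1),
            sample(which(net != k), 1))
    cross[r] <- cor(conn$ts[ab[1], ], conn$ts[ab[2], ])
  }
  expect_lt(abs(mean(same) - 0.6), 0.05)
  expect_lt(abs(mean(cross)), 0.05)

  # distributed-network property: disjoint patches of one network carry
  # the same latent signal, so cross-patch correlations also approach c
  patch <- atl$network$patches[conn$voxel_index]
  p_of_1 <- unique(patch[net == 1])
  v1 <- which(patch == p_of_1[1])[1:20]
  v2 <- which(patch == p_of_1[2])[1:20]
  cp <- cor(t(conn$ts[v1, ]), t(conn$ts[v2, ]))
  expect_lt(abs(mean(cp) - 0.6), 0.05)
})

test_that("tracts are corridors with valid probabilities and endpoints", {
  cfg <- small_synth_config(seed = 5L)
  atl <- make_atlases(cfg)
  tr <- atl$tracts
  expect_equal(length(tr$tracts), cfg$n_tracts)
  for (t in tr$tracts) {
    v <- t$visitation
    expect_true(all(v >= 0 & v <= 1))
    expect_gt(sum(v > 0), 0)
    expect_equal(max(v), 1)   # peak 1 on the core path
    # endpoint masks intersect the two patches of the tract's network
    for (e in t$endpoints)
      expect_gt(sum(e$data == 1 & atl$network$labels == t$network), 0)
  }
  tr2 <- make_tracts(cfg, atl$network)
  expect_identical(tr$tracts[[1]]$visitation, tr2$tracts[[1]]$visitation)
})

test_that("cohort outcomes follow the planted generative formula", {
  # degenerate: no weights, no covariates, no noise -> single mRS value
  cfg0 <- small_synth_config(outcome_weights = numeric(0),
                             covariate_effects = c(age = 0, sex = 0,
                                                   nihss = 0),
                             noise_sd = 0, outcome_intercept = 2,
                             seed = 6L)
  atl <- make_atlases(cfg0)
  coh0 <- make_cohort(cfg0, atl, atl$tracts)
  expect_equal(length(unique(coh0$outcomes$mrs)), 1L)

  # monotonicity: weight on one parcel only, noise-free -> mRS is a
  # nondecreasing function of the fraction of that parcel lesioned
  cfgm <- small_synth_config(outcome_weights = c("1" = 10),
                             covariate_effects = c(age = 0, sex = 0,
                                                   nihss = 0),
                             noise_sd = 0, outcome_intercept = 0.4,
                             n_subjects = 25L, seed = 7L)
  cohm <- make_cohort(cfgm, atl, atl$tracts)
  ord <- order(cohm$truth$parcel_fractions[, "1"])
  expect_true(all(diff(cohm$outcomes$mrs[ord]) >= 0))

  # lesions are 6-connected, inside the mask, and unilateral
  cfg <- small_synth_config(seed = 8L)
  coh <- make_cohort(cfg, atl, atl$tracts)
  shp <- cfg$grid_shape
  mid <- shp[1] / 2
  for (les in coh$lesions[1:5]) {
    vox <- which(les$data == 1L)
    expect_true(all(atl$brainmask$data[vox] == 1L))
    ijk <- arrayInd(vox, shp)
    expect_true(all(ijk[, 1] - 1 < mid) || all(ijk[, 1] - 1 >= mid))
    # connectedness via igraph over 6-neighbour adjacency
    d <- as.matrix(dist(ijk, method = "manhattan"))
    g <- igraph::graph_from_adjacency_matrix(d == 1, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1L)
  }
  expect_true(all(coh$outcomes$mrs %in% 0:6))
  expect_true(all(coh$outcomes$nihss >= 0 & coh$outcomes$nihss <= 42))

  # exact reproducibility from (config, seed)
  coh2 <- make_cohort(cfg, atl, atl$tracts)
  expect_identical(coh$outcomes, coh2$outcomes)
  expect_identical(coh$lesions[[3]]$data, coh2$lesions[[3]]$data)
})

test_that("cohort directories round-trip through write and load", {
  cfg <- small_synth_config(n_subjects = 4L, seed = 9L)
  atl <- make_atlases(cfg)
  conn <- make_connectome(cfg, atl$network)
  coh <- make_cohort(cfg, atl, atl$tracts)
  dir <- tempfile("cohort_")
  write_cohort(coh, atl, conn, dir)
  back <- load_cohort(dir)
  expect_equal(back$outcomes$mrs, coh$outcomes$mrs)
  expect_identical(back$lesions[[2]]$data, coh$lesions[[2]]$data)
  expect_identical(back$atlases$network$labels, atl$network$labels)
  expect_equal(back$connectome$ts, conn$ts, tolerance = 1e-6)
  expect_equal(back$tracts$tracts[[1]]$visitation,
               atl$tracts$tracts[[1]]$visitation, tolerance = 1e-6)

  unlink(file.path(dir, "participants.tsv"))
  expect_error(load_cohort(dir), "participants.tsv")
})
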