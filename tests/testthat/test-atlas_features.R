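make_two_parcel_fixture <- function() {
  # parcel A (label 1): 100 voxels; parcel B (label 2): 20 voxels;
  # lesion: 10 voxels, 6 in A and 4 in B
  grid <- tiny_grid(c(5L, 5L, 5L))
  labs <- array(0L, c(5, 5, 5))
  labs[1:100] <- 1L
  labs[101:120] <- 2L
  les <- array(0L, c(5, 5, 5))
  les[c(1:6, 101:104)] <- 1L
  list(atlas = parcellation_atlas(labs, grid, kind = "functional"),
       lesion = lesion_mask(les, grid))
}

test_that("overlap percentages follow the dual-percentage definition", {
  fx <- make_two_parcel_fixture()
  f <- compute_overlap(fx$lesion, fx$atlas)
  expect_equal(unname(f$lesion_pct), c(60, 40))
  expect_equal(unname(f$parcel_pct), c(6, 20))

  # lesion identical to parcel B -> 100/100 on B, 0 elsewhere
  lesB <- array(0L, c(5, 5, 5))
  lesB[101:120] <- 1L
  fB <- compute_overlap(lesion_mask(lesB, fx$atlas$grid), fx$atlas)
  expect_equal(unname(fB$lesion_pct), c(0, 100))
  expect_equal(unname(fB$parcel_pct), c(0, 100))

  # empty lesion -> all zeros, empty retained set
  fe <- compute_overlap(lesion_mask(array(0L, c(5, 5, 5)), fx$atlas$grid,
                                    allow_empty = TRUE), fx$atlas)
  expect_true(all(fe$lesion_pct == 0) && all(fe$parcel_pct == 0))
  expect_length(fe$retained, 0)

  g2 <- tiny_grid(c(5L, 5L, 5L), voxel = c(2, 2, 2))
  expect_error(compute_overlap(lesion_mask(lesB, g2), fx$atlas),
               "grid mismatch")
})

test_that("the 5% exclusion rule is an inclusive OR over the two metrics", {
  f <- structure(list(subject_id = "s",
                      lesion_pct = c("1" = 3, "2" = 3, "3" = 5.0),
                      parcel_pct = c("1" = 2, "2" = 7, "3" = 0),
                      retained = character(0), threshold_pct = 5),
                 class = "overlap_features")
  out <- apply_exclusion(f, 5)
  expect_false("1" %in% out$retained)  # 3/2: both below 5
  expect_true("2" %in% out$retained)   # 3/7: parcel side reaches 5
  expect_true("3" %in% out$retained)   # boundary: exactly 5 is retained
  expect_error(apply_exclusion(f, -1), ">= 0")
})

test_that("overlap features match per-voxel brute-force counting", {
  set.seed(11)
  grid <- tiny_grid(c(8L, 8L, 8L))
  for (rep in 1:10) {
    atlas <- random_atlas(grid, n_parcels = 4L)
    lesion <- random_lesion(grid, n_vox = sample(5:40, 1))
    f <- compute_overlap(lesion, atlas)
    o <- overlap_oracle(lesion$data, atlas$labels)
    expect_identical(f$lesion_pct, o$lesion_pct)
    expect_identical(f$parcel_pct, o$parcel_pct)
  }
})

test_that("design matrices have fixed shape, zeroed exclusions, ordering", {
  fx <- make_two_parcel_fixture()
  lesB <- array(0L, c(5, 5, 5))
  lesB[101:120] <- 1L
  feats <- list(
    apply_exclusion(compute_overlap(
      lesion_mask(lesB, fx$atlas$grid, subject_id = "sub-002"), fx$atlas)),
    apply_exclusion(compute_overlap(
      lesion_mask(fx$lesion$data, fx$atlas$grid, subject_id = "sub-001"),
      fx$atlas)))
  X <- build_design_matrix(feats, fx$atlas)
  expect_equal(dim(X), c(2L, 2L))
  expect_equal(rownames(X), c("sub-001", "sub-002"))  # sorted by id
  expect_equal(unname(X["sub-001", ]), c(60, 40))
  expect_equal(unname(X["sub-002", ]), c(0, 100))

  # empty lesion -> all-zero row; columns never dropped by exclusion
  fe <- compute_overlap(lesion_mask(array(0L, c(5, 5, 5)), fx$atlas$grid,
                                    subject_id = "sub-003",
                                    allow_empty = TRUE), fx$atlas)
  X3 <- build_design_matrix(c(feats, list(fe)), fx$atlas)
  expect_equal(dim(X3), c(3L, 2L))
  expect_true(all(X3["sub-003", ] == 0))

  # parcel_pct variant fills cells with the damage-fraction metric
  Xp <- build_design_matrix(feats, fx$atlas, value = "parcel_pct")
  expect_equal(unname(Xp["sub-001", ]), c(6, 20))

  expect_error(build_design_matrix(list(feats[[1]], feats[[1]]), fx$atlas),
               "duplicated subject ids")
})

test_that("features are translation-equivariant and additive under splits", {
  set.seed(12)
  grid <- tiny_grid(c(10L, 10L, 10L))
  # atlas and lesion confined to an interior block so a joint shift is
  # lossless at the array faces
  labs <- array(0L, c(10, 10, 10))
  labs[2:5, 2:5, 2:5] <- sample.int(3L, 64, replace = TRUE)
  les <- array(0L, c(10, 10, 10))
  les[2:4, 2:4, 2:4] <- 1L

  shift <- function(a, off) {
    out <- array(0L, dim(a))
    out[(1 + off[1]):10, (1 + off[2]):10, (1 + off[3]):10] <-
      a[1:(10 - off[1]), 1:(10 - off[2]), 1:(10 - off[3])]
    out
  }
  off <- c(3L, 2L, 4L)
  f1 <- compute_overlap(lesion_mask(les, grid),
                        parcellation_atlas(labs, grid, kind = "vascular"))
  f2 <- compute_overlap(lesion_mask(shift(les, off), grid),
                        parcellation_atlas(shift(labs, off), grid,
                                           kind = "vascular"))
  expect_equal(f1$lesion_pct, f2$lesion_pct)
  expect_equal(f1$parcel_pct, f2$parcel_pct)
  expect_equal(f1$retained, f2$retained)

  # splitting parcel 1 into two halves: lesion_pct of the halves sums to
  # the original's
  labs_split <- labs
  half <- which(labs == 1L)[seq_len(floor(sum(labs == 1L) / 2))]
  labs_split[half] <- 4L
  fs <- compute_overlap(lesion_mask(les, grid),
                        parcellation_atlas(labs_split, grid,
                                           kind = "vascular"))
  expect_equal(unname(fs$lesion_pct["1"] + fs$lesion_pct["4"]),
               unname(f1$lesion_pct["1"]))
})
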