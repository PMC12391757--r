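# Independent brute-force oracles used to freeze expected values.

# per-voxel counting oracle for lesion/parcel overlap percentages
overlap_oracle <- function(lesion_data, labels) {
  labs <- sort(unique(labels[labels > 0]))
  n_les <- sum(lesion_data == 1)
  lesion_pct <- parcel_pct <- setNames(numeric(length(labs)),
                                       as.character(labs))
  for (l in labs) {
    inter <- 0
    psize <- 0
    for (v in seq_along(labels)) {
      if (labels[v] == l) {
        psize <- psize + 1
        if (lesion_data[v] == 1) inter <- inter + 1
      }
    }
    lesion_pct[as.character(l)] <- if (n_les > 0) 100 * inter / n_les else 0
    parcel_pct[as.character(l)] <- 100 * inter / psize
  }
  list(lesion_pct = lesion_pct, parcel_pct = parcel_pct)
}

# threshold-loop TFCE oracle: components via igraph, one labeling per step
tfce_oracle <- function(t, E = 0.5, H = 2, dh, connectivity = 26) {
  out <- array(0, dim(t))
  mx <- max(t)
  if (mx <= 0) return(out)
  shp <- dim(t)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  if (connectivity == 6) off <- off[rowSums(abs(off)) == 1, , drop = FALSE]
  if (connectivity == 18) off <- off[rowSums(abs(off)) <= 2, , drop = FALSE]
  for (s in seq_len(floor(mx / dh + 1e-6))) {
    h <- s * dh
    sup <- which(t >= h - dh * 1e-6)
    if (!length(sup)) next
    pos <- arrayInd(sup, shp)
    idx <- array(0L, shp)
    idx[sup] <- seq_along(sup)
    el <- list()
    for (o in seq_len(nrow(off))) {
      nb <- sweep(pos, 2, off[o, ], `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 &
        nb[, 2] <= shp[2] & nb[, 3] >= 1 & nb[, 3] <= shp[3]
      lin <- nb[ok, 1] + shp[1] * (nb[ok, 2] - 1 + shp[2] * (nb[ok, 3] - 1))
      j <- idx[lin]
      i <- which(ok)[j > 0]
      el[[o]] <- cbind(i, j[j > 0])
    }
    el <- do.call(rbind, el)
    g <- igraph::make_empty_graph(length(sup), directed = FALSE)
    if (nrow(el)) g <- igraph::add_edges(g, t(el))
    comp <- igraph::components(g)
    out[sup] <- out[sup] + comp$csize[comp$membership]^E * h^H * dh
  }
  out
}

# tiny deterministic fixtures -------------------------------------------

tiny_grid <- function(shape = c(8L, 8L, 8L), voxel = c(1, 1, 1)) {
  volume_grid(shape, voxel_size_mm = voxel)
}

random_lesion <- function(grid, n_vox = 10L, id = "sub-001") {
  d <- array(0L, grid$shape)
  d[sample.int(prod(grid$shape), n_vox)] <- 1L
  lesion_mask(d, grid, subject_id = id)
}

random_atlas <- function(grid, n_parcels = 3L, kind = "vascular") {
  labs <- array(sample.int(n_parcels, prod(grid$shape), replace = TRUE),
                grid$shape)
  parcellation_atlas(labs, grid, kind = kind)
}

small_synth_config <- function(n_subjects = 10L, ...) {
  synthetic_config(grid_shape = c(16L, 18L, 16L), n_networks = 3L,
                   n_vascular_territories = 4L, n_tracts = 4L,
                   n_subjects = n_subjects, n_timepoints = 60L,
                   lesion_volume_range = c(10, 60), ...)
}
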