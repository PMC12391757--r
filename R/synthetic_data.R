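#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic inputs: grid geometry, atlas sizes,
#' connectome signal structure, cohort size and the planted outcome model.
#' Defaults emulate a 70-patient anterior-circulation thrombectomy cohort on
#' a desk-scale grid: unilateral contiguous lesions, seven distributed
#' resting-state networks, interhemispheric tract corridors, and a 3-month
#' mRS driven by weighted parcel damage plus age, sex and admission NIHSS.
#'
#' @param grid_shape integer triple, voxels per axis.
#' @param voxel_size_mm voxel edge lengths in mm.
#' @param n_networks number of resting-state networks (each realised as two
#'   disjoint patches, one per hemisphere).
#' @param n_vascular_territories number of contiguous vascular-like wedges.
#' @param n_tracts number of white-matter tract corridors.
#' @param n_subjects cohort size (>= 3).
#' @param n_timepoints connectome time series length (>= 2 * `n_networks`).
#' @param within_network_corr expected Pearson correlation between two
#'   voxels of the same network, in (0, 1).
#' @param noise_sd SD of the Gaussian noise on the latent outcome.
#' @param outcome_weights named numeric vector: network-atlas label ->
#'   weight on the fraction of that parcel lesioned.
#' @param covariate_effects named numeric triple `(age, sex, nihss)`:
#'   per-unit effects of (age - 73) years, female sex, and NIHSS points on
#'   the latent outcome.
#' @param outcome_intercept baseline of the latent outcome.
#' @param mrs_cutpoints six increasing cut-points discretizing the latent
#'   outcome into mRS 0-6.
#' @param lesion_volume_range voxel-count bounds for lesions; volumes are
#'   drawn log-uniformly within them.
#' @param left_fraction probability a lesion is in the left hemisphere
#'   (40/70 as in anterior-circulation LVO series).
#' @param seed integer seed; all generators are reproducible from it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(24L, 28L, 24L),
                             voxel_size_mm = c(2, 2, 2),
                             n_networks = 7L,
                             n_vascular_territories = 10L,
                             n_tracts = 8L,
                             n_subjects = 70L,
                             n_timepoints = 200L,
                             within_network_corr = 0.6,
                             noise_sd = 1.0,
                             outcome_weights = c("1" = 16, "2" = 12),
                             covariate_effects = c(age = 0.02, sex = 0.3,
                                                   nihss = 0.15),
                             outcome_intercept = 0,
                             mrs_cutpoints = c(0.5, 1.5, 2.5, 3.5, 4.5, 5.5),
                             lesion_volume_range = c(20L, 400L),
                             left_fraction = 40 / 70,
                             seed = 42L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = as.numeric(voxel_size_mm),
              n_networks = as.integer(n_networks),
              n_vascular_territories = as.integer(n_vascular_territories),
              n_tracts = as.integer(n_tracts),
              n_subjects = as.integer(n_subjects),
              n_timepoints = as.integer(n_timepoints),
              within_network_corr = within_network_corr,
              noise_sd = noise_sd,
              outcome_weights = outcome_weights,
              covariate_effects = covariate_effects,
              outcome_intercept = outcome_intercept,
              mrs_cutpoints = mrs_cutpoints,
              lesion_volume_range = as.numeric(lesion_volume_range),
              left_fraction = left_fraction,
              seed = as.integer(seed))
  if (cfg$n_subjects < 3L) stop("n_subjects must be >= 3")
  if (cfg$n_timepoints < 2L * cfg$n_networks)
    stop("n_timepoints must be >= 2 * n_networks")
  if (cfg$within_network_corr <= 0 || cfg$within_network_corr > 1)
    stop("within_network_corr must be in (0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(cfg$mrs_cutpoints) != 6L || is.unsorted(cfg$mrs_cutpoints,
                                                    strictly = TRUE))
    stop("mrs_cutpoints must be six increasing values")
  if (length(cfg$outcome_weights) && is.null(names(cfg$outcome_weights)))
    stop("outcome_weights must be named by network-atlas label")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Synthetic brain mask (ellipsoid)
#'
#' @param config a [synthetic_config()].
#' @return A [brain_mask()] covering an ellipsoid with semi-axes 0.45 times
#'   the grid extent.
#' @export
make_brain_mask <- function(config) {
  shp <- config$grid_shape
  grid <- volume_grid(shp, voxel_size_mm = config$voxel_size_mm)
  cen <- (shp - 1) / 2
  rad <- 0.45 * shp
  ii <- (seq_len(shp[1]) - 1 - cen[1]) / rad[1]
  jj <- (seq_len(shp[2]) - 1 - cen[2]) / rad[2]
  kk <- (seq_len(shp[3]) - 1 - cen[3]) / rad[3]
  d2 <- outer(outer(ii^2, jj^2, `+`), kk^2, `+`)
  brain_mask(array(as.integer(d2 <= 1), dim = shp), grid)
}

## left hemisphere = first-axis index (0-based) strictly below the midline
hemisphere_split <- function(shape) {
  mid <- shape[1] / 2
  i0 <- seq_len(shape[1]) - 1
  list(left = i0 < mid, right = i0 >= mid)
}

## farthest-point sampling of k well-separated seed voxels; coords n x 3
farthest_point_seeds <- function(coords, k) {
  n <- nrow(coords)
  if (n < k) stop("grid too small to host requested parcel counts")
  sel <- integer(k)
  sel[1] <- sample.int(n, 1L)
  mind <- rowSums(sweep(coords, 2, coords[sel[1], ])^2)
  if (k > 1) for (j in 2:k) {
    sel[j] <- which.max(mind)
    mind <- pmin(mind, rowSums(sweep(coords, 2, coords[sel[j], ])^2))
  }
  sel
}

## nearest-seed (Voronoi) labels for coords given seed coords
voronoi_assign <- function(coords, seed_coords) {
  k <- nrow(seed_coords)
  d <- matrix(0, nrow(coords), k)
  for (j in seq_len(k))
    d[, j] <- rowSums(sweep(coords, 2, seed_coords[j, ])^2)
  max.col(-d, ties.method = "first")
}

#' Generate the three synthetic parcellation atlases
#'
#' Builds (i) a vascular-like atlas of contiguous Voronoi wedges over the
#' whole brain mask, (ii) a network-like atlas in which each of
#' `n_networks` labels comprises two disjoint patches, one per hemisphere
#' (mimicking distributed resting-state networks), and (iii) a white-matter
#' tract atlas labelling the corridors that join the two patches of each
#' network. The two cortical atlases cover the identical brain mask with
#' unrelated boundaries, so lesions load differently onto them.
#'
#' @param config a [synthetic_config()].
#' @return List with elements `vascular`, `network`, `wm` (each a
#'   [parcellation_atlas()]), `brainmask` and `tracts` (the [tract_set]
#'   from which the wm atlas is derived).
#' @export
make_atlases <- function(config) {
  set.seed(config$seed + 101L)
  bm <- make_brain_mask(config)
  shp <- config$grid_shape
  mask_lin <- which(bm$data == 1L)
  coords <- arrayInd(mask_lin, shp) - 1L
  hemi <- hemisphere_split(shp)
  left <- hemi$left[coords[, 1] + 1]

  ## vascular: Voronoi wedges over the full mask
  nv <- config$n_vascular_territories
  vsd <- farthest_point_seeds(coords, nv)
  vlab3 <- array(0L, dim = shp)
  vlab3[mask_lin] <- voronoi_assign(coords, coords[vsd, , drop = FALSE])
  vascular <- parcellation_atlas(vlab3, bm$grid,
                                 names = setNames(sprintf("Territory%02d",
                                                          seq_len(nv)),
                                                  seq_len(nv)),
                                 kind = "vascular")

  ## network: distributed systems — two Voronoi patches per network per
  ## hemisphere (4 disjoint patches each), so vascular wedges straddle
  ## several networks and networks straddle several wedges
  nk <- config$n_networks
  nlab3 <- array(0L, dim = shp)
  patch3 <- array(0L, dim = shp)
  for (h in 1:2) {
    inh <- if (h == 1) left else !left
    if (sum(inh) < 2L * nk)
      stop("grid too small to host requested parcel counts")
    ch <- coords[inh, , drop = FALSE]
    sd_h <- farthest_point_seeds(ch, 2L * nk)
    cell <- voronoi_assign(ch, ch[sd_h, , drop = FALSE])
    ## farthest-point order alternates regions, so cells k and k + nk of
    ## the same network land far apart
    lab <- (cell - 1L) %% nk + 1L
    slot <- (cell - 1L) %/% nk + 1L
    nlab3[mask_lin[inh]] <- lab
    patch3[mask_lin[inh]] <- 4L * (lab - 1L) + 2L * (slot - 1L) + h
  }
  network <- parcellation_atlas(nlab3, bm$grid,
                                names = setNames(sprintf("Network%d",
                                                         seq_len(nk)),
                                                 seq_len(nk)),
                                kind = "functional")
  network$patches <- patch3
  network$patch_network <- rep(seq_len(nk), each = 4L)

  ## tracts and the wm atlas derived from them
  tracts <- make_tracts(config, network)
  nt <- length(tracts$tracts)
  vis <- vapply(tracts$tracts, function(tr) as.numeric(tr$visitation),
                numeric(prod(shp)))
  best <- max.col(vis, ties.method = "first")
  wlab <- ifelse(vis[cbind(seq_len(prod(shp)), best)] > 0, best, 0L)
  wlab3 <- array(as.integer(wlab), dim = shp)
  wm <- parcellation_atlas(wlab3, bm$grid,
                           names = setNames(vapply(tracts$tracts,
                                                   `[[`, "", "name"),
                                            seq_len(nt)),
                           kind = "structural-wm")

  list(vascular = vascular, network = network, wm = wm,
       brainmask = bm, tracts = tracts)
}

## distance (voxel units) from points P (n x 3, 0-based) to segment a-b
segment_distance <- function(P, a, b) {
  ab <- b - a
  L2 <- sum(ab^2)
  Pa <- sweep(P, 2, a)
  tt <- if (L2 == 0) rep(0, nrow(P)) else
    pmin(1, pmax(0, as.numeric(Pa %*% ab) / L2))
  D <- Pa - outer(tt, ab)
  sqrt(rowSums(D^2))
}

#' Generate the normative tract set
#'
#' Each tract is a voxel corridor joining the two patches of one network
#' through a (possibly bent) polyline between the patch centroids.
#' Visitation probability is 1 on the core path and decays linearly to 0 at
#' 3 voxels from it; corridors are clipped to the brain mask. When
#' `n_tracts` exceeds `n_networks` the extra tracts revisit networks in
#' order with a laterally displaced midpoint.
#'
#' @param config a [synthetic_config()].
#' @param network_atlas the network atlas from [make_atlases()] (must carry
#'   its `patches` field).
#' @return A [tract_set].
#' @export
make_tracts <- function(config, network_atlas) {
  if (is.null(network_atlas$patches))
    stop("network atlas must carry patch structure")
  shp <- config$grid_shape
  mask_lin <- which(network_atlas$labels > 0L)
  coords <- arrayInd(mask_lin, shp) - 1L
  nk <- config$n_networks
  cent <- matrix(0, 4L * nk, 3L)
  for (p in seq_len(4L * nk)) {
    sel <- network_atlas$patches[mask_lin] == p
    if (!any(sel)) stop("unreachable patch pairs on the grid")
    cent[p, ] <- colMeans(coords[sel, , drop = FALSE])
  }
  mask3 <- array(0L, dim = shp)
  mask3[mask_lin] <- 1L
  grid <- network_atlas$grid
  tracts <- vector("list", config$n_tracts)
  for (j in seq_len(config$n_tracts)) {
    k <- (j - 1L) %% nk + 1L
    dup <- (j - 1L) %/% nk
    slot <- dup %% 2L + 1L                # revisits take the second patch pair
    bend <- dup %/% 2L
    a <- cent[4L * (k - 1L) + 2L * (slot - 1L) + 1L, ]
    b <- cent[4L * (k - 1L) + 2L * (slot - 1L) + 2L, ]
    mid <- (a + b) / 2
    if (bend > 0) {                       # bend re-revisits away from the chord
      perp <- c(0, -(b - a)[3], (b - a)[2])
      if (sqrt(sum(perp^2)) < 1e-8) perp <- c(0, 1, 0)
      mid <- mid + perp / sqrt(sum(perp^2)) * 2.5 * bend
    }
    d <- pmin(segment_distance(coords, a, mid),
              segment_distance(coords, mid, b))
    v <- ifelse(d <= 0.5, 1, pmax(0, 1 - (d - 0.5) / 2.5))
    vis3 <- array(0, dim = shp)
    vis3[mask_lin] <- v
    if (!any(vis3 > 0)) stop("unreachable patch pairs on the grid")
    ends <- lapply(list(a, b), function(ct) {
      inball <- rowSums(sweep(coords, 2, ct)^2) <= 4
      e3 <- array(0L, dim = shp)
      e3[mask_lin[inball]] <- 1L
      brain_mask(e3, grid)
    })
    tracts[[j]] <- list(name = sprintf("Tract%02d", j), visitation = vis3,
                        endpoints = ends, network = k)
  }
  tract_set(tracts, grid)
}

#' Generate the normative connectome
#'
#' Every in-mask voxel's time series is
#' `sqrt(c) * g_net + sqrt(1 - c) * e`, where `g_net` is the latent signal
#' of the voxel's network, `e` is voxel-specific noise, both i.i.d.
#' standard normal over time, and `c = within_network_corr`. Two voxels of
#' the same network therefore correlate at `c` in expectation (including
#' across disjoint patches of a distributed network) and voxels of
#' different networks at 0. Series are standardized to zero mean and unit
#' variance over time.
#'
#' @param config a [synthetic_config()].
#' @param network_atlas network atlas on the same grid.
#' @return An object of class `normative_connectome` with fields `grid`,
#'   `brainmask`, `ts` (voxel x time matrix over in-mask voxels) and
#'   `voxel_index` (linear indices of the rows).
#' @export
make_connectome <- function(config, network_atlas) {
  if (config$n_timepoints < 2L) stop("n_timepoints must be >= 2")
  set.seed(config$seed + 202L)
  shp <- config$grid_shape
  mask_lin <- which(network_atlas$labels > 0L)
  net <- network_atlas$labels[mask_lin]
  K <- config$n_networks
  Tn <- config$n_timepoints
  cc <- config$within_network_corr
  latent <- matrix(rnorm(K * Tn), K, Tn)
  ts <- sqrt(cc) * latent[net, , drop = FALSE]
  if (cc < 1)
    ts <- ts + sqrt(1 - cc) * matrix(rnorm(length(mask_lin) * Tn),
                                     length(mask_lin), Tn)
  ts <- ts - rowMeans(ts)
  ts <- ts / sqrt(rowSums(ts^2) / (Tn - 1))
  bm3 <- array(0L, dim = shp)
  bm3[mask_lin] <- 1L
  structure(list(grid = network_atlas$grid,
                 brainmask = brain_mask(bm3, network_atlas$grid),
                 ts = ts, voxel_index = mask_lin),
            class = "normative_connectome")
}

## grow a 6-connected blob of `target` voxels inside `allowed` (logical 3D)
grow_blob <- function(allowed, target, max_retries = 25L) {
  shp <- dim(allowed)
  nbr_off <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                   c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  allowed_lin <- which(allowed)
  for (try in seq_len(max_retries)) {
    inblob <- array(FALSE, dim = shp)
    seen <- array(FALSE, dim = shp)
    start <- allowed_lin[sample.int(length(allowed_lin), 1L)]
    inblob[start] <- TRUE
    seen[start] <- TRUE
    frontier <- integer(0)
    add_neighbours <- function(lin) {
      ijk <- arrayInd(lin, shp)
      nb <- sweep(nbr_off, 2, as.integer(ijk), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= shp[1] & nb[, 2] >= 1 &
            nb[, 2] <= shp[2] & nb[, 3] >= 1 & nb[, 3] <= shp[3]
      nb <- nb[ok, , drop = FALSE]
      lin_nb <- nb[, 1] + shp[1] * (nb[, 2] - 1L + shp[2] * (nb[, 3] - 1L))
      lin_nb[allowed[lin_nb] & !seen[lin_nb]]
    }
    new <- add_neighbours(start)
    seen[new] <- TRUE
    frontier <- new
    size <- 1L
    while (size < target && length(frontier) > 0L) {
      pick <- sample.int(length(frontier), 1L)
      v <- frontier[pick]
      frontier <- frontier[-pick]
      inblob[v] <- TRUE
      size <- size + 1L
      new <- add_neighbours(v)
      seen[new] <- TRUE
      frontier <- c(frontier, new)
    }
    if (size == target) return(inblob)
  }
  stop("blob growth failure after bounded retries")
}

#' Generate the synthetic cohort: lesions, covariates and outcomes
#'
#' Lesions are connected blobs grown by random 6-connected accretion from a
#' seed voxel, confined to one hemisphere of the brain mask, with voxel
#' volume drawn log-uniformly within the configured bounds. The latent
#' outcome is `intercept + sum_p w_p * frac_p + b_age (age - 73) +
#' b_sex sex + b_nihss nihss + N(0, noise_sd)`, where `frac_p` is the
#' fraction of network parcel `p` lesioned; mRS is the latent outcome
#' discretized by the configured cut-points and clipped to 0-6. NIHSS
#' itself increases with lesion volume, as admission severity does.
#'
#' @param config a [synthetic_config()].
#' @param atlases result of [make_atlases()] (the network atlas and brain
#'   mask are used).
#' @param tracts optional [tract_set] recorded in the ground truth.
#' @return An object of class `synthetic_cohort`: `lesions` (list of
#'   [lesion_mask()]), `outcomes` (data.frame `subject_id`, `mrs`, `age`,
#'   `sex`, `nihss`) and `truth` (generating weights, latent outcomes,
#'   per-subject parcel damage fractions, network label volume).
#' @export
make_cohort <- function(config, atlases, tracts = NULL) {
  set.seed(config$seed + 303L)
  net <- atlases$network
  bm <- atlases$brainmask
  shp <- config$grid_shape
  w <- config$outcome_weights
  if (length(w)) {
    wl <- as.integer(names(w))
    if (any(is.na(wl)) || !all(wl %in% as.integer(names(net$names))))
      stop("outcome_weights keys must refer to existing network parcels")
  }
  hemi <- hemisphere_split(shp)
  i0 <- slice.index(array(0L, dim = shp), 1) - 1L
  left3 <- array(hemi$left[i0 + 1L], dim = shp)
  mask_l <- bm$data == 1L & left3
  mask_r <- bm$data == 1L & !left3
  parcel_sizes <- tabulate(net$labels[net$labels > 0L], nbins = config$n_networks)
  n_mask <- sum(bm$data)
  vr <- config$lesion_volume_range
  ce <- config$covariate_effects

  n <- config$n_subjects
  lesions <- vector("list", n)
  frac <- matrix(0, n, config$n_networks,
                 dimnames = list(NULL, names(net$names)))
  age <- sex <- nihss <- latent <- mrs <- numeric(n)
  hemis <- character(n)
  ids <- sprintf("sub-%03d", seq_len(n))
  for (i in seq_len(n)) {
    lh <- rbinom(1L, 1L, config$left_fraction) == 1L
    hemis[i] <- if (lh) "left" else "right"
    target <- round(exp(runif(1, log(vr[1]), log(vr[2]))))
    blob <- grow_blob(if (lh) mask_l else mask_r, target)
    lesions[[i]] <- lesion_mask(array(as.integer(blob), dim = shp), bm$grid,
                                subject_id = ids[i])
    cnt <- tabulate(net$labels[blob], nbins = config$n_networks)
    frac[i, ] <- cnt / parcel_sizes
    age[i] <- min(95, max(40, round(rnorm(1, 73, 12))))
    sex[i] <- rbinom(1L, 1L, 0.53)
    volfrac <- target / n_mask
    nihss[i] <- min(42, max(0, round(8 + 180 * volfrac + rnorm(1, 0, 5))))
    lesion_term <- if (length(w)) sum(w * frac[i, names(w)]) else 0
    latent[i] <- config$outcome_intercept + lesion_term +
      ce[[1]] * (age[i] - 73) + ce[[2]] * sex[i] + ce[[3]] * nihss[i] +
      rnorm(1, 0, config$noise_sd)
    mrs[i] <- min(6L, max(0L, findInterval(latent[i], config$mrs_cutpoints)))
  }
  outcomes <- data.frame(subject_id = ids, mrs = as.integer(mrs),
                         age = as.integer(age), sex = as.integer(sex),
                         nihss = as.integer(nihss),
                         stringsAsFactors = FALSE)
  truth <- list(outcome_weights = w, covariate_effects = ce,
                outcome_intercept = config$outcome_intercept,
                mrs_cutpoints = config$mrs_cutpoints,
                latent = setNames(latent, ids),
                parcel_fractions = frac, hemisphere = setNames(hemis, ids),
                network_labels = net$labels,
                tract_names = if (!is.null(tracts))
                  vapply(tracts$tracts, `[[`, "", "name") else NULL)
  structure(list(lesions = lesions, outcomes = outcomes, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a complete synthetic study to a cohort directory
#'
#' Layout: `lesions/sub-XXX.nii.gz`, `atlas_{vascular,network,wm}.nii.gz`
#' with sidecar label tables (`*_labels.tsv`: label, name),
#' `connectome.nii.gz` (4D) + `brainmask.nii.gz`, `tracts/tract-XX.nii.gz`,
#' `participants.tsv` and `truth.json`.
#'
#' @param cohort a [make_cohort()] result.
#' @param atlases a [make_atlases()] result.
#' @param connectome a [make_connectome()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, atlases, connectome, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "tracts"), showWarnings = FALSE)
  grid <- atlases$brainmask$grid
  for (les in cohort$lesions)
    write_mask(les, file.path(dir, "lesions",
                              paste0(les$subject_id, ".nii.gz")))
  for (nm in c("vascular", "network", "wm")) {
    atl <- atlases[[nm]]
    write_volume(atl$labels, grid,
                 file.path(dir, sprintf("atlas_%s.nii.gz", nm)),
                 datatype = "int16")
    write.table(data.frame(label = as.integer(names(atl$names)),
                           name = unname(atl$names)),
                file.path(dir, sprintf("atlas_%s_labels.tsv", nm)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write_mask(atlases$brainmask, file.path(dir, "brainmask.nii.gz"))
  ts4 <- array(0, dim = c(grid$shape, ncol(connectome$ts)))
  step <- prod(grid$shape)
  for (t in seq_len(ncol(connectome$ts)))
    ts4[(t - 1L) * step + connectome$voxel_index] <- connectome$ts[, t]
  write_volume(ts4, grid, file.path(dir, "connectome.nii.gz"))
  for (j in seq_along(atlases$tracts$tracts)) {
    tr <- atlases$tracts$tracts[[j]]
    write_volume(tr$visitation, grid,
                 file.path(dir, "tracts", sprintf("tract-%02d.nii.gz", j)))
  }
  write.table(cohort$outcomes, file.path(dir, "participants.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  tr <- cohort$truth
  jsonlite::write_json(list(outcome_weights = as.list(tr$outcome_weights),
                            covariate_effects = as.list(tr$covariate_effects),
                            outcome_intercept = tr$outcome_intercept,
                            mrs_cutpoints = tr$mrs_cutpoints,
                            latent = as.list(tr$latent),
                            hemisphere = as.list(tr$hemisphere),
                            seed = cohort$config$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return List with `lesions`, `outcomes`, `atlases` (vascular, network,
#'   wm), `brainmask`, `connectome` and `tracts`.
#' @export
load_cohort <- function(dir) {
  need <- c("participants.tsv", "brainmask.nii.gz", "atlas_vascular.nii.gz",
            "atlas_network.nii.gz", "atlas_wm.nii.gz", "connectome.nii.gz")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("cohort directory is missing ", f)
  outcomes <- read.delim(file.path(dir, "participants.tsv"),
                         stringsAsFactors = FALSE)
  bm_img <- load_volume(file.path(dir, "brainmask.nii.gz"))
  bm <- brain_mask(bm_img$data, bm_img$grid)
  atlases <- list()
  for (nm in c("vascular", "network", "wm")) {
    vol <- load_volume(file.path(dir, sprintf("atlas_%s.nii.gz", nm)))
    labs <- read.delim(file.path(dir, sprintf("atlas_%s_labels.tsv", nm)),
                       stringsAsFactors = FALSE)
    atlases[[nm]] <- parcellation_atlas(
      array(as.integer(round(vol$data)), dim = dim(vol$data)), vol$grid,
      names = setNames(labs$name, labs$label),
      kind = switch(nm, vascular = "vascular", network = "functional",
                    wm = "structural-wm"))
  }
  lesions <- lapply(outcomes$subject_id, function(id)
    load_mask(file.path(dir, "lesions", paste0(id, ".nii.gz")),
              expected_grid = bm$grid, subject_id = id, allow_empty = TRUE))
  img <- RNifti::readNifti(file.path(dir, "connectome.nii.gz"))
  if (length(dim(img)) != 4L) stop("connectome.nii.gz must be 4D")
  mask_lin <- which(bm$data == 1L)
  ts4 <- array(as.numeric(img), dim = dim(img))
  step <- prod(bm$grid$shape)
  ts <- vapply(seq_len(dim(ts4)[4]),
               function(t) ts4[(t - 1L) * step + mask_lin],
               numeric(length(mask_lin)))
  connectome <- structure(list(grid = bm$grid, brainmask = bm, ts = ts,
                               voxel_index = mask_lin),
                          class = "normative_connectome")
  tract_files <- sort(list.files(file.path(dir, "tracts"),
                                 pattern = "^tract-.*\\.nii(\\.gz)?$",
                                 full.names = TRUE))
  tracts <- NULL
  if (length(tract_files)) {
    trl <- lapply(seq_along(tract_files), function(j) {
      v <- load_volume(tract_files[j])
      list(name = sprintf("Tract%02d", j), visitation = v$data,
           endpoints = NULL)
    })
    tracts <- tract_set(trl, bm$grid)
  }
  list(lesions = lesions, outcomes = outcomes, atlases = atlases,
       brainmask = bm, connectome = connectome, tracts = tracts)
}
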