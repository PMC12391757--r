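#' TFCE parameters
#'
#' Field-standard threshold-free cluster enhancement parameterization:
#' extent exponent `E = 0.5`, height exponent `H = 2`, 26-voxel
#' neighbourhood, and an integration step of 1/100 of the map maximum
#' unless a fixed `dh` is given.
#'
#' @param E extent exponent (>= 0).
#' @param H height exponent (>= 0).
#' @param dh integration step; `NULL` means `max(stat) / 100`, recomputed
#'   per map.
#' @param connectivity 6, 18 or 26 voxel neighbourhood.
#' @return A list of class `tfce_params`.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = NULL, connectivity = 26L) {
  if (E < 0 || H < 0) stop("E and H must be >= 0")
  if (!is.null(dh) && dh <= 0) stop("dh must be > 0")
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  structure(list(E = E, H = H, dh = dh,
                 connectivity = as.integer(connectivity)),
            class = "tfce_params")
}

## extract a 3D numeric array from the accepted per-subject map types
map_values <- function(m) {
  if (inherits(m, "disconnection_map")) return(m$values)
  if (inherits(m, "lesion_mask")) return(m$data + 0)
  if (is.array(m) && length(dim(m)) == 3L) return(m)
  stop("maps must be 3D arrays, disconnection_maps or lesion_masks")
}

## subjects x voxels matrix over the brain mask, plus the analysis mask
## (voxels with >= min_coverage nonzero subjects and nonzero variance)
voxel_matrix <- function(maps, mask, min_coverage = 5L) {
  vox <- which(mask$data == 1L)
  M <- t(vapply(maps, function(m) map_values(m)[vox],
                numeric(length(vox))))
  n <- nrow(M)
  coverage <- colSums(M != 0)
  cm <- colMeans(M)
  v <- colSums(M^2) / n - cm^2
  keep <- coverage >= min_coverage & v > 1e-18
  list(M = M, vox = vox, keep = keep, n = n)
}

## Pearson r of standardized columns Z (n x K) with standardized y
cor_t_from_z <- function(Z, zy, n, t_cap = 1e6) {
  r <- as.numeric(crossprod(Z, zy)) / (n - 1)
  r <- pmin(1, pmax(-1, r))
  t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  pmin(t_cap, pmax(-t_cap, t))
}

#' Voxel-wise correlation statistic map
#'
#' Per in-mask voxel, the Pearson correlation between subjects' map values
#' and the outcome, converted to a t statistic
#' `t = r sqrt((n - 2) / (1 - r^2))` (capped at 1e6 for |r| = 1, which
#' preserves ordering). Voxels with fewer than `min_coverage` subjects
#' having nonzero values, or with zero variance, are excluded from the
#' analysis mask, not errored: correlations over near-constant columns are
#' noise.
#'
#' @param maps per-subject 3D arrays, `disconnection_map`s or
#'   `lesion_mask`s (one per subject).
#' @param y numeric outcome, one value per subject.
#' @param mask a [brain_mask()].
#' @param min_coverage minimal number of subjects with nonzero values.
#' @return Object of class `stat_map`: `grid`, `t_values` and `r_values`
#'   (3D, 0 outside the analysis mask), `analysis_mask` (3D 0/1) and `n`.
#' @export
voxelwise_statistic <- function(maps, y, mask, min_coverage = 5L) {
  vm <- voxel_matrix(maps, mask, min_coverage)
  if (vm$n < 3L) stop("at least 3 subjects required")
  if (length(y) != vm$n) stop("y must have one value per subject")
  shp <- mask$grid$shape
  tv <- array(0, dim = shp)
  rv <- array(0, dim = shp)
  am <- array(0L, dim = shp)
  am[vm$vox[vm$keep]] <- 1L
  if (any(vm$keep) && sd(y) > 0) {
    Z <- scale(vm$M[, vm$keep, drop = FALSE])
    zy <- as.numeric(scale(y))
    t <- cor_t_from_z(Z, zy, vm$n)
    tv[vm$vox[vm$keep]] <- t
    rv[vm$vox[vm$keep]] <- pmin(1, pmax(-1, as.numeric(crossprod(Z, zy)) /
                                          (vm$n - 1)))
  }
  structure(list(grid = mask$grid, t_values = tv, r_values = rv,
                 analysis_mask = am, n = vm$n),
            class = "stat_map")
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(v) = sum over h = dh, 2dh, ..., <= max(t) of e_h(v)^E h^H dh`,
#' where `e_h(v)` is the voxel count of the connected component containing
#' `v` in the supra-threshold set `{t >= h}`. Zero wherever `t <= 0`;
#' negative contrasts are handled by sign-flipping the statistic before
#' the call. The discrete integral is computed exactly (incremental
#' union-find over descending thresholds in compiled code).
#'
#' @param stat a `stat_map` or 3D numeric array of statistics.
#' @param params a [tfce_params()].
#' @return 3D numeric array of enhanced values.
#' @export
tfce <- function(stat, params = tfce_params()) {
  t <- if (inherits(stat, "stat_map")) stat$t_values else stat
  if (!is.array(t) || length(dim(t)) != 3L) stop("stat must be 3D")
  mx <- max(t)
  if (mx <= 0) return(array(0, dim = dim(t)))
  dh <- params$dh %||% (mx / 100)
  out <- tfce_cpp(as.numeric(t), dim(t), params$E, params$H, dh,
                  params$connectivity)
  array(out, dim = dim(t))
}

#' Max-statistic permutation inference with TFCE and FWE correction
#'
#' The observed statistic map is TFCE-enhanced; under each of `n_perm`
#' random permutations of the outcome across subjects (exchangeability
#' under the null of no map-outcome association) the statistic and TFCE
#' are recomputed and the maximum TFCE over the analysis mask recorded.
#' The family-wise-error-corrected p-value at voxel `v` is
#' `(1 + #{permutations with max >= TFCE_obs(v)}) / (n_perm + 1)` (add-one
#' estimator, so p-values are floored at `1/(n_perm + 1)`). Positive and
#' negative contrasts are separate runs on sign-flipped statistics.
#'
#' @param maps per-subject maps as in [voxelwise_statistic()].
#' @param y numeric outcome.
#' @param mask a [brain_mask()].
#' @param params a [tfce_params()]; when `dh` is `NULL` each map
#'   (observed and permuted) uses its own `max/100` step.
#' @param n_perm number of permutations (>= 1).
#' @param alpha FWE significance level.
#' @param direction `"positive"` tests r > 0, `"negative"` r < 0.
#' @param min_coverage analysis-mask coverage threshold.
#' @param seed optional RNG seed for the permutation sequence.
#' @return Object of class `inference_result`: `tfce_observed`, `fwe_p`,
#'   `significant` (3D), `t_values` (contrast-signed), `analysis_mask`,
#'   `null_max` (permutation maxima), `n_permutations`, `alpha`,
#'   `direction`.
#' @export
permutation_fwe <- function(maps, y, mask, params = tfce_params(),
                            n_perm = 1000L, alpha = 0.01,
                            direction = c("positive", "negative"),
                            min_coverage = 5L, seed = NULL) {
  direction <- match.arg(direction)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  vm <- voxel_matrix(maps, mask, min_coverage)
  n <- vm$n
  if (n < 3L) stop("at least 3 subjects required")
  if (length(y) != n) stop("y must have one value per subject")
  shp <- mask$grid$shape
  sgn <- if (direction == "positive") 1 else -1
  keep_vox <- vm$vox[vm$keep]
  am <- array(0L, dim = shp)
  am[keep_vox] <- 1L

  tfce_of <- function(tvec) {
    arr <- array(0, dim = shp)
    arr[keep_vox] <- tvec
    tfce(arr, params)
  }
  empty <- !any(vm$keep) || sd(y) == 0
  if (empty) {
    obs_tfce <- array(0, dim = shp)
    null_max <- rep(0, n_perm)
  } else {
    Z <- scale(vm$M[, vm$keep, drop = FALSE])
    zy <- as.numeric(scale(y))
    obs_t <- sgn * cor_t_from_z(Z, zy, n)
    obs_tfce <- tfce_of(obs_t)
    null_max <- vapply(seq_len(n_perm), function(p) {
      tp <- sgn * cor_t_from_z(Z, zy[sample.int(n)], n)
      max(tfce_of(tp))
    }, numeric(1))
  }
  fwe_p <- array(1, dim = shp)
  if (length(keep_vox)) {
    obs_v <- obs_tfce[keep_vox]
    smx <- sort(null_max)
    n_lt <- findInterval(obs_v, smx, left.open = TRUE)  # #{max < obs}
    fwe_p[keep_vox] <- (1 + n_perm - n_lt) / (n_perm + 1)
  }
  sig <- array(0L, dim = shp)
  sig[fwe_p < alpha & am == 1L] <- 1L
  tv <- array(0, dim = shp)
  if (!empty) tv[keep_vox] <- obs_t
  structure(list(tfce_observed = obs_tfce, fwe_p = fwe_p,
                 significant = sig, t_values = tv, analysis_mask = am,
                 null_max = null_max, n_permutations = as.integer(n_perm),
                 alpha = alpha, direction = direction),
            class = "inference_result")
}

#' Per-network disconnection-outcome correlation
#'
#' Each subject's per-network score is the mean disconnection-map value
#' over the network's voxels (maps are expected already thresholded per
#' their kind's convention); the table reports the Pearson correlation of
#' the scores with the outcome, its square, and the two-sided p-value
#' from the t distribution with n - 2 degrees of freedom. Constant scores
#' make r undefined; it is reported as 0 with the `degenerate` flag.
#'
#' @param disc_maps list of `disconnection_map`s (one per subject).
#' @param atlas a network-kind [parcellation_atlas()].
#' @param y numeric outcome.
#' @return `data.frame` with columns `label`, `network`, `r`, `r2`, `p`,
#'   `n_voxels`, `degenerate`.
#' @export
network_outcome_correlation <- function(disc_maps, atlas, y) {
  n <- length(disc_maps)
  if (n != length(y)) stop("one outcome per map required")
  labs <- as.integer(names(atlas$names))
  rows <- lapply(labs, function(l) {
    vox <- which(atlas$labels == l)
    if (length(vox) == 0L) stop("empty network ", l)
    score <- vapply(disc_maps, function(m) mean(map_values(m)[vox]),
                    numeric(1))
    degenerate <- sd(score) < 1e-12 || sd(y) < 1e-12
    if (degenerate) {
      r <- 0; p <- 1
    } else {
      r <- cor(score, y)
      if (abs(r) >= 1) {
        p <- 0
      } else {
        tt <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * pt(-abs(tt), df = n - 2)
      }
    }
    data.frame(label = l, network = unname(atlas$names[as.character(l)]),
               r = r, r2 = r^2, p = p, n_voxels = length(vox),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
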