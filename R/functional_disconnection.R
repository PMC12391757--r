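## rows of the connectome time-series matrix covered by a lesion,
## in ascending voxel order (deterministic under voxel permutation)
lesion_connectome_rows <- function(lesion, connectome) {
  stop_if_grid_mismatch(lesion$grid, connectome$grid,
                        "lesion and connectome")
  les_lin <- which(lesion$data == 1L)
  rows <- match(les_lin, connectome$voxel_index)
  keep <- !is.na(rows)
  if (!any(keep)) stop("no lesion voxels inside brain mask")
  list(rows = rows[keep], voxel_index = les_lin[keep])
}

#' Within-lesion functional connectivity matrix
#'
#' Pairwise Pearson correlations between the normative time series of all
#' lesion voxels that fall inside the connectome's brain mask. This matrix
#' is the input to the PCA-based lesion reshaping of [reshape_lesion()].
#'
#' @param lesion a [lesion_mask()] on the connectome grid (resampled and
#'   binarized beforehand if needed).
#' @param connectome a `normative_connectome`.
#' @return Square correlation matrix (diagonal 1) over in-mask lesion
#'   voxels in ascending voxel order; the voxel linear indices are in
#'   attribute `voxel_index`.
#' @export
within_lesion_connectivity <- function(lesion, connectome) {
  sel <- lesion_connectome_rows(lesion, connectome)
  ts <- connectome$ts[sel$rows, , drop = FALSE]
  C <- if (nrow(ts) == 1L) matrix(1, 1, 1) else cor(t(ts))
  diag(C) <- 1
  attr(C, "voxel_index") <- sel$voxel_index
  C
}

#' Reshape a lesion into a weighted seed by its principal connectivity axis
#'
#' The first principal component of the within-lesion connectivity matrix
#' identifies the dominant coherent sub-population of lesion voxels. Its
#' loading vector is oriented so the loadings sum to a nonnegative value
#' (resolving eigenvector sign ambiguity deterministically), negative
#' loadings are rectified to zero, and the result is normalized to sum 1.
#' Degenerate cases (two or fewer voxels, or a rank-deficient matrix) fall
#' back to uniform weights, so reshaping never extends support beyond the
#' original lesion.
#'
#' @param lesion a [lesion_mask()].
#' @param conn_matrix matrix from [within_lesion_connectivity()]; computed
#'   if `NULL`.
#' @param connectome the `normative_connectome`.
#' @return Object of class `lesion_seed`: `weights` (sum 1), `voxel_index`
#'   (linear indices into the grid) and `subject_id`.
#' @export
reshape_lesion <- function(lesion, conn_matrix = NULL, connectome) {
  if (is.null(conn_matrix))
    conn_matrix <- within_lesion_connectivity(lesion, connectome)
  vox <- attr(conn_matrix, "voxel_index")
  n <- nrow(conn_matrix)
  w <- rep(1 / n, n)
  if (n > 2L) {
    eig <- eigen(conn_matrix, symmetric = TRUE)
    if (eig$values[1] > 1e-8 &&
        eig$values[1] - eig$values[2] > 1e-10) {
      v <- eig$vectors[, 1]
      if (sum(v) < 0) v <- -v
      v <- pmax(v, 0)
      if (sum(v) > 1e-12) w <- v / sum(v)
    }
  }
  structure(list(weights = w, voxel_index = vox,
                 subject_id = lesion$subject_id),
            class = "lesion_seed")
}

#' Seed the reshaped lesion into the connectome
#'
#' The seed time series is the weighted mean of the lesion voxels' series;
#' the map value at every brain voxel is the Pearson correlation between
#' the seed series and that voxel's series, giving a whole-brain indirect
#' functional disconnection map. Values are stored unthresholded;
#' [threshold_map()] applies the analysis threshold.
#'
#' @param seed a [reshape_lesion()] result (weights sum to 1).
#' @param connectome the `normative_connectome`.
#' @return A `disconnection_map` of kind `"functional"` with values in
#'   `[-1, 1]`, zero outside the brain mask.
#' @export
seed_disconnectivity_map <- function(seed, connectome) {
  if (abs(sum(seed$weights) - 1) > 1e-8)
    stop("seed weights must sum to 1")
  rows <- match(seed$voxel_index, connectome$voxel_index)
  if (anyNA(rows)) stop("seed voxels outside the connectome mask")
  s <- as.numeric(seed$weights %*% connectome$ts[rows, , drop = FALSE])
  if (sd(s) < 1e-12) stop("constant seed series")
  Tn <- length(s)
  zs <- (s - mean(s)) / sd(s)
  ## connectome rows are standardized over time, so this is Pearson r
  r <- as.numeric(connectome$ts %*% zs) / (Tn - 1)
  r <- pmin(1, pmax(-1, r))
  vals <- array(0, dim = connectome$grid$shape)
  vals[connectome$voxel_index] <- r
  disconnection_map(seed$subject_id, connectome$grid, vals, "functional")
}

#' Construct a disconnection map object
#'
#' @param subject_id subject identifier.
#' @param grid `volume_grid`.
#' @param values 3D numeric array; functional maps must lie in `[-1, 1]`,
#'   structural maps in `[0, 1]`.
#' @param kind `"functional"` or `"structural"`.
#' @param threshold_applied threshold recorded on the map (`NA` until one
#'   is applied).
#' @return Object of class `disconnection_map`.
#' @export
disconnection_map <- function(subject_id, grid, values,
                              kind = c("functional", "structural"),
                              threshold_applied = NA_real_) {
  kind <- match.arg(kind)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("value dimensions do not match grid shape")
  rng <- range(values)
  if (kind == "functional" && (rng[1] < -1 - 1e-9 || rng[2] > 1 + 1e-9))
    stop("functional map values must lie in [-1, 1]")
  if (kind == "structural" && (rng[1] < 0 || rng[2] > 1 + 1e-9))
    stop("structural map values must lie in [0, 1]")
  structure(list(subject_id = subject_id, grid = grid, values = values,
                 kind = kind, threshold_applied = threshold_applied),
            class = "disconnection_map")
}

#' Threshold a functional disconnection map
#'
#' Correlations below `r_min` (default 0.2) are set to zero; the applied
#' threshold is recorded on the map. Negative correlations are retained up
#' to this point and removed here for any `r_min > 0`.
#'
#' @param map a `disconnection_map`.
#' @param r_min threshold in `[-1, 1]`.
#' @return The thresholded map.
#' @export
threshold_map <- function(map, r_min = 0.2) {
  if (r_min < -1 || r_min > 1) stop("r_min must lie in [-1, 1]")
  map$values[map$values < r_min] <- 0
  map$threshold_applied <- r_min
  map
}

#' Compute functional disconnection maps for a whole cohort
#'
#' Convenience wrapper chaining [within_lesion_connectivity()],
#' [reshape_lesion()] and [seed_disconnectivity_map()] per subject.
#'
#' @param lesions list of [lesion_mask()].
#' @param connectome the `normative_connectome`.
#' @return List of unthresholded functional `disconnection_map`s.
#' @export
functional_disconnection_maps <- function(lesions, connectome) {
  lapply(lesions, function(les) {
    seed <- reshape_lesion(les, connectome = connectome)
    seed_disconnectivity_map(seed, connectome)
  })
}
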