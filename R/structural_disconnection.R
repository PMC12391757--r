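#' Construct a normative tract set
#'
#' @param tracts list; each element has `name` (string), `visitation` (3D
#'   array of per-voxel visitation probabilities in `[0, 1]`, >= 1 positive
#'   voxel) and optionally `endpoints` (pair of [brain_mask()]).
#' @param grid the shared `volume_grid`.
#' @return Object of class `tract_set`.
#' @export
tract_set <- function(tracts, grid) {
  for (tr in tracts) {
    if (!identical(dim(tr$visitation), as.integer(grid$shape)))
      stop("tract '", tr$name, "' is not on the shared grid")
    rng <- range(tr$visitation)
    if (rng[1] < 0 || rng[2] > 1 + 1e-9)
      stop("tract '", tr$name, "' visitation must lie in [0, 1]")
    if (rng[2] <= 0)
      stop("tract '", tr$name, "' has no visited voxels")
  }
  nm <- vapply(tracts, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated tract names")
  structure(list(tracts = tracts, grid = grid), class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts on %s voxels\n", length(x$tracts),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Which tracts pass through a lesion
#'
#' A tract is hit when the maximum of its visitation probability over the
#' lesion voxels reaches `hit_min`: the lesion then plausibly interrupts
#' the bundle's core rather than grazing its fringe.
#'
#' @param lesion a [lesion_mask()] on the tract grid.
#' @param tracts a [tract_set()].
#' @param hit_min minimal within-lesion visitation for a hit (default 0.5,
#'   the same probability level used to threshold the maps).
#' @return Character vector of hit tract names (possibly empty).
#' @export
lesion_tract_hits <- function(lesion, tracts, hit_min = 0.5) {
  stop_if_grid_mismatch(lesion$grid, tracts$grid, "lesion and tracts")
  les_idx <- which(lesion$data == 1L)
  hit <- vapply(tracts$tracts, function(tr) {
    length(les_idx) > 0L && max(tr$visitation[les_idx]) >= hit_min
  }, logical(1))
  vapply(tracts$tracts[hit], `[[`, "", "name")
}

#' Indirect structural disconnection map
#'
#' For each voxel, the probability that a white-matter bundle directly
#' connected with the lesion passes through it: the voxel-wise maximum of
#' the visitation maps of all hit tracts (max keeps the `[0, 1]`
#' probability scale that the downstream 50% threshold assumes). Voxels on
#' no hit tract are 0; an empty hit set yields an all-zero map.
#'
#' @param lesion a [lesion_mask()].
#' @param tracts a [tract_set()].
#' @param hit_min hit criterion passed to [lesion_tract_hits()].
#' @return A `disconnection_map` of kind `"structural"`.
#' @export
structural_disconnectivity_map <- function(lesion, tracts, hit_min = 0.5) {
  hits <- lesion_tract_hits(lesion, tracts, hit_min)
  vals <- array(0, dim = lesion$grid$shape)
  for (tr in tracts$tracts)
    if (tr$name %in% hits) vals <- pmax(vals, tr$visitation)
  disconnection_map(lesion$subject_id, lesion$grid, vals, "structural")
}

#' Threshold a structural disconnection map
#'
#' Values are kept only when strictly above `p_min` (default 0.5: a
#' disconnection probability higher than 50%); everything else is zeroed
#' and the threshold recorded.
#'
#' @param map a structural `disconnection_map`.
#' @param p_min threshold in `[0, 1]`, exclusive bound.
#' @return The thresholded map.
#' @export
threshold_structural <- function(map, p_min = 0.5) {
  if (p_min < 0 || p_min > 1) stop("p_min must lie in [0, 1]")
  map$values[map$values <= p_min] <- 0
  map$threshold_applied <- p_min
  map
}

#' Overlap of a significant-voxel mask with the normative tracts
#'
#' Binarizes every tract's visitation map at `bin_threshold` and reports,
#' per tract, the voxel count of its intersection with the mask and that
#' count as a fraction of the binarized tract.
#'
#' @param significant_mask 3D binary array (or a [brain_mask()]) on the
#'   tract grid.
#' @param tracts a [tract_set()].
#' @param bin_threshold visitation binarization level (default 0.5).
#' @return `data.frame` with columns `tract`, `voxels`, `fraction`, sorted
#'   by descending overlap.
#' @export
tract_overlap_report <- function(significant_mask, tracts,
                                 bin_threshold = 0.5) {
  if (inherits(significant_mask, "brain_mask")) {
    stop_if_grid_mismatch(significant_mask$grid, tracts$grid,
                          "mask and tracts")
    significant_mask <- significant_mask$data
  }
  if (!identical(dim(significant_mask), as.integer(tracts$grid$shape)))
    stop("grid mismatch: mask and tracts are not on the same grid")
  sig <- significant_mask > 0.5
  rows <- lapply(tracts$tracts, function(tr) {
    bin <- tr$visitation >= bin_threshold
    nb <- sum(bin)
    cnt <- sum(bin & sig)
    data.frame(tract = tr$name, voxels = cnt,
               fraction = if (nb > 0) cnt / nb else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$voxels, out$tract), , drop = FALSE]
}

#' Compute structural disconnection maps for a whole cohort
#'
#' @param lesions list of [lesion_mask()].
#' @param tracts a [tract_set()].
#' @param hit_min hit criterion.
#' @return List of unthresholded structural `disconnection_map`s.
#' @export
structural_disconnection_maps <- function(lesions, tracts, hit_min = 0.5) {
  lapply(lesions, structural_disconnectivity_map, tracts = tracts,
         hit_min = hit_min)
}
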