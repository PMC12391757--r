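#' Define a volumetric sampling grid
#'
#' A grid is the geometry every volume in an analysis shares: the voxel
#' dimensions of the array and a 4x4 affine mapping 0-based voxel indices to
#' world coordinates (RAS, millimetres). All cross-volume operations in the
#' package require their inputs to live on the same grid and error otherwise;
#' [resample_mask()] is the only sanctioned way to move between grids.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size_mm positive numeric vector of length 3. Ignored when
#'   `affine` is supplied (it is then re-derived from the affine columns).
#' @param affine optional 4x4 numeric matrix, voxel (0-based) to world mm.
#'   Defaults to a diagonal affine with the given voxel size and origin 0.
#' @return An object of class `volume_grid` with fields `shape`,
#'   `voxel_size_mm` and `affine`.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (is.null(affine)) {
    voxel_size_mm <- as.numeric(voxel_size_mm)
    if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
      stop("'voxel_size_mm' must be three positive reals")
    affine <- diag(c(voxel_size_mm, 1))
  } else {
    affine <- unname(as.matrix(affine))
    if (!identical(dim(affine), c(4L, 4L)))
      stop("'affine' must be a 4x4 matrix")
    voxel_size_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  if (abs(det(affine)) < 1e-12) stop("'affine' must be invertible")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

#' Test whether two grids coincide
#'
#' @param a,b `volume_grid` objects.
#' @param tol absolute tolerance on affine entries.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!grid_equal(a, b))
    stop("grid mismatch: ", what, " are not on the same grid; resample first")
  invisible(TRUE)
}

## 0-based voxel indices (rows of a n x 3 matrix) -> world mm
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

## world mm -> continuous 0-based voxel indices
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  t(solve(grid$affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Construct a lesion mask object
#'
#' @param data 3D array; any value > 0.5 is treated as lesioned (masks are
#'   nominally binary; 0.5 splits the nominal levels symmetrically).
#' @param grid the `volume_grid` the data lives on.
#' @param subject_id subject identifier string.
#' @param allow_empty if `FALSE` (default) an all-zero mask is an error.
#' @return Object of class `lesion_mask`: `subject_id`, `grid`, `data`
#'   (integer 0/1 array) and derived `volume_mm3`.
#' @export
lesion_mask <- function(data, grid, subject_id = "sub-001",
                        allow_empty = FALSE) {
  if (length(dim(data)) != 3L) stop("non-3D image")
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("data dimensions do not match grid shape")
  bin <- array(as.integer(data > 0.5), dim = dim(data))
  n <- sum(bin)
  if (n == 0L && !allow_empty)
    stop("lesion mask is empty; pass allow_empty = TRUE if intended")
  structure(list(subject_id = as.character(subject_id), grid = grid,
                 data = bin,
                 volume_mm3 = n * prod(grid$voxel_size_mm)),
            class = "lesion_mask")
}

#' Construct a brain mask object
#'
#' @param data 3D array, binarized at > 0.5; must contain >= 1 voxel.
#' @param grid the `volume_grid` the data lives on.
#' @return Object of class `brain_mask` with fields `grid` and `data`.
#' @export
brain_mask <- function(data, grid) {
  if (length(dim(data)) != 3L) stop("non-3D image")
  if (!identical(dim(data), as.integer(grid$shape)))
    stop("data dimensions do not match grid shape")
  bin <- array(as.integer(data > 0.5), dim = dim(data))
  if (sum(bin) == 0L) stop("brain mask has no voxels")
  structure(list(grid = grid, data = bin), class = "brain_mask")
}

grid_from_nifti <- function(img) {
  aff <- unname(structure(RNifti::xform(img), code = NULL))
  volume_grid(dim(img), affine = matrix(as.numeric(aff), 4, 4))
}

#' Load a binary lesion mask from a NIfTI file
#'
#' Values > 0.5 become 1 (continuous inputs are tolerated but masks are
#' expected to be nominally binary). The grid is read from the NIfTI
#' sform/qform.
#'
#' @param path path to a 3D NIfTI volume (`.nii` or `.nii.gz`).
#' @param expected_grid optional `volume_grid`; if given and the file's grid
#'   differs, an error signals that the caller must resample first.
#' @param subject_id subject identifier; defaults to the file stem.
#' @param allow_empty accept an all-zero mask.
#' @return A [lesion_mask()].
#' @export
load_mask <- function(path, expected_grid = NULL, subject_id = NULL,
                      allow_empty = FALSE) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("non-3D image: ", path)
  grid <- grid_from_nifti(img)
  if (!is.null(expected_grid))
    stop_if_grid_mismatch(grid, expected_grid, basename(path))
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesion_mask(array(as.numeric(img), dim = dim(img)), grid,
              subject_id = subject_id, allow_empty = allow_empty)
}

#' Load any 3D volume with its grid
#'
#' @param path path to a 3D NIfTI volume.
#' @return List with `data` (3D numeric array) and `grid`.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("non-3D image: ", path)
  list(data = array(as.numeric(img), dim = dim(img)),
       grid = grid_from_nifti(img))
}

#' Write a volume to NIfTI
#'
#' @param data 3D (or 4D) numeric array.
#' @param grid the `volume_grid` describing the first three axes.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; masks use `"uint8"`, continuous maps
#'   `"float"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, grid, path, datatype = "float") {
  img <- RNifti::asNifti(data)
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  ## pixdim must be set explicitly or the scaling is lost on write
  RNifti::pixdim(img) <- grid$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a lesion or brain mask to NIfTI (unsigned 8-bit)
#'
#' @param mask a `lesion_mask` or `brain_mask`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_volume(mask$data, mask$grid, path, datatype = "uint8")
}

#' Resample a lesion mask to a target grid (nearest neighbour)
#'
#' Each target voxel takes the value of the source voxel whose centre is
#' nearest to the target voxel centre (pull interpolation through the two
#' affines). Exact half-way ties break toward the lower index so the result
#' is deterministic. Target voxels whose nearest source location falls
#' outside the source array are 0.
#'
#' @param mask a [lesion_mask()].
#' @param target the `volume_grid` to resample onto.
#' @return A `lesion_mask` on `target`.
#' @export
resample_mask <- function(mask, target) {
  if (!inherits(target, "volume_grid")) stop("'target' must be a volume_grid")
  if (grid_equal(mask$grid, target)) {
    out <- mask
    return(out)
  }
  shp <- target$shape
  n <- prod(shp)
  ijk <- arrayInd(seq_len(n), shp) - 1L
  src <- world_to_voxel(mask$grid, voxel_to_world(target, ijk))
  nearest <- ceiling(src - 0.5)              # ties toward the lower index
  inb <- nearest[, 1] >= 0 & nearest[, 1] < mask$grid$shape[1] &
         nearest[, 2] >= 0 & nearest[, 2] < mask$grid$shape[2] &
         nearest[, 3] >= 0 & nearest[, 3] < mask$grid$shape[3]
  vals <- integer(n)
  if (any(inb)) {
    lin <- 1L + nearest[inb, 1] +
      mask$grid$shape[1] * (nearest[inb, 2] +
                            mask$grid$shape[2] * nearest[inb, 3])
    vals[inb] <- mask$data[lin]
  }
  lesion_mask(array(vals, dim = shp), target, subject_id = mask$subject_id,
              allow_empty = TRUE)
}
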