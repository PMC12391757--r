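#' Construct a parcellation atlas
#'
#' @param labels 3D integer array; 0 is background, every positive value is
#'   a parcel label.
#' @param grid the `volume_grid` the labels live on.
#' @param names named character vector mapping label (as name) to parcel
#'   name; defaults to `P<label>`.
#' @param kind one of `"vascular"`, `"functional"`, `"structural-wm"`.
#' @return Object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, grid,
                               names = NULL,
                               kind = c("vascular", "functional",
                                        "structural-wm")) {
  kind <- match.arg(kind)
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (!identical(dim(labels), as.integer(grid$shape)))
    stop("label dimensions do not match grid shape")
  labels <- array(as.integer(labels), dim = dim(labels))
  if (any(labels < 0L)) stop("labels must be >= 0")
  present <- sort(unique(labels[labels > 0L]))
  if (length(present) == 0L) stop("atlas with zero parcels")
  if (is.null(names))
    names <- setNames(sprintf("P%d", present), present)
  if (!all(as.character(present) %in% base::names(names)))
    stop("every nonzero label must have a name")
  names <- names[as.character(sort(as.integer(base::names(names))))]
  structure(list(grid = grid, labels = labels, names = names, kind = kind),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> kind=%s, %d parcels, %s voxels\n",
              x$kind, length(x$names), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Dual lesion/parcel overlap percentages for one subject
#'
#' For each parcel L with voxel count `|P_L|` and a lesion of `|lesion|`
#' voxels: `lesion_pct[L] = 100 |lesion n P_L| / |lesion|` (how the lesion
#' distributes across parcels) and `parcel_pct[L] =
#' 100 |lesion n P_L| / |P_L|` (how much of the parcel is damaged). The two
#' measures jointly drive the exclusion rule of [apply_exclusion()]: a
#' parcel is retained when the overlap involves at least `threshold_pct` of
#' the lesion or of the parcel. An empty lesion yields all-zero features
#' and an empty retained set.
#'
#' @param lesion a [lesion_mask()] on the atlas grid.
#' @param atlas a [parcellation_atlas()].
#' @param threshold_pct retention threshold (percent, boundary inclusive).
#' @return Object of class `overlap_features`: `subject_id`, `lesion_pct`,
#'   `parcel_pct` (named by label), `retained` (character labels) and
#'   `threshold_pct`.
#' @export
compute_overlap <- function(lesion, atlas, threshold_pct = 5) {
  stop_if_grid_mismatch(lesion$grid, atlas$grid, "lesion and atlas")
  labs <- as.integer(names(atlas$names))
  nb <- max(labs)
  parcel_sizes <- tabulate(atlas$labels[atlas$labels > 0L], nbins = nb)[labs]
  les_idx <- which(lesion$data == 1L)
  n_les <- length(les_idx)
  counts <- if (n_les)
    tabulate(atlas$labels[les_idx][atlas$labels[les_idx] > 0L],
             nbins = nb)[labs] else rep(0L, length(labs))
  lesion_pct <- setNames(if (n_les) 100 * counts / n_les
                         else rep(0, length(labs)), labs)
  parcel_pct <- setNames(100 * counts / parcel_sizes, labs)
  out <- structure(list(subject_id = lesion$subject_id,
                        lesion_pct = lesion_pct, parcel_pct = parcel_pct,
                        retained = character(0),
                        threshold_pct = threshold_pct),
                   class = "overlap_features")
  if (n_les) out <- apply_exclusion(out, threshold_pct) else
    out$retained <- character(0)
  out
}

#' Apply the dual-percentage exclusion rule
#'
#' A parcel survives when at least `threshold_pct` of the lesion or at
#' least `threshold_pct` of the parcel is involved in the overlap (an OR
#' rule, boundary inclusive); overlaps below both thresholds are treated as
#' negligible lesion load and zeroed in downstream design matrices.
#'
#' @param features an [compute_overlap()] result.
#' @param threshold_pct retention threshold in percent (>= 0).
#' @return The features with `retained` recomputed.
#' @export
apply_exclusion <- function(features, threshold_pct = 5) {
  if (threshold_pct < 0) stop("threshold_pct must be >= 0")
  keep <- features$lesion_pct >= threshold_pct |
    features$parcel_pct >= threshold_pct
  features$retained <- names(features$lesion_pct)[keep]
  features$threshold_pct <- threshold_pct
  features
}

#' Assemble the cohort design matrix for one atlas
#'
#' One row per subject (ordered by subject id), one column per atlas parcel
#' (ascending label; exclusions zero cells, never drop columns). Cell
#' values are `lesion_pct` by default; `parcel_pct` or both (side by side)
#' are available for the alternative damage parameterizations.
#'
#' @param cohort_features list of [compute_overlap()] results with the
#'   exclusion rule already applied.
#' @param atlas the shared [parcellation_atlas()].
#' @param value which overlap measure fills the cells.
#' @return Numeric matrix with subject-id rownames and
#'   `<kind>_<label>_<name>` colnames; atlas kind in attribute
#'   `atlas_kind`.
#' @export
build_design_matrix <- function(cohort_features, atlas,
                                value = c("lesion_pct", "parcel_pct",
                                          "both")) {
  value <- match.arg(value)
  ids <- vapply(cohort_features, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicated subject ids")
  ord <- order(ids)
  labs <- names(atlas$names)
  one <- function(measure) {
    m <- t(vapply(cohort_features[ord], function(f) {
      v <- f[[measure]][labs]
      v[!(labs %in% f$retained)] <- 0
      v
    }, numeric(length(labs))))
    kindtag <- sub("-", "", atlas$kind)
    colnames(m) <- sprintf("%s_%s_%s", kindtag, labs, atlas$names[labs])
    rownames(m) <- ids[ord]
    m
  }
  out <- switch(value,
                lesion_pct = one("lesion_pct"),
                parcel_pct = one("parcel_pct"),
                both = {
                  a <- one("lesion_pct"); b <- one("parcel_pct")
                  colnames(a) <- paste0("lpct_", colnames(a))
                  colnames(b) <- paste0("ppct_", colnames(b))
                  cbind(a, b)
                })
  attr(out, "atlas_kind") <- atlas$kind
  out
}

#' Write a design matrix as TSV
#'
#' @param X matrix from [build_design_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(X, path) {
  df <- data.frame(subject_id = rownames(X), X, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
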