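#' Binary voxel mask
#'
#' A `voxel_mask` wraps a 3D binary array together with its voxel spacing
#' (mm per axis). Counting is always done in voxel units; spacing is carried
#' along for provenance and reporting only.
#'
#' @param grid 3D array; nonzero entries are foreground voxels.
#' @param spacing numeric length-3, voxel size in mm per axis.
#' @return An object of class `voxel_mask` with elements `grid`
#'   (3D 0/1 integer array) and `spacing`.
#' @export
voxel_mask <- function(grid, spacing = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  if (any(dim(grid) < 2L))
    stop("grid dimensions must be >= 2 in every axis", call. = FALSE)
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive voxel sizes (mm)", call. = FALSE)
  g <- array(as.integer(grid != 0), dim = dim(grid))
  structure(list(grid = g, spacing = as.numeric(spacing)),
            class = "voxel_mask")
}

as_voxel_mask <- function(x) {
  if (inherits(x, "voxel_mask")) return(x)
  voxel_mask(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, %d foreground, spacing %s mm\n",
              paste(dim(x$grid), collapse = "x"), sum(x$grid),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

n_foreground <- function(mask) sum(as_voxel_mask(mask)$grid)

#' ROI label map
#'
#' A 3D integer parcellation (label 0 = background) plus a table mapping
#' label ids to region names, e.g. the 90 AAL regions.
#'
#' @param grid 3D integer array of region labels; 0 is background.
#' @param label_table data.frame with columns `label` (integer > 0) and
#'   `region` (unique character names).
#' @param spacing voxel size in mm per axis.
#' @return An object of class `roi_labelmap`.
#' @seealso [aal90_labels()] for the shipped AAL-90 table.
#' @export
roi_labelmap <- function(grid, label_table, spacing = c(1, 1, 1)) {
  if (length(dim(grid)) != 3L)
    stop("`grid` must be a 3D array", call. = FALSE)
  stopifnot(is.data.frame(label_table),
            all(c("label", "region") %in% names(label_table)))
  label_table$label <- as.integer(label_table$label)
  label_table$region <- as.character(label_table$region)
  if (any(label_table$label <= 0L))
    stop("label 0 is reserved for background; labels must be > 0",
         call. = FALSE)
  if (anyDuplicated(label_table$label) || anyDuplicated(label_table$region))
    stop("duplicated label ids or region names in label_table", call. = FALSE)
  structure(list(grid = array(as.integer(round(grid)), dim = dim(grid)),
                 label_table = label_table[c("label", "region")],
                 spacing = as.numeric(spacing)),
            class = "roi_labelmap")
}

#' @export
print.roi_labelmap <- function(x, ...) {
  present <- sum(x$label_table$label %in% unique(as.vector(x$grid)))
  cat(sprintf("<roi_labelmap> %s voxels, %d labels in table (%d present)\n",
              paste(dim(x$grid), collapse = "x"),
              nrow(x$label_table), present))
  invisible(x)
}

#' AAL-90 region label table
#'
#' The 90-region Automated Anatomical Labeling parcellation names, in the
#' standard atlas ordering (45 left/right pairs, cortex then basal ganglia,
#' thalamus and temporal regions).
#'
#' @return data.frame with columns `label` (1..90) and `region`.
#' @export
aal90_labels <- function() {
  path <- system.file("extdata", "aal90_labels.tsv", package = "fdbs",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Extract the binary mask of one region from a label map
#'
#' @param labelmap an [roi_labelmap()].
#' @param label_id integer id that must exist in the label table.
#' @return [voxel_mask()] that is nonzero exactly where `grid == label_id`.
#' @export
extract_roi_mask <- function(labelmap, label_id) {
  stopifnot(inherits(labelmap, "roi_labelmap"))
  label_id <- as.integer(label_id)
  if (!label_id %in% labelmap$label_table$label)
    stop(sprintf("label id %d not present in label table", label_id),
         call. = FALSE)
  g <- labelmap$grid == label_id
  if (!any(g))
    stop(sprintf("empty ROI: label %d has no voxels", label_id),
         call. = FALSE)
  voxel_mask(array(as.integer(g), dim = dim(g)), spacing = labelmap$spacing)
}

#' Extract the boundary shell of a mask
#'
#' A voxel belongs to the boundary when it is foreground and at least one of
#' its 6 face neighbours is background; voxels on the array edge always
#' count as boundary (outside the array is background).
#'
#' @param mask a [voxel_mask()] or 3D array.
#' @return [voxel_mask()] containing the boundary shell (a subset of the
#'   input mask).
#' @export
extract_boundary <- function(mask) {
  m <- as_voxel_mask(mask)
  g <- m$grid
  if (!any(g != 0)) stop("empty mask: no foreground voxels", call. = FALSE)
  d <- dim(g)
  # pad with one background layer so array-edge voxels see a zero neighbour
  p <- array(0L, d + 2L)
  p[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- g
  core <- function(dx, dy, dz) {
    p[(2:(d[1] + 1L)) + dx, (2:(d[2] + 1L)) + dy, (2:(d[3] + 1L)) + dz]
  }
  n_full <- core(1L, 0L, 0L) + core(-1L, 0L, 0L) +
    core(0L, 1L, 0L) + core(0L, -1L, 0L) +
    core(0L, 0L, 1L) + core(0L, 0L, -1L)
  b <- (g == 1L) & (n_full < 6L)
  voxel_mask(array(as.integer(b), dim = d), spacing = m$spacing)
}
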