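#' Read a NIfTI label map
#'
#' Reads a `.nii`/`.nii.gz` parcellation volume (already co-registered to
#' subject space) and pairs it with a label table.
#'
#' @param path NIfTI-1 file containing integer region labels (0 =
#'   background).
#' @param label_table data.frame (`label`, `region`) or path to a TSV with
#'   those columns; defaults to the shipped AAL-90 table.
#' @return an [roi_labelmap()] with spacing taken from the NIfTI header.
#' @export
read_labelmap <- function(path, label_table = aal90_labels()) {
  img <- RNifti::readNifti(path)
  if (is.character(label_table))
    label_table <- utils::read.delim(label_table, stringsAsFactors = FALSE)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  roi_labelmap(array(as.integer(round(img)), dim = dim(img)[seq_len(3)]),
               label_table = label_table, spacing = spacing)
}

#' Write a voxel mask or label map as NIfTI
#'
#' @param x a [voxel_mask()] or [roi_labelmap()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  stopifnot(inherits(x, "voxel_mask") || inherits(x, "roi_labelmap"))
  img <- RNifti::asNifti(x$grid)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a regional FD table as CSV
#'
#' @param fd data.frame from [fd_table()] (`subject_id` + one column per
#'   region).
#' @param path CSV path.
#' @return `path` (write) / data.frame (read).
#' @export
write_fd_table <- function(fd, path) {
  stopifnot(is.data.frame(fd), names(fd)[1] == "subject_id")
  utils::write.csv(fd, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_table
#' @export
read_fd_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write box-count diagnostics as JSON
#'
#' @param result a `box_count_result` from [fit_fd()] / [mask_fd()].
#' @param path JSON output path.
#' @export
write_boxcount_json <- function(result, path) {
  stopifnot(inherits(result, "box_count_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
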