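#' Box-size schedule by integer halving
#'
#' The largest box equals the smallest grid dimension and each following
#' size is the integer floor of half the previous one, down to 1 voxel;
#' duplicates are removed. The lattice is anchored at array index (1,1,1)
#' and partial boxes at the far edges are counted.
#'
#' @param min_dim smallest grid dimension (integer >= 2).
#' @return decreasing integer vector of box edge lengths.
#' @export
auto_box_sizes <- function(min_dim) {
  min_dim <- as.integer(min_dim)
  stopifnot(min_dim >= 2L)
  s <- min_dim
  out <- integer(0)
  while (s >= 1L) {
    out <- c(out, s)
    if (s == 1L) break
    s <- s %/% 2L
  }
  unique(out)
}

#' Count covering boxes at one or more scales
#'
#' Partitions the array into a non-overlapping lattice of `s^3` boxes
#' anchored at the array corner and counts, for every box edge length `s`,
#' the boxes that contain at least one foreground voxel.
#'
#' @param mask a [voxel_mask()] or 3D array with at least one foreground
#'   voxel.
#' @param sizes `"auto"` for the halving schedule of [auto_box_sizes()], or
#'   an explicit vector of box edge lengths (each in `[1, min(dim)]`).
#' @return data.frame with columns `size` (descending) and `count`.
#' @export
box_count <- function(mask, sizes = "auto") {
  m <- as_voxel_mask(mask)
  dims <- dim(m$grid)
  if (identical(sizes, "auto")) {
    sizes <- auto_box_sizes(min(dims))
  } else {
    sizes <- as.integer(sizes)
    if (any(sizes < 1L))
      stop("box sizes must be >= 1 voxel", call. = FALSE)
    if (any(sizes > min(dims)))
      stop(sprintf("box size %d exceeds smallest grid dimension %d",
                   max(sizes), min(dims)), call. = FALSE)
    sizes <- sort(unique(sizes), decreasing = TRUE)
  }
  idx <- which(m$grid != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("empty mask: no foreground voxels", call. = FALSE)
  counts <- vapply(sizes, function(s) {
    b <- (idx - 1L) %/% s
    nb <- ceiling(dims / s)
    id <- (b[, 1] * nb[2] + b[, 2]) * nb[3] + b[, 3]
    length(unique(id))
  }, numeric(1))
  data.frame(size = sizes, count = counts)
}

#' Fit fractal dimension from box counts
#'
#' Ordinary least-squares slope of log(N) on log(1/s) (natural logs; the
#' slope is base-invariant). Requires at least 3 scales with strictly
#' positive counts.
#'
#' @param sizes box edge lengths.
#' @param counts box counts, same length as `sizes`.
#' @return object of class `box_count_result`: `sizes`, `counts`, `fd`
#'   (the slope), `fit_r2`, `intercept`, `log_base = "natural"`.
#' @export
fit_fd <- function(sizes, counts) {
  sizes <- as.numeric(sizes)
  counts <- as.numeric(counts)
  if (length(sizes) != length(counts))
    stop("sizes and counts must have equal length", call. = FALSE)
  if (length(sizes) < 3L)
    stop("need at least 3 scales to fit a fractal dimension", call. = FALSE)
  if (any(counts <= 0))
    stop("all box counts must be strictly positive", call. = FALSE)
  x <- log(1 / sizes)
  y <- log(counts)
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1.0 else 1 - ss_res / ss_tot
  structure(list(sizes = sizes, counts = counts,
                 fd = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_r2 = r2, log_base = "natural"),
            class = "box_count_result")
}

#' @export
print.box_count_result <- function(x, ...) {
  cat(sprintf("<box_count_result> fd = %.4f (R^2 = %.4f) over %d scales [%s]\n",
              x$fd, x$fit_r2, length(x$sizes),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Fractal dimension of a single mask
#'
#' Convenience wrapper: optional boundary extraction, box counting and
#' log-log fit in one call.
#'
#' @inheritParams box_count
#' @param surface_mode `"boundary"` counts the 6-connected boundary shell
#'   (the default: the quantity of interest is boundary complexity);
#'   `"volume"` counts all foreground voxels.
#' @return [fit_fd()] result with the mode recorded in `$surface_mode`.
#' @export
mask_fd <- function(mask, surface_mode = c("boundary", "volume"),
                    sizes = "auto") {
  surface_mode <- match.arg(surface_mode)
  m <- as_voxel_mask(mask)
  if (surface_mode == "boundary") m <- extract_boundary(m)
  bc <- box_count(m, sizes = sizes)
  res <- fit_fd(bc$size, bc$count)
  res$surface_mode <- surface_mode
  res
}

#' Regional fractal dimension for every region of a label map
#'
#' Runs [extract_roi_mask()], optionally [extract_boundary()], then
#' [box_count()] with the `"auto"` schedule and [fit_fd()] for every label
#' in the label table. Regions whose extraction or fit fails (e.g. empty
#' regions) are recorded as `NA` with the failure reason; the call errors
#' only when every region fails.
#'
#' @param labelmap an [roi_labelmap()].
#' @param surface_mode `"boundary"` (default) or `"volume"`; see [mask_fd()].
#' @param sizes passed to [box_count()].
#' @return named numeric vector of FD values (names = region names), with
#'   attributes `failures` (named character vector of reasons for `NA`
#'   regions) and `surface_mode`.
#' @export
compute_regional_fd <- function(labelmap,
                                surface_mode = c("boundary", "volume"),
                                sizes = "auto") {
  stopifnot(inherits(labelmap, "roi_labelmap"))
  surface_mode <- match.arg(surface_mode)
  tab <- labelmap$label_table
  fd <- stats::setNames(rep(NA_real_, nrow(tab)), tab$region)
  failures <- character(0)
  for (i in seq_len(nrow(tab))) {
    res <- tryCatch({
      mask <- extract_roi_mask(labelmap, tab$label[i])
      mask_fd(mask, surface_mode = surface_mode, sizes = sizes)$fd
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[tab$region[i]] <- conditionMessage(res)
    } else {
      fd[tab$region[i]] <- res
    }
  }
  if (all(is.na(fd)))
    stop("all regions empty or failed; no fractal dimension computed",
         call. = FALSE)
  attr(fd, "failures") <- failures
  attr(fd, "surface_mode") <- surface_mode
  fd
}

#' Regional FD table for a set of subjects
#'
#' @param labelmaps named list of [roi_labelmap()] objects, one per subject.
#' @inheritParams compute_regional_fd
#' @return data.frame: `subject_id` plus one FD column per region.
#' @export
fd_table <- function(labelmaps, surface_mode = c("boundary", "volume"),
                     sizes = "auto") {
  surface_mode <- match.arg(surface_mode)
  stopifnot(is.list(labelmaps), length(labelmaps) >= 1L,
            !is.null(names(labelmaps)))
  rows <- lapply(labelmaps, compute_regional_fd,
                 surface_mode = surface_mode, sizes = sizes)
  regions <- names(rows[[1]])
  for (r in rows) {
    if (!identical(names(r), regions))
      stop("region sets differ across subjects", call. = FALSE)
  }
  out <- data.frame(subject_id = names(labelmaps),
                    do.call(rbind, lapply(rows, as.numeric)),
                    row.names = NULL, check.names = FALSE)
  names(out)[-1] <- regions
  out
}
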