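#' Image stack container
#'
#' A single-channel 3D fluorescence volume with `(z, y, x)` axis order.
#' All voxel coordinates in this package are 1-based; a region of interest
#' with origin `o` and size `s` covers voxels `o .. o + s - 1` on each axis.
#'
#' @param voxels numeric array, `dim = c(nz, ny, nx)`, finite and `>= 0`.
#' @param channel_label free-text channel name (probe/fluorophore).
#' @param voxel_size optional physical voxel size in micrometres per axis,
#'   `(z, y, x)`; metadata only, never used by the detector.
#' @param origin position, in the frame of the parent stack, of this
#'   stack's voxel `(1, 1, 1)`. `(1, 1, 1)` for a full stack; set by
#'   [extract_roi()] so spot centroids can be mapped back.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, channel_label = "", voxel_size = NULL,
                        origin = c(1L, 1L, 1L)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array with dim (z, y, x)")
  if (any(dim(voxels) < 1L)) stop("each axis needs at least one plane")
  if (!all(is.finite(voxels))) stop("voxel intensities must be finite")
  if (min(voxels) < 0) stop("voxel intensities must be non-negative")
  structure(
    list(voxels = voxels, channel_label = channel_label,
         voxel_size = voxel_size, origin = as.integer(origin)),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> channel '%s'  %d x %d x %d (z,y,x)  range [%g, %g]\n",
              x$channel_label, d[1], d[2], d[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read a grayscale TIFF z-stack
#'
#' Reads a multi-page TIFF into an [image_stack()] with `(z, y, x)` axis
#' order. Integer (8/16-bit) data round-trips bit-exactly. Pages of a
#' multi-channel TIFF are split by giving `channel`, the 1-based channel
#' index along the page's third dimension.
#'
#' @param path TIFF file path.
#' @param channel_label channel name stored on the stack.
#' @param channel for multi-sample (RGB-like) pages, which sample to keep;
#'   `NULL` (default) requires grayscale pages.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_label = "", channel = NULL) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      stop("cannot read '", path, "' as TIFF: ",
                           conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (length(dim(p)) == 3L) {
      if (is.null(channel))
        stop("plane ", k, " of '", path,
             "' is not grayscale; pass `channel` to select one")
      if (channel > dim(p)[3])
        stop("plane ", k, ": channel ", channel, " out of range")
      pages[[k]] <- p[, , channel]
    } else if (length(dim(p)) != 2L) {
      stop("plane ", k, " of '", path, "' has unsupported shape")
    }
  }
  sh <- dim(pages[[1]])
  for (k in seq_along(pages))
    if (!identical(dim(pages[[k]]), sh))
      stop("plane ", k, " shape (", paste(dim(pages[[k]]), collapse = "x"),
           ") differs from plane 1 (", paste(sh, collapse = "x"), ")")
  vox <- array(0, dim = c(length(pages), sh[1], sh[2]))
  for (k in seq_along(pages)) vox[k, , ] <- pages[[k]]
  image_stack(vox, channel_label = channel_label)
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Intensities are rounded to integers and clipped to the bit depth;
#' integer-valued stacks within range round-trip exactly through
#' [read_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"), bits %in% c(8L, 16L))
  top <- 2^bits - 1
  v <- pmin(pmax(round(stack$voxels), 0), top)
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Region of interest
#'
#' A box of voxels defined by a 1-based origin and per-axis extents, both in
#' `(z, y, x)` order: voxels `origin .. origin + size - 1` are included.
#' `NA` entries in `size` mean "to the end of the stack on that axis"; the
#' conventional lateral window is 300 x 300 pixels through the full z-range.
#'
#' @param origin integer `(z, y, x)`, all `>= 1`.
#' @param size integer extents `(dz, dy, dx)`; `NA` = full remaining extent.
#' @return An object of class `roi`.
#' @export
roi <- function(origin = c(1L, 1L, 1L), size = c(NA, 300L, 300L)) {
  origin <- as.integer(origin); size <- as.integer(size)
  if (length(origin) != 3L || length(size) != 3L)
    stop("origin and size must each have 3 elements (z, y, x)")
  if (any(origin < 1L)) stop("roi origin must be >= 1 on every axis")
  if (any(!is.na(size) & size < 1L)) stop("roi size must be >= 1")
  structure(list(origin = origin, size = size), class = "roi")
}

resolve_roi <- function(r, dims) {
  size <- r$size
  size[is.na(size)] <- (dims - r$origin + 1L)[is.na(size)]
  list(origin = r$origin, size = as.integer(size))
}

#' Extract an ROI sub-volume
#'
#' Returns a copy of the boxed sub-volume as a new stack whose `origin`
#' records the ROI position, so centroids measured inside the ROI can be
#' mapped back to the parent frame with [spots_to_stack_frame()].
#'
#' @param stack an [image_stack()].
#' @param r an [roi()].
#' @return An [image_stack()] of the ROI.
#' @export
extract_roi <- function(stack, r) {
  stopifnot(inherits(stack, "image_stack"), inherits(r, "roi"))
  dims <- dim(stack$voxels)
  rr <- resolve_roi(r, dims)
  hi <- rr$origin + rr$size - 1L
  for (ax in 1:3) {
    if (hi[ax] > dims[ax] || rr$origin[ax] < 1L)
      stop(sprintf("roi out of bounds on %s axis: voxels %d..%d of %d",
                   c("z", "y", "x")[ax], rr$origin[ax], hi[ax], dims[ax]))
  }
  sub <- stack$voxels[rr$origin[1]:hi[1], rr$origin[2]:hi[2],
                      rr$origin[3]:hi[3], drop = FALSE]
  image_stack(sub, channel_label = stack$channel_label,
              voxel_size = stack$voxel_size,
              origin = stack$origin + rr$origin - 1L)
}

roi_table_columns <- c("sample", "roi", "origin_z", "origin_y", "origin_x",
                       "size_z", "size_y", "size_x", "nucleus_count")

#' Read a table of ROIs and manual nucleus counts
#'
#' CSV with header `sample, roi, origin_z, origin_y, origin_x, size_z,
#' size_y, size_x, nucleus_count`. Blank sizes mean full extent on that
#' axis; a blank `nucleus_count` stays missing (`NA`), never zero — nucleus
#' counts are an external (typically manual) input.
#'
#' @param path CSV path.
#' @return data.frame with one row per `(sample, roi)`.
#' @export
read_roi_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(roi_table_columns, names(tab))
  if (length(miss))
    stop("roi table is missing columns: ", paste(miss, collapse = ", "))
  key <- paste(tab$sample, tab$roi, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample, roi) keys: ",
         paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (any(!is.na(tab$nucleus_count) & tab$nucleus_count < 0))
    stop("nucleus_count must be non-negative")
  tab[roi_table_columns]
}

#' @rdname read_roi_table
#' @param tab data.frame as returned by [read_roi_table()].
#' @export
write_roi_table <- function(tab, path) {
  stopifnot(all(roi_table_columns %in% names(tab)))
  write.csv(tab[roi_table_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

roi_from_row <- function(row) {
  roi(origin = c(row$origin_z, row$origin_y, row$origin_x),
      size = c(row$size_z, row$size_y, row$size_x))
}

#' Map ROI-frame spot centroids into the parent stack frame
#'
#' @param spots a `spot_set` detected on an ROI sub-stack.
#' @param ... unused.
#' @return The spot set with centroids translated by the ROI origin.
#' @export
spots_to_stack_frame <- function(spots, ...) {
  stopifnot(inherits(spots, "spot_set"))
  off <- spots$origin - 1L
  spots$spots$z <- spots$spots$z + off[1]
  spots$spots$y <- spots$spots$y + off[2]
  spots$spots$x <- spots$spots$x + off[3]
  spots$origin <- c(1L, 1L, 1L)
  spots
}
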