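#' mRNA per cell
#'
#' Transcript count divided by the number of nuclei in the same ROI (the
#' nucleus count is the cell-number proxy, usually counted manually in the
#' counterstain channel).
#'
#' @param spot_count non-negative integer mRNA count.
#' @param nucleus_count positive integer; missing or zero is an error,
#'   never silently zero.
#' @return `spot_count / nucleus_count`.
#' @export
mrna_per_cell <- function(spot_count, nucleus_count) {
  if (length(nucleus_count) != 1L || is.na(nucleus_count) ||
      nucleus_count < 1)
    stop("mRNA per cell undefined: nucleus_count must be a positive integer")
  if (spot_count < 0) stop("spot_count must be non-negative")
  spot_count / nucleus_count
}

#' Normalized expression
#'
#' Target-channel transcript count divided by the reference-channel count
#' in the same ROI (e.g. AXIN2 normalized to APC).
#'
#' @param target_count non-negative integer.
#' @param reference_count positive integer.
#' @param roi_id optional label used in the error message.
#' @return `target_count / reference_count`.
#' @export
normalized_expression <- function(target_count, reference_count,
                                  roi_id = NULL) {
  if (length(reference_count) != 1L || is.na(reference_count) ||
      reference_count < 1)
    stop("normalized expression undefined",
         if (!is.null(roi_id)) paste0(" for ROI ", roi_id),
         ": reference count must be >= 1")
  if (target_count < 0) stop("target_count must be non-negative")
  target_count / reference_count
}

#' Regional count ratio
#'
#' Ratio between absolute transcript counts detected in two named regions
#' of one sample (e.g. organoid body over crypt) for a single channel.
#'
#' @param count_body non-negative integer count in the numerator region.
#' @param count_crypt positive integer count in the denominator region.
#' @return `count_body / count_crypt`.
#' @export
region_ratio <- function(count_body, count_crypt) {
  if (length(count_crypt) != 1L || is.na(count_crypt) || count_crypt < 1)
    stop("region ratio undefined: denominator region count must be >= 1")
  if (count_body < 0) stop("count_body must be non-negative")
  count_body / count_crypt
}

#' Automatic nucleus count from a counterstain stack
#'
#' Convenience counter: global threshold (Otsu, median across z-planes),
#' 3D connected components, size filter. Counts from this function are
#' always flagged `"automatic"` downstream so they are never confused with
#' supplied manual counts, which take precedence.
#'
#' @param hoechst counterstain [image_stack()].
#' @param min_volume,max_volume nucleus volume bounds in voxels. The upper
#'   bound discards implausibly large masses (fused staining, or the
#'   percolating foreground a near-unimodal noise histogram produces), so
#'   a spot-free noisy stack counts zero nuclei.
#' @param connectivity 6 or 26.
#' @return Integer count of size-filtered components.
#' @export
count_nuclei <- function(hoechst, min_volume = 100L, max_volume = 10000L,
                         connectivity = 6L) {
  stopifnot(inherits(hoechst, "image_stack"))
  v <- hoechst$voxels
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant counterstain stack: cannot threshold")
  thr_planes <- EBImage::otsu(EBImage::Image(aperm(v, c(2, 3, 1))),
                              range = rng)
  thr <- stats::median(thr_planes)
  lab <- cc_label3d(as.double(v), dim(v), thr, as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_volume & sizes <= max_volume)
}

#' Quality-control summary of a spot set
#'
#' Reports the spot volume histogram (fixed bin width of 1 voxel), the
#' number of modes of that distribution, and the Pearson correlation
#' between spot volume and total intensity. For diffraction-limited smFISH
#' dots the volume distribution should be unimodal and volume should
#' correlate linearly with integrated intensity; departures indicate
#' segmentation or thresholding problems. Mode counting is performed on a
#' Sturges-binned histogram lightly smoothed with a 3-point moving
#' average, so sampling noise in sparsely filled width-1 bins does not
#' masquerade as extra modes; the raw width-1 histogram is returned
#' alongside for plotting.
#'
#' @param spots a `spot_set` with at least 10 spots; fewer marks the QC
#'   record insufficient rather than erroring.
#' @return A `qc_record` list: `n_spots`, `sufficient`, `volume_breaks`,
#'   `volume_counts`, `mode_count`, `volume_intensity_r`.
#' @export
qc_summary <- function(spots) {
  stopifnot(inherits(spots, "spot_set"))
  d <- spots$spots
  n <- nrow(d)
  if (n < 10L)
    return(structure(list(n_spots = n, sufficient = FALSE,
                          volume_breaks = NULL, volume_counts = NULL,
                          mode_count = NA_integer_,
                          volume_intensity_r = NA_real_),
                     class = "qc_record"))
  breaks <- seq(min(d$volume) - 0.5, max(d$volume) + 0.5, by = 1)
  counts <- as.integer(table(cut(d$volume, breaks, include.lowest = TRUE)))
  r <- if (sd(d$volume) == 0 || sd(d$total_intensity) == 0) NA_real_
       else cor(d$volume, d$total_intensity)
  hs <- graphics::hist(d$volume, breaks = "Sturges", plot = FALSE)
  structure(list(n_spots = n, sufficient = TRUE,
                 volume_breaks = breaks, volume_counts = counts,
                 mode_count = count_modes(moving_average(hs$counts, 3L)),
                 volume_intensity_r = r),
            class = "qc_record")
}

# Number of modes of a nonnegative curve: maximal runs of equal values
# strictly greater than both flanking values (curve ends count as flanks
# of -Inf).
count_modes <- function(y) {
  if (!length(y)) return(0L)
  ext <- c(-Inf, y, -Inf)
  runs <- rle(ext)
  v <- runs$values
  k <- length(v)
  if (k < 3L) return(if (k == 1L) 0L else 1L)
  sum(vapply(2:(k - 1L), function(i) v[i] > v[i - 1L] && v[i] > v[i + 1L],
             logical(1)))
}

#' @export
print.qc_record <- function(x, ...) {
  if (!x$sufficient) {
    cat(sprintf("<qc_record> insufficient (%d spots, need >= 10)\n",
                x$n_spots))
  } else {
    cat(sprintf(
      "<qc_record> %d spots; volume modes: %d; volume~intensity r = %.3f\n",
      x$n_spots, x$mode_count, x$volume_intensity_r))
  }
  invisible(x)
}
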