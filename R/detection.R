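#' Detection parameters
#'
#' Settings for the per-channel spot detector. The pipeline
#' scans binarization thresholds, picks the one on the flat plateau of the
#' count curve, labels 3D connected components and filters them by volume.
#'
#' @param n_threshold_levels number of evenly spaced threshold levels
#'   strictly between the stack minimum and maximum (`>= 10`).
#' @param connectivity 6 (faces only) or 26 (faces, edges, corners);
#'   26 keeps diagonal voxels of one point-spread function in one spot.
#' @param min_volume,max_volume spot volume bounds in voxels, inclusive;
#'   components outside are discarded as noise/blobs.
#' @param smoothing_window odd moving-average window for the count curve.
#' @param manual_threshold optional intensity overriding threshold
#'   selection entirely.
#' @param weighted_centroid if `TRUE` (default) centroids are
#'   intensity-weighted (subvoxel); otherwise plain voxel means.
#' @return A `detection_config` list.
#' @export
detection_config <- function(n_threshold_levels = 100L, connectivity = 26L,
                             min_volume = 2L, max_volume = 200L,
                             smoothing_window = 5L, manual_threshold = NULL,
                             weighted_centroid = TRUE) {
  if (n_threshold_levels < 10L) stop("n_threshold_levels must be >= 10")
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  if (min_volume < 1L || min_volume > max_volume)
    stop("need 0 < min_volume <= max_volume")
  if (smoothing_window < 1L || smoothing_window %% 2L == 0L)
    stop("smoothing_window must be odd and >= 1")
  structure(list(n_threshold_levels = as.integer(n_threshold_levels),
                 connectivity = as.integer(connectivity),
                 min_volume = as.integer(min_volume),
                 max_volume = max_volume,
                 smoothing_window = as.integer(smoothing_window),
                 manual_threshold = manual_threshold,
                 weighted_centroid = isTRUE(weighted_centroid)),
            class = "detection_config")
}

#' Scan binarization thresholds
#'
#' Counts volume-filtered 3D connected components at each of
#' `n_threshold_levels` evenly spaced intensities strictly between the
#' stack minimum and maximum. The resulting curve drops steeply while the
#' threshold ascends through background noise and flattens into a plateau
#' where every real spot — and nothing else — is segmented; it is not
#' strictly monotone because merged blobs split and small spots drop below
#' `min_volume` as the threshold rises.
#'
#' @param stack an [image_stack()]; must not be constant.
#' @param config a [detection_config()].
#' @return A `threshold_curve`: thresholds, counts, `selected_index`
#'   (`NA` until [select_threshold()] is applied), smoothing window.
#' @export
scan_thresholds <- function(stack, config = detection_config()) {
  stopifnot(inherits(stack, "image_stack"))
  v <- stack$voxels
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("constant stack: threshold scan is undefined")
  n <- config$n_threshold_levels
  thr <- rng[1] + seq_len(n) * (rng[2] - rng[1]) / (n + 1)
  counts <- cc_count_curve(as.double(v), dim(v), thr, config$connectivity,
                           config$min_volume, config$max_volume)
  structure(list(thresholds = thr, counts = as.integer(counts),
                 selected_index = NA_integer_,
                 smoothing_window = config$smoothing_window,
                 flat = FALSE),
            class = "threshold_curve")
}

moving_average <- function(x, window) {
  if (window <= 1L) return(as.numeric(x))
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Select the plateau (inflection-point) threshold
#'
#' The working threshold is the level at which the detected count is least
#' sensitive to the threshold: the counts are smoothed with a centered
#' moving average and the level minimizing the absolute central-difference
#' slope with respect to threshold is chosen. Candidate levels are
#' restricted to the decaying branch at or after the curve's maximum:
#' below the background level the foreground fuses into oversized
#' components that the volume filter removes, so the curve has a
#' meaningless flat of zero counts at its low end. (Zero counts on the
#' decaying branch itself remain eligible — on a spot-free stack the
#' flattest stretch is the zero tail above the noise, correctly yielding
#' no detections.) The outer 5% of levels on each side is excluded. Ties
#' break toward the lower threshold, which lands tied plateaus at their
#' lowest level. If the interior is one flat plateau the lowest interior
#' level is returned and the curve is flagged.
#'
#' @param curve a `threshold_curve` from [scan_thresholds()] with at least
#'   10 levels.
#' @return The selected threshold (numeric) with attributes `index` (level
#'   index) and `flat` (all-flat warning flag).
#' @export
select_threshold <- function(curve) {
  stopifnot(inherits(curve, "threshold_curve"))
  n <- length(curve$thresholds)
  if (n < 10L) stop("threshold curve needs at least 10 levels")
  sm <- moving_average(curve$counts, curve$smoothing_window)
  thr <- curve$thresholds
  slope <- numeric(n)
  slope[1] <- (sm[2] - sm[1]) / (thr[2] - thr[1])
  slope[n] <- (sm[n] - sm[n - 1]) / (thr[n] - thr[n - 1])
  mid <- 2:(n - 1)
  slope[mid] <- (sm[mid + 1] - sm[mid - 1]) / (thr[mid + 1] - thr[mid - 1])
  margin <- ceiling(0.05 * n)
  interior <- (margin + 1L):(n - margin)
  peak <- which.max(sm)
  cand <- interior[interior >= peak]
  flat <- FALSE
  if (!length(cand)) {            # peak sits beyond the interior
    cand <- interior
    flat <- TRUE
  }
  best <- cand[which.min(abs(slope[cand]))]  # which.min ties -> lowest index
  if (diff(range(sm[interior])) == 0) flat <- TRUE
  structure(thr[best], index = best, flat = flat)
}

#' Binarize a stack
#'
#' Foreground iff intensity is strictly greater than the threshold (ties
#' are background).
#'
#' @param stack an [image_stack()].
#' @param threshold intensity cutoff within the stack's range.
#' @return Logical array of the stack's shape.
#' @export
binarize <- function(stack, threshold) {
  stopifnot(inherits(stack, "image_stack"))
  stack$voxels > threshold
}

#' Label 3D connected components
#'
#' Maximal connected sets of foreground voxels under 6- or 26-connectivity
#' receive distinct positive labels; background is 0.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param connectivity 6 or 26.
#' @return Integer array of labels, same shape as `mask`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3L, connectivity %in% c(6L, 26L))
  lab <- cc_label3d(as.double(mask), dim(mask), 0.5, as.integer(connectivity))
  array(lab, dim = dim(mask))
}

#' Volume-filter labeled components and measure spot features
#'
#' Discards components with volume outside `[min_volume, max_volume]`;
#' survivors are renumbered consecutively and measured: centroid (by
#' default intensity-weighted, hence subvoxel), volume in voxels, total and
#' peak intensity.
#'
#' @param labels integer label array from [label_components()].
#' @param stack the [image_stack()] the labels came from.
#' @param config a [detection_config()].
#' @return A `spot_set` (see [detect_spots()]).
#' @export
filter_and_measure <- function(labels, stack, config = detection_config()) {
  stopifnot(inherits(stack, "image_stack"),
            identical(dim(labels), dim(stack$voxels)))
  v <- stack$voxels
  dims <- dim(v)
  idx <- which(labels > 0L)
  empty <- data.frame(id = integer(), z = numeric(), y = numeric(),
                      x = numeric(), volume = integer(),
                      total_intensity = numeric(), max_intensity = numeric())
  if (!length(idx))
    return(new_spot_set(empty, stack, threshold = NA_real_, config = config))
  lab <- labels[idx]
  vol <- tabulate(lab)
  keep <- which(vol >= config$min_volume & vol <= config$max_volume)
  g <- match(lab, keep)
  ok <- !is.na(g)
  if (!any(ok))
    return(new_spot_set(empty, stack, threshold = NA_real_, config = config))
  idx <- idx[ok]; g <- g[ok]
  i0 <- idx - 1L
  z <- i0 %% dims[1] + 1L
  r <- i0 %/% dims[1]
  y <- r %% dims[2] + 1L
  x <- r %/% dims[2] + 1L
  inten <- v[idx]
  w <- if (config$weighted_centroid) inten else rep(1, length(idx))
  sw <- rowsum(w, g)[, 1]
  spots <- data.frame(
    id = seq_along(keep),
    z = rowsum(w * z, g)[, 1] / sw,
    y = rowsum(w * y, g)[, 1] / sw,
    x = rowsum(w * x, g)[, 1] / sw,
    volume = as.integer(vol[keep]),
    total_intensity = rowsum(inten, g)[, 1],
    max_intensity = vapply(split(inten, g), max, numeric(1), USE.NAMES = FALSE))
  rownames(spots) <- NULL
  new_spot_set(spots, stack, threshold = NA_real_, config = config)
}

new_spot_set <- function(spots, stack, threshold, config, curve = NULL) {
  structure(list(channel_label = stack$channel_label,
                 spots = spots,
                 threshold_used = threshold,
                 origin = stack$origin,
                 shape = dim(stack$voxels),
                 curve = curve,
                 config = config),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> channel '%s': %d spots (threshold %s)\n",
              x$channel_label, nrow(x$spots),
              if (is.na(x$threshold_used)) "unset"
              else format(x$threshold_used, digits = 4)))
  invisible(x)
}

#' Detect spots in one channel
#'
#' Full deterministic pipeline: threshold scan, plateau threshold
#' selection (or `manual_threshold` override), binarization, 3D connected
#' components, volume filtering, feature measurement. The selected
#' threshold and the scanned curve are recorded on the result.
#'
#' @param stack an [image_stack()].
#' @param config a [detection_config()].
#' @return A `spot_set`: `channel_label`, `spots` data.frame
#'   (id, z, y, x, volume, total_intensity, max_intensity),
#'   `threshold_used`, source `origin`/`shape`, the `curve` scanned.
#' @export
detect_spots <- function(stack, config = detection_config()) {
  stopifnot(inherits(stack, "image_stack"))
  curve <- NULL
  if (is.null(config$manual_threshold)) {
    curve <- scan_thresholds(stack, config)
    thr <- select_threshold(curve)
    curve$selected_index <- attr(thr, "index")
    curve$flat <- attr(thr, "flat")
    thr <- as.numeric(thr)
  } else {
    thr <- config$manual_threshold
  }
  labels <- cc_label3d(as.double(stack$voxels), dim(stack$voxels), thr,
                       config$connectivity)
  res <- filter_and_measure(array(labels, dim(stack$voxels)), stack, config)
  res$threshold_used <- thr
  res$curve <- curve
  res
}

#' Write a spot set as CSV
#'
#' One row per spot: channel, z, y, x, volume, total_intensity,
#' max_intensity, threshold_used.
#'
#' @param spots a `spot_set`.
#' @param path output CSV path.
#' @export
write_spots <- function(spots, path) {
  stopifnot(inherits(spots, "spot_set"))
  d <- spots$spots
  d <- cbind(channel = rep(spots$channel_label, nrow(d)), d,
             threshold_used = rep(spots$threshold_used, nrow(d)))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a spot-set CSV written by [write_spots()]
#'
#' @param path CSV path.
#' @return A `spot_set` (shape/origin unknown are set permissively).
#' @export
read_spots <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "id", "z", "y", "x", "volume", "total_intensity",
            "max_intensity")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("spot csv is missing columns: ", paste(miss, collapse = ", "))
  thr <- if ("threshold_used" %in% names(d) && nrow(d))
    d$threshold_used[1] else NA_real_
  structure(list(channel_label = if (nrow(d)) d$channel[1] else "",
                 spots = d[c("id", "z", "y", "x", "volume",
                             "total_intensity", "max_intensity")],
                 threshold_used = thr,
                 origin = c(1L, 1L, 1L), shape = NULL, curve = NULL,
                 config = NULL),
            class = "spot_set")
}

#' Write a threshold curve as CSV
#'
#' Columns threshold, count, smoothed_count, selected (0/1), for plotting
#' the count-versus-threshold curve and the chosen plateau level.
#'
#' @param curve a `threshold_curve`.
#' @param path output CSV path.
#' @export
write_threshold_curve <- function(curve, path) {
  stopifnot(inherits(curve, "threshold_curve"))
  d <- data.frame(threshold = curve$thresholds, count = curve$counts,
                  smoothed_count = moving_average(curve$counts,
                                                  curve$smoothing_window),
                  selected = as.integer(seq_along(curve$thresholds) ==
                                          curve$selected_index))
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
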