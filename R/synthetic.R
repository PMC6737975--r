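#' Synthetic scene parameters
#'
#' Describes a ground-truth dual-channel smFISH scene: diffraction-limited
#' spots rendered as anisotropic 3D Gaussians at subvoxel positions, a
#' fraction of spots shared between the two channels with positional
#' jitter (emulating two probe sets on one transcript), Gaussian camera
#' noise on a uniform background, and ellipsoidal nuclei in a counterstain
#' channel.
#'
#' Defaults emulate a typical organoid acquisition: a 300 x 300-pixel ROI
#' through a ~18 µm z-stack at ~1.5 µm steps (12 planes), spot amplitude
#' ~N(200, 20) over background 20 with noise sd 10 (peak SNR 20), lateral
#' PSF sigma 1.5 voxels and axial 1.0, and a 7-voxel minimum separation so
#' neighboring point-spread functions stay resolvable at plateau
#' thresholds.
#'
#' @param shape `(z, y, x)` stack dimensions.
#' @param n_spots spots per channel.
#' @param coloc_fraction fraction `f` of spots shared between channels;
#'   `round(f * n_spots)` spots of channel B sit at channel-A positions
#'   plus jitter.
#' @param jitter_sd per-axis Gaussian jitter (voxels) of shared spots.
#' @param spot_sigma Gaussian sigma `(z, y, x)` in voxels.
#' @param amplitude_mean,amplitude_sd spot peak amplitude distribution.
#' @param background_level uniform background offset.
#' @param noise_sd Gaussian noise sd (Poisson shot-noise approximation).
#' @param n_nuclei nuclei rendered in the counterstain channel.
#' @param nucleus_radii ellipsoid semi-axes `(z, y, x)` in voxels.
#' @param nucleus_intensity peak counterstain intensity above background.
#' @param min_separation minimum Euclidean distance between spot centers
#'   within one channel (voxels).
#' @param seed integer seed; identical parameters give bit-identical
#'   scenes. `NULL` uses the session RNG stream.
#' @return A `scene_params` list.
#' @export
scene_params <- function(shape = c(12L, 300L, 300L), n_spots = 200L,
                         coloc_fraction = 0.5, jitter_sd = 0.5,
                         spot_sigma = c(1.0, 1.5, 1.5),
                         amplitude_mean = 200, amplitude_sd = 20,
                         background_level = 20, noise_sd = 10,
                         n_nuclei = 25L, nucleus_radii = c(2.5, 9, 9),
                         nucleus_intensity = 120,
                         min_separation = 7, seed = NULL) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must be in [0, 1]")
  if (any(shape < 1L)) stop("shape must be positive on every axis")
  if (jitter_sd < 0 || noise_sd < 0 || amplitude_sd < 0)
    stop("standard deviations must be >= 0")
  structure(list(shape = as.integer(shape), n_spots = as.integer(n_spots),
                 coloc_fraction = coloc_fraction, jitter_sd = jitter_sd,
                 spot_sigma = spot_sigma, amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd,
                 background_level = background_level, noise_sd = noise_sd,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radii = nucleus_radii,
                 nucleus_intensity = nucleus_intensity,
                 min_separation = min_separation, seed = seed),
            class = "scene_params")
}

with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# Rejection-sample n points uniformly in the margin box, each at least
# min_sep (Euclidean, voxel units) from every already-accepted point in
# `existing` and from each other.
sample_positions <- function(n, shape, margin, min_sep, existing = NULL,
                             max_tries = 200L) {
  pts <- if (is.null(existing)) matrix(numeric(), 0, 3) else existing
  out <- matrix(numeric(), 0, 3,
                dimnames = list(NULL, c("z", "y", "x")))
  if (n == 0L) return(out)
  lo <- 1 + margin
  hi <- shape - margin
  if (any(hi < lo)) stop("stack too small for the spot margin")
  for (k in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- lo + runif(3) * (hi - lo)
      if (!nrow(pts) ||
          min(sqrt(colSums((t(pts) - p)^2))) >= min_sep) {
        pts <- rbind(pts, p)
        out <- rbind(out, p)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("spot placement infeasible: density too high for ",
           "min_separation = ", min_sep)
  }
  dimnames(out) <- list(NULL, c("z", "y", "x"))
  out
}

# Add one Gaussian spot (peak `amp`, sigma per axis) at a subvoxel center,
# truncated at 3 sigma, into `vol` (modified copy returned).
render_gaussian <- function(vol, center, amp, sigma) {
  dims <- dim(vol)
  lo <- pmax(1L, ceiling(center - 3 * sigma))
  hi <- pmin(dims, floor(center + 3 * sigma))
  if (any(hi < lo)) return(vol)
  gz <- exp(-0.5 * ((lo[1]:hi[1] - center[1]) / sigma[1])^2)
  gy <- exp(-0.5 * ((lo[2]:hi[2] - center[2]) / sigma[2])^2)
  gx <- exp(-0.5 * ((lo[3]:hi[3] - center[3]) / sigma[3])^2)
  add <- amp * outer(outer(gz, gy), gx)
  vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + add
  vol
}

render_channel <- function(cat, params) {
  vol <- array(0, dim = params$shape)
  for (k in seq_len(nrow(cat)))
    vol <- render_gaussian(vol, c(cat$z[k], cat$y[k], cat$x[k]),
                           cat$amplitude[k], params$spot_sigma)
  vol <- vol + params$background_level +
    rnorm(length(vol), 0, params$noise_sd)
  array(pmax(vol, 0), dim = params$shape)
}

render_nuclei <- function(cat, params) {
  vol <- array(0, dim = params$shape)
  rad <- params$nucleus_radii
  dims <- params$shape
  for (k in seq_len(nrow(cat))) {
    ctr <- c(cat$z[k], cat$y[k], cat$x[k])
    lo <- pmax(1L, ceiling(ctr - rad))
    hi <- pmin(dims, floor(ctr + rad))
    if (any(hi < lo)) next
    fz <- ((lo[1]:hi[1] - ctr[1]) / rad[1])^2
    fy <- ((lo[2]:hi[2] - ctr[2]) / rad[2])^2
    fx <- ((lo[3]:hi[3] - ctr[3]) / rad[3])^2
    r2 <- outer(outer(fz, fy, "+"), fx, "+")
    dome <- params$nucleus_intensity * sqrt(pmax(1 - r2, 0))
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      pmax(vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]], dome)
  }
  vol <- vol + params$background_level +
    rnorm(length(vol), 0, params$noise_sd)
  array(pmax(vol, 0), dim = params$shape)
}

#' Simulate a ground-truth dual-channel smFISH scene
#'
#' Generates channel A, channel B and a counterstain stack together with
#' the exact catalogs used to render them. `round(coloc_fraction *
#' n_spots)` channel-B spots are channel-A positions plus per-axis
#' Gaussian jitter (these carry `shared = TRUE` and a `partner` id); the
#' remainder of each channel is placed independently. Identical parameters
#' (including `seed`) give bit-identical output.
#'
#' @param params a [scene_params()].
#' @return A `synthetic_scene` list: [image_stack()]s `a`, `b`, `nuclei`,
#'   and `truth` with `spots_a`, `spots_b` (id, z, y, x, amplitude,
#'   shared, partner) and `nuclei` (id, z, y, x and semi-axes).
#' @export
simulate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, function() {
    shape <- params$shape
    margin <- 3 * params$spot_sigma
    n <- params$n_spots
    n_shared <- round(params$coloc_fraction * n)

    pos_a <- if (n > 0)
      sample_positions(n, shape, margin, params$min_separation)
    else matrix(numeric(), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
    amp_a <- pmax(rnorm(n, params$amplitude_mean, params$amplitude_sd),
                  params$amplitude_mean / 4)

    shared_b <- pos_a[seq_len(n_shared), , drop = FALSE]
    if (n_shared > 0 && params$jitter_sd > 0)
      shared_b <- shared_b + matrix(rnorm(3 * n_shared, 0, params$jitter_sd),
                                    ncol = 3)
    # keep jittered centers inside the rendering margin
    if (n_shared > 0)
      shared_b <- pmin(pmax(shared_b,
                            rep(1 + margin, each = nrow(shared_b))),
                       rep(shape - margin, each = nrow(shared_b)))
    pos_b <- rbind(shared_b,
                   sample_positions(n - n_shared, shape, margin,
                                    params$min_separation,
                                    existing = shared_b))
    dimnames(pos_b) <- list(NULL, c("z", "y", "x"))
    amp_b <- pmax(rnorm(n, params$amplitude_mean, params$amplitude_sd),
                  params$amplitude_mean / 4)

    spots_a <- data.frame(id = seq_len(n), z = pos_a[, 1], y = pos_a[, 2],
                          x = pos_a[, 3], amplitude = amp_a,
                          shared = seq_len(n) <= n_shared,
                          partner = ifelse(seq_len(n) <= n_shared,
                                           seq_len(n), NA_integer_))
    spots_b <- data.frame(id = seq_len(n), z = pos_b[, 1], y = pos_b[, 2],
                          x = pos_b[, 3], amplitude = amp_b,
                          shared = seq_len(n) <= n_shared,
                          partner = ifelse(seq_len(n) <= n_shared,
                                           seq_len(n), NA_integer_))

    nuc_rad <- params$nucleus_radii
    nuc_pos <- if (params$n_nuclei > 0)
      sample_positions(params$n_nuclei, shape, nuc_rad + 1,
                       2 * max(nuc_rad[2:3]) + 2)
    else matrix(numeric(), 0, 3, dimnames = list(NULL, c("z", "y", "x")))
    nuclei_cat <- data.frame(id = seq_len(params$n_nuclei),
                             z = nuc_pos[, 1], y = nuc_pos[, 2],
                             x = nuc_pos[, 3],
                             radius_z = rep(nuc_rad[1], params$n_nuclei),
                             radius_y = rep(nuc_rad[2], params$n_nuclei),
                             radius_x = rep(nuc_rad[3], params$n_nuclei))

    structure(list(
      a = image_stack(render_channel(spots_a, params), "A"),
      b = image_stack(render_channel(spots_b, params), "B"),
      nuclei = image_stack(render_nuclei(nuclei_cat, params), "nuclei"),
      truth = list(spots_a = spots_a, spots_b = spots_b,
                   nuclei = nuclei_cat),
      params = params),
      class = "synthetic_scene")
  })
}

#' Score detections against ground truth
#'
#' Greedy one-to-one matching (ascending distance, strict cutoff — the
#' same matcher used for channel co-localization) of detected centroids to
#' true positions within `match_radius` voxels. Precision is matched over
#' detected, recall matched over true; RMSE is over matched centroid
#' distances.
#'
#' @param detected a `spot_set`.
#' @param truth ground-truth catalog data.frame with columns z, y, x (one
#'   channel of a `synthetic_scene$truth`).
#' @param match_radius voxels; default 3.
#' @return List: `n_true`, `n_detected`, `n_matched`, `precision` (`NA`
#'   when nothing was detected), `recall`, `rmse` (`NA` without matches).
#' @export
evaluate_detection <- function(detected, truth, match_radius = 3) {
  stopifnot(inherits(detected, "spot_set"))
  det <- as.matrix(detected$spots[c("z", "y", "x")])
  tru <- as.matrix(truth[c("z", "y", "x")])
  m <- match_greedy(point_distances(det, tru), match_radius)
  list(n_true = nrow(tru), n_detected = nrow(det), n_matched = nrow(m),
       precision = if (nrow(det)) nrow(m) / nrow(det) else NA_real_,
       recall = if (nrow(tru)) nrow(m) / nrow(tru) else NA_real_,
       rmse = if (nrow(m)) sqrt(mean(m$distance^2)) else NA_real_)
}

#' Write a simulated scene to disk
#'
#' TIFF stacks (`a.tif`, `b.tif`, `nuclei.tif`) plus ground-truth CSVs
#' (`truth_a.csv`, `truth_b.csv`, `truth_nuclei.csv`).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "synthetic_scene"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$a, file.path(dir, "a.tif"))
  write_stack(scene$b, file.path(dir, "b.tif"))
  write_stack(scene$nuclei, file.path(dir, "nuclei.tif"))
  write.csv(scene$truth$spots_a, file.path(dir, "truth_a.csv"),
            row.names = FALSE)
  write.csv(scene$truth$spots_b, file.path(dir, "truth_b.csv"),
            row.names = FALSE)
  write.csv(scene$truth$nuclei, file.path(dir, "truth_nuclei.csv"),
            row.names = FALSE)
  invisible(dir)
}
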