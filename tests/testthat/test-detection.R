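test_that("binarize is strict: ties go to background", {
  vox <- array(0, c(3, 3, 3))
  vox[2, 2, 2] <- 10
  st <- image_stack(vox)
  expect_false(any(binarize(st, 10)))           # threshold == max -> empty
  expect_identical(sum(binarize(st, 9.5)), 1L)  # just below the lone voxel
  expect_true(all(binarize(st, -1)))            # below min -> all foreground
})

test_that("connectivity semantics: diagonal voxels join under 26, not 6", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26)), 1)
  expect_equal(max(label_components(m, 6)), 2)
  expect_equal(max(label_components(array(FALSE, c(3, 3, 3)), 26)), 0)
})

test_that("labeling agrees with brute-force flood fill on random masks", {
  set.seed(31)
  for (rep in 1:60) {
    m <- array(runif(8^3) < runif(1, 0.1, 0.5), dim = c(8, 8, 8))
    for (conn in c(6L, 26L)) {
      lab <- label_components(m, conn)
      expect_identical(max(lab, 0L), brute_component_count(m, conn))
      # labels partition the foreground exactly
      expect_identical(lab > 0L, m)
    }
  }
})

test_that("volume filter and measurement: symmetric cube, speck removal", {
  vox <- array(0, c(9, 9, 9))
  vox[4:6, 4:6, 4:6] <- 50          # 27-voxel cube
  vox[1, 1, 1] <- 80                # single-voxel speck
  st <- image_stack(vox)
  lab <- label_components(binarize(st, 10), 26)
  spots <- filter_and_measure(lab, st, detection_config())
  expect_equal(nrow(spots$spots), 1)            # speck dropped (min_volume 2)
  expect_equal(spots$spots$volume, 27L)
  expect_equal(unlist(spots$spots[c("z", "y", "x")]), c(z = 5, y = 5, x = 5))
  expect_equal(spots$spots$total_intensity, 27 * 50)
  expect_equal(spots$spots$max_intensity, 50)

  # min_volume = 1 keeps the speck; labels renumbered consecutively
  spots2 <- filter_and_measure(lab, st, detection_config(min_volume = 1))
  expect_equal(nrow(spots2$spots), 2)
  expect_identical(spots2$spots$id, 1:2)
})

test_that("threshold scan: single object gives count 1 across its range", {
  vox <- array(0, c(10, 20, 20))
  vox[4:6, 9:11, 9:11] <- 100
  st <- image_stack(vox)
  curve <- scan_thresholds(st, detection_config())
  inside <- curve$thresholds > 0 & curve$thresholds < 100
  expect_true(all(curve$counts[inside] == 1))
  expect_error(scan_thresholds(image_stack(array(5, c(3, 3, 3)))),
               "constant")
})

test_that("selected threshold sits on the ground-truth plateau", {
  sc <- small_scene(seed = 41, n_spots = 50)
  curve <- scan_thresholds(sc$a)
  thr <- select_threshold(curve)
  # oracle: exhaustive slope minimization on the recorded curve must agree
  sm <- smfish3d:::moving_average(curve$counts, curve$smoothing_window)
  n <- length(sm)
  slope <- abs(c(sm[2] - sm[1],
                 (sm[3:n] - sm[1:(n - 2)]) / 2,
                 sm[n] - sm[n - 1])) /
           c(diff(curve$thresholds)[1],
             rep(diff(curve$thresholds)[1], n - 2),
             diff(curve$thresholds)[1])
  interior <- (ceiling(0.05 * n) + 1):(n - ceiling(0.05 * n))
  cand <- interior[interior >= which.max(sm)]
  expect_equal(attr(thr, "index"), cand[which.min(slope[cand])])
  # plateau membership: the count at the selected level equals true n
  expect_equal(curve$counts[attr(thr, "index")], 50L)
  # two-population scene: threshold separates background (~20) from
  # spot amplitudes (~200)
  expect_gt(as.numeric(thr), 40)
  expect_lt(as.numeric(thr), 160)
})

test_that("all-tied curves resolve to the lowest interior level", {
  curve <- structure(list(thresholds = as.numeric(1:40),
                          counts = rep(7L, 40),
                          selected_index = NA_integer_,
                          smoothing_window = 5L, flat = FALSE),
                     class = "threshold_curve")
  thr <- select_threshold(curve)
  expect_equal(attr(thr, "index"), ceiling(0.05 * 40) + 1L)
  expect_true(attr(thr, "flat"))
  short <- curve; short$thresholds <- 1:5; short$counts <- rep(1L, 5)
  expect_error(select_threshold(short), "10 levels")
})

test_that("detect_spots is deterministic and honors the manual override", {
  sc <- small_scene(seed = 42, n_spots = 30)
  d1 <- detect_spots(sc$a)
  d2 <- detect_spots(sc$a)
  expect_identical(d1$spots, d2$spots)
  expect_identical(d1$threshold_used, d2$threshold_used)

  manual <- detect_spots(sc$a, detection_config(manual_threshold =
                                                  d1$threshold_used))
  expect_identical(manual$spots, d1$spots)
  expect_null(manual$curve)

  # manual path == binarize-at-override path
  byhand <- filter_and_measure(
    label_components(binarize(sc$a, d1$threshold_used), 26),
    sc$a, detection_config())
  expect_identical(byhand$spots[-1], manual$spots[-1])
})

test_that("volume bounds hold and tightening max_volume never adds spots", {
  sc <- small_scene(seed = 43, n_spots = 40)
  base <- detect_spots(sc$a)
  expect_true(all(base$spots$volume >= 2 & base$spots$volume <= 200))
  thr <- base$threshold_used
  prev <- Inf
  for (mx in c(200, 100, 60, 40, 20)) {
    n <- nrow(detect_spots(sc$a, detection_config(
      max_volume = mx, manual_threshold = thr))$spots)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("noise-only scenes yield zero spots", {
  for (s in 1:5) {
    sc <- simulate_scene(scene_params(shape = c(8L, 64L, 64L), n_spots = 0L,
                                      n_nuclei = 0L, seed = s))
    expect_equal(nrow(detect_spots(sc$a)$spots), 0)
  }
})

test_that("spot recovery on a ground-truth scene is essentially perfect", {
  sc <- small_scene(seed = 44, n_spots = 50)
  det <- detect_spots(sc$a)
  ev <- evaluate_detection(det, sc$truth$spots_a)
  expect_equal(ev$n_detected, 50)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  expect_lt(ev$rmse, 0.5)
  # every centroid within half a voxel of its true position
  expect_true(all(smfish3d:::match_greedy(
    smfish3d:::point_distances(
      as.matrix(det$spots[c("z", "y", "x")]),
      as.matrix(sc$truth$spots_a[c("z", "y", "x")])), 3)$distance < 0.5))
})
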