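test_that("pairwise distances match the elementwise definition", {
  expect_equal(pairwise_distances(point_set(c(0, 0, 0)),
                                  point_set(c(0, 3, 4)))[1, 1], 5)
  expect_equal(pairwise_distances(point_set(c(2, 5, 9)),
                                  point_set(c(2, 5, 9)))[1, 1], 0)
  set.seed(51)
  ca <- matrix(runif(15, 0, 10), ncol = 3)
  cb <- matrix(runif(21, 0, 10), ncol = 3)
  expect_equal(pairwise_distances(point_set(ca), point_set(cb)),
               brute_distances(ca, cb), tolerance = 1e-12)
})

test_that("spot sets from different frames refuse to be compared", {
  a <- point_set(c(1, 1, 1))
  b <- point_set(c(1, 1, 1))
  b$origin <- c(1L, 101L, 1L)
  expect_error(pairwise_distances(a, b), "frames")
})

test_that("the 3-voxel cutoff is strict and pairing is one-to-one", {
  near <- match_spots(point_set(c(0, 0, 0)), point_set(c(0, 0, 2)))
  expect_equal(nrow(near$pairs), 1)
  expect_equal(near$pairs$distance, 2)

  boundary <- match_spots(point_set(c(0, 0, 0)), point_set(c(0, 0, 3)))
  expect_equal(nrow(boundary$pairs), 0)      # 3 is not < 3

  # one A, two candidate B: only the nearest pairs, the other stays single
  m <- match_spots(point_set(c(0, 0, 0)),
                   point_set(rbind(c(0, 0, 1), c(0, 0, 2))))
  expect_equal(m$pairs$id_b, 1)
  expect_equal(m$unmatched_b, 2)

  # two A at equal distance from one B: tie resolved to the lower A id
  m2 <- match_spots(point_set(rbind(c(0, 0, 0), c(0, 0, 2))),
                    point_set(c(0, 0, 1)))
  expect_equal(nrow(m2$pairs), 1)
  expect_equal(m2$pairs$id_a, 1)
  expect_equal(length(m2$unmatched_a) + nrow(m2$pairs), m2$n_a)
})

test_that("greedy matching equals independent recomputation on random sets", {
  set.seed(52)
  gap_total <- 0L
  for (rep in 1:200) {
    na <- sample(0:8, 1); nb <- sample(0:8, 1)
    ca <- matrix(runif(3 * na, 0, 6), ncol = 3)
    cb <- matrix(runif(3 * nb, 0, 6), ncol = 3)
    m <- match_spots(point_set(ca), point_set(cb))
    # invariants on every result
    expect_true(!anyDuplicated(m$pairs$id_a) && !anyDuplicated(m$pairs$id_b))
    expect_true(all(m$pairs$distance < 3))
    expect_equal(nrow(m$pairs) + length(m$unmatched_a), m$n_a)
    expect_equal(nrow(m$pairs) + length(m$unmatched_b), m$n_b)
    # exact agreement with the pick-global-minimum greedy oracle
    d <- brute_distances(ca, cb)
    o <- greedy_rematch(d, 3)
    expect_equal(nrow(m$pairs), nrow(o))
    if (nrow(o)) {
      expect_equal(m$pairs$id_a, unname(o[, 1]))
      expect_equal(m$pairs$id_b, unname(o[, 2]))
      expect_equal(m$pairs$distance, unname(o[, 3]), tolerance = 1e-12)
    }
    gap_total <- gap_total + (max_matching_size(d, 3) - nrow(m$pairs))
  }
  # greedy may fall short of the optimum but never exceeds it
  expect_gte(gap_total, 0)
})

test_that("matching is symmetric under swapping the channels", {
  set.seed(53)
  for (rep in 1:50) {
    ca <- matrix(runif(3 * sample(1:8, 1), 0, 6), ncol = 3)
    cb <- matrix(runif(3 * sample(1:8, 1), 0, 6), ncol = 3)
    ab <- match_spots(point_set(ca), point_set(cb))
    ba <- match_spots(point_set(cb), point_set(ca))
    expect_equal(ab$pairs[order(ab$pairs$id_a), c("id_a", "id_b")],
                 setNames(ba$pairs[order(ba$pairs$id_b), c("id_b", "id_a")],
                          c("id_a", "id_b")),
                 ignore_attr = TRUE)
    expect_equal(ab$ratio_a_in_b, ba$ratio_b_in_a)
  }
})

test_that("co-localization ratios are pair count over reference size", {
  set.seed(54)
  ca <- cbind(5, seq(10, 100, 10), 50)           # 10 A spots in a line
  cb <- cbind(5, seq(10, 80, 10) + 0.4, 50)      # 8 B spots, all matchable
  m <- match_spots(point_set(ca), point_set(cb))
  expect_equal(nrow(m$pairs), 8)
  expect_equal(coloc_ratio(m, "a_in_b"), 0.8)
  expect_equal(coloc_ratio(m, "b_in_a"), 1.0)

  empty <- match_spots(point_set(matrix(numeric(), 0, 3)),
                       point_set(c(1, 1, 1)))
  expect_true(is.na(empty$ratio_a_in_b))
  expect_error(coloc_ratio(empty, "a_in_b"), "no spots")
})

test_that("perfectly and never co-localized scenes recover their ratios", {
  full <- small_scene(seed = 55, n_spots = 40, coloc_fraction = 1)
  ma <- match_spots(detect_spots(full$a), detect_spots(full$b))
  expect_gte(coloc_ratio(ma, "a_in_b"), 0.95)
  expect_gte(coloc_ratio(ma, "b_in_a"), 0.95)

  # 16 spots in 10x128x128 is the ~1e-4/voxel chance-pairing regime:
  # at most a couple of accidental pairs are plausible
  none <- small_scene(seed = 56, n_spots = 16, coloc_fraction = 0)
  mb <- match_spots(detect_spots(none$a), detect_spots(none$b))
  expect_lte(nrow(mb$pairs), 2)
})

test_that("match results serialize to CSV + JSON with consistent counts", {
  sc <- small_scene(seed = 57, n_spots = 30)
  m <- match_spots(detect_spots(sc$a), detect_spots(sc$b))
  prefix <- file.path(withr::local_tempdir(), "m")
  write_match_result(m, prefix)
  pairs <- read.csv(paste0(prefix, "_pairs.csv"))
  un <- read.csv(paste0(prefix, "_unmatched.csv"))
  js <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(nrow(pairs), js$n_pairs)
  expect_equal(nrow(pairs) + sum(un$channel == "a"), js$n_a)
  expect_equal(nrow(pairs) + sum(un$channel == "b"), js$n_b)
  expect_equal(js$ratio_a_in_b, nrow(pairs) / js$n_a)
})
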