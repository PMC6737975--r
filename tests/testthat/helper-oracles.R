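# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Component count by breadth-first flood fill over an explicit queue.
brute_component_count <- function(mask, connectivity) {
  dims <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6)
    offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  seen <- array(FALSE, dims)
  idx <- which(mask)
  coords <- arrayInd(idx, dims)
  n <- 0L
  for (k in seq_along(idx)) {
    if (seen[idx[k]]) next
    n <- n + 1L
    queue <- list(coords[k, ])
    seen[idx[k]] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1L) || any(q > dims)) next
        if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
          seen[q[1], q[2], q[3]] <- TRUE
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  n
}

# Greedy one-to-one matching recomputed by repeatedly taking the global
# minimum of the (masked) distance matrix; ties by lowest row, then column.
greedy_rematch <- function(dmat, d_max) {
  out <- matrix(numeric(), 0, 3, dimnames = list(NULL, c("i", "j", "d")))
  if (!length(dmat)) return(out)
  d <- dmat
  repeat {
    m <- suppressWarnings(min(d))
    if (!is.finite(m) || m >= d_max) break
    hits <- which(d == m, arr.ind = TRUE)
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    out <- rbind(out, c(i, j, m))
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  out
}

# Maximum-cardinality one-to-one matching size under the strict cutoff.
max_matching_size <- function(dmat, d_max) {
  edges <- which(dmat < d_max, arr.ind = TRUE)
  if (!nrow(edges)) return(0L)
  na <- nrow(dmat); nb <- ncol(dmat)
  g <- igraph::make_bipartite_graph(
    c(rep(TRUE, na), rep(FALSE, nb)),
    as.vector(t(cbind(edges[, 1], na + edges[, 2]))))
  igraph::max_bipartite_match(g)$matching_size
}

# Brute-force distance matrix, entry by entry.
brute_distances <- function(ca, cb) {
  d <- matrix(0, nrow(ca), nrow(cb))
  for (i in seq_len(nrow(ca)))
    for (j in seq_len(nrow(cb)))
      d[i, j] <- sqrt(sum((ca[i, ] - cb[j, ])^2))
  d
}

# A spot_set built directly from a centroid matrix, for matcher tests.
point_set <- function(centroids, channel = "pts") {
  centroids <- matrix(centroids, ncol = 3,
                      dimnames = list(NULL, c("z", "y", "x")))
  n <- nrow(centroids)
  structure(list(channel_label = channel,
                 spots = data.frame(id = seq_len(n), z = centroids[, 1],
                                    y = centroids[, 2], x = centroids[, 3],
                                    volume = rep(1L, n),
                                    total_intensity = rep(1, n),
                                    max_intensity = rep(1, n)),
                 threshold_used = NA_real_, origin = c(1L, 1L, 1L),
                 shape = NULL, curve = NULL, config = NULL),
            class = "spot_set")
}

# Small scene used throughout the unit tests (fast to simulate and detect).
small_scene <- function(seed, n_spots = 50, coloc_fraction = 0.5, ...) {
  simulate_scene(scene_params(shape = c(10L, 128L, 128L),
                              n_spots = n_spots,
                              coloc_fraction = coloc_fraction,
                              n_nuclei = 6L, seed = seed, ...))
}

mode_count_of <- function(spot_set) qc_summary(spot_set)$mode_count
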