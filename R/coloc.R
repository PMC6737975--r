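#' Pairwise centroid distances between two spot sets
#'
#' Euclidean distance in voxel units, with the z axis counted as one unit
#' per plane (per z-index, not micrometres). Both sets must live in the
#' same coordinate frame (same source origin).
#'
#' @param a,b `spot_set` objects sharing a frame.
#' @param scale optional per-axis `(z, y, x)` scale factors (e.g. µm per
#'   voxel) applied before the distance; default `c(1, 1, 1)` — distances
#'   in voxels, as the 3-voxel co-localization rule expects.
#' @return Matrix of distances, `nrow(a) x nrow(b)` spots.
#' @export
pairwise_distances <- function(a, b, scale = c(1, 1, 1)) {
  stopifnot(inherits(a, "spot_set"), inherits(b, "spot_set"))
  if (!is.null(a$origin) && !is.null(b$origin) &&
      !identical(as.integer(a$origin), as.integer(b$origin)))
    stop("spot sets come from different frames (origins ",
         paste(a$origin, collapse = ","), " vs ",
         paste(b$origin, collapse = ","), ")")
  point_distances(as.matrix(a$spots[c("z", "y", "x")]),
                  as.matrix(b$spots[c("z", "y", "x")]), scale)
}

point_distances <- function(ca, cb, scale = c(1, 1, 1)) {
  if (!nrow(ca) || !nrow(cb))
    return(matrix(numeric(), nrow = nrow(ca), ncol = nrow(cb)))
  ca <- sweep(ca, 2, scale, "*")
  cb <- sweep(cb, 2, scale, "*")
  d2 <- outer(ca[, 1], cb[, 1], "-")^2 +
    outer(ca[, 2], cb[, 2], "-")^2 +
    outer(ca[, 3], cb[, 3], "-")^2
  sqrt(d2)
}

# Greedy ascending-distance one-to-one matching on a distance matrix.
# Candidates with d < d_max are sorted by (distance, row, col) and accepted
# unless either member is already matched. Returns row/col index pairs.
match_greedy <- function(dmat, d_max) {
  cand <- which(dmat < d_max, arr.ind = TRUE)
  if (!nrow(cand))
    return(data.frame(i = integer(), j = integer(), distance = numeric()))
  d <- dmat[cand]
  o <- order(d, cand[, 1], cand[, 2])
  cand <- cand[o, , drop = FALSE]; d <- d[o]
  used_i <- logical(nrow(dmat)); used_j <- logical(ncol(dmat))
  keep <- logical(length(d))
  for (k in seq_along(d)) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_i[i] && !used_j[j]) {
      keep[k] <- TRUE
      used_i[i] <- TRUE; used_j[j] <- TRUE
    }
  }
  data.frame(i = cand[keep, 1], j = cand[keep, 2], distance = d[keep])
}

#' Match spots across two channels one-to-one
#'
#' Spots co-localize when the Euclidean distance between their centroids is
#' strictly below `d_max` voxels. To avoid overestimating co-localization,
#' each spot pairs with at most one spot in the other channel: candidate
#' pairs below the cutoff are taken in ascending distance order (ties by
#' lower id in `a`, then in `b`), skipping any pair whose member is already
#' matched. The pair set is symmetric under swapping the arguments.
#'
#' @param a,b `spot_set` objects in one coordinate frame.
#' @param d_max distance cutoff in voxels (strict `<`); default 3.
#' @param scale optional per-axis scale, see [pairwise_distances()].
#' @return A `match_result`: `pairs` (id_a, id_b, distance),
#'   `unmatched_a`, `unmatched_b`, `d_max`, counts `n_a`/`n_b`, and the
#'   bidirectional fractions `ratio_a_in_b` = pairs/|A|,
#'   `ratio_b_in_a` = pairs/|B| (`NA` for an empty reference channel).
#' @export
match_spots <- function(a, b, d_max = 3, scale = c(1, 1, 1)) {
  dmat <- pairwise_distances(a, b, scale)
  m <- match_greedy(dmat, d_max)
  ida <- a$spots$id; idb <- b$spots$id
  pairs <- data.frame(id_a = ida[m$i], id_b = idb[m$j], distance = m$distance)
  res <- structure(list(
    pairs = pairs,
    unmatched_a = setdiff(ida, pairs$id_a),
    unmatched_b = setdiff(idb, pairs$id_b),
    d_max = d_max,
    n_a = length(ida), n_b = length(idb),
    channel_a = a$channel_label, channel_b = b$channel_label,
    ratio_a_in_b = if (length(ida)) nrow(pairs) / length(ida) else NA_real_,
    ratio_b_in_a = if (length(idb)) nrow(pairs) / length(idb) else NA_real_),
    class = "match_result")
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> %d pairs (d < %g voxels); A '%s': %d spots, B '%s': %d spots\n",
    nrow(x$pairs), x$d_max, x$channel_a, x$n_a, x$channel_b, x$n_b))
  cat(sprintf("  A-in-B: %s   B-in-A: %s\n",
              format(x$ratio_a_in_b, digits = 3),
              format(x$ratio_b_in_a, digits = 3)))
  invisible(x)
}

#' Co-localization ratio in one direction
#'
#' Fraction of the reference channel's spots that were paired: direction
#' `"a_in_b"` divides the pair count by |A|, `"b_in_a"` by |B|. Both
#' directions are reported because probe-set specificity is asymmetric in
#' principle (5' vs 3' and 3' vs 5').
#'
#' @param result a `match_result`.
#' @param direction `"a_in_b"` or `"b_in_a"`.
#' @return Fraction in `[0, 1]`.
#' @export
coloc_ratio <- function(result, direction = c("a_in_b", "b_in_a")) {
  stopifnot(inherits(result, "match_result"))
  direction <- match.arg(direction)
  n <- if (direction == "a_in_b") result$n_a else result$n_b
  if (n == 0L)
    stop("co-localization ratio undefined: reference channel ",
         if (direction == "a_in_b") "A" else "B", " has no spots")
  nrow(result$pairs) / n
}

#' Write a match result as CSVs plus a JSON summary
#'
#' `<prefix>_pairs.csv` (id_a, id_b, distance), `<prefix>_unmatched.csv`
#' (channel, id), `<prefix>_summary.json` (counts, both ratios, d_max).
#'
#' @param result a `match_result`.
#' @param prefix output path prefix.
#' @export
write_match_result <- function(result, prefix) {
  stopifnot(inherits(result, "match_result"))
  write.csv(result$pairs, paste0(prefix, "_pairs.csv"), row.names = FALSE)
  un <- rbind(
    data.frame(channel = rep("a", length(result$unmatched_a)),
               id = result$unmatched_a),
    data.frame(channel = rep("b", length(result$unmatched_b)),
               id = result$unmatched_b))
  write.csv(un, paste0(prefix, "_unmatched.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(n_a = result$n_a, n_b = result$n_b, n_pairs = nrow(result$pairs),
         d_max = result$d_max, ratio_a_in_b = result$ratio_a_in_b,
         ratio_b_in_a = result$ratio_b_in_a,
         channel_a = result$channel_a, channel_b = result$channel_b),
    paste0(prefix, "_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
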