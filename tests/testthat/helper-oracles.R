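# Independent oracles, deliberately naive: exhaustive image enumeration and
# O(N^2) graph construction, used to validate the engine's cell-list and
# clustering paths.

# shortest periodic image by enumerating all 27 neighbour images of the
# (possibly tilted) cell
oracle_min_image <- function(d, box, tilt = 0) {
  a <- c(box[1], 0, 0)
  b <- c(0, box[2], 0)
  cc <- c(tilt, 0, box[3])
  best <- d
  bestn <- sum(d^2)
  for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
    cand <- d - n1 * a - n2 * b - n3 * cc
    if (sum(cand^2) < bestn) {
      best <- cand
      bestn <- sum(cand^2)
    }
  }
  best
}

# all-pairs minimum-image distance matrix: minimum over all 27 images,
# computed one image at a time (vectorised, still exhaustive)
oracle_dist <- function(pos, box, tilt = 0) {
  n <- nrow(pos)
  a <- c(box[1], 0, 0)
  b <- c(0, box[2], 0)
  cc <- c(tilt, 0, box[3])
  best <- matrix(Inf, n, n)
  for (n1 in -1:1) for (n2 in -1:1) for (n3 in -1:1) {
    shift <- n1 * a + n2 * b + n3 * cc
    d2 <- outer(pos[, 1], pos[, 1] - shift[1], `-`)^2 +
      outer(pos[, 2], pos[, 2] - shift[2], `-`)^2 +
      outer(pos[, 3], pos[, 3] - shift[3], `-`)^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# single-linkage components through igraph over the exhaustive distance matrix
oracle_components <- function(pos, box, cutoff, tilt = 0) {
  adj <- oracle_dist(pos, box, tilt) < cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$membership
}

# two labelings describe the same partition?
same_partition <- function(a, b) {
  identical(as.integer(match(a, unique(a))), as.integer(match(b, unique(b))))
}
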